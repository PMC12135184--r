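# ---------------------------------------------------------------------------
# Observables on simulated ensembles: packing ratio, interaction patterns,
# stems, fan plots, tail interactions.
# ---------------------------------------------------------------------------

.core_positions <- function(ensemble, frame) {
  ensemble$core_frames[[frame]][, 1:3, drop = FALSE]
}

.core_rotation <- function(ensemble, frame, core) {
  matrix(ensemble$core_frames[[frame]][core, 4:12], 3, 3, byrow = TRUE)
}

#' Packing ratio of a simulated fiber
#'
#' Per frame: the fiber axis is the first principal component of the core
#' centroids, the fiber length is the extent of centroid projections on
#' that axis, and the ratio is `n_cores * 11 / length` (nucleosomes per
#' 11 nm of fiber). Frames whose axis explains less than `min_var_frac` of
#' the centroid variance are flagged as strongly bent; degenerate frames
#' (coincident centroids) are skipped and counted.
#'
#' @param ensembles an `ensemble` or list of ensembles (replicates).
#' @param min_var_frac axis-variance flag threshold.
#' @return list: `mean`, `sd` (across frames pooled over replicates),
#'   `per_frame` data.frame (ratio, variance fraction, flag), `n_skipped`.
#' @export
packing_ratio <- function(ensembles, min_var_frac = 0.6) {
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  rows <- list(); skipped <- 0L
  for (ri in seq_along(ensembles)) {
    ens <- ensembles[[ri]]
    if (ens$template$n_cores < 3)
      stop("packing ratio needs >= 3 cores")
    for (fi in seq_along(ens$frames)) {
      pos <- .core_positions(ens, fi)
      cv <- stats::cov(pos)
      if (sum(diag(cv)) < 1e-9) { skipped <- skipped + 1L; next }
      eg <- eigen(cv, symmetric = TRUE)
      axis <- eg$vectors[, 1]
      proj <- pos %*% axis
      len <- max(proj) - min(proj)
      if (len < 1e-9) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1]] <- data.frame(
        replicate = ri, frame = fi,
        ratio = nrow(pos) * 11 / len,
        var_frac = eg$values[1] / sum(eg$values))
    }
  }
  if (!length(rows)) stop("no usable frames for the packing ratio")
  pf <- do.call(rbind, rows)
  pf$strongly_bent <- pf$var_frac < min_var_frac
  list(mean = mean(pf$ratio), sd = sd(pf$ratio),
       per_frame = pf, n_skipped = skipped)
}

#' Internucleosome interaction pattern of an ensemble
#'
#' Per frame, all core pairs with centroid distance below `contact_nm` are
#' counted into |i-j| bins (the full pairwise matrix, not only nearest
#' neighbors). Frequencies are normalized per nucleosome per frame
#' (pair count x 2 / n_cores, i.e. the mean number of separation-k contact
#' partners per nucleosome).
#'
#' @param ensembles an `ensemble` or list of replicates.
#' @param contact_nm contact threshold (nm).
#' @return list: `frequency` (named vector over k = 1..n-1), `matrix`
#'   (mean contact probability per (i, j)), `n_frames`.
#' @export
interaction_pattern <- function(ensembles, contact_nm = 11) {
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  stopifnot(length(ensembles) > 0, length(ensembles[[1]]$frames) > 0)
  nc <- ensembles[[1]]$template$n_cores
  kcount <- numeric(nc - 1)
  cmat <- matrix(0, nc, nc)
  nframes <- 0L
  for (ens in ensembles) for (fi in seq_along(ens$frames)) {
    pos <- .core_positions(ens, fi)
    dm <- as.matrix(stats::dist(pos))
    hit <- dm < contact_nm & upper.tri(dm)
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx)) {
      ks <- abs(idx[, 1] - idx[, 2])
      for (k in ks) kcount[k] <- kcount[k] + 1
      cmat[idx] <- cmat[idx] + 1
    }
    nframes <- nframes + 1L
  }
  freq <- 2 * kcount / (nc * nframes)
  names(freq) <- as.character(seq_len(nc - 1))
  cmat <- (cmat + t(cmat)) / nframes
  list(frequency = freq, matrix = cmat, n_frames = nframes)
}

#' Linker-DNA stem formation index
#'
#' For each eligible core (both flanking linkers with >= 3 beads, i.e.
#' > 26 bp) the entry- and exit-linker bead positions are transformed into
#' the core body frame, averaged over the trajectory, and bead j of the
#' entry linker is paired with bead j of the exit linker counting outward
#' from the core. The stem index is the fraction of pairs whose
#' mean-position distance is below `threshold_nm` (default 2.5 nm).
#'
#' @param ensemble a single-replicate `ensemble`.
#' @param threshold_nm stem distance criterion (nm).
#' @return data.frame per core: eligibility, stem_index (NA when
#'   ineligible), n_pairs, and the per-pair mean distances as a list
#'   column.
#' @export
stem_index <- function(ensemble, threshold_nm = 2.5) {
  stopifnot(inherits(ensemble, "ensemble"))
  nc <- ensemble$template$n_cores
  beads <- ensemble$template$linker_beads
  sites <- ensemble$sites
  rows <- list()
  for (core in seq_len(nc)) {
    exit_l <- core       # linker leaving core i (if any)
    entry_l <- core - 1  # linker entering core i
    n_exit <- if (exit_l <= nc - 1) beads[exit_l] else 0L
    n_entry <- if (entry_l >= 1) beads[entry_l] else 0L
    eligible <- n_exit >= 3 && n_entry >= 3
    if (!eligible) {
      rows[[core]] <- data.frame(core = core, eligible = FALSE,
                                 stem_index = NA_real_, n_pairs = 0L)
      rows[[core]]$pair_distances <- list(numeric(0))
      next
    }
    # exit linker beads counted from the core outward = rank order;
    # entry linker beads outward from core i = reversed rank order
    exit_rows <- which(sites$type == "linker" & sites$linker == exit_l)
    entry_rows <- rev(which(sites$type == "linker" & sites$linker == entry_l))
    npair <- min(length(exit_rows), length(entry_rows))
    me <- matrix(0, npair, 3); mn <- matrix(0, npair, 3)
    nf <- length(ensemble$frames)
    for (fi in seq_len(nf)) {
      fr <- ensemble$frames[[fi]]
      R <- .core_rotation(ensemble, fi, core)
      p0 <- ensemble$core_frames[[fi]][core, 1:3]
      # body-frame coordinates (average in the core frame so rigid-body
      # diffusion does not smear the stem)
      me <- me + t(t(fr[exit_rows[seq_len(npair)], , drop = FALSE]) - p0) %*% R / nf
      mn <- mn + t(t(fr[entry_rows[seq_len(npair)], , drop = FALSE]) - p0) %*% R / nf
    }
    dd <- sqrt(rowSums((me - mn)^2))
    rows[[core]] <- data.frame(core = core, eligible = TRUE,
                               stem_index = mean(dd < threshold_nm),
                               n_pairs = npair)
    rows[[core]]$pair_distances <- list(dd)
  }
  do.call(rbind, rows)
}

#' Fan distribution of linker DNA around a core
#'
#' Transforms every linker bead position of the core's entry and exit
#' linkers into the core body frame (x toward the dyad, z along the
#' superhelical axis), projects onto the nucleosome plane (x, y), and
#' returns the cumulative 2D histogram over a single trajectory together
#' with the trajectory-mean position of each bead index.
#'
#' @param ensemble a single-replicate `ensemble`.
#' @param core core index.
#' @param breaks histogram breaks (nm) for both plane axes.
#' @return list: `histogram` (2D counts), `bead_means` (data.frame with
#'   linker side, bead rank and mean body-frame position), `breaks`.
#' @export
fan_distribution <- function(ensemble, core,
                             breaks = seq(-20, 20, 1)) {
  stopifnot(inherits(ensemble, "ensemble"))
  sites <- ensemble$sites
  nc <- ensemble$template$n_cores
  sel <- list()
  if (core <= nc - 1)
    sel$exit <- which(sites$type == "linker" & sites$linker == core)
  if (core >= 2)
    sel$entry <- which(sites$type == "linker" & sites$linker == core - 1)
  h <- matrix(0, length(breaks) - 1, length(breaks) - 1)
  acc <- list()
  nf <- length(ensemble$frames)
  for (fi in seq_len(nf)) {
    fr <- ensemble$frames[[fi]]
    R <- .core_rotation(ensemble, fi, core)
    p0 <- ensemble$core_frames[[fi]][core, 1:3]
    for (side in names(sel)) {
      body <- t(t(fr[sel[[side]], , drop = FALSE]) - p0) %*% R
      acc[[side]] <- if (is.null(acc[[side]])) body / nf
        else acc[[side]] + body / nf
      bx <- cut(pmin(pmax(body[, 1], min(breaks)), max(breaks) - 1e-9),
                breaks, labels = FALSE)
      by <- cut(pmin(pmax(body[, 2], min(breaks)), max(breaks) - 1e-9),
                breaks, labels = FALSE)
      for (i in seq_along(bx)) h[bx[i], by[i]] <- h[bx[i], by[i]] + 1
    }
  }
  bm <- do.call(rbind, lapply(names(acc), function(side)
    data.frame(side = side, bead = seq_len(nrow(acc[[side]])),
               x = acc[[side]][, 1], y = acc[[side]][, 2],
               z = acc[[side]][, 3], stringsAsFactors = FALSE)))
  list(histogram = h, bead_means = bm, breaks = breaks)
}

#' Histone-tail interaction fractions
#'
#' Per frame, each tail bead is assigned to the category of its nearest
#' non-parent partner within `cutoff_nm`: linker DNA, non-parental core
#' (surface pseudo-charges), another tail, linker histone, or free when
#' nothing is within the cutoff. Fractions are averaged over frames and
#' sum to 1.
#'
#' @param ensembles an `ensemble` or list of replicates.
#' @param cutoff_nm partner cutoff (nm), default 2.0.
#' @return named fractions over categories
#'   `c("tail_dna", "tail_core", "tail_tail", "tail_lh", "free")`.
#' @export
tail_interaction_fractions <- function(ensembles, cutoff_nm = 2.0) {
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  sites <- ensembles[[1]]$sites
  tails <- which(sites$type == "tail")
  if (!length(tails)) stop("template has no tail beads")
  partners <- which(sites$type %in% c("linker", "core_charge", "tail", "lh"))
  pcat <- c(linker = "tail_dna", core_charge = "tail_core",
            tail = "tail_tail", lh = "tail_lh")[sites$type[partners]]
  pcore <- sites$core[partners]
  cats <- c("tail_dna", "tail_core", "tail_tail", "tail_lh", "free")
  tot <- stats::setNames(numeric(5), cats)
  nfr <- 0L
  for (ens in ensembles) for (fi in seq_along(ens$frames)) {
    fr <- ens$frames[[fi]]
    counts <- stats::setNames(numeric(5), cats)
    for (t in tails) {
      # exclude self, same-chain tail beads, and the parent core's rigid
      # sites (matching the energy model's exclusions); other-chain tails
      # of the same core are legitimate partners
      ok <- partners != t &
        !(pcore == sites$core[t] & pcat != "tail_tail") &
        !(pcat == "tail_tail" & pcore == sites$core[t] &
            sites$tail_chain[partners] == sites$tail_chain[t])
      dd <- sqrt(colSums((t(fr[partners[ok], , drop = FALSE]) - fr[t, ])^2))
      j <- which.min(dd)
      cat_t <- if (length(j) && dd[j] < cutoff_nm) pcat[ok][j] else "free"
      counts[cat_t] <- counts[cat_t] + 1
    }
    tot <- tot + counts / length(tails)
    nfr <- nfr + 1L
  }
  tot / nfr
}
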