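# ---------------------------------------------------------------------------
# Contact-capture (EMANIC-style) classification: every nucleosome is
# assigned exactly one category from its single nearest neighbor.
#   i+/-k  nearest neighbor k positions away in the same array (k capped at
#          4, larger separations pooled into "i+/->4")
#   trans  nearest neighbor in another array, confirmed unconnected
#   none   nearest neighbor at or beyond the contact threshold
#   unresolved  inter-array candidate that fails trans confirmation
# ---------------------------------------------------------------------------

.contact_levels <- c("i+/-1", "i+/-2", "i+/-3", "i+/-4", "i+/->4",
                     "trans", "unresolved", "none")

.spectrum_from_categories <- function(categories, n_total = length(categories)) {
  counts <- table(factor(categories, levels = .contact_levels))
  structure(list(fractions = as.numeric(counts) / n_total,
                 counts = as.integer(counts),
                 categories = .contact_levels,
                 n = n_total, sd = NULL),
            class = "contact_spectrum")
}

#' @export
print.contact_spectrum <- function(x, ...) {
  cat("contact_spectrum (fraction of total nucleosomes, n =", x$n, ")\n")
  print(round(stats::setNames(x$fractions, x$categories), 4))
  invisible(x)
}

#' Classify nearest-neighbor nucleosome contacts
#'
#' A contact exists when the nearest-neighbor distance N is below
#' `contact_nm` (default 11 nm, double nucleosome disk radii). Same-array
#' contacts are binned by chain separation `k = |index difference|`.
#' Inter-array candidates are confirmed as trans only when the two arrays
#' share no resolved linker connection (distinct arrays never do) and all
#' terminal-terminal distances between the two arrays exceed `trans_nm`
#' (default 28 nm, beyond plausible unresolved connectivity); otherwise
#' the candidate is surfaced as `unresolved`.
#'
#' @param scene a `scene`.
#' @param contact_nm contact threshold (nm).
#' @param trans_nm trans-confirmation terminal distance (nm).
#' @return list with `per_nucleosome` (identity, N, category) and
#'   `spectrum` (a `contact_spectrum`).
#' @export
classify_contacts <- function(scene, contact_nm = 11, trans_nm = 28) {
  geo <- compute_geometry(scene)
  poses <- scene$poses
  pos <- as.matrix(poses[, c("x", "y", "z")])

  terminals <- lapply(split(seq_len(nrow(poses)), poses$array_id), function(r) {
    r[c(which.min(poses$nuc_index[r]), which.max(poses$nuc_index[r]))]
  })

  cat_v <- character(nrow(geo))
  for (i in seq_len(nrow(geo))) {
    if (geo$N[i] >= contact_nm) { cat_v[i] <- "none"; next }
    if (geo$nearest_array[i] == geo$array_id[i]) {
      k <- abs(geo$nearest_index[i] - geo$nuc_index[i])
      cat_v[i] <- if (k > 4) "i+/->4" else sprintf("i+/-%d", k)
    } else {
      ta <- terminals[[geo$array_id[i]]]
      tb <- terminals[[geo$nearest_array[i]]]
      dd <- outer(ta, tb, Vectorize(function(u, v)
        sqrt(sum((pos[u, ] - pos[v, ])^2))))
      cat_v[i] <- if (all(dd > trans_nm)) "trans" else "unresolved"
    }
  }
  list(per_nucleosome = data.frame(array_id = geo$array_id,
                                   nuc_index = geo$nuc_index,
                                   N = geo$N, category = cat_v,
                                   stringsAsFactors = FALSE),
       spectrum = .spectrum_from_categories(cat_v))
}

#' Fold change between crosslinked and control contact spectra
#'
#' Ratio of category fractions, crosslinked over control. When a control
#' count is zero, a documented pseudo-fraction of half of 1/n (control) is
#' used; categories absent in both are reported as NA.
#'
#' @param crosslinked,control `contact_spectrum` objects.
#' @return data.frame: category, control and crosslinked fractions,
#'   fold_change.
#' @export
fold_change <- function(crosslinked, control) {
  stopifnot(inherits(crosslinked, "contact_spectrum"),
            inherits(control, "contact_spectrum"))
  if (control$n == 0) stop("control spectrum has n = 0")
  if (!identical(control$categories, crosslinked$categories))
    stop("spectra have incompatible category sets")
  fc <- numeric(length(control$categories))
  for (i in seq_along(fc)) {
    a <- crosslinked$fractions[i]; b <- control$fractions[i]
    fc[i] <- if (a == 0 && b == 0) NA_real_
      else a / (if (b == 0) 0.5 / control$n else b)
  }
  data.frame(category = control$categories,
             control = control$fractions,
             crosslinked = crosslinked$fractions,
             fold_change = fc, stringsAsFactors = FALSE)
}

#' Contact spectrum of a simulated ensemble
#'
#' Applies the experimental nearest-neighbor classification to the core
#' centroids of every sampled configuration and averages the category
#' fractions over frames (SD across frames reported).
#'
#' @param ensemble an `ensemble` from [run_mc()].
#' @param contact_nm contact threshold (nm).
#' @return a `contact_spectrum` with across-frame SDs.
#' @export
spectrum_from_ensemble <- function(ensemble, contact_nm = 11) {
  stopifnot(inherits(ensemble, "ensemble"))
  frames <- ensemble$frames
  if (!length(frames)) stop("empty ensemble")
  core_rows <- which(ensemble$sites$type == "core_center")
  per_frame <- vapply(frames, function(fr) {
    pos <- fr[core_rows, , drop = FALSE]
    n <- nrow(pos)
    dm <- as.matrix(stats::dist(pos)); diag(dm) <- Inf
    nearest <- apply(dm, 1, which.min)
    Nv <- dm[cbind(seq_len(n), nearest)]
    k <- abs(seq_len(n) - nearest)
    cat_v <- ifelse(Nv >= contact_nm, "none",
                    ifelse(k > 4, "i+/->4", sprintf("i+/-%d", k)))
    s <- .spectrum_from_categories(cat_v)
    s$fractions
  }, numeric(length(.contact_levels)))
  sp <- .spectrum_from_categories(character(0), n_total = 1)
  sp$fractions <- rowMeans(per_frame)
  sp$sd <- apply(per_frame, 1, sd)
  sp$counts <- NULL
  sp$n <- length(core_rows) * length(frames)
  sp
}
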