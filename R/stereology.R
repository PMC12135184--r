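# ---------------------------------------------------------------------------
# Stereology: per-nucleosome geometric descriptors of a scene.
#   D    center-to-center distance to the next nucleosome in the chain (nm)
#   N    center-to-center distance to the nearest nucleosome in 3D (nm),
#        searched over the whole scene (all arrays)
#   alpha  angle at nucleosome i between the axes to i-1 and i+1 (deg, 0-180)
#   beta   angle between consecutive nucleosome planes, folded to 0-90
#   para   angle between the planes of spatially nearest nucleosomes, 0-90
# ---------------------------------------------------------------------------

# unsigned angle between plane normals folded to [0, 90] via |cos|
.plane_angle <- function(n1, n2) {
  acos(pmin(1, abs(sum(n1 * n2)))) * 180 / pi
}

#' Compute stereological descriptors for every nucleosome in a scene
#'
#' @param scene a `scene` (see [build_scene()]) or any list with a `poses`
#'   data.frame obeying the pose-table schema.
#' @return data.frame with one row per nucleosome: identity columns, `D`,
#'   `N`, `nearest_array`, `nearest_index`, `alpha`, `beta`, `para`, plus
#'   the pass-through flags. Descriptors undefined at chain ends are `NA`.
#'   Nearest-neighbor ties are broken by lowest (array_id, nuc_index).
#' @export
compute_geometry <- function(scene) {
  poses <- scene$poses
  .validate_pose_table(poses)
  pos <- as.matrix(poses[, c("x", "y", "z")])
  nrm <- as.matrix(poses[, c("nx", "ny", "nz")])
  n <- nrow(pos)
  if (n < 2) stop("scene must contain at least 2 nucleosomes")

  # all-pairs distances (scenes are small: hundreds to a few thousand poses)
  dm <- as.matrix(stats::dist(pos))
  diag(dm) <- Inf
  # deterministic tie-break: order rows by (array_id, nuc_index), pick the
  # first minimizer in that order
  ord <- order(poses$array_id, poses$nuc_index)
  nearest <- integer(n)
  Nval <- numeric(n)
  for (i in seq_len(n)) {
    di <- dm[i, ord]
    j <- which.min(di)                   # first minimum in canonical order
    nearest[i] <- ord[j]
    Nval[i] <- di[j]
  }

  D <- alpha <- beta <- rep(NA_real_, n)
  para <- numeric(n)
  for (i in seq_len(n)) {
    aid <- poses$array_id[i]
    same <- poses$array_id == aid
    nxt <- which(same & poses$nuc_index == poses$nuc_index[i] + 1)
    prv <- which(same & poses$nuc_index == poses$nuc_index[i] - 1)
    if (length(nxt) == 1) {
      D[i] <- dm[i, nxt]
      beta[i] <- .plane_angle(nrm[i, ], nrm[nxt, ])
    }
    if (length(nxt) == 1 && length(prv) == 1) {
      v1 <- pos[prv, ] - pos[i, ]
      v2 <- pos[nxt, ] - pos[i, ]
      alpha[i] <- acos(max(-1, min(1, sum(v1 * v2) /
                                     sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    }
    para[i] <- .plane_angle(nrm[i, ], nrm[nearest[i], ])
  }

  data.frame(sample_id = poses$sample_id, array_id = poses$array_id,
             nuc_index = poses$nuc_index,
             D = D, N = Nval,
             nearest_array = poses$array_id[nearest],
             nearest_index = poses$nuc_index[nearest],
             alpha = alpha, beta = beta, para = para,
             near_boundary = poses$near_boundary,
             linker_to_next_resolved = poses$linker_to_next_resolved,
             stringsAsFactors = FALSE)
}

#' Apply the stereological exclusion rules
#'
#' Nucleosomes flagged within `boundary_nm` of the air/water boundary are
#' removed entirely. For flanks with unresolved linkers (density gaps), D,
#' alpha and beta are dropped while N and para are retained (mirroring the
#' D+ control analysis): D and beta at nucleosome i require linker i
#' resolved; alpha at i requires both linker i-1 and linker i resolved.
#'
#' @param records output of [compute_geometry()].
#' @param boundary_nm boundary-exclusion distance, default 5 nm (exclusion
#'   is driven by the `near_boundary` flag; the parameter is recorded in the
#'   audit).
#' @param drop_unresolved drop D/alpha/beta at unresolved flanks.
#' @return list with `records` (filtered data.frame) and `audit`
#'   (counts and percentages per exclusion reason).
#' @export
apply_exclusions <- function(records, boundary_nm = 5,
                             drop_unresolved = TRUE) {
  n0 <- nrow(records)
  n_boundary <- sum(records$near_boundary)
  out <- records[!records$near_boundary, , drop = FALSE]

  n_D_dropped <- 0L; n_alpha_dropped <- 0L
  if (drop_unresolved) {
    # linker i resolved flag sits on nucleosome i (linker_to_next_resolved)
    unres_next <- !out$linker_to_next_resolved & !is.na(out$D)
    n_D_dropped <- sum(unres_next)
    out$beta[unres_next] <- NA_real_
    # alpha needs the upstream linker too
    key <- paste(out$array_id, out$nuc_index)
    up_key <- paste(out$array_id, out$nuc_index - 1)
    up_res <- out$linker_to_next_resolved[match(up_key, key)]
    bad_alpha <- !is.na(out$alpha) &
      (!out$linker_to_next_resolved | !ifelse(is.na(up_res), TRUE, up_res))
    n_alpha_dropped <- sum(bad_alpha)
    out$alpha[bad_alpha] <- NA_real_
    out$D[unres_next] <- NA_real_
  }
  nD <- sum(!is.na(records$D) & !records$near_boundary)
  audit <- data.frame(
    reason = c("near_boundary", "unresolved_linker_D", "unresolved_alpha"),
    count = c(n_boundary, n_D_dropped, n_alpha_dropped),
    percent = 100 * c(n_boundary / max(1, n0),
                      n_D_dropped / max(1, nD),
                      n_alpha_dropped / max(1, nD)),
    stringsAsFactors = FALSE)
  attr(audit, "boundary_nm") <- boundary_nm
  list(records = out, audit = audit)
}

#' Fraction of tightly stacked nucleosomes
#'
#' A nucleosome counts as stacked when its nearest-neighbor distance N and
#' plane angle para fall below the thresholds (defaults: para < 25 degrees,
#' N < 8 nm; stacked disks sit near N ~ 6.5 nm).
#'
#' @param records stereology records with `N` and `para`.
#' @param para_max_deg,N_max_nm thresholds.
#' @param breaks_N,breaks_para histogram breaks for the returned 2D (N,
#'   para) histogram.
#' @return list with `fraction` (NA if no eligible records), `pairs`
#'   (the stacked records) and `histogram` (2D counts for plotting).
#' @export
stacked_fraction <- function(records, para_max_deg = 25, N_max_nm = 8,
                             breaks_N = seq(0, 50, 2),
                             breaks_para = seq(0, 90, 5)) {
  ok <- !is.na(records$N) & !is.na(records$para)
  r <- records[ok, , drop = FALSE]
  if (!nrow(r))
    return(list(fraction = NA_real_, pairs = r, histogram = NULL))
  stacked <- r$para < para_max_deg & r$N < N_max_nm
  hN <- cut(pmin(r$N, max(breaks_N) - 1e-9), breaks_N, include.lowest = TRUE)
  hp <- cut(r$para, breaks_para, include.lowest = TRUE)
  list(fraction = mean(stacked),
       pairs = r[stacked, , drop = FALSE],
       histogram = table(N = hN, para = hp))
}

#' Per-group summary of stereological descriptors
#'
#' Mean, SD and n per descriptor and group, pairwise Welch t-test and
#' Kolmogorov-Smirnov p-values, and percent change between condition pairs.
#'
#' @param records stereology records (possibly rbind-ed across samples).
#' @param group_by column name used for grouping (default `"sample_id"`).
#' @param descriptors descriptor columns to summarize.
#' @return list with `summary` (per-group table) and `tests` (pairwise
#'   comparisons; empty when fewer than 2 usable groups).
#' @export
summarize_stereology <- function(records, group_by = "sample_id",
                                 descriptors = c("D", "N", "alpha",
                                                 "beta", "para")) {
  g <- records[[group_by]]
  groups <- unique(g)
  rows <- list(); tests <- list()
  for (d in descriptors) {
    for (gr in groups) {
      x <- records[[d]][g == gr]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1]] <- data.frame(
        group = gr, descriptor = d, n = length(x),
        mean = if (length(x) >= 2) mean(x) else NA_real_,
        sd = if (length(x) >= 2) sd(x) else NA_real_,
        note = if (length(x) < 2) "n<2: statistics suppressed" else "",
        stringsAsFactors = FALSE)
    }
    if (length(groups) >= 2) {
      cmb <- utils::combn(groups, 2)
      for (ci in seq_len(ncol(cmb))) {
        x <- records[[d]][g == cmb[1, ci]]; x <- x[!is.na(x)]
        y <- records[[d]][g == cmb[2, ci]]; y <- y[!is.na(y)]
        if (length(x) < 2 || length(y) < 2) next
        tt <- t.test(x, y)                       # Welch, two-sided
        ks <- suppressWarnings(ks.test(x, y))
        tests[[length(tests) + 1]] <- data.frame(
          descriptor = d, group1 = cmb[1, ci], group2 = cmb[2, ci],
          mean1 = mean(x), mean2 = mean(y),
          percent_change = 100 * (mean(y) - mean(x)) / abs(mean(x)),
          p_welch = tt$p.value, p_ks = ks$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(summary = do.call(rbind, rows),
       tests = if (length(tests)) do.call(rbind, tests) else
         data.frame())
}
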