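# ---------------------------------------------------------------------------
# Linker-DNA calculus: traced open-DNA polylines -> O (bp), combined with
# peel annotations S (upstream exit) and E (downstream entry) into the
# signed linker length L = O - S - E and per-core constrained core length
# C = 146 - S_exit - E_entry.
# ---------------------------------------------------------------------------

#' Length of a traced polyline in base pairs
#'
#' Sum of segment Euclidean lengths (nm) divided by 0.34 nm/bp. Duplicate
#' consecutive points contribute zero-length segments.
#'
#' @param points numeric matrix (>= 2 rows, 3 columns) of 3D points in nm.
#' @return length in bp.
#' @export
polyline_length_bp <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("polyline needs at least 2 points")
  seg <- diff(points)
  nm_to_bp(sum(sqrt(rowSums(seg^2))))
}

#' Decompose an open-DNA length into linker length and core contributions
#'
#' `L = O - S - E` (signed; negative L means partially overlapping cores).
#' The peeled segments reduce the wrapped core DNA: a core's constrained
#' length is `C = 146 - S_exit - E_entry`, assembled across its two flanks
#' by [core_constrained_lengths()]; here the per-flank contributions are
#' returned.
#'
#' @param O open traced DNA length (bp).
#' @param S upstream (exit-side) peel (bp, >= 0).
#' @param E downstream (entry-side) peel (bp, >= 0).
#' @return data.frame with `L`, `C_exit_contribution` (= S, unwrapped from
#'   the upstream core's exit flank) and `C_entry_contribution` (= E, from
#'   the downstream core's entry flank). Vectorized.
#' @examples
#' decompose_linker(60, 10, 5) # L = 45
#' @export
decompose_linker <- function(O, S, E) {
  stopifnot(all(S >= 0), all(E >= 0))
  data.frame(L = O - S - E,
             C_exit_contribution = S,
             C_entry_contribution = E)
}

#' Per-linker measurements of a scene
#'
#' Computes O from each resolved traced polyline and combines it with the
#' peel annotations into L. Unresolved linkers are retained with `NA`
#' measurements and excluded from all statistics downstream.
#'
#' @param scene a `scene` with a `paths` table.
#' @return data.frame: array_id, linker_index, O, S, E, L, resolved.
#' @export
linker_measurements <- function(scene) {
  paths <- scene$paths
  O <- rep(NA_real_, nrow(paths))
  res <- which(paths$resolved)
  O[res] <- vapply(paths$points[res], polyline_length_bp, numeric(1))
  L <- O - paths$S_bp - paths$E_bp
  data.frame(array_id = paths$array_id, linker_index = paths$linker_index,
             O = O, S = paths$S_bp, E = paths$E_bp, L = L,
             resolved = paths$resolved, stringsAsFactors = FALSE)
}

#' Per-core constrained core DNA lengths
#'
#' Core i's exit flank is peeled by S of linker i; its entry flank by E of
#' linker i-1; `C = 146 - S_exit - E_entry`. Terminal cores (or cores with
#' an unresolved flanking linker) use 0 for the missing flank and are
#' flagged `partial`; the headline mean-C statistic is taken over cores
#' with both flanks measured (`partial == FALSE`), matching how traced-core
#' counts relate to array interiors. C below 100 bp is flagged suspicious.
#'
#' @param measurements output of [linker_measurements()].
#' @param core_bp reference core length, default 146.
#' @return data.frame: array_id, nuc_index, C, partial, suspicious.
#' @export
core_constrained_lengths <- function(measurements, core_bp = core_length_bp()) {
  out <- list()
  for (aid in unique(measurements$array_id)) {
    m <- measurements[measurements$array_id == aid, , drop = FALSE]
    n_link <- max(m$linker_index)
    n_cores <- n_link + 1
    for (i in seq_len(n_cores)) {
      exit_row <- m[m$linker_index == i, , drop = FALSE]       # linker i
      entry_row <- m[m$linker_index == i - 1, , drop = FALSE]  # linker i-1
      s_ok <- nrow(exit_row) == 1 && exit_row$resolved
      e_ok <- nrow(entry_row) == 1 && entry_row$resolved
      S <- if (s_ok) exit_row$S else 0
      E <- if (e_ok) entry_row$E else 0
      C <- core_bp - S - E
      out[[length(out) + 1]] <- data.frame(
        array_id = aid, nuc_index = i, C = C,
        partial = !(s_ok && e_ok), suspicious = C < 100,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-array average linker and core lengths
#'
#' Arithmetic means over resolved linkers (L_av) and both-flank cores
#' (C_av); arrays with no resolved linker are reported with a note and NA.
#'
#' @param measurements output of [linker_measurements()].
#' @param cores optional output of [core_constrained_lengths()]; computed
#'   if missing.
#' @return data.frame: array_id, n_linkers, L_av, n_cores, C_av, note.
#' @export
per_array_averages <- function(measurements,
                               cores = core_constrained_lengths(measurements)) {
  aids <- unique(measurements$array_id)
  rows <- lapply(aids, function(aid) {
    m <- measurements[measurements$array_id == aid & measurements$resolved, ,
                      drop = FALSE]
    cc <- cores[cores$array_id == aid & !cores$partial, , drop = FALSE]
    data.frame(array_id = aid,
               n_linkers = nrow(m),
               L_av = if (nrow(m)) mean(m$L) else NA_real_,
               n_cores = nrow(cc),
               C_av = if (nrow(cc)) mean(cc$C) else NA_real_,
               note = if (nrow(m)) "" else "all linkers unresolved",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Nucleosome repeat length estimate
#'
#' NRL = core DNA length + mean linker length.
#'
#' @param mean_L mean linker length (bp).
#' @param core_bp core reference length (bp), default 146.
#' @return NRL in bp.
#' @examples
#' nrl_estimate(30.7) # 176.7
#' @export
nrl_estimate <- function(mean_L, core_bp = core_length_bp()) {
  stopifnot(is.finite(mean_L))
  core_bp + mean_L
}

#' Correlation checks for the linker calculus
#'
#' Pearson and Spearman correlations (with p-values) for C vs L per
#' nucleosome, C_av vs L_av per array, and L_av vs array size.
#'
#' @param measurements output of [linker_measurements()].
#' @param cores optional output of [core_constrained_lengths()].
#' @return data.frame of correlations; constant inputs yield NA rows with a
#'   note.
#' @export
correlation_checks <- function(measurements,
                               cores = core_constrained_lengths(measurements)) {
  per_arr <- per_array_averages(measurements, cores)

  # pair C (of the downstream core of each linker) with that linker's L
  m <- measurements[measurements$resolved, , drop = FALSE]
  key <- paste(cores$array_id, cores$nuc_index)
  Cdn <- cores$C[match(paste(m$array_id, m$linker_index + 1), key)]
  pd <- cores$partial[match(paste(m$array_id, m$linker_index + 1), key)]
  ok <- !is.na(Cdn) & !pd
  sizes <- table(measurements$array_id)  # linkers per array
  pa <- per_arr[!is.na(per_arr$L_av), , drop = FALSE]

  one <- function(label, x, y, strict = FALSE) {
    if (length(x) < 3) {
      if (strict) stop(sprintf("%s: need >= 3 paired values", label))
      return(data.frame(pair = label, n = length(x),
                        pearson_r = NA_real_, pearson_p = NA_real_,
                        spearman_r = NA_real_, spearman_p = NA_real_,
                        note = "fewer than 3 paired values",
                        stringsAsFactors = FALSE))
    }
    if (sd(x) == 0 || sd(y) == 0)
      return(data.frame(pair = label, n = length(x),
                        pearson_r = NA_real_, pearson_p = NA_real_,
                        spearman_r = NA_real_, spearman_p = NA_real_,
                        note = "constant input: correlation undefined",
                        stringsAsFactors = FALSE))
    cp <- cor.test(x, y, method = "pearson")
    cs <- suppressWarnings(cor.test(x, y, method = "spearman"))
    data.frame(pair = label, n = length(x),
               pearson_r = unname(cp$estimate), pearson_p = cp$p.value,
               spearman_r = unname(cs$estimate), spearman_p = cs$p.value,
               note = "", stringsAsFactors = FALSE)
  }
  rbind(
    one("C_vs_L_per_nucleosome", Cdn[ok], m$L[ok], strict = TRUE),
    one("Cav_vs_Lav_per_array", pa$C_av, pa$L_av),
    one("Lav_vs_array_size", as.numeric(sizes[pa$array_id]) + 1, pa$L_av))
}
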