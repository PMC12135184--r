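# ---------------------------------------------------------------------------
# Synthetic 3D scene generator: chain-growth placement of nucleosome arrays
# with calibrated linker-length, distance, angle, peel and missing-linker
# statistics, plus crosslinked-scene construction with injected contacts.
# ---------------------------------------------------------------------------

.unit <- function(v) v / sqrt(sum(v^2))

.random_unit <- function() {
  repeat {
    v <- rnorm(3)
    n2 <- sum(v^2)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}

# unit vector perpendicular to d, uniform azimuth
.random_perp <- function(d) {
  u <- .random_unit()
  p <- u - sum(u * d) * d
  n2 <- sum(p^2)
  if (n2 < 1e-12) return(.random_perp(d))
  p / sqrt(n2)
}

#' Generate a synthetic nucleosome-array scene
#'
#' Chain-growth placement: per linker a signed length L is drawn from the
#' calibrated mixture (with the preset's array-level mean modulation), the
#' center-to-center distance is `D = max(floor, offset + slope * 0.34 * L +
#' noise)`, successive nucleosomes are placed at bend angle alpha (drawn from
#' the geometry preset) with uniform dihedral, plane normals get wide
#' isotropic noise around the local chain-plane normal, peel values S and E
#' are drawn from a gamma model, and traced open-DNA polylines consistent
#' with `O = L + S + E` are emitted. Linkers are flagged unresolved at the
#' preset missing rate, and nucleosomes boundary-flagged at the preset
#' boundary rate. Arrays are laid out on a coarse 3D grid (`array_spacing`)
#' so that distinct arrays do not interact geometrically.
#'
#' @param linker a calibrated [linker_preset()].
#' @param geometry a [geometry_preset()].
#' @param n_arrays number of arrays.
#' @param array_size_range integer range of nucleosomes per array; sizes are
#'   drawn uniformly. Must lie within 2..30 (traced arrays span 7-30
#'   nucleosomes; smaller arrays are allowed for unit tests).
#' @param seed optional integer seed.
#' @param sample_id sample label stored in the pose table.
#' @param array_spacing nm between array grid origins.
#' @return an object of class `scene`: list with `poses` (pose table
#'   data.frame), `paths` (traced-linker data.frame with a list column
#'   `points`), and `truth` (generator ground truth: drawn L, D, S, E per
#'   linker).
#' @export
build_scene <- function(linker, geometry, n_arrays,
                        array_size_range = c(10, 12), seed = NULL,
                        sample_id = linker$name, array_spacing = 150) {
  stopifnot(inherits(linker, "linker_preset"),
            inherits(geometry, "geometry_preset"),
            n_arrays >= 1,
            array_size_range[1] >= 2, array_size_range[2] <= 30,
            array_size_range[1] <= array_size_range[2])
  with_seed(seed, {
    pose_rows <- vector("list", n_arrays)
    path_rows <- vector("list", n_arrays)
    truth_rows <- vector("list", n_arrays)
    # coarse grid of array origins
    gside <- ceiling(n_arrays^(1 / 3))
    for (a in seq_len(n_arrays)) {
      sizes <- seq(array_size_range[1], array_size_range[2])
      n <- if (length(sizes) == 1) sizes else sample(sizes, 1)
      aid <- sprintf("A%03d", a)
      gi <- c((a - 1) %% gside,
              ((a - 1) %/% gside) %% gside,
              (a - 1) %/% gside^2)
      origin <- gi * array_spacing

      shift <- switch(linker$array_shift$type,
        none = 0,
        gaussian = rnorm(1, 0, linker$array_shift$sd),
        two_point = sample(linker$array_shift$points, 1,
                           prob = linker$array_shift$probs) +
          rnorm(1, 0, linker$array_shift$jitter_sd))
      L <- sample_linker_lengths(linker, n - 1) + shift
      D <- pmax(geometry$d_floor,
                geometry$d_offset + geometry$d_slope * bp_to_nm(L) +
                  rnorm(n - 1, 0, geometry$d_noise_sd))

      # chain growth
      pos <- matrix(0, n, 3)
      pos[1, ] <- origin
      d_prev <- .random_unit()
      pos[2, ] <- pos[1, ] + D[1] * d_prev
      if (n > 2) for (j in 2:(n - 1)) {
        alpha <- min(179, max(1, rnorm(1, geometry$alpha_mean,
                                       geometry$alpha_sd)))
        theta <- (180 - alpha) * pi / 180  # angle between chain segments
        u <- .random_perp(d_prev)
        d_next <- cos(theta) * d_prev + sin(theta) * u
        pos[j + 1, ] <- pos[j, ] + D[j] * d_next
        d_prev <- d_next
      }

      # plane normals: local chain-plane normal plus wide isotropic noise
      nrm <- matrix(0, n, 3)
      for (j in seq_len(n)) {
        ref <- if (j > 1 && j < n) {
          cr <- pracma_cross(pos[j, ] - pos[j - 1, ], pos[j + 1, ] - pos[j, ])
          if (sum(cr^2) > 1e-12) .unit(cr) else .random_unit()
        } else .random_unit()
        nrm[j, ] <- .unit(ref + geometry$normal_noise_sd * rnorm(3))
      }

      # peels; repair negative open length by splitting the deficit onto S,E
      S <- rgamma(n - 1, shape = geometry$peel_shape,
                  scale = geometry$peel_mean / geometry$peel_shape)
      E <- rgamma(n - 1, shape = geometry$peel_shape,
                  scale = geometry$peel_mean / geometry$peel_shape)
      O <- L + S + E
      bad <- O < 0
      if (any(bad)) {
        S[bad] <- S[bad] - O[bad] / 2
        E[bad] <- E[bad] - O[bad] / 2
        O[bad] <- 0
      }

      resolved <- runif(n - 1) >= geometry$missing_rate
      boundary <- runif(n) < geometry$boundary_rate

      pose_rows[[a]] <- data.frame(
        sample_id = sample_id, tomogram_id = "synthetic", array_id = aid,
        nuc_index = seq_len(n),
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
        near_boundary = boundary,
        linker_to_next_resolved = c(resolved, FALSE),
        stringsAsFactors = FALSE)

      pts <- vector("list", n - 1)
      for (j in seq_len(n - 1)) {
        pts[[j]] <- if (resolved[j])
          .make_polyline(pos[j, ], bp_to_nm(O[j])) else
            matrix(numeric(0), 0, 3)
      }
      path_rows[[a]] <- data.frame(
        array_id = aid, linker_index = seq_len(n - 1),
        S_bp = S, E_bp = E, resolved = resolved, stringsAsFactors = FALSE)
      path_rows[[a]]$points <- pts

      truth_rows[[a]] <- data.frame(
        array_id = aid, linker_index = seq_len(n - 1),
        L = L, D = D, S = S, E = E, O = O, resolved = resolved,
        stringsAsFactors = FALSE)
    }
    structure(list(poses = do.call(rbind, pose_rows),
                   paths = do.call(rbind, path_rows),
                   truth = list(linkers = do.call(rbind, truth_rows))),
              class = "scene")
  })
}

# minimal cross product (avoid pulling in a geometry package for one line)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# polyline with 4 random-walk segments rescaled to an exact total length
.make_polyline <- function(start, total_nm, n_seg = 4) {
  if (total_nm <= 0) return(rbind(start, start))
  dirs <- t(vapply(seq_len(n_seg), function(i) .random_unit(), numeric(3)))
  # mildly persistent walk so the trace looks like DNA, then exact rescale
  for (i in seq_len(n_seg - 1) + 1)
    dirs[i, ] <- .unit(0.7 * dirs[i - 1, ] + 0.3 * dirs[i, ])
  lens <- runif(n_seg, 0.5, 1)
  lens <- lens * (total_nm / sum(lens))
  pts <- matrix(0, n_seg + 1, 3)
  pts[1, ] <- start
  for (i in seq_len(n_seg)) pts[i + 1, ] <- pts[i, ] + lens[i] * dirs[i, ]
  pts
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("scene: %d nucleosomes in %d arrays; %d traced linkers\n",
              nrow(x$poses), length(unique(x$poses$array_id)),
              sum(x$paths$resolved)))
  invisible(x)
}

#' Number of nucleosomes per array in a scene
#' @param scene a `scene`.
#' @return named integer vector.
#' @export
array_sizes <- function(scene) {
  tapply(scene$poses$nuc_index, scene$poses$array_id, length)
}

# ---------------------------------------------------------------------------
# Crosslinked scenes: inject ground-truth contacts for classifier testing.
# ---------------------------------------------------------------------------

#' Build a crosslinked scene with injected ground-truth contacts
#'
#' Repositions nucleosomes of a base scene so that a controlled fraction of
#' pairs at prescribed chain separations k (and trans pairs between arrays)
#' sit at centroid distance below the contact threshold, emulating
#' formaldehyde-crosslinked (EMANIC) geometry. Chain bookkeeping
#' (identities, indices, resolved flags) is preserved. The realized contact
#' spectrum, recomputed from the final geometry by an exhaustive
#' nearest-neighbor scan, is returned as classification ground truth.
#'
#' @param base a `scene`.
#' @param mode "open" (no injection), "zigzag" (i+/-2 contacts) or "mixed"
#'   (a blend of i+/-1, i+/-2, i+/-4 and trans).
#' @param fraction for "zigzag": target fraction of nucleosomes involved in
#'   injected i+/-2 contacts.
#' @param spectrum optional named numeric overriding the injected fractions,
#'   e.g. `c("1" = 0.1, "2" = 0.2, trans = 0.05)`.
#' @param contact_nm contact threshold used for the realized ground truth.
#' @param seed optional seed.
#' @return a `scene` whose `truth$contacts` holds per-nucleosome realized
#'   categories and `truth$spectrum` the realized fractions.
#' @export
build_crosslinked_scene <- function(base, mode = c("open", "zigzag", "mixed"),
                                    fraction = 0.3, spectrum = NULL,
                                    contact_nm = 11, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(base, "scene"))
  if (is.null(spectrum)) {
    spectrum <- switch(mode,
      open = numeric(0),
      zigzag = c("2" = fraction),
      mixed = c("1" = fraction / 4, "2" = fraction / 4,
                "4" = fraction / 8, trans = fraction / 8))
  }
  with_seed(seed, {
    poses <- base$poses
    pos <- as.matrix(poses[, c("x", "y", "z")])
    arr <- poses$array_id
    idx <- poses$nuc_index
    ntot <- nrow(poses)
    used <- rep(FALSE, ntot)
    injected <- list()

    place_near <- function(target_row, move_row) {
      # candidate placements at 7.5-9.5 nm; keep the one farthest from
      # everything else so the pair are mutual nearest neighbors
      best <- NULL; best_score <- -Inf
      for (t in 1:24) {
        cand <- pos[target_row, ] + runif(1, 7.5, 9.5) * .random_unit()
        d2 <- rowSums(sweep(pos[-c(target_row, move_row), , drop = FALSE],
                            2, cand)^2)
        sc <- min(d2)
        if (sc > best_score) { best_score <- sc; best <- cand }
      }
      best
    }

    for (cat_name in names(spectrum)) {
      frac <- spectrum[[cat_name]]
      if (frac <= 0) next
      n_pairs <- ceiling(frac * ntot / 2)
      if (cat_name == "trans") {
        aids <- unique(arr)
        if (length(aids) < 2) stop("trans injection needs >= 2 arrays")
        made <- 0; tries <- 0
        while (made < n_pairs && tries < 50 * n_pairs) {
          tries <- tries + 1
          ab <- sample(aids, 2)
          ra <- which(arr == ab[1] & !used)
          rb <- which(arr == ab[2] & !used)
          # middle nucleosomes only: terminals must stay far apart
          ra <- ra[idx[ra] > 1 & idx[ra] < max(idx[arr == ab[1]])]
          rb <- rb[idx[rb] > 1 & idx[rb] < max(idx[arr == ab[2]])]
          if (!length(ra) || !length(rb)) next
          i <- sample(ra, 1); j <- sample(rb, 1)
          pos[j, ] <- place_near(i, j)
          used[c(i, j)] <- TRUE
          injected[[length(injected) + 1]] <-
            data.frame(row_i = i, row_j = j, category = "trans")
          made <- made + 1
        }
        if (made < n_pairs)
          stop("requested trans contact fraction not geometrically achievable")
      } else {
        k <- as.integer(cat_name)
        made <- 0
        for (aid in sample(unique(arr))) {
          rows <- which(arr == aid)
          n <- length(rows)
          i0 <- 1
          while (i0 + k <= n && made < n_pairs) {
            i <- rows[i0]; j <- rows[i0 + k]
            if (!used[i] && !used[j]) {
              pos[j, ] <- place_near(i, j)
              used[c(i, j)] <- TRUE
              injected[[length(injected) + 1]] <-
                data.frame(row_i = i, row_j = j,
                           category = sprintf("i+/-%d", k))
              made <- made + 1
            }
            i0 <- i0 + k + 1
          }
          if (made >= n_pairs) break
        }
        if (made < n_pairs)
          stop(sprintf(
            "requested i+/-%d contact fraction not geometrically achievable", k))
      }
    }

    poses$x <- pos[, 1]; poses$y <- pos[, 2]; poses$z <- pos[, 3]
    out <- base
    out$poses <- poses
    out$truth$injected <-
      if (length(injected)) do.call(rbind, injected) else NULL
    gt <- .ground_truth_contacts(poses, contact_nm)
    out$truth$contacts <- gt$per_nucleosome
    out$truth$spectrum <- gt$spectrum
    out
  })
}

# exhaustive (O(n^2), loop-based) nearest-neighbor contact scan: the
# generator-side ground truth, deliberately independent of classify_contacts
.ground_truth_contacts <- function(poses, contact_nm) {
  pos <- as.matrix(poses[, c("x", "y", "z")])
  n <- nrow(pos)
  cat_v <- character(n)
  for (i in seq_len(n)) {
    best <- Inf; bj <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (d < best - 1e-12 ||
          (abs(d - best) <= 1e-12 && !is.na(bj) &&
           (poses$array_id[j] < poses$array_id[bj] ||
            (poses$array_id[j] == poses$array_id[bj] &&
             poses$nuc_index[j] < poses$nuc_index[bj])))) {
        best <- d; bj <- j
      }
    }
    cat_v[i] <- if (best >= contact_nm) "none"
      else if (poses$array_id[i] == poses$array_id[bj]) {
        k <- abs(poses$nuc_index[i] - poses$nuc_index[bj])
        if (k > 4) "i+/->4" else sprintf("i+/-%d", k)
      } else "trans"
  }
  lev <- c("i+/-1", "i+/-2", "i+/-3", "i+/-4", "i+/->4", "trans", "none")
  counts <- table(factor(cat_v, levels = lev))
  list(per_nucleosome = data.frame(array_id = poses$array_id,
                                   nuc_index = poses$nuc_index,
                                   category = cat_v,
                                   stringsAsFactors = FALSE),
       spectrum = stats::setNames(as.numeric(counts) / n, lev))
}
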