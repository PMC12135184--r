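# Fixtures are built in code; nothing binary ships with the package.

# minimal pose table from a matrix of centroids (one array), unit normals
make_poses <- function(pos, normals = NULL, array_id = "A001",
                       sample_id = "test", resolved = TRUE,
                       boundary = FALSE) {
  n <- nrow(pos)
  if (is.null(normals)) {
    normals <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  }
  normals <- normals / sqrt(rowSums(normals^2))
  data.frame(sample_id = sample_id, tomogram_id = "t1", array_id = array_id,
             nuc_index = seq_len(n),
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             nx = normals[, 1], ny = normals[, 2], nz = normals[, 3],
             near_boundary = rep_len(boundary, n),
             linker_to_next_resolved = c(rep_len(resolved, n - 1), FALSE),
             stringsAsFactors = FALSE)
}

make_scene <- function(..., paths = NULL) {
  poses <- do.call(rbind, list(...))
  if (is.null(paths)) {
    paths <- data.frame(array_id = character(0), linker_index = integer(0),
                        S_bp = numeric(0), E_bp = numeric(0),
                        resolved = logical(0))
    paths$points <- list()
  }
  structure(list(poses = poses, paths = paths, truth = NULL),
            class = "scene")
}

# brute-force nearest-neighbor oracle: plain double loop, first minimum in
# (array_id, nuc_index) order breaks ties
brute_nearest <- function(poses) {
  pos <- as.matrix(poses[, c("x", "y", "z")])
  ord <- order(poses$array_id, poses$nuc_index)
  n <- nrow(pos)
  out_idx <- integer(n); out_d <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf; bj <- NA_integer_
    for (j in ord) {
      if (j == i) next
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (d < best - 1e-12) { best <- d; bj <- j }
    }
    out_idx[i] <- bj; out_d[i] <- best
  }
  list(index = out_idx, distance = out_d)
}

# synthetic ensemble with hand-placed sites (for observable unit tests)
fake_ensemble <- function(frames, sites, core_frames, template = NULL) {
  if (is.null(template))
    template <- structure(list(name = "fake",
                               n_cores = nrow(core_frames[[1]]),
                               linker_bp = numeric(0),
                               linker_beads = integer(0),
                               zero_linker = logical(0),
                               lh = integer(0)),
                          class = "fiber_template")
  structure(list(template = template, sites = sites, frames = frames,
                 core_frames = core_frames,
                 acceptance = c(bead = NA_real_), seed = 0L),
            class = "ensemble")
}

# core_frames row: position (3) + row-major identity rotation (9)
identity_core_frames <- function(pos_mat) {
  cbind(pos_mat, matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1),
                            each = nrow(pos_mat)), nrow(pos_mat), 9))
}

# small fiber ensemble via the real sampler (cheap settings)
tiny_ensemble <- function(n_cores = 3, linker_bp = 44, seed = 7,
                          n_frames = 5, salt = 150) {
  tpl <- build_fiber_template(rep(linker_bp, n_cores - 1))
  run_mc(tpl, set_conditions(energy_params(), salt),
         mc_settings(burnin_sweeps = 50, n_frames = n_frames,
                     sweep_interval = 2),
         seed = seed)
}
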