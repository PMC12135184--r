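core_only_sites <- function(n) {
  data.frame(type = rep("core_center", n), core = seq_len(n),
             linker = NA, rank = 1, tail_chain = NA,
             charge = 0, sigma = 0, stringsAsFactors = FALSE)
}

test_that("packing ratio matches the closed form and flags degeneracy", {
  pos <- cbind(seq(0, 33, length.out = 12), 0, 0)  # 12 cores over 33 nm
  ens <- fake_ensemble(frames = list(pos), sites = core_only_sites(12),
                       core_frames = list(identity_core_frames(pos)))
  pr <- packing_ratio(ens)
  expect_equal(pr$mean, 12 * 11 / 33, tolerance = 1e-12)
  expect_equal(pr$sd, NA_real_ * 0 + 0, tolerance = 1e-12)  # single frame

  # rigid ensemble: identical frames -> SD 0
  ens2 <- fake_ensemble(frames = list(pos, pos, pos),
                        sites = core_only_sites(12),
                        core_frames = rep(list(identity_core_frames(pos)), 3))
  expect_equal(packing_ratio(ens2)$sd, 0)

  # fewer than 3 cores is a precondition violation
  p2 <- pos[1:2, , drop = FALSE]
  ens3 <- fake_ensemble(frames = list(p2), sites = core_only_sites(2),
                        core_frames = list(identity_core_frames(p2)))
  expect_error(packing_ratio(ens3), ">= 3 cores")

  # coincident centroids are skipped with a count
  p0 <- matrix(0, 5, 3)
  ens4 <- fake_ensemble(frames = list(p0), sites = core_only_sites(5),
                        core_frames = list(identity_core_frames(p0)))
  expect_error(packing_ratio(ens4))  # no usable frame at all
})

test_that("interaction patterns equal an exhaustive recount", {
  set.seed(3)
  n <- 10
  frames <- lapply(1:6, function(i) matrix(rnorm(n * 3, sd = 8), n, 3))
  ens <- fake_ensemble(frames = frames, sites = core_only_sites(n),
                       core_frames = lapply(frames, identity_core_frames))
  ip <- interaction_pattern(ens, contact_nm = 11)
  # brute-force O(n^2) recount
  kc <- numeric(n - 1)
  for (fr in frames) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((fr[i, ] - fr[j, ])^2)) < 11)
      kc[j - i] <- kc[j - i] + 1
  }
  expect_equal(unname(ip$frequency), 2 * kc / (n * length(frames)),
               tolerance = 1e-12)

  # geometry-forced patterns
  zig <- cbind(seq(0, 35, by = 5), rep(c(0, 20), 4)[1:8], 0)
  ez <- fake_ensemble(frames = list(zig), sites = core_only_sites(8),
                      core_frames = list(identity_core_frames(zig)))
  fz <- interaction_pattern(ez)$frequency
  expect_equal(unname(which.max(fz)), 2L)

  ext <- cbind(seq(0, 150, by = 15), 0, 0)
  ee <- fake_ensemble(frames = list(ext),
                      sites = core_only_sites(nrow(ext)),
                      core_frames = list(identity_core_frames(ext)))
  expect_true(all(interaction_pattern(ee)$frequency == 0))
})

make_linker_ensemble <- function(entry_xyz, exit_xyz, n_frames = 3,
                                 jitter = 0) {
  # one core (id 2) flanked by linkers 1 (entry) and 2 (exit), 5 beads each
  nb <- nrow(entry_xyz)
  sites <- rbind(core_only_sites(3),
                 data.frame(type = "linker", core = NA, linker = 1,
                            rank = seq_len(nb), tail_chain = NA, charge = 0,
                            sigma = 0, stringsAsFactors = FALSE),
                 data.frame(type = "linker", core = NA, linker = 2,
                            rank = seq_len(nb), tail_chain = NA, charge = 0,
                            sigma = 0, stringsAsFactors = FALSE))
  core_pos <- rbind(c(-30, 0, 0), c(0, 0, 0), c(30, 0, 0))
  frames <- lapply(seq_len(n_frames), function(i) {
    rbind(core_pos,
          entry_xyz + rnorm(length(entry_xyz), sd = jitter),
          exit_xyz + rnorm(length(exit_xyz), sd = jitter))
  })
  tpl <- structure(list(name = "fake", n_cores = 3,
                        linker_bp = c(44, 44), linker_beads = c(nb, nb),
                        zero_linker = c(FALSE, FALSE), lh = c(1, 1, 1)),
                   class = "fiber_template")
  fake_ensemble(frames = frames, sites = sites,
                core_frames = lapply(frames, function(f)
                  identity_core_frames(core_pos)),
                template = tpl)
}

test_that("stem indices follow the paired-bead criterion and eligibility", {
  # entry beads run toward the core, so pairing is rank-reversed; build
  # parallel linkers 2.0 nm apart -> every pair under the 2.5-nm criterion
  exit_xyz <- cbind(5 + 3 * (1:5), 1, 0)
  entry_xyz <- cbind(5 + 3 * (5:1), -1, 0)   # bead 5 nearest the core
  ens <- make_linker_ensemble(entry_xyz, exit_xyz)
  si <- stem_index(ens)
  expect_true(si$eligible[2])
  expect_equal(si$stem_index[2], 1.0)

  # linkers splayed at 90 degrees: only the first pair is close
  exit2 <- cbind(5 + 3 * (1:5), 0, 0)
  entry2 <- cbind(rep(5, 5), -3 * (5:1), 0)
  si2 <- stem_index(make_linker_ensemble(entry2, exit2))
  expect_lt(si2$stem_index[2], 0.4)

  # a 2-bead linker (17.65 bp) makes the core ineligible
  ens3 <- make_linker_ensemble(entry_xyz, exit_xyz)
  ens3$template$linker_beads <- c(2L, 5L)
  si3 <- stem_index(ens3)
  expect_false(si3$eligible[2])
  expect_true(is.na(si3$stem_index[2]))
})

test_that("fan distributions are frame-order and rigid-motion invariant", {
  exit_xyz <- cbind(5 + 3 * (1:5), 1, 0.5)
  entry_xyz <- cbind(5 + 3 * (5:1), -1, 0.5)
  ens <- make_linker_ensemble(entry_xyz, exit_xyz, n_frames = 4,
                              jitter = 0.3)
  fd1 <- fan_distribution(ens, 2)
  shuf <- ens
  ord <- c(3, 1, 4, 2)
  shuf$frames <- ens$frames[ord]; shuf$core_frames <- ens$core_frames[ord]
  fd2 <- fan_distribution(shuf, 2)
  expect_equal(fd2$histogram, fd1$histogram)
  expect_equal(fd2$bead_means, fd1$bead_means, tolerance = 1e-12)

  # rotate every frame rigidly (cores and linkers together): body-frame
  # output is unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- ens
  rot$frames <- lapply(ens$frames, function(f) f %*% t(R) )
  rot$core_frames <- lapply(ens$core_frames, function(cf) {
    pos <- cf[, 1:3] %*% t(R)
    rots <- t(apply(cf, 1, function(row)
      as.vector(t(R %*% matrix(row[4:12], 3, 3, byrow = TRUE)))))
    cbind(pos, rots)
  })
  fd3 <- fan_distribution(rot, 2)
  expect_equal(fd3$bead_means$x, fd1$bead_means$x, tolerance = 1e-9)
  expect_equal(fd3$bead_means$y, fd1$bead_means$y, tolerance = 1e-9)

  # a rigid repeated configuration concentrates into point masses
  ens0 <- make_linker_ensemble(entry_xyz, exit_xyz, n_frames = 3)
  fd0 <- fan_distribution(ens0, 2)
  expect_equal(sum(fd0$histogram > 0), length(unique(
    paste(round(rbind(entry_xyz, exit_xyz)[, 1]),
          round(rbind(entry_xyz, exit_xyz)[, 2])))))
})

test_that("tail interaction fractions partition to one", {
  ens <- tiny_ensemble(n_cores = 3, n_frames = 4)
  fr <- tail_interaction_fractions(ens, cutoff_nm = 2.0)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_true(all(fr >= 0))

  # everything farther than the cutoff -> free
  fr0 <- tail_interaction_fractions(ens, cutoff_nm = 1e-6)
  expect_equal(unname(fr0["free"]), 1)

  no_tails <- ens
  no_tails$sites <- ens$sites[ens$sites$type != "tail", ]
  expect_error(tail_interaction_fractions(no_tails), "no tail beads")
})

test_that("observables are invariant under global rigid motion", {
  ens <- tiny_ensemble(n_cores = 4, n_frames = 3)
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  shift <- c(5, -3, 8)
  mv <- ens
  mv$frames <- lapply(ens$frames, function(f)
    sweep(f %*% t(R), 2, -shift))
  mv$core_frames <- lapply(ens$core_frames, function(cf) {
    pos <- sweep(cf[, 1:3] %*% t(R), 2, -shift)
    rots <- t(apply(cf, 1, function(row)
      as.vector(t(R %*% matrix(row[4:12], 3, 3, byrow = TRUE)))))
    cbind(pos, rots)
  })
  expect_equal(packing_ratio(mv)$mean, packing_ratio(ens)$mean,
               tolerance = 1e-9)
  expect_equal(interaction_pattern(mv)$frequency,
               interaction_pattern(ens)$frequency, tolerance = 1e-12)
  expect_equal(spectrum_from_ensemble(mv)$fractions,
               spectrum_from_ensemble(ens)$fractions, tolerance = 1e-12)
})
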