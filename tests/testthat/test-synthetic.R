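test_that("preset calibration matches target moments analytically", {
  # immature-retina targets: mean 30.7 bp, SD 24.1 bp, 10.7% negative
  p <- calibrate_preset(30.7, 24.1, 0.107)
  m <- preset_moments(p)
  expect_lt(abs(m$mean - 30.7), 0.2)
  expect_lt(abs(m$sd - 24.1), 0.5)
  expect_lt(abs(m$neg_fraction - 0.107), 0.003)

  # symmetric single component: negative mass is forced to 50%
  p0 <- calibrate_preset(0, 1, 0.5, n_components = 1)
  expect_equal(preset_moments(p0)$neg_fraction, 0.5, tolerance = 1e-12)
})

test_that("sampled moments converge to the analytic mixture moments", {
  for (nm in c("PN1", "PN56")) {
    p <- linker_preset(nm)
    m <- preset_moments(p)
    x <- sample_linker_lengths(p, 1e5, seed = 99)
    se_mean <- m$sd / sqrt(length(x))
    expect_lt(abs(mean(x) - m$mean), 3 * se_mean)
    se_neg <- sqrt(m$neg_fraction * (1 - m$neg_fraction) / length(x))
    expect_lt(abs(mean(x < 0) - m$neg_fraction), 3 * se_neg + 1e-4)
  }
})

test_that("sampling is reproducible and validates its preset", {
  p <- linker_preset("PN1")
  expect_identical(sample_linker_lengths(p, 1, seed = 5),
                   sample_linker_lengths(p, 1, seed = 5))
  bogus <- structure(list(calibrated = FALSE), class = "linker_preset")
  expect_error(sample_linker_lengths(bogus, 10), "calibrate_preset")
})

test_that("scene generation is seed-reproducible and self-consistent", {
  lk <- linker_preset("PN1"); gm <- geometry_preset("PN1")
  s1 <- build_scene(lk, gm, n_arrays = 4, seed = 77)
  s2 <- build_scene(lk, gm, n_arrays = 4, seed = 77)
  expect_identical(s1$poses, s2$poses)
  expect_identical(s1$truth$linkers$L, s2$truth$linkers$L)

  # identity chain: traced polyline length / 0.34 - S - E recovers drawn L
  m <- linker_measurements(s1)
  tr <- s1$truth$linkers
  res <- m$resolved
  expect_equal(m$L[res], tr$L[res], tolerance = 1e-6)
  expect_true(all(m$O[res] >= -1e-9))

  sizes <- array_sizes(s1)
  expect_true(all(sizes >= 10 & sizes <= 12))
})

test_that("degenerate geometry gives the closed-form distance", {
  lk <- calibrate_preset(40, 0.01, 0, n_components = 1)
  gm <- geometry_preset("PN1")
  gm$d_noise_sd <- 1e-9; gm$d_offset <- 12; gm$d_floor <- 6.5
  sc <- build_scene(lk, gm, n_arrays = 3, array_size_range = c(5, 5),
                    seed = 1)
  expected <- 12 + 0.65 * bp_to_nm(40)
  expect_equal(unname(sc$truth$linkers$D), rep(expected, nrow(sc$truth$linkers)),
               tolerance = 0.05)
})

test_that("scene statistics track the calibrated targets", {
  sc <- build_scene(linker_preset("PN1"), geometry_preset("PN1"),
                    n_arrays = 40, seed = 13)
  tr <- sc$truth$linkers
  # mean D over all linkers ~ calibrated 20.0 nm
  expect_lt(abs(mean(tr$D) - 20.0), 3 * sd(tr$D) / sqrt(nrow(tr)) + 0.3)
  # missing-linker rate ~ 5.4%
  expect_lt(abs(mean(!tr$resolved) - 0.054), 0.03)
})

test_that("per-array modulation makes PN56 array means biphasic", {
  sc <- build_scene(linker_preset("PN56"), geometry_preset("PN56"),
                    n_arrays = 120, seed = 21)
  m <- linker_measurements(sc)
  lav <- per_array_averages(m)$L_av
  # array means spread around the 40/50 two-point mixture: bimodal spread
  # wider than the within-array SE alone, and global mean stays on target
  expect_lt(abs(mean(lav, na.rm = TRUE) - 42.6), 2.5)
  expect_gt(sd(lav, na.rm = TRUE), 4)
})

test_that("fiber templates discretize and flag as specified", {
  tpl <- build_fiber_template(rep(44, 22), lh_per_nucleosome = 1)
  expect_equal(tpl$n_cores, 23)
  expect_true(all(tpl$linker_beads == 5L))          # 44 bp -> 5 beads
  expect_true(all(tpl$lh == 1L))                    # one LH per core

  expect_warning(tpl2 <- build_fiber_template(c(0, -12, 44)), "negative")
  expect_equal(tpl2$linker_beads, c(0L, 0L, 5L))
  expect_equal(tpl2$zero_linker, c(TRUE, TRUE, FALSE))

  tpl3 <- suppressWarnings(
    build_fiber_template(linker_preset("PN56"), 23, 1, seed = 4))
  tpl4 <- suppressWarnings(
    build_fiber_template(linker_preset("PN56"), 23, 1, seed = 4))
  expect_identical(tpl3$linker_bp, tpl4$linker_bp)
})

test_that("crosslinked scenes inject recoverable ground truth", {
  base <- build_scene(linker_preset("PN56"), geometry_preset("PN56"),
                      n_arrays = 6, seed = 3)
  open <- build_crosslinked_scene(base, "open", seed = 1)
  expect_null(open$truth$injected)

  zz <- build_crosslinked_scene(base, "zigzag", fraction = 0.2, seed = 1)
  inj <- zz$truth$injected
  expect_true(all(inj$category == "i+/-2"))
  expect_gte(nrow(inj), ceiling(0.2 * nrow(base$poses) / 2))
  # injected pairs really are within the contact threshold
  pos <- as.matrix(zz$poses[, c("x", "y", "z")])
  dd <- sqrt(rowSums((pos[inj$row_i, , drop = FALSE] -
                        pos[inj$row_j, , drop = FALSE])^2))
  expect_true(all(dd < 11))

  # infeasible request errors
  expect_error(build_crosslinked_scene(base, "zigzag", fraction = 0.95,
                                       seed = 1), "not geometrically")
})
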