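test_that("distances and angles follow their closed forms", {
  # D by Pythagoras; alpha at collinear and right-angle triples
  poses <- make_poses(rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 5)))
  geo <- compute_geometry(make_scene(poses))
  expect_equal(geo$D[1], 5)
  expect_equal(geo$D[2], 5)
  expect_true(is.na(geo$D[3]))       # last in chain
  expect_equal(geo$alpha[2], 90)
  expect_true(is.na(geo$alpha[1]) && is.na(geo$alpha[3]))

  collinear <- make_poses(rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)))
  expect_equal(compute_geometry(make_scene(collinear))$alpha[2], 180)
})

test_that("plane angles are folded and sign-invariant", {
  n <- rbind(c(0, 0, 1), c(0, 0, -1))
  poses <- make_poses(rbind(c(0, 0, 0), c(10, 0, 0)), normals = n)
  geo <- compute_geometry(make_scene(poses))
  expect_equal(geo$beta[1], 0)       # antiparallel normals: same plane

  sc <- build_scene(linker_preset("PN1"), geometry_preset("PN1"),
                    n_arrays = 3, seed = 8)
  g1 <- compute_geometry(sc)
  flipped <- sc
  flip <- sample(c(-1, 1), nrow(sc$poses), replace = TRUE)
  flipped$poses[, c("nx", "ny", "nz")] <-
    flipped$poses[, c("nx", "ny", "nz")] * flip
  g2 <- compute_geometry(flipped)
  expect_equal(g2$beta, g1$beta, tolerance = 1e-9)
  expect_equal(g2$para, g1$para, tolerance = 1e-9)
  expect_true(all(g1$alpha >= 0 & g1$alpha <= 180, na.rm = TRUE))
  expect_true(all(g1$beta >= 0 & g1$beta <= 90, na.rm = TRUE))
  expect_true(all(g1$para >= 0 & g1$para <= 90, na.rm = TRUE))
})

test_that("nearest-neighbor search equals the exhaustive oracle", {
  set.seed(42)
  for (rep in 1:20) {
    sc <- build_scene(linker_preset(sample(c("PN1", "PN56"), 1)),
                      geometry_preset("PN1"),
                      n_arrays = sample(2:4, 1),
                      array_size_range = c(4, 10),
                      seed = 500 + rep, array_spacing = 60)
    geo <- compute_geometry(sc)
    oracle <- brute_nearest(sc$poses)
    expect_equal(geo$N, oracle$distance, tolerance = 1e-12)
    expect_equal(paste(geo$nearest_array, geo$nearest_index),
                 paste(sc$poses$array_id[oracle$index],
                       sc$poses$nuc_index[oracle$index]))
    # N <= D whenever both are defined
    ok <- !is.na(geo$D)
    expect_true(all(geo$N[ok] <= geo$D[ok] + 1e-12))
  }
})

test_that("exclusion rules drop the right measurements", {
  sc <- build_scene(linker_preset("PN1"), geometry_preset("PN1"),
                    n_arrays = 4, seed = 44)
  geo <- compute_geometry(sc)

  # no flags: identity
  clean <- geo; clean$near_boundary <- FALSE
  clean$linker_to_next_resolved <-
    c(!is.na(clean$D))  # resolved wherever D defined
  ex0 <- apply_exclusions(clean)
  expect_equal(sum(!is.na(ex0$records$D)), sum(!is.na(clean$D)))

  # boundary-flagged nucleosomes disappear entirely
  flagged <- geo
  flagged$near_boundary[seq(1, nrow(flagged), by = 10)] <- TRUE
  ex1 <- apply_exclusions(flagged)
  expect_equal(nrow(ex1$records), sum(!flagged$near_boundary))
  expect_equal(ex1$audit$count[ex1$audit$reason == "near_boundary"],
               sum(flagged$near_boundary))

  # unresolved flanks lose D but keep N and para
  ex2 <- apply_exclusions(geo)
  unres <- !geo$linker_to_next_resolved & !is.na(geo$D)
  expect_true(all(is.na(ex2$records$D[unres])))
  expect_true(all(!is.na(ex2$records$N)))
  expect_true(all(!is.na(ex2$records$para)))
})

test_that("the missing-linker rate shows up in the exclusion audit", {
  sc <- build_scene(linker_preset("PN1"), geometry_preset("PN1"),
                    n_arrays = 60, seed = 4)
  ex <- apply_exclusions(compute_geometry(sc))
  pct <- ex$audit$percent[ex$audit$reason == "unresolved_linker_D"]
  expect_lt(abs(pct - 5.4), 2.5)   # binomial noise at ~600 linkers
})

test_that("stacked-nucleosome fractions honor both thresholds", {
  # one stacked pair (N ~ 6.5 nm, para 10 deg), one close but twisted pair
  p1 <- make_poses(rbind(c(0, 0, 0), c(6.5, 0, 0)),
                   normals = rbind(c(0, 0, 1),
                                   c(0, sin(10 * pi / 180), cos(10 * pi / 180))),
                   array_id = "A001")
  p2 <- make_poses(rbind(c(100, 0, 0), c(106.5, 0, 0)),
                   normals = rbind(c(0, 0, 1),
                                   c(0, sin(40 * pi / 180), cos(40 * pi / 180))),
                   array_id = "A002")
  geo <- compute_geometry(make_scene(p1, p2))
  st <- stacked_fraction(geo, para_max_deg = 25, N_max_nm = 8)
  expect_equal(st$fraction, 0.5)   # both of pair 1, none of pair 2
  expect_true(all(st$pairs$array_id == "A001"))

  empty <- geo[0, ]
  expect_true(is.na(stacked_fraction(empty)$fraction))
})

test_that("group summaries report means, tests and percent change", {
  sc1 <- build_scene(linker_preset("PN1"), geometry_preset("PN1"),
                     n_arrays = 10, seed = 1, sample_id = "PN1")
  rec <- apply_exclusions(compute_geometry(sc1))$records
  both <- rbind(rec, transform(rec, sample_id = "copy"))
  sm <- summarize_stereology(both)
  dD <- sm$tests[sm$tests$descriptor == "D", ]
  expect_equal(dD$percent_change, 0)
  expect_gt(dD$p_welch, 0.99)
  expect_gt(dD$p_ks, 0.99)

  one <- summarize_stereology(rec)
  expect_equal(nrow(one$tests), 0)
  sm1 <- one$summary
  expect_true(all(c("mean", "sd", "n") %in% names(sm1)))
})
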