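test_that("linker discretization matches the representable set", {
  expect_equal(discretize_linker(0), 0L)
  expect_equal(discretize_linker(44), 5L)     # 5 beads = 44.12 bp
  expect_equal(discretize_linker(-12), 0L)    # overlap: zero-linker spring
  expect_equal(discretize_linker(c(17.65, 26.47, 35.29, 114.71)),
               c(2L, 3L, 4L, 13L))
  expect_equal(round(beads_to_bp(4), 2), 35.29)
  expect_equal(round(beads_to_bp(13), 2), 114.71)
})

test_that("ionic conditions set screening and persistence length", {
  p <- set_conditions(energy_params(), 150)
  expect_equal(p$lambda_gen, 0.785, tolerance = 0.002)
  expect_equal(set_conditions(energy_params(), 5)$lambda_gen, 4.30,
               tolerance = 0.005)
  pm <- set_conditions(energy_params(), 150, mg = TRUE)
  expect_equal(pm$lp, 30)
  expect_equal(pm$lambda_dna, 0.4)            # 1 / (2.5 nm^-1)
  expect_equal(pm$lambda_gen, p$lambda_gen)
  lit <- set_conditions(energy_params(mg_literal_lambda = TRUE), 150,
                        mg = TRUE)
  expect_equal(lit$lambda_dna, 2.5)           # sensitivity reading
  expect_error(debye_length(0))
  expect_error(energy_params(not_a_param = 1), "unknown energy parameter")
})

test_that("the initial kinematic configuration is mechanically relaxed", {
  tpl <- build_fiber_template(c(44, 26, 53), lh_per_nucleosome = 1)
  e <- total_energy(tpl, energy_params(charges_on = FALSE))
  expect_equal(e$stretch, 0, tolerance = 1e-9)
  expect_equal(e$bend, 0, tolerance = 1e-9)
  expect_true(is.finite(e$total))
})

test_that("electrostatic component matches an R-side screened-Coulomb oracle", {
  # charge only the linker DNA so the oracle needs no exclusion bookkeeping
  # beyond adjacent linker beads
  par <- set_conditions(energy_params(q_charge = 0, q_face = 0, q_tail = 0,
                                      q_lh = 0), 150)
  tpl <- build_fiber_template(c(44, 44), lh_per_nucleosome = 0)
  fs <- fiber_sites(tpl, par)
  e <- total_energy(tpl, par, positions = fs$positions)

  li <- which(fs$sites$type == "linker")
  pos <- fs$positions[li, , drop = FALSE]
  lid <- fs$sites$linker[li]; rk <- fs$sites$rank[li]
  oracle <- 0
  for (a in seq_along(li)) for (b in seq_along(li)) {
    if (b <= a) next
    if (lid[a] == lid[b] && abs(rk[a] - rk[b]) <= 1) next  # bonded
    r <- sqrt(sum((pos[a, ] - pos[b, ])^2))
    if (r >= par$lambda_dna * par$elec_cutoff_factor) next
    re <- max(r, 0.9 * par$sig_link)           # smeared contact
    oracle <- oracle + par$lB * par$q_link^2 * exp(-re / par$lambda_dna) / re
  }
  expect_equal(e$elec, oracle, tolerance = 1e-9)
})

test_that("salt monotonicity: higher salt never raises DNA-DNA repulsion", {
  par0 <- energy_params(q_charge = 0, q_face = 0, q_tail = 0, q_lh = 0)
  tpl <- build_fiber_template(c(44, 44, 44), lh_per_nucleosome = 0)
  fs <- fiber_sites(tpl, par0)
  elec_at <- function(mM)
    total_energy(tpl, set_conditions(par0, mM), fs$positions)$elec
  e <- vapply(c(5, 25, 75, 150, 300), elec_at, numeric(1))
  expect_true(all(diff(e) <= 1e-9))
})

test_that("overlapping-core templates keep finite energies", {
  expect_warning(tpl <- build_fiber_template(c(-20, 0, 44)), "negative")
  e <- total_energy(tpl, set_conditions(energy_params(), 150))
  expect_true(all(is.finite(unlist(e))))
  ens <- run_mc(tpl, set_conditions(energy_params(), 150),
                mc_settings(burnin_sweeps = 50, n_frames = 3,
                            sweep_interval = 2), seed = 1)
  expect_true(all(is.finite(ens$frame_energy)))
})

test_that("sampling is deterministic and incremental energies are exact", {
  tpl <- build_fiber_template(c(44, 26), lh_per_nucleosome = 1)
  par <- set_conditions(energy_params(), 150)
  st <- mc_settings(burnin_sweeps = 100, n_frames = 5, sweep_interval = 3)
  e1 <- run_mc(tpl, par, st, seed = 11)
  e2 <- run_mc(tpl, par, st, seed = 11)
  expect_identical(e1$frames, e2$frames)       # bit-identical ensemble
  expect_identical(e1$acceptance, e2$acceptance)
  # incremental delta-E bookkeeping equals a full recomputation
  expect_lt(abs(e1$energy_incremental - e1$energy_full),
            1e-8 * (1 + abs(e1$energy_full)))
  expect_error(run_mc(tpl, par, st), "seed is mandatory")
  expect_equal(length(e1$frames), 5)           # size as configured
})

test_that("a tethered bead samples the analytic positional variance", {
  k <- 2.5
  out <- simulate_free_chain(1, tether_k = k, burnin_sweeps = 500,
                             n_frames = 4000, sweep_interval = 3,
                             amp = 0.8, seed = 21)
  xyz <- do.call(rbind, out$frames)
  v <- apply(xyz, 2, var)
  n_eff <- nrow(xyz) / 4                       # correlated samples, roughly
  se <- sqrt(2 / n_eff) * (1 / k)
  expect_true(all(abs(v - 1 / k) < 3 * se))
})

test_that("a free worm-like chain recovers its persistence length", {
  out <- simulate_free_chain(40, l0 = 3, lp = 50, burnin_sweeps = 1000,
                             n_frames = 1500, sweep_interval = 10,
                             amp = 0.35, seed = 5)
  lp_hat <- persistence_length(out$frames, max_sep = 8)
  expect_gt(lp_hat, 45)
  expect_lt(lp_hat, 55)
})
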