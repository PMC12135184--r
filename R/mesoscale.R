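# ---------------------------------------------------------------------------
# Mesoscale chromatin fiber model: templates, energy parameters, Monte Carlo.
# ---------------------------------------------------------------------------

#' Linker-DNA discretization at the mesoscale bead resolution
#'
#' One linker bead subsumes 3.0 nm of DNA = 8.8235 bp; a linker of `bp`
#' base pairs maps to `max(0, round(bp / 8.8235))` beads, so representable
#' lengths are multiples of 8.8235 bp (0, 17.65, 26.47, 35.29, 44.12, ...).
#' Negative lengths (overlapping cores) map to 0 beads; connectivity is then
#' maintained by the zero-linker spring.
#'
#' @param bp signed linker length(s) in bp.
#' @return integer bead count(s).
#' @examples
#' discretize_linker(44)  # 5
#' beads_to_bp(4)         # 35.29
#' @export
discretize_linker <- function(bp) {
  pmax(0L, as.integer(round(bp / .BEAD_BP)))
}

#' @rdname discretize_linker
#' @param beads integer bead count(s).
#' @export
beads_to_bp <- function(beads) beads * .BEAD_BP

#' Build a fiber template for the mesoscale simulator
#'
#' A template fixes the simulated topology: per-linker bead counts (from a
#' linker preset draw or an explicit bp list) and linker-histone occupancy.
#'
#' @param linkers a calibrated [linker_preset()] (linker lengths drawn at
#'   random) or an explicit numeric vector of n-1 linker lengths in bp.
#' @param n_nucleosomes number of cores (>= 2); ignored when `linkers` is an
#'   explicit list.
#' @param lh_per_nucleosome linker-histone occupancy per core in `[0, 1]`
#'   (1 = saturated, one molecule per nucleosome).
#' @param seed optional seed for preset draws.
#' @return object of class `fiber_template`.
#' @export
build_fiber_template <- function(linkers, n_nucleosomes = 23,
                                 lh_per_nucleosome = 1, seed = NULL) {
  if (inherits(linkers, "linker_preset")) {
    stopifnot(n_nucleosomes >= 2)
    bp <- sample_linker_lengths(linkers, n_nucleosomes - 1, seed = seed)
    name <- linkers$name
  } else {
    bp <- as.numeric(linkers)
    n_nucleosomes <- length(bp) + 1
    stopifnot(n_nucleosomes >= 2)
    name <- "explicit"
  }
  if (any(bp < 0))
    warning(sprintf(
      "%d negative linker length(s) mapped to 0 beads (zero-linker spring)",
      sum(bp < 0)))
  beads <- discretize_linker(bp)
  stopifnot(lh_per_nucleosome >= 0, lh_per_nucleosome <= 1)
  lh <- as.integer(round(rep(lh_per_nucleosome, n_nucleosomes)))
  structure(list(name = name, n_cores = n_nucleosomes,
                 linker_bp = bp, linker_beads = beads,
                 zero_linker = beads == 0L, lh = lh),
            class = "fiber_template")
}

#' @export
print.fiber_template <- function(x, ...) {
  cat(sprintf(
    "fiber_template '%s': %d cores; linker beads [%s]; LH/core %.1f\n",
    x$name, x$n_cores, paste(x$linker_beads, collapse = " "),
    mean(x$lh)))
  invisible(x)
}

#' Default mesoscale energy parameters
#'
#' Energies are expressed in kBT (293 K). Phenomenological charges (after
#' counterion condensation): linker-DNA bead -4.2 e; 8 core rim
#' pseudo-charges of -7.5 e (-60 e total, `q_face` patches available but 0
#' by default); histone-tail beads +3 e; linker-histone beads +15 e
#' arranged as two flanking 3-bead rows beside the dyad axis. These are
#' calibration parameters; the defaults are accepted because they
#' reproduce the qualitative salt-dependent folding behavior checked by
#' the test suite (see the methods vignette for the calibration account).
#'
#' @param ... overrides for individual parameters.
#' @return named list of class `energy_params`.
#' @export
energy_params <- function(...) {
  p <- list(
    temperature_K = 293,
    l0 = 3.0,           # DNA bead spacing, nm
    k_dna = 100,        # kBT/nm^2
    k_zero = 50,        # zero-linker spring (3 nm equilibrium)
    k_tail = 10, tail_l0 = 1.5,
    lp = 50,            # DNA persistence length, nm (30 in Mg mode)
    lB = 0.7006,        # Bjerrum length at 293 K, eps_r = 80
    lambda_gen = 0.785, # Debye length, set by set_conditions()
    lambda_dna = 0.785, # DNA-DNA override in Mg mode
    # 12 core pseudo-charges total -60 e: 8 rim sites (q_charge) + 4 face
    # patches (q_face, positive: histone-surface charge anisotropy)
    q_link = -4.2, q_charge = -7.5, q_face = 0, q_tail = 3, q_lh = 15,
    sig_link = 1.8, sig_charge = 2.5, sig_face = 2.0,
    sig_tail = 1.6, sig_lh = 1.0,
    eps_ev = 1.0,
    ev_cap = 30,        # every excluded-volume pair is capped (soft overlap)
    sig_cc = 6.0, cap_cc = 5.0,   # soft core-core term, capped (finite)
    elec_cutoff_factor = 6,
    charges_on = TRUE,
    mg_literal_lambda = FALSE)    # sensitivity switch: read "2.5 nm" literally
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown energy parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  structure(p, class = c("energy_params", "list"))
}

#' Debye screening length of a monovalent salt solution
#'
#' `lambda_D = 0.304 / sqrt(c)` nm with c in mol/L, at 293-298 K in water.
#'
#' @param NaCl_mM monovalent salt concentration in mM.
#' @return screening length in nm.
#' @examples
#' debye_length(150) # 0.785
#' debye_length(5)   # 4.30
#' @export
debye_length <- function(NaCl_mM) {
  stopifnot(NaCl_mM > 0)
  0.304 / sqrt(NaCl_mM / 1000)
}

#' Set the ionic conditions of the energy model
#'
#' Monovalent salt sets the Debye screening length. Implicit 1 mM Mg2+
#' ("Mg mode") additionally strengthens DNA-DNA screening and reduces the
#' DNA persistence length from 50 to 30 nm. The Mg-mode DNA-DNA screening
#' length defaults to 1/(2.5 nm^-1) = 0.4 nm (kappa conventionally denotes
#' the inverse Debye length in this model lineage); set
#' `mg_literal_lambda = TRUE` in [energy_params()] for the literal 2.5-nm
#' reading (sensitivity analysis).
#'
#' @param params an `energy_params` list.
#' @param NaCl_mM monovalent salt (mM), > 0.
#' @param mg logical: implicit 1 mM Mg2+.
#' @return updated `energy_params`.
#' @export
set_conditions <- function(params = energy_params(), NaCl_mM, mg = FALSE) {
  lam <- debye_length(NaCl_mM)
  params$lambda_gen <- lam
  params$lambda_dna <- lam
  if (mg) {
    params$lambda_dna <- if (isTRUE(params$mg_literal_lambda)) 2.5 else 0.4
    params$lp <- 30
  }
  params
}

.template_args <- function(template) {
  list(nbeads = as.integer(template$linker_beads),
       linker_bp = as.numeric(template$linker_bp),
       lh = as.integer(template$lh))
}

#' Total energy of a fiber configuration
#'
#' Recomputes the full energy (kBT) with components: stretch (harmonic
#' bonds incl. zero-linker springs), bend (discrete worm-like chain incl.
#' entry/exit joints), elec / elec_lh (screened Coulomb without / with
#' linker-histone participation), ev (repulsive truncated-shifted 12-6) and
#' ev_core (capped core-core soft term).
#'
#' @param template a `fiber_template`.
#' @param params `energy_params`.
#' @param positions optional site-position matrix (n_sites x 3, nm); the
#'   initial kinematic configuration is used when omitted.
#' @return named list of energy components (kBT), including `total`.
#' @export
total_energy <- function(template, params = energy_params(),
                         positions = NULL) {
  a <- .template_args(template)
  if (is.null(positions)) {
    out <- .cpp_fiber_sites(a$nbeads, a$linker_bp, a$lh, params)
    out$energy
  } else {
    .cpp_fiber_energy(a$nbeads, a$linker_bp, a$lh, params, positions)
  }
}

#' Site table and initial configuration of a template
#' @param template a `fiber_template`.
#' @param params `energy_params`.
#' @return list with `sites` (data.frame) and `positions` (matrix, nm).
#' @export
fiber_sites <- function(template, params = energy_params()) {
  a <- .template_args(template)
  out <- .cpp_fiber_sites(a$nbeads, a$linker_bp, a$lh, params)
  list(sites = out$sites, positions = out$positions)
}

#' Sampler settings for [run_mc()]
#'
#' Defaults are desk-scale: they sample a 23-nucleosome fiber in minutes.
#' Move amplitudes are auto-tuned toward 30-50% acceptance during burn-in
#' only (tuning then freezes, preserving detailed balance during sampling).
#'
#' @param burnin_sweeps sweeps discarded before recording.
#' @param n_frames configurations recorded.
#' @param sweep_interval sweeps between recorded frames.
#' @param amps initial amplitudes: bead displacement (nm), core translation
#'   (nm), core rotation (rad), pivot rotation (rad), tail rotation (rad),
#'   linker crankshaft rotation (rad).
#' @param autotune tune amplitudes during burn-in.
#' @param freeze_cores disable core and pivot moves (validation runs).
#' @param prob_bead,prob_core,prob_pivot,prob_tail move-mixture weights.
#' @return named list.
#' @export
mc_settings <- function(burnin_sweeps = 2000, n_frames = 200,
                        sweep_interval = 10,
                        amps = c(0.35, 0.6, 0.15, 0.12, 0.4, 1.0),
                        autotune = TRUE, freeze_cores = FALSE,
                        prob_bead = 0.83, prob_core = 0.02,
                        prob_pivot = 0.003, prob_tail = 0.1,
                        prob_crank = 0.047) {
  list(burnin_sweeps = as.integer(burnin_sweeps),
       n_frames = as.integer(n_frames),
       sweep_interval = as.integer(sweep_interval),
       amps = as.numeric(amps), autotune = autotune,
       freeze_cores = freeze_cores,
       prob_bead = prob_bead, prob_core = prob_core,
       prob_pivot = prob_pivot, prob_tail = prob_tail,
       prob_crank = prob_crank)
}

#' Metropolis Monte Carlo sampling of a chromatin fiber
#'
#' Moves: local bead displacement, rigid core translation+rotation, pivot
#' rotation of the chain downstream of a random node, and tail-chain
#' rotation; acceptance `min(1, exp(-dE/kBT))`. The same seed and settings
#' give a bit-identical ensemble.
#'
#' @param template a `fiber_template`.
#' @param params `energy_params` (use [set_conditions()] for salt/Mg).
#' @param settings [mc_settings()].
#' @param seed integer seed (mandatory).
#' @return object of class `ensemble`: `frames` (list of n_sites x 3
#'   matrices), `core_frames` (per-frame n_cores x 12: position + rotation
#'   rows), `sites` metadata, acceptance rates and the energy trace.
#' @export
run_mc <- function(template, params = energy_params(),
                   settings = mc_settings(), seed) {
  stopifnot(inherits(template, "fiber_template"))
  if (missing(seed) || is.null(seed)) stop("seed is mandatory for run_mc")
  a <- .template_args(template)
  out <- .cpp_run_mc(a$nbeads, a$linker_bp, a$lh, params, settings,
                     as.numeric(seed))
  acc <- out$acceptance
  if (any(!is.na(acc) & acc < 0.01))
    warning("move acceptance below 1% after auto-tuning: ",
            paste(sprintf("%s=%.3f", names(acc), acc), collapse = ", "))
  structure(list(template = template, params = params, settings = settings,
                 seed = seed,
                 sites = out$sites, frames = out$frames,
                 core_frames = out$core_frames,
                 frame_energy = out$frame_energy,
                 acceptance = acc,
                 energy_incremental = out$energy_incremental,
                 energy_full = out$energy_full),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf(
    "ensemble: %d frames of %d cores (%d sites); seed %s\n  acceptance: %s\n",
    length(x$frames), x$template$n_cores, nrow(x$sites),
    format(x$seed),
    paste(sprintf("%s %.2f", names(x$acceptance), x$acceptance),
          collapse = ", ")))
  invisible(x)
}

#' Run replicate ensembles with a documented seed-splitting rule
#'
#' Replicate r uses seed `master_seed * 1000 + r` (kept below 2^31).
#'
#' @param template,params,settings as in [run_mc()].
#' @param replicates number of replicates.
#' @param master_seed master integer seed.
#' @return list of `ensemble` objects.
#' @export
run_replicates <- function(template, params = energy_params(),
                           settings = mc_settings(), replicates = 20,
                           master_seed) {
  lapply(seq_len(replicates), function(r)
    run_mc(template, params, settings,
           seed = (master_seed * 1000 + r) %% .Machine$integer.max))
}

#' Free-chain / tethered-bead validation sampler
#'
#' A plain bead-spring chain (harmonic stretch, discrete worm-like-chain
#' bending) sampled with the same Metropolis machinery, for which closed
#' forms exist: a single bead tethered by an isotropic spring (`n_beads =
#' 1`, `tether_k > 0`) has positional variance kBT/k per axis; a free chain
#' with persistence length Lp has tangent autocorrelation decaying with
#' contour length at rate 1/Lp.
#'
#' @param n_beads chain length.
#' @param l0 bond length (nm).
#' @param k_stretch bond constant (kBT/nm^2).
#' @param lp persistence length (nm; 0 = flexible).
#' @param tether_k isotropic tether on bead 1 (kBT/nm^2; 0 = none).
#' @param burnin_sweeps,n_frames,sweep_interval,amp sampling controls.
#' @param seed integer seed.
#' @return list with `frames` (list of n_beads x 3 matrices) and
#'   `acceptance`.
#' @export
simulate_free_chain <- function(n_beads, l0 = 3.0, k_stretch = 100,
                                lp = 0, tether_k = 0,
                                burnin_sweeps = 2000, n_frames = 2000,
                                sweep_interval = 5, amp = 0.5, seed) {
  stopifnot(n_beads >= 1)
  .cpp_free_chain_mc(as.integer(n_beads), l0, k_stretch, lp, tether_k,
                     as.integer(burnin_sweeps), as.integer(n_frames),
                     as.integer(sweep_interval), amp, as.numeric(seed))
}

#' Tangent-autocorrelation persistence length of sampled chain frames
#'
#' Fits `<t_i . t_(i+s)> = exp(-s l0 / Lp)` by log-linear regression over
#' separations up to `max_sep`.
#'
#' @param frames list of n_beads x 3 coordinate matrices.
#' @param max_sep largest bond separation used in the fit.
#' @return estimated persistence length (nm).
#' @export
persistence_length <- function(frames, max_sep = 10) {
  tang <- lapply(frames, function(fr) {
    d <- diff(fr)
    d / sqrt(rowSums(d^2))
  })
  nb <- nrow(tang[[1]])
  max_sep <- min(max_sep, nb - 1)
  corr <- vapply(seq_len(max_sep), function(s) {
    mean(vapply(tang, function(tm) {
      mean(rowSums(tm[seq_len(nb - s), , drop = FALSE] *
                     tm[seq_len(nb - s) + s, , drop = FALSE]))
    }, numeric(1)))
  }, numeric(1))
  l0 <- mean(vapply(frames[1], function(fr)
    mean(sqrt(rowSums(diff(fr)^2))), numeric(1)))
  ok <- corr > 0
  fit <- stats::lm(log(corr[ok]) ~ 0 + seq_len(max_sep)[ok])
  -l0 / unname(stats::coef(fit)[1])
}
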