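#' Simulate a steady-state I-V family from the constant-field equation
#'
#' Sums [ghk_current()] over the permeant monovalent cations of the bath
#' and internal solutions at each holding potential, scales to the uA
#' range, and adds i.i.d. Gaussian noise of SD \code{protocol$noise_sd}.
#' The noiseless curve crosses zero exactly at the multi-ion GHK
#' reversal potential, which is recorded as ground truth.
#'
#' @param perms named relative permeabilities (must include every
#'   permeant species present in either solution).
#' @param solution_in,solution_out internal / external [solution_spec()].
#' @param protocol a [protocol_spec()]; supplies the holding potentials
#'   and noise SD.
#' @param seed RNG seed; identical seeds give identical output.
#' @param consts a [phys_constants()].
#' @param current_scale multiplies the raw constant-field current
#'   density into the uA range (instrument/expression scale).
#' @param construct,day,cell labels stored on the curve.
#' @return A list with \code{iv} (an \code{"iv_curve"}) and
#'   \code{ground_truth} (list with \code{E_rev_mV}, \code{perms}).
#' @export
simulate_iv <- function(perms, solution_in, solution_out, protocol,
                        seed = NULL, consts = phys_constants(),
                        current_scale = 2e-8,
                        construct = "WT", day = "day1", cell = "cell1") {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (all(perms == 0)) stop("all permeabilities are zero; nothing permeates")
  if (!is.null(seed)) set.seed(seed)
  E_true <- ghk_reversal(perms, solution_in, solution_out, consts)
  V <- protocol$holding_mV
  I <- vapply(V, function(v) {
    sum(vapply(names(perms), function(ion) {
      ghk_current(v, perms[[ion]], z = 1,
                  c_in = conc_of(solution_in, ion),
                  c_out = conc_of(solution_out, ion), consts = consts)
    }, 0))
  }, 0) * current_scale
  if (protocol$noise_sd > 0)
    I <- I + stats::rnorm(length(I), 0, protocol$noise_sd)
  list(iv = iv_curve(V, I, construct = construct,
                     solution = solution_out$label, day = day,
                     basis = "stationary"),
       ground_truth = list(E_rev_mV = E_true, perms = perms))
}

#' Closed-form biexponential decay fixture
#'
#' Builds a sweep whose current is exactly
#' A1 exp(-t/tau1) + A2 exp(-t/tau2) + offset on the protocol's sample
#' grid (plus optional Gaussian noise) — a known-truth fixture for
#' validating the exponential fitter.  The light window is collapsed to
#' the first few samples so the decay occupies the off segment.
#'
#' @param A1,A2 component amplitudes, uA.
#' @param tau1_ms,tau2_ms component time constants, ms; positive.
#' @param offset constant offset, uA.
#' @param protocol a [protocol_spec()] (sweep length and sample rate).
#' @param noise_sd Gaussian noise SD, uA.
#' @param seed RNG seed.
#' @return A [tevc_trace()].
#' @export
make_biexp_trace <- function(A1, tau1_ms, A2 = 0, tau2_ms = 1,
                             offset = 0, protocol = protocol_spec(),
                             noise_sd = 0, seed = NULL) {
  if (tau1_ms <= 0 || tau2_ms <= 0) stop("time constants must be positive")
  if (!is.null(seed)) set.seed(seed)
  tt <- protocol_times(protocol)
  y <- A1 * exp(-1000 * tt / tau1_ms) + A2 * exp(-1000 * tt / tau2_ms) + offset
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  tevc_trace(times = tt, currents = y, holding_mV = -120,
             light_on = tt[1], light_off = tt[5],
             construct = "fixture", solution = "Na",
             sample_rate_Hz = protocol$sample_rate_Hz)
}

#' Study-design configuration for the synthetic generator
#'
#' Describes a full synthetic TEVC study: constructs with their true
#' excluded-volume pore radii, the alkali solutions, the voltage
#' protocol, photocycle parameters and replication structure.  Each
#' construct's true permeability ratios follow the forward model
#' [predict_ratio()] from its pore radius; WT's default radius of
#' 3.11 A corresponds to a 6.22 A minimum pore diameter.
#'
#' @param constructs named numeric vector of true pore radii R_c (A);
#'   must contain \code{"WT"}.
#' @param ions bath-substituted cations.
#' @param n_cells cells per construct per day.
#' @param days day labels; every day gets its own WT cells so same-day
#'   normalization is always possible.
#' @param protocol a [protocol_spec()].
#' @param photocycle a [photocycle_params()] (shared by all constructs;
#'   mutant-specific kinetics are out of the generator's scope).
#' @param radii ion radius table.
#' @param internal internal [solution_spec()].
#' @param T_K bath temperature, K.
#' @param current_scale constant-field current scale to uA.
#' @param expression_cv lognormal coefficient of variation of per-cell
#'   expression (scales every current of a cell).
#' @return A list of class \code{"study_config"}.
#' @export
study_config <- function(constructs = c(WT = 3.11),
                         ions = c("Li", "Na", "K", "Rb", "Cs"),
                         n_cells = 2, days = "day1",
                         protocol = protocol_spec(),
                         photocycle = photocycle_params(),
                         radii = ion_radii(),
                         internal = oocyte_internal(), T_K = 293.15,
                         current_scale = 2e-8, expression_cv = 0.2) {
  stopifnot(is.numeric(constructs), !is.null(names(constructs)),
            length(ions) >= 1L, n_cells >= 1L)
  if (!"WT" %in% names(constructs))
    stop("the study needs a WT construct as normalization reference")
  if (!"Na" %in% ions) stop("the solution set must include Na (reference)")
  structure(list(constructs = constructs, ions = ions, n_cells = n_cells,
                 days = days, protocol = protocol, photocycle = photocycle,
                 radii = radii, internal = internal, T_K = T_K,
                 current_scale = current_scale, expression_cv = expression_cv),
            class = "study_config")
}

#' Generate a synthetic TEVC study on disk
#'
#' Writes one trace CSV per (construct, day, cell, solution, holding
#' potential), a JSON manifest listing every sweep, and a JSON
#' ground-truth sidecar carrying the true permeabilities, reversal
#' potentials, pore radii and dark off-decay time constants — enough
#' for full parameter-recovery tests of the analysis pipeline.
#'
#' The current of each sweep is the photocycle occupancy envelope
#' (O1 + gamma O2, normalized to its steady state) multiplied by the
#' constant-field steady-state current at that holding potential, so
#' traces show the peak-to-stationary decay under light, biexponential
#' off-decay with the dark-matrix eigenvalue rates, inward
#' rectification, and a zero crossing of the stationary I-V at the GHK
#' reversal potential.
#'
#' @param config a [study_config()].
#' @param seed integer RNG seed; same config + seed gives an identical
#'   directory tree.
#' @param out_dir output directory (created if needed).
#' @return Path to the manifest JSON, invisibly usable by
#'   [load_manifest()].
#' @export
generate_study <- function(config, seed, out_dir) {
  stopifnot(inherits(config, "study_config"))
  set.seed(seed)
  dir.create(file.path(out_dir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  consts <- phys_constants(config$T_K)
  internal <- config$internal
  sols <- alkali_solutions(config$ions)
  proto <- config$protocol

  # shared occupancy envelope: rates are voltage-independent by design
  traj <- simulate_photocycle(config$photocycle, proto)
  open_frac <- traj$O1 + config$photocycle$gamma * traj$O2
  ss <- photocycle_steady_state(config$photocycle)
  open_ss <- ss[2] + config$photocycle$gamma * ss[3]
  envelope <- open_frac / open_ss
  off_rates <- dark_decay_rates(config$photocycle)

  R_Na <- config$radii[["Na"]]
  records <- list()
  truth <- list(seed = seed,
                tau_off_components_ms = as.list(1000 / off_rates),
                constructs = list())
  sigma_ln <- sqrt(log(1 + config$expression_cv^2))

  for (cn in names(config$constructs)) {
    R_c <- config$constructs[[cn]]
    perms <- stats::setNames(
      predict_ratio(R_c, config$radii[config$ions], R_Na), config$ions)
    if (!"Na" %in% names(perms) || any(perms[config$ions] < 0))
      stop("invalid permeability set for ", cn)
    erev_true <- vapply(config$ions, function(ion) {
      ghk_reversal(perms, internal, sols[[ion]], consts)
    }, 0)
    truth$constructs[[cn]] <- list(R_c_A = R_c, d_min_A = 2 * R_c,
                                   perms = as.list(perms),
                                   E_rev_mV = as.list(erev_true))
    for (day in config$days) for (ci in seq_len(config$n_cells)) {
      cell <- sprintf("%s_%s_c%02d", cn, day, ci)
      expr_fac <- stats::rlnorm(1, -sigma_ln^2 / 2, sigma_ln)
      for (ion in config$ions) {
        # stationary constant-field current at each holding potential
        I_ss_V <- vapply(proto$holding_mV, function(v) {
          sum(vapply(names(perms), function(p) {
            ghk_current(v, perms[[p]], z = 1,
                        c_in = conc_of(internal, p),
                        c_out = conc_of(sols[[ion]], p), consts = consts)
          }, 0))
        }, 0) * config$current_scale * expr_fac
        for (k in seq_along(proto$holding_mV)) {
          v <- proto$holding_mV[k]
          y <- envelope * I_ss_V[k]
          if (proto$noise_sd > 0)
            y <- y + stats::rnorm(length(y), 0, proto$noise_sd)
          tr <- tevc_trace(times = traj$time, currents = y, holding_mV = v,
                           light_on = proto$light_on,
                           light_off = proto$light_off,
                           construct = cn, cell_id = cell, day = day,
                           solution = ion,
                           sample_rate_Hz = proto$sample_rate_Hz)
          fn <- sprintf("traces/%s_%s_V%s.csv", cell, ion,
                        gsub("-", "m", as.character(v)))
          write_trace_csv(tr, file.path(out_dir, fn))
          records[[length(records) + 1L]] <- list(
            path = fn, construct = cn, cell_id = cell, day = day,
            solution = ion, holding_mV = v,
            light_on_s = proto$light_on, light_off_s = proto$light_off,
            sample_rate_Hz = proto$sample_rate_Hz)
        }
      }
    }
  }

  manifest <- list(
    format = "chr2pore-manifest-v1",
    seed = seed,
    n_sweeps = length(records),
    ground_truth = "ground_truth.json",
    sweeps = records
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(out_dir, "manifest.json"))
}
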