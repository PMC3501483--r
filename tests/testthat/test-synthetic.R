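test_that("noiseless I-V families return the GHK ground-truth reversal potential", {
  perms <- predict_ratio(3.11, ion_radii(), 0.98)
  proto <- quick_protocol()
  inn <- oocyte_internal()
  for (ion in c("Li", "Na", "Cs")) {
    sim <- simulate_iv(perms, inn, alkali_solutions()[[ion]], proto)
    est <- estimate_erev(sim$iv)
    # 20 mV spacing: piecewise-linear interpolation is good to ~0.5 mV
    expect_lt(abs(est$E_rev_mV - sim$ground_truth$E_rev_mV), 0.5)
    # 2 mV spacing: interpolation error collapses
    fine <- quick_protocol(holding_mV = seq(-120, 60, by = 2))
    simf <- simulate_iv(perms, inn, alkali_solutions()[[ion]], fine)
    estf <- estimate_erev(simf$iv)
    expect_lt(abs(estf$E_rev_mV - simf$ground_truth$E_rev_mV), 0.05)
  }
})

test_that("identical seeds give identical simulated I-V points", {
  perms <- c(Na = 1, K = 0.5)
  proto <- quick_protocol(noise_sd = 0.05)
  inn <- oocyte_internal()
  out <- alkali_solutions("K")$K
  a <- simulate_iv(perms, inn, out, proto, seed = 3)
  b <- simulate_iv(perms, inn, out, proto, seed = 3)
  expect_identical(a$iv$points, b$iv$points)
  c <- simulate_iv(perms, inn, out, proto, seed = 4)
  expect_false(identical(a$iv$points$I_uA, c$iv$points$I_uA))
})

test_that("bi-ionic simulation reproduces the closed-form GHK shift", {
  pc <- phys_constants()
  perms <- c(Na = 1, K = 0.5)
  inn <- solution_spec("in", c(Na = 10, K = 10))
  proto <- quick_protocol()
  na <- simulate_iv(perms, inn, alkali_solutions("Na")$Na, proto)
  kk <- simulate_iv(perms, inn, alkali_solutions("K")$K, proto)
  dE_true <- kk$ground_truth$E_rev_mV - na$ground_truth$E_rev_mV
  expect_equal(dE_true, pc$RT_F * log(0.5), tolerance = 1e-10)  # -17.51 mV
  dE_est <- estimate_erev(kk$iv)$E_rev_mV - estimate_erev(na$iv)$E_rev_mV
  expect_equal(dE_est, dE_true, tolerance = 0.5)
  expect_error(simulate_iv(c(Na = 0, K = 0), inn,
                           alkali_solutions("K")$K, proto), "zero")
})

test_that("biexponential fixtures are exact and the fitter recovers them", {
  proto <- protocol_spec(sample_rate_Hz = 20000, sweep_s = 0.5,
                         light_on = 0, light_off = 0.01)
  # noiseless mono-exponential: machine-precision tau recovery
  tr <- make_biexp_trace(A1 = -2, tau1_ms = 12.1, protocol = proto)
  tt <- tr$times
  expect_equal(tr$currents, -2 * exp(-1000 * tt / 12.1), tolerance = 1e-12)
  fit <- fit_exponential(tr, "off", n_components = 1L)
  expect_true(fit$converged)
  expect_lt(abs(fit$components$tau_ms[1] - 12.1) / 12.1, 1e-6)
  # zero-amplitude trace is the constant offset and flags non-convergence
  tr0 <- make_biexp_trace(0, 5, 0, 50, offset = 0.3, protocol = proto)
  expect_true(all(tr0$currents == 0.3))
  f0 <- fit_exponential(tr0, "off")
  expect_false(f0$converged)
  expect_error(make_biexp_trace(1, -5), "positive")
})

test_that("a minimal study writes the promised files with a faithful sidecar", {
  dir <- withr::local_tempdir()
  cfg <- study_config(constructs = c(WT = 3.11), ions = "Na", n_cells = 1,
                      protocol = quick_protocol(
                        holding_mV = c(-120, -40, 60), sample_rate_Hz = 500),
                      expression_cv = 0)
  generate_study(cfg, seed = 5, out_dir = dir)
  expect_length(list.files(file.path(dir, "traces")), 3L)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(nrow(as.data.frame(man$sweeps)), 3L)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$constructs$WT$d_min_A, 6.22)

  # sidecar permeabilities equal the excluded-volume forward model
  dir2 <- withr::local_tempdir()
  cfg2 <- study_config(constructs = c(WT = 3.11), ions = c("Na", "K", "Rb"),
                       n_cells = 1,
                       protocol = quick_protocol(holding_mV = c(-120, 0, 60),
                                                 sample_rate_Hz = 500),
                       expression_cv = 0)
  generate_study(cfg2, seed = 5, out_dir = dir2)
  gt2 <- jsonlite::read_json(file.path(dir2, "ground_truth.json"),
                             simplifyVector = TRUE)
  rad <- ion_radii()
  want <- ((3.11 - rad[c("Na", "K", "Rb")]) / (3.11 - rad[["Na"]]))^2
  expect_equal(unlist(gt2$constructs$WT$perms), want, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("study generation is deterministic given config and seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  args <- list(constructs = c(WT = 3.11), ions = c("Na", "K"), n_cells = 1,
               protocol = quick_protocol(holding_mV = c(-120, 0, 60),
                                         sample_rate_Hz = 500,
                                         noise_sd = 0.02))
  generate_study(do.call(study_config, args), seed = 9, out_dir = d1)
  generate_study(do.call(study_config, args), seed = 9, out_dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})
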