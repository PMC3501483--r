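test_that("dark-adapted state is absorbing when the light never comes on", {
  p <- photocycle_params()
  traj <- simulate_photocycle(p, quick_protocol(), light_intensity = 0)
  expect_true(all(abs(traj$C1 - 1) < 1e-8))
  expect_true(all(abs(traj$O1) < 1e-8 & abs(traj$O2) < 1e-8 &
                  abs(traj$C2) < 1e-8))
})

test_that("occupancies stay in [0,1] and sum to one for random rate sets", {
  set.seed(7)
  for (i in 1:8) {
    p <- photocycle_params(ka1 = runif(1, 10, 300), ka2 = runif(1, 1, 100),
                           Gd1 = runif(1, 20, 300), Gd2 = runif(1, 10, 150),
                           e12 = runif(1, 1, 50), e21 = runif(1, 0, 10),
                           Gr = runif(1, 0.05, 1), gamma = runif(1, 0.05, 1))
    traj <- simulate_photocycle(p, quick_protocol())
    occ <- as.matrix(traj[, c("C1", "O1", "O2", "C2")])
    expect_lt(max(abs(rowSums(occ) - 1)), 1e-8)
    expect_true(all(occ > -1e-8 & occ < 1 + 1e-8))
  }
})

test_that("long-light occupancies converge to the rate-matrix null space", {
  p <- photocycle_params()
  # long continuous light so the trajectory reaches steady state
  proto <- protocol_spec(light_on = 0.01, light_off = 19.9, sweep_s = 20,
                         sample_rate_Hz = 200)
  traj <- simulate_photocycle(p, proto)
  row <- which.min(abs(traj$time - 19.89))  # just before light-off
  end <- unlist(traj[row, c("C1", "O1", "O2", "C2")])
  # oracle: direct linear solve of A x = 0 with sum(x) = 1
  A <- chr2pore:::photocycle_matrix(p, light = 1)
  x <- solve(rbind(A[1:3, ], rep(1, 4)), c(0, 0, 0, 1))
  expect_equal(unname(end), unname(x), tolerance = 1e-6)
})

test_that("trajectory agrees with an exact matrix-exponential propagator", {
  p <- photocycle_params()
  proto <- quick_protocol()
  traj <- simulate_photocycle(p, proto)
  A_dark <- chr2pore:::photocycle_matrix(p, light = 0)
  A_on <- chr2pore:::photocycle_matrix(p, light = 1)
  # state at light_on is still (1,0,0,0); propagate through the light phase
  for (t_check in c(0.15, 0.3, 0.6)) {
    ref <- as.vector(Matrix::expm(A_on * (t_check - proto$light_on)) %*%
                     c(1, 0, 0, 0))
    row <- which.min(abs(traj$time - t_check))
    expect_equal(unlist(traj[row, c("C1", "O1", "O2", "C2")], use.names = FALSE),
                 ref, tolerance = 1e-6)
  }
  # and across the off transition
  s_off <- as.vector(Matrix::expm(A_on * (proto$light_off - proto$light_on)) %*%
                     c(1, 0, 0, 0))
  ref <- as.vector(Matrix::expm(A_dark * 0.3) %*% s_off)
  row <- which.min(abs(traj$time - (proto$light_off + 0.3)))
  expect_equal(unlist(traj[row, c("C1", "O1", "O2", "C2")], use.names = FALSE),
               ref, tolerance = 1e-6)
})

test_that("off-decay of the photocurrent matches the dark-matrix eigenvalues", {
  p <- photocycle_params()
  trc <- wt_like_trace()
  fit <- fit_exponential(trc, "off", n_components = 2L)
  expect_true(fit$converged)
  fitted_rates <- sort(1000 / fit$components$tau_ms, decreasing = TRUE)
  eig <- dark_decay_rates(p)
  expect_equal(fitted_rates, eig, tolerance = 0.02)
})

test_that("continuous light gives peak >= stationary current when e12 > 0 and gamma < 1", {
  trc <- wt_like_trace()
  s <- summarize_sweep(trc)
  expect_gte(abs(s$I_p), abs(s$I_ss))
  expect_lt(s$Iss_over_Ip, 1)
})

test_that("photocycle_current obeys its sign and null contracts", {
  p <- photocycle_params()
  traj <- simulate_photocycle(p, quick_protocol(), light_intensity = 0)
  # closed channel: zero current at any voltage
  expect_true(all(photocycle_current(traj, p, -120, 7) == 0))
  traj_on <- simulate_photocycle(p, quick_protocol())
  # zero driving force
  expect_true(all(photocycle_current(traj_on, p, 7, 7) == 0))
  # inward (negative) current below E_rev wherever the channel is open
  I <- photocycle_current(traj_on, p, -120, 7)
  open <- traj_on$O1 + traj_on$O2 > 1e-12
  expect_true(all(I[open] < 0))
  expect_true(all(I[!open] == 0))
})

test_that("invalid photocycle inputs are rejected", {
  expect_error(photocycle_params(Gd1 = -5), "non-negative")
  expect_error(photocycle_params(gamma = 0), "gamma")
  expect_error(simulate_photocycle(photocycle_params(), quick_protocol(),
                                   initial = c(0.5, 0, 0, 0)),
               "sum to 1")
})
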