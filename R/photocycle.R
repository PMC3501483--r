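#' Four-state photocycle rate constants
#'
#' Parameters of the four-state ChR2 photocycle with a dark-adapted
#' closed state (C1), an early high-conductance open state (O1), a late
#' lower-conductance open state (O2) and a desensitized closed state
#' (C2).  Light drives C1 -> O1 (rate \code{ka1}) and C2 -> O2
#' (\code{ka2}), both proportional to photon flux; O1 <-> O2
#' interconvert (\code{e12}, \code{e21}); the channels close via
#' O1 -> C1 (\code{Gd1}) and O2 -> C2 (\code{Gd2}); C2 recovers to C1
#' in the dark on a much slower time scale (\code{Gr}).
#'
#' All rates are in 1/s.  \code{gamma} is the conductance of O2 relative
#' to O1 (0 < gamma <= 1); \code{g_max} is the maximal conductance scale
#' in uS.  The defaults are calibrated so that a simulated wild-type
#' trace analysed with [fit_exponential()] reproduces the apparent
#' constants of a typical WT recording (tau_on ~ 4.6 ms, tau_decay
#' ~ 122 ms, tau_off ~ 12.1 ms at -120 mV in Na+).
#'
#' @param ka1,ka2 light-driven activation rates C1->O1 and C2->O2 (1/s,
#'   at unit light intensity).
#' @param Gd1,Gd2 closing rates O1->C1 and O2->C2 (1/s).
#' @param e12,e21 open-state interconversion rates (1/s).
#' @param Gr slow dark recovery C2->C1 (1/s); should be much smaller
#'   than Gd1.
#' @param gamma relative conductance of O2.
#' @param g_max conductance scale, uS.
#' @return A list of class \code{"photocycle_params"}.
#' @export
photocycle_params <- function(ka1 = 77.95, ka2 = 42.08, Gd1 = 105.5,
                              Gd2 = 57.8, e12 = 16.8, e21 = 3.65,
                              Gr = 0.4, gamma = 0.111, g_max = 0.05) {
  rates <- c(ka1 = ka1, ka2 = ka2, Gd1 = Gd1, Gd2 = Gd2,
             e12 = e12, e21 = e21, Gr = Gr)
  if (any(!is.finite(rates))) stop("photocycle rates must be finite")
  if (any(rates < 0)) stop("photocycle rates must be non-negative, got ",
                           paste(names(rates)[rates < 0], collapse = ", "))
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  structure(c(as.list(rates), list(gamma = gamma, g_max = g_max)),
            class = "photocycle_params")
}

# generator matrix for d(C1,O1,O2,C2)/dt = A x ; light scales ka1, ka2
photocycle_matrix <- function(params, light = 1) {
  ka1 <- params$ka1 * light
  ka2 <- params$ka2 * light
  Gd1 <- params$Gd1; Gd2 <- params$Gd2
  e12 <- params$e12; e21 <- params$e21; Gr <- params$Gr
  matrix(c(
    -ka1,         Gd1,           0,             Gr,
     ka1,        -(Gd1 + e12),   e21,           0,
     0,           e12,          -(Gd2 + e21),   ka2,
     0,           0,             Gd2,          -(ka2 + Gr)),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("C1", "O1", "O2", "C2"), c("C1", "O1", "O2", "C2")))
}

#' Integrate the four-state photocycle over a light-step protocol
#'
#' Solves the linear ODE system for the state occupancies with the light
#' switched on during \code{[light_on, light_off)}.  Integration uses an
#' adaptive stiff-capable solver (lsoda) restarted at the two light
#' transitions so the discontinuity never crosses a solver step.
#'
#' @param params a [photocycle_params()] object.
#' @param protocol a [protocol_spec()]; only the light window, duration
#'   and sample rate are used.
#' @param initial occupancy 4-vector (C1, O1, O2, C2); must sum to 1.
#' @param light_intensity scalar photon-flux factor multiplying ka1, ka2.
#' @return A data.frame of class \code{"state_trajectory"} with columns
#'   \code{time}, \code{C1}, \code{O1}, \code{O2}, \code{C2}.
#' @examples
#' tr <- simulate_photocycle(photocycle_params(), protocol_spec())
#' max(abs(rowSums(tr[, c("C1", "O1", "O2", "C2")]) - 1))  # conservation
#' @export
simulate_photocycle <- function(params, protocol,
                                initial = c(1, 0, 0, 0),
                                light_intensity = 1) {
  stopifnot(inherits(params, "photocycle_params"),
            inherits(protocol, "protocol_spec"))
  if (length(initial) != 4L || any(initial < -1e-12))
    stop("initial must be a non-negative occupancy 4-vector")
  if (abs(sum(initial) - 1) > 1e-8)
    stop("initial occupancies must sum to 1, got ", sum(initial))

  times <- protocol_times(protocol)
  segs <- list(
    dark1 = c(0, protocol$light_on),
    light = c(protocol$light_on, protocol$light_off),
    dark2 = c(protocol$light_off, protocol$sweep_s)
  )
  lights <- c(0, light_intensity, 0)

  state <- c(C1 = initial[1], O1 = initial[2], O2 = initial[3], C2 = initial[4])
  eps_t <- 0.25 / protocol$sample_rate_Hz
  taken <- rep(FALSE, length(times))
  rows <- vector("list", 3L)
  for (i in seq_along(segs)) {
    lo <- segs[[i]][1]; hi <- segs[[i]][2]
    in_seg <- !taken & times >= lo - eps_t & times <= hi + eps_t
    taken <- taken | in_seg
    tt <- times[in_seg]
    # integrate across the full segment so the handoff state is exact,
    # padding the endpoints only when a sample does not already sit there
    grid <- tt
    pre <- 0L
    if (!length(grid) || grid[1] > lo + eps_t) { grid <- c(lo, grid); pre <- 1L }
    if (grid[length(grid)] < hi - eps_t) grid <- c(grid, hi)
    A <- photocycle_matrix(params, light = lights[i])
    if (length(grid) >= 2L) {
      sol <- deSolve::lsoda(
        y = state, times = grid,
        func = function(t, y, p) list(as.vector(A %*% y)),
        parms = NULL, rtol = 1e-8, atol = 1e-10
      )
      state <- sol[nrow(sol), c("C1", "O1", "O2", "C2")]
      rows[[i]] <- sol[pre + seq_along(tt), -1, drop = FALSE]
    } else {
      rows[[i]] <- matrix(state, nrow = length(tt), ncol = 4, byrow = TRUE,
                          dimnames = list(NULL, names(state)))
    }
  }
  out <- data.frame(time = times[taken], do.call(rbind, rows))
  names(out) <- c("time", "C1", "O1", "O2", "C2")
  class(out) <- c("state_trajectory", "data.frame")
  out
}

#' Eigenvalue decay rates of the dark open-state subsystem
#'
#' After light-off the two open states relax as
#' d(O1,O2)/dt = M (O1,O2) with
#' M = [ -(Gd1+e12), e21 ; e12, -(Gd2+e21) ]; the photocurrent off-decay
#' is therefore a sum of two exponentials whose rate constants are the
#' negated eigenvalues of M.  Used as the analytic reference for the
#' off-segment biexponential fit.
#'
#' @param params a [photocycle_params()] object.
#' @return Numeric vector of the two positive decay rates (1/s), sorted
#'   decreasing (fast first).
#' @export
dark_decay_rates <- function(params) {
  M <- matrix(c(-(params$Gd1 + params$e12), params$e21,
                params$e12, -(params$Gd2 + params$e21)),
              nrow = 2, byrow = TRUE)
  sort(-eigen(M, only.values = TRUE)$values, decreasing = TRUE)
}

#' Photocurrent from a state trajectory
#'
#' I(t) = g_max (V - E_rev) (O1 + gamma O2) / 1000, with g_max in uS,
#' potentials in mV and current in uA.  Ohmic driving force; the
#' constant-field (rectifying) voltage dependence used by the study
#' generator lives in [simulate_iv()] / [generate_study()].
#'
#' @param traj a [simulate_photocycle()] trajectory.
#' @param params a [photocycle_params()] object.
#' @param V_mV holding potential, mV.
#' @param E_rev_mV reversal potential, mV.
#' @return Numeric current vector (uA), one value per trajectory row.
#' @export
photocycle_current <- function(traj, params, V_mV, E_rev_mV) {
  stopifnot(inherits(traj, "state_trajectory"),
            inherits(params, "photocycle_params"),
            is.finite(V_mV), is.finite(E_rev_mV))
  params$g_max * (V_mV - E_rev_mV) * (traj$O1 + params$gamma * traj$O2) / 1000
}

# open-state steady state under continuous light, by direct linear solve:
# null space of A augmented with the conservation constraint
photocycle_steady_state <- function(params, light = 1) {
  A <- photocycle_matrix(params, light = light)
  B <- rbind(A[1:3, ], rep(1, 4))
  as.vector(solve(B, c(0, 0, 0, 1)))
}
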