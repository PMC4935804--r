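#' Model derivatives (reference implementation)
#'
#' Time derivative of the full model state at time `t`. This is a plain-R
#' transcription of the compiled right-hand side used by the integrator; it
#' exists as the readable reference form and for direct assertions on
#' instantaneous fluxes.
#'
#' @param state named numeric vector over the model species (see
#'   [steady_state()] for the naming).
#' @param t time (min).
#' @param params parameter list ([nfkb_params()]).
#' @param protocol an `nfkb_protocol`.
#' @return Named numeric vector of derivatives (molecules/min).
#' @export
nfkb_derivatives <- function(state, t, params, protocol) {
  if (any(state < 0)) stop("negative state component")
  s <- as.list(state)
  p <- params
  IKKKn_T <- max(0, p$IKKKtott_T - s$IKKKa_T - s$IKKKi_T)
  IKKKn_I <- max(0, p$IKKKtott_I - s$IKKKa_I - s$IKKKi_I)
  IKKn <- max(0, p$IKKtot - s$IKKa - s$IKKi)
  inh_T <- p$kA20_T / (p$kA20_T + s$A20)
  inh_I <- p$kA20_I / (p$kA20_I + s$A20)
  ra_T <- p$ka_T * receptor_signal(protocol, t, "TNF", p) * IKKKn_T * inh_T
  ra_I <- p$ka_I * receptor_signal(protocol, t, "IL1", p) * IKKKn_I * inh_I
  KKa <- s$IKKKa_T + s$IKKKa_I
  hikk <- KKa^p$hill_ikk / (p$sIKKK^p$hill_ikk + KKa^p$hill_ikk)
  hN <- s$NFKBn^p$hill_tr / (p$KN^p$hill_tr + s$NFKBn^p$hill_tr)
  drive <- p$b0 + (1 - p$b0) * hN
  assoc_c <- p$kb * s$NFKBc * s$IkBc
  assoc_n <- p$kb * s$NFKBn * s$IkBn
  deg_free <- p$kc2 * s$IKKa * s$IkBc / (p$Km_ikk + s$IkBc)
  rel_c <- p$kc1 * s$IKKa * s$Cc / (p$Km_ikk + s$Cc) + p$c5 * s$Cc
  c(IKKKa_T = ra_T - p$ki * s$IKKKa_T,
    IKKKi_T = p$ki * s$IKKKa_T - p$m3 * s$IKKKi_T,
    IKKKa_I = ra_I - p$ki * s$IKKKa_I,
    IKKKi_I = p$ki * s$IKKKa_I - p$m3 * s$IKKKi_I,
    IKKa = p$kact * IKKn * hikk - p$k1 * s$IKKa,
    IKKi = p$k1 * s$IKKa - p$k4 * s$IKKi,
    RmI = p$c1a * drive - p$c3a * s$RmI,
    RmA = p$c1 * drive - p$c3 * s$RmA,
    A20 = p$c2 * s$RmA - p$c4 * s$A20,
    IkBc = p$c2a * s$RmI - p$c4a * s$IkBc - deg_free -
      assoc_c + p$eI * s$IkBn - p$iI * s$IkBc,
    IkBn = p$iI * s$IkBc - p$eI * s$IkBn - p$c4a * s$IkBn - assoc_n,
    NFKBc = rel_c - assoc_c - p$iN * s$NFKBc,
    NFKBn = p$iN * s$NFKBc - assoc_n,
    Cc = assoc_c + p$eC * s$Cn - rel_c,
    Cn = assoc_n - p$eC * s$Cn)
}

.empty_protocol <- function(t_end = 300) nfkb_protocol(NULL, t_end = t_end)

.ode <- function(y, times, params, protocol, gate = c(1, 1),
                 boost = c(0, 0), rtol = 1e-8, atol = 1e-4) {
  pv <- .parms_vector(params, protocol, gate = gate, boost = boost)
  ev <- if (nrow(protocol$pulses)) {
    # restart the integrator at pulse edges so short pulses are never
    # stepped over by the adaptive solver
    e <- sort(unique(c(protocol$pulses$start,
                       protocol$pulses$start + protocol$pulses$duration)))
    e[e > min(times) & e < max(times)]
  } else numeric(0)
  solver_times <- sort(unique(c(times, ev)))
  out <- deSolve::lsoda(
    y = y, times = solver_times, func = "nfkb_derivs", parms = pv,
    dllname = "nfkbpulse", initfunc = "nfkb_initmod",
    rtol = rtol, atol = atol, maxsteps = 50000,
    events = if (length(ev)) list(
      data = data.frame(var = .state_names[1], time = ev,
                        value = 0, method = "add")) else NULL)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed (istate = ", attr(out, "istate")[1], ")")
  # event times not on the requested grid are added to the output by the
  # solver; return exactly the requested sample times
  idx <- match(round(times, 9), round(out[, "time"], 9))
  out[idx, , drop = FALSE]
}

#' Unstimulated steady state
#'
#' Finds the resting fixed point of the model by pre-equilibration from a
#' generic initial condition (all NF-kB complexed in the cytoplasm), then
#' verifies that the derivative norm is below tolerance.
#'
#' @param params parameter list.
#' @param t_eq equilibration horizon (min), default 2000.
#' @param tol relative derivative tolerance for acceptance.
#' @return Named state vector at rest.
#' @export
steady_state <- function(params, t_eq = 2000, tol = 1e-6) {
  validate_params(params)
  y0 <- setNames(numeric(length(.state_names)), .state_names)
  y0["Cc"] <- params$nfkbtot
  y0["IkBc"] <- 0.1 * params$nfkbtot
  prot <- .empty_protocol(t_eq)
  out <- .ode(y0, c(0, t_eq / 2, t_eq), params, prot)
  y <- out[nrow(out), .state_names]
  d <- nfkb_derivatives(pmax(y, 0), t_eq, params, prot)
  scale <- pmax(abs(y), 1)
  if (max(abs(d) / scale) > tol * 1e3)  # molecules/min vs molecule scale
    stop("steady state not reached: max scaled derivative ",
         signif(max(abs(d) / scale), 3))
  pmax(y, 0)
}

#' Simulate one cell
#'
#' Integrates the model from the unstimulated steady state under a pulse
#' protocol and returns a trajectory sampled on a uniform grid, with derived
#' observables (nuclear NF-kB fraction, total IkBa, A20 protein).
#'
#' @param params parameter list ([nfkb_params()]).
#' @param protocol an `nfkb_protocol`.
#' @param dt_out output step (min), default 1.
#' @param y0 optional initial state (defaults to [steady_state()]).
#' @param check_conservation verify closed totals at every sample
#'   (relative tolerance 1e-6).
#' @return `nfkb_trajectory`: list with `time`, `states` (matrix), and
#'   observables `nfkb_nuclear_fraction`, `total_ikba`, `a20_protein`.
#' @export
simulate_cell <- function(params, protocol, dt_out = 1, y0 = NULL,
                          check_conservation = TRUE) {
  if (!is.finite(protocol$t_end)) stop("protocol t_end must be finite")
  if (is.null(y0)) y0 <- steady_state(params)
  times <- seq(0, protocol$t_end, by = dt_out)
  out <- .ode(y0, times, params, protocol)
  st <- out[, .state_names, drop = FALSE]
  traj <- .new_trajectory(times, st, params, protocol)
  if (check_conservation) .check_conservation(traj, params)
  traj
}

.new_trajectory <- function(times, states, params, protocol) {
  structure(list(
    time = times,
    states = states,
    nfkb_nuclear_fraction =
      (states[, "NFKBn"] + states[, "Cn"]) / params$nfkbtot,
    total_ikba = states[, "IkBc"] + states[, "IkBn"] +
      states[, "Cc"] + states[, "Cn"],
    a20_protein = states[, "A20"],
    params = params, protocol = protocol),
    class = "nfkb_trajectory")
}

.check_conservation <- function(traj, params, rel_tol = 1e-6) {
  st <- traj$states
  nf <- st[, "NFKBc"] + st[, "NFKBn"] + st[, "Cc"] + st[, "Cn"]
  ikk <- st[, "IKKa"] + st[, "IKKi"]
  kkT <- st[, "IKKKa_T"] + st[, "IKKKi_T"]
  kkI <- st[, "IKKKa_I"] + st[, "IKKKi_I"]
  err <- max(abs(nf / params$nfkbtot - 1),
             abs(pmax(ikk - params$IKKtot, 0)) / params$IKKtot,
             abs(pmax(kkT - params$IKKKtott_T, 0)) / params$IKKKtott_T,
             abs(pmax(kkI - params$IKKKtott_I, 0)) / params$IKKKtott_I)
  if (err > rel_tol)
    stop("conservation violated: relative error ", signif(err, 3))
  invisible(TRUE)
}

#' @export
print.nfkb_trajectory <- function(x, ...) {
  cat("<nfkb_trajectory>", length(x$time), "samples,",
      "t = [", min(x$time), ",", max(x$time), "] min\n")
  invisible(x)
}

#' Convert a trajectory to a data frame
#'
#' @param x an `nfkb_trajectory`.
#' @param row.names,optional,... standard [as.data.frame()] arguments.
#' @return Data frame with `time_min`, all species, and the observables.
#' @export
as.data.frame.nfkb_trajectory <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(time_min = x$time, x$states,
             nfkb_nuclear_fraction = x$nfkb_nuclear_fraction,
             total_ikba = x$total_ikba,
             a20_protein = x$a20_protein)
}
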