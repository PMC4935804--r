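#' Population specification
#'
#' Describes a heterogeneous cell population: extrinsic noise (parameters
#' drawn once per cell from stated distributions, then fixed — the imprinted
#' cell state) or intrinsic noise (stochastic on/off switching of the IkBa
#' and A20 feedback genes within each cell).
#'
#' @param n_cells number of cells (>= 1).
#' @param noise_mode `"extrinsic"` or `"intrinsic"`.
#' @param distributed named list: parameter name -> list(mean, sd,
#'   family = "normal_truncated" or "lognormal"). Ignored entries with
#'   sd = 0 reproduce the base value.
#' @param gene_switch_rates list with `kon`, `koff` (per min), used in
#'   intrinsic mode; `kon` scales the NF-kB-dependent on-switch propensity.
#' @param seed RNG seed for reproducible sampling.
#' @return `nfkb_population_spec`.
#' @export
population_spec <- function(n_cells, noise_mode = c("extrinsic", "intrinsic"),
                            distributed = list(),
                            gene_switch_rates = list(kon = 0.2, koff = 0.1),
                            seed = NULL) {
  noise_mode <- match.arg(noise_mode)
  if (n_cells < 1) stop("n_cells must be >= 1")
  for (d in distributed) {
    if (is.null(d$sd) || d$sd < 0) stop("distributed sd must be >= 0")
  }
  structure(list(n_cells = as.integer(n_cells), noise_mode = noise_mode,
                 distributed = distributed,
                 gene_switch_rates = gene_switch_rates, seed = seed),
            class = "nfkb_population_spec")
}

#' Convenience spec: all rates distributed at sd = 0.3 mean
#'
#' The all-parameter extrinsic-noise mode: every kinetic rate drawn from a
#' truncated normal with mean at its nominal value and sd = `cv` times the
#' mean. Structural constants (totals are distributed; Hill coefficients,
#' dose constants and washout are not).
#'
#' @param base base parameters.
#' @param cv coefficient of variation, default 0.3.
#' @param n_cells,seed passed to [population_spec()].
#' @return `nfkb_population_spec`.
#' @export
all_param_spec <- function(base = nfkb_params(), cv = 0.3, n_cells = 100,
                           seed = NULL) {
  skip <- c("hill_tr", "hill_ikk", "Kd_T", "hd_T", "Kd_I", "hd_I",
            "tau_w", "b0")
  nm <- setdiff(names(base), skip)
  dist <- lapply(nm, function(n) list(mean = base[[n]], sd = cv * base[[n]],
                                      family = "normal_truncated"))
  names(dist) <- nm
  population_spec(n_cells, "extrinsic", dist, seed = seed)
}

.rtruncnorm0 <- function(n, mean, sd) {
  # normal truncated at 0 via inverse-CDF on the admissible quantile range
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Sample a heterogeneous population
#'
#' Draws per-cell parameter overrides according to the population spec. Each
#' cell's overrides are drawn once and fixed (imprinting); daughter cells in
#' the synthetic-data module copy them. When the TNF-branch IKKK total is
#' distributed and `tie_branches` is `TRUE` (default), the IL-1 branch total
#' is scaled by the same relative deviation: the transduction capacity is
#' treated as one imprinted cell state shared by both branches.
#'
#' @param spec an `nfkb_population_spec`.
#' @param base base parameters ([nfkb_params()]).
#' @param tie_branches scale `IKKKtott_I` with the cell's `IKKKtott_T` draw.
#' @return List of cell specs: `list(cell_id, overrides)`.
#' @export
sample_population <- function(spec, base = nfkb_params(),
                              tie_branches = TRUE) {
  bad <- setdiff(names(spec$distributed), names(base))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_cells
  draws <- lapply(names(spec$distributed), function(nm) {
    d <- spec$distributed[[nm]]
    if (d$sd == 0) return(rep(d$mean, n))
    fam <- if (is.null(d$family)) "normal_truncated" else d$family
    switch(fam,
      normal_truncated = .rtruncnorm0(n, d$mean, d$sd),
      lognormal = stats::rlnorm(n, meanlog = log(d$mean) -
                                  0.5 * log(1 + (d$sd / d$mean)^2),
                                sdlog = sqrt(log(1 + (d$sd / d$mean)^2))),
      stop("unknown family: ", fam))
  })
  names(draws) <- names(spec$distributed)
  lapply(seq_len(n), function(i) {
    ov <- lapply(draws, `[`, i)
    if (tie_branches && "IKKKtott_T" %in% names(ov) &&
        !"IKKKtott_I" %in% names(ov)) {
      ov$IKKKtott_I <- base$IKKKtott_I * ov$IKKKtott_T / base$IKKKtott_T
    }
    list(cell_id = i, overrides = ov)
  })
}

.cell_params <- function(base, cell) {
  p <- base
  if (length(cell$overrides)) p[names(cell$overrides)] <- cell$overrides
  p
}

#' Simulate every cell of a population
#'
#' Extrinsic mode is deterministic per cell: the same cell spec and protocol
#' always give the identical trajectory.
#'
#' @param cells list of cell specs from [sample_population()].
#' @param protocol an `nfkb_protocol`.
#' @param base base parameters.
#' @param dt_out output step (min).
#' @return List of `nfkb_trajectory`, one per cell.
#' @export
run_population <- function(cells, protocol, base = nfkb_params(),
                           dt_out = 1) {
  if (!length(cells)) stop("empty population")
  # the resting state does not involve the IKKK totals (active/inactive
  # pools are empty at rest), so populations that only vary those share
  # one pre-equilibration
  ov <- unique(unlist(lapply(cells, function(cl) names(cl$overrides))))
  y0 <- if (all(ov %in% c("IKKKtott_T", "IKKKtott_I")))
    steady_state(base) else NULL
  lapply(cells, function(cell) {
    tryCatch(
      simulate_cell(.cell_params(base, cell), protocol, dt_out = dt_out,
                    y0 = y0),
      error = function(e) stop("cell ", cell$cell_id, ": ",
                               conditionMessage(e)))
  })
}

#' Hybrid intrinsic-noise simulation of one cell
#'
#' The IkBa and A20 feedback genes follow a two-state telegraph process:
#' the on-switch propensity is `kon` scaled by the NF-kB-dependent
#' transcriptional occupancy, the off-switch propensity is the constant
#' `koff`. While a gene is on it transcribes at rate
#' `c1 * (occupancy + koff/kon)`; the additive term exactly compensates
#' for the fraction of time spent off, so the quasi-static mean
#' transcription equals the deterministic rate at every occupancy, and
#' both limits reduce to the ODE (fast switching, or `koff = 0` with the
#' gene on). Between switching events the species are integrated
#' deterministically; switching is sampled on a fine grid
#' (piecewise-constant hazard).
#'
#' @param params cell parameters.
#' @param protocol an `nfkb_protocol`.
#' @param rates list(kon, koff) per minute; `kon` must be > 0 (a `koff` of
#'   exactly 0 with genes starting on reproduces the deterministic model).
#' @param seed RNG seed.
#' @param dt_out output step (min).
#' @param dt_switch switching-grid step (min), default 1.
#' @return `nfkb_trajectory` (with attribute `gene_states`).
#' @export
simulate_cell_intrinsic <- function(params, protocol,
                                    rates = list(kon = 0.2, koff = 0.1),
                                    seed = NULL, dt_out = 1,
                                    dt_switch = 1) {
  if (rates$kon <= 0 || rates$koff < 0) stop("switch rates must be positive")
  if (!is.null(seed)) set.seed(seed)
  y <- steady_state(params)
  occ0 <- .tx_occupancy(y[["NFKBn"]], params)
  p_on0 <- rates$kon * occ0 / (rates$kon * occ0 + rates$koff)
  boost <- if (rates$koff > 0) rates$koff / rates$kon else 0
  gate <- c(I = stats::runif(1) < p_on0, A = stats::runif(1) < p_on0) * 1
  if (rates$koff == 0) gate <- c(1, 1)
  grid <- seq(0, protocol$t_end, by = dt_switch)
  times_out <- seq(0, protocol$t_end, by = dt_out)
  st <- matrix(NA_real_, nrow = length(times_out), ncol = length(.state_names),
               dimnames = list(NULL, .state_names))
  st[1, ] <- y
  gs <- matrix(NA_real_, nrow = length(grid), ncol = 2)
  gs[1, ] <- gate
  for (k in seq_len(length(grid) - 1)) {
    seg <- c(grid[k], grid[k + 1])
    keep <- which(times_out > seg[1] & times_out <= seg[2])
    tt <- sort(unique(c(seg, times_out[keep])))
    out <- .ode(y, tt, params, protocol, gate = gate,
                boost = c(boost, boost))
    y <- pmax(out[nrow(out), .state_names], 0)
    if (length(keep))
      st[keep, ] <- out[match(times_out[keep], out[, "time"]),
                        .state_names]
    occ <- .tx_occupancy(y[["NFKBn"]], params)
    for (g in 1:2) {
      a <- if (gate[g] == 1) rates$koff else rates$kon * occ
      if (stats::runif(1) < 1 - exp(-a * dt_switch)) gate[g] <- 1 - gate[g]
    }
    gs[k + 1, ] <- gate
  }
  traj <- .new_trajectory(times_out, st, params, protocol)
  attr(traj, "gene_states") <- gs
  traj
}

# NF-kB-dependent transcriptional occupancy (basal + Hill term), the same
# drive that multiplies c1/c1a in the deterministic model
.tx_occupancy <- function(nn, params) {
  nn <- max(nn, 0)
  h <- nn^params$hill_tr / (params$KN^params$hill_tr + nn^params$hill_tr)
  params$b0 + (1 - params$b0) * h
}

#' Quantile calibration of the IKKK distribution
#'
#' For each pulse interval, finds by bisection the minimal TNF-branch total
#' IKKK for which a cell responds to the second pulse of a two-pulse TNF
#' protocol (15% net nuclear translocation rule), then fits the standard
#' deviation of a zero-truncated normal IKKK distribution with fixed mean
#' `mu` so that the upper-tail probabilities beyond those thresholds match
#' the measured responder fractions.
#'
#' @param fractions named numeric: interval (min, as names) -> measured
#'   fraction responding; must be non-decreasing in the interval.
#' @param base base parameters (defines all other rates).
#' @param mu mean total IKKK (molecules), default 1e6.
#' @param dose,duration pulse dose (ng/ml) and duration (min).
#' @param theta_tol bisection tolerance as a fraction of `mu`.
#' @param bracket search bracket as multiples of `mu`.
#' @return List: `sigma` (fitted sd), `thresholds` (per interval),
#'   `achieved` (tail probabilities at the fit), `target`, `degenerate`.
#' @export
calibrate_ikkk_distribution <- function(fractions, base = nfkb_params(),
                                        mu = 1e6, dose = 10, duration = 5,
                                        theta_tol = 1e-3,
                                        bracket = c(0.01, 100)) {
  iv <- as.numeric(names(fractions))
  if (anyNA(iv)) stop("fractions must be named by interval (min)")
  o <- order(iv)
  iv <- iv[o]; fr <- unname(fractions[o])
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  if (is.unsorted(fr)) stop("fractions must be non-decreasing in interval")
  thr <- vapply(iv, function(d)
    response_threshold(d, base, mu = mu, dose = dose, duration = duration,
                       theta_tol = theta_tol, bracket = bracket),
    numeric(1))
  names(thr) <- iv
  if (all(fr == 1)) {
    return(list(sigma = NA_real_, thresholds = thr, achieved = fr,
                target = stats::setNames(fr, iv), degenerate = TRUE))
  }
  tail_p <- function(sigma) {
    (1 - stats::pnorm(thr, mu, sigma)) / (1 - stats::pnorm(0, mu, sigma))
  }
  obj <- function(sigma) sum((tail_p(sigma) - fr)^2)
  fit <- stats::optimize(obj, interval = c(1e-3 * mu, 2 * mu))
  list(sigma = fit$minimum, thresholds = thr,
       achieved = stats::setNames(tail_p(fit$minimum), iv),
       target = stats::setNames(fr, iv), degenerate = FALSE)
}

#' Minimal responding IKKK total for a second pulse
#'
#' Bisection for the response threshold theta(interval): the smallest
#' TNF-branch total IKKK at which the cell passes the 15% net-translocation
#' rule at the second pulse. The IL-1 branch total is scaled with the same
#' relative deviation (shared transduction state).
#'
#' @param interval pulse interval (min).
#' @param base base parameters.
#' @param mu reference mean IKKK for the bracket/tolerance scale.
#' @param pulse2_cytokine cytokine of the second pulse (default TNF).
#' @param pulse1_cytokine cytokine of the first pulse (default TNF).
#' @inheritParams calibrate_ikkk_distribution
#' @return Threshold (molecules).
#' @export
response_threshold <- function(interval, base = nfkb_params(), mu = 1e6,
                               dose = 10, duration = 5, theta_tol = 1e-3,
                               bracket = c(0.01, 100),
                               pulse2_cytokine = "TNF",
                               pulse1_cytokine = "TNF") {
  prot <- nfkb_protocol(data.frame(
    start = c(0, interval), duration = duration,
    cytokine = c(pulse1_cytokine, pulse2_cytokine), dose = dose),
    t_end = interval + 100)
  responds <- function(tott) {
    p <- base
    p$IKKKtott_I <- base$IKKKtott_I * tott / base$IKKKtott_T
    p$IKKKtott_T <- tott
    traj <- simulate_cell(p, prot)
    classify_responder_model(traj, interval)$responder
  }
  # coarse ascending scan first: at extreme IKKK the first response grows
  # so large (A20 carry-over) that the responder map need not stay
  # monotone, so bisect inside the first upward crossing
  grid <- mu * sort(unique(c(bracket[1], 0.1, 0.25, 0.5, 0.75, 1, 1.25,
                             1.5, 2, 3, bracket[2])))
  grid <- grid[grid >= bracket[1] * mu & grid <= bracket[2] * mu]
  calls <- vapply(grid, responds, logical(1))
  if (calls[1]) return(grid[1])
  if (!any(calls))
    stop("response threshold not bracketed in [", grid[1], ", ",
         grid[length(grid)], "]")
  i <- which(calls)[1]
  lo <- grid[i - 1]; hi <- grid[i]
  while ((hi - lo) > theta_tol * mu) {
    mid <- (lo + hi) / 2
    if (responds(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Calibrated population responder fraction
#'
#' Samples `n` cells with the TNF-branch IKKK total drawn from the
#' calibrated zero-truncated normal, simulates the given two-pulse
#' protocol, and reports the fraction responding to the second pulse.
#'
#' @param sigma fitted IKKK sd (from [calibrate_ikkk_distribution()]).
#' @param protocol an `nfkb_protocol` whose second pulse is probed.
#' @param n number of cells, default 300.
#' @param base base parameters.
#' @param mu mean IKKK.
#' @param seed RNG seed.
#' @return List: `fraction`, `n`, `calls` (logical), `cells`.
#' @export
population_response <- function(sigma, protocol, n = 300,
                                base = nfkb_params(), mu = 1e6,
                                seed = NULL) {
  spec <- population_spec(n, "extrinsic", distributed = list(
    IKKKtott_T = list(mean = mu, sd = sigma, family = "normal_truncated")),
    seed = seed)
  cells <- sample_population(spec, base)
  p2 <- protocol$pulses$start[min(2, nrow(protocol$pulses))]
  trajs <- run_population(cells, protocol, base)
  calls <- vapply(trajs, function(tr)
    classify_responder_model(tr, p2)$responder, logical(1))
  list(fraction = mean(calls), n = n, calls = calls, cells = cells)
}

#' Equilibrated four-pulse experiment
#'
#' Four pulses: a pair at interval `delta`, an equilibration gap, then the
#' same pair again (starts 0, delta, delta + gap, delta + gap + delta).
#' Returns per-cell responder calls for pulses 2 and 4; the discordant
#' fraction distinguishes extrinsic (exactly reproducible, 0 discordant)
#' from intrinsic noise (positive discordance).
#'
#' @param cells population cell specs.
#' @param delta pulse interval (min).
#' @param gap equilibration gap after the second pulse (min), default 240.
#' @param base base parameters.
#' @param noise_mode `"extrinsic"` or `"intrinsic"`.
#' @param rates,seed intrinsic-mode switch rates and seed.
#' @param check_equilibration require the pre-pulse-3 state to be back near
#'   rest (nuclear fraction within 0.05 of the resting value, extrinsic
#'   mode only).
#' @return Data frame: cell_id, responded_p2, responded_p4.
#' @export
equilibrated_pulse_experiment <- function(cells, delta, gap = 240,
                                          base = nfkb_params(),
                                          noise_mode = "extrinsic",
                                          rates = list(kon = 0.2, koff = 0.1),
                                          seed = NULL,
                                          check_equilibration = TRUE) {
  starts <- c(0, delta, delta + gap, delta + gap + delta)
  prot <- nfkb_protocol(data.frame(start = starts, duration = 5,
                                   cytokine = "TNF", dose = 10),
                        t_end = starts[4] + 100)
  if (!is.null(seed)) set.seed(seed)
  ov <- unique(unlist(lapply(cells, function(cl) names(cl$overrides))))
  y0 <- if (all(ov %in% c("IKKKtott_T", "IKKKtott_I")) &&
            noise_mode == "extrinsic") steady_state(base) else NULL
  res <- lapply(cells, function(cell) {
    p <- .cell_params(base, cell)
    traj <- if (noise_mode == "extrinsic")
      simulate_cell(p, prot, y0 = y0)
    else simulate_cell_intrinsic(p, prot, rates = rates)
    if (check_equilibration && noise_mode == "extrinsic") {
      i0 <- which.min(abs(traj$time - 0))
      i3 <- which.min(abs(traj$time - starts[3]))
      if (abs(traj$nfkb_nuclear_fraction[i3] -
              traj$nfkb_nuclear_fraction[i0]) > 0.05)
        stop("gap too short: cell ", cell$cell_id,
             " not re-equilibrated before pulse 3")
    }
    c(classify_responder_model(traj, starts[2])$responder,
      classify_responder_model(traj, starts[4])$responder)
  })
  m <- do.call(rbind, res)
  data.frame(cell_id = vapply(cells, `[[`, 0L, "cell_id"),
             responded_p2 = m[, 1], responded_p4 = m[, 2])
}
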