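#' Nominal model parameters
#'
#' Returns the calibrated nominal parameter set for the two-branch
#' IKKK/A20/IKK -- NF-kB/IkBa model. Units are molecules per cell and
#' per-minute rates; doses are ng/ml. The nominal values were fixed by an
#' explicit calibration step against population-level kinetic constraints
#' (post-pulse IkBa trough/peak timing, oscillation period, responder
#' fractions at 50--100 min pulse intervals); see the package vignette.
#'
#' @param ... named overrides of individual parameters.
#' @return A named list of class `nfkb_params`.
#'
#' @details Parameter roles:
#' \describe{
#'   \item{ka_T, ka_I}{IKKK activation rate per unit receptor signal
#'     (per min), TNF and IL-1 branch.}
#'   \item{ki}{IKKK inactivation rate (active -> inactive, per min).}
#'   \item{m3}{IKKK recovery rate (inactive -> neutral, per min); sets the
#'     recovery arm of the refractory period.}
#'   \item{kA20_T, kA20_I}{A20 half-inhibition constants (molecules) for
#'     IKKK activation in each branch; kA20_T < kA20_I makes the TNF branch
#'     more strongly A20-inhibited, the source of TNF/IL-1 asymmetry.}
#'   \item{IKKKtott_T, IKKKtott_I}{total IKKK per branch (molecules); the
#'     TNF-branch total is the extrinsically distributed cell state.}
#'   \item{kact, sIKKK, k1, k4, IKKtot}{IKK cycle: maximal activation rate,
#'     half-maximal IKKKa level (Hill 2), inactivation, recycling, total.}
#'   \item{c1a, c3a, c2a, c4a}{IkBa: max transcription, mRNA degradation,
#'     translation, free-protein degradation.}
#'   \item{c1, c3, c2, c4}{A20: same four roles.}
#'   \item{KN, hill_tr}{half-saturation (nuclear NF-kB molecules) and Hill
#'     coefficient of NF-kB-driven transcription.}
#'   \item{b0}{basal fraction of maximal transcription.}
#'   \item{kb}{NF-kB:IkBa association (per molecule per min).}
#'   \item{kc1, kc2}{IKKa catalytic turnover on complexed / free IkBa
#'     (per min); each pool is an independently saturable substrate with
#'     Michaelis constant `Km_ikk` (molecules) -- near-zero-order
#'     degradation of the complex provides the switch-like behaviour
#'     behind the relaxation oscillations.}
#'   \item{c5}{IKK-independent IkBa turnover within the complex.}
#'   \item{iN, iI, eI, eC}{transport: NF-kB nuclear import, IkBa import and
#'     export, complex export.}
#'   \item{nfkbtot}{total NF-kB (molecules).}
#'   \item{Kd_T, hd_T, Kd_I, hd_I}{dose-response constants (ng/ml).}
#'   \item{tau_w}{washout time constant after a pulse (min).}
#' }
#' @export
nfkb_params <- function(...) {
  p <- list(
    # IKKK module: fast TNF-branch activation, slow recovery (m3), strongly
    # asymmetric A20 gates (TNF branch ~20x more A20-sensitive)
    ka_T = 0.944,  ka_I = 1.9597, ki = 0.15045, m3 = 0.048852,
    kA20_T = 3825, kA20_I = 73662,
    IKKKtott_T = 1e6, IKKKtott_I = 1e6,
    # IKK cycle: slow activation, high catalytic capacity once active
    kact = 0.12, sIKKK = 5.292e5, k1 = 0.12, k4 = 0.045518,
    IKKtot = 2.2e4,
    # IkBa feedback
    c1a = 600, c3a = 0.017, c2a = 0.45, c4a = 0.023392,
    # A20 feedback: short mRNA and protein lifetimes so inhibition peaks
    # ~45 min after a pulse and recovers through the refractory window
    c1 = 33.04, c3 = 0.08, c2 = 1.5, c4 = 0.05,
    # transcription
    KN = 3e4, hill_tr = 2, hill_ikk = 2, b0 = 0.002,
    # complex / degradation / transport
    kb = 1.6891e-4, kc1 = 1.02, kc2 = 1.18, Km_ikk = 805.09, c5 = 1e-3,
    iN = 1.006, iI = 2.6272, eI = 0.4296, eC = 0.38947,
    nfkbtot = 1e5,
    # dose response and washout
    Kd_T = 0.25, hd_T = 1, Kd_I = 0.25, hd_I = 1, tau_w = 2
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  structure(p, class = "nfkb_params")
}

#' Validate a model parameter set
#'
#' Checks non-negativity of all rates, positivity of totals, and the
#' branch-asymmetry requirement kA20_T < kA20_I.
#'
#' @param params a list as returned by [nfkb_params()].
#' @return `params`, invisibly; errors on violation.
#' @export
validate_params <- function(params) {
  v <- unlist(params)
  if (any(!is.finite(v))) stop("non-finite parameter value")
  if (any(v < 0)) stop("negative parameter value: ",
                       paste(names(v)[v < 0], collapse = ", "))
  totals <- c("IKKKtott_T", "IKKKtott_I", "IKKtot", "nfkbtot")
  if (any(unlist(params[totals]) <= 0)) stop("totals must be > 0")
  if (params$kA20_T >= params$kA20_I)
    stop("kA20_T must be < kA20_I (TNF branch more strongly A20-inhibited)")
  invisible(params)
}

#' @export
print.nfkb_params <- function(x, ...) {
  cat("<nfkb_params>", length(x), "parameters\n")
  print(unlist(x))
  invisible(x)
}

# order of scalar parameters in the compiled RHS parameter vector
.parms_order <- c(
  "ka_T", "ka_I", "ki", "m3", "kA20_T", "kA20_I",
  "IKKKtott_T", "IKKKtott_I",
  "kact", "sIKKK", "k1", "k4", "IKKtot",
  "c1a", "c3a", "c2a", "c4a", "c1", "c3", "c2", "c4",
  "KN", "hill_tr", "hill_ikk", "b0",
  "kb", "kc1", "kc2", "Km_ikk", "c5", "iN", "iI", "eI", "eC",
  "nfkbtot", "Kd_T", "hd_T", "Kd_I", "hd_I", "tau_w"
)

.MAX_PULSES <- 8L

# build the full numeric parameter vector expected by the C derivatives:
# scalars, gene gates/compensation, then the encoded pulse table
.parms_vector <- function(params, protocol,
                          gate = c(1, 1), boost = c(0, 0)) {
  sc <- unlist(params[.parms_order])
  if (anyNA(sc)) stop("missing parameter(s): ",
                      paste(.parms_order[is.na(sc)], collapse = ", "))
  pulses <- protocol$pulses
  np <- nrow(pulses)
  if (np > .MAX_PULSES) stop("at most ", .MAX_PULSES, " pulses supported")
  ptab <- matrix(0, nrow = 4, ncol = .MAX_PULSES)
  if (np > 0) {
    ptab[1, seq_len(np)] <- pulses$start
    ptab[2, seq_len(np)] <- pulses$start + pulses$duration
    ptab[3, seq_len(np)] <- pulses$dose
    ptab[4, seq_len(np)] <- ifelse(pulses$cytokine == "TNF", 0, 1)
  }
  c(sc, gate_I = gate[1], gate_A = gate[2],
    boost_I = boost[1], boost_A = boost[2], npulses = np,
    as.numeric(ptab))
}

# state names, order fixed by the compiled RHS
.state_names <- c("IKKKa_T", "IKKKi_T", "IKKKa_I", "IKKKi_I",
                  "IKKa", "IKKi", "RmI", "RmA", "A20",
                  "IkBc", "IkBn", "NFKBc", "NFKBn", "Cc", "Cn")
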