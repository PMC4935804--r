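#' Latin hypercube design over model parameters
#'
#' For each parameter the range of +/- `range_frac` around its nominal
#' value is divided into `k` equal slices; one uniform draw is taken per
#' slice and slice order is permuted independently per parameter, so the
#' whole range is explored (the Latin property).
#'
#' @param base base parameters supplying nominal values.
#' @param names parameters to vary (default: the kinetic rates and totals).
#' @param k number of samples / slices (>= 2).
#' @param range_frac half-range as a fraction of nominal, default 0.5.
#' @param seed RNG seed.
#' @return `nfkb_lhs_design`: list with `samples` (k x p matrix), `names`,
#'   `nominal`, `range_frac`, `k`.
#' @export
lhs_sample <- function(base = nfkb_params(), names = NULL, k, range_frac = 0.5,
                       seed = NULL) {
  if (k < 2) stop("k must be >= 2")
  if (is.null(names))
    names <- c("ka_T", "ki", "m3", "kA20_T", "sIKKK", "IKKKtott_T",
               "kact", "k1", "k4", "IKKtot",
               "c1a", "c3a", "c2a", "c4a", "c1", "c3", "c2", "c4",
               "KN", "nfkbtot")
  nominal <- unlist(base[names])
  if (any(nominal <= 0)) stop("non-positive nominal value for: ",
                              paste(names[nominal <= 0], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::randomLHS(k, length(names))  # stratified uniforms in (0,1)
  lo <- nominal * (1 - range_frac)
  samples <- sweep(sweep(u, 2, 2 * range_frac * nominal, `*`), 2, lo, `+`)
  colnames(samples) <- names
  structure(list(samples = samples, names = names, nominal = nominal,
                 range_frac = range_frac, k = k),
            class = "nfkb_lhs_design")
}

#' Check the Latin slice property of a design
#'
#' Each parameter's `k` values must occupy each of the `k` equal slices of
#' its range exactly once.
#'
#' @param design an `nfkb_lhs_design`.
#' @return `TRUE` (invisibly); errors if violated.
#' @export
check_latin <- function(design) {
  k <- design$k
  for (j in seq_along(design$names)) {
    nom <- design$nominal[j]
    lo <- nom * (1 - design$range_frac)
    width <- 2 * design$range_frac * nom / k
    slice <- floor((design$samples[, j] - lo) / width)
    slice <- pmin(pmax(slice, 0), k - 1)
    if (!all(sort(slice) == 0:(k - 1)))
      stop("Latin property violated for ", design$names[j])
  }
  invisible(TRUE)
}

#' Evaluate model outputs over an LHS design
#'
#' For every sampled parameter combination, simulates the two-pulse TNF
#' protocol and records: the responder indicator at the second pulse, the
#' net second-pulse amplitude, and the AUC of nuclear NF-kB after the
#' second pulse. Optionally also the oscillation period under continuous
#' TNF (a separate simulation per sample). Integrator failures are recorded
#' as missing values.
#'
#' @param design an `nfkb_lhs_design`.
#' @param base base parameters (unvaried parameters keep these values).
#' @param protocol probed protocol; default two 5-min 10 ng/ml TNF pulses
#'   70 min apart.
#' @param period also compute the continuous-stimulation period.
#' @param progress print a dot every 25 samples.
#' @return Matrix k x outputs (`responder`, `amplitude`, `auc`, optionally
#'   `period`).
#' @export
evaluate_outputs <- function(design, base = nfkb_params(), protocol = NULL,
                             period = FALSE, progress = FALSE) {
  if (is.null(protocol)) protocol <- parse_protocol("T@0,T@70", t_end = 200)
  p2 <- protocol$pulses$start[min(2, nrow(protocol$pulses))]
  cont <- nfkb_protocol(data.frame(start = 0, duration = 800,
                                   cytokine = "TNF", dose = 10), t_end = 800)
  out <- matrix(NA_real_, nrow = design$k,
                ncol = 3 + period,
                dimnames = list(NULL, c("responder", "amplitude", "auc",
                                        if (period) "period")))
  for (i in seq_len(design$k)) {
    p <- base
    p[design$names] <- design$samples[i, ]
    if ("IKKKtott_T" %in% design$names)
      p$IKKKtott_I <- base$IKKKtott_I *
        p$IKKKtott_T / base$IKKKtott_T
    res <- tryCatch({
      traj <- simulate_cell(p, protocol)
      cl <- classify_responder_model(traj, p2)
      auc <- auc_nuclear(traj, c(p2, min(p2 + 100, max(traj$time))))
      c(as.numeric(cl$responder), cl$net_amplitude, auc,
        if (period) tryCatch(dominant_period(traj_cont <-
          simulate_cell(p, cont)), error = function(e) NA_real_))
    }, error = function(e) rep(NA_real_, 3 + period))
    out[i, ] <- res
    if (progress && i %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  out
}

#' Spearman sensitivity coefficients
#'
#' Rank correlation between each sampled parameter and each model output,
#' ties handled by average ranks, incomplete samples excluded pairwise.
#' Zero-variance outputs get a coefficient of 0 and are flagged.
#'
#' @param design an `nfkb_lhs_design`.
#' @param outputs matrix from [evaluate_outputs()].
#' @return Matrix p x outputs of Spearman rho; attribute `flat_outputs`
#'   names any zero-variance outputs.
#' @export
spearman_sensitivity <- function(design, outputs) {
  ok <- stats::complete.cases(outputs)
  if (sum(ok) < 10) stop("fewer than 10 complete samples")
  x <- design$samples[ok, , drop = FALSE]
  y <- outputs[ok, , drop = FALSE]
  flat <- colnames(y)[apply(y, 2, stats::sd) == 0]
  rho <- matrix(0, ncol(x), ncol(y), dimnames = list(colnames(x),
                                                     colnames(y)))
  for (j in seq_len(ncol(y)))
    if (!colnames(y)[j] %in% flat)
      rho[, j] <- suppressWarnings(
        stats::cor(x, y[, j], method = "spearman"))
  attr(rho, "flat_outputs") <- flat
  rho
}
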