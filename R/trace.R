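#' Responder classification, model rule
#'
#' A simulated cell is a responder to a pulse if the net peak amplitude of
#' nuclear NF-kB after the pulse — measured relative to the nuclear level at
#' the time of stimulation — exceeds 15% of the cell's total NF-kB
#' (strictly).
#'
#' @param traj an `nfkb_trajectory`.
#' @param pulse_time pulse start (min).
#' @param window response window after the pulse (min), default 45.
#' @param threshold responder threshold as a fraction of total NF-kB.
#' @return List: `responder` (logical), `net_amplitude` (fraction of total),
#'   `peak_time` (min).
#' @export
classify_responder_model <- function(traj, pulse_time, window = 45,
                                     threshold = 0.15) {
  t <- traj$time
  if (pulse_time < min(t) || pulse_time + window > max(t))
    stop("response window [", pulse_time, ", ", pulse_time + window,
         "] exceeds trajectory")
  nf <- traj$nfkb_nuclear_fraction
  base <- nf[which.min(abs(t - pulse_time))]
  win <- t > pulse_time & t <= pulse_time + window
  net <- max(nf[win] - base)
  idx <- which(win)[which.max(nf[win] - base)]
  list(responder = net > threshold, net_amplitude = net,
       peak_time = t[idx])
}

#' Responder classification, experimental-trace rule
#'
#' A measured cell is a responder to a pulse if the gradient of its total
#' IkBa reporter trajectory at the time of stimulation is not positive
#' (IkBa being degraded rather than accumulating). The gradient is the
#' least-squares slope over `[pulse_time + lag, pulse_time + lag + window]`.
#'
#' @param trace data frame for one cell with columns `time_min` and
#'   `ikba_total` (or an `nfkb_trajectory`).
#' @param pulse_time pulse start (min).
#' @param lag delay before the evaluation window (min), default 5.
#' @param window window length (min), default 20.
#' @return Logical: responder call.
#' @export
classify_responder_trace <- function(trace, pulse_time, lag = 5,
                                     window = 20) {
  if (inherits(trace, "nfkb_trajectory"))
    trace <- data.frame(time_min = trace$time, ikba_total = trace$total_ikba)
  w <- trace$time_min >= pulse_time + lag &
       trace$time_min <= pulse_time + lag + window
  if (sum(w) < 3) stop("fewer than 3 samples in the evaluation window")
  slope <- stats::coef(stats::lm(ikba_total ~ time_min, trace[w, ]))[2]
  unname(slope <= 0)
}

#' Fraction of cells responding at a pulse
#'
#' @param responses data frame with columns `cell_id`, `pulse`, `responder`.
#' @param pulse_index which pulse to evaluate.
#' @return List: `fraction`, `n`.
#' @export
fraction_responding <- function(responses, pulse_index) {
  r <- responses[responses$pulse == pulse_index, ]
  if (!nrow(r)) stop("no cells recorded for pulse ", pulse_index)
  list(fraction = mean(r$responder), n = nrow(r))
}

#' Refractory-period distribution from interval fractions
#'
#' Converts the fraction of cells responding at each pulse interval into a
#' probability distribution over refractory-period bins by successive
#' differences: mass in `[d_i, d_{i+1})` is `f(d_{i+1}) - f(d_i)`, mass
#' below the smallest interval is `f(d_min)`, and mass at or beyond the
#' largest is `1 - f(d_max)`. Negative increments (possible under sampling
#' noise) are clipped to zero and the masses renormalized, with a warning.
#'
#' @param fractions named numeric: interval (min) -> fraction responding.
#' @return `nfkb_refractory_distribution`: list with `breaks` (interval
#'   grid), `mass` (per bin, first bin is `< d_min`, last is `>= d_max`),
#'   and bin `labels`.
#' @export
refractory_distribution <- function(fractions) {
  iv <- as.numeric(names(fractions))
  if (anyNA(iv)) stop("fractions must be named by interval (min)")
  o <- order(iv)
  iv <- iv[o]; fr <- unname(fractions[o])
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  mass <- c(fr[1], diff(fr), 1 - fr[length(fr)])
  if (any(mass < 0)) {
    warning("negative increment(s) clipped and masses renormalized")
    mass <- pmax(mass, 0)
    mass <- mass / sum(mass)
  }
  labels <- c(paste0("<", iv[1]),
              if (length(iv) > 1)
                paste0("[", iv[-length(iv)], ",", iv[-1], ")"),
              paste0(">=", iv[length(iv)]))
  structure(list(breaks = iv, mass = mass, labels = labels),
            class = "nfkb_refractory_distribution")
}

#' @export
print.nfkb_refractory_distribution <- function(x, ...) {
  cat("<refractory-period distribution>\n")
  print(stats::setNames(round(x$mass, 4), x$labels))
  invisible(x)
}

.peak_series <- function(x) {
  if (inherits(x, "nfkb_trajectory"))
    data.frame(time_min = x$time, value = x$nfkb_nuclear_fraction)
  else data.frame(time_min = x$time_min, value = x$nfkb_nt)
}

#' Second-to-first peak amplitude ratio
#'
#' Ratio of the baseline-subtracted nuclear NF-kB (N/T) peak after the
#' second pulse to the peak after the first pulse.
#'
#' @param x `nfkb_trajectory` or one-cell trace data frame with `time_min`
#'   and `nfkb_nt`.
#' @param pulse_times numeric length 2: pulse starts (min).
#' @param window peak-search window after each pulse (min).
#' @return Numeric ratio P2/P1.
#' @export
amplitude_ratio <- function(x, pulse_times, window = 45) {
  s <- .peak_series(x)
  peak_net <- function(p) {
    base <- s$value[which.min(abs(s$time_min - p))]
    w <- s$time_min > p & s$time_min <= p + window
    max(s$value[w] - base)
  }
  p1 <- peak_net(pulse_times[1])
  if (p1 <= 0) stop("degenerate first peak (P1 <= 0)")
  peak_net(pulse_times[2]) / p1
}

#' Area under the nuclear NF-kB trajectory
#'
#' Trapezoidal area of the baseline-corrected, first-peak-normalized N/T
#' signal over a time range. The baseline is the signal value at the start
#' of the trace; the normalizer is the first-peak net amplitude.
#'
#' @param x `nfkb_trajectory` or trace data frame (`time_min`, `nfkb_nt`).
#' @param t_range numeric length 2 (min); default the full trace.
#' @return Area (min, in first-peak-amplitude units).
#' @export
auc_nuclear <- function(x, t_range = NULL) {
  s <- .peak_series(x)
  if (is.null(t_range)) t_range <- range(s$time_min)
  base <- s$value[1]
  v <- s$value - base
  if (all(v == 0)) return(0)
  # first translocation peak carries the global net maximum in the
  # reference pulse designs
  p1 <- max(v)
  if (p1 <= 0) stop("degenerate first peak")
  w <- s$time_min >= t_range[1] & s$time_min <= t_range[2]
  tt <- s$time_min[w]; vv <- v[w] / p1
  sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
}

# local minima of `value` with prominence and separation constraints;
# prominence of a trough = min(rise to the highest point before the next
# deeper trough on each side); ties broken by earliest time
.find_troughs <- function(time, value, prominence, min_sep) {
  n <- length(value)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(value))) > 0) + 1
  # plateau-robust: keep first index of equal-valued runs
  cand <- cand[value[cand] < Inf]
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    j <- cand[i]
    left <- if (i == 1) value[1:j] else value[cand[i - 1]:j]
    right <- if (i == length(cand)) value[j:n] else value[j:cand[i + 1]]
    prom <- min(max(left) - value[j], max(right) - value[j])
    keep[i] <- prom >= prominence
  }
  cand <- cand[keep]
  if (length(cand) > 1) {
    sel <- cand[1]
    for (j in cand[-1])
      if (time[j] - time[sel[length(sel)]] >= min_sep) sel <- c(sel, j)
    cand <- sel
  }
  cand
}

#' Peak-to-peak intervals from trough spacing
#'
#' Detects troughs of the total IkBa signal (local minima with a prominence
#' of at least `prominence_frac` of the trace range, separated by at least
#' `min_sep` minutes) and returns the spacings between consecutive troughs.
#'
#' @param x `nfkb_trajectory` or trace data frame (`time_min`,
#'   `ikba_total`).
#' @param prominence_frac prominence threshold as a fraction of the trace
#'   range, default 0.05.
#' @param min_sep minimum trough separation (min), default 40.
#' @return Numeric vector of intervals (min); empty if fewer than 2 troughs.
#' @export
peak_to_peak <- function(x, prominence_frac = 0.05, min_sep = 40) {
  if (inherits(x, "nfkb_trajectory"))
    x <- data.frame(time_min = x$time, ikba_total = x$total_ikba)
  v <- x$ikba_total
  idx <- .find_troughs(x$time_min, v, prominence_frac * diff(range(v)),
                       min_sep)
  if (length(idx) < 2) return(numeric(0))
  diff(x$time_min[idx])
}

#' Dominant oscillation period by power spectrum
#'
#' Discards the initial transient (t <= `t_skip`), removes mean and linear
#' trend, computes the discrete-Fourier power spectrum on a `pad`-fold
#' zero-padded series, and returns the period of maximal power within the
#' search band.
#'
#' @param x `nfkb_trajectory` or trace data frame (`time_min` plus
#'   `ikba_total` or `nfkb_nt`).
#' @param t_skip initial time to discard (min), default 35.
#' @param band period search band (min), default c(40, 300).
#' @param pad zero-padding factor, default 4.
#' @param signal which column to analyse for data-frame input.
#' @return Dominant period (min).
#' @export
dominant_period <- function(x, t_skip = 35, band = c(40, 300), pad = 4,
                            signal = c("ikba_total", "nfkb_nt")) {
  if (inherits(x, "nfkb_trajectory")) {
    tt <- x$time; vv <- x$total_ikba
  } else {
    signal <- match.arg(signal)
    tt <- x$time_min; vv <- x[[signal]]
  }
  keep <- tt > t_skip
  tt <- tt[keep]; vv <- vv[keep]
  if (length(vv) < 4) stop("trace too short after truncation")
  if (stats::sd(vv) == 0) stop("constant trace: no dominant period")
  dt <- stats::median(diff(tt))
  vv <- stats::residuals(stats::lm(vv ~ tt))
  n <- length(vv)
  nfft <- stats::nextn(pad * n, 2)
  pw <- Mod(stats::fft(c(vv, numeric(nfft - n))))^2
  freq <- seq_len(nfft %/% 2) / (nfft * dt)  # cycles per min, k = 1..n/2
  per <- 1 / freq
  inband <- per >= band[1] & per <= band[2]
  if (!any(inband)) stop("no spectral support in the period band")
  per[inband][which.max(pw[2:(nfft %/% 2 + 1)][inband])]
}

#' Two-group clustering of post-pulse IkBa traces
#'
#' Partitions cells into responding and non-responding groups by 2-means on
#' the standardized normalized IkBa feature vector over
#' `[pulse_time, pulse_time + window]`. The cluster whose mean trace dips
#' deeper is labelled responding.
#'
#' @param traces long data frame: `cell_id`, `time_min`, `ikba_total`.
#' @param pulse_time pulse start (min).
#' @param window feature window (min), default 40.
#' @param nstart k-means restarts, default 10.
#' @param seed RNG seed for the restarts.
#' @return Named logical vector: cell_id -> responding.
#' @export
cluster_responders <- function(traces, pulse_time, window = 40,
                               nstart = 10, seed = 1) {
  ids <- unique(traces$cell_id)
  if (length(ids) < 2) stop("need at least 2 cells")
  w <- traces$time_min >= pulse_time & traces$time_min <= pulse_time + window
  m <- do.call(rbind, lapply(ids, function(id) {
    tr <- traces[w & traces$cell_id == id, ]
    tr$ikba_total[order(tr$time_min)]
  }))
  if (all(apply(m, 2, stats::sd) == 0)) {
    warning("identical traces: single cluster")
    return(stats::setNames(rep(FALSE, length(ids)), ids))
  }
  z <- scale(m)
  z[, !is.finite(colSums(z))] <- 0
  set.seed(seed)
  km <- stats::kmeans(z, centers = 2, nstart = nstart)
  # deeper dip (lower mean raw level in window) = responding
  depth <- tapply(rowMeans(m), km$cluster, mean)
  responding <- km$cluster == as.integer(names(which.min(depth)))
  stats::setNames(responding, ids)
}

#' PCA embedding of sub-trajectories
#'
#' Cuts each cell's trace into the given windows (two 140-min stimulation
#' phases in the reference design), z-scores each time-point feature across
#' the pooled set of sub-trajectories, and projects onto the first two
#' principal axes.
#'
#' @param traces long data frame: `cell_id`, `time_min`, `ikba_total`.
#' @param windows list of numeric length-2 vectors (start, end), equal
#'   lengths.
#' @return Data frame: `cell_id`, `window`, `PC1`, `PC2`; attribute
#'   `explained` holds the component variances.
#' @export
pca_subtrajectories <- function(traces, windows) {
  len <- vapply(windows, diff, numeric(1))
  if (length(unique(len)) != 1) stop("windows must have equal lengths")
  ids <- unique(traces$cell_id)
  rows <- list(); meta <- list()
  for (wi in seq_along(windows)) {
    w <- windows[[wi]]
    for (id in ids) {
      tr <- traces[traces$cell_id == id &
                   traces$time_min >= w[1] & traces$time_min <= w[2], ]
      rows[[length(rows) + 1]] <- tr$ikba_total[order(tr$time_min)]
      meta[[length(meta) + 1]] <- data.frame(cell_id = id, window = wi)
    }
  }
  nlen <- lengths(rows)
  if (length(unique(nlen)) != 1)
    stop("windows cover different numbers of samples across cells")
  m <- do.call(rbind, rows)
  sds <- apply(m, 2, stats::sd)
  if (all(sds == 0)) {
    emb <- data.frame(do.call(rbind, meta), PC1 = 0, PC2 = 0)
    attr(emb, "explained") <- c(0, 0)
    return(emb)
  }
  z <- scale(m)
  z[, sds == 0] <- 0
  if (qr(z)$rank < 2) stop("rank-deficient pooled sub-trajectory matrix")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  emb <- data.frame(do.call(rbind, meta),
                    PC1 = pc$x[, 1], PC2 = pc$x[, 2])
  attr(emb, "explained") <- pc$sdev^2
  emb
}

#' Concordance of paired responder calls
#'
#' Fraction of cell pairs (for example daughter cells) whose responder
#' calls at the probed pulse agree.
#'
#' @param responses data frame: `cell_id`, `responder` (one row per cell at
#'   the probed pulse).
#' @param pairs data frame or 2-column matrix of paired cell ids.
#' @return Fraction of concordant pairs.
#' @export
pair_concordance <- function(responses, pairs) {
  pairs <- as.matrix(pairs)
  look <- stats::setNames(responses$responder, responses$cell_id)
  a <- look[as.character(pairs[, 1])]
  b <- look[as.character(pairs[, 2])]
  if (anyNA(a) || anyNA(b)) stop("unmatched cell id(s) in pairs")
  mean(a == b)
}
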