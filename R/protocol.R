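#' Construct a stimulation protocol
#'
#' A protocol is an ordered set of cytokine pulses (start time, duration,
#' cytokine identity, dose) plus a simulation end time.
#'
#' @param pulses data frame with columns `start` (min), `duration` (min),
#'   `cytokine` (`"TNF"` or `"IL1"`) and `dose` (ng/ml). May have zero rows.
#' @param t_end simulation end time (min); defaults to 300 min after the
#'   last pulse start (or 300 min if there are no pulses).
#' @return An object of class `nfkb_protocol`.
#' @export
nfkb_protocol <- function(pulses = NULL, t_end = NULL) {
  if (is.null(pulses) || nrow(pulses) == 0) {
    pulses <- data.frame(start = numeric(0), duration = numeric(0),
                         cytokine = character(0), dose = numeric(0))
  } else {
    need <- c("start", "duration", "cytokine", "dose")
    if (!all(need %in% names(pulses)))
      stop("pulses must have columns ", paste(need, collapse = ", "))
    pulses <- pulses[order(pulses$start), need, drop = FALSE]
    if (!all(pulses$cytokine %in% c("TNF", "IL1")))
      stop("unknown cytokine; use \"TNF\" or \"IL1\"")
    if (any(pulses$duration <= 0)) stop("pulse duration must be > 0")
    if (any(pulses$dose < 0)) stop("dose must be >= 0")
    for (cy in unique(pulses$cytokine)) {
      p <- pulses[pulses$cytokine == cy, ]
      if (nrow(p) > 1 &&
          any(p$start[-1] < (p$start + p$duration)[-nrow(p)]))
        stop("overlapping pulses for cytokine ", cy)
    }
  }
  last_end <- if (nrow(pulses)) max(pulses$start + pulses$duration) else 0
  if (is.null(t_end))
    t_end <- (if (nrow(pulses)) max(pulses$start) else 0) + 300
  if (t_end < last_end) stop("t_end must cover the last pulse")
  structure(list(pulses = pulses, t_end = t_end), class = "nfkb_protocol")
}

#' Parse a shorthand protocol string
#'
#' Accepts strings such as `"T@0,T@60"` or `"T@0,I@50,T@100"`: each entry is
#' a cytokine letter (`T` for TNF-alpha, `I` for IL-1beta) and a pulse start
#' time in minutes. All pulses share the given duration and dose.
#'
#' @param spec shorthand string.
#' @param duration pulse duration (min), default 5.
#' @param dose dose (ng/ml), default 10.
#' @param t_end optional end time (min).
#' @return An `nfkb_protocol`.
#' @export
parse_protocol <- function(spec, duration = 5, dose = 10, t_end = NULL) {
  spec <- gsub("[[:space:]]", "", spec)
  if (!nzchar(spec)) return(nfkb_protocol(NULL, t_end))
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([TI])@([0-9.]+)$", parts))
  if (any(lengths(m) != 3))
    stop("cannot parse protocol entry: ",
         paste(parts[lengths(m) != 3], collapse = ", "))
  cy <- vapply(m, `[`, "", 2)
  st <- as.numeric(vapply(m, `[`, "", 3))
  nfkb_protocol(data.frame(
    start = st, duration = duration,
    cytokine = ifelse(cy == "T", "TNF", "IL1"), dose = dose), t_end)
}

#' Build a protocol from a pulse pattern at a fixed interval
#'
#' Field shorthand such as `"TT"`, `"TIT"`, `"TTT"` or `"T_T"`: one slot per
#' interval, `T` = TNF pulse, `I` = IL-1 pulse, `_` = skipped slot.
#'
#' @param pattern pattern string.
#' @param interval slot spacing (min).
#' @inheritParams parse_protocol
#' @return An `nfkb_protocol`.
#' @export
pattern_protocol <- function(pattern, interval, duration = 5, dose = 10,
                             t_end = NULL) {
  ch <- strsplit(pattern, "")[[1]]
  if (!all(ch %in% c("T", "I", "_"))) stop("pattern may contain only T, I, _")
  keep <- ch != "_"
  st <- (seq_along(ch) - 1) * interval
  nfkb_protocol(data.frame(
    start = st[keep], duration = duration,
    cytokine = ifelse(ch[keep] == "T", "TNF", "IL1"), dose = dose), t_end)
}

#' Receptor signal at given times
#'
#' Dimensionless receptor drive in [0, 1] for one cytokine branch:
#' phi(d) = d^h / (d^h + Kd^h) during a pulse of that cytokine, decaying
#' exponentially with time constant `tau_w` after pulse end, and 0 before
#' any pulse. Where washout tails overlap a later pulse the maximum applies.
#'
#' @param protocol an `nfkb_protocol`.
#' @param t numeric vector of times (min).
#' @param cytokine `"TNF"` or `"IL1"`.
#' @param params parameter list supplying `Kd_*`, `hd_*`, `tau_w`.
#' @return Numeric vector of signals in [0, 1].
#' @export
receptor_signal <- function(protocol, t, cytokine,
                            params = nfkb_params()) {
  if (!cytokine %in% c("TNF", "IL1")) stop("unknown cytokine: ", cytokine)
  kd <- if (cytokine == "TNF") params$Kd_T else params$Kd_I
  hd <- if (cytokine == "TNF") params$hd_T else params$hd_I
  p <- protocol$pulses
  p <- p[p$cytokine == cytokine & p$dose > 0, , drop = FALSE]
  out <- numeric(length(t))
  for (i in seq_len(nrow(p))) {
    phi <- p$dose[i]^hd / (p$dose[i]^hd + kd^hd)
    e <- p$start[i] + p$duration[i]
    v <- ifelse(t < p$start[i], 0,
                ifelse(t < e, phi, phi * exp(-(t - e) / params$tau_w)))
    out <- pmax(out, v)
  }
  out
}

#' @export
print.nfkb_protocol <- function(x, ...) {
  cat("<nfkb_protocol>", nrow(x$pulses), "pulse(s), t_end =", x$t_end, "min\n")
  if (nrow(x$pulses)) print(x$pulses, row.names = FALSE)
  invisible(x)
}
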