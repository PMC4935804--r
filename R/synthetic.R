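#' Generate synthetic single-cell reporter traces
#'
#' Emulates fluorescence-microscopy trace tables. In model mode a
#' heterogeneous calibrated population is simulated and the observables are
#' corrupted with multiplicative lognormal measurement noise and a slow
#' linear drift (IkBa intensity only; the N/T ratio is self-normalizing).
#' In label mode responder / non-responder template responses (nominal
#' model runs at high and low IKKK) are spliced at the stated responder
#' fraction. Ground-truth labels are returned alongside, never mixed into
#' the trace table.
#'
#' @param n_cells number of cells.
#' @param protocol an `nfkb_protocol`.
#' @param mode `"model"` or `"label"`.
#' @param responder_fraction label mode: fraction of second-pulse
#'   responders.
#' @param sigma model mode: sd of the IKKK distribution (molecules).
#' @param base base parameters.
#' @param noise_sd multiplicative lognormal noise sd, default 0.05.
#' @param drift linear drift rate per minute on IkBa intensity, default
#'   -2e-4 (photobleaching-like).
#' @param dt_out sampling step (min), default 5.
#' @param seed RNG seed.
#' @return List: `traces` (long data frame `cell_id`, `time_min`,
#'   `ikba_total`, `nfkb_nt`), `labels` (data frame `cell_id`,
#'   `responder_p2`), `cells` (model mode: the sampled cell specs).
#' @export
generate_traces <- function(n_cells, protocol, mode = c("model", "label"),
                            responder_fraction = 0.3, sigma = 0.3e6,
                            base = nfkb_params(), noise_sd = 0.05,
                            drift = -2e-4, dt_out = 5, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  p2 <- if (nrow(protocol$pulses) >= 2) protocol$pulses$start[2] else NA
  if (mode == "model") {
    spec <- population_spec(n_cells, "extrinsic", distributed = list(
      IKKKtott_T = list(mean = base$IKKKtott_T, sd = sigma,
                        family = "normal_truncated")))
    cells <- sample_population(spec, base)
    trajs <- run_population(cells, protocol, base, dt_out = dt_out)
    labels <- data.frame(
      cell_id = seq_len(n_cells),
      responder_p2 = if (is.na(p2)) NA else vapply(trajs, function(tr)
        classify_responder_model(tr, p2)$responder, logical(1)))
  } else {
    # responder template: a high-IKKK cell that clearly responds to the
    # second pulse by both the model rule and the trace-gradient rule on
    # its own noiseless trace. Non-responder template: the same protocol
    # with the probed pulse omitted — a cell refractory to the second
    # pulse continues the single-pulse profile (its IkBa keeps
    # accumulating through the stimulation window).
    pick_responder <- function(factors) {
      for (f in factors) {
        q <- base
        q$IKKKtott_T <- f * base$IKKKtott_T
        q$IKKKtott_I <- f * base$IKKKtott_I
        tr <- simulate_cell(q, protocol, dt_out = dt_out)
        if (is.na(p2)) return(tr)
        if (classify_responder_model(tr, p2)$responder &&
            classify_responder_trace(tr, p2)) return(tr)
      }
      stop("no responder template found for this protocol")
    }
    t_resp <- pick_responder(c(1.4, 1.7, 2, 2.5))
    prot_non <- protocol
    if (!is.na(p2)) {
      keep <- protocol$pulses$start != p2
      prot_non <- nfkb_protocol(protocol$pulses[keep, , drop = FALSE],
                                t_end = protocol$t_end)
    }
    t_non <- simulate_cell(base, prot_non, dt_out = dt_out)
    is_resp <- stats::runif(n_cells) < responder_fraction
    trajs <- lapply(is_resp, function(r) if (r) t_resp else t_non)
    cells <- NULL
    labels <- data.frame(cell_id = seq_len(n_cells),
                         responder_p2 = is_resp)
  }
  traces <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    tr <- trajs[[i]]
    ik <- tr$total_ikba / tr$total_ikba[1]  # normalized to t = 0
    if (noise_sd > 0)
      ik <- ik * stats::rlnorm(length(ik), 0, noise_sd)
    ik <- ik * (1 + drift * tr$time)
    nt <- tr$nfkb_nuclear_fraction
    if (noise_sd > 0)
      nt <- pmin(pmax(nt * stats::rlnorm(length(nt), 0, noise_sd), 0), 1)
    data.frame(cell_id = i, time_min = tr$time, ikba_total = ik,
               nfkb_nt = nt)
  }))
  list(traces = traces, labels = labels, cells = cells)
}

#' Generate synthetic daughter-cell pairs
#'
#' Pairs share the mother's parameter draw (imprinting); with probability
#' `divergence_prob` one member's IKKK total is redrawn from the population
#' distribution. Division times are annotated in the lineage table.
#'
#' @param n_pairs number of pairs.
#' @param divergence_prob probability that a pair diverges, default 0.15.
#' @param protocol an `nfkb_protocol` (two TNF pulses in the reference
#'   design).
#' @param base base parameters.
#' @param mu,sigma IKKK distribution (molecules).
#' @param dt_out sampling step (min).
#' @param noise_sd measurement noise for the trace table.
#' @param seed RNG seed.
#' @return List: `traces` (long data frame), `lineage` (pair_id, cell_a,
#'   cell_b, division_time, diverged), `responses` (cell_id, responder:
#'   model-rule call at pulse 2).
#' @export
generate_daughter_pairs <- function(n_pairs, divergence_prob = 0.15,
                                    protocol = NULL, base = nfkb_params(),
                                    mu = 1e6, sigma = 0.3e6, dt_out = 5,
                                    noise_sd = 0.05, seed = NULL) {
  if (divergence_prob < 0 || divergence_prob > 1)
    stop("divergence_prob must be in [0, 1]")
  if (is.null(protocol)) protocol <- parse_protocol("T@0,T@70", t_end = 170)
  if (!is.null(seed)) set.seed(seed)
  p2 <- protocol$pulses$start[2]
  draw <- function() .rtruncnorm0(1, mu, sigma)
  rows <- list(); lin <- list(); resp <- list()
  for (i in seq_len(n_pairs)) {
    tott <- c(draw(), NA)
    tott[2] <- if (stats::runif(1) < divergence_prob) draw() else tott[1]
    ids <- c(2 * i - 1, 2 * i)
    for (j in 1:2) {
      p <- base
      p$IKKKtott_I <- base$IKKKtott_I * tott[j] / base$IKKKtott_T
      p$IKKKtott_T <- tott[j]
      tr <- simulate_cell(p, protocol, dt_out = dt_out)
      ik <- tr$total_ikba / tr$total_ikba[1]
      if (noise_sd > 0) ik <- ik * stats::rlnorm(length(ik), 0, noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = ids[j], time_min = tr$time, ikba_total = ik,
        nfkb_nt = tr$nfkb_nuclear_fraction)
      resp[[length(resp) + 1]] <- data.frame(
        cell_id = ids[j],
        responder = classify_responder_model(tr, p2)$responder)
    }
    lin[[i]] <- data.frame(pair_id = i, cell_a = ids[1], cell_b = ids[2],
                           division_time = stats::runif(1, -600, -30),
                           diverged = tott[1] != tott[2])
  }
  list(traces = do.call(rbind, rows), lineage = do.call(rbind, lin),
       responses = do.call(rbind, resp))
}

#' Generate a synthetic panel count matrix
#'
#' Negative-binomial counts whose condition means track integrated nuclear
#' NF-kB activity: mean = baseline * (1 + coefficient * activity).
#' Housekeeping and positive-control genes are generated flat; negative
#' controls near zero.
#'
#' @param genes data frame: `gene`, `class`, `baseline` (counts),
#'   `coef` (activity coefficient; ignored for controls).
#' @param activity named numeric: condition -> activity (arbitrary units).
#' @param n_rep replicates per condition (>= 2).
#' @param dispersion NB size parameter (larger = closer to Poisson).
#' @param seed RNG seed.
#' @return List: `counts` (an `nfkb_counts`), `true_fc` (genes x
#'   conditions matrix of true linear fold changes vs the zero-activity
#'   reference).
#' @export
generate_counts <- function(genes, activity, n_rep = 3, dispersion = 100,
                            seed = NULL) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (n_rep < 2) stop("n_rep must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  conds <- names(activity)
  cond_vec <- rep(conds, each = n_rep)
  mu <- sapply(conds, function(cc) {
    a <- activity[[cc]]
    ifelse(genes$class == "endogenous",
           genes$baseline * (1 + genes$coef * a),
           ifelse(genes$class == "negative_control", 2, genes$baseline))
  })
  m <- matrix(0L, nrow(genes), length(cond_vec),
              dimnames = list(genes$gene, NULL))
  for (s in seq_along(cond_vec)) {
    m[, s] <- stats::rnbinom(nrow(genes),
                             mu = mu[, match(cond_vec[s], conds)],
                             size = dispersion)
  }
  true_fc <- sweep(mu, 1, mu[, which.min(abs(unlist(activity)))], `/`)
  list(counts = count_matrix(m, genes$class, cond_vec),
       true_fc = true_fc)
}

#' Default synthetic gene panel
#'
#' A small panel mimicking a cytokine-response code set: NF-kB-driven
#' endogenous genes with a spread of activity coefficients, housekeeping
#' genes, positive and negative controls.
#'
#' @param n_endogenous number of endogenous genes, default 20.
#' @param seed RNG seed for the coefficients.
#' @return Data frame usable as the `genes` argument of
#'   [generate_counts()].
#' @export
default_gene_panel <- function(n_endogenous = 20, seed = 1) {
  set.seed(seed)
  data.frame(
    gene = c(paste0("GENE", seq_len(n_endogenous)),
             paste0("HK", 1:5), paste0("POS", 1:4), paste0("NEG", 1:4)),
    class = c(rep("endogenous", n_endogenous), rep("housekeeping", 5),
              rep("positive_control", 4), rep("negative_control", 4)),
    baseline = c(round(stats::runif(n_endogenous, 50, 500)),
                 rep(1000, 5), rep(800, 4), rep(0, 4)),
    coef = c(stats::runif(n_endogenous, 0.2, 3), rep(0, 13)))
}
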