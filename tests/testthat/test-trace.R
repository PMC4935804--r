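test_that("model responder rule uses strict 15% net translocation", {
  t <- 0:120
  flat <- fake_trajectory(t, rep(0.05, 121), rep(1e5, 121))
  r <- classify_responder_model(flat, 10)
  expect_false(r$responder)
  expect_equal(r$net_amplitude, 0)

  # net amplitude exactly at threshold is a non-responder (strict >)
  nf <- rep(0, 121); nf[t > 10 & t <= 40] <- 0.15
  edge <- fake_trajectory(t, nf, rep(1e5, 121))
  expect_false(classify_responder_model(edge, 10)$responder)
  nf[t > 10 & t <= 40] <- 0.1501
  expect_true(classify_responder_model(
    fake_trajectory(t, nf, rep(1e5, 121)), 10)$responder)

  expect_error(classify_responder_model(flat, 100), "window")
})

test_that("responder rule is invariant to uniform species rescaling", {
  t <- 0:120
  nf <- 0.05 + 0.3 * exp(-(t - 30)^2 / 100)
  a <- fake_trajectory(t, nf, rep(1e5, 121), nfkbtot = 1e5)
  b <- fake_trajectory(t, nf, rep(1e7, 121), nfkbtot = 1e7)
  ra <- classify_responder_model(a, 10)
  rb <- classify_responder_model(b, 10)
  expect_equal(ra$responder, rb$responder)
  expect_equal(ra$net_amplitude, rb$net_amplitude, tolerance = 1e-12)
})

test_that("experimental gradient rule calls degradation as response", {
  t <- seq(0, 120, by = 2)
  rising <- data.frame(time_min = t, ikba_total = 1 + 0.01 * t)
  expect_false(classify_responder_trace(rising, 10))
  dipping <- data.frame(time_min = t,
                        ikba_total = ifelse(t < 15, 1, 1 - 0.02 * (t - 15)))
  expect_true(classify_responder_trace(dipping, 10))
  expect_error(classify_responder_trace(rising[1:3, ], 100), "samples")
})

test_that("fraction_responding summarizes a response table", {
  tab <- data.frame(cell_id = 1:10, pulse = 2,
                    responder = rep(c(TRUE, FALSE), c(3, 7)))
  f <- fraction_responding(tab, 2)
  expect_equal(f$fraction, 0.3)
  expect_equal(f$n, 10)
  expect_equal(fraction_responding(
    data.frame(cell_id = 1, pulse = 1, responder = TRUE), 1)$fraction, 1)
  expect_error(fraction_responding(tab, 5), "no cells")
})

test_that("refractory distribution takes successive differences", {
  fr <- c(`50` = 0.05, `60` = 0.30, `70` = 0.70, `100` = 0.93)
  d <- refractory_distribution(fr)
  expect_equal(d$mass, c(0.05, 0.25, 0.40, 0.23, 0.07), tolerance = 1e-12)
  expect_equal(sum(d$mass), 1)
  # inverse consistency: cumulative masses reproduce the input fractions
  expect_equal(cumsum(d$mass)[seq_along(fr)], unname(fr), tolerance = 1e-12)

  all1 <- refractory_distribution(c(`50` = 1, `60` = 1))
  expect_equal(all1$mass, c(1, 0, 0))

  expect_warning(dd <- refractory_distribution(
    c(`50` = 0.4, `60` = 0.35, `70` = 0.8)), "clip")
  expect_equal(sum(dd$mass), 1)
  expect_true(all(dd$mass >= 0))
})

test_that("refractory masses sum to one for any monotone input", {
  set.seed(42)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    fr <- sort(runif(k))
    names(fr) <- sort(sample(30:200, k))
    d <- refractory_distribution(fr)
    expect_equal(sum(d$mass), 1, tolerance = 1e-12)
    expect_true(all(d$mass >= -1e-12))
    expect_equal(cumsum(d$mass)[seq_len(k)], unname(fr), tolerance = 1e-12)
  }
})

test_that("amplitude ratio compares baseline-subtracted peaks", {
  t <- 0:200
  bump <- function(t0, h) h * exp(-(t - t0)^2 / 50)
  tr <- data.frame(time_min = t, nfkb_nt = 0.1 + bump(30, 0.4) + bump(130, 0.4))
  expect_equal(amplitude_ratio(tr, c(0, 100)), 1, tolerance = 0.02)
  tr2 <- data.frame(time_min = t, nfkb_nt = 0.1 + bump(30, 0.4) + bump(130, 0.24))
  expect_equal(amplitude_ratio(tr2, c(0, 100)), 0.6, tolerance = 0.02)
  flat <- data.frame(time_min = t, nfkb_nt = rep(0.1, 201))
  expect_error(amplitude_ratio(flat, c(0, 100)), "first peak")
})

test_that("nuclear AUC is the area of the normalized bump", {
  t <- seq(0, 100, by = 0.5)
  zero <- data.frame(time_min = t, nfkb_nt = rep(0, length(t)))
  expect_equal(auc_nuclear(zero), 0)
  # rectangular unit bump of width 20 -> area 20 after peak normalization
  rect <- data.frame(time_min = t, nfkb_nt = as.numeric(t >= 40 & t < 60))
  expect_equal(auc_nuclear(rect), 20, tolerance = 0.6)
})

test_that("peak-to-peak intervals come from trough spacing", {
  t <- seq(0, 800, by = 1)
  sine <- data.frame(time_min = t, ikba_total = 1 + 0.4 * cos(2 * pi * t / 100))
  pp <- peak_to_peak(sine)
  expect_true(length(pp) >= 6)
  expect_equal(unique(round(pp)), 100)

  # two troughs at 35 and 140 -> single interval of 105
  v <- rep(1, 201)
  v[(0:200) %in% 25:45] <- 1 - 0.5 * exp(-((25:45) - 35)^2 / 10)[1:21]
  two <- data.frame(time_min = 0:200,
                    ikba_total = 1 - 0.5 * exp(-((0:200) - 35)^2 / 20) -
                      0.5 * exp(-((0:200) - 140)^2 / 20))
  expect_equal(peak_to_peak(two), 105)

  expect_equal(peak_to_peak(data.frame(time_min = 0:10,
                                       ikba_total = rep(1, 11))),
               numeric(0))
})

test_that("dominant period finds the strongest spectral component", {
  t <- seq(0, 800, by = 5)
  pure <- data.frame(time_min = t, ikba_total = sin(2 * pi * t / 100))
  expect_equal(dominant_period(pure), 100, tolerance = 0.05)

  mix <- data.frame(time_min = t,
                    ikba_total = sin(2 * pi * t / 100) +
                      0.3 * sin(2 * pi * t / 50))
  expect_equal(dominant_period(mix), 100, tolerance = 0.05)

  expect_error(dominant_period(
    data.frame(time_min = t, ikba_total = rep(1, length(t)))), "constant")
})

test_that("dominant period matches trough spacing on noiseless traces", {
  t <- seq(0, 800, by = 2)
  for (per in c(80, 100, 140)) {
    tr <- data.frame(time_min = t, ikba_total = cos(2 * pi * t / per))
    expect_equal(dominant_period(tr), mean(peak_to_peak(tr)),
                 tolerance = 0.1 * per)
  }
})

test_that("2-means clustering recovers well-separated responder groups", {
  t <- seq(0, 120, by = 2)
  resp <- function() 1 - 0.5 * exp(-(t - 70)^2 / 60) + rnorm(length(t), 0, 0.01)
  nonr <- function() 1 + 0.3 * (t / 120) + rnorm(length(t), 0, 0.01)
  set.seed(7)
  truth <- rep(c(TRUE, FALSE), c(10, 14))
  traces <- make_traces(lapply(truth, function(r) if (r) resp() else nonr()), t)
  labels <- cluster_responders(traces, pulse_time = 60)
  expect_equal(unname(labels), truth)
  expect_error(cluster_responders(traces[traces$cell_id == 1, ], 60),
               "2 cells")
})

test_that("clustering agrees with the gradient rule on separated cells", {
  t <- seq(0, 120, by = 2)
  set.seed(11)
  truth <- rep(c(TRUE, FALSE), each = 12)
  traces <- make_traces(lapply(truth, function(r) {
    if (r) 1 - 0.4 / (1 + exp(-(t - 75) / 5)) + rnorm(length(t), 0, 0.005)
    else 1 + 0.25 * (t / 120) + rnorm(length(t), 0, 0.005)
  }), t)
  km <- cluster_responders(traces, pulse_time = 60)
  grad <- vapply(unique(traces$cell_id), function(id)
    classify_responder_trace(traces[traces$cell_id == id, ], 60), logical(1))
  expect_gte(mean(km == grad), 0.95)
})

test_that("sub-trajectory PCA separates imprinted response classes", {
  t <- seq(0, 600, by = 5)
  set.seed(3)
  truth <- rep(c(TRUE, FALSE), each = 8)
  # same class-specific shape in both stimulation phases (imprinting)
  shape <- function(r, t0) if (r) -0.5 * exp(-(t - t0 - 40)^2 / 100)
                           else 0.3 * pmin((t - t0) / 140, 1) * (t > t0)
  traces <- make_traces(lapply(truth, function(r)
    1 + shape(r, 60) + shape(r, 360) + rnorm(length(t), 0, 0.01)), t)
  emb <- pca_subtrajectories(traces, list(c(60, 200), c(360, 500)))
  expect_equal(nrow(emb), 32)
  # explained variances non-increasing
  expect_true(all(diff(attr(emb, "explained")) <= 1e-8))
  # the two windows of one cell land in the same class cluster:
  # classify by sign of PC1 and compare with truth up to label flip
  cl <- tapply(sign(emb$PC1), list(emb$cell_id, emb$window), identity)
  expect_true(all(cl[, 1] == cl[, 2]))
  agree <- mean((emb$PC1 > 0)[emb$window == 1] == truth)
  expect_true(agree %in% c(0, 1))
})

test_that("pair concordance counts matching calls", {
  resp <- data.frame(cell_id = 1:8,
                     responder = c(TRUE, TRUE, FALSE, FALSE,
                                   TRUE, FALSE, TRUE, TRUE))
  pairs <- cbind(c(1, 3, 5, 7), c(2, 4, 6, 8))
  expect_equal(pair_concordance(resp, pairs), 0.75)
  twins <- data.frame(cell_id = 1:4, responder = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(pair_concordance(twins, cbind(c(1, 3), c(2, 4))), 1)
  expect_error(pair_concordance(twins, cbind(1, 99)), "unmatched")

  # independent Bernoulli(0.5) calls are concordant about half the time
  set.seed(5)
  calls <- data.frame(cell_id = 1:2000,
                      responder = runif(2000) < 0.5)
  expect_equal(pair_concordance(calls, cbind(seq(1, 1999, 2),
                                             seq(2, 2000, 2))),
               0.5, tolerance = 0.05)
})
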