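test_that("synthetic counts have the constructed statistical structure", {
  genes <- default_gene_panel(n_endogenous = 12, seed = 1)
  act <- c(U = 0, T = 1, TT = 1.4, TIT = 2.2)

  # near-Poisson limit: CV^2 ~ 1/mean for flat housekeeping genes
  g <- generate_counts(genes, act, n_rep = 40, dispersion = 1e8, seed = 2)
  hk <- g$counts$counts[genes$class == "housekeeping", ]
  cv2 <- apply(hk, 1, function(v) stats::var(v) / mean(v)^2)
  expect_equal(unname(cv2 * rowMeans(hk)), rep(1, 5), tolerance = 0.35)

  # equal activities: fold changes vanish
  g0 <- generate_counts(genes, c(U = 1, T = 1, TT = 1), n_rep = 4,
                        dispersion = 200, seed = 3)
  fc0 <- fold_change_table(normalize_counts(g0$counts))
  expect_lt(stats::median(abs(fc0[genes$class == "endogenous", ]),
                          na.rm = TRUE), 0.35)

  # reproducibility
  a <- generate_counts(genes, act, seed = 7)
  b <- generate_counts(genes, act, seed = 7)
  expect_identical(a$counts$counts, b$counts$counts)
})

test_that("activity-driven genes correlate with activity end to end", {
  genes <- default_gene_panel(n_endogenous = 15, seed = 5)
  act <- c(U = 0, T = 1, TT = 1.5, T_T = 0.8, TIT = 2.5)
  g <- generate_counts(genes, act, n_rep = 3, dispersion = 150, seed = 6)
  norm <- normalize_counts(g$counts)
  fc <- fold_change_table(norm, reference = "U")
  r <- correlate_activity(fc, act[colnames(fc)])
  endo <- intersect(names(r), genes$gene[genes$class == "endogenous"])
  expect_gt(stats::median(r[endo]), 0.9)
})

test_that("trace generator output is reproducible and labelled", {
  prot <- parse_protocol("T@0,T@60", t_end = 140)
  a <- generate_traces(6, prot, mode = "label", responder_fraction = 0.5,
                       noise_sd = 0.05, seed = 21)
  b <- generate_traces(6, prot, mode = "label", responder_fraction = 0.5,
                       noise_sd = 0.05, seed = 21)
  expect_identical(a$traces, b$traces)
  expect_identical(a$labels, b$labels)
  expect_equal(sort(unique(a$traces$cell_id)), 1:6)
  # labels stay in a sidecar, never in the trace table
  expect_false("responder_p2" %in% names(a$traces))

  # noiseless model mode returns the model observables exactly
  m <- generate_traces(2, prot, mode = "model", sigma = 1e5,
                       noise_sd = 0, drift = 0, seed = 3)
  tr <- m$traces[m$traces$cell_id == 1, ]
  ref <- run_population(m$cells[1], prot, nfkb_params(), dt_out = 5)[[1]]
  expect_equal(tr$nfkb_nt, unname(ref$nfkb_nuclear_fraction),
               tolerance = 1e-12)
  expect_equal(tr$ikba_total,
               unname(ref$total_ikba / ref$total_ikba[1]),
               tolerance = 1e-12)
})

test_that("noisy label-mode traces are recovered by the gradient rule", {
  prot <- parse_protocol("T@0,T@60", t_end = 140)
  g <- generate_traces(60, prot, mode = "label", responder_fraction = 0.4,
                       noise_sd = 0.05, seed = 31)
  calls <- vapply(unique(g$traces$cell_id), function(id)
    classify_responder_trace(g$traces[g$traces$cell_id == id, ], 60),
    logical(1))
  expect_gte(mean(calls == g$labels$responder_p2), 0.9)
})

test_that("daughter pairs share draws unless diverged", {
  prot <- parse_protocol("T@0,T@70", t_end = 160)
  g0 <- generate_daughter_pairs(3, divergence_prob = 0, protocol = prot,
                                seed = 41, noise_sd = 0)
  expect_false(any(g0$lineage$diverged))
  expect_equal(pair_concordance(g0$responses,
                                g0$lineage[, c("cell_a", "cell_b")]), 1)

  g1 <- generate_daughter_pairs(3, divergence_prob = 1, protocol = prot,
                                seed = 42, noise_sd = 0)
  expect_true(all(g1$lineage$diverged))
  expect_true(all(g1$lineage$division_time < 0))
  expect_error(generate_daughter_pairs(2, divergence_prob = 2), "divergence")
})

test_that("trace tables round-trip with normalization on load", {
  prot <- parse_protocol("T@0", t_end = 60)
  g <- generate_traces(2, prot, mode = "label", seed = 1, noise_sd = 0)
  tr <- g$traces
  tr$ikba_total <- tr$ikba_total * 123  # arbitrary intensity units
  f <- tempfile(fileext = ".csv")
  write_traces(tr, f)
  back <- read_traces(f)
  expect_equal(back$ikba_total[back$cell_id == 1][1], 1)
  unlink(f)
})
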