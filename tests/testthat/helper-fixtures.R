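# small constructors for synthetic trajectories and traces used across tests

fake_trajectory <- function(time, nf, ikba, nfkbtot = 1e5) {
  states <- matrix(0, nrow = length(time), ncol = 15,
                   dimnames = list(NULL, nfkbpulse:::.state_names))
  states[, "NFKBn"] <- nf * nfkbtot
  states[, "IkBc"] <- ikba
  structure(list(time = time, states = states,
                 nfkb_nuclear_fraction = nf, total_ikba = ikba,
                 a20_protein = states[, "A20"],
                 params = nfkb_params(), protocol = NULL),
            class = "nfkb_trajectory")
}

# long-format trace table from per-cell signal vectors
make_traces <- function(signals, time, nt = NULL) {
  do.call(rbind, lapply(seq_along(signals), function(i) {
    data.frame(cell_id = i, time_min = time, ikba_total = signals[[i]],
               nfkb_nt = if (is.null(nt)) 0 else nt[[i]])
  }))
}

expect_within <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
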