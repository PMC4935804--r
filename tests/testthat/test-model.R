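test_that("parameter constructor validates overrides", {
  p <- nfkb_params(m3 = 0.01)
  expect_equal(p$m3, 0.01)
  expect_error(nfkb_params(zz = 1), "unknown parameter")
  expect_error(validate_params(nfkb_params(c1 = -1)), "negative")
  expect_error(validate_params(nfkb_params(kA20_T = 1e5, kA20_I = 1e4)),
               "kA20_T")
})

test_that("unstimulated steady state is a resting fixed point", {
  p <- nfkb_params()
  ss <- steady_state(p)
  d <- nfkb_derivatives(ss, 0, p, nfkb_protocol(NULL, t_end = 100))
  expect_lt(max(abs(d) / pmax(ss, 1)), 1e-4)
  # no stimulus: no active or inactive IKKK, neutral pool = total
  expect_lt(ss["IKKKa_T"] + ss["IKKKi_T"], 1e-3 * p$IKKKtott_T)
  expect_lt(ss["IKKa"], 1e-2 * p$IKKtot)
  # resting cells are predominantly cytoplasmic: below the responder level
  expect_lt((ss["NFKBn"] + ss["Cn"]) / p$nfkbtot, 0.15)
})

test_that("removing A20 transcription empties the A20 pool at rest", {
  p <- nfkb_params(c1 = 0)
  ss <- steady_state(p)
  expect_equal(unname(ss["A20"]), 0, tolerance = 1e-6)
  expect_equal(unname(ss["RmA"]), 0, tolerance = 1e-6)
})

test_that("compiled and reference derivatives agree", {
  p <- nfkb_params()
  prot <- parse_protocol("T@0,I@50", t_end = 200)
  ss <- steady_state(p)
  traj <- simulate_cell(p, prot, dt_out = 10)
  for (i in c(2, 4, 8, 15)) {
    y <- pmax(traj$states[i, ], 0)
    t <- traj$time[i]
    dR <- nfkb_derivatives(y, t, p, prot)
    # finite-difference check against the integrated path
    h <- 1e-3
    fine <- nfkbpulse:::.ode(y, c(t, t + h), p, prot)
    dFD <- (fine[2, nfkbpulse:::.state_names] - y) / h
    scale <- pmax(abs(dR), 1e3)
    expect_lt(max(abs(dR - dFD) / scale), 1e-2)
  }
  expect_error(nfkb_derivatives(ss - 1e4, 0, p, prot), "negative")
})

test_that("instantaneous flux limits behave as the network dictates", {
  p <- nfkb_params()
  ss <- steady_state(p)
  prot <- nfkb_protocol(data.frame(start = 0, duration = 5,
                                   cytokine = "TNF", dose = 10),
                        t_end = 100)
  # saturating A20 fully inhibits IKKK activation during a pulse
  s <- ss; s["A20"] <- 1e12
  d_hi <- nfkb_derivatives(s, 2, p, prot)["IKKKa_T"]
  s["A20"] <- 0
  d_zero <- nfkb_derivatives(s, 2, p, prot)["IKKKa_T"]
  expect_lt(d_hi, 1e-6 * d_zero)

  # half-maximal point of the IKK activation Hill term:
  # IKKKa total = sIKKK and all IKK neutral -> flux = kact * IKKtot / 2
  s2 <- ss
  s2["IKKKa_T"] <- p$sIKKK / 2; s2["IKKKa_I"] <- p$sIKKK / 2
  s2["IKKa"] <- 0; s2["IKKi"] <- 0
  d2 <- nfkb_derivatives(s2, 50, p, .empty <- nfkb_protocol(NULL, 100))
  expect_equal(unname(d2["IKKa"]), p$kact * p$IKKtot / 2, tolerance = 1e-8)
})

test_that("simulation conserves totals and stays non-negative", {
  p <- nfkb_params()
  prot <- parse_protocol("T@0,T@60", t_end = 300)
  traj <- simulate_cell(p, prot)
  st <- traj$states
  nf <- rowSums(st[, c("NFKBc", "NFKBn", "Cc", "Cn")])
  expect_lt(max(abs(nf / p$nfkbtot - 1)), 1e-6)
  kkT <- rowSums(st[, c("IKKKa_T", "IKKKi_T")])
  expect_true(all(kkT <= p$IKKKtott_T * (1 + 1e-6)))
  ikk <- rowSums(st[, c("IKKa", "IKKi")])
  expect_true(all(ikk <= p$IKKtot * (1 + 1e-6)))
  expect_true(all(st > -1))
  # observables recompute from states
  expect_equal(traj$total_ikba,
               rowSums(st[, c("IkBc", "IkBn", "Cc", "Cn")]))
  expect_equal(traj$nfkb_nuclear_fraction,
               (st[, "NFKBn"] + st[, "Cn"]) / p$nfkbtot)
})

test_that("an unstimulated trajectory stays flat at the steady state", {
  p <- nfkb_params()
  traj <- simulate_cell(p, nfkb_protocol(NULL, t_end = 800), dt_out = 5)
  nf <- traj$nfkb_nuclear_fraction
  expect_lt(diff(range(nf)), 1e-4)
  expect_lt(diff(range(traj$total_ikba)) / traj$total_ikba[1], 1e-4)
})

test_that("trajectory export lists time, species and observables", {
  p <- nfkb_params()
  traj <- simulate_cell(p, parse_protocol("T@0", t_end = 50), dt_out = 10)
  df <- as.data.frame(traj)
  expect_equal(nrow(df), 6)
  expect_true(all(c("time_min", "NFKBn", "nfkb_nuclear_fraction",
                    "total_ikba", "a20_protein") %in% names(df)))
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- utils::read.csv(f)
  expect_equal(back$total_ikba, unname(df$total_ikba), tolerance = 1e-8)
  unlink(f)
})

test_that("parameter and protocol configs round-trip through YAML", {
  p <- nfkb_params(m3 = 0.0123)
  f <- tempfile(fileext = ".yml")
  write_params(p, f)
  expect_equal(read_params(f), p)
  prot <- parse_protocol("T@0,I@50,T@100", t_end = 400)
  g <- tempfile(fileext = ".yml")
  write_protocol(prot, g)
  back <- read_protocol(g)
  expect_equal(back$pulses, prot$pulses, ignore_attr = TRUE)
  expect_equal(back$t_end, 400)
  unlink(c(f, g))
})
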