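#!/usr/bin/env Rscript
# Extrinsic vs intrinsic noise: are single-cell refractory states imprinted?
#
# Two candidate noise models generate the same population-level fraction
# curve but make opposite predictions for repeat stimulation. Under
# extrinsic noise (parameters drawn once per cell) a cell's response to a
# pair of TNF pulses is exactly reproducible after a 4-h equilibration gap;
# under intrinsic noise (stochastic on/off switching of the IkBa and A20
# feedback genes) repeat responses are stochastic. Daughter-cell pairs
# probe the stability of the imprinted state across division.

suppressPackageStartupMessages(library(nfkbpulse))
dir.create("results", showWarnings = FALSE)

base <- nfkb_params()
mu <- base$IKKKtott_T
cal <- calibrate_ikkk_distribution(
  c(`50` = 0.05, `60` = 0.30, `70` = 0.70, `100` = 0.93), base, mu = mu)
n_cells <- 150  # per noise model

## equilibrated four-pulse protocol (pairs at 70 min, 4-h gap) ------------
cells <- sample_population(population_spec(n_cells, "extrinsic", list(
  IKKKtott_T = list(mean = mu, sd = cal$sigma)), seed = 801), base)
# at the experimental 4-h gap the model is not yet fully re-equilibrated
# (the IkBa mRNA/protein tail outlives 4 h), so borderline cells can flip;
# at a 12-h gap the extrinsic model is exactly reproducible
ext240 <- equilibrated_pulse_experiment(cells, delta = 70, gap = 240,
                                        base = base,
                                        check_equilibration = FALSE)
ext720 <- equilibrated_pulse_experiment(cells, delta = 70, gap = 720,
                                        base = base)
intr <- equilibrated_pulse_experiment(cells, delta = 70, gap = 720,
                                      base = base, noise_mode = "intrinsic",
                                      rates = list(kon = 0.2, koff = 0.1),
                                      seed = 802)
d240 <- mean(ext240$responded_p2 != ext240$responded_p4)
d720 <- mean(ext720$responded_p2 != ext720$responded_p4)
int_disc <- mean(intr$responded_p2 != intr$responded_p4)
cat(sprintf("Discordant cells (pulse 2 vs pulse 4):\n"))
cat(sprintf("  extrinsic, 4-h gap:  %.3f (borderline cells, incomplete re-equilibration)\n", d240))
cat(sprintf("  extrinsic, 12-h gap: %.3f\n", d720))
cat(sprintf("  intrinsic, 12-h gap: %.3f\n", int_disc))
cat("  (experimental reference: 3 of 79 cells discordant after a 4-h gap)\n")
write.csv(data.frame(model = c("extrinsic_4h", "extrinsic_12h",
                               "intrinsic_12h"),
                     discordant_fraction = c(d240, d720, int_disc),
                     n = n_cells),
          "results/noise_discordance.csv", row.names = FALSE)

## daughter-cell pairs -----------------------------------------------------
pairs <- generate_daughter_pairs(56, divergence_prob = 0.15,
                                 base = base, mu = mu, sigma = cal$sigma,
                                 seed = 803)
conc <- pair_concordance(pairs$responses,
                         pairs$lineage[, c("cell_a", "cell_b")])
cat(sprintf("\nDaughter-pair concordance (56 pairs, divergence 0.15): %.2f\n",
            conc))
write.csv(data.frame(n_pairs = 56, concordance = conc),
          "results/daughter_concordance.csv", row.names = FALSE)

## PCA of repeat-stimulation sub-trajectories ------------------------------
sub <- generate_traces(40, nfkb_protocol(data.frame(
  start = c(0, 70, 310, 380), duration = 5, cytokine = "TNF", dose = 10),
  t_end = 460), mode = "model", sigma = cal$sigma, base = base,
  noise_sd = 0.03, dt_out = 5, seed = 804)
emb <- pca_subtrajectories(sub$traces, list(c(0, 140), c(310, 450)))
agree <- mean(tapply(sign(emb$PC1), emb$cell_id, function(s) s[1] == s[2]))
cat(sprintf("\nPCA: %.0f%% of cells fall in the same cluster in both phases\n",
            100 * agree))
write.csv(cbind(emb, responder = sub$labels$responder_p2[emb$cell_id]),
          "results/pca_subtrajectories.csv", row.names = FALSE)
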