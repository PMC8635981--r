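#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Emulates the study design: 10 dioecious species in five sister pairs plus a
# hermaphrodite outgroup, 6 replicates per sex (5 females in two species),
# species-specific sex bias recruited preferentially from fast-evolving genes
# (the regime under which the ancestral-rate question is interesting), and a
# codon supermatrix whose fourfold-degenerate divergence matches the tree.

library(sbgevol)

seed <- 20260926L
cfg <- sim_config(
  n_genes = 2000, sbg_n = 90, sbg_effect_min = 1.5, sbg_effect_mean = 2.5,
  sbg_rate_quantile = 0.9, codon_sites = 3000, n_alignments = 2, seed = seed
)
data <- simulate_study(cfg)

dir.create("results", showWarnings = FALSE)
write_study(data, "results/data")

diag <- validate_inputs(data$counts, data$samples, data$lengths, data$tree,
                        data$alignments)
stopifnot(all(diag$ok))

message(sprintf("simulated %d genes x %d samples; %d true biased gene-species pairs",
                nrow(data$counts), ncol(data$counts), nrow(data$truth$bias)))
message("inputs written under results/data/")
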