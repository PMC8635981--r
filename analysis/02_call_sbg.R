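#!/usr/bin/env Rscript
# Stage 2: normalization and per-species sex-biased-gene calling.
#
# TMM factors over all samples together, log2(TMM-TPM + 1) expression for the
# downstream comparative analyses, and per-species exact tests at FDR 5% with
# a minimum twofold change.

library(sbgevol)

counts <- as.matrix(read.delim("results/data/counts.tsv", row.names = 1,
                               check.names = FALSE))
samples <- read.delim("results/data/samples.tsv")
lengths <- with(read.delim("results/data/lengths.tsv"),
                setNames(effective_length_bp, gene_id))

factors <- tmm_factors(counts)
norm <- normalized_expression(counts, lengths[rownames(counts)], factors)
calls <- call_sbg(counts, samples, fdr = 0.05, min_fc = 2)
summary <- sbg_summary_metrics(calls)

write.table(data.frame(sample_id = names(factors), tmm_factor = factors),
            "results/tmm_factors.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(gene_id = rownames(norm), round(norm, 4),
                       check.names = FALSE),
            "results/norm_expr.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(calls, "results/sbg_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(summary, "results/sbg_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

n_sbg <- length(unique(calls$gene_id[calls$status %in%
                                       c("male_biased", "female_biased")]))
message(sprintf("%d genes sex-biased in at least one species", n_sbg))
print(summary[, c("species", "n_expressed", "n_male", "n_female")])
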