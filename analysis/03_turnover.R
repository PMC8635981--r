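#!/usr/bin/env Rscript
# Stage 3: evolutionary histories of sex bias and the overlap permutation null.
#
# Each biased gene is classified (unique / shared single-ancestral / shared
# repeated / divergent) with 3-state Mk ancestral-state reconstruction, and
# observed category counts are tested against 10,000 within-species
# identity permutations; single-ancestral-gain genes are excluded from the
# permutation comparison.

library(sbgevol)

calls <- read.delim("results/sbg_calls.tsv")
tree <- read_newick("results/data/tree.nwk")

hist <- classify_histories(calls, tree)
ancestral <- hist$gene_id[grepl("single_ancestral", hist$category)]
overlap <- overlap_permutation_test(calls, n_perm = 10000, seed = 1L,
                                    exclude_genes = ancestral)

write.table(hist, "results/sbg_histories.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(overlap, "results/overlap_test.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("classified %d biased genes; %d gained bias only ancestrally",
                nrow(hist), length(ancestral)))
print(table(hist$category))
print(overlap)
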