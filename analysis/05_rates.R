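#!/usr/bin/env Rscript
# Stage 5: rates of expression evolution before/outside sex bias.
#
# (a) mean |PIC| per gene, with each gene's sex-biased species excluded, so
#     only non-biased observations carry rate information; permutation test
#     of SBGs vs never-biased genes.
# (b) 1 - Pearson expression distances vs fourfold sequence divergence over
#     all 55 species pairs: OLS slopes, Mantel tests, and 1000 noise-matched
#     (CV-matched) surrogate gene sets for the SBG slope.
# (c) hierarchical clustering of species/sex mean profiles (do samples group
#     by species rather than by sex?).

library(sbgevol)

norm <- as.matrix(read.delim("results/norm_expr.tsv", row.names = 1,
                             check.names = FALSE))
samples <- read.delim("results/data/samples.tsv")
counts <- as.matrix(read.delim("results/data/counts.tsv", row.names = 1,
                               check.names = FALSE))
calls <- read.delim("results/sbg_calls.tsv")
tree <- read_newick("results/data/tree.nwk")
seqd <- as.matrix(read.delim("results/seqdist.tsv", row.names = 1,
                             check.names = FALSE))

ss <- species_sex_means(norm, samples)
ing <- sort(unique(samples$species[samples$sex %in% c("M", "F")]))
sp_means <- vapply(ing, function(sp)
  rowMeans(ss[, paste0(sp, c("_M", "_F"))]), numeric(nrow(ss)))
sp_means <- cbind(sp_means, out = ss[, "out_H"])

biased <- calls[calls$status %in% c("male_biased", "female_biased"), ]
sbg_genes <- unique(biased$gene_id)
unb_genes <- setdiff(rownames(norm), sbg_genes)
mask <- matrix(FALSE, nrow(norm), length(ing),
               dimnames = list(rownames(norm), ing))
mask[cbind(biased$gene_id, biased$species)] <- TRUE

# (a) PIC rates with biased tips excluded
pic <- mean_abs_pic_excluding(tree, sp_means, exclude = mask)
pt <- permutation_mean_test(pic[sbg_genes][!is.na(pic[sbg_genes])],
                            pic[unb_genes][!is.na(pic[unb_genes])],
                            n_perm = 10000, alternative = "greater", seed = 2L)
message(sprintf("mean |PIC|: SBG - unbiased = %.3f (permutation p = %.2g)",
                pt$mean_diff, pt$p_value))
write.table(data.frame(gene_id = names(pic), mean_abs_pic = pic,
                       is_sbg = names(pic) %in% sbg_genes),
            "results/pic_rates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# (b) expression distance vs sequence divergence
d_unb <- expression_distance(ss, "unbiased_mean_of_sexes", genes = unb_genes)
fit_unb <- distance_divergence_fit(d_unb, seqd)
mant <- mantel_test(d_unb, seqd, n_perm = 100000, seed = 3L)
cv <- within_group_cv(counts, samples)
nulls <- lapply(c(males = "males", females = "females"), function(mode) {
  noise_matched_slope_null(ss, seqd, sbg_genes, unb_genes, cv, mode = mode,
                           biased_mask = mask, n_rep = 1000, seed = 4L)
})
fits <- data.frame(
  category = c("unbiased_mean_of_sexes", "sbg_males", "sbg_females"),
  slope = c(fit_unb$slope, nulls$males$slope_obs, nulls$females$slope_obs),
  intercept = c(fit_unb$intercept, nulls$males$intercept_obs,
                nulls$females$intercept_obs),
  noise_matched_p = c(NA, nulls$males$p_value, nulls$females$p_value)
)
write.table(fits, "results/distance_fits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("unbiased slope %.2f (Mantel r = %.2f, p = %.2g)",
                fit_unb$slope, mant$r, mant$p_value))
message(sprintf("SBG male slope %.2f exceeds %.1f%% of noise-matched nulls",
                nulls$males$slope_obs,
                100 * mean(nulls$males$null_slopes < nulls$males$slope_obs)))

# (c) clustering of species/sex profiles over the SBGs
hc <- cluster_expression(t(ss[sbg_genes, ]))
message(sprintf("species/sex profiles group by species: %s",
                by_species_grouping(hc, sub("_[MFH]$", "", colnames(ss)))))

# intragroup vs intergroup variation (context for the noise matching)
ii <- intra_inter_correlation(norm, samples)
message(sprintf("intra- vs inter-group correlation: r = %.2f (n = %d genes)",
                ii$pearson, ii$n_genes))
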