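# End-to-end orchestration: simulate -> normalize -> call -> ASR/turnover ->
# rates -> delta-x -> seqdiv -> report, with deterministic per-stage seeds.

# stable per-stage seed derived from the global seed and the stage name,
# so toggling stages never shifts another stage's randomness
stage_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 131L) %% 2147483647L
}

#' Validate cross-file input consistency
#'
#' Diagnostic-only checks: count columns vs sample table, tree tips vs
#' species names, gene-length coverage, alignment taxa coverage.
#'
#' @param counts count matrix.
#' @param samples sample table.
#' @param lengths named gene lengths (optional).
#' @param tree species tree (optional).
#' @param alignments list of alignments (optional).
#' @return data frame of findings (`check`, `ok`, `detail`); zero `!ok` rows
#'   means consistent inputs.
#' @export
validate_inputs <- function(counts, samples, lengths = NULL, tree = NULL,
                            alignments = NULL) {
  f <- list()
  add <- function(check, ok, detail = "") {
    f[[length(f) + 1]] <<- data.frame(check = check, ok = ok, detail = detail)
  }
  missing_cols <- setdiff(colnames(counts), samples$sample_id)
  add("counts columns in sample table", length(missing_cols) == 0,
      paste(missing_cols, collapse = ", "))
  missing_samp <- setdiff(samples$sample_id, colnames(counts))
  add("sample table rows in counts", length(missing_samp) == 0,
      paste(missing_samp, collapse = ", "))
  add("sexes valid", all(samples$sex %in% c("M", "F", "H")),
      paste(setdiff(unique(samples$sex), c("M", "F", "H")), collapse = ", "))
  if (!is.null(lengths)) {
    missing_len <- setdiff(rownames(counts), names(lengths))
    add("gene lengths cover counts", length(missing_len) == 0,
        if (length(missing_len) > 3) paste(length(missing_len), "genes")
        else paste(missing_len, collapse = ", "))
  }
  if (!is.null(tree)) {
    extra_tips <- setdiff(tree$tip.label, unique(samples$species))
    add("tree tips in sample species", length(extra_tips) == 0,
        paste(extra_tips, collapse = ", "))
    extra_sp <- setdiff(unique(samples$species), tree$tip.label)
    add("sample species in tree", length(extra_sp) == 0,
        paste(extra_sp, collapse = ", "))
  }
  if (!is.null(alignments)) {
    cover <- sort(unique(unlist(lapply(alignments, names))))
    missing_taxa <- setdiff(unique(samples$species), cover)
    add("alignment taxa cover species", length(missing_taxa) == 0,
        paste(missing_taxa, collapse = ", "))
  }
  do.call(rbind, f)
}

#' Run the full analysis pipeline
#'
#' Executes, on simulated (or supplied) data, every stage of the analysis in
#' dependency order: normalization, per-species SBG calling, history
#' classification with the overlap permutation test, PIC-based rate
#' comparison, expression-distance/sequence-divergence analysis with Mantel
#' test and noise-matched slope null, species/sex clustering, delta-x shift
#' classification with Yates chi-squared, and fourfold sequence divergence.
#' The permutation counts default to scaled-down values suitable for quick
#' runs; raise them for full analyses.
#'
#' @param cfg a [sim_config()]; its `seed` seeds every stage deterministically.
#' @param data optional pre-generated study (output of [simulate_study()]);
#'   when NULL, `simulate_study(cfg)` is run.
#' @param fdr,min_fc SBG thresholds.
#' @param shift_fc,deltax_high shift and adaptive-class thresholds.
#' @param n_perm_overlap,mantel_perms,null_reps,perm_mean permutation counts.
#' @param fpr_perms sex-randomization replicates for the empirical FPR stage
#'   (0 skips the stage, the default — it re-runs the full caller per
#'   replicate).
#' @return a report list with one element per stage.
#' @export
run_pipeline <- function(cfg = sim_config(), data = NULL,
                         fdr = 0.05, min_fc = 2,
                         shift_fc = 1.5, deltax_high = 5.0,
                         n_perm_overlap = 1000, mantel_perms = 999,
                         null_reps = 200, perm_mean = 2000, fpr_perms = 0) {
  if (is.null(data)) data <- simulate_study(cfg)
  tree <- data$tree
  report <- list(seed = cfg$seed)

  # normalization
  factors <- tmm_factors(data$counts)
  norm <- normalized_expression(data$counts, data$lengths, factors)
  masks <- expressed_masks(data$counts, data$samples)
  report$normalize <- list(factors = factors, n_expressed = colSums(masks))

  # SBG calling
  calls <- call_sbg(data$counts, data$samples, fdr = fdr, min_fc = min_fc)
  summary_metrics <- sbg_summary_metrics(calls)
  sbg_genes <- unique(calls$gene_id[calls$status %in%
                                      c("male_biased", "female_biased")])
  report$sbg <- list(calls = calls, summary = summary_metrics,
                     n_sbg_genes = length(sbg_genes))

  # turnover: histories + overlap permutations
  hist <- classify_histories(calls, tree)
  ancestral <- hist$gene_id[grepl("single_ancestral", hist$category)]
  overlap <- overlap_permutation_test(
    calls, n_perm = n_perm_overlap,
    seed = stage_seed(cfg$seed, "overlap"), exclude_genes = ancestral
  )
  report$turnover <- list(histories = hist, overlap = overlap,
                          n_ancestral_excluded = length(ancestral))

  # rates: PIC comparison with exclusion of biased tips
  ss <- species_sex_means(norm, data$samples)
  ing <- intersect(tree$tip.label, unique(data$samples$species[data$samples$sex %in% c("M", "F")]))
  sp_means <- vapply(ing, function(sp) {
    rowMeans(ss[, paste0(sp, c("_M", "_F")), drop = FALSE])
  }, numeric(nrow(ss)))
  if ("out" %in% tree$tip.label && "out_H" %in% colnames(ss)) {
    sp_means <- cbind(sp_means, out = ss[, "out_H"])
  }
  biased_mask <- matrix(FALSE, nrow(norm), length(ing),
                        dimnames = list(rownames(norm), ing))
  bb <- calls[calls$status %in% c("male_biased", "female_biased"), ]
  biased_mask[cbind(bb$gene_id, bb$species)] <- TRUE
  pic_all <- mean_abs_pic_excluding(tree, sp_means, exclude = biased_mask)
  unbiased_genes <- setdiff(rownames(norm), sbg_genes)
  pic_test <- if (length(sbg_genes) >= 2) {
    permutation_mean_test(
      pic_all[sbg_genes][!is.na(pic_all[sbg_genes])],
      pic_all[unbiased_genes][!is.na(pic_all[unbiased_genes])],
      n_perm = perm_mean, alternative = "greater",
      seed = stage_seed(cfg$seed, "picperm")
    )
  }
  report$rates_pic <- list(mean_abs_pic = pic_all, test = pic_test)

  # rates: distances vs sequence divergence
  seq_dist <- if (!is.null(data$alignments)) {
    divergence_matrix(data$alignments)
  } else {
    ape::cophenetic.phylo(tree)
  }
  labs <- rownames(seq_dist)
  d_unb <- expression_distance(ss, "unbiased_mean_of_sexes",
                               genes = unbiased_genes, species = labs)
  fit_unb <- distance_divergence_fit(d_unb, seq_dist)
  mant <- mantel_test(d_unb, seq_dist, n_perm = mantel_perms,
                      seed = stage_seed(cfg$seed, "mantel"))
  slope_null <- NULL
  if (null_reps > 0 && length(sbg_genes) >= 5) {
    cv <- within_group_cv(data$counts, data$samples)
    slope_null <- noise_matched_slope_null(
      ss, seq_dist, sbg_genes, unbiased_genes, cv, mode = "males",
      biased_mask = biased_mask, n_rep = null_reps,
      seed = stage_seed(cfg$seed, "slopenull"), species = labs
    )
  }
  hc <- cluster_expression(t(ss))
  grouping <- by_species_grouping(hc, sub("_[MFH]$", "", colnames(ss)))
  report$rates_dist <- list(
    fit_unbiased = fit_unb[c("slope", "intercept", "n_pairs")],
    mantel = mant, slope_null = slope_null,
    by_species_clustering = grouping
  )

  # delta-x
  pairs <- sister_pairs(tree)
  dx <- delta_x_table(norm, data$samples, pairs, masks, calls = calls)
  shifts <- classify_shifts(dx, shift_fc = shift_fc,
                            high_threshold = deltax_high)
  chi2 <- lapply(shifts$tables, function(tab) {
    if (is.null(tab) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      NULL
    } else {
      yates_chi2(tab)
    }
  })
  report$deltax <- list(tables = shifts$tables, chi2 = chi2,
                        n_shifts = sum(shifts$records$is_shift))

  # empirical FPR (optional; expensive)
  if (fpr_perms > 0) {
    sp1 <- ing[1]
    report$fpr <- empirical_fpr(data$counts, data$samples, sp1,
                                n_perm = fpr_perms,
                                seed = stage_seed(cfg$seed, "fpr"),
                                fdr = fdr, min_fc = min_fc)
  }
  report
}

#' Write a study's inputs as plain-text files
#'
#' @param data output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_study <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data.frame(gene_id = rownames(data$counts), data$counts,
                                check.names = FALSE),
                     file.path(dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = names(data$lengths),
                                effective_length_bp = data$lengths),
                     file.path(dir, "lengths.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_newick(data$tree, file.path(dir, "tree.nwk"))
  utils::write.table(data$truth$bias, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(data$alignments)) {
    adir <- file.path(dir, "alignments")
    dir.create(adir, showWarnings = FALSE)
    for (i in seq_along(data$alignments)) {
      write_fasta_alignment(data$alignments[[i]],
                            file.path(adir, sprintf("aln%03d.fasta", i)))
    }
  }
  invisible(dir)
}
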