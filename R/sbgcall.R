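# Per-species differential expression between the sexes: exact
# negative-binomial tests (edgeR), SBG classification at FDR + fold-change
# thresholds, and the sex-label randomization false-positive-rate check.

#' Estimate negative-binomial dispersions
#'
#' Quantile-adjusted conditional maximum likelihood on library-size-equalized
#' pseudo-counts: a common dispersion plus tag-wise (per-gene) dispersions
#' shrunk toward the common value with `prior_df` pseudo-degrees of freedom
#' (edgeR's classic qCML estimators, the pairing used with the exact test).
#'
#' @param counts count matrix restricted to the samples under test.
#' @param groups two-level factor/character vector of group labels.
#' @param prior_df shrinkage prior degrees of freedom (default 10).
#' @return list with `common` (scalar) and `tagwise` (per-gene vector), both
#'   >= 0.
#' @export
estimate_dispersions <- function(counts, groups, prior_df = 10) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (min(table(groups)) < 2 && ncol(counts) < 3) {
    warning("dispersion unidentifiable with one sample per group; using 0")
    return(list(common = 0, tagwise = rep(0, nrow(counts))))
  }
  y <- edgeR::DGEList(counts = counts, group = groups)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  y <- edgeR::estimateCommonDisp(y)
  y <- edgeR::estimateTagwiseDisp(y, prior.df = prior_df)
  list(common = y$common.dispersion, tagwise = y$tagwise.dispersion)
}

#' Exact negative-binomial test between two groups
#'
#' edgeR's exact test: libraries are equalized to a common size by quantile
#' adjustment; conditional on the total pseudo-count of a gene, the group sums
#' follow a distribution that is binomial when the dispersion is 0 and its
#' negative-binomial generalization otherwise; the two-sided p-value sums the
#' probabilities of outcomes at most as likely as the observed one (equal to
#' doubling the smaller tail in the symmetric case). The log2 fold-change uses
#' a small library-size-proportional prior count (default 0.125) so
#' sex-limited genes stay finite. Sign convention: positive = second group
#' level higher; with levels `c("F","M")` positive means male-biased.
#'
#' @param counts count matrix.
#' @param groups two-level grouping; the returned `log2fc` is level 2 minus
#'   level 1.
#' @param dispersions per-gene dispersion vector (or scalar); if NULL,
#'   estimated with [estimate_dispersions()].
#' @param norm_factors optional per-sample scaling factors (e.g. from
#'   [tmm_factors()]); NULL leaves raw library sizes, so that with equal
#'   libraries and zero dispersion the test is exactly the conditional
#'   binomial.
#' @param prior_count fold-change prior count (default 0.125).
#' @param prior_df passed to the dispersion estimator when needed.
#' @return data frame with `gene_id`, `log2fc`, `p_value`.
#' @export
nb_exact_test <- function(counts, groups, dispersions = NULL,
                          norm_factors = NULL, prior_count = 0.125,
                          prior_df = 10) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts, groups, prior_df)$tagwise
  }
  y <- edgeR::DGEList(counts = counts, group = groups)
  if (!is.null(norm_factors)) y$samples$norm.factors <- norm_factors
  res <- edgeR::exactTest(y, dispersion = pmax(dispersions, 0),
                          prior.count = prior_count,
                          pair = levels(groups))
  allzero <- rowSums(counts) == 0
  ids <- rownames(counts)
  if (is.null(ids)) ids <- sprintf("g%05d", seq_len(nrow(counts)))
  out <- data.frame(
    gene_id = ids,
    log2fc = res$table$logFC,
    p_value = pmin(res$table$PValue, 1),
    stringsAsFactors = FALSE
  )
  out$log2fc[allzero] <- 0
  out$p_value[allzero] <- 1
  rownames(out) <- NULL
  out
}

#' Classify genes as sex-biased
#'
#' Benjamini-Hochberg q-values are computed over the species' expressed genes
#' only; a gene is `male_biased` iff `q <= fdr` and `log2fc >= log2(min_fc)`,
#' `female_biased` symmetrically, otherwise `unbiased`; genes failing the
#' expression filter are `not_expressed`.
#'
#' @param p,log2fc per-gene p-values and male-minus-female log2 fold-changes,
#'   aligned with `expressed`.
#' @param expressed logical per-gene expression mask for the species.
#' @param fdr FDR threshold (default 0.05).
#' @param min_fc minimum fold-change between the sexes (default 2).
#' @param gene_ids optional gene identifiers.
#' @return data frame with `gene_id`, `status`, `log2fc`, `p_value`, `fdr_q`.
#' @export
classify_sbg <- function(p, log2fc, expressed, fdr = 0.05, min_fc = 2,
                         gene_ids = NULL) {
  stopifnot(length(p) == length(log2fc), length(p) == length(expressed))
  if (is.null(gene_ids)) gene_ids <- names(p)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_along(p))
  q <- rep(NA_real_, length(p))
  q[expressed] <- stats::p.adjust(p[expressed], method = "BH")
  lfc_min <- log2(min_fc)
  status <- rep("unbiased", length(p))
  status[expressed & q <= fdr & log2fc >= lfc_min] <- "male_biased"
  status[expressed & q <= fdr & log2fc <= -lfc_min] <- "female_biased"
  status[!expressed] <- "not_expressed"
  data.frame(
    gene_id = gene_ids, status = status, log2fc = log2fc,
    p_value = p, fdr_q = q, stringsAsFactors = FALSE
  )
}

#' Call sex-biased genes in every species
#'
#' Runs, per dioecious species: the expression filter, qCML dispersion
#' estimation, the exact test (male vs female), and the FDR + fold-change
#' classification. Tests and BH correction are strictly per species.
#'
#' @param counts full count matrix.
#' @param samples sample table (`sample_id`, `species`, `sex`).
#' @param fdr,min_fc classification thresholds (defaults 0.05 and 2).
#' @param min_reads,min_samples expression-filter parameters.
#' @param prior_df dispersion shrinkage prior df.
#' @return data frame (one row per gene x species) with `gene_id`, `species`,
#'   `status`, `log2fc`, `p_value`, `fdr_q`.
#' @export
call_sbg <- function(counts, samples, fdr = 0.05, min_fc = 2,
                     min_reads = 10, min_samples = 3, prior_df = 10) {
  species <- sort(unique(samples$species[samples$sex %in% c("M", "F")]))
  res <- lapply(species, function(sp) {
    ids <- samples$sample_id[samples$species == sp & samples$sex %in% c("M", "F")]
    sex <- samples$sex[match(ids, samples$sample_id)]
    cts <- counts[, ids, drop = FALSE]
    expressed <- expression_filter(cts, min_reads, min_samples)
    p <- rep(NA_real_, nrow(cts))
    lfc <- rep(NA_real_, nrow(cts))
    if (any(expressed)) {
      sub <- cts[expressed, , drop = FALSE]
      disp <- estimate_dispersions(sub, sex, prior_df)$tagwise
      et <- nb_exact_test(sub, factor(sex, levels = c("F", "M")), disp,
                          norm_factors = tmm_factors(sub))
      p[expressed] <- et$p_value
      lfc[expressed] <- et$log2fc
    }
    cl <- classify_sbg(p, lfc, expressed, fdr, min_fc,
                       gene_ids = rownames(counts))
    cl$species <- sp
    cl[, c("gene_id", "species", "status", "log2fc", "p_value", "fdr_q")]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Empirical false-positive rate by sex-label randomization
#'
#' Re-runs the full per-species SBG call (dispersion, exact test,
#' classification) on datasets in which sex labels are randomized within the
#' species (re-sampling males and females without replacement), and compares
#' the observed SBG count against the resulting null distribution.
#'
#' @param counts full count matrix.
#' @param samples sample table.
#' @param species focal species.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @inheritParams call_sbg
#' @return list with `observed` (SBG count), `null_counts` (length `n_perm`),
#'   and `p_value` = `(1 + #[null >= observed]) / (n_perm + 1)`.
#' @export
empirical_fpr <- function(counts, samples, species, n_perm = 1000, seed = 1L,
                          fdr = 0.05, min_fc = 2, min_reads = 10,
                          min_samples = 3, prior_df = 10) {
  ids <- samples$sample_id[samples$species == species &
                             samples$sex %in% c("M", "F")]
  sex <- samples$sex[match(ids, samples$sample_id)]
  if (min(table(sex)) < 2) stop("need >= 2 samples per sex")
  cts <- counts[, ids, drop = FALSE]
  count_sbgs <- function(labels) {
    st <- data.frame(sample_id = ids, species = species, sex = labels)
    calls <- call_sbg(cts, st, fdr, min_fc, min_reads, min_samples, prior_df)
    sum(calls$status %in% c("male_biased", "female_biased"))
  }
  observed <- count_sbgs(sex)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_perm), function(i) count_sbgs(sample(sex)),
                        numeric(1))
  list(
    observed = observed, null_counts = null_counts,
    p_value = (1 + sum(null_counts >= observed)) / (n_perm + 1)
  )
}
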