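# Count normalization (TMM scaling factors, TPM, log2 transform) and the
# per-species expression filter.

#' TMM scaling factors
#'
#' Trimmed-mean-of-M-values scaling factors via [edgeR::calcNormFactors()]
#' (reference sample by upper-quartile rule, gene-wise log2 ratios doubly
#' trimmed by log-ratio and abundance, precision weights, factors rescaled to
#' geometric mean 1).
#'
#' @param counts non-negative count matrix, genes x samples.
#' @param logratio_trim,abs_trim trim fractions on the log2 ratios (default
#'   0.30) and on absolute abundance (default 0.05).
#' @return named numeric vector of positive per-sample factors with geometric
#'   mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = abs_trim)
  names(f) <- colnames(counts)
  f
}

#' Transcripts per million
#'
#' Length-normalized within-sample relative expression:
#' `TPM_gs = 1e6 * (c_gs / len_g) / sum_g'(c_g's / len_g')`. Columns sum to
#' 1e6.
#'
#' @param counts count matrix, genes x samples.
#' @param lengths per-gene effective lengths (bp), aligned to rows.
#' @return TPM matrix.
#' @export
tpm_matrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0))
  cs <- colSums(counts)
  if (any(cs == 0)) stop("sample(s) with zero total counts")
  rate <- counts / lengths
  sweep(rate, 2, colSums(rate) / 1e6, "/")
}

#' Normalized log2 expression
#'
#' TMM-normalized TPM on the log2 scale: plain TPM (columns summing to 1e6)
#' is divided by the sample's TMM factor (equivalently, the effective library
#' size scales the denominator), then transformed by `log2(x + 1)`. A raw
#' count of 0 maps to exactly 0.
#'
#' @param counts count matrix, genes x samples.
#' @param lengths per-gene effective lengths.
#' @param factors per-sample TMM factors from [tmm_factors()].
#' @return matrix of `log2(TMM-scaled TPM + 1)` values, all finite and >= 0.
#' @export
normalized_expression <- function(counts, lengths, factors) {
  counts <- as.matrix(counts)
  stopifnot(length(factors) == ncol(counts), all(factors > 0))
  tpm <- tpm_matrix(counts, lengths)
  log2(sweep(tpm, 2, factors, "/") + 1)
}

#' Per-species expression filter
#'
#' A gene counts as expressed in a species if its CPM exceeds the cutoff
#' corresponding to `min_reads` mapped reads in the species' smallest library
#' (`cutoff = min_reads * 1e6 / min(library sizes)`) in at least
#' `min_samples` samples of that species. Genes expressed in only one sex
#' (sex-specific or sex-limited) can pass.
#'
#' @param counts counts restricted to one species' samples.
#' @param min_reads read cutoff in the smallest library (default 10).
#' @param min_samples minimum number of samples above the cutoff (default 3).
#' @return logical vector, one element per gene.
#' @export
expression_filter <- function(counts, min_reads = 10, min_samples = 3) {
  counts <- as.matrix(counts)
  libs <- colSums(counts)
  if (any(libs == 0)) stop("sample(s) with zero total counts")
  cutoff <- min_reads * 1e6 / min(libs)
  cpm <- sweep(counts, 2, libs / 1e6, "/")
  rowSums(cpm > cutoff) >= min_samples
}

#' Expression filter for every dioecious species
#'
#' Applies [expression_filter()] to each species with male and female samples
#' (the hermaphrodite outgroup is excluded: the filter is defined on
#' replicated samples and the outgroup is never tested for sex bias).
#'
#' @param counts full count matrix.
#' @param samples sample table with `sample_id`, `species`, `sex`.
#' @inheritParams expression_filter
#' @return logical matrix, genes x species.
#' @export
expressed_masks <- function(counts, samples, min_reads = 10, min_samples = 3) {
  sp <- sort(unique(samples$species[samples$sex %in% c("M", "F")]))
  masks <- vapply(sp, function(s) {
    ids <- samples$sample_id[samples$species == s]
    expression_filter(counts[, ids, drop = FALSE], min_reads, min_samples)
  }, logical(nrow(counts)))
  rownames(masks) <- rownames(counts)
  masks
}
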