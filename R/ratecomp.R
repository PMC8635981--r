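# Rates of expression evolution: 1 - Pearson expression distances with
# pair-level exclusion of sex-biased observations, Mantel tests, distance vs
# divergence regressions, noise-matched slope nulls, permutation mean tests,
# expression specificity, hierarchical clustering of species/sex profiles,
# intra/inter variation correlation, and per-species SBG summary metrics.

#' Mean expression per species and sex
#'
#' @param norm_expr normalized log2 expression matrix, genes x samples.
#' @param samples sample table (`sample_id`, `species`, `sex`).
#' @return genes x groups matrix with columns `"<species>_<sex>"`.
#' @export
species_sex_means <- function(norm_expr, samples) {
  grp <- paste0(samples$species, "_", samples$sex)
  ug <- unique(grp)
  out <- vapply(ug, function(g) {
    ids <- samples$sample_id[grp == g]
    rowMeans(norm_expr[, ids, drop = FALSE])
  }, numeric(nrow(norm_expr)))
  rownames(out) <- rownames(norm_expr)
  out
}

# per-species expression vectors for a distance mode
mode_values <- function(ss_means, mode, species) {
  cols <- colnames(ss_means)
  vapply(species, function(sp) {
    if (sp == "out" || paste0(sp, "_H") %in% cols) {
      ss_means[, paste0(sp, "_H")]
    } else if (mode == "unbiased_mean_of_sexes") {
      rowMeans(ss_means[, paste0(sp, c("_M", "_F")), drop = FALSE])
    } else if (mode == "males") {
      ss_means[, paste0(sp, "_M")]
    } else {
      ss_means[, paste0(sp, "_F")]
    }
  }, numeric(nrow(ss_means)))
}

#' Interspecific expression distance (1 - Pearson's r)
#'
#' For each species pair, the Pearson correlation across genes of the
#' designated expression vectors (mean over the sexes for unbiased-gene
#' distances; male or female columns for SBG distances), restricted to genes
#' not sex-biased in either member of the pair, so sex-biased expression
#' itself never contributes; distance = `1 - r`.
#'
#' @param ss_means genes x (species, sex) mean matrix from
#'   [species_sex_means()].
#' @param mode `"unbiased_mean_of_sexes"`, `"males"` or `"females"`.
#' @param genes genes to use (default all rows).
#' @param biased_mask optional genes x species logical matrix (TRUE = gene is
#'   sex-biased in that species); used for the pair-level exclusion.
#' @param species species to include (default: all species present).
#' @return symmetric distance matrix with zero diagonal (values in [0, 2]).
#' @export
expression_distance <- function(ss_means,
                                mode = c("unbiased_mean_of_sexes", "males", "females"),
                                genes = NULL, biased_mask = NULL,
                                species = NULL) {
  mode <- match.arg(mode)
  if (is.null(species)) {
    species <- unique(sub("_[MFH]$", "", colnames(ss_means)))
  }
  if (is.null(genes)) genes <- rownames(ss_means)
  vals <- mode_values(ss_means[genes, , drop = FALSE], mode, species)
  rownames(vals) <- genes
  n <- length(species)
  D <- matrix(0, n, n, dimnames = list(species, species))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sel <- rep(TRUE, length(genes))
      if (!is.null(biased_mask)) {
        for (sp in intersect(c(species[i], species[j]), colnames(biased_mask))) {
          sel <- sel & !biased_mask[genes, sp]
        }
      }
      if (sum(sel) < 3) {
        stop("fewer than 3 contributing genes for pair ",
             species[i], " - ", species[j])
      }
      r <- stats::cor(vals[sel, i], vals[sel, j])
      D[i, j] <- D[j, i] <- 1 - r
    }
  }
  D
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal triangles, with a one-sided
#' permutation p-value obtained by jointly permuting the rows/columns of the
#' second matrix (via [vegan::mantel()]):
#' `p = (#[perm r >= observed r] + 1) / (n_perm + 1)`.
#'
#' @param d1,d2 symmetric distance matrices with matching labels (>= 4).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1L) {
  labs <- rownames(d1)
  if (is.null(labs) || !setequal(labs, rownames(d2))) {
    stop("distance matrices must share labels")
  }
  if (nrow(d1) < 4) stop("need >= 4 labels")
  d2 <- d2[labs, labs]
  if (stats::sd(d1[lower.tri(d1)]) == 0 || stats::sd(d2[lower.tri(d2)]) == 0) {
    stop("constant distance matrix: correlation undefined")
  }
  set.seed(seed)
  m <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                     permutations = n_perm)
  list(r = unname(m$statistic), p_value = m$signif, n_perm = n_perm)
}

#' Regression of expression distance on sequence divergence
#'
#' Ordinary least squares over all unordered label pairs (n tips give
#' n(n-1)/2 points; 11 tips give 55).
#'
#' @param expr_dist,seq_dist symmetric matrices with matching labels.
#' @return list with `slope`, `intercept`, `se_slope`, `se_intercept`,
#'   `n_pairs` and the per-pair data frame `pairs`.
#' @export
distance_divergence_fit <- function(expr_dist, seq_dist) {
  labs <- rownames(expr_dist)
  if (is.null(labs) || !setequal(labs, rownames(seq_dist))) {
    stop("matrices must share labels")
  }
  seq_dist <- seq_dist[labs, labs]
  ut <- upper.tri(expr_dist)
  if (sum(ut) < 3) stop("need >= 3 pairs")
  df <- data.frame(
    seq = seq_dist[ut], expr = expr_dist[ut],
    a = labs[row(expr_dist)[ut]], b = labs[col(expr_dist)[ut]]
  )
  fit <- stats::lm(expr ~ seq, data = df)
  # exact fits are legitimate here (toy inputs); silence the perfect-fit note
  cf <- suppressWarnings(summary(fit))$coefficients
  list(slope = cf["seq", "Estimate"], intercept = cf["(Intercept)", "Estimate"],
       se_slope = cf["seq", "Std. Error"],
       se_intercept = cf["(Intercept)", "Std. Error"],
       n_pairs = nrow(df), pairs = df)
}

#' Within-group coefficient of variation per gene
#'
#' Mean, over all species x sex groups, of the per-group coefficient of
#' variation (SD/mean) of expression counts — the noise measure used to build
#' noise-matched null gene sets. Groups with zero mean are skipped.
#'
#' @param counts count (or expression) matrix.
#' @param samples sample table; groups with >= 2 replicates are used.
#' @return named per-gene numeric vector (NA if no group is usable).
#' @export
within_group_cv <- function(counts, samples) {
  grp <- paste0(samples$species, "_", samples$sex)
  use <- names(which(table(grp) >= 2))
  cvs <- vapply(use, function(g) {
    ids <- samples$sample_id[grp == g]
    m <- counts[, ids, drop = FALSE]
    mu <- rowMeans(m)
    sd <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
    ifelse(mu > 0, sd / mu, NA_real_)
  }, numeric(nrow(counts)))
  out <- rowMeans(cvs, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  names(out) <- rownames(counts)
  out
}

#' Noise-matched null distribution for the distance-divergence slope
#'
#' Tests whether the SBG slope of expression distance against sequence
#' divergence exceeds what expression noise alone produces: in each of
#' `n_rep` surrogate data sets, every SBG is replaced by an unbiased gene
#' matched within `window` (default 95%-105%) of its coefficient of
#' variation, the distance matrix and OLS slope are recomputed, and the
#' empirical p-value is `(#[null slope >= observed] + 1) / (n_rep + 1)`.
#' SBGs with no eligible match get their window widened stepwise by 5% (the
#' number of widenings is reported). Within a replicate, matches are sampled
#' without replacement whenever possible.
#'
#' @param ss_means genes x (species, sex) mean matrix.
#' @param seq_dist sequence-divergence matrix over the species used.
#' @param sbg_genes character vector of sex-biased gene ids.
#' @param pool_genes character vector of never-biased gene ids.
#' @param cv named per-gene coefficient of variation ([within_group_cv()]).
#' @param mode expression vectors to correlate (`"males"` or `"females"` for
#'   SBG distances).
#' @param biased_mask genes x species logical mask for the observed SBG
#'   distances (pair-level exclusion).
#' @param n_rep number of surrogate sets (default 1000).
#' @param window multiplicative CV matching window (default `c(0.95, 1.05)`).
#' @param seed integer seed.
#' @param species species to include.
#' @return list with `slope_obs`, `intercept_obs`, `null_slopes`, `p_value`,
#'   `n_widened`.
#' @export
noise_matched_slope_null <- function(ss_means, seq_dist, sbg_genes, pool_genes,
                                     cv, mode = "males", biased_mask = NULL,
                                     n_rep = 1000, window = c(0.95, 1.05),
                                     seed = 1L, species = NULL) {
  if (is.null(species)) species <- rownames(seq_dist)
  d_obs <- expression_distance(ss_means, mode, genes = sbg_genes,
                               biased_mask = biased_mask, species = species)
  fit_obs <- distance_divergence_fit(d_obs, seq_dist)
  pool_cv <- cv[pool_genes]
  matches <- vector("list", length(sbg_genes))
  n_widened <- 0L
  for (i in seq_along(sbg_genes)) {
    w <- window
    repeat {
      ok <- pool_genes[!is.na(pool_cv) &
                         pool_cv >= w[1] * cv[sbg_genes[i]] &
                         pool_cv <= w[2] * cv[sbg_genes[i]]]
      if (length(ok) > 0) break
      w <- c(w[1] - 0.05, w[2] + 0.05)
      n_widened <- n_widened + 1L
      if (w[1] <= 0) stop("no CV match found for gene ", sbg_genes[i])
    }
    matches[[i]] <- ok
  }
  if (length(unique(unlist(matches))) < length(sbg_genes)) {
    stop("matched pool smaller than the SBG set")
  }
  set.seed(seed)
  null_slopes <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    taken <- character(0)
    surrogate <- vapply(sample(seq_along(sbg_genes)), function(i) {
      avail <- setdiff(matches[[i]], taken)
      g <- if (length(avail) > 0) {
        if (length(avail) == 1) avail else sample(avail, 1)
      } else {
        m <- matches[[i]]
        if (length(m) == 1) m else sample(m, 1)
      }
      taken <<- c(taken, g)
      g
    }, "")
    d_null <- expression_distance(ss_means, mode, genes = surrogate,
                                  species = species)
    null_slopes[r] <- distance_divergence_fit(d_null, seq_dist)$slope
  }
  list(slope_obs = fit_obs$slope, intercept_obs = fit_obs$intercept,
       null_slopes = null_slopes,
       p_value = (1 + sum(null_slopes >= fit_obs$slope)) / (n_rep + 1),
       n_widened = n_widened)
}

#' Permutation test for a difference in means
#'
#' Unpaired: group labels are permuted. Paired: the signs of the per-pair
#' differences are flipped at random. p-values use the `+1` correction.
#'
#' @param a,b numeric vectors (equal length when `paired`).
#' @param n_perm number of permutations (default 10000).
#' @param alternative `"two.sided"`, `"greater"` (mean(a) > mean(b)) or
#'   `"less"`.
#' @param paired logical.
#' @param seed integer seed.
#' @return list with `mean_diff` (mean(a) - mean(b)), `p_value`, `n_perm`.
#' @export
permutation_mean_test <- function(a, b, n_perm = 10000,
                                  alternative = c("two.sided", "greater", "less"),
                                  paired = FALSE, seed = 1L) {
  alternative <- match.arg(alternative)
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  set.seed(seed)
  if (paired) {
    if (length(a) != length(b)) stop("paired test needs equal lengths")
    d <- a - b
    obs <- mean(d)
    null <- vapply(seq_len(n_perm), function(i) {
      mean(d * sample(c(-1, 1), length(d), replace = TRUE))
    }, numeric(1))
  } else {
    obs <- mean(a) - mean(b)
    pooled <- c(a, b)
    na <- length(a)
    null <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), na)
      mean(pooled[idx]) - mean(pooled[-idx])
    }, numeric(1))
  }
  p <- switch(alternative,
    two.sided = (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1),
    greater = (1 + sum(null >= obs)) / (n_perm + 1),
    less = (1 + sum(null <= obs)) / (n_perm + 1)
  )
  list(mean_diff = obs, p_value = p, n_perm = n_perm)
}

#' Expression specificity from a tissue/stage profile
#'
#' Shannon-entropy-based specificity on a 0-1 scale: with
#' `p_i = x_i / sum(x)` and `H = -sum p_i log2 p_i` (0 log 0 := 0),
#' specificity is `1 - H / log2(N)` — 0 for ubiquitous expression, 1 for
#' expression confined to a single tissue or stage.
#'
#' @param profile genes x N matrix of non-negative mean expression over N
#'   tissue/stage groups.
#' @return per-gene specificity in [0, 1]; all-zero genes are NA.
#' @export
specificity_from_profile <- function(profile) {
  profile <- as.matrix(profile)
  if (any(profile < 0)) stop("profile values must be >= 0")
  rs <- rowSums(profile)
  p <- profile / rs
  h <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  out <- 1 - h / log2(ncol(profile))
  out[rs == 0] <- NA_real_
  names(out) <- rownames(profile)
  out
}

#' Hierarchical clustering of species/sex expression profiles
#'
#' Agglomerative clustering (complete linkage) on `1 - Pearson's r` distances
#' between the rows (species x sex groups) of a mean-expression matrix.
#'
#' @param mat groups x genes matrix (rows are clustered).
#' @return an [stats::hclust] object.
#' @export
cluster_expression <- function(mat) {
  if (nrow(mat) < 3) stop("need >= 3 rows")
  d <- stats::as.dist(1 - stats::cor(t(mat)))
  stats::hclust(d, method = "complete")
}

#' Do samples group by species rather than by sex?
#'
#' The computable predicate behind the clustering check: TRUE iff, for every
#' species with both sexes present, the two sexes of that species are merged
#' (cophenetically closer to each other) before either joins any row of
#' another species.
#'
#' @param hc [stats::hclust] from [cluster_expression()].
#' @param species character vector assigning each clustered row to a species.
#' @return logical.
#' @export
by_species_grouping <- function(hc, species) {
  coph <- as.matrix(stats::cophenetic(hc))
  labs <- hc$labels
  ok <- TRUE
  for (sp in unique(species)) {
    rows <- which(species == sp)
    if (length(rows) != 2) next
    within <- coph[rows[1], rows[2]]
    others <- setdiff(seq_along(labs), rows)
    if (length(others) == 0) next
    if (within >= min(coph[rows, others])) ok <- FALSE
  }
  ok
}

#' Correlation of within-group variation with between-group differences
#'
#' Per gene: the pooled within-group SD across species x sex groups and the
#' mean absolute pairwise difference of group means; returns the Pearson and
#' Spearman correlations of the two quantities across genes (constant genes
#' excluded).
#'
#' @param norm_expr expression matrix, genes x samples.
#' @param samples sample table; groups need >= 2 replicates.
#' @return list with `pearson`, `spearman`, `n_genes`.
#' @export
intra_inter_correlation <- function(norm_expr, samples) {
  grp <- paste0(samples$species, "_", samples$sex)
  use <- names(which(table(grp) >= 2))
  if (length(use) < 2) stop("need >= 2 groups with >= 2 replicates")
  means <- vapply(use, function(g) {
    rowMeans(norm_expr[, samples$sample_id[grp == g], drop = FALSE])
  }, numeric(nrow(norm_expr)))
  ss <- vapply(use, function(g) {
    ids <- samples$sample_id[grp == g]
    m <- norm_expr[, ids, drop = FALSE]
    rowSums((m - rowMeans(m))^2)
  }, numeric(nrow(norm_expr)))
  df <- vapply(use, function(g) sum(grp == g) - 1, numeric(1))
  within_sd <- sqrt(rowSums(ss) / sum(df))
  pairs <- utils::combn(length(use), 2)
  between <- rowMeans(abs(means[, pairs[1, ], drop = FALSE] -
                            means[, pairs[2, ], drop = FALSE]))
  keep <- is.finite(within_sd) & is.finite(between) &
    (within_sd > 0 | between > 0)
  list(
    pearson = stats::cor(within_sd[keep], between[keep]),
    spearman = stats::cor(within_sd[keep], between[keep], method = "spearman"),
    n_genes = sum(keep)
  )
}

#' Per-species SBG summary metrics
#'
#' For each species and sex: the number of biased genes, their proportion of
#' the species' expressed genes, and the cumulative fold-change
#' `sum(2^|log2fc|)` over the biased genes — the responses regressed against
#' morphological dimorphism.
#'
#' @param calls SBG call table from [call_sbg()].
#' @return data frame per species: `species`, `n_expressed`, `n_male`,
#'   `n_female`, `prop_male`, `prop_female`, `prop_total`, `cumfc_male`,
#'   `cumfc_female`.
#' @export
sbg_summary_metrics <- function(calls) {
  species <- sort(unique(calls$species))
  rows <- lapply(species, function(sp) {
    cs <- calls[calls$species == sp, ]
    n_exp <- sum(cs$status != "not_expressed")
    male <- cs[cs$status == "male_biased", ]
    female <- cs[cs$status == "female_biased", ]
    data.frame(
      species = sp, n_expressed = n_exp,
      n_male = nrow(male), n_female = nrow(female),
      prop_male = if (n_exp > 0) nrow(male) / n_exp else 0,
      prop_female = if (n_exp > 0) nrow(female) / n_exp else 0,
      prop_total = if (n_exp > 0) (nrow(male) + nrow(female)) / n_exp else 0,
      cumfc_male = sum(2^abs(male$log2fc)),
      cumfc_female = sum(2^abs(female$log2fc))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
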