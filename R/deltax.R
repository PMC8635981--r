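# Interspecific expression shifts between sister species, the delta-x
# divergence/polymorphism statistic, adaptive-shift classification, and the
# Yates-corrected chi-squared association test.

#' Sister-species pairs from the tree
#'
#' Resolves each dioecious ingroup species to its single sister species:
#' cherries (two-tip sister clades) resolve automatically; other species need
#' an explicit pair list, which overrides the tree when supplied. The
#' outgroup (`"out"`) is excluded.
#'
#' @param tree species tree.
#' @param pairs optional two-column matrix/data frame of explicit pairs.
#' @return named character vector: `pairs["spA"]` is the sister of `spA`;
#'   symmetric over the ingroup.
#' @export
sister_pairs <- function(tree, pairs = NULL) {
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    out <- c(stats::setNames(pairs[, 2], pairs[, 1]),
             stats::setNames(pairs[, 1], pairs[, 2]))
    return(out)
  }
  ing <- setdiff(tree$tip.label, "out")
  n_tip <- length(tree$tip.label)
  out <- character(0)
  unresolved <- character(0)
  for (sp in ing) {
    tip <- which(tree$tip.label == sp)
    parent <- tree$edge[tree$edge[, 2] == tip, 1]
    sibs <- tree$edge[tree$edge[, 1] == parent, 2]
    sibs <- setdiff(sibs, tip)
    if (length(sibs) == 1 && sibs <= n_tip) {
      out[sp] <- tree$tip.label[sibs]
    } else {
      unresolved <- c(unresolved, sp)
    }
  }
  if (length(unresolved) > 0) {
    stop("species without a single sister tip (supply explicit pairs): ",
         paste(unresolved, collapse = ", "))
  }
  out
}

row_sd <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
}

#' Delta-x records for every gene, focal species and sex
#'
#' For each gene expressed in a focal species, each sex separately:
#' divergence = |mean focal - mean sister| of the per-sample log2 expression
#' values of that sex; polymorphism = sample SD (denominator n-1) over the
#' focal species' replicates of that sex; `delta_x` = divergence / SD
#' (`Inf` when SD = 0 with positive divergence, 0 when both are 0). Every
#' species is focal once per pair, so both directions of a pair are computed.
#'
#' @param norm_expr normalized log2 expression, genes x samples.
#' @param samples sample table.
#' @param pairs sister mapping from [sister_pairs()].
#' @param expressed_mask genes x species logical matrix ([expressed_masks()]).
#' @param calls optional SBG call table; fills `is_sex_biased` (gene biased,
#'   either direction, in the focal species).
#' @return data frame with `gene_id`, `focal`, `sister`, `sex`, `mean_focal`,
#'   `mean_sister`, `sd_focal`, `abs_diff`, `delta_x`, `is_sex_biased`.
#' @export
delta_x_table <- function(norm_expr, samples, pairs, expressed_mask,
                          calls = NULL) {
  res <- list()
  for (focal in names(pairs)) {
    sister <- pairs[[focal]]
    genes <- rownames(norm_expr)[expressed_mask[, focal]]
    if (length(genes) == 0) next
    biased <- rep(FALSE, length(genes))
    if (!is.null(calls)) {
      st <- calls[calls$species == focal &
                    calls$status %in% c("male_biased", "female_biased"), ]
      biased <- genes %in% st$gene_id
    }
    for (sex in c("M", "F")) {
      fids <- samples$sample_id[samples$species == focal & samples$sex == sex]
      sids <- samples$sample_id[samples$species == sister & samples$sex == sex]
      if (length(fids) < 2 || length(sids) < 1) next
      fm <- rowMeans(norm_expr[genes, fids, drop = FALSE])
      sm <- rowMeans(norm_expr[genes, sids, drop = FALSE])
      sd_f <- row_sd(norm_expr[genes, fids, drop = FALSE])
      ad <- abs(fm - sm)
      dx <- ifelse(sd_f > 0, ad / sd_f, ifelse(ad > 0, Inf, 0))
      res[[length(res) + 1]] <- data.frame(
        gene_id = genes, focal = focal, sister = sister, sex = sex,
        mean_focal = fm, mean_sister = sm, sd_focal = sd_f,
        abs_diff = ad, delta_x = dx, is_sex_biased = biased,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify expression shifts and build the contingency tables
#'
#' A record is a quantitative evolutionary shift iff the interspecific
#' fold-change of the means is at least `shift_fc` on the log2 scale
#' (`|delta of log2 means| >= log2(shift_fc)`, boundary included). Shifts with
#' `delta_x >= high_threshold` (boundary included by default) are "high
#' delta-x", the class more consistent with directional selection. Only
#' shifts enter the per-sex 2x2 tables of (high vs low delta-x) x (gene
#' sex-biased in the focal species vs not).
#'
#' @param records output of [delta_x_table()].
#' @param shift_fc minimum interspecific fold-change (default 1.5).
#' @param high_threshold delta-x cutoff for the adaptive class (default 5.0).
#' @param inclusive_high include the boundary in the high class (default TRUE).
#' @return list with `records` (flags added) and `tables`, a list of 2x2
#'   integer matrices per sex (rows high/low delta-x, columns sex_biased /
#'   unbiased); a sex with no shifts gets NULL with a message.
#' @export
classify_shifts <- function(records, shift_fc = 1.5, high_threshold = 5.0,
                            inclusive_high = TRUE) {
  records$is_shift <- records$abs_diff >= log2(shift_fc)
  records$is_high_delta_x <- if (inclusive_high) {
    records$delta_x >= high_threshold
  } else {
    records$delta_x > high_threshold
  }
  tables <- list()
  for (sex in c("M", "F")) {
    sub <- records[records$sex == sex & records$is_shift, ]
    if (nrow(sub) == 0) {
      message("no shifts for sex ", sex, "; contingency table skipped")
      tables[[sex]] <- NULL
      next
    }
    tables[[sex]] <- matrix(
      c(sum(sub$is_high_delta_x & sub$is_sex_biased),
        sum(!sub$is_high_delta_x & sub$is_sex_biased),
        sum(sub$is_high_delta_x & !sub$is_sex_biased),
        sum(!sub$is_high_delta_x & !sub$is_sex_biased)),
      2, 2,
      dimnames = list(c("high_delta_x", "low_delta_x"),
                      c("sex_biased", "unbiased"))
    )
  }
  list(records = records, tables = tables)
}

#' Yates-corrected chi-squared test on a 2x2 table
#'
#' Continuity-corrected chi-squared: with `E_ij = row_i col_j / N` and
#' correction `min(0.5, |O - E|)`, the statistic is
#' `sum((|O_ij - E_ij| - c)^2 / E_ij)` on 1 df (as in
#' [stats::chisq.test()] with `correct = TRUE`).
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @return list with `statistic`, `p_value`, `expected` (2x2 matrix).
#' @export
yates_chi2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in contingency table")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       expected = ct$expected)
}
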