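test_that("expression distance is 1 - r with pair-level exclusion", {
  ss <- cbind(
    A_M = c(1, 2, 3), A_F = c(1, 2, 3),
    B_M = c(1, 2, 3), B_F = c(1, 2, 3),
    C_M = c(3, 2, 1), C_F = c(3, 2, 1)
  )
  rownames(ss) <- c("g1", "g2", "g3")
  D <- expression_distance(ss, "unbiased_mean_of_sexes")
  expect_equal(D["A", "B"], 0)
  expect_equal(D["A", "C"], 2) # perfect anticorrelation
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))

  # exclusion of a gene biased in one species, checked against a manual
  # subset correlation on a 5-gene toy
  set.seed(5)
  v <- matrix(rnorm(10), 5, 2, dimnames = list(sprintf("g%d", 1:5), NULL))
  ss2 <- cbind(A_M = v[, 1], A_F = v[, 1], B_M = v[, 2], B_F = v[, 2])
  mask <- matrix(FALSE, 5, 2, dimnames = list(rownames(ss2), c("A", "B")))
  mask["g2", "A"] <- TRUE
  D2 <- expression_distance(ss2, "unbiased_mean_of_sexes", biased_mask = mask)
  manual <- 1 - cor(v[-2, 1], v[-2, 2])
  expect_equal(D2["A", "B"], manual, tolerance = 1e-12)

  # a pair with too few contributing genes errors with the pair named
  mask_all <- mask; mask_all[c("g1", "g3", "g4"), "B"] <- TRUE
  expect_error(expression_distance(ss2, "unbiased_mean_of_sexes",
                                   biased_mask = mask_all), "A - B")
})

test_that("Mantel test hits the permutation floor on identical matrices", {
  set.seed(6)
  n <- 8
  p <- matrix(rnorm(n * 3), n)
  D1 <- as.matrix(dist(p))
  dimnames(D1) <- list(letters[1:n], letters[1:n])
  r <- mantel_test(D1, D1, n_perm = 199, seed = 1)
  expect_equal(r$r, 1)
  expect_equal(r$p_value, 1 / 200)
  # affine transform preserves r = 1
  D2 <- 0.3 + 2 * D1; diag(D2) <- 0
  expect_equal(mantel_test(D1, D2, n_perm = 99, seed = 1)$r, 1)
  # constant matrix is rejected
  Dc <- matrix(1, n, n, dimnames = dimnames(D1)); diag(Dc) <- 0
  expect_error(mantel_test(D1, Dc * 0, n_perm = 9), "constant")
})

test_that("distance-divergence fit recovers exact lines over all pairs", {
  tr <- default_fixture_tree()
  seqd <- ape::cophenetic.phylo(tr)
  labs <- rownames(seqd)
  exprd <- 0.5 + 2 * seqd; diag(exprd) <- 0
  fit <- distance_divergence_fit(exprd, seqd)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-10)
  expect_equal(fit$n_pairs, 55) # 11 tips -> 55 unordered pairs
  perm <- sample(labs)
  fit2 <- distance_divergence_fit(exprd[perm, perm], seqd)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-12)
})

test_that("permutation mean test is exact in degenerate cases", {
  x <- c(1, 2, 3, 4)
  same <- permutation_mean_test(x, x, n_perm = 500, seed = 1)
  expect_equal(same$p_value, 1, tolerance = 0.05)
  sep <- permutation_mean_test(rnorm(200, 10), rnorm(200, 0),
                               n_perm = 2000, seed = 2)
  expect_equal(sep$p_value, 1 / 2001)
  paired0 <- permutation_mean_test(x, x, paired = TRUE, n_perm = 100, seed = 3)
  expect_equal(paired0$p_value, 1)
  expect_error(permutation_mean_test(numeric(0), x), "empty")
})

test_that("specificity transform spans 0 (ubiquitous) to 1 (specific)", {
  prof <- rbind(
    uniform = rep(4, 24),
    single = c(9, rep(0, 23)),
    half = c(5, 5, rep(0, 22))
  )
  s <- specificity_from_profile(prof[, 1:24])
  expect_equal(unname(s["uniform"]), 0)
  expect_equal(unname(s["single"]), 1)
  s4 <- specificity_from_profile(rbind(h = c(0.5, 0.5, 0, 0)))
  expect_equal(unname(s4["h"]), 0.5)
  # scale invariance and all-zero handling
  expect_equal(specificity_from_profile(prof * 17), s)
  expect_true(is.na(specificity_from_profile(rbind(z = rep(0, 5)))[["z"]]))
})

test_that("clustering predicate detects by-species grouping", {
  set.seed(7)
  base <- matrix(rnorm(2 * 50, sd = 3), 2, 50)
  rows <- rbind(base[1, ] + rnorm(50, sd = 0.01),
                base[1, ] + rnorm(50, sd = 0.01),
                base[2, ] + rnorm(50, sd = 0.01),
                base[2, ] + rnorm(50, sd = 0.01))
  rownames(rows) <- c("A_M", "A_F", "B_M", "B_F")
  hc <- cluster_expression(rows)
  expect_true(by_species_grouping(hc, c("A", "A", "B", "B")))
  # identical rows merge at height zero
  flat <- matrix(rep(1:10, 3), 3, 10, byrow = TRUE,
                 dimnames = list(c("r1", "r2", "r3"), NULL))
  hc0 <- cluster_expression(flat)
  expect_equal(hc0$height, rep(0, 2))
})

test_that("intra/inter correlation is null-calibrated and detects coupling", {
  set.seed(8)
  n <- 5000
  samples <- toy_samples(c("A", "B"), reps = 3)
  # homoskedastic null: equal means, equal noise
  x <- matrix(rnorm(n * nrow(samples)), n,
              dimnames = list(sprintf("g%d", 1:n), samples$sample_id))
  r0 <- intra_inter_correlation(x, samples)
  expect_lt(abs(r0$pearson), 0.05)
  # noise and between-group difference both proportional to gene scale
  scale <- exp(rnorm(n))
  y <- x * scale + outer(scale, as.numeric(samples$species == "B"))
  r1 <- intra_inter_correlation(y, samples)
  expect_gt(r1$pearson, 0.5)
})

test_that("summary metrics cumulate fold-changes and proportions", {
  calls <- data.frame(
    gene_id = sprintf("g%d", 1:6), species = "spA",
    status = c("male_biased", "male_biased", "unbiased", "unbiased",
               "not_expressed", "female_biased"),
    log2fc = c(1, 2, 0, 0.2, NA, -3),
    p_value = 0.01, fdr_q = 0.01
  )
  sm <- sbg_summary_metrics(calls)
  expect_equal(sm$n_expressed, 5)
  expect_equal(sm$n_male, 2)
  expect_equal(sm$cumfc_male, 2 + 4) # 2^1 + 2^2
  expect_equal(sm$cumfc_female, 8)
  expect_equal(sm$prop_total, 3 / 5)
  empty <- sbg_summary_metrics(data.frame(
    gene_id = "g1", species = "spA", status = "unbiased",
    log2fc = 0, p_value = 1, fdr_q = 1
  ))
  expect_equal(empty$n_male + empty$n_female, 0)
  expect_equal(empty$cumfc_male, 0)
})

test_that("noise-matched null brackets a negative-control gene set", {
  # surrogate observed set = literally unbiased genes: the observed slope
  # should fall inside the null distribution, not above it
  cfg <- sim_config(n_genes = 500, sbg_fraction = 0, seed = 41)
  d <- simulate_study(cfg)
  norm <- normalized_expression(d$counts, d$lengths, tmm_factors(d$counts))
  ss <- species_sex_means(norm, d$samples)
  seqd <- ape::cophenetic.phylo(d$tree)
  cv <- within_group_cv(d$counts, d$samples)
  genes <- rownames(norm)
  set.seed(42)
  fake_sbg <- sample(genes, 25)
  pool <- setdiff(genes, fake_sbg)
  nn <- noise_matched_slope_null(ss, seqd, fake_sbg, pool, cv,
                                 mode = "males", n_rep = 200, seed = 9)
  expect_gt(nn$p_value, 0.05)
  expect_lt(nn$slope_obs, max(nn$null_slopes))
  expect_equal(length(nn$null_slopes), 200)
})
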