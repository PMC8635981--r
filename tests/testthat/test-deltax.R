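test_that("sister pairs resolve from cherries and explicit lists", {
  tr <- default_fixture_tree()
  pr <- sister_pairs(tr)
  expect_equal(length(pr), 10)
  expect_equal(unname(pr["sp01"]), "sp02")
  expect_equal(unname(pr["sp02"]), "sp01")
  expect_equal(unname(pr[pr[paste0("sp", sprintf("%02d", 1:10))]]),
               paste0("sp", sprintf("%02d", 1:10))) # reciprocal
  expect_false("out" %in% names(pr))
  # caterpillar: internal species have no sister tip
  cat_tree <- read_newick("(((A:1,B:1):1,C:2):1,D:3);")
  cat_tree$tip.label <- paste0("sp", 1:4)
  expect_error(sister_pairs(cat_tree), "sp3")
  # explicit list overrides the tree
  pr2 <- sister_pairs(cat_tree, pairs = cbind(c("sp1", "sp3"), c("sp2", "sp4")))
  expect_equal(unname(pr2["sp3"]), "sp4")
})

make_dx_data <- function(focal_vals, sister_vals) {
  samples <- toy_samples(c("A", "B"), reps = 3)
  x <- matrix(5, 1, nrow(samples),
              dimnames = list("g1", samples$sample_id))
  x[1, samples$species == "A" & samples$sex == "M"] <- focal_vals
  x[1, samples$species == "B" & samples$sex == "M"] <- sister_vals
  mask <- matrix(TRUE, 1, 2, dimnames = list("g1", c("A", "B")))
  dx <- delta_x_table(x, samples, c(A = "B", B = "A"), mask)
  dx[dx$focal == "A" & dx$sex == "M", ]
}

test_that("delta-x is divergence over focal-sex replicate SD", {
  # focal mean 4 (SD 0.5), sister mean 2 -> delta-x = 4
  rec <- make_dx_data(c(3.5, 4, 4.5), c(2, 2, 2))
  expect_equal(rec$mean_focal, 4)
  expect_equal(rec$sd_focal, 0.5)
  expect_equal(rec$delta_x, 4)

  # identical means: no shift, delta-x 0
  rec0 <- make_dx_data(c(2, 2, 2), c(2, 2, 2))
  expect_equal(rec0$delta_x, 0)
  expect_false(classify_shifts(rec0)$records$is_shift)

  # 1.6-fold difference with SD 0.1: a shift, high delta-x
  rec16 <- make_dx_data(2 + log2(1.6) + c(-0.1, 0, 0.1), c(2, 2, 2))
  cl <- classify_shifts(rec16)$records
  expect_true(cl$is_shift)
  expect_equal(cl$delta_x, log2(1.6) / 0.1, tolerance = 1e-9)
  expect_true(cl$is_high_delta_x)

  # zero SD with positive divergence is classified high
  recinf <- make_dx_data(c(3, 3, 3), c(2, 2, 2))
  expect_true(is.infinite(recinf$delta_x))
  expect_true(classify_shifts(recinf)$records$is_high_delta_x)

  # invariance to adding a constant to both species
  reca <- make_dx_data(c(3.5, 4, 4.5) + 7, c(2, 2, 2) + 7)
  expect_equal(reca$delta_x, rec$delta_x)
})

test_that("shift and high-delta-x boundaries are inclusive", {
  # exactly representable boundary: |delta of log2 means| = 2 = log2(4),
  # delta-x = 2 / 0.5 = 4
  rec <- make_dx_data(c(3.5, 4, 4.5), c(2, 2, 2))
  expect_identical(rec$abs_diff, 2)
  expect_identical(rec$delta_x, 4)
  cl4 <- classify_shifts(rec, shift_fc = 4, high_threshold = 4)$records
  expect_true(cl4$is_shift) # fold-change exactly at the threshold counts
  expect_true(cl4$is_high_delta_x) # delta-x exactly at the threshold counts
  expect_false(classify_shifts(rec, shift_fc = 4, high_threshold = 4,
                               inclusive_high = FALSE)$records$is_high_delta_x)
  expect_false(classify_shifts(rec, shift_fc = 4.2)$records$is_shift)
})

test_that("contingency tables split shifts by bias and delta-x class", {
  samples <- toy_samples(c("A", "B"), reps = 3)
  set.seed(10)
  n <- 40
  x <- matrix(rnorm(n * nrow(samples), 5, 0.2), n,
              dimnames = list(sprintf("g%02d", 1:n), samples$sample_id))
  x[1:10, samples$species == "A"] <- x[1:10, samples$species == "A"] + 2
  mask <- matrix(TRUE, n, 2, dimnames = list(rownames(x), c("A", "B")))
  calls <- data.frame(gene_id = sprintf("g%02d", 1:n), species = "A",
                      status = c(rep("male_biased", 5), rep("unbiased", n - 5)),
                      log2fc = 0, p_value = 0.5, fdr_q = 0.5)
  dx <- delta_x_table(x, samples, c(A = "B", B = "A"), mask, calls = calls)
  cs <- classify_shifts(dx)
  expect_true(all(dim(cs$tables$M) == c(2, 2)))
  # counts in the tables equal the flagged records
  subM <- cs$records[cs$records$sex == "M" & cs$records$is_shift, ]
  expect_equal(sum(cs$tables$M), nrow(subM))
  expect_equal(cs$tables$M["high_delta_x", "sex_biased"],
               sum(subM$is_high_delta_x & subM$is_sex_biased))
})

test_that("Yates chi-squared equals the capped-correction formula", {
  # proportional table: statistic 0
  prop <- matrix(10, 2, 2)
  expect_equal(yates_chi2(prop)$statistic, 0)
  # expected table preserves margins
  set.seed(11)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 30) + 1, 2, 2)
    res <- yates_chi2(tab)
    expect_equal(res$statistic, yates_hand(tab), tolerance = 1e-9)
    expect_equal(rowSums(res$expected), rowSums(tab), tolerance = 1e-9)
    expect_equal(colSums(res$expected), colSums(tab), tolerance = 1e-9)
  }
  expect_error(yates_chi2(matrix(c(0, 0, 5, 5), 2, 2)), "margin")
})
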