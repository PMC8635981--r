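test_that("fixture tree matches the emulated divergence design", {
  tr <- default_fixture_tree()
  expect_equal(length(tr$tip.label), 11)
  expect_equal(tr$Nnode, 10)
  expect_true(ape::is.binary(tr))
  pd <- ape::cophenetic.phylo(tr)
  ing <- setdiff(tr$tip.label, "out")
  expect_equal(max(pd[ing, ing]), 0.037, tolerance = 0.001 / 0.037)
  expect_equal(unname(pd["out", ing]), rep(0.053, 10), tolerance = 1e-9)
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_true(all(depths > 0))
})

test_that("BM simulation has the Brownian moments and is deterministic", {
  tr2 <- read_newick("(A:1,B:1);")
  m <- simulate_bm_means(tr2, 10000, rates = rep(1, 10000),
                         roots = rep(0, 10000), seed = 42)
  # sexes are identical copies of the species value
  expect_identical(m[, "A_M"], m[, "A_F"])
  d <- m[, "A_M"] - m[, "B_M"]
  expect_equal(var(d), 2, tolerance = 0.05) # Var = sigma^2 (b1 + b2)
  # zero rate pins every tip at the root value
  m0 <- simulate_bm_means(tr2, 5, rates = rep(0, 5), roots = 1:5, seed = 1)
  expect_equal(unname(m0[, "A_M"]), 1:5 + 0)
  expect_equal(unname(m0[, "B_F"]), 1:5 + 0)
  # determinism
  ma <- simulate_bm_means(tr2, 50, rep(1, 50), rep(0, 50), seed = 9)
  mb <- simulate_bm_means(tr2, 50, rep(1, 50), rep(0, 50), seed = 9)
  expect_identical(ma, mb)
  expect_error(simulate_bm_means(tr2, 2, c(-1, 1), c(0, 0)), "non-negative")
})

test_that("empirical tip covariance converges to the BM covariance", {
  tr <- read_newick("((A:0.6,B:0.4):0.5,(C:0.8,D:0.7):0.3);")
  n <- 50000
  m <- simulate_bm_means(tr, n, rates = rep(1, n), roots = rep(0, n), seed = 3)
  X <- m[, c("A_M", "B_M", "C_M", "D_M")]
  emp <- cov(X)
  V <- ape::vcv(tr)[c("A", "B", "C", "D"), c("A", "B", "C", "D")]
  rel_err <- norm(emp - V, "F") / norm(V, "F")
  expect_lt(rel_err, 0.05)
})

test_that("sex-bias injection is additive, recoverable and count-targeted", {
  tr2 <- read_newick("(A:1,B:1);")
  base <- simulate_bm_means(tr2, 20, rep(1, 20), rep(5, 20), seed = 2)

  cfg0 <- sim_config(n_genes = 20, tree = tr2, sbg_fraction = 0)
  r0 <- inject_sex_bias(base, cfg0, seed = 1)
  expect_identical(r0$means, base)
  expect_equal(nrow(r0$truth), 0)

  # a single gene, fixed effect magnitude 2: the sex difference is exactly
  # the effect and no other cell moves
  cfg1 <- sim_config(n_genes = 20, tree = tr2, sbg_n = 1,
                     sbg_effect_min = 2, sbg_effect_mean = 2)
  r1 <- inject_sex_bias(base, cfg1, seed = 5)
  expect_equal(nrow(r1$truth), 1)
  g <- r1$truth$gene_id; sp <- r1$truth$species; sx <- r1$truth$sex
  diff_mf <- r1$means[g, paste0(sp, "_M")] - r1$means[g, paste0(sp, "_F")]
  expect_equal(unname(diff_mf), r1$truth$effect_log2fc)
  expect_equal(abs(r1$truth$effect_log2fc), 2)
  changed <- r1$means != base
  expect_equal(sum(changed), 1)

  # emulated study scale: 650 biased gene-species pairs among 16,194 genes
  trf <- default_fixture_tree()
  big <- simulate_bm_means(trf, 16194, rep(1, 16194), rep(5, 16194), seed = 4)
  cfg650 <- sim_config(n_genes = 16194, sbg_n = 650)
  r650 <- inject_sex_bias(big, cfg650, seed = 6)
  expect_equal(nrow(r650$truth), 650)
  expect_true(all(abs(r650$truth$effect_log2fc) >= 1))
})

test_that("count sampling matches Poisson moments and the sampling design", {
  # two genes, equal means and lengths, Poisson, fixed library 1000:
  # each gene's expected count is 500 and column sums match the library
  tr2 <- read_newick("(A:1,B:1);")
  cfg <- sim_config(n_genes = 2, tree = tr2, reps_per_sex = 2500,
                    five_female_species = character(0),
                    nb_dispersion = 0, libsize_meanlog = log(1000),
                    libsize_sdlog = 0, length_meanlog = log(1000),
                    length_sdlog = 0, include_outgroup = FALSE)
  means <- matrix(3, 2, 4, dimnames = list(c("g1", "g2"),
                                           c("A_M", "A_F", "B_M", "B_F")))
  cnt <- sample_nb_counts(means, cfg, seed = 8)
  n_samp <- ncol(cnt$counts)
  expect_equal(n_samp, 2 * 2 * 2500)
  expect_equal(mean(cnt$counts["g1", ]), 500,
               tolerance = 3 * sqrt(500 / n_samp) / 500)
  expect_equal(mean(colSums(cnt$counts)), 1000,
               tolerance = 3 * sqrt(1000 / n_samp) / 1000)

  # default design: a five-female species contributes 11 samples
  cfg_d <- sim_config(n_genes = 5, seed = 1)
  d <- simulate_study(cfg_d)
  expect_equal(sum(d$samples$species == "sp09"), 11)
  expect_equal(sum(d$samples$species == "sp01"), 12)
  expect_equal(sum(d$samples$sex == "H"), 1)
})

test_that("codon alignments follow the Jukes-Cantor closed form", {
  tr0 <- read_newick("(A:0,B:0);")
  a0 <- simulate_codon_alignments(tr0, 200, seed = 1)[[1]]
  expect_identical(a0[["A"]], a0[["B"]])

  tr <- read_newick("(A:0.03,B:0.02);")
  aln <- simulate_codon_alignments(tr, 10000, seed = 2)[[1]]
  expect_equal(nchar(aln[["A"]]) %% 3, 0)
  expect_true(all(strsplit(aln[["A"]], "")[[1]] %in% c("A", "C", "G", "T")))
  t1 <- substring(aln[["A"]], seq(3, 30000, 3), seq(3, 30000, 3))
  t2 <- substring(aln[["B"]], seq(3, 30000, 3), seq(3, 30000, 3))
  p_obs <- mean(t1 != t2)
  p_exp <- 0.75 * (1 - exp(-4 * 0.05 / 3))
  expect_equal(p_obs, p_exp, tolerance = 0.005 / p_exp)
})

test_that("the full generator is byte-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 120, seed = 77)
  d1 <- simulate_study(cfg)
  d2 <- simulate_study(cfg)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$alignments, d2$alignments)
  expect_identical(write_newick(d1$tree), write_newick(d2$tree))
})
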