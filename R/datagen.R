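# Synthetic study generator: Brownian-motion expression evolution on a species
# tree, species-specific injected sex bias, negative-binomial replicate counts,
# and matching fourfold-degenerate sequence divergence.

#' Default species tree fixture
#'
#' A rooted, fully bifurcating, ultrametric 11-tip tree: five ingroup cherries
#' (sister-species pairs `sp01`/`sp02` ... `sp09`/`sp10`) plus one
#' hermaphrodite outgroup tip `out`. Branch lengths are on the scale of
#' expected substitutions per site: tip depth is chosen so the maximum
#' patristic distance among the ten ingroup tips is 0.037 and every
#' ingroup-to-outgroup distance is 0.053, matching the divergence range the
#' design emulates (up to ~3.7% at synonymous sites within the ingroup, ~5.3%
#' to the outgroup).
#'
#' @return An [ape::phylo] object with 11 tips and 10 internal nodes.
#' @export
default_fixture_tree <- function() {
  txt <- paste0(
    "((((sp01:0.003,sp02:0.003):0.0115,(sp03:0.004,sp04:0.004):0.0105):0.004,",
    "((sp05:0.0035,sp06:0.0035):0.012,((sp07:0.0045,sp08:0.0045):0.008,",
    "(sp09:0.005,sp10:0.005):0.0075):0.003):0.003):0.008,out:0.0265);"
  )
  read_newick(txt)
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator with defaults that
#' emulate the study design: 10 dioecious ingroup species in five sister
#' pairs plus one hermaphrodite outgroup contributing a single sample, six
#' replicates per sex with two species reduced to five females, and a
#' sex-bias incidence of about 4% of genes (the emulated 650 / 16,194 ratio)
#' with each biased gene biased in a single species by default.
#'
#' @param n_genes number of genes (orthogroups). Default 2000, a scaled-down
#'   stand-in for the full 16,194; the full size is supported.
#' @param tree species tree; default [default_fixture_tree()].
#' @param include_outgroup simulate the hermaphrodite outgroup sample.
#' @param reps_per_sex replicates per species and sex (default 6).
#' @param five_female_species species whose female replicate count is reduced
#'   to `reps_per_sex - 1` (default `c("sp09", "sp10")`).
#' @param bm_rate_meanlog,bm_rate_sdlog lognormal parameters of the per-gene
#'   Brownian-motion rate sigma^2 (log2-expression variance per unit branch
#'   length).
#' @param root_mean,root_sd normal parameters of per-gene root log2 expression.
#' @param sbg_fraction fraction of genes assigned true sex bias (in [0,1]).
#' @param sbg_n absolute number of true sex-biased genes; overrides
#'   `sbg_fraction` when non-NULL.
#' @param sbg_effect_min,sbg_effect_mean injected |log2 effect| is
#'   `sbg_effect_min + Exp(mean = sbg_effect_mean - sbg_effect_min)`;
#'   `sbg_effect_min >= 1` keeps every true effect at least twofold.
#' @param sbg_rate_quantile if non-NULL, true SBGs are sampled only from genes
#'   whose BM rate lies above this quantile (models bias arising
#'   preferentially in fast-evolving genes).
#' @param p_shared,p_divergent probability that a true SBG is additionally
#'   biased in a second species with the same, respectively opposite,
#'   direction (defaults 0: strictly species-specific bias).
#' @param nb_dispersion negative-binomial dispersion phi (0 = Poisson).
#' @param sbg_disp_factor multiplier on the NB dispersion of true sex-biased
#'   genes (default 1: SBGs are no noisier than other genes; values > 1 give
#'   SBGs elevated within-species expression variance).
#' @param libsize_meanlog,libsize_sdlog lognormal parameters of per-sample
#'   library sizes (reads).
#' @param length_meanlog,length_sdlog lognormal parameters of gene effective
#'   lengths (bp).
#' @param codon_sites codons per simulated alignment.
#' @param n_alignments number of codon alignments to simulate.
#' @param seed integer seed; a fixed seed makes all outputs byte-identical.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       tree = default_fixture_tree(),
                       include_outgroup = TRUE,
                       reps_per_sex = 6,
                       five_female_species = c("sp09", "sp10"),
                       bm_rate_meanlog = log(30),
                       bm_rate_sdlog = 1,
                       root_mean = 5,
                       root_sd = 2,
                       sbg_fraction = 0.04,
                       sbg_n = NULL,
                       sbg_effect_min = 1,
                       sbg_effect_mean = 2,
                       sbg_rate_quantile = NULL,
                       p_shared = 0,
                       p_divergent = 0,
                       nb_dispersion = 0.05,
                       sbg_disp_factor = 1,
                       libsize_meanlog = log(2e6),
                       libsize_sdlog = 0.1,
                       length_meanlog = log(1500),
                       length_sdlog = 0.35,
                       codon_sites = 3000,
                       n_alignments = 1,
                       seed = 1L) {
  stopifnot(
    n_genes >= 1, reps_per_sex >= 1,
    sbg_fraction >= 0, sbg_fraction <= 1,
    is.null(sbg_n) || sbg_n >= 0,
    sbg_effect_min >= 0, sbg_effect_mean >= sbg_effect_min,
    p_shared >= 0, p_shared <= 1, p_divergent >= 0, p_divergent <= 1,
    nb_dispersion >= 0, sbg_disp_factor > 0, codon_sites >= 1,
    n_alignments >= 0
  )
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

ingroup_species <- function(tree) sort(setdiff(tree$tip.label, "out"))

#' Simulate Brownian-motion species/sex mean expression
#'
#' Draws, for each gene, tip values from a multivariate normal with mean equal
#' to the gene's root value and covariance `sigma^2 *` shared-path-length
#' matrix of the tree, then duplicates each dioecious species' value into
#' identical male and female columns (sex bias is injected separately).
#'
#' @param tree species tree (tip `out`, if present, is treated as the
#'   hermaphrodite outgroup and gets a single `_H` column).
#' @param n_genes number of genes.
#' @param rates per-gene BM rate sigma^2 (length `n_genes`, all >= 0).
#' @param roots per-gene root mean (length `n_genes`).
#' @param seed integer seed.
#' @return Numeric matrix, genes x (species, sex) columns named
#'   `"<species>_M"`, `"<species>_F"` and `"out_H"`.
#' @export
simulate_bm_means <- function(tree, n_genes, rates, roots, seed = 1L) {
  stopifnot(length(rates) == n_genes, length(roots) == n_genes)
  if (any(rates < 0)) stop("BM rates must be non-negative")
  if (any(tree$edge.length < 0)) stop("branch lengths must be non-negative")
  set.seed(seed)
  V <- ape::vcv(tree)
  tips <- colnames(V)
  # chol() needs strict PD; add a negligible ridge to guard ultrametric ties
  U <- chol(V + diag(1e-12, nrow(V)))
  Z <- matrix(stats::rnorm(n_genes * length(tips)), n_genes, length(tips))
  dev <- (Z %*% U) * sqrt(rates)
  X <- dev + roots
  colnames(X) <- tips
  rownames(X) <- sprintf("g%05d", seq_len(n_genes))
  ing <- ingroup_species(tree)
  cols <- c(rbind(paste0(ing, "_M"), paste0(ing, "_F")))
  out <- matrix(0, n_genes, 0)
  out <- X[, rep(ing, each = 2), drop = FALSE]
  colnames(out) <- cols
  if ("out" %in% tips) {
    out <- cbind(out, out_H = X[, "out"])
  }
  rownames(out) <- rownames(X)
  out
}

#' Inject species-specific sex bias into latent means
#'
#' Selects true sex-biased genes and adds a signed log2 effect to exactly one
#' sex's column in the chosen species. By default each true SBG is biased in
#' exactly one species; `p_shared` / `p_divergent` add a second species with
#' the same / opposite direction, so shared and divergent bias arise at
#' configurable rates.
#'
#' @param means matrix from [simulate_bm_means()].
#' @param cfg a [sim_config()].
#' @param rates per-gene BM rates; required when `cfg$sbg_rate_quantile` is
#'   set.
#' @param seed integer seed.
#' @return list with `means` (modified copy) and `truth`, a data frame with
#'   one row per biased (gene, species): `gene_id`, `species`, `sex`
#'   (direction of bias, `"M"` or `"F"`) and `effect_log2fc` (male minus
#'   female sign convention: positive = male-biased).
#' @export
inject_sex_bias <- function(means, cfg, rates = NULL, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  genes <- rownames(means)
  n_genes <- length(genes)
  species <- unique(sub("_[MF]$", "", grep("_[MF]$", colnames(means), value = TRUE)))
  n_sbg <- if (!is.null(cfg$sbg_n)) cfg$sbg_n else round(cfg$sbg_fraction * n_genes)
  truth <- data.frame(
    gene_id = character(0), species = character(0),
    sex = character(0), effect_log2fc = numeric(0)
  )
  if (n_sbg == 0) {
    return(list(means = means, truth = truth))
  }
  eligible <- genes
  if (!is.null(cfg$sbg_rate_quantile)) {
    if (is.null(rates)) stop("rates required when sbg_rate_quantile is set")
    eligible <- genes[rates >= stats::quantile(rates, cfg$sbg_rate_quantile)]
  }
  if (n_sbg > length(eligible)) stop("fewer eligible genes than requested SBGs")
  sbg_genes <- sample(eligible, n_sbg)
  draw_effect <- function(k) {
    extra <- cfg$sbg_effect_mean - cfg$sbg_effect_min
    cfg$sbg_effect_min + if (extra > 0) stats::rexp(k, 1 / extra) else 0
  }
  rows <- vector("list", n_sbg)
  for (i in seq_along(sbg_genes)) {
    g <- sbg_genes[i]
    sp1 <- sample(species, 1)
    sex1 <- sample(c("M", "F"), 1)
    recs <- data.frame(gene_id = g, species = sp1, sex = sex1,
                       effect = draw_effect(1))
    u <- stats::runif(1)
    if (u < cfg$p_shared + cfg$p_divergent && length(species) > 1) {
      sp2 <- sample(setdiff(species, sp1), 1)
      sex2 <- if (u < cfg$p_shared) sex1 else setdiff(c("M", "F"), sex1)
      recs <- rbind(recs, data.frame(gene_id = g, species = sp2, sex = sex2,
                                     effect = draw_effect(1)))
    }
    rows[[i]] <- recs
  }
  recs <- do.call(rbind, rows)
  for (j in seq_len(nrow(recs))) {
    col <- paste0(recs$species[j], "_", recs$sex[j])
    means[recs$gene_id[j], col] <- means[recs$gene_id[j], col] + recs$effect[j]
  }
  truth <- data.frame(
    gene_id = recs$gene_id,
    species = recs$species,
    sex = recs$sex,
    effect_log2fc = ifelse(recs$sex == "M", recs$effect, -recs$effect),
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$gene_id, truth$species), ]
  rownames(truth) <- NULL
  list(means = means, truth = truth)
}

#' Sample negative-binomial read counts from latent means
#'
#' For each sample, the expected count of gene g is
#' `library_size * length_g * 2^mean_g / sum_g'(length_g' * 2^mean_g')`;
#' counts are negative-binomial with dispersion `cfg$nb_dispersion`
#' (Poisson when 0). The hermaphrodite outgroup contributes a single sample.
#'
#' @param means latent species/sex mean matrix (possibly with injected bias).
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @param gene_dispersion optional per-gene NB dispersion vector overriding
#'   `cfg$nb_dispersion` (used to give true SBGs elevated dispersion).
#' @return list with integer `counts` (genes x samples), `samples` (data frame
#'   `sample_id`, `species`, `sex` in M/F/H, `individual`) and `lengths`
#'   (named numeric vector of effective lengths, bp).
#' @export
sample_nb_counts <- function(means, cfg, seed = 1L, gene_dispersion = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  genes <- rownames(means)
  n_genes <- length(genes)
  lengths <- round(stats::rlnorm(n_genes, cfg$length_meanlog, cfg$length_sdlog))
  lengths <- pmax(lengths, 100)
  names(lengths) <- genes

  species <- unique(sub("_[MF]$", "", grep("_[MF]$", colnames(means), value = TRUE)))
  samp <- list()
  for (sp in species) {
    for (sex in c("M", "F")) {
      n <- cfg$reps_per_sex
      if (sex == "F" && sp %in% cfg$five_female_species) n <- n - 1
      samp[[length(samp) + 1]] <- data.frame(
        sample_id = sprintf("%s_%s_%d", sp, sex, seq_len(n)),
        species = sp, sex = sex, individual = sprintf("%s_%d", sp, seq_len(n))
      )
    }
  }
  if ("out_H" %in% colnames(means) && isTRUE(cfg$include_outgroup)) {
    samp[[length(samp) + 1]] <- data.frame(
      sample_id = "out_H_1", species = "out", sex = "H", individual = "out_1"
    )
  }
  samples <- do.call(rbind, samp)
  rownames(samples) <- NULL

  counts <- matrix(0L, n_genes, nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  for (i in seq_len(nrow(samples))) {
    col <- paste0(samples$species[i], "_", samples$sex[i])
    lib <- stats::rlnorm(1, cfg$libsize_meanlog, cfg$libsize_sdlog)
    w <- lengths * 2^means[, col]
    mu <- lib * w / sum(w)
    phi <- if (is.null(gene_dispersion)) {
      rep(cfg$nb_dispersion, n_genes)
    } else {
      gene_dispersion
    }
    pois <- phi == 0
    x <- numeric(n_genes)
    x[pois] <- stats::rpois(sum(pois), mu[pois])
    x[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                               size = 1 / phi[!pois])
    counts[, i] <- x
  }
  list(counts = counts, samples = samples, lengths = lengths)
}

# fourfold-degenerate codon family prefixes under the standard genetic code
FOURFOLD_PREFIXES <- c("GC", "CG", "GG", "CT", "CC", "TC", "AC", "GT")

#' Simulate codon alignments with fourfold-degenerate divergence
#'
#' Evolves codons along the tree, substituting only third positions of
#' fourfold-degenerate codons under a Jukes-Cantor process whose rate matches
#' the branch lengths (expected substitutions per third-position site); first
#' and second positions are constant, so every codon stays synonymous.
#'
#' @param tree species tree with branch lengths.
#' @param n_codons codons per alignment.
#' @param seed integer seed.
#' @param n_alignments number of alignments.
#' @return list of alignments; each is a named character vector (one DNA
#'   string per tip, length `3 * n_codons`).
#' @export
simulate_codon_alignments <- function(tree, n_codons, seed = 1L,
                                      n_alignments = 1) {
  stopifnot(n_codons >= 1)
  set.seed(seed)
  nt <- c("A", "C", "G", "T")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  # parent-before-child edge ordering for a root-to-tip sweep
  edges <- tree$edge[rev(ape::postorder(tree)), , drop = FALSE]
  lens <- tree$edge.length[rev(ape::postorder(tree))]
  lapply(seq_len(n_alignments), function(a) {
    prefixes <- sample(FOURFOLD_PREFIXES, n_codons, replace = TRUE)
    third <- vector("list", n_tip + tree$Nnode)
    third[[root]] <- sample(nt, n_codons, replace = TRUE)
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1]; chd <- edges[e, 2]; t <- lens[e]
      p_change <- 0.75 * (1 - exp(-4 * t / 3))
      x <- third[[par]]
      mut <- stats::runif(n_codons) < p_change
      if (any(mut)) {
        x[mut] <- vapply(x[mut], function(b) sample(setdiff(nt, b), 1), "")
      }
      third[[chd]] <- x
    }
    seqs <- vapply(seq_len(n_tip), function(i) {
      paste0(prefixes, third[[i]], collapse = "")
    }, "")
    names(seqs) <- tree$tip.label
    seqs
  })
}

#' Simulate a complete synthetic study
#'
#' Runs the whole generator: per-gene BM rates and root means, latent
#' species/sex means on the tree, injected sex bias, negative-binomial counts
#' with a sample table, and (optionally) codon alignments. Sub-stage seeds are
#' derived deterministically from `cfg$seed`, so a fixed config is
#' byte-identical on rerun.
#'
#' @param cfg a [sim_config()].
#' @return list with `tree`, `means` (latent, bias included), `truth`
#'   (list: `genes` data frame with per-gene `rate` and `root`; `bias` the
#'   per-(gene, species) truth table), `counts`, `samples`, `lengths`,
#'   `alignments`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  tree <- cfg$tree
  set.seed(cfg$seed)
  rates <- stats::rlnorm(cfg$n_genes, cfg$bm_rate_meanlog, cfg$bm_rate_sdlog)
  roots <- stats::rnorm(cfg$n_genes, cfg$root_mean, cfg$root_sd)
  means <- simulate_bm_means(tree, cfg$n_genes, rates, roots,
                             seed = cfg$seed + 1L)
  inj <- inject_sex_bias(means, cfg, rates = rates, seed = cfg$seed + 2L)
  gene_disp <- NULL
  if (cfg$sbg_disp_factor != 1 && nrow(inj$truth) > 0) {
    gene_disp <- rep(cfg$nb_dispersion, cfg$n_genes)
    names(gene_disp) <- rownames(means)
    gene_disp[unique(inj$truth$gene_id)] <-
      cfg$nb_dispersion * cfg$sbg_disp_factor
  }
  cnt <- sample_nb_counts(inj$means, cfg, seed = cfg$seed + 3L,
                          gene_dispersion = gene_disp)
  aln <- if (cfg$n_alignments > 0) {
    simulate_codon_alignments(tree, cfg$codon_sites, seed = cfg$seed + 4L,
                              n_alignments = cfg$n_alignments)
  }
  genes_df <- data.frame(gene_id = rownames(means), rate = rates, root = roots)
  list(
    tree = tree, means = inj$means,
    truth = list(genes = genes_df, bias = inj$truth),
    counts = cnt$counts, samples = cnt$samples, lengths = cnt$lengths,
    alignments = aln
  )
}
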