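# Independent oracles used across the suite. These are deliberately written
# as direct, brute-force computations so they never share code with the
# implementation paths they check.

# random bifurcating tree with positive branch lengths
rand_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.2, 1.5)
  tr
}

# ER 3-state transition probability, written from the spectral form
oracle_pmat <- function(q, t) {
  e <- exp(-3 * q * t)
  m <- matrix((1 - e) / 3, 3, 3)
  diag(m) <- (1 + 2 * e) / 3
  m
}

# Mk likelihood and marginals by exhaustive enumeration over all unknown-node
# state assignments (internal nodes plus ambiguous tips), uniform root prior
mk_brute <- function(tree, tip_states, q, states = c("U", "M", "F")) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  fixed <- rep(NA_integer_, n_all)
  for (i in seq_len(n_tip)) {
    s <- tip_states[tree$tip.label[i]]
    if (!is.na(s) && s %in% states) fixed[i] <- match(s, states)
  }
  unknown <- which(is.na(fixed))
  grid <- as.matrix(expand.grid(rep(list(seq_along(states)), length(unknown))))
  root <- n_tip + 1L
  joint <- apply(grid, 1, function(g) {
    st <- fixed
    st[unknown] <- g
    p <- 1 / length(states)
    for (e in seq_len(nrow(tree$edge))) {
      P <- oracle_pmat(q, tree$edge.length[e])
      p <- p * P[st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    p
  })
  lik <- sum(joint)
  marg <- matrix(0, n_all, length(states))
  for (r in seq_len(nrow(grid))) {
    st <- fixed
    st[unknown] <- grid[r, ]
    for (v in seq_len(n_all)) marg[v, st[v]] <- marg[v, st[v]] + joint[r]
  }
  list(lik = lik, marginal = marg / lik)
}

# two-sided conditional binomial p-value: sum of outcome probabilities no
# larger than the observed one (equal library sizes, dispersion 0)
binom_doubletail <- function(s1, total, prob = 0.5) {
  p_all <- stats::dbinom(0:total, total, prob)
  sum(p_all[p_all <= p_all[s1 + 1] * (1 + 1e-10)])
}

# Yates chi-squared written straight from the capped-correction formula
yates_hand <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  cc <- pmin(0.5, abs(tab - E))
  sum((abs(tab - E) - cc)^2 / E)
}

# fourfold-degenerate divergence judged per codon with the genetic code:
# a site counts iff the two prefixes agree, everything is unambiguous DNA,
# and all four third-position variants of the prefix translate identically
fourfold_oracle <- function(aln, pair) {
  code <- Biostrings::GENETIC_CODE
  s1 <- strsplit(toupper(aln[[pair[1]]]), "")[[1]]
  s2 <- strsplit(toupper(aln[[pair[2]]]), "")[[1]]
  nt <- c("A", "C", "G", "T")
  n_sites <- 0L; n_diff <- 0L
  for (k in seq_len(length(s1) / 3)) {
    i <- 3 * (k - 1) + 1
    pre1 <- paste0(s1[i], s1[i + 1]); pre2 <- paste0(s2[i], s2[i + 1])
    t1 <- s1[i + 2]; t2 <- s2[i + 2]
    if (pre1 != pre2) next
    if (!all(c(s1[i], s1[i + 1], t1, t2) %in% nt)) next
    aas <- unique(code[paste0(pre1, nt)])
    if (length(aas) != 1) next
    n_sites <- n_sites + 1L
    if (t1 != t2) n_diff <- n_diff + 1L
  }
  list(divergence = if (n_sites) n_diff / n_sites else NA_real_,
       n_sites = n_sites, n_diff = n_diff)
}

# counts with all library sizes forced equal, by letting the last filler
# gene absorb the column-sum differences
equalize_libs <- function(counts, target = NULL) {
  cs <- colSums(counts)
  if (is.null(target)) target <- max(cs) + 50
  rbind(counts, filler_eq = target - cs)
}

# small two-species study table used by delta-x and distance tests
toy_samples <- function(species, reps = 3, sexes = c("M", "F")) {
  do.call(rbind, lapply(species, function(sp) {
    do.call(rbind, lapply(sexes, function(sx) {
      data.frame(sample_id = sprintf("%s_%s_%d", sp, sx, seq_len(reps)),
                 species = sp, sex = sx,
                 individual = sprintf("%s_%d", sp, seq_len(reps)))
    }))
  }))
}
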