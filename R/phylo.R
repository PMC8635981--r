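# Phylogenetic core: Newick I/O, standardized independent contrasts with tip
# exclusion, 3-state equal-rates Mk ancestral-state reconstruction with true
# marginal probabilities, gain counting, and PGLS regression under Brownian
# covariance.

#' Read a Newick tree
#'
#' @param x a Newick string or a path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(x) {
  tree <- if (length(x) == 1 && !grepl("\\(", x) && file.exists(x)) {
    ape::read.tree(x)
  } else {
    tryCatch(ape::read.tree(text = x),
             warning = function(w) NULL, error = function(e) NULL)
  }
  if (is.null(tree)) stop("failed to parse Newick input")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  tree
}

#' Write a tree as Newick
#'
#' @param tree an [ape::phylo] tree.
#' @param file optional output path; if NULL the Newick string is returned.
#' @return the Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = file)
    invisible(ape::write.tree(tree))
  }
}

#' Standardized phylogenetically independent contrasts
#'
#' Felsenstein's pruning: at each internal node the contrast is
#' `(x_i - x_j) / sqrt(b_i + b_j)`, the ancestral value is the
#' precision-weighted mean, and the parent branch is extended by
#' `b_i b_j / (b_i + b_j)` (computed with [ape::pic()]).
#'
#' @param tree bifurcating tree with strictly positive branch lengths.
#' @param tip_values named numeric vector covering every tip.
#' @return list with `contrasts` (length `n_tips - 1`) and `mean_abs`.
#' @export
pic_contrasts <- function(tree, tip_values) {
  if (!all(tree$tip.label %in% names(tip_values))) {
    stop("missing tip value(s): ",
         paste(setdiff(tree$tip.label, names(tip_values)), collapse = ", "))
  }
  if (!ape::is.binary(tree)) stop("tree must be bifurcating")
  if (any(tree$edge.length <= 0)) stop("branch lengths must be positive")
  ctr <- ape::pic(tip_values[tree$tip.label], tree)
  list(contrasts = ctr, mean_abs = mean(abs(ctr)))
}

#' Mean absolute PIC with per-gene tip exclusion
#'
#' The per-gene rate-of-expression-evolution measure: the mean of the absolute
#' standardized contrasts, computed after pruning, for each gene, the tips
#' where that gene is sex-biased — so that sex-biased expression values
#' themselves never contribute. Pruning merges branch lengths through removed
#' degree-2 nodes.
#'
#' @param tree species tree.
#' @param species_means genes x species matrix of (sex-averaged) mean log2
#'   expression; column names must match tip labels.
#' @param exclude either a genes x species logical matrix (TRUE = exclude that
#'   tip for that gene) or a named list of tip-label vectors; NULL excludes
#'   nothing.
#' @return named numeric vector of per-gene mean |PIC|; genes with fewer than
#'   3 remaining tips are NA, with the reasons in
#'   `attr(, "skipped")`.
#' @export
mean_abs_pic_excluding <- function(tree, species_means, exclude = NULL) {
  genes <- rownames(species_means)
  stopifnot(all(colnames(species_means) %in% tree$tip.label))
  excl_list <- if (is.null(exclude)) {
    rep(list(character(0)), length(genes))
  } else if (is.matrix(exclude)) {
    lapply(genes, function(g) colnames(exclude)[exclude[g, ]])
  } else {
    lapply(genes, function(g) {
      if (g %in% names(exclude)) exclude[[g]] else character(0)
    })
  }
  names(excl_list) <- genes
  keys <- vapply(excl_list, function(e) paste(sort(e), collapse = "|"), "")
  out <- stats::setNames(rep(NA_real_, length(genes)), genes)
  skipped <- character(0)
  use_tips <- intersect(tree$tip.label, colnames(species_means))
  base <- if (length(use_tips) < length(tree$tip.label)) {
    ape::drop.tip(tree, setdiff(tree$tip.label, use_tips))
  } else {
    tree
  }
  for (key in unique(keys)) {
    gset <- genes[keys == key]
    drop <- if (nzchar(key)) strsplit(key, "|", fixed = TRUE)[[1]] else character(0)
    keep <- setdiff(use_tips, drop)
    if (length(keep) < 3) {
      skipped <- c(skipped, stats::setNames(
        rep("fewer than 3 tips after exclusion", length(gset)), gset))
      next
    }
    tr <- if (length(drop)) ape::drop.tip(base, intersect(drop, base$tip.label)) else base
    for (g in gset) {
      out[g] <- mean(abs(ape::pic(species_means[g, tr$tip.label], tr)))
    }
  }
  attr(out, "skipped") <- skipped
  out
}

row_max <- function(m) apply(m, 1, max)

# ER transition probability matrix for k=3 states: off-diagonal rate q,
# eigenvalues 0 and -3q
mk_pmat <- function(q, t) {
  e <- exp(-3 * q * t)
  p_same <- 1 / 3 + 2 / 3 * e
  p_diff <- 1 / 3 - 1 / 3 * e
  m <- matrix(p_diff, 3, 3)
  diag(m) <- p_same
  m
}

mk_tip_liks <- function(tree, tip_states, states) {
  n_tip <- length(tree$tip.label)
  L <- matrix(1, n_tip, length(states),
              dimnames = list(tree$tip.label, states))
  for (i in seq_len(n_tip)) {
    s <- tip_states[tree$tip.label[i]]
    if (!is.na(s) && s %in% states) L[i, ] <- as.numeric(states == s)
    else if (!is.na(s) && !(s %in% states) && s != "?") {
      stop("unknown tip state: ", s)
    }
  }
  L
}

#' Mk log-likelihood by the pruning algorithm
#'
#' Equal-rates 3-state Mk model (single rate `q` on every off-diagonal) with a
#' uniform root prior. Tips with state NA or `"?"` are ambiguous (unit partial
#' likelihood for every state).
#'
#' @param tree bifurcating tree.
#' @param tip_states named character vector over tips with values in
#'   `states`, NA, or `"?"`.
#' @param q transition rate (> 0).
#' @param states state labels (default `c("U", "M", "F")`).
#' @return log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tip_states, q, states = c("U", "M", "F")) {
  mk_pass(tree, tip_states, q, states, marginals = FALSE)$loglik
}

# single upward pass (and optional downward pass for marginals)
mk_pass <- function(tree, tip_states, q, states, marginals = FALSE) {
  k <- length(states)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  po <- ape::postorder(tree)
  edge <- tree$edge
  elen <- tree$edge.length
  L <- matrix(1, n_all, k)
  L[seq_len(n_tip), ] <- mk_tip_liks(tree, tip_states, states)
  msg <- matrix(NA_real_, nrow(edge), k) # message child -> parent per edge
  logscale <- 0
  P <- lapply(seq_len(nrow(edge)), function(e) mk_pmat(q, elen[e]))
  for (e in po) {
    par <- edge[e, 1]; chd <- edge[e, 2]
    m <- as.vector(P[[e]] %*% L[chd, ])
    msg[e, ] <- m
    L[par, ] <- L[par, ] * m
    mx <- max(L[par, ])
    if (mx < 1e-100) {
      L[par, ] <- L[par, ] / mx
      logscale <- logscale + log(mx)
    }
  }
  root <- n_tip + 1L
  loglik <- log(sum(L[root, ] / k)) + logscale
  res <- list(loglik = loglik, L = L)
  if (marginals) {
    U <- matrix(NA_real_, n_all, k)
    U[root, ] <- 1 / k
    for (e in rev(po)) { # parents before children
      par <- edge[e, 1]; chd <- edge[e, 2]
      sib <- which(edge[, 1] == par)
      sib <- sib[sib != e]
      up <- U[par, ]
      for (s in sib) up <- up * msg[s, ]
      v <- as.vector(t(P[[e]]) %*% up)
      U[chd, ] <- v / max(v)
    }
    marg <- L * U
    marg <- marg / rowSums(marg)
    colnames(marg) <- states
    res$marginal <- marg
  }
  res
}

#' Maximum-likelihood Mk ancestral-state reconstruction
#'
#' Fits the single ER rate `q` by bounded 1-D maximum likelihood
#' (`q` in `[1e-8, 1e3]`) with the pruning algorithm and a uniform root
#' prior, then computes true marginal state probabilities at every node by
#' the standard two-pass (inside-outside, equivalent to re-rooting)
#' computation. The ML state is the argmax of the marginals; exact ties fall
#' back to the first state (`"U"`, unbiased).
#'
#' @inheritParams mk_loglik
#' @return list with `q`, `loglik`, `prob` (nodes x states marginal matrix
#'   over all tips and internal nodes, rows summing to 1), `state` (per-node
#'   ML state; observed tips keep their observed state) and `at_bound`
#'   (logical: rate optimization hit a bound).
#' @export
mk_asr <- function(tree, tip_states, states = c("U", "M", "F")) {
  if (!ape::is.binary(tree)) stop("tree must be bifurcating")
  bounds <- log(c(1e-8, 1e3))
  nll <- function(lq) -mk_loglik(tree, tip_states, exp(lq), states)
  opt <- stats::optimize(nll, interval = bounds, tol = 1e-9)
  q <- exp(opt$minimum)
  at_bound <- min(abs(opt$minimum - bounds)) < 1e-4
  if (at_bound) warning("Mk rate optimization at bound (q = ", signif(q, 3), ")")
  pass <- mk_pass(tree, tip_states, q, states, marginals = TRUE)
  n_tip <- length(tree$tip.label)
  prob <- pass$marginal
  rownames(prob) <- c(tree$tip.label,
                      paste0("node", seq_len(tree$Nnode) + n_tip))
  state <- states[max.col(prob, ties.method = "first")]
  ties <- rowSums(prob == row_max(prob)) > 1
  state[ties] <- states[1] # exact ties resolve to unbiased
  obs <- tip_states[tree$tip.label]
  known <- !is.na(obs) & obs %in% states
  state[seq_len(n_tip)][known] <- obs[known]
  names(state) <- rownames(prob)
  list(q = q, loglik = -opt$objective, prob = prob, state = state,
       at_bound = at_bound)
}

#' Count gains and losses of sex bias on the tree
#'
#' A gain is a branch whose parent ML state is unbiased (`"U"`) and whose
#' child state (ML for internal nodes, observed for tips) is a biased state;
#' a loss is the reverse; a direct switch between the two biased states is
#' reported separately.
#'
#' @param tree the tree used for the reconstruction.
#' @param asr result of [mk_asr()].
#' @return data frame, one row per branch: `parent`, `child`, `child_is_tip`,
#'   `parent_state`, `child_state`, `event` (`"gain"`, `"loss"`, `"switch"` or
#'   NA) and `sex` (gained state for gains).
#' @export
count_gains <- function(tree, asr) {
  n_tip <- length(tree$tip.label)
  st <- asr$state
  edge <- tree$edge
  ps <- st[edge[, 1]]
  cs <- st[edge[, 2]]
  event <- rep(NA_character_, nrow(edge))
  event[ps == "U" & cs %in% c("M", "F")] <- "gain"
  event[ps %in% c("M", "F") & cs == "U"] <- "loss"
  event[ps %in% c("M", "F") & cs %in% c("M", "F") & ps != cs] <- "switch"
  data.frame(
    parent = edge[, 1], child = edge[, 2],
    child_is_tip = edge[, 2] <= n_tip,
    parent_state = unname(ps), child_state = unname(cs),
    event = event,
    sex = ifelse(event == "gain", unname(cs), NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Phylogenetic generalized least squares
#'
#' GLS regression with residual covariance proportional to the Brownian
#' shared-path-length matrix of the tree:
#' `beta = (X' V^-1 X)^-1 X' V^-1 y`, standard errors from
#' `sigma2_hat (X' V^-1 X)^-1`, t-tests on `n - p` degrees of freedom.
#'
#' @param y named per-species response (names = tip labels).
#' @param X per-species predictor vector or matrix (an intercept is added).
#' @param tree species tree covering the names of `y`.
#' @return list with `coefficients` (data frame: estimate, se, t, p),
#'   `sigma2` and `df_residual`.
#' @export
pgls_fit <- function(y, X, tree) {
  sp <- names(y)
  if (is.null(sp)) stop("y must be named by species")
  V <- ape::vcv(tree)[sp, sp]
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- sp
  D <- cbind(`(Intercept)` = 1, X[sp, , drop = FALSE])
  Vi <- solve(V)
  XtVi <- crossprod(D, Vi)
  A <- XtVi %*% D
  qrA <- qr(A)
  if (qrA$rank < ncol(D)) stop("singular design matrix")
  beta <- solve(A, XtVi %*% y)
  r <- y - D %*% beta
  n <- length(y); p <- ncol(D)
  sigma2 <- as.numeric(crossprod(r, Vi %*% r)) / (n - p)
  covb <- sigma2 * solve(A)
  se <- sqrt(diag(covb))
  tval <- as.vector(beta) / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  list(
    coefficients = data.frame(
      term = colnames(D), estimate = as.vector(beta), se = se,
      t = tval, p = pval, stringsAsFactors = FALSE
    ),
    sigma2 = sigma2, df_residual = n - p
  )
}
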