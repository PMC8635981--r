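# Evolutionary-history classification of sex-biased genes and the
# within-species identity-permutation null for shared/divergent overlap.

sbg_calls_by_gene <- function(calls) {
  biased <- calls[calls$status %in% c("male_biased", "female_biased"), ]
  biased$direction <- ifelse(biased$status == "male_biased", "M", "F")
  split(biased[, c("species", "direction")], biased$gene_id)
}

#' Classify the evolutionary history of each sex-biased gene
#'
#' Maps every gene biased in at least one species to one of the history
#' categories: `uniquely_{male,female}_tip` (biased in exactly one species),
#' `shared_{male,female}_single_ancestral` (same direction in >= 2 species
#' explained by exactly one ancestral gain and no tip gains),
#' `shared_{male,female}_repeated` (same direction, >= 2 independent gains),
#' or `divergent` (opposite directions in different species). Multi-species
#' genes are reconstructed with [mk_asr()] on the species tree; a species in
#' which the gene is not expressed contributes an ambiguous tip state (a
#' configurable alternative treats it as unbiased).
#'
#' @param calls SBG call table from [call_sbg()].
#' @param tree species tree (tips = dioecious species; extra tips such as the
#'   outgroup are allowed and enter the reconstruction as ambiguous or
#'   unbiased depending on their call rows being absent).
#' @param unexpressed one of `"ambiguous"` (default) or `"unbiased"`: tip
#'   state for species where the gene is `not_expressed` (species absent from
#'   `calls`, e.g. the outgroup, are always ambiguous).
#' @return data frame per biased gene: `gene_id`, `category`, `direction`
#'   (`"M"`, `"F"` or `"both"`), `n_species`, `n_gains`, `n_losses`.
#' @export
classify_histories <- function(calls, tree, unexpressed = c("ambiguous", "unbiased")) {
  unexpressed <- match.arg(unexpressed)
  per_gene <- sbg_calls_by_gene(calls)
  if (length(per_gene) == 0) {
    return(data.frame(gene_id = character(0), category = character(0),
                      direction = character(0), n_species = integer(0),
                      n_gains = integer(0), n_losses = integer(0)))
  }
  called_species <- unique(calls$species)
  rows <- lapply(names(per_gene), function(g) {
    b <- per_gene[[g]]
    dirs <- unique(b$direction)
    sex_word <- c(M = "male", F = "female")
    n_sp <- nrow(b)
    if (length(dirs) > 1) {
      return(data.frame(gene_id = g, category = "divergent",
                        direction = "both", n_species = n_sp,
                        n_gains = NA_integer_, n_losses = NA_integer_))
    }
    if (n_sp == 1) {
      return(data.frame(
        gene_id = g,
        category = paste0("uniquely_", sex_word[dirs], "_tip"),
        direction = dirs, n_species = 1L,
        n_gains = 1L, n_losses = 0L))
    }
    # same direction in >= 2 species: reconstruct and count gains
    gcalls <- calls[calls$gene_id == g, ]
    st <- rep("?", length(tree$tip.label))
    names(st) <- tree$tip.label
    for (sp in intersect(called_species, tree$tip.label)) {
      row <- gcalls[gcalls$species == sp, ]
      if (nrow(row) == 0) next
      st[sp] <- switch(row$status[1],
                       male_biased = "M", female_biased = "F",
                       unbiased = "U",
                       not_expressed = if (unexpressed == "unbiased") "U" else "?")
    }
    asr <- suppressWarnings(mk_asr(tree, st))
    ev <- count_gains(tree, asr)
    n_gains <- sum(ev$event == "gain", na.rm = TRUE)
    n_losses <- sum(ev$event == "loss", na.rm = TRUE)
    ancestral_gain <- sum(ev$event == "gain" & !ev$child_is_tip, na.rm = TRUE)
    tip_gain <- sum(ev$event == "gain" & ev$child_is_tip, na.rm = TRUE)
    cat <- if (ancestral_gain == 1 && tip_gain == 0) {
      paste0("shared_", sex_word[dirs], "_single_ancestral")
    } else {
      paste0("shared_", sex_word[dirs], "_repeated")
    }
    data.frame(gene_id = g, category = cat, direction = dirs,
               n_species = n_sp, n_gains = n_gains, n_losses = n_losses)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# collapse per-species biased sets into the null-comparable categories
overlap_categories <- function(male_sets, female_sets) {
  all_genes <- unique(c(unlist(male_sets), unlist(female_sets)))
  cats <- c(uniquely_male_tip = 0, uniquely_female_tip = 0,
            shared_male = 0, shared_female = 0, divergent = 0)
  if (length(all_genes) == 0) return(cats)
  nm <- vapply(all_genes, function(g)
    sum(vapply(male_sets, function(s) g %in% s, logical(1))), numeric(1))
  nf <- vapply(all_genes, function(g)
    sum(vapply(female_sets, function(s) g %in% s, logical(1))), numeric(1))
  cats["divergent"] <- sum(nm > 0 & nf > 0)
  cats["shared_male"] <- sum(nm >= 2 & nf == 0)
  cats["shared_female"] <- sum(nf >= 2 & nm == 0)
  cats["uniquely_male_tip"] <- sum(nm == 1 & nf == 0)
  cats["uniquely_female_tip"] <- sum(nf == 1 & nm == 0)
  cats
}

#' Permutation test for shared and divergent sex-biased genes
#'
#' Tests the observed numbers of uniquely biased, shared (same direction in
#' >= 2 species) and divergent (opposite directions) genes against the null
#' hypothesis that SBG identities are random within each species: each
#' permutation redraws, within every species independently, which of its
#' expressed genes carry that species' male- and female-biased labels, keeping
#' the per-species counts intact. The ancestral-vs-tip distinction is
#' collapsed in the null; genes gaining bias only ancestrally can be excluded
#' via `exclude_genes`. One-sided p-values use the `+1` correction, with the
#' upper tail for shared/divergent categories and the lower tail for unique
#' categories (the tail used is reported).
#'
#' @param calls SBG call table from [call_sbg()].
#' @param universes named list (per species) of expressed gene identifiers;
#'   defaults to each species' genes not `not_expressed` in `calls`.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param exclude_genes genes excluded from both observed and permuted counts
#'   (e.g. those with a single ancestral gain).
#' @return data frame per category: `category`, `observed`, `expected_mean`,
#'   `p_value`, `tail`, `n_perm`.
#' @export
overlap_permutation_test <- function(calls, universes = NULL, n_perm = 10000,
                                     seed = 1L, exclude_genes = NULL) {
  species <- sort(unique(calls$species))
  if (is.null(universes)) {
    universes <- lapply(species, function(sp) {
      calls$gene_id[calls$species == sp & calls$status != "not_expressed"]
    })
    names(universes) <- species
  }
  keep <- !(calls$gene_id %in% exclude_genes)
  male_sets <- lapply(species, function(sp) {
    calls$gene_id[keep & calls$species == sp & calls$status == "male_biased"]
  })
  female_sets <- lapply(species, function(sp) {
    calls$gene_id[keep & calls$species == sp & calls$status == "female_biased"]
  })
  names(male_sets) <- names(female_sets) <- species
  for (sp in species) {
    n_lab <- length(male_sets[[sp]]) + length(female_sets[[sp]])
    if (n_lab > length(universes[[sp]])) {
      stop("species ", sp, " has more SBGs than expressed genes")
    }
  }
  observed <- overlap_categories(male_sets, female_sets)
  set.seed(seed)
  perm <- matrix(0, n_perm, length(observed),
                 dimnames = list(NULL, names(observed)))
  for (i in seq_len(n_perm)) {
    pm <- list(); pf <- list()
    for (sp in species) {
      nm <- length(male_sets[[sp]]); nf <- length(female_sets[[sp]])
      draw <- sample(universes[[sp]], nm + nf)
      pm[[sp]] <- draw[seq_len(nm)]
      pf[[sp]] <- draw[nm + seq_len(nf)]
    }
    perm[i, ] <- overlap_categories(pm, pf)
  }
  tail_for <- c(uniquely_male_tip = "lower", uniquely_female_tip = "lower",
                shared_male = "upper", shared_female = "upper",
                divergent = "upper")
  out <- data.frame(
    category = names(observed),
    observed = as.numeric(observed),
    expected_mean = colMeans(perm),
    p_value = NA_real_,
    tail = tail_for[names(observed)],
    n_perm = n_perm,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(nrow(out))) {
    v <- perm[, j]
    out$p_value[j] <- if (out$tail[j] == "upper") {
      (1 + sum(v >= out$observed[j])) / (n_perm + 1)
    } else {
      (1 + sum(v <= out$observed[j])) / (n_perm + 1)
    }
  }
  rownames(out) <- NULL
  out
}
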