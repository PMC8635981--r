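# Raw pairwise sequence divergence at fourfold-degenerate sites from codon
# alignments (p-distance, no multiple-hit correction).

#' Read / write FASTA alignments
#'
#' Thin wrappers over Biostrings returning alignments as named character
#' vectors (the representation used throughout this module).
#'
#' @param file FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta_alignment <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta_alignment
#' @param aln named character vector of aligned sequences.
#' @export
write_fasta_alignment <- function(aln, file) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln), file)
  invisible(file)
}

check_alignment <- function(aln) {
  if (is.null(names(aln)) || anyDuplicated(names(aln))) {
    stop("alignment taxa must be uniquely named")
  }
  n <- unique(nchar(aln))
  if (length(n) != 1) stop("sequences must have equal length")
  if (n %% 3 != 0) stop("alignment length must be divisible by 3")
  invisible(n)
}

#' Fourfold-degenerate site mask for a pair of taxa
#'
#' A third-codon-position column is selected iff, in both sequences, the
#' codon's first two positions are identical across the two sequences,
#' ungapped and unambiguous, define a fourfold-degenerate codon family under
#' the standard genetic code (GCN, CGN, GGN, CTN, CCN, TCN, ACN, GTN), and
#' both third positions are in {A, C, G, T}. This pairwise rule guarantees
#' the third-position comparison is synonymous.
#'
#' @param aln named character vector of aligned sequences.
#' @param pair two taxon names.
#' @return integer vector of codon indices (1-based) passing the mask.
#' @export
fourfold_site_mask <- function(aln, pair) {
  check_alignment(aln)
  if (!all(pair %in% names(aln))) {
    stop("taxa not in alignment: ",
         paste(setdiff(pair, names(aln)), collapse = ", "))
  }
  s1 <- toupper(aln[[pair[1]]])
  s2 <- toupper(aln[[pair[2]]])
  n <- nchar(s1) / 3
  start <- 3 * (seq_len(n) - 1) + 1
  p1 <- substring(s1, start, start + 1)
  p2 <- substring(s2, start, start + 1)
  t1 <- substring(s1, start + 2, start + 2)
  t2 <- substring(s2, start + 2, start + 2)
  nt <- c("A", "C", "G", "T")
  which(p1 == p2 & p1 %in% FOURFOLD_PREFIXES & t1 %in% nt & t2 %in% nt)
}

#' Raw divergence at fourfold-degenerate sites for a pair
#'
#' The proportion of masked third positions at which the two sequences differ
#' — a raw p-distance, no multiple-hit correction.
#'
#' @inheritParams fourfold_site_mask
#' @return list with `divergence` (NA when no sites), `n_sites`, `n_diff`.
#' @export
fourfold_divergence <- function(aln, pair) {
  idx <- fourfold_site_mask(aln, pair)
  if (length(idx) == 0) {
    return(list(divergence = NA_real_, n_sites = 0L, n_diff = 0L))
  }
  pos <- 3 * idx
  t1 <- substring(toupper(aln[[pair[1]]]), pos, pos)
  t2 <- substring(toupper(aln[[pair[2]]]), pos, pos)
  nd <- sum(t1 != t2)
  list(divergence = nd / length(idx), n_sites = length(idx), n_diff = nd)
}

#' Pairwise fourfold-divergence matrix over a set of alignments
#'
#' Pools fourfold sites across alignments with supermatrix semantics (total
#' differing sites / total sites per pair).
#'
#' @param alignments list of alignments (named character vectors).
#' @param taxa taxa to include; default: union over alignments.
#' @return symmetric matrix of divergences with zero diagonal; pairs covered
#'   by no sites are NA (with a warning).
#' @export
divergence_matrix <- function(alignments, taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(unique(unlist(lapply(alignments, names))))
  n <- length(taxa)
  sites <- diffs <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (aln in alignments) {
    present <- intersect(taxa, names(aln))
    if (length(present) < 2) next
    for (i in seq_len(length(present) - 1)) {
      for (j in (i + 1):length(present)) {
        fd <- fourfold_divergence(aln, c(present[i], present[j]))
        sites[present[i], present[j]] <- sites[present[i], present[j]] + fd$n_sites
        diffs[present[i], present[j]] <- diffs[present[i], present[j]] + fd$n_diff
      }
    }
  }
  sites <- sites + t(sites)
  diffs <- diffs + t(diffs)
  D <- diffs / sites
  diag(D) <- 0
  if (any(is.na(D[upper.tri(D)]))) {
    warning("taxon pair(s) with no fourfold sites: divergence NA")
  }
  D
}
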