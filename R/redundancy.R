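# Homology-aware redundancy reduction of training fragments.
#
# Two proteins sharing more than 30% local-alignment identity are treated
# as homologous; among homologous proteins, fragments whose 2n+1 windows
# are character-identical are collapsed to their first occurrence.  The
# positive and negative classes are reduced independently.

#' Local-alignment identity between two sequences
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps
#' (open 11, extend 1, the standard protein pairwise defaults), identity
#' defined as the number of identical aligned residue pairs divided by the
#' alignment length (gap columns included).  The pair is aligned in a
#' canonical (lexicographic) order, so the result is symmetric in its
#' arguments even when equal-score optimal alignments differ.
#'
#' @param seq_a,seq_b Protein sequences (non-empty strings).
#' @return A list with `identity` (fraction in `[0, 1]`),
#'   `aligned_length`, and `matches`.  A pair with no scoring local
#'   alignment has identity 0.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  # among equal-score optimal alignments the traceback can depend on
  # argument order; canonicalize so identity is symmetric by construction
  if (seq_b < seq_a) {
    tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  alen <- Biostrings::nchar(Biostrings::alignedPattern(aln))
  if (length(alen) == 0L || alen == 0L) {
    return(list(identity = 0, aligned_length = 0L, matches = 0L))
  }
  m <- Biostrings::nmatch(aln)
  list(identity = m / alen, aligned_length = as.integer(alen),
       matches = as.integer(m))
}

# protein-pair homology matrix for the ids actually present
.homology_matrix <- function(prot, ids, threshold) {
  ids <- unique(ids)
  h <- matrix(FALSE, length(ids), length(ids),
              dimnames = list(ids, ids))
  diag(h) <- TRUE  # a protein is trivially homologous to itself
  if (length(ids) > 1L) {
    for (a in seq_len(length(ids) - 1L)) {
      for (b in (a + 1L):length(ids)) {
        sa <- prot$sequence[.lookup_protein(prot, ids[a])]
        sb <- prot$sequence[.lookup_protein(prot, ids[b])]
        hom <- pairwise_identity(sa, sb)$identity > threshold
        h[a, b] <- hom
        h[b, a] <- hom
      }
    }
  }
  h
}

#' Collapse redundant fragments between homologous proteins
#'
#' For every protein pair whose full-sequence identity exceeds `threshold`,
#' any pair of their fragments with identical window strings (and the same
#' class label) is collapsed to the first occurrence in input order.  The
#' positive and negative sets are reduced independently, labels are never
#' altered, and the result is always a subset of the input.
#'
#' @param fragments Fragment data frame from [extract_fragments()]; all
#'   fragments must share one window length.
#' @param prot Protein table supplying the full sequences for the identity
#'   gate.
#' @param threshold Identity fraction above which two proteins count as
#'   homologous (default 0.30).
#' @return The kept fragments, with an attribute `removed` holding the
#'   dropped rows and the id of the fragment each was collapsed into.
#' @export
reduce_fragments <- function(fragments, prot, threshold = 0.30) {
  if (nrow(fragments) == 0L) return(fragments)
  if (length(unique(fragments$n)) != 1L) {
    stop("fragments mix window lengths")
  }
  hom <- .homology_matrix(prot, fragments$protein_id, threshold)
  keep <- logical(nrow(fragments))
  collapsed_into <- integer(0)
  removed_idx <- integer(0)
  for (lab in unique(fragments$label)) {
    idx <- which(fragments$label == lab)
    kept_here <- integer(0)
    for (i in idx) {
      dup <- kept_here[fragments$residues[kept_here] == fragments$residues[i] &
                         hom[fragments$protein_id[kept_here],
                             fragments$protein_id[i]]]
      if (length(dup) == 0L) {
        keep[i] <- TRUE
        kept_here <- c(kept_here, i)
      } else {
        removed_idx <- c(removed_idx, i)
        collapsed_into <- c(collapsed_into, dup[1])
      }
    }
  }
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  removed <- fragments[removed_idx, , drop = FALSE]
  if (nrow(removed) > 0L) removed$collapsed_into <- collapsed_into
  attr(out, "removed") <- removed
  out
}
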