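# Feature encoders.  Each encoder maps a fragment (and, where needed, its
# per-residue profiles) to one fixed-order numeric block; assemble()
# concatenates enabled blocks in the canonical order
# AAC, AAPC, BLOSUM, PSSM400, ASA, SS.
#
# Effective residues are the 20 standard amino acids: the terminal marker
# and the unknown residue X contribute nothing to compositions (neither to
# the counts nor to the denominator).

BLOCK_ORDER <- c("AAC", "AAPC", "BLOSUM", "PSSM400", "ASA", "SS")

.residue_chars <- function(residues) strsplit(residues, "")[[1]]

#' Amino-acid composition of a window
#'
#' Occurrence counts of the 20 amino acids normalized by the number of
#' effective residues (terminal markers and X excluded from counts and
#' denominator alike).
#'
#' @param residues Window string (may contain `-` and `X`).
#' @return Named numeric vector of length 20 in [AA_ORDER]; sums to 1.
#' @export
encode_aac <- function(residues) {
  ch <- .residue_chars(residues)
  eff <- ch[ch %in% AA_ORDER]
  if (length(eff) == 0L) stop("no effective residues in window")
  counts <- table(factor(eff, levels = AA_ORDER))
  v <- as.numeric(counts) / length(eff)
  names(v) <- paste0("AAC.", AA_ORDER)
  v
}

#' Amino-acid pair composition of a window
#'
#' Counts of the 400 ordered adjacent residue pairs, normalized by the
#' number of effective residues (so the vector sums to `(L-1)/L` for a
#' marker-free window of L residues).  Pairs spanning a terminal marker or
#' an X are skipped.
#'
#' @inheritParams encode_aac
#' @return Named numeric vector of length 400 (`AAPC.<a><b>`).
#' @export
encode_aapc <- function(residues) {
  ch <- .residue_chars(residues)
  eff_n <- sum(ch %in% AA_ORDER)
  if (eff_n < 2L) stop("need at least 2 effective residues for pairs")
  a <- ch[-length(ch)]
  b <- ch[-1]
  ok <- a %in% AA_ORDER & b %in% AA_ORDER
  pair <- factor(paste0(a[ok], b[ok]),
                 levels = as.vector(outer(AA_ORDER, AA_ORDER,
                                          function(x, y) paste0(x, y))))
  v <- as.numeric(table(pair)) / eff_n
  names(v) <- paste0("AAPC.", levels(pair))
  v
}

#' BLOSUM62 window encoding
#'
#' Each window position contributes 21 values: the min-max-normalized
#' BLOSUM62 row of its residue (20 values) plus a terminal flag that is 1
#' exactly when the position lies outside the protein (in which case the 20
#' row values are 0).  The unknown residue X also encodes as 20 zeros with
#' flag 0.
#'
#' @param residues Window string of length 2n+1.
#' @return Named numeric vector of length `21 * (2n+1)` in `[0, 1]`.
#' @export
encode_blosum <- function(residues) {
  ch <- .residue_chars(residues)
  b <- blosum62_normalized()
  n <- (length(ch) - 1L) %/% 2L
  offs <- -n:n
  v <- numeric(21L * length(ch))
  nm <- character(length(v))
  for (p in seq_along(ch)) {
    at <- (p - 1L) * 21L
    row <- numeric(20)
    flag <- 0
    if (ch[p] == TERMINAL_MARKER) {
      flag <- 1
    } else if (ch[p] %in% AA_ORDER) {
      row <- b[ch[p], ]
    }
    v[at + 1:20] <- row
    v[at + 21L] <- flag
    nm[at + 1:21] <- paste0("BLOSUM.", offs[p], ".", c(AA_ORDER, "term"))
  }
  names(v) <- nm
  v
}

#' 400-D summed PSSM window transform
#'
#' The `m` PSSM rows centered on the site (rows outside the protein are
#' skipped) are accumulated into a 20x20 matrix by residue type: row `t` of
#' the result is the sum of the PSSM rows whose sequence residue is `t`.
#' Every element is then divided by the window length `m` and squashed with
#' the logistic function `1/(1+exp(-x))`, and the matrix is flattened
#' row-major.  Window residue types absent from the window leave their row
#' at zero, hence at 0.5 after squashing.
#'
#' @param pssm L x 20 PSSM matrix of the protein.
#' @param sequence The protein sequence (supplies the residue type of each
#'   PSSM row).
#' @param center 1-based site position.
#' @param m Odd window length (default `2*20+1`).
#' @return Named numeric vector of length 400, all values in `(0, 1)`.
#' @export
encode_pssm400 <- function(pssm, sequence, center, m = 41L) {
  if (m %% 2L == 0L) stop("m must be odd")
  L <- nrow(pssm)
  if (nchar(sequence) != L) stop("PSSM rows do not match sequence length")
  if (center < 1L || center > L) stop("center out of range")
  half <- (m - 1L) %/% 2L
  idx <- (center - half):(center + half)
  idx <- idx[idx >= 1L & idx <= L]
  acc <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  res <- substring(sequence, idx, idx)
  for (i in seq_along(idx)) {
    t <- res[i]
    if (t %in% AA_ORDER) acc[t, ] <- acc[t, ] + pssm[idx[i], ]
  }
  sq <- 1 / (1 + exp(-acc / m))
  v <- as.numeric(t(sq))  # row-major flatten
  names(v) <- paste0("PSSM400.",
                     as.vector(t(outer(AA_ORDER, AA_ORDER, paste, sep = "."))))
  v
}

#' Scaled solvent-accessibility window
#'
#' ASA percentages in the window divided by 100; out-of-range positions 0.
#'
#' @param asa Per-residue percent-accessibility vector of the protein.
#' @param center 1-based site position.
#' @param n Half-window.
#' @return Named numeric vector of length `2n+1` in `[0, 1]`.
#' @export
encode_asa <- function(asa, center, n) {
  idx <- (center - n):(center + n)
  v <- numeric(length(idx))
  inr <- idx >= 1L & idx <= length(asa)
  v[inr] <- asa[idx[inr]] / 100
  names(v) <- paste0("ASA.", -n:n)
  v
}

#' One-hot secondary-structure window
#'
#' Each window position encodes helix as `1 0 0`, sheet as `0 1 0` and coil
#' as `0 0 1`; out-of-range positions are all-zero.
#'
#' @param ss Per-residue secondary-structure string over `{H, E, C}`.
#' @param center 1-based site position.
#' @param n Half-window.
#' @return Named numeric vector of length `3 * (2n+1)`.
#' @export
encode_ss <- function(ss, center, n) {
  idx <- (center - n):(center + n)
  offs <- -n:n
  v <- numeric(3L * length(idx))
  nm <- paste0("SS.", rep(offs, each = 3), ".", c("H", "E", "C"))
  for (p in seq_along(idx)) {
    if (idx[p] >= 1L && idx[p] <= nchar(ss)) {
      s <- substr(ss, idx[p], idx[p])
      k <- match(s, c("H", "E", "C"))
      v[(p - 1L) * 3L + k] <- 1
    }
  }
  names(v) <- nm
  v
}

#' Assemble the feature vector of one fragment
#'
#' Concatenates the enabled feature blocks in the canonical order
#' AAC, AAPC, BLOSUM, PSSM400, ASA, SS and records the block layout.
#'
#' @param fragment One-row fragment data frame.
#' @param profiles Per-protein profile list (elements `pssm`, `asa`, `ss`)
#'   for the fragment's protein, or `NULL` when only sequence blocks are
#'   enabled.
#' @param sequence Full protein sequence (needed for the PSSM400 block).
#' @param blocks Character vector of enabled block names.
#' @param m PSSM window length (default the fragment's `2n+1`).
#' @return Named numeric vector with attribute `blocks`, a data frame of
#'   `(block, offset, length)`.
#' @export
assemble <- function(fragment, profiles = NULL, sequence = NULL,
                     blocks = c("AAC", "PSSM400"), m = NULL) {
  blocks <- match.arg(blocks, BLOCK_ORDER, several.ok = TRUE)
  blocks <- BLOCK_ORDER[BLOCK_ORDER %in% blocks]
  n <- fragment$n
  if (is.null(m)) m <- 2L * n + 1L
  need_prof <- c(PSSM400 = "pssm", ASA = "asa", SS = "ss")
  for (blk in intersect(blocks, names(need_prof))) {
    if (is.null(profiles) || is.null(profiles[[need_prof[blk]]])) {
      stop("block ", blk, " enabled but profile '", need_prof[blk],
           "' is missing for protein '", fragment$protein_id, "'")
    }
  }
  parts <- lapply(blocks, function(blk) {
    switch(blk,
           AAC = encode_aac(fragment$residues),
           AAPC = encode_aapc(fragment$residues),
           BLOSUM = encode_blosum(fragment$residues),
           PSSM400 = encode_pssm400(profiles$pssm, sequence,
                                    fragment$center, m),
           ASA = encode_asa(profiles$asa, fragment$center, n),
           SS = encode_ss(profiles$ss, fragment$center, n))
  })
  lens <- vapply(parts, length, integer(1))
  v <- unlist(parts, use.names = TRUE)
  attr(v, "blocks") <- data.frame(
    block = blocks,
    offset = cumsum(c(0L, lens[-length(lens)])),
    length = lens, stringsAsFactors = FALSE)
  v
}

#' Encode a whole fragment set as a feature matrix
#'
#' @param fragments Fragment data frame.
#' @param prot Protein table.
#' @param profiles Named list (by protein id) of profile lists with
#'   elements `pssm`, `asa`, `ss`; may be `NULL` for sequence-only blocks.
#' @inheritParams assemble
#' @return A list with `x` (numeric matrix, one row per fragment, block-
#'   qualified column names), `labels` (character vector), and `blocks`
#'   (the block layout table).
#' @export
encode_dataset <- function(fragments, prot, profiles = NULL,
                           blocks = c("AAC", "PSSM400"), m = NULL) {
  rows <- lapply(seq_len(nrow(fragments)), function(i) {
    fr <- fragments[i, , drop = FALSE]
    j <- .lookup_protein(prot, fr$protein_id)
    assemble(fr, profiles[[fr$protein_id]], prot$sequence[j], blocks, m)
  })
  x <- do.call(rbind, rows)
  list(x = x, labels = fragments$label, blocks = attr(rows[[1]], "blocks"))
}
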