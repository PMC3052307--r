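#' Amino-acid alphabet and substitution-matrix helpers
#'
#' All encoders and file readers in the package share one fixed residue
#' order, `AA_ORDER` (the PSI-BLAST PSSM column order), so that feature
#' columns are bit-for-bit reproducible across blocks and files.
#'
#' @format `AA_ORDER` is a length-20 character vector.
#' @export
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# residues accepted in sequences: the 20 standard AAs plus X (unknown)
SEQ_ALPHABET <- c(AA_ORDER, "X")

# marker for window positions falling outside the protein termini
TERMINAL_MARKER <- "-"

#' Min-max normalized BLOSUM62 rows
#'
#' Returns the 20x20 BLOSUM62 substitution matrix (rows/columns in
#' [AA_ORDER]) rescaled globally to `[0, 1]` by the matrix-wide minimum and
#' maximum.  Global (rather than per-row) scaling preserves the ordering of
#' all substitution scores.
#'
#' @return A 20x20 numeric matrix with values in `[0, 1]`.
#' @export
blosum62_normalized <- function() {
  b <- get_blosum62()[AA_ORDER, AA_ORDER]
  (b - min(b)) / (max(b) - min(b))
}

# the integer BLOSUM62 from Biostrings, cached per session
get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})
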