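# Readers and writers for the external file formats, candidate-site
# enumeration, and fragment (window) extraction.
#
# Coordinates are 1-based inclusive throughout; window offsets run -n..+n
# relative to the central lysine.

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and whitespace-stripped.  Only the 20 standard
#' amino acids plus `X` (unknown residue) are accepted; any other character
#' is an error naming the record and offset, so malformed input never
#' propagates silently into the encoders.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` (first word of the header),
#'   `sequence`, and `length`, one row per record in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    stop("no FASTA records in '", path, "'")
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  for (i in seq_along(seqs)) {
    bad <- which(!strsplit(seqs[[i]], "")[[1]] %in% SEQ_ALPHABET)
    if (length(bad) > 0L) {
      stop("illegal residue character '",
           substr(seqs[[i]], bad[1], bad[1]),
           "' in record '", ids[i], "' at offset ", bad[1])
    }
  }
  proteins(ids, seqs)
}

#' Construct a protein table
#'
#' @param id Character vector of identifiers.
#' @param sequence Character vector of uppercase sequences over the
#'   20-letter amino-acid alphabet plus `X`.
#' @return A validated data frame with columns `id`, `sequence`, `length`.
#' @export
proteins <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  id <- unname(id)
  sequence <- unname(sequence)
  sequence <- toupper(sequence)
  if (anyDuplicated(id)) stop("duplicate protein ids")
  if (any(nchar(sequence) < 1L)) stop("empty sequence")
  ok <- vapply(strsplit(sequence, ""),
               function(ch) all(ch %in% SEQ_ALPHABET), logical(1))
  if (!all(ok)) {
    stop("sequence of '", id[which(!ok)[1]],
         "' contains characters outside the amino-acid alphabet")
  }
  data.frame(id = id, sequence = sequence, length = nchar(sequence),
             stringsAsFactors = FALSE)
}

#' Write a protein table to FASTA
#'
#' @param prot Protein data frame from [proteins()] or [read_fasta()].
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(prot, path, width = 60L) {
  lines <- unlist(lapply(seq_len(nrow(prot)), function(i) {
    s <- prot$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", prot$id[i]),
      substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

.lookup_protein <- function(prot, id) {
  j <- match(id, prot$id)
  if (is.na(j)) stop("unknown protein id '", id, "'")
  j
}

#' Read lysine site annotations
#'
#' Reads a tab-separated file with columns `protein_id`, `position`
#' (1-based) and `label` (`positive` or `negative`) and cross-checks every
#' row against its protein: the position must be in range and the residue
#' there must be lysine (K).
#'
#' @param path Path to the site TSV (no header).
#' @param prot Protein table the annotations refer to.
#' @return A data frame with columns `protein_id`, `position`, `label`.
#' @export
read_site_annotations <- function(path, prot) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("protein_id", "position", "label"),
                           colClasses = c("character", "integer", "character"),
                           quote = "", comment.char = "")
  site_annotations(tab$protein_id, tab$position, tab$label, prot)
}

#' Construct validated site annotations
#'
#' @param protein_id,position,label Parallel vectors describing candidate
#'   lysines.
#' @param prot Protein table.
#' @return A data frame with columns `protein_id`, `position`, `label`.
#' @export
site_annotations <- function(protein_id, position, label, prot) {
  stopifnot(length(protein_id) == length(position),
            length(position) == length(label))
  if (!all(label %in% c("positive", "negative"))) {
    stop("labels must be 'positive' or 'negative'")
  }
  for (i in seq_along(protein_id)) {
    j <- .lookup_protein(prot, protein_id[i])
    if (position[i] < 1L || position[i] > prot$length[j]) {
      stop("position ", position[i], " out of range for protein '",
           protein_id[i], "' (length ", prot$length[j], ")")
    }
    res <- substr(prot$sequence[j], position[i], position[i])
    if (res != "K") {
      stop("residue at position ", position[i], " of '", protein_id[i],
           "' is '", res, "', not K")
    }
  }
  data.frame(protein_id = protein_id, position = as.integer(position),
             label = label, stringsAsFactors = FALSE)
}

#' Write site annotations as TSV
#'
#' @param sites Site annotation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_annotations <- function(sites, path) {
  utils::write.table(sites[, c("protein_id", "position", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Enumerate non-annotated lysines as negative sites
#'
#' Every lysine of the protein that is not among the annotated positives is
#' returned as a negative site, following the convention that negatives are
#' drawn from the same proteins as the positives.
#'
#' @param prot Protein table.
#' @param protein_id Protein to enumerate.
#' @param positive_positions Integer vector of annotated positive lysines on
#'   that protein.
#' @return A site annotation data frame (possibly zero rows).
#' @export
enumerate_negative_sites <- function(prot, protein_id, positive_positions) {
  j <- .lookup_protein(prot, protein_id)
  kpos <- which(strsplit(prot$sequence[j], "")[[1]] == "K")
  if (length(positive_positions) > 0L &&
      !all(positive_positions %in% kpos)) {
    stop("positive positions not all lysines of '", protein_id, "'")
  }
  neg <- setdiff(kpos, positive_positions)
  data.frame(protein_id = rep(protein_id, length(neg)),
             position = as.integer(neg),
             label = rep("negative", length(neg)),
             stringsAsFactors = FALSE)
}

#' Extract the 2n+1 window around a candidate lysine
#'
#' Window positions falling outside the protein termini are filled with the
#' terminal marker `-`, which the encoders map to the dedicated terminal
#' channel.
#'
#' @param prot Protein table.
#' @param protein_id,position Site coordinates; the residue at `position`
#'   must be K.
#' @param n Half-window size; the fragment has `2n+1` residues covering
#'   offsets `-n..+n`.  Default 20 (41-mer).
#' @param label Optional class label carried along.
#' @return A one-row fragment data frame with columns `protein_id`,
#'   `center`, `n`, `residues`, `label`.
#' @export
extract_fragment <- function(prot, protein_id, position, n = 20L,
                             label = NA_character_) {
  stopifnot(n >= 1L)
  j <- .lookup_protein(prot, protein_id)
  L <- prot$length[j]
  if (position < 1L || position > L) {
    stop("position out of range")
  }
  if (substr(prot$sequence[j], position, position) != "K") {
    stop("residue at position ", position, " of '", protein_id,
         "' is not K")
  }
  idx <- (position - n):(position + n)
  chars <- rep(TERMINAL_MARKER, length(idx))
  inr <- idx >= 1L & idx <= L
  chars[inr] <- substring(prot$sequence[j], idx[inr], idx[inr])
  data.frame(protein_id = protein_id, center = as.integer(position),
             n = as.integer(n), residues = paste(chars, collapse = ""),
             label = label, stringsAsFactors = FALSE)
}

#' Extract windows for a whole site table
#'
#' @param prot Protein table.
#' @param sites Site annotation data frame.
#' @inheritParams extract_fragment
#' @return A fragment data frame with one row per site, in site order.
#' @export
extract_fragments <- function(prot, sites, n = 20L) {
  out <- lapply(seq_len(nrow(sites)), function(i) {
    extract_fragment(prot, sites$protein_id[i], sites$position[i], n,
                     sites$label[i])
  })
  do.call(rbind, out)
}

#' Read an L x 20 PSSM profile
#'
#' Two dialects are supported: `tsv` (a plain whitespace-separated L x 20
#' numeric table, optionally with a header row of the 20 residue letters)
#' and `psiblast_ascii` (the classic 44-column PSI-BLAST ASCII PSSM; the
#' first 20 score columns are used).  Columns are returned in the fixed
#' order given by [AA_ORDER].
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"psiblast_ascii"`.
#' @param expected_length If given, the row count is checked against it and
#'   a mismatch is an error (no silent truncation).
#' @return An L x 20 numeric matrix with columns named by [AA_ORDER].
#' @export
read_pssm_profile <- function(path, dialect = c("tsv", "psiblast_ascii"),
                              expected_length = NULL) {
  dialect <- match.arg(dialect)
  mat <- switch(dialect,
                tsv = .read_pssm_tsv(path),
                psiblast_ascii = .read_pssm_psiblast(path))
  if (!is.null(expected_length) && nrow(mat) != expected_length) {
    stop("PSSM in '", path, "' has ", nrow(mat),
         " rows but the sequence has ", expected_length, " residues")
  }
  colnames(mat) <- AA_ORDER
  mat
}

.read_pssm_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty PSSM file '", path, "'")
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (all(first %in% AA_ORDER) && length(first) == 20L) {
    if (!identical(first, AA_ORDER)) {
      stop("PSSM header column order must be ", paste(AA_ORDER, collapse = ""))
    }
    lines <- lines[-1]
  }
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) != 20L || anyNA(v)) {
      stop("malformed PSSM line ", i, " in '", path, "'")
    }
    v
  })
  do.call(rbind, rows)
}

# PSI-BLAST ASCII layout: 2 header/blank lines, one line of 40 column
# letters, then one row per residue (index, residue, 20 scores, 20
# percentages, 2 stats), terminated by a blank line before the K/Lambda
# footer.
.read_pssm_psiblast <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*A\\s+R\\s+N\\s+D", lines)
  if (length(hdr) == 0L) stop("not a PSI-BLAST ASCII PSSM: '", path, "'")
  rows <- list()
  for (i in seq(hdr[1] + 1L, length(lines))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) break
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 22L || is.na(suppressWarnings(as.integer(f[1])))) {
      stop("malformed PSI-BLAST PSSM line ", i, " in '", path, "'")
    }
    v <- suppressWarnings(as.numeric(f[3:22]))
    if (anyNA(v)) stop("malformed PSI-BLAST PSSM line ", i, " in '", path, "'")
    rows[[length(rows) + 1L]] <- v
  }
  if (length(rows) == 0L) stop("no PSSM rows in '", path, "'")
  do.call(rbind, rows)
}

#' Write a PSSM profile
#'
#' @param pssm L x 20 numeric matrix.
#' @param path Output file.
#' @param sequence For the `psiblast_ascii` dialect, the protein sequence
#'   (supplies the residue column).
#' @inheritParams read_pssm_profile
#' @return `path`, invisibly.
#' @export
write_pssm_profile <- function(pssm, path,
                               dialect = c("tsv", "psiblast_ascii"),
                               sequence = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    lines <- c(paste(AA_ORDER, collapse = "\t"),
               apply(pssm, 1, function(r) paste(format(r, trim = TRUE,
                                                       scientific = FALSE),
                                                collapse = "\t")))
  } else {
    if (is.null(sequence) || nchar(sequence) != nrow(pssm)) {
      stop("psiblast_ascii dialect needs the matching sequence")
    }
    res <- strsplit(sequence, "")[[1]]
    body <- vapply(seq_len(nrow(pssm)), function(i) {
      paste0(formatC(i, width = 5), " ", res[i], " ",
             paste(formatC(round(pssm[i, ]), width = 4), collapse = ""),
             " ", paste(formatC(rep(0L, 20), width = 4), collapse = ""),
             "  0.00 0.00")
    }, character(1))
    lines <- c("",
               "Last position-specific scoring matrix computed",
               paste0("      ", paste(c(AA_ORDER, AA_ORDER), collapse = "  ")),
               body, "", "                      K         Lambda")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-residue ASA profile
#'
#' One percent-accessibility value per residue, whitespace- or
#' newline-separated; values must lie in `[0, 100]`.
#'
#' @param path Input file.
#' @param expected_length Optional length check.
#' @return Numeric vector of percent accessibilities.
#' @export
read_asa_profile <- function(path, expected_length = NULL) {
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) == 0L) stop("empty ASA profile '", path, "'")
  if (any(!is.finite(vals)) || any(vals < 0 | vals > 100)) {
    stop("ASA values in '", path, "' must be finite and within [0, 100]")
  }
  if (!is.null(expected_length) && length(vals) != expected_length) {
    stop("ASA profile length ", length(vals), " does not match sequence (",
         expected_length, ")")
  }
  vals
}

#' Write an ASA profile
#' @param asa Numeric vector of percent accessibilities.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_asa_profile <- function(asa, path) {
  writeLines(format(asa, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Read a per-residue secondary-structure profile
#'
#' Accepts either a single-line string over `{H, E, C}` or a PSIPRED-style
#' `.ss2` table (the state letter in column 3).
#'
#' @param path Input file.
#' @param expected_length Optional length check.
#' @return A single string over `{H, E, C}`.
#' @export
read_ss_profile <- function(path, expected_length = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty SS profile '", path, "'")
  if (length(lines) == 1L && !grepl("\\s", trimws(lines[1]))) {
    ss <- toupper(trimws(lines[1]))
  } else {
    body <- lines[!grepl("^#", lines)]
    fields <- strsplit(trimws(body), "\\s+")
    fields <- fields[vapply(fields, length, integer(1)) >= 3L &
                       !is.na(suppressWarnings(
                         as.integer(vapply(fields, `[`, character(1), 1))))]
    ss <- paste(vapply(fields, `[`, character(1), 3), collapse = "")
  }
  bad <- which(!strsplit(ss, "")[[1]] %in% c("H", "E", "C"))
  if (length(bad) > 0L) {
    stop("illegal secondary-structure symbol '",
         substr(ss, bad[1], bad[1]), "' at position ", bad[1],
         " in '", path, "'")
  }
  if (!is.null(expected_length) && nchar(ss) != expected_length) {
    stop("SS profile length ", nchar(ss), " does not match sequence (",
         expected_length, ")")
  }
  ss
}

#' Write a secondary-structure profile as a single-line string
#' @param ss String over `{H, E, C}`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ss_profile <- function(ss, path) {
  writeLines(ss, path)
  invisible(path)
}
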