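# The F-score discrimination statistic: a univariate ratio of between-class
# squared deviations from the grand mean to the sum of the within-class
# sample variances.  (Distinct from the F1 classification metric.)

#' F-score of one feature
#'
#' \deqn{F = \frac{(\bar x^{+}-\bar x)^2 + (\bar x^{-}-\bar x)^2}
#'                {\frac{1}{n^{+}-1}\sum_k (x^{+}_k-\bar x^{+})^2 +
#'                 \frac{1}{n^{-}-1}\sum_k (x^{-}_k-\bar x^{-})^2}}
#'
#' where \eqn{\bar x} is the grand mean over both classes.  A high score
#' marks a feature whose class-conditional means are well separated
#' relative to the within-class spread.  When the numerator is zero the
#' score is 0; when the numerator is positive and the denominator zero
#' (perfect zero-variance separation) the score is `Inf`.
#'
#' @param pos_values,neg_values Numeric vectors of the feature in the
#'   positive and negative class; each needs at least 2 values (sample
#'   variances use `n - 1`).
#' @return A non-negative number, possibly `Inf`.
#' @export
f_score <- function(pos_values, neg_values) {
  if (length(pos_values) < 2L || length(neg_values) < 2L) {
    stop("need at least 2 instances per class")
  }
  mp <- mean(pos_values)
  mn <- mean(neg_values)
  m <- mean(c(pos_values, neg_values))
  num <- (mp - m)^2 + (mn - m)^2
  if (num == 0) return(0)
  den <- stats::var(pos_values) + stats::var(neg_values)
  if (den == 0) return(Inf)
  num / den
}

#' Rank matrix columns by F-score
#'
#' @param x Numeric matrix with named columns (instances in rows).
#' @param labels Binary class labels (`positive`/`negative` or any
#'   two-level vector; the lexicographically later level is taken as
#'   positive unless labels are the canonical strings).
#' @return A data frame with columns `feature`, `score`, `rank`, sorted by
#'   decreasing score (ties broken by column order), with attributes
#'   `n_pos` and `n_neg`.
#' @export
rank_features <- function(x, labels) {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("labels must have exactly two classes")
  pos_lab <- if ("positive" %in% lv) "positive" else sort(lv)[2]
  is_pos <- labels == pos_lab
  scores <- vapply(seq_len(ncol(x)), function(j) {
    f_score(x[is_pos, j], x[!is_pos, j])
  }, numeric(1))
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(x)))
  ord <- order(-scores, seq_along(scores))
  out <- data.frame(feature = nm[ord], score = scores[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "n_pos") <- sum(is_pos)
  attr(out, "n_neg") <- sum(!is_pos)
  out
}

#' Per-offset discrimination scan across the window
#'
#' For every window offset, computes 20 per-channel F-scores and aggregates
#' them into one score per position, flagging positions — possibly distant
#' from the central lysine — that discriminate the classes.  The
#' `composition` channel uses 20 residue-identity indicators per offset
#' (offset 0 is excluded: it is always K); the `pssm` channel uses the 20
#' PSSM scores of the residue at that offset.
#'
#' @param fragments Fragment data frame with a `label` column.
#' @param channel `"composition"` or `"pssm"`.
#' @param prot,profiles Needed for the `pssm` channel: protein table and
#'   per-protein profile list.
#' @param aggregate `"sum"` (default) or `"max"` over the 20 channels.
#' @return A data frame with columns `offset` and `score`.
#' @export
positional_scan <- function(fragments, channel = c("composition", "pssm"),
                            prot = NULL, profiles = NULL,
                            aggregate = c("sum", "max")) {
  channel <- match.arg(channel)
  aggregate <- match.arg(aggregate)
  if (nrow(fragments) == 0L) stop("empty fragment set")
  n <- fragments$n[1]
  offsets <- -n:n
  if (channel == "composition") offsets <- offsets[offsets != 0L]
  labels <- fragments$label
  is_pos <- labels == "positive"
  chars <- do.call(rbind, strsplit(fragments$residues, ""))
  agg_fun <- if (aggregate == "sum") sum else max
  score <- vapply(offsets, function(off) {
    p <- off + n + 1L
    feats <- if (channel == "composition") {
      vapply(AA_ORDER, function(a) as.numeric(chars[, p] == a),
             numeric(nrow(fragments)))
    } else {
      .pssm_at_offset(fragments, off, prot, profiles)
    }
    agg_fun(vapply(seq_len(20L), function(j) {
      f_score(feats[is_pos, j], feats[!is_pos, j])
    }, numeric(1)))
  }, numeric(1))
  data.frame(offset = offsets, score = score)
}

# the 20 PSSM scores at a fixed offset from each fragment center
# (out-of-range rows contribute zeros)
.pssm_at_offset <- function(fragments, off, prot, profiles) {
  if (is.null(prot) || is.null(profiles)) {
    stop("pssm channel needs 'prot' and 'profiles'")
  }
  t(vapply(seq_len(nrow(fragments)), function(i) {
    id <- fragments$protein_id[i]
    pos <- fragments$center[i] + off
    pssm <- profiles[[id]]$pssm
    if (is.null(pssm)) stop("missing PSSM profile for '", id, "'")
    if (pos >= 1L && pos <= nrow(pssm)) pssm[pos, ] else numeric(20)
  }, numeric(20)))
}
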