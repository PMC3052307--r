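# Confusion-count metrics and cross-validation harnesses: stratified
# k-fold CV over the RBFN, the window-length sweep, the named
# feature-combination comparison, and independent-set testing.

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth Character vectors of `positive`/`negative`.
#' @return A named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  c(TP = sum(predicted == "positive" & truth == "positive"),
    FP = sum(predicted == "positive" & truth == "negative"),
    TN = sum(predicted == "negative" & truth == "negative"),
    FN = sum(predicted == "negative" & truth == "positive"))
}

#' Precision, sensitivity, specificity and accuracy
#'
#' `Pr = TP/(TP+FP)`, `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `Acc = (TP+TN)/(TP+FP+TN+FN)`.  A ratio with zero denominator is
#' reported as `NA` (undefined), never as 0.
#'
#' @param counts Named vector with elements `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector `c(Pr, Sn, Sp, Acc)`.
#' @export
metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  c(Pr = ratio(tp, tp + fp),
    Sn = ratio(tp, tp + fn),
    Sp = ratio(tn, tn + fp),
    Acc = (tp + tn) / total)
}

# run body with a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, body) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  body
}

# fold assignment: stratified by class (fold sizes differ by <= 1 per
# stratum) or grouped so that all sites of one group share a fold
.make_folds <- function(labels, k, seed, stratified = TRUE, groups = NULL) {
  n <- length(labels)
  fold <- integer(n)
  with_seed(seed, {
    if (!is.null(groups)) {
      gids <- unique(groups)
      gfold <- rep_len(seq_len(k), length(gids))[sample.int(length(gids))]
      fold <- gfold[match(groups, gids)]
    } else if (stratified) {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < k) {
          stop("class '", cl, "' has fewer than k = ", k, " members")
        }
        fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k),
                                                      length(idx))
      }
    } else {
      fold <- rep_len(seq_len(k), n)[sample.int(n)]
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the RBFN
#'
#' The data are split into k approximately equal subgroups (stratified by
#' class by default; optionally grouped by protein so homologous sites
#' never straddle the train/test boundary).  Each subgroup is used as the
#' test set exactly once; per-fold confusion counts are summed into pooled
#' (micro-averaged) Pr/Sn/Sp/Acc.
#'
#' @param x Feature matrix.
#' @param labels `positive`/`negative` labels, one per row.
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling the partition (and nothing else;
#'   training itself is deterministic).
#' @param stratified Stratify folds by class (default `TRUE`).
#' @param groups Optional grouping vector (e.g. protein ids); when given,
#'   folds are formed over groups and stratification is by group.
#' @param sigma,ridge,threshold Passed to [rbfn()] / [predict.rbfn()].
#' @return An object of class `"ub_cv"`: list with `fold_counts` (k x 4),
#'   `pooled_counts`, `metrics`, `k`, `seed`, `assignment`.
#' @export
kfold_cv <- function(x, labels, k = 5L, seed = 1L, stratified = TRUE,
                     groups = NULL, sigma = 5, ridge = 1e-8,
                     threshold = NULL) {
  stopifnot(k >= 2L, nrow(x) == length(labels))
  fold <- .make_folds(labels, k, seed, stratified, groups)
  fold_counts <- matrix(0L, k, 4,
                        dimnames = list(paste0("fold", seq_len(k)),
                                        c("TP", "FP", "TN", "FN")))
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- rbfn(x[!test, , drop = FALSE], labels[!test],
                sigma = sigma, ridge = ridge)
    pred <- predict(fit, x[test, , drop = FALSE], threshold = threshold)
    fold_counts[f, ] <- confusion_counts(pred, labels[test])
  }
  pooled <- colSums(fold_counts)
  structure(list(fold_counts = fold_counts, pooled_counts = pooled,
                 metrics = metrics(pooled), k = k, seed = seed,
                 assignment = fold),
            class = "ub_cv")
}

#' @export
print.ub_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation (seed ", x$seed, ")\n", sep = "")
  cat("  pooled counts: ",
      paste(names(x$pooled_counts), x$pooled_counts, sep = "=",
            collapse = " "), "\n", sep = "")
  m <- x$metrics
  cat(sprintf("  Pr %.3f  Sn %.3f  Sp %.3f  Acc %.3f\n",
              m["Pr"], m["Sn"], m["Sp"], m["Acc"]))
  invisible(x)
}

#' Cross-validated performance across window lengths
#'
#' Re-extracts fragments and re-encodes features for each half-window in
#' `n_values`, running one cross-validation per window length with the same
#' partition seed so rows are comparable.
#'
#' @param prot Protein table.
#' @param sites Site annotations.
#' @param profiles Per-protein profile list (or `NULL` for sequence-only
#'   blocks).
#' @param n_values Integer vector of half-windows (default `5:20`,
#'   i.e. 11-mer to 41-mer).
#' @param blocks Feature blocks to encode (default `"AAC"`).
#' @param k,seed,sigma,ridge Passed to [kfold_cv()].
#' @return A data frame with one row per window length: `n`, `window`,
#'   `Sn`, `Sp`, `Acc`, `Pr`.
#' @export
window_sweep <- function(prot, sites, profiles = NULL, n_values = 5:20,
                         blocks = "AAC", k = 5L, seed = 1L,
                         sigma = 5, ridge = 1e-8) {
  rows <- lapply(n_values, function(n) {
    frags <- extract_fragments(prot, sites, n = n)
    ds <- encode_dataset(frags, prot, profiles, blocks = blocks)
    cv <- kfold_cv(ds$x, ds$labels, k = k, seed = seed,
                   sigma = sigma, ridge = ridge)
    m <- cv$metrics
    data.frame(n = n, window = 2L * n + 1L, Sn = m[["Sn"]], Sp = m[["Sp"]],
               Acc = m[["Acc"]], Pr = m[["Pr"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-validated comparison of feature combinations
#'
#' Runs one cross-validation per named block combination over a shared
#' fold partition, mirroring the classic comparison of composition,
#' BLOSUM, ASA, SS and PSSM encodings and their combinations.
#'
#' @param prot,sites,profiles Data as in [window_sweep()].
#' @param configs Named list; each element is a character vector of block
#'   names (e.g. `list("AAC" = "AAC", "AAC+PSSM" = c("AAC", "PSSM400"))`).
#'   Names must be unique.
#' @param n Half-window used for all configurations (default 20).
#' @param k,seed,sigma,ridge Passed to [kfold_cv()].
#' @return A data frame with one row per configuration: `config`, `Sn`,
#'   `Sp`, `Acc`, `Pr`.
#' @export
feature_comparison <- function(prot, sites, profiles = NULL, configs,
                               n = 20L, k = 5L, seed = 1L,
                               sigma = 5, ridge = 1e-8) {
  if (is.null(names(configs)) || anyDuplicated(names(configs))) {
    stop("configs must be uniquely named")
  }
  frags <- extract_fragments(prot, sites, n = n)
  rows <- lapply(names(configs), function(nm) {
    ds <- encode_dataset(frags, prot, profiles, blocks = configs[[nm]])
    cv <- kfold_cv(ds$x, ds$labels, k = k, seed = seed,
                   sigma = sigma, ridge = ridge)
    m <- cv$metrics
    data.frame(config = nm, Sn = m[["Sn"]], Sp = m[["Sp"]],
               Acc = m[["Acc"]], Pr = m[["Pr"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply a trained model to an independent test set
#'
#' Pure apply-and-count: no training data are touched.
#'
#' @param model A fitted [rbfn()] model.
#' @param x Test feature matrix (non-empty).
#' @param labels True labels.
#' @param threshold Optional decision threshold (see [predict.rbfn()]).
#' @return A list with `counts` and `metrics`.
#' @export
independent_test <- function(model, x, labels, threshold = NULL) {
  if (NROW(x) == 0L) stop("empty test set")
  stopifnot(NROW(x) == length(labels))
  pred <- predict(model, x, threshold = threshold)
  counts <- confusion_counts(pred, labels)
  list(counts = counts, metrics = metrics(counts))
}
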