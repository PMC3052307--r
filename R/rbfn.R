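# Radial basis function network with a Gaussian hidden layer and a linear
# output layer.  Every training instance is a center (k = n), the
# bandwidth is shared (default sigma = 5), and the output weights are the
# exact solution of the regularized linear system
#   (Phi + ridge * I) W = Y,
# where Phi[a, b] = exp(-||x_a - x_b||^2 / (2 sigma^2)) and Y holds one-hot
# class indicators.  On distinct points Phi is symmetric positive
# definite, so at ridge = 0 the network interpolates its training targets.

#' Fit a radial basis function network classifier
#'
#' @param x Numeric matrix of training instances (rows) by features
#'   (columns).
#' @param labels Class labels, one per row; at least two classes with at
#'   least one instance each.  The class order of the output nodes is
#'   `sort(unique(labels))` (so with `negative`/`positive` labels the
#'   negative node comes first).
#' @param sigma Shared Gaussian bandwidth (default 5).
#' @param ridge Regularization added to the kernel matrix diagonal
#'   (default `1e-8`).  `ridge = 0` requests the exact interpolating
#'   solve, which requires pairwise-distinct rows.
#' @param bandwidth_convention `"2sigma2"` (default) uses
#'   `exp(-d^2/(2 sigma^2))`; `"sigma2"` uses `exp(-d^2/sigma^2)`.
#' @param scale If `TRUE`, features are z-scaled before training and the
#'   centering/scaling is stored in the model and applied at prediction.
#' @param n_centers Optional number of hidden units: when smaller than the
#'   training size, that many instances are drawn uniformly (seeded by
#'   `center_seed`) as centers and the output weights solve the
#'   regularized least-squares system instead of the square interpolation
#'   system.  Default `NULL` keeps every instance as a center (k = n).
#' @param center_seed Seed for the center subsample (default 1).
#' @return An object of class `"rbfn"` with components `centers`, `sigma`,
#'   `ridge`, `weights` (k x c), `class_order`, `bandwidth_convention`,
#'   `center_means`/`center_sds` when scaled, and `feature_names`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
#' fit <- rbfn(x, rep(c("negative", "positive"), each = 20))
#' table(predict(fit, x), rep(c("negative", "positive"), each = 20))
#' @export
rbfn <- function(x, labels, sigma = 5, ridge = 1e-8,
                 bandwidth_convention = c("2sigma2", "sigma2"),
                 scale = FALSE, n_centers = NULL, center_seed = 1L) {
  bandwidth_convention <- match.arg(bandwidth_convention)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels), sigma > 0, ridge >= 0)
  class_order <- sort(unique(labels))
  if (length(class_order) < 2L) {
    stop("need at least two classes to train")
  }
  scaling <- NULL
  if (scale) {
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    sd[sd == 0] <- 1
    x <- sweep(sweep(x, 2, mu), 2, sd, "/")
    scaling <- list(means = mu, sds = sd)
  }
  centers <- x
  if (!is.null(n_centers) && n_centers < nrow(x)) {
    idx <- with_seed(center_seed, sort(sample.int(nrow(x), n_centers)))
    centers <- x[idx, , drop = FALSE]
  }
  if (ridge == 0 && anyDuplicated(centers)) {
    stop("duplicate feature rows make the exact solve singular; ",
         "use ridge > 0")
  }
  Phi <- .gauss_kernel(x, centers, sigma, bandwidth_convention)
  Y <- vapply(class_order, function(cl) as.numeric(labels == cl),
              numeric(length(labels)))
  W <- tryCatch(
    if (nrow(centers) == nrow(x)) {
      solve(Phi + diag(ridge, nrow(Phi)), Y)
    } else {
      # fewer centers than instances: regularized least squares
      solve(crossprod(Phi) + diag(ridge, ncol(Phi)), crossprod(Phi, Y))
    },
    error = function(e) {
      stop("kernel system is singular (", conditionMessage(e),
           "); increase ridge", call. = FALSE)
    })
  structure(list(centers = centers, sigma = sigma, ridge = ridge,
                 weights = W, class_order = class_order,
                 bandwidth_convention = bandwidth_convention,
                 scaling = scaling,
                 feature_names = colnames(x),
                 train_labels = labels),
            class = "rbfn")
}

# Gaussian kernel matrix between row sets a (m x d) and b (k x d)
.gauss_kernel <- function(a, b, sigma, convention = "2sigma2") {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0  # guard tiny negatives from cancellation
  denom <- if (convention == "2sigma2") 2 * sigma^2 else sigma^2
  exp(-d2 / denom)
}

.rbfn_prepare <- function(object, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != ncol(object$centers)) {
    stop("feature dimension mismatch: model has ", ncol(object$centers),
         ", input has ", ncol(x))
  }
  if (!is.null(object$scaling)) {
    x <- sweep(sweep(x, 2, object$scaling$means), 2, object$scaling$sds, "/")
  }
  x
}

#' Output-node activations of a fitted network
#'
#' Computes `y_j(x) = sum_i w_ji * exp(-||x - m_i||^2 / (2 sigma^2))` for
#' each output node `j`.
#'
#' @param object A fitted [rbfn()] model.
#' @param x Numeric matrix (or single vector) of instances.
#' @return Numeric matrix, one row per instance, columns named by
#'   `class_order`.
#' @export
rbfn_output <- function(object, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- .rbfn_prepare(object, x)
  act <- .gauss_kernel(x, object$centers, object$sigma,
                       object$bandwidth_convention) %*% object$weights
  colnames(act) <- object$class_order
  act
}

#' Predict classes or activations from a fitted network
#'
#' @param object A fitted [rbfn()] model.
#' @param newdata Instance matrix.
#' @param type `"class"` for labels, `"response"` for raw output-node
#'   activations.
#' @param threshold Optional decision threshold for two-class models:
#'   predict the positive class iff `y_pos - y_neg >= threshold`.
#'   `threshold = NULL` (default) uses the arg-max rule; exact ties go to
#'   the earlier class in `class_order` (the negative class under
#'   canonical labels).
#' @param positive For threshold mode, the label of the positive class
#'   (default the last element of `class_order`).
#' @param ... Unused.
#' @return Character vector of labels, or the activation matrix.
#' @export
predict.rbfn <- function(object, newdata, type = c("class", "response"),
                         threshold = NULL, positive = NULL, ...) {
  type <- match.arg(type)
  act <- rbfn_output(object, newdata)
  if (type == "response") return(act)
  if (is.null(threshold)) {
    # which.max alone would break ties towards the first column; make the
    # tie-break explicit and independent of column order
    idx <- apply(act, 1, function(r) which(r == max(r))[1])
    return(object$class_order[idx])
  }
  if (length(object$class_order) != 2L) {
    stop("threshold decisions require a two-class model")
  }
  if (is.null(positive)) positive <- object$class_order[2]
  negative <- setdiff(object$class_order, positive)
  ifelse(act[, positive] - act[, negative] >= threshold, positive, negative)
}

#' @export
print.rbfn <- function(x, ...) {
  cat("Radial basis function network classifier\n")
  k <- nrow(x$centers)
  n <- length(x$train_labels)
  cat("  centers: ", k,
      if (k == n) " (k = n)" else paste0(" (subsampled from ", n, ")"),
      ", features: ", ncol(x$centers), "\n", sep = "")
  cat("  sigma: ", x$sigma, " (", x$bandwidth_convention,
      "), ridge: ", format(x$ridge), "\n", sep = "")
  cat("  classes:", paste(x$class_order, collapse = ", "), "\n")
  invisible(x)
}

.check_all_centers <- function(object) {
  if (length(object$train_labels) != nrow(object$centers)) {
    stop("training-point diagnostics need the all-centers model ",
         "(n_centers = NULL)")
  }
}

# training points on the original feature scale (centers are stored
# post-scaling, but the predict path re-applies the stored scaling)
.centers_raw <- function(object) {
  x <- object$centers
  if (!is.null(object$scaling)) {
    x <- sweep(sweep(x, 2, object$scaling$sds, "*"), 2,
               object$scaling$means, "+")
  }
  x
}

#' @export
summary.rbfn <- function(object, ...) {
  .check_all_centers(object)
  fit <- predict(object, .centers_raw(object))
  acc <- mean(fit == object$train_labels)
  out <- list(model = object, training_accuracy = acc,
              weight_norm = sqrt(sum(object$weights^2)))
  class(out) <- "summary.rbfn"
  out
}

#' @export
print.summary.rbfn <- function(x, ...) {
  print(x$model)
  cat("  training accuracy: ", format(x$training_accuracy), "\n", sep = "")
  cat("  weight Frobenius norm: ", format(x$weight_norm), "\n", sep = "")
  invisible(x)
}

#' @export
coef.rbfn <- function(object, ...) object$weights

#' @export
fitted.rbfn <- function(object, ...) {
  .check_all_centers(object)
  rbfn_output(object, .centers_raw(object))
}

#' Residuals of a fitted network
#'
#' One-hot training targets minus the network activations at the training
#' points; at `ridge = 0` on distinct points these are numerically zero
#' (exact interpolation).
#' @param object A fitted [rbfn()] model.
#' @param ... Unused.
#' @export
residuals.rbfn <- function(object, ...) {
  Y <- vapply(object$class_order,
              function(cl) as.numeric(object$train_labels == cl),
              numeric(length(object$train_labels)))
  Y - fitted(object)
}

#' Save a fitted network to a portable JSON file
#'
#' All doubles are written at full precision, so `write_rbfn()` followed by
#' [read_rbfn()] reproduces the model (and hence its outputs) exactly.
#'
#' @param object A fitted [rbfn()] model.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rbfn <- function(object, path) {
  # doubles go through %.17g strings: 17 significant digits reproduce an
  # IEEE double exactly, unlike default JSON number formatting
  g17 <- function(x) {
    y <- sprintf("%.17g", x)
    if (!is.null(dim(x))) dim(y) <- dim(x)
    y
  }
  scaling <- object$scaling
  if (!is.null(scaling)) {
    scaling <- list(means = g17(scaling$means), sds = g17(scaling$sds))
  }
  payload <- list(
    format = "ubilys-rbfn", version = 1L,
    sigma = g17(object$sigma), ridge = g17(object$ridge),
    bandwidth_convention = object$bandwidth_convention,
    class_order = object$class_order,
    feature_names = object$feature_names,
    train_labels = object$train_labels,
    scaling = scaling,
    centers = g17(object$centers), weights = g17(object$weights))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a network saved by [write_rbfn()]
#'
#' @param path File written by [write_rbfn()].
#' @return An object of class `"rbfn"`.
#' @export
read_rbfn <- function(path) {
  p <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) {
                  stop("corrupt model file '", path, "': ",
                       conditionMessage(e), call. = FALSE)
                })
  if (!identical(p$format, "ubilys-rbfn")) {
    stop("'", path, "' is not a network model file")
  }
  if (!identical(as.integer(p$version), 1L)) {
    stop("unsupported model file version ", p$version)
  }
  num <- function(x) {
    y <- as.matrix(x)
    storage.mode(y) <- "double"
    y
  }
  centers <- num(p$centers)
  weights <- num(p$weights)
  if (is.null(p$sigma) || is.null(p$class_order) ||
      nrow(weights) != nrow(centers)) {
    stop("corrupt model file '", path, "': missing or inconsistent fields")
  }
  colnames(centers) <- p$feature_names
  colnames(weights) <- p$class_order
  scaling <- p$scaling
  if (!is.null(scaling) && length(scaling) > 0L) {
    scaling <- list(means = as.numeric(scaling$means),
                    sds = as.numeric(scaling$sds))
  } else {
    scaling <- NULL
  }
  structure(list(centers = centers, sigma = as.numeric(p$sigma),
                 ridge = as.numeric(p$ridge),
                 weights = weights, class_order = p$class_order,
                 bandwidth_convention = p$bandwidth_convention,
                 scaling = scaling, feature_names = p$feature_names,
                 train_labels = p$train_labels),
            class = "rbfn")
}
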