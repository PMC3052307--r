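# The exact-solve Gaussian RBF network.

test_that("a 2-point network interpolates its one-hot targets exactly", {
  x <- matrix(c(0, 1), 2, 1)
  fit <- rbfn(x, c("A", "B"), sigma = 5, ridge = 0)
  out <- rbfn_output(fit, x)
  # verify against the hand 2x2 solve: Phi = [[1, q], [q, 1]],
  # W = Phi^-1 Y with q = exp(-1/50)
  q <- exp(-1 / (2 * 25))
  W <- solve(matrix(c(1, q, q, 1), 2, 2), diag(2))
  expect_equal(unname(out), diag(2), tolerance = 1e-12)
  expect_equal(unname(fit$weights), W, tolerance = 1e-12)
})

test_that("training requires two classes and distinct rows at ridge zero", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(rbfn(x, rep("A", 5)), "two classes")
  xd <- rbind(x, x[1, ])
  expect_error(rbfn(xd, rep(c("A", "B"), 3), ridge = 0), "ridge")
  # same data trains fine with the default ridge
  fit <- rbfn(xd, rep(c("A", "B"), 3))
  expect_s3_class(fit, "rbfn")
})

test_that("separable training data are fit perfectly at tiny ridge", {
  s <- make_separable_set(50, 10, 2, seed = 42)
  fit <- rbfn(s$x, s$labels, sigma = 5, ridge = 1e-8)
  expect_equal(mean(predict(fit, s$x) == s$labels), 1)
})

test_that("activations match the double-loop oracle", {
  set.seed(43)
  s <- make_separable_set(30, 8, 1, seed = 43)
  for (conv in c("2sigma2", "sigma2")) {
    fit <- rbfn(s$x, s$labels, sigma = 3, bandwidth_convention = conv)
    xq <- matrix(rnorm(10 * 8), 10, 8)
    expect_equal(unname(rbfn_output(fit, xq)),
                 oracle_rbfn_output(fit, xq), tolerance = 1e-10)
  }
})

test_that("kernel decay and single-center sanity", {
  fit <- list(centers = matrix(0, 1, 2), sigma = 5, ridge = 0,
              weights = matrix(c(1, 0), 1, 2), class_order = c("A", "B"),
              bandwidth_convention = "2sigma2", scaling = NULL,
              feature_names = NULL, train_labels = "A")
  class(fit) <- "rbfn"
  expect_equal(unname(rbfn_output(fit, c(0, 0))[1, ]), c(1, 0))
  far <- rbfn_output(fit, c(1e4, 1e4))
  expect_equal(unname(far[1, ]), c(0, 0))
})

test_that("prediction ties break to the negative class and thresholds sweep Sn monotonically", {
  s <- make_separable_set(25, 5, 1, seed = 44)
  fit <- rbfn(s$x, s$labels)
  # degenerate all-zero weights force exact ties everywhere
  tie <- fit
  tie$weights[] <- 0
  expect_true(all(predict(tie, s$x) == "negative"))

  act <- predict(fit, s$x, type = "response")
  margins <- act[, "positive"] - act[, "negative"]
  thresholds <- c(-Inf, sort(margins), Inf)
  sn <- vapply(thresholds, function(th) {
    pred <- predict(fit, s$x, threshold = th)
    cc <- confusion_counts(pred, s$labels)
    metrics(cc)[["Sn"]]
  }, numeric(1))
  expect_equal(sn[1], 1)
  expect_equal(sn[length(sn)], 0)
  expect_true(all(diff(sn) <= 0))
})

test_that("predictions are translation-invariant", {
  s <- make_separable_set(20, 6, 1.5, seed = 45)
  fit <- rbfn(s$x, s$labels)
  shift <- matrix(rep(rnorm(6), each = nrow(s$x)), nrow(s$x))
  fit2 <- rbfn(s$x + shift, s$labels)
  xq <- matrix(rnorm(15 * 6), 15, 6)
  expect_equal(predict(fit, xq), predict(fit2, xq + shift[1:15, ]))
})

test_that("one-hot outputs sum to one at training points at ridge zero", {
  s <- make_separable_set(20, 5, 1, seed = 46)
  fit <- rbfn(s$x, s$labels, ridge = 0)
  sums <- rowSums(rbfn_output(fit, s$x))
  expect_equal(sums, rep(1, nrow(s$x)), tolerance = 1e-8)
  # residuals at training points are numerically zero
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("increasing ridge never increases the weight Frobenius norm", {
  s <- make_separable_set(30, 5, 0.5, seed = 47)
  norms <- vapply(c(0, 1e-8, 1e-4, 1e-2, 1), function(r) {
    sqrt(sum(coef(rbfn(s$x, s$labels, ridge = r))^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("center subsampling is seeded, smaller, and still predictive", {
  s <- make_separable_set(100, 8, 2, seed = 52)
  fit <- rbfn(s$x, s$labels, n_centers = 40, center_seed = 3)
  expect_equal(nrow(fit$centers), 40L)
  expect_equal(nrow(fit$weights), 40L)
  fit2 <- rbfn(s$x, s$labels, n_centers = 40, center_seed = 3)
  expect_identical(fit$centers, fit2$centers)
  fit3 <- rbfn(s$x, s$labels, n_centers = 40, center_seed = 4)
  expect_false(identical(fit$centers, fit3$centers))
  # well-separated clouds stay almost perfectly classified
  expect_gte(mean(predict(fit, s$x) == s$labels), 0.95)
  # training-point diagnostics are reserved for the all-centers model
  expect_error(fitted(fit), "all-centers")
})

test_that("dimension mismatches are rejected", {
  s <- make_separable_set(10, 4, 1, seed = 48)
  fit <- rbfn(s$x, s$labels)
  expect_error(predict(fit, matrix(0, 2, 3)), "dimension mismatch")
})

test_that("models round-trip through JSON files exactly", {
  set.seed(49)
  for (i in 1:10) {
    s <- make_separable_set(sample(5:20, 1), sample(2:8, 1),
                            runif(1, 0.5, 3), seed = 100 + i)
    fit <- rbfn(s$x, s$labels, sigma = runif(1, 1, 8),
                ridge = 10^runif(1, -10, -4),
                scale = sample(c(TRUE, FALSE), 1))
    f <- withr::local_tempfile(fileext = ".json")
    write_rbfn(fit, f)
    fit2 <- read_rbfn(f)
    expect_identical(rbfn_output(fit2, s$x), rbfn_output(fit, s$x))
    expect_identical(fit2$sigma, fit$sigma)
    expect_identical(fit2$class_order, fit$class_order)
  }
})

test_that("corrupt and truncated model files are rejected", {
  s <- make_separable_set(5, 2, 1, seed = 50)
  fit <- rbfn(s$x, s$labels)
  f <- withr::local_tempfile(fileext = ".json")
  write_rbfn(fit, f)
  full <- readLines(f, warn = FALSE)
  truncated <- substr(paste(full, collapse = ""), 1, 100)
  writeLines(truncated, f)
  expect_error(read_rbfn(f), "corrupt")
  writeLines('{"format": "something-else"}', f)
  expect_error(read_rbfn(f), "not a network model")
})

test_that("print, summary and fitted methods report the fit", {
  s <- make_separable_set(10, 3, 3, seed = 51)
  fit <- rbfn(s$x, s$labels)
  expect_output(print(fit), "Radial basis function")
  sm <- summary(fit)
  expect_equal(sm$training_accuracy, 1)
  expect_output(print(sm), "training accuracy")
  expect_equal(dim(fitted(fit)), c(20L, 2L))
})
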