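# Independent oracles, coded from first principles (explicit sums and
# loops), against which the vectorized package implementations are tested.

# F-score: explicit-sum transcription of the textbook formula
oracle_f_score <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  xbar <- sum(c(pos, neg)) / (np + nn)
  xp <- sum(pos) / np
  xn <- sum(neg) / nn
  num <- (xp - xbar)^2 + (xn - xbar)^2
  if (num == 0) return(0)
  den <- sum((pos - xp)^2) / (np - 1) + sum((neg - xn)^2) / (nn - 1)
  if (den == 0) return(Inf)
  num / den
}

# 400-D PSSM transform: two-loop accumulation + logistic, no vectorization
oracle_pssm400 <- function(pssm, sequence, center, m) {
  aa <- ubilys::AA_ORDER
  half <- (m - 1) %/% 2
  acc <- matrix(0, 20, 20)
  for (p in (center - half):(center + half)) {
    if (p < 1 || p > nrow(pssm)) next
    t_idx <- match(substr(sequence, p, p), aa)
    if (is.na(t_idx)) next
    for (j in 1:20) acc[t_idx, j] <- acc[t_idx, j] + pssm[p, j]
  }
  out <- numeric(400)
  for (t in 1:20) for (j in 1:20) {
    out[(t - 1) * 20 + j] <- 1 / (1 + exp(-acc[t, j] / m))
  }
  out
}

# RBFN output: double loop over instances and centers
oracle_rbfn_output <- function(model, x) {
  stopifnot(is.null(model$scaling))
  denom <- if (model$bandwidth_convention == "2sigma2") {
    2 * model$sigma^2
  } else {
    model$sigma^2
  }
  out <- matrix(0, nrow(x), length(model$class_order))
  for (i in seq_len(nrow(x))) {
    for (c_idx in seq_len(nrow(model$centers))) {
      phi <- exp(-sum((x[i, ] - model$centers[c_idx, ])^2) / denom)
      out[i, ] <- out[i, ] + phi * model$weights[c_idx, ]
    }
  }
  out
}

# random protein helpers
random_sequence <- function(L, force_k = TRUE) {
  ch <- sample(ubilys::AA_ORDER, L, replace = TRUE)
  if (force_k && !any(ch == "K")) ch[sample(L, 1)] <- "K"
  paste(ch, collapse = "")
}

toy_proteins <- function() {
  proteins(c("p1", "p2"), c("MKKA", "ARNDKCEQGHK"))
}
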