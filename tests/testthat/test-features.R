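# Feature encoders: compositions, BLOSUM62 windows, the 400-D PSSM
# transform, ASA and SS windows, and block assembly.

test_that("amino-acid composition counts, normalizes and excludes markers", {
  expect_equal(unname(encode_aac("AAAA")[1]), 1)
  expect_equal(sum(encode_aac("AAAA")), 1)
  v <- encode_aac("ARND")
  expect_equal(unname(v[c("AAC.A", "AAC.R", "AAC.N", "AAC.D")]),
               rep(0.25, 4))
  # markers and X drop out of counts and denominator alike
  expect_equal(encode_aac("--AXA-"), encode_aac("AA"))
  expect_error(encode_aac("---"), "no effective residues")

  # count oracle on a random 500-mer
  set.seed(2)
  s <- random_sequence(500)
  v <- encode_aac(s)
  expect_equal(sum(v), 1)
  counts <- table(factor(strsplit(s, "")[[1]], levels = AA_ORDER))
  expect_equal(unname(v), as.numeric(counts) / 500, tolerance = 1e-12)
})

test_that("AAC is compositional: concatenation = length-weighted mean", {
  set.seed(8)
  a <- random_sequence(120)
  b <- random_sequence(80)
  expect_equal(encode_aac(paste0(a, b)),
               (120 * encode_aac(a) + 80 * encode_aac(b)) / 200,
               tolerance = 1e-12)
})

test_that("pair composition uses the residue-count denominator", {
  v <- encode_aapc("AAA")
  expect_equal(unname(v["AAPC.AA"]), 2 / 3)
  expect_equal(sum(v), 2 / 3)
  expect_equal(unname(encode_aapc("AR")["AAPC.AR"]), 1 / 2)
  expect_error(encode_aapc("A-"), "at least 2")
  # pairs spanning a marker are skipped but the denominator keeps all
  # effective residues
  v2 <- encode_aapc("AA-AA")
  expect_equal(unname(v2["AAPC.AA"]), 2 / 4)

  # analytic identity: sum equals (L-1)/L on a marker-free window
  set.seed(9)
  s <- random_sequence(500)
  expect_equal(sum(encode_aapc(s)), 499 / 500, tolerance = 1e-12)
})

test_that("BLOSUM62 window encoding matches the published integer matrix", {
  v <- encode_blosum("MKK")
  expect_length(v, 63)
  # terminal marker: 20 zeros plus flag 1
  vm <- encode_blosum("-K-")
  expect_equal(unname(vm[1:21]), c(rep(0, 20), 1))
  # residue rows: recompute the min-max map from the published matrix
  b62 <- get("get_blosum62", asNamespace("ubilys"))()[AA_ORDER, AA_ORDER]
  for (a in c("M", "K", "W")) {
    expected <- (b62[a, ] - min(b62)) / (max(b62) - min(b62))
    frag <- paste0("A", a, "A")
    got <- encode_blosum(frag)[22:41]
    expect_equal(unname(got), unname(expected), tolerance = 1e-12)
    expect_equal(unname(encode_blosum(frag)[42]), 0)  # flag of a residue
    # diagonal entry is the row max after a global order-preserving map
    expect_equal(unname(which.max(got)), match(a, AA_ORDER))
  }
  expect_true(all(v >= 0 & v <= 1))
})

test_that("PSSM400 equals the two-loop oracle and handles absent types", {
  # all-zero PSSM -> logistic(0) = 0.5 everywhere
  z <- encode_pssm400(matrix(0, 9, 20), paste(rep("A", 9), collapse = ""),
                      5, m = 9)
  expect_equal(unname(z), rep(0.5, 400))
  # absent residue type -> its whole row is 0.5
  seqq <- paste(rep("A", 9), collapse = "")
  p <- matrix(rnorm(9 * 20), 9, 20)
  v <- encode_pssm400(p, seqq, 5, m = 9)
  expect_equal(unname(v[21:40]), rep(0.5, 20))  # row R: no R in sequence

  set.seed(10)
  for (i in 1:25) {
    L <- 41
    s <- random_sequence(L)
    p <- matrix(sample(-12:12, L * 20, replace = TRUE), L, 20)
    center <- sample(L, 1)
    v <- encode_pssm400(p, s, center, m = 41)
    expect_equal(unname(v), oracle_pssm400(p, s, center, 41),
                 tolerance = 1e-12)
    expect_true(all(v > 0 & v < 1))
  }
})

test_that("PSSM400 is invariant to permuting same-residue rows in the window", {
  set.seed(12)
  s <- paste(rep(c("A", "D"), 10), collapse = "")  # many same-type rows
  p <- matrix(sample(-8:8, 20 * 20, replace = TRUE), 20, 20)
  v1 <- encode_pssm400(p, s, 10, m = 19)
  # swap two PSSM rows that share residue type A (positions 1 and 5,
  # both inside the window)
  p2 <- p
  p2[c(1, 5), ] <- p[c(5, 1), ]
  expect_equal(encode_pssm400(p2, s, 10, m = 19), v1, tolerance = 0)
})

test_that("truncated PSSM windows still divide by the full m", {
  s <- "AAAAA"
  p <- matrix(1, 5, 20)
  # center at residue 1 with m = 9: only rows 1..5 exist, sum = 5 per
  # column of row A, divided by m = 9
  v <- encode_pssm400(p, s, 1, m = 9)
  expect_equal(unname(v[1]), 1 / (1 + exp(-5 / 9)), tolerance = 1e-12)
})

test_that("ASA windows scale to [0,1] and pad out-of-range with 0", {
  expect_equal(unname(encode_asa(rep(50, 9), 5, 1)), rep(0.5, 3))
  v <- encode_asa(rep(50, 9), 1, 2)
  expect_equal(unname(v[1:2]), c(0, 0))
  set.seed(4)
  asa <- runif(60, 0, 100)
  v <- encode_asa(asa, 30, 5)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(unname(v), asa[25:35] / 100, tolerance = 1e-12)
})

test_that("SS one-hot coding follows the H=100, E=010, C=001 rule", {
  v <- encode_ss("HEC", 2, 1)
  expect_equal(unname(v), c(1, 0, 0, 0, 1, 0, 0, 0, 1))
  # out-of-range positions are all-zero
  v2 <- encode_ss("HEC", 1, 1)
  expect_equal(unname(v2[1:3]), c(0, 0, 0))
  # every in-range triple sums to 1
  set.seed(5)
  ss <- paste(sample(c("H", "E", "C"), 80, replace = TRUE), collapse = "")
  v3 <- encode_ss(ss, 40, 20)
  sums <- colSums(matrix(v3, nrow = 3))
  expect_equal(unname(sums), rep(1, 41))
})

test_that("assembly concatenates blocks in canonical order with a layout table", {
  prot <- proteins("p", random_sequence(80))
  kpos <- which(strsplit(prot$sequence, "")[[1]] == "K")[1]
  frag <- extract_fragment(prot, "p", kpos, n = 20, label = "positive")
  prof <- list(pssm = matrix(0, 80, 20), asa = rep(50, 80),
               ss = paste(rep("C", 80), collapse = ""))
  v <- assemble(frag, prof, prot$sequence, blocks = c("AAC", "PSSM400"))
  expect_length(v, 420)
  expect_equal(attr(v, "blocks")$block, c("AAC", "PSSM400"))
  expect_equal(attr(v, "blocks")$offset, c(0L, 20L))

  v2 <- assemble(frag, blocks = c("AAC", "AAPC"))
  expect_length(v2, 420)

  v3 <- assemble(frag, prof, prot$sequence,
                 blocks = c("AAC", "AAPC", "BLOSUM", "PSSM400",
                            "ASA", "SS"))
  expect_length(v3, 20 + 400 + 861 + 400 + 41 + 123)

  # enabled block without its profile errors by name
  expect_error(assemble(frag, list(asa = rep(1, 80)), prot$sequence,
                        blocks = "PSSM400"), "PSSM400")
  # block order in the output is canonical regardless of request order
  v4 <- assemble(frag, prof, prot$sequence, blocks = c("PSSM400", "AAC"))
  expect_equal(attr(v4, "blocks")$block, c("AAC", "PSSM400"))
})

test_that("encoders are pure: identical inputs give identical bits", {
  set.seed(21)
  s <- random_sequence(41)
  expect_identical(encode_aac(s), encode_aac(s))
  expect_identical(encode_blosum(s), encode_blosum(s))
  p <- matrix(rnorm(41 * 20), 41, 20)
  expect_identical(encode_pssm400(p, s, 21, 41),
                   encode_pssm400(p, s, 21, 41))
})
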