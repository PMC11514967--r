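test_that("JASPAR parsing normalises counts and validates", {
  f <- tmpfile_with(c(">M1 TEST",
                      "A [ 60 0 10 ]",
                      "C [ 20 100 10 ]",
                      "G [ 10 0 40 ]",
                      "T [ 10 0 40 ]"), ".pfm")
  m <- read_jaspar(f)
  expect_s3_class(m, "ppm")
  expect_equal(colSums(m$probs), rep(1, 3))
  expect_equal(unname(m$probs["A", 1]), 0.6)

  ## plain (unbracketed) dialect
  f2 <- tmpfile_with(c(">M2", "1 2", "1 2", "1 2", "1 2"), ".pfm")
  expect_equal(read_jaspar(f2)$probs[, 1], rep(0.25, 4),
               ignore_attr = TRUE)

  expect_error(read_jaspar(tmpfile_with(
    c(">Z", "A [ 0 ]", "C [ 0 ]", "G [ 0 ]", "T [ 0 ]"))), "zero-count")
  expect_error(read_jaspar(tmpfile_with(
    c(">Z", "A [ 1 2 ]", "C [ 1 ]", "G [ 1 2 ]", "T [ 1 2 ]"))),
    "unequal")
})

test_that("JASPAR round-trip preserves probabilities", {
  m <- test_ppm("ACGTTGCA", p = 0.8)
  f <- tempfile(fileext = ".pfm")
  write_jaspar(m, f)
  m2 <- read_jaspar(f)
  expect_equal(m2$probs, m$probs, tolerance = 1e-7)
})

test_that("a multi-motif library file reads into a named list", {
  lib <- synthetic_pfm_library()
  expect_length(lib, 10L)
  expect_true(all(vapply(lib, inherits, TRUE, "ppm")))
  expect_true(all(grepl("^SYN", names(lib))))
  ## varied motif widths
  expect_gt(length(unique(vapply(lib, function(m) ncol(m$probs), 1L))), 1L)
})

test_that("ppm_to_pwm implements the pseudocount log-odds formula", {
  uni <- ppm(matrix(0.25, 4, 5))
  expect_equal(pwm_weights(ppm_to_pwm(uni)), matrix(0, 4, 5),
               ignore_attr = TRUE, tolerance = 1e-12)
  m <- ppm(matrix(c(1, 0, 0, 0), 4, 1))
  w <- pwm_weights(ppm_to_pwm(m, pseudocount = 0.01))
  ## direct evaluation of the stated formula
  expect_equal(unname(w[1, 1]), log2((1 + 0.01 * 0.25) / (1.01 * 0.25)))
  expect_equal(unname(w[2, 1]), log2((0 + 0.01 * 0.25) / (1.01 * 0.25)))
  expect_error(ppm_to_pwm(m, pseudocount = 0), "zero")
})

test_that("scan_best_hit matches brute-force enumeration on random input", {
  set.seed(21)
  for (rep in 1:20) {
    K <- sample(4:9, 1)
    w <- matrix(rnorm(4 * K), 4, K)
    p <- pwm(w, "jaspar_logodds", "rand")
    sq <- random_dna(1, 200)
    ## sprinkle Ns into some sequences
    if (rep %% 3 == 0) substr(sq, 50, 60) <- "NNNNNNNNNNN"
    hit <- scan_best_hit(sq, p)
    expect_equal(hit$score, brute_best_hit(sq, w), tolerance = 1e-9)
  }
})

test_that("reverse complement flips strand but preserves the best score", {
  set.seed(8)
  w <- matrix(rnorm(4 * 6), 4, 6)
  p <- pwm(w, "jaspar_logodds")
  for (rep in 1:10) {
    sq <- random_dna(1, 120)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
    h1 <- scan_best_hit(sq, p)
    h2 <- scan_best_hit(rc, p)
    expect_equal(h1$score, h2$score, tolerance = 1e-9)
    expect_false(h1$strand == h2$strand &&
                 h1$offset != (120 - 6 - h2$offset)) # same window, mirrored
  }
  expect_null(scan_best_hit(strrep("N", 100), p))
})

test_that("consensus sequences hit at full score on either strand", {
  cons <- "TTGACCA"
  m <- test_ppm(cons, p = 0.97)
  p <- ppm_to_pwm(m)
  wmax <- sum(apply(pwm_weights(p), 2, max))
  sq <- paste0(strrep("A", 30), cons, strrep("C", 30))
  h <- scan_best_hit(sq, p)
  expect_equal(h$offset, 30L)
  expect_equal(h$strand, "+")
  expect_equal(h$score, wmax, tolerance = 1e-9)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
  h2 <- scan_best_hit(rc, p)
  expect_equal(h2$strand, "-")
  expect_equal(h2$score, wmax, tolerance = 1e-9)
})

test_that("the DP hit threshold matches an exhaustive score distribution", {
  set.seed(3)
  ## tiny PWM: enumerate all 4^K sites exactly
  K <- 5
  w <- matrix(round(rnorm(4 * K), 3), 4, K)
  thr <- motifcontrast:::pwm_score_threshold(w, pval = 1e-2,
                                             granularity = 1e-3)
  sites <- as.matrix(expand.grid(rep(list(1:4), K)))
  scores <- apply(sites, 1, function(s) sum(w[cbind(s, 1:K)]))
  ## exhaustive tail probability at the DP threshold
  expect_lte(mean(scores >= thr - 1e-9), 1e-2)
  ## one granularity step below the threshold the tail must exceed pval
  expect_gt(mean(scores >= thr - 2e-3), 1e-2)
})

test_that("estimate_class_ppms counts frequencies per position", {
  pp <- estimate_class_ppms(rep("ACGT", 5), c("AAAA", "CCCC"))
  expect_equal(pp$class1$probs[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(pp$class1$probs[, 3], c(A = 0, C = 0, G = 1, T = 0))
  expect_equal(unname(pp$class2$probs["A", 2]), 0.5)
  ## valid PPMs for random input
  set.seed(2)
  pr <- estimate_class_ppms(random_dna(20, 6), random_dna(20, 6))
  expect_equal(colSums(pr$class1$probs), rep(1, 6))
  expect_error(estimate_class_ppms(c("AC", "ACG"), "AC"), "length")
})

test_that("gini_coefficient follows the discrete Lorenz construction", {
  ## independent cumulative-share oracle
  lorenz_gini <- function(x) {
    x <- sort(abs(x)); m <- length(x)
    cum <- cumsum(x) / sum(x)
    L <- sum(c(0, cum[-m]) + cum) / (2 * m) # trapezoid area
    1 - 2 * L
  }
  expect_equal(gini_coefficient(c(0, 0, 1, 1, 2)),
               lorenz_gini(c(0, 0, 1, 1, 2)))
  expect_equal(gini_coefficient(c(0, 0, 1, 1, 2)), 0.5)
  expect_equal(gini_coefficient(rep(3, 10)), 0)
  ## single nonzero among 4K cells: (m-1)/m, approaching 1 with K
  for (K in c(2, 10, 50)) {
    w <- matrix(0, 4, K); w[1, 1] <- 7
    expect_equal(gini_coefficient(w), (4 * K - 1) / (4 * K))
  }
  ## scale invariance
  set.seed(9)
  w <- matrix(rnorm(40), 4, 10)
  for (c_ in c(2, -3, 1e6))
    expect_equal(gini_coefficient(c_ * w), gini_coefficient(w),
                 tolerance = 1e-12)
  expect_error(gini_coefficient(matrix(0, 4, 3)), "all-zero")
})

test_that("mask_core replaces exactly the core span and is idempotent", {
  s <- toy_aligned(n = 5, len = 60, core = "ACGTACGTAC")
  m <- mask_core(s)
  cs <- s$core_start[1]
  expect_equal(substr(m$seq[1], cs, cs + 9), "NNNNNNNNNN")
  expect_equal(nchar(m$seq), nchar(s$seq))
  ## everything outside the core untouched
  expect_equal(substr(m$seq[1], 1, cs - 1), substr(s$seq[1], 1, cs - 1))
  expect_identical(mask_core(m)$seq, m$seq)
  un <- aligned_seqs(random_dna(3, 50), rep(c("a", "b"), length.out = 3))
  expect_error(mask_core(un), "anchored")
})

test_that("select_pwm_version picks the discriminative version", {
  set.seed(14)
  planted <- "TGGACGTA"; neutral <- "CCCTTTGG"
  sa <- random_dna(60, 300); sb <- random_dna(60, 300)
  ## plant `planted` in class A only; `neutral` in both
  substr(sa, 100, 107) <- planted
  substr(sa, 200, 207) <- neutral
  substr(sb, 150, 157) <- neutral
  sel <- select_pwm_version(list(test_ppm(neutral), test_ppm(planted)),
                            sa, sb)
  expect_equal(sel$index, 2L)
  expect_gt(sel$auroc, 0.9)
  ## reported AUROC equals auroc() of the underlying best-score lists
  single <- select_pwm_version(test_ppm(planted), sa, sb)
  expect_equal(single$auroc, max(sel$auroc_all[2], sel$auroc_all[2]))
  expect_error(select_pwm_version(list(), sa, sb), "empty")
})
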