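## Nucleotidic-environment (k-mer, region) discovery.

test_that("bin_layout covers the sequence with near-equal widths", {
  b7 <- bin_layout(1000, 7)
  expect_equal(b7$end - b7$start + 1L, c(143, 143, 143, 143, 143, 143, 142))
  expect_equal(b7$rel_start[1], -500L)
  expect_equal(b7$rel_end[7], 500L)
  ## contiguous: each bin starts where the previous ends
  expect_equal(b7$start[-1], b7$end[-7] + 1L)
  b4 <- bin_layout(1000, 4)
  expect_equal(unique(b4$end - b4$start + 1L), 250L)
  b13 <- bin_layout(1000, 13)
  expect_equal(b13$end - b13$start + 1L, c(rep(77L, 12), 76L))
  expect_error(bin_layout(10, 11), "n_bins")
})

test_that("kmer_frequency counts overlapping occurrences among valid windows", {
  expect_equal(kmer_frequency("ACACAC", "AC"), 3 / 5)
  expect_equal(kmer_frequency("AAAA", "AA"), 1)
  expect_equal(kmer_frequency("NNNNNN", "AC"), 0)
  ## N windows drop from numerator and denominator
  expect_equal(kmer_frequency("ACNAC", "AC"), 2 / 2)
  expect_error(kmer_frequency("ACGT", "AU"), "A/C/G/T")
  ## region restriction counts windows by their start position (boundary
  ## windows may extend past the region end)
  expect_equal(kmer_frequency("AAACCC", "CC", region = c(4, 6)), 1)
  expect_equal(kmer_frequency("AAACCC", "AC", region = c(1, 3)), 1 / 3)
})

test_that("regional frequency equals direct counting on the region (lattice exactness)", {
  set.seed(17)
  seqs <- random_dna(30, 140)
  layout <- bin_layout(140, 7)
  for (kmer in c("AC", "TTA", "ACGT")) {
    br <- best_region_for_kmer(kmer, seqs, rep(c("x", "y"), 15), n_bins = 7)
    direct <- kmer_frequency(seqs, kmer,
                             region = c(layout$start[br$first_bin],
                                        layout$end[br$last_bin]))
    expect_equal(br$freq, direct, tolerance = 1e-12)
  }
})

test_that("best_region_for_kmer agrees with exhaustive region enumeration", {
  set.seed(23)
  for (rep in 1:10) {
    n <- 24
    seqs <- random_dna(n, 105)
    labels <- rep(c("c1", "c2"), each = n / 2)
    kmer <- paste(sample(c("A", "C", "G", "T"), 2, TRUE), collapse = "")
    layout <- bin_layout(105, 7)
    ## independent oracle: direct counting over all 28 regions
    best <- NULL
    for (b1 in 1:7) for (b2 in b1:7) {
      f <- kmer_frequency(seqs, kmer,
                          region = c(layout$start[b1], layout$end[b2]))
      a <- max(auroc(f, labels == "c1"), 1 - auroc(f, labels == "c1"))
      if (is.null(best) || a > best$a + 1e-12 ||
          (abs(a - best$a) <= 1e-12 && (b2 - b1) > best$w))
        best <- list(a = a, b1 = b1, b2 = b2, w = b2 - b1)
    }
    got <- best_region_for_kmer(kmer, seqs, labels, n_bins = 7)
    expect_equal(got$auroc, best$a, tolerance = 1e-12)
    expect_equal(c(got$first_bin, got$last_bin), c(best$b1, best$b2))
  }
})

test_that("a planted regional k-mer signal is recovered", {
  set.seed(31)
  n <- 120
  sa <- random_dna(n, 1000); sb <- random_dna(n, 1000)
  ## enrich ACA in class1 over positions 351..850 (rel [-150, 350))
  for (i in seq_len(n)) {
    pos <- sample(351:848, 18)
    for (p in pos) substr(sa[i], p, p + 2) <- "ACA"
  }
  labels <- rep(c("c1", "c2"), each = n)
  feats <- explore_ne_features(c(sa, sb), labels, min_gain = 0.01)
  expect_gt(nrow(feats), 0)
  hit <- feats[grepl("ACA", feats$kmer), , drop = FALSE]
  expect_gt(nrow(hit), 0)
  top <- hit[which.max(hit$train_auroc), ]
  expect_gt(top$train_auroc, 0.9)
  ## recovered span overlaps the planted span by >= 50%
  ov <- min(top$rel_end, 350) - max(top$rel_start, -150)
  expect_gte(ov / 500, 0.5)
})

test_that("null data yields only chance-level features", {
  set.seed(37)
  n <- 60
  seqs <- random_dna(2 * n, 600)
  labels <- rep(c("c1", "c2"), each = n)
  feats <- explore_ne_features(seqs, labels, min_gain = 0.01)
  ## the exploration maximises folded AUROC over regions and extensions, so
  ## its null maximum sits above 0.5 by a selection bias; a 20-replicate
  ## null simulation at this n put the largest observed maximum at 0.72
  expect_lt(max(feats$train_auroc), 0.75)
})

test_that("min_gain = 1 blocks every extension", {
  set.seed(41)
  seqs <- random_dna(40, 300)
  feats <- explore_ne_features(seqs, rep(c("a", "b"), 20), min_gain = 1)
  expect_true(all(nchar(feats$kmer) == 2L))
  expect_equal(nrow(feats), 16L)
})

test_that("region optimisation can only help over the full-sequence variable", {
  set.seed(43)
  seqs <- random_dna(50, 420)
  labels <- rep(c("a", "b"), 25)
  feats <- explore_ne_features(seqs, labels, min_gain = 0.01)
  for (i in sample(nrow(feats), 5)) {
    f_full <- kmer_frequency(seqs, feats$kmer[i])
    a_full <- max(auroc(f_full, labels == "a"),
                  1 - auroc(f_full, labels == "a"))
    expect_gte(feats$train_auroc[i] + 1e-12, a_full)
  }
})

test_that("signal hidden inside the masked core does not leak into NE features", {
  set.seed(47)
  n <- 80
  s <- toy_aligned(n = n, len = 300, core = "TTTTTTTTTT", seed = 47)
  ## class1 carries GGGG inside the core span, class2 does not
  is1 <- s$label == "class1"
  substr(s$seq[is1], s$core_start[1] + 2, s$core_start[1] + 5) <- "GGGG"
  m <- mask_core(s)
  feats <- explore_ne_features(m$seq, s$label, min_gain = 0.01)
  ## must stay within the null selection-bias envelope (simulated maximum
  ## 0.69 over 20 null replicates at this n): no core leakage
  expect_lt(max(feats$train_auroc), 0.73)
})

test_that("ne_values reproduces discovery frequencies on the same rows", {
  set.seed(53)
  seqs <- random_dna(30, 280)
  labels <- rep(c("a", "b"), 15)
  feats <- explore_ne_features(seqs, labels, min_gain = 0.02)
  v <- ne_values(seqs, feats)
  expect_equal(ncol(v), nrow(feats))
  i <- which.max(feats$train_auroc)
  br <- best_region_for_kmer(feats$kmer[i], seqs, labels)
  if (br$first_bin == feats$first_bin[i] && br$last_bin == feats$last_bin[i])
    expect_equal(unname(v[, i]), br$freq)
})
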