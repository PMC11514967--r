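## End-to-end behaviour of motif_contrast() and its methods, at reduced n.

fit_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(synth_config(n_per_class = 150, seed = 19))
      cache <<- list(ds = ds,
                     fit = motif_contrast(seqs = ds$aligned,
                                          library = synthetic_pfm_library(),
                                          seed = 5))
    }
    cache
  }
})

test_that("the fitted object carries the full report surface", {
  fs <- fit_small()
  fit <- fs$fit
  expect_s3_class(fit, "motif_contrast")
  expect_named(fit$radar, c("original_pwm", "dm_only", "two_ppm", "full",
                            "wo_dm", "wo_ne", "wo_cf", "cf_whole_seq"))
  expect_gt(fit$auroc, 0.75)
  expect_equal(fit$importance_profile,
               c(DM = unname(fit$radar["full"] - fit$radar["wo_dm"]),
                 NE = unname(fit$radar["full"] - fit$radar["wo_ne"]),
                 CF = unname(fit$radar["full"] - fit$radar["wo_cf"])))
  ## location report: typed, ranked, class = coefficient sign
  loc <- fit$location
  expect_true(all(loc$type %in% c("DM", "NE", "CF")))
  expect_equal(loc$rank, seq_len(nrow(loc)))
  expect_equal(loc$class == "class1", loc$coefficient > 0)
  ## the DM variable reports the core +/- flank span
  if ("DM" %in% loc$variable) {
    dmrow <- loc[loc$variable == "DM", ]
    expect_equal(dmrow$rel_end - dmrow$rel_start, 10 + 2 * 4)
  }
})

test_that("print, summary, coef, residuals and plot methods work", {
  fit <- fit_small()$fit
  expect_output(print(fit), "held-out AUROC")
  expect_output(print(summary(fit)), "Model variants")
  cf <- coef(fit)
  expect_equal(length(cf), ncol(fit$x) + 1L)
  expect_equal(names(cf)[1], "(Intercept)")
  r <- residuals(fit)
  expect_equal(length(r), fit$n)
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  plot(fit, type = "radar"); plot(fit, type = "location")
  plot(fit, type = "logo")
  grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("predict recomputes features and matches the stored design", {
  fs <- fit_small()
  fit <- fs$fit
  lp_stored <- predict(fit)
  lp_recomp <- predict(fit, newdata = fs$ds$aligned)
  ## rows surviving the flank filter coincide with the stored rows
  expect_equal(length(lp_stored), fit$n)
  expect_equal(lp_recomp[seq_len(fit$n)], lp_stored, tolerance = 1e-9)
  pr <- predict(fit, type = "response")
  expect_true(all(pr >= 0 & pr <= 1))
  cl <- predict(fit, type = "class")
  expect_true(all(cl %in% fit$class_names))
  ## prediction tracks the labels
  expect_gt(auroc(lp_stored, fit$seqs$label), 0.8)
})

test_that("write_reports emits the documented files", {
  fit <- fit_small()$fit
  dir <- tempfile()
  write_reports(fit, dir)
  for (f in c("run.json", "features.tsv", "radar.tsv", "location.tsv",
              "dm_pwm.tsv", "class_ppms.tsv"))
    expect_true(file.exists(file.path(dir, f)))
  run <- jsonlite::read_json(file.path(dir, "run.json"))
  expect_equal(run$n, fit$n)
  rad <- read.delim(file.path(dir, "radar.tsv"))
  expect_equal(nrow(rad), 8L)
})

test_that("the BED/FASTA pipeline path reproduces the aligned-path model", {
  dir <- tempfile()
  ds <- generate_dataset(synth_config(n_per_class = 60, seed = 23),
                         dir = dir)
  fit <- motif_contrast(bed_a = file.path(dir, "class1.bed"),
                        bed_b = file.path(dir, "class2.bed"),
                        genome = file.path(dir, "genome.fa"),
                        target_motif = test_ppm("TGCATAAGGT", p = 0.85),
                        library = synthetic_pfm_library()[1:5],
                        mode = "as-given", seed = 3)
  expect_s3_class(fit, "motif_contrast")
  expect_false(is.na(fit$radar["original_pwm"]))
  expect_gt(fit$auroc, 0.6)
  ## the two classes live on different chromosomes: fully disjoint peaks
  expect_equal(fit$jaccard, 1)
  rep_ <- make_reports(fit)
  expect_named(rep_, c("radar", "location"))
  expect_identical(rep_$radar, fit$radar)
})

test_that("unique-vs-common mode contrasts unique-to-A against shared peaks", {
  dir <- tempfile()
  ds <- generate_dataset(synth_config(n_per_class = 60, seed = 41),
                         dir = dir)
  ## second file = a shifted copy of half of A's peaks: those become
  ## "common", the rest "unique to A"
  pk <- read_bed(file.path(dir, "class1.bed"), summit_col = 4)
  half <- seq_len(30)
  b <- peak_set(pk$chrom[half], pk$start[half] + 50, pk$end[half] + 50,
                genome_id = "genome")
  fb <- file.path(dir, "half.bed")
  write_bed(b, fb)
  fit <- motif_contrast(bed_a = file.path(dir, "class1.bed"), bed_b = fb,
                        genome = file.path(dir, "genome.fa"),
                        target_motif = test_ppm("TGCATAAGGT", p = 0.85),
                        library = synthetic_pfm_library()[1:3],
                        mode = "unique-vs-common", seed = 6)
  expect_s3_class(fit, "motif_contrast")
  ## the two halves come from the same class: near-chance separation
  expect_lt(fit$auroc, 0.75)
})

test_that("skip-anchoring drops the DM channel from the model", {
  ds <- generate_dataset(synth_config(n_per_class = 80, seed = 29))
  al <- ds$aligned
  al$core_start <- NA_integer_; al$core_width <- NA_integer_
  attr(al, "anchored") <- FALSE
  fit <- motif_contrast(seqs = al, library = synthetic_pfm_library()[1:5],
                        seed = 4)
  expect_false("DM" %in% colnames(fit$x))
  expect_true(is.na(fit$radar["dm_only"]))
  expect_true(all(fit$fit$column_type %in% c("NE", "CF")))
  expect_gt(fit$auroc, 0.55) # NE + CF signal remains
})

test_that("feature discovery and coefficients ignore test-row labels", {
  ds <- generate_dataset(synth_config(n_per_class = 80, seed = 31))
  lib <- synthetic_pfm_library()[1:5]
  f1 <- motif_contrast(seqs = ds$aligned, library = lib, seed = 7)
  ## permute the labels of the test rows only and refit on the same split
  al2 <- ds$aligned
  test_rows <- which(!f1$train)
  set.seed(99)
  al2$label[test_rows] <- sample(al2$label[test_rows])
  f2 <- motif_contrast(seqs = al2, library = lib, seed = 7,
                       split = f1$train)
  expect_identical(f1$fit$beta, f2$fit$beta)
  expect_identical(f1$fit$intercept, f2$fit$intercept)
  expect_identical(f1$ne_features, f2$ne_features)
  expect_identical(f1$cf_features, f2$cf_features)
  expect_identical(pwm_weights(f1$dm$pwm), pwm_weights(f2$dm$pwm))
})

test_that("identical inputs and seed give byte-identical fits", {
  ds <- generate_dataset(synth_config(n_per_class = 50, seed = 37))
  lib <- synthetic_pfm_library()[1:3]
  f1 <- motif_contrast(seqs = ds$aligned, library = lib, seed = 11)
  f2 <- motif_contrast(seqs = ds$aligned, library = lib, seed = 11)
  expect_identical(f1$fit$beta, f2$fit$beta)
  expect_identical(f1$radar, f2$radar)
  expect_identical(f1$location, f2$location)
})
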