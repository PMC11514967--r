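## The main modelling interface: motif_contrast() runs the whole pipeline
## and returns a classed fit with the usual methods.

#' Contrast the binding sequences of two ChIP-seq experiments
#'
#' Fits the full discriminative model of differential binding: sequences of
#' the two classes, anchored on the most likely core-motif occurrence, are
#' described by (1) the score of a discriminative core PWM learned on the
#' aligned sites, (2) regional k-mer frequencies (nucleotidic environment)
#' and (3) regional co-factor PWM scores; the three groups are combined in
#' one L1-penalised logistic regression
#' `P(1|s) = sigmoid(a DM(s) + sum b_i NE_i(s) + sum c_j CF_j(s))`.
#' Feature discovery and fitting use the training split only; accuracy is
#' the held-out AUROC; group ablations (coefficients zeroed, no retraining)
#' measure what each information source contributes.
#'
#' Either supply `seqs` (an [aligned_seqs], e.g. from [anchor_sequences()] or
#' the synthetic generator) or the raw inputs (`bed_a`, `bed_b`, `genome`,
#' `target_motif`) to run peak partitioning, anchoring and rebalancing
#' first.
#'
#' @param seqs an [aligned_seqs] with both classes, or `NULL`.
#' @param bed_a,bed_b BED paths or [peak_set]s of the two experiments.
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @param target_motif a [ppm] (or list of candidate versions, the most
#'   discriminative is selected) for anchoring and the DM module.
#' @param library list of [ppm]s (or a JASPAR file/directory path) for the
#'   co-factor module; `NULL` disables it.
#' @param mode which peaks to contrast: `"unique-vs-unique"` (default;
#'   peaks within `window_bp` of the other experiment are removed first),
#'   `"unique-vs-common"` (peaks unique to A against peaks shared by both
#'   experiments), or `"as-given"` (use the two files as-is).
#' @param skip_anchoring centre sequences on the peak summit and skip the
#'   discriminative-motif module (indirect binding / unknown motif).
#' @param window_bp peak-matching window for the unique/common partition.
#' @param halfwidth half sequence length (500 = 1-kb sequences).
#' @param n_flank flanking nucleotides added to the core for the
#'   discriminative PWM (default 4, the "+8" motif).
#' @param ne_bins,max_k,min_gain nucleotidic-environment module settings.
#' @param cf_bins co-factor module bin count.
#' @param train_fraction training fraction of the stratified split.
#' @param n_keep nonzero-coefficient count at which per-variable importance
#'   is measured.
#' @param top_n number of variables in the location report.
#' @param background,pseudocount,hit_pval scanning and log-odds settings.
#' @param class_names labels for the two classes (class 1 first).
#' @param split optional logical train-row indicator overriding the
#'   seeded stratified split (e.g. to audit that test rows never influence
#'   discovery or fitting).
#' @param seed master RNG seed (split, CV folds, rebalancing).
#' @return an object of class `"motif_contrast"`; see
#'   [summary.motif_contrast()], [coef.motif_contrast()],
#'   [predict.motif_contrast()], [plot.motif_contrast()].
#' @export
motif_contrast <- function(seqs = NULL, bed_a = NULL, bed_b = NULL,
                           genome = NULL, target_motif = NULL,
                           library = NULL,
                           mode = c("unique-vs-unique", "unique-vs-common",
                                    "as-given"),
                           skip_anchoring = FALSE,
                           window_bp = 1000L, halfwidth = 500L,
                           n_flank = 4L, ne_bins = 7L, max_k = 4L,
                           min_gain = 0.01, cf_bins = 13L,
                           train_fraction = 0.70, n_keep = 10L,
                           top_n = 15L, background = rep(0.25, 4),
                           pseudocount = 0.01, hit_pval = 1e-4,
                           class_names = c("class1", "class2"),
                           split = NULL, seed = 1L) {
  cl <- match.call()
  mode <- match.arg(mode)
  if (is.character(library)) library <- read_jaspar_library(library)
  original_auroc <- NA_real_
  target_pwm <- NULL

  if (is.null(seqs)) {
    if (is.null(bed_a) || is.null(bed_b) || is.null(genome))
      stop("supply either `seqs` or bed_a/bed_b/genome")
    if (is.character(bed_a)) bed_a <- read_bed(bed_a)
    if (is.character(bed_b)) bed_b <- read_bed(bed_b)
    genome <- load_genome(genome)
    if (mode == "unique-vs-unique") {
      part <- partition_peaks(bed_a, bed_b, window_bp)
      pk_a <- part$unique_a; pk_b <- part$unique_b
      if (nrow(pk_a) == 0L || nrow(pk_b) == 0L)
        stop("no unique peaks left after removing common peaks")
    } else if (mode == "unique-vs-common") {
      part <- partition_peaks(bed_a, bed_b, window_bp)
      pk_a <- part$unique_a; pk_b <- part$common
      if (nrow(pk_a) == 0L || nrow(pk_b) == 0L)
        stop("need both unique-to-A and common peaks for unique-vs-common")
    } else {
      part <- NULL; pk_a <- bed_a; pk_b <- bed_b
    }
    if (!skip_anchoring) {
      if (is.null(target_motif)) stop("target_motif is required for anchoring")
      wa <- extract_summit_windows(pk_a, genome, halfwidth)
      wb <- extract_summit_windows(pk_b, genome, halfwidth)
      sel <- select_pwm_version(target_motif, wa$seq, wb$seq,
                                background, pseudocount)
      target_pwm <- sel$pwm
      original_auroc <- sel$auroc
      sa <- anchor_sequences(pk_a, genome, target_pwm, class_names[1],
                             halfwidth = halfwidth, hit_pval = hit_pval,
                             background = background)
      sb <- anchor_sequences(pk_b, genome, target_pwm, class_names[2],
                             halfwidth = halfwidth, hit_pval = hit_pval,
                             background = background)
    } else {
      sa <- anchor_sequences(pk_a, genome, NULL, class_names[1],
                             halfwidth = halfwidth, skip_anchoring = TRUE)
      sb <- anchor_sequences(pk_b, genome, NULL, class_names[2],
                             halfwidth = halfwidth, skip_anchoring = TRUE)
    }
    jaccard <- jaccard_distance(bed_a, bed_b, window_bp)
    bal <- rebalance_classes(sa, sb, seed = seed)
    seqs <- rbind_aligned(bal$class1, bal$class2)
  } else {
    if (nlevels(factor(seqs$label)) != 2L)
      stop("`seqs` must contain two classes")
    part <- NULL; jaccard <- NA_real_
  }

  anchored <- is_anchored(seqs) && !skip_anchoring
  labels <- factor(seqs$label)
  class_names <- levels(labels)

  ## drop rows whose core + flank would overflow the window
  if (anchored) {
    sites_all <- extract_core_flank(seqs, n_flank)
    keep <- !is.na(sites_all)
    if (!all(keep)) {
      seqs <- subset_rows(seqs, which(keep))
      labels <- factor(seqs$label)
      sites_all <- sites_all[keep]
    }
  }

  if (!is.null(split)) {
    if (!is.logical(split) || length(split) != nrow(seqs))
      stop("`split` must be a logical train indicator of length ", nrow(seqs))
    train <- split
  } else {
    train <- split_train_test(labels, train_fraction, seed = seed + 1L)
  }
  test <- !train
  y1 <- as_class1(labels)

  cols <- list(); types <- character(0)
  meta <- list()
  dm_fit <- class_ppms <- NULL
  two_ppm_auroc <- NA_real_

  if (anchored) {
    dm_fit <- fit_discriminative_pwm(sites_all[train & y1],
                                     sites_all[train & !y1],
                                     seed = seed + 2L)
    dm_col <- dm_score(sites_all, dm_fit)
    cols$DM <- matrix(dm_col, ncol = 1, dimnames = list(NULL, "DM"))
    types <- c(types, "DM")
    K <- seqs$core_width[1L]
    core_rel <- seqs$core_start[1L] - 1L - halfwidth
    meta[["DM"]] <- data.frame(identity = "DM",
                               rel_start = core_rel - n_flank,
                               rel_end = core_rel + K + n_flank)
    cores_all <- extract_core_flank(seqs, 0L)
    class_ppms <- estimate_class_ppms(cores_all[train & y1],
                                      cores_all[train & !y1],
                                      pseudocount = 0.5)
    two_ppm_auroc <- two_ppm_baseline(class_ppms$class1, class_ppms$class2,
                                      cores_all[train], labels[train],
                                      cores_all[test], labels[test],
                                      background, pseudocount)
    masked <- mask_core(seqs)
  } else {
    masked <- seqs
  }

  ne_features <- explore_ne_features(masked$seq[train], labels[train],
                                     max_k = max_k, min_gain = min_gain,
                                     n_bins = ne_bins)
  if (nrow(ne_features) > 0L) {
    nev <- ne_values(masked$seq, ne_features, n_bins = ne_bins)
    cols$NE <- nev
    types <- c(types, rep("NE", ncol(nev)))
    for (i in seq_len(ncol(nev)))
      meta[[colnames(nev)[i]]] <- data.frame(
        identity = ne_features$kmer[i],
        rel_start = ne_features$rel_start[i],
        rel_end = ne_features$rel_end[i])
  }

  cf <- NULL
  if (!is.null(library)) {
    cf <- cf_scan_library(library, masked$seq, labels, train = train,
                          n_bins = cf_bins, background = background,
                          pseudocount = pseudocount)
    cols$CF <- cf$values
    types <- c(types, rep("CF", ncol(cf$values)))
    for (i in seq_len(ncol(cf$values)))
      meta[[colnames(cf$values)[i]]] <- data.frame(
        identity = cf$features$pwm[i],
        rel_start = cf$features$rel_start[i],
        rel_end = cf$features$rel_end[i])
  }

  x <- do.call(cbind, cols)
  if (is.null(x) || ncol(x) < 2L)
    stop("not enough features to fit the global model")
  column_meta <- do.call(rbind, meta)
  column_meta <- data.frame(variable = rownames(column_meta), column_meta,
                            type = types, row.names = NULL,
                            stringsAsFactors = FALSE)

  fit <- fit_global(x, labels, train, types, seed = seed + 3L)

  xt <- x[test, , drop = FALSE]
  yt <- labels[test]
  full_auroc <- auroc(model_scores(fit, xt), yt)
  abl <- c(DM = if (anchored) ablate(fit, xt, yt, "DM") else NA_real_,
           NE = ablate(fit, xt, yt, "NE"),
           CF = if (!is.null(cf)) ablate(fit, xt, yt, "CF") else NA_real_)

  ## position-agnostic co-factor baseline: same model family, CF columns
  ## replaced by whole-sequence best scores
  cf_whole_auroc <- NA_real_
  if (!is.null(cf)) {
    xw <- x
    xw[, types == "CF"] <- cf$whole_seq
    colnames(xw) <- colnames(x)
    fit_w <- fit_global(xw, labels, train, types, seed = seed + 3L)
    cf_whole_auroc <- auroc(model_scores(fit_w, xw[test, , drop = FALSE]), yt)
  }

  if (anchored && is.na(original_auroc) && !all(is.na(seqs$core_score)))
    original_auroc <- folded_auroc(seqs$core_score[test], yt)

  radar <- c(original_pwm = original_auroc,
             dm_only = if (anchored) auroc(x[test, "DM"], yt) else NA_real_,
             two_ppm = two_ppm_auroc,
             full = full_auroc,
             wo_dm = unname(abl["DM"]), wo_ne = unname(abl["NE"]),
             wo_cf = unname(abl["CF"]),
             cf_whole_seq = cf_whole_auroc)

  importance <- variable_importance(fit, xt, yt, n_keep = n_keep)
  loc_rank <- variable_importance(fit, xt, yt,
                                  n_keep = max(top_n, n_keep))
  loc <- loc_rank[loc_rank$coefficient != 0, , drop = FALSE]
  loc <- utils::head(loc, top_n)
  loc <- merge(loc, column_meta, by = "variable", sort = FALSE)
  location <- data.frame(rank = seq_len(nrow(loc)),
                         variable = loc$variable, type = loc$type.x,
                         identity = loc$identity,
                         rel_start = loc$rel_start, rel_end = loc$rel_end,
                         coefficient = loc$coefficient,
                         delta_auroc = loc$delta_auroc,
                         class = ifelse(loc$coefficient > 0, class_names[1],
                                        class_names[2]),
                         stringsAsFactors = FALSE)

  profile <- c(DM = full_auroc - unname(abl["DM"]),
               NE = full_auroc - unname(abl["NE"]),
               CF = full_auroc - unname(abl["CF"]))

  structure(list(
    call = cl,
    class_names = class_names,
    n = nrow(seqs), n_train = sum(train),
    anchored = anchored,
    seqs = seqs, train = train,
    x = x, column_meta = column_meta,
    fit = fit,
    dm = dm_fit, class_ppms = class_ppms,
    target_pwm = target_pwm,
    ne_features = ne_features,
    cf_features = if (!is.null(cf)) cf$features else NULL,
    library = library,
    params = list(n_flank = n_flank, ne_bins = ne_bins, cf_bins = cf_bins,
                  max_k = max_k, min_gain = min_gain, halfwidth = halfwidth,
                  train_fraction = train_fraction, background = background,
                  pseudocount = pseudocount, n_keep = n_keep, top_n = top_n,
                  seed = seed),
    partition = part,
    jaccard = jaccard,
    auroc = full_auroc,
    radar = radar,
    importance = importance,
    location = location,
    importance_profile = profile,
    dm_gini = if (anchored && any(pwm_weights(dm_fit$pwm) != 0))
      gini_coefficient(dm_fit$pwm) else NA_real_),
    class = "motif_contrast")
}

## Concatenate two aligned_seqs row-wise preserving attributes.
rbind_aligned <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  rownames(out) <- NULL
  class(out) <- class(a)
  attr(out, "anchored") <- is_anchored(a) && is_anchored(b)
  attr(out, "seq_length") <- attr(a, "seq_length")
  out
}

#' @export
print.motif_contrast <- function(x, ...) {
  cat("Differential binding-site model:",
      x$class_names[1], "vs", x$class_names[2], "\n")
  cat(sprintf("  %d sequences (%d train / %d test)\n",
              x$n, x$n_train, x$n - x$n_train))
  cat(sprintf("  held-out AUROC: %.3f\n", x$auroc))
  nz <- sum(x$fit$beta != 0)
  cat(sprintf("  %d of %d feature coefficients nonzero\n",
              nz, length(x$fit$beta)))
  invisible(x)
}

#' Summary of a fitted differential binding model
#'
#' @param object a [motif_contrast] fit.
#' @param ... unused.
#' @export
summary.motif_contrast <- function(object, ...) {
  structure(list(obj = object), class = "summary.motif_contrast")
}

#' @export
print.summary.motif_contrast <- function(x, ...) {
  o <- x$obj
  print(o)
  cat("\nModel variants (test AUROC):\n")
  r <- o$radar
  for (nm in names(r))
    if (!is.na(r[nm])) cat(sprintf("  %-14s %.3f\n", nm, r[nm]))
  cat("\nAblation importance profile (AUROC loss): DM",
      sprintf("%.3f", o$importance_profile["DM"]), " NE",
      sprintf("%.3f", o$importance_profile["NE"]), " CF",
      sprintf("%.3f", o$importance_profile["CF"]), "\n")
  if (!is.na(o$dm_gini))
    cat(sprintf("Discriminative PWM Gini coefficient: %.3f\n", o$dm_gini))
  cat("\nTop variables (location report):\n")
  print(utils::head(o$location, 10), row.names = FALSE)
  invisible(x)
}

#' @export
coef.motif_contrast <- function(object, ...) {
  c(`(Intercept)` = object$fit$intercept, object$fit$beta)
}

#' Predict class-1 scores for new aligned sequences
#'
#' Recomputes the discovered features (discriminative-motif score, regional
#' k-mer frequencies, regional co-factor scores) on `newdata` and applies
#' the fitted coefficients.
#'
#' @param object a [motif_contrast] fit.
#' @param newdata an [aligned_seqs] (anchored if the fit used anchoring), or
#'   a feature matrix with the fit's columns; default: the fitted rows.
#' @param type `"link"` (linear predictor), `"response"` (probability of
#'   class 1), or `"class"`.
#' @param ... unused.
#' @export
predict.motif_contrast <- function(object, newdata = NULL,
                                   type = c("link", "response", "class"),
                                   ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    x <- object$x
  } else if (is.matrix(newdata)) {
    x <- newdata[, colnames(object$x), drop = FALSE]
  } else {
    x <- features_for(object, newdata)
  }
  lp <- model_scores(object$fit, x)
  switch(type,
         link = lp,
         response = stats::plogis(lp),
         class = ifelse(lp > 0, object$class_names[1], object$class_names[2]))
}

## Rebuild the feature matrix of a fit for new aligned sequences.
features_for <- function(object, seqs) {
  stopifnot(inherits(seqs, "aligned_seqs"))
  p <- object$params
  cols <- list()
  if (object$anchored) {
    sites <- extract_core_flank(seqs, p$n_flank)
    if (anyNA(sites)) stop("some sequences cannot fit core + flank")
    cols$DM <- matrix(dm_score(sites, object$dm), ncol = 1,
                      dimnames = list(NULL, "DM"))
    masked <- mask_core(seqs)
  } else masked <- seqs
  if (nrow(object$ne_features) > 0L)
    cols$NE <- ne_values(masked$seq, object$ne_features, n_bins = p$ne_bins)
  if (!is.null(object$cf_features)) {
    pwms <- lapply(object$library, function(m)
      if (inherits(m, "ppm")) ppm_to_pwm(m, p$background, p$pseudocount)
      else m)
    cols$CF <- cf_values(pwms, object$cf_features, masked$seq,
                         n_bins = p$cf_bins)
  }
  x <- do.call(cbind, cols)
  x[, colnames(object$x), drop = FALSE]
}

#' @export
residuals.motif_contrast <- function(object, ...) {
  y <- as.numeric(as_class1(object$seqs$label))
  mu <- stats::plogis(model_scores(object$fit, object$x))
  d <- -2 * (y * log(mu) + (1 - y) * log(1 - mu))
  sign(y - mu) * sqrt(pmax(d, 0))
}

#' Radar, location and mirror-logo displays of a fit
#'
#' `type = "radar"` draws the test AUROC of the model variants;
#' `"location"` draws the top variables as segments over the anchor-relative
#' axis; `"logo"` draws the mirror logo of the discriminative PWM (weights
#' for class 1 upward, class 2 downward).
#'
#' @param x a [motif_contrast] fit.
#' @param type `"radar"`, `"location"` or `"logo"`.
#' @param ... passed to the underlying graphics calls.
#' @export
plot.motif_contrast <- function(x, type = c("radar", "location", "logo"),
                                ...) {
  type <- match.arg(type)
  if (type == "radar") {
    r <- x$radar[!is.na(x$radar)]
    graphics::dotchart(rev(r), xlim = c(0.4, 1), pch = 19,
                       xlab = "test AUROC", ...)
    graphics::abline(v = 0.5, lty = 3)
  } else if (type == "location") {
    loc <- x$location
    n <- nrow(loc)
    graphics::plot(NULL, xlim = c(-x$params$halfwidth, x$params$halfwidth),
                   ylim = c(0.5, n + 0.5), yaxt = "n",
                   xlab = "position relative to anchor (bp)",
                   ylab = "", ...)
    graphics::axis(2, at = n:1,
                   labels = paste0(loc$type, ":", loc$identity), las = 2,
                   cex.axis = 0.7)
    cols <- c(DM = "black", NE = "forestgreen", CF = "steelblue")
    graphics::segments(loc$rel_start, n:1, loc$rel_end, n:1,
                       lwd = 3, col = cols[loc$type])
  } else {
    mirror_logo(x$dm$pwm, ...)
  }
  invisible(x)
}

#' Mirror logo of a signed PWM
#'
#' Letters are drawn per position with height proportional to |weight|:
#' positive weights (favouring class 1) stack upward, negative weights
#' (class 2) downward.
#'
#' @param x a [pwm] (typically discriminative).
#' @param ... passed to `plot`.
#' @export
mirror_logo <- function(x, ...) {
  w <- pwm_weights(x)
  K <- ncol(w)
  ymax <- max(colSums(pmax(w, 0))); ymin <- -max(colSums(pmax(-w, 0)))
  graphics::plot(NULL, xlim = c(0.5, K + 0.5),
                 ylim = c(min(ymin, -0.1), max(ymax, 0.1)),
                 xlab = "position", ylab = "weight", ...)
  graphics::abline(h = 0)
  cols <- c(A = "forestgreen", C = "blue", G = "orange", T = "red")
  for (k in seq_len(K)) {
    up <- sort(w[w[, k] > 0, k, drop = FALSE][, 1], decreasing = FALSE)
    y0 <- 0
    for (nm in names(up)) {
      graphics::text(k, y0 + up[nm] / 2, nm, col = cols[nm],
                     cex = 0.5 + 2 * up[nm] / max(abs(w)))
      y0 <- y0 + up[nm]
    }
    dn <- sort(-w[w[, k] < 0, k, drop = FALSE][, 1], decreasing = FALSE)
    y0 <- 0
    for (nm in names(dn)) {
      graphics::text(k, -(y0 + dn[nm] / 2), nm, col = cols[nm],
                     cex = 0.5 + 2 * dn[nm] / max(abs(w)))
      y0 <- y0 + dn[nm]
    }
  }
  invisible(x)
}

#' Report records of a fitted model
#'
#' Returns the radar record (named test AUROCs of the model variants) and
#' the location record (top variables with type, identity, anchor-relative
#' region, rank and associated class).
#'
#' @param object a [motif_contrast] fit.
#' @return list with `radar` and `location`.
#' @export
make_reports <- function(object) {
  stopifnot(inherits(object, "motif_contrast"))
  list(radar = object$radar, location = object$location)
}

#' Write the standard report files of a fit
#'
#' Emits `run.json` (configuration, seeds, AUROCs), `features.tsv` (the
#' feature table with labels and split), `dm_pwm.tsv`, `class_ppms.tsv`,
#' `radar.tsv` and `location.tsv` into `dir`.
#'
#' @param object a [motif_contrast] fit.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  ft <- data.frame(label = object$seqs$label,
                   split = ifelse(object$train, "train", "test"),
                   object$x, check.names = FALSE)
  tsv(ft, "features.tsv")
  tsv(data.frame(variant = names(object$radar), auroc = object$radar),
      "radar.tsv")
  tsv(object$location, "location.tsv")
  if (!is.null(object$dm)) {
    w <- pwm_weights(object$dm$pwm)
    tsv(data.frame(nucleotide = rownames(w), w, check.names = FALSE),
        "dm_pwm.tsv")
    pp <- rbind(data.frame(class = object$class_names[1],
                           nucleotide = NUCS, object$class_ppms$class1$probs,
                           check.names = FALSE),
                data.frame(class = object$class_names[2],
                           nucleotide = NUCS, object$class_ppms$class2$probs,
                           check.names = FALSE))
    tsv(pp, "class_ppms.tsv")
  }
  run <- list(classes = object$class_names, n = object$n,
              n_train = object$n_train, anchored = object$anchored,
              params = object$params, auroc = object$auroc,
              jaccard = object$jaccard,
              radar = as.list(object$radar),
              importance_profile = as.list(object$importance_profile),
              lambda = object$fit$lambda,
              cv = object$fit$cv,
              dm_lambda = if (!is.null(object$dm)) object$dm$lambda,
              dm_cv = if (!is.null(object$dm)) object$dm$cv,
              dm_gini = object$dm_gini)
  jsonlite::write_json(run, file.path(dir, "run.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
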