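## Co-factor features: (library PWM, region) variables.
##
## For each PWM of a motif library, every (core-masked) sequence is reduced
## to its best both-strand window score per bin (13 bins by default); the
## best score of any contiguous-bin region follows from the bin scores by a
## bottom-up max() over the region lattice (each node's score is the max of
## its two children), and the region whose scores best separate the classes
## (folded AUROC) defines the co-factor variable.

## Floor score ranking below any real hit (used for all-N / empty bins).
pwm_floor <- function(w) sum(apply(w, 2, min)) - 1

## n x n_bins matrix of per-bin best both-strand scores for an encoded
## sequence set. Windows are assigned to the bin containing their start;
## windows containing an N never score.
cf_bin_matrix <- function(codes, w, layout) {
  sc <- window_scores(codes, w)$best
  floor_s <- pwm_floor(w)
  sc[!is.finite(sc)] <- floor_s
  n_bins <- nrow(layout)
  out <- matrix(floor_s, nrow(codes), n_bins)
  W <- ncol(sc)
  for (b in seq_len(n_bins)) {
    if (layout$start[b] > W) next
    cols <- layout$start[b]:min(layout$end[b], W)
    out[, b] <- Reduce(pmax, as.data.frame(sc[, cols, drop = FALSE]))
  }
  out
}

#' Per-bin best PWM scores of one sequence
#'
#' @param seq a DNA string (core already masked).
#' @param pwm a log-odds [pwm].
#' @param n_bins number of bins (default 13).
#' @return numeric vector of length `n_bins`: the best both-strand window
#'   score among windows starting in each bin; bins with no valid window get
#'   a floor score below any achievable hit.
#' @export
bin_best_scores <- function(seq, pwm, n_bins = 13L) {
  codes <- encode_seqs(seq)
  layout <- bin_layout(ncol(codes), n_bins)
  drop(cf_bin_matrix(codes, pwm_weights(pwm), layout))
}

#' Best score of every contiguous-bin region
#'
#' Computed bottom-up on the region lattice: the score of a region of width
#' w is the max of its two width-(w-1) children, so every node costs one
#' max(); the top node is the whole-sequence best score.
#'
#' @param bins numeric vector of per-bin best scores.
#' @return data frame with `first_bin`, `last_bin`, `score` for all
#'   `n(n+1)/2` regions.
#' @export
lattice_region_scores <- function(bins) {
  n <- length(bins)
  lev <- list(bins)
  for (wdt in seq_len(n - 1L))
    lev[[wdt + 1L]] <- pmax(lev[[wdt]][seq_len(n - wdt)],
                            lev[[wdt]][seq_len(n - wdt) + 1L])
  out <- do.call(rbind, lapply(seq_len(n), function(wdt)
    data.frame(first_bin = seq_len(n - wdt + 1L),
               last_bin = seq_len(n - wdt + 1L) + wdt - 1L,
               score = lev[[wdt]])))
  out[order(out$first_bin, out$last_bin), , drop = FALSE]
}

## Region-score matrix n x n_regions from a bin-score matrix, lattice
## recurrence column-wise; region order matches all_regions(n_bins).
region_score_matrix <- function(binmat) {
  n <- ncol(binmat)
  regions <- all_regions(n)
  out <- matrix(NA_real_, nrow(binmat), nrow(regions))
  lev <- binmat
  ## width-1 regions
  for (wdt in seq_len(n)) {
    if (wdt > 1L)
      lev <- pmax(lev[, seq_len(n - wdt + 1L), drop = FALSE],
                  lev[, seq_len(n - wdt + 1L) + 1L, drop = FALSE])
    idx <- which(regions$last_bin - regions$first_bin == wdt - 1L)
    out[, idx] <- lev[, regions$first_bin[idx], drop = FALSE]
  }
  out
}

#' Most discriminant region for one library PWM
#'
#' @param pwm a log-odds [pwm].
#' @param seqs character vector of masked sequences.
#' @param labels two-class labels.
#' @param n_bins number of bins (default 13).
#' @return list with `pwm_name`, `first_bin`, `last_bin`, `rel_start`,
#'   `rel_end`, `auroc` (folded, training), and `score` (per-sequence best
#'   score in the selected region).
#' @export
best_region_for_pwm <- function(pwm, seqs, labels, n_bins = 13L) {
  codes <- encode_seqs(seqs)
  layout <- bin_layout(ncol(codes), n_bins)
  binmat <- cf_bin_matrix(codes, pwm_weights(pwm), layout)
  rsm <- region_score_matrix(binmat)
  regions <- all_regions(n_bins)
  aucs <- vapply(seq_len(ncol(rsm)), function(i)
    folded_auroc(rsm[, i], labels), 1)
  i <- pick_region(regions, aucs)
  sp <- region_span(layout, regions$first_bin[i], regions$last_bin[i])
  list(pwm_name = pwm$name, first_bin = regions$first_bin[i],
       last_bin = regions$last_bin[i], rel_start = sp[1], rel_end = sp[2],
       auroc = aucs[i], score = rsm[, i])
}

#' Scan a PWM library for discriminant (PWM, region) variables
#'
#' For every PWM of the library, the most discriminant contiguous-bin region
#' is selected on the training rows; the feature value of every sequence
#' (train and test) is the best score of that PWM in the selected region.
#' The target TF's own PWM may stay in the library: secondary occurrences of
#' the core motif around the anchored site are genuine signal. The whole-
#' sequence (top-node) score of each PWM is also returned, as the
#' position-agnostic baseline.
#'
#' @param library list of [ppm]s or log-odds [pwm]s (PPMs are converted).
#' @param seqs character vector of masked sequences (all rows).
#' @param labels two-class labels (all rows).
#' @param train logical vector: rows used for region selection (default
#'   all).
#' @param n_bins number of bins (default 13).
#' @param background,pseudocount PPM-to-PWM conversion parameters.
#' @return list with `features` (data frame: `pwm`, `first_bin`, `last_bin`,
#'   `rel_start`, `rel_end`, `train_auroc`), `values` (n x J matrix of
#'   region scores) and `whole_seq` (n x J matrix of top-node scores).
#' @export
cf_scan_library <- function(library, seqs, labels, train = NULL,
                            n_bins = 13L, background = rep(0.25, 4),
                            pseudocount = 0.01) {
  if (length(library) == 0L) stop("empty PWM library")
  if (is.null(train)) train <- rep(TRUE, length(seqs))
  pwms <- lapply(library, function(m)
    if (inherits(m, "ppm")) ppm_to_pwm(m, background, pseudocount) else m)
  codes <- encode_seqs(seqs)
  layout <- bin_layout(ncol(codes), n_bins)
  regions <- all_regions(n_bins)
  J <- length(pwms)
  values <- whole <- matrix(NA_real_, length(seqs), J)
  feats <- vector("list", J)
  for (j in seq_len(J)) {
    w <- pwm_weights(pwms[[j]])
    binmat <- cf_bin_matrix(codes, w, layout)
    rsm <- region_score_matrix(binmat)
    aucs <- vapply(seq_len(ncol(rsm)), function(i)
      folded_auroc(rsm[train, i], labels[train]), 1)
    i <- pick_region(regions, aucs)
    sp <- region_span(layout, regions$first_bin[i], regions$last_bin[i])
    feats[[j]] <- data.frame(pwm = pwms[[j]]$name,
                             first_bin = regions$first_bin[i],
                             last_bin = regions$last_bin[i],
                             rel_start = sp[1], rel_end = sp[2],
                             train_auroc = aucs[i],
                             stringsAsFactors = FALSE)
    values[, j] <- rsm[, i]
    top <- which(regions$first_bin == 1L & regions$last_bin == n_bins)
    whole[, j] <- rsm[, top] # top lattice node = full sequence
  }
  features <- do.call(rbind, feats)
  nm <- paste0("CF:", features$pwm, "@[", features$rel_start, ",",
               features$rel_end, ")")
  colnames(values) <- nm
  colnames(whole) <- paste0("CFfull:", features$pwm)
  list(features = features, values = values, whole_seq = whole)
}

## Region scores of already-selected (PWM, region) features on new
## sequences; `pwms` must be named to match features$pwm.
cf_values <- function(pwms, features, seqs, n_bins = 13L) {
  codes <- encode_seqs(seqs)
  layout <- bin_layout(ncol(codes), n_bins)
  out <- matrix(NA_real_, length(seqs), nrow(features))
  nms <- vapply(pwms, `[[`, "", "name")
  for (i in seq_len(nrow(features))) {
    w <- pwm_weights(pwms[[match(features$pwm[i], nms)]])
    binmat <- cf_bin_matrix(codes, w, layout)
    bins <- features$first_bin[i]:features$last_bin[i]
    out[, i] <- Reduce(pmax, as.data.frame(binmat[, bins, drop = FALSE]))
  }
  colnames(out) <- paste0("CF:", features$pwm, "@[", features$rel_start,
                          ",", features$rel_end, ")")
  out
}
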