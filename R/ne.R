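## Nucleotidic-environment features: (k-mer, region) variables.
##
## Sequences (core masked) are segmented into contiguous bins; for every
## candidate k-mer the region of consecutive bins whose regional k-mer
## frequency best discriminates the two classes (folded AUROC) is found by
## exhaustive enumeration of the bin lattice, and 2-mers are then greedily
## extended to 3- and 4-mers while the criterion improves.
##
## Window-to-bin convention: a k-mer window belongs to the bin (or region)
## containing its START; windows near a boundary may extend into the next
## bin. This makes regional counts an exact sum of bin counts, so the
## lattice aggregation is exact rather than approximate.

#' Segment a sequence into contiguous bins
#'
#' Bin widths differ by at most 1 bp: with `L = q * n + r`, the first `r`
#' bins get `q + 1` bp (1000 bp in 7 bins: six bins of 143 bp then 142 bp).
#'
#' @param seq_length sequence length in bp.
#' @param n_bins number of bins.
#' @return data frame with 1-based `start`/`end` (inclusive) and
#'   anchor-relative `rel_start`/`rel_end` (0-based half-open, 0 = the
#'   sequence midpoint/anchor).
#' @export
bin_layout <- function(seq_length = 1000L, n_bins = 7L) {
  if (n_bins < 1L || n_bins > seq_length)
    stop("n_bins must be in [1, seq_length]")
  q <- seq_length %/% n_bins; r <- seq_length %% n_bins
  widths <- rep(q, n_bins) + c(rep(1L, r), rep(0L, n_bins - r))
  end <- cumsum(widths)
  start <- end - widths + 1L
  half <- seq_length %/% 2L
  data.frame(bin = seq_len(n_bins), start = start, end = end,
             rel_start = start - half - 1L, rel_end = end - half)
}

## Anchor-relative [rel_start, rel_end) span of a bin region.
region_span <- function(layout, first_bin, last_bin) {
  c(layout$rel_start[first_bin], layout$rel_end[last_bin])
}

#' Frequency of a k-mer in a sequence region
#'
#' Overlapping occurrences whose start lies in the region, divided by the
#' number of valid windows there (windows containing an N are excluded from
#' numerator and denominator); 0 when no window is valid.
#'
#' @param seqs character vector of sequences.
#' @param kmer k-mer over A/C/G/T.
#' @param region 1-based `c(start, end)` within the sequence; default the
#'   whole sequence.
#' @return numeric vector of frequencies in \[0, 1\].
#' @export
kmer_frequency <- function(seqs, kmer, region = NULL) {
  kmer <- toupper(kmer)
  if (grepl("[^ACGT]", kmer)) stop("k-mer must be over A/C/G/T")
  k <- nchar(kmer)
  codes <- encode_seqs(seqs)
  L <- ncol(codes)
  if (is.null(region)) region <- c(1L, L)
  starts <- region[1]:min(region[2], L - k + 1L)
  if (region[1] > L - k + 1L) return(numeric(nrow(codes)))
  ids <- kmer_id_matrix(codes, k)
  target <- kmer_to_id(kmer)
  sub <- ids[, starts, drop = FALSE]
  num <- rowSums(sub == target, na.rm = TRUE)
  den <- rowSums(!is.na(sub))
  ifelse(den > 0, num / den, 0)
}

kmer_to_id <- function(kmer) {
  v <- match(strsplit(kmer, "")[[1]], NUCS)
  sum((v - 1L) * 4L^(seq_along(v) - 1L)) + 1L
}

id_to_kmer <- function(id, k) {
  id <- id - 1L
  paste(NUCS[(id %/% 4L^(0:(k - 1L))) %% 4L + 1L], collapse = "")
}

## n x (L-k+1) matrix of k-mer identities (1..4^k), NA where the window
## contains an N.
kmer_id_matrix <- function(codes, k) {
  L <- ncol(codes); W <- L - k + 1L
  ids <- matrix(0L, nrow(codes), W)
  bad <- matrix(FALSE, nrow(codes), W)
  for (j in seq_len(k)) {
    cj <- codes[, j:(j + W - 1L), drop = FALSE]
    bad <- bad | cj == 5L
    ids <- ids + (pmin(cj, 4L) - 1L) * 4L^(j - 1L)
  }
  ids <- ids + 1L
  ids[bad] <- NA_integer_
  ids
}

## Per-bin numerator/denominator of a k-mer id, from a precomputed id matrix.
## Returns list(num = n x n_bins, den = n x n_bins).
bin_kmer_counts <- function(ids, target, layout, L) {
  k_max_start <- ncol(ids)
  n_bins <- nrow(layout)
  num <- den <- matrix(0, nrow(ids), n_bins)
  for (b in seq_len(n_bins)) {
    cols <- layout$start[b]:min(layout$end[b], k_max_start)
    if (layout$start[b] > k_max_start) next
    sub <- ids[, cols, drop = FALSE]
    num[, b] <- rowSums(sub == target, na.rm = TRUE)
    den[, b] <- rowSums(!is.na(sub))
  }
  list(num = num, den = den)
}

## Folded AUROC of every contiguous-bin region for precomputed bin counts;
## returns the regions table with an auroc column and the per-region
## frequency closure.
region_aurocs_from_counts <- function(counts, labels, regions) {
  nb <- ncol(counts$num)
  cnum <- cbind(0, t(apply(counts$num, 1, cumsum)))
  cden <- cbind(0, t(apply(counts$den, 1, cumsum)))
  vapply(seq_len(nrow(regions)), function(i) {
    b1 <- regions$first_bin[i]; b2 <- regions$last_bin[i]
    num <- cnum[, b2 + 1L] - cnum[, b1]
    den <- cden[, b2 + 1L] - cden[, b1]
    f <- ifelse(den > 0, num / den, 0)
    folded_auroc(f, labels)
  }, 1)
}

region_freq <- function(counts, first_bin, last_bin) {
  num <- rowSums(counts$num[, first_bin:last_bin, drop = FALSE])
  den <- rowSums(counts$den[, first_bin:last_bin, drop = FALSE])
  ifelse(den > 0, num / den, 0)
}

#' Most discriminant region for one k-mer
#'
#' Enumerates all contiguous-bin regions (n(n+1)/2; 28 for 7 bins) and
#' returns the one whose regional k-mer frequency has the highest folded
#' AUROC `max(a, 1 - a)` between the classes. Ties go to the widest, then
#' leftmost region.
#'
#' @param kmer k-mer over A/C/G/T.
#' @param seqs character vector of (masked) sequences.
#' @param labels two-class labels.
#' @param n_bins number of bins (default 7).
#' @return list with `kmer`, `first_bin`, `last_bin`, `rel_start`,
#'   `rel_end`, `auroc` (folded), and `freq` (per-sequence regional
#'   frequency).
#' @export
best_region_for_kmer <- function(kmer, seqs, labels, n_bins = 7L) {
  codes <- encode_seqs(seqs)
  layout <- bin_layout(ncol(codes), n_bins)
  ids <- kmer_id_matrix(codes, nchar(kmer))
  counts <- bin_kmer_counts(ids, kmer_to_id(kmer), layout, ncol(codes))
  regions <- all_regions(n_bins)
  aucs <- region_aurocs_from_counts(counts, labels, regions)
  i <- pick_region(regions, aucs)
  sp <- region_span(layout, regions$first_bin[i], regions$last_bin[i])
  list(kmer = toupper(kmer),
       first_bin = regions$first_bin[i], last_bin = regions$last_bin[i],
       rel_start = sp[1], rel_end = sp[2], auroc = aucs[i],
       freq = region_freq(counts, regions$first_bin[i], regions$last_bin[i]))
}

#' Discover discriminant (k-mer, region) variables
#'
#' For each of the 16 dinucleotides, the most discriminant region is found;
#' the k-mer is then repeatedly extended by one nucleotide on either side
#' (8 candidates, region re-optimised each time) and an extension is kept
#' only when the folded AUROC improves by at least `min_gain`, up to length
#' `max_k`. Run on training sequences only.
#'
#' @param seqs character vector of masked training sequences.
#' @param labels training labels.
#' @param max_k maximum k-mer length (default 4).
#' @param min_gain minimum folded-AUROC improvement to accept an extension.
#' @param n_bins number of bins (default 7).
#' @param include_seeds also emit every 2-mer seed variable, not only the
#'   final extended ones.
#' @return data frame of features (`kmer`, `first_bin`, `last_bin`,
#'   `rel_start`, `rel_end`, `train_auroc`), de-duplicated.
#' @export
explore_ne_features <- function(seqs, labels, max_k = 4L, min_gain = 0.01,
                                n_bins = 7L, include_seeds = FALSE) {
  codes <- encode_seqs(seqs)
  L <- ncol(codes)
  layout <- bin_layout(L, n_bins)
  regions <- all_regions(n_bins)
  ids_by_k <- lapply(2:max_k, function(k) kmer_id_matrix(codes, k))
  eval_kmer <- function(kmer) {
    k <- nchar(kmer)
    counts <- bin_kmer_counts(ids_by_k[[k - 1L]], kmer_to_id(kmer), layout, L)
    aucs <- region_aurocs_from_counts(counts, labels, regions)
    i <- pick_region(regions, aucs)
    list(kmer = kmer, first_bin = regions$first_bin[i],
         last_bin = regions$last_bin[i], auroc = aucs[i])
  }
  seeds <- apply(expand.grid(NUCS, NUCS), 1, paste, collapse = "")
  out <- list()
  for (seed_kmer in seeds) {
    cur <- eval_kmer(seed_kmer)
    if (include_seeds) out[[length(out) + 1L]] <- cur
    repeat {
      if (nchar(cur$kmer) >= max_k) break
      cands <- c(paste0(NUCS, cur$kmer), paste0(cur$kmer, NUCS))
      evs <- lapply(cands, eval_kmer)
      best <- evs[[which.max(vapply(evs, `[[`, 1, "auroc"))]]
      if (best$auroc >= cur$auroc + min_gain) cur <- best else break
    }
    out[[length(out) + 1L]] <- cur
  }
  df <- do.call(rbind, lapply(out, function(x)
    data.frame(kmer = x$kmer, first_bin = x$first_bin, last_bin = x$last_bin,
               stringsAsFactors = FALSE)))
  auc <- vapply(out, `[[`, 1, "auroc")
  df$rel_start <- layout$rel_start[df$first_bin]
  df$rel_end <- layout$rel_end[df$last_bin]
  df$train_auroc <- auc
  df <- df[!duplicated(df[c("kmer", "first_bin", "last_bin")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Evaluate (k-mer, region) variables on a sequence set
#'
#' Computes the regional k-mer frequency columns of a feature table for
#' any sequence set (train and test rows alike) from a feature table
#' produced by [explore_ne_features()].
#'
#' @param seqs character vector of masked sequences.
#' @param features data frame with `kmer`, `first_bin`, `last_bin`.
#' @param n_bins number of bins the features were discovered with.
#' @return numeric matrix, one column per feature, named `NE:<kmer>@<span>`.
#' @export
ne_values <- function(seqs, features, n_bins = 7L) {
  codes <- encode_seqs(seqs)
  L <- ncol(codes)
  layout <- bin_layout(L, n_bins)
  vals <- matrix(0, nrow(codes), nrow(features))
  ids_cache <- list()
  for (i in seq_len(nrow(features))) {
    k <- nchar(features$kmer[i])
    key <- as.character(k)
    if (is.null(ids_cache[[key]])) ids_cache[[key]] <- kmer_id_matrix(codes, k)
    counts <- bin_kmer_counts(ids_cache[[key]], kmer_to_id(features$kmer[i]),
                              layout, L)
    vals[, i] <- region_freq(counts, features$first_bin[i],
                             features$last_bin[i])
  }
  colnames(vals) <- paste0("NE:", features$kmer, "@[",
                           layout$rel_start[features$first_bin], ",",
                           layout$rel_end[features$last_bin], ")")
  vals
}
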