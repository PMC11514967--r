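## Motif matrices (PPM / PWM), JASPAR IO, anchoring and motif utilities.

#' Position probability matrix
#'
#' A 4 x K matrix of per-position nucleotide probabilities in fixed row order
#' A, C, G, T; every column sums to 1.
#'
#' @param probs 4 x K numeric matrix (columns = positions).
#' @param name motif identifier.
#' @return an object of class `"ppm"`.
#' @export
ppm <- function(probs, name = "motif") {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("a PPM needs 4 rows (A, C, G, T)")
  if (any(probs < 0)) stop("PPM probabilities must be non-negative")
  cs <- colSums(probs)
  if (any(abs(cs - 1) > 1e-9)) stop("PPM columns must sum to 1")
  rownames(probs) <- NUCS
  structure(list(probs = probs, name = name), class = "ppm")
}

#' Position weight matrix
#'
#' A 4 x K matrix of additive per-position scores; a site's score is the sum
#' of the weights of its nucleotides. `source` records whether the weights
#' are background log-odds (for scanning) or logistic-regression coefficients
#' (a discriminative PWM).
#'
#' @param weights 4 x K numeric matrix.
#' @param source `"jaspar_logodds"` or `"discriminative"`.
#' @param name motif identifier.
#' @return an object of class `"pwm"`.
#' @export
pwm <- function(weights, source = c("jaspar_logodds", "discriminative"),
                name = "motif") {
  weights <- as.matrix(weights)
  if (nrow(weights) != 4L) stop("a PWM needs 4 rows (A, C, G, T)")
  if (!all(is.finite(weights))) stop("PWM weights must be finite")
  rownames(weights) <- NUCS
  structure(list(weights = weights, source = match.arg(source), name = name),
            class = "pwm")
}

pwm_weights <- function(x) {
  if (inherits(x, "pwm")) x$weights
  else if (inherits(x, "ppm")) stop("got a PPM where a PWM is required; convert with ppm_to_pwm()")
  else as.matrix(x)
}

#' @export
print.ppm <- function(x, ...) {
  cat("PPM", x$name, "-", ncol(x$probs), "positions\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$name, "(", x$source, ") -", ncol(x$weights), "positions\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' Consensus sequence of a motif
#'
#' @param x a [ppm] or [pwm].
#' @return character string of per-position argmax nucleotides.
#' @export
consensus_seq <- function(x) {
  m <- if (inherits(x, "ppm")) x$probs else pwm_weights(x)
  paste(NUCS[apply(m, 2, which.max)], collapse = "")
}

## ---- JASPAR IO -------------------------------------------------------------

parse_jaspar_block <- function(lines, name) {
  rows <- lapply(lines, function(l) {
    l <- sub("^\\s*[ACGTacgt]\\s*", "", l)
    l <- gsub("[][]", " ", l)
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (any(is.na(v))) stop("non-numeric counts in motif '", name, "'")
    v
  })
  len <- vapply(rows, length, 1L)
  if (length(unique(len)) != 1L)
    stop("rows of unequal length in motif '", name, "'")
  counts <- do.call(rbind, rows)
  cs <- colSums(counts)
  if (any(cs == 0)) stop("zero-count column in motif '", name, "'")
  ppm(sweep(counts, 2, cs, "/"), name = name)
}

#' Read motifs in JASPAR PFM text format
#'
#' Accepts both the plain 4-row count dialect and the bracketed
#' `A [ 1 2 3 ]` dialect, with `>ID NAME` headers. `read_jaspar()` reads a
#' single motif (the file must contain exactly one);
#' `read_jaspar_library()` reads every motif of a file or of all `*.pfm` /
#' `*.jaspar` / `*.txt` files in a directory.
#'
#' @param path file (or, for the library reader, file or directory) path.
#' @return a [ppm], or a named list of [ppm]s.
#' @export
read_jaspar <- function(path) {
  mots <- read_jaspar_library(path)
  if (length(mots) != 1L)
    stop("expected exactly one motif in ", path, ", found ", length(mots))
  mots[[1L]]
}

#' @rdname read_jaspar
#' @export
read_jaspar_library <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(pfm|jaspar|txt)$",
                        full.names = TRUE)
    if (length(files) == 0L) stop("no motif files found in ", path)
    mots <- unlist(lapply(sort(files), read_jaspar_library),
                   recursive = FALSE)
    return(mots)
  }
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) { hdr <- 0L; names_ <- basename(path) } else {
    names_ <- vapply(lines[hdr], function(h) {
      f <- strsplit(sub("^>\\s*", "", h), "\\s+")[[1]]
      paste(f[!is.na(f) & nzchar(f)], collapse = "_")
    }, "")
  }
  starts <- if (hdr[1] == 0L) 1L else hdr + 1L
  ends <- if (hdr[1] == 0L) length(lines) else
    c(hdr[-1] - 1L, length(lines))
  mots <- lapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[i]]
    if (length(block) != 4L)
      stop("motif '", names_[i], "' must have 4 count rows, found ",
           length(block))
    parse_jaspar_block(block, names_[i])
  })
  names(mots) <- names_
  mots
}

#' Write a motif in JASPAR PFM text format
#'
#' Probabilities are written scaled to counts (default total 100 per column)
#' in the bracketed dialect.
#'
#' @param x a [ppm].
#' @param path output file.
#' @param total per-column count total.
#' @export
write_jaspar <- function(x, path, total = 1e6) {
  stopifnot(inherits(x, "ppm"))
  counts <- x$probs * total
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0(">", x$name), con)
  for (j in 1:4)
    writeLines(sprintf("%s [ %s ]", NUCS[j],
                       paste(format(counts[j, ], scientific = FALSE, trim = TRUE),
                             collapse = " ")), con)
  invisible(path)
}

#' Convert a probability matrix to a log-odds scanning PWM
#'
#' `weight(j,k) = log2((p(j,k) + pc * bg_j) / ((1 + pc) * bg_j))` — the usual
#' background log-ratio with an additive pseudocount proportional to the
#' background.
#'
#' @param x a [ppm].
#' @param background nucleotide background probabilities (A, C, G, T).
#' @param pseudocount non-negative pseudocount weight.
#' @return a scanning [pwm].
#' @export
ppm_to_pwm <- function(x, background = rep(0.25, 4), pseudocount = 0.01) {
  stopifnot(inherits(x, "ppm"), pseudocount >= 0,
            abs(sum(background) - 1) < 1e-8)
  p <- x$probs
  if (pseudocount == 0 && any(p == 0))
    stop("zero probability with zero pseudocount gives infinite weights")
  w <- log2(sweep(sweep(p, 1, pseudocount * background, "+"),
                  1, (1 + pseudocount) * background, "/"))
  pwm(w, source = "jaspar_logodds", name = x$name)
}

## ---- aligned sequences -----------------------------------------------------

#' Aligned 1-kb sequence set
#'
#' The unit of all downstream feature extraction: fixed-length sequences with
#' a class label and, when anchored, the span of the core-motif occurrence
#' (always given in motif orientation: minus-strand windows are reverse
#' complemented at extraction).
#'
#' @param seq character vector of equal-length DNA strings.
#' @param label two-class label vector (first factor level = class 1).
#' @param chrom,anchor,strand optional genomic provenance (anchor is the
#'   0-based genome coordinate of the sequence midpoint).
#' @param core_start 1-based start of the core-motif span within each
#'   sequence (NA when not anchored).
#' @param core_width core motif length K.
#' @param core_score best-hit score of the scanning PWM (NA when unknown).
#' @return a data frame of class `"aligned_seqs"`; attribute `anchored` says
#'   whether core spans are available.
#' @export
aligned_seqs <- function(seq, label, chrom = NA_character_,
                         anchor = NA_integer_, strand = NA_character_,
                         core_start = NA_integer_, core_width = NA_integer_,
                         core_score = NA_real_) {
  n <- length(seq)
  L <- unique(nchar(seq))
  if (length(L) != 1L) stop("sequences must all have the same length")
  df <- data.frame(seq = toupper(seq),
                   label = factor(label),
                   chrom = rep_len(chrom, n),
                   anchor = rep_len(anchor, n),
                   strand = rep_len(strand, n),
                   core_start = rep_len(as.integer(core_start), n),
                   core_width = rep_len(as.integer(core_width), n),
                   core_score = rep_len(core_score, n),
                   stringsAsFactors = FALSE)
  structure(df, class = c("aligned_seqs", "data.frame"),
            anchored = !all(is.na(df$core_start)),
            seq_length = L)
}

is_anchored <- function(s) isTRUE(attr(s, "anchored"))

#' Mask the core-motif span with Ns
#'
#' Replaces the K-length core sub-sequence of every aligned sequence with
#' K N characters so that environment and co-factor features cannot capture
#' core-motif information. Idempotent.
#'
#' @param s an anchored [aligned_seqs].
#' @return the masked [aligned_seqs].
#' @export
mask_core <- function(s) {
  if (!is_anchored(s)) stop("mask_core() needs anchored sequences")
  sq <- s$seq
  for (i in seq_along(sq)) {
    k <- s$core_width[i]
    substr(sq[i], s$core_start[i], s$core_start[i] + k - 1L) <-
      strrep("N", k)
  }
  s$seq <- sq
  s
}

## ---- anchoring -------------------------------------------------------------

#' Anchor peak sequences on the most likely binding site
#'
#' For each peak, the window of +/- `search_bp` around the summit is scanned
#' with the target-motif PWM on both strands; the best hit above the score
#' threshold becomes the anchor: a `2 * halfwidth` sequence centred on the
#' hit midpoint is extracted (reverse complemented when the hit is on the
#' minus strand, so the core always reads in motif orientation). Peaks with
#' no hit, or whose window leaves the chromosome, are dropped and counted.
#'
#' @param peaks a [peak_set].
#' @param genome a named `DNAStringSet` or FASTA path.
#' @param pwm the scanning [pwm] of the target motif.
#' @param label class label assigned to all extracted sequences.
#' @param halfwidth half the extracted length (default 500, i.e. 1-kb
#'   sequences).
#' @param search_bp summit-centred search radius (default 500).
#' @param threshold hit threshold; `NULL` computes the score whose
#'   tail p-value is `hit_pval` under `background`.
#' @param hit_pval,background threshold computation parameters.
#' @param skip_anchoring if `TRUE`, no scan: sequences are centred on the
#'   summit, no core span is recorded, and the discriminative-motif module is
#'   disabled downstream (for indirect binding or unknown motifs).
#' @return an [aligned_seqs]; attribute `dropped` is a named count of drop
#'   reasons, attribute `dropped_fraction` the dropped fraction.
#' @export
anchor_sequences <- function(peaks, genome, pwm, label,
                             halfwidth = 500L, search_bp = 500L,
                             threshold = NULL, hit_pval = 1e-4,
                             background = rep(0.25, 4),
                             skip_anchoring = FALSE) {
  genome <- load_genome(genome)
  if (skip_anchoring) {
    res <- extract_summit_windows(peaks, genome, halfwidth)
    out <- aligned_seqs(res$seq, rep(label, length(res$seq)),
                        chrom = res$chrom, anchor = res$center, strand = "+")
    attr(out, "dropped") <- res$dropped
    attr(out, "dropped_fraction") <- sum(res$dropped) / nrow(peaks)
    return(out)
  }
  w <- pwm_weights(pwm)
  K <- ncol(w)
  if (is.null(threshold))
    threshold <- pwm_score_threshold(w, background, hit_pval)
  chrlen <- Biostrings::width(genome)
  names(chrlen) <- names(genome)
  keep <- list()
  dropped <- c(no_hit = 0L, out_of_bounds = 0L)
  for (i in seq_len(nrow(peaks))) {
    chrom <- peaks$chrom[i]
    if (!chrom %in% names(genome))
      stop("chromosome not in genome: ", chrom)
    summit <- peaks$summit[i] # 0-based
    lo <- summit - search_bp; hi <- summit + search_bp # 0-based half-open
    if (lo < 0L || hi > chrlen[[chrom]]) { # clip the scan to the chromosome
      lo <- max(lo, 0L); hi <- min(hi, chrlen[[chrom]])
    }
    if (hi - lo < K) { dropped["out_of_bounds"] <- dropped["out_of_bounds"] + 1L; next }
    span_seq <- toupper(as.character(Biostrings::subseq(genome[[chrom]],
                                                        lo + 1L, hi)))
    hit <- scan_best_hit(span_seq, pwm, threshold = threshold,
                         center = summit - lo + 0.5)
    if (is.null(hit)) { dropped["no_hit"] <- dropped["no_hit"] + 1L; next }
    hit_start <- lo + hit$offset            # 0-based genome
    anchor <- hit_start + K %/% 2L          # midpoint convention
    ws <- anchor - halfwidth; we <- anchor + halfwidth # [ws, we)
    if (ws < 0L || we > chrlen[[chrom]]) {
      dropped["out_of_bounds"] <- dropped["out_of_bounds"] + 1L; next
    }
    sq <- toupper(as.character(Biostrings::subseq(genome[[chrom]],
                                                  ws + 1L, we)))
    core_start <- hit_start - ws + 1L # 1-based within the window
    if (hit$strand == "-") {
      sq <- reverse_complement(sq)
      core_start <- 2L * halfwidth - (core_start + K - 1L) + 1L
    }
    keep[[length(keep) + 1L]] <-
      list(seq = sq, chrom = chrom, anchor = anchor, strand = hit$strand,
           core_start = core_start, core_score = hit$score)
  }
  if (length(keep) == 0L)
    stop("no sequence could be anchored")
  out <- aligned_seqs(
    seq = vapply(keep, `[[`, "", "seq"),
    label = rep(label, length(keep)),
    chrom = vapply(keep, `[[`, "", "chrom"),
    anchor = vapply(keep, function(x) as.integer(x$anchor), 1L),
    strand = vapply(keep, `[[`, "", "strand"),
    core_start = vapply(keep, function(x) as.integer(x$core_start), 1L),
    core_width = K,
    core_score = vapply(keep, function(x) x$core_score, 1))
  attr(out, "dropped") <- dropped
  attr(out, "dropped_fraction") <- sum(dropped) / nrow(peaks)
  out
}

extract_summit_windows <- function(peaks, genome, halfwidth) {
  chrlen <- Biostrings::width(genome); names(chrlen) <- names(genome)
  seqs <- character(); chs <- character(); centers <- integer()
  dropped <- c(out_of_bounds = 0L)
  for (i in seq_len(nrow(peaks))) {
    chrom <- peaks$chrom[i]
    if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
    s <- extract_window(genome, chrom, peaks$summit[i], halfwidth)
    if (is.null(s)) { dropped["out_of_bounds"] <- dropped["out_of_bounds"] + 1L; next }
    seqs <- c(seqs, s); chs <- c(chs, chrom)
    centers <- c(centers, peaks$summit[i])
  }
  list(seq = seqs, chrom = chs, center = centers, dropped = dropped)
}

#' Choose the most discriminative version of the target motif
#'
#' Every candidate PPM version is converted to a log-odds PWM, each sequence
#' is summarised by its best both-strand hit score, and the version whose
#' scores best rank class 1 over class 2 (highest AUROC) is kept. This AUROC
#' is also the "original PWM" baseline reported alongside the fitted model.
#'
#' @param versions a [ppm], [pwm], or list of them.
#' @param seqs_a,seqs_b character vectors of summit-centred sequences of the
#'   two classes.
#' @param background,pseudocount log-odds conversion parameters.
#' @return list with `pwm` (the winning scanning PWM), `ppm` (its source PPM
#'   when available), `auroc`, `index`, and `auroc_all`.
#' @export
select_pwm_version <- function(versions, seqs_a, seqs_b,
                               background = rep(0.25, 4), pseudocount = 0.01) {
  if (inherits(versions, "ppm") || inherits(versions, "pwm"))
    versions <- list(versions)
  if (length(versions) == 0L) stop("empty version list")
  pwms <- lapply(versions, function(v)
    if (inherits(v, "ppm")) ppm_to_pwm(v, background, pseudocount) else v)
  labels <- c(rep(TRUE, length(seqs_a)), rep(FALSE, length(seqs_b)))
  aucs <- vapply(pwms, function(p) {
    sa <- best_scores(encode_seqs(seqs_a), pwm_weights(p))
    sb <- best_scores(encode_seqs(seqs_b), pwm_weights(p))
    folded_auroc(c(sa, sb), labels)
  }, 1)
  i <- which.max(aucs)
  list(pwm = pwms[[i]],
       ppm = if (inherits(versions[[i]], "ppm")) versions[[i]] else NULL,
       auroc = aucs[i], index = i, auroc_all = aucs)
}

#' Per-class probability matrices of the aligned core sites
#'
#' Estimates one PPM per class by counting nucleotide frequencies at each
#' position of the aligned K-length sites, as an interpretable companion to
#' the discriminative PWM.
#'
#' @param sites_a,sites_b character vectors of equal-length sites.
#' @param pseudocount additive count added to every cell before
#'   normalisation.
#' @return list of two [ppm]s.
#' @export
estimate_class_ppms <- function(sites_a, sites_b, pseudocount = 0) {
  one <- function(sites, nm) {
    codes <- encode_seqs(sites)
    K <- ncol(codes)
    counts <- matrix(pseudocount, 4, K)
    for (j in 1:4) counts[j, ] <- counts[j, ] + colSums(codes == j)
    cs <- colSums(counts)
    if (any(cs == 0)) stop("position with no A/C/G/T observation")
    ppm(sweep(counts, 2, cs, "/"), name = nm)
  }
  list(class1 = one(sites_a, "class1"), class2 = one(sites_b, "class2"))
}

#' Gini coefficient of a PWM's weight distribution
#'
#' The 4K weights are pooled, ordered by ascending absolute value, and the
#' Gini coefficient of the discrete Lorenz curve of absolute weights is
#' returned: 0 when all |weights| are equal, approaching 1 when a single
#' weight carries everything. Scale-invariant, so PWMs from different
#' learning methods are comparable; high Gini = few informative cells = a
#' simpler motif.
#'
#' @param x a [pwm] or numeric vector/matrix of weights.
#' @return Gini coefficient in \[0, 1).
#' @export
gini_coefficient <- function(x) {
  w <- abs(as.numeric(pwm_weights(x)))
  if (all(w == 0)) stop("Gini coefficient undefined for an all-zero PWM")
  w <- sort(w)
  m <- length(w)
  sum((2 * seq_len(m) - m - 1) * w) / (m * sum(w))
}
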