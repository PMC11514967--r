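## Peak sets: BED IO, unique/common partitioning, Jaccard distance,
## class rebalancing and genomic window extraction.
##
## All internal coordinates are 0-based half-open (the BED convention);
## 1-based coordinates appear only in human-readable reports.

#' ChIP-seq peak set
#'
#' @param chrom,start,end interval columns (0-based half-open).
#' @param summit 0-based absolute summit position; defaults to the interval
#'   midpoint.
#' @param genome_id genome build identifier, checked when two sets are
#'   combined.
#' @return data frame of class `"peak_set"`, sorted by (chrom, start).
#' @export
peak_set <- function(chrom, start, end, summit = NULL, genome_id = "genome") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0)) stop("negative start coordinate")
  if (any(end <= start)) stop("interval with end <= start")
  if (is.null(summit)) summit <- start + (end - start) %/% 2L
  summit <- as.integer(summit)
  if (any(summit < start | summit >= end))
    stop("summit outside its interval")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   summit = summit, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("peak_set", "data.frame"), genome_id = genome_id)
}

#' Read a BED / narrowPeak file as a peak set
#'
#' Requires at least 3 tab-separated columns (chrom, start, end; 0-based
#' half-open). With `summit_col` set (narrowPeak uses column 10, the summit
#' offset from the interval start; -1 means unknown), the summit is taken
#' from that column; otherwise it is the interval midpoint.
#'
#' @param path BED file path.
#' @param summit_col optional 1-based index of a summit-offset column.
#' @param genome_id genome build identifier to attach.
#' @return a [peak_set].
#' @export
read_bed <- function(path, summit_col = NULL, genome_id = "genome") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(peak_set(character(), integer(), integer(), genome_id = genome_id))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  bad <- which(nf < 3L)
  if (length(bad))
    stop("malformed BED line ", bad[1L], ": fewer than 3 tab-separated columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1L], ": non-integer coordinates")
  bad <- which(end <= start)
  if (length(bad))
    stop("malformed BED line ", bad[1L], ": end <= start")
  summit <- NULL
  if (!is.null(summit_col)) {
    if (any(nf < summit_col))
      stop("summit column ", summit_col, " absent on line ",
           which(nf < summit_col)[1L])
    off <- suppressWarnings(as.integer(vapply(fields, `[[`, "", summit_col)))
    if (any(is.na(off)))
      stop("non-integer summit offset on line ", which(is.na(off))[1L])
    summit <- ifelse(off >= 0L, start + off, start + (end - start) %/% 2L)
  }
  peak_set(chrom, start, end, summit, genome_id = genome_id)
}

#' Write a peak set as BED3 (+ summit offset as column 4)
#' @param x a [peak_set].
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  utils::write.table(
    data.frame(x$chrom, x$start, x$end, x$summit - x$start),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Distance between two 0-based half-open intervals (0 when overlapping).
interval_gap <- function(s1, e1, s2, e2) pmax(0L, pmax(s2 - e1, s1 - e2))

## For each peak of `a`, is some peak of `b` within `window_bp`?
matched_in <- function(a, b, window_bp) {
  out <- logical(nrow(a))
  for (ch in unique(a$chrom)) {
    ia <- which(a$chrom == ch)
    bb <- b[b$chrom == ch, , drop = FALSE]
    if (nrow(bb) == 0L) next
    out[ia] <- vapply(ia, function(i)
      any(interval_gap(a$start[i], a$end[i], bb$start, bb$end) <= window_bp),
      TRUE)
  }
  out
}

#' Partition two peak sets into experiment-unique and common peaks
#'
#' A peak of A is "common" iff some peak of B lies within `window_bp` of it
#' (interval distance, overlap counting as 0), and symmetrically for B; the
#' unique sets are the complements. Downstream analyses contrast the two
#' unique sets, since shared peaks carry no information about the binding
#' difference.
#'
#' @param a,b [peak_set]s on the same genome build.
#' @param window_bp matching window in bp (default 1000).
#' @return list of class `"peak_partition"` with `unique_a`, `unique_b`,
#'   `common` (matched peaks of both sets combined), `window_bp`, and the
#'   per-set matched counts.
#' @export
partition_peaks <- function(a, b, window_bp = 1000L) {
  if (!identical(attr(a, "genome_id"), attr(b, "genome_id")))
    stop("peak sets come from different genome builds")
  ma <- matched_in(a, b, window_bp)
  mb <- matched_in(b, a, window_bp)
  gid <- attr(a, "genome_id")
  sub <- function(x, keep) peak_set(x$chrom[keep], x$start[keep],
                                    x$end[keep], x$summit[keep],
                                    genome_id = gid)
  common <- rbind(as.data.frame(a)[ma, ], as.data.frame(b)[mb, ])
  structure(list(
    unique_a = sub(a, !ma), unique_b = sub(b, !mb),
    common = peak_set(common$chrom, common$start, common$end, common$summit,
                      genome_id = gid),
    matched_a = sum(ma), matched_b = sum(mb),
    window_bp = window_bp), class = "peak_partition")
}

## Merge overlapping-or-touching intervals; returns a plain data frame.
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  out <- df[1, c("chrom", "start", "end"), drop = FALSE]
  for (i in seq_len(nrow(df))[-1]) {
    j <- nrow(out)
    if (df$chrom[i] == out$chrom[j] && df$start[i] <= out$end[j]) {
      out$end[j] <- max(out$end[j], df$end[i])
    } else {
      out <- rbind(out, df[i, c("chrom", "start", "end")])
    }
  }
  out
}

#' Jaccard distance between two peak sets
#'
#' `D_J = 1 - |A intersect B| / |A union B|`. By default the counting unit is
#' merged peak intervals: the intersection is the merged set of peaks of
#' either experiment matched (within `window_bp`) by the other, and the union
#' the merged set of all peaks. `unit = "bp"` counts overlapping /
#' covered base pairs instead.
#'
#' @param a,b [peak_set]s.
#' @param window_bp matching window for the merged-peak unit.
#' @param unit `"merged_peaks"` (default) or `"bp"`.
#' @return distance in \[0, 1\].
#' @export
jaccard_distance <- function(a, b, window_bp = 1000L,
                             unit = c("merged_peaks", "bp")) {
  unit <- match.arg(unit)
  if (nrow(a) + nrow(b) == 0L) stop("Jaccard distance undefined: both sets empty")
  if (unit == "bp") {
    un <- merge_intervals(rbind(as.data.frame(a)[c("chrom", "start", "end")],
                                as.data.frame(b)[c("chrom", "start", "end")]))
    union_bp <- sum(un$end - un$start)
    inter_bp <- 0
    for (ch in unique(a$chrom)) {
      aa <- merge_intervals(as.data.frame(a)[a$chrom == ch, , drop = FALSE])
      bb <- merge_intervals(as.data.frame(b)[b$chrom == ch, , drop = FALSE])
      if (nrow(aa) == 0L || nrow(bb) == 0L) next
      for (i in seq_len(nrow(aa)))
        inter_bp <- inter_bp +
          sum(pmax(0L, pmin(aa$end[i], bb$end) - pmax(aa$start[i], bb$start)))
    }
    return(1 - inter_bp / union_bp)
  }
  ma <- matched_in(a, b, window_bp)
  mb <- matched_in(b, a, window_bp)
  matched <- rbind(as.data.frame(a)[ma, c("chrom", "start", "end")],
                   as.data.frame(b)[mb, c("chrom", "start", "end")])
  inter <- nrow(merge_intervals(matched))
  un <- nrow(merge_intervals(rbind(as.data.frame(a)[c("chrom", "start", "end")],
                                   as.data.frame(b)[c("chrom", "start", "end")])))
  1 - inter / un
}

#' Rebalance two classes to equal size
#'
#' Uniform-random removal (without replacement) from the larger class until
#' both have the size of the smaller; the smaller class is returned
#' unchanged. Strong class imbalance would bias the logistic fits
#' downstream.
#'
#' @param class1,class2 vectors or data frames (rows = sequences).
#' @param seed RNG seed making the removal reproducible.
#' @return list with rebalanced `class1` and `class2`.
#' @export
rebalance_classes <- function(class1, class2, seed = 1L) {
  n1 <- NROW(class1); n2 <- NROW(class2)
  if (n1 == 0L || n2 == 0L) stop("cannot rebalance an empty class")
  n <- min(n1, n2)
  take <- function(x, idx) {
    idx <- sort(idx)
    if (is.data.frame(x)) subset_rows(x, idx) else x[idx]
  }
  with_seed(seed, {
    if (n1 > n) class1 <- take(class1, sample.int(n1, n))
    if (n2 > n) class2 <- take(class2, sample.int(n2, n))
  })
  list(class1 = class1, class2 = class2)
}

#' Write a peak partition to disk
#'
#' Emits `unique_a.bed`, `unique_b.bed`, `common.bed` and a `summary.tsv`
#' with the peak counts and matching window.
#'
#' @param part a [partition_peaks] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_partition <- function(part, dir) {
  stopifnot(inherits(part, "peak_partition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(part$unique_a, file.path(dir, "unique_a.bed"))
  write_bed(part$unique_b, file.path(dir, "unique_b.bed"))
  write_bed(part$common, file.path(dir, "common.bed"))
  utils::write.table(
    data.frame(set = c("unique_a", "unique_b", "common",
                       "matched_a", "matched_b", "window_bp"),
               count = c(nrow(part$unique_a), nrow(part$unique_b),
                         nrow(part$common), part$matched_a,
                         part$matched_b, part$window_bp)),
    file.path(dir, "summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome)) # named character vector of chromosomes
    return(Biostrings::DNAStringSet(genome))
  stop("genome must be a DNAStringSet, FASTA path, or named character vector")
}

#' Extract a genomic window as an uppercase sequence
#'
#' @param genome `DNAStringSet`, FASTA path, or named character vector.
#' @param chrom chromosome name.
#' @param center 0-based coordinate.
#' @param halfwidth half window width; the window is
#'   `[center - halfwidth, center + halfwidth)`.
#' @return uppercase sequence string, or `NULL` when the window leaves the
#'   chromosome (the caller logs and discards).
#' @export
extract_window <- function(genome, chrom, center, halfwidth) {
  genome <- load_genome(genome)
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  L <- Biostrings::width(genome[chrom])
  s <- center - halfwidth; e <- center + halfwidth
  if (s < 0L || e > L) return(NULL)
  toupper(as.character(Biostrings::subseq(genome[[chrom]], s + 1L, e)))
}
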