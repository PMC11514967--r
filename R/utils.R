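#' @keywords internal
"_PACKAGE"

NUCS <- c("A", "C", "G", "T")

## Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Encode sequences (equal length) as an n x L integer matrix:
## A,C,G,T -> 1..4, anything else (N) -> 5.
encode_seqs <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("all sequences must have the same length")
  chars <- strsplit(seqs, "", fixed = TRUE)
  codes <- match(unlist(chars), NUCS, nomatch = 5L)
  matrix(codes, nrow = length(seqs), ncol = L, byrow = TRUE)
}

decode_codes <- function(codes) {
  letters5 <- c(NUCS, "N")
  apply(codes, 1L, function(r) paste(letters5[r], collapse = ""))
}

reverse_complement <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Area under the ROC curve of a score vector
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a random class-1
#' score exceeds a random class-2 score, with tied pairs counted 1/2.
#'
#' @param scores numeric scores, larger meaning "more class 1".
#' @param labels logical (TRUE = class 1), or a factor/vector with exactly two
#'   distinct values, the first sorted level taken as class 1.
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))
#' @export
auroc <- function(scores, labels) {
  pos <- as_class1(labels)
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

folded_auroc <- function(scores, labels) {
  a <- auroc(scores, labels)
  max(a, 1 - a)
}

## Coerce a two-class label vector to logical "is class 1".
as_class1 <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- if (is.factor(labels)) labels else factor(labels)
  if (nlevels(f) != 2L) stop("labels must have exactly two classes")
  f == levels(f)[1L]
}

## Row-subset a classed data frame (e.g. aligned_seqs) preserving its class
## and custom attributes.
subset_rows <- function(x, idx) {
  at <- attributes(x)
  out <- as.data.frame(x)[idx, , drop = FALSE]
  rownames(out) <- NULL
  for (nm in setdiff(names(at), c("row.names", "names", "class")))
    attr(out, nm) <- at[[nm]]
  class(out) <- at$class
  out
}

## Contiguous-bin region bookkeeping -----------------------------------------

## All n*(n+1)/2 contiguous regions of n bins, ordered by (first_bin, last_bin).
all_regions <- function(n_bins) {
  first <- rep(seq_len(n_bins), times = n_bins - seq_len(n_bins) + 1L)
  last <- unlist(lapply(seq_len(n_bins), function(i) i:n_bins))
  data.frame(first_bin = first, last_bin = last)
}

## Pick a region index by max criterion; ties -> widest region, then leftmost.
pick_region <- function(regions, crit) {
  width <- regions$last_bin - regions$first_bin
  ord <- order(-crit, -width, regions$first_bin)
  ord[1L]
}
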