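## PWM scanning engine.
##
## All scanning works on an integer code matrix (rows = sequences) so that a
## whole sequence set is scored with K vectorised lookups per strand rather
## than per-window loops. Windows containing an N score -Inf and can never be
## a best hit.

## Reverse complement of a 4 x K weight (or probability) matrix in A,C,G,T
## row order: complement = reverse rows, then reverse positions.
pwm_revcomp <- function(w) {
  w[4:1, rev(seq_len(ncol(w))), drop = FALSE]
}

## Forward-strand window scores: n x (L-K+1) matrix. `codes` is n x L with
## values 1..5 (5 = N).
window_scores_fwd <- function(codes, weights) {
  K <- ncol(weights)
  L <- ncol(codes)
  W <- L - K + 1L
  if (W < 1L) stop("sequences shorter than the motif")
  aug <- rbind(weights, rep(-Inf, K)) # row 5: N
  acc <- matrix(0, nrow(codes), W)
  for (k in seq_len(K)) {
    wk <- aug[, k][codes[, k:(k + W - 1L), drop = FALSE]]
    acc <- acc + matrix(wk, nrow(codes), W)
  }
  acc
}

## Both-strand window scores. The reverse-strand score at window start p is
## the score of the reverse complement of that window, i.e. a forward scan
## with the reverse-complemented PWM.
window_scores <- function(codes, weights, both_strands = TRUE) {
  fwd <- window_scores_fwd(codes, weights)
  if (!both_strands) return(list(fwd = fwd, rev = NULL, best = fwd))
  rev <- window_scores_fwd(codes, pwm_revcomp(weights))
  best <- pmax(fwd, rev)
  # pmax(-Inf, -Inf) is -Inf; NaN cannot arise because weights are finite
  list(fwd = fwd, rev = rev, best = best)
}

## Best both-strand score per sequence (-Inf when every window has an N).
best_scores <- function(codes, weights) {
  sc <- window_scores(codes, weights)$best
  do.call(pmax, as.data.frame(sc))
}

## Exact distribution of the forward PWM score under a 0-order background,
## by dynamic programming on weights discretised at `granularity`. Returns
## the smallest score s such that P(score >= s) <= pval (a FIMO-style hit
## threshold).
pwm_score_threshold <- function(weights, background = rep(0.25, 4),
                                pval = 1e-4, granularity = 1e-3) {
  stopifnot(abs(sum(background) - 1) < 1e-8, all(is.finite(weights)))
  iw <- round(weights / granularity)
  K <- ncol(iw)
  lo <- sum(apply(iw, 2, min)); hi <- sum(apply(iw, 2, max))
  n <- hi - lo + 1
  if (n > 5e7) stop("PWM score range too wide for the chosen granularity")
  ## p[i] = P(partial sum == lo_part + i - 1)
  p <- 1; off <- 0
  for (k in seq_len(K)) {
    cmin <- min(iw[, k]); cmax <- max(iw[, k])
    newlen <- length(p) + (cmax - cmin)
    np <- numeric(newlen)
    for (j in 1:4) {
      sh <- iw[j, k] - cmin
      np[(sh + 1):(sh + length(p))] <- np[(sh + 1):(sh + length(p))] +
        background[j] * p
    }
    p <- np; off <- off + cmin
  }
  tail_p <- rev(cumsum(rev(p))) # P(score >= off + i - 1)
  idx <- which(tail_p <= pval)
  if (length(idx) == 0L) return(Inf) # pval smaller than any achievable tail
  (off + idx[1L] - 1) * granularity
}

#' Best PWM hit in a sequence
#'
#' Scores every K-length window of `seq` on both strands (the reverse strand
#' scores the reverse complement of the window) and returns the best-scoring
#' hit. Windows containing an N are never hits. Ties are broken in favour of
#' the window whose midpoint is closest to `center`, then leftmost.
#'
#' @param seq a DNA string.
#' @param pwm a [pwm] (log-odds weights).
#' @param span optional integer pair: 1-based first and last sequence position
#'   the hit window may touch (the scan is restricted to windows fully inside
#'   it). Default: the whole sequence.
#' @param threshold minimum score for a window to count as a hit; `NULL`
#'   accepts any finite score.
#' @param center 1-based position used for tie-breaking (default: middle of
#'   the span).
#' @return `NULL` if no window passes, else a list with `offset` (0-based
#'   window start relative to the sequence start), `strand` (`"+"`/`"-"`) and
#'   `score`.
#' @export
scan_best_hit <- function(seq, pwm, span = NULL, threshold = NULL,
                          center = NULL) {
  w <- pwm_weights(pwm)
  K <- ncol(w)
  L <- nchar(seq)
  if (is.null(span)) span <- c(1L, L)
  span <- as.integer(span)
  if (span[1] < 1L || span[2] > L) stop("span outside the sequence")
  if (span[2] - span[1] + 1L < K) stop("span shorter than the motif")
  sub <- substr(seq, span[1], span[2])
  codes <- encode_seqs(sub)
  sc <- window_scores(codes, w)
  starts <- span[1]:(span[2] - K + 1L) # 1-based starts in full sequence
  fwd <- sc$fwd[1L, ]; rev <- sc$rev[1L, ]
  strand <- ifelse(fwd >= rev, "+", "-")
  score <- pmax(fwd, rev)
  ok <- is.finite(score)
  if (!is.null(threshold)) ok <- ok & score >= threshold
  if (!any(ok)) return(NULL)
  if (is.null(center)) center <- (span[1] + span[2]) / 2
  mid <- starts + (K - 1) / 2
  cand <- which(ok)
  cand <- cand[order(-score[cand], abs(mid[cand] - center), starts[cand])]
  i <- cand[1L]
  list(offset = starts[i] - 1L, strand = strand[i], score = score[i])
}
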