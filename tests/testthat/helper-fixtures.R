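## Shared fixtures built in code at test time.

## Random 0-order DNA strings.
random_dna <- function(n, len, seed = NULL, prob = rep(0.25, 4)) {
  gen <- function() vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
          collapse = ""), "")
  if (is.null(seed)) gen() else { set.seed(seed); gen() }
}

## Sharp PPM around a consensus (duplicated here so tests do not rely on the
## unexported internal).
test_ppm <- function(consensus, p = 0.9) {
  nucs <- c("A", "C", "G", "T")
  v <- match(strsplit(consensus, "")[[1]], nucs)
  probs <- matrix((1 - p) / 3, 4, length(v))
  probs[cbind(v, seq_along(v))] <- p
  ppm(probs, name = consensus)
}

## Brute-force AUROC over all class1 x class2 pairs (independent oracle).
pairwise_auroc <- function(scores, is1) {
  s1 <- scores[is1]; s2 <- scores[!is1]
  tot <- 0
  for (a in s1) for (b in s2)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s2))
}

## Brute-force best both-strand PWM hit by explicit window enumeration
## (independent of the vectorised scanner).
brute_best_hit <- function(seq, w) {
  nucs <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  K <- ncol(w); L <- nchar(seq)
  best <- -Inf
  for (p in 1:(L - K + 1)) {
    win <- strsplit(substr(seq, p, p + K - 1), "")[[1]]
    if (any(!win %in% nucs)) next
    fwd <- sum(w[cbind(match(win, nucs), 1:K)])
    rcw <- rev(unname(comp[win]))
    rev_ <- sum(w[cbind(match(rcw, nucs), 1:K)])
    best <- max(best, fwd, rev_)
  }
  best
}

## Bernoulli log-likelihood of a logistic model (intercept first).
logistic_loglik <- function(theta, X, y) {
  eta <- theta[1] + drop(X %*% theta[-1])
  sum(y * eta - log1p(exp(eta)))
}

## Independent optimisation oracle: deterministic coordinate-wise grid
## refinement (pattern search) of the logistic log-likelihood. Pure grid
## evaluation; never calls glm/glmnet.
grid_refine_loglik <- function(X, y, step = 1, iters = 60) {
  theta <- numeric(ncol(X) + 1)
  best <- logistic_loglik(theta, X, y)
  for (it in seq_len(iters)) {
    improved <- FALSE
    for (j in seq_along(theta)) {
      for (d in step * c(-2, -1, 1, 2)) {
        cand <- theta; cand[j] <- cand[j] + d
        ll <- logistic_loglik(cand, X, y)
        if (ll > best + 1e-12) { theta <- cand; best <- ll; improved <- TRUE }
      }
    }
    if (!improved) {
      step <- step / 2
      if (step < 1e-5) break
    }
  }
  list(theta = theta, loglik = best)
}

## Write lines to a temp file, return path.
tmpfile_with <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

## A small aligned two-class sequence set with a planted core at the centre.
toy_aligned <- function(n = 40, len = 200, core = "ACGTACGT", seed = 1) {
  set.seed(seed)
  half <- len %/% 2
  K <- nchar(core)
  core_start <- half + 1 - K %/% 2
  sq <- random_dna(2 * n, len)
  substr(sq, core_start, core_start + K - 1) <- core
  aligned_seqs(sq, rep(c("class1", "class2"), each = n),
               core_start = core_start, core_width = K)
}
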