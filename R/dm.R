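## Discriminative core-motif learning.
##
## The aligned K-length sites (plus optional flanks) of the two classes are
## one-hot encoded and an L1-penalised logistic regression is fitted:
## P(class1 | site) = sigmoid(sum_k sum_j a_kj s_kj). The coefficient matrix
## a is, by construction, a regular PWM — the discriminative PWM — whose
## score orders sequences exactly as the fitted class-1 probability does.
## Because the (penalised) logistic likelihood is convex, the fitted PWM is
## the optimal PWM for this aligned-site discrimination problem.

#' Extract the core site plus flanking nucleotides
#'
#' @param s an anchored [aligned_seqs].
#' @param n_flank number of flanking nucleotides on each side (0 = core
#'   only; 4 gives the "+8" variant used by default downstream).
#' @return character vector of `(K + 2 n_flank)`-length sites, `NA` where a
#'   flank would overflow the sequence (such rows are dropped by callers;
#'   attribute `n_dropped` counts them).
#' @export
extract_core_flank <- function(s, n_flank = 0L) {
  if (!is_anchored(s)) stop("core span absent: sequences are not anchored")
  from <- s$core_start - n_flank
  to <- s$core_start + s$core_width - 1L + n_flank
  ok <- from >= 1L & to <= nchar(s$seq)
  out <- rep(NA_character_, nrow(s))
  out[ok] <- substr(s$seq[ok], from[ok], to[ok])
  attr(out, "n_dropped") <- sum(!ok)
  out
}

## One-hot encode equal-length sites: n x (4L) binary matrix, position-major
## columns named like "p3.G". N rows encode as all-zero (contribute nothing).
one_hot_sites <- function(sites) {
  codes <- encode_seqs(sites)
  L <- ncol(codes); n <- nrow(codes)
  X <- matrix(0, n, 4L * L)
  for (k in seq_len(L)) for (j in 1:4)
    X[, (k - 1L) * 4L + j] <- as.numeric(codes[, k] == j)
  colnames(X) <- paste0("p", rep(seq_len(L), each = 4), ".",
                        rep(NUCS, L))
  X
}

#' Learn a discriminative PWM from two sets of aligned sites
#'
#' Fits the L1-penalised logistic model over one-hot encoded sites; the
#' coefficient matrix is returned as a PWM (`source = "discriminative"`).
#' The penalty level is chosen by internal 10-fold cross-validation
#' (deviance, lambda at the CV minimum) unless `lambda` is given;
#' `lambda = 0` gives the unpenalised maximum-likelihood fit.
#'
#' @param sites_a,sites_b equal-length aligned sites of class 1 and class 2.
#' @param seed RNG seed fixing the cross-validation folds.
#' @param lambda `"cv"` (default), or a single non-negative penalty value.
#' @param nfolds CV folds.
#' @return object of class `"discriminative_pwm"`: list with `pwm`,
#'   `intercept`, `lambda`, `site_length`, and `cv` (the lambda path:
#'   lambda, number of nonzero coefficients, CV deviance when applicable).
#' @export
fit_discriminative_pwm <- function(sites_a, sites_b, seed = 1L,
                                   lambda = "cv", nfolds = 10L) {
  if (length(sites_a) == 0L || length(sites_b) == 0L)
    stop("both classes must be non-empty")
  sites <- c(sites_a, sites_b)
  if (length(unique(nchar(sites))) != 1L)
    stop("all sites must have the same length")
  y <- c(rep(1, length(sites_a)), rep(0, length(sites_b)))
  X <- one_hot_sites(sites)
  L <- nchar(sites[1L])
  if (identical(lambda, "cv")) {
    foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), length(y))))
    cvfit <- glmnet::cv.glmnet(X, y, family = "binomial", foldid = foldid,
                               standardize = FALSE, thresh = 1e-9)
    lam <- cvfit$lambda.min
    beta <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
    cv <- data.frame(lambda = cvfit$lambda, nonzero = cvfit$nzero,
                     cv_deviance = cvfit$cvm)
  } else {
    lambda <- as.numeric(lambda)
    stopifnot(length(lambda) == 1L, lambda >= 0)
    ## decreasing path ending at the requested lambda (warm starts keep the
    ## coordinate descent accurate near 0)
    path <- sort(unique(c(0.25, 0.1, 0.05, 0.02, 0.01, 0.005, 0.002, 0.001,
                          lambda)), decreasing = TRUE)
    path <- path[path >= lambda]
    fit <- glmnet::glmnet(X, y, family = "binomial", lambda = path,
                          standardize = FALSE, thresh = 1e-12,
                          maxit = 1e6)
    lam <- lambda
    beta <- as.numeric(stats::coef(fit, s = lambda, exact = TRUE, x = X, y = y))
    cv <- data.frame(lambda = fit$lambda, nonzero = fit$df,
                     cv_deviance = NA_real_)
  }
  a <- matrix(beta[-1L], nrow = 4L) # 4 x L, position-major as encoded
  structure(list(pwm = pwm(a, source = "discriminative", name = "DM"),
                 intercept = beta[1L], lambda = lam, site_length = L,
                 cv = cv),
            class = "discriminative_pwm")
}

#' @export
print.discriminative_pwm <- function(x, ...) {
  nz <- sum(pwm_weights(x$pwm) != 0)
  cat("Discriminative PWM over", x$site_length, "positions;",
      nz, "of", 4L * x$site_length, "weights nonzero",
      sprintf("(lambda = %.4g)\n", x$lambda))
  invisible(x)
}

#' Discriminative-motif score of aligned sites
#'
#' The linear PWM score `sum_k a[nuc_k, k]` (no intercept): a monotone
#' surrogate of the fitted class-1 probability. N positions contribute 0.
#'
#' @param sites character vector of sites, or an anchored [aligned_seqs]
#'   (core + flank extracted to match the fitted site length).
#' @param dpwm a fitted [fit_discriminative_pwm] object (or bare [pwm]).
#' @return numeric score per site.
#' @export
dm_score <- function(sites, dpwm) {
  w <- if (inherits(dpwm, "discriminative_pwm")) pwm_weights(dpwm$pwm)
       else pwm_weights(dpwm)
  if (inherits(sites, "aligned_seqs")) {
    n_flank <- (ncol(w) - sites$core_width[1L]) %/% 2L
    sites <- extract_core_flank(sites, n_flank)
    if (anyNA(sites)) stop("some sites overflow the sequence window")
  }
  codes <- encode_seqs(sites)
  if (ncol(codes) != ncol(w))
    stop("site length ", ncol(codes), " does not match PWM length ", ncol(w))
  aug <- unname(rbind(w, rep(0, ncol(w)))) # N contributes 0
  sc <- numeric(nrow(codes))
  for (k in seq_len(ncol(w))) sc <- sc + aug[codes[, k], k]
  sc
}

## Log-odds score of fixed-length sites under a scanning PWM (site length
## must equal the PWM length; no scanning).
site_scores <- function(sites, w) {
  codes <- encode_seqs(sites)
  aug <- unname(rbind(w, rep(0, ncol(w))))
  sc <- numeric(nrow(codes))
  for (k in seq_len(ncol(w))) sc <- sc + aug[codes[, k], k]
  sc
}

#' Two-PPM baseline classifier
#'
#' The generative alternative to the discriminative PWM: per-class PPMs
#' (estimated on training sites only) are converted to log-odds PWMs and
#' combined in the logistic model
#' `P(1|s) = sigmoid(a + b1 PWM1(s) + b2 PWM2(s))`; the held-out AUROC is
#' returned.
#'
#' @param ppm1,ppm2 per-class [ppm]s (train-estimated).
#' @param train_sites,train_labels,test_sites,test_labels aligned sites and
#'   two-class labels of the two splits.
#' @param background,pseudocount log-odds conversion parameters.
#' @return held-out AUROC.
#' @export
two_ppm_baseline <- function(ppm1, ppm2, train_sites, train_labels,
                             test_sites, test_labels,
                             background = rep(0.25, 4), pseudocount = 0.01) {
  w1 <- pwm_weights(ppm_to_pwm(ppm1, background, pseudocount))
  w2 <- pwm_weights(ppm_to_pwm(ppm2, background, pseudocount))
  if (ncol(w1) != nchar(train_sites[1L]))
    stop("PPM length does not match site length")
  tr <- data.frame(y = as.numeric(as_class1(train_labels)),
                   s1 = site_scores(train_sites, w1),
                   s2 = site_scores(train_sites, w2))
  fit <- stats::glm(y ~ s1 + s2, family = stats::binomial(), data = tr)
  te <- data.frame(s1 = site_scores(test_sites, w1),
                   s2 = site_scores(test_sites, w2))
  pred <- stats::predict(fit, newdata = te)
  auroc(pred, test_labels)
}
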