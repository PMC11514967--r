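## Global model: feature assembly, LASSO-logistic fit, ablation, importance.

#' Stratified train/test split
#'
#' @param labels two-class label vector.
#' @param train_fraction fraction of each class assigned to training
#'   (default 0.70).
#' @param seed RNG seed.
#' @return logical vector, `TRUE` = training row.
#' @export
split_train_test <- function(labels, train_fraction = 0.70, seed = 1L) {
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("labels must have exactly two classes")
  sizes <- table(f)
  if (any(sizes < 2L)) stop("each class needs at least 2 sequences")
  if (any(sizes < 10L))
    warning("fewer than 10 sequences in a class; estimates will be unstable")
  train <- logical(length(f))
  with_seed(seed, {
    for (lv in levels(f)) {
      idx <- which(f == lv)
      n_tr <- round(length(idx) * train_fraction)
      train[sample(idx, n_tr)] <- TRUE
    }
  })
  train
}

#' Fit the global LASSO-logistic model over a feature table
#'
#' `P(1|s) = sigmoid(a DM(s) + sum_i b_i NE_i(s) + sum_j c_j CF_j(s))`,
#' fitted with an L1 penalty on the training rows; columns are standardised
#' internally (training statistics), and the penalty is chosen by 10-fold
#' cross-validated deviance (lambda at the minimum). Constant columns are
#' dropped with a warning.
#'
#' @param x numeric feature matrix (all rows), columns named.
#' @param labels two-class labels (all rows; class 1 = first level).
#' @param train logical training-row indicator.
#' @param column_type character vector: `"DM"`, `"NE"` or `"CF"` per column.
#' @param seed RNG seed fixing the CV folds.
#' @param nfolds CV folds.
#' @return object of class `"global_fit"`: coefficients at the chosen
#'   lambda, the whole lambda path, and column metadata.
#' @export
fit_global <- function(x, labels, train, column_type, seed = 1L,
                       nfolds = 10L) {
  y <- as.numeric(as_class1(labels))
  stopifnot(ncol(x) == length(column_type))
  keep <- apply(x[train, , drop = FALSE], 2, function(v) stats::sd(v) > 0)
  if (!all(keep))
    warning("dropping ", sum(!keep), " constant column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  if (sum(keep) < 2L) stop("need at least 2 non-constant feature columns")
  xk <- x[, keep, drop = FALSE]
  foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), sum(train))))
  cvfit <- glmnet::cv.glmnet(xk[train, , drop = FALSE], y[train],
                             family = "binomial", foldid = foldid,
                             standardize = TRUE, thresh = 1e-9)
  ## conservative CV choice (largest lambda within 1 SE of the deviance
  ## minimum): keeps the null model honest when no feature carries signal
  beta_k <- as.numeric(stats::coef(cvfit, s = "lambda.1se"))[-1L]
  beta <- numeric(ncol(x)); beta[keep] <- beta_k
  names(beta) <- colnames(x)
  structure(list(
    beta = beta,
    intercept = as.numeric(stats::coef(cvfit, s = "lambda.1se"))[1L],
    lambda = cvfit$lambda.1se,
    column_type = stats::setNames(column_type, colnames(x)),
    kept = keep,
    path = cvfit$glmnet.fit,
    cv = data.frame(lambda = cvfit$lambda, nonzero = cvfit$nzero,
                    cv_deviance = cvfit$cvm)),
    class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat("LASSO-logistic model:", sum(x$beta != 0), "of", length(x$beta),
      "coefficients nonzero at lambda =", signif(x$lambda, 3), "\n")
  invisible(x)
}

## Linear predictor with optional group/variable ablation (coefficients set
## to zero, no retraining).
model_scores <- function(fit, x, ablate_groups = NULL, zero_vars = NULL,
                         beta = NULL, intercept = NULL) {
  if (is.null(beta)) beta <- fit$beta
  if (is.null(intercept)) intercept <- fit$intercept
  if (!is.null(ablate_groups))
    beta[fit$column_type[names(beta)] %in% ablate_groups] <- 0
  if (!is.null(zero_vars)) beta[zero_vars] <- 0
  drop(x %*% beta) + intercept
}

#' AUROC after ablating a variable group
#'
#' Sets the fitted coefficients of one feature group (`"DM"`, `"NE"` or
#' `"CF"`) to zero — no retraining — re-scores the given rows and returns
#' the AUROC. The drop relative to the full model measures the group's
#' importance.
#'
#' @param fit a [fit_global] object.
#' @param x feature matrix rows to score (typically the test rows).
#' @param labels their labels.
#' @param group one or more of `"DM"`, `"NE"`, `"CF"`.
#' @return AUROC of the ablated model.
#' @export
ablate <- function(fit, x, labels, group) {
  if (!all(group %in% c("DM", "NE", "CF"))) stop("unknown ablation group")
  sc <- model_scores(fit, x, ablate_groups = group)
  if (stats::sd(sc) == 0) return(0.5) # constant score: no ranking
  auroc(sc, labels)
}

#' Ablation importance of individual variables
#'
#' Takes the lambda-path model whose nonzero-coefficient count is closest to
#' `n_keep` (warning when the path never gets there) and measures each kept
#' variable by the test-AUROC difference between that model and the same
#' model with the variable's coefficient set to zero. Variables at zero in
#' that model have importance exactly 0.
#'
#' @param fit a [fit_global] object.
#' @param x,labels test rows and labels.
#' @param n_keep target number of nonzero coefficients (default 10).
#' @return data frame ranked by decreasing `delta_auroc`, with the model
#'   AUROC and chosen lambda as attributes.
#' @export
variable_importance <- function(fit, x, labels, n_keep = 10L) {
  path <- fit$path
  df <- path$df
  if (max(df) < n_keep)
    warning("lambda path never reaches ", n_keep,
            " nonzero coefficients; using the densest model (", max(df), ")")
  i <- which.min(abs(df - n_keep))
  lam <- path$lambda[i]
  beta_k <- as.numeric(path$beta[, i])
  beta <- numeric(length(fit$beta)); beta[fit$kept] <- beta_k
  names(beta) <- names(fit$beta)
  a0 <- path$a0[i]
  full_sc <- model_scores(fit, x, beta = beta, intercept = a0)
  full_auc <- auroc(full_sc, labels)
  nz <- which(beta != 0)
  delta <- stats::setNames(numeric(length(beta)), names(beta))
  for (v in nz) {
    sc <- model_scores(fit, x, beta = beta, intercept = a0,
                       zero_vars = names(beta)[v])
    delta[v] <- full_auc - (if (stats::sd(sc) == 0) 0.5 else auroc(sc, labels))
  }
  out <- data.frame(variable = names(beta),
                    type = unname(fit$column_type[names(beta)]),
                    coefficient = unname(beta),
                    delta_auroc = unname(delta),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$delta_auroc, -abs(out$coefficient)), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "model_auroc") <- full_auc
  attr(out, "lambda") <- lam
  attr(out, "n_nonzero") <- length(nz)
  out
}

#' K-means clustering of importance profiles
#'
#' Importance profiles are the 3-vectors of test-AUROC losses from ablating
#' the DM, NE and CF groups; clustering them across many paired-experiment
#' runs summarises the prevailing genomic strategies. An elbow curve (total
#' within-cluster sum of squares over k) is attached for choosing k.
#'
#' @param profiles numeric matrix, rows = runs, 3 columns (DM, NE, CF
#'   losses).
#' @param k number of clusters (default 3).
#' @param seed RNG seed.
#' @param nstart random restarts (default 25).
#' @return `stats::kmeans` result with an `elbow` attribute
#'   (data frame k, tot_withinss).
#' @export
cluster_importance_profiles <- function(profiles, k = 3L, seed = 1L,
                                        nstart = 25L) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < k) stop("fewer profiles than clusters")
  km <- with_seed(seed, stats::kmeans(profiles, centers = k,
                                      nstart = nstart))
  kmax <- min(8L, nrow(unique(profiles)))
  elbow <- with_seed(seed + 1L, data.frame(
    k = seq_len(kmax),
    tot_withinss = vapply(seq_len(kmax), function(kk)
      stats::kmeans(profiles, centers = kk, nstart = nstart)$tot.withinss,
      1)))
  attr(km, "elbow") <- elbow
  km
}

#' Exact two-sided binomial sign test
#'
#' Tests `k` successes out of `n` against p = 0.5 with the
#' minimum-likelihood-sum two-sided convention (as used to test whether
#' identified co-factors are more often over-expressed in the cell type they
#' are associated with).
#'
#' @param k number of successes.
#' @param n number of trials.
#' @return two-sided p-value.
#' @examples
#' binomial_sign_test(149, 194) # ~3e-14
#' @export
binomial_sign_test <- function(k, n) {
  if (n == 0L) stop("n must be positive")
  stopifnot(k >= 0L, k <= n)
  stats::binom.test(k, n, p = 0.5)$p.value
}
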