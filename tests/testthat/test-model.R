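## Global model assembly, AUROC, ablation, importance, clustering.

## Small feature-table fixture: one strong column + noise.
toy_table <- function(n = 200, p_noise = 8, strength = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x <- cbind(signal = rnorm(n) + strength * y,
             matrix(rnorm(n * p_noise), n,
                    dimnames = list(NULL, paste0("noise", 1:p_noise))))
  labels <- factor(ifelse(y, "c1", "c2"), levels = c("c1", "c2"))
  list(x = x, labels = labels,
       types = c("DM", rep(c("NE", "CF"), length.out = p_noise)))
}

test_that("split_train_test stratifies and reproduces under seed", {
  labels <- rep(c("a", "b"), each = 1000)
  tr <- split_train_test(labels, seed = 5)
  expect_equal(sum(tr[1:1000]), 700)
  expect_equal(sum(tr[1001:2000]), 700)
  expect_identical(tr, split_train_test(labels, seed = 5))
  expect_false(identical(tr, split_train_test(labels, seed = 6)))
  expect_warning(split_train_test(rep(c("a", "b"), each = 5)), "unstable")
  expect_error(split_train_test(rep(c("a", "b"), c(1, 30))), "at least 2")
})

test_that("auroc matches the exhaustive pairwise oracle", {
  expect_equal(auroc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  set.seed(83)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    sc <- sample(round(rnorm(n), 1)) # ties likely
    is1 <- sample(c(TRUE, FALSE), n, TRUE)
    if (length(unique(is1)) < 2) next
    expect_equal(auroc(sc, is1), pairwise_auroc(sc, is1))
  }
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("a single separating feature is found; noise stays out", {
  tt <- toy_table(strength = 4, seed = 7)
  tr <- split_train_test(tt$labels, seed = 1)
  fit <- fit_global(tt$x, tt$labels, tr, tt$types, seed = 1)
  expect_gt(abs(fit$beta["signal"]), 0)
  sc <- motifcontrast:::model_scores(fit, tt$x[!tr, ])
  expect_gt(auroc(sc, tt$labels[!tr]), 0.95)
})

test_that("all-noise tables give chance AUROC and near-empty models", {
  aucs <- c(); frac_nz <- c()
  for (seed in 1:5) {
    tt <- toy_table(strength = 0, seed = seed)
    tr <- split_train_test(tt$labels, seed = seed)
    fit <- fit_global(tt$x, tt$labels, tr, tt$types, seed = seed)
    sc <- motifcontrast:::model_scores(fit, tt$x[!tr, ])
    aucs <- c(aucs, if (stats::sd(sc) == 0) 0.5 else auroc(sc, tt$labels[!tr]))
    frac_nz <- c(frac_nz, mean(fit$beta != 0))
  }
  expect_gt(mean(aucs), 0.35); expect_lt(mean(aucs), 0.65)
  expect_lt(mean(frac_nz), 0.25)
})

test_that("constant columns are dropped with a warning", {
  tt <- toy_table(seed = 11)
  x <- cbind(tt$x, flat = rep(1, nrow(tt$x)))
  tr <- split_train_test(tt$labels, seed = 1)
  expect_warning(
    fit <- fit_global(x, tt$labels, tr, c(tt$types, "CF"), seed = 1),
    "constant")
  expect_equal(unname(fit$beta["flat"]), 0)
})

test_that("ablation identities hold exactly", {
  tt <- toy_table(strength = 3, seed = 13)
  tr <- split_train_test(tt$labels, seed = 2)
  fit <- fit_global(tt$x, tt$labels, tr, tt$types, seed = 2)
  xt <- tt$x[!tr, ]; yt <- tt$labels[!tr]
  full <- auroc(motifcontrast:::model_scores(fit, xt), yt)
  ## ablating a group whose coefficients are all zero changes nothing
  for (g in c("NE", "CF")) {
    if (all(fit$beta[fit$column_type == g] == 0))
      expect_identical(ablate(fit, xt, yt, g), full)
  }
  ## ablating all three groups leaves a constant score: chance
  expect_equal(ablate(fit, xt, yt, c("DM", "NE", "CF")), 0.5)
  ## the importance-profile identity: profile = full - ablated, exactly
  prof <- c(full - ablate(fit, xt, yt, "DM"),
            full - ablate(fit, xt, yt, "NE"),
            full - ablate(fit, xt, yt, "CF"))
  expect_identical(prof[1], full - ablate(fit, xt, yt, "DM"))
  expect_error(ablate(fit, xt, yt, "XX"), "unknown")
})

test_that("variable importance ranks the dominant variable first", {
  tt <- toy_table(strength = 3, p_noise = 12, seed = 17)
  tr <- split_train_test(tt$labels, seed = 3)
  fit <- fit_global(tt$x, tt$labels, tr, tt$types, seed = 3)
  imp <- variable_importance(fit, tt$x[!tr, ], tt$labels[!tr], n_keep = 5)
  expect_equal(imp$variable[1], "signal")
  expect_gt(imp$delta_auroc[1], 0.2)
  ## zero-coefficient variables have importance exactly 0
  expect_true(all(imp$delta_auroc[imp$coefficient == 0] == 0))
  ## requesting more nonzeros than the path reaches warns
  expect_warning(variable_importance(fit, tt$x[!tr, ], tt$labels[!tr],
                                     n_keep = 500L), "never reaches")
})

test_that("duplicated columns: LASSO keeps a sparse representative set", {
  set.seed(19)
  n <- 200
  y <- rep(c(TRUE, FALSE), each = n / 2)
  v <- rnorm(n) + 2 * y
  x <- cbind(dup1 = v, dup2 = v, matrix(rnorm(n * 4), n,
             dimnames = list(NULL, paste0("z", 1:4))))
  labels <- factor(ifelse(y, "c1", "c2"))
  tr <- split_train_test(labels, seed = 4)
  fit <- fit_global(x, labels, tr, rep("CF", 6), seed = 4)
  ## the correlated pair carries the signal without sign-opposed inflation
  b <- fit$beta[c("dup1", "dup2")]
  expect_gte(sum(b != 0), 1)
  expect_true(all(b >= 0)) # no cancelling pair
  sc <- motifcontrast:::model_scores(fit, x[!tr, ])
  expect_gt(auroc(sc, labels[!tr]), 0.85)
})

test_that("importance-profile clustering recovers planted regimes", {
  fx <- importance_profile_fixtures(k = 3, n = 90, noise = 0, seed = 2)
  km <- cluster_importance_profiles(fx$profiles, k = 3, seed = 1)
  tab <- table(km$cluster, fx$labels)
  expect_equal(sum(apply(tab, 2, max)), 90) # perfect up to relabelling
  ## moderate noise: high agreement
  fx2 <- importance_profile_fixtures(k = 3, n = 120, noise = 0.015, seed = 3)
  km2 <- cluster_importance_profiles(fx2$profiles, k = 3, seed = 1)
  tab2 <- table(km2$cluster, fx2$labels)
  expect_gt(sum(apply(tab2, 2, max)) / 120, 0.9)
  ## permuting rows permutes assignments identically
  perm <- sample(nrow(fx$profiles))
  km3 <- cluster_importance_profiles(fx$profiles[perm, ], k = 3, seed = 1)
  tab3 <- table(km3$cluster, fx$labels[perm])
  expect_equal(sum(apply(tab3, 2, max)), 90)
  expect_s3_class(attr(km, "elbow"), "data.frame")
  expect_error(cluster_importance_profiles(fx$profiles[1:2, ], k = 3),
               "fewer")
})

test_that("binomial sign test is exact and two-sided", {
  expect_equal(binomial_sign_test(10, 20), 1.0)
  expect_equal(binomial_sign_test(0, 10), binomial_sign_test(10, 10))
  ## cross-check against direct tail summation for an asymmetric case
  p_direct <- sum(dbinom(0:2, 12, 0.5)[dbinom(0:2, 12, 0.5) <=
                                       dbinom(2, 12, 0.5)]) +
    sum(dbinom(10:12, 12, 0.5))
  expect_equal(binomial_sign_test(2, 12), p_direct, tolerance = 1e-12)
  expect_error(binomial_sign_test(1, 0), "positive")
})
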