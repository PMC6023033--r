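toy_matrix <- function(n = 40, p = 6, seed = 3) {
  set.seed(seed)
  x <- matrix(rpois(n * p, 2), n, p,
              dimnames = list(paste0("c", 1:n), paste0("0:[F", 1:p, "]")))
  x
}

test_that("pca_filter importance matches an independent prcomp computation", {
  set.seed(11)
  n <- 30
  strong <- rnorm(n, sd = 4)
  x <- cbind(s1 = strong, s2 = strong + rnorm(n, sd = 0.05),
             n1 = rnorm(n, sd = 0.3), n2 = rnorm(n, sd = 0.3),
             const = rep(2, n))
  sel <- pca_filter(x, variance_cutoff = 0.95, importance_rule = "mean")

  # oracle: prcomp loadings weighted by variance fractions
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  k <- which(cumsum(vf) >= 0.95 - 1e-9)[1]
  imp_oracle <- as.numeric(abs(pr$rotation[, 1:k, drop = FALSE]) %*% vf[1:k])
  expect_equal(unname(sel$importance), imp_oracle, tolerance = 1e-8)

  # both correlated informative columns in, constant column out
  expect_true(all(c("s1", "s2") %in% sel$selected))
  expect_false("const" %in% sel$selected)
  expect_equal(unname(sel$importance["const"]), 0, tolerance = 1e-10)
})

test_that("pca_filter keeps every non-constant column at cutoff 1 with rule nonzero", {
  x <- toy_matrix()
  x <- cbind(x, `0:[const]` = 5L)
  sel <- pca_filter(x, variance_cutoff = 1, importance_rule = "nonzero")
  expect_setequal(sel$selected, setdiff(colnames(x), "0:[const]"))

  expect_error(pca_filter(matrix(1, 5, 3)), "degenerate")
})

test_that("GA search equals exhaustive search on 6-feature toy problems", {
  for (seed in 1:3) {
    x <- toy_matrix(seed = seed)
    # labels driven by two of the six columns
    y <- ifelse(x[, 2] + x[, 5] + rnorm(nrow(x), sd = 0.5) > 4,
                "active", "inactive")
    if (length(unique(y)) < 2) next
    spec <- small_spec()
    res <- ga_svm_search(x, y, spec = spec,
                         ga = ga_config(population = 40, max_iter = 30,
                                        stall_stop = 15),
                         seed = seed)
    fold_id <- sigscreen:::cv_folds(sigscreen:::normalize_labels(y),
                                    min(spec$folds, length(y)), seed,
                                    "classification")
    best_exhaustive <- -Inf
    for (mask in 1:63) {
      sel <- which(bitwAnd(mask, 2^(0:5)) > 0)
      f <- sigscreen:::subset_fitness(x[, sel, drop = FALSE],
                                      sigscreen:::normalize_labels(y),
                                      fold_id, "classification",
                                      spec$cost_grid, spec$nu)
      best_exhaustive <- max(best_exhaustive, f$fitness)
    }
    expect_equal(1 - res$models[[1]]$cv_error, best_exhaustive,
                 label = paste("seed", seed))
  }
})

test_that("elitism makes the best fitness non-decreasing over generations", {
  x <- toy_matrix(seed = 8)
  y <- ifelse(x[, 1] > 1, "active", "inactive")
  res <- ga_svm_search(x, y, spec = small_spec(),
                       ga = ga_config(population = 12, max_iter = 10,
                                      stall_stop = 10), seed = 2)
  expect_true(all(diff(res$history) >= 0))
})

test_that("identical seeds reproduce the identical ensemble", {
  lib <- generate_library(planted_rule(), n = 60, active_fraction = 0.2, seed = 4)
  fit1 <- ga_svm_search(build_matrix(lib), library_classes(lib),
                        spec = small_spec(), ga = small_ga(), seed = 7)
  fit2 <- ga_svm_search(build_matrix(lib), library_classes(lib),
                        spec = small_spec(), ga = small_ga(), seed = 7)
  expect_identical(lapply(fit1$models, `[[`, "features"),
                   lapply(fit2$models, `[[`, "features"))
  expect_identical(lapply(fit1$models, `[[`, "w"),
                   lapply(fit2$models, `[[`, "w"))
})

test_that("a deterministic planted rule is recovered with zero CV error", {
  lib <- generate_library(planted_rule(), n = 150, active_fraction = 0.15, seed = 21)
  dm <- build_matrix(lib)
  pca <- pca_filter(dm)
  res <- ga_svm_search(dm, library_classes(lib), pca = pca,
                       spec = small_spec(), ga = small_ga(), seed = 21)
  expect_equal(res$models[[1]]$cv_error, 0)
  for (m in res$models)
    expect_true(any(grepl("[S]", m$features, fixed = TRUE)))
})

test_that("stratified fold assignment is a pure function of seed and labels", {
  y <- rep(c("active", "inactive"), c(15, 85))
  f1 <- sigscreen:::cv_folds(y, 10, 42, "classification")
  f2 <- sigscreen:::cv_folds(y, 10, 42, "classification")
  f3 <- sigscreen:::cv_folds(y, 10, 43, "classification")
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  # stratification: every fold receives 1-2 of the 15 actives
  per_fold <- table(f1[y == "active"])
  expect_true(all(per_fold >= 1 & per_fold <= 2))
})

test_that("nu-SVR recovers a noiseless linear response as cost grows", {
  set.seed(6)
  x <- matrix(runif(300, 0, 3), 100, 3,
              dimnames = list(NULL, c("0:[A]", "0:[B]", "0:[C]")))
  y <- 0.8 * x[, 1] - 0.5 * x[, 2] + 0.1
  rmse_at <- function(cost) {
    m <- sigscreen:::svm_train_metric(x, y, "regression", cost, nu = 0.2)
    m$metric
  }
  expect_lt(rmse_at(1), rmse_at(0.01))
  expect_lt(rmse_at(1), 0.05)
})

test_that("evaluate_model computes accuracy, ROC and trapezoid AUC", {
  # perfectly separated scores
  sep <- evaluate_model(c(3, 2.5, 2, -1, -2), c("active", "active", "active",
                                                "inactive", "inactive"))
  expect_equal(sep$auc, 1)
  expect_equal(sep$accuracy, 1)

  # 4 TP + 3 FP at threshold zero reproduces the 4/7 precision arithmetic
  ev <- evaluate_model(rep(1, 7), c(rep("active", 4), rep("inactive", 3)))
  expect_equal(ev$accuracy, 4 / 7, tolerance = 1e-12)
  expect_equal(ev$tp, 4); expect_equal(ev$fp, 3)
  expect_equal(ev$tn, 0); expect_equal(ev$fn, 0)

  expect_error(evaluate_model(c(1, 2), c("active", "active")), "single class")

  # agreement with an independent ROC implementation
  skip_if_not_installed("pROC")
  set.seed(9)
  for (k in 1:20) {
    sc <- rnorm(30)
    y <- sample(rep(c("active", "inactive"), 15))
    mine <- evaluate_model(sc, y)$auc
    theirs <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = sc, levels = c("inactive", "active"),
      direction = "<", quiet = TRUE)))
    expect_equal(mine, theirs, tolerance = 1e-10)
  }
})

test_that("random scores on balanced labels give chance-level AUC", {
  set.seed(31)
  aucs <- replicate(2000, {
    sc <- rnorm(20)
    y <- rep(c("active", "inactive"), 10)
    evaluate_model(sc, y)$auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})
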