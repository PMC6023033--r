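#' PCA-based descriptor pre-filtering
#'
#' Reduces the Signature vocabulary before the GA-SVM search.  The count
#' matrix is column-centered and the covariance eigendecomposed; principal
#' components are retained up to `variance_cutoff` cumulative variance, and
#' each descriptor's importance is the sum over retained components of its
#' absolute loading weighted by the component's variance fraction.  The
#' default rule keeps descriptors whose importance reaches the mean
#' importance; `"nonzero"` keeps every descriptor with any loading on the
#' retained components (a constant column always scores zero and is never
#' selected).
#'
#' @param dm a `sig_matrix` (or plain numeric matrix).
#' @param variance_cutoff cumulative variance fraction in (0, 1] retained.
#' @param importance_rule `"mean"` or `"nonzero"`.
#' @return an object of class `sig_pca`: list with `selected` (column
#'   keys), `selected_idx`, `importance` (named, all columns),
#'   `n_components`, `variance_cutoff`, `importance_rule`.
#' @export
pca_filter <- function(dm, variance_cutoff = 0.95,
                       importance_rule = c("mean", "nonzero")) {
  importance_rule <- match.arg(importance_rule)
  assert_that(variance_cutoff > 0 && variance_cutoff <= 1,
              "variance_cutoff must be in (0, 1]")
  x <- if (inherits(dm, "sig_matrix")) dm$counts else dm
  assert_that(nrow(x) >= 2L, "need at least 2 compounds for PCA")
  xc <- scale(x, center = TRUE, scale = FALSE)
  cv <- crossprod(xc) / (nrow(x) - 1L)
  eig <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  total <- sum(vals)
  if (total <= .Machine$double.eps) stop("degenerate descriptor matrix: rank 0",
                                         call. = FALSE)
  varfrac <- vals / total
  k <- which(cumsum(varfrac) >= variance_cutoff - 1e-9)[1L]
  importance <- as.numeric(abs(eig$vectors[, seq_len(k), drop = FALSE]) %*%
                             varfrac[seq_len(k)])
  names(importance) <- colnames(x)
  sel <- switch(importance_rule,
                mean = importance >= mean(importance),
                nonzero = importance > 1e-12)
  assert_that(any(sel), "PCA filter selected no descriptors")
  structure(list(selected = colnames(x)[sel],
                 selected_idx = which(sel),
                 importance = importance,
                 n_components = k,
                 variance_cutoff = variance_cutoff,
                 importance_rule = importance_rule),
            class = "sig_pca")
}

#' @export
print.sig_pca <- function(x, ...) {
  cat(sprintf("<sig_pca: %d of %d descriptors selected (%d components, cutoff %.2f, rule '%s')>\n",
              length(x$selected), length(x$importance), x$n_components,
              x$variance_cutoff, x$importance_rule))
  invisible(x)
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the published screening protocol: elitism rate 0.7,
#' crossover rate 0.8, mutation rate 0.1, population 1000, at most 1000
#' generations, stopping after 100 generations without improvement.
#' Operator semantics mirror binary-GA convention: single-point crossover
#' applied per offspring with probability `crossover`, single random bit
#' flip per individual with probability `mutation`, and the top
#' `round(elitism * population)` chromosomes carried over unchanged.
#'
#' @param elitism,crossover,mutation rates in `[0, 1]`.
#' @param population number of chromosomes per generation.
#' @param max_iter maximum generations.
#' @param stall_stop stop after this many generations without improvement.
#' @export
ga_config <- function(elitism = 0.7, crossover = 0.8, mutation = 0.1,
                      population = 1000L, max_iter = 1000L, stall_stop = 100L) {
  for (r in c(elitism, crossover, mutation))
    assert_that(r >= 0 && r <= 1, "GA rates must be in [0, 1]")
  assert_that(population >= 2L, "population must be >= 2")
  structure(list(elitism = elitism, crossover = crossover, mutation = mutation,
                 population = as.integer(population),
                 max_iter = as.integer(max_iter),
                 stall_stop = as.integer(stall_stop)),
            class = "sig_ga_config")
}

#' Linear SVM specification
#'
#' Soft-margin linear support vector machines: C-classification searched
#' over the cost grid (default 0.01 to 1 in steps of 0.01), nu-regression
#' with nu = 0.2 over the same grid; 10-fold cross-validation.
#'
#' @param task `"classification"` or `"regression"`.
#' @param cost_grid candidate cost values.
#' @param nu nu parameter for regression.
#' @param folds cross-validation folds.
#' @export
svm_spec <- function(task = c("classification", "regression"),
                     cost_grid = seq(0.01, 1, by = 0.01), nu = 0.2,
                     folds = 10L) {
  task <- match.arg(task)
  assert_that(all(cost_grid > 0), "costs must be positive")
  structure(list(task = task, kernel = "linear", cost_grid = cost_grid,
                 nu = nu, folds = as.integer(folds)),
            class = "sig_svm_spec")
}

# Stratified (classification) or shuffled (regression) fold assignment.
# A pure function of (y, folds, seed): identical inputs give identical folds.
cv_folds <- function(y, folds, seed, task) {
  n <- length(y)
  fold_id <- integer(n)
  with_seed(seed, {
    if (task == "classification") {
      for (cl in unique(y)) {
        idx <- which(y == cl)
        idx <- idx[sample.int(length(idx))]
        fold_id[idx] <- rep_len(seq_len(folds), length(idx))
      }
    } else {
      idx <- sample.int(n)
      fold_id[idx] <- rep_len(seq_len(folds), n)
    }
  })
  fold_id
}

# Fit a linear SVM and extract the linear decision function (w, b) with the
# convention that a positive score means the active (first-level) class.
fit_linear_svm <- function(x, y, task, cost, nu) {
  if (task == "classification") {
    m <- e1071::svm(x, factor(y, levels = c("active", "inactive")),
                    type = "C-classification", kernel = "linear",
                    cost = cost, scale = FALSE)
  } else {
    m <- e1071::svm(x, y, type = "nu-regression", kernel = "linear",
                    cost = cost, nu = nu, scale = FALSE)
  }
  w <- as.numeric(crossprod(m$coefs, m$SV))
  b <- -m$rho
  if (task == "classification") {
    # libsvm orients the decision value toward the first class seen in the
    # data; normalize so positive always means active
    dv <- stats::predict(m, x[1L, , drop = FALSE], decision.values = TRUE)
    nm <- colnames(attr(dv, "decision.values"))[1L]
    if (!startsWith(nm, "active")) { w <- -w; b <- -b }
  }
  names(w) <- colnames(x)
  list(w = w, b = b, fit = m)
}

svm_decision <- function(w, b, x) as.numeric(x %*% w + b)

# Cross-validated and training metrics for one feature subset and cost.
# Classification metric: accuracy; regression metric: RMSE.
svm_cv_metric <- function(x, y, fold_id, task, cost, nu) {
  folds <- sort(unique(fold_id))
  pred <- numeric(length(y))
  for (f in folds) {
    hold <- fold_id == f
    if (!any(hold) || length(unique(y[!hold])) < 2L && task == "classification")
      return(NA_real_)
    m <- fit_linear_svm(x[!hold, , drop = FALSE], y[!hold], task, cost, nu)
    pred[hold] <- svm_decision(m$w, m$b, x[hold, , drop = FALSE])
  }
  if (task == "classification") mean((pred > 0) == (y == "active"))
  else sqrt(mean((pred - y)^2))
}

svm_train_metric <- function(x, y, task, cost, nu) {
  m <- fit_linear_svm(x, y, task, cost, nu)
  sc <- svm_decision(m$w, m$b, x)
  metric <- if (task == "classification") mean((sc > 0) == (y == "active"))
            else sqrt(mean((sc - y)^2))
  list(metric = metric, w = m$w, b = m$b)
}

# Fitness of a chromosome: best cross-validated metric over the cost grid
# (accuracy maximized / RMSE minimized), with the training metric at the
# best cost as tie-breaker.  Returns (fitness, train_fit, cost) where both
# fitnesses are maximized.
subset_fitness <- function(x, y, fold_id, task, cost_grid, nu) {
  best <- list(fitness = -Inf, train_fit = -Inf, cost = NA_real_)
  for (cost in cost_grid) {
    cvm <- svm_cv_metric(x, y, fold_id, task, cost, nu)
    if (is.na(cvm)) next
    fit <- if (task == "classification") cvm else -cvm
    if (fit > best$fitness) {
      tr <- svm_train_metric(x, y, task, cost, nu)$metric
      trf <- if (task == "classification") tr else -tr
      best <- list(fitness = fit, train_fit = trf, cost = cost)
    }
  }
  best
}

#' GA-SVM feature-subset search
#'
#' Wraps a binary genetic algorithm around linear SVM models: chromosomes
#' are bit vectors over the PCA-selected Signature columns, fitness is the
#' cross-validated accuracy (classification) or negative cross-validated
#' RMSE (regression) maximized over the cost grid for each subset, with the
#' training metric as tie-breaker.  All final-population chromosomes tied
#' at the best (cross-validation, training) metrics are returned as
#' models, deduplicated by feature subset; an all-zero chromosome is
#' penalized and never returned.
#'
#' @param dm a `sig_matrix` or numeric matrix (compounds x descriptors).
#' @param y class labels (`"active"`/`"inactive"`, a factor, or a logical
#'   where `TRUE` = active) for classification; numeric targets for
#'   regression.
#' @param pca optional `sig_pca` restricting the searched columns.
#' @param spec a [svm_spec()].
#' @param ga a [ga_config()].
#' @param seed integer seed controlling fold assignment and all GA
#'   randomness; identical seeds give identical results.
#' @return an object of class `sig_ga_result`: list with `models` (each a
#'   `sig_model`: `features`, `w`, `b`, `cost`, `cv_error`,
#'   `training_error`, `task`), `task`, `history` (best fitness per
#'   generation), `generations`, `seed`.
#' @export
ga_svm_search <- function(dm, y, pca = NULL, spec = svm_spec(), ga = ga_config(),
                          seed = 1L) {
  x_all <- if (inherits(dm, "sig_matrix")) dm$counts else dm
  x_all <- matrix(as.numeric(x_all), nrow = nrow(x_all),
                  dimnames = dimnames(x_all))
  keys <- if (!is.null(pca)) pca$selected else colnames(x_all)
  x <- x_all[, keys, drop = FALSE]
  task <- spec$task
  if (task == "classification") {
    y <- normalize_labels(y)
    assert_that(length(unique(y)) == 2L, "classification needs both classes present")
  } else {
    y <- as.numeric(y)
    assert_that(length(y) >= spec$folds,
                "regression needs at least as many samples as folds")
  }
  assert_that(length(y) == nrow(x), "labels must align with matrix rows")
  folds <- min(spec$folds, length(y))
  fold_id <- cv_folds(y, folds, seed, task)

  p <- ncol(x)
  cache <- new.env(parent = emptyenv())
  eval_chrom <- function(chrom) {
    key <- paste(which(chrom), collapse = ",")
    if (key == "") return(list(fitness = -Inf, train_fit = -Inf, cost = NA_real_))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- subset_fitness(x[, chrom, drop = FALSE], y, fold_id, task,
                          spec$cost_grid, spec$nu)
    cache[[key]] <- res
    res
  }

  run <- with_seed(seed + 1L, {
    pop <- matrix(stats::runif(ga$population * p) < 0.5, nrow = ga$population)
    scores <- lapply(seq_len(nrow(pop)), function(i) eval_chrom(pop[i, ]))
    history <- numeric(0)
    best_key <- c(-Inf, -Inf)
    stall <- 0L
    gen <- 0L
    while (gen < ga$max_iter) {
      gen <- gen + 1L
      fit <- vapply(scores, `[[`, numeric(1), "fitness")
      trf <- vapply(scores, `[[`, numeric(1), "train_fit")
      ord <- order(-fit, -trf)
      pop <- pop[ord, , drop = FALSE]
      scores <- scores[ord]
      fit <- fit[ord]; trf <- trf[ord]
      history <- c(history, fit[1L])
      if (fit[1L] > best_key[1L] ||
          (fit[1L] == best_key[1L] && trf[1L] > best_key[2L])) {
        best_key <- c(fit[1L], trf[1L])
        stall <- 0L
      } else stall <- stall + 1L
      if (stall >= ga$stall_stop) break
      if (gen >= ga$max_iter) break

      n_elite <- max(1L, round(ga$elitism * ga$population))
      n_off <- ga$population - n_elite
      if (n_off > 0L) {
        offspring <- matrix(FALSE, nrow = n_off, ncol = p)
        for (o in seq_len(n_off)) {
          p1 <- tournament_pick(fit, trf)
          if (stats::runif(1) < ga$crossover) {
            p2 <- tournament_pick(fit, trf)
            cut <- sample.int(p, 1L)
            child <- c(pop[p1, seq_len(cut)],
                       if (cut < p) pop[p2, (cut + 1L):p])
          } else child <- pop[p1, ]
          if (stats::runif(1) < ga$mutation) {
            flip <- sample.int(p, 1L)
            child[flip] <- !child[flip]
          }
          offspring[o, ] <- child
        }
        pop <- rbind(pop[seq_len(n_elite), , drop = FALSE], offspring)
        scores <- c(scores[seq_len(n_elite)],
                    lapply(seq_len(n_off), function(o) eval_chrom(offspring[o, ])))
      }
    }
    list(pop = pop, scores = scores, history = history, generations = gen)
  })

  fit <- vapply(run$scores, `[[`, numeric(1), "fitness")
  trf <- vapply(run$scores, `[[`, numeric(1), "train_fit")
  best_fit <- max(fit)
  assert_that(is.finite(best_fit), "no feasible feature subset found")
  best_trf <- max(trf[fit == best_fit])
  tied <- which(fit == best_fit & trf == best_trf)
  subsets <- unique(lapply(tied, function(i) which(run$pop[i, ])))
  models <- lapply(subsets, function(sel) {
    chrom <- logical(p); chrom[sel] <- TRUE
    sc <- eval_chrom(chrom)
    xm <- x[, sel, drop = FALSE]
    tr <- svm_train_metric(xm, y, task, sc$cost, spec$nu)
    cv_err <- if (task == "classification") 1 - sc$fitness else -sc$fitness
    tr_err <- if (task == "classification") 1 - tr$metric else tr$metric
    structure(list(features = keys[sel], w = tr$w, b = tr$b, cost = sc$cost,
                   nu = if (task == "regression") spec$nu else NULL,
                   cv_error = cv_err, training_error = tr_err, task = task),
              class = "sig_model")
  })
  structure(list(models = models, task = task, history = run$history,
                 generations = run$generations, seed = seed,
                 folds = folds, spec = spec, ga = ga),
            class = "sig_ga_result")
}

tournament_pick <- function(fit, trf, size = 2L) {
  cand <- sample.int(length(fit), size, replace = TRUE)
  ord <- order(-fit[cand], -trf[cand])
  cand[ord[1L]]
}

normalize_labels <- function(y) {
  if (is.logical(y)) return(ifelse(y, "active", "inactive"))
  y <- as.character(y)
  out <- map_activity_class(y)
  assert_that(!any(out == "unknown"),
              "labels must be active/inactive (or 1/0, TRUE/FALSE)")
  out
}

#' @export
print.sig_model <- function(x, ...) {
  cat(sprintf("<sig_model [%s]: %d features, cost %.2f, train err %.3f, CV err %.3f>\n",
              x$task, length(x$features), x$cost, x$training_error, x$cv_error))
  invisible(x)
}

#' @export
print.sig_ga_result <- function(x, ...) {
  cat(sprintf("<sig_ga_result [%s]: %d tied model(s) after %d generation(s); best CV error %.3f>\n",
              x$task, length(x$models), x$generations, x$models[[1L]]$cv_error))
  invisible(x)
}

#' Model evaluation: accuracy, ROC curve and AUC
#'
#' Computes the a priori performance of decision scores against known
#' classes: accuracy of the sign rule (score > 0 predicts active), the ROC
#' curve obtained by sweeping the decision threshold, and the area under it
#' by the trapezoid rule.  For a `sig_model` the scores are its linear
#' decision values on the supplied matrix; for an ensemble the binding
#' score under the unanimity rule (the minimum over classifiers) is used.
#'
#' @param object numeric decision scores, a `sig_model`, or a
#'   `sig_ensemble`.
#' @param truth known classes aligned with the scores/matrix rows.
#' @param dm descriptor matrix (`sig_matrix`), required for model input.
#' @param ... unused.
#' @return list with `accuracy`, `roc_points` (data.frame `threshold`,
#'   `fpr`, `tpr`), `auc`, and the confusion counts at threshold 0.
#' @export
evaluate_model <- function(object, truth, dm = NULL, ...) UseMethod("evaluate_model")

#' @export
evaluate_model.default <- function(object, truth, dm = NULL, ...) {
  scores <- as.numeric(object)
  y <- normalize_labels(truth)
  assert_that(length(scores) == length(y), "scores and truth must align")
  if (length(unique(y)) < 2L)
    stop("AUC undefined: truth contains a single class", call. = FALSE)
  pos <- y == "active"
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  tp <- sum(scores > 0 & pos); tn <- sum(scores <= 0 & !pos)
  fp <- sum(scores > 0 & !pos); fn <- sum(scores <= 0 & pos)
  list(accuracy = (tp + tn) / length(y),
       roc_points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc, tp = tp, tn = tn, fp = fp, fn = fn)
}

#' @export
evaluate_model.sig_model <- function(object, truth, dm = NULL, ...) {
  assert_that(!is.null(dm), "a descriptor matrix is required to score a model")
  scores <- model_scores(object, dm)
  evaluate_model(scores, truth)
}

#' @export
evaluate_model.sig_ensemble <- function(object, truth, dm = NULL, ...) {
  assert_that(!is.null(dm), "a descriptor matrix is required to score an ensemble")
  # the binding score under the unanimity rule: the minimum over classifiers
  per_model <- vapply(object$classifiers, model_scores, numeric(nrow(
    if (inherits(dm, "sig_matrix")) dm$counts else dm)), dm = dm)
  scores <- apply(as.matrix(per_model), 1L, min)
  evaluate_model(scores, truth)
}

# Linear decision values of one model over a sig_matrix (or count matrix);
# features absent from the matrix contribute zero.
model_scores <- function(model, dm) {
  x <- if (inherits(dm, "sig_matrix")) dm$counts else dm
  v <- matrix(0, nrow = nrow(x), ncol = length(model$features))
  hit <- intersect(model$features, colnames(x))
  v[, match(hit, model$features)] <- x[, hit, drop = FALSE]
  as.numeric(v %*% model$w + model$b)
}
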