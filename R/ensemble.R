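#' Fit the vHTS model ensemble
#'
#' The single fitting entry point of the pipeline.  From a labelled
#' training library it (1) builds the Signature descriptor matrix at the
#' requested heights, (2) PCA-filters the vocabulary, (3) runs the GA-SVM
#' feature search for classification on all compounds, keeping every model
#' tied on (cross-validation error, training error), and (4) repeats the
#' procedure as a regression on the actives alone (their own Signature
#' vocabulary) to predict IC50.  The result carries the training-set
#' occurrence windows needed by the overlap applicability-domain metric.
#'
#' @param lib a `sig_library` whose records are labelled active/inactive
#'   (actives with `ic50_um` when regression is fitted).
#' @param heights Signature heights (default 0:2).
#' @param variance_cutoff,importance_rule passed to [pca_filter()].
#' @param spec a [svm_spec()]; its task field is ignored (both tasks are
#'   fitted from the same grid/folds settings).
#' @param ga a [ga_config()].
#' @param seed integer; controls fold assignment and the GA search.
#' @param regression whether to fit the IC50 regressor (needs at least
#'   `spec$folds` actives with IC50 values).
#' @param regression_target `"log10"` (default; models log10 IC50 and
#'   exponentiates predictions back to uM) or `"linear"`.
#' @param dedupe_degenerate_heights passed to [build_matrix()].
#' @return an object of class `sig_ensemble`.
#' @seealso [screen_library()], [score_candidate()], [overlap()]
#' @export
sigscreen_fit <- function(lib, heights = 0:2, variance_cutoff = 0.95,
                          importance_rule = "mean", spec = svm_spec(),
                          ga = ga_config(), seed = 1L, regression = TRUE,
                          regression_target = c("log10", "linear"),
                          dedupe_degenerate_heights = FALSE) {
  regression_target <- match.arg(regression_target)
  cls <- library_classes(lib)
  known <- cls %in% c("active", "inactive")
  if (!all(known)) {
    warning(sum(!known), " compound(s) with unknown class excluded from training")
    lib <- lib[known]
    cls <- cls[known]
  }
  assert_that(length(unique(cls)) == 2L, "training library needs both classes")

  dm <- build_matrix(lib, heights = heights,
                     dedupe_degenerate_heights = dedupe_degenerate_heights)
  pca_c <- pca_filter(dm, variance_cutoff, importance_rule)
  spec_c <- svm_spec("classification", cost_grid = spec$cost_grid,
                     nu = spec$nu, folds = spec$folds)
  ga_c <- ga_svm_search(dm, cls, pca = pca_c, spec = spec_c, ga = ga, seed = seed)

  regressor <- NULL; pca_r <- NULL; dm_act <- NULL
  if (regression) {
    act <- which(cls == "active")
    ic50 <- library_ic50(lib)[act]
    assert_that(!anyNA(ic50), "every active needs an IC50 for regression")
    assert_that(length(act) >= spec$folds,
                "need at least `folds` actives to fit the regressor")
    dm_act <- build_matrix(lib[act], heights = heights,
                           dedupe_degenerate_heights = dedupe_degenerate_heights)
    pca_r <- pca_filter(dm_act, variance_cutoff, importance_rule)
    targets <- if (regression_target == "log10") log10(ic50) else ic50
    spec_r <- svm_spec("regression", cost_grid = spec$cost_grid,
                       nu = spec$nu, folds = spec$folds)
    ga_r <- ga_svm_search(dm_act, targets, pca = pca_r, spec = spec_r,
                          ga = ga, seed = seed)
    regressor <- ga_r$models[[1L]]
  }

  structure(list(classifiers = ga_c$models,
                 regressor = regressor,
                 vocab = colnames(dm$counts),
                 col_min = dm$col_min, col_max = dm$col_max,
                 heights = dm$heights, dedupe = dm$dedupe,
                 regression_target = regression_target,
                 pca_classification = pca_c, pca_regression = pca_r,
                 n_train = length(lib),
                 n_active = sum(cls == "active"),
                 n_inactive = sum(cls == "inactive"),
                 signature_tally = table(factor(dm$height)),
                 active_signature_tally = if (!is.null(dm_act)) table(factor(dm_act$height)),
                 seed = seed),
            class = "sig_ensemble")
}

#' @export
print.sig_ensemble <- function(x, ...) {
  cat(sprintf("<sig_ensemble: %d tied SVM-C model(s)%s>\n",
              length(x$classifiers),
              if (!is.null(x$regressor)) " + 1 SVM-R regressor" else ""))
  cat(sprintf("  training set: %d compounds (%d active, %d inactive)\n",
              x$n_train, x$n_active, x$n_inactive))
  cat(sprintf("  vocabulary: %d unique atomic signatures (%s)\n",
              length(x$vocab),
              paste(sprintf("%s h=%s", x$signature_tally,
                            names(x$signature_tally)), collapse = "; ")))
  cat(sprintf("  SVM-C: train err %.3f, CV err %.3f\n",
              x$classifiers[[1L]]$training_error, x$classifiers[[1L]]$cv_error))
  if (!is.null(x$regressor))
    cat(sprintf("  SVM-R: train RMSE %.3f, CV RMSE %.3f (%s IC50)\n",
                x$regressor$training_error, x$regressor$cv_error,
                x$regression_target))
  invisible(x)
}

#' @export
summary.sig_ensemble <- function(object, ...) {
  cls <- object$classifiers
  out <- list(
    n_classifiers = length(cls),
    feature_counts = vapply(cls, function(m) length(m$features), integer(1)),
    cv_error = cls[[1L]]$cv_error,
    training_error = cls[[1L]]$training_error,
    pca_selected = length(object$pca_classification$selected),
    vocabulary = length(object$vocab),
    regressor = if (!is.null(object$regressor))
      list(features = length(object$regressor$features),
           cv_error = object$regressor$cv_error,
           training_error = object$regressor$training_error))
  class(out) <- "summary.sig_ensemble"
  out
}

#' @export
print.summary.sig_ensemble <- function(x, ...) {
  cat(sprintf("GA-SVM ensemble: %d tied classifier(s), %d-%d features each\n",
              x$n_classifiers, min(x$feature_counts), max(x$feature_counts)))
  cat(sprintf("  PCA kept %d of %d signatures\n", x$pca_selected, x$vocabulary))
  cat(sprintf("  classification: train err %.3f, CV err %.3f\n",
              x$training_error, x$cv_error))
  if (!is.null(x$regressor))
    cat(sprintf("  regression: %d features, train RMSE %.3f, CV RMSE %.3f\n",
                x$regressor$features, x$regressor$training_error,
                x$regressor$cv_error))
  invisible(x)
}

# Predicted IC50 in uM for a candidate count vector (named by signature key).
predict_ic50 <- function(ensemble, counts) {
  m <- ensemble$regressor
  if (is.null(m)) return(NA_real_)
  v <- numeric(length(m$features))
  hit <- intersect(names(counts), m$features)
  v[match(hit, m$features)] <- counts[hit]
  raw <- sum(v * m$w) + m$b
  if (ensemble$regression_target == "log10") 10^raw else raw
}

#' Predict screening scores for new compounds
#'
#' @param object a `sig_ensemble`.
#' @param newdata a `sig_library`, a single `sig_compound`/`sig_mol`, or a
#'   list of them.
#' @param criteria optional [criteria_set()]; when supplied the returned
#'   frame carries `passed` and `failed_criteria` columns.
#' @param ... unused.
#' @return data.frame with one row per compound: `id`, `overlap`,
#'   `min_score`, `mean_score`, `predicted_ic50_um` (and pass/fail columns
#'   when criteria are given).
#' @export
predict.sig_ensemble <- function(object, newdata, criteria = NULL, ...) {
  recs <- if (inherits(newdata, "sig_library")) newdata$records
          else if (inherits(newdata, c("sig_compound", "sig_mol"))) list(newdata)
          else newdata
  rows <- lapply(recs, function(r) {
    v <- score_candidate(r, object, criteria %||% permissive_criteria())
    data.frame(id = v$id, overlap = v$overlap,
               min_score = min(v$svmc_scores), mean_score = mean(v$svmc_scores),
               predicted_ic50_um = v$predicted_ic50_um,
               passed = v$passed,
               failed_criteria = paste(v$failed_criteria, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (is.null(criteria)) out$passed <- out$failed_criteria <- NULL
  out
}

#' Serialize / restore a fitted ensemble
#'
#' The ensemble is written as JSON: linear weights and intercepts per
#' model, feature subsets as canonical signature strings, the training
#' vocabulary with its occurrence windows, and the fit settings.
#'
#' @param ensemble a `sig_ensemble`.
#' @param path JSON file path.
#' @export
write_ensemble <- function(ensemble, path) {
  ser_model <- function(m) if (is.null(m)) NULL else
    list(features = m$features, w = as.numeric(m$w), b = m$b, cost = m$cost,
         nu = m$nu, cv_error = m$cv_error, training_error = m$training_error,
         task = m$task)
  obj <- list(classifiers = lapply(ensemble$classifiers, ser_model),
              regressor = ser_model(ensemble$regressor),
              vocab = ensemble$vocab,
              col_min = as.integer(ensemble$col_min),
              col_max = as.integer(ensemble$col_max),
              heights = ensemble$heights, dedupe = ensemble$dedupe,
              regression_target = ensemble$regression_target,
              n_train = ensemble$n_train, n_active = ensemble$n_active,
              n_inactive = ensemble$n_inactive, seed = ensemble$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  de_model <- function(m) {
    if (is.null(m) || length(m) == 0L) return(NULL)
    features <- as.character(unlist(m$features))
    w <- as.numeric(unlist(m$w)); names(w) <- features
    structure(list(features = features, w = w, b = m$b, cost = m$cost,
                   nu = m$nu, cv_error = m$cv_error,
                   training_error = m$training_error, task = m$task),
              class = "sig_model")
  }
  classifiers <- lapply(obj$classifiers, de_model)
  vocab <- as.character(unlist(obj$vocab))
  col_min <- as.integer(unlist(obj$col_min))
  col_max <- as.integer(unlist(obj$col_max))
  names(col_min) <- names(col_max) <- vocab
  structure(list(classifiers = unname(classifiers),
                 regressor = de_model(obj$regressor),
                 vocab = vocab, col_min = col_min, col_max = col_max,
                 heights = as.integer(unlist(obj$heights)), dedupe = obj$dedupe,
                 regression_target = obj$regression_target,
                 pca_classification = NULL, pca_regression = NULL,
                 n_train = obj$n_train, n_active = obj$n_active,
                 n_inactive = obj$n_inactive,
                 signature_tally = NULL, active_signature_tally = NULL,
                 seed = obj$seed),
            class = "sig_ensemble")
}
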