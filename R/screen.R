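#' Screening selection criteria
#'
#' A candidate passes when its overlap reaches `min_overlap`
#' (non-strict, as the round-2 protocol prints "overlap >= 0.9"), every
#' classifier decision score strictly exceeds `min_svmc_score` under the
#' unanimity rule, and its predicted IC50 is strictly below
#' `max_pred_ic50_um`.  `round1_criteria()` is the strict first-round set
#' (overlap = 1, score > 2, IC50 < 50 uM); `round2_criteria()` the relaxed
#' second-round set (overlap >= 0.9, score > 0, IC50 < 50 uM).
#'
#' @param min_overlap overlap floor in `[0, 1]`.
#' @param min_svmc_score decision-score floor (strict).
#' @param unanimity require every classifier above the floor (default);
#'   otherwise the ensemble mean score is compared.
#' @param max_pred_ic50_um predicted-IC50 ceiling in uM (strict).
#' @export
criteria_set <- function(min_overlap, min_svmc_score, unanimity = TRUE,
                         max_pred_ic50_um = 50) {
  assert_that(is.finite(min_overlap) && min_overlap >= 0 && min_overlap <= 1,
              "min_overlap must be finite in [0, 1]")
  assert_that(is.numeric(min_svmc_score) && !is.na(min_svmc_score),
              "min_svmc_score must be numeric (-Inf disables the floor)")
  assert_that(is.numeric(max_pred_ic50_um) && !is.na(max_pred_ic50_um) &&
                max_pred_ic50_um > 0,
              "max_pred_ic50_um must be positive (Inf disables the ceiling)")
  structure(list(min_overlap = min_overlap, min_svmc_score = min_svmc_score,
                 unanimity = isTRUE(unanimity),
                 max_pred_ic50_um = max_pred_ic50_um),
            class = "sig_criteria")
}

#' @rdname criteria_set
#' @export
round1_criteria <- function() criteria_set(1, 2, TRUE, 50)

#' @rdname criteria_set
#' @export
round2_criteria <- function() criteria_set(0.9, 0, TRUE, 50)

# used by predict() when no criteria are supplied
permissive_criteria <- function() {
  structure(list(min_overlap = 0, min_svmc_score = -Inf, unanimity = TRUE,
                 max_pred_ic50_um = Inf),
            class = "sig_criteria")
}

#' @export
print.sig_criteria <- function(x, ...) {
  cat(sprintf("<criteria: overlap >= %s; SVM-C score > %s (%s); predicted IC50 < %s uM>\n",
              x$min_overlap, x$min_svmc_score,
              if (x$unanimity) "unanimous" else "mean", x$max_pred_ic50_um))
  invisible(x)
}

#' Overlap applicability-domain metric
#'
#' The fraction of a candidate's unique atomic Signatures that occur in
#' the training set with an occurrence count inside the training-observed
#' (min, max) window.  Overlap 1 means every candidate signature was seen
#' in training at a familiar multiplicity (no extrapolation); signatures
#' absent from the training vocabulary, or present at an unseen count,
#' reduce it.
#'
#' @param candidate a `sig_molsig`, or a molecule/compound to featurize at
#'   the training heights.
#' @param train_stats a fitted `sig_ensemble` or a training `sig_matrix`
#'   supplying the occurrence windows.
#' @return overlap in `[0, 1]`.
#' @export
overlap <- function(candidate, train_stats) {
  st <- overlap_stats(train_stats)
  ms <- if (inherits(candidate, "sig_molsig")) candidate
        else molecular_signature(candidate, heights = st$heights)
  keys <- names(ms)
  assert_that(length(keys) > 0L, "candidate has an empty signature set")
  hit <- match(keys, st$vocab)
  ok <- !is.na(hit) &
    as.integer(ms) >= st$col_min[ifelse(is.na(hit), 1L, hit)] &
    as.integer(ms) <= st$col_max[ifelse(is.na(hit), 1L, hit)]
  sum(ok) / length(keys)
}

overlap_stats <- function(x) {
  if (inherits(x, "sig_ensemble"))
    list(vocab = x$vocab, col_min = x$col_min, col_max = x$col_max,
         heights = x$heights)
  else if (inherits(x, "sig_matrix"))
    list(vocab = colnames(x$counts), col_min = x$col_min, col_max = x$col_max,
         heights = x$heights)
  else stop("train_stats must be a sig_ensemble or sig_matrix", call. = FALSE)
}

#' Score one candidate against the ensemble and criteria
#'
#' Featurizes the candidate at the ensemble heights, computes the overlap,
#' one linear decision value per tied classifier (signatures outside a
#' model's subset contribute zero; signatures outside the training
#' vocabulary affect only the overlap) and the regressor's predicted IC50,
#' then applies the criteria.
#'
#' @param x a `sig_compound`, `sig_mol` or `sig_molsig`.
#' @param ensemble a fitted `sig_ensemble`.
#' @param criteria a [criteria_set()].
#' @return an object of class `sig_verdict`: list with `id`, `overlap`,
#'   `svmc_scores`, `predicted_ic50_um`, `passed`, `failed_criteria`
#'   (subset of `"overlap"`, `"svmc_score"`, `"predicted_ic50"`).
#' @export
score_candidate <- function(x, ensemble, criteria = round1_criteria()) {
  ms <- if (inherits(x, "sig_molsig")) x
        else molecular_signature(x, heights = ensemble$heights)
  assert_that(identical(as.integer(attr(ms, "heights")),
                        as.integer(ensemble$heights)),
              "candidate featurized at different heights than the ensemble")
  counts <- as.integer(ms); names(counts) <- names(ms)
  om <- overlap(ms, ensemble)
  scores <- vapply(ensemble$classifiers, function(m) {
    v <- numeric(length(m$features))
    hit <- intersect(names(counts), m$features)
    v[match(hit, m$features)] <- counts[hit]
    sum(v * m$w) + m$b
  }, numeric(1))
  ic50 <- predict_ic50(ensemble, counts)

  failed <- character(0)
  if (om < criteria$min_overlap) failed <- c(failed, "overlap")
  score_ok <- if (criteria$unanimity) all(scores > criteria$min_svmc_score)
              else mean(scores) > criteria$min_svmc_score
  if (!score_ok) failed <- c(failed, "svmc_score")
  if (!is.na(ic50) && !(ic50 < criteria$max_pred_ic50_um))
    failed <- c(failed, "predicted_ic50")
  structure(list(id = attr(ms, "id") %||% "candidate", overlap = om,
                 svmc_scores = scores, predicted_ic50_um = ic50,
                 passed = length(failed) == 0L, failed_criteria = failed),
            class = "sig_verdict")
}

#' @export
print.sig_verdict <- function(x, ...) {
  cat(sprintf("<verdict %s: overlap %.3f, min score %.3f, predicted IC50 %.3g uM -> %s%s>\n",
              x$id, x$overlap, min(x$svmc_scores), x$predicted_ic50_um,
              if (x$passed) "PASS" else "fail",
              if (length(x$failed_criteria))
                paste0(" (", paste(x$failed_criteria, collapse = ","), ")") else ""))
  invisible(x)
}

#' Screen a candidate library in chunks
#'
#' Applies [score_candidate()] to every compound of a library, processing
#' `chunk_size` compounds at a time so the verdict table is the only thing
#' that grows with library size.  Verdicts are independent of the
#' chunking.
#'
#' @param lib a `sig_library`, or a path to a `.smi`/`.csv` library file
#'   read chunk-wise.
#' @param ensemble fitted `sig_ensemble`.
#' @param criteria a [criteria_set()].
#' @param chunk_size compounds per chunk (>= 1).
#' @return object of class `sig_screen_result`: list with `verdicts`
#'   (data.frame: `id`, `overlap`, `min_score`, `mean_score`,
#'   `predicted_ic50_um`, `passed`, `failed_criteria`) and `summary`
#'   (list `screened`, `passed`, `skipped`).
#' @export
screen_library <- function(lib, ensemble, criteria = round1_criteria(),
                           chunk_size = 1000L) {
  assert_that(chunk_size >= 1L, "chunk_size must be >= 1")
  if (is.character(lib)) return(screen_library_file(lib, ensemble, criteria, chunk_size))
  recs <- lib$records
  n <- length(recs)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))
  verdicts <- do.call(rbind, lapply(chunks, function(idx)
    predict(ensemble, recs[idx], criteria = criteria)))
  rownames(verdicts) <- NULL
  structure(list(verdicts = verdicts,
                 summary = list(screened = n, passed = sum(verdicts$passed),
                                skipped = 0L)),
            class = "sig_screen_result")
}

screen_library_file <- function(path, ensemble, criteria, chunk_size) {
  assert_that(file.exists(path), paste("no such file:", path))
  ext <- tolower(tools::file_ext(path))
  assert_that(ext %in% c("smi", "csv"),
              "chunked file screening supports .smi and .csv")
  con <- file(path, open = "r")
  on.exit(close(con))
  header <- NULL
  if (ext == "csv") header <- strsplit(readLines(con, n = 1L), ",")[[1L]]
  verdicts <- list(); screened <- 0L; skipped <- 0L; offset <- 0L
  repeat {
    lines <- tryCatch(readLines(con, n = chunk_size),
                      error = function(e)
                        stop(sprintf("I/O error in %s after record %d: %s",
                                     path, offset, conditionMessage(e)),
                             call. = FALSE))
    if (!length(lines)) break
    recs <- list()
    for (ln in lines) {
      offset <- offset + 1L
      if (!nzchar(trimws(ln))) next
      rec <- tryCatch({
        if (ext == "smi") {
          tok <- strsplit(trimws(ln), "\\s+")[[1L]]
          parse_smiles(tok[1L], if (length(tok) >= 2L) tok[2L]
                                else sprintf("mol%07d", offset))
        } else {
          tok <- strsplit(ln, ",")[[1L]]
          names(tok) <- header[seq_along(tok)]
          parse_smiles(tok[["smiles"]], tok[["id"]])
        }
      }, error = function(e) NULL)
      if (is.null(rec)) skipped <- skipped + 1L else recs[[length(recs) + 1L]] <- rec
    }
    if (length(recs)) {
      verdicts[[length(verdicts) + 1L]] <- predict(ensemble, recs, criteria = criteria)
      screened <- screened + length(recs)
    }
  }
  v <- do.call(rbind, verdicts)
  rownames(v) <- NULL
  structure(list(verdicts = v,
                 summary = list(screened = screened,
                                passed = sum(v$passed %||% logical(0)),
                                skipped = skipped)),
            class = "sig_screen_result")
}

#' @export
print.sig_screen_result <- function(x, ...) {
  cat(sprintf("<screen result: %d screened, %d passed, %d skipped>\n",
              x$summary$screened, x$summary$passed, x$summary$skipped))
  invisible(x)
}

#' Experimental hit rate of a validation round
#'
#' The fraction of predicted positives that proved experimentally active:
#' TP / (TP + FP), the precision of the screen.  Input rows/elements must
#' all be predicted positives (the compounds actually tested).
#'
#' @param tested logical vector (`TRUE` = experimentally active), or a
#'   data.frame with a logical `active` column.
#' @return hit rate in `[0, 1]`.
#' @examples
#' hit_rate(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))  # 4/7
#' @export
hit_rate <- function(tested) {
  act <- if (is.data.frame(tested)) tested$active else tested
  assert_that(length(act) > 0L, "no tested compounds")
  assert_that(is.logical(act) && !anyNA(act),
              "activity outcomes must be TRUE/FALSE")
  mean(act)
}

#' Write screening verdicts to CSV
#'
#' @param result a `sig_screen_result`.
#' @param path output CSV.
#' @export
write_verdicts <- function(result, path) {
  utils::write.csv(result$verdicts, path, row.names = FALSE)
  invisible(path)
}
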