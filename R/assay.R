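#' Percent inhibition from raw fluorescence
#'
#' `100 * (1 - (signal - blank) / (control - blank))`: a well reading at
#' the blank level is full (100%) inhibition, a reading at the uninhibited
#' control level is 0%.  The statistic is invariant under affine rescaling
#' of the fluorescence values.
#'
#' @param signal raw well fluorescence (vectorized).
#' @param blank_mean mean fluorescence of the blank (no-enzyme) wells.
#' @param control_mean mean fluorescence of the uninhibited control wells.
#' @return percent inhibition (same length as `signal`).
#' @export
percent_inhibition <- function(signal, blank_mean, control_mean) {
  assert_that(is.finite(blank_mean) && is.finite(control_mean),
              "blank and control means must be finite")
  if (isTRUE(all.equal(control_mean, blank_mean)))
    stop("degenerate plate: control mean equals blank mean", call. = FALSE)
  100 * (1 - (signal - blank_mean) / (control_mean - blank_mean))
}

#' Read an 8 x 12 plate of fluorescence values
#'
#' Plate layout convention: columns 1-9 carry compounds (one compound per
#' column, one dilution per row, highest concentration in row 1), column
#' 10 is the protein check (enzyme without substrate), column 11 the blank
#' (buffer for enzyme) and column 12 the uninhibited control.
#'
#' @param path CSV file of 8 rows x 12 columns, no header.
#' @return numeric matrix of class `sig_plate`.
#' @export
read_plate <- function(path) {
  df <- utils::read.csv(path, header = FALSE)
  assert_that(nrow(df) == 8L && ncol(df) == 12L,
              "plate file must be 8 rows x 12 columns")
  m <- as.matrix(df)
  dimnames(m) <- list(LETTERS[1:8], paste0("col", 1:12))
  class(m) <- c("sig_plate", class(m))
  m
}

#' Reduce a plate to percent inhibition
#'
#' Aggregates the blank (column 11) and control (column 12) wells by
#' arithmetic mean and converts the compound wells (columns 1-9) to
#' percent inhibition.  The protein-check column (10) is reduced to a QC
#' ratio, `(mean(col 10) - blank) / (control - blank)`, attached as the
#' `qc_ratio` attribute and otherwise unused.
#'
#' @param plate a `sig_plate` (or plain 8 x 12 matrix).
#' @return 8 x 9 matrix of percent inhibition with attribute `qc_ratio`.
#' @export
plate_inhibition <- function(plate) {
  assert_that(nrow(plate) == 8L && ncol(plate) == 12L,
              "plate must be 8 rows x 12 columns")
  blank <- mean(plate[, 11L])
  control <- mean(plate[, 12L])
  inh <- percent_inhibition(plate[, 1:9, drop = FALSE], blank, control)
  attr(inh, "qc_ratio") <- (mean(plate[, 10L]) - blank) / (control - blank)
  inh
}

#' Default eight-point four-fold dilution series
#'
#' Final in-well test concentrations: eight four-fold steps descending
#' from 50 uM to 3.05 nM.
#' @export
default_dilutions <- function() 50 / 4^(0:7)

#' A dose-response dilution series
#'
#' @param inhibition_pct percent inhibition per concentration.
#' @param concentrations_um test concentrations in uM, descending positive
#'   (default the standard eight four-fold steps from 50 uM).
#' @param replicate replicate index (bookkeeping only).
#' @return object of class `sig_dilution`.
#' @export
dilution_series <- function(inhibition_pct,
                            concentrations_um = default_dilutions(),
                            replicate = 1L) {
  assert_that(length(inhibition_pct) == length(concentrations_um),
              "one inhibition value per concentration required")
  assert_that(all(concentrations_um > 0) &&
                !is.unsorted(rev(concentrations_um), strictly = TRUE),
              "concentrations must be descending positive")
  structure(list(concentrations_um = as.numeric(concentrations_um),
                 inhibition_pct = as.numeric(inhibition_pct),
                 replicate = as.integer(replicate)),
            class = "sig_dilution")
}

#' Extract one compound column of a plate as a dilution series
#'
#' @param plate a `sig_plate`.
#' @param column compound column (1-9).
#' @inheritParams dilution_series
#' @export
plate_series <- function(plate, column,
                         concentrations_um = default_dilutions(),
                         replicate = 1L) {
  assert_that(column >= 1L && column <= 9L, "compound columns are 1-9")
  inh <- plate_inhibition(plate)
  dilution_series(inh[, column], concentrations_um, replicate)
}

#' IC50 by linear interpolation of the bracketing dilution points
#'
#' Finds the adjacent concentration pair whose inhibition values bracket
#' 50% (the closest points below and above) and interpolates linearly in
#' concentration.  If no pair brackets 50% the compound is deemed inactive
#' (no IC50).  A curve already above 50% at the lowest tested
#' concentration is flagged `below_range` (the IC50 lies below the tested
#' range) but still yields no IC50, per the stated inactive rule; a curve
#' crossing 50% more than once is flagged `non_monotone` and the bracket
#' nearest the highest concentration is used.
#'
#' @param series a `sig_dilution`.
#' @return list with `ic50_um` (numeric or `NA`), `crossed`,
#'   `below_range`, `non_monotone`.
#' @export
ic50_interpolate <- function(series) {
  assert_that(inherits(series, "sig_dilution"), "expected a sig_dilution")
  n <- length(series$concentrations_um)
  assert_that(n >= 1L, "empty dilution series")
  ord <- order(series$concentrations_um)
  conc <- series$concentrations_um[ord]
  inh <- series$inhibition_pct[ord]
  d <- inh - 50

  exact <- which(d == 0)
  cross <- if (n >= 2L) which(d[-n] * d[-1L] < 0) else integer(0)
  candidates <- c(exact, cross + 0.5)          # position along the curve
  if (length(candidates) == 0L) {
    return(list(ic50_um = NA_real_, crossed = FALSE,
                below_range = all(d > 0), non_monotone = FALSE))
  }
  pick <- max(candidates)                      # bracket nearest max conc
  ic50 <- if (pick == floor(pick)) {
    conc[pick]
  } else {
    k <- floor(pick)
    conc[k] + (50 - inh[k]) * (conc[k + 1L] - conc[k]) / (inh[k + 1L] - inh[k])
  }
  list(ic50_um = ic50, crossed = TRUE, below_range = FALSE,
       non_monotone = length(candidates) > 1L)
}

#' Call a compound active or inactive from replicate dose-response curves
#'
#' A compound is active only when every replicate yields an interpolated
#' IC50; the reported IC50 is the mean over replicates.  Replicates that
#' cross 50% in some but not all runs are recorded as inactive with a
#' weak-activity flag (the ">50 *" annotation convention).
#'
#' @param replicates list of `sig_dilution` (one per replicate, usually 3).
#' @param id compound identifier.
#' @param max_conc_um highest tested concentration (reporting only).
#' @return object of class `sig_activity_call`: list with `id`, `ic50_um`,
#'   `active`, `weak_activity`, `replicates`, `replicate_ic50s`.
#' @export
call_activity <- function(replicates, id = "compound", max_conc_um = 50) {
  if (inherits(replicates, "sig_dilution")) replicates <- list(replicates)
  assert_that(length(replicates) >= 1L, "at least one replicate required")
  fits <- lapply(replicates, ic50_interpolate)
  crossed <- vapply(fits, `[[`, logical(1), "crossed")
  ic50s <- vapply(fits, `[[`, numeric(1), "ic50_um")
  active <- all(crossed)
  structure(list(id = id,
                 ic50_um = if (active) mean(ic50s) else NA_real_,
                 active = active,
                 weak_activity = any(crossed) && !active,
                 replicates = length(replicates),
                 replicate_ic50s = ic50s,
                 max_conc_um = max_conc_um),
            class = "sig_activity_call")
}

#' @export
print.sig_activity_call <- function(x, ...) {
  cat(sprintf("<activity call %s: %s%s (n = %d)>\n", x$id,
              if (x$active) sprintf("active, IC50 %.3g uM", x$ic50_um)
              else sprintf("inactive (> %g uM)", x$max_conc_um),
              if (x$weak_activity) " *weak activity at top concentration*" else "",
              x$replicates))
  invisible(x)
}

#' Fold validated compounds back into the training set
#'
#' Appends the experimentally tested candidates to the training library
#' for the next modelling round: actives join with their measured IC50,
#' inactives join as inactive.  A call whose id already exists in the
#' training library is an error (label conflicts are never silently
#' resolved).
#'
#' @param train the current training `sig_library`.
#' @param calls list of `sig_activity_call` (or a data.frame with columns
#'   `id`, `active`, `ic50_um`).
#' @param structures a `sig_library` holding the structures of the called
#'   compounds.
#' @return the augmented `sig_library`.
#' @export
augment_training_set <- function(train, calls, structures) {
  if (is.data.frame(calls)) {
    calls <- lapply(seq_len(nrow(calls)), function(k)
      list(id = as.character(calls$id[k]), active = isTRUE(calls$active[k]),
           ic50_um = calls$ic50_um[k]))
  }
  if (inherits(calls, "sig_activity_call")) calls <- list(calls)
  train_ids <- library_ids(train)
  recs <- train$records
  for (cl in calls) {
    assert_that(!(cl$id %in% train_ids),
                paste0("duplicate id in training set: ", cl$id))
    rec <- structures$records[[cl$id]]
    assert_that(!is.null(rec), paste0("no structure for called compound ", cl$id))
    rec$activity_class <- if (cl$active) "active" else "inactive"
    rec$ic50_um <- if (cl$active) cl$ic50_um else NA_real_
    recs[[cl$id]] <- rec
    train_ids <- c(train_ids, cl$id)
  }
  sig_library(recs, provenance = paste0(train$provenance, " + validated"))
}
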