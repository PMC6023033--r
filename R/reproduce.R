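#' Printed validation outcomes of the two screening rounds
#'
#' The experimentally tested candidates of each vHTS round with their
#' predicted and measured IC50 values and activity calls, shipped as CSV
#' inputs for hit-rate and retraining arithmetic.  Compounds reported
#' `>50 uM` carry no experimental IC50; some of those showed weak activity
#' at the top tested concentration and are flagged.
#'
#' @param round 1 or 2.
#' @return data.frame with columns `cid`, `predicted_ic50_um`,
#'   `experimental_ic50_um`, `active` (logical), `weak_activity`
#'   (logical).
#' @export
validation_outcomes <- function(round = 1) {
  assert_that(round %in% c(1, 2), "round must be 1 or 2")
  path <- system.file("extdata", sprintf("round%d_validation.csv", round),
                      package = "sigscreen", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$active <- as.logical(df$active)
  df$weak_activity <- as.logical(df$weak_activity)
  df
}

#' Reproduce the training-data reduction chain from a bioassay export
#'
#' Runs the full pre-modelling pipeline on a local bioassay export:
#' parse the compound records, remove PAINS, remove structures similar to
#' the identified PAINS (signature-set Tanimoto against them), and tally
#' the unique atomic Signatures of the filtered set and of its actives.
#' Intended for reproduction runs against a public bioassay record
#' downloaded as CSV (`id`, `smiles`, `class`, optional `ic50_um`); note
#' that the filtered counts depend on the PAINS pattern list supplied, and
#' the shipped list is a curated subset of the published families.
#'
#' @param csv_path bioassay export CSV.
#' @param patterns PAINS patterns (see [pains_patterns()]).
#' @param threshold near-duplicate Tanimoto threshold (default 0.9).
#' @param heights Signature heights tallied.
#' @param standardize reserved switch for input standardization; the
#'   default parses structures as supplied (largest fragment, perceived
#'   aromaticity).
#' @return list with `n_parsed`, `n_active`, `pains_removed`,
#'   `near_duplicates_removed`, `n_filtered`, `n_filtered_active`,
#'   `signature_tally` (unique signatures per height, filtered set),
#'   `n_signatures`, `active_signature_tally`, `n_active_signatures`,
#'   and the filtered `library`.
#' @export
reproduce_bioassay <- function(csv_path, patterns = pains_patterns(),
                               threshold = 0.9, heights = 0:2,
                               standardize = TRUE) {
  lib <- read_library(csv_path, format = "csv")
  cls <- library_classes(lib)
  rep_pains <- pains_filter(lib, patterns)
  pains_ids <- rep_pains$removed$id
  pains_lib <- if (length(pains_ids)) lib[pains_ids] else NULL
  rep_dup <- if (!is.null(pains_lib))
    near_duplicate_filter(rep_pains$kept, pains_lib, threshold, heights)
  else list(kept = rep_pains$kept,
            removed = data.frame(id = character(0), reason = character(0)))
  kept <- rep_dup$kept
  kept_cls <- library_classes(kept)
  dm <- build_matrix(kept, heights = heights)
  act <- which(kept_cls == "active")
  dm_act <- if (length(act) >= 1L) build_matrix(kept[act], heights = heights)
  list(n_parsed = length(lib),
       n_active = sum(cls == "active"),
       pains_removed = rep_pains$removed,
       near_duplicates_removed = rep_dup$removed,
       n_filtered = length(kept),
       n_filtered_active = sum(kept_cls == "active"),
       signature_tally = table(factor(dm$height)),
       n_signatures = ncol(dm$counts),
       active_signature_tally = if (!is.null(dm_act)) table(factor(dm_act$height)),
       n_active_signatures = if (!is.null(dm_act)) ncol(dm_act$counts) else 0L,
       library = kept)
}
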