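#' A planted substructure-activity rule for synthetic libraries
#'
#' Defines the ground truth of a synthetic screening library: molecules
#' are built as an aromatic scaffold with substituents drawn from a small
#' grammar at the ortho/meta/para positions plus an anchor slot, and a
#' compound carries the pharmacophore group with probability equal to the
#' requested active fraction.  Activity is then Bernoulli given
#' pharmacophore presence (deterministic with the defaults: active if and
#' only if the pharmacophore is present), and actives draw an IC50 from a
#' log-normal distribution.  The default pharmacophore is a primary
#' sulfonamide; no decoy substituent contains sulfur, so the planted
#' activity signal maps onto the sulfur-rooted atomic Signatures.
#'
#' @param pharmacophore SMILES branch grafted onto active scaffolds.
#' @param p_active_match,p_active_nomatch probability of the active label
#'   given pharmacophore presence/absence.
#' @param ic50_meanlog,ic50_sdlog log-normal parameters (natural log, uM)
#'   of active IC50s; defaults centre near 5 uM with most mass inside the
#'   tested 0.003-50 uM window.
#' @param scaffolds,decoys SMILES fragments of the generator grammar.
#' @return object of class `sig_planted_rule`.
#' @export
planted_rule <- function(pharmacophore = "S(N)(=O)=O",
                         p_active_match = 1, p_active_nomatch = 0,
                         ic50_meanlog = log(5), ic50_sdlog = 0.6,
                         scaffolds = c("c1c%sc%sc%sc%sc1", "c1c%sc%sc%sc%sn1"),
                         decoys = c("Br", "Cl", "C", "O", "OC", "N", "C#N",
                                    "CC", "C(=O)OC", "C(=O)C")) {
  for (p in c(p_active_match, p_active_nomatch))
    assert_that(p >= 0 && p <= 1, "activity probabilities must be in [0, 1]")
  assert_that(ic50_sdlog > 0, "ic50_sdlog must be positive")
  structure(list(pharmacophore = pharmacophore,
                 p_active_match = p_active_match,
                 p_active_nomatch = p_active_nomatch,
                 ic50_meanlog = ic50_meanlog, ic50_sdlog = ic50_sdlog,
                 scaffolds = scaffolds, decoys = decoys),
            class = "sig_planted_rule")
}

#' Generate a synthetic labelled compound library
#'
#' Seeded and reproducible: the same seed yields a byte-identical library.
#' Each molecule samples a scaffold and decoy substituents; with
#' probability `active_fraction` it carries the rule's pharmacophore at a
#' random ring position (ortho, meta, para or the anchor slot), so
#' positional isomers are exercised.  Labels follow the rule's
#' probabilities and active compounds draw an IC50 from its log-normal.
#'
#' @param rule a [planted_rule()].
#' @param n number of compounds (>= 10).
#' @param active_fraction probability a compound carries the
#'   pharmacophore; default 0.118, mirroring a realistic screening-assay
#'   active:inactive imbalance.
#' @param seed integer seed.
#' @return a `sig_library` with labelled records and attribute `truth`
#'   (data.frame `id`, `smiles`, `match`, `active`, `ic50_um`).
#' @export
generate_library <- function(rule = planted_rule(), n = 200L,
                             active_fraction = 0.118, seed = 1L) {
  assert_that(n >= 10L, "n must be >= 10")
  assert_that(active_fraction >= 0 && active_fraction <= 1,
              "active_fraction must be in [0, 1]")
  truth <- with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      scaffold <- sample(rule$scaffolds, 1L)
      subs <- vapply(1:4, function(s)
        if (stats::runif(1) < 0.5) sprintf("(%s)", sample(rule$decoys, 1L)) else "",
        character(1))
      match <- stats::runif(1) < active_fraction
      if (match) subs[sample.int(4L, 1L)] <- sprintf("(%s)", rule$pharmacophore)
      smiles <- sprintf(scaffold, subs[1L], subs[2L], subs[3L], subs[4L])
      active <- stats::runif(1) <
        (if (match) rule$p_active_match else rule$p_active_nomatch)
      ic50 <- if (active) stats::rlnorm(1, rule$ic50_meanlog, rule$ic50_sdlog)
              else NA_real_
      data.frame(id = sprintf("SYN%05d", i), smiles = smiles, match = match,
                 active = active, ic50_um = ic50, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  recs <- lapply(seq_len(n), function(i) {
    rec <- parse_smiles(truth$smiles[i], truth$id[i])
    rec$activity_class <- if (truth$active[i]) "active" else "inactive"
    rec$ic50_um <- truth$ic50_um[i]
    rec
  })
  lib <- sig_library(recs, provenance = sprintf("synthetic planted-rule library (seed %d)", seed))
  attr(lib, "truth") <- truth
  lib
}

#' Simulate a 96-well plate from known IC50s
#'
#' Fluorescence follows a saturating one-site inhibition curve at each
#' dilution, `inhibition = c / (c + IC50)`, scaled between the blank and
#' control levels, plus Gaussian noise.  Columns 1-9 hold up to nine
#' compounds (row 1 = highest concentration), column 10 the protein
#' check, column 11 the blank, column 12 the uninhibited control.
#'
#' @param ic50_um named numeric vector (<= 9 compounds); `Inf` or `NA`
#'   simulates an inactive compound.
#' @param noise_sd Gaussian noise standard deviation in fluorescence units
#'   (the blank-to-control window spans `control_mean - blank_mean`
#'   units).
#' @param seed integer seed.
#' @param concentrations_um dilution series (descending), default the
#'   standard eight four-fold steps from 50 uM.
#' @param blank_mean,control_mean fluorescence anchors of the plate.
#' @return a `sig_plate` matrix with attributes `ids`, `concentrations_um`
#'   and `truth_ic50_um`.
#' @export
generate_plate <- function(ic50_um, noise_sd = 0, seed = 1L,
                           concentrations_um = default_dilutions(),
                           blank_mean = 500, control_mean = 10000) {
  assert_that(length(ic50_um) >= 1L && length(ic50_um) <= 9L,
              "a plate holds 1-9 compounds")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(length(concentrations_um) == 8L,
              "plate rows hold an 8-point dilution series")
  window <- control_mean - blank_mean
  plate <- with_seed(seed, {
    m <- matrix(NA_real_, 8L, 12L, dimnames = list(LETTERS[1:8], paste0("col", 1:12)))
    for (k in seq_along(ic50_um)) {
      ic50 <- ic50_um[k]
      frac <- if (is.na(ic50) || is.infinite(ic50)) rep(0, 8L)
              else concentrations_um / (concentrations_um + ic50)
      m[, k] <- blank_mean + window * (1 - frac) + stats::rnorm(8L, 0, noise_sd)
    }
    m[, 10L] <- blank_mean + stats::rnorm(8L, 0, noise_sd)       # protein check
    m[, 11L] <- blank_mean + stats::rnorm(8L, 0, noise_sd)       # blank
    m[, 12L] <- control_mean + stats::rnorm(8L, 0, noise_sd)     # control
    empty <- setdiff(1:9, seq_along(ic50_um))
    for (k in empty) m[, k] <- control_mean + stats::rnorm(8L, 0, noise_sd)
    m
  })
  class(plate) <- c("sig_plate", class(plate))
  attr(plate, "ids") <- names(ic50_um) %||% paste0("cmpd", seq_along(ic50_um))
  attr(plate, "concentrations_um") <- concentrations_um
  attr(plate, "truth_ic50_um") <- unname(ic50_um)
  plate
}
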