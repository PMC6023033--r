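test_that("percent inhibition anchors at blank (100%) and control (0%)", {
  expect_equal(percent_inhibition(500, 500, 10000), 100)
  expect_equal(percent_inhibition(10000, 500, 10000), 0)
  expect_equal(percent_inhibition(5250, 500, 10000), 50)
  expect_error(percent_inhibition(1, 7, 7), "degenerate")
})

test_that("percent inhibition is invariant under affine fluorescence rescaling", {
  set.seed(1)
  for (k in 1:25) {
    sig <- runif(8, 500, 10000)
    a <- runif(1, 0.1, 10); b <- runif(1, -1000, 1000)
    expect_equal(percent_inhibition(a * sig + b, a * 500 + b, a * 10000 + b),
                 percent_inhibition(sig, 500, 10000), tolerance = 1e-9)
  }
})

test_that("IC50 interpolation brackets 50% linearly in concentration", {
  s <- dilution_series(c(60, 40), concentrations_um = c(40, 10))
  expect_equal(ic50_interpolate(s)$ic50_um, 25)

  # never crosses 50%: inactive, no flags
  s2 <- dilution_series(c(45, 40, 30, 22, 15, 8, 4, 1))
  f2 <- ic50_interpolate(s2)
  expect_false(f2$crossed)
  expect_true(is.na(f2$ic50_um))
  expect_false(f2$below_range)

  # everything above 50%: IC50 below tested range, flagged, still no IC50
  s3 <- dilution_series(c(99, 98, 95, 90, 85, 75, 65, 55))
  f3 <- ic50_interpolate(s3)
  expect_true(f3$below_range)
  expect_true(is.na(f3$ic50_um))

  # an exact 50% point is its own IC50
  s4 <- dilution_series(c(80, 50, 20, 10, 5, 2, 1, 0.5))
  expect_equal(ic50_interpolate(s4)$ic50_um, default_dilutions()[2])

  # non-monotone curve: bracket nearest the highest concentration, flagged
  s5 <- dilution_series(c(80, 40, 60, 30, 20, 10, 5, 1))
  f5 <- ic50_interpolate(s5)
  expect_true(f5$non_monotone)
  expect_true(f5$ic50_um > default_dilutions()[2] &&
              f5$ic50_um < default_dilutions()[1])
})

test_that("interpolated IC50 always lies inside the crossed bracket (seeded curves)", {
  set.seed(77)
  conc <- default_dilutions()
  for (k in 1:1000) {
    # monotone inhibition rising through 50% between points 3 and 4
    # (concentration-ascending order), with jitter away from the crossing
    low <- sort(runif(4, 0, 44))            # below 50, ascending with conc
    high <- sort(runif(4, 56, 100))
    inh_asc <- c(low, high)                 # index 1 = lowest concentration
    s <- dilution_series(rev(inh_asc), concentrations_um = conc)
    f <- ic50_interpolate(s)
    expect_true(f$crossed)
    lo <- rev(conc)[4]; hi <- rev(conc)[5]
    expect_true(f$ic50_um > lo && f$ic50_um < hi)
    expect_true(f$ic50_um >= min(conc) && f$ic50_um <= max(conc))
  }
})

test_that("activity calls demand an IC50 in every replicate", {
  crossing <- function(ic50) {
    conc <- default_dilutions()
    dilution_series(100 * conc / (conc + ic50), concentrations_um = conc)
  }
  flat <- dilution_series(rep(5, 8))

  call1 <- call_activity(list(crossing(10), crossing(12), crossing(11)), "c1")
  expect_true(call1$active)
  expect_equal(call1$ic50_um, mean(call1$replicate_ic50s))
  expect_false(call1$weak_activity)

  call2 <- call_activity(list(crossing(10), crossing(12), flat), "c2")
  expect_false(call2$active)
  expect_true(call2$weak_activity)
  expect_true(is.na(call2$ic50_um))

  call3 <- call_activity(list(flat, flat, flat), "c3")
  expect_false(call3$active)
  expect_false(call3$weak_activity)
})

test_that("training-set augmentation adds validated calls additively", {
  train <- make_labelled_lib(136, 16)
  outcomes <- validation_outcomes(1)
  structures <- generate_library(planted_rule(), n = 10, active_fraction = 0.5,
                                 seed = 55)
  # give the structures the tested compounds' ids
  recs <- structures$records[1:7]
  for (k in 1:7) recs[[k]]$id <- as.character(outcomes$cid[k])
  structures <- sig_library(recs, "tested candidates")
  calls <- data.frame(id = as.character(outcomes$cid), active = outcomes$active,
                      ic50_um = outcomes$experimental_ic50_um)

  aug <- augment_training_set(train, calls, structures)
  cls <- library_classes(aug)
  expect_length(aug, 143L)
  expect_equal(sum(cls == "active"), 20L)
  expect_equal(sum(cls == "inactive"), 123L)

  # empty calls: unchanged
  same <- augment_training_set(train, calls[0, ], structures)
  expect_length(same, 136L)

  # re-adding an id is a label conflict
  expect_error(augment_training_set(aug, calls, structures), "duplicate id")

  # occurrence windows only widen under augmentation
  dm_before <- build_matrix(train)
  dm_after <- build_matrix(aug)
  old <- colnames(dm_before$counts)
  expect_true(all(old %in% colnames(dm_after$counts)))
  expect_true(all(dm_after$col_min[old] <= dm_before$col_min))
  expect_true(all(dm_after$col_max[old] >= dm_before$col_max))
})

test_that("plate reduction recovers simulated IC50s", {
  # noiseless: recovery exact up to interpolation bias, inside the bracket
  plate <- generate_plate(c(cmpdA = 5), noise_sd = 0, seed = 1)
  s <- plate_series(plate, 1)
  f <- ic50_interpolate(s)
  conc <- default_dilutions()
  bracket <- conc[conc >= 5][sum(conc >= 5)]      # 12.5
  expect_true(f$ic50_um > 3.125 && f$ic50_um < 12.5)

  # IC50 above the tested range is called inactive
  plate2 <- generate_plate(c(weak = 80), noise_sd = 0, seed = 2)
  call <- call_activity(plate_series(plate2, 1), "weak")
  expect_false(call$active)

  # the protein-check QC ratio sits at the blank level
  expect_equal(attr(plate_inhibition(plate), "qc_ratio"), 0, tolerance = 1e-9)
})

test_that("triplicate means are noise-stable around the noiseless recovery", {
  truth <- 5
  noiseless <- ic50_interpolate(plate_series(
    generate_plate(c(x = truth), noise_sd = 0, seed = 1), 1))$ic50_um
  set.seed(101)
  means <- replicate(100, {
    reps <- lapply(1:3, function(r)
      plate_series(generate_plate(c(x = truth), noise_sd = 40,
                                  seed = sample.int(1e6, 1)), 1, replicate = r))
    call_activity(reps, "x")$ic50_um
  })
  expect_true(all(is.finite(means)))
  expect_lt(abs(mean(means) - noiseless) / noiseless, 0.1)
  expect_true(mean(abs(means - noiseless) / noiseless < 0.1) > 0.9)
})

test_that("read_plate round-trips a plate written as CSV", {
  plate <- generate_plate(c(a = 2, b = 30), noise_sd = 10, seed = 3)
  f <- tempfile(fileext = ".csv")
  write.table(unclass(plate), f, sep = ",", row.names = FALSE, col.names = FALSE)
  plate2 <- read_plate(f)
  expect_equal(unname(unclass(plate2)), unname(unclass(plate)), tolerance = 1e-12,
               ignore_attr = TRUE)
})
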