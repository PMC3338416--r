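# IC50 fitting with censoring, p-log conversion, selectivity ratios and
# their classification.

dilution <- function(top = 50, k = 3, n = 6) top / k^(0:(n - 1))

test_that("noise-free curves refit to their generating IC50", {
  conc <- rep(dilution(), each = 2)
  f <- fit_curve(conc, hill_viability(conc, 5, 1))
  expect_false(f$censored)
  expect_equal(f$ic50, 5, tolerance = 1e-3)
  expect_equal(f$hill_slope, 1, tolerance = 1e-3)

  # steeper slope, different midpoint
  f2 <- fit_curve(conc, hill_viability(conc, 1.8, 2.5))
  expect_equal(f2$ic50, 1.8, tolerance = 1e-3)
})

test_that("curves never crossing 50% are censored at the top concentration", {
  conc <- rep(dilution(), each = 2)
  f <- fit_curve(conc, rep(95, length(conc)))
  expect_true(f$censored)
  expect_equal(f$censor_limit, 50)
  expect_true(is.na(f$ic50))
  expect_error(fit_curve(c(1, 2, 3), c(90, 50, 10)), "4 distinct")
})

test_that("fitted IC50 is bracketed by the 50% crossing interval", {
  conc <- rep(dilution(), each = 2)
  set.seed(9)
  viab <- hill_viability(conc, 9, 1.2) + rnorm(length(conc), 0, 3)
  mv <- tapply(viab, conc, mean)
  cs <- sort(unique(conc))
  above <- mv[as.character(cs)] > 50
  lo <- max(cs[!above][which(cs[!above] < min(cs[above]))], cs[1])
  f <- fit_curve(conc, viab)
  expect_gt(f$ic50, max(cs[above & cs < min(cs[!above])], cs[1]) / 3)
  expect_lt(f$ic50, min(cs[!above]) * 3)
})

test_that("IC50 fitting is scale-equivariant in concentration", {
  conc <- rep(dilution(), each = 2)
  set.seed(2)
  noise <- rnorm(length(conc), 0, 2)
  f1 <- fit_curve(conc, hill_viability(conc, 4, 1) + noise)
  k <- 7.5
  f2 <- fit_curve(conc * k, hill_viability(conc, 4, 1) + noise)
  expect_equal(f2$ic50 / f1$ic50, k, tolerance = 1e-6)
})

test_that("p-log conversion matches printed reference values", {
  expect_equal(round(potency_to_plog(6.4e-6), 2), 5.19)
  expect_equal(potency_to_plog(1e-6), 6.00)
  expect_equal(round(potency_to_plog(80e-9), 2), 7.10)
  expect_equal(plog_to_potency(potency_to_plog(3.7e-8)), 3.7e-8,
               tolerance = 1e-12)
  expect_error(potency_to_plog(0), "positive")
  expect_error(potency_to_plog(-1), "positive")
})

cens <- function(limit) list(ic50 = NA_real_, censored = TRUE,
                             censor_limit = limit)
unc <- function(x) list(ic50 = x, censored = FALSE, censor_limit = 50)

test_that("selectivity ratios handle censoring as bounds and NT", {
  expect_equal(selectivity_ratio(unc(25), unc(5))$ratio, 5)
  expect_equal(selectivity_ratio(unc(10), unc(10))$ratio, 1)

  b <- selectivity_ratio(cens(50), unc(0.5))
  expect_equal(b$ratio, 100)
  expect_equal(b$type, "lower_bound")
  expect_equal(classify_selectivity(b), "tumor_strong")

  nt <- selectivity_ratio(unc(10), cens(50))
  expect_equal(nt$type, "nt")
  expect_equal(classify_selectivity(nt), "NT")
  expect_equal(selectivity_ratio(cens(50), cens(50))$type, "nt")
})

test_that("selectivity bins partition (0, Inf) with the documented edges", {
  expect_equal(classify_selectivity(5.0), "tumor_strong")   # inclusive
  expect_equal(classify_selectivity(4.999), "tumor_moderate")
  expect_equal(classify_selectivity(2.0), "tumor_moderate") # inclusive
  expect_equal(classify_selectivity(1.0), "unselective")
  expect_equal(classify_selectivity(0.5), "normal_moderate") # closed at 0.5
  expect_equal(classify_selectivity(0.2), "normal_strong")   # closed at 0.2
  expect_equal(classify_selectivity(0.1), "normal_strong")
  # every positive ratio gets exactly one class
  set.seed(5)
  for (r in c(10^runif(50, -3, 3), 0.2, 0.5, 2, 5)) {
    expect_length(classify_selectivity(r), 1L)
  }
})

test_that("swapping cell lines maps tumor classes to normal classes", {
  set.seed(6)
  for (r in 10^runif(40, -2, 2)) {
    cls <- classify_selectivity(r)
    swapped <- classify_selectivity(1 / r)
    map <- c(tumor_strong = "normal_strong", tumor_moderate = "normal_moderate",
             unselective = "unselective",
             normal_moderate = "tumor_moderate", normal_strong = "tumor_strong")
    # at reciprocal bin edges (5 <-> 0.2, 2 <-> 0.5) the closed sides match
    expect_equal(unname(map[cls]), swapped)
  }
})

test_that("fit_dose_response fits every compound/cell-line group", {
  ex <- small_campaign()
  truthc <- ex$camp$truth$compounds
  ids <- head(truthc$id[truthc$role == "tumor_selective"], 3)
  dr <- rbind(simulate_dose_response(ids, ex$camp$truth, "HCT116", ex$cfg),
              simulate_dose_response(ids, ex$camp$truth, "MRC5", ex$cfg))
  fits <- fit_dose_response(dr)
  expect_equal(nrow(fits), 2L * length(ids))
  sel <- selectivity_table(fits)
  expect_equal(sort(sel$compound_id), sort(ids))
  expect_true(all(sel$class %in% c("tumor_strong", "tumor_moderate",
                                   "unselective", "normal_moderate",
                                   "normal_strong", "NT")))
})
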