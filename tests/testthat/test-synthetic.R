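# Synthetic campaign generators: determinism, planted structure, and
# consistency between ground truth and the viability model.

test_that("campaign config validates its domains", {
  expect_s3_class(campaign_config(), "campaign_config")
  expect_error(campaign_config(frac_cytotoxic = 1.2), "\\[0, 1\\]")
  expect_error(campaign_config(n_conc = 3), "n_conc")
  expect_error(campaign_config(dilution_factor = 1), "dilution_factor")
  expect_error(campaign_config(frac_tumor_selective = 0.7,
                               frac_normal_selective = 0.7), "sum")
})

test_that("an empty library and identical-seed determinism hold", {
  cfg0 <- campaign_config(n_compounds = 0L, seed = 3L)
  g0 <- generate_library(cfg0)
  expect_equal(nrow(g0$library), 0L)
  expect_equal(nrow(g0$truth$compounds), 0L)

  cfg <- campaign_config(n_compounds = 60L, seed = 3L)
  a <- generate_library(cfg)
  b <- generate_library(cfg)
  expect_identical(a$library$smiles, b$library$smiles)
  expect_identical(a$truth$compounds, b$truth$compounds)
  c2 <- generate_library(campaign_config(n_compounds = 60L, seed = 4L))
  expect_false(identical(a$library$smiles, c2$library$smiles))
})

test_that("all generated structures are valid and fractions hold", {
  cfg <- campaign_config(n_compounds = 100L, frac_cytotoxic = 0.13, seed = 8L)
  g <- generate_library(cfg)
  expect_equal(parse_report(g$library)$rejected, 0L)
  n_cyto <- sum(g$truth$compounds$ic50_tumor_um <= 50)
  # binomial band: 13 +/- 3 sd
  expect_lt(abs(n_cyto - 13), 3 * sqrt(100 * 0.13 * 0.87) + 1)
})

test_that("ground truth is internally consistent", {
  ex <- small_campaign()
  t <- ex$camp$truth$targets
  expect_true(all(t$tumor_weight[t$is_cancer] > t$normal_weight[t$is_cancer]))
  cmp <- ex$camp$truth$compounds
  act <- !is.na(cmp$target_id)
  i <- match(cmp$target_id[act], t$target_id)
  shift <- ex$cfg$cell_potency_shift
  expect_equal(cmp$ic50_tumor_um[act],
               10^(6 - cmp$pact[act]) * shift / t$tumor_weight[i])
  expect_true(all(is.infinite(cmp$ic50_tumor_um[!act])))
})

test_that("primary screen wells follow the Hill expectation", {
  cfg <- campaign_config(n_compounds = 40L, viab_noise_sd = 0,
                         pos_cv = 0, neg_cv = 0, seed = 12L)
  g <- generate_library(cfg)
  scr <- simulate_primary_screen(g$library, g$truth, cfg)
  viab <- normalize_plates(scr)
  tr <- g$truth$compounds
  m <- tapply(viab$viability, viab$compound_id, mean)
  expected <- hill_viability(50, tr$ic50_tumor_um[match(names(m), tr$id)], 1)
  expect_equal(as.numeric(m), unname(expected), tolerance = 1e-9)
  # inactive compounds sit at 100%, duplicates identical without noise
  inact <- tr$id[tr$role == "inactive"]
  expect_true(all(abs(m[names(m) %in% inact] - 100) < 1e-9))
  w <- viab[viab$compound_id == viab$compound_id[1], ]
  expect_equal(w$viability[w$replicate == 1], w$viability[w$replicate == 2])
})

test_that("a compound with tumor IC50 1 uM reads ~2% viability at 50 uM", {
  expect_equal(hill_viability(50, 1, 1), 100 / 51, tolerance = 1e-12)
})

test_that("noise-free dose-response curves invert exactly", {
  cfg <- campaign_config(n_compounds = 50L, viab_noise_sd = 0, seed = 13L)
  g <- generate_library(cfg)
  tr <- g$truth$compounds
  ids <- head(tr$id[!is.na(tr$target_id)], 6)
  dr <- simulate_dose_response(ids, g$truth, "HCT116", cfg)
  # Hill midpoint: viability at the true IC50 is exactly 50%
  for (id in ids) {
    ic <- tr$ic50_tumor_um[tr$id == id]
    expect_equal(hill_viability(ic, ic, cfg$hill_slope), 50)
  }
  fits <- fit_dose_response(dr)
  tru <- tr$ic50_tumor_um[match(fits$compound_id, tr$id)]
  inr <- !fits$censored & tru >= min(dr$concentration_um) &
    tru <= max(dr$concentration_um)
  expect_true(any(inr))
  expect_lt(max(abs(fits$ic50_um[inr] - tru[inr]) / tru[inr]), 0.001)
  expect_error(simulate_dose_response(ids, g$truth, "HELA", cfg), "cell line")
})

test_that("the chemogenomics DB plants recoverable neighbor structure", {
  cfg <- campaign_config(n_compounds = 0L, n_cancer_targets = 1L,
                         n_normal_targets = 0L, n_housekeeping_targets = 0L,
                         db_ligands_per_target = 5L, seed = 21L)
  g <- generate_library(cfg)
  db <- generate_chemogenomics_db(g$truth, cfg)
  expect_equal(db_counts(db)$targets, 1L)
  expect_equal(db_counts(db)$interactions, 5L)

  # the archetype itself is a DB ligand: distance 0 to its own model
  arch <- g$truth$targets$archetype_smiles[1]
  models <- build_target_models(db)
  p <- predict_affinity(arch, models[[1]], "SHED")
  expect_false(is.null(p))

  # planted potency center: sample mean close to the archetype potency
  cfg2 <- campaign_config(n_compounds = 0L, n_cancer_targets = 1L,
                          n_normal_targets = 0L, n_housekeeping_targets = 0L,
                          db_ligands_per_target = 50L, db_pact_sd = 0.3,
                          seed = 22L)
  g2 <- generate_library(cfg2)
  db2 <- generate_chemogenomics_db(g2$truth, cfg2)
  expect_lt(abs(mean(db2$pact) - g2$truth$targets$archetype_pact[1]), 0.15)
})

test_that("every planted cancer target has an in-domain selective compound", {
  ex <- small_campaign()
  truth <- ex$camp$truth
  models <- build_target_models(ex$camp$db)
  sel <- truth$compounds[truth$compounds$role == "tumor_selective", ]
  covered <- unique(sel$target_id)
  lib <- ex$camp$library
  for (t in covered) {
    ids <- sel$id[sel$target_id == t]
    hits <- FALSE
    for (id in ids) {
      prof <- profile_compound(lib$smiles[lib$id == id], models, id)
      if (t %in% prof$target_id) { hits <- TRUE; break }
    }
    expect_true(hits, label = paste("target", t, "recoverable"))
  }
})

test_that("annotations reflect planted oncogene structure", {
  cfg <- campaign_config(n_compounds = 0L, n_cancer_targets = 20L,
                         n_normal_targets = 0L, n_housekeeping_targets = 0L,
                         oncoscore_na_fraction = 0, seed = 30L)
  g <- generate_library(cfg)
  ann <- generate_annotations(g$truth, cfg)
  expect_gt(mean(ann$oncoscore), 0.7)   # Beta(8, 2) has mean 0.8

  cfg2 <- campaign_config(n_compounds = 0L, seed = 30L,
                          family_proportions = c(enzyme = 1))
  g2 <- generate_library(cfg2)
  ann2 <- generate_annotations(g2$truth, cfg2)
  expect_true(all(ann2$family == "enzyme"))
  expect_true(all(ann2$ec_class != "none"))
  expect_identical(ann2, generate_annotations(g2$truth, cfg2))
})
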