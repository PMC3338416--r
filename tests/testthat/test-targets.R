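# Target models, applicability domain and IDW affinity prediction.

test_that("model building stores every reference and honors min_ligands", {
  db <- chemogenomics_db(data.frame(
    ligand_id = c("l1", "l2", "l3", "l4"),
    smiles = c("CCO", "CCN", "CCCO", "c1ccccc1"),
    target_id = c("T1", "T1", "T1", "T2"),
    pact = c(5, 6, 7, 8)))
  ms <- build_target_models(db)
  expect_length(ms, 2L)
  expect_setequal(ms$T1$pact, c(5, 6, 7))
  expect_true(all(ms$T1$radius > 0))

  ms2 <- build_target_models(db, min_ligands = 2)
  expect_length(ms2, 1L)
  expect_equal(attr(ms2, "excluded"), "T2")
  expect_error(build_target_models(db, min_ligands = 10), "no target")

  one <- build_target_models(chemogenomics_db(data.frame(
    ligand_id = "l1", smiles = "CCO", target_id = "T1", pact = 7)))
  expect_length(one, 1L)
  expect_length(one$T1$pact, 1L)
})

test_that("IDW prediction follows the zero-distance and weighting rules", {
  m <- fake_model(list(c(0, 0), c(1, 0), c(2, 0)), pacts = c(7.2, 6, 9))
  # exact match -> that reference's pAct
  expect_equal(predict_affinity(list(SHED = fake_shed(c(0, 0))), m, "SHED")$pact,
               7.2)
  # hand IDW: neighbors at d=1 (pact 6) and d=2 (pact 9), power 2,
  # query at (2,0) sees d=2 to (0,0)... use a query at (1,0)+offset instead
  m2 <- fake_model(list(c(1, 0), c(2, 0)), pacts = c(6, 9))
  p <- predict_affinity(list(SHED = fake_shed(c(0, 0))), m2, "SHED", power = 2)
  expect_equal(p$pact, (6 + 9 / 4) / (1 + 1 / 4))  # 6.6
  expect_equal(p$n_neighbors, 2L)
  # all references beyond the radius -> no prediction
  m3 <- fake_model(list(c(5, 0)), pacts = 8, radius = 1)
  expect_null(predict_affinity(list(SHED = fake_shed(c(0, 0))), m3, "SHED"))
})

test_that("IDW equals a brute-force oracle on random synthetic cases", {
  set.seed(10)
  for (case in 1:100) {
    k <- sample(2:8, 1)
    refs <- lapply(seq_len(k), function(i) runif(5, 0, 3))
    pacts <- runif(k, 3, 9)
    radius <- runif(1, 0.5, 4)
    power <- sample(c(1, 2, 3), 1)
    q <- runif(5, 0, 3)
    m <- fake_model(refs, pacts, radius = radius)
    got <- predict_affinity(list(SHED = fake_shed(q)), m, "SHED", power = power)
    # independent recomputation
    d <- vapply(refs, function(r) sqrt(sum((q - r)^2)), 0)
    nb <- which(d <= radius)
    if (!length(nb)) {
      expect_null(got)
    } else if (any(d[nb] == 0)) {
      expect_equal(got$pact, mean(pacts[nb][d[nb] == 0]), tolerance = 1e-9)
    } else {
      w <- d[nb]^(-power)
      expect_equal(got$pact, sum(w * pacts[nb]) / sum(w), tolerance = 1e-9)
      expect_gte(got$pact, min(pacts[nb]) - 1e-9)   # boundedness
      expect_lte(got$pact, max(pacts[nb]) + 1e-9)
    }
  }
})

test_that("shrinking the applicability radius never adds predictions", {
  ex <- small_campaign()
  db <- ex$camp$db
  lib <- ex$camp$library[1:12, ]
  class(lib) <- c("compound_library", "data.frame")
  m_wide <- build_target_models(db, radius = c(SHED = 2, FPD = 2, PHRAG = 0.6))
  m_narrow <- build_target_models(db, radius = c(SHED = 0.5, FPD = 0.5,
                                                 PHRAG = 0.15))
  p_wide <- profile_library(lib, m_wide)
  p_narrow <- profile_library(lib, m_narrow)
  expect_lte(nrow(p_narrow), nrow(p_wide))
  expect_true(all(paste(p_narrow$compound_id, p_narrow$target_id) %in%
                    paste(p_wide$compound_id, p_wide$target_id)))
})

test_that("profiles use max-consensus across spaces", {
  m <- fake_model(list(c(1, 0), c(2, 0)), pacts = c(6, 9))
  # SHED predicts 6.6; FPD descriptors are the same synthetic vectors so
  # also predict; PHRAG has empty bags (distance 0 to empty query: exact)
  desc <- list(SHED = fake_shed(c(0, 0)), FPD = structure(c(0, 0), space = "FPD"),
               PHRAG = structure(integer(), names = character(), space = "PHRAG"))
  prof <- profile_compound(desc, list(FAKE = m), "q")
  expect_equal(nrow(prof), 1L)
  # PHRAG sees both refs at distance 0 -> mean(6, 9) = 7.5, the max
  expect_equal(prof$pact_pred, 7.5)
  expect_equal(prof$space, "PHRAG")

  expect_equal(nrow(profile_compound(desc, list(), "q")), 0L)
})

test_that("potency filtering is inclusive at the cutoff", {
  x <- data.frame(compound_id = "c", target_id = c("a", "b", "c"),
                  pact_pred = c(5.5, 6.0, 7.3))
  expect_equal(filter_potent(x)$pact_pred, c(6.0, 7.3))
  expect_equal(nrow(filter_potent(x, 7.31)), 0L)
})

test_that("profile summaries report printed-style coverage statistics", {
  ids <- sprintf("c%03d", 1:265)
  covered <- ids[1:173]
  # 2356 raw interactions over 173 covered molecules; 818 of them potent,
  # spread over 139 molecules and 229 targets
  raw <- data.frame(
    compound_id = c(rep(covered[1:139], length.out = 818),
                    rep(covered, length.out = 2356 - 818)),
    target_id = c(sprintf("t%03d", rep(1:229, length.out = 818)),
                  rep("t001", 2356 - 818)),
    pact_pred = c(rep(6.5, 818), rep(5.0, 2356 - 818)))
  s <- profile_summary(ids, raw)
  expect_equal(s$pct_covered, 65)
  expect_equal(s$n_filtered, 818L)
  expect_equal(s$n_molecules_filtered, 139L)
  expect_equal(s$targets_per_molecule, 6)

  s0 <- profile_summary(ids, raw[0, ])
  expect_equal(s0$n_covered, 0L)
  expect_equal(s0$pct_covered, 0)
})

test_that("archetype probes recover their own target within the domain", {
  ex <- small_campaign()
  truth <- ex$camp$truth
  models <- build_target_models(ex$camp$db)
  t <- truth$targets[truth$targets$is_cancer, ][1:8, ]
  errs <- vapply(seq_len(nrow(t)), function(i) {
    prof <- profile_compound(t$archetype_smiles[i], models)
    row <- prof[prof$target_id == t$target_id[i], ]
    expect_gte(nrow(row), 1L)   # inside own applicability domain
    abs(row$pact_pred[1] - t$archetype_pact[i])
  }, 0)
  expect_lt(stats::median(errs), 0.5)
})
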