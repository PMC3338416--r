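# Differential target-set analytics: Venn algebra, compositions,
# OncoScore prioritization, drug ranking, pathway overlaps.

test_that("Venn partition reproduces the published set arithmetic", {
  tum <- sprintf("T%03d", 1:229)
  nor <- c(sprintf("T%03d", 116:229), sprintf("N%03d", 1:46))  # 114 shared
  v <- venn_partition(tum, nor)
  expect_equal(unname(v$sizes), c(115L, 114L, 46L))

  d <- venn_partition(c("a", "b"), c("c"))
  expect_equal(d$shared, character())
  e <- venn_partition(c("a", "b"), c("b", "a"))
  expect_equal(unname(e$sizes), c(0L, 2L, 0L))
})

test_that("Venn sizes are conserved for random sets", {
  set.seed(14)
  for (i in 1:25) {
    t <- sample(letters, sample(0:20, 1))
    n <- sample(letters, sample(0:20, 1))
    v <- venn_partition(t, n)
    expect_equal(v$sizes[["tumor_unique"]] + v$sizes[["shared"]],
                 length(unique(t)))
    expect_equal(v$sizes[["normal_unique"]] + v$sizes[["shared"]],
                 length(unique(n)))
    expect_equal(length(intersect(v$tumor_unique, v$normal_unique)), 0L)
  }
})

test_that("family composition matches printed percentages", {
  panel <- synthetic_tumor_panel()
  fam <- family_composition(panel$target_id, panel)
  expect_equal(sum(fam$counts), 115L)
  expect_equal(unname(fam$counts["enzyme"]), 67L)
  expect_equal(unname(fam$percent["enzyme"]), 58)
  expect_equal(unname(fam$percent["GPCR"]), 16)

  single <- target_annotations(data.frame(
    target_id = c("a", "b"), gene = c("A", "B"), family = "GPCR",
    ec_class = "none", oncoscore = NA, regulation = "none"))
  fc <- family_composition(c("a", "b"), single)
  expect_equal(unname(fc$percent["GPCR"]), 100)
  expect_length(family_composition(character(), single)$counts, 0L)
})

test_that("enzyme class composition is restricted to enzymes", {
  panel <- synthetic_tumor_panel()
  ec <- enzyme_class_composition(panel$target_id, panel)
  expect_equal(sum(ec$counts), 67L)
  expect_equal(unname(ec$counts["transferase"]), 29L)
  expect_equal(unname(ec$percent["transferase"]), 43)
  no_enz <- target_annotations(data.frame(
    target_id = "a", gene = "A", family = "GPCR", ec_class = "none",
    oncoscore = NA, regulation = "none"))
  expect_length(enzyme_class_composition("a", no_enz)$counts, 0L)
})

test_that("OncoScore analytics reproduce the published table facts", {
  panel <- synthetic_tumor_panel()
  expect_equal(nrow(panel), 115L)
  # 42 of 115 strictly above 0.7 -> 36.5%
  expect_equal(oncoscore_cumulative(panel$target_id, panel, 0.7), 36.5)
  expect_equal(oncoscore_cumulative(panel$target_id, panel, 1.0), 0)

  top <- high_score_subset(panel$target_id, panel, 0.7)
  expect_equal(nrow(top), 42L)
  expect_true(all(diff(top$oncoscore) <= 0))
  expect_equal(count_regulation_flagged(top), 10L)

  # monotone filter: a higher cutoff returns a subset
  top99 <- high_score_subset(panel$target_id, panel, 0.9999)
  expect_true(all(top99$target_id %in% top$target_id))
  expect_equal(nrow(high_score_subset(character(), panel, 0.7)), 0L)
  expect_equal(count_regulation_flagged(top[top$regulation == "none", ]), 0L)
})

test_that("oncoscore_cumulative is non-increasing in the cutoff", {
  panel <- synthetic_tumor_panel()
  vals <- vapply(seq(0, 1, by = 0.1), function(ct)
    oncoscore_cumulative(panel$target_id, panel, ct), 0)
  expect_true(all(diff(vals) <= 0))
  all1 <- target_annotations(data.frame(
    target_id = letters[1:5], gene = LETTERS[1:5], family = "other",
    ec_class = "none", oncoscore = 1.0, regulation = "none"))
  expect_equal(oncoscore_cumulative(letters[1:5], all1, 0.7), 100)
})

test_that("drug ranking counts, bins and thresholds correctly", {
  mk <- function(id, pacts) data.frame(
    ligand_id = id, smiles = "CCO",
    target_id = sprintf("%s_t%d", id, seq_along(pacts)), pact = pacts)
  df <- rbind(mk("d6", c(6.5, 6.0, 6.9, 7.2, 8.1, 9.3)),
              mk("d5", c(6.5, 6.1, 6.9, 7.2, 8.1)),
              mk("dlow", c(5.0, 5.5)),
              mk("edge", c(7.0, 6, 6, 6, 6, 6)))
  targets <- unique(df$target_id)
  r <- rank_drugs(df, targets, paff_min = 6, min_targets = 5)
  expect_setequal(r$drug_id, c("d6", "edge"))   # exactly 5 targets excluded
  d6 <- r[r$drug_id == "d6", ]
  expect_equal(unlist(d6[c("bin_6_7", "bin_7_8", "bin_8_9", "bin_9_plus")],
                      use.names = FALSE), c(3L, 1L, 1L, 1L))
  # pAffinity exactly 7 goes to [7, 8)
  edge <- r[r$drug_id == "edge", ]
  expect_equal(edge$bin_7_8, 1L)
  expect_equal(edge$bin_6_7, 5L)

  # invariant to permuting interaction rows
  set.seed(15)
  r2 <- rank_drugs(df[sample(nrow(df)), ], targets, 6, 5)
  expect_identical(r, r2)
})

test_that("pathway overlap counts reproduce the published memberships", {
  pw <- synthetic_pathway_fixture()
  t1 <- load_oncoscore_table()
  po <- pathway_overlap(pw, t1$gene)
  expect_equal(po$overlap$n_overlap[po$overlap$pathway == "MAPK_SIGNALING"], 7L)
  expect_equal(po$overlap$n_overlap[po$overlap$pathway == "ERK1_ERK2_MAPK"], 6L)
  expect_equal(po$overlap$n_overlap[po$overlap$pathway == "UNRELATED_SET"], 0L)
  expect_equal(po$summary$n_ge2, 2L)
  expect_equal(po$summary$n_ge5, 2L)

  sub <- structure(list(S = list(name = "S", description = "",
                                 genes = c("BRAF", "RAF1"))),
                   class = "pathway_sets")
  expect_equal(pathway_overlap(sub, t1$gene)$overlap$n_overlap, 2L)
})

test_that("the published high-OncoScore table fixture is intact", {
  t1 <- load_oncoscore_table()
  expect_equal(nrow(t1), 42L)
  expect_equal(count_regulation_flagged(t1), 10L)
  expect_true(all(t1$oncoscore > 0.7))
  expect_equal(t1$gene[1], "PDGFRA")
  expect_equal(t1$oncoscore[42], 0.701)
})
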