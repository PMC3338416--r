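# Murcko chemotype assignment, clustering, enrichment and selection.

test_that("chemotype keys are ring-linker frameworks or acyclic singletons", {
  benzene <- assign_chemotype("c1ccccc1")
  expect_equal(assign_chemotype("Cc1ccccc1"), benzene)    # side chains pruned
  expect_equal(assign_chemotype("CCc1ccccc1"), benzene)
  expect_equal(assign_chemotype("CCC"), "CCC")            # acyclic singleton
  # biphenyl keeps its linker
  bip <- assign_chemotype("c1ccc(-c2ccccc2)cc1")
  expect_equal(assign_chemotype("Cc1ccc(-c2ccccc2C)cc1"), bip)
  expect_false(bip == benzene)
  expect_error(assign_chemotype("C1CC"), "unparseable")
})

test_that("cluster_library partitions the library by framework", {
  lib <- compound_library(c("t", "e", "c"),
                          c("Cc1ccccc1", "CCc1ccccc1", "C1CCCCC1"))
  cl <- cluster_library(lib)
  expect_equal(nrow(cl), 2L)
  expect_equal(sum(cl$n_members), nrow(lib))
  expect_setequal(cl$member_ids[[which(cl$n_members == 2)]], c("t", "e"))

  empty <- cluster_library(compound_library(character(), character()))
  expect_equal(nrow(empty), 0L)
})

test_that("clustering is a deterministic partition on generated libraries", {
  ex <- small_campaign()
  lib <- ex$camp$library[1:80, ]
  class(lib) <- c("compound_library", "data.frame")
  cl1 <- cluster_library(lib)
  cl2 <- cluster_library(lib)
  expect_identical(cl1$scaffold_key, cl2$scaffold_key)
  expect_equal(sum(cl1$n_members), nrow(lib))
  expect_equal(sort(unlist(cl1$member_ids)), sort(lib$id))
})

test_that("enrichment is selective over tested members only", {
  members <- sprintf("m%02d", 1:15)
  tested <- members[1:10]
  selective <- members[c(1, 4, 7)]
  expect_equal(enrichment_score(members, selective, tested), 0.30)
  expect_equal(enrichment_score(members, character(), tested), 0)
  expect_true(is.na(enrichment_score(c("x", "y"), selective, tested)))
  expect_error(enrichment_score(members, c("zzz"), tested), "subset")
  # untested members never change the score
  expect_equal(enrichment_score(c(members, "extra1", "extra2"),
                                selective, tested), 0.30)
})

test_that("expansion selects untested members of clusters above threshold", {
  clusters <- data.frame(scaffold_key = c("A", "B", "C"),
                         n_members = c(8L, 5L, 4L))
  clusters$member_ids <- list(sprintf("a%d", 1:8), sprintf("b%d", 1:5),
                              sprintf("c%d", 1:4))
  tested <- c(sprintf("a%d", 1:4), sprintf("b%d", 1:5), "c1")
  selective <- c("a1", "a2", "b1")   # A: 2/4 = 0.5, B: 1/5 = 0.2, C: 0/1
  scored <- score_clusters(structure(clusters,
                                     class = c("chemotype_clusters", "data.frame")),
                           selective, tested)
  untested <- c(sprintf("a%d", 5:8), sprintf("c%d", 2:4))
  sel <- select_expansion(scored, untested, 0.20)
  # exactly-20% cluster B is excluded ("higher than 20%" is strict)
  expect_setequal(sel, sprintf("a%d", 5:8))
  expect_equal(select_expansion(scored, untested, 0.60), character())

  # monotone: raising the threshold never adds compounds
  for (th in c(0, 0.1, 0.3, 0.5, 0.9)) {
    expect_true(all(select_expansion(scored, untested, min(th + 0.1, 1)) %in%
                      select_expansion(scored, untested, th)))
  }
})

test_that("MaxMin diversity selection is greedy, nested and deterministic", {
  lib <- compound_library(c("p1", "p2", "p3"), c("C", "CC", "CCC"))
  d <- matrix(c(0, 1, 2,
                1, 0, 1,
                2, 1, 0), 3, 3, dimnames = list(lib$id, lib$id))
  # three colinear points: the two extremes win for k = 2 (brute force:
  # the pair (p1, p3) maximizes the pairwise distance)
  expect_setequal(diversity_select(lib, 2, dist_matrix = d), c("p1", "p3"))
  expect_setequal(diversity_select(lib, 3, dist_matrix = d), lib$id)
  expect_length(diversity_select(lib, 1, dist_matrix = d), 1L)
  expect_error(diversity_select(lib, 4, dist_matrix = d), "exceeds")

  ex <- small_campaign()
  sub <- ex$camp$library[1:25, ]
  class(sub) <- c("compound_library", "data.frame")
  sels <- lapply(1:6, function(k) diversity_select(sub, k))
  for (k in 1:5) expect_identical(sels[[k]], sels[[k + 1]][1:k])
})
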