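# Plate QC, viability normalization, hit calling, bookkeeping.

test_that("viability normalization follows the control-anchored formula", {
  p <- plate_stats("P1", pos_mean = 1000, pos_sd = 50, neg_mean = 100,
                   neg_sd = 40)
  expect_equal(normalize_viability(1000, p), 100)
  expect_equal(normalize_viability(100, p), 0)
  expect_equal(normalize_viability(550, p), 50)
  # out-of-range values are preserved, never clipped
  expect_equal(normalize_viability(1090, p), 110)
  expect_error(normalize_viability(500, plate_stats("P2", 100, 1, 100, 1)),
               "degenerate")
})

test_that("Z' matches closed forms and caps at 1", {
  expect_equal(zprime(plate_stats("a", 1000, 0, 100, 0)), 1.0)
  expect_equal(zprime(plate_stats("b", 1000, 50, 100, 40)), 0.70)
  expect_equal(zprime(plate_stats("c", 1000, 100, 100, 50)), 0.50)
  expect_error(zprime(plate_stats("d", 5, 1, 5, 1)), "degenerate")
})

test_that("Z' is invariant under positive affine transforms of the signal", {
  set.seed(4)
  for (i in 1:20) {
    mp <- runif(1, 500, 5000); mn <- runif(1, 10, mp / 2)
    sp <- runif(1, 0, mp / 10); sn <- runif(1, 0, mn / 3)
    a <- runif(1, 0.1, 50); b <- runif(1, -100, 100)
    z0 <- zprime(plate_stats("x", mp, sp, mn, sn))
    z1 <- zprime(plate_stats("x", a * mp + b, a * sp, a * mn + b, a * sn))
    expect_equal(z0, z1)
    expect_lte(z1, 1)
  }
})

test_that("signal-to-background is mu_p / mu_n with guarded domain", {
  expect_equal(signal_to_background(plate_stats("a", 1000, 1, 100, 1)), 10)
  expect_equal(signal_to_background(plate_stats("b", 100, 1, 100, 1)), 1)
  expect_error(signal_to_background(plate_stats("c", 100, 1, 0, 0)),
               "positive")
})

test_that("hit calling averages replicates and is inclusive at the threshold", {
  rec <- data.frame(
    compound_id = rep(c("a", "b", "c", "d"), each = 2),
    viability = c(10, 10, 20.05, 20.15, 19.8, 20.0, 99, 101))
  hits <- call_cytotoxic_hits(rec, 20)
  expect_setequal(hits, c("a", "c"))
  # exactly 20.0 mean is a hit ("20% or lower")
  expect_true("e" %in% call_cytotoxic_hits(
    data.frame(compound_id = "e", viability = 20.0)))
})

test_that("hit calls are invariant to plate gain", {
  ex <- small_campaign()
  plates <- ex$camp$plates
  h1 <- call_cytotoxic_hits(normalize_plates(plates))
  plates$raw_signal <- plates$raw_signal * 3.7
  h2 <- call_cytotoxic_hits(normalize_plates(plates))
  expect_identical(h1, h2)
})

test_that("duplicate concordance returns pairs and Pearson r", {
  rec <- data.frame(compound_id = rep(c("a", "b", "c"), each = 2),
                    replicate = rep(1:2, 3),
                    viability = c(10, 10, 50, 50, 90, 90))
  expect_equal(duplicate_concordance(rec)$correlation, 1.0)

  rec$viability[rec$replicate == 2] <- 100 - rec$viability[rec$replicate == 2]
  expect_equal(duplicate_concordance(rec)$correlation, -1.0)

  # hand pairs against the explicit textbook formula
  x <- c(12, 40, 77); y <- c(15, 52, 60)
  rec2 <- data.frame(compound_id = rep(c("a", "b", "c"), each = 2),
                     replicate = rep(1:2, 3),
                     viability = as.vector(rbind(x, y)))
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(duplicate_concordance(rec2)$correlation, r_hand)

  # missing replicate: compound excluded and counted
  rec3 <- rbind(rec2, data.frame(compound_id = "d", replicate = 1,
                                 viability = 5))
  cc <- duplicate_concordance(rec3)
  expect_equal(cc$n_excluded, 1L)
  expect_equal(nrow(cc$pairs), 3L)
})

test_that("campaign data-point bookkeeping is exact", {
  expect_equal(count_data_points(30000, 2, 2480, 6, 2, 2), 119520)
  expect_equal(count_data_points(0, 0, 0, 0, 0, 0), 0)
  expect_equal(count_data_points(10, 2, 2, 6, 2, 2), 68)
})

test_that("simulated plates land in the documented Z' band", {
  ex <- small_campaign()
  zs <- vapply(compute_plate_stats(ex$camp$plates), zprime, 0)
  expect_true(all(zs > 0.5 & zs < 0.9))
  sb <- vapply(compute_plate_stats(ex$camp$plates), signal_to_background, 0)
  expect_true(all(abs(sb - 10) < 2))
})
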