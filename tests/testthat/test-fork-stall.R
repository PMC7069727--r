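one_chrom <- function(len = 1e6) tibble::tibble(chrom = "chrI", length = len)

test_that("stall zones are flanked, clipped and merged intervals", {
  z <- build_stall_zones(tibble::tibble(chrom = "chrI", pos = 1e5),
                         one_chrom())
  expect_equal(c(z$start, z$end), c(95000, 105000))
  # two forks 6 kb apart merge into one 16-kb zone
  z2 <- build_stall_zones(tibble::tibble(chrom = "chrI", pos = c(1e5, 1.06e5)),
                          one_chrom())
  expect_equal(nrow(z2), 1)
  expect_equal(z2$end - z2$start, 16000)
  # near the chromosome start: clipped at 0
  z3 <- build_stall_zones(tibble::tibble(chrom = "chrI", pos = 2000),
                          one_chrom())
  expect_equal(c(z3$start, z3$end), c(0, 7000))
  # empty input: empty zone set with zero bp
  z4 <- build_stall_zones(tibble::tibble(chrom = character(), pos = numeric()),
                          one_chrom())
  expect_equal(nrow(z4), 0)
  expect_equal(attr(z4, "zone_bp"), 0)
  expect_error(
    build_stall_zones(tibble::tibble(chrom = "chrI", pos = 2e6), one_chrom()),
    "outside"
  )
})

test_that("duplicating a fork position never changes the zone set", {
  pos <- tibble::tibble(chrom = "chrI", pos = c(1e5, 3e5, 3e5, 1e5))
  z_dup <- build_stall_zones(pos, one_chrom())
  z <- build_stall_zones(dplyr::distinct(pos), one_chrom())
  expect_equal(as.data.frame(z_dup), as.data.frame(z))
  expect_equal(attr(z_dup, "zone_bp"), attr(z, "zone_bp"))
})

test_that("chi-square enrichment reproduces the hand-worked table", {
  # 10 features, zones 10% of the genome, 5 observed inside:
  # expected 1 in / 9 out, X2 = 16/1 + 16/9
  z <- build_stall_zones(tibble::tibble(chrom = "chrI", pos = 5e4),
                         one_chrom(), flank = 5e4)
  feats <- tibble::tibble(
    chrom = "chrI",
    start = c(seq(1e4, 9e4, 2e4), seq(1.5e5, 9.5e5, 2e5)),
    end = c(seq(1e4, 9e4, 2e4), seq(1.5e5, 9.5e5, 2e5)) + 1
  )
  res <- feature_enrichment(feats, z)
  expect_equal(res$observed_in_zones, 5)
  expect_equal(res$expected_in_zones, 1)
  expect_equal(res$chi_square, 16 / 1 + 16 / 9, tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(16 + 16 / 9, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$direction, "over")
  expect_false(res$low_count)  # expected in-zone cell exactly 1, not < 1
  # one fewer feature pushes the expected in-zone cell below 1
  res9 <- feature_enrichment(feats[-1, ], z)
  expect_true(res9$low_count)
})

test_that("observed equal to expected gives a null chi-square", {
  # zones covering the whole genome: every feature inside, X2 = 0, p = 1
  z <- build_stall_zones(tibble::tibble(chrom = "chrI", pos = 5e5),
                         one_chrom(), flank = 5e5)
  feats <- tibble::tibble(chrom = "chrI", start = seq(1e4, 9e5, 1e5),
                          end = seq(1e4, 9e5, 1e5) + 1)
  res <- feature_enrichment(feats, z)
  expect_equal(res$observed_in_zones, res$n_total)
  expect_equal(res$chi_square, 0)
  expect_equal(res$p_value, 1)
})

test_that("per-class tests honour the membership rule", {
  z <- build_stall_zones(tibble::tibble(chrom = "chrI", pos = 1e5),
                         one_chrom())
  feats <- tibble::tibble(
    chrom = "chrI",
    start = c(96000, 5e5), end = c(97000, 5.01e5),
    class = c("tRNA", "LTR")
  )
  res <- feature_enrichment(feats, z)
  expect_equal(nrow(res), 2)
  expect_equal(res$observed_in_zones[res$feature_class == "tRNA"], 1)
  expect_equal(res$observed_in_zones[res$feature_class == "LTR"], 0)
  # a feature straddling the zone edge counts under any_overlap
  straddle <- tibble::tibble(chrom = "chrI", start = 104000, end = 120000)
  expect_equal(feature_enrichment(straddle, z)$observed_in_zones, 0) # midpoint out
  expect_equal(feature_enrichment(straddle, z,
                                  by = "any_overlap")$observed_in_zones, 1)
})

test_that("simulated feature placement matches its normalised probability", {
  zones <- tibble::tibble(start = 0, end = 1e5)  # 10% of a 1-Mb genome
  # enrichment factor 1: expected in-zone count = n * zone fraction
  out <- simulate_feature_annotations(1e6, zones, 500, 1, seed = 21)
  expect_lt(abs(sum(out$start < 1e5) - 50), 3 * sqrt(500 * 0.1 * 0.9))
  # factor 5: P(in) = 0.5/1.4, expected ~ 35.7 of 100
  p_in <- sim_truth(simulate_feature_annotations(1e6, zones, 100, 5,
                                                 seed = 1))$p_in_zone
  expect_equal(p_in, 0.5 / 1.4, tolerance = 1e-12)
  ins <- vapply(1:60, function(s) {
    sum(simulate_feature_annotations(1e6, zones, 100, 5,
                                     seed = 100 + s)$start < 1e5)
  }, numeric(1))
  se <- sqrt(100 * p_in * (1 - p_in) / length(ins))
  expect_lt(abs(mean(ins) - 100 * p_in), 3 * se)
  # zones covering the whole genome: everything inside
  all_in <- simulate_feature_annotations(1e6, tibble::tibble(start = 0,
                                                             end = 1e6),
                                         50, 2, seed = 3)
  expect_equal(nrow(all_in), 50)
  expect_error(simulate_feature_annotations(1e6, zones, -1), ">= 0")
})

test_that("enrichment direction matches the simulated factor", {
  z <- build_stall_zones(tibble::tibble(chrom = "chr_sim", pos = 5e4),
                         tibble::tibble(chrom = "chr_sim", length = 1e6),
                         flank = 5e4)
  hits <- vapply(1:20, function(s) {
    f <- simulate_feature_annotations(1e6, tibble::tibble(start = 0, end = 1e5),
                                      100, 5, seed = 500 + s)
    feature_enrichment(f, z)$direction == "over"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
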