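test_that("probe-to-region mapping uses half-open intervals", {
  ds <- toy_dataset(n_probes = 1, pos = 100)
  regions <- data.frame(chrom = "chr1", start = c(100L, 0L), end = c(200L, 100L),
                        name = c("in", "out"))
  m <- map_probes_to_regions(ds, regions)
  expect_equal(names(m$region_probes), "in")
  expect_equal(m$skipped, "out")

  # overlapping regions both get the probe
  regions2 <- data.frame(chrom = "chr1", start = c(50L, 90L), end = c(150L, 110L),
                         name = c("r1", "r2"))
  m2 <- map_probes_to_regions(ds, regions2)
  expect_equal(unname(m2$region_probes), list(1L, 1L))
})

test_that("ACF estimation honours its degenerate and exact contracts", {
  # constant z: zero variance -> all bins 0
  acf0 <- estimate_acf(rep(1, 100), rep("chr1", 100), seq(0, by = 10, length.out = 100))
  expect_equal(acf0$corr, rep(0, 6))

  # identical z duplicated at 10 bp apart -> the covering bin estimates 1
  set.seed(3)
  z <- rep(rnorm(40), each = 2)
  pos <- as.vector(rbind(seq(0, by = 5000, length.out = 40),
                         seq(0, by = 5000, length.out = 40) + 10))
  acf1 <- estimate_acf(z, rep("chr1", 80), pos, lag_bins = c(1, 11, 101))
  expect_equal(acf1$corr[2], 1)

  # i.i.d. z: all bins near 0 (and never negative by the truncation rule)
  set.seed(4)
  n <- 10000
  acf2 <- estimate_acf(rnorm(n), rep("chr1", n),
                       cumsum(pmax(2, round(rexp(n, 1 / 200)))))
  expect_true(all(acf2$corr >= 0 & acf2$corr <= 0.05))

  expect_error(estimate_acf(1, "chr1", 10), "2 probes")
})

test_that("Stouffer-Liptak matches its closed forms", {
  # identity on a singleton
  expect_equal(stouffer_liptak(0.03, matrix(1, 1, 1)), 0.03, tolerance = 1e-12)
  # four independent p = 0.05
  expected <- pnorm(2 * qnorm(0.95), lower.tail = FALSE)
  expect_equal(stouffer_liptak(rep(0.05, 4), diag(4)), expected, tolerance = 1e-12)
  expect_equal(expected, 5.0145833e-4, tolerance = 1e-6)
  # complete dependence collapses to a single test
  sig <- matrix(1, 5, 5)
  expect_equal(stouffer_liptak(rep(0.2, 5), sig), 0.2, tolerance = 1e-12)
  expect_error(stouffer_liptak(numeric(0)), "empty")
})

test_that("combined p is monotone in member p-values", {
  set.seed(8)
  sig <- diag(6); sig[sig == 0] <- 0.3
  p <- runif(6, 0.1, 0.9)
  base <- stouffer_liptak(p, sig)
  for (i in 1:6) {
    p2 <- p; p2[i] <- p[i] * 0.5
    expect_lt(stouffer_liptak(p2, sig), base)
  }
})

test_that("Sidak correction matches direct evaluation and is monotone", {
  # p = 0.01, m = 10
  expect_equal(sidak_correct(0.01, 100, 1000), 1 - 0.99^10, tolerance = 1e-12)
  # m = 1 returns p unchanged
  expect_identical(sidak_correct(0.37, 500, 500), 0.37)
  # small-p linearization: q ~ m p
  expect_equal(sidak_correct(1e-9, 100, 10000), 100 * 1e-9, tolerance = 1e-2)
  # monotone in p and in m
  p <- seq(0.001, 0.5, length.out = 50)
  q <- sidak_correct(p, 100, 5000)
  expect_true(all(diff(q) > 0))
  expect_true(all(q >= p))
  q_m <- vapply(c(1, 2, 5, 10, 100), function(m) sidak_correct(0.01, 100, 100 * m), 0)
  expect_true(all(diff(q_m) > 0))
  expect_error(sidak_correct(0.1, 0, 100), "positive")
})

test_that("region change summary is the min/median/max of per-probe median differences", {
  # identical groups: all zero
  b <- matrix(rep(c(0.3, 0.6), each = 4), 2, 4, byrow = TRUE)
  ds <- toy_dataset(beta = b)
  expect_equal(unname(region_change_summary(ds, c("A", "B"), c("p01", "p02"))),
               c(0, 0, 0))

  # single probe, group medians 0.5 (A) and 0.7 (B)
  b1 <- matrix(c(0.4, 0.6, 0.65, 0.75), 1, 4)
  ds1 <- toy_dataset(beta = b1)
  expect_equal(unname(region_change_summary(ds1, c("A", "B"), "p01")),
               c(0.2, 0.2, 0.2), tolerance = 1e-12)

  # three probes constructed to give d = {-0.1, 0.05, 0.3}
  b3 <- rbind(c(0.5, 0.5, 0.4, 0.4),
              c(0.2, 0.2, 0.25, 0.25),
              c(0.1, 0.1, 0.4, 0.4))
  ds3 <- toy_dataset(beta = b3)
  expect_equal(unname(region_change_summary(ds3, c("A", "B"), c("p01", "p02", "p03"))),
               c(-0.1, 0.05, 0.3), tolerance = 1e-12)
})

test_that("call_dmrs returns every tested region at permissive thresholds", {
  set.seed(21)
  ds <- toy_dataset(n_probes = 30, groups = c(A = 4, B = 4), seed = 21,
                    pos = seq(100, by = 50, length.out = 30))
  regions <- make_tiles(c(chr1 = 2000L), 500)
  res <- call_dmrs(ds, regions, q_cutoff = 1, min_abs_median_change = 0)
  mapped <- map_probes_to_regions(ds, regions)
  expect_equal(nrow(res), length(mapped$region_probes))
  expect_true(all(res$q > 0 & res$q <= 1))
  expect_true(all(res$q_group1 >= res$p_group1))
  expect_true(all(res$q_group2 >= res$p_group2))
  expect_true(all(res$change_min <= res$change_median))
  expect_true(all(res$change_median <= res$change_max))
  expect_true(!is.unsorted(res$q))
})

test_that("with one probe per region, region q is the Sidak-corrected probe p", {
  set.seed(33)
  ds <- toy_dataset(n_probes = 12, groups = c(A = 4, B = 4), seed = 33,
                    pos = seq(0, by = 5000, length.out = 12))
  # one 100-bp region per probe: too far apart for any ACF bin
  regions <- data.frame(chrom = "chr1", start = ds$probes$pos,
                        end = ds$probes$pos + 100L,
                        name = paste0("r", 1:12))
  pt <- all_pairs_probe_tests(ds)
  res <- call_dmrs(ds, regions, q_cutoff = 1)
  res <- res[match(paste0("r", 1:12), res$name), ]
  m <- 12  # total span 1200 bp / region span 100 bp
  expect_equal(res$p_group1, pt$p_group1_greater, tolerance = 1e-12)
  expect_equal(res$q_group1, sidak_correct(pt$p_group1_greater, 100, 1200),
               tolerance = 1e-12)
  expect_equal(res$q_group2, sidak_correct(pt$p_group2_greater, 100, 1200),
               tolerance = 1e-12)
})

test_that("direction matches the sign of the median change under a pure shift", {
  sim <- simulate_dataset(simulation_config(
    n_probes = 600, n_chroms = 1, groups = c(case = 8L, control = 8L),
    spike = list(n_regions = 4, delta = 0.3, group = "case", width_bp = 10000),
    seed = 77
  ))
  tiles <- make_tiles(sim$chrom_sizes, 10000)
  res <- call_dmrs(sim$dataset, tiles, q_cutoff = 0.05)
  hits <- res[res$name %in% sim$truth$name, ]
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$direction == "case"))
  expect_true(all(hits$change_median < 0))  # change = control - case < 0
})
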