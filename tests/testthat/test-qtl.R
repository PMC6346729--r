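lay3 <- genome_layout(c("SSC1", "SSC2", "X"), c(2e6, 2e6, 2e6),
                      autosome = c(TRUE, TRUE, FALSE))

test_that("the two-stage QTL filter drops linkage, non-autosomes and long spans", {
  qtl <- toy_qtl(
    list(method = "association", chrom = "SSC1", start = 1, end = 5e5),
    list(method = "linkage", chrom = "SSC1", start = 1, end = 1e4),
    list(method = "association", chrom = "X", start = 1, end = 1e4),
    list(method = "association", chrom = "SSC2", start = 1, end = 1.2e6),
    list(method = "association", chrom = "chrUn", start = 1, end = 100))
  f <- filter_qtls(qtl, lay3)
  expect_equal(f$records$qtl_id, "Q001")
  expect_equal(unname(f$audit["n_dropped_linkage"]), 1L)
  expect_equal(unname(f$audit["n_dropped_location"]), 3L)
  expect_equal(unname(f$audit["n_dropped_unknown_chrom"]), 1L)
  # audit counts are internally consistent
  expect_equal(unname(f$audit["n_input"] - f$audit["n_dropped_linkage"] -
                        f$audit["n_dropped_location"]),
               unname(f$audit["n_retained"]))
  # a span of exactly 1 Mb is retained (strictly "more than 1 Mb" drops)
  q2 <- toy_qtl(list(method = "association", chrom = "SSC1",
                     start = 1, end = 1e6))
  expect_equal(nrow(filter_qtls(q2, lay3)$records), 1L)
})

test_that("deduplication collapses same-group same-interval records", {
  qtl <- toy_qtl(
    list(group = "reproduction", start = 100, end = 300),
    list(group = "reproduction", start = 100, end = 300),
    list(group = "health", start = 100, end = 300),
    list(group = "health", start = 500, end = 700))
  d <- dedup_and_peaks(qtl)
  expect_equal(d$n_all, 3L)               # group-inclusive key
  expect_equal(d$n_all_groupless, 2L)     # intervals only
  expect_equal(unname(d$n_by_group["reproduction"]), 1L)
  expect_equal(unname(d$n_by_group["health"]), 2L)
  expect_equal(d$records$peak[1], 200)    # midpoint of [100, 300]
})

test_that("peak-in-region membership is half-open and matches brute force", {
  regions <- data.frame(chrom = "SSC1", start = 50000, end = 100000)
  at <- function(p) {
    q <- toy_qtl(list(start = p, end = p))
    q$peak <- p
    count_in_regions(q, regions)$n_all
  }
  expect_equal(at(50001), 1L)  # 1-based peak 50001 = 0-based 50000: start inclusive
  expect_equal(at(100001), 0L) # 0-based 100000: end exclusive
  expect_equal(at(100000), 1L)

  set.seed(51)
  regions <- data.frame(chrom = sample(c("SSC1", "SSC2"), 5, replace = TRUE),
                        start = (0:4) * 2e5, end = (0:4) * 2e5 + 1e5)
  peaks <- data.frame(qtl_id = sprintf("q%d", 1:200), trait = "t",
                      trait_group = "health", method = "association",
                      chrom = sample(c("SSC1", "SSC2"), 200, replace = TRUE),
                      start = sample.int(1e6, 200), end = 0,
                      stringsAsFactors = FALSE)
  peaks$end <- peaks$start
  peaks$peak <- peaks$start
  got <- count_in_regions(peaks, regions)
  oracle <- 0L
  for (i in 1:200) for (j in 1:5) {
    if (peaks$chrom[i] == regions$chrom[j] &&
        peaks$peak[i] - 1 >= regions$start[j] &&
        peaks$peak[i] - 1 < regions$end[j]) {
      oracle <- oracle + 1L
      break
    }
  }
  expect_equal(got$n_all, oracle)
})

perm_fixture <- function(W, cand0, peak_win, groups = "health") {
  lay <- genome_layout("SSC1", W * 50000)
  grid <- window_grid(lay, 50000)
  peaks <- data.frame(chrom = rep("SSC1", length(peak_win)),
                      peak = peak_win * 50000 + 1,
                      trait_group = rep(groups, length.out = length(peak_win)),
                      stringsAsFactors = FALSE)
  list(grid = grid, peaks = peaks, cand0 = cand0)
}

test_that("rotation by the full circle is the identity and degenerate cases give p = 1", {
  fx <- perm_fixture(10, 0:9, c(0, 3, 7))   # every window is a candidate
  pt <- circular_permutation_test(fx$cand0, fx$peaks, fx$grid,
                                  n_perm = 50, seed = 1)
  expect_equal(pt$results$p[pt$results$scope == "all"], 1)
  expect_true(all(pt$null_counts[, "all"] == 3L))

  fx0 <- perm_fixture(10, 0:1, integer(0))  # zero peaks
  pt0 <- circular_permutation_test(fx0$cand0, fx0$peaks[0, ], fx0$grid,
                                   n_perm = 50, seed = 1)
  expect_equal(pt0$results$observed[1], 0L)
  expect_equal(pt0$results$p[1], 1)

  # empty candidate set: undefined p with a reason
  pte <- circular_permutation_test(integer(0), fx$peaks, fx$grid,
                                   n_perm = 50, seed = 1)
  expect_true(is.na(pte$results$p[1]))
  expect_match(pte$reason, "empty")
  expect_error(circular_permutation_test(fx$cand0, fx$peaks, fx$grid,
                                         n_perm = 0), "n_perm")
})

test_that("exact enumeration matches the direct rotation oracle", {
  set.seed(52)
  for (rep in 1:20) {
    W <- sample(6:20, 1)
    cand0 <- sort(sample(0:(W - 1), sample(1:(W - 1), 1)))
    peak_win <- sample(0:(W - 1), sample(1:30, 1), replace = TRUE)
    fx <- perm_fixture(W, cand0, peak_win)
    pt <- circular_permutation_test(cand0, fx$peaks, fx$grid, exact = TRUE)
    oracle <- oracle_rotation_counts(cand0, peak_win, W)
    expect_equal(sort(pt$null_counts[, "all"]), sort(oracle))
    expect_equal(pt$results$observed[1], sum(peak_win %in% cand0))
    expect_equal(pt$results$p[1],
                 mean(oracle >= sum(peak_win %in% cand0)))
  }
})

test_that("offset zero would reproduce the observed count and is never drawn", {
  fx <- perm_fixture(12, c(2, 3, 8), c(2, 5, 8, 8))
  pt <- circular_permutation_test(fx$cand0, fx$peaks, fx$grid,
                                  n_perm = 5000, seed = 7)
  # identity rotation recovers the observation (checked by hand count)
  expect_equal(pt$results$observed[1], 3L)
  # the sampled null of a small circle never contains the identity:
  # all 11 possible offsets appear, 12th (zero) does not -> max 11 values
  expect_lte(length(unique(pt$null_counts[, "all"])), 11L)
})

test_that("Monte-Carlo p-values are stable across seeds on a fixed fixture", {
  fx <- perm_fixture(30, c(0, 1, 2, 10, 11), sample(0:29, 40, replace = TRUE))
  p1 <- circular_permutation_test(fx$cand0, fx$peaks, fx$grid,
                                  n_perm = 4000, seed = 1)$results$p[1]
  p2 <- circular_permutation_test(fx$cand0, fx$peaks, fx$grid,
                                  n_perm = 4000, seed = 2)$results$p[1]
  se <- sqrt(max(p1, 1e-4) * (1 - min(p1, 0.9999)) / 4000)
  expect_lt(abs(p1 - p2), 3 * se + 2 / 4000)
})

test_that("per-group scopes share rotation draws with the all-traits scope", {
  fx <- perm_fixture(15, c(1, 2), sample(0:14, 30, replace = TRUE),
                     groups = c("health", "production"))
  pt <- circular_permutation_test(fx$cand0, fx$peaks, fx$grid,
                                  n_perm = 500, seed = 3)
  # group nulls decompose the all-traits null draw by draw
  groups <- c("meat and carcass", "production", "reproduction", "health",
              "exterior")
  expect_equal(rowSums(pt$null_counts[, groups]),
               unname(pt$null_counts[, "all"]))
})
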