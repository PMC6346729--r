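test_that("zero drift collapses all donor frequencies onto the ancestral", {
  cfg <- tiny_config(donor_divergence = c(MS = 0, BMX = 0, EUW = 0))
  panels <- simulate_panels(cfg)
  expect_equal(panels$freq[, "MS"], panels$freq[, "ancestral"])
  expect_equal(panels$freq[, "BMX"], panels$freq[, "ancestral"])
  expect_equal(panels$freq[, "EUW"], panels$freq[, "ancestral"])
})

test_that("Meishan sits closer to Bamaxiang than to EUW in frequency space", {
  cfg <- tiny_config(seed = 3, n_chromosomes = 4L, chrom_length_bp = 4e6,
                     snp_density = 1e-3)  # >= 10,000 expected sites
  panels <- simulate_panels(cfg)
  expect_gt(nrow(panels$sites), 10000)
  d_ms_bmx <- mean(abs(panels$freq[, "MS"] - panels$freq[, "BMX"]))
  d_ms_euw <- mean(abs(panels$freq[, "MS"] - panels$freq[, "EUW"]))
  # the gap is large at the default divergences; a strict < is the claim
  expect_lt(d_ms_bmx, d_ms_euw)
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- tiny_config(seed = 9, sweep_regions = one_sweep(),
                     enrichment_rho = 0.2)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$panels, s2$panels)
  expect_identical(s1$admixed$haplotypes, s2$admixed$haplotypes)
  expect_identical(s1$admixed$track, s2$admixed$track)
  expect_identical(s1$qtl, s2$qtl)
  # and the generator leaves no global RNG state behind: a different
  # seed gives a different draw
  s3 <- simulate_dataset(tiny_config(seed = 10, sweep_regions = one_sweep(),
                                     enrichment_rho = 0.2))
  expect_false(identical(s1$panels$sites, s3$panels$sites))
})

test_that("a zero switch rate gives one tract per haplotype-chromosome", {
  cfg <- tiny_config(seed = 4, switch_rate_per_bp = 0)
  panels <- simulate_panels(cfg)
  adm <- simulate_admixed(cfg, panels, genotypes = FALSE)
  tr <- adm$truth$tracts
  expect_equal(nrow(tr), cfg$recipient_haplotypes * cfg$n_chromosomes)
  expect_true(all(tr$start == 0 & tr$end == cfg$chrom_length_bp))
  # truth proportions at every SNP equal the empirical donor draw fractions
  for (ch in unique(tr$chrom)) {
    frac <- mean(tr$donor[tr$chrom == ch] == "MS")
    expect_true(all(adm$track$p_MS[adm$track$chrom == ch] == frac))
  }
})

test_that("ancestry tracts tile each chromosome and rows sum to one", {
  cfg <- tiny_config(seed = 6, sweep_regions = one_sweep())
  adm <- simulate_admixed(cfg, simulate_panels(cfg), genotypes = FALSE)
  tr <- adm$truth$tracts
  spans <- tapply(tr$end - tr$start, paste(tr$hap, tr$chrom), sum)
  expect_true(all(spans == cfg$chrom_length_bp))
  # no gaps/overlaps: each tract starts where the previous ended
  by_hc <- split(tr, paste(tr$hap, tr$chrom))
  ok <- vapply(by_hc, function(d) all(d$start == c(0, d$end[-nrow(d)])), TRUE)
  expect_true(all(ok))
  p <- as.matrix(adm$track[, c("p_MS", "p_BMX", "p_EUW")])
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
})

test_that("mean tract length converges to the switch-rate reciprocal", {
  # long chromosome relative to the tract scale to keep edge censoring small
  cfg <- tiny_config(seed = 8, n_chromosomes = 1L, chrom_length_bp = 5e6,
                     snp_density = 1e-5, recipient_haplotypes = 40L,
                     switch_rate_per_bp = 2e-5)  # mean 50 kb, ~100 tracts/hap
  adm <- simulate_admixed(cfg, simulate_panels(cfg), genotypes = FALSE)
  len <- adm$truth$tracts$end - adm$truth$tracts$start
  expect_gt(length(len), 1000)
  se <- sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - 1 / cfg$switch_rate_per_bp), 4 * se + 1000)
})

test_that("genome-wide truth ancestry matches the stationary distribution", {
  means <- sapply(1:5, function(seed) {
    cfg <- tiny_config(seed = seed, n_chromosomes = 10L,
                       chrom_length_bp = 1e6, snp_density = 2e-4,
                       recipient_haplotypes = 100L,
                       switch_rate_per_bp = 5e-6)
    adm <- simulate_admixed(cfg, simulate_panels(cfg), genotypes = FALSE)
    colMeans(as.matrix(adm$track[, c("p_MS", "p_BMX", "p_EUW")]))
  })
  est <- rowMeans(means)
  se <- apply(means, 1, sd) / sqrt(ncol(means))
  target <- c(0.12, 0.13, 0.75)
  expect_true(all(abs(est - target) < 3 * se + 0.01))
})

test_that("boosted sweep regions raise the boosted donor's ancestry", {
  diffs <- sapply(1:20, function(seed) {
    cfg <- tiny_config(seed = seed, recipient_haplotypes = 30L,
                       sweep_regions = one_sweep(prob = 0.95))
    adm <- simulate_admixed(cfg, simulate_panels(cfg), genotypes = FALSE)
    tk <- adm$track
    inside <- tk$chrom == "SSC1" & tk$pos > 1e5 & tk$pos <= 2e5
    mean(tk$p_MS[inside]) - mean(tk$p_MS[!inside])
  })
  expect_true(all(diffs > 0))
  expect_gt(mean(diffs) / (sd(diffs) / sqrt(length(diffs))), 3)
})

test_that("QTL generation respects planting, linkage and group weights", {
  cfg <- tiny_config(enrichment_rho = 0)
  qtl <- simulate_qtl_table(cfg)
  expect_false(any(qtl$planted_in_sweep))

  # all-linkage tables leave nothing after the filter
  cfg2 <- tiny_config(qtl_linkage_fraction = 1)
  filt <- filter_qtls(simulate_qtl_table(cfg2), sim_layout(cfg2))
  expect_equal(nrow(filt$records), 0L)
  expect_equal(unname(filt$audit["n_dropped_linkage"]), cfg2$qtl_count)

  # planting without sweeps is rejected
  expect_error(simulate_qtl_table(tiny_config(enrichment_rho = 0.3)),
               "sweep")

  # group counts within the multinomial 99% CI (Bonferroni over groups)
  w <- c(0.48, 0.06, 0.05, 0.30, 0.10)
  w <- w / sum(w)
  cfg3 <- tiny_config(qtl_count = 10000L, qtl_group_weights = w)
  qtl3 <- simulate_qtl_table(cfg3)
  counts <- table(factor(qtl3$trait_group,
                         levels = names(cfg3$qtl_group_weights)))
  for (g in seq_along(w)) {
    lo <- qbinom(0.001, 10000, cfg3$qtl_group_weights[g])
    hi <- qbinom(0.999, 10000, cfg3$qtl_group_weights[g])
    expect_true(counts[g] >= lo && counts[g] <= hi)
  }

  # lengths respect the cap and decoys exercise the autosome filter
  span <- qtl3$end - qtl3$start + 1
  expect_true(all(span <= cfg3$qtl_length_cap))
  expect_true(any(qtl3$chrom == "SSCX"))
})

test_that("degenerate site densities are rejected", {
  expect_error(simulate_panels(tiny_config(snp_density = 1e-9)), "below 1")
})
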