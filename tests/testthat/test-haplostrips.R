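# Build a tiny phased VCF from an explicit haplotype matrix.
write_test_vcf <- function(mat, pops, path, chrom = "SSC1",
                           pos = seq_len(ncol(mat)) * 100) {
  lay <- genome_layout(chrom, max(pos) + 100)
  haps <- split.data.frame(mat, pops)
  haps <- lapply(haps, as.matrix)
  sites <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  pm <- write_vcf(sites, haps, lay, path)
  pm
}

test_that("block extraction splits diploids and drops monomorphic sites", {
  mat <- rbind(c(0, 1, 0, 0, 1), c(0, 1, 1, 0, 0),
               c(0, 0, 0, 0, 1), c(0, 1, 0, 0, 0),
               c(0, 0, 1, 0, 1), c(0, 1, 1, 0, 0))
  path <- tempfile(fileext = ".vcf")
  pm <- write_test_vcf(mat, rep("DU", 6), path)
  blk <- extract_block(path, "SSC1", 1, 1000, pm)
  # columns 1 and 4 are monomorphic and dropped
  expect_equal(dim(blk$mat), c(6L, 3L))
  expect_equal(blk$pos, c(200, 300, 500))
  expect_equal(unname(blk$mat), unname(mat[, c(2, 3, 5)]))

  blk_all <- extract_block(path, "SSC1", 1, 1000, pm,
                           drop_monomorphic = FALSE)
  expect_equal(dim(blk_all$mat), c(6L, 5L))
})

test_that("unphased or missing genotypes are rejected with the sample named", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
               "SSC1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0|1\t0/1",
               "SSC1\t200\t.\tA\tC\t.\tPASS\t.\tGT\t1|1\t0|0"), path)
  pm <- data.frame(sample = c("s1", "s2"), pop = "DU",
                   stringsAsFactors = FALSE)
  expect_error(extract_block(path, "SSC1", 1, 300, pm), "unphased.*s2")
  expect_error(extract_block(path, "SSC1", 250, 200, pm), "empty region")
})

test_that("the reference consensus is the majority allele with ties to 0", {
  mat <- rbind(c(0, 1, 0), c(0, 1, 1), c(0, 1, 0), c(1, 0, 1))
  blk <- structure(list(pos = c(100, 200, 300), mat = mat,
                        pop = c("DU", "DU", "DU", "MS"),
                        region = list(chrom = "SSC1", start = 1, end = 400)),
                   class = "haplotype_block")
  expect_equal(reference_consensus(blk, "DU"), c(0L, 1L, 0L))
  # single reference haplotype: consensus equals it
  blk1 <- blk; blk1$pop <- c("DU", "MS", "MS", "MS")
  expect_equal(reference_consensus(blk1, "DU"), c(0L, 1L, 0L))
  # 2-2 tie resolves to 0
  blk2 <- blk; blk2$mat <- rbind(c(0), c(0), c(1), c(1))
  blk2$pos <- 100; blk2$pop <- rep("DU", 4)
  expect_equal(reference_consensus(blk2, "DU"), 0L)
  expect_error(reference_consensus(blk, "EUW"), "absent")
})

test_that("distances are Hamming and the display order matches the oracle", {
  set.seed(61)
  for (rep in 1:30) {
    n <- sample(3:6, 1)
    S <- sample(4:10, 1)
    mat <- matrix(rbinom(n * S, 1, 0.5), nrow = n)
    # force some duplicate haplotypes
    if (n >= 4) mat[n, ] <- mat[1, ]
    blk <- structure(list(pos = seq_len(S) * 10, mat = mat,
                          pop = rep("DU", n),
                          region = list(chrom = "c", start = 1, end = S * 10)),
                     class = "haplotype_block")
    consensus <- rbinom(S, 1, 0.5)
    hs <- distances_and_order(blk, consensus = consensus)
    expect_equal(hs$distance,
                 apply(mat, 1, function(h) sum(h != consensus)))
    expect_equal(hs$order, oracle_hap_order(mat, consensus))
    # identical haplotypes are adjacent in the output
    key <- apply(mat[hs$order, , drop = FALSE], 1, paste, collapse = "")
    expect_true(all(!duplicated(key) | key == c("", key[-length(key)])))
    # the first display block contains the minimal-distance haplotype
    expect_equal(hs$distance[hs$order[1]], min(hs$distance))
  }
})

test_that("a haplotype equal to the consensus leads the display", {
  mat <- rbind(c(1, 0, 1, 1), c(0, 0, 0, 0), c(1, 1, 1, 1))
  blk <- structure(list(pos = c(10, 20, 30, 40), mat = mat,
                        pop = c("MS", "DU", "EUW"),
                        region = list(chrom = "c", start = 1, end = 50)),
                   class = "haplotype_block")
  hs <- distances_and_order(blk, consensus = c(0, 0, 0, 0))
  expect_equal(hs$order[1], 2L)
  expect_equal(hs$distance, c(3, 0, 4))
})

test_that("VCF round trip preserves the haplotype block", {
  set.seed(62)
  mat <- matrix(rbinom(8 * 12, 1, 0.4), nrow = 8)
  mat[, 3] <- c(rep(0, 7), 1)  # keep every column polymorphic
  pops <- rep(c("DU", "MS"), each = 4)
  path <- tempfile(fileext = ".vcf")
  pm <- write_test_vcf(mat, pops, path)
  blk <- extract_block(path, "SSC1", 1, 2000, pm, drop_monomorphic = FALSE)
  expect_equal(unname(blk$mat), unname(mat))
  expect_equal(blk$pop, pops)
})

test_that("recipient sweep haplotypes sit closer to the boosted donor consensus", {
  hits <- 0L
  for (seed in 1:5) {
    cfg <- tiny_config(seed = seed, n_chromosomes = 1L,
                       chrom_length_bp = 2e5, snp_density = 2e-3,
                       recipient_haplotypes = 20L,
                       switch_rate_per_bp = 1e-5,
                       sweep_regions = one_sweep(start = 0, end = 2e5,
                                                 prob = 0.98))
    sim <- simulate_dataset(cfg)
    dir <- tempfile(); paths <- write_fixture_set(sim, dir)
    pm <- read_pop_map(paths[["pop_map"]])
    blk <- extract_block(paths[["vcf"]], "SSC1", 1, 2e5, pm)
    cons_ms <- reference_consensus(blk, "MS")
    cons_euw <- reference_consensus(blk, "EUW")
    du <- blk$pop == "DU"
    d_ms <- mean(rowSums(blk$mat[du, , drop = FALSE] !=
                           rep(cons_ms, each = sum(du))))
    d_euw <- mean(rowSums(blk$mat[du, , drop = FALSE] !=
                            rep(cons_euw, each = sum(du))))
    if (d_ms < d_euw) hits <- hits + 1L
    unlink(dir, recursive = TRUE)
  }
  expect_gte(hits, 4L)
})
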