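# Shared fixture builders (everything generated in code; no stored data
# beyond inst/extdata/fixture).

# Small, fast simulation config for unit tests.
tiny_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_chromosomes = 2L, chrom_length_bp = 5e5,
                   snp_density = 1e-3,
                   donor_haplotypes = c(MS = 8L, BMX = 8L, EUW = 8L),
                   recipient_haplotypes = 20L, switch_rate_per_bp = 2e-5,
                   qtl_count = 200L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

one_sweep <- function(chrom = "SSC1", start = 1e5, end = 2e5,
                      donor = "MS", prob = 0.95) {
  data.frame(chrom = chrom, start = start, end = end, donor = donor,
             prob = prob, stringsAsFactors = FALSE)
}

# Window table with prescribed per-window Meishan ancestry and FST on a
# single chromosome (one value per 50-kb window); p_BMX = 0.
toy_window_table <- function(p_ms, fst, n_snps = 10L) {
  stopifnot(length(p_ms) == length(fst))
  lay <- genome_layout("SSC1", length(p_ms) * 50000)
  wt <- window_grid(lay, 50000)
  wt$n_snps <- rep(n_snps, length(p_ms))
  wt$p_MS <- p_ms
  wt$p_BMX <- 0
  wt$p_EUW <- 1 - p_ms
  wt$p_CHN <- wt$p_MS + wt$p_BMX
  wt$fst_MS_BMX <- fst
  wt
}

# QTL data frame from a compact spec list.
toy_qtl <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(qtl_id = sprintf("Q%03d", i), trait = r$trait %||% "t",
               trait_group = r$group %||% "health",
               method = r$method %||% "association",
               chrom = r$chrom %||% "SSC1",
               start = r$start, end = r$end, stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force Hudson estimator (scalar arithmetic, no reuse
# of the package's vectorised code path).
oracle_hudson <- function(ref1, n1, ref2, n2) {
  if (n1 < 2 || n2 < 2) return(NA_real_)
  p1 <- ref1 / n1; p2 <- ref2 / n2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (den == 0) return(NA_real_)
  ((p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)) / den
}

# Exhaustive rotation null for the window circle: counts for every
# offset 1..W-1 by direct membership testing.
oracle_rotation_counts <- function(cand0, peak0, W) {
  vapply(seq_len(W - 1L), function(off) {
    rot <- (cand0 + off) %% W
    sum(peak0 %in% rot)
  }, 0L)
}

# Haplostrip display-order oracle for small inputs: blocks are classes
# of identical haplotypes, ordered by distance to consensus then first
# input index; rows within a block by input order.
oracle_hap_order <- function(mat, consensus) {
  d <- apply(mat, 1L, function(h) sum(h != consensus))
  key <- apply(mat, 1L, paste, collapse = "")
  first <- stats::ave(seq_len(nrow(mat)), key, FUN = min)
  order(d[first], first, seq_len(nrow(mat)))
}
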