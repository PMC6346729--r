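#' Extract a regional haplotype block from a phased VCF
#'
#' Pulls the biallelic SNPs of a region for a set of samples and splits
#' each diploid phased genotype into two haplotype rows coded 0
#' (reference) / 1 (alternate). Sites monomorphic across the selected
#' haplotypes are dropped. Missing or unphased genotypes are rejected
#' (the input is expected to be imputed and phased).
#'
#' @param vcf path to a VCF file, or a \code{vcfR} object.
#' @param chrom,start,end region (1-based inclusive bp).
#' @param pop_map data frame with columns \code{sample}, \code{pop};
#'   only listed samples are extracted.
#' @param drop_monomorphic drop columns invariant across the selected
#'   haplotypes (default TRUE).
#' @return A \code{haplotype_block}: list with \code{pos} (positions),
#'   \code{mat} (haplotypes x SNPs 0/1 matrix), \code{pop} (label per
#'   row), \code{region}.
#' @export
extract_block <- function(vcf, chrom, start, end, pop_map,
                          drop_monomorphic = TRUE) {
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  if (end < start) stop_("empty region: end < start")
  fix <- vcfR::getFIX(vcf)
  pos <- as.numeric(fix[, "POS"])
  keep <- fix[, "CHROM"] == chrom & pos >= start & pos <= end &
    vcfR::is.biallelic(vcf)
  if (!any(keep)) stop_("no biallelic SNPs in %s:%d-%d", chrom,
                        as.integer(start), as.integer(end))
  gt <- vcfR::extract.gt(vcf)[keep, , drop = FALSE]
  pos <- pos[keep]
  samples <- intersect(colnames(gt), pop_map$sample)
  if (!length(samples)) stop_("none of the mapped samples are in the VCF")
  gt <- gt[, samples, drop = FALSE]
  miss <- is.na(gt) | gt == "." | gt == "./." | gt == ".|."
  if (any(miss)) {
    stop_("missing genotype for sample %s (phase and impute first)",
          samples[ceiling(which(miss)[1L] / nrow(gt))])
  }
  unphased <- !grepl("|", gt, fixed = TRUE)
  if (any(unphased)) {
    stop_("unphased genotype for sample %s",
          samples[ceiling(which(unphased)[1L] / nrow(gt))])
  }
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  if (!all(c(a1, a2) %in% c("0", "1"))) stop_("non-biallelic allele code in GT")
  # interleave the two haplotypes of each sample: rows = haplotypes
  mat <- matrix(0L, nrow = 2L * length(samples), ncol = length(pos))
  mat[seq(1L, by = 2L, length.out = length(samples)), ] <- t(a1 == "1")
  mat[seq(2L, by = 2L, length.out = length(samples)), ] <- t(a2 == "1")
  rownames(mat) <- paste0(rep(samples, each = 2L), "_", 1:2)
  pop <- rep(pop_map$pop[match(samples, pop_map$sample)], each = 2L)
  if (drop_monomorphic) {
    poly <- colSums(mat) > 0 & colSums(mat) < nrow(mat)
    mat <- mat[, poly, drop = FALSE]
    pos <- pos[poly]
  }
  structure(list(pos = pos, mat = mat, pop = pop,
                 region = list(chrom = chrom, start = start, end = end)),
            class = "haplotype_block")
}

#' Majority consensus haplotype of a reference population
#'
#' Per SNP, the majority allele among the reference-population
#' haplotypes; exact ties resolve to the reference allele (0).
#'
#' @param block a \code{haplotype_block}.
#' @param ref_pop reference population label (e.g. "DU").
#' @return Integer 0/1 vector, one entry per SNP.
#' @export
reference_consensus <- function(block, ref_pop) {
  rows <- block$pop == ref_pop
  if (!any(rows)) stop_("reference population %s absent from block", ref_pop)
  as.integer(colMeans(block$mat[rows, , drop = FALSE]) > 0.5)
}

#' Cluster and order haplotypes by distance to a reference consensus
#'
#' Per-haplotype distance is the Hamming distance (number of SNPs with a
#' different allele) to the reference consensus. Haplotypes are grouped
#' by average-linkage hierarchical clustering on pairwise Hamming
#' distances, the tree cut at \code{cut_height} (default 0: blocks of
#' identical haplotypes, which are therefore always adjacent in the
#' display). Blocks are ordered by increasing mean distance to the
#' consensus, rows within a block by increasing distance, residual ties
#' by input order.
#'
#' @param block a \code{haplotype_block}.
#' @param consensus 0/1 consensus vector; if NULL, computed from
#'   \code{ref_pop} via \code{\link{reference_consensus}}.
#' @param ref_pop reference population (used when \code{consensus} is
#'   NULL, and for the per-haplotype minimum-distance variant).
#' @param cut_height height at which the average-linkage tree is cut
#'   into display blocks (default 0).
#' @param per_hap_min if TRUE, the displayed distance is the minimum
#'   Hamming distance to any individual reference haplotype instead of
#'   the distance to the consensus.
#' @return A \code{haplostrip} object: \code{order} (row permutation),
#'   \code{distance}, \code{pop}, \code{mat} (original matrix),
#'   \code{block_id} (cluster block per row, in input order).
#' @export
distances_and_order <- function(block, consensus = NULL, ref_pop = NULL,
                                cut_height = 0, per_hap_min = FALSE) {
  mat <- block$mat
  if (is.null(consensus)) {
    if (is.null(ref_pop)) stop_("give either a consensus or ref_pop")
    consensus <- reference_consensus(block, ref_pop)
  }
  if (length(consensus) != ncol(mat)) {
    stop_("consensus length %d != SNP count %d", length(consensus), ncol(mat))
  }
  if (per_hap_min) {
    if (is.null(ref_pop)) stop_("per_hap_min needs ref_pop")
    ref <- mat[block$pop == ref_pop, , drop = FALSE]
    d <- apply(mat, 1L, function(h) min(colSums(t(ref) != h)))
  } else {
    d <- as.vector(rowSums(mat != rep(consensus, each = nrow(mat))))
  }
  n <- nrow(mat)
  if (n > 1L) {
    pd <- stats::dist(mat, method = "manhattan")  # = Hamming on 0/1
    hc <- stats::hclust(pd, method = "average")
    blk <- stats::cutree(hc, h = cut_height)
  } else {
    blk <- 1L
  }
  bmean <- tapply(d, blk, mean)
  bmin <- tapply(seq_len(n), blk, min)
  brank <- order(bmean, bmin)  # block order: mean distance, then input order
  block_pos <- match(blk, brank)
  ord <- order(block_pos, d, seq_len(n))
  structure(list(order = ord, distance = d, pop = block$pop, mat = mat,
                 block_id = blk, pos = block$pos, consensus = consensus),
            class = "haplostrip")
}

#' @export
print.haplostrip <- function(x, ...) {
  cat(sprintf("haplostrip: %d haplotypes x %d SNPs, distances %d..%d\n",
              nrow(x$mat), ncol(x$mat), min(x$distance), max(x$distance)))
  invisible(x)
}

#' Render an ordered haplotype panel
#'
#' Rows are haplotypes in display order (smallest distance to the
#' reference consensus at the top), columns SNPs; reference alleles
#' white, alternate alleles black.
#'
#' @param x a \code{haplostrip}.
#' @param ... passed to \code{image}.
#' @export
plot.haplostrip <- function(x, ...) {
  m <- x$mat[rev(x$order), , drop = FALSE]
  graphics::image(t(m), col = c("white", "black"), axes = FALSE,
                  xlab = "SNP", ylab = "haplotype", ...)
  graphics::box()
  invisible(x)
}

#' Write an ordered haplotype table
#'
#' Tab-separated: row label, population, distance to reference, allele
#' string, in display order.
#'
#' @param x a \code{haplostrip}.
#' @param path output file.
#' @export
write_haplostrip <- function(x, path) {
  o <- x$order
  df <- data.frame(haplotype = rownames(x$mat)[o], pop = x$pop[o],
                   distance = x$distance[o],
                   alleles = apply(x$mat[o, , drop = FALSE], 1L, paste,
                                   collapse = ""),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
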