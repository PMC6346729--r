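#' Per-SNP donor ancestry track
#'
#' Validates and assembles a table of per-SNP donor copying proportions
#' for the recipient population (the reduced form of chromosome-painting
#' output): one row per SNP, three donor proportions summing to 1.
#'
#' @param chrom chromosome per SNP.
#' @param pos 1-based bp position per SNP; strictly increasing within
#'   each chromosome.
#' @param p_MS,p_BMX,p_EUW donor proportions in [0,1].
#' @param tol tolerance on the row sum (default 1e-6).
#' @return An \code{ancestry_track} data frame.
#' @export
ancestry_track <- function(chrom, pos, p_MS, p_BMX, p_EUW, tol = 1e-6) {
  n <- length(pos)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n, length(p_MS) == n, length(p_BMX) == n,
            length(p_EUW) == n)
  out <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                    p_MS = as.numeric(p_MS), p_BMX = as.numeric(p_BMX),
                    p_EUW = as.numeric(p_EUW), stringsAsFactors = FALSE)
  if (anyNA(out)) stop_("ancestry track contains missing values")
  p <- as.matrix(out[, c("p_MS", "p_BMX", "p_EUW")])
  if (any(p < 0 | p > 1)) stop_("ancestry proportions outside [0,1]")
  bad <- which(abs(rowSums(p) - 1) > tol)
  if (length(bad)) {
    stop_("ancestry proportions do not sum to 1 at row %d (sum = %.6g)",
          bad[1L], sum(p[bad[1L], ]))
  }
  ord <- order(factor(out$chrom, levels = unique(out$chrom)), out$pos)
  out <- out[ord, , drop = FALSE]
  for (ch in unique(out$chrom)) {
    po <- out$pos[out$chrom == ch]
    if (any(diff(po) <= 0)) {
      stop_("positions not strictly increasing on %s", ch)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("ancestry_track", "data.frame")
  out
}

#' Aggregate per-SNP ancestry into the window grid
#'
#' Fills each window's donor ancestry means with the unweighted mean over
#' the SNPs falling in the window, plus the SNP count and Chinese
#' ancestry (mean p_MS + mean p_BMX). Windows without SNPs keep NA means
#' and \code{n_snps = 0}; they are excluded from candidate calling and
#' from empirical quantiles downstream.
#'
#' @param track an \code{ancestry_track}.
#' @param grid a \code{window_table} from \code{\link{window_grid}} on
#'   the same layout.
#' @return The grid with \code{n_snps}, \code{p_MS}, \code{p_BMX},
#'   \code{p_EUW}, \code{p_CHN} filled.
#' @export
aggregate_ancestry <- function(track, grid) {
  stopifnot(inherits(track, "ancestry_track"), inherits(grid, "window_table"))
  idx <- match_windows(track$chrom, track$pos, grid)
  n <- tabulate(idx, nbins = nrow(grid))
  grid$n_snps <- n
  for (col in c("p_MS", "p_BMX", "p_EUW")) {
    s <- rep(0, nrow(grid))
    agg <- rowsum(track[[col]], idx)
    s[as.integer(rownames(agg))] <- agg[, 1L]
    grid[[col]] <- ifelse(n > 0, s / n, NA_real_)
  }
  grid$p_CHN <- grid$p_MS + grid$p_BMX
  grid
}

#' Genome-wide ancestry summary (mean and standard error per donor)
#'
#' The primary summary is across SNPs: per-donor mean over all SNPs and
#' SE = sd/sqrt(n SNPs). A window-level summary (mean and SE across
#' SNP-bearing windows) is reported alongside for comparison.
#'
#' @param track an \code{ancestry_track}.
#' @param table optional aggregated \code{window_table} for the
#'   window-level columns.
#' @return data frame with one row per donor: \code{donor},
#'   \code{mean_snp}, \code{se_snp} and, when \code{table} is given,
#'   \code{mean_window}, \code{se_window}.
#' @export
genomewide_summary <- function(track, table = NULL) {
  stopifnot(inherits(track, "ancestry_track"), nrow(track) > 0)
  out <- data.frame(donor = DONORS, stringsAsFactors = FALSE)
  cols <- paste0("p_", DONORS)
  out$mean_snp <- vapply(cols, function(cl) mean(track[[cl]]), 0)
  out$se_snp <- vapply(cols, function(cl) {
    stats::sd(track[[cl]]) / sqrt(nrow(track))
  }, 0)
  if (!is.null(table)) {
    tb <- table[!is.na(table$n_snps) & table$n_snps > 0, , drop = FALSE]
    out$mean_window <- vapply(cols, function(cl) mean(tb[[cl]]), 0)
    out$se_window <- vapply(cols, function(cl) {
      stats::sd(tb[[cl]]) / sqrt(nrow(tb))
    }, 0)
  }
  rownames(out) <- NULL
  out
}
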