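#' Call candidate adaptive-introgression windows
#'
#' A window is a candidate when its Chinese ancestry (mean Meishan +
#' Bamaxiang) is strictly greater than \code{chinese_min} AND its
#' Meishan-Bamaxiang FST is not strictly above the empirical
#' \code{fst_q} quantile (the top-5% exclusion guards against
#' back-introgression from Europe to China). Windows without SNPs or
#' without a defined FST value are excluded and do not enter the
#' quantile. Adjacent candidate windows are also reported merged into
#' runs.
#'
#' @param table aggregated \code{window_table} with ancestry and the
#'   \code{fst_col} column filled.
#' @param chinese_min Chinese-ancestry threshold (default 0.5, strict).
#' @param fst_col name of the window FST column used for the exclusion
#'   (default \code{"fst_MS_BMX"}).
#' @param fst_q quantile for the extreme-FST exclusion (default 0.95).
#' @return A \code{candidate_set}: list with \code{windows} (the table
#'   plus a logical \code{candidate} column), \code{regions} (merged
#'   runs of adjacent candidate windows), \code{fst_threshold} and the
#'   filter parameters.
#' @export
call_candidates <- function(table, chinese_min = 0.5, fst_col = "fst_MS_BMX",
                            fst_q = 0.95) {
  stopifnot(inherits(table, "window_table"))
  if (!fst_col %in% names(table)) stop_("column %s not present", fst_col)
  has_snps <- !is.na(table$n_snps) & table$n_snps > 0
  if (!any(has_snps)) stop_("no SNP-bearing windows in the table")
  fst <- table[[fst_col]]
  thr <- fst_quantile(fst[has_snps], fst_q)
  cand <- has_snps & !is.na(fst) & table$p_CHN > chinese_min & fst <= thr
  table$candidate <- cand
  regions <- merge_window_runs(table, which(cand))
  structure(list(windows = table, regions = regions, fst_threshold = thr,
                 chinese_min = chinese_min, fst_col = fst_col, fst_q = fst_q),
            class = "candidate_set")
}

# Merge runs of adjacent (consecutive-row, same-chromosome) windows into
# regions with member ids and mean ancestries.
merge_window_runs <- function(table, idx) {
  if (!length(idx)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      p_MS = numeric(), p_BMX = numeric(), p_CHN = numeric(),
                      window_ids = I(list()), stringsAsFactors = FALSE))
  }
  idx <- sort(idx)
  new_run <- c(TRUE, diff(idx) != 1L |
                 table$chrom[idx[-1L]] != table$chrom[idx[-length(idx)]])
  run <- cumsum(new_run)
  rows <- lapply(split(idx, run), function(ii) {
    data.frame(chrom = table$chrom[ii[1L]], start = table$start[ii[1L]],
               end = table$end[ii[length(ii)]], n_windows = length(ii),
               p_MS = mean(table$p_MS[ii]), p_BMX = mean(table$p_BMX[ii]),
               p_CHN = mean(table$p_CHN[ii]), window_ids = I(list(ii)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extend top-ancestry windows into regions
#'
#' Iteratively seeds on the unassigned window with the highest donor
#' ancestry (Meishan or Bamaxiang) that is SNP-bearing, not extreme-FST
#' and has donor ancestry of at least 0.5, then extends in both
#' directions while the next window on the same chromosome is
#' SNP-bearing, not extreme-FST and has donor ancestry >= 0.5 (the stop
#' rule is the first window with <50% donor ancestry). The first
#' \code{k} regions with at least \code{min_windows} windows are
#' returned, ranked by seed-window ancestry (ties broken by earlier
#' genomic coordinate).
#'
#' @param table aggregated \code{window_table} with ancestry and
#'   \code{fst_col} filled.
#' @param donor \code{"MS"} or \code{"BMX"}.
#' @param k number of regions to return (default 5).
#' @param min_windows minimum windows per region (default 2).
#' @param fst_col,fst_q extreme-FST exclusion as in
#'   \code{\link{call_candidates}}.
#' @return A \code{region_set} data frame (chrom, start, end, n_windows,
#'   seed ancestry, mean donor ancestry, member window ids), with
#'   attribute \code{short = TRUE} when fewer than \code{k} qualifying
#'   regions exist (a warning is raised).
#' @export
extend_top_regions <- function(table, donor = c("MS", "BMX"), k = 5L,
                               min_windows = 2L, fst_col = "fst_MS_BMX",
                               fst_q = 0.95) {
  donor <- match.arg(donor)
  stopifnot(inherits(table, "window_table"))
  anc <- table[[paste0("p_", donor)]]
  has_snps <- !is.na(table$n_snps) & table$n_snps > 0
  if (!any(has_snps)) stop_("no SNP-bearing windows in the table")
  fst <- table[[fst_col]]
  thr <- fst_quantile(fst[has_snps], fst_q)
  # A window can belong to a region iff it has SNPs, a defined non-extreme
  # FST, and >= 50% donor ancestry. SNP-less / extreme windows terminate
  # extension; seeds additionally must be unassigned.
  extendable <- has_snps & !is.na(fst) & fst <= thr & !is.na(anc) & anc >= 0.5
  assigned <- rep(FALSE, nrow(table))
  regions <- list()
  repeat {
    pool <- which(extendable & !assigned)
    if (!length(pool)) break
    seed <- pool[order(-anc[pool], pool)][1L]
    lo <- seed
    while (lo > 1L && table$chrom[lo - 1L] == table$chrom[seed] &&
           extendable[lo - 1L] && !assigned[lo - 1L]) lo <- lo - 1L
    hi <- seed
    while (hi < nrow(table) && table$chrom[hi + 1L] == table$chrom[seed] &&
           extendable[hi + 1L] && !assigned[hi + 1L]) hi <- hi + 1L
    ii <- lo:hi
    assigned[ii] <- TRUE
    regions[[length(regions) + 1L]] <- data.frame(
      chrom = table$chrom[seed], start = table$start[lo],
      end = table$end[hi], n_windows = length(ii),
      seed_window = seed, seed_ancestry = anc[seed],
      mean_ancestry = mean(anc[ii]), window_ids = I(list(ii)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, regions %||% list())
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_windows = integer(), seed_window = integer(),
                      seed_ancestry = numeric(), mean_ancestry = numeric(),
                      window_ids = I(list()), stringsAsFactors = FALSE)
  }
  out <- out[out$n_windows >= min_windows, , drop = FALSE]
  ord <- order(-out$seed_ancestry, out$seed_window)
  out <- out[ord, , drop = FALSE]
  short <- nrow(out) < k
  if (short) {
    warning(sprintf("only %d region(s) with >= %d windows found (asked for %d)",
                    nrow(out), min_windows, k), call. = FALSE)
  } else {
    out <- out[seq_len(k), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "donor") <- donor
  attr(out, "fst_threshold") <- thr
  attr(out, "short") <- short
  class(out) <- c("region_set", "data.frame")
  out
}
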