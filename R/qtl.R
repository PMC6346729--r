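#' Two-stage QTL record filter with audit counts
#'
#' Stage 1 drops records mapped by linkage analysis (uncertain genomic
#' locations); stage 2 drops records on non-autosomes (including
#' chromosomes absent from the layout) or spanning more than
#' \code{max_span_bp} (span = end - start + 1, 1-based inclusive
#' coordinates). The audit reports counts dropped at each stage in
#' order, mirroring the database bookkeeping.
#'
#' @param records QTL data frame with columns \code{qtl_id},
#'   \code{trait}, \code{trait_group}, \code{method}, \code{chrom},
#'   \code{start}, \code{end}.
#' @param layout a \code{genome_layout} marking autosomes.
#' @param max_span_bp maximum retained span (default 1 Mb).
#' @return list with \code{records} (retained rows) and \code{audit}
#'   (named counts: input, dropped per stage, retained).
#' @export
filter_qtls <- function(records, layout, max_span_bp = 1e6) {
  stopifnot(inherits(layout, "genome_layout"))
  need <- c("qtl_id", "trait_group", "method", "chrom", "start", "end")
  if (!all(need %in% names(records))) {
    stop_("QTL table missing column(s): %s",
          paste(setdiff(need, names(records)), collapse = ", "))
  }
  n_input <- nrow(records)
  assoc <- records[records$method != "linkage", , drop = FALSE]
  n_linkage <- n_input - nrow(assoc)
  auto <- layout$chrom[layout$autosome]
  known <- assoc$chrom %in% layout$chrom
  on_autosome <- assoc$chrom %in% auto
  span_ok <- (assoc$end - assoc$start + 1) <= max_span_bp
  keep <- on_autosome & span_ok
  out <- assoc[keep, , drop = FALSE]
  rownames(out) <- NULL
  audit <- c(n_input = n_input,
             n_dropped_linkage = n_linkage,
             n_after_linkage = nrow(assoc),
             n_dropped_location = sum(!keep),
             n_dropped_non_autosome = sum(!on_autosome),
             n_dropped_unknown_chrom = sum(!known),
             n_dropped_span = sum(on_autosome & !span_ok),
             n_retained = nrow(out))
  list(records = out, audit = audit)
}

#' Deduplicate QTL records and derive peak positions
#'
#' Records with identical (trait group, chromosome, start, end) are
#' counted as one QTL; the key includes the trait group, so the same
#' interval in two different groups counts twice toward the all-traits
#' tally (the group-ignoring tally is reported alongside). The peak is
#' the interval midpoint, \code{floor((start + end)/2)}.
#'
#' @param records filtered QTL data frame.
#' @return list with \code{records} (deduplicated, with a \code{peak}
#'   column), \code{n_all} (group-inclusive tally), \code{n_by_group},
#'   and \code{n_all_groupless} (identical intervals collapsed across
#'   groups).
#' @export
dedup_and_peaks <- function(records) {
  key <- paste(records$trait_group, records$chrom, records$start,
               records$end, sep = "\r")
  out <- records[!duplicated(key), , drop = FALSE]
  out$peak <- (out$start + out$end) %/% 2
  rownames(out) <- NULL
  key2 <- paste(records$chrom, records$start, records$end, sep = "\r")
  by_group <- table(factor(out$trait_group, levels = TRAIT_GROUPS))
  list(records = out, n_all = nrow(out),
       n_by_group = stats::setNames(as.integer(by_group), TRAIT_GROUPS),
       n_all_groupless = sum(!duplicated(key2)))
}

#' Count QTL peaks inside candidate regions
#'
#' Membership is half-open on the internal 0-based coordinates: a peak
#' at 1-based position p lies in region [start, end) iff
#' start <= p - 1 < end, so a peak at the region start boundary counts
#' and one at the end boundary does not.
#'
#' @param records deduplicated QTL data frame with a \code{peak} column.
#' @param regions data frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), e.g. \code{candidate_set$regions}.
#' @return list with \code{n_all}, \code{n_by_group} and the logical
#'   membership vector \code{in_region}.
#' @export
count_in_regions <- function(records, regions) {
  p0 <- records$peak - 1
  inr <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(regions))) {
    inr <- inr | (records$chrom == regions$chrom[i] &
                    p0 >= regions$start[i] & p0 < regions$end[i])
  }
  by_group <- table(factor(records$trait_group[inr], levels = TRAIT_GROUPS))
  list(n_all = sum(inr),
       n_by_group = stats::setNames(as.integer(by_group), TRAIT_GROUPS),
       in_region = inr)
}

# Global 0-based index on the autosomal window circle (windows laid out
# in layout order) for each 1-based peak position; NA off-circle.
peak_window_index <- function(chrom, pos, grid) {
  auto <- attr(grid, "layout")$chrom[attr(grid, "layout")$autosome]
  gi <- which(grid$chrom %in% auto)
  key <- paste(grid$chrom[gi], grid$start[gi], sep = ":")
  size <- attr(grid, "size_bp")
  m <- match(paste(chrom, window_index0(pos, size) * size, sep = ":"), key)
  m - 1L
}

#' Circular-rotation permutation test for QTL enrichment
#'
#' The autosomes are concatenated, in layout order, into a circle of
#' 50-kb windows. Each permutation draws one uniform whole-window
#' rotation offset in 1..W-1 (identity excluded) and applies it jointly
#' to all candidate windows, preserving their relative positions; QTL
#' peaks stay fixed and are re-counted against the rotated windows. The
#' empirical p-value is the fraction of permutations whose null count is
#' >= the observed count; all-traits and per-group scopes share the same
#' rotation draws so their nulls are comparable.
#'
#' @param candidate_windows 0-based window indices on the autosomal
#'   circle (e.g. from a \code{candidate_set} via
#'   \code{\link{candidate_window_circle}}).
#' @param peaks deduplicated QTL data frame with \code{chrom},
#'   \code{peak}, \code{trait_group}.
#' @param grid the \code{window_table} the candidates were called on.
#' @param n_perm number of permutations (default 10,000).
#' @param seed integer seed for the rotation draws (recorded in the
#'   result); NULL uses the current RNG stream.
#' @param exact if TRUE, enumerate all W-1 rotations instead of
#'   sampling (\code{n_perm} ignored).
#' @return A \code{perm_test} object: data frame \code{results} with one
#'   row per scope (observed count, n_perm, p), the matrix of null
#'   counts, and the seed.
#' @export
circular_permutation_test <- function(candidate_windows, peaks, grid,
                                      n_perm = 10000L, seed = NULL,
                                      exact = FALSE) {
  W <- sum(grid$chrom %in% attr(grid, "layout")$chrom[attr(grid, "layout")$autosome])
  if (W < 2L) stop_("need at least two autosomal windows on the circle")
  if (!exact && (!is_count(n_perm) || n_perm < 1)) stop_("n_perm must be >= 1")
  scopes <- c("all", TRAIT_GROUPS)
  if (!length(candidate_windows)) {
    res <- data.frame(scope = scopes, observed = NA_integer_,
                      n_perm = 0L, p = NA_real_, stringsAsFactors = FALSE)
    return(structure(list(results = res, null_counts = NULL, seed = seed,
                          reason = "empty candidate set"),
                     class = "perm_test"))
  }
  cand <- as.integer(candidate_windows)
  stopifnot(!anyNA(cand), all(cand >= 0 & cand < W))
  pk <- peak_window_index(peaks$chrom, peaks$peak, grid)
  ok <- !is.na(pk)
  pk <- pk[ok]
  grp <- factor(peaks$trait_group[ok], levels = TRAIT_GROUPS)
  # peaks per window, one column per scope
  tab <- matrix(0L, nrow = W, ncol = length(scopes),
                dimnames = list(NULL, scopes))
  tab[, "all"] <- tabulate(pk + 1L, nbins = W)
  for (g in TRAIT_GROUPS) {
    tab[, g] <- tabulate(pk[grp == g] + 1L, nbins = W)
  }
  observed <- colSums(tab[cand + 1L, , drop = FALSE])
  offsets <- if (exact) seq_len(W - 1L) else
    with_seed(seed, sample.int(W - 1L, n_perm, replace = TRUE))
  # null counts depend on the offset only; compute once per distinct offset
  uoff <- sort(unique(offsets))
  by_off <- matrix(0L, nrow = length(uoff), ncol = length(scopes),
                   dimnames = list(NULL, scopes))
  for (j in seq_along(uoff)) {
    rot <- (cand + uoff[j]) %% W + 1L
    by_off[j, ] <- colSums(tab[rot, , drop = FALSE])
  }
  null <- by_off[match(offsets, uoff), , drop = FALSE]
  p <- vapply(scopes, function(s) mean(null[, s] >= observed[[s]]), 0)
  res <- data.frame(scope = scopes, observed = as.integer(observed),
                    n_perm = length(offsets), p = p,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(list(results = res, null_counts = null, seed = seed,
                 exact = exact, n_windows = W),
            class = "perm_test")
}

#' Candidate window indices on the autosomal circle
#'
#' @param cs a \code{candidate_set} from \code{\link{call_candidates}}.
#' @return 0-based indices of candidate windows on the concatenated
#'   autosomal window sequence.
#' @export
candidate_window_circle <- function(cs) {
  stopifnot(inherits(cs, "candidate_set"))
  grid <- cs$windows
  layout <- attr(grid, "layout")
  auto_rows <- which(grid$chrom %in% layout$chrom[layout$autosome])
  match(which(cs$windows$candidate), auto_rows) - 1L
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Circular-rotation permutation test",
      if (isTRUE(x$exact)) "(exact enumeration)" else "", "\n")
  if (!is.null(x$reason)) cat("  undefined:", x$reason, "\n")
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Null-distribution histogram for one scope of a permutation test
#' @param x a \code{perm_test}.
#' @param scope scope to plot (default "all").
#' @param ... passed to \code{hist}.
#' @export
plot.perm_test <- function(x, scope = "all", ...) {
  if (is.null(x$null_counts)) stop_("no null distribution (empty candidate set)")
  counts <- x$null_counts[, scope]
  graphics::hist(counts, main = paste("Null QTL counts:", scope),
                 xlab = "QTLs in rotated regions", ...)
  obs <- x$results$observed[x$results$scope == scope]
  graphics::abline(v = obs, lty = 2)
  invisible(x)
}
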