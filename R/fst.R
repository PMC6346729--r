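#' Per-site Hudson FST between two populations
#'
#' The two-population Hudson estimator at a biallelic site, with the
#' unbiased within-population correction. With sample allele frequencies
#' p1 = ref1/n1 and p2 = ref2/n2:
#' \deqn{F_{ST} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
#'               {p_1(1-p_2) + p_2(1-p_1)}}
#' Undefined (NA) when either population has fewer than 2 called alleles
#' (the within-population term cannot be unbiased) or when the
#' denominator is 0 (site monomorphic for the same allele in both
#' populations). Site values may be negative; clamping happens only at
#' window level (\code{\link{window_fst}}).
#'
#' @param ref1,ref2 reference-allele counts per site in populations 1, 2.
#' @param n1,n2 total called allele counts per site.
#' @return Numeric vector of per-site FST, NA where undefined. The
#'   estimator is symmetric in the populations and invariant to which
#'   allele is labelled reference.
#' @examples
#' hudson_fst(10, 10, 0, 10)              # fixed difference: 1
#' hudson_fst(5, 10, 5, 10)               # -1/9
#' @export
hudson_fst <- function(ref1, n1, ref2, n2) {
  p1 <- ref1 / n1
  p2 <- ref2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  out <- num / den
  out[n1 < 2 | n2 < 2 | den == 0] <- NA_real_
  out
}

#' Reference-allele counts per site from a haplotype matrix
#'
#' @param h matrix of 0/1 alleles (rows = haplotypes, columns = sites);
#'   NA for missing calls, which reduce the called-allele count.
#' @return list with \code{ref} (allele-0 counts) and \code{n} (called
#'   allele counts) per site.
#' @export
allele_counts <- function(h) {
  stopifnot(is.matrix(h))
  list(ref = colSums(h == 0, na.rm = TRUE), n = colSums(!is.na(h)))
}

#' Per-site FST tracks for population pairs from haplotype matrices
#'
#' @param sites data frame with \code{chrom}, \code{pos} (one row per
#'   site, matching the haplotype matrix columns).
#' @param haps named list of 0/1 haplotype matrices, one per population.
#' @param pairs list of length-2 character vectors of population names;
#'   default all pairs.
#' @return data frame \code{chrom}, \code{pos} plus one
#'   \code{fst_<A>_<B>} column per pair.
#' @export
fst_sites <- function(sites, haps, pairs = NULL) {
  stopifnot(is.list(haps), !is.null(names(haps)))
  if (is.null(pairs)) {
    nm <- names(haps)
    pairs <- utils::combn(nm, 2L, simplify = FALSE)
  }
  counts <- lapply(haps, allele_counts)
  out <- sites[, c("chrom", "pos"), drop = FALSE]
  for (pr in pairs) {
    a <- counts[[pr[1L]]]; b <- counts[[pr[2L]]]
    if (is.null(a) || is.null(b)) stop_("unknown population in pair %s-%s", pr[1L], pr[2L])
    out[[paste0("fst_", pr[1L], "_", pr[2L])]] <-
      hudson_fst(a$ref, a$n, b$ref, b$n)
  }
  out
}

#' Window-average FST with negative clamping
#'
#' Per window, the unweighted mean over defined site values; windows with
#' a negative average are set to 0 (true FST lies in [0,1]); windows with
#' no defined site stay NA.
#'
#' @param site_fst data frame from \code{\link{fst_sites}} (columns
#'   \code{chrom}, \code{pos}, \code{fst_*}).
#' @param grid a \code{window_table}.
#' @return The grid with one clamped mean column per \code{fst_*} input
#'   column.
#' @export
window_fst <- function(site_fst, grid) {
  stopifnot(inherits(grid, "window_table"))
  idx <- match_windows(site_fst$chrom, site_fst$pos, grid)
  for (col in grep("^fst_", names(site_fst), value = TRUE)) {
    v <- site_fst[[col]]
    ok <- !is.na(v)
    n <- tabulate(idx[ok], nbins = nrow(grid))
    s <- rep(0, nrow(grid))
    if (any(ok)) {
      agg <- rowsum(v[ok], idx[ok])
      s[as.integer(rownames(agg))] <- agg[, 1L]
    }
    grid[[col]] <- ifelse(n > 0, pmax(s / n, 0), NA_real_)
  }
  grid
}

#' Empirical quantile threshold over window FST values
#'
#' Linear interpolation between closest order statistics
#' (\code{stats::quantile} type 7) over the defined window means.
#' Windows strictly above the threshold count as "extreme".
#'
#' @param x window FST values (NAs ignored).
#' @param q probability in (0,1); default 0.95 (top-5% exclusion).
#' @return The threshold (scalar).
#' @export
fst_quantile <- function(x, q = 0.95) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1) {
    stop_("q must be a probability strictly inside (0,1)")
  }
  x <- x[!is.na(x)]
  if (!length(x)) stop_("no defined window FST values")
  stats::quantile(x, q, type = 7, names = FALSE)
}

#' Composite Duroc-Chinese FST track
#'
#' Per window, the arithmetic mean of the Duroc-Meishan and
#' Duroc-Bamaxiang window values; NA if either is undefined.
#'
#' @param fst_du_ms,fst_du_bmx window FST vectors on the same grid.
#' @return numeric vector of composite values.
#' @export
composite_duroc_chinese <- function(fst_du_ms, fst_du_bmx) {
  if (length(fst_du_ms) != length(fst_du_bmx)) {
    stop_("the two window FST tracks are on different grids (lengths %d and %d)",
          length(fst_du_ms), length(fst_du_bmx))
  }
  (fst_du_ms + fst_du_bmx) / 2
}
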