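#' Genome layout
#'
#' An ordered table of chromosomes with lengths. The order is meaningful:
#' it defines the concatenation used by the circular permutation test
#' (SSC1..SSC18 semantics). Coordinates are 0-based half-open internally.
#'
#' @param chrom character vector of unique chromosome names, in order.
#' @param length positive integer chromosome lengths in bp.
#' @param autosome logical flag per chromosome; by default chromosomes
#'   named like \code{"SSC1"} or a bare number are autosomes, anything
#'   else (e.g. \code{"SSCX"}) is not.
#' @return A \code{genome_layout} data frame with columns \code{chrom},
#'   \code{length}, \code{autosome}.
#' @examples
#' genome_layout(c("SSC1", "SSC2"), c(5e6, 4e6))
#' @export
genome_layout <- function(chrom, length, autosome = NULL) {
  chrom <- as.character(chrom)
  if (length(chrom) == 0L) stop_("genome layout is empty")
  if (anyDuplicated(chrom)) stop_("duplicated chromosome names in layout")
  length <- as.numeric(length)
  if (length(length) != length(chrom) || anyNA(length) || any(length <= 0)) {
    stop_("chromosome lengths must be positive and match names")
  }
  if (is.null(autosome)) autosome <- grepl("^(SSC)?[0-9]+$", chrom)
  stopifnot(is.logical(autosome), length(autosome) == length(chrom))
  out <- data.frame(chrom = chrom, length = length, autosome = autosome,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Default scaled-down layout: n autosomes of equal length named SSC1..SSCn.
#' @param n_chromosomes number of autosomes.
#' @param chrom_length_bp length of each, in bp.
#' @return A \code{genome_layout}.
#' @export
default_layout <- function(n_chromosomes = 18L, chrom_length_bp = 5e6) {
  genome_layout(paste0("SSC", seq_len(n_chromosomes)),
                rep(chrom_length_bp, n_chromosomes))
}

#' Non-overlapping window grid over a genome
#'
#' Tiles each chromosome with half-open windows \code{[0, size)},
#' \code{[size, 2*size)}, ..., the final window truncated at the
#' chromosome length. Total window count is \code{sum(ceiling(len/size))}.
#'
#' @param layout a \code{genome_layout}.
#' @param size_bp window size in bp (default 50 kb).
#' @return A \code{window_table} data frame with columns \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{n_snps} and
#'   per-donor ancestry columns initialised to NA, to be filled by
#'   \code{\link{aggregate_ancestry}} and \code{\link{window_fst}}.
#' @examples
#' grid <- window_grid(genome_layout("SSC1", 125000), size_bp = 50000)
#' grid[, c("start", "end")]  # [0,50000) [50000,100000) [100000,125000)
#' @export
window_grid <- function(layout, size_bp = 50000L) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is_count(size_bp) || size_bp <= 0) stop_("size_bp must be a positive integer")
  size_bp <- as.numeric(size_bp)
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    L <- layout$length[i]
    starts <- seq(0, L - 1, by = size_bp)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = pmin(starts + size_bp, L), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$n_snps <- NA_integer_
  for (col in c("p_MS", "p_BMX", "p_EUW", "p_CHN")) out[[col]] <- NA_real_
  rownames(out) <- NULL
  attr(out, "size_bp") <- size_bp
  attr(out, "layout") <- layout
  class(out) <- c("window_table", "data.frame")
  out
}

# 0-based window index within its chromosome for a 1-based bp position.
window_index0 <- function(pos, size_bp) (pos - 1) %/% size_bp

# Row indices in `grid` for SNPs at (chrom, pos); error on off-layout SNPs.
match_windows <- function(chrom, pos, grid) {
  size <- attr(grid, "size_bp")
  key <- paste(grid$chrom, grid$start, sep = ":")
  snp_key <- paste(chrom, window_index0(pos, size) * size, sep = ":")
  idx <- match(snp_key, key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop_("SNP %s:%d falls outside the window grid (unknown chromosome or position beyond chromosome length)",
          chrom[bad], as.integer(pos[bad]))
  }
  idx
}
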