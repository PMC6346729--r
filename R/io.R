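# On-disk conventions: SNP/QTL tables are 1-based inclusive; window/BED
# outputs are 0-based half-open. Each writer states its convention in a
# comment header where the format allows one.

#' Read a per-SNP ancestry table
#'
#' Tab-separated with header \code{chrom pos p_MS p_BMX p_EUW}
#' (positions 1-based). Rows whose proportions do not sum to 1 within
#' \code{tol}, unsorted positions or malformed lines are rejected with
#' the offending line number.
#'
#' @param path input file.
#' @param tol row-sum tolerance (default 1e-6).
#' @return An \code{ancestry_track}.
#' @export
read_ancestry_table <- function(path, tol = 1e-6) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "p_MS", "p_BMX", "p_EUW")
  if (!all(need %in% names(df))) {
    stop_("%s: expected header '%s'", path, paste(need, collapse = "\t"))
  }
  s <- rowSums(df[, c("p_MS", "p_BMX", "p_EUW")])
  bad <- which(abs(s - 1) > tol)
  if (length(bad)) {
    stop_("%s line %d: proportions sum to %.6g, not 1", path, bad[1L] + 1L,
          s[bad[1L]])
  }
  for (ch in unique(df$chrom)) {
    po <- df$pos[df$chrom == ch]
    if (any(diff(po) <= 0)) {
      ln <- which(df$chrom == ch)[which(diff(po) <= 0)[1L] + 1L]
      stop_("%s line %d: positions not strictly increasing on %s",
            path, ln + 1L, ch)
    }
  }
  ancestry_track(df$chrom, df$pos, df$p_MS, df$p_BMX, df$p_EUW, tol = tol)
}

#' Write a per-SNP ancestry table (1-based positions)
#' @param track an \code{ancestry_track}.
#' @param path output file.
#' @export
write_ancestry_table <- function(track, path) {
  utils::write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a QTL table
#'
#' Tab-separated with header
#' \code{qtl_id trait trait_group method chrom start end}, 1-based
#' inclusive coordinates.
#'
#' @param path input file.
#' @return QTL data frame.
#' @export
read_qtl_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("qtl_id", "trait", "trait_group", "method", "chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop_("%s: expected header '%s'", path, paste(need, collapse = "\t"))
  }
  bad <- which(df$start > df$end)
  if (length(bad)) stop_("%s line %d: start > end", path, bad[1L] + 1L)
  df
}

#' Write a QTL table (1-based inclusive coordinates)
#' @param qtl QTL data frame.
#' @param path output file.
#' @export
write_qtl_table <- function(qtl, path) {
  cols <- intersect(c("qtl_id", "trait", "trait_group", "method", "chrom",
                      "start", "end"), names(qtl))
  utils::write.table(qtl[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a chromosome-length table (two columns: chrom, length)
#' @param path input file.
#' @param autosome optional logical per chromosome; default inferred
#'   from the name (numeric suffix = autosome).
#' @return A \code{genome_layout}.
#' @export
read_genome_layout <- function(path, autosome = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  genome_layout(df[[1L]], df[[2L]], autosome)
}

#' Write a chromosome-length table
#' @param layout a \code{genome_layout}.
#' @param path output file.
#' @export
write_genome_layout <- function(layout, path) {
  utils::write.table(layout[, c("chrom", "length")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a window table as BED-like tab-separated text
#'
#' 0-based half-open starts (BED dialect); the documented header line is
#' prefixed with \code{#}.
#'
#' @param table a \code{window_table}.
#' @param path output file.
#' @export
write_window_table <- function(table, path) {
  df <- as.data.frame(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a window table written by \code{\link{write_window_table}}
#' @param path input file.
#' @param layout the \code{genome_layout} of the table.
#' @param size_bp window size used to build the grid.
#' @return A \code{window_table}.
#' @export
read_window_table <- function(path, layout, size_bp = 50000L) {
  header <- sub("^#", "", readLines(path, n = 1L))
  df <- utils::read.table(path, header = FALSE, sep = "\t", skip = 1L,
                          col.names = strsplit(header, "\t")[[1L]],
                          stringsAsFactors = FALSE)
  attr(df, "size_bp") <- as.numeric(size_bp)
  attr(df, "layout") <- layout
  class(df) <- c("window_table", "data.frame")
  df
}

#' Read a sample-to-population map (columns: sample, pop)
#' @param path input file.
#' @return data frame with columns \code{sample}, \code{pop}.
#' @export
read_pop_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "pop") %in% names(df))) {
    stop_("%s: expected header 'sample\tpop'", path)
  }
  df
}

#' Write a phased VCF 4.2 for simulated haplotypes
#'
#' Haplotype matrices pair consecutive rows into diploid samples (so row
#' counts must be even); genotypes are written phased (\code{0|1}).
#' Sites carry placeholder REF/ALT alleles A/C (the simulator models
#' biallelic SNPs, not sequence content).
#'
#' @param sites data frame \code{chrom}, \code{pos} (1-based, sorted).
#' @param haps named list of 0/1 haplotype matrices per population;
#'   sample names become \code{<pop>_<i>}.
#' @param layout a \code{genome_layout} (for contig headers).
#' @param path output file (plain text).
#' @return Invisibly, the data frame mapping sample to population.
#' @export
write_vcf <- function(sites, haps, layout, path) {
  gt_cols <- list(); samples <- character(0); pops <- character(0)
  for (pop in names(haps)) {
    h <- haps[[pop]]
    if (nrow(h) %% 2L != 0L) stop_("odd haplotype count for %s", pop)
    i1 <- seq(1L, nrow(h), by = 2L)
    gt <- matrix(paste0(h[i1, , drop = FALSE], "|",
                        h[i1 + 1L, , drop = FALSE]), nrow = length(i1))
    nm <- paste0(pop, "_", seq_along(i1))
    gt_cols[[pop]] <- gt
    samples <- c(samples, nm)
    pops <- c(pops, rep(pop, length(nm)))
  }
  gt_all <- do.call(rbind, gt_cols)  # samples x sites
  body <- paste(sites$chrom, sites$pos, ".", "A", "C", ".", "PASS", ".",
                "GT", apply(gt_all, 2L, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", layout$chrom,
                      as.integer(layout$length)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(data.frame(sample = samples, pop = pops, stringsAsFactors = FALSE))
}

#' Read phased haplotypes from a VCF, grouped by population
#'
#' @param path VCF file (or a \code{vcfR} object).
#' @param pop_map data frame \code{sample}, \code{pop}.
#' @return list with \code{sites} (chrom, pos) and \code{haplotypes}
#'   (named list of 0/1 matrices per population; two rows per sample,
#'   NA for missing calls).
#' @export
read_vcf_haplotypes <- function(path, pop_map) {
  vcf <- if (is.character(path)) vcfR::read.vcfR(path, verbose = FALSE) else path
  keep <- vcfR::is.biallelic(vcf)
  fix <- vcfR::getFIX(vcf)
  sites <- data.frame(chrom = fix[keep, "CHROM"],
                      pos = as.numeric(fix[keep, "POS"]),
                      stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf)[keep, , drop = FALSE]
  haps <- list()
  for (pop in unique(pop_map$pop)) {
    sm <- intersect(pop_map$sample[pop_map$pop == pop], colnames(gt))
    if (!length(sm)) next
    g <- gt[, sm, drop = FALSE]
    a1 <- suppressWarnings(as.integer(substr(g, 1L, 1L)))
    a2 <- suppressWarnings(as.integer(substr(g, 3L, 3L)))
    m <- matrix(NA_integer_, nrow = 2L * length(sm), ncol = nrow(sites))
    m[seq(1L, by = 2L, length.out = length(sm)), ] <- t(matrix(a1, nrow = nrow(g)))
    m[seq(2L, by = 2L, length.out = length(sm)), ] <- t(matrix(a2, nrow = nrow(g)))
    rownames(m) <- paste0(rep(sm, each = 2L), "_", 1:2)
    haps[[pop]] <- m
  }
  list(sites = sites, haplotypes = haps)
}

#' Write the truth of a simulation as JSON
#' @param admixed an \code{admixed_sim}.
#' @param qtl the simulated QTL table (for planted flags).
#' @param path output file.
#' @export
write_truth_json <- function(admixed, qtl, path) {
  jsonlite::write_json(list(tracts = admixed$truth$tracts,
                            sweeps = admixed$truth$sweeps,
                            qtl_planted = qtl[, c("qtl_id", "planted_in_sweep")]),
                       path, digits = NA)
  invisible(path)
}

#' Read a truth JSON written by \code{\link{write_truth_json}}
#' @param path input file.
#' @return list with \code{tracts}, \code{sweeps}, \code{qtl_planted}
#'   data frames.
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a complete fixture set for a simulated data set
#'
#' Phased VCF (donors + recipients), ancestry table, QTL table,
#' chromosome-length table, sample-population map and truth JSON; all
#' plain text, all round-tripping losslessly through the package
#' readers.
#'
#' @param sim an \code{introgression_sim} from
#'   \code{\link{simulate_dataset}} (with genotypes).
#' @param outdir output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_fixture_set <- function(sim, outdir) {
  stopifnot(inherits(sim, "introgression_sim"))
  if (is.null(sim$admixed$haplotypes)) {
    stop_("simulation was run without genotypes; cannot write a VCF")
  }
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok) stop_("cannot create output directory %s", outdir)
  paths <- c(vcf = file.path(outdir, "genotypes.vcf"),
             ancestry = file.path(outdir, "ancestry.tsv"),
             qtl = file.path(outdir, "qtl.tsv"),
             layout = file.path(outdir, "chrom_lengths.tsv"),
             pop_map = file.path(outdir, "pop_map.tsv"),
             truth = file.path(outdir, "truth.json"))
  haps <- c(list(DU = sim$admixed$haplotypes), sim$panels$haplotypes)
  pm <- write_vcf(sim$panels$sites, haps, sim$layout, paths[["vcf"]])
  utils::write.table(pm, paths[["pop_map"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_ancestry_table(sim$admixed$track, paths[["ancestry"]])
  write_qtl_table(sim$qtl, paths[["qtl"]])
  write_genome_layout(sim$layout, paths[["layout"]])
  write_truth_json(sim$admixed, sim$qtl, paths[["truth"]])
  paths
}

#' Tolerant reader for Animal QTLdb GFF-dialect dumps
#'
#' Parses GFF lines whose attribute column carries at least a QTL id, a
#' trait and a trait group; mapping method defaults to association
#' unless the attributes say linkage. Records that cannot be parsed are
#' skipped and counted in the audit attribute.
#'
#' @param path GFF file.
#' @return QTL data frame (same columns as \code{\link{read_qtl_table}})
#'   with attribute \code{n_skipped}.
#' @export
read_qtldb_gff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  skipped <- 0L
  rows <- lapply(fields, function(f) {
    if (length(f) < 9L) return(NULL)
    attrs <- strsplit(f[9L], ";", fixed = TRUE)[[1L]]
    kv <- strsplit(attrs, "=", fixed = TRUE)
    keys <- tolower(trimws(vapply(kv, `[`, "", 1L)))
    vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
    get <- function(...) {
      for (k in c(...)) if (k %in% keys) return(vals[match(k, keys)])
      NA_character_
    }
    id <- get("qtl_id", "id")
    trait <- get("trait", "name", "trait_name")
    group <- tolower(get("trait_group", "trait_type", "traitgroup"))
    if (is.na(id) || is.na(trait) || !(group %in% TRAIT_GROUPS)) return(NULL)
    method <- get("mapping_method", "method", "map_type")
    method <- if (!is.na(method) && grepl("link", method, ignore.case = TRUE))
      "linkage" else "association"
    start <- suppressWarnings(as.numeric(f[4L]))
    end <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(start) || is.na(end) || start > end) return(NULL)
    data.frame(qtl_id = id, trait = trait, trait_group = group,
               method = method, chrom = f[1L], start = start, end = end,
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, TRUE)
  out <- do.call(rbind, rows[keep])
  if (is.null(out)) {
    out <- data.frame(qtl_id = character(), trait = character(),
                      trait_group = character(), method = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  }
  attr(out, "n_skipped") <- sum(!keep)
  out
}
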