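#' Pipeline configuration
#'
#' Bundles the analysis parameters (all defaults are the scan's
#' published settings: 50-kb windows, >50% Chinese ancestry, top-5% FST
#' exclusion, 10,000 permutations, 1-Mb QTL span cap, five top regions
#' with at least two windows) with the input paths and the seed.
#'
#' @param ancestry,vcf,qtl,layout,pop_map input file paths (ancestry
#'   table, phased VCF, QTL table, chromosome lengths, sample-population
#'   map).
#' @param outdir output directory.
#' @param window_size window size in bp.
#' @param chinese_min Chinese-ancestry threshold (strict).
#' @param fst_q FST quantile for the extreme-FST exclusion. As a point
#'   of reference, the published scan's 95% quantile of the
#'   Meishan-Bamaxiang window distribution was 0.51; the threshold is
#'   always recomputed from the data at hand.
#' @param n_perm permutation count.
#' @param max_span_bp QTL span cap.
#' @param top_k,min_windows top-region selection.
#' @param recipient,donor_ms,donor_bmx,donor_euw population labels in
#'   the pop map.
#' @param haplostrip_top if TRUE, run the haplotype-clustering display
#'   on the top Meishan region.
#' @param seed seed for the permutation draws.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(ancestry, vcf, qtl, layout, pop_map, outdir,
                            window_size = 50000L, chinese_min = 0.5,
                            fst_q = 0.95, n_perm = 10000L,
                            max_span_bp = 1e6, top_k = 5L, min_windows = 2L,
                            recipient = "DU", donor_ms = "MS",
                            donor_bmx = "BMX", donor_euw = "EUW",
                            haplostrip_top = TRUE, seed = 1L) {
  stopifnot(window_size > 0, chinese_min >= 0, chinese_min <= 1,
            fst_q > 0, fst_q < 1, n_perm >= 1, max_span_bp > 0,
            top_k >= 1, min_windows >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full adaptive-introgression scan
#'
#' Stages: window aggregation of the ancestry track; per-site Hudson FST
#' for Duroc-Meishan, Duroc-Bamaxiang and Meishan-Bamaxiang with window
#' averaging and the Duroc-Chinese composite; candidate-window calling;
#' top-region extension for both Chinese donors; QTL filtering,
#' deduplication and circular-permutation enrichment (all traits and per
#' trait group, sharing rotation draws); optionally the haplotype
#' display of the top Meishan region. Writes the window table, candidate
#' and region BED files, QTL results and a JSON manifest with the
#' per-stage audit counts. Identical config and seed give byte-identical
#' outputs.
#'
#' @param config a \code{pipeline_config}.
#' @return Invisibly, a list with the in-memory results
#'   (\code{windows}, \code{candidates}, \code{regions_MS},
#'   \code{regions_BMX}, \code{qtl}, \code{enrichment},
#'   \code{haplostrip}, \code{manifest}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  ok <- dir.exists(cfg$outdir) || dir.create(cfg$outdir, recursive = TRUE)
  if (!ok) stop_("cannot create output directory %s", cfg$outdir)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  layout <- stage("layout", read_genome_layout(cfg$layout))
  track <- stage("ancestry", read_ancestry_table(cfg$ancestry))
  pm <- stage("pop_map", read_pop_map(cfg$pop_map))

  grid <- window_grid(layout, cfg$window_size)
  wt <- stage("aggregate", aggregate_ancestry(track, grid))

  vh <- stage("vcf", read_vcf_haplotypes(cfg$vcf, pm))
  pops <- c(cfg$recipient, cfg$donor_ms, cfg$donor_bmx)
  missing_pops <- setdiff(pops, names(vh$haplotypes))
  if (length(missing_pops)) {
    stop_("pipeline stage 'fst' failed: population(s) %s absent from VCF",
          paste(missing_pops, collapse = ", "))
  }
  site_fst <- stage("fst", fst_sites(
    vh$sites, vh$haplotypes,
    pairs = list(c(cfg$recipient, cfg$donor_ms),
                 c(cfg$recipient, cfg$donor_bmx),
                 c(cfg$donor_ms, cfg$donor_bmx))))
  wt <- stage("window_fst", window_fst(site_fst, wt))
  du_ms <- paste0("fst_", cfg$recipient, "_", cfg$donor_ms)
  du_bmx <- paste0("fst_", cfg$recipient, "_", cfg$donor_bmx)
  ms_bmx <- paste0("fst_", cfg$donor_ms, "_", cfg$donor_bmx)
  wt$fst_DU_CHN <- composite_duroc_chinese(wt[[du_ms]], wt[[du_bmx]])

  cands <- stage("candidates", call_candidates(
    wt, chinese_min = cfg$chinese_min, fst_col = ms_bmx, fst_q = cfg$fst_q))
  regions_ms <- stage("regions", suppressWarnings(extend_top_regions(
    cands$windows, "MS", k = cfg$top_k, min_windows = cfg$min_windows,
    fst_col = ms_bmx, fst_q = cfg$fst_q)))
  regions_bmx <- stage("regions", suppressWarnings(extend_top_regions(
    cands$windows, "BMX", k = cfg$top_k, min_windows = cfg$min_windows,
    fst_col = ms_bmx, fst_q = cfg$fst_q)))

  qtl_raw <- stage("qtl", read_qtl_table(cfg$qtl))
  filt <- stage("qtl_filter", filter_qtls(qtl_raw, layout, cfg$max_span_bp))
  dedup <- stage("qtl_dedup", dedup_and_peaks(filt$records))
  cand_circle <- candidate_window_circle(cands)
  perm <- stage("enrichment", circular_permutation_test(
    cand_circle, dedup$records, cands$windows, n_perm = cfg$n_perm,
    seed = cfg$seed))

  hs <- NULL
  if (isTRUE(cfg$haplostrip_top) && nrow(regions_ms)) {
    hs <- stage("haplostrip", {
      r <- regions_ms[1L, ]
      blk <- extract_block(cfg$vcf, r$chrom, r$start + 1, r$end, pm)
      distances_and_order(blk, ref_pop = cfg$recipient)
    })
    write_haplostrip(hs, file.path(cfg$outdir, "haplostrip_top_MS.tsv"))
  }

  write_window_table(cands$windows, file.path(cfg$outdir, "windows.tsv"))
  write_bed_regions(cands$regions, file.path(cfg$outdir, "candidates.bed"),
                    "candidate")
  write_bed_regions(regions_ms, file.path(cfg$outdir, "top_regions_MS.bed"),
                    "top_MS")
  write_bed_regions(regions_bmx, file.path(cfg$outdir, "top_regions_BMX.bed"),
                    "top_BMX")
  utils::write.table(perm$results, file.path(cfg$outdir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "introgscan",
    version = as.character(utils::packageVersion("introgscan")),
    seed = cfg$seed,
    parameters = cfg[c("window_size", "chinese_min", "fst_q", "n_perm",
                       "max_span_bp", "top_k", "min_windows")],
    audit = list(
      n_snps = nrow(track),
      n_windows = nrow(wt),
      n_snp_windows = sum(wt$n_snps > 0),
      n_candidate_windows = sum(cands$windows$candidate),
      n_candidate_regions = nrow(cands$regions),
      fst_threshold = cands$fst_threshold,
      qtl = as.list(filt$audit),
      qtl_dedup_all = dedup$n_all,
      qtl_dedup_by_group = as.list(dedup$n_by_group)),
    enrichment = perm$results)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(windows = cands$windows, candidates = cands,
                 regions_MS = regions_ms, regions_BMX = regions_bmx,
                 qtl = dedup, enrichment = perm, haplostrip = hs,
                 manifest = manifest))
}

# BED (0-based half-open) with a name column carrying provenance.
write_bed_regions <- function(regions, path, label) {
  if (!nrow(regions)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- data.frame(chrom = regions$chrom,
                   start = format(regions$start, scientific = FALSE, trim = TRUE),
                   end = format(regions$end, scientific = FALSE, trim = TRUE),
                   name = paste0(label, "_", seq_len(nrow(regions))),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
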