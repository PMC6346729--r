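#' Simulation configuration
#'
#' Parameters of the seeded synthetic-data generator. Defaults mirror
#' the study conditions of the adaptive-introgression scan they emulate:
#' donor haplotype counts 60/12/30 (Meishan, Bamaxiang, European wild
#' boar), 180 recipient (Duroc) haplotypes, stationary donor fractions
#' (0.12, 0.13, 0.75), QTL trait-group weights and a lognormal QTL
#' length distribution with mean ~24 kb capped at 1 Mb, and a linkage
#' fraction of 0.349. The genome itself is scaled down (18 autosomes of
#' 5 Mb by default); the methods vignette documents these choices.
#'
#' @param seed master seed; all randomness flows from it through local
#'   RNG scopes (operation k uses \code{seed + k - 1}).
#' @param n_chromosomes,chrom_length_bp genome layout (equal-length
#'   autosomes SSC1..SSCn).
#' @param snp_density expected SNPs per bp.
#' @param donor_divergence named Balding-Nichols drift parameter per
#'   donor, each in [0,1).
#' @param asian_divergence drift of the shared Asian branch from which
#'   both Meishan and Bamaxiang frequencies are drawn (making them
#'   mutually closer than either is to EUW); default half the mean of
#'   the MS/BMX divergences.
#' @param donor_haplotypes named haplotype count per donor panel.
#' @param recipient_haplotypes recipient haplotype count (even, so
#'   haplotypes pair into diploid VCF samples).
#' @param stationary_ancestry donor probability triple (MS, BMX, EUW)
#'   summing to 1.
#' @param switch_rate_per_bp intensity of the Markov ancestry-switch
#'   process; mean tract length is its reciprocal (0 = single tract per
#'   chromosome).
#' @param sweep_regions data frame \code{chrom}, \code{start},
#'   \code{end} (0-based half-open bp), \code{donor}, \code{prob}:
#'   inside each region the boosted donor is drawn with \code{prob},
#'   the others sharing the remainder proportionally.
#' @param qtl_count number of QTL records to generate.
#' @param qtl_group_weights probabilities of the five trait groups.
#' @param qtl_linkage_fraction probability a record is linkage-mapped.
#' @param qtl_length_meanlog,qtl_length_sdlog,qtl_length_cap lognormal
#'   QTL length (bp), capped.
#' @param qtl_non_autosome_fraction fraction of records planted on a
#'   decoy non-autosomal chromosome ("SSCX") to exercise the filters.
#' @param enrichment_rho fraction of association records whose midpoint
#'   is forced uniformly inside a sweep region.
#' @param ancestry_noise Dirichlet concentration blurring the delivered
#'   ancestry proportions around the truth (NULL = none, the default).
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 18L,
                       chrom_length_bp = 5e6,
                       snp_density = 5e-4,
                       donor_divergence = c(MS = 0.15, BMX = 0.15, EUW = 0.3),
                       asian_divergence = NULL,
                       donor_haplotypes = c(MS = 60L, BMX = 12L, EUW = 30L),
                       recipient_haplotypes = 180L,
                       stationary_ancestry = c(MS = 0.12, BMX = 0.13, EUW = 0.75),
                       switch_rate_per_bp = 5e-7,
                       sweep_regions = NULL,
                       qtl_count = 1000L,
                       qtl_group_weights = c(7654, 957, 837, 4774, 1634) / 15856,
                       qtl_linkage_fraction = 0.349,
                       qtl_length_meanlog = log(2e4),
                       qtl_length_sdlog = 1.5,
                       qtl_length_cap = 1e6,
                       qtl_non_autosome_fraction = 0.02,
                       enrichment_rho = 0,
                       ancestry_noise = NULL) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = chrom_length_bp, snp_density = snp_density,
              donor_divergence = donor_divergence[DONORS],
              asian_divergence = asian_divergence,
              donor_haplotypes = donor_haplotypes[DONORS],
              recipient_haplotypes = as.integer(recipient_haplotypes),
              stationary_ancestry = stationary_ancestry[DONORS],
              switch_rate_per_bp = switch_rate_per_bp,
              sweep_regions = sweep_regions,
              qtl_count = as.integer(qtl_count),
              qtl_group_weights = stats::setNames(qtl_group_weights, TRAIT_GROUPS),
              qtl_linkage_fraction = qtl_linkage_fraction,
              qtl_length_meanlog = qtl_length_meanlog,
              qtl_length_sdlog = qtl_length_sdlog,
              qtl_length_cap = qtl_length_cap,
              qtl_non_autosome_fraction = qtl_non_autosome_fraction,
              enrichment_rho = enrichment_rho,
              ancestry_noise = ancestry_noise)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!is_count(n_chromosomes) || n_chromosomes < 1) stop_("n_chromosomes must be >= 1")
    if (chrom_length_bp < 1) stop_("chrom_length_bp must be positive")
    if (anyNA(donor_divergence) || any(donor_divergence < 0 | donor_divergence >= 1)) {
      stop_("donor_divergence must name MS, BMX, EUW with values in [0,1)")
    }
    if (anyNA(donor_haplotypes) || any(donor_haplotypes < 1)) {
      stop_("donor_haplotypes must name MS, BMX, EUW with positive counts")
    }
    if (abs(sum(stationary_ancestry) - 1) > 1e-12) {
      stop_("stationary_ancestry must sum to 1 (got %.15g)", sum(stationary_ancestry))
    }
    if (!is_prob(stationary_ancestry)) stop_("stationary_ancestry outside [0,1]")
    if (switch_rate_per_bp < 0) stop_("switch_rate_per_bp must be >= 0")
    if (abs(sum(qtl_group_weights) - 1) > 1e-9) stop_("qtl_group_weights must sum to 1")
    if (!is_prob(qtl_group_weights)) stop_("qtl_group_weights outside [0,1]")
    if (!is_prob(qtl_linkage_fraction) || !is_prob(enrichment_rho) ||
        !is_prob(qtl_non_autosome_fraction)) {
      stop_("qtl fractions must be probabilities in [0,1]")
    }
    if (!is.null(sweep_regions) && nrow(sweep_regions)) {
      lay <- sim_layout_fields(n_chromosomes, chrom_length_bp)
      m <- match(sweep_regions$chrom, lay$chrom)
      if (anyNA(m)) stop_("sweep region on unknown chromosome %s",
                          sweep_regions$chrom[which(is.na(m))[1L]])
      if (any(sweep_regions$start < 0 | sweep_regions$end > lay$length[m] |
                sweep_regions$start >= sweep_regions$end)) {
        stop_("sweep region outside its chromosome")
      }
      if (!all(sweep_regions$donor %in% DONORS)) stop_("sweep donor must be MS, BMX or EUW")
      if (!is_prob(sweep_regions$prob)) stop_("sweep prob outside [0,1]")
    }
  })
  invisible(cfg)
}

sim_layout_fields <- function(n, L) {
  list(chrom = paste0("SSC", seq_len(n)), length = rep(L, n))
}

#' Genome layout implied by a simulation config
#' @param config a \code{sim_config}.
#' @return A \code{genome_layout} of equal-length autosomes.
#' @export
sim_layout <- function(config) {
  f <- sim_layout_fields(config$n_chromosomes, config$chrom_length_bp)
  genome_layout(f$chrom, f$length)
}

# Balding-Nichols draw around frequency p with drift F:
# Beta(p(1-F)/F, (1-p)(1-F)/F); F = 0 collapses to p itself.
rbn <- function(p, F) {
  if (F <= 0) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate diverged donor allele-frequency panels
#'
#' Places biallelic sites uniformly at the configured density, draws a
#' per-site ancestral alternate-allele frequency Uniform(0.05, 0.95),
#' then donor frequencies down a two-level Balding-Nichols tree:
#' ancestral -> Asian branch -> {Meishan, Bamaxiang}; ancestral -> EUW.
#' Meishan and Bamaxiang thus share the Asian branch and are mutually
#' closer than either is to EUW. Donor haplotypes are sampled
#' independently per site from the donor frequencies.
#'
#' @param config a \code{sim_config}.
#' @param seed RNG seed for this operation; default \code{config$seed}.
#' @return A \code{donor_panels} list: \code{sites} (chrom, pos),
#'   \code{freq} (matrix of ancestral/asian/per-donor frequencies),
#'   \code{haplotypes} (named list of 0/1 matrices, rows = haplotypes).
#' @export
simulate_panels <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  lay <- sim_layout_fields(config$n_chromosomes, config$chrom_length_bp)
  if (config$snp_density * config$chrom_length_bp * config$n_chromosomes < 1) {
    stop_("expected number of sites is below 1; increase snp_density or genome size")
  }
  with_seed(seed, {
    sites <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(i) {
      n <- stats::rpois(1L, config$snp_density * lay$length[i])
      data.frame(chrom = lay$chrom[i],
                 pos = sort(sample.int(lay$length[i], min(n, lay$length[i]))),
                 stringsAsFactors = FALSE)
    }))
    if (!nrow(sites)) stop_("zero sites generated")
    S <- nrow(sites)
    anc <- stats::runif(S, 0.05, 0.95)
    dd <- config$donor_divergence
    F_asian <- config$asian_divergence %||% (mean(dd[c("MS", "BMX")]) / 2)
    asian <- rbn(anc, F_asian)
    freq <- cbind(ancestral = anc, asian = asian,
                  MS = rbn(asian, dd["MS"]), BMX = rbn(asian, dd["BMX"]),
                  EUW = rbn(anc, dd["EUW"]))
    haps <- lapply(DONORS, function(d) {
      nh <- config$donor_haplotypes[[d]]
      matrix(stats::rbinom(nh * S, 1L, rep(freq[, d], each = nh)),
             nrow = nh, ncol = S)
    })
    names(haps) <- DONORS
    structure(list(sites = sites, freq = freq, haplotypes = haps),
              class = "donor_panels")
  })
}

# Donor sampling probabilities for a segment: stationary, or boosted
# inside a sweep (others share the remainder proportionally).
segment_probs <- function(stationary, sweep_donor = NULL, sweep_prob = NULL) {
  if (is.null(sweep_donor)) return(stationary)
  p <- stationary
  rest <- setdiff(DONORS, sweep_donor)
  p[sweep_donor] <- sweep_prob
  p[rest] <- (1 - sweep_prob) * stationary[rest] / sum(stationary[rest])
  p
}

# Tracts tiling [0, L) for one haplotype on one chromosome: segments cut
# at sweep boundaries, exponential tract lengths inside each segment.
sim_tracts_chrom <- function(L, rate, stationary, sweeps_chr) {
  cuts <- sort(unique(c(0, L, sweeps_chr$start, sweeps_chr$end)))
  cuts <- cuts[cuts >= 0 & cuts <= L]
  starts <- numeric(0); ends <- numeric(0); donors <- integer(0)
  for (s in seq_len(length(cuts) - 1L)) {
    a <- cuts[s]; b <- cuts[s + 1L]
    insw <- which(sweeps_chr$start <= a & sweeps_chr$end >= b)
    probs <- if (length(insw)) {
      segment_probs(stationary, sweeps_chr$donor[insw[1L]],
                    sweeps_chr$prob[insw[1L]])
    } else stationary
    if (rate > 0) {
      br <- a
      repeat {
        len <- stats::rexp(1L, rate)
        nxt <- min(br + len, b)
        starts <- c(starts, br); ends <- c(ends, nxt)
        donors <- c(donors, sample.int(3L, 1L, prob = probs))
        br <- nxt
        if (br >= b) break
      }
    } else {
      starts <- c(starts, a); ends <- c(ends, b)
      donors <- c(donors, sample.int(3L, 1L, prob = probs))
    }
  }
  list(start = starts, end = ends, donor = donors)
}

#' Simulate the admixed recipient population
#'
#' For each recipient haplotype and chromosome, ancestry follows a
#' Markov tract process along the genome: tract lengths are exponential
#' with rate \code{switch_rate_per_bp}, tract donors are drawn from the
#' stationary probabilities (boosted inside sweep regions). Alleles
#' inside a tract are copied from one randomly chosen donor haplotype of
#' the tract's donor, re-chosen at each ancestry switch, preserving
#' within-tract haplotype structure. The truth ancestry track at each
#' SNP is the across-haplotype fraction of each donor, optionally
#' blurred with Dirichlet noise.
#'
#' @param config a \code{sim_config}.
#' @param panels output of \code{\link{simulate_panels}}.
#' @param genotypes if FALSE, skip allele copying and return only tracts
#'   and the truth track (faster for ancestry-only studies).
#' @param seed RNG seed; default \code{config$seed + 1}.
#' @return An \code{admixed_sim} list: \code{haplotypes} (recipient 0/1
#'   matrix or NULL), \code{track} (truth \code{ancestry_track}),
#'   \code{truth} (tract table, sweeps), \code{layout}.
#' @export
simulate_admixed <- function(config, panels, genotypes = TRUE,
                             seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(panels, "donor_panels"))
  layout <- sim_layout(config)
  sites <- panels$sites
  S <- nrow(sites)
  R <- config$recipient_haplotypes
  sweeps <- config$sweep_regions
  if (is.null(sweeps)) {
    sweeps <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), donor = character(),
                         prob = numeric(), stringsAsFactors = FALSE)
  }
  pos_by_chr <- split(seq_len(S), factor(sites$chrom, levels = layout$chrom))
  with_seed(seed, {
    counts <- matrix(0L, nrow = S, ncol = 3L, dimnames = list(NULL, DONORS))
    hapmat <- if (genotypes) matrix(0L, nrow = R, ncol = S) else NULL
    tracts <- vector("list", R)
    for (h in seq_len(R)) {
      tr_h <- vector("list", nrow(layout))
      for (ci in seq_len(nrow(layout))) {
        ch <- layout$chrom[ci]
        sw <- sweeps[sweeps$chrom == ch, , drop = FALSE]
        tr <- sim_tracts_chrom(layout$length[ci], config$switch_rate_per_bp,
                               config$stationary_ancestry, sw)
        idx <- pos_by_chr[[ch]]
        if (length(idx)) {
          p0 <- sites$pos[idx] - 1  # 0-based, tract [start,end) half-open
          ti <- findInterval(p0, tr$start)
          dn <- tr$donor[ti]
          counts[idx + (dn - 1L) * S] <- counts[idx + (dn - 1L) * S] + 1L
          if (genotypes) {
            for (t in unique(ti)) {
              d <- tr$donor[t]
              src <- sample.int(config$donor_haplotypes[[d]], 1L)
              snps <- idx[ti == t]
              hapmat[h, snps] <- panels$haplotypes[[DONORS[d]]][src, snps]
            }
          }
        }
        tr_h[[ci]] <- data.frame(hap = h, chrom = ch, start = tr$start,
                                 end = tr$end, donor = DONORS[tr$donor],
                                 stringsAsFactors = FALSE)
      }
      tracts[[h]] <- do.call(rbind, tr_h)
    }
    props <- counts / R
    if (!is.null(config$ancestry_noise)) {
      conc <- config$ancestry_noise
      g <- matrix(stats::rgamma(3L * S, shape = conc * pmax(props, 1e-8)),
                  nrow = S)
      props <- g / rowSums(g)
    }
    track <- ancestry_track(sites$chrom, sites$pos, props[, "MS"],
                            props[, "BMX"], props[, "EUW"])
    structure(list(haplotypes = hapmat, track = track,
                   truth = list(tracts = do.call(rbind, tracts),
                                sweeps = sweeps),
                   layout = layout),
              class = "admixed_sim")
  })
}

#' Simulate a QTL table
#'
#' Generates \code{qtl_count} records: mapping method linkage with
#' probability \code{qtl_linkage_fraction} else association; trait group
#' multinomial by the group weights; lengths lognormal capped at the
#' configured cap (minimum 1 bp); a fraction
#' \code{qtl_non_autosome_fraction} of records lands on the decoy
#' chromosome "SSCX" to exercise the autosome filter; a fraction
#' \code{enrichment_rho} of the remaining association records has its
#' midpoint placed uniformly inside a sweep region (regions weighted by
#' length), the rest uniformly on the genome. Intervals are clipped to
#' their chromosome; coordinates 1-based inclusive.
#'
#' @param config a \code{sim_config}.
#' @param layout a \code{genome_layout}; default from the config.
#' @param sweeps sweep-region data frame; default from the config.
#' @param seed RNG seed; default \code{config$seed + 2}.
#' @return QTL data frame with a truth column \code{planted_in_sweep}.
#' @export
simulate_qtl_table <- function(config, layout = sim_layout(config),
                               sweeps = config$sweep_regions,
                               seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$qtl_count
  has_sweeps <- !is.null(sweeps) && nrow(sweeps) > 0
  if (config$enrichment_rho > 0 && !has_sweeps) {
    stop_("enrichment_rho > 0 but no sweep regions to plant QTLs in")
  }
  with_seed(seed, {
    method <- ifelse(stats::runif(n) < config$qtl_linkage_fraction,
                     "linkage", "association")
    group <- sample(TRAIT_GROUPS, n, replace = TRUE,
                    prob = config$qtl_group_weights)
    len <- pmax(1, pmin(round(stats::rlnorm(n, config$qtl_length_meanlog,
                                            config$qtl_length_sdlog)),
                        config$qtl_length_cap))
    decoy <- stats::runif(n) < config$qtl_non_autosome_fraction
    planted <- !decoy & method == "association" &
      stats::runif(n) < config$enrichment_rho
    chrom <- character(n); mid <- numeric(n)
    u <- !decoy & !planted
    if (any(u)) {
      ci <- sample.int(nrow(layout), sum(u), replace = TRUE,
                       prob = layout$length)
      chrom[u] <- layout$chrom[ci]
      mid[u] <- floor(stats::runif(sum(u)) * layout$length[ci]) + 1
    }
    if (any(planted)) {
      si <- sample.int(nrow(sweeps), sum(planted), replace = TRUE,
                       prob = sweeps$end - sweeps$start)
      chrom[planted] <- sweeps$chrom[si]
      mid[planted] <- sweeps$start[si] +
        floor(stats::runif(sum(planted)) * (sweeps$end[si] - sweeps$start[si])) + 1
    }
    if (any(decoy)) {
      chrom[decoy] <- "SSCX"
      mid[decoy] <- floor(stats::runif(sum(decoy)) * layout$length[1L]) + 1
    }
    start <- mid - len %/% 2
    end <- start + len - 1
    cl <- layout$length[match(chrom, layout$chrom)]
    cl[is.na(cl)] <- layout$length[1L]  # decoy chromosome length
    start <- pmax(start, 1)
    end <- pmin(end, cl)
    out <- data.frame(qtl_id = sprintf("QTL%05d", seq_len(n)),
                      trait = sprintf("trait_%03d",
                                      match(group, TRAIT_GROUPS) * 100 +
                                        (seq_len(n) %% 97)),
                      trait_group = group, method = method, chrom = chrom,
                      start = start, end = end,
                      planted_in_sweep = planted, stringsAsFactors = FALSE)
    out
  })
}

#' Simulate a complete synthetic data set
#'
#' Panels, admixed recipients and QTL table from one master seed
#' (operations use consecutive derived seeds, so each stage is also
#' reproducible in isolation).
#'
#' @param config a \code{sim_config}.
#' @param genotypes passed to \code{\link{simulate_admixed}}.
#' @return An \code{introgression_sim} list: \code{config},
#'   \code{layout}, \code{panels}, \code{admixed}, \code{qtl}.
#' @export
simulate_dataset <- function(config = sim_config(), genotypes = TRUE) {
  panels <- simulate_panels(config)
  admixed <- simulate_admixed(config, panels, genotypes = genotypes)
  qtl <- simulate_qtl_table(config)
  structure(list(config = config, layout = admixed$layout, panels = panels,
                 admixed = admixed, qtl = qtl),
            class = "introgression_sim")
}

#' Windows overlapping the planted sweep regions
#'
#' @param sweeps sweep-region data frame.
#' @param grid a \code{window_table}.
#' @return integer row indices of grid windows overlapping any sweep.
#' @export
sweep_windows <- function(sweeps, grid) {
  idx <- integer(0)
  for (i in seq_len(nrow(sweeps))) {
    idx <- c(idx, which(grid$chrom == sweeps$chrom[i] &
                          grid$start < sweeps$end[i] &
                          grid$end > sweeps$start[i]))
  }
  sort(unique(idx))
}
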