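## Synthetic diploid population with background recombination and one
## planted non-recombining region carrying sex-linked haplotypes. Outside
## the region, each haplotype is a founder mosaic with per-bp crossover
## probability, which yields distance-decaying r2. Inside, crossover
## probability is zero, so each haplotype carries one intact ancestral SDR
## haplotype: either the M-like haplotype (one copy in every heterogametic
## individual, carrying M-specific alleles) or one of a small pool of
## F-like SDR founder haplotypes (two deep classes with founder-specific
## polymorphic sites). Complete linkage across the region produces elevated
## r2, and the M-specific alleles produce elevated heterozygosity in
## heterogametic samples.

#' Default sample sheet for the population simulator
#'
#' Three females, three males (heterogametic) and four hermaphrodites,
#' mirroring a ten-accession resequencing panel.
#'
#' @return data.frame with `sample_id`, `sex_type`.
#' @export
default_sample_sheet <- function() {
  data.frame(
    sample_id = c(sprintf("F%d", 1:3), sprintf("M%d", 1:3), sprintf("H%d", 1:4)),
    sex_type = c(rep("homogametic", 3L), rep("heterogametic", 3L),
                 rep("homogametic", 4L)),
    stringsAsFactors = FALSE)
}

#' Configuration for the population simulator
#'
#' @param samples data.frame with `sample_id` and `sex_type`
#'   (`"homogametic"`/`"heterogametic"`); at least 4 samples.
#' @param chrom_length_bp Chromosome length (default 2 Mbp).
#' @param snp_density Background SNP density per bp outside the SDR
#'   (default 3e-3).
#' @param recomb_rate Per-bp crossover probability of the founder mosaic
#'   outside the SDR (0 inside).
#' @param sdr_interval `c(start, end)` of the non-recombining region
#'   (1-based bp), or `NULL` for a fully recombining chromosome.
#' @param sdr_divergence Per-bp density of M-specific differences inside
#'   the SDR (sites where only the M-like haplotype carries the alternate
#'   allele; heterozygous in every heterogametic sample).
#' @param sdr_poly_density Per-bp density of sites polymorphic among the
#'   F-like SDR founder haplotypes.
#' @param n_founders Founder haplotypes of the background mosaic.
#' @param n_sdr_founders F-like SDR founder haplotypes (complete linkage
#'   inside the region keeps them intact; default 4, split into two deep
#'   classes).
#' @param geno_error Per-call error probability flipping a genotype one
#'   step (default 0).
#' @param dp_mean Mean simulated per-sample read depth.
#' @param contig Contig name in the emitted VCF.
#' @param seed Simulation seed.
#' @return A `pop_sim_config`.
#' @export
pop_sim_config <- function(samples = default_sample_sheet(),
                           chrom_length_bp = 2e6, snp_density = 3e-3,
                           recomb_rate = 3e-4,
                           sdr_interval = c(1.2e6, 1.35e6),
                           sdr_divergence = 4.5e-3,
                           sdr_poly_density = 1.5e-3,
                           n_founders = 8L, n_sdr_founders = 4L,
                           geno_error = 0,
                           dp_mean = 20, contig = "chr2", seed = 1L) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "sex_type") %in% names(samples)),
            all(samples$sex_type %in% c("homogametic", "heterogametic")),
            snp_density > 0, recomb_rate >= 0, n_founders >= 2L,
            n_sdr_founders >= 2L)
  if (nrow(samples) < 4L) stopf("need at least 4 samples for LD estimation")
  if (!is.null(sdr_interval)) {
    stopifnot(length(sdr_interval) == 2L, sdr_interval[1L] >= 1,
              sdr_interval[2L] <= chrom_length_bp,
              sdr_interval[1L] < sdr_interval[2L])
  }
  structure(list(samples = samples, chrom_length_bp = chrom_length_bp,
                 snp_density = snp_density, recomb_rate = recomb_rate,
                 sdr_interval = sdr_interval,
                 sdr_divergence = sdr_divergence,
                 sdr_poly_density = sdr_poly_density,
                 n_founders = as.integer(n_founders),
                 n_sdr_founders = as.integer(n_sdr_founders),
                 geno_error = geno_error, dp_mean = dp_mean,
                 contig = contig, seed = as.integer(seed)),
            class = "pop_sim_config")
}

## random carrier patterns: for each site, a nonempty proper subset of the
## `nf` founders carries the alternate allele
random_carrier_patterns <- function(nf, n_sites) {
  carriers <- matrix(FALSE, nf, n_sites)
  if (n_sites == 0L) return(carriers)
  n_alt <- sample.int(nf - 1L, n_sites, replace = TRUE)
  for (s in seq_len(n_sites)) carriers[sample.int(nf, n_alt[s]), s] <- TRUE
  carriers
}

#' Simulate a diploid population with a planted non-recombining region
#'
#' @param cfg A [pop_sim_config()].
#' @param vcf_path Optional path; when given, the genotypes are also written
#'   as a VCF (with QUAL, per-sample DP and the INFO metrics populated, so
#'   the full filtering path is exercisable). Deterministic under the seed:
#'   the same config writes a byte-identical file.
#' @return List with `matrix` (a [genotype_matrix]), `truth` (SDR bounds,
#'   per-sample sex, per-haplotype SDR founder assignment, model rates,
#'   seed), and `vcf_path`.
#' @export
simulate_population <- function(cfg, vcf_path = NULL) {
  stopifnot(inherits(cfg, "pop_sim_config"))
  set.seed(cfg$seed)
  L <- cfg$chrom_length_bp
  ns <- nrow(cfg$samples)
  nh <- 2L * ns
  sdr <- cfg$sdr_interval
  in_sdr <- function(p) if (is.null(sdr)) rep(FALSE, length(p)) else {
    p >= sdr[1L] & p <= sdr[2L]
  }
  ## --- site positions -------------------------------------------------
  bg_len <- L - if (is.null(sdr)) 0 else (sdr[2L] - sdr[1L] + 1)
  n_bg <- rpois(1L, cfg$snp_density * bg_len)
  bg_pos <- sort(sample.int(L, min(n_bg, L)))
  bg_pos <- bg_pos[!in_sdr(bg_pos)]
  if (!is.null(sdr)) {
    sdr_len <- sdr[2L] - sdr[1L] + 1
    n_m <- min(rpois(1L, cfg$sdr_divergence * sdr_len), sdr_len)
    n_sf <- min(rpois(1L, cfg$sdr_poly_density * sdr_len), sdr_len)
    m_pos <- sort(sdr[1L] - 1L + sample.int(sdr_len, n_m))
    sf_pos <- sort(sdr[1L] - 1L + sample.int(sdr_len, n_sf))
    sf_pos <- setdiff(sf_pos, m_pos)
  } else {
    m_pos <- sf_pos <- integer()
  }
  pos <- sort(c(bg_pos, m_pos, sf_pos))
  type <- ifelse(pos %in% m_pos, "M", ifelse(pos %in% sf_pos, "SF", "bg"))
  nv <- length(pos)
  bg_idx <- which(type == "bg")
  sf_idx <- which(type == "SF")
  m_idx <- which(type == "M")
  ## --- ancestral patterns ----------------------------------------------
  nf <- cfg$n_founders
  carriers_bg <- random_carrier_patterns(nf, length(bg_idx))
  nsf <- cfg$n_sdr_founders
  carriers_sf <- random_carrier_patterns(nsf, length(sf_idx))
  ## --- haplotypes -------------------------------------------------------
  hap_alleles <- matrix(0L, nh, nv)
  hetero <- cfg$samples$sex_type == "heterogametic"
  ## haplotype 2s-1 / 2s belong to sample s; the first haplotype of each
  ## heterogametic sample carries the M-like SDR haplotype (founder 0)
  sdr_founder <- integer(nh)
  for (h in seq_len(nh)) {
    smp <- ceiling(h / 2)
    is_m_hap <- hetero[smp] && (h %% 2L == 1L)
    sdr_founder[h] <- if (is.null(sdr)) NA_integer_ else if (is_m_hap) 0L else
      sample.int(nsf, 1L)
    ## founder mosaic with crossover breakpoints outside the SDR
    n_cross <- rpois(1L, cfg$recomb_rate * bg_len)
    cross <- sort(runif(n_cross, 1, L))
    if (!is.null(sdr)) cross <- cross[!in_sdr(cross)]
    founder_path <- sample.int(nf, length(cross) + 1L, replace = TRUE)
    f_at <- founder_path[findInterval(pos[bg_idx], cross) + 1L]
    hap_alleles[h, bg_idx] <- as.integer(carriers_bg[cbind(f_at, seq_along(bg_idx))])
    if (!is.null(sdr)) {
      if (sdr_founder[h] == 0L) {
        hap_alleles[h, m_idx] <- 1L    # M-specific alleles; ref at SF sites
      } else {
        hap_alleles[h, sf_idx] <-
          as.integer(carriers_sf[sdr_founder[h], seq_along(sf_idx)])
      }
    }
  }
  geno <- vapply(seq_len(ns), function(s) {
    hap_alleles[2L * s - 1L, ] + hap_alleles[2L * s, ]
  }, integer(nv))          # variants x samples
  if (cfg$geno_error > 0) {
    flip <- matrix(runif(length(geno)) < cfg$geno_error, nrow(geno))
    geno[flip] <- pmin(2L, pmax(0L, geno[flip] +
                                  sample(c(-1L, 1L), sum(flip), replace = TRUE)))
  }
  ## drop monomorphic sites
  poly <- apply(geno, 1L, function(g) length(unique(g)) > 1L)
  pos <- pos[poly]; type <- type[poly]
  geno <- geno[poly, , drop = FALSE]
  nv <- length(pos)
  ## --- QC fields --------------------------------------------------------
  qual <- round(runif(nv, 50, 2000), 2)
  dp <- matrix(rpois(nv * ns, cfg$dp_mean), nv, ns)
  info <- data.frame(QD = round(runif(nv, 15, 35), 2),
                     FS = round(runif(nv, 0, 10), 2),
                     MQ = 60,
                     MQRankSum = round(rnorm(nv, 0, 1), 2),
                     ReadPosRankSum = round(rnorm(nv, 0, 1), 2),
                     SOR = round(runif(nv, 0.5, 2.5), 2))
  m <- genotype_matrix(cfg$contig, pos, rep("A", nv), rep("G", nv), qual,
                       geno, dp, info, cfg$samples$sample_id)
  truth <- list(sdr_interval = sdr,
                samples = cfg$samples,
                sdr_founder = sdr_founder,
                site_type = setNames(type, pos),
                recomb_rate = cfg$recomb_rate,
                sdr_divergence = cfg$sdr_divergence,
                seed = cfg$seed)
  if (!is.null(vcf_path)) write_genotype_vcf(m, vcf_path)
  list(matrix = m, truth = truth, vcf_path = vcf_path)
}
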