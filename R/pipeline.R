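## End-to-end orchestration: each runner consumes a validated config list
## (typically read from YAML), runs one analysis through the module
## functions, and writes its outputs atomically under an output directory.
## A thin command-line dispatcher over these runners ships in
## inst/cli/sdrkit.

check_config <- function(config, allowed, required = character()) {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stopf("missing config key(s): %s", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("cannot read config: %s", path)
  yaml::read_yaml(path)
}

log_msg <- function(...) message(sprintf("[sdrkit %s] ", format(Sys.time(), "%H:%M:%S")),
                                 sprintf(...))

#' Run the synthetic-data generators
#'
#' Writes a simulated genome set (GFF3 + hit tables + truth) and a
#' simulated population VCF under `out_dir`.
#'
#' @param config List with keys `out_dir`, `seed`, and optional `genome`
#'   and `population` sub-lists overriding [genome_sim_config()] /
#'   [pop_sim_config()] arguments.
#' @return Invisibly, a list with the two simulator results.
#' @export
run_simulate <- function(config) {
  check_config(config, c("out_dir", "seed", "genome", "population"),
               c("out_dir", "seed"))
  seed <- as.integer(config$seed)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  gargs <- config$genome %||% list()
  gargs$seed <- derive_seed(seed, 1L)
  gs <- simulate_genome_set(do.call(genome_sim_config, gargs))
  write_genome_set(gs, file.path(out, "genomes"))
  pargs <- config$population %||% list()
  pargs$seed <- derive_seed(seed, 2L)
  ps <- simulate_population(do.call(pop_sim_config, pargs),
                            vcf_path = file.path(out, "population.vcf"))
  write_sim_truth(ps$truth[setdiff(names(ps$truth), "samples")],
                  file.path(out, "population.truth.json"))
  log_msg("simulate: %d haplotypes, %d SNPs -> %s",
          length(gs$targets), n_variants(ps$matrix), out)
  invisible(list(genomes = gs, population = ps))
}

#' Run synteny detection and window conservation end to end
#'
#' Detects collinear blocks between the reference and every target
#' haplotype, assigns 12-gene windows in the requested mode, summarizes
#' conservation, and writes the per-window table plus a summary JSON.
#'
#' @param config List with keys: `ref_gff`, `haplotypes` (list of
#'   `list(id, gff, hits, clade)`), `out_dir`, and optional `window_size`
#'   (12), `min_block_size` (5), `max_gap` (25), `evalue_max` (0.001),
#'   `max_targets` (100), `mode` (`"orthologous"`), `min_window_anchors`
#'   (2), `focus_window`.
#' @return Invisibly, the [summarize_conservation()] result.
#' @export
run_synteny_windows <- function(config) {
  check_config(config,
               c("ref_gff", "haplotypes", "out_dir", "window_size",
                 "min_block_size", "max_gap", "evalue_max", "max_targets",
                 "mode", "min_window_anchors", "focus_window"),
               c("ref_gff", "haplotypes", "out_dir"))
  mode <- config$mode %||% "orthologous"
  stopifnot(mode %in% c("orthologous", "homologous"))
  ref <- read_gff_genes(config$ref_gff)
  windows <- make_windows(ref, config$window_size %||% 12L)
  assignments <- list()
  clade_of <- character()
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (h in config$haplotypes) {
    target <- read_gff_genes(h$gff, haplotype_id = h$id,
                             clade = h$clade %||% "eudicot")
    hits <- read_hit_table(h$hits, evalue_max = config$evalue_max %||% 0.001,
                           max_targets = config$max_targets %||% 100L)
    blocks <- detect_collinear_blocks(ref, target, hits,
                                      min_block_size = config$min_block_size %||% 5L,
                                      max_gap = config$max_gap %||% 25L)
    write_collinearity(blocks, file.path(out, paste0(h$id, ".collinearity")))
    assignments[[h$id]] <- if (mode == "orthologous") {
      assign_orthologous(windows, blocks, hits$self_scores, h$id)
    } else {
      assign_homologous(windows, blocks, hits$self_scores, h$id,
                        config$min_window_anchors %||% 2L)
    }
    clade_of[h$id] <- h$clade %||% "eudicot"
    log_msg("synteny: %s -> %d blocks", h$id, length(blocks))
  }
  summ <- summarize_conservation(assignments, clade_of,
                                 focus_window = config$focus_window)
  write_tsv(summ$table, file.path(out, "window_table.tsv"))
  write_tsv(summ$window_stats, file.path(out, "window_stats.tsv"))
  write_atomic(function(tmp) {
    jsonlite::write_json(list(n_windows = nrow(windows$windows),
                              mode = mode,
                              focus_window = config$focus_window,
                              tests = summ$tests),
                         tmp, auto_unbox = TRUE, digits = NA)
  }, file.path(out, "summary.json"))
  invisible(summ)
}

#' Run the LD scan: filtering, pairwise r2, landscape, decay fit
#'
#' @param config List with keys: `vcf`, `out_dir`, and optional `region`,
#'   `filter` (sub-list of [filter_profile()] arguments or `false` to
#'   skip), `maf_min` (0.05), `max_dist_bp` (300000), `bin_bp` (1000),
#'   `min_snps` (5), `n_chromosomes` (2 x samples), `landscape_region`.
#' @return Invisibly, a list with `pairs`, `landscape`, `fit`.
#' @export
run_ld_scan <- function(config) {
  check_config(config,
               c("vcf", "region", "out_dir", "filter", "maf_min",
                 "max_dist_bp", "bin_bp", "min_snps", "n_chromosomes",
                 "landscape_region"),
               c("vcf", "out_dir"))
  m <- read_vcf_region(config$vcf, config$region)
  if (!isFALSE(config$filter)) {
    prof <- do.call(filter_profile, config$filter %||% list())
    m <- filter_variants(m, prof)
  }
  pairs <- pairwise_r2(m, maf_min = config$maf_min %||% 0.05,
                       max_dist_bp = config$max_dist_bp %||% 300000L)
  region <- config$landscape_region %||% range(m$pos)
  landscape <- aggregate_ld_bins(pairs, region,
                                 bin_bp = config$bin_bp %||% 1000L,
                                 min_snps = config$min_snps %||% 5L)
  n_chr <- config$n_chromosomes %||% (2L * length(m$samples))
  fit <- tryCatch(fit_ld_decay(pairs, n_chr), error = function(e) NULL)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_tsv(pairs, file.path(out, "ld_pairs.tsv"))
  write_tsv(landscape, file.path(out, "ld_landscape.tsv"))
  if (!is.null(fit)) {
    write_atomic(function(tmp) {
      jsonlite::write_json(unclass(fit), tmp, auto_unbox = TRUE, digits = NA)
    }, file.path(out, "ld_decay.json"))
  }
  log_msg("ld-scan: %d SNPs, %d pairs", n_variants(m), nrow(pairs))
  invisible(list(matrix = m, pairs = pairs, landscape = landscape, fit = fit))
}

#' Run molecular-clock dating
#'
#' Dates features either from explicit genetic distances or from pairwise
#' aligned FASTA sequences (K2P on nucleotide pairs).
#'
#' @param config List with keys: `out_dir`, plus either `K` (numeric
#'   vector) or `fasta` (path; consecutive records are paired), and
#'   optional `mu`, `generation_time_years`.
#' @return Invisibly, the [date_feature()] result.
#' @export
run_date <- function(config) {
  check_config(config, c("K", "fasta", "mu", "generation_time_years",
                         "out_dir"), "out_dir")
  clock <- clock_params(mu = config$mu %||% 2.5e-9,
                        generation_time_years = config$generation_time_years %||% 3)
  K <- if (!is.null(config$K)) as.numeric(config$K) else {
    seqs <- read_fasta(config$fasta)
    if (length(seqs) %% 2L != 0L) stopf("fasta must hold sequence pairs")
    vapply(seq(1L, length(seqs), by = 2L), function(i) {
      kimura2p(seqs[[i]], seqs[[i + 1L]])$value
    }, numeric(1L))
  }
  res <- date_feature(K, clock)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_atomic(function(tmp) {
    jsonlite::write_json(c(list(K = K), res[c("mean_time_my", "sd_my")]),
                         tmp, auto_unbox = TRUE, digits = NA)
  }, file.path(config$out_dir, "dating.json"))
  log_msg("date: %d estimates -> %.1f My", length(K), res$mean_time_my)
  invisible(res)
}

#' Run the promoter TF-binding-site analysis
#'
#' @param config List with keys: `promoters_fasta` (records named
#'   `haplotype|group`), `pfm`, `out_dir`, and optional `min_rel_score`
#'   (0.8), `window_bp` (30).
#' @return Invisibly, a list with `hits`, `specific`, `differential`.
#' @export
run_tfbs <- function(config) {
  check_config(config, c("promoters_fasta", "pfm", "out_dir",
                         "min_rel_score", "window_bp"),
               c("promoters_fasta", "pfm", "out_dir"))
  seqs <- read_fasta(config$promoters_fasta)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  promoters <- data.frame(
    gene_id = "promoter", haplotype_id = vapply(parts, `[`, "", 1L),
    group = vapply(parts, function(p) p[2L] %||% NA_character_, ""),
    sequence = unname(seqs), length = nchar(unname(seqs)),
    stringsAsFactors = FALSE)
  pfms <- read_pfm_jaspar(config$pfm)
  pwms <- lapply(names(pfms), function(id) make_pwm(pfms[[id]], motif_id = id))
  hits <- scan_promoters(promoters, pwms,
                         min_rel_score = config$min_rel_score %||% 0.80)
  specific <- group_specific_sites(hits, promoters,
                                   window_bp = config$window_bp %||% 30L)
  differential <- differential_site_counts(hits, promoters)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_tsv(hits, file.path(out, "tfbs_hits.tsv"))
  write_tsv(specific, file.path(out, "tfbs_group_specific.tsv"))
  write_tsv(differential, file.path(out, "tfbs_differential.tsv"))
  log_msg("tfbs: %d hits, %d group-specific site(s)", nrow(hits),
          nrow(specific))
  invisible(list(hits = hits, specific = specific,
                 differential = differential))
}
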