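## Synthetic comparative-genomics panel: a clade-structured set of haplotypes
## derived from one ancestral gene order by inversion / loss / gain / tandem
## duplication / WGD, with homology bit scores decaying in divergence time
## and one planted hyper-conserved window. Ground truth travels with the
## data so every downstream stage can be checked against what was planted.

#' Default haplotype panel for the genome simulator
#'
#' Eudicot and other-angiosperm haplotypes at increasing divergence times,
#' plus non-flowering outgroups (whose planted-window genes are deleted,
#' emulating the absence of the region outside flowering plants).
#'
#' @param n_eudicot,n_other,n_nonflowering Panel sizes.
#' @param n_wgd How many of the angiosperm haplotypes carry a whole-genome
#'   duplication.
#' @param seed Seed for the divergence-time draws.
#' @return data.frame with `haplotype_id`, `clade`, `time`, `wgd`.
#' @export
default_haplotype_panel <- function(n_eudicot = 10L, n_other = 10L,
                                    n_nonflowering = 4L, n_wgd = 2L,
                                    seed = 1L) {
  set.seed(derive_seed(seed, 11L))
  hap <- data.frame(
    haplotype_id = c(sprintf("eud%02d", seq_len(n_eudicot)),
                     sprintf("ang%02d", seq_len(n_other)),
                     sprintf("nfl%02d", seq_len(n_nonflowering))),
    clade = c(rep("eudicot", n_eudicot), rep("other_angiosperm", n_other),
              rep("non_flowering", n_nonflowering)),
    time = c(runif(n_eudicot, 0.3, 1.0), runif(n_other, 1.0, 2.0),
             runif(n_nonflowering, 2.5, 3.0)),
    stringsAsFactors = FALSE)
  hap$wgd <- FALSE
  if (n_wgd > 0L && n_eudicot + n_other > 0L) {
    hap$wgd[sample(which(hap$clade != "non_flowering"),
                   min(n_wgd, n_eudicot + n_other))] <- TRUE
  }
  hap
}

#' Configuration for the genome-set simulator
#'
#' @param n_genes Ancestral gene count (default 2400 = 200 windows of 12).
#' @param n_contigs Number of reference contigs the genes are split over.
#' @param haplotypes data.frame as from [default_haplotype_panel()].
#' @param rates Per-gene per-unit-time event rates: `gene_loss`,
#'   `gene_gain`, `inversion`, `tandem_dup`.
#' @param planted_window `list(index, boost)`: window index (in
#'   [make_windows()] numbering at `window_size`) whose genes decay
#'   `(1 - boost)` times as fast and are lost `(1 - boost)` times as often.
#' @param window_size Window size used to resolve the planted window.
#' @param bitscore `list(self_min, self_max, lambda, noise_sd)`: self scores
#'   are uniform on `[self_min, self_max]`; a pair score is
#'   `self * exp(-lambda * t * (1 - boost))` times lognormal noise.
#' @param seed Simulation seed.
#' @return A `genome_sim_config`.
#' @export
genome_sim_config <- function(n_genes = 2400L, n_contigs = 4L,
                              haplotypes = default_haplotype_panel(seed = seed),
                              rates = list(gene_loss = 0.04, gene_gain = 0.02,
                                           inversion = 0.0015,
                                           tandem_dup = 0.01),
                              planted_window = list(index = 40L, boost = 0.9),
                              window_size = 12L,
                              bitscore = list(self_min = 500, self_max = 2000,
                                              lambda = 0.5, noise_sd = 0.03),
                              seed = 1L) {
  stopifnot(is_count(n_genes, 10L), is_count(n_contigs),
            n_genes %% n_contigs == 0L,
            all(c("gene_loss", "gene_gain", "inversion", "tandem_dup") %in%
                  names(rates)),
            all(unlist(rates) >= 0),
            planted_window$boost >= 0, planted_window$boost <= 1)
  if (max(haplotypes$time) * rates$gene_loss >= 1) {
    stopf("gene_loss rate x max divergence time implies losing the genome")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_contigs = as.integer(n_contigs),
                 haplotypes = haplotypes, rates = rates,
                 planted_window = planted_window,
                 window_size = as.integer(window_size),
                 bitscore = bitscore, seed = as.integer(seed)),
            class = "genome_sim_config")
}

ref_annotation_from_order <- function(gene_ids, contig_of, hap_id, clade) {
  pos <- stats::ave(seq_along(gene_ids), contig_of, FUN = seq_along)
  genome_annotation(data.frame(
    gene_id = gene_ids, contig = contig_of,
    start = (pos - 1L) * 2000L, end = (pos - 1L) * 2000L + 1000L,
    strand = "+", stringsAsFactors = FALSE),
    haplotype_id = hap_id, clade = clade)
}

#' Simulate a clade-structured genome set with a planted conserved window
#'
#' Evolves each haplotype independently from the ancestral (reference) gene
#' order: genes are lost, gained and tandem-duplicated, contiguous rank
#' segments are inverted, and WGD haplotypes carry a duplicate of every
#' contig. Homology bit scores decay exponentially in divergence time;
#' genes of the planted window decay and are lost `(1 - boost)` times as
#' fast, and are deleted outright in non-flowering haplotypes.
#'
#' @param cfg A [genome_sim_config()].
#' @return List with `ref` ([genome_annotation]), `targets` (named list of
#'   annotations), `hits` (named list of [hit_table]s), and `truth`
#'   (planted window index and gene ids, boost, panel table, model
#'   parameters, seed).
#' @export
simulate_genome_set <- function(cfg) {
  stopifnot(inherits(cfg, "genome_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  per_contig <- n %/% cfg$n_contigs
  ref_ids <- sprintf("ref_g%05d", seq_len(n))
  contig_of <- rep(sprintf("chr%d", seq_len(cfg$n_contigs)), each = per_contig)
  ref <- ref_annotation_from_order(ref_ids, contig_of, "reference", "eudicot")
  self_scores <- setNames(round(runif(n, cfg$bitscore$self_min,
                                      cfg$bitscore$self_max), 1), ref_ids)
  windows <- make_windows(ref, cfg$window_size)
  pw <- cfg$planted_window$index
  if (pw > nrow(windows$windows)) stopf("planted window index out of range")
  planted_genes <- windows$gene_ids[[pw]]
  boost_of <- setNames(rep(0, n), ref_ids)
  boost_of[planted_genes] <- cfg$planted_window$boost
  lambda <- cfg$bitscore$lambda
  noise_sd <- cfg$bitscore$noise_sd

  targets <- list()
  hits <- list()
  for (k in seq_len(nrow(cfg$haplotypes))) {
    hap <- cfg$haplotypes[k, ]
    t <- hap$time
    ## per-contig gene order, tracked as ancestor ids (NA = gained gene)
    order_by_contig <- split(ref_ids, contig_of)[unique(contig_of)]
    ## losses: planted genes are lost (1 - boost) times as often; in
    ## non-flowering haplotypes the planted window is absent outright
    p_loss <- 1 - exp(-cfg$rates$gene_loss * t * (1 - boost_of))
    lost <- runif(n) < p_loss[ref_ids]
    if (hap$clade == "non_flowering") lost[match(planted_genes, ref_ids)] <- TRUE
    lost_ids <- ref_ids[lost]
    order_by_contig <- lapply(order_by_contig, setdiff, y = lost_ids)
    ## inversions: reverse contiguous rank segments
    n_inv <- rpois(1L, cfg$rates$inversion * n * t)
    for (i in seq_len(n_inv)) {
      ctg <- sample(names(order_by_contig), 1L)
      v <- order_by_contig[[ctg]]
      if (length(v) < 6L) next
      len <- sample(5:50, 1L)
      from <- sample(seq_len(max(1L, length(v) - len)), 1L)
      to <- min(length(v), from + len - 1L)
      v[from:to] <- rev(v[from:to])
      order_by_contig[[ctg]] <- v
    }
    ## tandem duplications: a copy inserted next to the original
    p_dup <- 1 - exp(-cfg$rates$tandem_dup * t)
    order_by_contig <- lapply(order_by_contig, function(v) {
      dup <- runif(length(v)) < p_dup
      if (!any(dup)) return(v)
      unlist(lapply(seq_along(v), function(i) {
        if (dup[i] && !is.na(v[i])) c(v[i], v[i]) else v[i]
      }), use.names = FALSE)
    })
    ## gains: novel genes without a reference ancestor
    n_gain <- rpois(1L, cfg$rates$gene_gain * n * t)
    if (n_gain > 0L) {
      ctgs <- sample(names(order_by_contig), n_gain, replace = TRUE)
      for (ctg in names(order_by_contig)) {
        m <- sum(ctgs == ctg)
        if (m == 0L) next
        v <- order_by_contig[[ctg]]
        at <- sample(seq_len(length(v) + 1L), m, replace = TRUE)
        out <- character(length(v) + m)
        take <- sort(at) + seq_len(m) - 1L
        out[take] <- NA_character_
        out[-take] <- v
        order_by_contig[[ctg]] <- out
      }
    }
    ## WGD: every contig duplicated wholesale
    if (isTRUE(hap$wgd)) {
      dups <- order_by_contig
      names(dups) <- paste0(names(dups), "_b")
      order_by_contig <- c(order_by_contig, dups)
    }
    ## materialise the target annotation
    anc <- unlist(order_by_contig, use.names = FALSE)
    ctg_vec <- rep(names(order_by_contig), lengths(order_by_contig))
    n_t <- length(anc)
    tgt_ids <- sprintf("%s_g%05d", hap$haplotype_id, seq_len(n_t))
    targets[[hap$haplotype_id]] <- ref_annotation_from_order(
      tgt_ids, ctg_vec, hap$haplotype_id, hap$clade)
    ## homology hits: score decays in time, boosted window decays less;
    ## WGD/tandem copies take a small extra decay so the primary copy wins
    has_anc <- !is.na(anc)
    anc_ids <- anc[has_anc]
    extra <- numeric(sum(has_anc))
    dup_rank <- stats::ave(seq_along(anc_ids),
                           paste(anc_ids, grepl("_b$", ctg_vec[has_anc])),
                           FUN = seq_along)
    extra[dup_rank > 1L] <- 0.1
    extra[grepl("_b$", ctg_vec[has_anc])] <- extra[grepl("_b$", ctg_vec[has_anc])] + 0.15
    decay <- exp(-lambda * (t * (1 - boost_of[anc_ids]) + extra))
    noise <- if (noise_sd > 0) exp(rnorm(length(anc_ids), 0, noise_sd)) else 1
    bits <- pmin(self_scores[anc_ids], self_scores[anc_ids] * decay * noise)
    hits[[hap$haplotype_id]] <- hit_table(
      data.frame(query_id = anc_ids, subject_id = tgt_ids[has_anc],
                 bitscore = round(pmax(bits, 1), 1), evalue = 1e-30,
                 stringsAsFactors = FALSE),
      self_scores = self_scores)
  }
  truth <- list(planted_window = pw, boost = cfg$planted_window$boost,
                planted_gene_ids = planted_genes,
                window_size = cfg$window_size,
                haplotypes = cfg$haplotypes,
                lambda = lambda, seed = cfg$seed)
  list(ref = ref, targets = targets, hits = hits, truth = truth)
}

#' Write a simulated genome set to disk in standard formats
#'
#' GFF3 per haplotype, 12-column tabular hits per haplotype, clade map TSV,
#' and the ground truth as JSON.
#'
#' @param sim Result of [simulate_genome_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_set <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gff_genes(sim$ref, file.path(dir, "reference.gff3"))
  for (id in names(sim$targets)) {
    write_gff_genes(sim$targets[[id]], file.path(dir, paste0(id, ".gff3")))
    write_hit_table(sim$hits[[id]], file.path(dir, paste0(id, ".hits.tsv")))
  }
  write_tsv(sim$truth$haplotypes, file.path(dir, "panel.tsv"))
  write_sim_truth(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Serialize / read simulation ground truth
#'
#' @param truth Truth list from a simulator.
#' @param path JSON path.
#' @export
write_sim_truth <- function(truth, path) {
  write_atomic(function(tmp) {
    jsonlite::write_json(truth, tmp, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }, path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
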