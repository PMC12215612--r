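small_panel <- function(seed = 3) {
  default_haplotype_panel(n_eudicot = 2, n_other = 2, n_nonflowering = 1,
                          n_wgd = 1, seed = seed)
}

small_genome_cfg <- function(seed = 3, ...) {
  genome_sim_config(n_genes = 480, n_contigs = 2,
                    haplotypes = small_panel(seed),
                    planted_window = list(index = 10, boost = 0.9),
                    seed = seed, ...)
}

test_that("generators are pure functions of config and seed", {
  a <- simulate_genome_set(small_genome_cfg())
  b <- simulate_genome_set(small_genome_cfg())
  expect_equal(a, b)
  p1 <- tempfile(fileext = ".vcf")
  p2 <- tempfile(fileext = ".vcf")
  cfg <- pop_sim_config(chrom_length_bp = 2e5, sdr_interval = c(5e4, 9e4),
                        seed = 17)
  simulate_population(cfg, p1)
  simulate_population(cfg, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_equal(simulate_codon_pairs(0.05, 200, seed = 9),
               simulate_codon_pairs(0.05, 200, seed = 9),
               ignore_attr = TRUE)
})

test_that("null evolution keeps every window fully collinear at exp(-lambda t)", {
  cfg <- genome_sim_config(
    n_genes = 240, n_contigs = 2,
    haplotypes = data.frame(haplotype_id = "h1", clade = "eudicot",
                            time = 0.5, wgd = FALSE),
    rates = list(gene_loss = 0, gene_gain = 0, inversion = 0,
                 tandem_dup = 0),
    planted_window = list(index = 1, boost = 0),
    bitscore = list(self_min = 500, self_max = 2000, lambda = 0.5,
                    noise_sd = 0),
    seed = 5)
  sim <- simulate_genome_set(cfg)
  windows <- make_windows(sim$ref)
  blocks <- detect_collinear_blocks(sim$ref, sim$targets$h1, sim$hits$h1)
  a <- assign_orthologous(windows, blocks, sim$hits$h1$self_scores, "h1")
  expect_true(all(a$summary$collinear_gene_count == 12))
  ## bit scores are emitted rounded to one decimal, hence the tolerance
  expect_equal(a$gene_scores$score,
               rep(exp(-0.5 * 0.5), nrow(a$gene_scores)), tolerance = 1e-3)
})

test_that("WGD haplotypes show two homologous regions per window", {
  cfg <- genome_sim_config(
    n_genes = 240, n_contigs = 2,
    haplotypes = data.frame(haplotype_id = "w1", clade = "eudicot",
                            time = 0.5, wgd = TRUE),
    rates = list(gene_loss = 0, gene_gain = 0, inversion = 0,
                 tandem_dup = 0),
    planted_window = list(index = 1, boost = 0),
    seed = 5)
  sim <- simulate_genome_set(cfg)
  windows <- make_windows(sim$ref)
  blocks <- detect_collinear_blocks(sim$ref, sim$targets$w1, sim$hits$w1)
  hom <- assign_homologous(windows, blocks, sim$hits$w1$self_scores, "w1")
  expect_true(all(hom$summary$region_count == 2))
  ort <- assign_orthologous(windows, blocks, sim$hits$w1$self_scores, "w1")
  ## orthologous counts never exceed homologous counts
  expect_true(all(ort$summary$collinear_gene_count <=
                    hom$summary$collinear_gene_count))
})

test_that("simulated genome sets parse cleanly back through the readers", {
  dir <- tempfile("genomes")
  sim <- simulate_genome_set(small_genome_cfg())
  expect_no_warning(write_genome_set(sim, dir))
  expect_no_warning({
    ref <- read_gff_genes(file.path(dir, "reference.gff3"))
    tgt <- read_gff_genes(file.path(dir, "eud01.gff3"), haplotype_id = "eud01")
    ht <- read_hit_table(file.path(dir, "eud01.hits.tsv"))
  })
  expect_equal(ref$genes[, c("gene_id", "start", "end")],
               sim$ref$genes[, c("gene_id", "start", "end")])
  expect_equal(nrow(ht$hits), nrow(sim$hits$eud01$hits))
  truth <- read_sim_truth(file.path(dir, "truth.json"))
  expect_equal(truth$planted_window, sim$truth$planted_window)
  expect_equal(truth$planted_gene_ids, sim$truth$planted_gene_ids)
})

test_that("excessive loss rates are rejected at config time", {
  expect_error(genome_sim_config(
    haplotypes = data.frame(haplotype_id = "x", clade = "eudicot",
                            time = 30, wgd = FALSE),
    rates = list(gene_loss = 0.1, gene_gain = 0, inversion = 0,
                 tandem_dup = 0)),
    "losing the genome")
  expect_error(pop_sim_config(samples = default_sample_sheet()[1:3, ]),
               "at least 4")
})

test_that("zero recombination with two founders gives complete linkage", {
  samples <- data.frame(sample_id = sprintf("S%d", 1:8),
                        sex_type = "homogametic")
  sim <- simulate_population(pop_sim_config(
    samples = samples, chrom_length_bp = 5e4, recomb_rate = 0,
    sdr_interval = NULL, n_founders = 2, seed = 13))
  pairs <- pairwise_r2(sim$matrix, maf_min = 0, max_dist_bp = 5e4)
  expect_true(all(abs(pairs$r2 - 1) < 1e-12))
})

test_that("codon-pair simulation is synonymous-only and stop-free", {
  aa_of <- function(seq) {
    paste(Biostrings::GENETIC_CODE[sdrkit:::split_codons(seq)], collapse = "")
  }
  for (seed in 1:25) {
    aln <- simulate_codon_pairs(0.3, 60, seed = seed)
    a <- paste(aln$codons_a, collapse = "")
    b <- paste(aln$codons_b, collapse = "")
    expect_equal(aa_of(a), aa_of(b))             # no amino-acid change
    expect_false(grepl("\\*", aa_of(b)))         # no stops ever
  }
  null <- simulate_codon_pairs(0, 100, seed = 1)
  expect_equal(null$codons_a, null$codons_b)
})

test_that("LTR pairs at K = 0 are identical and date to the present", {
  p <- simulate_ltr_pair(0, 2000, seed = 4)
  expect_equal(p$seq_a, p$seq_b)
  expect_equal(date_feature(kimura2p(p$seq_a, p$seq_b)$value)$mean_time_my, 0)
})
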