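## In-code fixtures shared across test files.

## n genes in order on one contig, ids <prefix>01..<prefix>NN
linear_annotation <- function(n, prefix, contig = "c1", hap = prefix,
                              clade = "eudicot", strand = "+") {
  genome_annotation(data.frame(
    gene_id = sprintf("%s%02d", prefix, seq_len(n)),
    contig = contig, start = seq_len(n) * 100, end = seq_len(n) * 100 + 50,
    strand = strand, stringsAsFactors = FALSE),
    haplotype_id = hap, clade = clade)
}

## hits mapping ref gene ids to target gene ids 1:1 with given bitscores
hits_between <- function(ref_ids, target_ids, bitscores = 100,
                         self_scores = NULL) {
  hit_table(data.frame(query_id = ref_ids, subject_id = target_ids,
                       bitscore = bitscores, evalue = 1e-10,
                       stringsAsFactors = FALSE),
            self_scores = self_scores)
}

## hand-built collinear block (for window-assignment tests)
make_block <- function(block_id, ref_ids, target_ids, ref_ranks, target_ranks,
                       bitscores, orientation = "plus",
                       ref_contig = "c1", target_contig = "c1") {
  structure(list(block_id = block_id, ref_contig = ref_contig,
                 target_contig = target_contig, orientation = orientation,
                 score = sum(bitscores),
                 anchors = data.frame(ref_gene_id = ref_ids,
                                      target_gene_id = target_ids,
                                      ref_rank = ref_ranks,
                                      target_rank = target_ranks,
                                      bitscore = bitscores,
                                      stringsAsFactors = FALSE)),
            class = "collinear_block")
}

## the six-record hard-filter toy: each record fails exactly one filter of
## QUAL > 30, DP > 5 (& <= 3 x median), MAF > 0.05, no missing, QD >= 2;
## the sixth passes everything. 12 samples, DP otherwise 20 (median 20).
filter_toy_matrix <- function() {
  ns <- 12
  geno <- rbind(
    c(1, 1, rep(0, ns - 2)),          # qual 25
    c(1, 1, rep(0, ns - 2)),          # DP 4 in one sample
    c(1, rep(0, ns - 1)),             # MAF 1/24 = 0.042
    c(1, 1, NA, rep(0, ns - 3)),      # one missing genotype
    c(1, 1, rep(0, ns - 2)),          # QD 1.5
    c(1, 1, 1, rep(0, ns - 3)))       # passes
  dp <- matrix(20L, 6, ns)
  dp[2, 5] <- 4L
  info <- data.frame(QD = c(25, 25, 25, 25, 1.5, 30),
                     FS = 1, MQ = 60, MQRankSum = 0, ReadPosRankSum = 0,
                     SOR = 1)
  genotype_matrix("chr1", (1:6) * 100, rep("A", 6), rep("G", 6),
                  qual = c(25, 100, 100, 100, 100, 500),
                  geno = geno, dp = dp, info = info,
                  samples = sprintf("S%02d", seq_len(ns)))
}

## depth-boundary toy for the low-coverage profile (DP must be > 1 and < 15):
## minimum per-record DP of 1, 2, 14, 15
depth_boundary_matrix <- function() {
  ns <- 12
  geno <- matrix(rep(c(1, 1, 1, rep(0, ns - 3)), 4), 4, ns, byrow = TRUE)
  dp <- matrix(10L, 4, ns)
  dp[1, 1] <- 1L
  dp[2, 1] <- 2L
  dp[3, 1] <- 14L
  dp[4, 1] <- 15L
  info <- data.frame(QD = 25, FS = 1, MQ = 60, MQRankSum = 0,
                     ReadPosRankSum = 0, SOR = 1)
  genotype_matrix("chr1", (1:4) * 100, rep("A", 4), rep("G", 4),
                  qual = rep(100, 4), geno = geno, dp = dp,
                  info = info[rep(1, 4), ],
                  samples = sprintf("S%02d", seq_len(ns)))
}

## small deterministic genotype matrix from explicit code rows
codes_matrix <- function(rows, pos = NULL, qual = 100, dp = 20L) {
  g <- do.call(rbind, rows)
  n <- nrow(g)
  if (is.null(pos)) pos <- seq_len(n) * 1000
  genotype_matrix("chr1", pos, rep("A", n), rep("G", n),
                  qual = rep(qual, n), geno = g,
                  dp = matrix(dp, n, ncol(g)),
                  samples = sprintf("S%d", seq_len(ncol(g))))
}

sex_groups <- function(samples) {
  setNames(samples$sex_type, samples$sample_id)
}

random_dna_test <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## sequence pair with exact transition/transversion counts
seq_pair_pq <- function(nP, nQ, L = 1000) {
  a <- rep("A", L)
  b <- a
  if (nP > 0) b[seq_len(nP)] <- "G"                       # transitions
  if (nQ > 0) b[nP + seq_len(nQ)] <- "C"                  # transversions
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}
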