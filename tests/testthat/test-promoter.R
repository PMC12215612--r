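test_that("promoters are the upstream slice, truncated and stranded", {
  set.seed(3)
  ctg <- random_dna_test(12000)
  ann <- genome_annotation(data.frame(
    gene_id = c("plus", "short", "minus"),
    contig = "c1",
    start = c(10000, 1199, 4000),       # internal 0-based: TSS at 1-based 10001
    end = c(10500, 1500, 5000),
    strand = c("+", "+", "-")), "hap")
  prom <- extract_promoters(ann, c(c1 = ctg), max_len = 3000)
  p <- prom[prom$gene_id == "plus", ]
  expect_equal(p$length, 3000)
  expect_equal(p$sequence, substr(ctg, 7001, 10000))
  expect_equal(prom$length[prom$gene_id == "short"], 1199)
  expect_equal(prom$sequence[prom$gene_id == "short"], substr(ctg, 1, 1199))
  m <- prom[prom$gene_id == "minus", ]
  expect_equal(m$length, 3000)
  expect_equal(m$sequence, sdrkit:::revcomp(substr(ctg, 5001, 8000)))
  ## zero upstream bases: skipped with a warning
  edge <- genome_annotation(data.frame(gene_id = "edge", contig = "c1",
                                       start = 0, end = 100, strand = "+"),
                            "hap")
  expect_warning(expect_error(extract_promoters(edge, c(c1 = ctg)),
                              "no promoters"), "skipped")
})

test_that("JASPAR PFM parsing returns ACGT count matrices", {
  path <- tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 TEST",
               "A [ 4 19  0  0 ]",
               "C [16  0 20  0 ]",
               "G [ 0  1  0 20 ]",
               "T [ 0  0  0  0 ]"), path)
  pfms <- read_pfm_jaspar(path)
  expect_named(pfms, "MA0001.1")
  m <- pfms[["MA0001.1"]]
  expect_equal(rownames(m), c("A", "C", "G", "T"))
  expect_equal(unname(m["C", 1]), 16)
  expect_equal(unname(m["G", 4]), 20)
})

test_that("scanning finds a planted consensus at its upstream offset", {
  consensus <- "TAACGGTCAC"
  pwm <- make_pwm(consensus_pfm(consensus), motif_id = "myb")
  set.seed(8)
  seq <- random_dna_test(3000)
  i <- 3000 - 2104 + 1
  planted <- paste0(substr(seq, 1, i - 1), consensus,
                    substr(seq, i + nchar(consensus), 3000))
  hits <- scan_pwm(planted, pwm)
  top <- hits[hits$rel_score == 1, ]
  expect_true(any(top$upstream_offset == 2104 & top$strand == "+"))
})

test_that("a complement-only occurrence is found on the minus strand", {
  consensus <- "TAACGGTCAC"
  pwm <- make_pwm(consensus_pfm(consensus), motif_id = "myb")
  rc <- sdrkit:::revcomp(consensus)
  seq <- paste0(strrep("A", 100), rc, strrep("A", 100))
  hits <- scan_pwm(seq, pwm, min_rel_score = 0.99)
  expect_true(all(hits$strand == "-"))
  expect_equal(nrow(hits), 1)
})

test_that("relative scores match exhaustive enumeration on a toy PWM", {
  consensus <- "TAACGGTC"
  pwm <- make_pwm(consensus_pfm(consensus), motif_id = "toy")
  ## independent brute-force scorer
  brute <- function(seq) {
    chars <- strsplit(seq, "")[[1]]
    w <- nchar(consensus)
    vapply(seq_len(length(chars) - w + 1), function(i) {
      sum(vapply(seq_len(w), function(k) {
        pwm$matrix[chars[i + k - 1], k]
      }, numeric(1)))
    }, numeric(1))
  }
  set.seed(4)
  seq <- random_dna_test(200)
  smin <- sum(pwm$col_min)
  smax <- sum(pwm$col_max)
  expect_equal(sdrkit:::scan_scores(seq, pwm), brute(seq))
  ## with single-consensus columns the relative score is 1 - k/w for k
  ## mismatches: two mismatches on an 8-mer score 0.75 < 0.80, not reported
  two_mm <- paste0("TTACGGTA", strrep("A", 50))
  rel <- (brute(two_mm)[1] - smin) / (smax - smin)
  expect_equal(rel, 0.75)
  hits <- scan_pwm(two_mm, pwm, min_rel_score = 0.80)
  expect_false(58 %in% hits$upstream_offset[hits$strand == "+"])
  expect_equal(nrow(scan_pwm(strrep("A", 4), pwm)), 0)  # motif > promoter
})

test_that("scanning a promoter and its reverse complement mirrors hits", {
  pwm <- make_pwm(consensus_pfm("TAACGGTCAC"), motif_id = "myb")
  set.seed(12)
  seq <- random_dna_test(500)
  fwd <- scan_pwm(seq, pwm, min_rel_score = 0.6)
  rev <- scan_pwm(sdrkit:::revcomp(seq), pwm, min_rel_score = 0.6)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sort(fwd$rel_score), sort(rev$rel_score))
  expect_equal(sum(fwd$strand == "+"), sum(rev$strand == "-"))
})

test_that("group-specific sites require presence in all members, absence elsewhere", {
  roster <- data.frame(gene_id = "g", haplotype_id = c(paste0("M", 1:4),
                                                       paste0("F", 1:3),
                                                       paste0("H", 1:3)),
                       group = rep(c("M", "F", "H"), c(4, 3, 3)),
                       sequence = "", length = 3000,
                       stringsAsFactors = FALSE)
  hit <- function(hap, grp, off) {
    data.frame(motif_id = "myb", gene_id = "g", haplotype_id = hap,
               group = grp, upstream_offset = off, strand = "+",
               rel_score = 0.95, stringsAsFactors = FALSE)
  }
  all_m <- do.call(rbind, lapply(1:4, function(i) {
    hit(paste0("M", i), "M", 2100 + c(-10, 10, 0, 5)[i])
  }))
  res <- group_specific_sites(all_m, roster, window_bp = 30)
  expect_equal(res$group, "M")
  expect_equal(res$motif_id, "myb")
  expect_lt(abs(res$consensus_offset - 2101), 10)
  ## only 3 of 4 M promoters carry it: not reported
  expect_equal(nrow(group_specific_sites(all_m[1:3, ], roster, 30)), 0)
  ## present in all M but also in one H promoter: not reported
  with_h <- rbind(all_m, hit("H2", "H", 2095))
  expect_equal(nrow(group_specific_sites(with_h, roster, 30)), 0)
  ## an H hit far away does not block the M site
  with_far_h <- rbind(all_m, hit("H2", "H", 300))
  expect_equal(group_specific_sites(with_far_h, roster, 30)$group, "M")
})

test_that("differential counts report strict majorities and omit ties", {
  roster <- data.frame(gene_id = "g",
                       haplotype_id = c(paste0("M", 1:2), paste0("F", 1:2)),
                       group = rep(c("M", "F"), each = 2), sequence = "",
                       length = 3000, stringsAsFactors = FALSE)
  mk <- function(hap, grp, n, motif = "myb") {
    data.frame(motif_id = motif, gene_id = "g", haplotype_id = hap,
               group = grp, upstream_offset = seq_len(n) * 100,
               strand = "+", rel_score = 0.9, stringsAsFactors = FALSE)
  }
  hits <- rbind(mk("M1", "M", 3), mk("M2", "M", 3),
                mk("F1", "F", 1), mk("F2", "F", 1),
                mk("M1", "M", 2, "even"), mk("M2", "M", 2, "even"),
                mk("F1", "F", 2, "even"), mk("F2", "F", 2, "even"))
  res <- differential_site_counts(hits, roster)
  expect_equal(res$motif_id, "myb")          # the tied motif is omitted
  expect_equal(res$direction, "M")
  expect_equal(res$margin, 2)
  expect_equal(res$mean_M, 3)
  expect_equal(res$mean_F, 1)
})

test_that("planted group-specific motifs are recovered end to end", {
  pg <- simulate_promoter_groups(seed = 2)
  hits <- scan_promoters(pg$promoters, pg$pwm)
  res <- group_specific_sites(hits, pg$promoters)
  expect_equal(res$group, "M")
  expect_equal(res$consensus_offset, 2104)
  ## planted extras drive the differential count in the M direction
  pg2 <- simulate_promoter_groups(extra_copies = 3, seed = 6)
  hits2 <- scan_promoters(pg2$promoters, pg2$pwm)
  diff2 <- differential_site_counts(hits2, pg2$promoters)
  expect_equal(diff2$direction, "M")
  expect_gt(diff2$margin, 0)
})

test_that("planted offsets are exact for plus and minus strand genes", {
  consensus <- "TAACGGTCAC"
  set.seed(21)
  up <- random_dna_test(3000)
  i <- 3000 - 2104 + 1
  up_planted <- paste0(substr(up, 1, i - 1), consensus,
                       substr(up, i + nchar(consensus), 3000))
  body <- random_dna_test(500)
  down <- random_dna_test(1000)
  ## plus gene: promoter precedes the gene; minus gene: promoter is the
  ## reverse complement downstream, so embed revcomp(promoter) after it
  ctg_plus <- paste0(up_planted, body, down)
  ctg_minus <- paste0(down, body, sdrkit:::revcomp(up_planted))
  ann_plus <- genome_annotation(data.frame(gene_id = "gp", contig = "c1",
                                           start = 3000, end = 3500,
                                           strand = "+"), "h1")
  ann_minus <- genome_annotation(data.frame(gene_id = "gm", contig = "c1",
                                            start = 1000, end = 1500,
                                            strand = "-"), "h2")
  pwm <- make_pwm(consensus_pfm(consensus), motif_id = "myb")
  for (case in list(list(ann_plus, ctg_plus), list(ann_minus, ctg_minus))) {
    prom <- extract_promoters(case[[1]], c(c1 = case[[2]]))
    hits <- scan_pwm(prom$sequence, pwm, min_rel_score = 0.999)
    expect_true(2104 %in% hits$upstream_offset)
  }
})
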