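test_that("windows tile contigs and drop trailing partial windows", {
  expect_equal(nrow(make_windows(linear_annotation(24, "g"), 12)$windows), 2)
  w <- make_windows(linear_annotation(25, "g"), 12)
  expect_equal(nrow(w$windows), 2)
  expect_false("g25" %in% unlist(w$gene_ids))
  ## the reference scale: 27,684 genes in full windows -> 2307 windows
  big <- make_windows(linear_annotation(27684, "g"), 12)
  expect_equal(nrow(big$windows), 2307)
  ## windows restart per contig
  two <- genome_annotation(data.frame(
    gene_id = sprintf("g%02d", 1:30),
    contig = rep(c("c1", "c2"), c(15, 15)),
    start = rep(1:15, 2) * 100, end = rep(1:15, 2) * 100 + 50,
    strand = "+"), "h")
  expect_equal(nrow(make_windows(two, 12)$windows), 2)
})

test_that("conservation score is the clamped self-normalized bit score", {
  expect_equal(conservation_score(250, 500), 0.5)
  expect_equal(conservation_score(500, 500), 1)
  expect_equal(conservation_score(520, 500), 1)
  expect_error(conservation_score(100, 0), "self_bitscore")
})

test_that("rank normalization maps groups to [0,1] with mean tied ranks", {
  expect_equal(rank_normalize(c(0.2, 0.5, 0.9), rep("a", 3)),
               c(0, 0.5, 1))
  expect_equal(rank_normalize(c(0.3, 0.3, 0.8), rep("a", 3)),
               c(0.25, 0.25, 1))
  expect_equal(rank_normalize(rep(0.7, 5), rep("a", 5)), rep(0.5, 5))
  ## groups are normalized independently; singletons map to 0.5
  expect_equal(rank_normalize(c(0.1, 0.9, 42), c("a", "a", "b")),
               c(0, 1, 0.5))
})

test_that("orthologous assignment picks the block covering most window genes", {
  win <- make_windows(linear_annotation(12, "r"), 12)
  selfs <- setNames(rep(100, 12), sprintf("r%02d", 1:12))
  b_big <- make_block("b2", sprintf("r%02d", 1:7), sprintf("t%02d", 1:7),
                      0:6, 0:6, rep(50, 7))
  b_small <- make_block("b1", sprintf("r%02d", 9:12), sprintf("t%02d", 9:12),
                        8:11, 8:11, rep(500, 4))
  a <- assign_orthologous(win, list(b_small, b_big), selfs, "hap")
  expect_equal(a$summary$block_id, "b2")
  expect_equal(a$summary$collinear_gene_count, 7)
  expect_equal(nrow(a$gene_scores), 7)
  expect_equal(unique(a$gene_scores$score), 0.5)       # 50/100
})

test_that("orthologous ties break by block score then block id", {
  win <- make_windows(linear_annotation(12, "r"), 12)
  selfs <- setNames(rep(100, 12), sprintf("r%02d", 1:12))
  ids <- sprintf("r%02d", 1:5)
  weak <- make_block("b1", ids, sprintf("t%02d", 1:5), 0:4, 0:4, rep(10, 5))
  strong <- make_block("b2", ids, sprintf("u%02d", 1:5), 0:4, 10:14,
                       rep(90, 5))
  a <- assign_orthologous(win, list(weak, strong), selfs, "hap")
  expect_equal(a$summary$block_id, "b2")
  ## persistent tie (same coverage, same score): smaller block id wins
  twin <- make_block("b0", ids, sprintf("v%02d", 1:5), 0:4, 20:24, rep(90, 5))
  a2 <- assign_orthologous(win, list(strong, twin), selfs, "hap")
  expect_equal(a2$summary$block_id, "b0")
  ## no overlapping block at all
  a3 <- assign_orthologous(win, list(), selfs, "hap")
  expect_equal(a3$summary$collinear_gene_count, 0)
  expect_equal(nrow(a3$gene_scores), 0)
})

test_that("homologous assignment counts regions and pools best partners", {
  win <- make_windows(linear_annotation(12, "r"), 12)
  selfs <- setNames(rep(1000, 12), sprintf("r%02d", 1:12))
  regionA <- make_block("bA", sprintf("r%02d", 1:6), sprintf("t%02d", 1:6),
                        0:5, 0:5, rep(300, 6))
  regionB <- make_block("bB", sprintf("r%02d", 1:6), sprintf("u%02d", 1:6),
                        0:5, 40:45, rep(450, 6))
  stray <- make_block("bC", "r12", "w01", 11, 90, 800)
  a <- assign_homologous(win, list(regionA, regionB, stray), selfs, "hap",
                         min_window_anchors = 2)
  expect_equal(a$summary$region_count, 2)              # stray: 1 anchor only
  expect_equal(a$summary$collinear_gene_count, 6)
  ## each gene is scored from its best-bitscore partner across regions
  expect_equal(unique(a$gene_scores$bitscore), 450)
  expect_equal(unique(a$gene_scores$target_gene_id[
    a$gene_scores$ref_gene_id == "r01"]), "u01")
  a0 <- assign_homologous(win, list(stray), selfs, "hap")
  expect_equal(a0$summary$region_count, 0)
})

test_that("focus-window comparison detects separation and degenerate input", {
  vals <- c(rep(5, 10), rep(1, 100)) + rep(c(0.1, 0), c(10, 100))
  idx <- rep(c(99, 1), c(10, 100))
  res <- compare_windows(vals, idx, focus_window = 99)
  expect_lt(res$p, 0.001)
  expect_warning(res0 <- compare_windows(rep(3, 20), rep(1:2, 10), 2),
                 "identical")
  expect_equal(res0$H, 0)
  expect_equal(res0$p, 1)
})

test_that("focus-window test holds its type-I error rate", {
  set.seed(2024)
  reps <- 1000
  rejected <- 0
  for (i in seq_len(reps)) {
    vals <- rnorm(110)
    idx <- rep(1:11, each = 10)
    if (compare_windows(vals, idx, focus_window = 1)$p < 0.05) {
      rejected <- rejected + 1
    }
  }
  expect_gt(rejected / reps, 0.03)
  expect_lt(rejected / reps, 0.07)
})

test_that("summaries pool haplotypes and flag the focus window", {
  win <- make_windows(linear_annotation(24, "r"), 12)
  selfs <- setNames(rep(100, 24), sprintf("r%02d", 1:24))
  mk <- function(hap, s1, s2) {
    b1 <- make_block("b1", sprintf("r%02d", 1:12), sprintf("%s_t%02d", hap, 1:12),
                     0:11, 0:11, rep(s1, 12))
    b2 <- make_block("b2", sprintf("r%02d", 13:24), sprintf("%s_u%02d", hap, 1:12),
                     12:23, 20:31, rep(s2, 12))
    assign_orthologous(win, list(b1, b2), selfs, hap)
  }
  assignments <- list(h1 = mk("h1", 90, 30), h2 = mk("h2", 85, 20))
  ## counts are identical everywhere here, so the count comparison warns
  summ <- suppressWarnings(
    summarize_conservation(assignments,
                           c(h1 = "eudicot", h2 = "other_angiosperm"),
                           focus_window = 1))
  expect_s3_class(summ, "conservation_summary")
  expect_true(all(summ$gene_scores$normalized >= 0 &
                    summ$gene_scores$normalized <= 1))
  ## window 1 scores higher in both haplotypes
  ws <- summ$window_stats
  expect_gt(ws$mean_norm_score[ws$window_index == 1],
            ws$mean_norm_score[ws$window_index == 2])
  expect_equal(ws$mean_count, c(12, 12))
})
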