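test_that("perfectly collinear hits form a single plus block", {
  ref <- linear_annotation(6, "r")
  tgt <- linear_annotation(6, "t")
  hits <- hits_between(sprintf("r%02d", 1:6), sprintf("t%02d", 1:6))
  blocks <- detect_collinear_blocks(ref, tgt, hits)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$orientation, "plus")
  expect_equal(nrow(blocks[[1]]$anchors), 6)
  expect_true(sdrkit:::validate_block(blocks[[1]]))
})

test_that("fewer ordered anchors than the minimum block size yield no block", {
  ref <- linear_annotation(6, "r")
  tgt <- linear_annotation(6, "t")
  hits <- hits_between(sprintf("r%02d", 1:4), sprintf("t%02d", 1:4))
  expect_length(detect_collinear_blocks(ref, tgt, hits, min_block_size = 5), 0)
})

test_that("the rank gap constraint is max_gap + 1 on both genomes", {
  ref <- linear_annotation(5, "r")
  tgt <- linear_annotation(31, "t")
  ## target ranks 0,1,2,29,30 (genes t01,t02,t03,t30,t31): the jump is 27
  hits <- hits_between(sprintf("r%02d", 1:5),
                       sprintf("t%02d", c(1, 2, 3, 30, 31)))
  expect_length(detect_collinear_blocks(ref, tgt, hits, 5, max_gap = 25), 0)
  blocks <- detect_collinear_blocks(ref, tgt, hits, 5, max_gap = 27)
  expect_length(blocks, 1)
  expect_equal(nrow(blocks[[1]]$anchors), 5)
  ## agrees with the exhaustive oracle on both gap settings
  expect_equal(block_fingerprint(blocks),
               block_fingerprint(oracle_blocks(ref, tgt, hits, 5, 27)))
})

test_that("reversed hits form a minus block", {
  ref <- linear_annotation(5, "r")
  tgt <- linear_annotation(5, "t")
  hits <- hits_between(sprintf("r%02d", 1:5), sprintf("t%02d", 5:1))
  blocks <- detect_collinear_blocks(ref, tgt, hits)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$orientation, "minus")
  expect_equal(blocks[[1]]$anchors$target_rank, 4:0)
})

test_that("hits naming unknown genes raise an informative error", {
  ref <- linear_annotation(5, "r")
  tgt <- linear_annotation(5, "t")
  hits <- hits_between(c("r01", "ghost"), c("t01", "t02"))
  expect_error(detect_collinear_blocks(ref, tgt, hits), "ghost")
})

test_that("block/window overlap counts distinct window genes", {
  b <- make_block("b1", sprintf("r%02d", c(1:7, 7)), sprintf("t%02d", 1:8),
                  c(0:6, 6), 0:7, rep(100, 8))
  win <- sprintf("r%02d", 1:12)
  expect_equal(block_window_overlap(b, win), 7)        # duplicate r07 once
  expect_equal(block_window_overlap(b, sprintf("x%02d", 1:12)), 0)
})

test_that("chainer matches exhaustive enumeration on random instances", {
  for (seed in 1:60) {
    inst <- random_synteny_instance(seed)
    dp <- detect_collinear_blocks(inst$ref, inst$target, inst$hits,
                                  inst$min_block_size, inst$max_gap)
    for (b in dp) {
      expect_true(sdrkit:::validate_block(b, inst$min_block_size,
                                          inst$max_gap))
    }
    expect_equal(block_fingerprint(dp),
                 block_fingerprint(oracle_blocks(inst$ref, inst$target,
                                                 inst$hits,
                                                 inst$min_block_size,
                                                 inst$max_gap)),
                 info = paste("seed", seed))
  }
})

test_that("relabeling gene ids yields isomorphic blocks", {
  inst <- random_synteny_instance(7)
  relabel <- function(ann, prefix) {
    g <- ann$genes
    g$gene_id <- sprintf("%s_%s", prefix, g$gene_id)
    genome_annotation(g[, c("gene_id", "contig", "start", "end", "strand")],
                      ann$haplotype_id, ann$clade)
  }
  h2 <- inst$hits$hits
  h2$query_id <- sprintf("RX_%s", h2$query_id)
  h2$subject_id <- sprintf("TX_%s", h2$subject_id)
  b1 <- detect_collinear_blocks(inst$ref, inst$target, inst$hits,
                                inst$min_block_size, inst$max_gap)
  b2 <- detect_collinear_blocks(relabel(inst$ref, "RX"),
                                relabel(inst$target, "TX"), hit_table(h2),
                                inst$min_block_size, inst$max_gap)
  shape <- function(blocks) {
    lapply(blocks, function(b) {
      list(b$orientation, b$anchors$ref_rank, b$anchors$target_rank,
           b$anchors$bitscore)
    })
  }
  expect_equal(shape(b1), shape(b2))
})

test_that("widening the gap allowance never shrinks the largest block", {
  ## near-unit bitscores make chain score track chain length, so the best
  ## block is a longest valid chain at every gap setting
  for (seed in 1:10) {
    set.seed(seed)
    inst <- random_synteny_instance(seed)
    h <- inst$hits$hits
    h$bitscore <- runif(nrow(h), 0.99, 1.01)
    prev <- 0
    for (g in 1:8) {
      blocks <- detect_collinear_blocks(inst$ref, inst$target, hit_table(h),
                                        min_block_size = 1, max_gap = g)
      sizes <- vapply(blocks, function(b) nrow(b$anchors), integer(1))
      expect_gte(max(sizes), prev)
      prev <- max(sizes)
    }
  }
})
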