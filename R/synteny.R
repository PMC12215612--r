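## Collinear block detection.
##
## Anchors are homologous gene pairs placed on the rank coordinates of their
## two genomes. A block is a chain of anchors whose ref ranks strictly
## increase and whose target ranks strictly increase (plus orientation) or
## strictly decrease (minus), with consecutive anchors at most max_gap + 1
## ranks apart on both genomes. Chains are scored by the sum of their anchor
## bit scores and extracted greedily: the best-scoring chain with at least
## min_block_size anchors is reported, its anchors are retired, and the
## search repeats. Greedy single-membership is how the MCScanX "-w1" overlap
## window is emulated here.

build_anchors <- function(ref, target, hits) {
  h <- hits$hits
  rg <- ref$genes
  tg <- target$genes
  miss_q <- setdiff(unique(h$query_id), rg$gene_id)
  miss_s <- setdiff(unique(h$subject_id), tg$gene_id)
  if (length(miss_q) || length(miss_s)) {
    stopf("hit table names genes absent from the annotations: %s",
          paste(head(c(miss_q, miss_s), 10L), collapse = ", "))
  }
  qi <- match(h$query_id, rg$gene_id)
  si <- match(h$subject_id, tg$gene_id)
  data.frame(ref_gene_id = h$query_id, target_gene_id = h$subject_id,
             ref_contig = rg$contig[qi], target_contig = tg$contig[si],
             ref_rank = rg$rank[qi], target_rank = tg$rank[si],
             bitscore = h$bitscore, stringsAsFactors = FALSE)
}

## DP over anchors sorted by (ref_rank, target_rank): best-scoring chain with
## at least `k` anchors among `active` rows, or NULL. The count dimension is
## capped at k ("k or more").
best_chain <- function(anc, active, orientation, max_gap, k) {
  idx <- which(active)
  n <- length(idx)
  if (n < k) return(NULL)
  r <- anc$ref_rank[idx]
  t <- anc$target_rank[idx]
  s <- anc$bitscore[idx]
  G <- max_gap + 1L
  dp <- matrix(-Inf, n, k)
  pred_i <- matrix(NA_integer_, n, k)
  pred_c <- matrix(NA_integer_, n, k)
  for (i in seq_len(n)) {
    dp[i, 1L] <- s[i]
    ## predecessors: sorted r allows a binary-search window on ref rank
    lo <- findInterval(r[i] - G - 0.5, r) + 1L
    hi <- findInterval(r[i] - 0.5, r)
    if (hi < lo) next
    js <- lo:hi
    dt <- if (orientation == "plus") t[i] - t[js] else t[js] - t[i]
    js <- js[dt >= 1L & dt <= G]
    for (j in js) {
      for (cj in seq_len(k)) {
        if (dp[j, cj] == -Inf) next
        ci <- min(cj + 1L, k)
        cand <- dp[j, cj] + s[i]
        if (cand > dp[i, ci]) {
          dp[i, ci] <- cand
          pred_i[i, ci] <- j
          pred_c[i, ci] <- cj
        }
      }
    }
  }
  best <- which.max(dp[, k])
  if (dp[best, k] == -Inf) return(NULL)
  chain <- integer()
  i <- best
  ci <- k
  repeat {
    chain <- c(i, chain)
    if (is.na(pred_i[i, ci])) break
    nxt_i <- pred_i[i, ci]
    nxt_c <- pred_c[i, ci]
    i <- nxt_i
    ci <- nxt_c
  }
  list(rows = idx[chain], score = dp[best, k])
}

## chain comparator shared with the exhaustive oracle used in tests: larger
## score wins, then more anchors, then smaller first (ref_rank, target_rank)
chain_better <- function(a, b, anc) {
  if (is.null(b)) return(TRUE)
  if (is.null(a)) return(FALSE)
  if (a$score != b$score) return(a$score > b$score)
  if (length(a$rows) != length(b$rows)) return(length(a$rows) > length(b$rows))
  ra <- anc$ref_rank[a$rows[1L]]; rb <- anc$ref_rank[b$rows[1L]]
  if (ra != rb) return(ra < rb)
  anc$target_rank[a$rows[1L]] < anc$target_rank[b$rows[1L]]
}

#' Detect collinear gene blocks between two haplotypes
#'
#' Dynamic-programming chaining of homologous gene pairs into collinear
#' blocks, per contig pair and orientation, emulating MCScanX run with a
#' minimum block size of 5 anchors and a maximum gap of 25 genes
#' (`-s5 -m25`). Each anchor belongs to at most one reported block.
#'
#' @param ref,target [genome_annotation] objects.
#' @param hits A [hit_table] whose queries are `ref` genes and subjects are
#'   `target` genes. A hit naming a gene absent from either annotation is an
#'   error.
#' @param min_block_size Minimum number of anchors per block.
#' @param max_gap Maximum number of intervening genes between consecutive
#'   anchors on either genome.
#' @return List of `collinear_block` objects ordered by
#'   (ref contig, first ref rank). Each block carries `block_id`,
#'   `ref_contig`, `target_contig`, `orientation` (`"plus"`/`"minus"`),
#'   `score` and an `anchors` data.frame.
#' @export
detect_collinear_blocks <- function(ref, target, hits, min_block_size = 5L,
                                    max_gap = 25L) {
  stopifnot(inherits(ref, "genome_annotation"),
            inherits(target, "genome_annotation"),
            inherits(hits, "hit_table"),
            is_count(min_block_size), is_count(max_gap))
  anc_all <- build_anchors(ref, target, hits)
  if (nrow(anc_all) == 0L) return(list())
  blocks <- list()
  groups <- split(seq_len(nrow(anc_all)),
                  paste(anc_all$ref_contig, anc_all$target_contig, sep = "\r"))
  for (g in groups) {
    anc <- anc_all[g, , drop = FALSE]
    ord <- order(anc$ref_rank, anc$target_rank)
    anc <- anc[ord, , drop = FALSE]
    active <- rep(TRUE, nrow(anc))
    repeat {
      cp <- best_chain(anc, active, "plus", max_gap, min_block_size)
      cm <- best_chain(anc, active, "minus", max_gap, min_block_size)
      if (is.null(cp) && is.null(cm)) break
      if (chain_better(cp, cm, anc)) {
        chosen <- cp; orientation <- "plus"
      } else {
        chosen <- cm; orientation <- "minus"
      }
      a <- anc[chosen$rows, , drop = FALSE]
      rownames(a) <- NULL
      blocks[[length(blocks) + 1L]] <- structure(
        list(block_id = NA_character_,
             ref_contig = a$ref_contig[1L],
             target_contig = a$target_contig[1L],
             orientation = orientation,
             score = sum(a$bitscore),
             anchors = a[, c("ref_gene_id", "target_gene_id", "ref_rank",
                             "target_rank", "bitscore")]),
        class = "collinear_block")
      active[chosen$rows] <- FALSE
    }
  }
  if (length(blocks) == 0L) return(blocks)
  ord <- order(vapply(blocks, function(b) b$ref_contig, character(1L)),
               vapply(blocks, function(b) b$anchors$ref_rank[1L], numeric(1L)),
               vapply(blocks, function(b) b$anchors$target_rank[1L], numeric(1L)))
  blocks <- blocks[ord]
  for (i in seq_along(blocks)) blocks[[i]]$block_id <- sprintf("b%04d", i)
  blocks
}

#' @export
print.collinear_block <- function(x, ...) {
  cat(sprintf("<collinear_block> %s %s~%s [%s] %d anchors, score %.1f\n",
              x$block_id %||% "?", x$ref_contig, x$target_contig,
              x$orientation, nrow(x$anchors), x$score))
  invisible(x)
}

## type-invariant validator (exercised by tests on every emitted block)
validate_block <- function(block, min_block_size = 5L, max_gap = 25L) {
  a <- block$anchors
  ok <- nrow(a) >= min_block_size &&
    all(diff(a$ref_rank) >= 1) && all(diff(a$ref_rank) <= max_gap + 1) &&
    all(a$bitscore > 0) &&
    abs(block$score - sum(a$bitscore)) < 1e-8
  dt <- diff(a$target_rank)
  ok && if (block$orientation == "plus") {
    all(dt >= 1) && all(dt <= max_gap + 1)
  } else {
    all(dt <= -1) && all(dt >= -(max_gap + 1))
  }
}

#' Count window genes anchored by a block
#'
#' Number of distinct reference window genes that appear on the ref side of
#' at least one anchor of the block.
#'
#' @param block A `collinear_block`.
#' @param window_gene_ids Character vector of window gene ids.
#' @return Integer count.
#' @export
block_window_overlap <- function(block, window_gene_ids) {
  stopifnot(inherits(block, "collinear_block"))
  length(intersect(unique(block$anchors$ref_gene_id), window_gene_ids))
}

#' Flatten blocks to a TSV-ready anchor table
#'
#' @param blocks List of `collinear_block` objects.
#' @return data.frame with one row per anchor: block_id, orientation,
#'   ref_gene, target_gene, bitscore.
#' @export
blocks_to_table <- function(blocks) {
  if (length(blocks) == 0L) {
    return(data.frame(block_id = character(), orientation = character(),
                      ref_gene = character(), target_gene = character(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(blocks, function(b) {
    data.frame(block_id = b$block_id, orientation = b$orientation,
               ref_gene = b$anchors$ref_gene_id,
               target_gene = b$anchors$target_gene_id,
               bitscore = b$anchors$bitscore, stringsAsFactors = FALSE)
  }))
}

#' Write blocks as an MCScanX-like collinearity report
#'
#' @param blocks List of `collinear_block` objects.
#' @param path Output path.
#' @export
write_collinearity <- function(blocks, path) {
  write_atomic(function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con), add = TRUE)
    writeLines("############### sdrkit collinearity ###############", con)
    for (b in blocks) {
      writeLines(sprintf("## Alignment %s: score=%.1f orientation=%s %s&%s",
                         b$block_id, b$score, b$orientation,
                         b$ref_contig, b$target_contig), con)
      writeLines(sprintf("%s-%3d:\t%s\t%s\t%.1f", b$block_id,
                         seq_len(nrow(b$anchors)) - 1L,
                         b$anchors$ref_gene_id, b$anchors$target_gene_id,
                         b$anchors$bitscore), con)
    }
  }, path)
}
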