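## Independent oracle for collinear-block detection: exhaustive enumeration
## of maximal anchor chains (depth-first, no dynamic programming), extracted
## greedily with the same comparator as the production chainer.

enum_best_chain <- function(anc, active, orientation, max_gap, k) {
  idx <- which(active)
  if (length(idx) < k) return(NULL)
  r <- anc$ref_rank[idx]
  t <- anc$target_rank[idx]
  s <- anc$bitscore[idx]
  G <- max_gap + 1
  succ_of <- function(i) {
    dr <- r - r[i]
    dt <- if (orientation == "plus") t - t[i] else t[i] - t
    which(dr >= 1 & dr <= G & dt >= 1 & dt <= G)
  }
  has_pred <- vapply(seq_along(idx), function(i) {
    dr <- r[i] - r
    dt <- if (orientation == "plus") t[i] - t else t - t[i]
    any(dr >= 1 & dr <= G & dt >= 1 & dt <= G)
  }, logical(1))
  best <- NULL
  consider <- function(chain) {
    if (length(chain) < k) return()
    cand <- list(rows = idx[chain], score = sum(s[chain]))
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score && length(cand$rows) > length(best$rows))) {
      best <<- cand
    }
  }
  dfs <- function(chain) {
    nxt <- succ_of(chain[length(chain)])
    if (length(nxt) == 0) {
      consider(chain)
      return()
    }
    for (j in nxt) dfs(c(chain, j))
  }
  for (i in which(!has_pred)) dfs(i)
  best
}

oracle_blocks <- function(ref, target, hits, min_block_size = 5,
                          max_gap = 25) {
  anc_all <- sdrkit:::build_anchors(ref, target, hits)
  blocks <- list()
  groups <- split(seq_len(nrow(anc_all)),
                  paste(anc_all$ref_contig, anc_all$target_contig, sep = "\r"))
  for (g in groups) {
    anc <- anc_all[g, , drop = FALSE]
    anc <- anc[order(anc$ref_rank, anc$target_rank), , drop = FALSE]
    active <- rep(TRUE, nrow(anc))
    repeat {
      cp <- enum_best_chain(anc, active, "plus", max_gap, min_block_size)
      cm <- enum_best_chain(anc, active, "minus", max_gap, min_block_size)
      if (is.null(cp) && is.null(cm)) break
      if (sdrkit:::chain_better(cp, cm, anc)) {
        chosen <- cp
        orientation <- "plus"
      } else {
        chosen <- cm
        orientation <- "minus"
      }
      a <- anc[chosen$rows, , drop = FALSE]
      blocks[[length(blocks) + 1]] <- list(
        orientation = orientation,
        anchors = paste(a$ref_gene_id, a$target_gene_id, sep = ":"),
        score = chosen$score)
      active[chosen$rows] <- FALSE
    }
  }
  blocks
}

## canonical string form of a block set, for set comparison between routes
block_fingerprint <- function(blocks) {
  sort(vapply(blocks, function(b) {
    anchors <- if (is.data.frame(b$anchors)) {
      paste(b$anchors$ref_gene_id, b$anchors$target_gene_id, sep = ":")
    } else {
      b$anchors
    }
    paste(b$orientation, paste(anchors, collapse = ","), sep = "|")
  }, character(1)))
}

random_synteny_instance <- function(seed) {
  set.seed(seed)
  nr <- sample(6:15, 1)
  nt <- sample(6:15, 1)
  ref <- linear_annotation(nr, "r")
  tgt <- linear_annotation(nt, "t")
  nh <- sample(5:20, 1)
  h <- data.frame(query_id = sprintf("r%02d", sample(nr, nh, replace = TRUE)),
                  subject_id = sprintf("t%02d", sample(nt, nh, replace = TRUE)),
                  bitscore = runif(nh, 50, 500), evalue = 1e-10,
                  stringsAsFactors = FALSE)
  h <- h[!duplicated(paste(h$query_id, h$subject_id)), ]
  list(ref = ref, target = tgt, hits = hit_table(h),
       max_gap = sample(1:6, 1), min_block_size = sample(2:4, 1))
}
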