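## Fixed-size gene windows and conservation scoring.
##
## The reference gene order is split into consecutive, non-overlapping
## windows of `window_size` genes per contig (trailing genes that do not fill
## a window are dropped). Each window is then mapped, per target haplotype,
## either to the single collinear block covering the most window genes
## ("orthologous" mode) or to every block anchoring enough window genes
## ("homologous" mode, which counts WGD/paralogous copies as extra regions).
## Anchored genes are scored by pair bit score over reference self bit score,
## and scores are rank-normalized within clade groups before the focus window
## (e.g. the SDR) is compared against the genome background.

#' Split a reference annotation into fixed-size gene windows
#'
#' @param ref A [genome_annotation].
#' @param window_size Genes per window (default 12, the size of the grape
#'   SDR gene complement).
#' @return A `gene_windows` object: data.frame `windows` (window_index,
#'   contig, start_rank) and list `gene_ids` keyed by window index.
#' @export
make_windows <- function(ref, window_size = 12L) {
  stopifnot(inherits(ref, "genome_annotation"), is_count(window_size, 2L))
  g <- ref$genes
  windows <- list()
  gene_ids <- list()
  wi <- 0L
  for (contig in unique(g$contig)) {
    cg <- g[g$contig == contig, , drop = FALSE]
    cg <- cg[order(cg$rank), , drop = FALSE]
    n_full <- nrow(cg) %/% window_size
    for (w in seq_len(n_full)) {
      wi <- wi + 1L
      rows <- ((w - 1L) * window_size + 1L):(w * window_size)
      windows[[wi]] <- data.frame(window_index = wi, contig = contig,
                                  start_rank = cg$rank[rows[1L]],
                                  stringsAsFactors = FALSE)
      gene_ids[[wi]] <- cg$gene_id[rows]
    }
  }
  structure(list(windows = do.call(rbind, windows) %||%
                   data.frame(window_index = integer(), contig = character(),
                              start_rank = integer()),
                 gene_ids = gene_ids,
                 window_size = as.integer(window_size)),
            class = "gene_windows")
}

#' @export
print.gene_windows <- function(x, ...) {
  cat(sprintf("<gene_windows> %d windows of %d genes\n",
              nrow(x$windows), x$window_size))
  invisible(x)
}

#' Gene conservation score
#'
#' Pair bit score divided by the reference protein's self-alignment bit
#' score, clamped to `[0, 1]`.
#'
#' @param pair_bitscore Bit score of the collinear gene pair.
#' @param self_bitscore Self-alignment bit score of the reference gene
#'   (must be > 0).
#' @return Score in `[0, 1]` (vectorised).
#' @export
conservation_score <- function(pair_bitscore, self_bitscore) {
  if (any(!is.finite(self_bitscore)) || any(self_bitscore <= 0)) {
    stopf("self_bitscore must be > 0")
  }
  pmin(1, pair_bitscore / self_bitscore)
}

## score the anchors of `blocks` that hit window genes; per window gene the
## max-bitscore anchor across the supplied blocks wins
score_window_genes <- function(win_genes, blocks, self_scores) {
  if (length(blocks) == 0L) {
    return(data.frame(ref_gene_id = character(), target_gene_id = character(),
                      bitscore = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  anchors <- do.call(rbind, lapply(blocks, function(b) b$anchors))
  anchors <- anchors[anchors$ref_gene_id %in% win_genes, , drop = FALSE]
  if (nrow(anchors) == 0L) {
    return(data.frame(ref_gene_id = character(), target_gene_id = character(),
                      bitscore = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(anchors$ref_gene_id, -anchors$bitscore, anchors$target_gene_id)
  anchors <- anchors[ord, , drop = FALSE]
  anchors <- anchors[!duplicated(anchors$ref_gene_id), , drop = FALSE]
  missing_self <- setdiff(anchors$ref_gene_id, names(self_scores))
  if (length(missing_self)) {
    stopf("no self score for reference gene(s): %s",
          paste(head(missing_self, 5L), collapse = ", "))
  }
  anchors$score <- conservation_score(anchors$bitscore,
                                      self_scores[anchors$ref_gene_id])
  rownames(anchors) <- NULL
  anchors[, c("ref_gene_id", "target_gene_id", "bitscore", "score")]
}

new_assignment <- function(summary, gene_scores, mode) {
  structure(list(summary = summary, gene_scores = gene_scores, mode = mode),
            class = "window_assignment")
}

#' Assign each window its best collinear block (orthologous mode)
#'
#' Per window, the single block anchoring the greatest number of window
#' genes is selected; ties go to the block with the larger total anchor bit
#' score, then to the lexicographically smaller block id. Window genes are
#' scored from their best anchor within the selected block.
#'
#' @param windows A `gene_windows` object from [make_windows()].
#' @param blocks List of `collinear_block`s between the reference and one
#'   target haplotype.
#' @param self_scores Named vector of reference self bit scores (from the
#'   [hit_table] used for block detection).
#' @param haplotype_id Target haplotype label carried into the output.
#' @return A `window_assignment`: `summary` data.frame (window_index,
#'   haplotype_id, mode, block_id, collinear_gene_count, region_count,
#'   mean_score) and `gene_scores` data.frame of per-gene conservation
#'   scores.
#' @export
assign_orthologous <- function(windows, blocks, self_scores, haplotype_id) {
  stopifnot(inherits(windows, "gene_windows"))
  n_win <- nrow(windows$windows)
  block_scores <- vapply(blocks, function(b) b$score, numeric(1L))
  block_ids <- vapply(blocks, function(b) b$block_id, character(1L))
  rows <- vector("list", n_win)
  scores <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    wg <- windows$gene_ids[[w]]
    overlap <- vapply(blocks, block_window_overlap, integer(1L),
                      window_gene_ids = wg)
    if (length(overlap) == 0L || max(overlap) == 0L) {
      rows[[w]] <- data.frame(window_index = w, haplotype_id = haplotype_id,
                              mode = "orthologous", block_id = NA_character_,
                              collinear_gene_count = 0L, region_count = 0L,
                              mean_score = NA_real_, stringsAsFactors = FALSE)
      next
    }
    cand <- which(overlap == max(overlap))
    cand <- cand[order(-block_scores[cand], block_ids[cand])]
    sel <- cand[1L]
    sc <- score_window_genes(wg, blocks[sel], self_scores)
    rows[[w]] <- data.frame(window_index = w, haplotype_id = haplotype_id,
                            mode = "orthologous", block_id = block_ids[sel],
                            collinear_gene_count = max(overlap),
                            region_count = 1L,
                            mean_score = mean(sc$score),
                            stringsAsFactors = FALSE)
    if (nrow(sc)) {
      sc$window_index <- w
      sc$haplotype_id <- haplotype_id
      scores[[w]] <- sc
    }
  }
  new_assignment(do.call(rbind, rows), do.call(rbind, scores) %||%
                   data.frame(), "orthologous")
}

#' Assign each window all its homologous regions (homologous mode)
#'
#' Counts every block anchoring at least `min_window_anchors` window genes
#' as a homologous region (orthologs plus WGD/paralogous copies); per window
#' gene, the collinear partner with the greatest bit score across all
#' counted regions is scored.
#'
#' @inheritParams assign_orthologous
#' @param min_window_anchors Minimum window genes a block must anchor to
#'   count as a region.
#' @return A `window_assignment` (see [assign_orthologous()]); `region_count`
#'   is the number of counted regions.
#' @export
assign_homologous <- function(windows, blocks, self_scores, haplotype_id,
                              min_window_anchors = 2L) {
  stopifnot(inherits(windows, "gene_windows"), is_count(min_window_anchors))
  n_win <- nrow(windows$windows)
  rows <- vector("list", n_win)
  scores <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    wg <- windows$gene_ids[[w]]
    overlap <- vapply(blocks, block_window_overlap, integer(1L),
                      window_gene_ids = wg)
    sel <- which(overlap >= min_window_anchors)
    if (length(sel) == 0L) {
      rows[[w]] <- data.frame(window_index = w, haplotype_id = haplotype_id,
                              mode = "homologous", block_id = NA_character_,
                              collinear_gene_count = 0L, region_count = 0L,
                              mean_score = NA_real_, stringsAsFactors = FALSE)
      next
    }
    sc <- score_window_genes(wg, blocks[sel], self_scores)
    rows[[w]] <- data.frame(
      window_index = w, haplotype_id = haplotype_id, mode = "homologous",
      block_id = paste(vapply(blocks[sel], function(b) b$block_id,
                              character(1L)), collapse = ","),
      collinear_gene_count = nrow(sc), region_count = length(sel),
      mean_score = mean(sc$score), stringsAsFactors = FALSE)
    if (nrow(sc)) {
      sc$window_index <- w
      sc$haplotype_id <- haplotype_id
      scores[[w]] <- sc
    }
  }
  new_assignment(do.call(rbind, rows), do.call(rbind, scores) %||%
                   data.frame(), "homologous")
}

#' Rank-normalize scores within groups
#'
#' Within each group, values are mapped to `(rank - 1) / (n - 1)` with tied
#' values receiving their mean rank; a single-member group maps to 0.5.
#'
#' @param scores Numeric vector.
#' @param groups Group label per score.
#' @return Numeric vector of normalized scores in `[0, 1]`.
#' @export
rank_normalize <- function(scores, groups) {
  stopifnot(length(scores) == length(groups))
  out <- rep(NA_real_, length(scores))
  for (g in unique(groups)) {
    i <- which(groups == g & !is.na(scores))
    if (length(i) == 0L) {
      warnf("rank_normalize: group '%s' is empty, skipped", g)
      next
    }
    if (length(i) == 1L) {
      out[i] <- 0.5
    } else {
      out[i] <- (rank(scores[i], ties.method = "average") - 1) /
        (length(i) - 1)
    }
  }
  out
}

## clade label -> normalization group: eudicots vs all other angiosperms,
## with non-flowering lineages kept apart
clade_group <- function(clade) {
  ifelse(clade %in% c("eudicot", "eudicots"), "eudicot",
         ifelse(clade %in% c("non_flowering", "non-flowering"),
                "non_flowering", "other_angiosperm"))
}

#' Summarize window conservation across haplotypes
#'
#' Pools per-window assignments across haplotypes, rank-normalizes the gene
#' conservation scores within clade groups (eudicots vs the other angiosperm
#' clades, non-flowering lineages apart), and compares a focus window (e.g.
#' the SDR window) against the genome background with Kruskal-Wallis tests
#' on both the collinear gene counts and the normalized scores.
#'
#' @param assignments List of `window_assignment` objects, one per haplotype.
#' @param clade_of Named character vector haplotype_id -> clade label.
#' @param focus_window Window index of the focus window, or `NULL` to skip
#'   the comparison.
#' @return A `conservation_summary`: `table` (per window x haplotype),
#'   `gene_scores` (with `normalized` column), `window_stats` (per-window
#'   means across haplotypes), and `tests` (`counts` and `scores`, each
#'   `list(H, p)`).
#' @export
summarize_conservation <- function(assignments, clade_of, focus_window = NULL) {
  stopifnot(length(assignments) > 0L)
  tab <- do.call(rbind, lapply(assignments, function(a) a$summary))
  sc <- do.call(rbind, lapply(assignments, function(a) a$gene_scores))
  rownames(tab) <- rownames(sc) <- NULL
  tab$clade <- unname(clade_of[tab$haplotype_id])
  if (anyNA(tab$clade)) stopf("clade_of is missing some haplotypes")
  sc$clade <- unname(clade_of[sc$haplotype_id])
  sc$normalized <- rank_normalize(sc$score, clade_group(sc$clade))
  ## per (window, haplotype) mean normalized score
  key <- paste(sc$window_index, sc$haplotype_id, sep = "\r")
  norm_mean <- tapply(sc$normalized, key, mean)
  tab$mean_norm_score <- as.numeric(norm_mean[paste(tab$window_index,
                                                    tab$haplotype_id,
                                                    sep = "\r")])
  angio <- clade_group(tab$clade) != "non_flowering"
  window_stats <- data.frame(
    window_index = sort(unique(tab$window_index)),
    stringsAsFactors = FALSE)
  window_stats$mean_count <- as.numeric(tapply(tab$collinear_gene_count[angio],
                                               tab$window_index[angio], mean)[
                                                 as.character(window_stats$window_index)])
  window_stats$mean_norm_score <- as.numeric(
    tapply(tab$mean_norm_score[angio], tab$window_index[angio],
           function(v) mean(v, na.rm = TRUE))[
             as.character(window_stats$window_index)])
  tests <- NULL
  if (!is.null(focus_window)) {
    grp <- ifelse(tab$window_index == focus_window, "focus", "background")
    cnt <- kruskal_groups(tab$collinear_gene_count[angio], grp[angio])
    ok <- angio & !is.na(tab$mean_norm_score)
    scr <- kruskal_groups(tab$mean_norm_score[ok], grp[ok])
    tests <- list(counts = cnt, scores = scr)
  }
  structure(list(table = tab, gene_scores = sc, window_stats = window_stats,
                 focus_window = focus_window, tests = tests),
            class = "conservation_summary")
}

#' Compare a focus window against the background
#'
#' Two-group Kruskal-Wallis comparing the focus window's values (across
#' haplotypes) to all other windows' values; with three or more groups
#' supplied via `extra_groups`, Dunn's BH-adjusted post-hoc is exposed.
#'
#' @param values Numeric vector of per-(window, haplotype) values (counts or
#'   normalized scores).
#' @param window_index Window index per value.
#' @param focus_window The focus window index.
#' @param extra_groups Optional explicit grouping overriding the binary
#'   focus/background split; with >= 3 levels Dunn's test is added.
#' @return List with `H`, `p`, and (when applicable) `dunn`.
#' @export
compare_windows <- function(values, window_index, focus_window,
                            extra_groups = NULL) {
  grp <- extra_groups %||%
    ifelse(window_index == focus_window, "focus", "background")
  res <- kruskal_groups(values, grp)
  if (length(unique(grp)) >= 3L) res$dunn <- dunn_test(values, grp)
  res
}
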