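## Promoter extraction and position-weight-matrix scanning, used to find
## transcription-factor binding sites present in every promoter of one
## allele group (e.g. the M haplotypes) and absent from the others.

#' Extract promoter sequences
#'
#' The promoter is the up-to-`max_len` bases immediately upstream of the
#' TSS (the annotated gene start on the + strand, the gene end on the -
#' strand), truncated at contig edges; minus-strand promoters are
#' reverse-complemented so that the stored sequence always reads 5' to 3'
#' toward the TSS and "offset" means bp upstream of the TSS.
#'
#' @param ann A [genome_annotation].
#' @param genome Named character vector contig -> sequence.
#' @param max_len Maximum promoter length in bp (default 3000).
#' @param groups Optional named vector gene_id -> allele group
#'   (e.g. `"M"`, `"F"`, `"H"`).
#' @return data.frame with `gene_id`, `haplotype_id`, `group`, `sequence`,
#'   `length`. Genes with a TSS at the contig edge are skipped with a
#'   warning.
#' @export
extract_promoters <- function(ann, genome, max_len = 3000L, groups = NULL) {
  stopifnot(inherits(ann, "genome_annotation"), is.character(genome),
            !is.null(names(genome)))
  g <- ann$genes
  missing_ctg <- setdiff(unique(g$contig), names(genome))
  if (length(missing_ctg)) {
    stopf("contig(s) absent from genome: %s",
          paste(missing_ctg, collapse = ", "))
  }
  rows <- vector("list", nrow(g))
  skipped <- character()
  for (i in seq_len(nrow(g))) {
    ctg <- genome[[g$contig[i]]]
    L <- nchar(ctg)
    if (g$strand[i] == "+") {
      tss0 <- g$start[i]                      # 0-based TSS position
      len <- min(max_len, tss0)
      if (len <= 0L) { skipped <- c(skipped, g$gene_id[i]); next }
      seq <- substr(ctg, tss0 - len + 1L, tss0)   # 1-based slice ends at TSS-1
    } else {
      tss0 <- g$end[i]                        # 0-based half-open end = TSS
      len <- min(max_len, L - tss0)
      if (len <= 0L) { skipped <- c(skipped, g$gene_id[i]); next }
      seq <- revcomp(substr(ctg, tss0 + 1L, tss0 + len))
    }
    rows[[i]] <- data.frame(gene_id = g$gene_id[i],
                            haplotype_id = ann$haplotype_id,
                            group = if (is.null(groups)) NA_character_ else
                              unname(groups[g$gene_id[i]]),
                            sequence = seq, length = nchar(seq),
                            stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    warnf("%d gene(s) with no upstream sequence skipped: %s", length(skipped),
          paste(head(skipped, 5L), collapse = ", "))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no promoters could be extracted")
  rownames(out) <- NULL
  out
}

#' Read JASPAR-style PFM files
#'
#' Parses the JASPAR text format: a `>motif_id name` header followed by four
#' rows `A [ 4 19 0 ... ]` (brackets optional).
#'
#' @param path Path to a PFM file (may contain several matrices).
#' @return Named list of `pwm_matrix` count matrices (4 x L, rows ACGT).
#' @export
read_pfm_jaspar <- function(path) {
  if (!file.exists(path)) stopf("cannot read PFM file: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stopf("no '>' header in %s", path)
  out <- list()
  for (h in seq_along(heads)) {
    from <- heads[h] + 1L
    to <- if (h < length(heads)) heads[h + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) != 4L) {
      stopf("PFM '%s': expected 4 base rows, found %d",
            lines[heads[h]], length(block))
    }
    rows <- lapply(block, function(ln) {
      base <- sub("^([ACGTacgt]).*$", "\\1", ln)
      nums <- gsub("[][ACGTacgt]", " ", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1L]]))
      if (anyNA(vals)) stopf("non-numeric PFM row: %s", ln)
      list(base = toupper(base), vals = vals)
    })
    bases <- vapply(rows, `[[`, character(1L), "base")
    if (!setequal(bases, c("A", "C", "G", "T"))) {
      stopf("PFM '%s': rows must be A, C, G, T", lines[heads[h]])
    }
    m <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(m) <- bases
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    id <- sub("^>\\s*", "", lines[heads[h]])
    id <- strsplit(id, "\\s+")[[1L]][1L]
    out[[id]] <- m
  }
  out
}

#' Build a log-odds PWM from a count or frequency matrix
#'
#' Columns are normalized (after adding `pseudocount * background` to count
#' matrices) and converted to log2 odds against the background.
#'
#' @param counts 4 x L matrix with rows A, C, G, T (counts or frequencies).
#' @param pseudocount Pseudocount added per column (default 0.8).
#' @param background Background base frequencies (default uniform).
#' @return A `pwm` object: log-odds `matrix`, `motif_id`, per-column score
#'   bounds.
#' @param motif_id Identifier carried into hits.
#' @export
make_pwm <- function(counts, motif_id = "motif", pseudocount = 0.8,
                     background = rep(0.25, 4)) {
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  background <- background / sum(background)
  p <- apply(counts, 2L, function(col) {
    col <- col + pseudocount * background
    col / sum(col)
  })
  lo <- log2(p / background)
  structure(list(motif_id = motif_id, matrix = lo,
                 col_max = apply(lo, 2L, max), col_min = apply(lo, 2L, min),
                 width = ncol(lo)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d\n", x$motif_id, x$width))
  invisible(x)
}

## score every offset of `seq` (character string) against a pwm; returns the
## raw log-odds score vector. Non-ACGT symbols take the column minimum.
scan_scores <- function(seq, pwm) {
  chars <- strsplit(seq, "")[[1L]]
  code <- match(chars, c("A", "C", "G", "T"))
  n <- length(code)
  w <- pwm$width
  if (n < w) return(numeric())
  s <- numeric(n - w + 1L)
  for (k in seq_len(w)) {
    idx <- code[k:(n - w + k)]
    col <- pwm$matrix[, k]
    vals <- unname(col[idx])
    vals[is.na(idx)] <- pwm$col_min[k]
    s <- s + vals
  }
  s
}

#' Scan a promoter with a PWM
#'
#' Log-odds scoring at every offset on one or both strands. The relative
#' score is `(score - min_possible) / (max_possible - min_possible)`; hits
#' at or above `min_rel_score` are reported with their upstream offset (bp
#' upstream of the TSS of the hit's most-upstream base).
#'
#' @param sequence Promoter sequence, 5' to 3' toward the TSS.
#' @param pwm A [make_pwm()] object.
#' @param min_rel_score Relative-score threshold (default 0.80).
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @return data.frame with `motif_id`, `upstream_offset`, `strand`,
#'   `rel_score`; empty when the motif is longer than the promoter.
#' @export
scan_pwm <- function(sequence, pwm, min_rel_score = 0.80,
                     both_strands = TRUE) {
  stopifnot(inherits(pwm, "pwm"))
  Lp <- nchar(sequence)
  w <- pwm$width
  empty <- data.frame(motif_id = character(), upstream_offset = integer(),
                      strand = character(), rel_score = numeric(),
                      stringsAsFactors = FALSE)
  if (Lp < w) return(empty)
  smin <- sum(pwm$col_min)
  smax <- sum(pwm$col_max)
  rel <- function(s) (s - smin) / (smax - smin)
  res <- list()
  sp <- rel(scan_scores(sequence, pwm))
  hit <- which(sp >= min_rel_score)
  if (length(hit)) {
    res[[1L]] <- data.frame(motif_id = pwm$motif_id,
                            upstream_offset = Lp - hit + 1L,
                            strand = "+", rel_score = sp[hit],
                            stringsAsFactors = FALSE)
  }
  if (both_strands) {
    sm <- rel(scan_scores(revcomp(sequence), pwm))
    hit <- which(sm >= min_rel_score)
    if (length(hit)) {
      ## position j on the reverse complement covers promoter positions
      ## (Lp-j-w+2)..(Lp-j+1); the most-upstream base is Lp-j-w+2
      res[[length(res) + 1L]] <- data.frame(
        motif_id = pwm$motif_id, upstream_offset = hit + w - 1L,
        strand = "-", rel_score = sm[hit], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res) %||% empty
  rownames(out) <- NULL
  out
}

#' Scan a set of promoters with one or more PWMs
#'
#' @param promoters data.frame from [extract_promoters()].
#' @param pwms A `pwm` or list of `pwm`s.
#' @inheritParams scan_pwm
#' @return data.frame of hits with `gene_id`, `haplotype_id`, `group`
#'   columns prepended.
#' @export
scan_promoters <- function(promoters, pwms, min_rel_score = 0.80,
                           both_strands = TRUE) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  rows <- list()
  for (i in seq_len(nrow(promoters))) {
    for (pwm in pwms) {
      h <- scan_pwm(promoters$sequence[i], pwm, min_rel_score, both_strands)
      if (nrow(h)) {
        h$gene_id <- promoters$gene_id[i]
        h$haplotype_id <- promoters$haplotype_id[i]
        h$group <- promoters$group[i]
        rows[[length(rows) + 1L]] <- h
      }
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(motif_id = character(), upstream_offset = integer(),
               strand = character(), rel_score = numeric(),
               gene_id = character(), haplotype_id = character(),
               group = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[, c("motif_id", "gene_id", "haplotype_id", "group", "upstream_offset",
          "strand", "rel_score")]
}

#' Detect allele-group-specific binding sites
#'
#' A site is group-specific when every promoter of one group carries a hit
#' for the motif within `window_bp` of a common offset and no promoter of
#' any other group has any hit for that motif within that window — the
#' pattern of a binding site present in all M haplotypes and absent from
#' all F and H haplotypes.
#'
#' @param hits data.frame from [scan_promoters()] (needs `haplotype_id` as
#'   promoter identity and `group`).
#' @param promoters The promoter roster the hits came from (so promoters
#'   without hits count).
#' @param window_bp Co-localization window (default 30).
#' @return data.frame with `motif_id`, `group`, `consensus_offset`,
#'   `n_carriers`; zero rows when nothing qualifies.
#' @export
group_specific_sites <- function(hits, promoters, window_bp = 30L) {
  groups <- unique(promoters$group)
  groups <- groups[!is.na(groups)]
  out <- list()
  for (motif in unique(hits$motif_id)) {
    mh <- hits[hits$motif_id == motif, , drop = FALSE]
    for (g in groups) {
      members <- unique(promoters$haplotype_id[promoters$group %in% g])
      others <- unique(promoters$haplotype_id[!promoters$group %in% g &
                                                !is.na(promoters$group)])
      gh <- mh[mh$haplotype_id %in% members, , drop = FALSE]
      if (nrow(gh) == 0L) next
      for (center in sort(unique(gh$upstream_offset))) {
        near <- abs(gh$upstream_offset - center) <= window_bp
        carriers <- unique(gh$haplotype_id[near])
        if (length(carriers) < length(members)) next
        oh <- mh[mh$haplotype_id %in% others &
                   abs(mh$upstream_offset - center) <= window_bp, , drop = FALSE]
        if (nrow(oh) > 0L) next
        per_member <- vapply(members, function(p) {
          off <- gh$upstream_offset[gh$haplotype_id == p & near]
          off[which.min(abs(off - center))]
        }, numeric(1L))
        out[[length(out) + 1L]] <- data.frame(
          motif_id = motif, group = g,
          consensus_offset = mean(per_member),
          n_carriers = length(members), stringsAsFactors = FALSE)
        break   # one consensus site per motif x group
      }
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(motif_id = character(), group = character(),
               consensus_offset = numeric(), n_carriers = integer(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Differential binding-site counts between allele groups
#'
#' Per motif, the mean number of hits per promoter in each group; motifs
#' whose mean in one group strictly exceeds every other group are listed
#' with that direction and the margin over the runner-up.
#'
#' @inheritParams group_specific_sites
#' @return data.frame with `motif_id`, one `mean_<group>` column per group,
#'   `direction`, `margin`; ties are omitted.
#' @export
differential_site_counts <- function(hits, promoters) {
  groups <- unique(promoters$group)
  groups <- groups[!is.na(groups)]
  stopifnot(length(groups) >= 2L)
  motifs <- unique(hits$motif_id)
  rows <- list()
  for (motif in motifs) {
    means <- vapply(groups, function(g) {
      members <- promoters$haplotype_id[promoters$group %in% g]
      counts <- vapply(members, function(p) {
        sum(hits$motif_id == motif & hits$haplotype_id == p)
      }, numeric(1L))
      mean(counts)
    }, numeric(1L))
    top <- which.max(means)
    sorted <- sort(means, decreasing = TRUE)
    if (length(sorted) > 1L && sorted[1L] == sorted[2L]) next  # tie: omitted
    row <- as.data.frame(as.list(setNames(means, paste0("mean_", groups))))
    row$motif_id <- motif
    row$direction <- groups[top]
    row$margin <- sorted[1L] - sorted[2L]
    rows[[length(rows) + 1L]] <- row
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(motif_id = character(), direction = character(),
                      margin = numeric(), stringsAsFactors = FALSE)
  } else {
    res <- res[, c("motif_id", paste0("mean_", groups), "direction", "margin")]
  }
  rownames(res) <- NULL
  res
}
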