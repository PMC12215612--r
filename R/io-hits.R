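#' Construct a homology hit table
#'
#' A `hit_table` holds filtered all-vs-all protein hits (query, subject,
#' bitscore, e-value) plus each reference gene's self-alignment bit score,
#' the denominator of the gene conservation score. Self hits
#' (query == subject) are routed out of `hits` into `self_scores`.
#'
#' @param hits data.frame with columns `query_id`, `subject_id`, `bitscore`,
#'   `evalue`. May contain self hits; these are moved to `self_scores`.
#' @param self_scores Optional named numeric vector gene_id -> self bit score;
#'   merged with any self hits found in `hits`.
#' @param evalue_max Drop hits with e-value above this threshold.
#' @param max_targets Keep at most this many best-bitscore subjects per query
#'   (ties broken by subject id).
#' @return A `hit_table` object.
#' @export
hit_table <- function(hits, self_scores = NULL, evalue_max = 0.001,
                      max_targets = 100L) {
  stopifnot(is.data.frame(hits),
            all(c("query_id", "subject_id", "bitscore", "evalue") %in% names(hits)))
  hits <- hits[, c("query_id", "subject_id", "bitscore", "evalue")]
  hits$query_id <- as.character(hits$query_id)
  hits$subject_id <- as.character(hits$subject_id)
  hits$bitscore <- as.numeric(hits$bitscore)
  hits$evalue <- as.numeric(hits$evalue)
  if (anyNA(hits$bitscore) || anyNA(hits$evalue)) {
    stopf("non-numeric bitscore/evalue in hit table")
  }
  if (any(hits$bitscore <= 0)) stopf("bitscore must be > 0")
  ## self hits become self scores, never pair hits
  is_self <- hits$query_id == hits$subject_id
  selfs <- hits[is_self, , drop = FALSE]
  self_vec <- setNames(selfs$bitscore, selfs$query_id)
  if (anyDuplicated(names(self_vec))) {
    self_vec <- tapply(selfs$bitscore, selfs$query_id, max)
    self_vec <- setNames(as.numeric(self_vec), names(self_vec))
  }
  if (!is.null(self_scores)) {
    stopifnot(is.numeric(self_scores), !is.null(names(self_scores)))
    add <- setdiff(names(self_scores), names(self_vec))
    self_vec <- c(self_vec, self_scores[add])
  }
  hits <- hits[!is_self, , drop = FALSE]
  ## e-value filter, then per-query subject cap ranked by bitscore desc,
  ## ties by subject id (deterministic reading of -max-target-seqs)
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (nrow(hits) > 0L) {
    ord <- order(hits$query_id, -hits$bitscore, hits$subject_id)
    hits <- hits[ord, , drop = FALSE]
    keep <- stats::ave(seq_len(nrow(hits)), hits$query_id,
                       FUN = seq_along) <= max_targets
    hits <- hits[keep, , drop = FALSE]
  }
  rownames(hits) <- NULL
  structure(list(hits = hits, self_scores = self_vec,
                 evalue_max = evalue_max, max_targets = as.integer(max_targets)),
            class = "hit_table")
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("<hit_table> %d hits, %d queries, %d self scores\n",
              nrow(x$hits), length(unique(x$hits$query_id)),
              length(x$self_scores)))
  invisible(x)
}

#' Read a BLAST/DIAMOND tabular hit file
#'
#' Reads 12-column `outfmt 6` output (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore), applies the e-value
#' threshold and the per-query subject cap, and routes self hits to
#' `self_scores`.
#'
#' @param path Path to the tabular file.
#' @inheritParams hit_table
#' @return A [hit_table].
#' @export
read_hit_table <- function(path, evalue_max = 0.001, max_targets = 100L) {
  if (!file.exists(path)) stopf("cannot read hit table: %s", path)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "", comment.char = "#")
  if (ncol(tab) != 12L) {
    stopf("expected 12 tab-separated columns (outfmt 6) in %s, found %d",
          path, ncol(tab))
  }
  ev <- suppressWarnings(as.numeric(tab[[11L]]))
  bs <- suppressWarnings(as.numeric(tab[[12L]]))
  if (anyNA(ev) || anyNA(bs)) {
    bad <- which(is.na(ev) | is.na(bs))[1L]
    stopf("non-numeric evalue/bitscore on line %d of %s", bad, path)
  }
  hit_table(data.frame(query_id = tab[[1L]], subject_id = tab[[2L]],
                       bitscore = bs, evalue = ev, stringsAsFactors = FALSE),
            evalue_max = evalue_max, max_targets = max_targets)
}

#' Write a hit table in 12-column tabular format
#'
#' Pair hits and self hits are emitted together; placeholder values fill the
#' alignment-coordinate columns that sdrkit does not track.
#'
#' @param ht A [hit_table].
#' @param path Output path.
#' @export
write_hit_table <- function(ht, path) {
  stopifnot(inherits(ht, "hit_table"))
  h <- ht$hits
  selfs <- data.frame(query_id = names(ht$self_scores),
                      subject_id = names(ht$self_scores),
                      bitscore = as.numeric(ht$self_scores),
                      evalue = 0, stringsAsFactors = FALSE)
  all <- rbind(h, selfs)
  out <- data.frame(all$query_id, all$subject_id, 100.0, 100L, 0L, 0L,
                    1L, 100L, 1L, 100L,
                    format(all$evalue, scientific = TRUE, trim = TRUE),
                    all$bitscore)
  write_atomic(function(tmp) {
    write.table(out, tmp, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }, path)
}
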