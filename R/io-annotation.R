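#' Construct a genome annotation
#'
#' A `genome_annotation` holds the ordered gene models of one haplotype: one
#' row per gene with contig, 0-based half-open coordinates, strand, and a
#' dense 0-based `rank` giving the order of the gene on its contig. The rank
#' order is what the windowing and collinearity machinery operates on.
#'
#' @param genes data.frame with columns `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`). Extra columns are dropped.
#' @param haplotype_id Haplotype identifier.
#' @param clade Clade label, e.g. `"eudicot"`, `"other_angiosperm"`,
#'   `"non_flowering"`.
#' @return A `genome_annotation` object.
#' @export
genome_annotation <- function(genes, haplotype_id, clade = "eudicot") {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "contig", "start", "end", "strand") %in% names(genes)))
  genes <- genes[, c("gene_id", "contig", "start", "end", "strand")]
  genes$gene_id <- as.character(genes$gene_id)
  genes$contig <- as.character(genes$contig)
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  genes$strand <- as.character(genes$strand)
  if (anyDuplicated(genes$gene_id)) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    stopf("duplicate gene_id in annotation '%s': %s", haplotype_id,
          paste(head(dup, 5L), collapse = ", "))
  }
  if (any(genes$start >= genes$end)) {
    bad <- genes$gene_id[genes$start >= genes$end][1L]
    stopf("gene '%s' has start >= end after coordinate conversion", bad)
  }
  if (!all(genes$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  ## sort by contig (order of first appearance), then start; ties broken by
  ## end then gene_id for determinism
  contig_levels <- unique(genes$contig)
  ord <- order(match(genes$contig, contig_levels), genes$start, genes$end,
               genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$contig,
                           FUN = seq_along) - 1L
  rownames(genes) <- NULL
  structure(list(haplotype_id = as.character(haplotype_id),
                 clade = as.character(clade),
                 genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s (%s): %d genes on %d contig(s)\n",
              x$haplotype_id, x$clade, nrow(x$genes),
              length(unique(x$genes$contig))))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Reads the requested feature type and returns a [genome_annotation] with
#' genes sorted per contig and dense 0-based ranks. GFF3 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @param feature Feature type to keep (default `"gene"`).
#' @param haplotype_id Haplotype identifier (defaults to the file base name).
#' @param clade Clade label for the haplotype.
#' @return A [genome_annotation].
#' @export
read_gff_genes <- function(path, feature = "gene",
                           haplotype_id = sub("\\.gff3?$", "", basename(path)),
                           clade = "eudicot") {
  if (!file.exists(path)) stopf("cannot read GFF file: %s", path)
  ## light structural validation so parse errors can name the offending line
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    stopf("malformed GFF3 line %d in %s (expected 9 tab-separated fields)",
          body[which(nfield != 9L)[1L]], path)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature]
  if (length(gr) == 0L) stopf("no '%s' features in %s", feature, path)
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) stopf("feature without ID attribute in %s", path)
  genes <- data.frame(
    gene_id = as.character(ids),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  genome_annotation(genes, haplotype_id = haplotype_id, clade = clade)
}

#' Write an annotation as GFF3
#'
#' Inverse of [read_gff_genes()]: internal 0-based half-open coordinates are
#' emitted as 1-based inclusive GFF3.
#'
#' @param ann A [genome_annotation].
#' @param path Output path.
#' @export
write_gff_genes <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  g <- ann$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand
  )
  gr$source <- "sdrkit"
  gr$type <- "gene"
  gr$ID <- g$gene_id
  write_atomic(function(tmp) rtracklayer::export(gr, tmp, format = "gff3"), path)
}
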