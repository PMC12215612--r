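#' Construct a genotype matrix
#'
#' Holds biallelic SNPs of one contig/region as variants x samples genotype
#' codes (0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing), with per-sample
#' depth and the INFO metrics used by the hard filters.
#'
#' @param contig Contig name.
#' @param pos Integer vector of 1-based positions (VCF convention), strictly
#'   increasing.
#' @param ref,alt Character vectors of alleles.
#' @param qual Numeric QUAL values.
#' @param geno Integer matrix (variants x samples) of genotype codes.
#' @param dp Integer matrix of per-sample read depth (same shape as `geno`).
#' @param info data.frame of INFO metrics (`QD`, `FS`, `MQ`, `MQRankSum`,
#'   `ReadPosRankSum`, `SOR`); missing metrics may be `NA`.
#' @param samples Character vector of sample ids (column order of `geno`).
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(contig, pos, ref, alt, qual, geno, dp = NULL,
                            info = NULL, samples = colnames(geno)) {
  n <- length(pos)
  geno <- as.matrix(geno)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(geno)))
  stopifnot(nrow(geno) == n, length(ref) == n, length(alt) == n,
            length(qual) == n)
  if (n > 1L && any(diff(pos) <= 0)) {
    stopf("variant positions must be strictly increasing on '%s'", contig)
  }
  if (!all(geno[!is.na(geno)] %in% 0:2)) {
    stopf("genotype codes must be 0, 1, 2 or NA")
  }
  if (is.null(dp)) dp <- matrix(NA_integer_, n, length(samples))
  if (is.null(info)) {
    info <- as.data.frame(lapply(setNames(INFO_METRICS, INFO_METRICS),
                                 function(k) rep(NA_real_, n)))
  }
  dimnames(geno) <- list(NULL, samples)
  dp <- as.matrix(dp)
  dimnames(dp) <- list(NULL, samples)
  structure(list(contig = as.character(contig), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 qual = as.numeric(qual), geno = geno, dp = dp,
                 info = info, samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %s: %d SNPs x %d samples\n",
              x$contig, length(x$pos), length(x$samples)))
  invisible(x)
}

n_variants <- function(m) length(m$pos)

subset_variants <- function(m, keep) {
  genotype_matrix(m$contig, m$pos[keep], m$ref[keep], m$alt[keep],
                  m$qual[keep], m$geno[keep, , drop = FALSE],
                  m$dp[keep, , drop = FALSE],
                  m$info[keep, , drop = FALSE], m$samples)
}

INFO_METRICS <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")

gt_to_code <- function(gt) {
  gt <- sub(":.*$", "", gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- rep(NA_integer_, length(gt))
  code[gt %in% "0/0"] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt %in% "1/1"] <- 2L
  code
}

#' Read biallelic SNPs from a VCF file
#'
#' Reads a VCF (plain or gzipped) through vcfR, restricts to biallelic SNP
#' records (multiallelic and indel records are skipped with a counted
#' warning), maps genotypes to codes 0/1/2/`NA`, and extracts per-sample DP
#' and the INFO metrics used by [filter_variants()]. Positions are asserted
#' strictly increasing.
#'
#' @param path Path to a VCF file.
#' @param region Optional region string `"contig"` or `"contig:start-end"`
#'   (1-based inclusive). A region on an absent contig yields an empty matrix
#'   with a warning, not a failure.
#' @return A [genotype_matrix].
#' @export
read_vcf_region <- function(path, region = NULL) {
  if (!file.exists(path)) stopf("cannot read VCF file: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  reg <- parse_region(region)
  contig <- if (is.null(reg)) {
    if (length(unique(chrom)) > 1L) {
      stopf("VCF spans multiple contigs; pass a region to select one")
    }
    unique(chrom)[1L]
  } else {
    reg$contig
  }
  keep <- chrom == contig
  if (!is.null(reg) && !is.na(reg$start)) {
    keep <- keep & pos >= reg$start & pos <= reg$end
  }
  if (!any(keep)) {
    warnf("region '%s' matches no records in %s", region %||% contig, path)
    samples <- colnames(vcf@gt)[-1L] %||% character()
    return(genotype_matrix(contig, integer(), character(), character(),
                           numeric(),
                           matrix(integer(), 0L, length(samples),
                                  dimnames = list(NULL, samples)),
                           matrix(integer(), 0L, length(samples)),
                           NULL, samples))
  }
  idx <- which(keep)
  ref <- fix[idx, "REF"]
  alt <- fix[idx, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!snp)) {
    warnf("%d non-biallelic-SNP record(s) skipped", sum(!snp))
  }
  idx <- idx[snp]
  if (length(idx) == 0L) {
    samples <- colnames(vcf@gt)[-1L]
    return(genotype_matrix(contig, integer(), character(), character(),
                           numeric(),
                           matrix(integer(), 0L, length(samples),
                                  dimnames = list(NULL, samples)),
                           NULL, NULL, samples))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")[idx, , drop = FALSE]
  geno <- matrix(gt_to_code(gt), nrow = length(idx),
                 dimnames = list(NULL, colnames(gt)))
  dp_raw <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  dp <- if (is.null(dp_raw)) NULL else dp_raw[idx, , drop = FALSE]
  info <- as.data.frame(lapply(setNames(INFO_METRICS, INFO_METRICS), function(k) {
    v <- suppressWarnings(vcfR::extract.info(vcf, element = k, as.numeric = TRUE))
    if (is.null(v)) rep(NA_real_, length(idx)) else as.numeric(v[idx])
  }))
  genotype_matrix(contig, pos[idx], ref[idx], alt[idx],
                  suppressWarnings(as.numeric(fix[idx, "QUAL"])),
                  geno, dp, info, colnames(gt))
}

#' Write a genotype matrix as a VCF v4.2 file
#'
#' Emits GT:DP per sample and the hard-filter INFO metrics, so files written
#' by the simulators exercise the full read/filter path.
#'
#' @param m A [genotype_matrix].
#' @param path Output path (plain text).
#' @export
write_genotype_vcf <- function(m, path) {
  stopifnot(inherits(m, "genotype_matrix"))
  n <- n_variants(m)
  info_str <- vapply(seq_len(max(n, 0L)), function(i) {
    vals <- unlist(m$info[i, INFO_METRICS])
    ok <- !is.na(vals)
    if (!any(ok)) return(".")
    paste(sprintf("%s=%.4g", INFO_METRICS[ok], vals[ok]), collapse = ";")
  }, character(1L))
  code_to_gt <- c("0/0", "0/1", "1/1")
  gt_cols <- vapply(seq_along(m$samples), function(j) {
    g <- m$geno[, j]
    gt <- ifelse(is.na(g), "./.", code_to_gt[g + 1L])
    d <- m$dp[, j]
    paste0(gt, ":", ifelse(is.na(d), ".", as.character(d)))
  }, character(n))
  if (n == 1L) gt_cols <- matrix(gt_cols, nrow = 1L)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sdrkit",
    sprintf("##contig=<ID=%s>", m$contig),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQ rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Symmetric odds ratio\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", m$samples), collapse = "\t")
  )
  body <- if (n == 0L) character() else {
    apply(cbind(m$contig, m$pos, ".", m$ref, m$alt,
                formatC(m$qual, format = "f", digits = 2), "PASS",
                info_str, "GT:DP", gt_cols), 1L, paste, collapse = "\t")
  }
  write_atomic(function(tmp) writeLines(c(header, body), tmp), path)
}
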