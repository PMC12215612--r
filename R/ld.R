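## SNP hard filtering, pairwise r2, Hill-Weir LD decay, LD landscapes, and
## the homozygous/heterozygous call ratio contrast used to probe
## recombination suppression in candidate sex-determining regions.

#' SNP hard-filter profile
#'
#' Thresholds mirroring a GATK/vcftools/bcftools post-calling filter chain:
#' QUAL above a minimum, per-sample depth above a floor and at most a
#' multiple of the median depth across accessions (or inside explicit
#' exclusive bounds for low-coverage panels), minor allele frequency above a
#' floor, a cap on missing genotypes, and INFO-metric hard filters.
#'
#' @param qual_min Keep records with QUAL strictly greater (default 30).
#' @param dp_min Keep samples' calls with DP strictly greater (default 5).
#' @param dp_max_factor Upper depth cap as a multiple of the median DP
#'   across all samples and sites (default 3; inclusive).
#' @param maf_min Keep records with minor allele frequency strictly greater
#'   (default 0.05).
#' @param max_missing Maximum missing genotypes per record (default 0).
#' @param hard_filters List of `list(metric, cmp, threshold)` removal rules;
#'   a record failing any rule is removed. `cmp` is one of `"<"`, `">"`,
#'   `"<="`, `">="` and states the *removal* condition, e.g.
#'   `list("QD", "<", 2)` removes records with QD < 2. Records whose metric
#'   is absent (`NA`) pass the rule. Defaults to the standard
#'   QD/FS/MQ/MQRankSum/ReadPosRankSum/SOR set.
#' @param dp_bounds_override Optional `c(low, high)`: when set, per-sample
#'   depth must satisfy `low < DP < high` (both exclusive) and the
#'   median-based cap is ignored — the profile used for low-coverage panels
#'   such as the Tetrastigma set (`c(1, 15)`).
#' @return A `filter_profile` object.
#' @export
filter_profile <- function(qual_min = 30, dp_min = 5L, dp_max_factor = 3,
                           maf_min = 0.05, max_missing = 0L,
                           hard_filters = default_hard_filters(),
                           dp_bounds_override = NULL) {
  stopifnot(qual_min >= 0, dp_min >= 0, dp_max_factor >= 0, maf_min >= 0,
            max_missing >= 0)
  for (hf in hard_filters) {
    stopifnot(length(hf) == 3L, hf[[2L]] %in% c("<", ">", "<=", ">="))
  }
  if (!is.null(dp_bounds_override)) {
    stopifnot(length(dp_bounds_override) == 2L,
              dp_bounds_override[1L] < dp_bounds_override[2L])
  }
  structure(list(qual_min = qual_min, dp_min = dp_min,
                 dp_max_factor = dp_max_factor, maf_min = maf_min,
                 max_missing = as.integer(max_missing),
                 hard_filters = hard_filters,
                 dp_bounds_override = dp_bounds_override),
            class = "filter_profile")
}

#' @rdname filter_profile
#' @export
default_hard_filters <- function() {
  list(list("QD", "<", 2.0), list("FS", ">", 60.0), list("MQ", "<", 40.0),
       list("MQRankSum", "<", -12.5), list("ReadPosRankSum", "<", -8.0),
       list("SOR", ">", 3.0))
}

## minor allele frequency from genotype codes, missing excluded
maf_from_codes <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) == 0L) return(NA_real_)
  p <- sum(g) / (2 * length(g))
  min(p, 1 - p)
}

#' Apply a hard-filter profile to a genotype matrix
#'
#' Filters are applied record-wise in the order QUAL, depth, MAF,
#' missingness, INFO hard filters; the rejection tally attributes each
#' removed record to the first filter it fails. Record order is preserved.
#'
#' @param m A [genotype_matrix].
#' @param profile A [filter_profile].
#' @return The filtered [genotype_matrix]; attribute `"rejections"` carries
#'   the named per-filter tally (`qual`, `depth`, `maf`, `missing`, `hard`),
#'   also retrievable with [filter_tally()].
#' @export
filter_variants <- function(m, profile = filter_profile()) {
  stopifnot(inherits(m, "genotype_matrix"), inherits(profile, "filter_profile"))
  n <- n_variants(m)
  tally <- c(qual = 0L, depth = 0L, maf = 0L, missing = 0L, hard = 0L)
  if (n == 0L) {
    attr(m, "rejections") <- tally
    return(m)
  }
  med_dp <- median(m$dp, na.rm = TRUE)
  dp_ok <- if (!is.null(profile$dp_bounds_override)) {
    b <- profile$dp_bounds_override
    m$dp > b[1L] & m$dp < b[2L]
  } else {
    m$dp > profile$dp_min & m$dp <= profile$dp_max_factor * med_dp
  }
  dp_ok[is.na(dp_ok)] <- FALSE
  pass_dp <- rowSums(dp_ok) == ncol(m$dp)
  pass_qual <- !is.na(m$qual) & m$qual > profile$qual_min
  maf <- apply(m$geno, 1L, maf_from_codes)
  pass_maf <- !is.na(maf) & maf > profile$maf_min
  pass_miss <- rowSums(is.na(m$geno)) <= profile$max_missing
  pass_hard <- rep(TRUE, n)
  for (hf in profile$hard_filters) {
    v <- m$info[[hf[[1L]]]]
    if (is.null(v)) next
    bad <- switch(hf[[2L]],
                  "<" = v < hf[[3L]], ">" = v > hf[[3L]],
                  "<=" = v <= hf[[3L]], ">=" = v >= hf[[3L]])
    bad[is.na(bad)] <- FALSE
    pass_hard <- pass_hard & !bad
  }
  ## first-failure attribution in the declared order
  fail_first <- rep(NA_character_, n)
  fail_first[!pass_hard] <- "hard"
  fail_first[!pass_miss] <- "missing"
  fail_first[!pass_maf] <- "maf"
  fail_first[!pass_dp] <- "depth"
  fail_first[!pass_qual] <- "qual"
  keep <- is.na(fail_first)
  tc <- table(fail_first)
  tally[names(tc)] <- as.integer(tc)
  out <- subset_variants(m, keep)
  attr(out, "rejections") <- tally
  out
}

#' @rdname filter_variants
#' @param filtered A matrix returned by `filter_variants`.
#' @export
filter_tally <- function(filtered) attr(filtered, "rejections")

#' Pairwise r2 between SNPs
#'
#' Composite linkage disequilibrium from unphased data: r2 is the squared
#' Pearson correlation of genotype codes across samples (plink-style, no
#' phasing). Pairs farther apart than `max_dist_bp` are omitted; monomorphic
#' sites and sites below `maf_min` are skipped; pairs with fewer than 3
#' shared non-missing samples are skipped and tallied.
#'
#' @param m A [genotype_matrix].
#' @param maf_min Minimum minor allele frequency for a site to enter.
#' @param max_dist_bp Maximum pair distance in bp (default 300 kbp).
#' @return data.frame with `pos_a`, `pos_b`, `distance`, `r2`; attribute
#'   `"skipped_pairs"` counts pairs dropped for insufficient shared calls.
#' @export
pairwise_r2 <- function(m, maf_min = 0.05, max_dist_bp = 300000L) {
  stopifnot(inherits(m, "genotype_matrix"))
  maf <- apply(m$geno, 1L, maf_from_codes)
  v <- apply(m$geno, 1L, function(g) stats::var(g[!is.na(g)]))
  use <- which(!is.na(maf) & maf >= maf_min & !is.na(v) & v > 0)
  pos <- m$pos[use]
  g <- m$geno[use, , drop = FALSE]
  nv <- length(use)
  res <- vector("list", nv)
  skipped <- 0L
  for (i in seq_len(nv)) {
    hi <- findInterval(pos[i] + max_dist_bp + 0.5, pos)
    if (hi <= i) next
    js <- (i + 1L):hi
    gi <- g[i, ]
    gj <- t(g[js, , drop = FALSE])
    shared <- colSums(!is.na(gi) & !is.na(gj))
    r <- suppressWarnings(as.numeric(cor(gi, gj,
                                         use = "pairwise.complete.obs")))
    ok <- shared >= 3L & !is.na(r)
    skipped <- skipped + sum(shared < 3L)
    if (!any(ok)) next
    res[[i]] <- data.frame(pos_a = pos[i], pos_b = pos[js[ok]],
                           r2 = r[ok]^2)
  }
  out <- do.call(rbind, res) %||%
    data.frame(pos_a = integer(), pos_b = integer(), r2 = numeric())
  out$distance <- abs(out$pos_b - out$pos_a)
  rownames(out) <- NULL
  out <- out[, c("pos_a", "pos_b", "distance", "r2")]
  attr(out, "skipped_pairs") <- skipped
  out
}

#' Hill-Weir expectation for r2
#'
#' The Hill & Weir (1988) sample-size-adjusted drift expectation
#' \deqn{E[r^2](C) = \frac{10+C}{(2+C)(11+C)}\left[1 +
#'   \frac{(3+C)(12+12C+C^2)}{n(2+C)(11+C)}\right]}
#' with \eqn{C = \rho d} the population recombination parameter at distance
#' `d` and `n` the number of sampled chromosomes.
#'
#' @param d Distance in bp (vectorised).
#' @param rho Per-bp recombination coefficient.
#' @param n Number of sampled chromosomes.
#' @return Expected r2.
#' @export
hill_weir_expectation <- function(d, rho, n) {
  C <- rho * d
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit Hill-Weir LD decay and the half-decay distance
#'
#' Least-squares fit of [hill_weir_expectation()] over `rho`; the half-decay
#' distance is the distance at which the fitted curve falls to half its
#' value at distance zero (the maximum average r2), found by bisection.
#'
#' @param pairs data.frame from [pairwise_r2()] (needs `distance`, `r2`).
#' @param n Number of sampled chromosomes (2 x diploid samples).
#' @return A `hill_weir_fit`: `rho`, `n`, `half_decay_bp`, `residual` (root
#'   mean squared residual), and `no_decay` (TRUE when the half-decay
#'   distance exceeds the largest observed distance, i.e. no decay was seen
#'   within the data).
#' @export
fit_ld_decay <- function(pairs, n) {
  stopifnot(is.data.frame(pairs), all(c("distance", "r2") %in% names(pairs)),
            is_count(n, 2L))
  d <- pairs$distance
  r2 <- pairs$r2
  keep <- !is.na(d) & !is.na(r2)
  d <- d[keep]; r2 <- r2[keep]
  if (length(d) < 3L) stopf("need at least 3 LD pairs to fit decay")
  if (stats::var(r2) == 0) stopf("degenerate fit: all r2 values are equal")
  sse <- function(log_rho) {
    sum((r2 - hill_weir_expectation(d, exp(log_rho), n))^2)
  }
  grid <- seq(log(1e-10), log(1), length.out = 120L)
  vals <- vapply(grid, sse, numeric(1L))
  best <- which.min(vals)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  opt <- optimize(sse, interval = c(lo, hi), tol = 1e-12)
  rho <- exp(opt$minimum)
  if (best == 1L || best == length(grid)) {
    warnf("Hill-Weir fit at the search boundary (rho = %.3g)", rho)
  }
  residual <- sqrt(opt$objective / length(d))
  ## half-decay: solve E[r2](d_half) = E[r2](0) / 2 by bisection
  e0 <- hill_weir_expectation(0, rho, n)
  target <- e0 / 2
  d_max <- max(d)
  f <- function(x) hill_weir_expectation(x, rho, n) - target
  upper <- d_max
  while (f(upper) > 0 && upper < 1e15) upper <- upper * 10
  half <- if (f(upper) > 0) Inf else stats::uniroot(f, c(0, upper),
                                                    tol = 1e-9)$root
  no_decay <- !is.finite(half) || half > d_max
  if (no_decay) {
    warnf("no decay within the observed distance range (half-decay %.3g bp)",
          half)
  }
  structure(list(rho = rho, n = as.integer(n), half_decay_bp = half,
                 residual = residual, no_decay = no_decay),
            class = "hill_weir_fit")
}

#' @export
print.hill_weir_fit <- function(x, ...) {
  cat(sprintf("<hill_weir_fit> rho = %.4g /bp, n = %d, half-decay = %.1f bp\n",
              x$rho, x$n, x$half_decay_bp))
  invisible(x)
}

#' Aggregate pairwise r2 into an LD landscape
#'
#' Bins of `bin_bp` tile the region; each pair contributes its r2 to the bin
#' of each of its two SNP positions. Bins with fewer than `min_snps`
#' distinct SNPs are masked.
#'
#' @param pairs data.frame from [pairwise_r2()].
#' @param region `c(start, end)` in bp (1-based inclusive) delimiting the
#'   landscape.
#' @param bin_bp Bin width (default 1000).
#' @param min_snps Mask bins with fewer distinct SNP positions than this
#'   (0 disables masking; the landscape reported for SDR scans uses 5).
#' @return data.frame with `bin_start` (0-based bp on the bin grid),
#'   `mean_r2`, `snp_count`, `masked`.
#' @export
aggregate_ld_bins <- function(pairs, region, bin_bp = 1000L, min_snps = 0L) {
  stopifnot(is.data.frame(pairs), length(region) == 2L, region[1L] <= region[2L])
  start0 <- floor((region[1L] - 1) / bin_bp) * bin_bp
  bin_starts <- seq(start0, region[2L] - 1, by = bin_bp)
  pos <- c(pairs$pos_a, pairs$pos_b)
  r2 <- c(pairs$r2, pairs$r2)
  inside <- pos >= region[1L] & pos <= region[2L]
  pos <- pos[inside]; r2 <- r2[inside]
  bin <- floor((pos - 1) / bin_bp) * bin_bp
  key <- match(bin, bin_starts)
  mean_r2 <- rep(NA_real_, length(bin_starts))
  snp_count <- rep(0L, length(bin_starts))
  if (length(pos)) {
    mr <- tapply(r2, key, mean)
    mean_r2[as.integer(names(mr))] <- as.numeric(mr)
    sc <- tapply(pos, key, function(p) length(unique(p)))
    snp_count[as.integer(names(sc))] <- as.integer(sc)
  }
  data.frame(bin_start = bin_starts, mean_r2 = mean_r2,
             snp_count = snp_count, masked = snp_count < min_snps)
}

#' Recover an elevated-LD segment from a landscape
#'
#' Thresholds the unmasked bins and returns the contiguous run (allowing
#' `max_bridge` below-threshold bins to be bridged) with the greatest summed
#' r2 — the operating definition of "elevated LD between X and Y bp" used to
#' delimit a recombination-suppressed region.
#'
#' @param landscape data.frame from [aggregate_ld_bins()].
#' @param r2_threshold Bins with `mean_r2 >=` this value are "elevated".
#' @param max_bridge Number of consecutive non-elevated bins a run may span.
#' @return `c(start, end)` in bp (1-based inclusive bounds of the segment),
#'   or `NULL` when no bin is elevated.
#' @export
detect_high_ld_segment <- function(landscape, r2_threshold,
                                   max_bridge = 1L) {
  elevated <- !landscape$masked & !is.na(landscape$mean_r2) &
    landscape$mean_r2 >= r2_threshold
  if (!any(elevated)) return(NULL)
  idx <- which(elevated)
  runs <- split(idx, cumsum(c(1L, diff(idx) > max_bridge + 1L)))
  weight <- vapply(runs, function(r) {
    sum(landscape$mean_r2[min(r):max(r)], na.rm = TRUE)
  }, numeric(1L))
  best <- runs[[which.max(weight)]]
  bin_bp <- if (nrow(landscape) > 1L) diff(landscape$bin_start[1:2]) else 1000L
  c(landscape$bin_start[min(best)] + 1L,
    landscape$bin_start[max(best)] + bin_bp)
}

#' Homozygous/heterozygous call ratio per sample
#'
#' Per sample, the number of homozygous-alternate calls divided by the
#' number of heterozygous calls within a region; samples with no
#' heterozygous call are reported as infinite and flagged. Heterogametic
#' individuals carrying a diverged sex haplotype show a depressed ratio in
#' the sex-determining region. An optional grouping adds the
#' Kruskal-Wallis + BH-adjusted Dunn comparison.
#'
#' @param m A [genotype_matrix].
#' @param region Optional `c(start, end)` (1-based inclusive) restricting
#'   the variants used.
#' @param groups Optional named vector sample -> group label.
#' @return List with `per_sample` (sample, hom_alt, het, ratio, infinite)
#'   and, when `groups` is given, `kruskal` and `dunn`.
#' @export
hom_het_ratio <- function(m, region = NULL, groups = NULL) {
  stopifnot(inherits(m, "genotype_matrix"))
  keep <- if (is.null(region)) rep(TRUE, n_variants(m)) else {
    m$pos >= region[1L] & m$pos <= region[2L]
  }
  g <- m$geno[keep, , drop = FALSE]
  hom <- colSums(g == 2L, na.rm = TRUE)
  het <- colSums(g == 1L, na.rm = TRUE)
  ratio <- ifelse(het == 0L, Inf, hom / het)
  per_sample <- data.frame(sample = m$samples, hom_alt = hom, het = het,
                           ratio = ratio, infinite = het == 0L,
                           row.names = NULL, stringsAsFactors = FALSE)
  out <- list(per_sample = per_sample)
  if (!is.null(groups)) {
    grp <- unname(groups[m$samples])
    if (anyNA(grp)) stopf("groups is missing some samples")
    out$kruskal <- kruskal_groups(per_sample$ratio, grp)
    out$dunn <- dunn_test(per_sample$ratio, grp)
  }
  out
}
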