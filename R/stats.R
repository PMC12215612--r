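#' Kruskal-Wallis test tolerant of degenerate input
#'
#' Thin wrapper around [stats::kruskal.test()] that returns `H = 0`, `p = 1`
#' with a warning when all observations are identical (where the plain test
#' is undefined), and handles infinite values through their ranks.
#'
#' @param x Numeric values (may contain `Inf`).
#' @param g Group labels (coerced to factor).
#' @return List with `H` (chi-squared statistic) and `p`.
#' @export
kruskal_groups <- function(x, g) {
  g <- factor(g)
  keep <- !is.na(x)
  x <- x[keep]; g <- droplevels(g[keep])
  if (length(x) == 0L || nlevels(g) < 2L) {
    stopf("kruskal_groups needs at least two non-empty groups")
  }
  if (length(unique(x)) == 1L) {
    warnf("all observations identical; Kruskal-Wallis H = 0, p = 1")
    return(list(H = 0, p = 1))
  }
  kt <- kruskal.test(rank(x), g)   # ranks make +/-Inf harmless
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Dunn's post-hoc test with Benjamini-Hochberg adjustment
#'
#' Pairwise z statistics on the joint ranks, with the usual tie correction,
#' following Dunn (1964). P values are two-sided and BH-adjusted across
#' comparisons.
#'
#' @param x Numeric values.
#' @param g Group labels.
#' @return data.frame with `group_a`, `group_b`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(x, g) {
  g <- factor(g)
  keep <- !is.na(x)
  x <- x[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2L) stopf("dunn_test needs at least two groups")
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ## tie correction term
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  combs <- utils::combn(levels(g), 2L)
  res <- apply(combs, 2L, function(ab) {
    a <- ab[1L]; b <- ab[2L]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(group_a = combs[1L, ], group_b = combs[2L, ],
                    z = res["z", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
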