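## Molecular-evolution estimators and the clock: Kimura two-parameter
## distances, NG86 synonymous divergence, dating via T = K/(2*mu) x
## generation time, the dS landscape along a region, and feature dating
## (inversion ends, LTR pairs) from multiple distance estimates.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

is_transition <- function(a, b) {
  (a %in% PURINES & b %in% PURINES) | (a %in% PYRIMIDINES & b %in% PYRIMIDINES)
}

#' Kimura two-parameter distance
#'
#' Separates transition (P) and transversion (Q) proportions over the
#' compared sites and applies
#' \eqn{K = -\frac{1}{2}\ln(1-2P-Q) - \frac{1}{4}\ln(1-2Q)}.
#' Sites where either sequence carries a non-ACGT symbol are excluded
#' pairwise.
#'
#' @param seq_a,seq_b Equal-length nucleotide sequences (strings).
#' @return A `divergence_estimate` with `kind = "K2P"`, `value` (K), `P`,
#'   `Q` and `sites` (compared sites).
#' @export
kimura2p <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1L]]
  b <- strsplit(toupper(seq_b), "")[[1L]]
  if (length(a) != length(b)) stopf("sequences must have equal length")
  ok <- a %in% c(PURINES, PYRIMIDINES) & b %in% c(PURINES, PYRIMIDINES)
  a <- a[ok]; b <- b[ok]
  L <- length(a)
  if (L == 0L) stopf("no comparable sites")
  diff <- a != b
  P <- sum(diff & is_transition(a, b)) / L
  Q <- sum(diff & !is_transition(a, b)) / L
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    stopf("K2P saturation: P = %.3f, Q = %.3f", P, Q)
  }
  K <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  structure(list(kind = "K2P", value = K, P = P, Q = Q, sites = L),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("<divergence_estimate> %s = %.5f (%.1f sites)\n",
              x$kind, x$value, x$sites))
  invisible(x)
}

## --- codon machinery -------------------------------------------------------

codon_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  if (is.null(codon_env$code)) {
    gc <- Biostrings::GENETIC_CODE
    codon_env$code <- setNames(as.character(gc), names(gc))
    codon_env$stops <- names(gc)[gc == "*"]
    codon_env$sense <- setdiff(names(gc), codon_env$stops)
  }
  codon_env$code
}

stop_codons <- function() { genetic_code(); codon_env$stops }
sense_codons <- function() { genetic_code(); codon_env$sense }

## fraction of the 9 single-base changes of a codon that are synonymous,
## expressed as synonymous sites (0..3): per position, (# synonymous of the
## 3 changes)/3, summed over positions. Changes producing stops are not
## synonymous.
syn_sites_codon <- function(codon) {
  code <- genetic_code()
  aa <- code[[codon]]
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1L]]
  s <- 0
  for (p in 1:3) {
    for (nb in setdiff(bases, chars[p])) {
      alt <- chars
      alt[p] <- nb
      alt_codon <- paste(alt, collapse = "")
      if (code[[alt_codon]] == aa && code[[alt_codon]] != "*") s <- s + 1 / 3
    }
  }
  s
}

syn_sites_table <- function() {
  if (is.null(codon_env$syn_sites)) {
    codons <- names(genetic_code())
    codon_env$syn_sites <- setNames(vapply(codons, syn_sites_codon,
                                           numeric(1L)), codons)
  }
  codon_env$syn_sites
}

## synonymous neighbours of a sense codon (single-base changes to another
## sense codon with the same amino acid); used by the codon-pair simulator
syn_neighbors_table <- function() {
  if (is.null(codon_env$syn_nb)) {
    code <- genetic_code()
    bases <- c("A", "C", "G", "T")
    codon_env$syn_nb <- lapply(setNames(nm = sense_codons()), function(codon) {
      chars <- strsplit(codon, "")[[1L]]
      out <- character()
      for (p in 1:3) {
        for (nb in setdiff(bases, chars[p])) {
          alt <- chars
          alt[p] <- nb
          alt_codon <- paste(alt, collapse = "")
          if (code[[alt_codon]] == code[[codon]] && code[[alt_codon]] != "*") {
            out <- c(out, alt_codon)
          }
        }
      }
      out
    })
  }
  codon_env$syn_nb
}

## path-averaged synonymous/total difference counts between two codons
## (NG86): all orders of the differing positions are enumerated; paths
## passing through a stop codon are excluded unless every path does.
codon_path_counts <- function(c1, c2) {
  key <- paste0(c1, c2)
  if (!is.null(codon_env$paths[[key]])) return(codon_env$paths[[key]])
  code <- genetic_code()
  p1 <- strsplit(c1, "")[[1L]]
  p2 <- strsplit(c2, "")[[1L]]
  dpos <- which(p1 != p2)
  nd <- length(dpos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(dpos) else {
    if (nd == 2L) list(dpos, rev(dpos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(i) dpos[i])
    }
  }
  count_path <- function(order) {
    cur <- p1
    sd <- 0; ndiff <- 0; via_stop <- FALSE
    for (p in order) {
      nxt <- cur
      nxt[p] <- p2[p]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      if (code[[to]] == "*") via_stop <- TRUE
      if (code[[from]] == code[[to]] && code[[to]] != "*") sd <- sd + 1
      ndiff <- ndiff + 1
      cur <- nxt
    }
    list(sd = sd, nd = ndiff, via_stop = via_stop)
  }
  paths <- lapply(perms, count_path)
  ok <- !vapply(paths, `[[`, logical(1L), "via_stop")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  sd <- mean(vapply(paths[ok], `[[`, numeric(1L), "sd"))
  res <- c(sd = sd, nd = nd)
  if (is.null(codon_env$paths)) codon_env$paths <- list()
  codon_env$paths[[key]] <- res
  res
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) stopf("sequence length %d not divisible by 3", n)
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Construct a pairwise codon alignment
#'
#' Upper-cases, verifies equal length divisible by 3, prunes codon columns
#' containing gaps or ambiguity codes in either sequence, and rejects
#' internal stop codons.
#'
#' @param seq_a,seq_b Aligned nucleotide sequences.
#' @param id Optional identifier.
#' @return A `codon_alignment` with codon vectors `codons_a`, `codons_b`.
#' @export
codon_alignment <- function(seq_a, seq_b, id = NULL) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) stopf("aligned sequences differ in length")
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[clean]; cb <- cb[clean]
  ## trailing stop codons are tolerated (and dropped); internal stops are not
  n <- length(ca)
  if (n > 0L && (ca[n] %in% stop_codons() || cb[n] %in% stop_codons())) {
    ca <- ca[-n]; cb <- cb[-n]; n <- n - 1L
  }
  if (any(ca %in% stop_codons()) || any(cb %in% stop_codons())) {
    stopf("internal stop codon in alignment%s",
          if (is.null(id)) "" else paste0(" '", id, "'"))
  }
  structure(list(id = id, codons_a = ca, codons_b = cb),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment>%s %d codons\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              length(x$codons_a)))
  invisible(x)
}

#' NG86 synonymous divergence
#'
#' Nei-Gojobori (1986) estimator: synonymous sites are the per-position
#' fractions of synonymous single-base changes averaged over the two
#' sequences; synonymous differences are counted over all minimal edit paths
#' between differing codons (path-averaged, stop-free paths preferred);
#' the proportion is Jukes-Cantor corrected,
#' \eqn{dS = -\frac{3}{4}\ln(1 - \frac{4}{3} pS)}.
#'
#' @param aln A [codon_alignment] (or two raw sequences via `seq_b`).
#' @param seq_b Optional second sequence when `aln` is a raw string.
#' @return A `divergence_estimate` with `kind = "dS"`, `value` (dS),
#'   `sites` (synonymous sites S) and `sd_count` (synonymous differences).
#' @export
ng86_ds <- function(aln, seq_b = NULL) {
  if (!inherits(aln, "codon_alignment")) aln <- codon_alignment(aln, seq_b)
  ca <- aln$codons_a
  cb <- aln$codons_b
  if (length(ca) == 0L) stopf("empty codon alignment")
  st <- syn_sites_table()
  S <- (sum(st[ca]) + sum(st[cb])) / 2
  differing <- which(ca != cb)
  Sd <- 0
  for (i in differing) Sd <- Sd + codon_path_counts(ca[i], cb[i])[["sd"]]
  pS <- Sd / S
  if (pS >= 0.75) stopf("NG86 saturation: pS = %.3f >= 3/4", pS)
  ds <- -0.75 * log(1 - (4 / 3) * pS)
  structure(list(kind = "dS", value = ds, P = NA_real_, Q = NA_real_,
                 sites = S, sd_count = Sd),
            class = "divergence_estimate")
}

#' Molecular clock parameters
#'
#' @param mu Substitution rate per base per year (default 2.5e-9).
#' @param generation_time_years Generation time in years (default 3).
#' @return A `clock_params` object.
#' @export
clock_params <- function(mu = 2.5e-9, generation_time_years = 3) {
  stopifnot(mu > 0, generation_time_years > 0)
  structure(list(mu = mu, generation_time_years = generation_time_years),
            class = "clock_params")
}

#' Date a divergence with the molecular clock
#'
#' \eqn{T = K / (2\mu) \times \mathrm{generation\ time}}, reported in
#' million years.
#'
#' @param K Genetic distance (K2P or dS; vectorised, must be >= 0).
#' @param clock A [clock_params].
#' @return Time(s) in million years.
#' @export
divergence_time <- function(K, clock = clock_params()) {
  stopifnot(inherits(clock, "clock_params"))
  if (any(K < 0)) stopf("negative genetic distance")
  K / (2 * clock$mu) * clock$generation_time_years / 1e6
}

#' Date a feature from distance estimates at its ends
#'
#' Each K is dated with [divergence_time()]; the mean and the n-denominator
#' standard deviation over the estimates are returned (for the two flank
#' estimates of an inversion this equals the half-range). A single estimate
#' yields `sd_my = NA` with `sd_defined = FALSE`.
#'
#' @param K_estimates Numeric vector of genetic distances (e.g. K2P at the
#'   two inversion ends, or one per LTR pair).
#' @param clock A [clock_params].
#' @return List with `mean_time_my`, `sd_my`, `sd_defined`, `times_my`.
#' @export
date_feature <- function(K_estimates, clock = clock_params()) {
  if (length(K_estimates) == 0L) stopf("no distance estimates supplied")
  times <- divergence_time(K_estimates, clock)
  m <- mean(times)
  sd_defined <- length(times) >= 2L
  sd_my <- if (sd_defined) sqrt(mean((times - m)^2)) else NA_real_
  list(mean_time_my = m, sd_my = sd_my, sd_defined = sd_defined,
       times_my = times)
}

#' dS landscape along a region
#'
#' Per-gene synonymous divergence with loess smoothing over gene position,
#' and a Kruskal-Wallis comparison of dS inside vs outside a focus interval
#' (e.g. the SDR): a recombination-suppressed interval shows elevated dS
#' relative to its flanks, a still-recombining one does not.
#'
#' @param positions Numeric vector of gene positions (bp), ordered.
#' @param alignments List of [codon_alignment]s, one per gene (or a numeric
#'   vector of precomputed dS values).
#' @param sdr_interval `c(start, end)` in bp.
#' @param span Loess span (default 0.75; tricube weights, degree 2).
#' @return List with `table` (position, ds, smoothed, inside), `H`, `p`.
#' @export
ds_landscape <- function(positions, alignments, sdr_interval, span = 0.75) {
  if (length(positions) < 5L) stopf("need at least 5 genes for a dS landscape")
  if (is.unsorted(positions)) stopf("gene positions must be ordered")
  ds <- if (is.numeric(alignments)) alignments else {
    vapply(alignments, function(a) ng86_ds(a)$value, numeric(1L))
  }
  stopifnot(length(ds) == length(positions))
  inside <- positions >= sdr_interval[1L] & positions <= sdr_interval[2L]
  if (all(inside) || !any(inside)) {
    stopf("all genes fall on one side of the interval; cannot compare")
  }
  fit <- loess(ds ~ positions, span = span, degree = 2,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  smoothed <- predict(fit, positions)
  kw <- kruskal_groups(ds, ifelse(inside, "inside", "outside"))
  list(table = data.frame(position = positions, ds = ds, smoothed = smoothed,
                          inside = inside),
       H = kw$H, p = kw$p)
}
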