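## Sequence-level simulators: codon pairs diverged at a known synonymous
## rate, LTR pairs diverged at a known K2P distance, and promoter groups
## with planted allele-group-specific motifs.

#' Simulate a codon-alignment pair at a known synonymous divergence
#'
#' One sequence of random sense codons; the second is evolved from it by a
#' synonymous-only continuous-time process: each synonymous single-base
#' change of the current codon fires at rate 1/3 per unit time, for a total
#' time of `true_ds` (so the expected number of synonymous substitutions per
#' synonymous site equals `true_ds`). Stop codons can never arise.
#'
#' @param true_ds Target synonymous divergence (below NG86 saturation).
#' @param n_codons Number of codons.
#' @param seed Simulation seed.
#' @return A [codon_alignment]; attribute `"true_ds"` carries the truth.
#' @export
simulate_codon_pairs <- function(true_ds, n_codons, seed = 1L) {
  stopifnot(true_ds >= 0, true_ds < 0.75, is_count(n_codons))
  set.seed(seed)
  nb <- syn_neighbors_table()
  n_nb <- lengths(nb)
  cur <- sample(sense_codons(), n_codons, replace = TRUE)
  seq_a <- paste(cur, collapse = "")
  t_rem <- rep(true_ds, n_codons)
  repeat {
    rate <- n_nb[cur] / 3
    active <- which(rate > 0 & t_rem > 0)
    if (length(active) == 0L) break
    wait <- rexp(length(active), rate[active])
    fires <- wait < t_rem[active]
    t_rem[active] <- t_rem[active] - wait
    t_rem[active][!fires] <- 0
    hot <- active[fires]
    if (length(hot) == 0L) break
    cur[hot] <- vapply(cur[hot], function(c) {
      opts <- nb[[c]]
      opts[sample.int(length(opts), 1L)]
    }, character(1L))
  }
  aln <- codon_alignment(seq_a, paste(cur, collapse = ""),
                         id = sprintf("sim_ds_%g", true_ds))
  attr(aln, "true_ds") <- true_ds
  aln
}

#' Simulate an LTR pair diverged at a known K2P distance
#'
#' The two long terminal repeats start identical (as at insertion) and one
#' accumulates Poisson-distributed substitution events totalling `true_K`
#' per site, with transitions twice as frequent as transversions.
#'
#' @param true_K Target K2P distance (below saturation).
#' @param length_bp Repeat length.
#' @param seed Simulation seed.
#' @return List with `seq_a`, `seq_b`, `true_K`.
#' @export
simulate_ltr_pair <- function(true_K, length_bp, seed = 1L) {
  stopifnot(true_K >= 0, is_count(length_bp))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  anc <- sample(bases, length_bp, replace = TRUE)
  der <- anc
  n_events <- rpois(length_bp, true_K)
  for (i in which(n_events > 0L)) {
    for (e in seq_len(n_events[i])) {
      if (runif(1L) < 2 / 3) {
        der[i] <- transition_of[[der[i]]]
      } else {
        tv <- setdiff(bases, c(der[i], transition_of[[der[i]]]))
        der[i] <- tv[sample.int(2L, 1L)]
      }
    }
  }
  list(seq_a = paste(anc, collapse = ""), seq_b = paste(der, collapse = ""),
       true_K = true_K)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate promoter groups with a planted group-specific motif
#'
#' Random promoters for each allele group; every promoter of
#' `planted_group` receives the motif consensus with its most-upstream base
#' `planted_offset` bp upstream of the TSS. The generator guarantees the
#' postcondition that the motif occurs (at scanning threshold
#' `min_rel_score`) in the designated group only: accidental high-scoring
#' occurrences elsewhere are re-randomized.
#'
#' @param consensus Motif consensus sequence (default a 10-bp MYB-like
#'   site).
#' @param groups Named integer vector group -> number of promoters
#'   (default 4 M, 3 F, 3 H).
#' @param planted_offset Offset of the planted site in bp upstream of the
#'   TSS (default 2104).
#' @param planted_group Group receiving the site (default `"M"`).
#' @param promoter_len Promoter length (default 3000).
#' @param extra_copies Additional copies planted at random offsets in the
#'   designated group (for differential-count scenarios).
#' @param min_rel_score Scanning threshold used for the scrubbing guarantee.
#' @param seed Simulation seed.
#' @return List with `promoters` (data.frame as from
#'   [extract_promoters()]), `pwm` (the planted motif as a [make_pwm()]
#'   object), and `truth`.
#' @export
simulate_promoter_groups <- function(consensus = "TAACGGTCAC",
                                     groups = c(M = 4L, F = 3L, H = 3L),
                                     planted_offset = 2104L,
                                     planted_group = "M",
                                     promoter_len = 3000L,
                                     extra_copies = 0L,
                                     min_rel_score = 0.80, seed = 1L) {
  stopifnot(planted_group %in% names(groups),
            planted_offset >= nchar(consensus),
            planted_offset <= promoter_len)
  set.seed(seed)
  w <- nchar(consensus)
  pwm <- make_pwm(consensus_pfm(consensus), motif_id = "planted")
  plant_at <- function(seq, offset) {
    i <- nchar(seq) - offset + 1L   # most-upstream base `offset` bp upstream
    paste0(substr(seq, 1L, i - 1L), consensus, substr(seq, i + w, nchar(seq)))
  }
  scrub <- function(seq, keep_offsets = integer()) {
    ## re-randomize accidental occurrences so only planted sites score
    repeat {
      h <- scan_pwm(seq, pwm, min_rel_score = min_rel_score)
      h <- h[!(h$upstream_offset %in% keep_offsets), , drop = FALSE]
      if (nrow(h) == 0L) return(seq)
      off <- h$upstream_offset[1L]
      i <- max(1L, nchar(seq) - off + 1L - (w - 1L))
      j <- min(nchar(seq), i + 2L * w)
      seq <- paste0(substr(seq, 1L, i - 1L), random_dna(j - i + 1L),
                    substr(seq, j + 1L, nchar(seq)))
    }
  }
  rows <- list()
  extra_offsets <- list()
  for (g in names(groups)) {
    for (k in seq_len(groups[[g]])) {
      seq <- random_dna(promoter_len)
      keep <- integer()
      if (g == planted_group) {
        seq <- plant_at(seq, planted_offset)
        keep <- planted_offset
        if (extra_copies > 0L) {
          offs <- sample(seq(w, promoter_len, by = 4L * w), extra_copies)
          offs <- offs[abs(offs - planted_offset) > 2L * w]
          for (o in offs) seq <- plant_at(seq, o)
          keep <- c(keep, offs)
          extra_offsets[[paste0(g, k)]] <- offs
        }
      }
      seq <- scrub(seq, keep)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = "focal_gene", haplotype_id = paste0(g, k), group = g,
        sequence = seq, length = nchar(seq), stringsAsFactors = FALSE)
    }
  }
  promoters <- do.call(rbind, rows)
  rownames(promoters) <- NULL
  list(promoters = promoters, pwm = pwm,
       truth = list(consensus = consensus, planted_offset = planted_offset,
                    planted_group = planted_group,
                    extra_offsets = extra_offsets, seed = seed))
}

#' Count matrix for a consensus sequence
#'
#' @param consensus Consensus string (ACGT).
#' @param n_obs Observation count given to the consensus base per column.
#' @return 4 x L count matrix usable by [make_pwm()].
#' @export
consensus_pfm <- function(consensus, n_obs = 20L) {
  chars <- strsplit(toupper(consensus), "")[[1L]]
  stopifnot(all(chars %in% c("A", "C", "G", "T")))
  m <- matrix(0, 4L, length(chars), dimnames = list(c("A", "C", "G", "T")))
  m[cbind(match(chars, rownames(m)), seq_along(chars))] <- n_obs
  m
}
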