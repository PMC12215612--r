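---
title: "Detecting and dating recombination-suppressed sex-determining regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating recombination-suppressed sex-determining regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrkit)
```

sdrkit implements four analyses around plant sex-determining regions (SDRs):
windowed collinearity conservation across a genome panel, linkage-
disequilibrium (LD) landscapes and decay, molecular-clock dating of
haplotype divergence, and promoter motif contrasts between allele groups.
This vignette is the package's account of the models behind each analysis,
the parameters that matter, the numerical and design choices that were
genuinely open, and what the synthetic-data generators do and do not
emulate.

## Collinear blocks and gene windows

### Model

Two annotated haplotypes are compared on *rank* coordinates: the i-th gene
on a contig has rank i - 1, so gene distance is insensitive to intergenic
length. Every homology hit between a reference and a target gene is an
*anchor* at (ref rank, target rank) weighted by its bit score. A collinear
block is a chain of anchors whose ref ranks strictly increase and whose
target ranks strictly increase (plus orientation) or strictly decrease
(minus), with consecutive anchors at most `max_gap + 1` ranks apart on both
genomes. Chains are scored by the sum of anchor bit scores — gap constraints
are hard limits, so no separate gap penalty is applied — and extracted
greedily: the best-scoring chain with at least `min_block_size` anchors is
reported, its anchors retired, and the search repeats per contig pair.

Defaults `min_block_size = 5` and `max_gap = 25` reproduce the MCScanX
`-s5 -m25` regime. MCScanX's `-w1` overlap window has no published
algorithmic definition; we read it conservatively as *single block
membership per anchor*, which the greedy extraction enforces. Tandem
duplicate collapsing is deliberately not performed: duplicates simply
compete as alternative anchors, and at most one copy per reference rank can
enter a chain. The chainer is validated against exhaustive enumeration of
maximal chains on 200 random instances in the test suite; ties between
equal-scoring chains are broken by anchor count, then by the first anchor's
rank pair, identically in both routes.

### Windows, modes, scores

The reference gene order is cut into consecutive, non-overlapping windows of
`window_size = 12` genes per contig; trailing genes that do not fill a
window are dropped so that all windows are directly comparable (a reference
of 27,684 genes in full windows yields exactly 2307 windows). Windows
restart at contig boundaries.

Per target haplotype, a window is assigned either

* **orthologous**: the single block anchoring the greatest number of
  distinct window genes; ties go to the larger summed block bit score, then
  the lexicographically smaller block id; or
* **homologous**: every block anchoring at least `min_window_anchors = 2`
  window genes counts as a region (so WGD and paralogous copies are
  visible). A single-anchor "region" is indistinguishable from a stray hit,
  hence the floor of 2; the parameter is exposed.

Each anchored window gene is scored by `min(1, pair bitscore / reference
self bitscore)`, a quantity in [0, 1] that is 1 for a perfectly conserved
protein. In orthologous mode the best anchor *within the selected block* is
scored (a choice we make; the greatest-bit-score rule is only defined for
the homologous analysis, where partners are pooled across all counted
regions).

Scores are rank-normalized — `(rank - 1)/(n - 1)`, mean ranks for ties,
0.5 for singleton groups — separately within eudicots and within the other
angiosperm clades, which removes the clade-level decay of raw bit-score
ratios with divergence time; non-flowering lineages are kept apart. The
focus window (the SDR) is then compared against all other windows with a
two-group Kruskal–Wallis test on (a) collinear gene counts and (b) mean
normalized scores; for three or more groups Dunn's z with
Benjamini–Hochberg adjustment is exposed (the adjustment method is our
choice; only "adjusted P" is conventionally reported). Degenerate input
(all values identical) reports H = 0, p = 1 with a warning rather than
failing.

## LD machinery

### Filtering

`filter_profile()` encodes a GATK/vcftools/bcftools-style chain: QUAL > 30;
per-sample depth > 5 and at most 3 × the median depth, where the median is
taken over all per-sample DP values of the matrix (one global cap — the
alternative, per-accession medians, changes little on balanced panels and
is harder to reason about); minor allele frequency > 0.05 computed from
genotype codes over non-missing calls; zero missing genotypes; and removal
rules QD < 2, FS > 60, MQ < 40, MQRankSum < -12.5, ReadPosRankSum < -8,
SOR > 3. Records whose INFO metric is absent pass that rule (the behaviour
of the usual filtering tools). For shallow panels an exclusive depth window
replaces the depth rules (`dp_bounds_override = c(1, 15)` keeps DP 2–14).
Rejections are tallied per filter with first-failure attribution in the
order QUAL, depth, MAF, missingness, hard filters. Readers never impute:
missing genotypes survive parsing and are handled here.

### r², decay, landscape

r² is the squared Pearson correlation of genotype codes across samples —
composite LD from unphased data, matching plink's default — for pairs
within `max_dist_bp = 300000`; monomorphic sites are skipped and pairs
sharing fewer than 3 non-missing samples are dropped with a tally. The
plink pair-count window (`-ld-window`) is a compute shortcut, not
statistics, and is not emulated.

Decay is fitted by least squares over ρ in the Hill & Weir (1988)
sample-size-adjusted drift expectation (the formula printed in
`?hill_weir_expectation`). The objective is one-dimensional and smooth, so
a log-grid scan followed by golden-section refinement recovers noiseless
curves to ~10⁻⁸ relative error and is free of starting-value failures. The
*half-decay distance* solves E[r²](d) = E[r²](0)/2 by bisection —
"half of the maximum average r²", the maximum of a monotone curve being its
value at d → 0. When that distance exceeds the largest observed distance
the fit is flagged `no_decay` and a warning is raised.

Landscapes aggregate pairs into 1-kbp bins; a pair contributes its r² to
the bin of *each* endpoint (a one-dimensional projection of the
two-dimensional aggregation used by Tomahawk-style tools), and bins with
fewer than `min_snps = 5` distinct SNPs can be masked. Elevated segments
are recovered by thresholding unmasked bins and taking the contiguous run
(bridging up to `max_bridge` below-threshold bins) with the greatest summed
r²; with the simulator's defaults this reproduces planted boundaries to
about one bin.

The hom-alt/het call ratio is computed per sample in a region; samples with
no heterozygous call report an infinite ratio, flagged, and handled by the
rank-based tests. Heterogametic individuals carrying one diverged sex
haplotype are heterozygous at every sex-diagnostic site, so their ratio
collapses inside a true SDR — the direction the group comparison tests.

## Divergence and dating

K2P distances use the closed form K = -½ln(1-2P-Q) - ¼ln(1-2Q) with sites
carrying ambiguity codes excluded pairwise and explicit saturation errors.
Synonymous divergence uses NG86 (Nei–Gojobori 1986): per-codon synonymous
site fractions averaged over the two sequences, synonymous differences
path-averaged over all orders of the differing positions (paths through
stop codons excluded unless every path is), and Jukes–Cantor correction
dS = -¾ln(1 - 4/3·pS). NG86 rather than the yn00 estimator: yn00's
codon-frequency and ts/tv weighting is a large sub-project, and at the
divergences relevant here (dS ≤ ~0.07) the two agree closely; the package's
recovery tests show NG86 within ~5% of simulated truth at dS 0.01–0.10.
Gapped or ambiguous codon columns are pruned before counting; a terminal
stop codon is tolerated and dropped, an internal one is an error.

The clock is applied exactly as T = K/(2μ) × generation time with defaults
μ = 2.5×10⁻⁹ per site per year and a 3-year generation. The expression
multiplies a per-year rate by a generation time; we follow that arithmetic
as the field uses it for these estimates without asserting a dimensional
interpretation. `date_feature()` averages clock estimates (e.g. the two
flank distances of an inversion) and reports the n-denominator standard
deviation, which for two estimates equals the half-range — the natural
"±" of a two-point estimate; a single estimate flags its sd as undefined.

The dS landscape smooths per-gene dS along the region with loess (span
0.75, degree 2, tricube weights — no span is conventionally reported, so
the loess default is kept and exposed) and compares inside vs outside a
focus interval by Kruskal–Wallis. Segmented-regression breakpoint
estimation is out of scope.

## Promoter scanning

Promoters are the ≤ 3000 bp immediately upstream of the TSS — the annotated
gene start (+) or end (−), reverse-complemented on the minus strand so
position always means "bp upstream of the TSS" — truncated at contig edges.
PWMs come from JASPAR-style count matrices with pseudocount 0.8 and a
uniform background unless given; scores are log₂ odds summed over columns,
reported as relative scores (score - min)/(max - min) with threshold 0.80
(the common scanning default; no published cutoff exists for this analysis)
on both strands.

A site is *group-specific* when every promoter of one allele group has a
hit for the motif within 30 bp of a common offset and no promoter of any
other group has any hit within that window. The 30-bp co-localization
window is an alignment-free surrogate for comparing alignment columns:
promoters here are unaligned, and indel jitter between haplotypes is small
against motif spacing. Differential counts are per-motif mean hits per
promoter per group, reported when one group's mean strictly exceeds all
others.

## What the generators emulate — and what they do not

**Genome panel.** One ancestral gene order evolves independently per
haplotype: per-gene loss with probability 1 - exp(-rate·t), Poisson numbers
of inversions (reversing 5–50-gene segments) and gains, tandem
duplications, and optional WGD duplicating every contig. Bit scores decay
as self·exp(-λt) with small lognormal noise. The planted window's genes
decay *and are lost* (1 - boost) times as fast — a hyper-conserved window
is conserved in content as well as sequence — and are deleted outright in
non-flowering haplotypes, reproducing the presence/absence contrast the
conservation analysis is designed to detect. Default panel: 10 eudicots
(t ∈ 0.3–1), 10 other angiosperms (t ∈ 1–2), 4 non-flowering outgroups
(t ∈ 2.5–3), 2400 genes, window 40 planted with boost 0.9. Not emulated:
real codon evolution behind the bit scores, gene fission/fusion,
tandem-array expansion beyond single duplications, and assembly or
annotation error.

**Population.** Outside the SDR each haplotype is a mosaic of 8 founder
haplotypes with per-bp crossover probability (default 3×10⁻⁴), which gives
distance-decaying composite r²; this is a copying model, not a coalescent —
it produces the right qualitative decay and a controllable planted signal
at desk scale, but no realistic site-frequency spectrum or demography.
Inside the SDR the crossover probability is zero, so each haplotype carries
one intact ancestral SDR haplotype: the M-like haplotype (one copy per
heterogametic sample, alternate alleles at M-specific sites, density
4.5×10⁻³/bp) or one of 4 F-like founders (their polymorphic sites at
1.5×10⁻³/bp). Complete linkage plus the M-diagnostic sites produce the
elevated per-kbp r² and the depressed hom/het ratio in heterogametic
samples that the detection machinery must recover. Default panel: 10
samples (3 female, 3 male, 4 hermaphrodite), a 2-Mbp chromosome with a
150-kbp SDR at 1.20–1.35 Mbp. QUAL, DP and INFO fields are drawn so the
full filter chain is exercised.

**Sequences.** Codon pairs evolve by a synonymous-only continuous-time
process (each synonymous single-base neighbour fires at rate 1/3 per unit
dS), so amino acids never change and stops never arise; LTR pairs evolve
with transitions twice as frequent as transversions so both K2P proportions
are exercised. Promoter groups carry the planted consensus at an exact
offset in the designated group; the generator re-randomizes accidental
high-scoring occurrences elsewhere, making "present only in the designated
group" a guaranteed postcondition rather than a probabilistic one.

Because the generators plant their truth explicitly, passing tests show
that the *machinery* recovers known signals under the stated noise model —
they do not show that real data satisfy that model (real LD landscapes have
heterogeneous recombination and coverage; real conservation scores inherit
annotation quality; real promoters align imperfectly).

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; GFF3 (1-based inclusive) and
  VCF (1-based positions) are converted at the I/O boundary only. Gene rank
  ties at equal start break by end, then gene id.
* The per-query subject cap of a hit table (default 100) applies after the
  e-value cut (default 0.001), ranked by bit score with subject-id
  tie-break, making parsing order-independent.
* Reading a region absent from a VCF warns and returns an empty matrix;
  filtering an empty matrix returns an empty matrix; positions are asserted
  strictly increasing on every read.
* All-identical r² values make the decay fit error out (degenerate);
  saturated K2P/NG86 inputs error rather than returning NaN.
* Seeds: every generator is a pure function of its config including the
  seed; derived seeds are reduced modulo 2³¹ - 19 in double precision to
  stay valid 32-bit integers.

## Problem sizes in the test suite

The suite runs the full machinery at the study scale it is designed for:
the conservation acceptance run uses the default 2400-gene, 24-haplotype
panel; LD checks use 2-Mbp populations (~6000 SNPs) and a three-level
recombination dose; estimator recovery uses 10,000-codon alignments over
10 seeds and 5-kbp LTR pairs over 20 seeds; the chainer equivalence check
enumerates 200 random instances of up to 15 genes per side. The whole suite
completes in about a minute on one CPU.

## Known limitations

* The chainer's greedy extraction is order-dependent by design (best chain
  first); it is not guaranteed to maximize total anchors across all blocks.
* Composite-LD r² from 10 diploids is noisy; half-decay estimates below a
  few hundred bp depend on having many short-range pairs.
* NG86 underestimates dS when synonymous ts/tv bias is strong; for dating
  far beyond dS ≈ 0.1 a codon-model estimator should replace it.
* Group-specific site calling treats promoters as unaligned; sites that
  moved more than the co-localization window between haplotypes are missed.
* The population simulator's SDR has a single M lineage; it cannot emulate
  partial recombination suppression or evolutionary strata.
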