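# sdrkit

Tools for asking, with genomes and resequencing data, the questions that
surround a plant sex-determining region (SDR): *is the region it sits in
anciently conserved in gene content and order? is it recombination-suppressed?
when did its haplotypes stop exchanging? and do its promoter alleles differ
in regulatory potential?* The package grew out of the analysis of the ~200-kbp
grape SDR, whose twelve-gene neighbourhood is collinear across flowering
plants while being absent from non-flowering lineages, and whose M/F
haplotypes stopped recombining tens of millions of years ago.

It is aimed at comparative and population genomicists who have gene
annotations (GFF3), all-vs-all protein hits (DIAMOND/BLAST `outfmt 6`),
genotypes (VCF) and promoter sequences, and want a tested, scriptable
implementation of the following machinery:

**Windowed collinearity conservation.** Collinear gene blocks between a
reference and each target haplotype are chained by dynamic programming from
homologous gene pairs (minimum block size 5 anchors, maximum gap 25 genes,
single block membership per anchor — the MCScanX `-s5 -m25 -w1` regime).
The reference is split into non-overlapping windows of 12 consecutive genes;
each window maps either to the single block covering the most window genes
(*orthologous* windows) or to every block with enough anchors (*homologous*
windows, counting WGD/paralogous copies). Each anchored gene gets a
conservation score

    score = min(1, bitscore(pair) / bitscore(reference self-hit))

which is rank-normalized within clade groups (eudicots vs the other
angiosperm clades) before a focus window — the SDR — is compared against the
genome background with Kruskal–Wallis tests.

**LD landscape and decay.** SNPs pass the standard hard-filter chain
(QUAL > 30, DP > 5 and ≤ 3 × median depth, MAF > 0.05, no missing calls,
QD/FS/MQ/MQRankSum/ReadPosRankSum/SOR cuts; an exclusive low-coverage DP
window is available for shallow panels). Pairwise r² is the squared
genotype-code correlation (plink-style composite LD, pairs within 300 kbp).
LD decay is fitted with the Hill & Weir (1988) drift expectation

    E[r²](C) = (10+C)/((2+C)(11+C)) · [1 + (3+C)(12+12C+C²)/(n(2+C)(11+C))],  C = ρd

and summarized by the half-decay distance (where the fitted curve falls to
half its value at d = 0). Landscapes aggregate r² into 1-kbp bins (masking
bins with < 5 SNPs), elevated segments are recovered by thresholding, and
the per-sample hom-alt/het call ratio contrasts heterogametic against
homogametic individuals (Kruskal–Wallis + BH-adjusted Dunn).

**Divergence dating.** Kimura two-parameter distances, Nei–Gojobori (NG86)
synonymous divergence on codon alignments, and the molecular clock

    T = K / (2μ) × generation time        (μ = 2.5×10⁻⁹ /site/year, g = 3 y)

date inversions (from flank distances), LTR insertions (from LTR pair
divergence) and recombination cessation (from per-gene M/F dS), with a
loess-smoothed dS landscape along the region.

**Promoter motif contrasts.** Promoters (≤ 3 kbp upstream of the TSS,
strand-aware) are scanned with JASPAR-style PWMs (log-odds, relative score
threshold 0.80, both strands) to find binding sites present in *every*
promoter of one allele group and absent from all others — the signature of
an M-specific regulatory site — plus differential site counts per motif.

**Synthetic data with ground truth.** Generators emulate every input: a
clade-structured genome panel evolved from one ancestral gene order
(inversions, losses, gains, tandem duplications, WGD, bit scores decaying
with divergence time, one planted hyper-conserved window that is deleted in
non-flowering lineages); a diploid population with background recombination
and a planted non-recombining sex region; codon pairs at known dS; LTR pairs
at known K; and promoter groups with planted motifs. Truth travels with
every dataset, so the whole pipeline is testable offline.

## Worked example

Simulate a small panel (8 angiosperm + 2 non-flowering haplotypes, 480
genes, a hyper-conserved window planted at index 10), run synteny and window
conservation, and date a divergence:

```r
library(sdrkit)

cfg <- genome_sim_config(n_genes = 480, n_contigs = 2,
                         haplotypes = default_haplotype_panel(4, 4, 2, 1, seed = 7),
                         planted_window = list(index = 10, boost = 0.9),
                         seed = 7)
sim <- simulate_genome_set(cfg)
windows <- make_windows(sim$ref)          # 40 windows of 12 genes
assignments <- list(); clade_of <- character()
for (id in names(sim$targets)) {
  blocks <- detect_collinear_blocks(sim$ref, sim$targets[[id]], sim$hits[[id]])
  assignments[[id]] <- assign_orthologous(windows, blocks,
                                          sim$hits[[id]]$self_scores, id)
  clade_of[id] <- sim$targets[[id]]$clade
}
summ <- summarize_conservation(assignments, clade_of, focus_window = 10)
head(summ$window_stats[order(-summ$window_stats$mean_norm_score), ], 3)
#>    window_index mean_count mean_norm_score
#> 10           10     12.000       0.9871373
#> 19           19     11.125       0.5259545
#> 29           29     11.375       0.5117232
summ$tests$scores
#> H = 23.3, p = 1.4e-06
divergence_time(0.0230)       # dS -> million years under the default clock
#> [1] 13.8
```

The planted window ranks first on mean rank-normalized conservation
(0.987 vs ≈ 0.5 background), stays fully collinear (12/12 genes, vs ~11 for
background windows that suffered losses and inversions), and separates from
the background at p ≈ 10⁻⁶; a synonymous divergence of 0.0230 dates to
13.8 My under the default clock.

Each analysis is also runnable from a shell via the thin dispatcher in
`inst/cli/sdrkit` (subcommands `simulate`, `synteny-windows`, `ld-scan`,
`date`, `tfbs`, each driven by a YAML config; see `?run_simulate` and
friends).

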