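---
title: "Discovering UGA-recoded endosymbiont genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering UGA-recoded endosymbiont genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opalscan)
```

## The problem

Bacteria with extremely reduced genomes (roughly 100–200 kb) occur only as
obligate intracellular symbionts. Some of them abandon the opal stop codon:
under NCBI translation table 4, TGA encodes tryptophan, and only TAA/TAG
terminate translation. A genome written in code 4 but annotated under the
standard bacterial table 11 appears riddled with premature stops — so its
apparent coding density is far below the 90–97% typical of bacteria.
Re-reading the same sequence under table 4 restores long open reading
frames. That contrast is a usable discovery signal: scanning assembled
metagenome contigs for sequences whose coding potential jumps under table 4
surfaces candidate recoded genomes without any reference database, and the
candidates can then be tied to a eukaryotic host by abundance co-occurrence
across samples.

`opalscan` implements this discovery analysis end to end, together with a
synthetic-community generator that provides ground truth for every stage.

## Recoding score

For a contig the package calls, in all six frames, every maximal ORF — from
the first start codon (ATG/GTG/TTG) after the previous in-frame stop
through the next in-frame stop — under both tables, and computes

* `d11`, `d4`: the fraction of contig positions covered by the union of
  ORF intervals (both strands) under tables 11 and 4;
* `delta = d4 - d11`;
* `merged_pairs`: table-11 ORF pairs of the same strand and frame nested
  inside a single table-4 ORF — TGA-split gene fragments that fuse when
  TGA is read as tryptophan.

A contig is a candidate when `d4 >= d4_min`, `delta >= delta_min` and
`merged_pairs >= min_merged_pairs` (default 1).
Because tables 4 and 11 differ only at TGA, `delta` is exactly zero for
any contig with no TGA triplet in any frame, and is structurally
non-negative: removing a stop codon can only lengthen or merge ORFs.

The merged-pair requirement is the mechanistic half of the signal. On
short contigs (roughly 2–5 kb) random sequence occasionally reaches
`d4 >= 0.85` and a large `delta` purely through spurious ORF extension —
the union-of-six-frames density proxy is noisy at that scale — but such
chance candidates essentially never contain a fused stop (observed
merged-pair counts on random kb-scale contigs: median 0, 99th percentile
1), whereas genuinely recoded genomes fuse many ORF pairs (10+ even for a
15-gene organelle-sized genome at 1–1.5% interior TGA). Requiring at
least one fused pair therefore removes the density-noise false positives
without costing sensitivity; `min_merged_pairs = 0` restores the pure
density rule.

**Thresholds.** The defaults `d4_min = 0.85` and `delta_min = 0.10` were
fixed from first principles before looking at simulation outcomes: real
bacterial genomes exceed 85% coding density while eukaryotic and random
sequence falls far below; and at ~1% interior TGA per codon a code-4 genome
read under table 11 loses well over 10% of its coding cover, while a
TGA-free genome gains well under 2% from spurious-ORF extension. On the
generator's default classes the observed margins are wide (code-4 deltas
~0.15–0.25 against code-11 deltas ~0.005).

**ORF-caller choices.** The minimum ORF length defaults to 150 nt
(configurable 90–300). Codons containing N are neither start nor stop and
translate to X. Nested and overlapping ORFs are all retained: the score is
a union measure, so no gene selection heuristic is needed, and the caller
stays exactly reproducible — unlike trained gene finders, whose scores
depend on model versions. The cost is that `merged_pairs` counts ORFs, not
curated genes; on a default synthetic symbiont it is of the same order as,
but not equal to, the number of planted TGA-interrupted genes.

## Triage: organelle markers and circularity

Mitochondria also use TGA-to-Trp codes and chloroplast sequence co-occurs
with eukaryote hosts, so both are false-positive sources. The screen
excludes any candidate whose marker-hit table (produced externally, e.g.
by homology annotation) matches a configurable organelle vocabulary —
multi-subunit NADH dehydrogenase / cytochrome oxidase labels
(mitochondrion-like) or photosystem/photosynthesis labels
(chloroplast-like). Candidates with no marker rows pass: absence of
evidence is not grounds for exclusion at this stage.

An assembled circular genome appears as a contig whose two ends repeat
exactly. `detect_terminal_overlap()` reports the largest `k` with
`k_min <= k <= L/2` whose length-`k` prefix and suffix are identical,
computed from the sequence's border (failure) function in linear time.
Overlaps are exact by design — the assembler copied the sequence, so
mismatch tolerance would only admit spurious repeats; `k_min` defaults to
50 nt, far above the ~1/4^20 chance level for 20 nt at these contig
lengths. Trimming removes one copy; `canonical_rotation()` then maps the
circle to the lexicographically smallest string over all rotations of both
strands, the unique representative invariant to rotation and strand choice
(computed with Booth's least-rotation algorithm).

## Genome characterization

`genome_stats()` reports the statistics used to recognize reduced genomes:

* **Coding density**, as union coverage of features divided by genome
  length — over all feature types (CDS, rRNA, tRNA, tmRNA) and over CDS
  only. RNA genes are accepted from external prediction; the pipeline
  itself supplies table-4 ORFs as CDS.
* **Overlapping gene pairs**: pairs of features sharing at least one
  position, regardless of strand or type — a count, matching how such
  numbers are reported for reduced genomes.
* **Intergenic lengths**: the lengths of maximal genomic segments covered
  by no feature; on circular genomes the segment spanning the origin is a
  single gap.
* **Isoelectric points**: per protein, the pH at which the
  Henderson–Hasselbalch net charge (positive groups: N-terminus, K, R, H;
  negative: C-terminus, D, E, C, Y) is zero, found by bisection on
  [0, 14] continued to a 1e-7 pH bracket (the |charge| < 1e-4 criterion
  alone leaves visible slack on near-neutral, flat titration curves). The
  pKa set is explicit and swappable; the default is the EMBOSS set
  (N-term 8.6, C-term 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5,
  Y 10.1), since published pI calculators support many sets and results
  are only comparable when the set is declared. The mean proteome pI is
  the unweighted arithmetic mean over proteins. AT-rich reduced genomes
  skew strongly basic (lysine- and isoleucine-rich codons), which the
  synthetic symbiont reproduces (mean pI ≈ 9.4).

## Host attribution from compositional abundances

Per-sample bin abundance is the sum over the bin's contigs of contig
length × mean depth. Such abundances are compositional: only relative
information survives sequencing, and naive correlations on proportions are
spurious. The package implements the SparCC estimator (Friedman & Alm
2012): for bins *i*, *j* the log-ratio variance
`t_ij = var(log(x_i/x_j))` is closure-invariant and satisfies
`t_ij = w_i + w_j - 2 r_ij sqrt(w_i w_j)` for basis variances `w` and
basis correlations `r`. Assuming most pairs are uncorrelated (sparsity),
the `w` solve a linear system in the row sums of `t`; the strongest
correlated pair above `exclusion_threshold` (default 0.1) is then
iteratively removed from the system and the solution refined, up to
`max_iterations` (default 10, the published defaults). Per-component
exclusions are capped at D−3 pairs so the system stays non-singular, and
non-positive basis-variance estimates are floored at the smallest positive
estimate.

Fraction uncertainty is integrated out by Dirichlet resampling, and the
reported correlation is the element-wise median over resamples (default
20), clipped to [−1, 1]. Two numerical choices matter:

* **Per-sample renormalization.** Each sample is renormalized to a fixed
  effective depth (`prior_depth`, default 1000) before the +1 Dirichlet
  prior is applied. Raw length-weighted abundances have arbitrary
  per-sample scale, so a prior on raw values would make results depend on
  sequencing effort; after renormalization the fit is exactly invariant
  (to machine precision, with a fixed seed) under per-sample rescaling.
* **Point-estimate mode.** `n_dirichlet_resamples = 0` uses plain
  fractions, with the pseudocount applied only to true zeros, preserving
  exact proportionality relations — useful for noise-free checks.

Significance comes from permutations: sample labels are shuffled
independently per bin, the full estimator re-run, and
`p = (1 + #(|rho_perm| >= |rho_obs|)) / (1 + n_permutations)`. The
smallest attainable value is `1/(n_permutations + 1)`; a "p = 0" from
permutation schemes is reported as that floor, never literal zero.
`attribute_host()` ranks bins with `rho >= rho_min` (default 0.8) and
`p <= alpha` (default 0.01), ties broken by bin label.

Small problems (≲ 10 bins or ≲ 15 samples) leave the basis solve noisy
and the permutation null heavy-tailed; the estimator needs the study's
scale (≈ 20+ bins, ≈ 29 samples) for calibrated p-values, and `sparcc()`
refuses fewer than 4 bins outright.

## The synthetic-data generator

`generate_genome()` writes a genome gene by gene: a start codon
(ATG 80% / GTG 15% / TTG 5%), interior codons drawn from a codon
distribution conditioned on a per-base GC probability, and a TAA/TAG stop.
Under code 4 each interior codon is independently replaced by TGA
(tryptophan) with probability `tga_trp_rate`. The per-base GC probability
is calibrated by root-finding so the interior-codon mixture realizes
`gc_target`; unreachable targets (e.g. 0, with start codons required) are
rejected as invalid specs. Gene lengths are gamma-distributed
(CV ≈ 1/3), intergenic gaps geometric, strands random, and circularity is
emulated by appending an exact copy of the first `circular_overlap_len`
bases. Everything is deterministic given the spec's seed.

Defaults emulate the discovered class of genome: 160 genes of mean 900 nt,
30 nt mean gaps (coding density ≈ 0.95 by truth annotation), GC 0.32, 1%
interior TGA, and a 100-nt terminal overlap — a ~150 kb circular genome.
Background genomes are code-11, 30 genes each (a representative contig per
bin rather than a full genome, which keeps a 20-bin community at desk
scale), GC spread over 0.30–0.60, 100 nt gaps.

`generate_community()` adds a eukaryote-like host bin (12 contigs of
random, low-coding-density sequence, GC 0.38, mean 4 kb with a 2.5 kb
floor — the usual binning cutoff, so host bins never contain contigs a
binner would have discarded), two organelle decoys — a
mitochondrion-like code-4 genome carrying NADH dehydrogenase and
cytochrome c oxidase marker labels, and a chloroplast-like code-11 genome
carrying a photosystem label — and the abundance model: host and symbiont
per-sample log-abundances are bivariate normal with correlation
`rho_true` (default 0.9) and unit log-variance, all other bins
independent; abundances are closed to sum 1 per sample; contig coverage
is the bin's relative abundance × `depth_scale` × multiplicative
lognormal noise (sd 0.2, the standard model for depth variation — it
keeps coverage positive).

**What the generator does not emulate**, and hence what passing tests do
not show about real data: assembly artifacts and chimerism; strain
variation; genomes using TGA stop codons (generated gene stops are
TAA/TAG under both codes — real code-11 genomes terminate a quarter or
more of their genes with TGA, which adds a small positive delta, ~0.02–
0.04 at these genome sizes, still far from `delta_min`); codon-usage
structure beyond GC (no amino-acid frequency model, no hexamer bias); RNA
genes; and read-level sampling (coverage noise is lognormal, not
Poisson-binomial from mapping).

## Problem sizes and degenerate inputs

The shipped tests and the acceptance script run entirely on synthetic
communities: discovery checks use the default community (about 35 contigs,
24 bins, 29 samples) across tens of seeds, correlation-recovery checks use
21-bin/29-sample communities across 50 seeds, and oracle comparisons use
hundreds of random sequences of 1–10 kb — sizes chosen so every stage is
exercised at the study's design points while a full run stays in the
minutes range. Contigs under 1 kb are reported unevaluable rather than
scored; empty ORF sets give coding fraction 0; bins absent from the bin
table are pooled as "unassigned"; bins with all-zero abundance are dropped
with a warning before inference.

## Known limitations

* The coding-potential proxy is ORF-union density, not a trained gene
  caller's total coding score; absolute densities differ from annotation
  pipelines even though the code-4/code-11 contrast is preserved.
* Only the TGA→Trp (opal) reassignment is wired into the pipeline,
  though `score_recoding()`'s machinery accepts any pair of tables that
  differ at one codon family (amber/ochre searches would need analogous
  generator support to be testable).
* Detection rests on coding-density contrast alone; tRNA evidence (e.g. a
  tRNA-Trp with a UGA-reading anticodon) is annotation outside this
  package's scope.
* The organelle screen consumes an externally produced marker table; no
  homology search is performed.
* Permutation p-values re-run the full estimator per permutation; at 999
  permutations on large communities this is the dominant cost.
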