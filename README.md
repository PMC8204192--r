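# opalscan

Discovery of UGA-to-Trp recoded endosymbiont genomes in metagenome
assemblies, and attribution of their eukaryotic hosts.

## The problem

The smallest bacterial genomes (~100–200 kb) belong to obligate
intracellular symbionts, and some of them switch to genetic code 4, in
which the opal stop codon UGA encodes tryptophan. Annotated under the
standard bacterial code (table 11), such a genome looks shredded by
premature stops; re-read under table 4 its open reading frames snap back
together. `opalscan` turns that contrast into a reference-free screen for
novel endosymbionts in assembled metagenomes, for microbial ecologists and
genome miners working with binned assemblies and per-sample coverage
tables.

The pipeline: **scan** every contig for recoding, **screen** out
organelle look-alikes by marker hits, detect assembled **circles** from
exact terminal overlaps, characterize the candidate genome
(**coding density**, gene overlap, intergenic gaps, proteome pI), and
attribute a host by **compositional co-occurrence** of bin abundances
across samples.

## The statistics at the core

* **Recoding score.** For contig *c* with ORF sets `O_t` called under
  translation table *t* (all six frames, start codons ATG/GTG/TTG,
  minimum length 150 nt), the coding fraction is
  `d_t = |union of O_t| / L`, and the score is `delta = d4 − d11`, with
  candidacy when `d4 ≥ 0.85` and `delta ≥ 0.10`. Tables 4 and 11 differ
  only at TGA, so `delta = 0` exactly for TGA-free sequence and `delta`
  is structurally non-negative.
* **Basis correlations (SparCC).** Per-sample bin abundance
  `A[b,s] = Σ_contigs length × depth` is compositional, so correlations
  are estimated from closure-invariant log-ratio variances
  `t_ij = var log(x_i/x_j) = w_i + w_j − 2 ρ_ij √(w_i w_j)` under a
  sparsity assumption, with iterative exclusion of strongly correlated
  pairs, Dirichlet resampling of fractions, and permutation p-values
  `p = (1 + #{|ρ_perm| ≥ |ρ_obs|}) / (1 + n_perm)`.

A synthetic-community generator with full ground truth (recoded symbiont,
code-11 backgrounds, eukaryote-like host bin, organelle decoys, correlated
lognormal abundances) makes every stage testable offline.

## Worked example

```r
library(opalscan)

com  <- generate_community(seed = 42)          # 35 contigs, 24 bins, 29 samples
scan <- scan_contigs(com$sequences) |>
  screen_organelle_markers(com$markers)
dplyr::filter(scan, candidate | !is.na(excluded_reason))
#>   contig_id     length    gc   d11    d4 delta merged_pairs candidate excluded_reason
#> 1 symbiont_c1   148445 0.318 0.769 0.984 0.215          128 TRUE      <NA>
#> 2 decoy_mito_c1  16079 0.294 0.620 0.974 0.353           19 FALSE     organelle-like
```

The implanted symbiont's coding fraction jumps from 0.77 (table 11) to
0.98 (table 4): 128 ORF pairs fuse when TGA is read as tryptophan. The
mitochondrion-like decoy also scores as recoded — mitochondria genuinely
use TGA-to-Trp codes — and is excluded by its NADH dehydrogenase /
cytochrome oxidase marker hits.

```r
detect_terminal_overlap(com$sequences[["symbiont_c1"]], k_min = 50)
#>   contig_id   length overlap_len is_circular trimmed_length
#> 1 symbiont_c1 148445         100 TRUE                148345
```

The candidate carries an exact 100-nt terminal repeat: an assembled
circle; trimming one copy gives the 148,345-bp circular genome.

```r
A   <- bin_abundance(com$coverage, com$bins,
                     setNames(nchar(com$sequences), names(com$sequences)))
fit <- sparcc(A, seed = 42) |> sparcc_pvalues(n_permutations = 99, seed = 42)
attribute_host(fit, "bin_symbiont", rho_min = 0.5, alpha = 0.05)
#>   bin_id     rho  pval
#> 1 bin_host 0.839  0.01
```

Across the 29 samples the symbiont's abundance tracks the host bin with
basis correlation 0.84 at the permutation floor p = 0.01 — the host bin is
the only bin passing the attribution thresholds (true log-space
correlation in this simulation: 0.9).

```r
genome <- trim_terminal_overlap(com$sequences[["symbiont_c1"]])
orfs   <- call_orfs(genome, genetic_code(4), 150)
feats  <- tibble::tibble(type = "CDS", start = orfs$start,
                         end = orfs$end, strand = orfs$strand)
genome_stats(genome, feats, circular = TRUE)
#> <genome_stats> 148345 bp | GC 0.318 | density 0.985 (all) 0.985 (CDS) |
#>   576 overlapping pairs | mean pI 9.25
```

A ~148-kb, GC 32%, densely coded genome with a strongly alkaline proteome
— the signature of extreme genome reduction. `run_discovery()` chains all
of the above into one deterministic JSON report;
`vignette("recoding-discovery")` documents the models, parameters and
design choices.

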