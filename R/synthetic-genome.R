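#' Specification of a synthetic genome
#'
#' Parameter bundle consumed by [generate_genome()].  The defaults emulate a
#' tiny UGA-recoded endosymbiont genome: ~160 genes of ~900 nt, ~30 nt
#' intergenic gaps (coding density ~0.95), GC 0.32, about 1% of gene codons
#' written as TGA tryptophans, and a 100-nt exact terminal overlap marking an
#' assembled circle.
#'
#' @param genome_id Label used for the emitted contig.
#' @param code_id Genetic code the genome is written in: 4 (TGA = Trp) or 11.
#' @param n_genes Number of protein-coding genes.
#' @param mean_gene_len Mean gene length, nucleotides.
#' @param mean_intergenic_len Mean intergenic gap, nucleotides.
#' @param gc_target Target genomic GC fraction in \[0, 1\].
#' @param tga_trp_rate Per-codon probability that an interior gene codon is
#'   written as TGA (tryptophan).  Only meaningful under code 4; forced to 0
#'   under code 11, where TGA is a stop.
#' @param circular_overlap_len Length of the exact terminal repeat appended
#'   to simulate an assembled circular genome; 0 for a linear contig.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return Object of class `genome_spec`.
#' @export
genome_spec <- function(genome_id = "symbiont", code_id = 4, n_genes = 160,
                        mean_gene_len = 900, mean_intergenic_len = 30,
                        gc_target = 0.32, tga_trp_rate = 0.01,
                        circular_overlap_len = 100, seed = 1) {
  if (!code_id %in% c(4, 11)) stop("code_id must be 4 or 11")
  if (gc_target < 0 || gc_target > 1) stop("gc_target must lie in [0, 1]")
  if (tga_trp_rate < 0 || tga_trp_rate > 1) {
    stop("tga_trp_rate must lie in [0, 1]")
  }
  if (code_id == 11) tga_trp_rate <- 0
  if (n_genes < 1 || mean_gene_len < 60 || mean_intergenic_len < 0 ||
      circular_overlap_len < 0) {
    stop("n_genes, mean_gene_len must be positive (gene length >= 60); ",
         "intergenic and overlap lengths must be non-negative")
  }
  structure(
    list(genome_id = genome_id, code_id = as.integer(code_id),
         n_genes = as.integer(n_genes), mean_gene_len = mean_gene_len,
         mean_intergenic_len = mean_intergenic_len, gc_target = gc_target,
         tga_trp_rate = tga_trp_rate,
         circular_overlap_len = as.integer(circular_overlap_len),
         seed = as.integer(seed)),
    class = "genome_spec"
  )
}

# Codon sampling weights conditioned on a per-base GC probability p:
# weight(codon) = prod over bases of p/2 (G or C) or (1-p)/2 (A or T).
codon_weights <- function(codons, p) {
  gc_n <- vapply(strsplit(codons, ""), function(b) sum(b %in% c("G", "C")), 0L)
  (p / 2)^gc_n * ((1 - p) / 2)^(3 - gc_n)
}

# Solve for the per-base GC probability whose interior-codon distribution
# (background codons mixed with forced TGAs at rate r) realizes gc_target.
calibrate_gc <- function(allowed, gc_target, tga_rate) {
  gc_of <- function(cod) {
    vapply(strsplit(cod, ""), function(b) sum(b %in% c("G", "C")), 0L) / 3
  }
  expected_gc <- function(p) {
    w <- codon_weights(allowed, p)
    bg <- sum(w * gc_of(allowed)) / sum(w)
    (1 - tga_rate) * bg + tga_rate * (1 / 3)
  }
  lo <- expected_gc(1e-4); hi <- expected_gc(1 - 1e-4)
  if (gc_target < lo - 1e-6 || gc_target > hi + 1e-6) {
    stop("invalid-spec: gc_target ", gc_target,
         " is unreachable given the required start/stop codons (attainable ",
         "range ", signif(lo, 3), "-", signif(hi, 3), ")")
  }
  stats::uniroot(function(p) expected_gc(p) - gc_target,
                 c(1e-4, 1 - 1e-4), tol = 1e-9)$root
}

#' Generate a synthetic genome with known gene truth
#'
#' Builds a genome gene by gene and codon by codon: each gene starts with a
#' start codon (ATG/GTG/TTG), continues with interior codons drawn from a
#' GC-calibrated codon distribution that excludes the code's stop codons,
#' and terminates with a stop codon of the code.  Under code 4 each interior
#' codon is independently written as TGA (tryptophan) with probability
#' `tga_trp_rate`.  Genes are placed on random strands and separated by
#' random intergenic sequence; an exact copy of the first
#' `circular_overlap_len` bases is appended to emulate an assembled circle.
#'
#' By construction every gene is a valid ORF under the spec's code (no
#' interior stop); code-11 genomes contain no in-frame interior TGA in any
#' gene.
#'
#' @param spec A [genome_spec()].
#' @return Object of class `synthetic_genome`: list with `sequence`
#'   (character), `genes` (tibble of 0-based half-open forward-strand gene
#'   coordinates with `strand`, `n_interior_codons`, `n_tga`), `gc`
#'   (realized), and the `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, generate_genome_impl(spec))
}

generate_genome_impl <- function(spec) {
  code <- genetic_code(spec$code_id)
  all64 <- names(code$codons)
  # gene stops restricted to TAA/TAG under both codes: code 4 has no other
  # stop, and under code 11 this keeps TGA out of genes entirely so the
  # null class of the recoding contrast is clean (see methods vignette)
  stops <- intersect(c("TAA", "TAG"), code$stop_codons)
  allowed <- setdiff(all64, c(code$stop_codons, "TGA"))
  p <- calibrate_gc(allowed, spec$gc_target, spec$tga_trp_rate)
  w_int <- codon_weights(allowed, p)
  w_stop <- codon_weights(stops, p)

  mean_cod <- spec$mean_gene_len / 3
  n_cod <- pmax(20L, as.integer(round(
    stats::rgamma(spec$n_genes, shape = 9, rate = 9 / mean_cod))))
  gaps <- stats::rgeom(spec$n_genes, 1 / (1 + spec$mean_intergenic_len))
  strands <- sample(c("+", "-"), spec$n_genes, replace = TRUE)

  intergenic <- function(n) {
    if (n == 0L) return("")
    paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                 prob = c((1 - spec$gc_target) / 2, (1 - spec$gc_target) / 2,
                          spec$gc_target / 2, spec$gc_target / 2)),
          collapse = "")
  }

  pieces <- character(2L * spec$n_genes)
  g_start <- g_end <- n_int_v <- n_tga_v <- integer(spec$n_genes)
  at <- 0L
  for (i in seq_len(spec$n_genes)) {
    gap <- intergenic(gaps[i])
    n_int <- n_cod[i] - 2L
    interior <- sample(allowed, n_int, replace = TRUE, prob = w_int)
    n_tga <- 0L
    if (spec$tga_trp_rate > 0 && n_int > 0L) {
      hit <- stats::runif(n_int) < spec$tga_trp_rate
      interior[hit] <- "TGA"
      n_tga <- sum(hit)
    }
    gene <- paste(c(
      sample(code$start_codons, 1L, prob = c(0.8, 0.15, 0.05)),
      interior,
      sample(stops, 1L, prob = w_stop)), collapse = "")
    if (strands[i] == "-") gene <- revcomp(gene)
    g_start[i] <- at + nchar(gap)
    g_end[i] <- g_start[i] + 3L * n_cod[i]
    n_int_v[i] <- n_int
    n_tga_v[i] <- n_tga
    pieces[2L * i - 1L] <- gap
    pieces[2L * i] <- gene
    at <- g_end[i]
  }
  genes <- tibble::tibble(
    gene_id = sprintf("%s_g%03d", spec$genome_id, seq_len(spec$n_genes)),
    start = g_start, end = g_end, strand = strands,
    n_interior_codons = n_int_v, n_tga = n_tga_v
  )
  sequence <- paste(pieces, collapse = "")
  if (spec$circular_overlap_len > 0L) {
    if (spec$circular_overlap_len > nchar(sequence) %/% 2L) {
      stop("invalid-spec: circular_overlap_len exceeds half the genome length")
    }
    sequence <- paste0(sequence,
                       substr(sequence, 1L, spec$circular_overlap_len))
  }
  structure(
    list(sequence = sequence, genes = genes,
         gc = gc_fraction(sequence), spec = spec),
    class = "synthetic_genome"
  )
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome>", x$spec$genome_id,
      "| code", x$spec$code_id,
      "|", nchar(x$sequence), "bp |", nrow(x$genes), "genes | GC",
      sprintf("%.3f", x$gc), "\n")
  invisible(x)
}
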