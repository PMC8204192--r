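FEATURE_TYPES <- c("CDS", "rRNA", "tRNA", "tmRNA")

check_features <- function(features, genome_length = NULL) {
  stopifnot(all(c("start", "end", "type") %in% names(features)))
  if (!all(features$type %in% FEATURE_TYPES)) {
    stop("feature types must be one of: ", paste(FEATURE_TYPES, collapse = ", "))
  }
  if (any(features$end <= features$start)) {
    stop("features must have end > start (0-based half-open)")
  }
  if (!is.null(genome_length) &&
      (any(features$start < 0) || any(features$end > genome_length))) {
    stop("features fall outside [0, genome_length)")
  }
  invisible(features)
}

#' Coding density of a genome
#'
#' Fraction of genome positions covered by the union of the selected
#' feature types.  The "all genes" density of a reduced genome uses CDS
#' plus rRNA, tRNA and tmRNA genes; the CDS-only density uses `types =
#' "CDS"`.  Overlapping features are counted once.
#'
#' @param features Feature tibble with columns `type` (one of CDS, rRNA,
#'   tRNA, tmRNA), `start`, `end` (0-based half-open).
#' @param genome_length Genome length in bp (> 0).
#' @param types Feature types included in the union.
#' @return Fraction in \[0, 1\].
#' @examples
#' f <- tibble::tibble(type = c("CDS", "tRNA"), start = c(0, 40),
#'                     end = c(50, 60))
#' coding_density(f, 100)            # 0.6 (union, not sum)
#' coding_density(f, 100, "CDS")     # 0.5
#' @export
coding_density <- function(features, genome_length, types = FEATURE_TYPES) {
  if (genome_length <= 0) stop("genome_length must be > 0")
  check_features(features, genome_length)
  sel <- features[features$type %in% types, , drop = FALSE]
  if (nrow(sel) == 0L) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = sel$start + 1L,
                                         end = sel$end))
  sum(IRanges::width(ir)) / genome_length
}

#' Overlapping gene pairs and intergenic gap lengths
#'
#' Two features overlap when they share at least one genomic position,
#' regardless of strand or type.  Intergenic lengths are the lengths of the
#' maximal genomic segments not covered by any feature; for a circular
#' genome the segment spanning the origin (after the last feature, before
#' the first) is reported as a single gap.
#'
#' @param features Feature tibble (`type`, `start`, `end`; 0-based
#'   half-open).
#' @param genome_length Genome length in bp.
#' @param circular Close the last-to-first gap around the origin.
#' @return List with `n_overlapping_pairs` (integer) and
#'   `intergenic_lengths` (integer vector).
#' @export
overlap_and_intergenic <- function(features, genome_length,
                                   circular = FALSE) {
  check_features(features, genome_length)
  if (nrow(features) == 0L) {
    return(list(n_overlapping_pairs = 0L,
                intergenic_lengths = as.integer(genome_length)))
  }
  ir <- IRanges::IRanges(start = features$start + 1L, end = features$end)
  hits <- IRanges::findOverlaps(ir, minoverlap = 1L,
                                drop.self = TRUE, drop.redundant = TRUE)
  n_pairs <- length(hits)

  gaps_ir <- IRanges::gaps(IRanges::reduce(ir), start = 1L,
                           end = genome_length)
  gaps <- IRanges::width(gaps_ir)
  if (circular && length(gaps) >= 1L) {
    head_gap <- IRanges::start(gaps_ir) == 1L
    tail_gap <- IRanges::end(gaps_ir) == genome_length
    if (any(head_gap) && any(tail_gap) && length(gaps) >= 2L) {
      joined <- gaps[head_gap] + gaps[tail_gap]
      gaps <- c(gaps[!(head_gap | tail_gap)], joined)
    }
  }
  list(n_overlapping_pairs = n_pairs,
       intergenic_lengths = as.integer(gaps))
}

#' Read a feature table from GFF3
#'
#' Extracts CDS/rRNA/tRNA/tmRNA features from a GFF3 file into the tibble
#' layout [genome_stats()] consumes, converting the 1-based inclusive GFF3
#' coordinates to 0-based half-open.
#'
#' @param path GFF3 file.
#' @param types Feature types kept.
#' @return Tibble: `feature_id`, `type`, `start`, `end`, `strand`.
#' @export
read_features_gff3 <- function(path, types = FEATURE_TYPES) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(f, length, 0L) < 8L
  if (any(bad)) stop("malformed GFF3 row(s) in ", path)
  tab <- tibble::tibble(
    type = vapply(f, `[[`, "", 3L),
    start = as.integer(vapply(f, `[[`, "", 4L)) - 1L,
    end = as.integer(vapply(f, `[[`, "", 5L)),
    strand = vapply(f, `[[`, "", 7L)
  )
  tab <- tab[tab$type %in% types, , drop = FALSE]
  tab$feature_id <- sprintf("feat_%04d", seq_len(nrow(tab)))
  tab[, c("feature_id", "type", "start", "end", "strand")]
}

#' EMBOSS pKa set for isoelectric-point calculation
#'
#' Named vector of pKa values: `Nterm`, `Cterm` and the ionizable side
#' chains C, D, E, H, K, R, Y.
#'
#' @return Named numeric vector.
#' @export
pka_emboss <- function() {
  c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
    H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
}

#' Isoelectric point of a protein
#'
#' Finds the pH at which the Henderson--Hasselbalch net charge of the
#' protein is zero, by bisection on \[0, 14\] to |charge| < 1e-4.
#' Positively ionizable groups: N-terminus, K, R, H; negatively ionizable:
#' C-terminus, D, E, C, Y.  The pI depends only on residue composition,
#' not order; `X` and unknown residues carry no charge.
#'
#' @param protein Amino-acid string (one-letter codes; terminal `*`
#'   stripped).
#' @param pka Named pKa vector, default [pka_emboss()].
#' @return pI in \[0, 14\].
#' @examples
#' isoelectric_point("GGGG")  # 6.10: midpoint of the two termini pKas
#' @export
isoelectric_point <- function(protein, pka = pka_emboss()) {
  protein <- gsub("\\*+$", "", toupper(protein))
  if (nchar(protein) == 0L) stop("empty protein sequence")
  aa <- strsplit(protein, "")[[1]]
  n_pos <- c(Nterm = 1, K = sum(aa == "K"), R = sum(aa == "R"),
             H = sum(aa == "H"))
  n_neg <- c(Cterm = 1, D = sum(aa == "D"), E = sum(aa == "E"),
             C = sum(aa == "C"), Y = sum(aa == "Y"))
  charge <- function(ph) {
    pos <- sum(n_pos / (1 + 10^(ph - pka[names(n_pos)])))
    neg <- sum(n_neg / (1 + 10^(pka[names(n_neg)] - ph)))
    pos - neg
  }
  # bisect past |charge| < 1e-4 down to a 1e-7 pH bracket: near-neutral
  # compositions have very flat titration curves, where the charge
  # criterion alone leaves visible pH slack
  lo <- 0; hi <- 14
  while (hi - lo > 1e-7) {
    mid <- (lo + hi) / 2
    if (charge(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Reduced-genome characterization report
#'
#' Bundles the statistics used to characterize a candidate reduced genome:
#' length, GC, coding density over all feature types and over CDS only,
#' overlapping-gene count, intergenic gap lengths, and per-protein plus
#' mean isoelectric points.
#'
#' @param sequence Genome DNA string.
#' @param features Feature tibble (`feature_id` optional, `type`, `start`,
#'   `end`, `strand`; 0-based half-open forward-strand coordinates).
#' @param circular Treat the genome as circular when computing intergenic
#'   gaps.
#' @param table Genetic code used to translate CDS features for pI.
#' @param pka pKa set for [isoelectric_point()].
#' @return Object of class `genome_stats`: list with `genome_length`, `gc`,
#'   `density_all`, `density_cds`, `n_overlapping_pairs`,
#'   `intergenic_lengths`, `pI_per_protein`, `pI_mean`.
#' @export
genome_stats <- function(sequence, features, circular = FALSE,
                         table = genetic_code(4), pka = pka_emboss()) {
  sequence <- check_dna(sequence)
  L <- nchar(sequence)
  check_features(features, L)
  ovl <- overlap_and_intergenic(features, L, circular = circular)
  cds <- features[features$type == "CDS", , drop = FALSE]
  pis <- numeric(0)
  if (nrow(cds) > 0L) {
    pis <- vapply(seq_len(nrow(cds)), function(i) {
      nt <- substr(sequence, cds$start[i] + 1L, cds$end[i])
      if (!is.null(cds$strand) && cds$strand[i] == "-") nt <- revcomp(nt)
      aa <- translate_cds(nt, table)
      aa <- gsub("\\*+$", "", aa)
      if (nchar(aa) == 0L) return(NA_real_)
      isoelectric_point(aa, pka)
    }, 0)
    pis <- pis[!is.na(pis)]
  }
  structure(
    list(
      genome_length = L,
      gc = gc_fraction(sequence),
      density_all = coding_density(features, L),
      density_cds = coding_density(features, L, types = "CDS"),
      n_overlapping_pairs = ovl$n_overlapping_pairs,
      intergenic_lengths = ovl$intergenic_lengths,
      pI_per_protein = pis,
      pI_mean = if (length(pis)) mean(pis) else NA_real_
    ),
    class = "genome_stats"
  )
}

#' @export
print.genome_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "<genome_stats> %d bp | GC %.3f | density %.3f (all) %.3f (CDS) | ",
    "%d overlapping pairs | mean pI %.2f\n"),
    x$genome_length, x$gc, x$density_all, x$density_cds,
    x$n_overlapping_pairs, x$pI_mean))
  invisible(x)
}

#' @rdname genome_stats
#' @param x A `genome_stats` object.
#' @param ... Unused.
#' @export
tidy.genome_stats <- function(x, ...) {
  tibble::tibble(
    genome_length = x$genome_length, gc = x$gc,
    density_all = x$density_all, density_cds = x$density_cds,
    n_overlapping_pairs = x$n_overlapping_pairs,
    median_intergenic = stats::median(x$intergenic_lengths),
    pI_mean = x$pI_mean
  )
}
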