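#' Specification of a eukaryote-like host bin
#'
#' The host is emulated as a bin of many contigs of random (low coding
#' density) sequence: the recoding detector must not flag them, and the
#' co-occurrence stage must recover them from coverage alone.
#'
#' @param genome_id Bin label.
#' @param n_contigs Number of contigs in the host bin.
#' @param mean_contig_len Mean contig length, nucleotides.
#' @param gc GC fraction of the random sequence.
#' @return Object of class `host_spec`.
#' @export
host_spec <- function(genome_id = "host", n_contigs = 12,
                      mean_contig_len = 4000, gc = 0.38) {
  if (n_contigs < 1 || mean_contig_len < 2500) {
    stop("host bin needs >= 1 contig with mean length >= 2.5 kb ",
         "(the binning cutoff)")
  }
  structure(list(genome_id = genome_id, n_contigs = as.integer(n_contigs),
                 mean_contig_len = mean_contig_len, gc = gc),
            class = "host_spec")
}

#' Default background genome specs
#'
#' Twenty code-11 genomes spanning GC 0.30--0.60, one contig per bin, used
#' as the uncorrelated community background.
#'
#' @param n_background Number of background genomes.
#' @param n_genes,mean_gene_len,mean_intergenic_len Passed to [genome_spec()].
#' @param seed Base seed; background i uses `seed + i`.
#' @return List of [genome_spec()] objects (code 11, linear).
#' @export
background_specs <- function(n_background = 20, n_genes = 30,
                             mean_gene_len = 900, mean_intergenic_len = 100,
                             seed = 1000) {
  gcs <- seq(0.30, 0.60, length.out = n_background)
  lapply(seq_len(n_background), function(i) {
    genome_spec(genome_id = sprintf("bg%02d", i), code_id = 11,
                n_genes = n_genes, mean_gene_len = mean_gene_len,
                mean_intergenic_len = mean_intergenic_len,
                gc_target = gcs[i], tga_trp_rate = 0,
                circular_overlap_len = 0, seed = seed + i)
  })
}

#' Generate a synthetic metagenome community with known ground truth
#'
#' Assembles the full test bed for the discovery pipeline: one UGA-recoded
#' symbiont genome (code 4), a set of code-11 background genomes (one contig
#' and bin each), a multi-contig eukaryote-like host bin of random sequence,
#' and two organelle decoys — a mitochondrion-like code-4 genome carrying
#' respiratory-chain marker labels and a chloroplast-like code-11 genome
#' carrying a photosynthesis marker.  Per-sample log-abundances of host and
#' symbiont bins are drawn from a bivariate normal with correlation
#' `rho_true`; all other bins are independent.  Abundances are closed to
#' relative form per sample, and contig coverage equals the bin's relative
#' abundance times `depth_scale` times multiplicative lognormal noise.
#'
#' @param specs List of [genome_spec()] objects: the symbiont plus the
#'   background genomes.  `NULL` uses the default symbiont spec and
#'   [background_specs()].
#' @param host A [host_spec()].
#' @param n_samples Number of samples (>= 3); the study design uses 29.
#' @param rho_true True log-space correlation between host and symbiont
#'   abundances, in \[-1, 1\].
#' @param noise_sd SD of the lognormal coverage noise (log scale).
#' @param depth_scale Mean sequencing depth scale (> 0).
#' @param decoys Include the two organelle decoy contigs.
#' @param sequences Generate nucleotide sequences.  With `FALSE`, contig
#'   lengths are set to their expected values and no sequence is emitted —
#'   sufficient (and much faster) for abundance/co-occurrence work.
#' @param seed Integer seed; the community is deterministic given it.
#' @return Object of class `community`: list with `contigs` (tibble:
#'   `contig_id`, `bin_id`, `role`, `length`), `sequences` (named character
#'   vector), `genes` (gene truth for genomes), `coverage`, `bins`,
#'   `markers` (tibbles matching the TSV interfaces), `abundance` (tibble of
#'   true per-sample bin abundances: `log_abundance` pre-closure,
#'   `rel_abundance` closed to 1 per sample), and `params`.
#' @export
generate_community <- function(specs = NULL, host = host_spec(),
                               n_samples = 29, rho_true = 0.9,
                               noise_sd = 0.2, depth_scale = 100,
                               decoys = TRUE, sequences = TRUE, seed = 1) {
  if (n_samples < 3) stop("n_samples must be >= 3")
  if (abs(rho_true) > 1) stop("rho_true must lie in [-1, 1]")
  if (depth_scale <= 0) stop("depth_scale must be > 0")
  if (is.null(specs)) {
    specs <- c(list(genome_spec(seed = seed + 1)),
               background_specs(seed = seed + 100))
  }
  stopifnot(inherits(host, "host_spec"))
  withr::with_seed(seed, generate_community_impl(
    specs, host, n_samples, rho_true, noise_sd, depth_scale,
    decoys, sequences, seed))
}

generate_community_impl <- function(specs, host, n_samples, rho_true,
                                    noise_sd, depth_scale, decoys,
                                    sequences, seed) {
  role_of <- function(s) if (s$code_id == 4L) "symbiont" else "background"
  if (decoys) {
    specs <- c(specs, list(
      genome_spec(genome_id = "decoy_mito", code_id = 4, n_genes = 15,
                  mean_gene_len = 900, mean_intergenic_len = 60,
                  gc_target = 0.30, tga_trp_rate = 0.015,
                  circular_overlap_len = 0, seed = seed + 901),
      genome_spec(genome_id = "decoy_chloro", code_id = 11, n_genes = 15,
                  mean_gene_len = 900, mean_intergenic_len = 60,
                  gc_target = 0.35, tga_trp_rate = 0,
                  circular_overlap_len = 0, seed = seed + 902)))
  }

  expected_len <- function(s) {
    as.integer(round(s$n_genes * (s$mean_gene_len + s$mean_intergenic_len) +
                     s$circular_overlap_len))
  }

  contigs <- list(); seqs <- character(0); genes <- list()
  for (s in specs) {
    cid <- paste0(s$genome_id, "_c1")
    role <- if (s$genome_id %in% c("decoy_mito", "decoy_chloro")) {
      "decoy"
    } else {
      role_of(s)
    }
    if (sequences) {
      g <- generate_genome(s)
      len <- nchar(g$sequence)
      seqs[cid] <- g$sequence
      gg <- g$genes
      gg$contig_id <- cid
      genes[[length(genes) + 1L]] <- gg
    } else {
      len <- expected_len(s)
    }
    contigs[[length(contigs) + 1L]] <- tibble::tibble(
      contig_id = cid, bin_id = paste0("bin_", s$genome_id),
      role = role, length = len)
  }

  # host contigs: random sequence, no planted genes; floor 2500 bp, the
  # usual binning cutoff, so host bins contain no contigs shorter than a
  # binner would admit
  host_lens <- pmax(2500L, as.integer(round(
    stats::rgamma(host$n_contigs, shape = 6,
                  rate = 6 / host$mean_contig_len))))
  for (i in seq_len(host$n_contigs)) {
    cid <- sprintf("%s_c%02d", host$genome_id, i)
    if (sequences) {
      seqs[cid] <- paste(sample(
        c("A", "T", "G", "C"), host_lens[i], replace = TRUE,
        prob = c((1 - host$gc) / 2, (1 - host$gc) / 2,
                 host$gc / 2, host$gc / 2)), collapse = "")
    }
    contigs[[length(contigs) + 1L]] <- tibble::tibble(
      contig_id = cid, bin_id = paste0("bin_", host$genome_id),
      role = "host", length = host_lens[i])
  }
  contigs <- dplyr::bind_rows(contigs)

  markers <- tibble::tibble(contig_id = character(),
                            marker_label = character())
  if (decoys) {
    markers <- tibble::tibble(
      contig_id = c("decoy_mito_c1", "decoy_mito_c1", "decoy_chloro_c1"),
      marker_label = c("NADH dehydrogenase subunit",
                       "cytochrome c oxidase", "photosystem"))
  }

  # per-sample true abundances: host/symbiont bivariate lognormal,
  # everything else independent lognormal
  bins <- unique(contigs$bin_id)
  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  mu <- stats::setNames(rep(0, length(bins)), bins)
  mu[paste0("bin_", host$genome_id)] <- 2
  sym_bin <- contigs$bin_id[contigs$role == "symbiont"][1]
  if (!is.na(sym_bin)) mu[sym_bin] <- 1.5
  z <- matrix(stats::rnorm(length(bins) * n_samples), nrow = length(bins),
              dimnames = list(bins, sample_ids))
  hb <- paste0("bin_", host$genome_id)
  if (!is.na(sym_bin)) {
    z[sym_bin, ] <- rho_true * z[hb, ] +
      sqrt(1 - rho_true^2) * z[sym_bin, ]
  }
  log_ab <- z + mu
  ab <- exp(log_ab)
  rel <- sweep(ab, 2, colSums(ab), "/")

  abundance <- tibble::as_tibble(expand.grid(
    bin_id = bins, sample_id = sample_ids, stringsAsFactors = FALSE,
    KEEP.OUT.ATTRS = FALSE))
  abundance$log_abundance <- log_ab[cbind(abundance$bin_id,
                                          abundance$sample_id)]
  abundance$rel_abundance <- rel[cbind(abundance$bin_id,
                                       abundance$sample_id)]

  noise <- matrix(exp(stats::rnorm(nrow(contigs) * n_samples,
                                   sd = noise_sd)),
                  nrow = nrow(contigs))
  coverage <- tidyr::crossing(contig_id = contigs$contig_id,
                              sample_id = sample_ids)
  bin_of <- stats::setNames(contigs$bin_id, contigs$contig_id)
  ci <- match(coverage$contig_id, contigs$contig_id)
  si <- match(coverage$sample_id, sample_ids)
  coverage$mean_depth <- rel[cbind(bin_of[coverage$contig_id],
                                   coverage$sample_id)] *
    depth_scale * noise[cbind(ci, si)]

  structure(
    list(
      contigs = contigs,
      sequences = if (sequences) seqs else NULL,
      genes = if (length(genes)) dplyr::bind_rows(genes) else NULL,
      coverage = coverage[order(coverage$contig_id, coverage$sample_id), ],
      bins = contigs[, c("contig_id", "bin_id")],
      markers = markers,
      abundance = abundance,
      params = list(n_samples = n_samples, rho_true = rho_true,
                    noise_sd = noise_sd, depth_scale = depth_scale,
                    seed = seed, host_bin = hb, symbiont_bin = sym_bin)
    ),
    class = "community"
  )
}

#' @export
print.community <- function(x, ...) {
  cat("<community>", nrow(x$contigs), "contigs,",
      length(unique(x$contigs$bin_id)), "bins,",
      x$params$n_samples, "samples | rho_true =", x$params$rho_true, "\n")
  invisible(x)
}

#' Write a community to disk in standard formats
#'
#' Emits `contigs.fasta`, `coverage.tsv` (contig_id, sample_id, mean_depth),
#' `bins.tsv` (contig_id, bin_id), `markers.tsv` (contig_id, marker_label)
#' and `truth.json`.  Output is byte-identical across runs for a community
#' generated from the same seed.
#'
#' @param community A [generate_community()] result (with sequences).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "community"))
  if (is.null(community$sequences)) {
    stop("community was generated with sequences = FALSE")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dna <- Biostrings::DNAStringSet(community$sequences)
  Biostrings::writeXStringSet(dna, file.path(dir, "contigs.fasta"))
  readr::write_tsv(community$coverage, file.path(dir, "coverage.tsv"))
  readr::write_tsv(community$bins, file.path(dir, "bins.tsv"))
  readr::write_tsv(community$markers, file.path(dir, "markers.tsv"))
  truth <- list(
    contigs = community$contigs,
    genes = community$genes,
    abundance = community$abundance,
    params = community$params
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
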