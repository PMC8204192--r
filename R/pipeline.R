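#' Build a discovery-run configuration
#'
#' Collects the thresholds and input paths for [run_discovery()], checks
#' each against its documented range, and returns a plain named list that
#' is echoed verbatim into the run report.  A YAML file with the same
#' field names can be loaded with `discovery_config(yaml = path)`.
#'
#' @param contigs Path to the assembly FASTA (or a named sequence vector).
#' @param coverage Path to the coverage TSV (`contig_id`, `sample_id`,
#'   `mean_depth`) or a tibble.
#' @param bins Path to the bin TSV (`contig_id`, `bin_id`) or a tibble.
#' @param markers Optional path to the marker TSV (`contig_id`,
#'   `marker_label`) or a tibble; `NULL` skips the organelle screen.
#' @param min_orf_len Minimum ORF length, nt (90--300).
#' @param d4_min,delta_min,min_merged_pairs Candidate thresholds for
#'   [score_recoding()].
#' @param k_min Minimum terminal overlap for circularity (>= 20).
#' @param rho_min,alpha Host-attribution thresholds.
#' @param n_permutations Permutations for p-values.
#' @param seed Integer seed for the stochastic stages.
#' @param yaml Optional YAML file whose fields override the defaults.
#' @return Named list of class `discovery_config`.
#' @export
discovery_config <- function(contigs = NULL, coverage = NULL, bins = NULL,
                             markers = NULL, min_orf_len = 150,
                             d4_min = 0.85, delta_min = 0.10,
                             min_merged_pairs = 1, k_min = 50,
                             rho_min = 0.8, alpha = 0.01,
                             n_permutations = 99, seed = 1, yaml = NULL) {
  cfg <- list(contigs = contigs, coverage = coverage, bins = bins,
              markers = markers, min_orf_len = min_orf_len,
              d4_min = d4_min, delta_min = delta_min,
              min_merged_pairs = min_merged_pairs, k_min = k_min,
              rho_min = rho_min, alpha = alpha,
              n_permutations = n_permutations, seed = seed)
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    cfg[names(y)] <- y
  }
  if (cfg$min_orf_len < 90 || cfg$min_orf_len > 300 ||
      cfg$min_orf_len %% 3 != 0) {
    stop("min_orf_len must be in [90, 300] and divisible by 3")
  }
  if (cfg$d4_min < 0 || cfg$d4_min > 1 || cfg$delta_min < 0 ||
      cfg$delta_min > 1) {
    stop("d4_min and delta_min must lie in [0, 1]")
  }
  if (cfg$min_merged_pairs < 0) stop("min_merged_pairs must be >= 0")
  if (cfg$k_min < 20) stop("k_min must be >= 20")
  if (cfg$rho_min < -1 || cfg$rho_min > 1) stop("rho_min must lie in [-1, 1]")
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("alpha must lie in (0, 1]")
  if (cfg$n_permutations < 99) stop("n_permutations must be >= 99")
  structure(cfg, class = c("discovery_config", "list"))
}

read_table_input <- function(x, required, what) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) {
    tab <- tibble::as_tibble(x)
  } else {
    if (!file.exists(x)) stop("cannot read ", what, " input: ", x)
    tab <- readr::read_tsv(x, show_col_types = FALSE, progress = FALSE)
  }
  if (!all(required %in% names(tab))) {
    stop(what, " input must have columns: ", paste(required, collapse = ", "))
  }
  tab
}

#' Run the endosymbiont discovery pipeline
#'
#' Orchestrates the full analysis on an assembled metagenome: (1) score
#' every contig for UGA-to-Trp recoding; (2) screen candidates against
#' organelle marker hits; (3) detect and trim terminal overlaps on the
#' surviving candidates; (4) characterize each candidate genome (table-4
#' ORFs as CDS features, coding density, overlaps, intergenic gaps,
#' proteome pI); (5) compute length-weighted bin abundances and attribute
#' a host to each candidate's bin by SparCC correlation with permutation
#' p-values.  Zero candidates is a valid outcome and still produces a
#' complete report.
#'
#' @param config A [discovery_config()].
#' @param out Optional path; when given, the report is written there as
#'   JSON (deterministic for a fixed seed and config).
#' @return The report: a list with `config`, `n_contigs`, `scan` (the
#'   per-contig recoding table), `candidates` (one entry per candidate
#'   with recoding, circularity, genome stats and host attribution) and
#'   `host_attribution`.
#' @export
run_discovery <- function(config, out = NULL) {
  stopifnot(inherits(config, "discovery_config"))
  seqs <- as_sequence_vector(config$contigs)
  coverage <- read_table_input(config$coverage,
                               c("contig_id", "sample_id", "mean_depth"),
                               "coverage")
  bins <- read_table_input(config$bins, c("contig_id", "bin_id"), "bins")
  markers <- read_table_input(config$markers,
                              c("contig_id", "marker_label"), "markers")

  scan <- scan_contigs(seqs, min_orf_len = config$min_orf_len,
                       d4_min = config$d4_min,
                       delta_min = config$delta_min,
                       min_merged_pairs = config$min_merged_pairs)
  scan <- screen_organelle_markers(scan, markers)

  circ <- purrr::map_dfr(scan$contig_id[scan$candidate], function(id) {
    detect_terminal_overlap(seqs[[id]], k_min = config$k_min,
                            contig_id = id)
  })
  scan <- dplyr::left_join(
    scan,
    if (nrow(circ)) circ[, c("contig_id", "overlap_len", "is_circular",
                             "trimmed_length")] else
      tibble::tibble(contig_id = character(), overlap_len = integer(),
                     is_circular = logical(), trimmed_length = integer()),
    by = "contig_id")

  fit <- NULL
  host <- NULL
  if (!is.null(coverage) && !is.null(bins)) {
    lens <- stats::setNames(nchar(seqs), names(seqs))
    A <- bin_abundance(coverage, bins, lens)
    if (nrow(A) >= 4L) {
      fit <- sparcc(A, seed = config$seed)
      fit <- sparcc_pvalues(fit, n_permutations = config$n_permutations,
                            seed = config$seed)
    }
  }

  bin_of <- if (!is.null(bins)) {
    stats::setNames(bins$bin_id, bins$contig_id)
  } else NULL

  candidates <- lapply(scan$contig_id[scan$candidate], function(id) {
    row <- scan[scan$contig_id == id, ]
    s <- seqs[[id]]
    if (isTRUE(row$is_circular)) s <- substr(s, 1L, row$trimmed_length)
    orfs <- call_orfs(s, genetic_code(4), min_orf_len = config$min_orf_len,
                      contig_id = id)
    feats <- tibble::tibble(feature_id = sprintf("cds_%04d",
                                                 seq_len(nrow(orfs))),
                            type = "CDS", start = orfs$start,
                            end = orfs$end, strand = orfs$strand)
    gs <- genome_stats(s, feats, circular = isTRUE(row$is_circular))
    attribution <- NULL
    if (!is.null(fit) && !is.null(bin_of) && !is.na(bin_of[id]) &&
        bin_of[id] %in% rownames(fit$rho)) {
      attribution <- attribute_host(fit, bin_of[id],
                                    rho_min = config$rho_min,
                                    alpha = config$alpha)
    }
    list(
      contig_id = id,
      recoding = as.list(row[, c("length", "gc", "d11", "d4", "delta",
                                 "merged_pairs")]),
      circularity = as.list(row[, c("overlap_len", "is_circular",
                                    "trimmed_length")]),
      genome_stats = list(
        genome_length = gs$genome_length, gc = gs$gc,
        density_all = gs$density_all, density_cds = gs$density_cds,
        n_overlapping_pairs = gs$n_overlapping_pairs,
        median_intergenic = stats::median(gs$intergenic_lengths),
        pI_mean = gs$pI_mean, n_proteins = length(gs$pI_per_protein)),
      host_attribution = attribution
    )
  })

  report <- list(
    config = unclass(config)[setdiff(names(config),
                                     c("contigs", "coverage", "bins",
                                       "markers", "yaml"))],
    inputs = list(
      contigs = if (is.character(config$contigs) &&
                    length(config$contigs) == 1L) config$contigs else
        "<in-memory>",
      n_contigs = length(seqs)),
    scan = scan,
    n_candidates = length(candidates),
    candidates = candidates
  )
  validate_report(report)
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(report)
}

# Structural check of the report against the shipped schema's required
# fields, applied on every run before the report leaves the function.
validate_report <- function(report) {
  schema <- jsonlite::read_json(
    system.file("schema", "discovery_report.schema.json",
                package = "opalscan"))
  need <- function(obj, req, where) {
    missing <- setdiff(unlist(req), names(obj))
    if (length(missing) > 0L) {
      stop("discovery report fails schema at ", where, ": missing ",
           paste(missing, collapse = ", "))
    }
  }
  need(report, schema$required, "top level")
  need(report$config, schema$properties$config$required, "config")
  need(report$inputs, schema$properties$inputs$required, "inputs")
  need(report$scan, schema$properties$scan$items$required, "scan")
  cand_schema <- schema$properties$candidates$items
  for (cand in report$candidates) {
    need(cand, cand_schema$required, "candidate")
    for (part in c("recoding", "circularity", "genome_stats")) {
      need(cand[[part]], cand_schema$properties[[part]]$required, part)
    }
  }
  invisible(TRUE)
}
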