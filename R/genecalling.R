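#' Call open reading frames under a pluggable genetic code
#'
#' Scans all six reading frames of a contig and reports every maximal ORF:
#' from the first valid start codon after the previous in-frame stop through
#' the next in-frame stop (stop codon included).  The genetic code table
#' decides which codons terminate translation, so the same contig can yield
#' very different ORF sets under tables 11 and 4 when in-frame TGA codons are
#' present — the signal exploited by [score_recoding()].
#'
#' Codons containing N are treated as neither start nor stop and translate to
#' `X`.  Coordinates are always reported on the forward strand, 0-based
#' half-open, so `end - start == length` for every ORF.
#'
#' @param sequence Contig DNA string over A/C/G/T/N (case-insensitive).
#' @param table A [genetic_code()] table (default table 11).
#' @param min_orf_len Minimum ORF length in nucleotides, stop codon included;
#'   must be >= 30 and divisible by 3.
#' @param allow_partial Also report ORFs that run off the contig end without
#'   reaching a stop (flagged in the `partial` column).
#' @param contig_id Label copied into the output.
#' @return Tibble with columns `contig_id`, `start`, `end` (0-based
#'   half-open, forward strand), `strand` (`"+"`/`"-"`), `frame` (0--2 offset
#'   on the ORF's own strand), `length` (nt) and `partial`, sorted by
#'   `start`.  Empty sequence gives a zero-row tibble.
#' @examples
#' call_orfs(paste0("ATG", strrep("AAA", 20), "TAG"), min_orf_len = 30)
#' @export
call_orfs <- function(sequence, table = genetic_code(11), min_orf_len = 150,
                      allow_partial = FALSE, contig_id = "contig") {
  stopifnot(inherits(table, "genetic_code"))
  if (min_orf_len < 30 || min_orf_len %% 3 != 0) {
    stop("min_orf_len must be >= 30 and divisible by 3")
  }
  sequence <- check_dna(sequence)
  L <- nchar(sequence)
  empty <- tibble::tibble(
    contig_id = character(), start = integer(), end = integer(),
    strand = character(), frame = integer(), length = integer(),
    partial = logical()
  )
  if (L < min_orf_len) return(empty)

  scan_strand <- function(s, strand) {
    res <- orf_scan(s, table, min_orf_len, allow_partial)
    if (nrow(res) == 0L) return(res)
    if (strand == "+") {
      res$start <- res$nt_start
      res$end <- res$nt_end
    } else {
      # interval on revcomp maps to [L - nt_end, L - nt_start) forward
      res$start <- L - res$nt_end
      res$end <- L - res$nt_start
    }
    res$strand <- strand
    res
  }

  fwd <- scan_strand(sequence, "+")
  rev <- scan_strand(revcomp(sequence), "-")
  out <- dplyr::bind_rows(fwd, rev)
  if (nrow(out) == 0L) return(empty)
  out$contig_id <- contig_id
  out$length <- out$end - out$start
  out <- out[order(out$start, out$end, out$strand), ]
  tibble::as_tibble(out[, c("contig_id", "start", "end", "strand",
                            "frame", "length", "partial")])
}

# Scan the three frames of one strand.  Returns nt_start/nt_end 0-based
# half-open on the scanned strand's own coordinates.
orf_scan <- function(s, table, min_orf_len, allow_partial) {
  L <- nchar(s)
  sym <- table$codons
  starts <- table$start_codons
  acc <- vector("list", 3L)
  for (f in 0:2) {
    n_cod <- (L - f) %/% 3L
    if (n_cod < 2L) next
    pos <- f + 1L + 3L * (0:(n_cod - 1L))
    cods <- substring(s, pos, pos + 2L)
    aa <- unname(sym[cods])                 # NA for N-containing codons
    stop_idx <- which(!is.na(aa) & aa == "*")
    start_idx <- which(cods %in% starts)
    if (length(start_idx) == 0L) next
    # region r = number of in-frame stops at or before the codon; a start
    # codon is never a stop so ties cannot occur
    reg <- findInterval(start_idx, stop_idx)
    first <- start_idx[!duplicated(reg)]
    freg <- reg[!duplicated(reg)]
    stop_for <- ifelse(freg + 1L <= length(stop_idx),
                       stop_idx[freg + 1L], NA_integer_)
    partial <- is.na(stop_for)
    end_cod <- ifelse(partial, n_cod, stop_for)
    len_nt <- 3L * (end_cod - first + 1L)
    keep <- len_nt >= min_orf_len & (allow_partial | !partial)
    if (!any(keep)) next
    acc[[f + 1L]] <- data.frame(
      nt_start = f + 3L * (first[keep] - 1L),
      nt_end = f + 3L * end_cod[keep],
      frame = f,
      partial = partial[keep]
    )
  }
  out <- dplyr::bind_rows(acc)
  if (is.null(out) || nrow(out) == 0L) {
    data.frame(nt_start = integer(), nt_end = integer(),
               frame = integer(), partial = logical())
  } else {
    out
  }
}

#' Fraction of a contig covered by ORFs
#'
#' Coding potential used by the recoding detector: the fraction of contig
#' positions covered by the union of ORF intervals from both strands,
#' projected onto forward coordinates.  Overlapping and nested ORFs are
#' counted once (union, not sum).
#'
#' @param orfs Tibble from [call_orfs()] (columns `start`, `end`).
#' @param contig_length Contig length in nucleotides (> 0).
#' @return Fraction in \[0, 1\].
#' @export
coding_fraction <- function(orfs, contig_length) {
  if (contig_length <= 0) stop("contig_length must be > 0")
  if (nrow(orfs) == 0L) return(0)
  if (any(orfs$start < 0 | orfs$end > contig_length)) {
    stop("ORF coordinates fall outside [0, contig_length)")
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = orfs$start + 1L, end = orfs$end))
  sum(IRanges::width(ir)) / contig_length
}

#' Write ORFs as GFF3
#'
#' Feature type `CDS`, score = ORF length, 1-based inclusive coordinates as
#' GFF3 requires.
#'
#' @param orfs Tibble from [call_orfs()].
#' @param path Output file path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_orfs_gff3 <- function(orfs, path, source = "opalscan") {
  lines <- c("##gff-version 3")
  if (nrow(orfs) > 0L) {
    attrs <- sprintf("ID=orf_%04d;partial=%s", seq_len(nrow(orfs)),
                     ifelse(orfs$partial, "true", "false"))
    lines <- c(lines, sprintf(
      "%s\t%s\tCDS\t%d\t%d\t%d\t%s\t0\t%s",
      orfs$contig_id, source, orfs$start + 1L, orfs$end, orfs$length,
      orfs$strand, attrs
    ))
  }
  writeLines(lines, path)
  invisible(path)
}
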