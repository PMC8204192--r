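#' Score a contig for UGA-to-Trp recoding
#'
#' Computes the contig's coding fraction under the standard bacterial code
#' (table 11, `d11`) and under the UGA-to-Trp code (table 4, `d4`), their
#' difference `delta = d4 - d11`, and the number of adjacent same-frame
#' table-11 ORF pairs that fuse into a single ORF under table 4
#' (`merged_pairs`).  A genome written in code 4 has tryptophan TGA codons
#' inside genes, which table 11 reads as premature stops: its coding
#' fraction jumps when re-read under table 4, while a code-11 genome gains
#' essentially nothing.  A contig is a recoding candidate when
#' `d4 >= d4_min` and `delta >= delta_min`.
#'
#' `merged_pairs` is counted as, for every table-4 ORF, the number of
#' table-11 ORFs of the same strand and frame nested inside it, minus one
#' (floored at zero): within a fused table-4 ORF the only possible in-frame
#' table-11 stops are TGA, so nested table-11 ORFs are necessarily
#' TGA-separated fragments of the fused gene.
#'
#' Candidacy additionally requires `merged_pairs >= min_merged_pairs`
#' (default 1): a density gain without a single fused stop is not evidence
#' of stop-codon reassignment, merely of spurious ORF extension — short
#' random sequence occasionally reaches high `d4` by chance but
#' essentially never fuses ORF pairs, while genuinely recoded genomes fuse
#' many.
#'
#' Contigs shorter than 1 kb are reported as unevaluable (`evaluable =
#' FALSE`, densities `NA`): the density contrast is too noisy to classify.
#'
#' @param sequence Contig DNA string.
#' @param min_orf_len Minimum ORF length (nt) for both calls.
#' @param d4_min Minimum `d4` for candidacy.
#' @param delta_min Minimum `delta` for candidacy.
#' @param min_merged_pairs Minimum fused ORF pairs for candidacy (0
#'   restores the pure density rule).
#' @param contig_id Label copied into the report.
#' @return One-row tibble: `contig_id`, `length`, `gc`, `d11`, `d4`,
#'   `delta`, `merged_pairs`, `evaluable`, `candidate`.
#' @export
score_recoding <- function(sequence, min_orf_len = 150, d4_min = 0.85,
                           delta_min = 0.10, min_merged_pairs = 1,
                           contig_id = "contig") {
  sequence <- check_dna(sequence)
  L <- nchar(sequence)
  if (L < 1000L) {
    return(tibble::tibble(
      contig_id = contig_id, length = L, gc = gc_fraction(sequence),
      d11 = NA_real_, d4 = NA_real_, delta = NA_real_,
      merged_pairs = NA_integer_, evaluable = FALSE, candidate = FALSE))
  }
  o11 <- call_orfs(sequence, genetic_code(11), min_orf_len,
                   contig_id = contig_id)
  o4 <- call_orfs(sequence, genetic_code(4), min_orf_len,
                  contig_id = contig_id)
  d11 <- coding_fraction(o11, L)
  d4 <- coding_fraction(o4, L)
  mp <- count_merged_pairs(o11, o4)
  tibble::tibble(
    contig_id = contig_id, length = L, gc = gc_fraction(sequence),
    d11 = d11, d4 = d4, delta = d4 - d11,
    merged_pairs = mp,
    evaluable = TRUE,
    candidate = d4 >= d4_min & (d4 - d11) >= delta_min &
      mp >= min_merged_pairs
  )
}

count_merged_pairs <- function(o11, o4) {
  if (nrow(o4) == 0L || nrow(o11) == 0L) return(0L)
  total <- 0L
  for (i in seq_len(nrow(o4))) {
    nested <- sum(o11$strand == o4$strand[i] & o11$frame == o4$frame[i] &
                    o11$start >= o4$start[i] & o11$end <= o4$end[i])
    total <- total + max(0L, nested - 1L)
  }
  total
}

#' Score every contig of an assembly for recoding
#'
#' Vectorized front end to [score_recoding()]: one report row per contig.
#'
#' @param sequences Named character vector of contig sequences, a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @inheritParams score_recoding
#' @return Tibble with one [score_recoding()] row per contig.
#' @export
scan_contigs <- function(sequences, min_orf_len = 150, d4_min = 0.85,
                         delta_min = 0.10, min_merged_pairs = 1) {
  sequences <- as_sequence_vector(sequences)
  purrr::imap_dfr(sequences, function(s, id) {
    score_recoding(s, min_orf_len = min_orf_len, d4_min = d4_min,
                   delta_min = delta_min,
                   min_merged_pairs = min_merged_pairs, contig_id = id)
  })
}

as_sequence_vector <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) {
    return(stats::setNames(as.character(sequences), names(sequences)))
  }
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences) && !grepl("^[ACGTNacgtn]+$", sequences)) {
    dna <- Biostrings::readDNAStringSet(sequences)
    names(dna) <- sub("\\s.*$", "", names(dna))
    return(stats::setNames(as.character(dna), names(dna)))
  }
  if (!is.character(sequences) || is.null(names(sequences))) {
    stop("sequences must be a named character vector, DNAStringSet, ",
         "or FASTA path")
  }
  sequences
}

#' Exclude organelle-like recoding candidates by marker hits
#'
#' Mitochondria (which also use UGA-to-Trp codes) and chloroplasts are the
#' main false-positive sources for a recoding scan of a mixed community.
#' Any candidate contig carrying a marker hit matching the organelle
#' vocabulary — by default multi-subunit NADH dehydrogenase or cytochrome
#' oxidase labels (mitochondrion-like) and photosystem/photosynthesis
#' labels (chloroplast-like) — is excluded with reason `"organelle-like"`.
#' Candidates absent from the marker table pass unchanged.
#'
#' @param reports Tibble from [scan_contigs()] / [score_recoding()].
#' @param markers Tibble with columns `contig_id`, `marker_label` (may have
#'   zero rows).  Rows naming unknown contigs are ignored with a warning.
#' @param organelle_patterns Character vector of regular expressions
#'   matched case-insensitively against `marker_label`.
#' @return `reports` with an `excluded_reason` column (`NA` or
#'   `"organelle-like"`) and `candidate` updated to exclude flagged contigs.
#' @export
screen_organelle_markers <- function(
    reports, markers,
    organelle_patterns = c("NADH dehydrogenase", "cytochrome c? ?oxidase",
                           "photosystem", "photosynthesis")) {
  stopifnot(all(c("contig_id", "candidate") %in% names(reports)))
  if (is.null(markers) || nrow(markers) == 0L) {
    reports$excluded_reason <- NA_character_
    return(reports)
  }
  stopifnot(all(c("contig_id", "marker_label") %in% names(markers)))
  unknown <- setdiff(unique(markers$contig_id), reports$contig_id)
  if (length(unknown) > 0L) {
    warning("ignoring marker rows for unknown contigs: ",
            paste(unknown, collapse = ", "))
  }
  pat <- paste0("(", paste(organelle_patterns, collapse = ")|("), ")")
  flagged <- unique(markers$contig_id[
    grepl(pat, markers$marker_label, ignore.case = TRUE)])
  reports$excluded_reason <- ifelse(
    reports$candidate & reports$contig_id %in% flagged,
    "organelle-like", NA_character_)
  reports$candidate <- reports$candidate & is.na(reports$excluded_reason)
  reports
}

#' Detect assembly circularity from an exact terminal overlap
#'
#' An assembled circular genome shows up as a linear contig whose two ends
#' repeat the same sequence exactly.  This reports the largest `k` with
#' `k_min <= k <= floor(length/2)` such that the first and last `k` bases
#' are identical (0 if none); the contig is called circular when such an
#' overlap exists, and the circular genome length is the contig length
#' minus one copy of the overlap.
#'
#' Overlaps are exact (no mismatches) and found via the classical
#' border/failure function of the sequence, so detection is linear-time.
#'
#' @param sequence Contig DNA string with `nchar > 2 * k_min`.
#' @param k_min Minimum overlap length considered evidence of circularity
#'   (>= 20).
#' @param contig_id Label copied into the result.
#' @return One-row tibble: `contig_id`, `length`, `overlap_len`,
#'   `is_circular`, `trimmed_length`.
#' @export
detect_terminal_overlap <- function(sequence, k_min = 50,
                                    contig_id = "contig") {
  if (k_min < 20) stop("k_min must be >= 20")
  sequence <- check_dna(sequence)
  L <- nchar(sequence)
  if (L <= 2L * k_min) {
    stop("sequence must be longer than 2 * k_min")
  }
  pf <- prefix_function(sequence)
  b <- pf[L]
  half <- L %/% 2L
  # walk the border chain down to the largest border <= L/2
  while (b > half) b <- pf[b]
  overlap <- if (b >= k_min) b else 0L
  tibble::tibble(
    contig_id = contig_id, length = L, overlap_len = overlap,
    is_circular = overlap > 0L,
    trimmed_length = L - overlap
  )
}

# failure function (KMP); returns the border length of every prefix
prefix_function <- function(sequence) {
  x <- utf8ToInt(sequence)
  L <- length(x)
  pf <- integer(L)
  k <- 0L
  for (i in 2:L) {
    while (k > 0L && x[k + 1L] != x[i]) k <- pf[k]
    if (x[k + 1L] == x[i]) k <- k + 1L
    pf[i] <- k
  }
  pf
}

#' Trim one copy of a detected terminal overlap
#'
#' @param sequence Contig DNA string.
#' @param k_min Passed to [detect_terminal_overlap()].
#' @return The sequence with the trailing overlap copy removed (unchanged
#'   when no overlap is detected).
#' @export
trim_terminal_overlap <- function(sequence, k_min = 50) {
  res <- detect_terminal_overlap(sequence, k_min = k_min)
  substr(sequence, 1L, res$trimmed_length)
}

#' Canonical form of a circular sequence
#'
#' Returns the lexicographically smallest string among all rotations of the
#' sequence and all rotations of its reverse complement — the unique
#' representative of the circle that is invariant to rotation and strand
#' choice, so independently assembled copies of the same circular genome
#' compare equal.  Idempotent.
#'
#' @param sequence Circular (already trimmed) DNA string.
#' @return Canonical rotation, as a character scalar.
#' @export
canonical_rotation <- function(sequence) {
  sequence <- check_dna(sequence)
  a <- least_rotation(sequence)
  b <- least_rotation(revcomp(sequence))
  if (a <= b) a else b
}

# Booth's least-rotation algorithm, O(n)
least_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(s)
  x <- utf8ToInt(paste0(s, s))
  n2 <- 2L * n
  f <- rep(-1L, n2)
  k <- 0L
  for (j in 1:(n2 - 1L)) {          # 0-based positions
    sj <- x[j + 1L]
    i <- f[j - k]                   # f[(j-k-1) + 1]
    while (i != -1L && sj != x[k + i + 2L]) {
      if (sj < x[k + i + 2L]) k <- j - i - 1L
      i <- f[i + 1L]
    }
    if (i == -1L && sj != x[k + 1L]) {
      if (sj < x[k + 1L]) k <- j
      f[j - k + 1L] <- -1L
    } else {
      f[j - k + 1L] <- i + 1L
    }
  }
  substr(paste0(s, s), k + 1L, k + n)
}
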