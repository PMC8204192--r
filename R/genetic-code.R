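#' Genetic code tables for ORF calling
#'
#' Builds a codon translation table usable by [call_orfs()]. Table 11 is the
#' standard bacterial/archaeal code (TAA, TAG and TGA are stops); table 4 is
#' the mold/protozoan/mycoplasma code in which the opal codon TGA encodes
#' tryptophan, leaving TAA and TAG as the only stops.  The two tables differ
#' at TGA and nowhere else, which is what makes the coding-density contrast
#' in [score_recoding()] specific to UGA-to-Trp reassignment.
#'
#' Start codons are ATG, GTG and TTG for both tables, the common prokaryotic
#' set.
#'
#' @param code_id Integer NCBI translation table identifier (supported: 4, 11).
#' @return An object of class `genetic_code`: a list with `code_id`, `codons`
#'   (named character vector over all 64 codons; `"*"` marks a stop),
#'   `stop_codons` and `start_codons`.
#' @examples
#' genetic_code(4)$codons[["TGA"]]   # "W"
#' genetic_code(11)$codons[["TGA"]]  # "*"
#' @export
genetic_code <- function(code_id = 11) {
  if (!code_id %in% c(4L, 11L)) {
    stop("unsupported translation table: ", code_id, " (supported: 4, 11)")
  }
  codons <- Biostrings::getGeneticCode(as.character(code_id))
  structure(
    list(
      code_id = as.integer(code_id),
      codons = codons,
      stop_codons = names(codons)[codons == "*"],
      start_codons = c("ATG", "GTG", "TTG")
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> table", x$code_id,
      "| stops:", paste(x$stop_codons, collapse = " "),
      "| starts:", paste(x$start_codons, collapse = " "), "\n")
  invisible(x)
}

# DNA string helpers ---------------------------------------------------------

#' Reverse complement of a DNA string
#'
#' @param x Character scalar over A/C/G/T/N (case-insensitive).
#' @return Character scalar.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

#' GC fraction of a DNA string
#'
#' N bases are excluded from the denominator.
#'
#' @param x Character scalar over A/C/G/T/N.
#' @return Fraction in \[0, 1\].
#' @export
gc_fraction <- function(x) {
  counts <- Biostrings::alphabetFrequency(Biostrings::DNAString(x))
  acgt <- sum(counts[c("A", "C", "G", "T")])
  if (acgt == 0) return(NA_real_)
  sum(counts[c("G", "C")]) / acgt
}

check_dna <- function(x, arg = "sequence") {
  if (!is.character(x) || length(x) != 1L) {
    stop(arg, " must be a single character string")
  }
  x <- toupper(x)
  if (grepl("[^ACGTN]", x)) {
    stop(arg, " contains characters outside {A,C,G,T,N}")
  }
  x
}

#' Translate a DNA coding sequence
#'
#' Simple codon-by-codon translation under a [genetic_code()] table; codons
#' containing N translate to `X`.  Trailing incomplete codons are dropped.
#'
#' @param x Coding DNA string (in-frame, forward orientation).
#' @param table A [genetic_code()] table.
#' @return Amino-acid string; stops appear as `"*"`.
#' @export
translate_cds <- function(x, table = genetic_code(11)) {
  x <- check_dna(x)
  n_cod <- nchar(x) %/% 3L
  if (n_cod == 0L) return("")
  pos <- 1L + 3L * (0:(n_cod - 1L))
  aa <- unname(table$codons[substring(x, pos, pos + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
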