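# Independent brute-force oracles used to pin down expected values.
# These deliberately use different algorithms from the package internals.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Brute-force ORF enumeration: list every (start codon, next in-frame stop)
# pair by direct forward scanning, then keep the earliest start per
# stop-free stretch.  O(starts x stops) per frame.
oracle_orfs <- function(sequence, table, min_orf_len, allow_partial = FALSE) {
  L <- nchar(sequence)
  one_strand <- function(s, strand) {
    rows <- list()
    for (f in 0:2) {
      n_cod <- (nchar(s) - f) %/% 3L
      if (n_cod < 2L) next
      pos <- f + 1L + 3L * (0:(n_cod - 1L))
      cods <- substring(s, pos, pos + 2L)
      aa <- unname(table$codons[cods])
      stop_at <- which(!is.na(aa) & aa == "*")
      start_at <- which(cods %in% table$start_codons)
      pairs <- lapply(start_at, function(i) {
        nxt <- stop_at[stop_at >= i]
        if (length(nxt)) c(i, nxt[1], 0L) else c(i, n_cod, 1L)
      })
      if (!length(pairs)) next
      m <- do.call(rbind, pairs)
      # earliest start per closing stop (== first start after previous stop)
      keep <- !duplicated(m[, 2] + 0.5 * m[, 3])
      m <- m[keep, , drop = FALSE]
      len <- 3L * (m[, 2] - m[, 1] + 1L)
      ok <- len >= min_orf_len & (allow_partial | m[, 3] == 0L)
      if (!any(ok)) next
      m <- m[ok, , drop = FALSE]
      a <- f + 3L * (m[, 1] - 1L)
      b <- f + 3L * m[, 2]
      rows[[length(rows) + 1L]] <- data.frame(
        start = if (strand == "+") a else L - b,
        end = if (strand == "+") b else L - a,
        strand = strand, frame = f, partial = m[, 3] == 1L)
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(start = integer(), end = integer(), strand = character(),
                 frame = integer(), partial = logical())
  }
  out <- rbind(one_strand(sequence, "+"),
               one_strand(opalscan::revcomp(sequence), "-"))
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# Position-bitmap union coverage of intervals (0-based half-open)
oracle_union_fraction <- function(starts, ends, L) {
  hit <- logical(L)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) hit[(starts[i] + 1):ends[i]] <- TRUE
  }
  sum(hit) / L
}

# Direct scan over all k for the largest exact terminal overlap
oracle_terminal_overlap <- function(sequence, k_min) {
  L <- nchar(sequence)
  for (k in (L %/% 2L):k_min) {
    if (substr(sequence, 1L, k) == substr(sequence, L - k + 1L, L)) {
      return(k)
    }
  }
  0L
}

# Enumerate all rotations of both strands, return the smallest
oracle_canonical_rotation <- function(sequence) {
  n <- nchar(sequence)
  rots <- function(s) {
    d <- paste0(s, s)
    vapply(seq_len(n), function(i) substr(d, i, i + n - 1L), "")
  }
  min(c(rots(sequence), rots(opalscan::revcomp(sequence))))
}

# Fine-grid scan for the isoelectric point (argmin |net charge|)
oracle_pi_grid <- function(protein, pka = opalscan::pka_emboss(),
                           step = 1e-4) {
  protein <- gsub("\\*+$", "", toupper(protein))
  aa <- strsplit(protein, "")[[1]]
  grid <- seq(0, 14, by = step)
  q <- rep(0, length(grid))
  n_pos <- c(Nterm = 1, K = sum(aa == "K"), R = sum(aa == "R"),
             H = sum(aa == "H"))
  n_neg <- c(Cterm = 1, D = sum(aa == "D"), E = sum(aa == "E"),
             C = sum(aa == "C"), Y = sum(aa == "Y"))
  for (g in names(n_pos)) q <- q + n_pos[[g]] / (1 + 10^(grid - pka[[g]]))
  for (g in names(n_neg)) q <- q - n_neg[[g]] / (1 + 10^(pka[[g]] - grid))
  grid[which.min(abs(q))]
}

# All-pairs interval intersection count (>= 1 shared position)
oracle_overlap_pairs <- function(starts, ends) {
  n <- length(starts)
  cnt <- 0L
  if (n < 2L) return(0L)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (min(ends[i], ends[j]) - max(starts[i], starts[j]) >= 1L) {
        cnt <- cnt + 1L
      }
    }
  }
  cnt
}

rand_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Random DNA free of TGA in all six frames (no TGA, no TCA substring)
rand_dna_tga_free <- function(n, gc = 0.5) {
  s <- rand_dna(n, gc)
  repeat {
    m <- regexpr("TGA|TCA", s)
    if (m < 0) return(s)
    substr(s, m + 1L, m + 1L) <- sample(c("A", "T"), 1L)
  }
}

orf_key <- function(df) {
  paste(df$start, df$end, df$strand, df$frame, df$partial, sep = ":")
}
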