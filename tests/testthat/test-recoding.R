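test_that("delta is exactly zero for contigs with no TGA in any frame", {
  withr::local_seed(9)
  s <- rand_dna_tga_free(2000, 0.45)
  r <- score_recoding(s)
  expect_identical(r$delta, 0)
  expect_false(r$candidate)
})

test_that("a TGA-interrupted gene fuses under table 4 and is counted", {
  filler <- function(n) strrep("GCT", n)
  # spacer codon after the TGA so the downstream fragment starts later and
  # the fused table-4 ORF strictly extends the table-11 union
  gene <- paste0("ATG", filler(30), "TGA", "GCT", "ATG", filler(30), "TAA")
  s <- paste0(strrep("C", 500), gene, strrep("C", 500))
  o11 <- call_orfs(s, genetic_code(11), 90)
  o4 <- call_orfs(s, genetic_code(4), 90)
  expect_equal(nrow(o11), 2L)
  expect_equal(nrow(o4), 1L)
  r <- score_recoding(s, min_orf_len = 90)
  expect_equal(r$merged_pairs, 1L)
  expect_gt(r$delta, 0)
})

test_that("short contigs are reported unevaluable, not scored", {
  r <- score_recoding(strrep("ACGT", 100))  # 400 bp
  expect_false(r$evaluable)
  expect_true(is.na(r$d4))
  expect_false(r$candidate)
})

test_that("synthetic code-4 and code-11 genomes separate cleanly", {
  g4 <- generate_genome(genome_spec(seed = 51))
  r4 <- score_recoding(g4$sequence)
  expect_gte(r4$delta, 0.10)
  expect_gte(r4$d4, 0.85)
  expect_true(r4$candidate)

  g11 <- generate_genome(genome_spec(code_id = 11, circular_overlap_len = 0,
                                     seed = 52))
  r11 <- score_recoding(g11$sequence)
  expect_lt(abs(r11$delta), 0.02)
  expect_false(r11$candidate)
})

test_that("organelle marker screen excludes flagged candidates only", {
  reports <- tibble::tibble(
    contig_id = c("c1", "c2", "c3"),
    candidate = c(TRUE, TRUE, FALSE))
  markers <- tibble::tibble(
    contig_id = c("c1", "c3", "ghost"),
    marker_label = c("NADH dehydrogenase subunit I", "photosystem II",
                     "cytochrome c oxidase"))
  expect_warning(out <- screen_organelle_markers(reports, markers), "ghost")
  expect_identical(out$excluded_reason,
                   c("organelle-like", NA_character_, NA_character_))
  expect_identical(out$candidate, c(FALSE, TRUE, FALSE))
  # empty marker table: vacuous filter
  out2 <- screen_organelle_markers(
    reports, tibble::tibble(contig_id = character(),
                            marker_label = character()))
  expect_identical(out2$candidate, reports$candidate)
})

test_that("decoy organelle contig is excluded, symbiont retained", {
  com <- generate_community(
    specs = c(list(genome_spec(n_genes = 40, seed = 61)),
              background_specs(n_background = 4, n_genes = 10)),
    host = host_spec(n_contigs = 3), seed = 62)
  scan <- scan_contigs(com$sequences)
  scan <- screen_organelle_markers(scan, com$markers)
  expect_identical(scan$excluded_reason[scan$contig_id == "decoy_mito_c1"],
                   "organelle-like")
  expect_true(scan$candidate[scan$contig_id == "symbiont_c1"])
  expect_equal(scan$contig_id[scan$candidate], "symbiont_c1")
})

test_that("planted terminal overlaps are detected exactly and trimmed", {
  withr::local_seed(15)
  core <- rand_dna(5000, 0.4)
  p <- rand_dna(100, 0.4)
  s <- paste0(p, core, p)
  res <- detect_terminal_overlap(s, k_min = 50)
  expect_equal(res$overlap_len, 100L)
  expect_true(res$is_circular)
  expect_equal(res$trimmed_length, nchar(s) - 100L)
  trimmed <- trim_terminal_overlap(s, k_min = 50)
  expect_equal(nchar(trimmed), nchar(s) - 100L)
  # trimming removes the planted repeat for good
  expect_equal(detect_terminal_overlap(trimmed, k_min = 50)$overlap_len, 0L)
})

test_that("terminal overlap agrees with the brute-force scan", {
  withr::local_seed(16)
  for (i in 1:60) {
    L <- sample(60:240, 1)
    s <- rand_dna(L, gc = 0.5)
    if (runif(1) < 0.5) {
      k <- sample(20:(L %/% 3), 1)
      s <- paste0(substr(s, 1, k), s)  # plant a terminal repeat
    }
    got <- detect_terminal_overlap(s, k_min = 20)$overlap_len
    expect_identical(got, oracle_terminal_overlap(s, 20L))
  }
  expect_error(detect_terminal_overlap(rand_dna(50, 0.5), k_min = 30),
               "longer")
  expect_error(detect_terminal_overlap(rand_dna(500, 0.5), k_min = 10),
               "k_min")
})

test_that("canonical rotation equals enumeration over both strands", {
  expect_identical(canonical_rotation("GAT"),
                   oracle_canonical_rotation("GAT"))
  withr::local_seed(17)
  for (i in 1:40) {
    s <- rand_dna(sample(3:25, 1), 0.5)
    expect_identical(canonical_rotation(s), oracle_canonical_rotation(s))
  }
})

test_that("canonical rotation is idempotent and rotation/strand invariant", {
  withr::local_seed(18)
  for (i in 1:10) {
    s <- rand_dna(sample(10:60, 1), 0.45)
    canon <- canonical_rotation(s)
    expect_identical(canonical_rotation(canon), canon)
    shift <- sample(nchar(s), 1)
    rot <- paste0(substr(s, shift, nchar(s)), substr(s, 1, shift - 1))
    expect_identical(canonical_rotation(rot), canon)
    expect_identical(canonical_rotation(revcomp(s)), canon)
  }
})
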