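test_that("genome_spec validates its invariants", {
  expect_error(genome_spec(gc_target = 1.2), "gc_target")
  expect_error(genome_spec(tga_trp_rate = -0.1), "tga_trp_rate")
  expect_error(genome_spec(code_id = 3), "code_id")
  expect_error(genome_spec(mean_gene_len = 30), "gene length")
  # tga_trp_rate forced to 0 under code 11
  sp <- genome_spec(code_id = 11, tga_trp_rate = 0.5)
  expect_equal(sp$tga_trp_rate, 0)
  # unreachable GC errors as an invalid spec
  expect_error(generate_genome(genome_spec(gc_target = 0)), "invalid-spec")
})

test_that("generation is deterministic: same seed, identical bytes", {
  a <- generate_genome(genome_spec(n_genes = 30, seed = 7))
  b <- generate_genome(genome_spec(n_genes = 30, seed = 7))
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$genes, b$genes)
  c <- generate_genome(genome_spec(n_genes = 30, seed = 8))
  expect_false(identical(a$sequence, c$sequence))
})

test_that("every emitted gene round-trips: valid ORF under the spec's code", {
  for (code in c(4, 11)) {
    g <- generate_genome(genome_spec(code_id = code, n_genes = 40,
                                     circular_overlap_len = 0, seed = 31))
    tab <- genetic_code(code)
    for (i in seq_len(nrow(g$genes))) {
      nt <- substr(g$sequence, g$genes$start[i] + 1, g$genes$end[i])
      if (g$genes$strand[i] == "-") nt <- revcomp(nt)
      aa <- translate_cds(nt, tab)
      expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
      expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
      expect_true(substr(nt, 1, 3) %in% tab$start_codons)
    }
    if (code == 11) {
      # no in-frame interior TGA in any gene, by construction
      expect_equal(sum(g$genes$n_tga), 0L)
    }
  }
})

test_that("interior TGA placement follows the requested rate", {
  g <- generate_genome(genome_spec(code_id = 4, n_genes = 200,
                                   mean_gene_len = 900,
                                   tga_trp_rate = 0.01, seed = 13))
  n <- sum(g$genes$n_interior_codons)
  k <- sum(g$genes$n_tga)
  ci <- qbinom(c(0.005, 0.995), n, 0.01)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("realized GC tracks the target within 0.03 on large genomes", {
  for (target in c(0.32, 0.50)) {
    g <- generate_genome(genome_spec(gc_target = target, n_genes = 80,
                                     seed = 19))
    expect_gt(nchar(g$sequence), 50000)
    expect_lt(abs(g$gc - target), 0.03)
  }
})

test_that("circular genomes carry an exact terminal repeat", {
  g <- generate_genome(genome_spec(n_genes = 30, circular_overlap_len = 100,
                                   seed = 3))
  L <- nchar(g$sequence)
  expect_identical(substr(g$sequence, 1, 100),
                   substr(g$sequence, L - 99, L))
})

test_that("community shapes, closure and determinism hold", {
  com <- generate_community(sequences = FALSE, seed = 21)
  n_contigs <- nrow(com$contigs)
  expect_equal(nrow(com$coverage), n_contigs * 29L)
  # per-sample true abundances sum to 1
  sums <- tapply(com$abundance$rel_abundance, com$abundance$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # every contig belongs to exactly one bin
  expect_equal(anyDuplicated(com$bins$contig_id), 0L)
  # determinism
  com2 <- generate_community(sequences = FALSE, seed = 21)
  expect_identical(com$coverage, com2$coverage)
  expect_identical(com$abundance, com2$abundance)
  expect_error(generate_community(depth_scale = 0), "depth_scale")
  expect_error(generate_community(n_samples = 2), "n_samples")
  expect_error(generate_community(rho_true = 1.5), "rho_true")
})

test_that("zero-noise, rho 1: host and symbiont abundances proportional", {
  com <- generate_community(sequences = FALSE, rho_true = 1, noise_sd = 0,
                            seed = 5)
  ab <- com$abundance
  h <- ab$rel_abundance[ab$bin_id == com$params$host_bin]
  s <- ab$rel_abundance[ab$bin_id == com$params$symbiont_bin]
  ratio <- h / s
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
})

test_that("log-abundance correlation of host and symbiont matches rho_true", {
  # Monte-Carlo over the generator's own truth output
  rs <- vapply(1:15, function(i) {
    com <- generate_community(sequences = FALSE, rho_true = 0.9,
                              seed = 400 + i)
    ab <- com$abundance
    h <- ab$log_abundance[ab$bin_id == com$params$host_bin]
    s <- ab$log_abundance[ab$bin_id == com$params$symbiont_bin]
    cor(h, s)
  }, 0)
  expect_lt(abs(mean(rs) - 0.9), 0.07)
})

test_that("written community files are byte-identical across runs", {
  com <- generate_community(
    specs = c(list(genome_spec(n_genes = 20, seed = 2)),
              background_specs(n_background = 4, n_genes = 10)),
    host = host_spec(n_contigs = 3), decoys = TRUE, seed = 33)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_community(com, d1)
  write_community(com, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  expect_setequal(list.files(d1),
                  c("contigs.fasta", "coverage.tsv", "bins.tsv",
                    "markers.tsv", "truth.json"))
})
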