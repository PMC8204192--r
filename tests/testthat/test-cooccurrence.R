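test_that("bin abundance is the length-weighted coverage sum", {
  cov <- tibble::tibble(contig_id = c("c1", "c2"), sample_id = "S1",
                        mean_depth = c(10, 4))
  bins <- tibble::tibble(contig_id = c("c1", "c2"), bin_id = "b1")
  A <- bin_abundance(cov, bins, c(c1 = 100, c2 = 50))
  expect_equal(A["b1", "S1"], 1200)
  expect_equal(attr(A, "bin_lengths")[["b1"]], 150)

  # all-zero coverage in a sample stays zero; missing pairs read as zero
  cov2 <- tibble::tibble(contig_id = c("c1", "c2", "c1"),
                         sample_id = c("S1", "S1", "S2"),
                         mean_depth = c(0, 0, 3))
  A2 <- bin_abundance(cov2, bins, c(c1 = 100, c2 = 50))
  expect_equal(A2["b1", "S1"], 0)
  expect_equal(A2["b1", "S2"], 300)

  # unbinned contigs are collected, negative input rejected
  bins3 <- tibble::tibble(contig_id = "c1", bin_id = "b1")
  A3 <- bin_abundance(cov, bins3, c(c1 = 100, c2 = 50))
  expect_true("unassigned" %in% rownames(A3))
  expect_error(bin_abundance(dplyr::mutate(cov, mean_depth = -1), bins,
                             c(c1 = 100, c2 = 50)), "negative")
})

test_that("bin abundance matches an independent per-row summation", {
  withr::local_seed(31)
  contigs <- sprintf("c%02d", 1:30)
  lens <- stats::setNames(sample(1000:50000, 30), contigs)
  bins <- tibble::tibble(contig_id = contigs,
                         bin_id = sample(sprintf("b%d", 1:6), 30,
                                         replace = TRUE))
  cov <- tidyr::crossing(contig_id = contigs,
                         sample_id = sprintf("S%d", 1:5)) |>
    dplyr::mutate(mean_depth = runif(dplyr::n(), 0, 50))
  A <- bin_abundance(cov, bins, lens)
  bin_of <- stats::setNames(bins$bin_id, bins$contig_id)
  for (b in rownames(A)) {
    for (s in colnames(A)) {
      rows <- cov$contig_id[cov$sample_id == s & bin_of[cov$contig_id] == b]
      want <- sum(lens[rows] *
                    cov$mean_depth[cov$sample_id == s &
                                     cov$contig_id %in% rows])
      expect_equal(A[b, s], want)
    }
  }
})

make_lognormal_matrix <- function(D, n, seed) {
  withr::with_seed(seed, {
    A <- matrix(exp(rnorm(D * n)), nrow = D,
                dimnames = list(sprintf("b%02d", 1:D),
                                sprintf("S%02d", 1:n)))
    A
  })
}

test_that("exactly proportional bins have zero log-ratio variance, rho 1", {
  A <- make_lognormal_matrix(10, 25, seed = 41)
  A["b02", ] <- 2 * A["b01", ]
  fit <- sparcc(A, n_dirichlet_resamples = 0)
  expect_equal(fit$t_mat["b01", "b02"], 0, tolerance = 1e-12)
  expect_equal(fit$rho["b01", "b02"], 1)
  expect_true(isSymmetric(fit$rho))
  expect_equal(unname(diag(fit$rho)), rep(1, 10))
  expect_true(all(abs(fit$rho) <= 1))
})

test_that("sparcc rejects unsupported sizes and drops dead bins", {
  A <- make_lognormal_matrix(3, 10, seed = 42)
  expect_error(sparcc(A), "unsupported size")
  B <- make_lognormal_matrix(6, 10, seed = 43)
  B["b03", ] <- 0
  expect_warning(fit <- sparcc(B, n_dirichlet_resamples = 0), "zero")
  expect_equal(nrow(fit$rho), 5L)
  expect_error(suppressWarnings(sparcc(B[, 1:2])), "samples")
  B["b01", 1] <- -1
  expect_error(sparcc(B), "non-negative")
})

test_that("sparcc is deterministic given a seed and scale invariant", {
  A <- make_lognormal_matrix(12, 20, seed = 44)
  f1 <- sparcc(A, seed = 7)
  f2 <- sparcc(A, seed = 7)
  expect_identical(f1$rho, f2$rho)
  # multiplying all abundances in one sample leaves t and rho unchanged
  A2 <- sweep(A, 2, c(10, rep(1, 19)), "*")
  f3 <- sparcc(A2, seed = 7)
  expect_lt(max(abs(f1$rho - f3$rho)), 1e-9)
  expect_lt(max(abs(f1$t_mat - f3$t_mat)), 1e-9)
})

test_that("permutation p-values hit the add-one floor for a perfect pair", {
  A <- make_lognormal_matrix(12, 30, seed = 45)
  A["b02", ] <- 3 * A["b01", ]
  fit <- sparcc(A, n_dirichlet_resamples = 0)
  fit <- sparcc_pvalues(fit, n_permutations = 999, seed = 8)
  expect_equal(fit$pval["b01", "b02"], 1 / 1000)
  expect_true(all(fit$pval >= 1 / 1000, na.rm = TRUE))
  expect_true(all(fit$pval <= 1, na.rm = TRUE))
  # determinism
  fit2 <- sparcc_pvalues(fit, n_permutations = 999, seed = 8)
  expect_identical(fit$pval, fit2$pval)
  expect_error(sparcc_pvalues(fit, n_permutations = 10), ">= 99")
})

test_that("null p-values are roughly uniform for independent bins", {
  A <- make_lognormal_matrix(8, 24, seed = 46)
  fit <- sparcc(A, n_dirichlet_resamples = 5, seed = 3)
  fit <- sparcc_pvalues(fit, n_permutations = 99, seed = 4)
  ps <- fit$pval[upper.tri(fit$pval)]
  frac05 <- mean(ps <= 0.05)
  expect_gte(frac05, 0)      # sanity: well-defined
  expect_lte(frac05, 0.15)   # no excess of spurious significance
})

test_that("host attribution ranks by rho with label tie-break", {
  withr::local_seed(48)
  bins <- c("target", "binA", "binB", "binC", sprintf("x%03d", 1:185))
  rho <- matrix(0.3, length(bins), length(bins),
                dimnames = list(bins, bins))
  rho["target", ] <- rho[, "target"] <-
    c(1, 0.89, 0.95, 0.85, runif(185, -0.2, 0.54))
  diag(rho) <- 1
  pv <- matrix(1e-3, length(bins), length(bins))
  dimnames(pv) <- dimnames(rho)
  fit <- structure(list(rho = rho, pval = pv), class = "sparcc_fit")
  got <- attribute_host(fit, "target", rho_min = 0.8, alpha = 0.01)
  expect_identical(got$bin_id, c("binB", "binA", "binC"))
  # all below threshold: empty
  expect_equal(nrow(attribute_host(fit, "target", rho_min = 0.99)), 0L)
  # ties broken by label
  rho["target", c("binA", "binB", "binC")] <- 0.9
  fit2 <- structure(list(rho = rho, pval = pv), class = "sparcc_fit")
  expect_identical(attribute_host(fit2, "target", rho_min = 0.8,
                                  alpha = 0.01)$bin_id,
                   c("binA", "binB", "binC"))
  expect_error(attribute_host(fit, "nope"), "not present")
})

test_that("tidy and glance summarize a fit", {
  A <- make_lognormal_matrix(6, 15, seed = 47)
  fit <- sparcc(A, n_dirichlet_resamples = 5, seed = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), choose(6, 2))
  expect_true(all(c("bin_a", "bin_b", "rho", "pval") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_bins, 6L)
  expect_equal(gl$n_samples, 15L)
})
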