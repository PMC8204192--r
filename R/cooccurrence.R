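#' Length-weighted bin abundances from coverage tables
#'
#' The per-sample abundance of a bin is the sum over its contigs of contig
#' length times mean read depth — a read-count proxy that weights each
#' contig by how much sequence it contributes.  Contigs present in the
#' coverage table but absent from the bin table are collected into bin
#' `"unassigned"`; missing (contig, sample) pairs count as depth 0.
#'
#' @param coverage Tibble with columns `contig_id`, `sample_id`,
#'   `mean_depth` (>= 0).
#' @param bins Tibble with columns `contig_id`, `bin_id`.
#' @param contig_lengths Named numeric vector of contig lengths, or a
#'   tibble with columns `contig_id`, `length`.
#' @return Numeric matrix bins x samples (rows/columns in sorted order)
#'   with a `bin_lengths` attribute (total length per bin).
#' @examples
#' cov <- tibble::tibble(contig_id = c("c1", "c2"), sample_id = "S1",
#'                       mean_depth = c(10, 4))
#' bins <- tibble::tibble(contig_id = c("c1", "c2"), bin_id = "b1")
#' bin_abundance(cov, bins, c(c1 = 100, c2 = 50))  # 100*10 + 50*4 = 1200
#' @export
bin_abundance <- function(coverage, bins, contig_lengths) {
  stopifnot(all(c("contig_id", "sample_id", "mean_depth") %in%
                  names(coverage)),
            all(c("contig_id", "bin_id") %in% names(bins)))
  if (is.data.frame(contig_lengths)) {
    contig_lengths <- stats::setNames(contig_lengths$length,
                                      contig_lengths$contig_id)
  }
  if (any(coverage$mean_depth < 0)) stop("negative coverage values")
  if (any(contig_lengths < 0)) stop("negative contig lengths")
  missing_len <- setdiff(unique(coverage$contig_id), names(contig_lengths))
  if (length(missing_len) > 0L) {
    stop("no length for contigs: ", paste(missing_len, collapse = ", "))
  }
  bin_of <- stats::setNames(bins$bin_id, bins$contig_id)
  tab <- coverage |>
    dplyr::mutate(
      bin_id = dplyr::coalesce(bin_of[.data$contig_id], "unassigned"),
      mass = contig_lengths[.data$contig_id] * .data$mean_depth) |>
    dplyr::group_by(.data$bin_id, .data$sample_id) |>
    dplyr::summarise(abundance = sum(.data$mass), .groups = "drop")
  bin_ids <- sort(unique(tab$bin_id))
  sample_ids <- sort(unique(tab$sample_id))
  A <- matrix(0, nrow = length(bin_ids), ncol = length(sample_ids),
              dimnames = list(bin_ids, sample_ids))
  A[cbind(tab$bin_id, tab$sample_id)] <- tab$abundance
  lens <- tibble::tibble(contig_id = names(contig_lengths),
                         length = unname(contig_lengths)) |>
    dplyr::mutate(bin_id = dplyr::coalesce(bin_of[.data$contig_id],
                                           "unassigned")) |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::summarise(length = sum(.data$length), .groups = "drop")
  attr(A, "bin_lengths") <- stats::setNames(lens$length, lens$bin_id)[bin_ids]
  A
}

# Sample-wise renormalization to a fixed effective depth: abundances carry
# only relative information, so the Dirichlet prior must not depend on the
# per-sample scale.
dirichlet_prior <- function(A, prior_depth) {
  sweep(A, 2, colSums(A), "/") * prior_depth + 1
}

rdirichlet_cols <- function(alpha) {
  g <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow = nrow(alpha))
  sweep(g, 2, colSums(g), "/")
}

# One basis-correlation estimate from a fraction matrix (bins x samples),
# with iterative exclusion of strongly correlated pairs.
sparcc_basis <- function(frac, exclusion_threshold, max_iterations) {
  D <- nrow(frac)
  logf <- log(frac)
  v <- apply(logf, 1, stats::var)
  cv <- stats::cov(t(logf))
  t_mat <- outer(v, v, "+") - 2 * cv        # var(log(x_i/x_j))
  diag(t_mat) <- 0
  t_mat[t_mat < 0] <- 0

  M <- matrix(1, D, D) + diag(D - 2, D)
  rowsum_t <- rowSums(t_mat)
  excluded <- matrix(FALSE, D, D)
  rho_from <- function(omega) {
    # non-positive basis variances (sparsity violations at small D) are
    # floored at the smallest positive estimate to keep rho finite
    pos <- omega[omega > 0]
    omega <- pmax(omega, if (length(pos)) min(pos) else 1e-4)
    r <- (outer(omega, omega, "+") - t_mat) /
      (2 * sqrt(outer(omega, omega, "*")))
    r[r > 1] <- 1; r[r < -1] <- -1
    diag(r) <- 1
    r
  }
  omega <- solve(M, rowsum_t)
  rho <- rho_from(omega)
  excl_log <- list()
  excl_count <- integer(D)
  for (it in seq_len(max_iterations)) {
    cand <- abs(rho)
    diag(cand) <- 0
    cand[excluded] <- 0
    # components already excluded from D-3 pairs stay in the solve but
    # cannot lose further pairs, keeping the system non-singular
    saturated <- excl_count >= D - 3L
    cand[saturated, ] <- 0
    cand[, saturated] <- 0
    m <- max(cand)
    if (m <= exclusion_threshold) break
    ij <- which(cand == m, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    excluded[i, j] <- excluded[j, i] <- TRUE
    excl_count[i] <- excl_count[i] + 1L
    excl_count[j] <- excl_count[j] + 1L
    excl_log[[length(excl_log) + 1L]] <-
      c(i = unname(i), j = unname(j), rho = unname(rho[i, j]))
    rowsum_t[i] <- rowsum_t[i] - t_mat[i, j]
    rowsum_t[j] <- rowsum_t[j] - t_mat[i, j]
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    M[i, j] <- M[j, i] <- 0
    omega_new <- tryCatch(solve(M, rowsum_t), error = function(e) NULL)
    if (is.null(omega_new)) break
    omega <- omega_new
    rho <- rho_from(omega)
  }
  list(rho = rho, omega = omega, t_mat = t_mat, exclusions = excl_log)
}

#' SparCC-style basis correlations from compositional abundances
#'
#' Estimates the correlations of underlying (basis) log-abundances from
#' compositional data, following the SparCC approach: the variance of the
#' log-ratio `log(x_i/x_j)` satisfies `t_ij = w_i + w_j - 2 rho_ij
#' sqrt(w_i w_j)`; under the sparsity assumption that most pairs are
#' uncorrelated, the basis variances `w` solve a linear system in the
#' row sums of `t`, and pairs whose estimated correlation exceeds
#' `exclusion_threshold` are iteratively removed from that system and the
#' solution refined.  Uncertainty in the fractions is integrated out by
#' Dirichlet resampling: each resample draws per-sample fractions from
#' `Dirichlet(rel_abundance * prior_depth + 1)` and the reported `rho` is
#' the element-wise median over resamples, clipped to \[-1, 1\].
#'
#' Samples are renormalized to a fixed effective depth (`prior_depth`)
#' before the Dirichlet draw, so results are invariant to per-sample
#' rescaling of the input (sequencing effort carries no information in
#' compositional data).  With `n_dirichlet_resamples = 0` the point
#' fractions are used directly (deterministic, exact for noise-free
#' checks).
#'
#' @param A Abundance matrix (bins x samples) from [bin_abundance()], all
#'   values >= 0; needs >= 4 bins and >= 3 samples.  Bins that are zero in
#'   every sample are dropped with a warning.
#' @param n_dirichlet_resamples Number of Dirichlet resamples (default 20;
#'   0 = deterministic point estimate).
#' @param exclusion_threshold Correlation magnitude above which the
#'   strongest pair is excluded from the sparsity approximation.
#' @param max_iterations Maximum exclusion iterations.
#' @param prior_depth Effective per-sample depth of the Dirichlet prior.
#' @param seed Integer seed making the resampling reproducible.
#' @return Object of class `sparcc_fit`: list with `rho` (basis
#'   correlation matrix, unit diagonal), `omega` (basis variances),
#'   `t_mat` (log-ratio variance matrix), `exclusions` (iteration log of
#'   the final resample), `pval` (`NULL` until [sparcc_pvalues()] is run)
#'   and the call parameters.
#' @references Friedman & Alm (2012) Inferring correlation networks from
#'   genomic survey data. PLoS Comput Biol 8:e1002687.
#' @export
sparcc <- function(A, n_dirichlet_resamples = 20, exclusion_threshold = 0.1,
                   max_iterations = 10, prior_depth = 1000, seed = 1) {
  stopifnot(is.matrix(A))
  if (any(A < 0)) stop("abundances must be non-negative")
  dead <- rowSums(A) == 0
  if (any(dead)) {
    warning("dropping bins with zero abundance in every sample: ",
            paste(rownames(A)[dead], collapse = ", "))
    A <- A[!dead, , drop = FALSE]
  }
  if (nrow(A) < 4L) {
    stop("unsupported size: SparCC basis solve needs >= 4 bins, got ",
         nrow(A))
  }
  if (ncol(A) < 3L) stop("need >= 3 samples")

  alpha <- dirichlet_prior(A, prior_depth)
  run <- function() {
    if (n_dirichlet_resamples == 0L) {
      # point estimate: plain fractions, pseudocount only where the
      # observation is a true zero, so exact proportionality is preserved
      a0 <- sweep(A, 2, colSums(A), "/") * prior_depth + (A == 0)
      frac <- sweep(a0, 2, colSums(a0), "/")
      return(sparcc_basis(frac, exclusion_threshold, max_iterations))
    }
    rhos <- array(NA_real_,
                  c(nrow(A), nrow(A), n_dirichlet_resamples))
    last <- NULL
    for (r in seq_len(n_dirichlet_resamples)) {
      frac <- rdirichlet_cols(alpha)
      dimnames(frac) <- dimnames(A)
      last <- sparcc_basis(frac, exclusion_threshold, max_iterations)
      rhos[, , r] <- last$rho
    }
    rho <- apply(rhos, c(1, 2), stats::median)
    rho[rho > 1] <- 1; rho[rho < -1] <- -1
    diag(rho) <- 1
    dimnames(rho) <- dimnames(last$rho)
    list(rho = rho, omega = last$omega, t_mat = last$t_mat,
         exclusions = last$exclusions)
  }
  res <- withr::with_seed(seed, run())
  dimnames(res$rho) <- list(rownames(A), rownames(A))
  dimnames(res$t_mat) <- list(rownames(A), rownames(A))
  names(res$omega) <- rownames(A)
  structure(
    list(rho = res$rho, omega = res$omega, t_mat = res$t_mat,
         exclusions = res$exclusions, pval = NULL,
         params = list(n_dirichlet_resamples = n_dirichlet_resamples,
                       exclusion_threshold = exclusion_threshold,
                       max_iterations = max_iterations,
                       prior_depth = prior_depth, seed = seed),
         abundance = A),
    class = "sparcc_fit"
  )
}

#' Permutation p-values for SparCC correlations
#'
#' For every bin pair, permutes sample labels independently per bin,
#' re-estimates the correlation matrix with the fit's own settings, and
#' reports the add-one permutation p-value `p = (1 + #{|rho_perm| >=
#' |rho_obs|}) / (1 + n_permutations)`.  The smallest attainable p-value is
#' therefore `1/(n_permutations + 1)`, never a literal zero.
#'
#' @param fit A [sparcc()] fit.
#' @param n_permutations Number of permutations (>= 99).
#' @param seed Integer seed; results are deterministic given it.
#' @return The fit, with `pval` filled in (matrix, `NA` diagonal).
#' @export
sparcc_pvalues <- function(fit, n_permutations = 99, seed = 1) {
  stopifnot(inherits(fit, "sparcc_fit"))
  if (n_permutations < 99) stop("n_permutations must be >= 99")
  A <- fit$abundance
  obs <- abs(fit$rho)
  p <- fit$params
  count <- matrix(0L, nrow(A), nrow(A))
  withr::with_seed(seed, {
    for (k in seq_len(n_permutations)) {
      Ap <- t(apply(A, 1, sample))
      perm <- sparcc(Ap, n_dirichlet_resamples = p$n_dirichlet_resamples,
                     exclusion_threshold = p$exclusion_threshold,
                     max_iterations = p$max_iterations,
                     prior_depth = p$prior_depth,
                     seed = sample.int(.Machine$integer.max, 1))
      count <- count + (abs(perm$rho) >= obs)
    }
  })
  pval <- (1 + count) / (1 + n_permutations)
  diag(pval) <- NA_real_
  dimnames(pval) <- dimnames(fit$rho)
  fit$pval <- pval
  fit$params$n_permutations <- n_permutations
  fit
}

#' Rank candidate host bins for a target bin
#'
#' Returns the bins whose basis correlation with the target passes
#' `rho_min` and (when p-values are available) whose permutation p-value
#' passes `alpha`, sorted by correlation descending with ties broken by
#' bin label.
#'
#' @param fit A [sparcc()] fit, ideally after [sparcc_pvalues()].
#' @param target_bin Bin whose host is sought (e.g. the symbiont bin).
#' @param rho_min Minimum correlation.
#' @param alpha Maximum permutation p-value (ignored with a message if the
#'   fit carries no p-values).
#' @return Tibble: `bin_id`, `rho`, `pval`, sorted as described.
#' @export
attribute_host <- function(fit, target_bin, rho_min = 0.8, alpha = 0.01) {
  stopifnot(inherits(fit, "sparcc_fit"))
  if (!target_bin %in% rownames(fit$rho)) {
    stop("target bin not present: ", target_bin)
  }
  others <- setdiff(rownames(fit$rho), target_bin)
  out <- tibble::tibble(
    bin_id = others,
    rho = fit$rho[target_bin, others],
    pval = if (is.null(fit$pval)) NA_real_ else fit$pval[target_bin, others]
  )
  keep <- out$rho >= rho_min
  if (!is.null(fit$pval)) keep <- keep & out$pval <= alpha
  out <- out[keep, , drop = FALSE]
  out[order(-out$rho, out$bin_id), ]
}

#' @export
print.sparcc_fit <- function(x, ...) {
  cat("<sparcc_fit>", nrow(x$rho), "bins |",
      ncol(x$abundance), "samples |",
      x$params$n_dirichlet_resamples, "resamples |",
      length(x$exclusions), "pairs excluded",
      if (!is.null(x$pval)) {
        paste("|", x$params$n_permutations, "permutations")
      } else "", "\n")
  invisible(x)
}

#' Tidy a SparCC fit into a long pair table
#'
#' @param x A `sparcc_fit`.
#' @param ... Unused.
#' @return Tibble with one row per unordered bin pair: `bin_a`, `bin_b`,
#'   `rho`, `pval`.
#' @export
tidy.sparcc_fit <- function(x, ...) {
  bins <- rownames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(
    bin_a = bins[idx[, 1]],
    bin_b = bins[idx[, 2]],
    rho = x$rho[idx],
    pval = if (is.null(x$pval)) NA_real_ else x$pval[idx]
  ) |> dplyr::arrange(dplyr::desc(.data$rho))
}

#' One-row summary of a SparCC fit
#'
#' @param x A `sparcc_fit`.
#' @param ... Unused.
#' @return Tibble: `n_bins`, `n_samples`, `n_excluded_pairs`, `max_rho`,
#'   `mean_abs_rho` (off-diagonal).
#' @export
glance.sparcc_fit <- function(x, ...) {
  off <- x$rho[upper.tri(x$rho)]
  tibble::tibble(
    n_bins = nrow(x$rho),
    n_samples = ncol(x$abundance),
    n_excluded_pairs = length(x$exclusions),
    max_rho = max(off),
    mean_abs_rho = mean(abs(off))
  )
}
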