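# Bayesian PSI quantification: conjugate Beta posterior per LSV edge.
#
# Reads r_j for edge j of a J-edge LSV are modelled as
#   r_j ~ Binomial(sum_j r_j, Psi_j)
# with the generalized Jeffreys prior Psi_j ~ Beta(1/J, 1 - 1/J), giving the
# closed-form posterior
#   Psi_j | r ~ Beta(1/J + r_j, 1 - 1/J + sum_{j' != j} r_j').

#' Conjugate PSI posterior for one read vector
#'
#' @param reads non-negative read rates, one per LSV edge (J >= 2).
#' @return data.frame with columns `alpha`, `beta`, `mean`, one row per edge.
#' @export
psi_posterior <- function(reads) {
  J <- length(reads)
  if (J < 2) stop("an LSV needs at least two edges (J >= 2)")
  if (any(reads < 0)) stop("read rates must be non-negative")
  alpha <- 1 / J + reads
  beta <- 1 - 1 / J + (sum(reads) - reads)
  data.frame(alpha = alpha, beta = beta, mean = alpha / (alpha + beta))
}

#' PSI discretization grid
#' @param B number of bins on \[0, 1\].
#' @return list with `breaks` (length B+1) and `centers` (length B).
#' @export
psi_grid <- function(B = 40L) {
  breaks <- seq(0, 1, length.out = B + 1)
  list(B = B, breaks = breaks,
       centers = (breaks[-1] + breaks[-(B + 1)]) / 2)
}

# discretize a Beta(a, b) to bin masses on the grid
discretize_beta <- function(alpha, beta, grid) {
  p <- diff(stats::pbeta(grid$breaks, alpha, beta))
  p / sum(p)
}

#' Group PSI posterior for one LSV
#'
#' Experiments passing the quantifiability thresholds contribute their
#' bootstrap read rates; per bootstrap replicate the passing experiments'
#' reads are summed and the conjugate posterior applied; the final density
#' per edge is the average of the replicate densities.
#'
#' @param experiments list, one element per experiment, each a list with:
#'   `boot` — an M x J matrix of bootstrap read rates (replicates x edges);
#'   `raw_reads` — total raw reads for the LSV in the experiment;
#'   `positions` — number of nonzero positions for the LSV.
#' @param min_reads,min_pos quantifiability thresholds (stricter than the
#'   builder's); an experiment passes when `raw_reads >= min_reads` and
#'   `positions >= min_pos`.
#' @param B discretization bins.
#' @return object of class `psi_posterior_group` with per-edge `means`,
#'   `density` (B x J), the grid, `n_pass`, and `quantifiable`; when no
#'   experiment passes, `quantifiable` is `FALSE` and no estimate is given.
#' @export
group_psi <- function(experiments, min_reads = 10, min_pos = 3, B = 40L) {
  pass <- vapply(experiments, function(e) {
    e$raw_reads >= min_reads && e$positions >= min_pos
  }, logical(1))
  grid <- psi_grid(B)
  if (!any(pass)) {
    return(structure(list(quantifiable = FALSE, n_pass = 0L, grid = grid,
                          means = NULL, density = NULL),
                     class = "psi_posterior_group"))
  }
  boots <- lapply(experiments[pass], `[[`, "boot")
  M <- nrow(boots[[1]])
  J <- ncol(boots[[1]])
  stopifnot(all(vapply(boots, nrow, integer(1)) == M),
            all(vapply(boots, ncol, integer(1)) == J))
  dens <- matrix(0, grid$B, J)
  means <- numeric(J)
  for (m in seq_len(M)) {
    r <- Reduce(`+`, lapply(boots, function(b) b[m, ]))
    post <- psi_posterior(r)
    for (j in seq_len(J)) dens[, j] <- dens[, j] +
        discretize_beta(post$alpha[j], post$beta[j], grid)
    means <- means + post$mean
  }
  dens <- dens / M
  means <- means / M
  structure(list(quantifiable = TRUE, n_pass = sum(pass), grid = grid,
                 means = means, density = dens),
            class = "psi_posterior_group")
}

#' @export
print.psi_posterior_group <- function(x, ...) {
  if (!x$quantifiable) {
    cat("PSI posterior: unquantifiable (no experiment passed thresholds)\n")
  } else {
    cat(sprintf("PSI posterior over %d edges (%d experiments): E[Psi] = %s\n",
                length(x$means), x$n_pass,
                paste(sprintf("%.3f", x$means), collapse = ", ")))
  }
  invisible(x)
}

#' Per-experiment PSI posterior (heterogeneous mode)
#'
#' Quantifies one experiment on its own for one LSV edge set, averaging the
#' posterior over bootstrap replicates; used by the HET comparisons where
#' experiments are not pooled.
#'
#' @param boot M x J bootstrap read-rate matrix for the experiment.
#' @param B discretization bins.
#' @return list with per-edge `means` and `density` (B x J).
#' @export
experiment_psi <- function(boot, B = 40L) {
  grid <- psi_grid(B)
  M <- nrow(boot); J <- ncol(boot)
  dens <- matrix(0, grid$B, J)
  means <- numeric(J)
  for (m in seq_len(M)) {
    post <- psi_posterior(boot[m, ])
    for (j in seq_len(J)) dens[, j] <- dens[, j] +
        discretize_beta(post$alpha[j], post$beta[j], grid)
    means <- means + post$mean
  }
  list(means = means / M, density = dens / M, grid = grid)
}
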