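# Independent oracles used across tests.

# Exhaustive label-enumeration p values for the three rank statistics:
# every C(n, n1) assignment of group-1 labels to the pooled values.
enum_rank_pvalues <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  idx <- utils::combn(n1 + n2, n1)
  u_obs <- lsvquant:::mwu_2u(x, y)
  tn_obs <- tnom(x, y)$statistic
  is_obs <- infoscore(x, y)$statistic
  n12 <- n1 * n2
  us <- apply(idx, 2, function(s) lsvquant:::mwu_2u(vals[s], vals[-s]))
  tns <- apply(idx, 2, function(s) tnom(vals[s], vals[-s])$statistic)
  iss <- apply(idx, 2, function(s) infoscore(vals[s], vals[-s])$statistic)
  list(mwu = mean(abs(us - n12) >= abs(u_obs - n12)),
       tnom = mean(tns <= tn_obs),
       infoscore = mean(iss >= is_obs - 1e-9))
}

# Brute-force grid posterior: binomial likelihood times the generalized
# Jeffreys prior, normalized on a fine PSI grid.
grid_bayes_psi <- function(r, j, n_grid = 4001) {
  J <- length(r)
  psi <- seq(1 / (2 * n_grid), 1 - 1 / (2 * n_grid), length.out = n_grid)
  lik <- psi^r[j] * (1 - psi)^(sum(r) - r[j])
  pri <- stats::dbeta(psi, 1 / J, 1 - 1 / J)
  w <- lik * pri
  list(psi = psi, density = w / sum(w))
}

# total-variation distance between the conjugate posterior and the grid
# posterior for edge j
conjugacy_tv <- function(r, j, n_grid = 4001) {
  post <- psi_posterior(r)
  psi <- seq(1 / (2 * n_grid), 1 - 1 / (2 * n_grid), length.out = n_grid)
  exact <- stats::dbeta(psi, post$alpha[j], post$beta[j])
  exact <- exact / sum(exact)
  0.5 * sum(abs(exact - grid_bayes_psi(r, j, n_grid)$density))
}

exon_mat <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

# a hand-built cassette-exon splicegraph (E1, E2, E3; J12, J13, J23)
cassette_sg <- function(gene_id = "g", strand = "+") {
  splicegraph(
    gene_id, "chr1", strand,
    exons = data.frame(start = c(0, 1000, 2000), end = c(400, 1400, 2400),
                       annotated = TRUE, denovo_extended = FALSE),
    junctions = data.frame(start = c(400, 400, 1400),
                           end = c(1000, 2000, 2000),
                           annotated = TRUE, simplified = FALSE)
  )
}

# discretized Beta(a, b) on the B-bin PSI grid
discretize_grid_beta <- function(a, b, B = 40) {
  p <- diff(stats::pbeta(seq(0, 1, length.out = B + 1), a, b))
  p / sum(p)
}
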