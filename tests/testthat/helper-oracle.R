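# Independent brute-force oracle for partial correlations: the partial
# correlation of (i, j) given the rest is the correlation of the
# residuals from the population least-squares regressions of Y_i and
# Y_j on all remaining variables, computed directly from a covariance
# matrix by Schur complement.  This path never touches the precision
# matrix, so it checks the matrix-inversion estimator independently.
pcor_oracle <- function(S, i, j) {
  rest <- setdiff(seq_len(nrow(S)), c(i, j))
  if (length(rest) == 0) {
    return(S[i, j] / sqrt(S[i, i] * S[j, j]))
  }
  Srr <- S[c(i, j), c(i, j)]
  Sro <- S[c(i, j), rest, drop = FALSE]
  Soo <- S[rest, rest, drop = FALSE]
  resid_cov <- Srr - Sro %*% solve(Soo, t(Sro))
  resid_cov[1, 2] / sqrt(resid_cov[1, 1] * resid_cov[2, 2])
}

# Random symmetric positive definite matrix via Wishart draws.
random_pd <- function(p, df = p + 5) {
  stats::rWishart(1, df = df, Sigma = diag(p))[, , 1]
}

# Small chain-graph dataset used by several tests.
small_chain_data <- function(M = 10, h2 = 0.5, seed = 1) {
  simulate_traits(trait_model(canonical_graph("chain"), h2),
                  build_families(M), seed = seed)
}
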