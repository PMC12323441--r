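#' Sample covariance of a clustered dataset
#'
#' Standard unbiased sample covariance (divisor \eqn{N - 1}) of the
#' trait matrix, ignoring cluster labels.  Clustering affects the
#' sampling distribution of downstream statistics, not the point
#' estimate itself.
#'
#' @param data a [clustered_dataset()].
#' @return A \eqn{p \times p} covariance matrix.
#' @export
sample_covariance <- function(data) {
  stopifnot(inherits(data, "clustered_dataset"))
  if (nrow(data$values) < 2) {
    stop("need at least 2 observations for a sample covariance",
         call. = FALSE)
  }
  stats::cov(data$values)
}

#' Partial correlations from a covariance matrix
#'
#' Inverts the covariance matrix and normalizes the negated off-diagonal
#' of the precision matrix:
#' \deqn{\hat\rho_{ij} = -\frac{\hat k_{ij}}{\sqrt{\hat k_{ii}\hat k_{jj}}}}
#' The diagonal is set to 1 by convention (only off-diagonal entries are
#' used for inference).
#'
#' @param S symmetric positive definite covariance matrix.
#' @param n_obs optional sample size the covariance was computed from
#'   (carried along for downstream tests).
#' @return An object of class `partial_corr_estimate` with components
#'   `S`, `P_hat`, and `n_obs`.
#' @export
partial_corr_from_cov <- function(S, n_obs = NA_integer_) {
  if (!is_square_symmetric(S, tol = 1e-8)) {
    stop("`S` must be a symmetric numeric matrix", call. = FALSE)
  }
  p <- nrow(S)
  if (rcond(S) < 1e-12) {
    stop("precision matrix not estimable: covariance matrix of dimension ",
         p, " is singular or near-singular (constant column or N <= p?)",
         call. = FALSE)
  }
  K <- chol2inv(chol(S))
  P_hat <- -stats::cov2cor(K)
  diag(P_hat) <- 1
  P_hat <- (P_hat + t(P_hat)) / 2
  structure(list(S = S, P_hat = P_hat, n_obs = n_obs),
            class = "partial_corr_estimate")
}

#' Fisher Z transformation
#'
#' The variance-stabilizing transform \eqn{R = \frac{1}{2}\log\frac{1 +
#' \rho}{1 - \rho}}.  For a partial correlation estimated from \eqn{N}
#' iid Gaussian observations on \eqn{p} variables, \eqn{R} is
#' approximately \eqn{N(0, 1/(N - p - 3))} under the null \eqn{\rho = 0}.
#'
#' @param rho correlation value(s) strictly inside (-1, 1).
#' @return Transformed value(s).
#' @examples
#' fisher_z(0.5)  # 0.5493061
#' @export
fisher_z <- function(rho) {
  if (any(!is.finite(rho)) || any(abs(rho) >= 1)) {
    stop("`rho` must lie strictly in (-1, 1); a degenerate estimate ",
         "usually means the sample size is too close to the number of ",
         "variables", call. = FALSE)
  }
  0.5 * log((1 + rho) / (1 - rho))
}

## Assemble the per-pair edge table shared by all tests.
edge_table <- function(P_hat, Z, alpha, correction, var_names) {
  p <- nrow(P_hat)
  pairs <- all_pairs(p)
  n_tests <- nrow(pairs)
  level <- switch(correction,
                  none = alpha,
                  bonferroni = alpha / n_tests,
                  stop("unknown correction: ", correction, call. = FALSE))
  rho <- P_hat[pairs]
  z <- Z[pairs]
  pval <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(var_i = var_names[pairs[, 1]],
                    var_j = var_names[pairs[, 2]],
                    i = pairs[, 1], j = pairs[, 2],
                    rho_hat = rho,
                    R = fisher_z(rho),
                    Z = z,
                    p_value = pval,
                    reject = pval < level,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "operative_level") <- level
  attr(out, "correction") <- correction
  class(out) <- c("edge_inference", "data.frame")
  out
}

#' Fisher Z edge test assuming independent observations
#'
#' The conventional GGM edge test: for each variable pair, the Fisher
#' statistic of the estimated partial correlation is compared against
#' its iid null distribution \eqn{N(0, 1/(N - p - 3))}, i.e.
#' \eqn{Z_{ij} = \sqrt{N - p - 3}\, R_{ij}}, two-sided.  Cluster labels
#' are ignored: with correlated observations this test is anti-
#' conservative and serves as the baseline the cluster bootstrap is
#' compared against.
#'
#' @param data a [clustered_dataset()].
#' @param alpha significance level (default 0.05).
#' @param correction `"none"` (per-edge tests, default) or
#'   `"bonferroni"` (level divided by the number of pairs
#'   \eqn{p(p-1)/2}).
#' @return A data frame of class `edge_inference` with one row per
#'   unordered pair: `var_i`, `var_j`, `rho_hat`, `R`, `Z`, `p_value`,
#'   `reject`.
#' @export
iid_edge_test <- function(data, alpha = 0.05,
                          correction = c("none", "bonferroni")) {
  stopifnot(inherits(data, "clustered_dataset"))
  correction <- match.arg(correction)
  N <- nrow(data$values)
  p <- ncol(data$values)
  if (N <= p + 3) {
    stop("test statistic undefined: need N > p + 3 (N = ", N,
         ", p = ", p, ")", call. = FALSE)
  }
  est <- partial_corr_from_cov(sample_covariance(data), n_obs = N)
  R <- suppressWarnings(atanh(est$P_hat))
  Z <- sqrt(N - p - 3) * R
  edge_table(est$P_hat, Z, alpha, correction, data$variable_names)
}

#' Write an edge inference table to TSV
#'
#' @param edges an `edge_inference` data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(edges, path) {
  stopifnot(inherits(edges, "edge_inference"))
  cols <- c("var_i", "var_j", "rho_hat", "R", "Z", "p_value", "reject")
  utils::write.table(edges[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
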