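#' Ground-truth Gaussian graphical model specifications
#'
#' A `graph_spec` bundles the three equivalent descriptions of a Gaussian
#' graphical model (GGM): the covariance matrix \eqn{\Sigma}, the precision
#' matrix \eqn{K = \Sigma^{-1}}, and the partial correlation matrix \eqn{P}
#' with entries \eqn{\rho_{ij} = -k_{ij} / \sqrt{k_{ii} k_{jj}}} off the
#' diagonal and 1 on the diagonal.  An edge \eqn{\{i, j\}} is present
#' exactly when \eqn{\rho_{ij} \neq 0}.
#'
#' @param P symmetric partial correlation matrix with unit diagonal and
#'   off-diagonal entries in (-1, 1).  The implied precision matrix (unit
#'   diagonal, off-diagonal \eqn{-P_{ij}}) must be positive definite.
#' @param mean optional mean vector (default all zeros).
#' @return An object of class `graph_spec` with components `p`, `edges`
#'   (2-column matrix of 1-based vertex pairs, i < j), `partial_corr`,
#'   `precision`, `covariance`, and `mean`.
#' @examples
#' P <- diag(3)
#' P[1, 2] <- P[2, 1] <- 0.3
#' P[2, 3] <- P[3, 2] <- 0.3
#' g <- graph_from_partial_corr(P)
#' g$edges
#' @export
graph_from_partial_corr <- function(P, mean = NULL) {
  if (!is_square_symmetric(P, tol = 1e-10)) {
    stop("`P` must be a symmetric numeric matrix", call. = FALSE)
  }
  p <- nrow(P)
  if (max(abs(diag(P) - 1)) > 1e-10) {
    stop("`P` must have unit diagonal", call. = FALSE)
  }
  off <- P[upper.tri(P)]
  if (any(abs(off) >= 1)) {
    stop("off-diagonal partial correlations must lie in (-1, 1)",
         call. = FALSE)
  }
  ## With K scaled to unit diagonal, rho_ij = -k_ij, so K = -P off the
  ## diagonal and 1 on it.
  K <- -P
  diag(K) <- 1
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("invalid partial correlation structure: implied precision matrix ",
         "is not positive definite (smallest eigenvalue ",
         format(min(ev), digits = 4), ")", call. = FALSE)
  }
  Sigma <- chol2inv(chol(K))
  Sigma <- (Sigma + t(Sigma)) / 2
  pairs <- all_pairs(p)
  on_edge <- abs(P[pairs]) > 1e-10
  mu <- if (is.null(mean)) numeric(p) else as.numeric(mean)
  stopifnot(length(mu) == p)
  structure(
    list(p = p,
         edges = pairs[on_edge, , drop = FALSE],
         partial_corr = P,
         precision = K,
         covariance = Sigma,
         mean = mu),
    class = "graph_spec")
}

#' @export
print.graph_spec <- function(x, ...) {
  cat("Gaussian graphical model:", x$p, "vertices,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges) > 0) {
    cat("edges:",
        paste(sprintf("{%d,%d}", x$edges[, 1], x$edges[, 2]),
              collapse = " "), "\n")
  }
  invisible(x)
}

## Membership test for an unordered pair in a graph_spec edge matrix.
has_edge <- function(graph, i, j) {
  e <- graph$edges
  any(e[, 1] == min(i, j) & e[, 2] == max(i, j))
}

#' Canonical simulation graphs
#'
#' Builds the ground-truth GGMs used throughout the simulation study:
#' \describe{
#'   \item{`independence`}{3 marginally independent variables, no edges.}
#'   \item{`chain`}{3 variables with edges \{1,2\} and \{2,3\}; variables
#'     1 and 3 are conditionally independent given 2 while remaining
#'     marginally correlated.}
#'   \item{`triangle_tail`}{4 variables; 1, 2, 3 fully connected and a
#'     tail vertex 4 attached only to 3, so 4 is independent of 1 and 2
#'     given 3.}
#'   \item{`prs_like`}{a sparse random graph standing in for a network of
#'     polygenic risk scores; edge partial correlations have magnitude at
#'     least 0.01 and non-edges are exact zeros.}
#' }
#'
#' @param name one of `"independence"`, `"chain"`, `"triangle_tail"`,
#'   `"prs_like"`.
#' @param strength partial correlation magnitude placed on edges (for
#'   `prs_like`, the upper end of the magnitude range).  Default 0.3.
#' @param p_extra vertex count for `prs_like` (default 30).
#' @param density fraction of vertex pairs connected in `prs_like`
#'   (default 0.1).
#' @param seed integer seed making `prs_like` reproducible.
#' @return A [graph_from_partial_corr()] `graph_spec`.
#' @export
canonical_graph <- function(name = c("independence", "chain",
                                     "triangle_tail", "prs_like"),
                            strength = 0.3, p_extra = 30,
                            density = 0.1, seed = 1L) {
  name <- match.arg(name)
  if (!is.numeric(strength) || strength <= 0 || strength >= 1) {
    stop("`strength` must lie in (0, 1)", call. = FALSE)
  }
  if (name == "independence") {
    return(graph_from_partial_corr(diag(3)))
  }
  if (name == "chain") {
    P <- diag(3)
    P[1, 2] <- P[2, 1] <- strength
    P[2, 3] <- P[3, 2] <- strength
    return(graph_from_partial_corr(P))
  }
  if (name == "triangle_tail") {
    P <- diag(4)
    for (e in list(c(1, 2), c(1, 3), c(2, 3), c(3, 4))) {
      P[e[1], e[2]] <- P[e[2], e[1]] <- strength
    }
    return(graph_from_partial_corr(P))
  }
  ## prs_like: seeded sparse random partial correlation matrix.  Edge
  ## magnitudes are drawn in [0.01, strength]; if the implied precision
  ## matrix is not positive definite the magnitudes are dampened and the
  ## draw retried.
  if (density <= 0 || density >= 1) {
    stop("`density` must lie in (0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    pairs <- all_pairs(p_extra)
    n_pairs <- nrow(pairs)
    n_edges <- max(1L, round(density * n_pairs))
    on <- sample.int(n_pairs, n_edges)
    mag <- stats::runif(n_edges, min = 0.01, max = strength)
    sgn <- sample(c(-1, 1), n_edges, replace = TRUE)
    for (attempt in seq_len(50)) {
      P <- diag(p_extra)
      vals <- sgn * pmax(mag, 0.01)
      P[pairs[on, , drop = FALSE]] <- vals
      P[pairs[on, 2:1, drop = FALSE]] <- vals
      g <- tryCatch(graph_from_partial_corr(P), error = function(e) NULL)
      if (!is.null(g)) return(g)
      mag <- mag * 0.8
      if (max(mag) < 0.01) break
    }
    stop("could not generate a positive definite `prs_like` structure ",
         "for the requested strength/density; reduce one of them",
         call. = FALSE)
  })
}

#' Serialize a graph specification to JSON
#'
#' Writes (or returns) a plain JSON document with fields `p`, `mean`,
#' `partial_corr` (nested arrays) and `edges` (pairs of 1-based vertex
#' labels).  The precision and covariance matrices are reconstructed on
#' read, so the document is minimal and exact.
#'
#' @param graph a `graph_spec`.
#' @param path optional file path; when omitted the JSON string is
#'   returned.
#' @return `path` invisibly, or the JSON string.
#' @export
graph_to_json <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "graph_spec"))
  doc <- list(p = graph$p,
              mean = graph$mean,
              partial_corr = graph$partial_corr,
              edges = graph$edges)
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname graph_to_json
#' @param json a JSON string or file path produced by [graph_to_json()].
#' @export
graph_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  P <- matrix(as.numeric(doc$partial_corr), nrow = doc$p)
  graph_from_partial_corr(P, mean = doc$mean)
}
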