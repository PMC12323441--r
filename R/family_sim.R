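#' Pedigrees of two-generation nuclear families
#'
#' A `pedigree_set` holds an ordered list of nuclear families, each with
#' two unrelated parents and one or more offspring.  Within a family,
#' parent-offspring and full-sib pairs are first-degree relatives
#' (relatedness coefficient \eqn{2^{-1} = 0.5}); the two parents are
#' unrelated.  Members of different families are unrelated.
#'
#' @param offspring_counts integer vector, one entry per family, giving
#'   the number of offspring (each family also has two parents).
#' @return An object of class `pedigree_set` with components `families`
#'   (list of per-family data frames with columns `member` and `role`),
#'   `sizes`, and `n` (total individuals).
#' @export
pedigree_set <- function(offspring_counts) {
  offspring_counts <- as.integer(offspring_counts)
  if (length(offspring_counts) < 1 || any(offspring_counts < 1)) {
    stop("each family needs at least one offspring", call. = FALSE)
  }
  families <- lapply(seq_along(offspring_counts), function(m) {
    k <- offspring_counts[m]
    data.frame(member = seq_len(2L + k),
               role = c("parent1", "parent2",
                        paste0("offspring_", seq_len(k))),
               stringsAsFactors = FALSE)
  })
  structure(list(families = families,
                 sizes = 2L + offspring_counts,
                 n = sum(2L + offspring_counts)),
            class = "pedigree_set")
}

#' Mixed family structure for the simulation study
#'
#' Builds `M` families, the first half with two parents and one
#' offspring (size 3) and the second half with two parents and five
#' offspring (size 7), for a total of \eqn{N = 5M} individuals.
#'
#' @param M even number of families, at least 2.
#' @return A [pedigree_set()].
#' @examples
#' build_families(40)$n   # 200
#' @export
build_families <- function(M) {
  if (!is.numeric(M) || length(M) != 1 || M < 2) {
    stop("`M` must be a single number >= 2", call. = FALSE)
  }
  M <- as.integer(M)
  if (M %% 2L != 0L) {
    stop("`M` must be even: the design splits families equally between ",
         "3-member and 7-member households", call. = FALSE)
  }
  pedigree_set(c(rep(1L, M %/% 2L), rep(5L, M %/% 2L)))
}

#' @export
print.pedigree_set <- function(x, ...) {
  cat("pedigree_set:", length(x$families), "families,", x$n,
      "individuals (sizes:",
      paste(rle(x$sizes)$values, "x", rle(x$sizes)$lengths,
            collapse = ", "), ")\n")
  invisible(x)
}

## Relatedness block for one nuclear family with k offspring: members
## ordered parent1, parent2, offspring_1..k.  Parents unrelated (0);
## parent-offspring and sib-sib pairs are first degree (2^-1).
family_phi_block <- function(size) {
  phi <- matrix(0.5, size, size)
  diag(phi) <- 1
  phi[1, 2] <- phi[2, 1] <- 0
  phi
}

#' Relatedness matrix of a pedigree
#'
#' Returns the block-diagonal \eqn{N \times N} relatedness matrix
#' \eqn{\Phi}: entries are \eqn{2^{-d}} for \eqn{d}-th degree relative
#' pairs, 1 on the diagonal (\eqn{d = 0}, as for monozygotic twins), and
#' 0 between members of different families.
#'
#' @param ped a [pedigree_set()].
#' @return A list of class `relatedness_matrix` with `phi` (a sparse
#'   symmetric [Matrix::Matrix()]), `blocks` (per-family dense blocks),
#'   and `family_index` (row-to-family map).
#' @export
relatedness_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree_set"))
  blocks <- lapply(ped$sizes, family_phi_block)
  phi <- Matrix::bdiag(blocks)
  structure(list(phi = phi,
                 blocks = blocks,
                 family_index = rep(seq_along(ped$sizes), ped$sizes)),
            class = "relatedness_matrix")
}

#' Variance-components trait model
#'
#' Decomposes the target covariance \eqn{\Sigma} of a [graph_spec] into a
#' genetic component \eqn{\Sigma_g = h^2 \Sigma} shared among relatives
#' and an environmental component \eqn{\Sigma_e = (1 - h^2) \Sigma}
#' independent across individuals, so that \eqn{\Sigma_e + \Sigma_g =
#' \Sigma} exactly.  `heritability` is the scalar \eqn{h^2}, the fraction
#' of each trait's variance attributable to the genetic component; the
#' same value applies to every trait (a diagonal heritability matrix
#' \eqn{H = h^2 I}).  Non-scalar heritability is not supported because
#' the implied covariance is not guaranteed to be positive semi-definite.
#'
#' @param graph a [graph_spec] supplying \eqn{\Sigma} and \eqn{\mu}.
#' @param heritability scalar \eqn{h^2} in \[0, 1).
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(graph, heritability) {
  stopifnot(inherits(graph, "graph_spec"))
  if (!is.numeric(heritability) || length(heritability) != 1 ||
      heritability < 0 || heritability >= 1) {
    stop("`heritability` must be a single value in [0, 1)", call. = FALSE)
  }
  structure(list(graph = graph,
                 heritability = heritability,
                 sigma_g = heritability * graph$covariance,
                 sigma_e = (1 - heritability) * graph$covariance),
            class = "trait_model")
}

#' Clustered multivariate datasets
#'
#' Container for an \eqn{N \times p} trait matrix whose rows are grouped
#' into clusters (families).  Missing values are not permitted.
#'
#' @param values numeric matrix, one row per observation.
#' @param cluster_ids length-N vector of cluster labels.
#' @param variable_names optional column names (default `V1..Vp`).
#' @return An object of class `clustered_dataset`.
#' @export
clustered_dataset <- function(values, cluster_ids, variable_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values)) {
    stop("`values` must be a numeric matrix without missing values",
         call. = FALSE)
  }
  if (nrow(values) < 1 || ncol(values) < 2) {
    stop("need at least 1 observation and 2 variables", call. = FALSE)
  }
  if (length(cluster_ids) != nrow(values)) {
    stop("`cluster_ids` must label every row", call. = FALSE)
  }
  vn <- variable_names %||% colnames(values) %||%
    paste0("V", seq_len(ncol(values)))
  colnames(values) <- vn
  structure(list(values = values,
                 cluster_ids = as.character(cluster_ids),
                 variable_names = vn),
            class = "clustered_dataset")
}

#' @export
print.clustered_dataset <- function(x, ...) {
  cat("clustered_dataset:", nrow(x$values), "observations x",
      ncol(x$values), "variables in",
      length(unique(x$cluster_ids)), "clusters\n")
  invisible(x)
}

## Per-family-size upper Cholesky factors of the trait covariance
## kronecker(Phi_s, Sigma_g) + kronecker(I_s, Sigma_e), individual-major
## (individuals outer, traits inner).  Cached per distinct family size.
family_chol_factors <- function(model, sizes) {
  out <- list()
  for (s in unique(sizes)) {
    cov_block <- kronecker(family_phi_block(s), model$sigma_g) +
      kronecker(diag(s), model$sigma_e)
    out[[as.character(s)]] <- chol(cov_block)
  }
  out
}

#' Simulate family traits under the variance-components model
#'
#' Draws \eqn{Y = \mu + E + G} where the environmental components are
#' independent across individuals, \eqn{E \sim MVN(0, I \otimes
#' \Sigma_e)}, and the genetic components are shared within families
#' according to the relatedness matrix, \eqn{G \sim MVN(0, \Phi \otimes
#' \Sigma_g)}.  Families are mutually independent, so sampling is done
#' family by family from the per-family covariance block
#' \eqn{\Phi_m \otimes \Sigma_g + I \otimes \Sigma_e} (individual-major
#' ordering: individuals outer, traits inner).  For speed, families are
#' drawn in batches sharing a Cholesky factor: one batch per distinct
#' family size, sizes taken in order of first appearance and families
#' within a batch in pedigree order.  The batch order fixes the RNG
#' stream, so with a fixed seed the output is bit-reproducible.
#'
#' @param model a [trait_model()].
#' @param ped a [pedigree_set()].
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return A [clustered_dataset()] whose cluster labels are `fam<m>`.
#' @examples
#' g <- canonical_graph("chain")
#' d <- simulate_traits(trait_model(g, 0.5), build_families(4), seed = 1)
#' d
#' @export
simulate_traits <- function(model, ped, seed = NULL) {
  stopifnot(inherits(model, "trait_model"), inherits(ped, "pedigree_set"))
  p <- model$graph$p
  sizes <- ped$sizes
  chol_by_size <- family_chol_factors(model, sizes)
  row_start <- cumsum(c(0L, sizes))
  with_seed(seed, {
    values <- matrix(NA_real_, ped$n, p)
    for (s in unique(sizes)) {
      fams <- which(sizes == s)
      R <- chol_by_size[[as.character(s)]]
      Z <- matrix(stats::rnorm(length(fams) * s * p), nrow = length(fams))
      block <- Z %*% R
      rows <- sequence(rep(s, length(fams))) +
        rep(row_start[fams], each = s)
      values[rows, ] <- matrix(t(block), ncol = p, byrow = TRUE)
    }
    values <- sweep(values, 2, model$graph$mean, "+")
    clustered_dataset(values,
                      cluster_ids = rep(paste0("fam", seq_along(ped$sizes)),
                                        ped$sizes),
                      variable_names = paste0("V", seq_len(p)))
  })
}

#' Read and write clustered datasets as delimited text
#'
#' The on-disk format is a delimited table (tab by default) with the
#' cluster label in the first column and one named column per trait.
#'
#' @param data a [clustered_dataset()].
#' @param path file path.
#' @param cluster_col name for/of the cluster ID column (default
#'   `"cluster"`; on read, a column name or index).
#' @param sep field separator.
#' @return `write_clustered_tsv` returns `path` invisibly;
#'   `read_clustered_tsv` returns a [clustered_dataset()].
#' @export
write_clustered_tsv <- function(data, path, cluster_col = "cluster",
                                sep = "\t") {
  stopifnot(inherits(data, "clustered_dataset"))
  df <- data.frame(data$cluster_ids, data$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- cluster_col
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_clustered_tsv
#' @export
read_clustered_tsv <- function(path, cluster_col = 1, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (is.character(cluster_col)) {
    cluster_col <- match(cluster_col, names(df))
    if (is.na(cluster_col)) stop("cluster column not found", call. = FALSE)
  }
  ids <- df[[cluster_col]]
  values <- as.matrix(df[, -cluster_col, drop = FALSE])
  if (anyNA(values)) {
    stop("missing values are not permitted in a clustered dataset",
         call. = FALSE)
  }
  clustered_dataset(values, ids)
}
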