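test_that("the mixed family design yields N = 5M individuals", {
  for (M in c(40, 120, 360)) {
    ped <- build_families(M)
    expect_equal(ped$n, 5 * M)
    expect_equal(sum(ped$sizes == 3), M / 2)
    expect_equal(sum(ped$sizes == 7), M / 2)
  }
  ped <- build_families(2)
  expect_equal(sort(ped$sizes), c(3, 7))
  expect_equal(ped$n, 10)
  expect_error(build_families(1), ">= 2")
  expect_error(build_families(5), "even")
})

test_that("relatedness matrix encodes 2^-d within families, 0 across", {
  ped <- build_families(2)
  rel <- relatedness_matrix(ped)
  phi <- as.matrix(rel$phi)
  expect_equal(dim(phi), c(10, 10))
  expect_equal(diag(phi), rep(1, 10))
  expect_equal(phi, t(phi))
  b7 <- rel$blocks[[2]]                      # 2 parents + 5 offspring
  expect_equal(b7[1, 2], 0)                  # spouses unrelated
  expect_equal(b7[1, 3], 0.5)                # parent-offspring, d = 1
  expect_equal(b7[3, 4], 0.5)                # full sibs, d = 1
  expect_equal(phi[1:3, 4:10], matrix(0, 3, 7))  # across families
})

test_that("trait model splits the covariance exactly by heritability", {
  g <- canonical_graph("chain")
  m <- trait_model(g, 0.25)
  expect_identical(m$sigma_e + m$sigma_g, g$covariance)
  m0 <- trait_model(g, 0)
  expect_identical(m0$sigma_g, 0 * g$covariance)
  expect_error(trait_model(g, 1), "\\[0, 1\\)")
  expect_error(trait_model(g, -0.1), "\\[0, 1\\)")
})

test_that("the two variance decompositions agree algebraically", {
  # (Phi - I) kron h2*Sigma + I kron Sigma == Phi kron Sigma_g + I kron Sigma_e
  g <- canonical_graph("triangle_tail")
  h2 <- 0.6
  m <- trait_model(g, h2)
  rel <- relatedness_matrix(build_families(2))
  phi <- as.matrix(rel$phi)
  n <- nrow(phi)
  lhs <- kronecker(phi - diag(n), h2 * g$covariance) +
    kronecker(diag(n), g$covariance)
  rhs <- kronecker(phi, m$sigma_g) + kronecker(diag(n), m$sigma_e)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("simulation is seed-reproducible and seed-sensitive", {
  g <- canonical_graph("chain")
  m <- trait_model(g, 0.5)
  ped <- build_families(4)
  d1 <- simulate_traits(m, ped, seed = 11)
  d2 <- simulate_traits(m, ped, seed = 11)
  d3 <- simulate_traits(m, ped, seed = 12)
  expect_identical(d1$values, d2$values)
  expect_false(identical(d1$values, d3$values))
  expect_equal(nrow(d1$values), ped$n)
  expect_equal(length(unique(d1$cluster_ids)), 4)
})

test_that("seeded simulation leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_traits(trait_model(canonical_graph("chain"), 0.3),
                            build_families(2), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("zero heritability gives iid rows with covariance Sigma", {
  g <- canonical_graph("chain")
  d <- simulate_traits(trait_model(g, 0), build_families(2000), seed = 21)
  S <- cov(d$values)
  # entries of S have Monte-Carlo sd ~ sqrt((sigma_ii sigma_jj + sigma_ij^2)/N)
  N <- nrow(d$values)
  for (i in 1:3) for (j in 1:3) {
    mc_se <- sqrt((g$covariance[i, i] * g$covariance[j, j] +
                     g$covariance[i, j]^2) / N)
    expect_lt(abs(S[i, j] - g$covariance[i, j]), 4 * mc_se)
  }
})

test_that("within-family trait covariance follows phi * Sigma_g + I * Sigma_e", {
  # Monte Carlo over many independent 7-member families at high
  # heritability: a sib pair's shared trait-1 covariance should be
  # 0.5 * h2 * Sigma[1,1]; a parent pair's should be ~0.
  g <- canonical_graph("chain")
  h2 <- 0.95
  n_fam <- 30000
  d <- simulate_traits(trait_model(g, h2), pedigree_set(rep(5, n_fam)),
                       seed = 31)
  y <- d$values[, 1]
  sib1 <- y[seq(3, by = 7, length.out = n_fam)]
  sib2 <- y[seq(4, by = 7, length.out = n_fam)]
  par1 <- y[seq(1, by = 7, length.out = n_fam)]
  par2 <- y[seq(2, by = 7, length.out = n_fam)]
  target <- 0.5 * h2 * g$covariance[1, 1]
  mc_se <- sqrt((g$covariance[1, 1]^2 + target^2) / n_fam)
  expect_lt(abs(cov(sib1, sib2) - target), 3 * mc_se)
  expect_lt(abs(cov(par1, par2) - 0), 3 * mc_se)
  # across families: independent
  expect_lt(abs(cov(sib1[-1], sib2[-n_fam])), 3 * mc_se)
})

test_that("clustered datasets round-trip through delimited text", {
  d <- small_chain_data(M = 4, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clustered_tsv(d, path, cluster_col = "FAMID")
  d2 <- read_clustered_tsv(path, cluster_col = "FAMID")
  expect_equal(d2$values, d$values, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(d2$cluster_ids, d$cluster_ids)
  expect_identical(d2$variable_names, d$variable_names)
})

test_that("malformed datasets are rejected", {
  expect_error(clustered_dataset(matrix(c(1, NA, 2, 3), 2), c("a", "b")),
               "missing")
  expect_error(clustered_dataset(matrix(1:6, 3, 2), c("a", "b")),
               "label every row")
  expect_error(clustered_dataset(matrix(1:4, 4, 1), letters[1:4]),
               "2 variables")
})
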