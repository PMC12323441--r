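test_that("the inflation-rescaling update follows the printed rule", {
  # measured FPR 0.10 at level 0.05, nominal 0.05 -> inflation 2 -> 0.025
  expect_equal(ggmboot:::next_alpha(0.05, 0.10, 0.05), 0.025)
  # already at nominal: fixed point
  expect_equal(ggmboot:::next_alpha(0.05, 0.05, 0.05), 0.05)
  # deflated FPR raises the level, capped at 1
  expect_equal(ggmboot:::next_alpha(0.05, 0.01, 0.05), 0.25)
  expect_equal(ggmboot:::next_alpha(0.5, 1e-6, 0.9), 1)
})

test_that("FPR estimation is reproducible and respects the null band", {
  g <- canonical_graph("independence")
  scn <- scenario(g, M = 120, h2 = 0, method = "fisher")
  f1 <- estimate_fpr(scn, replicates = 400, seed = 31)
  f2 <- estimate_fpr(scn, replicates = 400, seed = 31)
  expect_identical(f1$per_pair, f2$per_pair)
  expect_equal(nrow(f1$per_pair), 3)   # three null pairs
  # iid data, iid test: FPR within the 99% binomial band of 0.05
  band <- 2.576 * sqrt(0.05 * 0.95 / 400)
  expect_true(all(abs(f1$per_pair$proportion - 0.05) <= band))
  expect_equal(f1$mean_inflation, f1$mean_fpr / 0.05)
})

test_that("ignoring family structure inflates the FPR at high heritability", {
  scn <- scenario(canonical_graph("chain"), M = 120, h2 = 0.75,
                  method = "fisher")
  f <- estimate_fpr(scn, replicates = 300, seed = 32)
  expect_gt(f$mean_fpr, 0.075)   # well above nominal 0.05
})

test_that("alpha adjustment brings an inflated test back toward nominal", {
  scn <- scenario(canonical_graph("chain"), M = 120, h2 = 0.75,
                  method = "fisher")
  adj <- adjust_alpha(scn, replicates = 400, nominal_alpha = 0.05,
                      tol = 0.012, max_iter = 6, seed = 33)
  expect_equal(adj$trace$level[1], 0.05)   # trace starts at nominal
  expect_lt(adj$alpha_star, 0.05)          # inflation forces a lower level
  # verify on a fresh stream: FPR at alpha_star is near nominal
  f <- estimate_fpr(scn, replicates = 400, alpha = adj$alpha_star,
                    seed = 34)
  expect_lt(abs(f$mean_fpr - 0.05), 0.025)
  expect_error(adjust_alpha(scn, 50, nominal_alpha = 1.5), "\\(0, 1\\)")
})

test_that("power estimation detects strong edges and grows with M", {
  g <- canonical_graph("chain", strength = 0.3)
  p_small <- estimate_power(scenario(g, 40, 0, "fisher"),
                            replicates = 300, seed = 35)
  p_large <- estimate_power(scenario(g, 360, 0, "fisher"),
                            replicates = 300, seed = 36)
  expect_equal(nrow(p_small$per_pair), 2)  # the two chain edges
  expect_gte(p_large$min_power, p_small$min_power)
  expect_gt(p_large$min_power, 0.95)       # rho = 0.3 at N = 1800
  expect_error(
    estimate_power(scenario(canonical_graph("independence"), 40, 0,
                            "fisher"), 50, seed = 1),
    "no true edge")
  full <- graph_from_partial_corr(matrix(c(1, 0.3, 0.3, 1), 2))
  expect_error(
    estimate_fpr(scenario(full, 40, 0, "fisher"), 50, seed = 1),
    "no conditionally independent pair")
})

test_that("a small scenario grid runs to completion and writes outputs", {
  out_dir <- withr::local_tempdir()
  cfg <- list(graphs = c("independence", "chain"),
              M_values = c(4, 8), h2_values = c(0, 0.5),
              methods = c("fisher", "cluster_boot"),
              replicates = 3, adjust_replicates = 3,
              T = 10, max_iter = 1, seed = 37, out_dir = out_dir)
  # tiny replicate counts can estimate an FPR of exactly 0, which the
  # alpha adjustment flags with a warning; that is expected here
  res <- suppressWarnings(run_grid(cfg))
  expect_s3_class(res, "grid_result")
  expect_true(all(res$proportion >= 0 & res$proportion <= 1))
  expect_setequal(unique(res$pair_type), c("null", "true"))
  # replicates = 3: proportions land on thirds
  expect_true(all(res$proportion %in% ((0:3) / 3)))
  expect_true(file.exists(file.path(out_dir, "grid_results.tsv")))
  expect_true(file.exists(file.path(out_dir, "grid_summary.json")))
  disk <- read.delim(file.path(out_dir, "grid_results.tsv"))
  expect_equal(nrow(disk), nrow(res))
})

test_that("grid configurations load from YAML with validation", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("graphs: [chain]",
               "M_values: [4]",
               "h2_values: [0.0, 0.5]",
               "methods: [fisher]",
               "replicates: 5"), path)
  cfg <- read_grid_config(path)
  expect_equal(cfg$h2_values, c(0, 0.5))
  writeLines("graphs: [chain]", path)
  expect_error(read_grid_config(path), "missing")
})
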