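test_that("latent correlation matrix has the planted block structure", {
  # 2 modules of 3, no connectors
  spec <- synthetic_spec(n_asvs = 6, module_sizes = c(3, 3), rho_within = 0.8,
                         group_names = "G", n_samples_per_group = 5)
  R <- build_latent_correlation(spec)
  expect_equal(dim(R), c(6, 6))
  expect_equal(diag(R), rep(1, 6), ignore_attr = TRUE)
  expect_equal(R[1, 2], 0.8)
  expect_equal(R[4, 6], 0.8)
  expect_equal(R[1, 4], 0)
  expect_true(isSymmetric(R))

  # single-ASV module: identity
  spec1 <- synthetic_spec(n_asvs = 1, module_sizes = c(1), group_names = "G",
                          n_samples_per_group = 5)
  expect_equal(build_latent_correlation(spec1), diag(1), ignore_attr = TRUE)

  # one connector to a foreign module of size 2: exactly 2 off-block entries
  spec2 <- synthetic_spec(n_asvs = 5, module_sizes = c(3, 2), rho_within = 0.5,
                          connectors = list(ASV_004 = 1L), rho_cross = 0.3,
                          group_names = "G", n_samples_per_group = 5)
  R2 <- build_latent_correlation(spec2)
  expect_equal(unname(R2[4, 1:3]), rep(0.3, 3))
  expect_equal(unname(R2[1:3, 4]), rep(0.3, 3))
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(rho_within = 1), "latent correlations")
  expect_error(synthetic_spec(rho_cross = 1.2), "latent correlations")
  expect_error(synthetic_spec(n_asvs = 4, module_sizes = c(3, 3)), "module sizes")
  expect_error(synthetic_spec(effect_size = 0), "effect_size")
  expect_error(synthetic_spec(depth_mean = -1), "depth_mean")
  expect_error(synthetic_spec(effect_asvs = "ASV_001", effect_group = "nope"),
               "effect_group")
})

test_that("PSD repair yields a valid correlation matrix under infeasible requests", {
  # connector at 0.9 to two near-unifactor blocks is far from PSD
  spec <- synthetic_spec(n_asvs = 20, module_sizes = c(10, 10), rho_within = 0.9,
                         connectors = list(ASV_001 = 2L), rho_cross = 0.9,
                         group_names = "G", n_samples_per_group = 5)
  R <- build_latent_correlation(spec)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(diag(R), rep(1, 20), ignore_attr = TRUE)
  expect_true(all(abs(R) <= 1 + 1e-12))
})

test_that("sampled tables are deterministic, integer, with Poisson depths", {
  spec <- synthetic_spec(n_samples_per_group = 5, group_names = c("LT", "HT"),
                         n_asvs = 30, module_sizes = c(5), rho_within = 0.7,
                         depth_mean = 500, seed = 11)
  a <- sample_counts(spec)
  b <- sample_counts(spec)
  expect_identical(a, b)                       # same seed, same table
  expect_true(all(a$counts >= 0))
  expect_true(all(a$counts == round(a$counts)))
  expect_equal(nrow(a$counts), 10)
  expect_setequal(a$metadata$group, c("LT", "HT"))
  expect_equal(a$metadata$sample_id, rownames(a$counts))
  # row sums are the drawn library sizes: reproduce the Poisson draw,
  # which consumes the stream right after the n*p normals
  set.seed(11)
  invisible(stats::rnorm(10 * 30))
  depths <- pmax(stats::rpois(10, 500), 1L)
  expect_equal(unname(rowSums(a$counts)), depths)
})

test_that("copula rank correlation approaches the Greiner transform of latent rho", {
  # module pair at rho 0.9 inside a 50-ASV background table, n = 20;
  # theory: (6/pi) asin(rho/2) = 0.891, attenuated slightly by count noise
  rhos <- vapply(1:100, function(s) {
    spec <- synthetic_spec(n_samples_per_group = 20, group_names = "G",
                           n_asvs = 50, module_sizes = c(2), rho_within = 0.9,
                           seed = s)
    sim <- sample_counts(spec)
    stats::cor(sim$counts[, 1], sim$counts[, 2], method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0.7)
  expect_lt(abs(mean(rhos) - (6 / pi) * asin(0.45)), 0.1)
})

test_that("effect_size multiplies mean abundance in the effect group only", {
  spec <- synthetic_spec(n_samples_per_group = 30, group_names = c("A", "B"),
                         n_asvs = 20, module_sizes = integer(0),
                         effect_asvs = c("ASV_001", "ASV_002"),
                         effect_group = "B", effect_size = 5,
                         depth_mean = 5000, seed = 21)
  sim <- sample_counts(spec)
  in_b <- sim$metadata$group == "B"
  fold <- colMeans(sim$counts[in_b, 1:2]) / colMeans(sim$counts[!in_b, 1:2])
  expect_true(all(fold > 2))                   # clearly shifted
  fold_bg <- colMeans(sim$counts[in_b, 10:20]) / colMeans(sim$counts[!in_b, 10:20])
  expect_true(all(fold_bg < 1.5))              # background roughly flat
})

test_that("ground truth exports and reads back losslessly", {
  spec <- synthetic_spec(n_asvs = 8, module_sizes = c(3, 2), rho_within = 0.5,
                         connectors = list(ASV_006 = 1L), rho_cross = 0.3,
                         group_names = "G", n_samples_per_group = 5)
  truth <- ground_truth(spec)
  expect_true(isSymmetric(truth$latent_correlation))
  expect_equal(unname(truth$module_of[6:8]), rep("none", 3))
  dir <- withr::local_tempdir()
  export_truth(truth, dir)
  back <- read_truth(dir)
  expect_equal(back$module_of, truth$module_of)
  expect_equal(back$connector_set, truth$connector_set)
  expect_equal(back$differential_set, truth$differential_set)

  # empty connector set round-trips too
  spec2 <- synthetic_spec(n_asvs = 4, module_sizes = c(2), group_names = "G",
                          n_samples_per_group = 5)
  dir2 <- withr::local_tempdir()
  export_truth(ground_truth(spec2), dir2)
  expect_length(read_truth(dir2)$connector_set, 0)
})
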