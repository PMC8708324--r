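test_that("smoothing operator conserves interior mass with a unit-sum kernel", {
  S <- gaussian_smoothing_matrix(16, 16, kernel_size = 5)
  m <- matrix(0, 16, 16)
  m[6:10, 6:10] <- with_seed(1, runif(25)) # interior-only mass
  sm <- S %*% as.vector(m)
  expect_equal(sum(sm), sum(m), tolerance = 1e-12)
  # boundary mass can only be lost (zero padding), never created
  m2 <- matrix(0, 16, 16); m2[1, 1] <- 1
  expect_lt(sum(S %*% as.vector(m2)), 1)
  expect_error(gaussian_smoothing_matrix(8, 8, kernel_size = 4), "odd")
})

test_that("variance maps obey the closed form for linear projectors", {
  with_seed(2, lat <- matrix(rnorm(30 * 3), 30, 3))
  W <- with_seed(3, matrix(rnorm(3 * 64), 3, 64))
  proj <- function(X) X %*% W
  for (q in 1:3) {
    sm <- latent_feature_variance_map(proj, lat, q, c(8, 8))
    expected <- stats::var(lat[, q]) * W[q, ]^2
    expect_equal(as.vector(t(sm$values)), expected, tolerance = 1e-10)
    expect_true(all(sm$values >= 0))
  }
  # a projector insensitive to the varied dimension gives an all-zero map
  proj0 <- function(X) X[, c(2, 3)] %*% W[c(2, 3), ]
  sm0 <- latent_feature_variance_map(proj0, lat, 1, c(8, 8))
  expect_true(all(sm0$values == 0))
  expect_error(latent_feature_variance_map(proj, lat, 9, c(8, 8)), "range")
})

test_that("constant and all-zero maps are never significant", {
  cm <- saliency_map(matrix(3, 12, 12), source = "external")
  pm <- saliency_significance(cm, n_randomizations = 200, seed = 1)
  expect_true(all(pm$p_values == 1))
  expect_warning(pz <- saliency_significance(saliency_map(matrix(0, 8, 8)),
                                             n_randomizations = 50, seed = 1),
                 "all-zero")
  expect_true(all(pz$p_values == 1))
})

test_that("a single spike's p-value approaches the placement probability", {
  v <- matrix(0, 16, 16); v[8, 8] <- 5
  pm <- saliency_significance(saliency_map(v), n_randomizations = 8000,
                              kernel_size = 3, seed = 4)
  # the spike beats a permuted map unless the permutation lands the spike in
  # the 3x3 neighborhood with a weight at least as large as the center weight,
  # i.e. exactly at the center: p -> 1/256
  expect_equal(pm$p_values[8, 8], 1 / 256, tolerance = 0.5 / 256 * 3)
  # Monte-Carlo oracle on the same quantity
  S <- gaussian_smoothing_matrix(16, 16, kernel_size = 3)
  s_alt <- (S %*% as.vector(v))[(8 - 1) * 16 + 8]
  hits <- with_seed(9, mean(replicate(4000, {
    (S %*% as.vector(matrix(v[sample.int(256)], 16)))[(8 - 1) * 16 + 8] >= s_alt - 1e-9
  })))
  expect_equal(pm$p_values[8, 8], hits, tolerance = 3 * sqrt(hits * (1 - hits) / 4000) + 1e-3)
})

test_that("p-value maps are deterministic under a seed and masks are nested", {
  nm <- generate_null_map(null_map_spec(c(16, 16), 30, seed = 3))
  p1 <- saliency_significance(nm, n_randomizations = 300, seed = 5)
  p2 <- saliency_significance(nm, n_randomizations = 300, seed = 5)
  expect_identical(p1$p_values, p2$p_values)
  p3 <- saliency_significance(nm, n_randomizations = 300, seed = 6)
  expect_false(identical(p1$p_values, p3$p_values))
  # nested masks across fuzzed thresholds
  for (i in 1:20) {
    alphas <- sort(with_seed(i, runif(2)))
    expect_true(all(threshold_map(p1, alphas[1]) <= threshold_map(p1, alphas[2])))
  }
  expect_true(all(threshold_map(p1, 1)))
  expect_error(threshold_map(p1, 0), "alpha")
  # permuting only the nonzero marks is equivalent in distribution for sparse
  # maps: pooled p-values from both variants agree by a KS test
  pa <- saliency_significance(nm, n_randomizations = 400, seed = 7, permute = "all")
  pb <- saliency_significance(nm, n_randomizations = 400, seed = 8, permute = "nonzero")
  ks <- suppressWarnings(stats::ks.test(as.vector(pa$p_values), as.vector(pb$p_values)))
  expect_gt(ks$p.value, 0.01)
})

test_that("p-values are distribution-invariant to relabeling null pixel locations", {
  nm <- generate_null_map(null_map_spec(c(16, 16), 40, seed = 11))
  perm_vals <- with_seed(12, matrix(nm$values[sample.int(256)], 16, 16))
  pa <- saliency_significance(nm, n_randomizations = 500, seed = 13)
  pb <- saliency_significance(saliency_map(perm_vals), n_randomizations = 500, seed = 14)
  ks <- suppressWarnings(stats::ks.test(as.vector(pa$p_values), as.vector(pb$p_values)))
  expect_gt(ks$p.value, 0.01)
})

test_that("saliency maps round-trip through CSV and PNG export records scale", {
  sm <- generate_null_map(null_map_spec(c(12, 12), 20, seed = 2))
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "map.csv")
  write_saliency_csv(sm, csv)
  back <- read_saliency_csv(csv)
  expect_equal(back$values, sm$values, tolerance = 1e-12, ignore_attr = TRUE)
  pngf <- file.path(dir, "map.png")
  write_saliency_png(sm, pngf)
  expect_true(file.exists(pngf))
  expect_true(file.exists(file.path(dir, "map_scale.csv")))
})
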