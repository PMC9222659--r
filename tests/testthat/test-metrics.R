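test_that("correlation metric handles self, inverse, and affine cases", {
  a <- rand_img(16, 16, seed = 1)
  expect_equal(metric_cc(a, a, a), 1)
  # fused = CT, MRI = inverted CT: correlations +1 and -1 average to 0
  expect_equal(metric_cc(a, a, 1 - a), 0)
  # invariant under affine rescaling of the fused image
  expect_equal(metric_cc(0.2 + 0.5 * a, a, rand_img(16, 16, seed = 2)),
               metric_cc(a, a, rand_img(16, 16, seed = 2)))
  # constant image contributes zero correlation
  expect_equal(metric_cc(matrix(0.5, 8, 8), a[1:8, 1:8], a[1:8, 1:8] / 2),
               0)
  expect_error(metric_cc(a, a[1:8, ], a), "shape")
})

test_that("mutual information reduces to entropy for identical images", {
  f <- rand_img(32, 32, seed = 3)
  q <- quantize_levels(f, 256L)
  p <- tabulate(q + 1L, 256L) / length(q)
  h <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_equal(metric_mi(f, f, f), 2 * h, tolerance = 1e-9)
  expect_gte(metric_mi(f, rand_img(32, 32, seed = 4), rand_img(32, 32, seed = 5)), 0)
  # MI against an independent image decays with size (finite-sample bias)
  mi_small <- metric_mi(rand_img(64, 64, seed = 6), rand_img(64, 64, seed = 7),
                        rand_img(64, 64, seed = 8)) / 2
  mi_large <- metric_mi(rand_img(448, 448, seed = 6), rand_img(448, 448, seed = 7),
                        rand_img(448, 448, seed = 8)) / 2
  expect_lt(mi_large, mi_small)
  expect_lt(mi_large, 0.3)
})

test_that("spatial frequency follows the difference-count convention", {
  expect_equal(metric_sf(matrix(0.7, 10, 10)), 0)
  checker <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(metric_sf(checker), sqrt(2))
  a <- rand_img(12, 12, seed = 9)
  expect_equal(metric_sf(0.5 * a), 0.5 * metric_sf(a))
  expect_error(metric_sf(matrix(1, 1, 5)), "at least 2 x 2")
})

test_that("phase congruency preservation is 1 for self-fusion and bounded", {
  a <- make_pair(phantom_spec(size = 48L, seed = 10L))$mri
  expect_equal(metric_pc(a, a, a), 1)
  f <- rand_img(32, 32, seed = 11)
  b <- rand_img(32, 32, seed = 12)
  g <- rand_img(32, 32, seed = 13)
  v <- metric_pc(f, b, g)
  expect_gte(v, 0)
  expect_lte(v, 1)
  expect_identical(metric_pc(f, b, g), v) # deterministic
  expect_error(metric_pc(f[1:16, 1:16], b[1:16, 1:16], g[1:16, 1:16]),
               "at least 32 x 32")
})

test_that("NCIE is 1 for identical images and near its floor for noise", {
  a <- rand_img(64, 64, seed = 14)
  expect_equal(metric_ncie(a, a, a), 1, tolerance = 1e-10)
  expect_lte(metric_ncie(a, rand_img(64, 64, seed = 15),
                         rand_img(64, 64, seed = 16)), 1)
  # three independent images: R ~ identity, NCIE ~ 1 - log(3)/log(256)
  floor_val <- 1 - log(3) / log(256)
  got <- metric_ncie(rand_img(448, 448, seed = 17),
                     rand_img(448, 448, seed = 18),
                     rand_img(448, 448, seed = 19))
  expect_equal(got, floor_val, tolerance = 0.02)
})

test_that("SCD recovers complementary construction and stays bounded", {
  medfuse:::with_seed(20L, {
    a <- matrix(rnorm(400), 20, 20); a <- a - mean(a)
    b <- matrix(rnorm(400), 20, 20); b <- b - mean(b)
  })
  expect_equal(metric_scd(a + b, a, b), 2, tolerance = 1e-6)
  for (s in 1:25) {
    f <- rand_img(12, 12, seed = 300 + s)
    x <- rand_img(12, 12, seed = 600 + s)
    y <- rand_img(12, 12, seed = 900 + s)
    v <- metric_scd(f, x, y)
    expect_gte(v, -2)
    expect_lte(v, 2)
    expect_equal(metric_scd(f, y, x), v) # symmetric in the sources
  }
})

test_that("dataset evaluation averages per-image metrics", {
  pair <- make_pair(phantom_spec(size = 32L, seed = 21L))
  f <- (unclass(pair$ct) + unclass(pair$mri)) / 2
  tri <- list(list(f = f, a = unclass(pair$ct), b = unclass(pair$mri)))
  r1 <- evaluate_dataset(tri, pc = FALSE)
  expect_identical(r1$n_images, 1L)
  expect_equal(unname(r1$summary[["cc"]]),
               metric_cc(f, unclass(pair$ct), unclass(pair$mri)))
  # duplicating the list leaves the means unchanged
  r2 <- evaluate_dataset(c(tri, tri), pc = FALSE)
  expect_equal(r2$summary, r1$summary)
  expect_identical(r2$n_images, 2L)
  expect_error(evaluate_dataset(list()), "nonempty")
})
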