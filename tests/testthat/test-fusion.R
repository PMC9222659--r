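test_that("l1 activity sums absolute channel responses", {
  ones <- array(1, c(3, 3, 4))
  expect_equal(l1_activity(ones), matrix(4, 3, 3))
  m <- matrix(c(-1, 2), 1, 2)
  expect_equal(l1_activity(array(m, c(1, 2, 1))), matrix(c(1, 2), 1, 2))
  expect_equal(l1_activity(array(0, c(2, 2, 3))), matrix(0, 2, 2))
  expect_error(l1_activity(array(0, c(2, 2, 0))), "empty")
})

test_that("minmax normalization maps range ends and degenerates to zero", {
  expect_equal(minmax_normalize(matrix(c(2, 4, 6), 1, 3)),
               matrix(c(0, 0.5, 1), 1, 3))
  expect_equal(minmax_normalize(matrix(5, 3, 3)), matrix(0, 3, 3))
  already <- matrix(c(0, 0.25, 1, 0.5), 2, 2)
  expect_equal(minmax_normalize(already), already)
  expect_error(minmax_normalize(matrix(c(1, NA, 0, 1), 2, 2)), "non-finite")
})

test_that("histogram saliency matches the brute-force definition", {
  # worked 2x2 case: three pixels at 0, one at 255
  img <- matrix(c(0L, 0L, 0L, 255L), 2, 2, byrow = TRUE)
  s <- vsm(img, 256L)
  expect_equal(s[img == 0L], rep(255, 3))
  expect_equal(s[img == 255L], 765)
  # constant image has no saliency
  expect_true(all(vsm(matrix(7L, 5, 5), 256L) == 0))
  # exact equivalence with the O(P*L) oracle on random images
  for (s_i in 1:20) {
    q <- medfuse:::with_seed(s_i, matrix(sample(0:255, 256, TRUE), 16, 16))
    expect_identical(vsm(q, 256L), structure(vsm_bruteforce(q, 256L),
                                             levels = 256L))
  }
  expect_error(vsm(matrix(-1L, 2, 2), 256L), "0 .. L-1")
})

test_that("saliency depends only on the histogram, not pixel positions", {
  q <- medfuse:::with_seed(4, matrix(sample(0:63, 100, TRUE), 10, 10))
  perm <- medfuse:::with_seed(5, sample(100))
  s1 <- vsm(q, 64L)
  s2 <- vsm(matrix(as.vector(q)[perm], 10, 10), 64L)
  expect_equal(as.vector(s2), as.vector(s1)[perm])
})

test_that("the CT weight map chain lands in [0,1] and finds dense structure", {
  # spatially constant stack: constant activity => zero weights
  expect_equal(ct_weight_map(array(3, c(6, 6, 2))), matrix(0, 6, 6))
  # bounded on arbitrary features
  f <- rand_stack(12, 12, 5, seed = 2)
  w1 <- ct_weight_map(f)
  expect_gte(min(w1), 0)
  expect_lte(max(w1), 1)
  # on noiseless phantom encoder features the weight concentrates on bone
  spec <- phantom_spec(size = 32L, seed = 2L, noise_sd = 0, n_lesions = 0L)
  pair <- make_pair(spec)
  wts <- init_net_weights(tiny_cfg(), seed = 3L)
  w1 <- ct_weight_map(encode(pair$ct, wts))
  mask <- phantom_annulus_mask(spec)
  expect_gt(mean(w1[mask]), mean(w1[!mask]))
})

test_that("saliency-weighted fusion satisfies its algebraic identities", {
  f_ct <- rand_stack(5, 4, 3, seed = 10)
  f_mri <- rand_stack(5, 4, 3, seed = 11)
  ones <- matrix(1, 5, 4)
  zeros <- matrix(0, 5, 4)
  expect_equal(fuse_features(f_ct, f_mri, ones, gamma = 1), f_ct)
  expect_equal(fuse_features(f_ct, f_mri, zeros, gamma = 0.3), f_mri)
  # weight conservation: fusing a stack with itself returns it
  for (s in 1:10) {
    w1 <- rand_img(5, 4, seed = s)
    gam <- medfuse:::with_seed(100 + s, runif(1))
    expect_equal(fuse_features(f_ct, f_ct, w1, gam), f_ct)
  }
  # fused value is affine in w1 at every pixel
  w_a <- matrix(0.2, 5, 4); w_b <- matrix(0.8, 5, 4)
  half <- fuse_features(f_ct, f_mri, (w_a + w_b) / 2, 0.4)
  ends <- (fuse_features(f_ct, f_mri, w_a, 0.4) +
           fuse_features(f_ct, f_mri, w_b, 0.4)) / 2
  expect_equal(half, ends)
  # the literal complement reading is a different rule
  w1 <- rand_img(5, 4, seed = 20)
  expect_false(isTRUE(all.equal(
    fuse_features(f_ct, f_mri, w1, 0.5, mri_term = "scaled"),
    fuse_features(f_ct, f_mri, w1, 0.5, mri_term = "complement"))))
  expect_error(fuse_features(f_ct, rand_stack(4, 4, 3), ones), "shape")
})

test_that("baseline fusion rules obey their elementwise definitions", {
  f <- rand_stack(4, 4, 2, seed = 1)
  expect_equal(fuse_baseline(f, f, "avg"), f)
  expect_equal(fuse_baseline(f, f - 1, "max"), f)
  expect_equal(fuse_baseline(f, array(0, dim(f)), "sum"), f)
  a <- abs(rand_stack(4, 4, 2, seed = 2)); b <- abs(rand_stack(4, 4, 2, seed = 3))
  l1 <- fuse_baseline(a, b, "l1norm")
  # l1norm is a per-pixel convex combination, so it lies between the inputs
  expect_true(all(l1 >= pmin(a, b) - 1e-12 & l1 <= pmax(a, b) + 1e-12))
})
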