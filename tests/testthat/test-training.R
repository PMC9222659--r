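test_that("the mixed loss obeys its identities", {
  a <- rand_img(6, 6, seed = 1)
  z <- mixed_loss(a, a, mu = 3, phi = 2)
  expect_equal(z$total, 0)
  expect_equal(z$pixel_term, 0)
  expect_equal(z$gradient_term, 0)

  # hand-computed 2x2 case: one pixel off by 0.1, pixel term only
  i_in <- matrix(0.5, 2, 2)
  i_f <- i_in; i_f[1, 1] <- 0.6
  l <- mixed_loss(i_f, i_in, mu = 1, phi = 0)
  expect_equal(l$total, 0.0025)
  expect_equal(l$pixel_term, 0.0025)

  # linear in mu and phi, and total recombines the terms
  b <- rand_img(6, 6, seed = 2)
  l1 <- mixed_loss(a, b, mu = 1, phi = 0)
  l2 <- mixed_loss(a, b, mu = 2, phi = 0)
  expect_equal(l2$total, 2 * l1$total)
  l3 <- mixed_loss(a, b, mu = 0, phi = 1)
  l4 <- mixed_loss(a, b, mu = 0, phi = 3)
  expect_equal(l4$total, 3 * l3$total)
  lm <- mixed_loss(a, b, mu = 0.7, phi = 1.3)
  expect_equal(lm$total, 0.7 * lm$pixel_term + 1.3 * lm$gradient_term)
  expect_gte(lm$pixel_term, 0)
  expect_gte(lm$gradient_term, 0)
  expect_error(mixed_loss(a, rand_img(5, 6)), "shapes differ")
  expect_error(train_config(mu = 0, phi = 0), "mu \\+ phi")
})

test_that("forward differences are available as the loss gradient operator", {
  a <- rand_img(6, 6, seed = 3)
  b <- rand_img(6, 6, seed = 4)
  ls <- mixed_loss(a, b, grad_op = "sobel")
  ld <- mixed_loss(a, b, grad_op = "diff")
  expect_gt(ls$gradient_term, 0)
  expect_gt(ld$gradient_term, 0)
  expect_false(isTRUE(all.equal(ls$gradient_term, ld$gradient_term)))
})

test_that("training runs are seeded, loss-decreasing, and restartable", {
  cfg <- tiny_cfg()
  imgs <- lapply(1:12, function(s) rand_img(12, 12, seed = s))

  # epochs = 0: initial weights, empty history
  r0 <- train(imgs, train_config(epochs = 0L, seed = 2L), cfg)
  expect_identical(r0$weights$params, init_net_weights(cfg, 2L)$params)
  expect_identical(nrow(r0$history), 0L)

  # same seed twice: identical loss histories
  tc <- train_config(epochs = 2L, batch_size = 4L, seed = 3L, lr = 1e-3)
  r1 <- train(imgs, tc, cfg)
  r2 <- train(imgs, tc, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$weights$params, r2$weights$params)

  # reconstruction improves on an easy over-parameterized task
  pairs <- make_dataset(6L, phantom_spec(size = 16L), seed = 4L)$pairs
  pimgs <- unlist(lapply(pairs, function(p) list(unclass(p$ct), unclass(p$mri))),
                  recursive = FALSE)
  fit <- train(pimgs, train_config(epochs = 15L, batch_size = 4L, seed = 5L,
                                   lr = 1e-3), cfg)
  h <- fit$history
  expect_lt(h$mean_loss[nrow(h)], h$mean_loss[1L])
  expect_identical(fit$weights$epochs, 15L)
})

test_that("the training graph touches exactly the encoder-decoder parameters", {
  cfg <- tiny_cfg()
  wts <- init_net_weights(cfg, seed = 6L)
  batch <- medfuse:::as_batch(lapply(1:2, function(s) rand_img(10, 10, seed = s)))
  step <- medfuse:::train_step(batch, wts$params, cfg, train_config(epochs = 1L))
  expect_setequal(names(step$grads), names(wts$params))
  expect_true(all(vapply(step$grads, function(g) any(g != 0), TRUE)))
  expect_equal(step$total, step$pixel + step$gradient)
})

test_that("reconstruction PSNR is order-invariant and rewards training", {
  cfg <- tiny_cfg()
  imgs <- lapply(1:6, function(s) rand_img(16, 16, seed = s))
  w0 <- init_net_weights(cfg, seed = 7L)
  p_a <- reconstruction_quality(w0, imgs)
  p_b <- reconstruction_quality(w0, rev(imgs))
  expect_equal(p_a, p_b)
  expect_true(is.finite(p_a))
  pairs <- make_dataset(6L, phantom_spec(size = 16L), seed = 9L)$pairs
  pimgs <- unlist(lapply(pairs, function(p) list(unclass(p$ct), unclass(p$mri))),
                  recursive = FALSE)
  fit <- train(pimgs, train_config(epochs = 15L, batch_size = 4L, seed = 8L,
                                   lr = 1e-3), cfg)
  expect_gt(reconstruction_quality(fit$weights, pimgs),
            reconstruction_quality(init_net_weights(cfg, 8L), pimgs))
  expect_error(reconstruction_quality(w0, list()), "nonempty")
})
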