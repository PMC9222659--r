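test_that("network configuration enforces its consistency rules", {
  cfg <- net_config()
  expect_identical(cfg$encoder_out_channels, 240L)
  expect_identical(cfg$decoder_channels[1L], 240L)
  expect_error(net_config(branch_channels = 10L), "decoder input channels")
  expect_error(net_config(decoder_channels = c(240L, 64L, 32L, 16L)),
               "five convolution layers")
  expect_error(net_config(branch_channels = 5L,
                          decoder_channels = c(20L, 8L, 4L, 2L, 2L),
                          reduction = 16L), "divisible")
})

test_that("every stage preserves spatial dimensions for odd and even sizes", {
  cfg <- tiny_cfg()
  wts <- init_net_weights(cfg, seed = 1L)
  for (d in list(c(9L, 12L), c(10L, 11L))) {
    img <- rand_img(d[1], d[2], seed = 1)
    f <- mc_block(img, wts)
    expect_identical(dim(f), c(d, cfg$encoder_out_channels))
    r <- ma_block(f, wts)
    expect_identical(dim(r), c(d, cfg$encoder_out_channels))
    out <- decode(encode(img, wts), wts)
    expect_identical(dim(out), d)
  }
})

test_that("zero input with zero biases propagates to zero output", {
  wts <- init_net_weights(tiny_cfg(), seed = 2L)
  z <- matrix(0, 8, 8)
  expect_true(all(mc_block(z, wts) == 0))
  expect_true(all(ma_block(array(0, c(8, 8, 8L)), wts) == 0))
})

test_that("the res2b and res2db variants are distinct topologies", {
  w_db <- init_net_weights(tiny_cfg(dense_variant = "res2db"), seed = 5L)
  w_b <- init_net_weights(tiny_cfg(dense_variant = "res2b"), seed = 5L)
  # branch 3 and 4 second convs see different channel counts
  expect_identical(dim(w_db$params[["b4.c2.w"]])[3L], 8L)
  expect_identical(dim(w_b$params[["b4.c2.w"]])[3L], 4L)
  img <- rand_img(9, 9, seed = 6)
  expect_false(isTRUE(all.equal(mc_block(img, w_db), mc_block(img, w_b))))
})

test_that("channel attention degenerates correctly on constant input", {
  cfg <- tiny_cfg()
  wts <- init_net_weights(cfg, seed = 3L)
  C <- cfg$encoder_out_channels
  lv <- seq_len(C) / C
  const <- array(rep(lv, each = 36), c(6, 6, C)) # spatially constant
  out <- channel_attention(const, wts)
  # max-pool equals avg-pool, so the gate is sigmoid(2 * bottleneck(lv))
  conv1 <- function(v, nm) {
    w <- wts$params[[paste0(nm, ".w")]]
    drop(t(matrix(w, dim(w)[3L], dim(w)[4L])) %*% v) + wts$params[[paste0(nm, ".b")]]
  }
  m_c <- 1 / (1 + exp(-2 * conv1(pmax(conv1(lv, "ca.reduce"), 0), "ca.expand")))
  expect_true(all(m_c > 0 & m_c < 1))
  expect_equal(out, array(rep(lv * m_c, each = 36), c(6, 6, C)))
})

test_that("attention gates rescale without changing sign or mixing axes", {
  cfg <- tiny_cfg()
  wts <- init_net_weights(cfg, seed = 4L)
  f <- rand_stack(7, 6, cfg$encoder_out_channels, seed = 7)
  ca <- channel_attention(f, wts)
  # per-channel ratio is constant and in (0, 1)
  for (c in seq_len(dim(f)[3])) {
    ratio <- ca[, , c] / f[, , c]
    expect_lt(diff(range(ratio)), 1e-12)
    expect_gt(ratio[1], 0)
    expect_lt(ratio[1], 1)
  }
  sa <- spatial_attention(f, wts)
  # per-pixel ratio is constant across channels and in (0, 1)
  r <- sa / f
  expect_lt(max(apply(r, c(1, 2), function(v) diff(range(v)))), 1e-12)
  expect_true(all(r > 0 & r < 1))
  # single-channel input: channel max-pool and avg-pool both equal the input
  x1 <- abs(rand_stack(6, 6, 1, seed = 8))
  tape <- medfuse:::new_tape()
  xn <- medfuse:::ad_const(tape, array(x1, c(6, 6, 1, 1)))
  mx <- medfuse:::ad_cpool_max(tape, xn)
  av <- medfuse:::ad_cpool_avg(tape, xn)
  expect_equal(mx$value, xn$value)
  expect_equal(av$value, xn$value)
})

test_that("the decoder has five layers with a linear final activation", {
  cfg <- tiny_cfg()
  wts <- init_net_weights(cfg, seed = 9L)
  dec_layers <- grep("^dec\\.l[0-9]+\\.w$", names(wts$params), value = TRUE)
  expect_length(dec_layers, 5L)
  # raw output of the linear last layer goes negative for some input
  raws <- vapply(1:20, function(s) {
    min(decode(rand_stack(8, 8, cfg$decoder_channels[1L], seed = s), wts,
               clip = FALSE))
  }, 0)
  expect_lt(min(raws), 0)
  # clipped export stays in [0, 1]
  out <- decode(rand_stack(8, 8, cfg$decoder_channels[1L], seed = 1), wts)
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
})

test_that("encoding is deterministic and siamese across modalities", {
  wts <- init_net_weights(tiny_cfg(), seed = 10L)
  pair <- make_pair(phantom_spec(size = 16L, seed = 1L))
  expect_identical(encode(pair$ct, wts), encode(pair$ct, wts))
  # one weights object serves both modalities; outputs differ only via input
  f_ct <- encode(pair$ct, wts)
  f_mri <- encode(pair$mri, wts)
  expect_identical(dim(f_ct), dim(f_mri))
  expect_false(identical(f_ct, f_mri))
})

test_that("analytic gradients match finite differences through the network", {
  cfg <- tiny_cfg()
  wts <- init_net_weights(cfg, seed = 7L)
  img <- medfuse:::with_seed(21L, array(runif(10 * 9), c(10, 9, 1, 1)))
  lossval <- function(params) {
    tape <- medfuse:::new_tape()
    P <- medfuse:::params_to_nodes(tape, params)
    xn <- medfuse:::ad_const(tape, img)
    rec <- medfuse:::fwd_decoder(tape, medfuse:::fwd_encoder(tape, xn, P, cfg),
                                 P, cfg)
    pix <- medfuse:::ad_mse(tape, rec, img, 90)
    gr <- medfuse:::grad_responses(tape, rec, "sobel")
    tg <- medfuse:::grad_responses(tape, xn, "sobel")$value
    gl <- medfuse:::ad_mse(tape, gr, tg, 90)
    list(tape = tape,
         tot = medfuse:::ad_wsum(tape, list(pix, gl), c(1, 1)), P = P)
  }
  r <- lossval(wts$params)
  medfuse:::ad_backward(r$tape, r$tot)
  # every parameter receives a gradient and it is not all-zero
  for (nm in names(wts$params)) expect_false(is.null(r$P[[nm]]$grad))
  gnorm <- vapply(r$P, function(n) sqrt(sum(n$grad^2)), 0)
  expect_true(all(gnorm > 0))
  # spot-check weight entries against central differences (smooth
  # directions; ReLU kinks are excluded by the fixed seed)
  medfuse:::with_seed(31L, {
    for (nm in c("shallow.w", "b3.c2.w", "integrate.w", "ca.expand.w",
                 "sa.conv.w", "refine.w", "dec.l2.w", "dec.l5.b")) {
      k <- sample(length(wts$params[[nm]]), 1L)
      eps <- 1e-5
      up <- wts$params; up[[nm]][k] <- up[[nm]][k] + eps
      dn <- wts$params; dn[[nm]][k] <- dn[[nm]][k] - eps
      num <- (lossval(up)$tot$value - lossval(dn)$tot$value) / (2 * eps)
      ana <- r$P[[nm]]$grad[k]
      expect_equal(ana, num, tolerance = 1e-3)
    }
  })
})

test_that("weights serialize with configuration verification", {
  tmp <- withr::local_tempfile(fileext = ".rds")
  wts <- init_net_weights(tiny_cfg(), seed = 12L)
  save_net_weights(wts, tmp)
  back <- load_net_weights(tmp)
  expect_equal(back$params, wts$params)
  # a corrupted layer shape is refused
  bad <- wts
  bad$params[["dec.l1.w"]] <- array(0, c(3, 3, 2, 2))
  save_net_weights(bad, tmp)
  expect_error(load_net_weights(tmp), "disagrees")
})
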