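test_that("GLU halves the channels and matches the scalar-loop oracle", {
  expect_equal(glu(matrix(c(1, -2, 0, 0), nrow = 1)),
               matrix(c(0.5, -1.0), nrow = 1))
  # saturated gate passes A through
  expect_equal(glu(matrix(c(3, -4, 50, 50), nrow = 1)),
               matrix(c(3, -4), nrow = 1), tolerance = 1e-12)
  withr::with_seed(10, {
    x <- matrix(rnorm(9 * 8), 9, 8)
    expect_lt(max(abs(glu(x) - oracle_glu(x))), 1e-6)
  })
  expect_error(glu(matrix(0, 2, 3)), "even")
})

test_that("LayerNorm and width-k convolution match scalar-loop oracles", {
  withr::with_seed(11, {
    x <- matrix(rnorm(7 * 6), 7, 6)
    g <- runif(6, 0.5, 1.5); b <- rnorm(6)
    ln <- bindsite:::layer_norm_forward(x, g, b)$y
    expect_lt(max(abs(ln - oracle_layer_norm(x, g, b))), 1e-10)
    W <- bindsite:::make_conv_weight(matrix(rnorm(3 * 6 * 4), 18, 4), 3)
    bb <- rnorm(4)
    cv <- bindsite:::conv1d_forward(x, W, bb, 1, 1)$y
    expect_lt(max(abs(cv - oracle_conv1d(x, W, bb, 1, 1))), 1e-10)
    # causal paddings shift the window one-sidedly
    cvl <- bindsite:::conv1d_forward(x, W, bb, 2, 0)$y
    expect_lt(max(abs(cvl - oracle_conv1d(x, W, bb, 2, 0))), 1e-10)
  })
})

test_that("a block is LN-GLU-Conv plus residual and matches a composed oracle", {
  withr::with_seed(12, {
    cfg <- network_config(k = 3, n_blocks = 1, channels = 2, n_stages = 1,
                          dropout_rate = 0)
    w <- generic_weights(cfg)
    x <- matrix(rnorm(7 * 4), 7, 4)
    got <- basic_block_forward(x, w, "enc.s1.b1")
    want <- oracle_basic_block(x, w[["enc.s1.b1.ln.g"]], w[["enc.s1.b1.ln.b"]],
                               w[["enc.s1.b1.W"]], w[["enc.s1.b1.b"]])
    expect_equal(dim(got), dim(x))
    expect_lt(max(abs(got - want)), 1e-5)
    # zero convolution weights reduce the block to the identity
    w0 <- w
    w0[["enc.s1.b1.W"]][] <- 0
    w0[["enc.s1.b1.b"]][] <- 0
    expect_equal(basic_block_forward(x, w0, "enc.s1.b1"), x)
    # the Plain variant drops the residual
    expect_lt(max(abs(basic_block_forward(x, w, "enc.s1.b1", residual = FALSE) -
                        (want - x))), 1e-5)
  })
})

test_that("encoder preserves shape across lengths and rejects wrong input width", {
  cfg <- network_config(k = 3, n_blocks = 2, channels = 4, dropout_rate = 0)
  w <- withr::with_seed(13, generic_weights(cfg))
  for (m in c(1, 5, 80)) {
    fmap <- withr::with_seed(m, matrix(rnorm(m * 30), m, 30))
    out <- encoder_forward(fmap, cfg, w)
    expect_equal(dim(out), c(m, 8L))
  }
  expect_error(encoder_forward(matrix(0, 5, 29), cfg, w), "columns")
})

test_that("empirical receptive field of a random encoder equals 1 + n(k-1)", {
  for (k in c(3L, 5L)) {
    for (n in c(2L, 4L)) {
      cfg <- network_config(k = k, n_blocks = n - 1L, channels = 3,
                            n_stages = 1L, dropout_rate = 0)
      expect_equal(bindsite:::conv_layer_count(cfg), n)
      w <- withr::with_seed(100 + 10 * k + n, generic_weights(cfg))
      m <- 41L; j <- 21L
      fmap <- withr::with_seed(50 + k + n, matrix(rnorm(m * 30), m, 30))
      base <- encoder_forward(fmap, cfg, w)
      fmap2 <- fmap
      fmap2[j, ] <- fmap2[j, ] + 1
      pert <- encoder_forward(fmap2, cfg, w)
      touched <- which(rowSums(abs(pert - base)) > 1e-12)
      expect_equal(max(touched) - min(touched) + 1L, receptive_field(n, k))
      expect_true(all(abs(touched - j) <= (receptive_field(n, k) - 1L) / 2L))
    }
  }
})

test_that("decoder rows are softmax-normalized and masked rows are dropped", {
  cfg <- network_config(k = 3, n_blocks = 1, channels = 4, n_stages = 1,
                        dropout_rate = 0.5)
  w <- withr::with_seed(14, generic_weights(cfg))
  enc <- withr::with_seed(15, matrix(rnorm(10 * 8), 10, 8))
  mask <- c(rep(TRUE, 7), FALSE, FALSE, FALSE)
  p <- std_decoder_forward(enc, cfg, w, mask)
  expect_equal(nrow(p), 7L)
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-9)
  # inference is deterministic (dropout only under training)
  expect_identical(p, std_decoder_forward(enc, cfg, w, mask))
  expect_warning(p0 <- std_decoder_forward(enc, cfg, w, rep(FALSE, 10)),
                 "masked")
  expect_equal(nrow(p0), 0L)
  expect_true(isTRUE(attr(p0, "empty")))
})

test_that("predictions are invariant to padding and batch composition", {
  cfg <- network_config(k = 3, n_blocks = 2, channels = 4, dropout_rate = 0)
  w <- withr::with_seed(16, generic_weights(cfg))
  model <- list(config = cfg, weights = w)
  pr_short <- random_protein("short", 9, seed = 17)
  pr_long <- random_protein("long", 23, seed = 18)
  alone <- predict_binding(model, pr_short)
  # manual padded-batch forward with the dummy-residue rows of build_batches
  emb <- bindsite:::embed_corpus(list(pr_short, pr_long))
  batch <- build_batches(emb, batch_size = 2)[[1]]
  i_short <- which(batch$ids == "short")
  p_batch <- std_decoder_forward(
    encoder_forward(batch$features[[i_short]], cfg, w, batch$masks[[i_short]]),
    cfg, w, batch$masks[[i_short]])
  expect_equal(as.numeric(p_batch[, 2]), alone$p_positive, tolerance = 1e-6)
  # same protein, different companion: identical predictions
  pr_other <- random_protein("other", 31, seed = 19)
  emb2 <- bindsite:::embed_corpus(list(pr_short, pr_other))
  batch2 <- build_batches(emb2, batch_size = 2)[[1]]
  i2 <- which(batch2$ids == "short")
  p_batch2 <- std_decoder_forward(
    encoder_forward(batch2$features[[i2]], cfg, w, batch2$masks[[i2]]),
    cfg, w, batch2$masks[[i2]])
  expect_equal(p_batch, p_batch2, tolerance = 1e-12)
})

test_that("context branches are one-sidedly causal and zero context is first-pass", {
  cfg <- network_config(k = 3, n_blocks = 1, m_blocks = 2, channels = 4,
                        n_stages = 1, mode = "en", dropout_rate = 0)
  w <- withr::with_seed(20, generic_weights(cfg))
  m <- 15L
  ctx <- withr::with_seed(21, matrix(runif(m * 2), m, 2))
  left0 <- bindsite:::context_branch_forward(ctx, "ctxL", cfg, w)$out
  right0 <- bindsite:::context_branch_forward(ctx, "ctxR", cfg, w)$out
  for (i in c(2L, 8L, 14L)) {
    ctx2 <- ctx
    ctx2[i, ] <- ctx2[i, ] + 1
    left1 <- bindsite:::context_branch_forward(ctx2, "ctxL", cfg, w)$out
    right1 <- bindsite:::context_branch_forward(ctx2, "ctxR", cfg, w)$out
    # left branch at positions <= i never sees context at i
    expect_lt(max(abs(left1[seq_len(i), ] - left0[seq_len(i), ])), 1e-12)
    expect_lt(max(abs(right1[i:m, ] - right0[i:m, ])), 1e-12)
    # and the perturbation does reach the other side
    expect_gt(max(abs(left1 - left0)), 1e-8)
    expect_gt(max(abs(right1 - right0)), 1e-8)
  }
  enc <- withr::with_seed(22, matrix(rnorm(m * 8), m, 8))
  p <- en_decoder_forward(enc, matrix(0, m, 2), cfg, w)
  expect_equal(rowSums(p), rep(1, m), tolerance = 1e-9)
  expect_error(en_decoder_forward(enc, matrix(0, m - 1, 2), cfg, w), "rows")
})

test_that("predict_binding thresholds correctly at the extremes", {
  cfg <- network_config(k = 3, n_blocks = 1, channels = 4, n_stages = 1,
                        dropout_rate = 0)
  w <- withr::with_seed(23, generic_weights(cfg))
  model <- list(config = cfg, weights = w)
  pr <- random_protein("p", 12, seed = 24)
  expect_true(all(predict_binding(model, pr, threshold = 1 + 1e-9)$label_pred == 0))
  expect_true(all(predict_binding(model, pr, threshold = 0)$label_pred == 1))
})

test_that("weight/config mismatches are rejected with a shape diagnostic", {
  cfg <- network_config(k = 3, n_blocks = 1, channels = 4, n_stages = 1)
  w <- withr::with_seed(25, init_weights(cfg))
  cfg_big <- network_config(k = 5, n_blocks = 1, channels = 4, n_stages = 1)
  expect_error(predict_binding(list(config = cfg_big, weights = w),
                               random_protein("p", 8, seed = 26)),
               "incompatible")
})
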