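test_that("the objective matches its closed forms and ignores padding", {
  # rows: labels 1, 0, 1 predicted perfectly
  p_perfect <- cbind(c(0, 1, 0), c(1, 0, 1))
  expect_equal(masked_loss(p_perfect, c(1, 0, 1), gamma = 0), 0,
               tolerance = 1e-9)
  p_unif <- matrix(0.5, 4, 2)
  expect_equal(masked_loss(p_unif, c(0, 1, 1, 0), gamma = 0), log(2))
  expect_equal(masked_loss(p_unif, c(0, 1, 1, 0), gamma = 0,
                           reduction = "sum"), 4 * log(2))
  expect_error(masked_loss(matrix(0, 0, 2), integer(0)), "no valid residues")
  # L2 term covers kernels only
  cfg <- network_config(k = 3, n_blocks = 1, channels = 2, n_stages = 1)
  w <- withr::with_seed(40, init_weights(cfg))
  l2 <- bindsite:::l2_penalty(w)
  expect_equal(masked_loss(p_unif, c(0, 1, 1, 0), w, gamma = 0.2),
               log(2) + 0.2 * l2)
  w_ln <- w
  w_ln[["enc.s1.b1.ln.g"]] <- w_ln[["enc.s1.b1.ln.g"]] * 100
  expect_equal(bindsite:::l2_penalty(w_ln), l2)
})

test_that("loss is unchanged when padded residues join the batch", {
  cfg <- network_config(k = 3, n_blocks = 1, channels = 4, n_stages = 1,
                        dropout_rate = 0)
  w <- withr::with_seed(41, generic_weights(cfg))
  pr <- random_protein("p", 11, seed = 42)
  fmap <- embed_protein(pr)
  p_alone <- std_decoder_forward(encoder_forward(fmap, cfg, w), cfg, w)
  # pad with 6 dummy rows as inside a batch
  dummy <- bindsite:::dummy_feature_row()
  fmap_pad <- rbind(fmap, matrix(dummy, 6, 30, byrow = TRUE))
  mask <- c(rep(TRUE, 11), rep(FALSE, 6))
  p_pad <- std_decoder_forward(encoder_forward(fmap_pad, cfg, w, mask),
                               cfg, w, mask)
  expect_equal(unclass(p_pad), unclass(p_alone), tolerance = 1e-9)
  expect_equal(masked_loss(p_pad, pr$labels, gamma = 0),
               masked_loss(p_alone, pr$labels, gamma = 0), tolerance = 1e-12)
})

test_that("batches keep whole sequences, pad to batch maximum, and shuffle reproducibly", {
  prot <- lapply(c(3L, 5L, 4L, 7L), function(m) {
    random_protein(paste0("p", m), m, seed = m)
  })
  emb <- bindsite:::embed_corpus(prot)
  b <- build_batches(emb[1:2], batch_size = 2)
  expect_equal(nrow(b[[1]]$features[[1]]), 5L)
  expect_equal(sum(!b[[1]]$masks[[1]]), 2L)
  expect_equal(sum(!b[[1]]$masks[[2]]), 0L)
  # dummy rows carry the dummy-residue embedding
  expect_equal(unname(b[[1]]$features[[1]][4, ]),
               unname(bindsite:::dummy_feature_row()))
  # batch size 1: no padding ever
  b1 <- build_batches(emb, batch_size = 1)
  expect_true(all(vapply(b1, function(x) all(x$masks[[1]]), TRUE)))
  # seeded shuffling is reproducible and batches may differ in padded length
  s1 <- build_batches(emb, batch_size = 2, seed = 9)
  s2 <- build_batches(emb, batch_size = 2, seed = 9)
  expect_identical(lapply(s1, `[[`, "ids"), lapply(s2, `[[`, "ids"))
  expect_error(build_batches(list(), 2), "empty")
})

test_that("learning-rate schedule decays exponentially within stages and resets at boundaries", {
  tc <- training_config(stages = list(
    list(init = 0.1, decay = 0.5, interval = 100L, budget = 300L),
    list(init = 0.4, decay = 0.9, interval = 50L, budget = 200L),
    list(init = 0.01, decay = 0.8, interval = 100L, budget = 100L)))
  expect_equal(lr_schedule(0, tc), 0.1)
  expect_equal(lr_schedule(250, tc), 0.1 * 0.25)
  expect_equal(lr_schedule(300, tc), 0.4)     # stage-2 initial exceeds stage 1
  expect_equal(lr_schedule(375, tc), 0.4 * 0.9)
  expect_equal(lr_schedule(500, tc), 0.01)
  expect_equal(lr_schedule(10000, tc), lr_schedule(599, tc))  # held
  expect_error(lr_schedule(-1, tc), ">= 0")
})

test_that("training is reproducible given a seed and records a sane history", {
  cfg <- network_config(k = 3, n_blocks = 1, channels = 3, n_stages = 1,
                        dropout_rate = 0.2)
  prot <- lapply(1:4, function(i) random_protein(paste0("p", i), 8, seed = 50 + i))
  tc <- training_config(gamma = 1e-3, dropout_rate = 0.2, batch_size = 2,
                        optimizer = "sgd", seed = 51,
                        stages = list(list(init = 0.05, decay = 0.9,
                                           interval = 10, budget = 20),
                                      list(init = 0.1, decay = 0.9,
                                           interval = 10, budget = 20),
                                      list(init = 0.01, decay = 0.8,
                                           interval = 10, budget = 10)))
  m1 <- train_std(prot, cfg, tc)
  m2 <- train_std(prot, cfg, tc)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
  expect_equal(m1$history$iteration, 1:50)
  expect_equal(unique(m1$history$stage), c(1L, 2L, 3L))
  # loss trends downward over the run on average
  expect_lt(mean(tail(m1$history$loss, 10)), mean(head(m1$history$loss, 10)))
})

test_that("a huge L2 coefficient collapses predictions to the majority class", {
  cfg <- network_config(k = 3, n_blocks = 1, channels = 3, n_stages = 1,
                        dropout_rate = 0)
  prot <- lapply(1:3, function(i) {
    pr <- random_protein(paste0("p", i), 10, seed = 60 + i)
    pr$labels <- as.integer(seq_len(10) %in% c(2, 3))
    pr
  })
  tc <- training_config(gamma = 5, dropout_rate = 0, batch_size = 3,
                        optimizer = "sgd", seed = 61,
                        stages = list(list(init = 0.02, decay = 1,
                                           interval = 50, budget = 60),
                                      list(init = 0.02, decay = 1,
                                           interval = 50, budget = 60),
                                      list(init = 0.01, decay = 1,
                                           interval = 50, budget = 30)))
  model <- train_std(prot, cfg, tc)
  # kernels shrink hard toward zero...
  expect_lt(sqrt(bindsite:::l2_penalty(model$weights)), 0.5)
  # ...and everything is called non-binding (majority class)
  preds <- predict_binding(model, prot, threshold = 0.4)
  expect_true(all(preds$label_pred == 0))
})

test_that("enhanced training freezes the encoder and stays defined at zero iterations", {
  cfg <- network_config(k = 3, n_blocks = 1, channels = 3, n_stages = 1,
                        dropout_rate = 0)
  prot <- lapply(1:3, function(i) random_protein(paste0("p", i), 9, seed = 70 + i))
  tc <- training_config(gamma = 0, dropout_rate = 0, batch_size = 3,
                        optimizer = "sgd", seed = 71,
                        stages = list(list(init = 0.02, decay = 1,
                                           interval = 10, budget = 10),
                                      list(init = 0.02, decay = 1,
                                           interval = 10, budget = 10),
                                      list(init = 0.01, decay = 1,
                                           interval = 10, budget = 5)))
  std_model <- train_std(prot, cfg, tc)
  en_model <- train_en(prot, std_model, tc)
  enc_names <- grep("^enc\\.", names(std_model$weights), value = TRUE)
  expect_identical(std_model$weights[enc_names], en_model$weights[enc_names])
  # minimal-iteration en model still predicts (context branches at init)
  tc1 <- training_config(gamma = 0, dropout_rate = 0, batch_size = 3,
                         optimizer = "sgd", seed = 72,
                         stages = list(list(init = 1e-9, decay = 1,
                                            interval = 1, budget = 1),
                                       list(init = 1e-9, decay = 1,
                                            interval = 1, budget = 1),
                                       list(init = 1e-9, decay = 1,
                                            interval = 1, budget = 1)))
  en0 <- train_en(prot, std_model, tc1)
  preds <- predict_binding(en0, prot[[1]])
  expect_equal(nrow(preds), 9L)
  expect_true(all(is.finite(preds$p_positive)))
})
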