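# Independent scalar-loop oracles for the network primitives and metrics.
# Deliberately naive: plain loops, no shared code with the implementation.

oracle_glu <- function(x) {
  half <- ncol(x) / 2
  y <- matrix(0, nrow(x), half)
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(half)) {
      b <- x[i, half + j]
      y[i, j] <- x[i, j] * (1 / (1 + exp(-b)))
    }
  }
  y
}

oracle_layer_norm <- function(x, g, b, eps = 1e-5) {
  y <- x
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    mu <- mean(r)
    v <- mean((r - mu)^2)
    y[i, ] <- g * (r - mu) / sqrt(v + eps) + b
  }
  y
}

oracle_conv1d <- function(x, W, b, pad_left, pad_right) {
  k <- attr(W, "k")
  cin <- ncol(x)
  cout <- ncol(W)
  xp <- rbind(matrix(0, pad_left, cin), x, matrix(0, pad_right, cin))
  m_out <- nrow(xp) - k + 1
  y <- matrix(0, m_out, cout)
  for (i in seq_len(m_out)) {
    acc <- b
    for (t in seq_len(k)) {
      for (ci in seq_len(cin)) {
        acc <- acc + xp[i + t - 1, ci] * W[(t - 1) * cin + ci, ]
      }
    }
    y[i, ] <- acc
  }
  y
}

oracle_basic_block <- function(x, ln_g, ln_b, W, b, residual = TRUE) {
  k <- attr(W, "k")
  h <- oracle_layer_norm(x, ln_g, ln_b)
  h <- oracle_glu(h)
  h <- oracle_conv1d(h, W, b, (k - 1) / 2, (k - 1) / 2)
  if (residual) h + x else h
}

oracle_confusion <- function(labels, preds, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(labels))
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(labels)) {
    if (!mask[i]) next
    if (labels[i] == 1 && preds[i] == 1) tp <- tp + 1
    if (labels[i] == 0 && preds[i] == 1) fp <- fp + 1
    if (labels[i] == 0 && preds[i] == 0) tn <- tn + 1
    if (labels[i] == 1 && preds[i] == 0) fn <- fn + 1
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Random weights moved off the all-zero-bias init so every LayerNorm sits at
# a generic (differentiable) point.
generic_weights <- function(config, sd = 0.3) {
  w <- init_weights(config)
  lapply(w, function(x) {
    a <- attributes(x)
    x[] <- x + stats::rnorm(length(x), sd = sd)
    attributes(x) <- a
    x
  })
}

# Tiny labeled protein with random features, for fast end-to-end checks.
random_protein <- function(id, m, seed = NULL) {
  gen <- function() {
    letters20 <- names(aa_alphabet())[1:20]
    feats <- data.frame(matrix(stats::rnorm(m * 20), m, 20))
    names(feats) <- paste0("pssm_", 1:20)
    feats$rsa <- stats::runif(m)
    feats$ss_h <- stats::runif(m); feats$ss_e <- stats::runif(m)
    feats$ss_c <- stats::runif(m)
    feats$phi <- stats::runif(m, -180, 180)
    feats$psi <- stats::runif(m, -180, 180)
    feats$cs_re <- stats::runif(m); feats$cs_jsd <- stats::runif(m)
    list(id = id, sequence = paste(sample(letters20, m, TRUE), collapse = ""),
         labels = stats::rbinom(m, 1, 0.2), features = feats)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
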