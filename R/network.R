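# Network architecture: an encoder of stacked LN-GLU-Conv blocks with
# residual connections, a standard decoder (two 1x1 convolutions + 2-way
# softmax) and an enhanced decoder that folds a context prediction back in
# through two causal branches before the same decoding head.

#' Network configuration
#'
#' @param k Convolution kernel width; must be odd. Default 5.
#' @param n_blocks Blocks per encoder stage (N). Default 10.
#' @param m_blocks Blocks per context stage of the enhanced decoder (M).
#'   Default 2.
#' @param channels Channel half-width c; every block carries `2c` channels.
#'   Default 256.
#' @param d Input feature dimensions. Default 30.
#' @param dropout_rate Dropout on the first decoder layer during training.
#'   Default 0.5.
#' @param mode `"std"` (single-pass decoder) or `"en"` (two-pass,
#'   context-aware decoder).
#' @param n_stages Number of encoder stages. Default 2.
#' @return An object of class `network_config`.
#' @export
network_config <- function(k = 5L, n_blocks = 10L, m_blocks = 2L,
                           channels = 256L, d = 30L, dropout_rate = 0.5,
                           mode = c("std", "en"), n_stages = 2L) {
  mode <- match.arg(mode)
  k <- as.integer(k); n_blocks <- as.integer(n_blocks)
  m_blocks <- as.integer(m_blocks); channels <- as.integer(channels)
  d <- as.integer(d); n_stages <- as.integer(n_stages)
  if (k < 1L || k %% 2L == 0L) stop("network_config: k must be odd and >= 1")
  if (n_blocks < 1L || m_blocks < 1L) stop("network_config: N and M must be >= 1")
  if (channels < 1L) stop("network_config: channels must be >= 1")
  if (n_stages < 1L) stop("network_config: n_stages must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("network_config: dropout_rate must be in [0, 1)")
  }
  structure(list(k = k, n_blocks = n_blocks, m_blocks = m_blocks,
                 channels = channels, d = d, dropout_rate = dropout_rate,
                 mode = mode, n_stages = n_stages),
            class = "network_config")
}

# Number of k-width convolution layers between input and decoder; 1x1
# decoder layers do not widen the context.
conv_layer_count <- function(config) 1L + config$n_stages * config$n_blocks

#' Receptive field of stacked convolutions
#'
#' `n` stacked stride-1 convolutions of width `k` give one output position a
#' context of `1 + n * (k - 1)` input elements.
#'
#' @param n Number of stacked convolution layers.
#' @param k Kernel width.
#' @return Integer span of the input field.
#' @export
#' @examples
#' receptive_field(10, 3)  # 21
#' receptive_field(20, 5)  # 81
receptive_field <- function(n, k) {
  if (any(n < 0) || any(k < 1)) stop("receptive_field: need n >= 0, k >= 1")
  as.integer(1 + n * (k - 1))
}

# --- weight bookkeeping ------------------------------------------------------

# Weights live in a flat named list. Kernel matrices end in ".W", biases in
# ".b", LayerNorm gains/offsets in ".g"/".ln.b"/".top.b". L2 regularization
# and variance-scaled init apply to ".W" entries only.
kernel_names <- function(weights) grep("\\.W$", names(weights), value = TRUE)

weight_groups <- function(config) {
  g <- list(enc = character(0), dec = character(0), ctx = character(0))
  g$enc <- c("enc.in.W", "enc.in.b",
             unlist(lapply(seq_len(config$n_stages), function(s) {
               c(unlist(lapply(seq_len(config$n_blocks), function(j) {
                 p <- sprintf("enc.s%d.b%d", s, j)
                 paste0(p, c(".ln.g", ".ln.b", ".W", ".b"))
               })),
               sprintf("enc.s%d.top.%s", s, c("g", "b")))
             })))
  g$dec <- c("dec.fc1.W", "dec.fc1.b", "dec.fc2.W", "dec.fc2.b")
  if (config$mode == "en") {
    g$ctx <- unlist(lapply(c("ctxL", "ctxR"), function(side) {
      c(paste0(side, ".in.W"), paste0(side, ".in.b"),
        unlist(lapply(seq_len(config$m_blocks), function(j) {
          p <- sprintf("%s.b%d", side, j)
          paste0(p, c(".ln.g", ".ln.b", ".W", ".b"))
        })),
        paste0(side, ".top.", c("g", "b")))
    }))
  }
  g
}

init_conv <- function(k, cin, cout) {
  fan_in <- k * cin
  make_conv_weight(
    matrix(stats::rnorm(fan_in * cout, sd = sqrt(1 / fan_in)), fan_in, cout),
    k)
}

#' Initialize network weights
#'
#' Variance-scaling (1/fan-in) Gaussian initialization for convolution and
#' projection kernels, zeros for biases and LayerNorm offsets, ones for
#' LayerNorm gains. Draws from the session RNG; call `set.seed()` first for
#' reproducibility.
#'
#' @param config A [network_config()].
#' @return Flat named list of weight tensors.
#' @export
init_weights <- function(config) {
  k <- config$k; c2 <- 2L * config$channels; ch <- config$channels
  w <- list()
  add_block <- function(w, prefix) {
    w[[paste0(prefix, ".ln.g")]] <- rep(1, c2)
    w[[paste0(prefix, ".ln.b")]] <- rep(0, c2)
    w[[paste0(prefix, ".W")]] <- init_conv(k, ch, c2)
    w[[paste0(prefix, ".b")]] <- rep(0, c2)
    w
  }
  w[["enc.in.W"]] <- init_conv(k, config$d, c2)
  w[["enc.in.b"]] <- rep(0, c2)
  for (s in seq_len(config$n_stages)) {
    for (j in seq_len(config$n_blocks)) {
      w <- add_block(w, sprintf("enc.s%d.b%d", s, j))
    }
    w[[sprintf("enc.s%d.top.g", s)]] <- rep(1, c2)
    w[[sprintf("enc.s%d.top.b", s)]] <- rep(0, c2)
  }
  w[["dec.fc1.W"]] <- init_conv(1L, c2, ch)
  w[["dec.fc1.b"]] <- rep(0, ch)
  w[["dec.fc2.W"]] <- init_conv(1L, ch, 2L)
  w[["dec.fc2.b"]] <- rep(0, 2)
  if (config$mode == "en") {
    for (side in c("ctxL", "ctxR")) {
      w[[paste0(side, ".in.W")]] <- init_conv(k, 2L, c2)
      w[[paste0(side, ".in.b")]] <- rep(0, c2)
      for (j in seq_len(config$m_blocks)) {
        w <- add_block(w, sprintf("%s.b%d", side, j))
      }
      w[[paste0(side, ".top.g")]] <- rep(1, c2)
      w[[paste0(side, ".top.b")]] <- rep(0, c2)
    }
  }
  w
}

# --- blocks ------------------------------------------------------------------

block_forward <- function(x, weights, prefix, pad_mode, mask = NULL,
                          residual = TRUE, keep_cache = FALSE) {
  k <- attr(weights[[paste0(prefix, ".W")]], "k")
  ln <- layer_norm_forward(x, weights[[paste0(prefix, ".ln.g")]],
                           weights[[paste0(prefix, ".ln.b")]],
                           keep_cache = keep_cache)
  gl <- glu_forward(ln$y, keep_cache = keep_cache)
  pads <- conv_pads(k, pad_mode)
  cv <- conv1d_forward(gl$y, weights[[paste0(prefix, ".W")]],
                       weights[[paste0(prefix, ".b")]],
                       pads[1], pads[2], mask = mask, keep_cache = keep_cache)
  y <- if (residual) cv$y + x else cv$y
  cache <- NULL
  if (keep_cache) {
    cache <- list(ln = ln$cache, gl = gl$cache, cv = cv$cache,
                  residual = residual, prefix = prefix)
  }
  list(y = y, cache = cache)
}

block_backward <- function(dy, cache, grads) {
  cv <- conv1d_backward(dy, cache$cv)
  dgl <- glu_backward(cv$dx, cache$gl)
  dln <- layer_norm_backward(dgl, cache$ln)
  dx <- if (cache$residual) dln$dx + dy else dln$dx
  p <- cache$prefix
  grads[[paste0(p, ".W")]] <- grads[[paste0(p, ".W")]] + cv$dW
  grads[[paste0(p, ".b")]] <- grads[[paste0(p, ".b")]] + cv$db
  grads[[paste0(p, ".ln.g")]] <- grads[[paste0(p, ".ln.g")]] + dln$dg
  grads[[paste0(p, ".ln.b")]] <- grads[[paste0(p, ".ln.b")]] + dln$db
  list(dx = dx, grads = grads)
}

#' Forward pass of one LN-GLU-Conv block
#'
#' Layer-normalizes the `m x 2c` input per residue, gates it down to `c`
#' channels with a GLU, convolves back up to `2c` channels with a width-`k`
#' kernel (zero-padded to keep `m`), and adds the raw block input back
#' (unless `residual = FALSE`, the "Plain" variant used at the bottom of a
#' stage).
#'
#' @param x Numeric matrix `m x 2c`.
#' @param weights Flat weight list containing `<prefix>.ln.g`,
#'   `<prefix>.ln.b`, `<prefix>.W`, `<prefix>.b`.
#' @param prefix Name prefix of this block's weights.
#' @param residual Add the residual connection? Default `TRUE`.
#' @param pad_mode `"same"`, `"left"` or `"right"` zero-padding.
#' @param mask Optional logical validity mask of length `m`.
#' @return Numeric matrix `m x 2c`.
#' @export
basic_block_forward <- function(x, weights, prefix, residual = TRUE,
                                pad_mode = "same", mask = NULL) {
  ch <- ncol(x)
  kw <- weights[[paste0(prefix, ".W")]]
  if (is.null(kw)) stop("basic_block_forward: no weights under prefix ", prefix)
  if (nrow(kw) != attr(kw, "k") * (ch %/% 2L) || ncol(kw) != ch) {
    stop("basic_block_forward: input channels (", ch,
         ") incompatible with block weights")
  }
  block_forward(x, weights, prefix, pad_mode, mask, residual)$y
}

# --- encoder -----------------------------------------------------------------

#' Encoder forward pass
#'
#' A width-`k` convolution lifts the `m x d` feature map to `2c` channels;
#' each stage then applies one Plain block followed by `N - 1` residual
#' blocks and a stage-top LayerNorm.
#'
#' @param fmap Numeric `m x d` feature matrix.
#' @param config A [network_config()].
#' @param weights Weight list from [init_weights()] (or trained).
#' @param mask Optional logical validity mask (TRUE = real residue).
#' @return Numeric matrix `m x 2c` (use the internal cache-keeping variant
#'   for training).
#' @export
encoder_forward <- function(fmap, config, weights, mask = NULL) {
  encoder_forward_cached(fmap, config, weights, mask, keep_cache = FALSE)$out
}

encoder_forward_cached <- function(fmap, config, weights, mask = NULL,
                                   keep_cache = FALSE) {
  if (ncol(fmap) != config$d) {
    stop("encoder_forward: feature map has ", ncol(fmap),
         " columns, config expects d = ", config$d)
  }
  p <- (config$k - 1L) %/% 2L
  cv <- conv1d_forward(fmap, weights[["enc.in.W"]], weights[["enc.in.b"]],
                       p, p, mask = mask, keep_cache = keep_cache)
  h <- cv$y
  stages <- vector("list", config$n_stages)
  for (s in seq_len(config$n_stages)) {
    blocks <- vector("list", config$n_blocks)
    for (j in seq_len(config$n_blocks)) {
      bf <- block_forward(h, weights, sprintf("enc.s%d.b%d", s, j), "same",
                          mask, residual = j > 1L, keep_cache = keep_cache)
      h <- bf$y
      blocks[[j]] <- bf$cache
    }
    ln <- layer_norm_forward(h, weights[[sprintf("enc.s%d.top.g", s)]],
                             weights[[sprintf("enc.s%d.top.b", s)]],
                             keep_cache = keep_cache)
    h <- ln$y
    stages[[s]] <- list(blocks = blocks, top = ln$cache)
  }
  cache <- if (keep_cache) list(cv = cv$cache, stages = stages) else NULL
  list(out = h, cache = cache)
}

encoder_backward <- function(dh, cache, config, grads) {
  for (s in rev(seq_len(config$n_stages))) {
    st <- cache$stages[[s]]
    ln <- layer_norm_backward(dh, st$top)
    gname <- sprintf("enc.s%d.top.g", s)
    bname <- sprintf("enc.s%d.top.b", s)
    grads[[gname]] <- grads[[gname]] + ln$dg
    grads[[bname]] <- grads[[bname]] + ln$db
    dh <- ln$dx
    for (j in rev(seq_len(config$n_blocks))) {
      bb <- block_backward(dh, st$blocks[[j]], grads)
      dh <- bb$dx
      grads <- bb$grads
    }
  }
  cv <- conv1d_backward(dh, cache$cv, need_dx = FALSE)
  grads[["enc.in.W"]] <- grads[["enc.in.W"]] + cv$dW
  grads[["enc.in.b"]] <- grads[["enc.in.b"]] + cv$db
  grads
}

# --- standard decoder --------------------------------------------------------

#' Standard decoder forward pass
#'
#' Two 1x1 convolutions (`2c -> c`, dropout-wrapped during training, then
#' `c -> 2`) followed by a 2-way softmax. Dummy (masked) rows are dropped
#' immediately before the softmax, so the result has one row per valid
#' residue.
#'
#' @param encoding Numeric matrix `m x 2c` from the encoder (plus context
#'   branches in `"en"` mode).
#' @param config A [network_config()].
#' @param weights Weight list.
#' @param mask Optional logical validity mask of length `m`.
#' @param training Apply dropout? Default `FALSE`.
#' @return Numeric matrix `t x 2` of class probabilities (columns: negative,
#'   positive) over the `t` valid residues, with attribute `"valid"` giving
#'   their row indices in the input. If every row is masked the result has
#'   zero rows and attribute `"empty" = TRUE`.
#' @export
std_decoder_forward <- function(encoding, config, weights, mask = NULL,
                                training = FALSE) {
  std_decoder_forward_cached(encoding, config, weights, mask, training)$p
}

std_decoder_forward_cached <- function(encoding, config, weights, mask = NULL,
                                       training = FALSE, keep_cache = FALSE) {
  m <- nrow(encoding)
  if (!is.null(mask) && length(mask) != m) {
    stop("std_decoder_forward: mask length ", length(mask),
         " does not match ", m, " rows")
  }
  z1 <- encoding %*% weights[["dec.fc1.W"]]
  z1 <- sweep(z1, 2L, weights[["dec.fc1.b"]], "+")
  dp <- dropout_forward(z1, config$dropout_rate, training)
  z2 <- dp$y %*% weights[["dec.fc2.W"]]
  z2 <- sweep(z2, 2L, weights[["dec.fc2.b"]], "+")
  valid <- if (is.null(mask)) seq_len(m) else which(mask)
  p <- softmax_rows(z2[valid, , drop = FALSE])
  colnames(p) <- c("p_negative", "p_positive")
  attr(p, "valid") <- valid
  if (length(valid) == 0L) {
    attr(p, "empty") <- TRUE
    warning("std_decoder_forward: all residues masked; empty prediction")
  }
  cache <- NULL
  if (keep_cache) {
    cache <- list(encoding = encoding, z1d = dp$y, drop_mask = dp$mask,
                  valid = valid, m = m)
  }
  list(p = p, cache = cache)
}

# dlogits: t x 2 gradient at the pre-softmax logits of the valid rows.
std_decoder_backward <- function(dlogits, cache, weights, grads) {
  dz2 <- matrix(0, cache$m, 2L)
  dz2[cache$valid, ] <- dlogits
  grads[["dec.fc2.W"]] <- grads[["dec.fc2.W"]] + crossprod(cache$z1d, dz2)
  grads[["dec.fc2.b"]] <- grads[["dec.fc2.b"]] + colSums(dz2)
  dz1 <- tcrossprod(dz2, weights[["dec.fc2.W"]])
  if (!is.null(cache$drop_mask)) dz1 <- dz1 * cache$drop_mask
  grads[["dec.fc1.W"]] <- grads[["dec.fc1.W"]] + crossprod(cache$encoding, dz1)
  grads[["dec.fc1.b"]] <- grads[["dec.fc1.b"]] + colSums(dz1)
  dh <- tcrossprod(dz1, weights[["dec.fc1.W"]])
  list(dh = dh, grads = grads)
}

# --- context branches (enhanced decoder) -------------------------------------

# One causal branch: shift the 2-channel context off by one position, pad k
# zeros on the leading side, lift to 2c channels with a k x 2 kernel, then a
# causal stage (Plain + M-1 Basic blocks + top LayerNorm). The left branch's
# output at position i depends only on context at positions < i; the right
# branch only on positions > i.
context_branch_forward <- function(ctx, side, config, weights, mask = NULL,
                                   keep_cache = FALSE) {
  m <- nrow(ctx)
  if (!is.null(mask) && m > 0L) ctx[!mask, ] <- 0
  if (side == "ctxL") {
    z <- ctx[-m, , drop = FALSE]
    pads <- c(config$k, 0L)
    pad_mode <- "left"
  } else {
    z <- ctx[-1L, , drop = FALSE]
    pads <- c(0L, config$k)
    pad_mode <- "right"
  }
  cv <- conv1d_forward(z, weights[[paste0(side, ".in.W")]],
                       weights[[paste0(side, ".in.b")]],
                       pads[1], pads[2], keep_cache = keep_cache)
  h <- cv$y
  blocks <- vector("list", config$m_blocks)
  for (j in seq_len(config$m_blocks)) {
    bf <- block_forward(h, weights, sprintf("%s.b%d", side, j), pad_mode,
                        mask, residual = j > 1L, keep_cache = keep_cache)
    h <- bf$y
    blocks[[j]] <- bf$cache
  }
  ln <- layer_norm_forward(h, weights[[paste0(side, ".top.g")]],
                           weights[[paste0(side, ".top.b")]],
                           keep_cache = keep_cache)
  cache <- if (keep_cache) list(cv = cv$cache, blocks = blocks,
                                top = ln$cache, side = side) else NULL
  list(out = ln$y, cache = cache)
}

context_branch_backward <- function(dh, cache, config, grads) {
  side <- cache$side
  ln <- layer_norm_backward(dh, cache$top)
  grads[[paste0(side, ".top.g")]] <- grads[[paste0(side, ".top.g")]] + ln$dg
  grads[[paste0(side, ".top.b")]] <- grads[[paste0(side, ".top.b")]] + ln$db
  dh <- ln$dx
  for (j in rev(seq_len(config$m_blocks))) {
    bb <- block_backward(dh, cache$blocks[[j]], grads)
    dh <- bb$dx
    grads <- bb$grads
  }
  cv <- conv1d_backward(dh, cache$cv, need_dx = FALSE)
  grads[[paste0(side, ".in.W")]] <- grads[[paste0(side, ".in.W")]] + cv$dW
  grads[[paste0(side, ".in.b")]] <- grads[[paste0(side, ".in.b")]] + cv$db
  grads
}

#' Enhanced (context-aware) decoder forward pass
#'
#' Transforms the `m x 2` context prediction through two causal branches
#' (left context and right context), adds both branch outputs to the
#' encoder output, and applies the standard decoding head. A zero context
#' tensor reproduces first-pass behaviour.
#'
#' @inheritParams std_decoder_forward
#' @param context Numeric `m x 2` matrix of context class scores (one-hot
#'   labels during teacher forcing, first-pass probabilities at inference).
#' @return As [std_decoder_forward()].
#' @export
en_decoder_forward <- function(encoding, context, config, weights,
                               mask = NULL, training = FALSE) {
  en_decoder_forward_cached(encoding, context, config, weights, mask,
                            training)$p
}

en_decoder_forward_cached <- function(encoding, context, config, weights,
                                      mask = NULL, training = FALSE,
                                      keep_cache = FALSE) {
  if (!is.matrix(context) || ncol(context) != 2L) {
    stop("en_decoder_forward: context must be an m x 2 matrix")
  }
  if (nrow(context) != nrow(encoding)) {
    stop("en_decoder_forward: context has ", nrow(context),
         " rows but encoding has ", nrow(encoding))
  }
  lf <- context_branch_forward(context, "ctxL", config, weights, mask,
                               keep_cache)
  rf <- context_branch_forward(context, "ctxR", config, weights, mask,
                               keep_cache)
  s <- encoding + lf$out + rf$out
  dec <- std_decoder_forward_cached(s, config, weights, mask, training,
                                    keep_cache)
  cache <- if (keep_cache) list(left = lf$cache, right = rf$cache,
                                dec = dec$cache) else NULL
  list(p = dec$p, cache = cache)
}

# --- prediction --------------------------------------------------------------

one_hot_context <- function(labels) {
  cbind(1 - labels, labels)
}

#' Predict binding residues for one or more proteins
#'
#' Runs the forward pass of a trained model. In `"std"` mode this is a
#' single decoding; in `"en"` mode the decoder runs twice: first with a zero
#' context tensor, then with the first pass's probabilities as context.
#' Residues whose positive-class probability reaches `threshold` are called
#' binding.
#'
#' @param model A list with elements `config` ([network_config()]) and
#'   `weights`, e.g. from [train_std()], [train_en()] or
#'   [load_checkpoint()].
#' @param proteins A protein record or list of protein records (each with
#'   `id`, `sequence`, `features`).
#' @param threshold Minimum positive-class probability to call a residue
#'   binding. Default 0.4.
#' @param force_context Optional `m x 2` context matrix (single protein
#'   only); bypasses the first pass in `"en"` mode, e.g. for teacher-forced
#'   evaluation.
#' @return A `data.frame` with columns `protein_id`, `pos`, `residue`,
#'   `p_positive`, `label_pred`.
#' @export
predict_binding <- function(model, proteins, threshold = 0.4,
                            force_context = NULL) {
  config <- model$config
  weights <- model$weights
  check_weight_shapes(config, weights)
  if (!is.null(proteins$sequence)) proteins <- list(proteins)
  if (!is.null(force_context) && length(proteins) != 1L) {
    stop("predict_binding: force_context applies to a single protein")
  }
  out <- lapply(proteins, function(pr) {
    fmap <- embed_protein(pr)
    enc <- encoder_forward(fmap, config, weights)
    if (config$mode == "en") {
      ctx <- force_context
      if (is.null(ctx)) {
        p1 <- en_decoder_forward(enc, matrix(0, nrow(fmap), 2L), config,
                                 weights)
        ctx <- unclass_probs(p1)
      }
      p <- en_decoder_forward(enc, ctx, config, weights)
    } else {
      p <- std_decoder_forward(enc, config, weights)
    }
    data.frame(protein_id = pr$id,
               pos = seq_len(nrow(fmap)),
               residue = strsplit(pr$sequence, "")[[1]],
               p_positive = as.numeric(p[, 2L]),
               label_pred = as.integer(p[, 2L] >= threshold),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "threshold") <- threshold
  res
}

unclass_probs <- function(p) {
  attributes(p) <- list(dim = dim(p))
  p
}

# Validate that every weight tensor has the shape the config dictates.
check_weight_shapes <- function(config, weights) {
  expected <- weight_groups(config)
  need <- c(expected$enc, expected$dec, expected$ctx)
  missing_w <- setdiff(need, names(weights))
  if (length(missing_w)) {
    stop("weights incompatible with config: missing ",
         paste(utils::head(missing_w, 4L), collapse = ", "),
         if (length(missing_w) > 4L) ", ...")
  }
  c2 <- 2L * config$channels
  w_in <- weights[["enc.in.W"]]
  if (nrow(w_in) != config$k * config$d || ncol(w_in) != c2) {
    stop("weights incompatible with config: enc.in.W is ",
         nrow(w_in), "x", ncol(w_in), ", expected ",
         config$k * config$d, "x", c2)
  }
  for (nm in grep("\\.b[0-9]+\\.W$", need, value = TRUE)) {
    W <- weights[[nm]]
    if (nrow(W) != config$k * config$channels || ncol(W) != c2) {
      stop("weights incompatible with config: ", nm, " is ",
           nrow(W), "x", ncol(W), ", expected ",
           config$k * config$channels, "x", c2)
    }
  }
  invisible(TRUE)
}
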