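# Low-level network primitives on m x channels matrices, each with a
# hand-derived backward pass. Convolutions are 1D along the sequence,
# realized as im2col + matrix multiply. A weight matrix W is stored as
# (k * c_in) x c_out with rows ordered tap-major (tap 1 channels, tap 2
# channels, ...) and carries its kernel width as attr "k".

make_conv_weight <- function(W, k) {
  attr(W, "k") <- as.integer(k)
  W
}

# Masked rows are zeroed before windowing so that trailing padding inside a
# batch is indistinguishable from the zero-padding a lone sequence gets:
# predictions on valid rows are then independent of batch composition.
conv1d_forward <- function(x, W, b, pad_left, pad_right, mask = NULL,
                           keep_cache = FALSE) {
  k <- attr(W, "k")
  cin <- ncol(x)
  m <- nrow(x)
  if (!is.null(mask) && m > 0L) x[!mask, ] <- 0
  mp <- m + pad_left + pad_right
  xp <- matrix(0, mp, cin)
  if (m > 0L) xp[(pad_left + 1L):(pad_left + m), ] <- x
  m_out <- mp - k + 1L
  if (m_out < 1L) stop("conv1d_forward: input too short for kernel width ", k)
  Xc <- matrix(0, m_out, k * cin)
  for (t in seq_len(k)) {
    Xc[, ((t - 1L) * cin + 1L):(t * cin)] <- xp[t:(t + m_out - 1L), , drop = FALSE]
  }
  y <- Xc %*% W
  y <- y + matrix(b, m_out, length(b), byrow = TRUE)
  cache <- NULL
  if (keep_cache) {
    cache <- list(Xc = Xc, W = W, k = k, cin = cin, m = m, mp = mp,
                  pad_left = pad_left, mask = mask)
  }
  list(y = y, cache = cache)
}

conv1d_backward <- function(dy, cache, need_dx = TRUE) {
  k <- cache$k; cin <- cache$cin
  dW <- crossprod(cache$Xc, dy)
  db <- colSums(dy)
  dx <- NULL
  if (need_dx) {
    dXc <- tcrossprod(dy, cache$W)
    m_out <- nrow(dy)
    dxp <- matrix(0, cache$mp, cin)
    for (t in seq_len(k)) {
      idx <- t:(t + m_out - 1L)
      dxp[idx, ] <- dxp[idx, ] + dXc[, ((t - 1L) * cin + 1L):(t * cin), drop = FALSE]
    }
    if (cache$m > 0L) {
      dx <- dxp[(cache$pad_left + 1L):(cache$pad_left + cache$m), , drop = FALSE]
      if (!is.null(cache$mask)) dx[!cache$mask, ] <- 0
    } else {
      dx <- matrix(0, 0L, cin)
    }
  }
  list(dx = dx, dW = make_conv_weight(dW, k), db = db)
}

# Padding amounts for a width-k kernel. "same" keeps the output centred;
# "left"/"right" are the causal variants used by the context branches.
conv_pads <- function(k, mode) {
  switch(mode,
    same  = c((k - 1L) %/% 2L, (k - 1L) %/% 2L),
    left  = c(k - 1L, 0L),
    right = c(0L, k - 1L),
    stop("unknown padding mode: ", mode)
  )
}

# LayerNorm per residue (row) over channels, learned gain g / offset b.
layer_norm_forward <- function(x, g, b, eps = 1e-5, keep_cache = FALSE) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2L, g, "*")
  y <- sweep(y, 2L, b, "+")
  cache <- if (keep_cache) list(xhat = xhat, inv = inv, g = g) else NULL
  list(y = y, cache = cache)
}

layer_norm_backward <- function(dy, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2L, cache$g, "*")
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  h1 <- rowMeans(dxhat)
  h2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - h1 - xhat * h2)
  list(dx = dx, dg = dg, db = db)
}

#' Gated linear unit
#'
#' Splits the channels of `x` in half into `A` (first half) and gates `B`
#' (second half) and returns `A * sigmoid(B)`, halving the channel count.
#'
#' @param x Numeric matrix `m x 2c` (even channel count).
#' @return Numeric matrix `m x c`.
#' @export
#' @examples
#' glu(matrix(c(1, -2, 0, 0), nrow = 1))  # 0.5, -1
glu <- function(x) {
  glu_forward(x)$y
}

glu_forward <- function(x, keep_cache = FALSE) {
  ch <- ncol(x)
  if (ch %% 2L != 0L) stop("glu: channel count must be even, got ", ch)
  half <- ch %/% 2L
  A <- x[, seq_len(half), drop = FALSE]
  s <- stats::plogis(x[, half + seq_len(half), drop = FALSE])
  cache <- if (keep_cache) list(A = A, s = s) else NULL
  list(y = A * s, cache = cache)
}

glu_backward <- function(dy, cache) {
  dA <- dy * cache$s
  dB <- dy * cache$A * cache$s * (1 - cache$s)
  cbind(dA, dB)
}

# Inverted dropout; mask drawn from the session RNG so training is seedable.
dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  keep <- 1 - rate
  dm <- matrix((stats::runif(length(x)) < keep) / keep, nrow(x), ncol(x))
  list(y = x * dm, mask = dm)
}

softmax_rows <- function(z) {
  if (nrow(z) == 0L) return(z)
  mx <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - mx)
  e / rowSums(e)
}
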