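# Low-level differentiable layer primitives.
#
# Every layer has a forward returning list(y, cache) and a backward taking
# (dy, cache, params...) returning the input gradient plus parameter
# gradients. Activations operate on (length, channels) matrices; there is no
# batch dimension (training uses batch size 1, the protocol's setting, and
# larger batches accumulate gradients across examples).

add_bias <- function(y, b) y + rep(b, each = nrow(y))

# -- linear ------------------------------------------------------------------

linear_fwd <- function(x, W, b) {
  list(y = add_bias(x %*% W, b), x = x)
}

linear_bwd <- function(dy, cache, W) {
  list(dx = dy %*% t(W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

# -- 1-D convolution via im2col ---------------------------------------------
# 'same' zero padding, odd kernel. `iv` is the precomputed gather index into
# the padded input; columns of the unrolled matrix are ordered offset-fastest
# within input channel, and weight rows follow the same order.

conv_iv <- function(L, k) as.vector(outer(seq_len(L), 0:(k - 1L), "+"))

conv_fwd <- function(x, W, b, k, iv) {
  if (k == 1L) return(list(y = add_bias(x %*% W, b), Xc = x, k = 1L))
  L <- nrow(x); C <- ncol(x); pad <- (k - 1L) %/% 2L
  xp <- rbind(matrix(0, pad, C), x, matrix(0, pad, C))
  Xc <- xp[iv, , drop = FALSE]
  dim(Xc) <- c(L, k * C)
  list(y = add_bias(Xc %*% W, b), Xc = Xc, k = k)
}

conv_bwd <- function(dy, cache, W) {
  k <- cache$k
  dW <- crossprod(cache$Xc, dy)
  db <- colSums(dy)
  if (k == 1L) return(list(dx = dy %*% t(W), dW = dW, db = db))
  L <- nrow(dy)
  kC <- nrow(W)
  C <- kC %/% k
  pad <- (k - 1L) %/% 2L
  dXc <- dy %*% t(W)            # (L, k*C)
  dim(dXc) <- c(L * k, C)
  dxp <- matrix(0, L + 2L * pad, C)
  idx <- seq_len(L)
  for (o in 0:(k - 1L)) {
    dxp[idx + o, ] <- dxp[idx + o, ] + dXc[o * L + idx, , drop = FALSE]
  }
  list(dx = dxp[pad + idx, , drop = FALSE], dW = dW, db = db)
}

# -- layer normalization (over channels, per position) -----------------------

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = add_bias(xhat * rep(g, each = nrow(x)), b), xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxh <- dy * rep(g, each = nrow(dy))
  dx <- cache$inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
  list(dx = dx, dg = dg, db = db)
}

# -- activations -------------------------------------------------------------

gelu_fwd <- function(x) {
  px <- stats::pnorm(x)
  list(y = x * px, x = x, px = px)
}
gelu_bwd <- function(dy, cache) {
  x <- cache$x
  dy * (cache$px + x * stats::dnorm(x))
}

softplus_fwd <- function(x) {
  y <- ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  list(y = y, x = x)
}
softplus_bwd <- function(dy, cache) dy * stats::plogis(cache$x)

# -- pooling by 2 ------------------------------------------------------------
# Attention pooling: per-channel softmax over each pair of positions with a
# learned per-channel logit scale w; max pooling is the hard alternative.

pool_attn_fwd <- function(x, w) {
  L <- nrow(x)
  xa <- x[seq(1L, L, 2L), , drop = FALSE]
  xb <- x[seq(2L, L, 2L), , drop = FALSE]
  wl <- rep(w, each = L %/% 2L)
  pa <- stats::plogis((xa - xb) * wl)
  list(y = pa * xa + (1 - pa) * xb, xa = xa, xb = xb, pa = pa)
}

pool_attn_bwd <- function(dy, cache, w) {
  xa <- cache$xa; xb <- cache$xb; pa <- cache$pa
  wl <- rep(w, each = nrow(dy))
  dpa <- dy * (xa - xb)
  dd <- pa * (1 - pa) * dpa          # grad wrt logit difference la - lb
  dxa <- dy * pa + dd * wl
  dxb <- dy * (1 - pa) - dd * wl
  dw <- colSums(dd * (xa - xb))
  L <- 2L * nrow(dy)
  dx <- matrix(0, L, ncol(dy))
  dx[seq(1L, L, 2L), ] <- dxa
  dx[seq(2L, L, 2L), ] <- dxb
  list(dx = dx, dw = dw)
}

pool_max_fwd <- function(x) {
  L <- nrow(x)
  xa <- x[seq(1L, L, 2L), , drop = FALSE]
  xb <- x[seq(2L, L, 2L), , drop = FALSE]
  sel <- xa >= xb
  list(y = ifelse(sel, xa, xb), sel = sel)
}

pool_max_bwd <- function(dy, cache) {
  L <- 2L * nrow(dy)
  dx <- matrix(0, L, ncol(dy))
  dx[seq(1L, L, 2L), ] <- dy * cache$sel
  dx[seq(2L, L, 2L), ] <- dy * (1 - cache$sel)
  dx
}

# -- dropout -----------------------------------------------------------------

dropout_fwd <- function(x, rate) {
  if (rate <= 0) return(list(y = x, mask = NULL))
  mask <- matrix((stats::runif(length(x)) >= rate) / (1 - rate), nrow(x), ncol(x))
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

# -- multi-head self-attention ----------------------------------------------
# Relative-position bias is added to the attention logits; `dvec` indexes
# each (i, j) cell by |i - j| + 1 so one learned value (or basis expansion)
# per distance is shared across the map.

attn_bias_matrix <- function(pos, scheme, dvec, Fb, L) {
  if (scheme == "none") return(NULL)
  per_dist <- if (scheme == "learned_relative") pos else Fb %*% pos  # (Ld, H)
  lapply(seq_len(ncol(per_dist)), function(h) matrix(per_dist[dvec, h], L, L))
}

mha_fwd <- function(a, P, nm, cfg, st) {
  H <- cfg$num_heads; d <- cfg$head_dim; L <- nrow(a)
  Q <- add_bias(a %*% P[[nm("Wq")]], P[[nm("bq")]])
  K <- add_bias(a %*% P[[nm("Wk")]], P[[nm("bk")]])
  V <- add_bias(a %*% P[[nm("Wv")]], P[[nm("bv")]])
  Bh <- if (cfg$positional_scheme == "none") NULL else
    attn_bias_matrix(P[[nm("pos")]], cfg$positional_scheme, st$dvec, st$Fb, L)
  O <- matrix(0, L, H * d)
  heads <- vector("list", H)
  sc <- 1 / sqrt(d)
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * d + 1L):(h * d)
    Qh <- Q[, cols, drop = FALSE]; Kh <- K[, cols, drop = FALSE]; Vh <- V[, cols, drop = FALSE]
    S <- tcrossprod(Qh, Kh) * sc
    if (!is.null(Bh)) S <- S + Bh[[h]]
    S <- S - apply(S, 1L, max)
    A <- exp(S)
    A <- A / rowSums(A)
    O[, cols] <- A %*% Vh
    heads[[h]] <- list(A = A, Qh = Qh, Kh = Kh, Vh = Vh)
  }
  list(O = O, heads = heads, a = a)
}

mha_bwd <- function(dO, cache, P, nm, cfg, st) {
  H <- cfg$num_heads; d <- cfg$head_dim; L <- nrow(dO)
  sc <- 1 / sqrt(d)
  dQ <- matrix(0, L, H * d); dK <- dQ; dV <- dQ
  dpos <- NULL
  if (cfg$positional_scheme != "none") dpos <- array(0, dim(P[[nm("pos")]]))
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * d + 1L):(h * d)
    hc <- cache$heads[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, hc$Vh)              # dOh %*% t(Vh)
    dV[, cols] <- crossprod(hc$A, dOh)
    dS <- hc$A * (dA - rowSums(hc$A * dA))
    dQ[, cols] <- dS %*% hc$Kh * sc
    dK[, cols] <- crossprod(dS, hc$Qh) * sc
    if (!is.null(dpos)) {
      dbd <- rowsum(as.vector(dS), st$dvec)   # gradient per distance, sorted
      if (cfg$positional_scheme == "learned_relative") dpos[, h] <- dbd
      else dpos[, h] <- crossprod(st$Fb, dbd)
    }
  }
  a <- cache$a
  grads <- list()
  grads[[nm("Wq")]] <- crossprod(a, dQ); grads[[nm("bq")]] <- colSums(dQ)
  grads[[nm("Wk")]] <- crossprod(a, dK); grads[[nm("bk")]] <- colSums(dK)
  grads[[nm("Wv")]] <- crossprod(a, dV); grads[[nm("bv")]] <- colSums(dV)
  if (!is.null(dpos)) grads[[nm("pos")]] <- dpos
  da <- dQ %*% t(P[[nm("Wq")]]) + dK %*% t(P[[nm("Wk")]]) + dV %*% t(P[[nm("Wv")]])
  list(da = da, grads = grads)
}
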