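# Neural-network primitives for the 3D segmentation backend: dense,
# layer/instance normalization, GELU, windowed multi-head
# self-attention, patch grouping, 3x3x3 convolution via shifted
# matrix products. Each primitive has a forward returning (out, cache)
# and a backward consuming (cache, dout) and accumulating parameter
# gradients into an environment. Feature maps are (n_voxels x channels)
# matrices in array (first-axis-fastest) order over their 3D grid.

nn_init_param <- function(P, name, value) {
  P[[name]] <- value
  invisible(NULL)
}

nn_grad_add <- function(G, name, value) {
  cur <- G[[name]]
  G[[name]] <- if (is.null(cur)) value else cur + value
  invisible(NULL)
}

trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, sd = sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

# ---- dense -----------------------------------------------------------

linear_init <- function(P, name, nin, nout, sd = 0.02) {
  nn_init_param(P, paste0(name, ".W"),
                matrix(trunc_normal(nin * nout, sd), nin, nout))
  nn_init_param(P, paste0(name, ".b"), numeric(nout))
}

linear_fwd <- function(P, name, X) {
  out <- X %*% P[[paste0(name, ".W")]]
  out <- sweep(out, 2, P[[paste0(name, ".b")]], `+`)
  list(out = out, cache = X)
}

linear_bwd <- function(P, G, name, cache, dout) {
  nn_grad_add(G, paste0(name, ".W"), crossprod(cache, dout))
  nn_grad_add(G, paste0(name, ".b"), colSums(dout))
  dout %*% t(P[[paste0(name, ".W")]])
}

# ---- layer norm (per row over channels) ------------------------------

layernorm_init <- function(P, name, C) {
  nn_init_param(P, paste0(name, ".g"), rep(1, C))
  nn_init_param(P, paste0(name, ".b"), numeric(C))
}

layernorm_fwd <- function(P, name, X, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(xhat %*% diag(P[[paste0(name, ".g")]]), 2,
               P[[paste0(name, ".b")]], `+`)
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

layernorm_bwd <- function(P, G, name, cache, dout) {
  g <- P[[paste0(name, ".g")]]
  xhat <- cache$xhat
  inv <- cache$inv
  nn_grad_add(G, paste0(name, ".g"), colSums(dout * xhat))
  nn_grad_add(G, paste0(name, ".b"), colSums(dout))
  dxh <- sweep(dout, 2, g, `*`)
  (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) * inv
}

# ---- instance norm (per channel over all voxels) ---------------------

instnorm_init <- function(P, name, C) {
  nn_init_param(P, paste0(name, ".g"), rep(1, C))
  nn_init_param(P, paste0(name, ".b"), numeric(C))
}

instnorm_fwd <- function(P, name, X, eps = 1e-5) {
  mu <- colMeans(X)
  xc <- sweep(X, 2, mu)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  out <- sweep(sweep(xhat, 2, P[[paste0(name, ".g")]], `*`), 2,
               P[[paste0(name, ".b")]], `+`)
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

instnorm_bwd <- function(P, G, name, cache, dout) {
  g <- P[[paste0(name, ".g")]]
  xhat <- cache$xhat
  inv <- cache$inv
  nn_grad_add(G, paste0(name, ".g"), colSums(dout * xhat))
  nn_grad_add(G, paste0(name, ".b"), colSums(dout))
  dxh <- sweep(dout, 2, g, `*`)
  t1 <- sweep(dxh, 2, colMeans(dxh))
  t2 <- sweep(xhat, 2, colMeans(dxh * xhat), `*`)
  sweep(t1 - t2, 2, inv, `*`)
}

# ---- activations -----------------------------------------------------

gelu_fwd <- function(X) {
  ph <- stats::pnorm(X)
  list(out = X * ph, cache = list(X = X, ph = ph))
}

gelu_bwd <- function(cache, dout) {
  dout * (cache$ph + cache$X * stats::dnorm(cache$X))
}

relu_fwd <- function(X) list(out = pmax(X, 0), cache = X > 0)

relu_bwd <- function(cache, dout) dout * cache

softmax_rows <- function(X) {
  m <- apply(X, 1, max)
  e <- exp(X - m)
  e / rowSums(e)
}

# ---- index helpers on 3D grids ---------------------------------------

# Linear (1-based, first-axis-fastest) indices of the members of each
# p-cube group on a grid with dims divisible by p. Rows: groups in array
# order of the coarse grid; columns: p^3 members (first axis fastest).
make_group_index <- function(dims, p = 2L) {
  gd <- dims %/% p
  n <- prod(gd)
  gi <- arrayInd(seq_len(n), gd) - 1L          # coarse coords, 0-based
  off <- arrayInd(seq_len(p^3), c(p, p, p)) - 1L
  idx <- matrix(0L, n, p^3)
  for (m in seq_len(p^3)) {
    fine <- sweep(gi * p, 2, off[m, ], `+`)    # fine coords, 0-based
    idx[, m] <- 1L + fine[, 1] + dims[1] * (fine[, 2] + dims[2] * fine[, 3])
  }
  idx
}

# Gather p-cube groups of channel vectors into one wide matrix
# (n_groups x p^3*C); inverse scatter for the backward pass.
group_gather <- function(X, gidx) {
  C <- ncol(X)
  p3 <- ncol(gidx)
  out <- matrix(0, nrow(gidx), p3 * C)
  for (m in seq_len(p3)) {
    out[, ((m - 1) * C + 1):(m * C)] <- X[gidx[, m], , drop = FALSE]
  }
  out
}

group_scatter <- function(dwide, gidx, n, C) {
  dX <- matrix(0, n, C)
  p3 <- ncol(gidx)
  for (m in seq_len(p3)) {
    dX[gidx[, m], ] <- dX[gidx[, m], , drop = FALSE] +
      dwide[, ((m - 1) * C + 1):(m * C), drop = FALSE]
  }
  dX
}

# Window partition permutation with optional cyclic shift: perm orders
# tokens window-by-window; tokens_per_window is constant because window
# dims divide the token grid.
make_window_index <- function(tg, wdims, shift = c(0L, 0L, 0L)) {
  n <- prod(tg)
  co <- arrayInd(seq_len(n), tg) - 1L
  sh <- sweep(co, 2, shift, `+`)
  sh <- sweep(sh, 2, tg, `%%`)
  wid <- sh %/% matrix(wdims, n, 3, byrow = TRUE)
  woff <- sh %% matrix(wdims, n, 3, byrow = TRUE)
  nwin <- tg %/% wdims
  wlin <- wid[, 1] + nwin[1] * (wid[, 2] + nwin[2] * wid[, 3])
  olin <- woff[, 1] + wdims[1] * (woff[, 2] + wdims[2] * woff[, 3])
  perm <- order(wlin, olin)
  list(perm = perm, inv = order(perm), m = prod(wdims),
       n_windows = prod(nwin))
}

# Largest divisor of n that is <= w (window fitting).
fit_window_axis <- function(n, w) {
  for (d in seq(min(w, n), 1L)) if (n %% d == 0L) return(d)
  1L
}

# Shift index pairs for 3x3x3 convolution: for each of the 27 offsets,
# the destination and source voxel indices that stay on the grid.
make_shift_index <- function(tg) {
  n <- prod(tg)
  co <- arrayInd(seq_len(n), tg)                # 1-based coords
  off <- arrayInd(seq_len(27), c(3, 3, 3)) - 2L # -1..1 offsets
  lapply(seq_len(27), function(o) {
    src <- sweep(co, 2, off[o, ], `+`)
    ok <- src[, 1] >= 1 & src[, 1] <= tg[1] &
      src[, 2] >= 1 & src[, 2] <= tg[2] &
      src[, 3] >= 1 & src[, 3] <= tg[3]
    list(dst = which(ok),
         src = src[ok, 1] + tg[1] * (src[ok, 2] - 1L) +
           tg[1] * tg[2] * (src[ok, 3] - 1L))
  })
}

# ---- 3x3x3 convolution ----------------------------------------------

conv3_init <- function(P, name, Cin, Cout) {
  sd <- sqrt(2 / (27 * Cin))
  W <- array(stats::rnorm(27 * Cin * Cout, sd = sd), c(27, Cin, Cout))
  nn_init_param(P, paste0(name, ".W"), W)
  nn_init_param(P, paste0(name, ".b"), numeric(Cout))
}

conv3_fwd <- function(P, name, X, shifts) {
  W <- P[[paste0(name, ".W")]]
  Cout <- dim(W)[3]
  out <- matrix(0, nrow(X), Cout)
  for (o in seq_len(27)) {
    s <- shifts[[o]]
    Wo <- array(W[o, , ], dim(W)[2:3])
    out[s$dst, ] <- out[s$dst, , drop = FALSE] +
      X[s$src, , drop = FALSE] %*% Wo
  }
  out <- sweep(out, 2, P[[paste0(name, ".b")]], `+`)
  list(out = out, cache = X)
}

conv3_bwd <- function(P, G, name, cache, dout, shifts) {
  W <- P[[paste0(name, ".W")]]
  X <- cache
  dW <- array(0, dim(W))
  dX <- matrix(0, nrow(X), ncol(X))
  for (o in seq_len(27)) {
    s <- shifts[[o]]
    xs <- X[s$src, , drop = FALSE]
    dy <- dout[s$dst, , drop = FALSE]
    dW[o, , ] <- crossprod(xs, dy)
    Wo <- array(W[o, , ], dim(W)[2:3])
    dX[s$src, ] <- dX[s$src, , drop = FALSE] + dy %*% t(Wo)
  }
  nn_grad_add(G, paste0(name, ".W"), dW)
  nn_grad_add(G, paste0(name, ".b"), colSums(dout))
  dX
}

# ---- windowed multi-head self-attention ------------------------------

attention_init <- function(P, name, C) {
  linear_init(P, paste0(name, ".qkv"), C, 3 * C)
  linear_init(P, paste0(name, ".proj"), C, C)
}

# X must already be permuted into window order (win$perm applied).
attention_fwd <- function(P, name, X, win, n_heads) {
  C <- ncol(X)
  dh <- C %/% n_heads
  qkv <- linear_fwd(P, paste0(name, ".qkv"), X)
  M <- win$m
  nW <- win$n_windows
  out <- matrix(0, nrow(X), C)
  heads <- vector("list", nW * n_heads)
  scale <- 1 / sqrt(dh)
  hidx <- 0L
  for (w in seq_len(nW)) {
    rows <- ((w - 1) * M + 1):(w * M)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      Q <- qkv$out[rows, cols, drop = FALSE]
      K <- qkv$out[rows, C + cols, drop = FALSE]
      V <- qkv$out[rows, 2 * C + cols, drop = FALSE]
      A <- softmax_rows(tcrossprod(Q, K) * scale)
      out[rows, cols] <- A %*% V
      hidx <- hidx + 1L
      heads[[hidx]] <- list(rows = rows, cols = cols, Q = Q, K = K,
                            V = V, A = A)
    }
  }
  proj <- linear_fwd(P, paste0(name, ".proj"), out)
  list(out = proj$out,
       cache = list(qkv_cache = qkv$cache, proj_cache = proj$cache,
                    heads = heads, C = C, dh = dh, scale = scale))
}

attention_bwd <- function(P, G, name, cache, dout) {
  C <- cache$C
  dattn <- linear_bwd(P, G, paste0(name, ".proj"), cache$proj_cache, dout)
  dqkv <- matrix(0, nrow(dout), 3 * C)
  for (hd in cache$heads) {
    dO <- dattn[hd$rows, hd$cols, drop = FALSE]
    dA <- tcrossprod(dO, hd$V)
    dV <- crossprod(hd$A, dO)
    # softmax backward per row
    dS <- hd$A * (dA - rowSums(dA * hd$A))
    dQ <- dS %*% hd$K * cache$scale
    dK <- crossprod(dS, hd$Q) * cache$scale
    dqkv[hd$rows, hd$cols] <- dqkv[hd$rows, hd$cols, drop = FALSE] + dQ
    dqkv[hd$rows, C + hd$cols] <- dqkv[hd$rows, C + hd$cols, drop = FALSE] + dK
    dqkv[hd$rows, 2 * C + hd$cols] <-
      dqkv[hd$rows, 2 * C + hd$cols, drop = FALSE] + dV
  }
  linear_bwd(P, G, paste0(name, ".qkv"), cache$qkv_cache, dqkv)
}

# ---- composite blocks ------------------------------------------------

# Swin transformer block: LN -> (S)W-MSA -> residual, LN -> MLP ->
# residual. `win` carries the (possibly shifted) window permutation.
swin_block_init <- function(P, name, C, mlp_ratio = 4) {
  layernorm_init(P, paste0(name, ".ln1"), C)
  attention_init(P, paste0(name, ".attn"), C)
  layernorm_init(P, paste0(name, ".ln2"), C)
  linear_init(P, paste0(name, ".mlp1"), C, mlp_ratio * C)
  linear_init(P, paste0(name, ".mlp2"), mlp_ratio * C, C)
}

swin_block_fwd <- function(P, name, X, win, n_heads) {
  ln1 <- layernorm_fwd(P, paste0(name, ".ln1"), X)
  xp <- ln1$out[win$perm, , drop = FALSE]
  att <- attention_fwd(P, paste0(name, ".attn"), xp, win, n_heads)
  x1 <- X + att$out[win$inv, , drop = FALSE]
  ln2 <- layernorm_fwd(P, paste0(name, ".ln2"), x1)
  m1 <- linear_fwd(P, paste0(name, ".mlp1"), ln2$out)
  ge <- gelu_fwd(m1$out)
  m2 <- linear_fwd(P, paste0(name, ".mlp2"), ge$out)
  list(out = x1 + m2$out,
       cache = list(ln1 = ln1$cache, att = att$cache, ln2 = ln2$cache,
                    m1 = m1$cache, ge = ge$cache, m2 = m2$cache, win = win))
}

swin_block_bwd <- function(P, G, name, cache, dout) {
  win <- cache$win
  dm2 <- linear_bwd(P, G, paste0(name, ".mlp2"), cache$m2, dout)
  dge <- gelu_bwd(cache$ge, dm2)
  dm1 <- linear_bwd(P, G, paste0(name, ".mlp1"), cache$m1, dge)
  dx1 <- dout + layernorm_bwd(P, G, paste0(name, ".ln2"), cache$ln2, dm1)
  datt <- attention_bwd(P, G, paste0(name, ".attn"), cache$att,
                        dx1[win$perm, , drop = FALSE])
  dx1 + layernorm_bwd(P, G, paste0(name, ".ln1"), cache$ln1,
                      datt[win$inv, , drop = FALSE])
}

# Residual convolution block with instance norm (decoder unit).
conv_block_init <- function(P, name, Cin, Cout) {
  conv3_init(P, paste0(name, ".c1"), Cin, Cout)
  instnorm_init(P, paste0(name, ".n1"), Cout)
  conv3_init(P, paste0(name, ".c2"), Cout, Cout)
  instnorm_init(P, paste0(name, ".n2"), Cout)
  if (Cin != Cout) linear_init(P, paste0(name, ".skip"), Cin, Cout)
}

conv_block_fwd <- function(P, name, X, shifts) {
  c1 <- conv3_fwd(P, paste0(name, ".c1"), X, shifts)
  n1 <- instnorm_fwd(P, paste0(name, ".n1"), c1$out)
  r1 <- relu_fwd(n1$out)
  c2 <- conv3_fwd(P, paste0(name, ".c2"), r1$out, shifts)
  n2 <- instnorm_fwd(P, paste0(name, ".n2"), c2$out)
  has_skip <- !is.null(P[[paste0(name, ".skip.W")]])
  sk <- if (has_skip) linear_fwd(P, paste0(name, ".skip"), X) else
    list(out = X, cache = NULL)
  r2 <- relu_fwd(n2$out + sk$out)
  list(out = r2$out,
       cache = list(c1 = c1$cache, n1 = n1$cache, r1 = r1$cache,
                    c2 = c2$cache, n2 = n2$cache, sk = sk$cache,
                    r2 = r2$cache, has_skip = has_skip))
}

conv_block_bwd <- function(P, G, name, cache, dout, shifts) {
  dsum <- relu_bwd(cache$r2, dout)
  dskip <- if (cache$has_skip) {
    linear_bwd(P, G, paste0(name, ".skip"), cache$sk, dsum)
  } else {
    dsum
  }
  dn2 <- instnorm_bwd(P, G, paste0(name, ".n2"), cache$n2, dsum)
  dc2 <- conv3_bwd(P, G, paste0(name, ".c2"), cache$c2, dn2, shifts)
  dr1 <- relu_bwd(cache$r1, dc2)
  dn1 <- instnorm_bwd(P, G, paste0(name, ".n1"), cache$n1, dr1)
  dc1 <- conv3_bwd(P, G, paste0(name, ".c1"), cache$c1, dn1, shifts)
  dc1 + dskip
}
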