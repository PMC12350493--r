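# Internal neural-network primitives for the encoder-decoder.
# Tensors are R arrays with dim (H, W, C, B); convolutions run in compiled
# code (src/conv.cpp), pooling/upsampling use column-major reshape tricks.

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

relu_bwd <- function(x, dy) {
  dy * (x > 0)
}

# 2x2 max pooling, stride 2. Returns pooled output plus the routing masks
# needed for backprop (ties routed to the first position in scan order).
maxpool_fwd <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  xr <- x
  dim(xr) <- c(2L, h2, 2L, w2, d[3], d[4])
  a11 <- xr[1, , 1, , , , drop = FALSE]
  a21 <- xr[2, , 1, , , , drop = FALSE]
  a12 <- xr[1, , 2, , , , drop = FALSE]
  a22 <- xr[2, , 2, , , , drop = FALSE]
  y <- pmax(a11, a21, a12, a22)
  m11 <- (a11 == y)
  m21 <- (a21 == y) & !m11
  m12 <- (a12 == y) & !(m11 | m21)
  m22 <- !(m11 | m21 | m12)
  dim(y) <- c(h2, w2, d[3], d[4])
  list(y = y, masks = list(m11, m21, m12, m22), in_dim = d)
}

maxpool_bwd <- function(pool, dy) {
  d <- pool$in_dim
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  dyr <- dy
  dim(dyr) <- c(1L, h2, 1L, w2, d[3], d[4])
  dx <- array(0, c(2L, h2, 2L, w2, d[3], d[4]))
  m <- pool$masks
  dx[1, , 1, , , ] <- dyr * m[[1]]
  dx[2, , 1, , , ] <- dyr * m[[2]]
  dx[1, , 2, , , ] <- dyr * m[[3]]
  dx[2, , 2, , , ] <- dyr * m[[4]]
  dim(dx) <- d
  dx
}

# Nearest-neighbour 2x upsampling.
upsample_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

upsample_bwd <- function(dy) {
  d <- dim(dy)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  dyr <- dy
  dim(dyr) <- c(2L, h2, 2L, w2, d[3], d[4])
  dx <- dyr[1, , 1, , , , drop = FALSE] + dyr[2, , 1, , , , drop = FALSE] +
    dyr[1, , 2, , , , drop = FALSE] + dyr[2, , 2, , , , drop = FALSE]
  dim(dx) <- c(h2, w2, d[3], d[4])
  dx
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

split_channels <- function(dy, c1) {
  d <- dim(dy)
  list(dy[, , seq_len(c1), , drop = FALSE],
       dy[, , (c1 + 1L):d[3], , drop = FALSE])
}

# 1x1 convolution (channel mixing) done as a plain matrix product.
conv1x1_fwd <- function(x, w, b) {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  ym <- xm %*% w
  ym <- sweep(ym, 2L, b, "+")
  dim(ym) <- c(d[1], d[2], d[4], ncol(w))
  aperm(ym, c(1, 2, 4, 3))
}

conv1x1_bwd <- function(x, w, dy) {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  dym <- aperm(dy, c(1, 2, 4, 3))
  dim(dym) <- c(d[1] * d[2] * d[4], ncol(w))
  dw <- crossprod(xm, dym)
  db <- colSums(dym)
  dxm <- dym %*% t(w)
  dim(dxm) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dxm, c(1, 2, 4, 3)), dw = dw, db = db)
}

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

# A double 3x3 conv + ReLU block.
block_init <- function(cin, cout) {
  list(w1 = he_init(3L, cin, cout), b1 = numeric(cout),
       w2 = he_init(3L, cout, cout), b2 = numeric(cout))
}

block_fwd <- function(p, x) {
  z1 <- conv2d_fwd(x, p$w1, p$b1)
  a1 <- relu_fwd(z1)
  z2 <- conv2d_fwd(a1, p$w2, p$b2)
  a2 <- relu_fwd(z2)
  list(x = x, z1 = z1, a1 = a1, z2 = z2, a2 = a2)
}

block_bwd <- function(p, cache, da2) {
  dz2 <- relu_bwd(cache$z2, da2)
  g2 <- conv2d_bwd(cache$a1, p$w2, dz2)
  dz1 <- relu_bwd(cache$z1, g2$dx)
  g1 <- conv2d_bwd(cache$x, p$w1, dz1)
  list(dx = g1$dx,
       grads = list(w1 = g1$dw, b1 = g1$db, w2 = g2$dw, b2 = g2$db))
}

#' @keywords internal
unet_init <- function(config) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  depth <- config$encoder_depth
  base <- config$base_channels
  ch <- base * 2^(seq_len(depth) - 1L)
  enc <- vector("list", depth)
  cin <- 1L
  for (d in seq_len(depth)) {
    enc[[d]] <- block_init(cin, ch[d])
    cin <- ch[d]
  }
  bott <- block_init(cin, base * 2^depth)
  dec <- vector("list", depth)
  up_in <- base * 2^depth
  for (d in rev(seq_len(depth))) {
    dec[[d]] <- block_init(up_in + ch[d], ch[d])
    up_in <- ch[d]
  }
  head_w <- matrix(stats::rnorm(base * config$n_classes,
                                sd = sqrt(2 / base)),
                   nrow = base, ncol = config$n_classes)
  list(enc = enc, bott = bott, dec = dec,
       head_w = head_w, head_b = numeric(config$n_classes),
       depth = depth)
}

unet_fwd <- function(params, x, keep_cache = TRUE) {
  depth <- params$depth
  caches <- list(enc = vector("list", depth), pools = vector("list", depth),
                 dec = vector("list", depth), cats = vector("list", depth))
  h <- x
  for (d in seq_len(depth)) {
    bc <- block_fwd(params$enc[[d]], h)
    caches$enc[[d]] <- bc
    pl <- maxpool_fwd(bc$a2)
    caches$pools[[d]] <- pl
    h <- pl$y
  }
  bottc <- block_fwd(params$bott, h)
  caches$bott <- bottc
  h <- bottc$a2
  for (d in rev(seq_len(depth))) {
    up <- upsample_fwd(h)
    cat_ <- concat_channels(up, caches$enc[[d]]$a2)
    caches$cats[[d]] <- dim(up)[3]
    dc <- block_fwd(params$dec[[d]], cat_)
    caches$dec[[d]] <- dc
    h <- dc$a2
  }
  logits <- conv1x1_fwd(h, params$head_w, params$head_b)
  caches$pre_head <- h
  if (keep_cache) list(logits = logits, cache = caches) else
    list(logits = logits)
}

unet_bwd <- function(params, cache, dlogits) {
  depth <- params$depth
  grads <- list(enc = vector("list", depth), dec = vector("list", depth))
  gh <- conv1x1_bwd(cache$pre_head, params$head_w, dlogits)
  grads$head_w <- gh$dw
  grads$head_b <- gh$db
  dh <- gh$dx
  denc_extra <- vector("list", depth)  # gradient into enc skips
  for (d in seq_len(depth)) {
    bb <- block_bwd(params$dec[[d]], cache$dec[[d]], dh)
    grads$dec[[d]] <- bb$grads
    sp <- split_channels(bb$dx, cache$cats[[d]])
    denc_extra[[d]] <- sp[[2]]
    dh <- upsample_bwd(sp[[1]])
  }
  bb <- block_bwd(params$bott, cache$bott, dh)
  grads$bott <- bb$grads
  dh <- bb$dx
  for (d in rev(seq_len(depth))) {
    dpool <- maxpool_bwd(cache$pools[[d]], dh)
    da2 <- dpool + denc_extra[[d]]
    bb <- block_bwd(params$enc[[d]], cache$enc[[d]], da2)
    grads$enc[[d]] <- bb$grads
    dh <- bb$dx
  }
  grads
}

# Adam optimizer operating recursively on the nested parameter lists.
# The gradient list drives the recursion, so non-trainable entries of the
# parameter list (e.g. `depth`) are left untouched.
nested_zero <- function(g) {
  if (is.list(g)) lapply(g, nested_zero) else g * 0
}

adam_init <- function(grads_template) {
  list(m = nested_zero(grads_template), v = nested_zero(grads_template),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v) {
    if (is.list(g)) {
      idx <- if (is.null(names(g))) seq_along(g) else names(g)
      for (nm in idx) {
        r <- rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  r <- rec(params, grads, state$m, state$v)
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}
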