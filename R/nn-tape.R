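## Lightweight reverse-mode automatic differentiation on base-R arrays.
##
## A tape records every operation of a forward pass; ad_backward() walks it
## in reverse, accumulating gradients into node$grad. Node values are plain
## numeric arrays/matrices; images are stored channel-last as (H, W, C).
## The engine is deliberately small: only the operations the package's
## networks need are implemented, several of them as fused nodes with
## hand-written backward rules (layer norm, group norm, softmax, conv).

.ad <- new.env(parent = emptyenv())
.ad$geom <- new.env(parent = emptyenv())   # conv/upsample geometry cache

ad_tape_start <- function() {
  .ad$nodes <- vector("list", 512L)
  .ad$n <- 0L
  invisible(NULL)
}

.ad_node <- function(value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  n <- .ad$n + 1L
  if (n > length(.ad$nodes))
    .ad$nodes <- c(.ad$nodes, vector("list", length(.ad$nodes)))
  .ad$nodes[[n]] <- nd
  .ad$n <- n
  nd
}

ad_leaf <- function(value) .ad_node(value)

ad_value <- function(nd) nd$value

ad_grad <- function(nd) if (is.null(nd$grad)) nd$value * 0 else nd$grad

# Backpropagate from a scalar loss node through the current tape.
ad_backward <- function(loss) {
  loss$grad <- 1
  for (i in seq(.ad$n, 1L)) {
    nd <- .ad$nodes[[i]]
    if (is.null(nd) || is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (is.null(gs[[j]])) next
      pj <- nd$parents[[j]]
      pj$grad <- if (is.null(pj$grad)) gs[[j]] else pj$grad + gs[[j]]
    }
  }
  invisible(NULL)
}

## ---- elementwise and linear-algebra ops ----

ad_add <- function(a, b) .ad_node(a$value + b$value, list(a, b),
                                  function(g) list(g, g))

ad_sub <- function(a, b) .ad_node(a$value - b$value, list(a, b),
                                  function(g) list(g, -g))

ad_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  .ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# multiply by a plain numeric constant
ad_scale <- function(a, s) .ad_node(a$value * s, list(a),
                                    function(g) list(g * s))

ad_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  .ad_node(av %*% bv, list(a, b),
           function(g) list(g %*% t(bv), crossprod(av, g)))
}

# A %*% t(B)
ad_matmul_t <- function(a, b) {
  av <- a$value; bv <- b$value
  .ad_node(tcrossprod(av, bv), list(a, b),
           function(g) list(g %*% bv, crossprod(g, av)))
}

# matrix (N x D) + row-broadcast bias (length D)
ad_bias_rows <- function(x, b) {
  .ad_node(x$value + rep(b$value, each = nrow(x$value)), list(x, b),
           function(g) list(g, colSums(g)))
}

# array (H, W, C) + channel bias (length C)
ad_bias_chan <- function(x, b) {
  d <- dim(x$value)
  .ad_node(x$value + rep(b$value, each = d[1] * d[2]), list(x, b),
           function(g) list(g, colSums(matrix(g, d[1] * d[2], d[3]))))
}

ad_relu <- function(x) {
  m <- x$value > 0
  .ad_node(x$value * m, list(x), function(g) list(g * m))
}

ad_silu <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  v <- x$value * s
  .ad_node(v, list(x), function(g) list(g * (s + v * (1 - s))))
}

ad_tanh <- function(x) {
  y <- tanh(x$value)
  .ad_node(y, list(x), function(g) list(g * (1 - y^2)))
}

ad_reshape <- function(x, dims) {
  od <- dim(x$value)
  v <- x$value
  dim(v) <- dims
  .ad_node(v, list(x), function(g) { dim(g) <- od; list(g) })
}

# concatenate arrays along the channel (last) axis
ad_concat_c <- function(...) {
  xs <- list(...)
  ds <- lapply(xs, function(x) dim(x$value))
  ch <- vapply(ds, function(d) d[3], numeric(1))
  v <- array(0, c(ds[[1]][1], ds[[1]][2], sum(ch)))
  at <- 0L
  for (x in xs) {
    v[, , at + seq_len(dim(x$value)[3])] <- x$value
    at <- at + dim(x$value)[3]
  }
  .ad_node(v, xs, function(g) {
    out <- vector("list", length(xs)); at <- 0L
    for (j in seq_along(xs)) {
      nc <- ch[j]
      out[[j]] <- g[, , at + seq_len(nc), drop = FALSE]
      at <- at + nc
    }
    out
  })
}

# concatenate matrices column-wise
ad_concat_cols <- function(...) {
  xs <- list(...)
  nc <- vapply(xs, function(x) ncol(x$value), numeric(1))
  v <- do.call(cbind, lapply(xs, ad_value))
  .ad_node(v, xs, function(g) {
    out <- vector("list", length(xs)); at <- 0L
    for (j in seq_along(xs)) {
      out[[j]] <- g[, at + seq_len(nc[j]), drop = FALSE]
      at <- at + nc[j]
    }
    out
  })
}

## ---- normalization and softmax (fused) ----

ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  mu <- rowMeans(xv)
  xc <- xv - mu
  s <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / s
  gv <- gamma$value
  v <- xhat * rep(gv, each = nrow(xv)) + rep(beta$value, each = nrow(xv))
  .ad_node(v, list(x, gamma, beta), function(g) {
    dxhat <- g * rep(gv, each = nrow(xv))
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / s
    list(dx, colSums(g * xhat), colSums(g))
  })
}

# group norm over (H, W, C) with C %% groups == 0
ad_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x$value)
  stopifnot(d[3] %% groups == 0L, length(gamma$value) == d[3])
  cg <- d[3] %/% groups
  xm <- matrix(x$value, d[1] * d[2] * cg, groups)   # columns are groups
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = nrow(xm))
  s <- sqrt(colMeans(xc^2) + eps)
  xhat <- xc / rep(s, each = nrow(xm))
  xhat_a <- array(xhat, d)
  gv <- rep(gamma$value, each = d[1] * d[2])
  v <- array(xhat, d) * array(gv, d) + array(rep(beta$value, each = d[1] * d[2]), d)
  .ad_node(v, list(x, gamma, beta), function(g) {
    dxhat <- matrix(g * array(gv, d), nrow(xm), groups)
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- (dxhat - rep(m1, each = nrow(xm)) - xhat * rep(m2, each = nrow(xm))) /
      rep(s, each = nrow(xm))
    gx <- matrix(g * xhat_a, d[1] * d[2], d[3])
    list(array(dx, d), colSums(gx), colSums(matrix(g, d[1] * d[2], d[3])))
  })
}

ad_softmax_rows <- function(x) {
  o <- x$value - apply(x$value, 1, max)
  e <- exp(o)
  y <- e / rowSums(e)
  .ad_node(y, list(x), function(g) list((g - rowSums(g * y)) * y))
}

## ---- losses ----

ad_mse <- function(x, target) {
  r <- x$value - target
  n <- length(r)
  .ad_node(mean(r^2), list(x), function(g) list(g * 2 * r / n))
}

# mean over rows of KL(p || softmax(o)); p is a constant row-stochastic matrix
ad_kl_softmax <- function(logits, p) {
  o <- logits$value - apply(logits$value, 1, max)
  lse <- log(rowSums(exp(o)))
  q <- exp(o - lse)
  n <- nrow(o)
  pe <- pmax(p, 1e-12)
  val <- mean(rowSums(p * (log(pe) - (o - lse))))
  .ad_node(val, list(logits), function(g) list(g * (q - p) / n))
}

ad_add_scalar <- function(a, b) .ad_node(a$value + b$value, list(a, b),
                                         function(g) list(g, g))

## ---- convolution ----

# Geometry (im2col index + scatter matrix) cached per configuration.
.conv_geom <- function(H, W, Cin, k, stride, pad, dil = 1L) {
  key <- paste("c", H, W, Cin, k, stride, pad, dil, sep = "_")
  g <- .ad$geom[[key]]
  if (!is.null(g)) return(g)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  span <- dil * (k - 1L) + 1L
  Ho <- (Hp - span) %/% stride + 1L
  Wo <- (Wp - span) %/% stride + 1L
  off <- expand.grid(dh = (0:(k - 1L)) * dil, dw = (0:(k - 1L)) * dil,
                     c = seq_len(Cin))
  bh <- (seq_len(Ho) - 1L) * stride + 1L
  bw <- (seq_len(Wo) - 1L) * stride + 1L
  outp <- expand.grid(h = bh, w = bw)
  # idx[r, c]: linear index into padded array for kernel-row r, out-pixel c
  hh <- outer(off$dh, outp$h, `+`)
  ww <- outer(off$dw, outp$w, `+`)
  idx <- hh + (ww - 1L) * Hp + (off$c - 1L) * (Hp * Wp)
  idx <- as.integer(idx)
  S <- Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                            dims = c(Hp * Wp * Cin, length(idx)))
  g <- list(H = H, W = W, Cin = Cin, k = k, stride = stride, pad = pad,
            dil = dil, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo,
            idx = idx, S = S, nrow = as.integer(k * k * Cin))
  .ad$geom[[key]] <- g
  g
}

.pad_hw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

# 2-D convolution; x: (H, W, Cin), W weight: (Cout, Cin*k*k), b: length Cout
ad_conv2d <- function(x, w, b, k, stride = 1L, pad = (k %/% 2L), dil = 1L) {
  d <- dim(x$value)
  geom <- .conv_geom(d[1], d[2], d[3], k, stride, pad, dil)
  xp <- .pad_hw(x$value, pad)
  cols <- matrix(xp[geom$idx], nrow = geom$nrow)
  out <- w$value %*% cols + b$value
  v <- array(t(out), c(geom$Ho, geom$Wo, nrow(w$value)))
  .ad_node(v, list(x, w, b), function(g) {
    gm <- t(matrix(g, geom$Ho * geom$Wo, dim(v)[3]))
    dW <- tcrossprod(gm, cols)
    db <- rowSums(gm)
    dcols <- crossprod(w$value, gm)
    dxp <- as.numeric(geom$S %*% as.vector(dcols))
    dxp <- array(dxp, c(geom$Hp, geom$Wp, geom$Cin))
    dx <- if (geom$pad > 0)
      dxp[geom$pad + seq_len(geom$H), geom$pad + seq_len(geom$W), , drop = FALSE]
    else dxp
    list(dx, dW, db)
  })
}

## ---- bilinear upsampling (x2) ----

.upsample_geom <- function(H, W) {
  key <- paste("u", H, W, sep = "_")
  g <- .ad$geom[[key]]
  if (!is.null(g)) return(g)
  Ho <- 2L * H; Wo <- 2L * W
  src <- function(o, n) pmin(pmax((o + 0.5) / 2 - 0.5, 0), n - 1)
  sh <- src(0:(Ho - 1L), H); sw <- src(0:(Wo - 1L), W)
  h0 <- pmin(floor(sh), H - 1); fh <- sh - h0; h1 <- pmin(h0 + 1, H - 1)
  w0 <- pmin(floor(sw), W - 1); fw <- sw - w0; w1 <- pmin(w0 + 1, W - 1)
  op <- expand.grid(i = seq_len(Ho), j = seq_len(Wo))
  rows <- op$i + (op$j - 1L) * Ho
  ii <- rep(rows, 4L)
  jj <- c(h0[op$i] + w0[op$j] * H, h1[op$i] + w0[op$j] * H,
          h0[op$i] + w1[op$j] * H, h1[op$i] + w1[op$j] * H) + 1
  xx <- c((1 - fh[op$i]) * (1 - fw[op$j]), fh[op$i] * (1 - fw[op$j]),
          (1 - fh[op$i]) * fw[op$j], fh[op$i] * fw[op$j])
  U <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(Ho * Wo, H * W))
  g <- list(U = U, Ho = Ho, Wo = Wo)
  .ad$geom[[key]] <- g
  g
}

ad_upsample2 <- function(x) {
  d <- dim(x$value)
  geom <- .upsample_geom(d[1], d[2])
  xf <- matrix(x$value, d[1] * d[2], d[3])
  v <- array(as.matrix(geom$U %*% xf), c(geom$Ho, geom$Wo, d[3]))
  .ad_node(v, list(x), function(g) {
    gf <- matrix(g, geom$Ho * geom$Wo, d[3])
    list(array(as.matrix(Matrix::crossprod(geom$U, gf)), d))
  })
}

## ---- optimizer ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# Wrap a flat named parameter list as tape leaves.
ad_params <- function(store) lapply(store, ad_leaf)

# Collect gradients from parameter leaves (zero where unused).
ad_collect_grads <- function(pnodes) lapply(pnodes, ad_grad)
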