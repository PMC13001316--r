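## Composite building blocks shared by the diffusion networks. Parameters
## live in flat named lists ("prefix.name" keys); forward functions take the
## corresponding list of tape leaves.

.he_conv <- function(cout, cin, k) {
  matrix(rnorm(cout * cin * k * k, 0, sqrt(2 / (cin * k * k))), cout)
}

.he_lin <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin)

# add a (1 x C) matrix node as a channel-broadcast bias to an (H, W, C) array
ad_add_chan_row <- function(x, b) {
  d <- dim(x$value)
  .ad_node(x$value + rep(as.vector(b$value), each = d[1] * d[2]), list(x, b),
           function(g) list(g, matrix(colSums(matrix(g, d[1] * d[2], d[3])), 1)))
}

## ---- residual block: GN -> SiLU -> conv, timestep injection, skip ----

rb_params <- function(cin, cout, tdim = 0L) {
  p <- list(gn1.g = rep(1, cin), gn1.b = numeric(cin),
            conv1.W = .he_conv(cout, cin, 3L), conv1.b = numeric(cout),
            gn2.g = rep(1, cout), gn2.b = numeric(cout),
            conv2.W = .he_conv(cout, cout, 3L), conv2.b = numeric(cout))
  if (tdim > 0L) {
    p$temb.W <- .he_lin(tdim, cout)
    p$temb.b <- numeric(cout)
  }
  if (cin != cout) {
    p$skip.W <- .he_conv(cout, cin, 1L)
    p$skip.b <- numeric(cout)
  }
  p
}

.with_prefix <- function(p, prefix) {
  function(nm) p[[paste(prefix, nm, sep = ".")]]
}

.gn_groups <- function(ch) if (ch %% 4L == 0L) 4L else 1L

rb_forward <- function(p, prefix, x, temb = NULL) {
  P <- .with_prefix(p, prefix)
  cin <- length(ad_value(P("gn1.g")))
  h <- ad_groupnorm(x, P("gn1.g"), P("gn1.b"), .gn_groups(cin))
  h <- ad_conv2d(ad_silu(h), P("conv1.W"), P("conv1.b"), 3L)
  if (!is.null(temb) && !is.null(P("temb.W"))) {
    tb <- ad_bias_rows(ad_matmul(temb, P("temb.W")), P("temb.b"))
    h <- ad_add_chan_row(h, tb)
  }
  cout <- length(ad_value(P("gn2.g")))
  h <- ad_groupnorm(h, P("gn2.g"), P("gn2.b"), .gn_groups(cout))
  h <- ad_conv2d(ad_silu(h), P("conv2.W"), P("conv2.b"), 3L)
  sk <- if (!is.null(P("skip.W")))
    ad_conv2d(x, P("skip.W"), P("skip.b"), 1L, pad = 0L) else x
  ad_add(sk, h)
}

## ---- multi-head attention over token matrices ----

attn_params <- function(dq, dkv, dh, nheads, dout = dq) {
  p <- list()
  for (h in seq_len(nheads)) {
    p[[sprintf("q%d.W", h)]] <- .he_lin(dq, dh)
    p[[sprintf("k%d.W", h)]] <- .he_lin(dkv, dh)
    p[[sprintf("v%d.W", h)]] <- .he_lin(dkv, dh)
  }
  p$out.W <- .he_lin(nheads * dh, dout)
  p$out.b <- numeric(dout)
  p
}

attn_forward <- function(p, prefix, q, kv, nheads, dh) {
  P <- .with_prefix(p, prefix)
  heads <- vector("list", nheads)
  for (h in seq_len(nheads)) {
    Q <- ad_matmul(q, P(sprintf("q%d.W", h)))
    K <- ad_matmul(kv, P(sprintf("k%d.W", h)))
    V <- ad_matmul(kv, P(sprintf("v%d.W", h)))
    A <- ad_softmax_rows(ad_scale(ad_matmul_t(Q, K), 1 / sqrt(dh)))
    heads[[h]] <- ad_matmul(A, V)
  }
  o <- if (nheads == 1L) heads[[1]] else do.call(ad_concat_cols, heads)
  ad_bias_rows(ad_matmul(o, P("out.W")), P("out.b"))
}

# attention block over an (H, W, C) feature map (self-attention if kv NULL)
attn_block <- function(p, prefix, x, kv = NULL, nheads = 2L) {
  d <- dim(x$value)
  tok <- ad_reshape(x, c(d[1] * d[2], d[3]))
  kvTok <- if (is.null(kv)) tok else kv
  dh <- max(4L, d[3] %/% nheads)
  o <- attn_forward(p, prefix, tok, kvTok, nheads, dh)
  ad_add(x, ad_reshape(o, d))
}

## ---- sinusoidal embeddings ----

#' Four-channel sinusoidal positional encoding
#'
#' For a grid of the given size, returns the array with channels
#' \code{sin(2 pi x), cos(2 pi x), sin(2 pi y), cos(2 pi y)} where x and y
#' are pixel coordinates normalized to [0, 1) (x along columns, y along
#' rows, 0-based).
#'
#' @param Hz,Wz grid height and width.
#' @return numeric array (Hz, Wz, 4).
#' @export
positionalEncoding <- function(Hz, Wz) {
  y <- (seq_len(Hz) - 1) / Hz
  x <- (seq_len(Wz) - 1) / Wz
  pe <- array(0, c(Hz, Wz, 4))
  pe[, , 1] <- matrix(sin(2 * pi * x), Hz, Wz, byrow = TRUE)
  pe[, , 2] <- matrix(cos(2 * pi * x), Hz, Wz, byrow = TRUE)
  pe[, , 3] <- matrix(sin(2 * pi * y), Hz, Wz)
  pe[, , 4] <- matrix(cos(2 * pi * y), Hz, Wz)
  pe
}

# sinusoidal timestep embedding, returned as a 1 x dim matrix
timestep_embedding <- function(t, dims = 16L) {
  half <- dims %/% 2L
  freq <- exp(-log(10000) * (seq_len(half) - 1) / max(1, half - 1))
  matrix(c(sin(t * freq), cos(t * freq)), 1)
}
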