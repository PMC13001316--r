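## The two denoising networks of the cascade. Both are x0-parameterized:
## they predict the clean sample directly, and training minimizes the mean
## squared error to it. Every shape contract is resolution-parametric, so
## the same code runs at the production scale (512-pixel images, 64-pixel
## latents) and at the desk scale used by the tests (64-pixel images,
## 8-pixel latents).

.tmlp_params <- function(tdim, tout) {
  list(t1.W = .he_lin(tdim, tout), t1.b = numeric(tout),
       t2.W = .he_lin(tout, tout), t2.b = numeric(tout))
}

.tmlp_forward <- function(p, t, tdim) {
  e <- ad_leaf(timestep_embedding(t, tdim))
  h <- ad_silu(ad_bias_rows(ad_matmul(e, p$t1.W), p$t1.b))
  ad_bias_rows(ad_matmul(h, p$t2.W), p$t2.b)
}

.named <- function(p, prefix) setNames(p, paste0(prefix, ".", names(p)))

## ---- latent UNet: conditional denoiser with cross-attention on the prompt ----

#' Create the latent-stage conditional UNet
#'
#' A small two-level UNet over the 4-channel latent. Timestep embeddings are
#' injected into every residual block through an MLP; the spatial prompt is
#' attended to by cross-attention in every resolution block. Predicts the
#' clean latent (x0 parameterization).
#'
#' @param tokenDim feature width of the spatial-prompt tokens.
#' @param latentCh latent channels (default 4).
#' @param base channel width (default 32).
#' @param tdim sinusoidal timestep embedding dimension (default 16).
#' @param nheads cross-attention heads (default 2).
#' @param seed integer seed.
#' @return A \code{latentUNet} model.
#' @export
latentUNet <- function(tokenDim, latentCh = 4L, base = 32L, tdim = 16L,
                       nheads = 2L, seed = 0L) {
  set.seed(seed)
  b <- base; tw <- 2L * tdim
  p <- c(.tmlp_params(tdim, tw),
         list(in.W = .he_conv(b, latentCh, 3L), in.b = numeric(b)),
         .named(rb_params(b, b, tw), "rb1"),
         .named(attn_params(b, tokenDim, max(4L, b %/% nheads), nheads), "xa1"),
         list(dn.W = .he_conv(2L * b, b, 3L), dn.b = numeric(2L * b)),
         .named(rb_params(2L * b, 2L * b, tw), "rb2"),
         .named(attn_params(2L * b, tokenDim, max(4L, 2L * b %/% nheads),
                            nheads), "xa2"),
         .named(rb_params(2L * b, 2L * b, tw), "rbmid"),
         list(up.W = .he_conv(b, 2L * b, 3L), up.b = numeric(b)),
         .named(rb_params(2L * b, b, tw), "rb3"),
         .named(attn_params(b, tokenDim, max(4L, b %/% nheads), nheads), "xa3"),
         list(og.g = rep(1, b), og.b = numeric(b),
              out.W = .he_conv(latentCh, b, 3L), out.b = numeric(latentCh)))
  structure(list(params = p, base = b, latentCh = latentCh, tdim = tdim,
                 nheads = nheads, tokenDim = tokenDim, seed = seed),
            class = "latentUNet")
}

.xattn <- function(model, pn, prefix, h, Pnode) {
  d <- dim(ad_value(h))
  tok <- ad_reshape(h, c(d[1] * d[2], d[3]))
  o <- attn_forward(pn, prefix, tok, Pnode, model$nheads,
                    max(4L, d[3] %/% model$nheads))
  ad_add(h, ad_reshape(o, d))
}

.latent_unet_forward <- function(model, pn, zt, t, Pnode) {
  temb <- .tmlp_forward(pn, t, model$tdim)
  h1 <- ad_conv2d(zt, pn$in.W, pn$in.b, 3L)
  h1 <- rb_forward(pn, "rb1", h1, temb)
  h1 <- .xattn(model, pn, "xa1", h1, Pnode)
  h2 <- ad_conv2d(h1, pn$dn.W, pn$dn.b, 3L, stride = 2L)
  h2 <- rb_forward(pn, "rb2", h2, temb)
  h2 <- .xattn(model, pn, "xa2", h2, Pnode)
  h2 <- rb_forward(pn, "rbmid", h2, temb)
  u <- ad_conv2d(ad_upsample2(h2), pn$up.W, pn$up.b, 3L)
  u <- rb_forward(pn, "rb3", ad_concat_c(u, h1), temb)
  u <- .xattn(model, pn, "xa3", u, Pnode)
  o <- ad_silu(ad_groupnorm(u, pn$og.g, pn$og.b, .gn_groups(model$base)))
  ad_conv2d(o, pn$out.W, pn$out.b, 3L)
}

#' Predict the clean latent from a noised latent
#'
#' @param model a \code{latentUNet}.
#' @param zt noised latent (Hz, Wz, C).
#' @param t timestep.
#' @param P spatial prompt matrix (64 x tokenDim).
#' @return predicted clean latent, same shape as \code{zt}.
#' @export
latentUnetPredict <- function(model, zt, t, P) {
  ad_tape_start()
  ad_value(.latent_unet_forward(model, ad_params(model$params), ad_leaf(zt),
                                t, ad_leaf(P)))
}

## ---- latent adapter: multi-scale conditioning pyramid ----

#' Create the latent adapter
#'
#' Concatenates the four-channel sinusoidal positional encoding to the
#' reconstructed latent, refines it with a dilated residual block (parallel
#' 3x3 convolutions at dilation rates 1, 2 and 4, fused by a 1x1
#' convolution with a residual add), and emits a conditioning pyramid at 1x,
#' 2x, 4x and 8x the latent resolution through bilinear upsampling, 3x3
#' convolutions and residual blocks, each projected to the conditioning
#' width by a 1x1 convolution.
#'
#' @param latentCh latent channels (default 4).
#' @param cint internal channel width (default 16).
#' @param ccond conditioning channels per pyramid level (default 8).
#' @param seed integer seed.
#' @return A \code{latentAdapter} model.
#' @export
latentAdapter <- function(latentCh = 4L, cint = 16L, ccond = 8L, seed = 0L) {
  set.seed(seed)
  cin <- latentCh + 4L
  p <- list(pj.W = .he_conv(cint, cin, 1L), pj.b = numeric(cint),
            d1.W = .he_conv(cint, cint, 3L), d1.b = numeric(cint),
            d2.W = .he_conv(cint, cint, 3L), d2.b = numeric(cint),
            d4.W = .he_conv(cint, cint, 3L), d4.b = numeric(cint),
            fg.g = rep(1, 3L * cint), fg.b = numeric(3L * cint),
            fu.W = .he_conv(cint, 3L * cint, 1L), fu.b = numeric(cint),
            p1.W = .he_conv(ccond, cint, 1L), p1.b = numeric(ccond))
  for (l in 2:4) {
    p[[sprintf("u%d.W", l)]] <- .he_conv(cint, cint, 3L)
    p[[sprintf("u%d.b", l)]] <- numeric(cint)
    p <- c(p, .named(rb_params(cint, cint), sprintf("ur%d", l)))
    p[[sprintf("p%d.W", l)]] <- .he_conv(ccond, cint, 1L)
    p[[sprintf("p%d.b", l)]] <- numeric(ccond)
  }
  structure(list(params = p, latentCh = latentCh, cint = cint, ccond = ccond,
                 seed = seed), class = "latentAdapter")
}

.adapter_forward <- function(model, pn, zNode) {
  d <- dim(ad_value(zNode))
  zin <- ad_concat_c(zNode, ad_leaf(positionalEncoding(d[1], d[2])))
  x <- ad_conv2d(zin, pn$pj.W, pn$pj.b, 1L, pad = 0L)
  h1 <- ad_conv2d(x, pn$d1.W, pn$d1.b, 3L, dil = 1L)
  h2 <- ad_conv2d(x, pn$d2.W, pn$d2.b, 3L, pad = 2L, dil = 2L)
  h4 <- ad_conv2d(x, pn$d4.W, pn$d4.b, 3L, pad = 4L, dil = 4L)
  hf <- ad_silu(ad_groupnorm(ad_concat_c(h1, h2, h4), pn$fg.g, pn$fg.b,
                             .gn_groups(3L * model$cint)))
  hf <- ad_conv2d(hf, pn$fu.W, pn$fu.b, 1L, pad = 0L)
  x <- ad_add(x, hf)
  s <- list(ad_conv2d(x, pn$p1.W, pn$p1.b, 1L, pad = 0L))
  for (l in 2:4) {
    x <- ad_conv2d(ad_upsample2(x), pn[[sprintf("u%d.W", l)]],
                   pn[[sprintf("u%d.b", l)]], 3L)
    x <- rb_forward(pn, sprintf("ur%d", l), x)
    s[[l]] <- ad_conv2d(x, pn[[sprintf("p%d.W", l)]],
                        pn[[sprintf("p%d.b", l)]], 1L, pad = 0L)
  }
  s
}

#' Conditioning pyramid from a reconstructed latent
#'
#' @param model a \code{latentAdapter}.
#' @param z latent array (Hz, Wz, C).
#' @return list of four conditioning arrays at 1x, 2x, 4x, 8x the latent
#'   resolution (e.g. 64/128/256/512 at production scale, 8/16/32/64 at the
#'   desk scale).
#' @export
adapterForward <- function(model, z) {
  ad_tape_start()
  lapply(.adapter_forward(model, ad_params(model$params), ad_leaf(z)),
         ad_value)
}

## ---- pixel UNet: conditional diffusion decoder ----

#' Create the pixel-stage conditional UNet
#'
#' Encoder from image resolution down to 1/8 with residual blocks, the two
#' intermediate conditioning tensors concatenated on the way down; a
#' bottleneck with multi-head self-attention plus the coarsest conditioning
#' tensor; a mirrored decoder concatenating skips and the matching
#' conditioning tensors; final 3x3 convolution and tanh mapped linearly
#' from (-1, 1) to the [0, 1] embedding range. Predicts the clean image.
#'
#' @param base channel width (default 16).
#' @param ccond conditioning channels per pyramid level (default 8).
#' @param tdim timestep embedding dimension (default 16).
#' @param nheads self-attention heads at the bottleneck (default 2).
#' @param seed integer seed.
#' @return A \code{pixelUNet} model.
#' @export
pixelUNet <- function(base = 16L, ccond = 8L, tdim = 16L, nheads = 2L,
                      seed = 0L) {
  set.seed(seed)
  b <- base; tw <- 2L * tdim; cc <- ccond
  p <- c(.tmlp_params(tdim, tw),
         list(in.W = .he_conv(b, 3L, 3L), in.b = numeric(b)),
         .named(rb_params(b, b, tw), "e64"),
         list(d32.W = .he_conv(2L * b, b, 3L), d32.b = numeric(2L * b)),
         .named(rb_params(2L * b + cc, 2L * b, tw), "e32"),
         list(d16.W = .he_conv(2L * b, 2L * b, 3L), d16.b = numeric(2L * b)),
         .named(rb_params(2L * b + cc, 2L * b, tw), "e16"),
         list(d8.W = .he_conv(2L * b, 2L * b, 3L), d8.b = numeric(2L * b)),
         .named(attn_params(2L * b, 2L * b, max(4L, 2L * b %/% nheads),
                            nheads), "sa8"),
         .named(rb_params(2L * b + cc, 2L * b, tw), "m1"),
         .named(rb_params(2L * b, 2L * b, tw), "m2"),
         list(u16.W = .he_conv(2L * b, 2L * b, 3L), u16.b = numeric(2L * b)),
         .named(rb_params(4L * b + cc, 2L * b, tw), "d16r"),
         list(u32.W = .he_conv(2L * b, 2L * b, 3L), u32.b = numeric(2L * b)),
         .named(rb_params(4L * b + cc, 2L * b, tw), "d32r"),
         list(u64.W = .he_conv(b, 2L * b, 3L), u64.b = numeric(b)),
         .named(rb_params(2L * b + cc, b, tw), "d64r"),
         list(og.g = rep(1, b), og.b = numeric(b),
              out.W = .he_conv(3L, b, 3L), out.b = numeric(3L)))
  structure(list(params = p, base = b, ccond = cc, tdim = tdim,
                 nheads = nheads, seed = seed), class = "pixelUNet")
}

.pixel_unet_forward <- function(model, pn, xt, t, cond) {
  # cond: list of 4 nodes at 1/8, 1/4, 1/2, 1/1 of the image resolution
  if (dim(ad_value(cond[[4]]))[1] != dim(ad_value(xt))[1])
    stop("conditioning pyramid does not match the image scale")
  temb <- .tmlp_forward(pn, t, model$tdim)
  h64 <- rb_forward(pn, "e64", ad_conv2d(xt, pn$in.W, pn$in.b, 3L), temb)
  h32 <- ad_conv2d(h64, pn$d32.W, pn$d32.b, 3L, stride = 2L)
  h32 <- rb_forward(pn, "e32", ad_concat_c(h32, cond[[3]]), temb)
  h16 <- ad_conv2d(h32, pn$d16.W, pn$d16.b, 3L, stride = 2L)
  h16 <- rb_forward(pn, "e16", ad_concat_c(h16, cond[[2]]), temb)
  h8 <- ad_conv2d(h16, pn$d8.W, pn$d8.b, 3L, stride = 2L)
  d8 <- dim(ad_value(h8))
  tok <- ad_reshape(h8, c(d8[1] * d8[2], d8[3]))
  sa <- attn_forward(pn, "sa8", tok, tok, model$nheads,
                     max(4L, d8[3] %/% model$nheads))
  h8 <- ad_add(h8, ad_reshape(sa, d8))
  h8 <- rb_forward(pn, "m1", ad_concat_c(h8, cond[[1]]), temb)
  h8 <- rb_forward(pn, "m2", h8, temb)
  u16 <- ad_conv2d(ad_upsample2(h8), pn$u16.W, pn$u16.b, 3L)
  u16 <- rb_forward(pn, "d16r", ad_concat_c(u16, h16, cond[[2]]), temb)
  u32 <- ad_conv2d(ad_upsample2(u16), pn$u32.W, pn$u32.b, 3L)
  u32 <- rb_forward(pn, "d32r", ad_concat_c(u32, h32, cond[[3]]), temb)
  u64 <- ad_conv2d(ad_upsample2(u32), pn$u64.W, pn$u64.b, 3L)
  u64 <- rb_forward(pn, "d64r", ad_concat_c(u64, h64, cond[[4]]), temb)
  o <- ad_silu(ad_groupnorm(u64, pn$og.g, pn$og.b, .gn_groups(model$base)))
  o <- ad_tanh(ad_conv2d(o, pn$out.W, pn$out.b, 3L))
  ad_scale(.ad_node(o$value + 1, list(o), function(g) list(g)), 0.5)
}

#' Predict the clean image from a noised image
#'
#' @param model a \code{pixelUNet}.
#' @param xt noised image (H, W, 3).
#' @param t timestep.
#' @param cond conditioning pyramid (list of 4 arrays) from
#'   \code{\link{adapterForward}}.
#' @return predicted clean image in [0, 1].
#' @export
pixelUnetPredict <- function(model, xt, t, cond) {
  ad_tape_start()
  ad_value(.pixel_unet_forward(model, ad_params(model$params), ad_leaf(xt),
                               t, lapply(cond, ad_leaf)))
}
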