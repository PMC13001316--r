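## Latent codec: a small trainable convolutional autoencoder providing the
## 8x spatial compression of the cascaded pipeline (3 x H x W images to
## 4-channel latents at H/8 x W/8). The production-scale pretrained VAE
## backbone is pluggable; this codec trains on CPU in minutes and satisfies
## the same shape contract.

.codec_params <- function(base = 12L, latentCh = 4L) {
  b <- base
  c(list(e0.W = .he_conv(b, 3L, 3L), e0.b = numeric(b),
         e1.W = .he_conv(b, b, 3L), e1.b = numeric(b),
         e2.W = .he_conv(2L * b, b, 3L), e2.b = numeric(2L * b),
         e3.W = .he_conv(2L * b, 2L * b, 3L), e3.b = numeric(2L * b),
         eo.W = .he_conv(latentCh, 2L * b, 3L), eo.b = numeric(latentCh),
         d0.W = .he_conv(2L * b, latentCh, 3L), d0.b = numeric(2L * b),
         d1.W = .he_conv(2L * b, 2L * b, 3L), d1.b = numeric(2L * b),
         d2.W = .he_conv(b, 2L * b, 3L), d2.b = numeric(b),
         d3.W = .he_conv(b, b, 3L), d3.b = numeric(b),
         do.W = .he_conv(3L, b, 3L), do.b = numeric(3L)))
}

.codec_enc <- function(p, x) {
  h <- ad_silu(ad_conv2d(x, p$e0.W, p$e0.b, 3L))
  h <- ad_silu(ad_conv2d(h, p$e1.W, p$e1.b, 3L, stride = 2L))
  h <- ad_silu(ad_conv2d(h, p$e2.W, p$e2.b, 3L, stride = 2L))
  h <- ad_silu(ad_conv2d(h, p$e3.W, p$e3.b, 3L, stride = 2L))
  ad_conv2d(h, p$eo.W, p$eo.b, 3L)
}

.codec_dec <- function(p, z) {
  h <- ad_silu(ad_conv2d(z, p$d0.W, p$d0.b, 3L))
  h <- ad_silu(ad_conv2d(ad_upsample2(h), p$d1.W, p$d1.b, 3L))
  h <- ad_silu(ad_conv2d(ad_upsample2(h), p$d2.W, p$d2.b, 3L))
  h <- ad_silu(ad_conv2d(ad_upsample2(h), p$d3.W, p$d3.b, 3L))
  ad_conv2d(h, p$do.W, p$do.b, 3L)
}

#' Train the latent codec
#'
#' Fits the convolutional encoder/decoder pair by mean squared
#' reconstruction error over the training images (Adam, seeded).
#'
#' @param images list of \linkS4class{TissueImage} (sides divisible by 8).
#' @param steps optimizer steps (default 300).
#' @param base channel width (default 12).
#' @param lr learning rate.
#' @param seed integer seed.
#' @return A \code{latentCodec} model (parameters, config, final training
#'   MSE).
#' @export
trainLatentCodec <- function(images, steps = 300L, base = 12L, lr = 2e-3,
                             seed = 0L) {
  set.seed(seed)
  p <- .codec_params(base)
  st <- adam_init(p)
  mseLast <- NA_real_
  for (s in seq_len(steps)) {
    img <- images[[sample.int(length(images), 1L)]]
    ad_tape_start()
    pn <- ad_params(p)
    x <- imageData(img)
    out <- .codec_dec(pn, .codec_enc(pn, ad_leaf(x)))
    loss <- ad_mse(out, x)
    ad_backward(loss)
    upd <- adam_step(p, ad_collect_grads(pn), st, lr)
    p <- upd$params; st <- upd$state
    mseLast <- ad_value(loss)
  }
  structure(list(params = p, base = base, trained = TRUE, seed = seed,
                 finalMSE = mseLast), class = "latentCodec")
}

#' Encode an image into the 4-channel latent space
#'
#' @param codec a trained \code{latentCodec}.
#' @param img a \linkS4class{TissueImage} or (H, W, 3) array.
#' @return latent array (H/8, W/8, 4).
#' @export
encodeLatent <- function(codec, img) {
  if (!isTRUE(codec$trained)) stop("codec is untrained")
  x <- if (is(img, "TissueImage")) imageData(img) else img
  ad_tape_start()
  ad_value(.codec_enc(ad_params(codec$params), ad_leaf(x)))
}

#' Decode a latent back to image space
#'
#' @param codec a trained \code{latentCodec}.
#' @param z latent array (Hz, Wz, 4).
#' @return image array (8 Hz, 8 Wz, 3), clamped to [0, 1].
#' @export
decodeLatent <- function(codec, z) {
  if (!isTRUE(codec$trained)) stop("codec is untrained")
  ad_tape_start()
  out <- ad_value(.codec_dec(ad_params(codec$params), ad_leaf(z)))
  pmin(pmax(out, 0), 1)
}

#' @export
print.latentCodec <- function(x, ...) {
  cat(sprintf("latentCodec: 3ch -> 4ch at 1/8 resolution (base %d, final MSE %.4g)\n",
              x$base, x$finalMSE))
  invisible(x)
}
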