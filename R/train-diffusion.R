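## Cascade training. Stage 1 (latent): the spatial prompt encoder and the
## latent UNet are optimized jointly to predict the clean latent z0 = E(I)
## from the masked-and-noised latent z_t (noise applied only inside the
## latent mask) under the spatial prompt. Stage 2 (pixel): the adapter and
## the pixel UNet are optimized jointly to predict the clean image from the
## globally noised image under the conditioning pyramid of the clean latent.

# Training-mask distribution, mirroring the inference mask families:
# free rectangles (inpainting), full-height vertical bands (2D imputation
# gaps and outpainting strips), full-width horizontal bands, and full-frame
# masks whose prompt is computed from the clean image (the cross-slice
# conditioning surrogate used by 3D imputation).
.sample_mask <- function(S, pFull = 0.25) {
  u <- runif(1)
  if (u < pFull) return(list(mask = rectMask(S, S, c(0, 0, 1, 1)),
                             full = TRUE))
  if (u < pFull + 0.25) {                      # vertical band
    w <- runif(1, 0.15, 0.5); x1 <- runif(1, 0, 1 - w)
    return(list(mask = rectMask(S, S, c(x1, 0, x1 + w, 1)), full = FALSE))
  }
  if (u < pFull + 0.35) {                      # horizontal band
    h <- runif(1, 0.15, 0.5); y1 <- runif(1, 0, 1 - h)
    return(list(mask = rectMask(S, S, c(0, y1, 1, y1 + h)), full = FALSE))
  }
  w <- runif(1, 0.3, 0.8); h <- runif(1, 0.3, 0.8)
  x1 <- runif(1, 0, 1 - w); y1 <- runif(1, 0, 1 - h)
  list(mask = rectMask(S, S, c(x1, y1, x1 + w, y1 + h)), full = FALSE)
}

#' Train the latent diffusion stage
#'
#' @param images list of \linkS4class{TissueImage} training maps.
#' @param codec a trained \code{latentCodec} (frozen).
#' @param promptEnc a \code{spatialPromptEncoder} (optimized jointly).
#' @param unet a \code{latentUNet} (optimized jointly).
#' @param sched a \code{\link{noiseSchedule}}.
#' @param steps optimizer steps.
#' @param lr learning rate.
#' @param pFull probability of a full-frame training mask with the prompt
#'   computed from the clean image.
#' @param seed integer seed.
#' @return list with the updated \code{promptEnc}, \code{unet} and the
#'   per-step \code{losses}.
#' @export
trainLatentDiffusion <- function(images, codec, promptEnc, unet, sched,
                                 steps = 400L, lr = 1e-3, pFull = 0.3,
                                 seed = 0L) {
  set.seed(seed)
  store <- c(.named(promptEnc$params, "pe"), .named(unet$params, "lu"))
  st <- adam_init(store)
  losses <- numeric(steps)
  S <- dim(imageData(images[[1]]))[1]
  for (s in seq_len(steps)) {
    img <- images[[sample.int(length(images), 1L)]]
    ms <- .sample_mask(S)
    Im <- applyMask(img, ms$mask)
    z0 <- encodeLatent(codec, img)
    z0m <- encodeLatent(codec, Im)
    M <- downsampleMask(ms$mask, S / dim(z0)[1])
    t <- sample.int(sched$T, 1L)
    zt <- forwardNoiseLatent(z0m, M, t, sched)
    pimg <- if (ms$full) imageData(img) else imageData(Im)
    coords <- c(ms$mask@box, ms$mask@aspect, ms$mask@area)
    ad_tape_start()
    pn <- ad_params(store)
    pe <- lapply(setNames(names(promptEnc$params),
                          names(promptEnc$params)),
                 function(nm) pn[[paste0("pe.", nm)]])
    lu <- lapply(setNames(names(unet$params), names(unet$params)),
                 function(nm) pn[[paste0("lu.", nm)]])
    P <- .prompt_forward(promptEnc, pe, ad_leaf(pimg), coords)
    zhat <- .latent_unet_forward(unet, lu, ad_leaf(zt), t, P)
    loss <- ad_mse(zhat, z0)
    ad_backward(loss)
    upd <- adam_step(store, ad_collect_grads(pn), st, lr)
    store <- upd$params; st <- upd$state
    losses[s] <- ad_value(loss)
  }
  promptEnc$params <- setNames(store[paste0("pe.", names(promptEnc$params))],
                               names(promptEnc$params))
  unet$params <- setNames(store[paste0("lu.", names(unet$params))],
                          names(unet$params))
  list(promptEnc = promptEnc, unet = unet, losses = losses)
}

#' Train the pixel diffusion stage
#'
#' @param images list of \linkS4class{TissueImage} training maps.
#' @param codec a trained \code{latentCodec} (frozen).
#' @param adapter a \code{latentAdapter} (optimized jointly).
#' @param punet a \code{pixelUNet} (optimized jointly).
#' @param sched a \code{\link{noiseSchedule}}.
#' @param steps,lr,seed optimizer settings.
#' @return list with the updated \code{adapter}, \code{punet} and
#'   \code{losses}.
#' @export
trainPixelDiffusion <- function(images, codec, adapter, punet, sched,
                                steps = 400L, lr = 1e-3, seed = 0L) {
  set.seed(seed)
  store <- c(.named(adapter$params, "ad"), .named(punet$params, "pu"))
  st <- adam_init(store)
  losses <- numeric(steps)
  for (s in seq_len(steps)) {
    img <- images[[sample.int(length(images), 1L)]]
    x0 <- imageData(img)
    z0 <- encodeLatent(codec, img)
    t <- sample.int(sched$T, 1L)
    xt <- forwardNoisePixel(x0, t, sched)
    ad_tape_start()
    pn <- ad_params(store)
    adp <- lapply(setNames(names(adapter$params), names(adapter$params)),
                  function(nm) pn[[paste0("ad.", nm)]])
    pup <- lapply(setNames(names(punet$params), names(punet$params)),
                  function(nm) pn[[paste0("pu.", nm)]])
    cond <- .adapter_forward(adapter, adp, ad_leaf(z0))
    xhat <- .pixel_unet_forward(punet, pup, ad_leaf(xt), t, cond)
    loss <- ad_mse(xhat, x0)
    ad_backward(loss)
    upd <- adam_step(store, ad_collect_grads(pn), st, lr)
    store <- upd$params; st <- upd$state
    losses[s] <- ad_value(loss)
  }
  adapter$params <- setNames(store[paste0("ad.", names(adapter$params))],
                             names(adapter$params))
  punet$params <- setNames(store[paste0("pu.", names(punet$params))],
                           names(punet$params))
  list(adapter = adapter, punet = punet, losses = losses)
}

#' Assemble and train the cascaded generative model
#'
#' Trains (or initializes, when a step count is 0) the three trainable
#' pieces of the cascade: the latent codec, the latent stage (prompt encoder
#' + latent UNet) and the pixel stage (adapter + pixel UNet).
#'
#' @param images list of \linkS4class{TissueImage} training maps (all the
#'   same square size, side divisible by 8).
#' @param T diffusion steps (default 50 for desk-scale runs; 1000 at
#'   production scale).
#' @param stepsCodec,stepsLatent,stepsPixel optimizer steps per stage; 0
#'   leaves the component freshly initialized (untrained).
#' @param codec optional pre-trained \code{latentCodec} to reuse (then
#'   \code{stepsCodec} is ignored).
#' @param baseLatent,basePixel,featDim,ccond network widths.
#' @param lr learning rate for the diffusion stages.
#' @param seed integer seed.
#' @return A \code{cascadeModel} list: \code{codec}, \code{prompt},
#'   \code{lunet}, \code{adapter}, \code{punet}, \code{sched},
#'   \code{imageSize}, plus the training loss traces.
#' @export
trainCascade <- function(images, T = 50L, stepsCodec = 300L,
                         stepsLatent = 500L, stepsPixel = 500L, codec = NULL,
                         baseLatent = 32L, basePixel = 16L, featDim = 32L,
                         ccond = 8L, lr = 1e-3, seed = 0L) {
  S <- dim(imageData(images[[1]]))[1]
  if (is.null(codec))
    codec <- trainLatentCodec(images, steps = stepsCodec, seed = seed)
  promptEnc <- spatialPromptEncoder(imageSize = S, featDim = featDim,
                                    seed = seed + 1L)
  lunet <- latentUNet(tokenDim = promptEnc$tokenDim, base = baseLatent,
                      seed = seed + 2L)
  adapter <- latentAdapter(ccond = ccond, seed = seed + 3L)
  punet <- pixelUNet(base = basePixel, ccond = ccond, seed = seed + 4L)
  sched <- noiseSchedule(T)
  lossL <- numeric(0); lossP <- numeric(0)
  if (stepsLatent > 0L) {
    r <- trainLatentDiffusion(images, codec, promptEnc, lunet, sched,
                              steps = stepsLatent, lr = lr, seed = seed + 5L)
    promptEnc <- r$promptEnc; lunet <- r$unet; lossL <- r$losses
  }
  if (stepsPixel > 0L) {
    r <- trainPixelDiffusion(images, codec, adapter, punet, sched,
                             steps = stepsPixel, lr = lr, seed = seed + 6L)
    adapter <- r$adapter; punet <- r$punet; lossP <- r$losses
  }
  structure(list(codec = codec, prompt = promptEnc, lunet = lunet,
                 adapter = adapter, punet = punet, sched = sched,
                 imageSize = S, latentLosses = lossL, pixelLosses = lossP,
                 seed = seed),
            class = "cascadeModel")
}

#' @export
print.cascadeModel <- function(x, ...) {
  cat(sprintf("cascadeModel: %dpx images, %dpx latent, T = %d\n",
              x$imageSize, x$imageSize %/% 8L, x$sched$T))
  if (length(x$latentLosses))
    cat(sprintf("  latent-stage loss: %.4f -> %.4f\n",
                mean(head(x$latentLosses, 20)),
                mean(utils::tail(x$latentLosses, 20))))
  if (length(x$pixelLosses))
    cat(sprintf("  pixel-stage loss:  %.4f -> %.4f\n",
                mean(head(x$pixelLosses, 20)),
                mean(utils::tail(x$pixelLosses, 20))))
  invisible(x)
}
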