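## The four inference procedures built on the cascaded core. All of them
## share one reverse-diffusion routine: a clamped latent chain (unmasked
## latent entries are held at the masked-image latent while masked entries
## are denoised from pure noise under the spatial prompt), followed by the
## adapter and a pixel-space reverse chain conditioned on the reconstructed
## latent. Observed pixels are composited back over the output by default,
## so scientific data are never silently rewritten.

.as_timage <- function(data, background = c(0, 0, 0)) {
  occ <- (abs(data[, , 1] - background[1]) + abs(data[, , 2] - background[2]) +
          abs(data[, , 3] - background[3])) > 1e-9
  new("TissueImage", data = data, occupancy = occ,
      background = as.numeric(background))
}

.hash_seed <- function(seed, z) {
  as.integer((as.numeric(seed) * 7919 + round(as.numeric(z) * 1009)) %%
               2147483646) + 1L
}

# core cascaded generation: returns the raw generated image (H, W, 3)
.cascade_generate <- function(model, img, mask, seed, P = NULL) {
  codec <- model$codec; sched <- model$sched
  Im <- applyMask(img, mask)
  z0m <- encodeLatent(codec, Im)
  f <- dim(imageData(img))[1] %/% dim(z0m)[1]
  M <- downsampleMask(mask, f)
  Ma <- array(M, dim(z0m))
  if (is.null(P)) P <- buildSpatialPrompt(Im, mask, model$prompt)
  set.seed(seed)
  zt <- array(rnorm(length(z0m)), dim(z0m))
  for (t in seq(sched$T, 1L)) {
    zt <- (1 - Ma) * z0m + Ma * zt
    zhat <- latentUnetPredict(model$lunet, zt, t, P)
    zt <- ddpmStep(zt, t, zhat, sched)
  }
  ztilde <- (1 - Ma) * z0m + Ma * zt
  cond <- adapterForward(model$adapter, ztilde)
  d <- dim(imageData(img))
  xt <- array(rnorm(prod(d)), d)
  for (t in seq(sched$T, 1L)) {
    xhat <- pixelUnetPredict(model$punet, xt, t, cond)
    xt <- ddpmStep(xt, t, xhat, sched)
  }
  pmin(pmax(xt, 0), 1)
}

# merge two CellMaps, reassigning unique ids
.bind_cells <- function(a, b) {
  lev <- union(levels(cellTypes(a)), levels(cellTypes(b)))
  CellMap(coords = rbind(cellCoords(a), cellCoords(b)),
          cellType = factor(c(as.character(cellTypes(a)),
                              as.character(cellTypes(b))), levels = lev),
          z = c(a@z, b@z),
          provenance = c(as.character(cellProvenance(a)),
                         as.character(cellProvenance(b))))
}

# decode a generation result into observed + generated cells
.decode_result <- function(outData, inputImg, mask, embedding, tau = 0.05) {
  m <- mask@mask
  obs <- readImage(applyMask(inputImg, mask), embedding, tau = tau,
                   provenance = "observed")
  genImg <- .as_timage(outData)
  genImg@occupancy[] <- FALSE
  gen <- readImage(genImg, embedding, mask = m, tau = tau,
                   provenance = "generated")
  .bind_cells(obs, gen)
}

#' Inpaint a masked region of a tissue map
#'
#' Runs the cascaded reverse diffusion over the masked latent conditioned on
#' the spatial prompt, adapts the reconstructed latent into the conditioning
#' pyramid, runs the pixel-space reverse chain, and (by default) composites
#' the observed pixels back over the output so that every pixel outside the
#' mask is bit-identical to the input.
#'
#' @param img a \linkS4class{TissueImage}.
#' @param mask a \linkS4class{MaskSpec} (arbitrary shape).
#' @param model a trained \code{cascadeModel}.
#' @param seed integer seed; fixed seed and checkpoints give bit-identical
#'   output.
#' @param embedding optional \code{typeEmbedding}; when given, generated
#'   pixels are decoded back to typed cells.
#' @param composite keep observed pixels exactly (default TRUE).
#' @return A \linkS4class{GenerationResult}.
#' @export
inpaint <- function(img, mask, model, seed = 0L, embedding = NULL,
                    composite = TRUE) {
  if (!any(mask@mask > 0L)) {
    warning("empty mask; returning input unchanged")
    cells <- if (is.null(embedding))
      CellMap(matrix(numeric(0), 0, 2), factor(character(0)))
    else readImage(img, embedding)
    return(new("GenerationResult", image = img, cells = cells, mask = mask,
               seed = as.integer(seed), log = data.frame()))
  }
  gen <- .cascade_generate(model, img, mask, seed)
  out <- imageData(img)
  m <- mask@mask
  if (composite) {
    for (ch in 1:3) out[, , ch] <- out[, , ch] * (1 - m) + gen[, , ch] * m
  } else out <- gen
  cells <- if (is.null(embedding))
    CellMap(matrix(numeric(0), 0, 2), factor(character(0)))
  else .decode_result(out, img, mask, embedding)
  resImg <- new("TissueImage", data = out,
                occupancy = occupancyMask(img) & (m == 0L),
                background = img@background)
  new("GenerationResult", image = resImg, cells = cells, mask = mask,
      seed = as.integer(seed), log = data.frame(iteration = 1L,
                                                maskedPixels = sum(m)))
}

# orientation helpers so outpainting only has to handle "right"
.orient_in <- function(d, direction) {
  switch(direction,
         right = d,
         left = d[, rev(seq_len(ncol(d))), , drop = FALSE],
         down = aperm(d, c(2, 1, 3)),
         up = aperm(d, c(2, 1, 3))[, rev(seq_len(nrow(d))), , drop = FALSE])
}

.orient_out <- function(d, direction) {
  switch(direction,
         right = d,
         left = d[, rev(seq_len(ncol(d))), , drop = FALSE],
         down = aperm(d, c(2, 1, 3)),
         up = aperm(d[, rev(seq_len(ncol(d))), , drop = FALSE], c(2, 1, 3)))
}

#' Outpaint a tissue map beyond its boundary
#'
#' Sliding-window extension: each iteration masks a border strip of about
#' \code{fracPerIter} of the working frame, generates it with the cascade,
#' concatenates the new strip outward and drops the farthest old columns so
#' the working latent width stays constant. The original pixels are never
#' modified.
#'
#' @param img a \linkS4class{TissueImage} (square, the model's frame size).
#' @param direction one of \code{"right"}, \code{"left"}, \code{"up"},
#'   \code{"down"}.
#' @param nIter number of extension iterations.
#' @param model a trained \code{cascadeModel}.
#' @param fracPerIter fraction of the frame generated per iteration
#'   (default 0.05, at most 0.25).
#' @param seed integer seed (iteration i uses \code{seed + i}).
#' @param embedding optional \code{typeEmbedding} for cell decoding.
#' @return A \linkS4class{GenerationResult}; the result image has width
#'   (along the chosen direction) input + nIter x strip width.
#' @export
outpaint <- function(img, direction = c("right", "left", "up", "down"),
                     nIter, model, fracPerIter = 0.05, seed = 0L,
                     embedding = NULL) {
  direction <- match.arg(direction)
  if (nIter <= 0L) stop("nIter must be positive")
  if (fracPerIter <= 0 || fracPerIter > 0.25)
    stop("fracPerIter must lie in (0, 0.25]")
  S <- model$imageSize
  Wz <- S %/% 8L
  sCols <- max(1L, round(fracPerIter * Wz))
  sPx <- 8L * sCols
  canvas <- .orient_in(imageData(img), direction)
  log <- data.frame()
  for (it in seq_len(nIter)) {
    work <- array(0, c(S, S, 3))
    keep <- S - sPx
    work[, seq_len(keep), ] <-
      canvas[, ncol(canvas) - keep + seq_len(keep), , drop = FALSE]
    msk <- rectMask(S, S, c(keep / S, 0, 1, 1))
    gen <- .cascade_generate(model, .as_timage(work), msk, seed + it)
    strip <- gen[, keep + seq_len(sPx), , drop = FALSE]
    newCanvas <- array(0, c(S, ncol(canvas) + sPx, 3))
    newCanvas[, seq_len(ncol(canvas)), ] <- canvas
    newCanvas[, ncol(canvas) + seq_len(sPx), ] <- strip
    canvas <- newCanvas
    log <- rbind(log, data.frame(iteration = it, stripCols = sCols,
                                 width = ncol(canvas)))
  }
  outData <- .orient_out(canvas, direction)
  resImg <- .as_timage(outData, img@background)
  genMask <- matrix(1L, nrow(outData), ncol(outData))
  genMask[.orient_out_mask(S, nrow(outData), ncol(outData), direction)] <- 0L
  cells <- if (is.null(embedding))
    CellMap(matrix(numeric(0), 0, 2), factor(character(0)))
  else {
    obsData <- outData
    for (ch in 1:3) obsData[, , ch] <- obsData[, , ch] * (1 - genMask)
    obs <- readImage(.as_timage(obsData, img@background), embedding,
                     provenance = "observed")
    genImg <- resImg
    genImg@occupancy[] <- FALSE
    gen <- readImage(genImg, embedding, mask = genMask,
                     provenance = "generated")
    .bind_cells(obs, gen)
  }
  new("GenerationResult", image = resImg, cells = cells,
      mask = maskSpec(genMask), seed = as.integer(seed), log = log)
}

# logical matrix marking the original (observed) block inside the extended
# frame, for each direction
.orient_out_mask <- function(S, H, W, direction) {
  m <- matrix(FALSE, H, W)
  switch(direction,
         right = m[, seq_len(S)] <- TRUE,
         left = m[, W - S + seq_len(S)] <- TRUE,
         down = m[seq_len(S), ] <- TRUE,
         up = m[H - S + seq_len(S), ] <- TRUE)
  m
}

#' Impute the gap between two lateral tissue maps
#'
#' Composes [left | zero gap | right], then iteratively generates the
#' remaining gap within a sliding window centered on it, committing the
#' outermost generated columns on each side per iteration so the fill grows
#' symmetrically inward. When the two fronts meet, a final joint pass over
#' the central two latent columns removes the seam. Observed pixels are
#' preserved exactly.
#'
#' @param left,right \linkS4class{TissueImage}s of equal height.
#' @param gapCols gap width in latent columns (> 0; 0 returns the plain
#'   concatenation).
#' @param model a trained \code{cascadeModel}.
#' @param patchCols committed columns per side per iteration (default 1).
#' @param maxIter iteration budget (default enough to fill the gap); if the
#'   budget is hit first the partial fill is returned and reported.
#' @param seed integer seed.
#' @param embedding optional \code{typeEmbedding} for cell decoding.
#' @return A \linkS4class{GenerationResult}.
#' @export
impute2d <- function(left, right, gapCols, model, patchCols = 1L,
                     maxIter = NULL, seed = 0L, embedding = NULL) {
  S <- model$imageSize
  ld <- imageData(left); rd <- imageData(right)
  if (nrow(ld) != nrow(rd)) stop("incompatible heights")
  gapPx <- 8L * gapCols
  canvas <- array(0, c(nrow(ld), ncol(ld) + gapPx + ncol(rd), 3))
  canvas[, seq_len(ncol(ld)), ] <- ld
  canvas[, ncol(ld) + gapPx + seq_len(ncol(rd)), ] <- rd
  if (gapCols == 0L)
    return(new("GenerationResult", image = .as_timage(canvas),
               cells = CellMap(matrix(numeric(0), 0, 2), factor(character(0))),
               mask = maskSpec(matrix(0L, nrow(canvas), ncol(canvas))),
               seed = as.integer(seed), log = data.frame()))
  Wl <- ncol(ld) %/% 8L
  remaining <- Wl + seq_len(gapCols)
  Wz <- S %/% 8L
  Wc <- ncol(canvas) %/% 8L
  if (is.null(maxIter)) maxIter <- ceiling(gapCols / (2 * patchCols)) + 1L
  log <- data.frame()
  it <- 0L
  while (length(remaining) && it < maxIter) {
    it <- it + 1L
    lo <- min(remaining); hi <- max(remaining)
    w0 <- max(1L, min(Wc - Wz + 1L, round((lo + hi) / 2 - Wz / 2)))
    winCols <- w0:(w0 + Wz - 1L)
    px0 <- (w0 - 1L) * 8L
    work <- canvas[, px0 + seq_len(S), , drop = FALSE]
    inWin <- intersect(remaining, winCols)
    mm <- matrix(0L, S, S)
    for (cc in inWin) mm[, (cc - w0) * 8L + seq_len(8L)] <- 1L
    gen <- .cascade_generate(model, .as_timage(work), maskSpec(mm),
                             seed + it)
    commit <- intersect(c(lo:(lo + patchCols - 1L),
                          (hi - patchCols + 1L):hi), inWin)
    for (cc in commit) {
      px <- (cc - 1L) * 8L + seq_len(8L)
      canvas[, px, ] <- gen[, (cc - w0) * 8L + seq_len(8L), , drop = FALSE]
    }
    remaining <- setdiff(remaining, commit)
    log <- rbind(log, data.frame(iteration = it, phase = "fill",
                                 committed = length(commit),
                                 remaining = length(remaining)))
  }
  partial <- length(remaining) > 0L
  if (partial)
    warning(length(remaining), " gap column(s) left unfilled at budget")
  if (!partial && gapCols >= 2L) {          # seam pass over the meeting point
    mid <- Wl + gapCols / 2
    seam <- unique(pmin(pmax(floor(mid):(floor(mid) + 1L), Wl + 1L),
                        Wl + gapCols))
    w0 <- max(1L, min(Wc - Wz + 1L, round(mean(seam) - Wz / 2)))
    px0 <- (w0 - 1L) * 8L
    work <- canvas[, px0 + seq_len(S), , drop = FALSE]
    mm <- matrix(0L, S, S)
    for (cc in seam) mm[, (cc - w0) * 8L + seq_len(8L)] <- 1L
    gen <- .cascade_generate(model, .as_timage(work), maskSpec(mm),
                             seed + it + 1L)
    for (cc in seam) {
      px <- (cc - 1L) * 8L + seq_len(8L)
      canvas[, px, ] <- gen[, (cc - w0) * 8L + seq_len(8L), , drop = FALSE]
    }
    log <- rbind(log, data.frame(iteration = it + 1L, phase = "seam",
                                 committed = length(seam), remaining = 0L))
  }
  gm <- matrix(0L, nrow(canvas), ncol(canvas))
  gm[, ncol(ld) + seq_len(gapPx)] <- 1L
  resImg <- .as_timage(canvas)
  cells <- if (is.null(embedding))
    CellMap(matrix(numeric(0), 0, 2), factor(character(0)))
  else {
    obs <- readImage(.as_timage(canvas * rep(1 - gm, 3)), embedding,
                     provenance = "observed")
    genImg <- .as_timage(canvas); genImg@occupancy[] <- FALSE
    gen <- readImage(genImg, embedding, mask = gm, provenance = "generated")
    .bind_cells(obs, gen)
  }
  new("GenerationResult", image = resImg, cells = cells, mask = maskSpec(gm),
      seed = as.integer(seed), log = log)
}

#' Distance-aware blending weights for 3D imputation
#'
#' For a target axial position strictly between two endpoint slices,
#' returns weights inversely proportional to the distances:
#' \code{wPrev = dNext / (dPrev + dNext)}, \code{wNext = dPrev / (dPrev +
#' dNext)}; they sum to one and swap under reflection of the target.
#'
#' @param zi,zj endpoint positions with \code{zi < zj}.
#' @param zt target position in (zi, zj).
#' @return named numeric c(wPrev, wNext).
#' @export
blendWeights <- function(zi, zj, zt) {
  if (!(zi < zt && zt < zj)) stop("target position outside (zi, zj)")
  dPrev <- zt - zi; dNext <- zj - zt
  c(wPrev = dNext / (dPrev + dNext), wNext = dPrev / (dPrev + dNext))
}

#' Impute intermediate slices of a 3D series
#'
#' For each target axial position, linearly combines the spatial prompts of
#' the two bracketing observed slices with the distance-aware weights of
#' \code{\link{blendWeights}} and generates the full slice with the cascade
#' (full-frame mask). Targets are generated independently with per-target
#' seeds derived from the global seed and the position, so the generation
#' order has no effect.
#'
#' @param series a \linkS4class{SliceSeries} of \linkS4class{TissueImage}
#'   slices.
#' @param targets axial positions to generate; each must be bracketed by
#'   (or coincide with) observed slices.
#' @param model a trained \code{cascadeModel}.
#' @param seed integer global seed.
#' @return A \linkS4class{SliceSeries} containing the observed and the
#'   generated slices, merged in axial order.
#' @export
impute3d <- function(series, targets, model, seed = 0L) {
  pos <- series@positions
  S <- model$imageSize
  fullMask <- rectMask(S, S, c(0, 0, 1, 1))
  promptOf <- function(k) buildSpatialPrompt(imageData(series@slices[[k]]),
                                             fullMask, model$prompt)
  prompts <- lapply(seq_along(pos), promptOf)
  outPos <- pos
  outSlices <- series@slices
  for (zt in targets) {
    iPrev <- which(pos <= zt)
    iNext <- which(pos >= zt)
    if (!length(iPrev) || !length(iNext))
      stop("target ", zt, " outside the endpoint bracket")
    iPrev <- max(iPrev); iNext <- min(iNext)
    P <- if (iPrev == iNext) prompts[[iPrev]] else {
      w <- blendWeights(pos[iPrev], pos[iNext], zt)
      w[1] * prompts[[iPrev]] + w[2] * prompts[[iNext]]
    }
    blank <- .as_timage(array(0, c(S, S, 3)))
    gen <- .cascade_generate(model, blank, fullMask,
                             .hash_seed(seed, zt), P = P)
    outPos <- c(outPos, zt)
    outSlices <- c(outSlices, list(.as_timage(gen)))
  }
  ord <- order(outPos)
  keep <- !duplicated(outPos[ord])
  SliceSeries(outPos[ord][keep], outSlices[ord][keep])
}
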