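#' Construct a MaskSpec from a binary matrix
#'
#' Computes the normalized bounding box (x1, y1, x2, y2) of the mask
#' support, its aspect ratio and its area fraction.
#'
#' @param mask H x W matrix of 0/1 (or logical); 1 marks pixels to generate.
#' @return A \linkS4class{MaskSpec}.
#' @export
maskSpec <- function(mask) {
  m <- mask
  if (is.logical(m)) m <- m * 1L
  if (!all(m %in% c(0, 1))) stop("mask must be binary")
  storage.mode(m) <- "integer"
  H <- nrow(m); W <- ncol(m)
  box <- c(0, 0, 0, 0)
  aspect <- 0
  if (any(m > 0L)) {
    rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
    box <- c((cc[1] - 1) / W, (rr[1] - 1) / H, cc[2] / W, rr[2] / H)
    aspect <- (box[3] - box[1]) / (box[4] - box[2])
  }
  new("MaskSpec", mask = m, box = box, aspect = aspect, area = mean(m))
}

#' Rectangular generation mask
#'
#' @param H,W frame size in pixels.
#' @param box normalized (x1, y1, x2, y2) rectangle in [0,1].
#' @return A \linkS4class{MaskSpec}.
#' @export
rectMask <- function(H, W, box) {
  m <- matrix(0L, H, W)
  cs <- max(1L, floor(box[1] * W) + 1L); ce <- min(W, ceiling(box[3] * W))
  rs <- max(1L, floor(box[2] * H) + 1L); re <- min(H, ceiling(box[4] * H))
  if (ce >= cs && re >= rs) m[rs:re, cs:ce] <- 1L
  maskSpec(m)
}

#' Mask out the generation region of an image
#'
#' \code{I_masked = I * (1 - M)}: masked pixels are zeroed (and marked
#' unoccupied), visible pixels pass through unchanged.
#'
#' @param img a \linkS4class{TissueImage}.
#' @param mask a \linkS4class{MaskSpec} (or binary matrix) of matching shape.
#' @return The masked \linkS4class{TissueImage}.
#' @export
applyMask <- function(img, mask) {
  m <- if (is(mask, "MaskSpec")) mask@mask else mask
  if (!all(m %in% c(0, 1))) stop("mask must be binary")
  d <- imageData(img)
  if (!all(dim(m) == dim(d)[1:2])) stop("mask/image shape mismatch")
  keep <- 1 - m
  for (ch in 1:3) d[, , ch] <- d[, , ch] * keep
  new("TissueImage", data = d, occupancy = occupancyMask(img) & (m == 0L),
      background = img@background)
}

#' Downsample a pixel mask to latent resolution
#'
#' Deterministic block-max semantics: a latent pixel is masked iff any pixel
#' it covers is masked, so unknown pixels are never treated as known.
#'
#' @param mask a \linkS4class{MaskSpec} or binary matrix.
#' @param factor spatial downsampling factor (default 8).
#' @return binary matrix of size (H/factor) x (W/factor).
#' @export
downsampleMask <- function(mask, factor = 8L) {
  m <- if (is(mask, "MaskSpec")) mask@mask else mask
  if (!all(m %in% c(0, 1))) stop("mask must be binary")
  H <- nrow(m); W <- ncol(m)
  Hz <- H %/% factor; Wz <- W %/% factor
  out <- matrix(0L, Hz, Wz)
  for (i in seq_len(Hz)) for (j in seq_len(Wz)) {
    out[i, j] <- as.integer(any(m[(i - 1L) * factor + seq_len(factor),
                                  (j - 1L) * factor + seq_len(factor)] > 0L))
  }
  out
}
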