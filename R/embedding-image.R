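#' Paint cell embeddings onto a tissue image
#'
#' Produces the 3-channel continuous cell-map image: every occupied pixel of
#' the grid carries its cell's normalized 3-D embedding; empty pixels carry
#' the background value (default 0 in all channels).
#'
#' @param grid a \linkS4class{PixelGrid} indexing cells.
#' @param z \code{Embedding3} (or N x 3 normalized matrix) aligned with the
#'   grid's companion cell table: row i holds the embedding of cell i.
#' @param background per-channel background value (length 3, default 0).
#' @return A \linkS4class{TissueImage}.
#' @export
paintImage <- function(grid, z, background = c(0, 0, 0)) {
  if (inherits(z, "Embedding3")) z <- z$normalized
  px <- gridPixels(grid)
  H <- nrow(px); W <- ncol(px)
  occ <- px > 0L
  idx <- px[occ]
  if (length(idx) && max(idx) > nrow(z)) stop("grid/embedding shape mismatch")
  d <- array(rep(background, each = H * W), c(H, W, 3))
  for (ch in 1:3) {
    plane <- d[, , ch]
    plane[occ] <- z[idx, ch]
    d[, , ch] <- plane
  }
  new("TissueImage", data = d, occupancy = occ,
      background = as.numeric(background))
}

#' Decode a tissue image back to typed cells
#'
#' Every candidate pixel (occupied pixels, plus all pixels under
#' \code{mask} if given, e.g. a generation mask) is classified as empty or
#' cell-bearing: a pixel is called empty when its channel vector is nearer
#' the background than any per-type codebook embedding by at least
#' \code{tau}. Cell-bearing pixels are decoded through the autoencoder to
#' soft type probabilities and an argmax label; pixel centers become the
#' cell coordinates (grid units).
#'
#' @param img a \linkS4class{TissueImage}.
#' @param model a trained \code{typeEmbedding}.
#' @param mask optional \linkS4class{MaskSpec} (or binary matrix) of pixels
#'   to decode in addition to occupied ones.
#' @param tau empty-vs-cell margin on Euclidean distance (default 0.05).
#' @param provenance provenance flag for the decoded cells.
#' @return A \linkS4class{CellMap} (markers empty; z left NA).
#' @export
readImage <- function(img, model, mask = NULL, tau = 0.05,
                      provenance = "observed") {
  d <- imageData(img)
  H <- dim(d)[1]; W <- dim(d)[2]
  cand <- occupancyMask(img)
  if (!is.null(mask)) {
    mm <- if (is(mask, "MaskSpec")) mask@mask else mask
    cand <- cand | (mm > 0)
  }
  idx <- which(cand)
  if (!length(idx))
    return(CellMap(coords = matrix(numeric(0), 0, 2),
                   cellType = factor(character(0), levels = model$labels)))
  V <- cbind(d[, , 1][idx], d[, , 2][idx], d[, , 3][idx])
  bg <- img@background
  dBg <- sqrt(rowSums(sweep(V, 2, bg)^2))
  cb <- model$codebook
  dCb <- matrix(Inf, length(idx), nrow(cb))
  for (k in seq_len(nrow(cb)))
    dCb[, k] <- sqrt(rowSums(sweep(V, 2, cb[k, ])^2))
  isCell <- dBg + tau > apply(dCb, 1, min)
  idx <- idx[isCell]
  if (!length(idx))
    return(CellMap(coords = matrix(numeric(0), 0, 2),
                   cellType = factor(character(0), levels = model$labels)))
  V <- V[isCell, , drop = FALSE]
  dec <- decodeCells(V, model)
  CellMap(coords = cbind((idx - 1L) %/% H + 0.5,   # x = column center
                         (idx - 1L) %% H + 0.5),   # y = row center
          cellType = factor(dec$types, levels = model$labels),
          provenance = provenance)
}

#' Build a tissue image from a raw cell table
#'
#' Convenience pipeline: kNN graph, GCN soft typing, autoencoder embedding,
#' rasterization and painting.
#'
#' @param cells a \linkS4class{CellMap} with coordinates in [0, dOrig).
#' @param gcn a trained \code{gcnModel}.
#' @param ae a trained \code{typeEmbedding}.
#' @param dOrig world frame side; default the smallest power-of-two bound.
#' @param size image side in pixels (default 64).
#' @param k graph neighbor count (default the GCN training default, 20).
#' @return list with \code{image} (\linkS4class{TissueImage}), \code{grid},
#'   \code{probs} and \code{embedding}.
#' @export
cellsToImage <- function(cells, gcn, ae, dOrig, size = 64L, k = 20L) {
  graph <- buildKnnGraph(cells, k = k)
  probs <- gcnForward(graph, gcn)$probs
  emb <- encodeCells(probs, ae)
  grid <- rasterizeCells(cells, dOrig, size)
  list(image = paintImage(grid, emb), grid = grid, probs = probs,
       embedding = emb)
}
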