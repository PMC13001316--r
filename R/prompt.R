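## Spatial prompt: a residual convolutional encoder maps the masked image to
## an 8 x 8 feature map, flattened to a fixed sequence of 64 tokens enriched
## with a 2-D positional encoding and layer-normalized; the mask's geometric
## parameters (x1, y1, x2, y2, aspect, area) pass through a single linear
## layer and are concatenated to every token along the feature axis.

#' Create a spatial prompt encoder
#'
#' @param imageSize input side length in pixels (divisible by 8; the
#'   encoder always reduces to an 8 x 8 map, hence 64 tokens).
#' @param featDim image-feature channels at the 8 x 8 stage (the
#'   production-scale configuration uses 736; toy default 32).
#' @param coordDim width of the encoded mask-geometry block (default 8).
#' @param base first-stage channel width.
#' @param seed integer seed for initialization.
#' @return A \code{spatialPromptEncoder} model; its \code{tokenDim} field is
#'   \code{featDim + 4 + coordDim}.
#' @export
spatialPromptEncoder <- function(imageSize = 64L, featDim = 32L,
                                 coordDim = 8L, base = 16L, seed = 0L) {
  nStages <- as.integer(round(log2(imageSize / 8L)))
  if (8L * 2L^nStages != imageSize) stop("imageSize must be 8 * 2^n")
  set.seed(seed)
  p <- list(in.W = .he_conv(base, 3L, 3L), in.b = numeric(base))
  cin <- base
  for (s in seq_len(nStages)) {
    cout <- if (s == nStages) featDim else min(featDim, cin * 2L)
    p[[sprintf("s%d.W", s)]] <- .he_conv(cout, cin, 3L)
    p[[sprintf("s%d.b", s)]] <- numeric(cout)
    rbp <- rb_params(cout, cout)
    p <- c(p, setNames(rbp, paste0(sprintf("rb%d", s), ".", names(rbp))))
    cin <- cout
  }
  p$ln.g <- rep(1, featDim + 4L)
  p$ln.b <- numeric(featDim + 4L)
  p$co.W <- .he_lin(6L, coordDim)
  p$co.b <- numeric(coordDim)
  structure(list(params = p, imageSize = imageSize, featDim = featDim,
                 coordDim = coordDim, base = base, nStages = nStages,
                 tokenDim = featDim + 4L + coordDim, seed = seed),
            class = "spatialPromptEncoder")
}

# tape forward: img node (H, W, 3), coords length-6 numeric -> (64, tokenDim)
.prompt_forward <- function(enc, pn, imgNode, coords) {
  h <- ad_silu(ad_conv2d(imgNode, pn$in.W, pn$in.b, 3L))
  for (s in seq_len(enc$nStages)) {
    h <- ad_silu(ad_conv2d(h, pn[[sprintf("s%d.W", s)]],
                           pn[[sprintf("s%d.b", s)]], 3L, stride = 2L))
    h <- rb_forward(pn, sprintf("rb%d", s), h)
  }
  pe <- ad_leaf(matrix(positionalEncoding(8L, 8L), 64L, 4L))
  tok <- ad_concat_cols(ad_reshape(h, c(64L, enc$featDim)), pe)
  tok <- ad_layernorm(tok, pn$ln.g, pn$ln.b)
  cvec <- ad_bias_rows(ad_matmul(ad_leaf(matrix(coords, 1L)), pn$co.W),
                       pn$co.b)
  ctile <- .ad_node(matrix(ad_value(cvec), 64L, length(ad_value(cvec)),
                           byrow = TRUE), list(cvec),
                    function(g) list(matrix(colSums(g), 1L)))
  ad_concat_cols(tok, ctile)
}

#' Build the spatial prompt for a masked image
#'
#' @param maskedImg the masked \linkS4class{TissueImage} (or (H, W, 3)
#'   array), i.e. \code{I * (1 - M)}.
#' @param mask the \linkS4class{MaskSpec} whose geometry (normalized box,
#'   aspect ratio, area) forms the coordinate block.
#' @param encoder a \code{spatialPromptEncoder}.
#' @return numeric matrix of 64 tokens x \code{encoder$tokenDim}.
#' @export
buildSpatialPrompt <- function(maskedImg, mask, encoder) {
  x <- if (is(maskedImg, "TissueImage")) imageData(maskedImg) else maskedImg
  coords <- c(mask@box, mask@aspect, mask@area)
  ad_tape_start()
  ad_value(.prompt_forward(encoder, ad_params(encoder$params), ad_leaf(x),
                           coords))
}
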