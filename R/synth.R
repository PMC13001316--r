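#' Specify a synthetic layered tissue
#'
#' Describes a seeded, download-free synthetic tissue emulating the
#' statistical structure of multiplexed-imaging cell maps: spatially layered
#' cell types (stripes, concentric rings, or a crypt-like disc), per-type
#' Gaussian marker-intensity profiles, per-type planar densities, and an
#' optional axial gradient for slice series.
#'
#' @param frameSize side length of the square frame (micrometres).
#' @param K number of cell types.
#' @param layout \code{"stripes"} (horizontal bands), \code{"rings"}
#'   (concentric annuli) or \code{"disc"} (type-2..K discs on a type-1
#'   background).
#' @param density cells per square unit, recycled to length K (per layer).
#' @param nMarkers number of biomarkers m.
#' @param markerSep separation of per-type marker means (in units of the
#'   within-type standard deviation); means are placed deterministically on
#'   a circle in marker space.
#' @param markerSd within-type marker standard deviation (diagonal
#'   covariance).
#' @param markerMeans optional K x nMarkers matrix overriding the
#'   deterministic mean placement.
#' @param mixWidth boundary-mixing length scale (units); a cell at distance
#'   d from a layer boundary flips to the adjacent layer's type with
#'   probability \code{plogis(-d / mixWidth)}. 0 disables mixing.
#' @param proportions optional per-type area proportions (stripe heights /
#'   annulus areas); default equal.
#' @param discCenter,discRadius disc layout geometry (normalized center,
#'   radius in units).
#' @param typeNames labels; default \code{paste0("type", 1:K)}.
#' @return A \code{TissueSpec} list.
#' @export
tissueSpec <- function(frameSize = 1000, K = 5, layout = c("stripes", "rings", "disc"),
                       density = 0.01, nMarkers = 3, markerSep = 3,
                       markerSd = 1, markerMeans = NULL, mixWidth = 10,
                       proportions = NULL, discCenter = c(0.5, 0.5),
                       discRadius = 0.2 * frameSize,
                       typeNames = paste0("type", seq_len(K))) {
  layout <- match.arg(layout)
  if (any(density <= 0)) stop("densities must be positive")
  if (is.null(proportions)) proportions <- rep(1 / K, K)
  proportions <- proportions / sum(proportions)
  if (is.null(markerMeans)) {
    ang <- 2 * pi * (seq_len(K) - 1) / K
    markerMeans <- matrix(0, K, nMarkers)
    markerMeans[, 1] <- markerSep * markerSd * cos(ang)
    if (nMarkers >= 2) markerMeans[, 2] <- markerSep * markerSd * sin(ang)
    if (nMarkers >= 3) markerMeans[, 3] <- markerSep * markerSd *
        (seq_len(K) - 1) / max(1, K - 1)
  }
  structure(list(frameSize = frameSize, K = K, layout = layout,
                 density = rep(density, length.out = K), nMarkers = nMarkers,
                 markerSd = rep(markerSd, length.out = nMarkers),
                 markerMeans = markerMeans, mixWidth = mixWidth,
                 proportions = proportions, discCenter = discCenter,
                 discRadius = discRadius, typeNames = typeNames),
            class = "TissueSpec")
}

# Layer index of each point and signed distance to the nearest layer
# boundary, for each supported layout.
.layer_of <- function(spec, xy) {
  fs <- spec$frameSize
  cum <- cumsum(spec$proportions)
  if (spec$layout == "stripes") {
    frac <- xy[, 2] / fs
    layer <- findInterval(frac, cum, left.open = TRUE) + 1L
    layer <- pmin(layer, spec$K)
    bnd <- c(0, cum) * fs
    dist <- pmin(abs(xy[, 2] - bnd[layer]), abs(bnd[layer + 1L] - xy[, 2]))
  } else if (spec$layout == "rings") {
    ctr <- spec$discCenter * fs
    r <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
    rmax <- fs / 2
    edges <- sqrt(cum) * rmax                 # equal-area annuli when equal props
    layer <- findInterval(r, edges, left.open = TRUE) + 1L
    layer <- pmin(layer, spec$K)
    bnd <- c(0, edges)
    dist <- pmin(abs(r - bnd[layer]), abs(bnd[layer + 1L] - r))
    dist[layer == spec$K] <- abs(r - bnd[spec$K])[layer == spec$K]
  } else {                                    # disc: type 2 inside, 1 outside
    ctr <- spec$discCenter * fs
    r <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
    layer <- ifelse(r <= spec$discRadius, 2L, 1L)
    dist <- abs(r - spec$discRadius)
  }
  list(layer = layer, dist = dist)
}

#' Draw a synthetic tissue
#'
#' Cells are placed by homogeneous Poisson sampling per layer, typed by
#' layer with logistic boundary mixing, and given markers from their type's
#' Gaussian profile. Fully seeded and deterministic.
#'
#' @param spec a \code{\link{tissueSpec}}.
#' @param seed integer seed.
#' @return A \linkS4class{CellMap}.
#' @export
makeTissue <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "TissueSpec"))
  set.seed(seed)
  fs <- spec$frameSize
  areas <- spec$proportions * fs^2
  if (spec$layout == "disc") {
    adisc <- pi * spec$discRadius^2
    if (adisc <= 0 || adisc >= fs^2) stop("zero-area layer in disc layout")
    areas <- c(fs^2 - adisc, rep(adisc, spec$K - 1L))
  }
  if (any(areas <= 0)) stop("zero-area layer")
  nPer <- rpois(spec$K, spec$density * areas)
  n <- sum(nPer)
  xy <- matrix(NA_real_, n, 2)
  pos <- 0L
  for (k in seq_len(spec$K)) {
    if (nPer[k] == 0L) next
    got <- 0L
    while (got < nPer[k]) {                    # rejection-sample within layer k
      m <- max(64L, 2L * (nPer[k] - got))
      cand <- cbind(runif(m, 0, fs), runif(m, 0, fs))
      keep <- which(.layer_of(spec, cand)$layer == k)
      keep <- head(keep, nPer[k] - got)
      if (length(keep)) {
        xy[pos + got + seq_along(keep), ] <- cand[keep, , drop = FALSE]
        got <- got + length(keep)
      }
    }
    pos <- pos + nPer[k]
  }
  info <- .layer_of(spec, xy)
  type <- info$layer
  if (spec$mixWidth > 0) {
    pFlip <- stats::plogis(-info$dist / spec$mixWidth)
    flip <- runif(n) < pFlip
    nb <- ifelse(type == spec$K, type - 1L,
                 ifelse(type == 1L, 2L, type + sample(c(-1L, 1L), n, TRUE)))
    type[flip] <- nb[flip]
  }
  mk <- spec$markerMeans[type, , drop = FALSE] +
    matrix(rnorm(n * spec$nMarkers), n) %*% diag(spec$markerSd, spec$nMarkers)
  CellMap(coords = xy,
          cellType = factor(spec$typeNames[type], levels = spec$typeNames),
          markers = mk)
}

#' Draw an axially varying slice series
#'
#' Interpolates a tissue specification linearly along z between two endpoint
#' conditions (type proportions and/or disc radius) and draws each slice
#' independently with its interpolated spec, emulating smooth slice-to-slice
#' biological variation in serial sections.
#'
#' @param spec base \code{\link{tissueSpec}}.
#' @param positions strictly increasing axial positions (micrometres).
#' @param proportionsEnd optional type proportions at the last position
#'   (start = \code{spec$proportions}).
#' @param discRadiusEnd optional disc radius at the last position.
#' @param seed integer seed; slice i uses \code{seed + i}.
#' @return A \linkS4class{SliceSeries} of \linkS4class{CellMap} slices with
#'   their z fields set.
#' @export
makeSliceSeries <- function(spec, positions, proportionsEnd = NULL,
                            discRadiusEnd = NULL, seed = 0L) {
  if (length(positions) < 2L) stop("need at least two positions")
  zr <- range(positions)
  slices <- vector("list", length(positions))
  for (i in seq_along(positions)) {
    w <- if (diff(zr) == 0) 0 else (positions[i] - zr[1]) / diff(zr)
    sp <- spec
    if (!is.null(proportionsEnd)) {
      p <- (1 - w) * spec$proportions + w * proportionsEnd
      sp$proportions <- p / sum(p)
    }
    if (!is.null(discRadiusEnd))
      sp$discRadius <- (1 - w) * spec$discRadius + w * discRadiusEnd
    sl <- makeTissue(sp, seed = seed + i)
    sl@z[] <- positions[i]
    slices[[i]] <- sl
  }
  SliceSeries(positions, slices)
}

#' Apply a controlled corruption to a cell table
#'
#' Used to verify that each fidelity metric degrades under its matched
#' corruption. Severity 0 is the exact identity.
#'
#' @param cells a \linkS4class{CellMap}.
#' @param mode one of \code{"type_shuffle"} (a fraction \code{severity} of
#'   cells get randomly permuted labels), \code{"type_dropout"} (each cell
#'   of \code{type} is removed with probability \code{severity}),
#'   \code{"jitter"} (coordinates perturbed by Gaussian noise of sd
#'   \code{severity * scale}), \code{"channel_shift"} (all marker values
#'   shifted by \code{severity * shift}).
#' @param severity corruption rate in [0, 1].
#' @param seed integer seed.
#' @param type target type for \code{type_dropout} (default: first level).
#' @param scale jitter length scale (units), default 20.
#' @param shift channel-shift magnitude, default 1.
#' @return The corrupted \linkS4class{CellMap}.
#' @export
corruptCells <- function(cells, mode, severity, seed = 0L, type = NULL,
                         scale = 20, shift = 1) {
  if (severity < 0 || severity > 1) stop("severity must lie in [0, 1]")
  if (severity == 0) return(cells)
  set.seed(seed)
  n <- nCells(cells)
  switch(mode,
    type_shuffle = {
      m <- round(severity * n)
      sel <- sample.int(n, m)
      lv <- cells@cellType
      lv[sel] <- lv[sel][sample.int(m)]
      cells@cellType <- lv
      cells
    },
    type_dropout = {
      if (is.null(type)) type <- levels(cellTypes(cells))[1]
      hit <- cellTypes(cells) == type & runif(n) < severity
      if (severity >= 1) hit <- cellTypes(cells) == type
      cells[!hit]
    },
    jitter = {
      cells@coords <- cells@coords + matrix(rnorm(2 * n, 0, severity * scale), n)
      cells
    },
    channel_shift = {
      cells@markers <- cells@markers + severity * shift
      cells
    },
    stop("unknown corruption mode: ", mode)
  )
}

#' Shift the channels of a tissue image
#'
#' Image-level analogue of the \code{channel_shift} corruption: adds a
#' constant to every occupied pixel's channels, clamped to [0, 1].
#'
#' @param img a \linkS4class{TissueImage}.
#' @param severity shift fraction in [0, 1].
#' @param shift per-channel shift at severity 1 (recycled to 3).
#' @return The shifted \linkS4class{TissueImage}.
#' @export
shiftImageChannels <- function(img, severity, shift = c(0.3, 0.3, 0.3)) {
  if (severity == 0) return(img)
  shift <- rep(shift, length.out = 3)
  d <- imageData(img)
  occ <- occupancyMask(img)
  for (ch in 1:3) {
    plane <- d[, , ch]
    plane[occ] <- pmin(1, pmax(0, plane[occ] + severity * shift[ch]))
    d[, , ch] <- plane
  }
  img@data <- d
  img
}
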