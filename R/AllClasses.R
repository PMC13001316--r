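#' @import methods
#' @importFrom stats rnorm runif rpois sd kmeans dist cor quantile setNames
#' @importFrom utils head read.csv write.csv
NULL

#' CellMap: a table of typed, spatially resolved cells
#'
#' The universal currency of the package: one row per cell, carrying its
#' planar centroid, an optional axial position, a categorical cell-type label
#' drawn from a declared label set, a fixed-length vector of biomarker
#' intensities (protein or mRNA), and a provenance flag distinguishing
#' observed from generated cells.
#'
#' @slot coords numeric matrix, N x 2, columns x (column direction) and y
#'   (row direction); origin top-left, 0-based world coordinates in dataset
#'   units (typically micrometres).
#' @slot z numeric vector of axial positions (micrometres) or NA for planar
#'   data.
#' @slot cellType factor of length N; levels are the declared label set.
#' @slot markers numeric matrix, N x m, biomarker intensities.
#' @slot cellId integer vector of unique cell identifiers.
#' @slot provenance factor with levels \code{observed}, \code{generated}.
#' @export
setClass("CellMap", representation(
  coords = "matrix", z = "numeric", cellType = "factor",
  markers = "matrix", cellId = "integer", provenance = "factor"
))

setValidity("CellMap", function(object) {
  n <- nrow(object@coords)
  msg <- character()
  if (ncol(object@coords) != 2L) msg <- c(msg, "coords must have 2 columns")
  if (length(object@cellType) != n) msg <- c(msg, "cellType length mismatch")
  if (nrow(object@markers) != n) msg <- c(msg, "markers row mismatch")
  if (length(object@cellId) != n) msg <- c(msg, "cellId length mismatch")
  if (length(object@z) != n) msg <- c(msg, "z length mismatch")
  if (length(object@provenance) != n) msg <- c(msg, "provenance length mismatch")
  if (anyDuplicated(object@cellId)) msg <- c(msg, "cellId must be unique")
  if (n > 0 && !all(is.finite(object@coords))) msg <- c(msg, "coords must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a CellMap
#'
#' @param coords N x 2 numeric matrix of (x, y) centroids.
#' @param cellType character or factor of cell-type labels; pass a factor to
#'   declare a label set larger than the observed one.
#' @param markers N x m numeric matrix of marker intensities.
#' @param cellId integer identifiers (default \code{seq_len(N)}).
#' @param z axial positions in micrometres (default NA).
#' @param provenance \code{"observed"} or \code{"generated"}, recycled.
#' @return A \linkS4class{CellMap}.
#' @export
CellMap <- function(coords, cellType, markers = NULL, cellId = NULL,
                    z = NULL, provenance = "observed") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  n <- nrow(coords)
  if (!is.factor(cellType)) cellType <- factor(cellType)
  if (is.null(markers)) markers <- matrix(numeric(0), nrow = n, ncol = 0)
  markers <- as.matrix(markers)
  storage.mode(markers) <- "double"
  if (is.null(cellId)) cellId <- seq_len(n)
  if (is.null(z)) z <- rep(NA_real_, n)
  prov <- factor(rep(provenance, length.out = n),
                 levels = c("observed", "generated"))
  new("CellMap", coords = coords, z = as.numeric(z), cellType = cellType,
      markers = markers, cellId = as.integer(cellId), provenance = prov)
}

#' PixelGrid: a raster of cell indices
#'
#' An H x W integer raster in which each pixel holds the row index of the
#' cell occupying it in a companion \linkS4class{CellMap}, or 0 for an empty
#' pixel. Carries the scaling metadata used by the linear projection and a
#' log of cells dropped during conflict resolution.
#'
#' @slot pixels integer matrix H x W; 0 = empty, otherwise a CellMap row index.
#' @slot dOrig numeric, side length of the source frame (world units).
#' @slot dNew numeric, side length of the raster in pixels.
#' @slot dropped integer vector of CellMap row indices dropped at this stage.
#' @export
setClass("PixelGrid", representation(
  pixels = "matrix", dOrig = "numeric", dNew = "numeric", dropped = "integer"
))

setValidity("PixelGrid", function(object) {
  px <- object@pixels[object@pixels > 0L]
  if (anyDuplicated(px)) return("a cell index appears in more than one pixel")
  TRUE
})

#' MaskSpec: a binary generation mask with box metadata
#'
#' @slot mask integer matrix H x W in {0,1}; 1 marks pixels to generate.
#' @slot box numeric length-4 normalized bounding box (x1, y1, x2, y2) of the
#'   mask support in [0,1].
#' @slot aspect numeric, box aspect ratio (width/height).
#' @slot area numeric, masked fraction of the frame.
#' @export
setClass("MaskSpec", representation(
  mask = "matrix", box = "numeric", aspect = "numeric", area = "numeric"
))

setValidity("MaskSpec", function(object) {
  if (!all(object@mask %in% c(0L, 1L))) return("mask must be binary")
  if (length(object@box) != 4L) return("box must have length 4")
  TRUE
})

#' TissueImage: a three-channel continuous cell-map image
#'
#' @slot data numeric array H x W x 3, channel values in [0,1].
#' @slot occupancy logical matrix H x W; TRUE where a pixel carries a cell.
#' @slot background numeric length-3 value painted on empty pixels.
#' @export
setClass("TissueImage", representation(
  data = "array", occupancy = "matrix", background = "numeric"
))

setValidity("TissueImage", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L || d[3] != 3L) return("data must be H x W x 3")
  if (!all(dim(object@occupancy) == d[1:2])) return("occupancy shape mismatch")
  TRUE
})

#' SliceSeries: an axially ordered set of tissue slices
#'
#' @slot positions numeric vector of strictly increasing axial positions
#'   (micrometres).
#' @slot slices list of \linkS4class{CellMap} or \linkS4class{TissueImage},
#'   one per position.
#' @export
setClass("SliceSeries", representation(positions = "numeric", slices = "list"))

setValidity("SliceSeries", function(object) {
  if (length(object@positions) != length(object@slices))
    return("positions/slices length mismatch")
  if (is.unsorted(object@positions, strictly = TRUE))
    return("positions must be strictly increasing")
  TRUE
})

#' @rdname SliceSeries-class
#' @param positions axial positions.
#' @param slices list of slices.
#' @export
SliceSeries <- function(positions, slices) {
  new("SliceSeries", positions = as.numeric(positions), slices = slices)
}

#' MetricReport: the five generation-fidelity scores
#'
#' @slot scores named numeric vector with entries \code{structure},
#'   \code{density}, \code{composition}, \code{featureAlignment},
#'   \code{neighborhood}, each in [0,1].
#' @slot perType list of per-cell-type breakdowns (per-type density scores,
#'   centroid distances, matched-cluster distances).
#' @slot params list of every hyperparameter used, recorded verbatim.
#' @export
setClass("MetricReport", representation(
  scores = "numeric", perType = "list", params = "list"
))

setValidity("MetricReport", function(object) {
  s <- object@scores
  if (any(s < -1e-9 | s > 1 + 1e-9)) return("scores must lie in [0,1]")
  TRUE
})

#' GenerationResult: output of one generative inference
#'
#' @slot image completed \linkS4class{TissueImage}.
#' @slot cells decoded \linkS4class{CellMap} with provenance flags; cells
#'   with provenance \code{observed} are identical to the input cells.
#' @slot mask the \linkS4class{MaskSpec} (or list of masks) used.
#' @slot seed integer seed that produced the result.
#' @slot log per-iteration log (data.frame).
#' @export
setClass("GenerationResult", representation(
  image = "TissueImage", cells = "CellMap", mask = "ANY",
  seed = "integer", log = "data.frame"
))

setMethod("show", "CellMap", function(object) {
  n <- nrow(object@coords)
  cat(sprintf("CellMap with %d cells, %d marker(s), %d declared type(s)\n",
              n, ncol(object@markers), nlevels(object@cellType)))
  if (n > 0) {
    cat(sprintf("  x: [%.1f, %.1f]  y: [%.1f, %.1f]%s\n",
                min(object@coords[, 1]), max(object@coords[, 1]),
                min(object@coords[, 2]), max(object@coords[, 2]),
                if (all(is.na(object@z))) "" else
                  sprintf("  z: [%.1f, %.1f]", min(object@z), max(object@z))))
    tt <- table(object@cellType)
    cat("  types:", paste(sprintf("%s(%d)", names(tt), tt), collapse = " "), "\n")
    ng <- sum(object@provenance == "generated")
    if (ng > 0) cat(sprintf("  %d generated cell(s)\n", ng))
  }
})

setMethod("show", "PixelGrid", function(object) {
  cat(sprintf("PixelGrid %d x %d (D_orig=%g, D_new=%g): %d cells, %d dropped\n",
              nrow(object@pixels), ncol(object@pixels), object@dOrig,
              object@dNew, sum(object@pixels > 0L), length(object@dropped)))
})

setMethod("show", "TissueImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("TissueImage %d x %d x 3, %d occupied pixel(s)\n",
              d[1], d[2], sum(object@occupancy)))
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport\n")
  for (nm in names(object@scores))
    cat(sprintf("  %-17s %.4f\n", nm, object@scores[[nm]]))
  if (!is.null(object@params$structureBackend))
    cat("  structure backend:", object@params$structureBackend, "\n")
})

setMethod("show", "GenerationResult", function(object) {
  cat(sprintf("GenerationResult (seed %d): %d cells (%d generated)\n",
              object@seed, nrow(object@cells@coords),
              sum(object@cells@provenance == "generated")))
})

setMethod("show", "SliceSeries", function(object) {
  cat(sprintf("SliceSeries with %d slice(s), z = %s\n",
              length(object@positions),
              paste(signif(object@positions, 4), collapse = ", ")))
})

## ---- accessors ----

#' Accessors for CellMap and friends
#'
#' @param x a \linkS4class{CellMap} (or for \code{gridPixels}, a
#'   \linkS4class{PixelGrid}; for \code{imageData}, a
#'   \linkS4class{TissueImage}; for \code{metricScores}, a
#'   \linkS4class{MetricReport}).
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
cellCoords <- function(x) x@coords

#' @rdname accessors
#' @export
cellTypes <- function(x) x@cellType

#' @rdname accessors
#' @export
markerMatrix <- function(x) x@markers

#' @rdname accessors
#' @export
cellIds <- function(x) x@cellId

#' @rdname accessors
#' @export
cellProvenance <- function(x) x@provenance

#' @rdname accessors
#' @export
nCells <- function(x) nrow(x@coords)

#' @rdname accessors
#' @export
gridPixels <- function(x) x@pixels

#' @rdname accessors
#' @export
droppedCells <- function(x) x@dropped

#' @rdname accessors
#' @export
imageData <- function(x) x@data

#' @rdname accessors
#' @export
occupancyMask <- function(x) x@occupancy

#' @rdname accessors
#' @export
metricScores <- function(x) x@scores

#' Subset a CellMap by row index
#'
#' @param x a CellMap.
#' @param i integer or logical index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "CellMap", function(x, i, j, ..., drop = TRUE) {
  new("CellMap", coords = x@coords[i, , drop = FALSE], z = x@z[i],
      cellType = x@cellType[i], markers = x@markers[i, , drop = FALSE],
      cellId = x@cellId[i], provenance = x@provenance[i])
})

#' Coerce a CellMap to data.frame
#'
#' Columns: cell_id, x, y, z, cell_type, provenance, marker_1..marker_m.
#'
#' @param x a CellMap.
#' @param ... ignored.
#' @export
as.data.frame.CellMap <- function(x, ...) {
  df <- data.frame(cell_id = x@cellId, x = x@coords[, 1], y = x@coords[, 2],
                   z = x@z, cell_type = as.character(x@cellType),
                   provenance = as.character(x@provenance))
  m <- x@markers
  if (ncol(m) > 0) {
    colnames(m) <- if (is.null(colnames(m)))
      paste0("marker_", seq_len(ncol(m))) else colnames(m)
    df <- cbind(df, as.data.frame(m))
  }
  df
}
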