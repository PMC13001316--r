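## Coordinate convention used throughout: origin top-left, x = column
## direction, y = row direction, world coordinates 0-based and half-open.
## Pixel (i, j) (0-based) covers [i, i+1) x [j, j+1); its center is at i+0.5.

#' Standardize a tissue frame to an M x M square
#'
#' Brings all cell coordinates into the half-open square [0, M) x [0, M),
#' either by padding (translating the cloud to the origin and extending the
#' frame with empty space) or by cropping (selecting the M x M window that
#' contains the most cells).
#'
#' @param cells a \linkS4class{CellMap}.
#' @param M side length of the target frame (world units, e.g. micrometres).
#' @param mode \code{"pad"} or \code{"crop"}.
#' @param stride candidate-offset stride for the crop search; default
#'   \code{ceiling(M/10)}. Set to 1 for an exact scan.
#' @return A \linkS4class{CellMap} with coordinates in [0, M). In crop mode
#'   cells outside the selected window are removed.
#' @details The crop search maximizes the number of contained cells over a
#'   regular lattice of candidate window offsets (coarse by default); the
#'   densest window wins, ties going to the smallest (y, x) offset.
#' @export
standardizeFrame <- function(cells, M, mode = c("pad", "crop"),
                             stride = NULL) {
  mode <- match.arg(mode)
  if (M <= 0) stop("M must be positive")
  if (nCells(cells) == 0L) stop("empty cell table")
  xy <- cellCoords(cells)
  xy <- sweep(xy, 2, apply(xy, 2, min))       # translate cloud to origin
  span <- apply(xy, 2, max)
  if (mode == "pad") {
    if (any(span >= M))
      stop("cells span ", signif(max(span), 4),
           " >= M; use mode = 'crop'")
    cells@coords[] <- xy
    return(cells)
  }
  if (all(span < M)) {
    warning("region smaller than M in both axes; crop is a no-op")
    cells@coords[] <- xy
    return(cells)
  }
  if (is.null(stride)) stride <- ceiling(M / 10)
  offs <- function(s) if (s <= M) 0 else
    unique(c(seq(0, s - M, by = stride), s - M))
  ox <- offs(span[1]); oy <- offs(span[2])
  best <- c(-1L, 0, 0)
  for (o2 in oy) for (o1 in ox) {
    cnt <- sum(xy[, 1] >= o1 & xy[, 1] < o1 + M &
               xy[, 2] >= o2 & xy[, 2] < o2 + M)
    if (cnt > best[1]) best <- c(cnt, o1, o2)
  }
  keep <- xy[, 1] >= best[2] & xy[, 1] < best[2] + M &
          xy[, 2] >= best[3] & xy[, 2] < best[3] + M
  out <- cells[keep]
  out@coords[, 1] <- xy[keep, 1] - best[2]
  out@coords[, 2] <- xy[keep, 2] - best[3]
  out
}

#' Project cells onto a pixel grid by linear scaling
#'
#' Each cell at world position (x, y) in [0, D_orig) is scaled to
#' (x * D_new / D_orig, y * D_new / D_orig) and assigned to the pixel whose
#' half-open unit square contains the scaled position. When several cells
#' land in one pixel, only the cell whose exact scaled position lies nearest
#' the pixel center (i + 0.5) is retained; ties break to the lowest cell id.
#'
#' @param cells a \linkS4class{CellMap} with coordinates in [0, dOrig).
#' @param dOrig side length of the source frame.
#' @param dNew side length (pixels) of the target grid; must not exceed
#'   \code{dOrig}.
#' @return A \linkS4class{PixelGrid} whose \code{dropped} slot lists the row
#'   indices of conflict-dropped cells.
#' @export
rasterizeCells <- function(cells, dOrig, dNew) {
  if (dNew > dOrig) stop("dNew must not exceed dOrig")
  xy <- cellCoords(cells)
  bad <- which(xy[, 1] < 0 | xy[, 1] >= dOrig | xy[, 2] < 0 | xy[, 2] >= dOrig)
  if (length(bad))
    stop("cell id ", cellIds(cells)[bad[1]], " has coordinates outside [0, dOrig)")
  sx <- xy[, 1] * dNew / dOrig
  sy <- xy[, 2] * dNew / dOrig
  cx <- floor(sx); cy <- floor(sy)                   # 0-based pixel indices
  d2 <- (sx - (cx + 0.5))^2 + (sy - (cy + 0.5))^2    # distance to center
  pix <- cy * dNew + cx                              # linear pixel key
  ord <- order(pix, d2, cellIds(cells))
  keep <- ord[!duplicated(pix[ord])]
  px <- matrix(0L, nrow = dNew, ncol = dNew)
  px[cbind(cy[keep] + 1L, cx[keep] + 1L)] <- keep
  new("PixelGrid", pixels = px, dOrig = as.numeric(dOrig),
      dNew = as.numeric(dNew),
      dropped = as.integer(sort(setdiff(seq_len(nrow(xy)), keep))))
}

# Positions of the Chebyshev ring at radius r around (0,0), row-major order.
.cheby_ring <- function(r) {
  d <- -r:r
  ring <- rbind(cbind(-r, d), cbind(r, d), cbind(d[-c(1, length(d))], -r),
                cbind(d[-c(1, length(d))], r))
  ring[order(ring[, 1], ring[, 2]), , drop = FALSE]
}

#' Downsample a cell raster with nearest-neighbor reassignment
#'
#' Maps each occupied pixel of a grid to the target resolution using
#' nearest-neighbor scaling. When two cells collide at the target
#' resolution, the first claimant (scanning source pixels in row-major
#' order) keeps the pixel and every later cell is reassigned to the nearest
#' available empty pixel, searched over expanding Chebyshev rings
#' (row-major within each ring) up to a configurable radius; beyond the cap
#' the cell is dropped and logged.
#'
#' @param grid a \linkS4class{PixelGrid}.
#' @param target target side length in pixels (at most the current size).
#' @param maxRadius Chebyshev search radius cap (pixels), default 8.
#' @return A \linkS4class{PixelGrid} at the target resolution; its
#'   \code{dropped} slot logs cells dropped at this stage only.
#' @export
downsampleGrid <- function(grid, target, maxRadius = 8L) {
  src <- gridPixels(grid)
  size <- nrow(src)
  if (target > size) stop("target must not exceed the current grid size")
  occ <- which(src > 0L)                       # column-major linear indices
  r0 <- (occ - 1L) %% size                     # 0-based row
  c0 <- (occ - 1L) %/% size                    # 0-based col
  ord <- order(r0, c0)                         # row-major scan order
  r0 <- r0[ord]; c0 <- c0[ord]
  idx <- src[occ][ord]
  nr <- floor(r0 * target / size)
  nc <- floor(c0 * target / size)
  out <- matrix(0L, nrow = target, ncol = target)
  dropped <- integer(0)
  rings <- lapply(seq_len(maxRadius), .cheby_ring)
  for (i in seq_along(idx)) {
    ri <- nr[i] + 1L; ci <- nc[i] + 1L
    if (out[ri, ci] == 0L) { out[ri, ci] <- idx[i]; next }
    placed <- FALSE
    for (ring in rings) {
      rr <- ri + ring[, 1]; cc <- ci + ring[, 2]
      ok <- rr >= 1L & rr <= target & cc >= 1L & cc <= target
      for (j in which(ok)) {
        if (out[rr[j], cc[j]] == 0L) {
          out[rr[j], cc[j]] <- idx[i]; placed <- TRUE; break
        }
      }
      if (placed) break
    }
    if (!placed) dropped <- c(dropped, idx[i])
  }
  new("PixelGrid", pixels = out, dOrig = grid@dNew, dNew = as.numeric(target),
      dropped = as.integer(sort(dropped)))
}

#' Recover the retained cell table from a grid
#'
#' Inverse of \code{\link{rasterizeCells}} up to conflict-dropped cells:
#' returns the sub-table of cells referenced by the grid, with coordinates
#' replaced by their pixel centers (grid units). Row order follows the
#' original table.
#'
#' @param grid a \linkS4class{PixelGrid}.
#' @param cells the companion \linkS4class{CellMap} the grid indexes into.
#' @return A \linkS4class{CellMap} of the retained cells.
#' @export
gridToCells <- function(grid, cells) {
  px <- gridPixels(grid)
  occ <- which(px > 0L)
  idx <- px[occ]
  if (length(idx) && max(idx) > nCells(cells))
    stop("grid references a row outside the cell table")
  ord <- order(idx)
  occ <- occ[ord]; idx <- idx[ord]
  out <- cells[idx]
  out@coords[, 1] <- (occ - 1L) %/% nrow(px) + 0.5   # x = column center
  out@coords[, 2] <- (occ - 1L) %% nrow(px) + 0.5    # y = row center
  out
}

#' Full rasterization pipeline
#'
#' Standardize to an M x M frame, project to a mid-resolution grid, then
#' downsample to the final grid with nearest-neighbor reassignment.
#'
#' @param cells a \linkS4class{CellMap}.
#' @param M frame side (world units).
#' @param mid mid-resolution side (pixels), default 1024.
#' @param final final side (pixels), default 512.
#' @param mode frame standardization mode, \code{"pad"} or \code{"crop"}.
#' @return list with the standardized \code{cells}, the mid-resolution grid
#'   \code{gridMid}, the final \code{grid}, and \code{retention}, the
#'   fraction of standardized cells present in the final grid.
#' @export
rasterizePipeline <- function(cells, M, mid = 1024L, final = 512L,
                              mode = c("pad", "crop")) {
  std <- standardizeFrame(cells, M, match.arg(mode))
  g1 <- rasterizeCells(std, M, mid)
  g2 <- downsampleGrid(g1, final)
  list(cells = std, gridMid = g1, grid = g2,
       retention = sum(gridPixels(g2) > 0L) / nCells(std))
}
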