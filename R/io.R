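#' Read a cell table from CSV/TSV
#'
#' Expects columns \code{cell_id, x, y, cell_type} plus optional \code{z},
#' \code{provenance} and any number of \code{marker_*} columns.
#'
#' @param path file path; delimiter inferred from the extension
#'   (\code{.tsv}/\code{.txt} = tab, otherwise comma).
#' @param markerCols optional character vector naming the marker columns;
#'   default: every column whose name starts with \code{marker}.
#' @param levels optional declared cell-type label set.
#' @return A \linkS4class{CellMap}.
#' @export
readCellTable <- function(path, markerCols = NULL, levels = NULL) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("cell_id", "x", "y", "cell_type")
  if (!all(req %in% names(df)))
    stop("missing required columns: ", paste(setdiff(req, names(df)), collapse = ", "))
  if (is.null(markerCols)) markerCols <- grep("^marker", names(df), value = TRUE)
  ct <- if (is.null(levels)) factor(df$cell_type) else
    factor(df$cell_type, levels = levels)
  CellMap(coords = cbind(df$x, df$y), cellType = ct,
          markers = if (length(markerCols))
            as.matrix(df[, markerCols, drop = FALSE]) else NULL,
          cellId = df$cell_id,
          z = if ("z" %in% names(df)) df$z else NULL,
          provenance = if ("provenance" %in% names(df)) df$provenance else "observed")
}

#' Write a cell table to CSV
#'
#' @param cells a \linkS4class{CellMap}.
#' @param path output path.
#' @export
writeCellTable <- function(cells, path) {
  write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}

#' Write a PixelGrid as a plain-text raster plus JSON sidecar
#'
#' The raster is written as a headerless CSV of integer cell indices
#' (0 = empty); the sidecar records shape, scaling metadata and the drop log.
#'
#' @param grid a \linkS4class{PixelGrid}.
#' @param path output path for the raster; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @export
writeGridMap <- function(grid, path) {
  utils::write.table(grid@pixels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(shape = dim(grid@pixels), d_orig = grid@dOrig,
               d_new = grid@dNew, dropped = grid@dropped)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE), paste0(path, ".json"))
  invisible(path)
}

#' Read a PixelGrid written by writeGridMap
#'
#' @param path raster path (the sidecar \code{paste0(path, ".json")} must
#'   exist).
#' @return A \linkS4class{PixelGrid}.
#' @export
readGridMap <- function(path) {
  px <- as.matrix(read.csv(path, header = FALSE))
  dimnames(px) <- NULL
  storage.mode(px) <- "integer"
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  new("PixelGrid", pixels = px, dOrig = as.numeric(meta$d_orig),
      dNew = as.numeric(meta$d_new), dropped = as.integer(meta$dropped))
}
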