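## Portable on-disk formats for models, images, masks, generation results
## and metric reports: plain-text arrays + JSON descriptors, 8-bit PNG for
## display forms. Nothing here uses R-specific binary serialization, so
## checkpoints remain language-portable.

#' Write a model checkpoint as plain-text arrays plus a JSON descriptor
#'
#' Works for every fitted model in the package (\code{gcnModel},
#' \code{typeEmbedding}, \code{latentCodec}, \code{spatialPromptEncoder},
#' \code{latentUNet}, \code{latentAdapter}, \code{pixelUNet}): each
#' parameter array is written as a headerless CSV under \code{dir/params/},
#' and every non-parameter field (architecture, configuration, stored
#' statistics) goes into \code{dir/model.json}.
#'
#' @param model a fitted model list with a \code{params} element.
#' @param dir checkpoint directory (created if missing).
#' @export
writeModelCheckpoint <- function(model, dir) {
  dir.create(file.path(dir, "params"), showWarnings = FALSE, recursive = TRUE)
  shapes <- list()
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    shapes[[nm]] <- if (is.matrix(p)) dim(p) else length(p)
    utils::write.table(as.vector(p),
                       file.path(dir, "params", paste0(nm, ".csv")),
                       row.names = FALSE, col.names = FALSE)
  }
  meta <- model[setdiff(names(model), "params")]
  meta$.class <- class(model)[1]
  meta$.shapes <- shapes
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(dir, "model.json"))
  invisible(dir)
}

#' Read a model checkpoint written by \code{\link{writeModelCheckpoint}}
#'
#' @param dir checkpoint directory.
#' @return The fitted model list, with its original class.
#' @export
readModelCheckpoint <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "model.json"),
                             simplifyVector = TRUE)
  shapes <- meta$.shapes
  cls <- meta$.class
  meta$.shapes <- NULL
  meta$.class <- NULL
  params <- list()
  for (nm in names(shapes)) {
    v <- utils::read.table(file.path(dir, "params", paste0(nm, ".csv")))[[1]]
    sh <- shapes[[nm]]
    params[[nm]] <- if (length(sh) == 2L) matrix(v, sh[1], sh[2]) else v
  }
  out <- c(list(params = params), meta)
  # restore split indices and similar list columns coerced by JSON
  structure(out, class = cls)
}

#' Write a tissue image as PNG (display form) plus a lossless float sidecar
#'
#' The PNG holds the 8-bit display form (\code{round(255 * value)}); the
#' sidecar \code{paste0(path, ".csv")} holds the exact float channels
#' (H*W rows, columns R,G,B, column-major pixel order) and
#' \code{paste0(path, ".json")} the shape, occupancy and background.
#'
#' @param img a \linkS4class{TissueImage}.
#' @param path output PNG path.
#' @param floats also write the lossless sidecar (default TRUE).
#' @export
writeTissueImage <- function(img, path, floats = TRUE) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required to write PNG images")
  png::writePNG(imageData(img), path)
  if (floats) {
    d <- imageData(img)
    utils::write.table(cbind(as.vector(d[, , 1]), as.vector(d[, , 2]),
                             as.vector(d[, , 3])),
                       paste0(path, ".csv"), sep = ",", row.names = FALSE,
                       col.names = c("R", "G", "B"))
    meta <- list(shape = dim(d), background = img@background,
                 occupancy = which(occupancyMask(img)))
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
               paste0(path, ".json"))
  }
  invisible(path)
}

#' Read a tissue image written by \code{\link{writeTissueImage}}
#'
#' Uses the lossless sidecar when present, otherwise the 8-bit PNG.
#'
#' @param path PNG path.
#' @return A \linkS4class{TissueImage}.
#' @export
readTissueImage <- function(path) {
  if (file.exists(paste0(path, ".csv"))) {
    meta <- jsonlite::fromJSON(paste0(path, ".json"))
    v <- utils::read.csv(paste0(path, ".csv"))
    d <- array(c(v$R, v$G, v$B), meta$shape)
    occ <- matrix(FALSE, meta$shape[1], meta$shape[2])
    occ[meta$occupancy] <- TRUE
    return(new("TissueImage", data = d, occupancy = occ,
               background = as.numeric(meta$background)))
  }
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required to read PNG images")
  .as_timage(png::readPNG(path))
}

#' Read a generation mask from an 8-bit PNG
#'
#' Pixels with value 255 (1.0) mark the region to generate.
#'
#' @param path PNG path (grayscale or RGB; first channel used).
#' @param threshold mask cutoff on [0,1] intensities (default 0.5).
#' @return A \linkS4class{MaskSpec}.
#' @export
readMaskPNG <- function(path, threshold = 0.5) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required to read PNG masks")
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  maskSpec((m > threshold) * 1L)
}

#' Write a generation result to a directory
#'
#' Writes \code{cells.csv} (the decoded cell table), \code{map.png} plus
#' float sidecar (the completed image), \code{mask.png} (255 = generated)
#' and \code{provenance.json} (seed, mask box, per-iteration log).
#'
#' @param result a \linkS4class{GenerationResult}.
#' @param dir output directory (created if missing).
#' @export
writeGenerationResult <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCellTable(result@cells, file.path(dir, "cells.csv"))
  writeTissueImage(result@image, file.path(dir, "map.png"))
  if (is(result@mask, "MaskSpec") &&
      requireNamespace("png", quietly = TRUE))
    png::writePNG(result@mask@mask, file.path(dir, "mask.png"))
  meta <- list(seed = result@seed,
               maskBox = if (is(result@mask, "MaskSpec"))
                 result@mask@box else NULL,
               log = result@log)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "provenance.json"))
  invisible(dir)
}

#' Write a metric report as JSON
#'
#' @param report a \linkS4class{MetricReport}.
#' @param path output path.
#' @export
writeMetricReport <- function(report, path) {
  writeLines(jsonlite::toJSON(list(scores = as.list(metricScores(report)),
                                   perType = report@perType,
                                   params = report@params),
                              auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' Read or write a tissue specification as YAML
#'
#' @param path YAML file.
#' @return \code{readTissueSpec}: a \code{TissueSpec}.
#' @export
readTissueSpec <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for YAML tissue specs")
  v <- yaml::read_yaml(path)
  if (!is.null(v$markerMeans)) v$markerMeans <- do.call(rbind, v$markerMeans)
  do.call(tissueSpec, v)
}

#' @rdname readTissueSpec
#' @param spec a \code{TissueSpec}.
#' @export
writeTissueSpec <- function(spec, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for YAML tissue specs")
  v <- unclass(spec)
  v$markerMeans <- lapply(seq_len(nrow(v$markerMeans)),
                          function(i) as.numeric(v$markerMeans[i, ]))
  yaml::write_yaml(v, path)
  invisible(path)
}
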