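## Field directories (JSON manifest + labels CSV + PNG tiles) and model
## stores (predictor parameters + reference scores as version-stamped
## JSON). These are the on-disk formats the CLI works with.

#' Write a field to a directory
#'
#' Creates \code{manifest.json} (\code{rows}, \code{cols},
#' \code{zone_area_m2}, plus pointers to the label CSV and tile
#' directory), \code{labels.csv} (columns row, col, label with 1 healthy),
#' and one PNG per zone tile under \code{tiles/}.
#'
#' @param field A \linkS4class{FieldGrid}.
#' @param dir Output directory (created if needed).
#' @param writeTiles Write PNG tiles (skipped when the field has none).
#' @return \code{dir}, invisibly.
#' @export
writeFieldDir <- function(field, dir, writeTiles = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- fieldDim(field)
  manifest <- list(rows = d[1L], cols = d[2L], zone_area_m2 = field@zoneArea)
  if (!all(is.na(field@truth))) {
    coords <- which(!is.na(field@truth), arr.ind = TRUE)
    utils::write.csv(data.frame(row = coords[, 1L], col = coords[, 2L],
                                label = field@truth[coords]),
                     file.path(dir, "labels.csv"), row.names = FALSE)
    manifest$labels_csv <- "labels.csv"
  }
  if (writeTiles && length(field@tiles)) {
    tdir <- file.path(dir, "tiles")
    dir.create(tdir, showWarnings = FALSE)
    for (cc in seq_len(d[2L])) for (rr in seq_len(d[1L]))
      png::writePNG(field@tiles[[.zoneIndex(rr, cc, d[1L])]],
                    file.path(tdir, sprintf("r%03d_c%03d.png", rr, cc)))
    manifest$image_dir <- "tiles"
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a field from a directory
#'
#' @param dir A directory written by \code{\link{writeFieldDir}} (or any
#'   directory following the same manifest convention).
#' @param readTiles Load PNG tiles if the manifest points to them.
#' @return A \linkS4class{FieldGrid}.
#' @export
readFieldDir <- function(dir, readTiles = TRUE) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  rows <- as.integer(manifest$rows); cols <- as.integer(manifest$cols)
  truth <- matrix(NA_integer_, rows, cols)
  if (!is.null(manifest$labels_csv)) {
    lab <- utils::read.csv(file.path(dir, manifest$labels_csv))
    truth[cbind(lab$row, lab$col)] <- as.integer(lab$label)
  }
  tiles <- list()
  if (readTiles && !is.null(manifest$image_dir)) {
    tdir <- file.path(dir, manifest$image_dir)
    tiles <- vector("list", rows * cols)
    for (cc in seq_len(cols)) for (rr in seq_len(rows)) {
      f <- file.path(tdir, sprintf("r%03d_c%03d.png", rr, cc))
      if (!file.exists(f)) stop("missing tile image: ", f)
      tl <- png::readPNG(f)
      if (length(dim(tl)) == 3L && dim(tl)[3L] > 3L)
        tl <- tl[, , 1:3, drop = FALSE]  # drop alpha
      tiles[[.zoneIndex(rr, cc, rows)]] <- tl
    }
  }
  FieldGrid(truth = truth, tiles = tiles,
            zoneArea = manifest$zone_area_m2 %||% 4.3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save trained models to a JSON store
#'
#' Serializes the eight directional backends and the reference-set scores
#' (with features) to a single version-stamped JSON file.
#'
#' @param ensemble A \linkS4class{DirectionalEnsemble}.
#' @param ref A \linkS4class{ReferenceSet}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
saveModelStore <- function(ensemble, ref, path) {
  store <- list(
    format = "cropscout-model-store", version = 1L,
    featureNames = ensemble@featureNames,
    backends = lapply(ensemble@backends, function(b) b),
    reference = list(conf = ref@conf,
                     features = unname(ref@features)))
  jsonlite::write_json(store, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load trained models from a JSON store
#'
#' @param path A file written by \code{\link{saveModelStore}}.
#' @return List with elements \code{ensemble} and \code{ref}.
#' @export
loadModelStore <- function(path) {
  store <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
  if (!identical(store$format, "cropscout-model-store"))
    stop("not a cropscout model store: ", path)
  backends <- lapply(store$backends, function(b) {
    b$type <- as.character(b$type)
    if (b$type == "logistic") {
      b$beta <- as.numeric(b$beta)
      b$center <- as.numeric(b$center)
      b$scale <- as.numeric(b$scale)
    }
    b
  })
  ensemble <- new("DirectionalEnsemble", backends = backends,
                  featureNames = as.character(store$featureNames))
  feats <- store$reference$features
  if (is.list(feats)) feats <- do.call(rbind, feats)
  feats <- matrix(as.numeric(feats), nrow = length(store$reference$conf))
  colnames(feats) <- store$featureNames
  ref <- new("ReferenceSet", conf = as.numeric(store$reference$conf),
             features = feats, tiles = list())
  list(ensemble = ensemble, ref = ref)
}

#' Write a mission result to JSON
#'
#' @param result A \linkS4class{MissionResult}.
#' @param path Output file path.
#' @param seed Seed recorded in the metadata block.
#' @return \code{path}, invisibly.
#' @export
writeMissionResult <- function(result, path, seed = NA) {
  out <- list(
    metadata = list(format = "cropscout-mission", version = 1L, seed = seed),
    policy = result@policy, coverage = result@coverage,
    charges = result@charges, relocations = result@relocations,
    path = unname(result@path), batteryTrace = result@batteryTrace,
    predictedMap = unname(result@predictedMap))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
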