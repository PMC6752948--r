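#' Write a rendered scene to disk
#'
#' Writes the multi-channel image as a multi-page 8-bit TIFF, the ground
#' truth as CSV (cluster id, channel, coordinates in nm, AZ id, role) and a
#' JSON scene manifest (field geometry, channels, seed).
#'
#' @param truth a [GroundTruth-class].
#' @param image the matching [StedImage-class].
#' @param dir output directory (created if missing).
#' @param name basename for the three files.
#' @return invisibly, the paths written.
#' @export
writeSceneData <- function(truth, image, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maxval <- 255
  pages <- lapply(seq_along(image@channels),
                  function(k) stedChannel(image, k) / maxval)
  tifPath <- file.path(dir, paste0(name, ".tif"))
  tiff::writeTIFF(pages, tifPath, bits.per.sample = 8L)
  cl <- truth@clusters
  cl$cluster_id <- seq_len(nrow(cl))
  csvPath <- file.path(dir, paste0(name, "_truth.csv"))
  utils::write.csv(cl[, c("cluster_id", "channel", "x_nm", "y_nm", "az",
                          "role", "pair_d_nm")], csvPath, row.names = FALSE)
  spec <- truth@spec
  manifest <- list(fieldSize_nm = spec@fieldSize,
                   pixelSize_nm = spec@pixelSize,
                   channels = spec@channels,
                   referenceChannel = spec@referenceChannel,
                   targetChannel = spec@targetChannel,
                   dTrue_nm = spec@dTrue, jitterSD_nm = spec@jitterSD,
                   nAZ = nrow(truth@azCenters), seed = spec@seed)
  jsonPath <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(tif = tifPath, csv = csvPath, json = jsonPath))
}

#' Read a multi-page TIFF into a StedImage
#'
#' @param path TIFF file; each page becomes one channel.
#' @param pixelSize nm per pixel.
#' @param channels channel names (defaults to `ch1..chN`).
#' @param maxval intensity scale (255 restores 8-bit counts).
#' @param imageId identifier.
#' @return A [StedImage-class].
#' @export
readStedTiff <- function(path, pixelSize = 25.25, channels = NULL,
                         maxval = 255, imageId = basename(path)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (is.null(channels)) channels <- paste0("ch", seq_along(pages))
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    arr[, , k] <- round(pg * maxval)
  }
  new("StedImage", data = arr, pixelSize = pixelSize, channels = channels,
      imageId = imageId)
}

#' Write / read a cluster table CSV
#'
#' Per-channel cluster export with image id, channel, label, centroid,
#' area and peak intensity.
#'
#' @param cm a [ClusterMap-class].
#' @param path CSV path.
#' @return `writeClusterCsv` invisibly returns `path`; `readClusterCsv`
#'   returns a [ClusterMap-class].
#' @export
writeClusterCsv <- function(cm, path) {
  cl <- cm@clusters
  out <- data.frame(image_id = cm@imageId, channel = cm@channel,
                    label = cl$label, x_nm = cl$x_nm, y_nm = cl$y_nm,
                    area_um2 = cl$area_um2, peak = cl$peak,
                    pixel_count = cl$pixel_count)
  attrLine <- sprintf("# pixel_size_nm=%g dim=%d,%d", cm@pixelSize,
                      cm@dim[1], cm@dim[2])
  writeLines(attrLine, path)
  suppressWarnings(utils::write.table(out, path, append = TRUE, sep = ",",
                                      row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' @rdname writeClusterCsv
#' @export
readClusterCsv <- function(path) {
  header <- readLines(path, n = 1)
  ps <- as.numeric(sub(".*pixel_size_nm=([0-9.]+).*", "\\1", header))
  dd <- as.integer(strsplit(sub(".*dim=", "", header), ",")[[1]])
  df <- utils::read.csv(path, skip = 1)
  new("ClusterMap", channel = as.character(df$channel[1]),
      imageId = as.character(df$image_id[1]),
      clusters = df[, c("label", "x_nm", "y_nm", "area_um2", "peak",
                        "pixel_count")],
      pixelSize = ps, dim = dd)
}

#' Write / read EM active-zone annotations as CSV
#'
#' One row per vesicle, AZ-level fields repeated; AZs without vesicles get
#' one row with missing vesicle fields.
#'
#' @param azs list of [AZAnnotation-class].
#' @param path CSV path.
#' @return `writeEmCsv` invisibly returns `path`; `readEmCsv` returns a
#'   list of [AZAnnotation-class].
#' @export
writeEmCsv <- function(azs, path) {
  rows <- lapply(azs, function(az) {
    v <- az@vesicles
    if (!nrow(v))
      v <- data.frame(diameter_nm = NA_real_, membrane_distance_nm = NA_real_)
    data.frame(az_id = az@azId, animal = az@animal, genotype = az@genotype,
               az_length_nm = az@azLength, psd_length_nm = az@psdLength,
               diameter_nm = v$diameter_nm,
               membrane_distance_nm = v$membrane_distance_nm)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEmCsv
#' @export
readEmCsv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, factor(df$az_id, levels = unique(df$az_id))), function(d) {
    v <- d[!is.na(d$diameter_nm), c("diameter_nm", "membrane_distance_nm")]
    rownames(v) <- NULL
    new("AZAnnotation", azId = as.character(d$az_id[1]),
        animal = as.character(d$animal[1]),
        genotype = as.character(d$genotype[1]),
        azLength = d$az_length_nm[1], psdLength = d$psd_length_nm[1],
        vesicles = v)
  })
}
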