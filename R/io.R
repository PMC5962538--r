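#' Read / write grayscale images and centroid tables
#'
#' Images travel as numeric matrices in `[0, 1]`. PNG files are 8-bit;
#' TIFF files are written as 32-bit float, which round-trips intensities
#' exactly and is the format used for probability maps.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param image numeric matrix in `[0, 1]`.
#' @return `read_image()` returns a numeric matrix; writers return the path
#'   invisibly.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  image <- pmin(pmax(image, 0), 1)
  switch(ext,
         png = png::writePNG(image, path),
         tif = ,
         tiff = tiff::writeTIFF(image, path, bits.per.sample = 32L,
                                reduce = FALSE),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' @rdname read_image
#' @param centroids matrix with columns `row`, `col` (0-based).
#' @export
write_centroids <- function(centroids, path) {
  centroids <- as_centroids(centroids)
  utils::write.csv(as.data.frame(centroids), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_image
#' @export
read_centroids <- function(path) {
  df <- utils::read.csv(path)
  as_centroids(df)
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a single archive of the named parameter arrays (R
#' serialisation of the `network_params` tree: `conv1`, `mdlstm1[[1..4]]`
#' with stacked `win`/`rup`/`rleft`/`bias` in gate order i, f1, f2, o, g,
#' `conv2`, `mdlstm2`, `fc_hidden`, `fc_out`). A JSON sidecar
#' (`<path>.json`) records the architecture and initialisation metadata so
#' checkpoints are self-describing.
#'
#' @param params a `network_params` object.
#' @param path checkpoint file path (`.rds`).
#' @return `load_checkpoint()` returns the `network_params`; the saver
#'   returns `path` invisibly.
#' @export
save_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "network_params"))
  saveRDS(params, path)
  jsonlite::write_json(params$meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  params <- readRDS(path)
  stopifnot(inherits(params, "network_params"))
  params
}
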