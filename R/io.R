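# File I/O: MRC2014 volumes, STAR metadata tables, CSV coordinates, JSON
# transforms. All coordinates written to disk follow the package convention:
# 0-based, pixel/voxel-centre origin, (x, y[, z]) ordering.

#' Construct a tomogram object
#'
#' A tomogram is a 3D density volume plus its voxel size. Axis order is
#' (x, y, z) with x the fastest-varying (MRC) axis. Internally density is
#' "mass bright" (protein/lipid dense regions have high values); use
#' `invert = TRUE` in [read_mrc()] when loading conventional cryo-EM contrast.
#'
#' @param data 3D numeric array, dim c(nx, ny, nz).
#' @param voxel_size voxel edge length in Angstrom.
#' @return object of class `tomogram`.
#' @export
tomogram <- function(data, voxel_size) {
  stopifnot(is.array(data), length(dim(data)) == 3, voxel_size > 0)
  structure(list(data = data, voxel_size = voxel_size), class = "tomogram")
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tomogram> %d x %d x %d voxels, %.3g A/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  invisible(x)
}

#' Write a volume as MRC2014 (mode 2, float32, little-endian)
#'
#' @param tomo a [tomogram()] (or 3D array, in which case `voxel_size` is used).
#' @param path output file.
#' @param voxel_size voxel size in Angstrom when `tomo` is a bare array.
#' @export
write_mrc <- function(tomo, path, voxel_size = 1) {
  if (!inherits(tomo, "tomogram")) tomo <- tomogram(tomo, voxel_size)
  d <- dim(tomo$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- as.numeric(tomo$data)
  wi(d)                         # nx ny nz
  wi(2)                         # mode 2 = float32
  wi(c(0, 0, 0))                # nxstart..
  wi(d)                         # mx my mz
  wf(d * tomo$voxel_size)       # cella
  wf(c(90, 90, 90))             # cellb
  wi(c(1, 2, 3))                # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))
  wi(1)                         # ispg (volume)
  wi(0)                         # nsymbt
  writeBin(raw(100), con)       # extra
  wf(c(0, 0, 0))                # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(v))              # rms
  wi(0)                         # nlabl
  writeBin(raw(800), con)       # labels
  wf(v)
  invisible(path)
}

#' Read an MRC2014 volume
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32).
#'
#' @param path file path.
#' @param invert logical; flip density polarity on load (cryo-EM conventionally
#'   records mass as dark, the package works mass-bright).
#' @return a [tomogram()].
#' @export
read_mrc <- function(path, invert = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)                   # nxstart
  m <- ri(3)              # mx my mz
  cella <- rf(3)
  seek(con, 1024)
  n <- prod(d)
  v <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    stop("unsupported MRC mode: ", mode))
  if (invert) v <- -v
  vs <- if (m[1] > 0 && cella[1] > 0) cella[1] / m[1] else 1
  tomogram(array(v, d), vs)
}

#' Write a data frame as a single-block STAR table
#' @param df data frame; column names become `_rln<Name>` style labels
#'   verbatim (prefix with `_` automatically).
#' @param path output file.
#' @param block data block name.
#' @export
write_star <- function(df, path, block = "particles") {
  lines <- c(paste0("data_", block), "", "loop_")
  lines <- c(lines, sprintf("_%s #%d", names(df), seq_along(df)))
  body <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.6f", col) else as.character(col)
  }), sep = " "))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a single-block STAR table written by [write_star()]
#' @param path file path.
#' @return data frame.
#' @export
read_star <- function(path) {
  lines <- readLines(path)
  lab <- grep("^_", lines)
  names <- sub("^_(\\S+).*$", "\\1", lines[lab])
  body <- lines[(max(lab) + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  df <- utils::read.table(text = body, col.names = names,
                          stringsAsFactors = FALSE)
  df
}

#' Serialize a fitted transform to JSON
#' @param tf a `fitted_transform` (see [fit_transform()]).
#' @param path output file.
#' @export
write_transform_json <- function(tf, path) {
  jsonlite::write_json(list(
    model = tf$model_tag,
    linear_part = tf$linear_part,
    translation = tf$translation,
    rms_residual = tf$rms_residual
  ), path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a transform serialized by [write_transform_json()]
#' @param path file path.
#' @return a `fitted_transform`.
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    linear_part = matrix(as.numeric(t(j$linear_part)), 2, 2, byrow = TRUE),
    translation = as.numeric(j$translation),
    model_tag = j$model, rms_residual = j$rms_residual,
    per_point_residuals = NULL
  ), class = "fitted_transform")
}

#' Write clicked membrane points as CSV (columns x, y, z in voxels, ordered)
#' @param clicks a [click_set()].
#' @param path output file.
#' @export
write_clicks_csv <- function(clicks, path) {
  df <- as.data.frame(clicks$points)
  names(df) <- c("x", "y", "z")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read clicked membrane points from CSV
#' @param path file path.
#' @param voxel_size voxel size in Angstrom.
#' @param ... passed to [click_set()].
#' @export
read_clicks_csv <- function(path, voxel_size = 7, ...) {
  df <- utils::read.csv(path)
  click_set(as.matrix(df[, c("x", "y", "z")]), voxel_size = voxel_size, ...)
}

#' Read a 2D image for spot localization (TIFF or single-section MRC)
#'
#' @param path file path ending in .tif/.tiff (requires the `tiff` package)
#'   or .mrc.
#' @param invert flip density polarity (MRC input only).
#' @return numeric matrix (row = y + 1, col = x + 1).
#' @export
read_image <- function(path, invert = FALSE) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(img)
  }
  tomo <- read_mrc(path, invert = invert)
  t(tomo$data[, , 1])
}

#' Read a pipeline configuration file (JSON, or YAML when available)
#' @param path file ending in .json, .yml or .yaml.
#' @return named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    return(jsonlite::read_json(path, simplifyVector = TRUE))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML requires the 'yaml' package")
  yaml::read_yaml(path)
}
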