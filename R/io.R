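#' Write a vector field as a legacy ASCII VTK structured-points file
#'
#' The format is readable by Paraview: a `STRUCTURED_POINTS` dataset with a
#' 3-component `VECTORS` attribute (A/m) and the mask as a `SCALARS`
#' attribute.  Coordinates are in meters.
#'
#' @param field a [vector_field3d].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(field, path) {
  d <- dim(field$mx)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "magnetization vector field",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
    sprintf("ORIGIN %.9e %.9e %.9e",
            field$origin[1], field$origin[2], field$origin[3]),
    sprintf("SPACING %.9e %.9e %.9e",
            field$voxel_size, field$voxel_size, field$voxel_size),
    sprintf("POINT_DATA %d", prod(d)),
    "VECTORS magnetization double"), con)
  m <- cbind(as.vector(field$mx), as.vector(field$my), as.vector(field$mz))
  utils::write.table(format(m, digits = 9, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(c("SCALARS mask int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(as.vector(field$mask))), con)
  invisible(path)
}

#' Read a vector field written by [write_field_vtk()]
#'
#' @param path VTK file path.
#' @return A [vector_field3d].
#' @export
read_field_vtk <- function(path) {
  lines <- readLines(path)
  gv <- function(key) {
    l <- grep(paste0("^", key), lines, value = TRUE)[1]
    as.numeric(strsplit(trimws(sub(key, "", l)), "\\s+")[[1]])
  }
  d <- as.integer(gv("DIMENSIONS"))
  origin <- gv("ORIGIN")
  spacing <- gv("SPACING")
  n <- prod(d)
  vstart <- grep("^VECTORS", lines)[1] + 1L
  vals <- scan(text = paste(lines[vstart:(vstart + n - 1)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  sstart <- grep("^LOOKUP_TABLE", lines)[1] + 1L
  mk <- as.logical(as.integer(lines[sstart:(sstart + n - 1)]))
  mask <- array(mk, d)
  attr(mask, "voxel_size") <- spacing[1]
  attr(mask, "origin") <- origin
  vector_field3d(array(m[, 1], d), array(m[, 2], d), array(m[, 3], d),
                 spacing[1], mask, origin)
}

#' Write a traced core path as CSV
#'
#' Columns: z, x, y (m) and polarization; Bloch points, if any, are written
#' to a sidecar `<path>.bloch.csv`.
#'
#' @param core a [trace_core()] result.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_core_csv <- function(core, path) {
  df <- cbind(core$points[, c("z", "x", "y")],
              polarization = core$polarization)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(core$bloch_points))
    utils::write.csv(as.data.frame(core$bloch_points),
                     paste0(path, ".bloch.csv"), row.names = FALSE)
  invisible(path)
}

#' Write a tilt series' metadata sidecar as JSON
#'
#' Records angles, axis id, pixel size and the applied shifts; the image
#' stack itself lives in memory (or in whatever volume format the caller
#' chooses).
#'
#' @param series a [tilt_series].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_series_sidecar <- function(series, path) {
  jsonlite::write_json(list(
    axis_id = series$axis_id,
    angles = series$angles,
    pixel_size = series$pixel_size,
    applied_shifts = series$applied_shifts,
    n_images = length(series$images),
    image_dim = dim(series$images[[1]])
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
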