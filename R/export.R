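# Plain-text exports: CSV with metadata headers, JSON sweep summaries, and
# legacy-ASCII VTK field maps.

#' Write an impedance spectrum (or study spectra table) to CSV
#'
#' Metadata (shape, voltage, resolution, ...) is written as leading
#' `# key: value` comment lines; the CSV body follows. Output is
#' deterministic: identical inputs give bit-identical files.
#'
#' @param x An `impedance_spectrum` or a data.frame of spectra.
#' @param path Output path.
#' @param metadata Named list of extra metadata lines.
#' @return Invisibly, `path`.
#' @export
write_spectrum_csv <- function(x, path, metadata = list()) {
  meta <- metadata
  if (inherits(x, "impedance_spectrum")) {
    meta <- c(list(shape = attr(x, "shape"), V = attr(x, "V")), meta)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Write a line profile to CSV with a metadata header
#'
#' @param profile A `line_profile`.
#' @param path Output path.
#' @param metadata Named list of metadata lines (shape, f, V, resolution...).
#' @return Invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path, metadata = list()) {
  stopifnot(inherits(profile, "line_profile"))
  metadata <- c(list(axis = attr(profile, "axis")), metadata)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(metadata))
    writeLines(sprintf("# %s: %s", nm, format(metadata[[nm]])), con)
  utils::write.csv(as.data.frame(profile), con, row.names = FALSE)
  invisible(path)
}

#' Write a study report summary as JSON
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_study_json <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  jsonlite::write_json(
    list(provenance = report$provenance,
         spectra = report$spectra,
         solution_spectra = report$solution_spectra,
         sensitivity = report$sensitivity,
         extrema = report$extrema,
         errors = report$errors),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Export a field solution as a legacy-ASCII VTK unstructured grid
#'
#' Point data: Re(phi), Im(phi). Cell data: |E| and region id. Readable by
#' ParaView/meshio.
#'
#' @param sol A `field_solution`.
#' @param path Output `.vtk` path.
#' @return Invisibly, `path`.
#' @export
write_field_vtk <- function(sol, path) {
  stopifnot(inherits(sol, "field_solution"))
  m <- sol$mesh
  n <- nrow(m$nodes); ntri <- nrow(m$triangles)
  ef <- electric_field(sol)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# vtk DataFile Version 3.0")
  w("electro-quasistatic field solution")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w(sprintf("POINTS %d double", n))
  writeLines(sprintf("%.9e %.9e 0", m$nodes[, 1], m$nodes[, 2]), con)
  w(sprintf("CELLS %d %d", ntri, 4L * ntri))
  writeLines(sprintf("3 %d %d %d", m$triangles[, 1] - 1L,
                     m$triangles[, 2] - 1L, m$triangles[, 3] - 1L), con)
  w(sprintf("CELL_TYPES %d", ntri))
  writeLines(rep("5", ntri), con)
  w(sprintf("POINT_DATA %d", n))
  w("SCALARS phi_real double 1")
  w("LOOKUP_TABLE default")
  writeLines(sprintf("%.9e", Re(sol$phi)), con)
  w("SCALARS phi_imag double 1")
  w("LOOKUP_TABLE default")
  writeLines(sprintf("%.9e", Im(sol$phi)), con)
  w(sprintf("CELL_DATA %d", ntri))
  w("SCALARS E_magnitude double 1")
  w("LOOKUP_TABLE default")
  mag <- ef$magnitude; mag[is.na(mag)] <- 0
  writeLines(sprintf("%.9e", mag), con)
  w("SCALARS region int 1")
  w("LOOKUP_TABLE default")
  rid <- match(m$elem_region, c("PBS", "CELL", "ELECTRODE_A", "ELECTRODE_B"))
  writeLines(sprintf("%d", rid), con)
  invisible(path)
}
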