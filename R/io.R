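# Minimal GIFTI (ASCII encoding), label-file and mask I/O.
#
# Only the subset of GIFTI needed by this pipeline is supported: one
# POINTSET + one TRIANGLE data array for surfaces, and per-vertex data
# arrays for functional maps, all with ASCII encoding. Label files are
# plain text with one 0-based vertex index per line; a JSON dialect
# carries a name plus indices.

gifti_data_array <- function(doc, values, intent, datatype, dims) {
  da <- xml2::xml_add_child(doc, "DataArray",
                            Intent = intent,
                            DataType = datatype,
                            ArrayIndexingOrder = "RowMajorOrder",
                            Dimensionality = as.character(length(dims)),
                            Encoding = "ASCII",
                            Endian = "LittleEndian")
  for (i in seq_along(dims)) {
    xml2::xml_set_attr(da, paste0("Dim", i - 1L), as.character(dims[i]))
  }
  txt <- if (is.matrix(values)) {
    paste(apply(values, 1L, paste, collapse = " "), collapse = "\n")
  } else {
    paste(values, collapse = "\n")
  }
  xml2::xml_add_child(da, "Data", txt)
  invisible(da)
}

#' Write a surface mesh as an ASCII GIFTI file
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path (conventionally `.surf.gii`).
#' @return `path`, invisibly.
#' @export
write_gifti_surface <- function(mesh, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "2")
  gifti_data_array(doc, format(mesh$vertices, trim = TRUE, digits = 17),
                   "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                   dim(mesh$vertices))
  gifti_data_array(doc, mesh$faces - 1L, "NIFTI_INTENT_TRIANGLE",
                   "NIFTI_TYPE_INT32", dim(mesh$faces))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a surface mesh from an ASCII GIFTI file
#'
#' @param path file written by [write_gifti_surface()] or another tool
#'   using ASCII encoding.
#' @return a [triangle_mesh()].
#' @export
read_gifti_surface <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  intents <- xml2::xml_attr(das, "Intent")
  pget <- function(intent) {
    da <- das[[which(intents == intent)[1L]]]
    dims <- as.integer(c(xml2::xml_attr(da, "Dim0"),
                         xml2::xml_attr(da, "Dim1")))
    vals <- scan(text = xml2::xml_text(xml2::xml_find_first(da, ".//Data")),
                 quiet = TRUE)
    matrix(vals, nrow = dims[1L], ncol = dims[2L], byrow = TRUE)
  }
  verts <- pget("NIFTI_INTENT_POINTSET")
  faces <- pget("NIFTI_INTENT_TRIANGLE") + 1L
  triangle_mesh(verts, faces)
}

#' Write per-vertex values as an ASCII GIFTI functional file
#'
#' @param values numeric vector or matrix (vertices by maps); complex
#'   input is stored as two columns (real, imaginary).
#' @param path output path (conventionally `.func.gii`).
#' @return `path`, invisibly.
#' @export
write_gifti_metric <- function(values, path) {
  if (is.complex(values)) values <- cbind(Re(values), Im(values))
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(ncol(values)))
  for (k in seq_len(ncol(values))) {
    gifti_data_array(doc, format(values[, k], trim = TRUE, digits = 17),
                     "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32",
                     nrow(values))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read per-vertex values from an ASCII GIFTI functional file
#'
#' @param path file path.
#' @return numeric matrix, vertices by data arrays.
#' @export
read_gifti_metric <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  cols <- lapply(das, function(da) {
    scan(text = xml2::xml_text(xml2::xml_find_first(da, ".//Data")),
         quiet = TRUE)
  })
  do.call(cbind, cols)
}

#' Read and write vertex label masks
#'
#' Plain-text label files carry one 0-based vertex index per line
#' (surface-tool convention); the JSON dialect stores `name` and a
#' 0-based `indices` array. Indices are converted to 1-based on read.
#'
#' @param mask integer vector of 1-based vertex indices.
#' @param path file path; a `.json` extension selects the JSON dialect.
#' @param name mask name for the JSON dialect.
#' @return `read_label()`: integer vector of 1-based indices (the JSON
#'   name, if any, as attribute `name`); `write_label()`: `path`.
#' @export
write_label <- function(mask, path, name = "mask") {
  mask <- as.integer(mask)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(name = name, indices = mask - 1L), path,
                         auto_unbox = TRUE)
  } else {
    writeLines(as.character(mask - 1L), path)
  }
  invisible(path)
}

#' @rdname write_label
#' @export
read_label <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- as.integer(obj$indices) + 1L
    attr(out, "name") <- obj$name
    out
  } else {
    as.integer(readLines(path)) + 1L
  }
}

#' Write a decoded phase-map table as CSV
#'
#' One row per vertex with amplitude, phase, F, p and (optionally) the
#' decoded map coordinate.
#'
#' @param stat result of [fourier_stat()] or a group map.
#' @param path output CSV path.
#' @param coordinate optional decoded coordinate vector.
#' @return `path`, invisibly.
#' @export
write_phase_csv <- function(stat, path, coordinate = NULL) {
  df <- data.frame(vertex = seq_along(stat$amplitude) - 1L,
                   amplitude = stat$amplitude, phase = stat$phase,
                   f = stat$f, p = stat$p)
  if (!is.null(coordinate)) df$coordinate <- coordinate
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a block-design event table from CSV
#'
#' Expects columns `condition`, `onset`, `duration` (seconds).
#'
#' @param path CSV path.
#' @param run_s,tr,highpass_s design parameters (see [block_design()]).
#' @return a [block_design()].
#' @export
read_events_csv <- function(path, run_s, tr, highpass_s = 100) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  block_design(ev, run_s, tr, highpass_s)
}
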