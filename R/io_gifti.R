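# Minimal GIFTI surface-data container support (ASCII encoding).
#
# Covers the label (.label.gii), metric (.func.gii) and surface geometry
# (.surf.gii) conventions this package needs. Data arrays are written with
# Encoding="ASCII" so all fixtures remain plain text; readers accept any
# ASCII-encoded GIFTI with the matching intent.

gii_num <- function(x) {
  # full-precision, locale-independent number formatting; missing -> NaN
  out <- formatC(x, format = "g", digits = 17)
  out[is.na(x)] <- "NaN"
  out
}

gifti_doc <- function() {
  xml2::xml_new_root("GIFTI", Version = "1.0")
}

gifti_add_array <- function(root, values, intent, datatype) {
  n <- length(values)
  da <- xml2::xml_add_child(root, "DataArray",
                            Intent = intent, DataType = datatype,
                            ArrayIndexingOrder = "RowMajorOrder",
                            Dimensionality = "1", Dim0 = as.character(n),
                            Encoding = "ASCII", Endian = "LittleEndian",
                            ExternalFileName = "", ExternalFileOffset = "")
  txt <- if (datatype == "NIFTI_TYPE_INT32") paste(as.integer(values), collapse = " ")
         else paste(gii_num(as.numeric(values)), collapse = " ")
  xml2::xml_add_child(da, "Data", txt)
  invisible(da)
}

gifti_add_matrix_array <- function(root, mat, intent, datatype) {
  da <- xml2::xml_add_child(root, "DataArray",
                            Intent = intent, DataType = datatype,
                            ArrayIndexingOrder = "RowMajorOrder",
                            Dimensionality = "2",
                            Dim0 = as.character(nrow(mat)),
                            Dim1 = as.character(ncol(mat)),
                            Encoding = "ASCII", Endian = "LittleEndian",
                            ExternalFileName = "", ExternalFileOffset = "")
  flat <- as.vector(t(mat))  # row-major
  txt <- if (datatype == "NIFTI_TYPE_INT32") paste(as.integer(flat), collapse = " ")
         else paste(gii_num(as.numeric(flat)), collapse = " ")
  xml2::xml_add_child(da, "Data", txt)
  invisible(da)
}

#' Write a label map as a GIFTI label file
#'
#' ASCII-encoded `.label.gii` with a `LabelTable` naming every label
#' (key 0 is written as `"???"`, the unassigned convention).
#'
#' @param map a [label_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gifti_label <- function(map, path) {
  stopifnot(inherits(map, "label_map"))
  root <- gifti_doc()
  lt <- xml2::xml_add_child(root, "LabelTable")
  xml2::xml_add_child(lt, "Label", "???", Key = "0")
  for (k in names(map$label_table))
    xml2::xml_add_child(lt, "Label", map$label_table[[k]], Key = k)
  gifti_add_array(root, map$values, "NIFTI_INTENT_LABEL", "NIFTI_TYPE_INT32")
  xml2::write_xml(root, path)
  invisible(path)
}

#' Write per-vertex metric values as a GIFTI metric file
#'
#' ASCII-encoded `.func.gii`; one `DataArray` per column. Missing values are
#' written as `NaN`.
#'
#' @param values numeric vector, or matrix with one column per map dimension.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gifti_metric <- function(values, path) {
  if (inherits(values, "metric_map")) values <- values$values
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  root <- gifti_doc()
  for (j in seq_len(ncol(values)))
    gifti_add_array(root, values[, j], "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32")
  xml2::write_xml(root, path)
  invisible(path)
}

#' Write mesh geometry as a GIFTI surface file
#'
#' ASCII-encoded `.surf.gii` with a pointset and a (0-based) triangle array;
#' intended for visual inspection of generated icosphere fixtures in standard
#' surface viewers.
#'
#' @param mesh a [sphere_mesh()].
#' @param path output path.
#' @param radius scale factor applied to the unit-sphere coordinates (mm).
#' @return `path`, invisibly.
#' @export
write_gifti_surface <- function(mesh, path, radius = 100) {
  stopifnot(inherits(mesh, "sphere_mesh"))
  root <- gifti_doc()
  gifti_add_matrix_array(root, mesh$vertices * radius,
                         "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32")
  gifti_add_matrix_array(root, mesh$triangles - 1L,
                         "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32")
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read an ASCII-encoded GIFTI data file
#'
#' Parses label and metric GIFTI files written with ASCII encoding.
#'
#' @param path file path.
#' @return A list with `data` (numeric matrix, one column per data array),
#'   `intents` (character, one per array) and `label_table` (named character
#'   vector, or `NULL` for metric files).
#' @export
read_gifti <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (!length(arrays)) stopf("no DataArray in GIFTI file: %s", path)
  enc <- xml2::xml_attr(arrays, "Encoding")
  if (!all(enc == "ASCII"))
    stopf("only ASCII-encoded GIFTI is supported (found %s)",
          paste(unique(enc), collapse = ", "))
  cols <- lapply(arrays, function(a) {
    txt <- xml2::xml_text(xml2::xml_find_first(a, "./Data"))
    as.numeric(strsplit(trimws(txt), "\\s+")[[1L]])
  })
  lens <- lengths(cols)
  if (length(unique(lens)) != 1L)
    stopf("data arrays have differing lengths: %s", paste(lens, collapse = ", "))
  labs <- xml2::xml_find_all(doc, ".//LabelTable/Label")
  lt <- NULL
  if (length(labs)) {
    lt <- setNames(xml2::xml_text(labs), xml2::xml_attr(labs, "Key"))
    lt <- lt[names(lt) != "0"]
  }
  list(data = do.call(cbind, cols),
       intents = xml2::xml_attr(arrays, "Intent"),
       label_table = lt)
}
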