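# Minimal GIFTI reader/writer (ASCII-encoded DataArrays, the text form of
# the format). Covers the three kinds this pipeline exchanges: surfaces
# (POINTSET + TRIANGLE), per-vertex metrics, and label maps with a label
# table. Readers validate loudly: a surface file must contain exactly one
# pointset and one triangle array with consistent indices.

gii_data_text <- function(x, fmt) {
  paste(apply(matrix(sprintf(fmt, t(x)), ncol = ncol(x), byrow = TRUE),
              1, paste, collapse = " "), collapse = "\n")
}

gii_array_node <- function(doc_root, intent, dtype, x, fmt) {
  da <- xml2::xml_add_child(doc_root, "DataArray",
    Intent = intent, DataType = dtype, ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(length(dim(x))),
    Dim0 = as.character(nrow(x)), Dim1 = as.character(ncol(x)),
    Encoding = "ASCII", Endian = "LittleEndian")
  xml2::xml_add_child(da, "Data", gii_data_text(x, fmt))
  da
}

gii_write <- function(arrays, path, label_table = NULL) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(length(arrays)))
  if (!is.null(label_table)) {
    lt <- xml2::xml_add_child(doc, "LabelTable")
    for (i in seq_along(label_table)) {
      lab <- xml2::xml_add_child(lt, "Label", names(label_table)[i])
      xml2::xml_set_attr(lab, "Key", as.character(label_table[[i]]))
    }
  }
  for (a in arrays) gii_array_node(doc, a$intent, a$dtype, a$x, a$fmt)
  xml2::write_xml(doc, path)
  invisible(path)
}

gii_read_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  if (!length(das)) stop("no DataArray in ", path)
  arrays <- lapply(das, function(da) {
    enc <- xml2::xml_attr(da, "Encoding")
    if (!identical(enc, "ASCII"))
      stop("unsupported GIFTI encoding '", enc, "' in ", path)
    txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
    vals <- scan(text = txt, quiet = TRUE)
    d0 <- as.integer(xml2::xml_attr(da, "Dim0"))
    d1 <- xml2::xml_attr(da, "Dim1")
    d1 <- if (is.na(d1)) 1L else as.integer(d1)
    list(intent = xml2::xml_attr(da, "Intent"),
         x = matrix(vals, nrow = d0, ncol = d1, byrow = TRUE))
  })
  lt <- xml2::xml_find_all(doc, ".//LabelTable/Label")
  labels <- NULL
  if (length(lt))
    labels <- stats::setNames(as.integer(xml2::xml_attr(lt, "Key")),
                              xml2::xml_text(lt))
  list(arrays = arrays, label_table = labels)
}

#' Write a surface mesh as a GIFTI surface file
#'
#' @param mesh a [triangle_mesh()].
#' @param path output `.surf.gii` path.
#' @return the path, invisibly.
#' @export
write_surface_gii <- function(mesh, path) {
  gii_write(list(
    list(intent = "NIFTI_INTENT_POINTSET", dtype = "NIFTI_TYPE_FLOAT32",
         x = mesh$vertices, fmt = "%.7g"),
    list(intent = "NIFTI_INTENT_TRIANGLE", dtype = "NIFTI_TYPE_INT32",
         x = mesh$faces - 1L, fmt = "%d")), path)
}

#' Read a GIFTI surface file
#'
#' @param path a `.surf.gii` path.
#' @param validate run [validate_mesh()] (topology report) after reading.
#' @return a [triangle_mesh()].
#' @export
read_surface_gii <- function(path, validate = TRUE) {
  g <- gii_read_arrays(path)
  intents <- vapply(g$arrays, `[[`, "", "intent")
  ip <- which(intents == "NIFTI_INTENT_POINTSET")
  it <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (length(ip) != 1 || length(it) != 1)
    stop(path, " is not a surface GIFTI (needs one POINTSET and one TRIANGLE)")
  triangle_mesh(g$arrays[[ip]]$x, g$arrays[[it]]$x + 1L, validate = validate)
}

#' Write a per-vertex metric as a GIFTI func/shape file
#'
#' @param metric a [metric_map()] or numeric vector.
#' @param path output `.func.gii` / `.shape.gii` path.
#' @return the path, invisibly.
#' @export
write_metric_gii <- function(metric, path) {
  v <- if (inherits(metric, "metric_map")) metric$values else as.numeric(metric)
  gii_write(list(list(intent = "NIFTI_INTENT_NONE",
                      dtype = "NIFTI_TYPE_FLOAT32",
                      x = matrix(v, ncol = 1), fmt = "%.9g")), path)
}

#' Read a per-vertex metric GIFTI file
#'
#' @param path the metric file path.
#' @param mesh optional mesh; if given, the vertex count must match.
#' @return a [metric_map()].
#' @export
read_metric_gii <- function(path, mesh = NULL) {
  g <- gii_read_arrays(path)
  v <- as.numeric(g$arrays[[1]]$x)
  if (!is.null(mesh) && length(v) != nrow(mesh$vertices))
    stop("metric in ", path, " has ", length(v),
         " values; mesh has ", nrow(mesh$vertices), " vertices")
  metric_map(v)
}

#' Write a parcel label map as a GIFTI label file
#'
#' @param labels a [parcel_labels()].
#' @param path output `.label.gii` path.
#' @return the path, invisibly.
#' @export
write_label_gii <- function(labels, path) {
  tab <- c(stats::setNames(0L, "???"), labels$names)
  gii_write(list(list(intent = "NIFTI_INTENT_LABEL",
                      dtype = "NIFTI_TYPE_INT32",
                      x = matrix(labels$labels, ncol = 1), fmt = "%d")),
            path, label_table = tab)
}

#' Read a GIFTI label file
#'
#' @param path the label file path.
#' @param mesh optional mesh for a vertex-count check.
#' @return a [parcel_labels()].
#' @export
read_label_gii <- function(path, mesh = NULL) {
  g <- gii_read_arrays(path)
  v <- as.integer(g$arrays[[1]]$x)
  if (!is.null(mesh) && length(v) != nrow(mesh$vertices))
    stop("labels in ", path, " have ", length(v),
         " values; mesh has ", nrow(mesh$vertices), " vertices")
  tab <- g$label_table
  tab <- tab[tab != 0L]
  parcel_labels(v, tab)
}
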