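#' Per-vertex scalar map
#'
#' One scalar per mesh vertex with a units label. Masked vertices are `NA`.
#'
#' @param values numeric vector, one value per vertex.
#' @param units one of `"ratio"`, `"mm"`, `"mm2"`, `"mm3"`, `"1/mm"`, `"1"`.
#' @param mesh_id optional identifier of the mesh the map lives on; maps are
#'   only combined when their ids agree (or either id is `NULL`).
#' @return object of class `metric_map`.
#' @export
metric_map <- function(values, units = "1", mesh_id = NULL) {
  stopifnot(is.numeric(values))
  structure(list(values = as.numeric(values), units = units, mesh_id = mesh_id),
            class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf("metric_map [%s]: %d vertices (%d masked), range [%.4g, %.4g]\n",
              x$units, length(x$values), sum(!is.finite(x$values)),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

# accept metric_map or bare numeric; check length against mesh
metric_values <- function(metric, mesh = NULL) {
  v <- if (inherits(metric, "metric_map")) metric$values else as.numeric(metric)
  if (!is.null(mesh) && length(v) != nrow(mesh$vertices))
    stop("metric length ", length(v), " does not match mesh vertex count ",
         nrow(mesh$vertices))
  v
}

check_same_mesh <- function(a, b) {
  ida <- if (inherits(a, "metric_map")) a$mesh_id else NULL
  idb <- if (inherits(b, "metric_map")) b$mesh_id else NULL
  if (!is.null(ida) && !is.null(idb) && !identical(ida, idb))
    stop("metric maps live on different meshes: ", ida, " vs ", idb)
  invisible(TRUE)
}

#' 3-D scalar volume with voxel-to-world affine
#'
#' @param data 3-D numeric array of voxel values.
#' @param affine 4x4 voxel-to-world matrix mapping 0-based voxel indices to
#'   world mm (RAS) coordinates.
#' @return object of class `volume_image`.
#' @export
volume_image <- function(data, affine) {
  stopifnot(length(dim(data)) == 3, identical(dim(affine), c(4L, 4L)))
  structure(list(data = data, affine = affine), class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_image: %d x %d x %d voxels, voxel size %.3g mm\n",
              d[1], d[2], d[3], mean(sqrt(colSums(x$affine[1:3, 1:3]^2)))))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("volume grids differ: ", paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
  if (max(abs(a$affine - b$affine)) > 1e-9)
    stop("volume affines differ")
  invisible(TRUE)
}

# world mm -> continuous 0-based voxel coordinates
world_to_voxel <- function(vol, xyz) {
  inv <- solve(vol$affine)
  xyz1 <- cbind(xyz, 1)
  out <- xyz1 %*% t(inv)
  out[, 1:3, drop = FALSE]
}

# continuous 0-based voxel coords -> world mm (used by generators)
voxel_to_world <- function(affine, ijk) {
  out <- cbind(ijk, 1) %*% t(affine)
  out[, 1:3, drop = FALSE]
}

#' Per-vertex integer parcel labels with a name table
#'
#' Label 0 means unassigned; every nonzero label must appear in `names`.
#'
#' @param labels integer vector of per-vertex labels (0 = unassigned).
#' @param names named integer vector or list mapping parcel name -> label.
#' @return object of class `parcel_labels`.
#' @export
parcel_labels <- function(labels, names = integer()) {
  labels <- as.integer(labels)
  if (any(labels < 0L)) stop("labels must be >= 0")
  nm <- unlist(names)
  used <- setdiff(unique(labels), 0L)
  missing <- setdiff(used, as.integer(nm))
  if (length(missing))
    stop("labels without names: ", paste(missing, collapse = ", "))
  structure(list(labels = labels, names = nm), class = "parcel_labels")
}

#' @export
print.parcel_labels <- function(x, ...) {
  cat(sprintf("parcel_labels: %d vertices, %d parcels (%s), %d unassigned\n",
              length(x$labels), length(x$names),
              paste(names(x$names), collapse = ", "),
              sum(x$labels == 0L)))
  invisible(x)
}

#' Integer label of a named parcel
#'
#' @param plab a [parcel_labels()].
#' @param name parcel name present in the label table.
#' @return the integer label.
#' @export
label_of <- function(plab, name) {
  v <- plab$names[[name]]
  if (is.null(v)) stop("unknown parcel name: ", name)
  as.integer(v)
}
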