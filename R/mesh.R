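#' Triangle mesh in world coordinates
#'
#' Lightweight container for a triangulated surface: an `N x 3` matrix of
#' vertex coordinates in millimetres and an `M x 3` integer matrix of
#' 1-based vertex indices. Faces are wound counter-clockwise seen from
#' outside, so the signed volume of a closed mesh is positive.
#'
#' @param vertices numeric `N x 3` matrix of vertex positions (mm).
#' @param faces integer `M x 3` matrix of vertex indices (1-based).
#' @param validate run [validate_mesh()] on construction.
#' @return object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, area %.2f mm^2\n",
              nrow(x$vertices), nrow(x$faces), total_area(x)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Validate mesh topology and geometry
#'
#' Checks index ranges, degenerate (zero-area) faces, and edge connectivity.
#' Orientation consistency is checked for closed meshes via the requirement
#' that every edge is used once in each direction.
#'
#' @param mesh a [triangle_mesh()].
#' @param require_connected fail if the mesh has more than one edge-connected
#'   component.
#' @param area_tol faces with area below this (mm^2) are degenerate.
#' @return invisibly `TRUE`; stops with a message on violation.
#' @export
validate_mesh <- function(mesh, require_connected = TRUE, area_tol = 1e-12) {
  nv <- nrow(mesh$vertices)
  f <- mesh$faces
  if (any(f < 1L) || any(f > nv)) stop("face indices out of range [1, N]")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("face with repeated vertex")
  if (any(face_areas(mesh) <= area_tol)) stop("degenerate (zero-area) face")
  if (require_connected) {
    g <- mesh_graph(mesh)
    if (igraph::count_components(g) != 1L)
      stop("mesh is not edge-connected (", igraph::count_components(g),
           " components)")
  }
  invisible(TRUE)
}

#' Paired white and pial surfaces with 1:1 vertex correspondence
#'
#' @param white,pial [triangle_mesh()] objects sharing vertex count and an
#'   identical face list.
#' @return object of class `surface_pair`.
#' @export
surface_pair <- function(white, pial) {
  if (!identical(dim(white$vertices), dim(pial$vertices)))
    stop("white and pial meshes differ in vertex count")
  if (!identical(white$faces, pial$faces))
    stop("white and pial meshes differ in face list (no 1:1 correspondence)")
  structure(list(white = white, pial = pial), class = "surface_pair")
}

#' @export
print.surface_pair <- function(x, ...) {
  th <- correspondence_thickness(x)
  cat(sprintf("surface_pair: %d vertices, thickness %.2f +/- %.2f mm\n",
              nrow(x$white$vertices), mean(th$values), stats::sd(th$values)))
  invisible(x)
}

# undirected edge list (E x 2, i < j), one row per unique edge
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

mesh_graph <- function(mesh) {
  igraph::graph_from_edgelist(mesh_edges(mesh), directed = FALSE)
}

# neighbor index list, one integer vector per vertex
vertex_neighbors <- function(mesh) {
  e <- mesh_edges(mesh)
  nv <- nrow(mesh$vertices)
  adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(nv)))
  lapply(adj, as.integer)
}

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr^2))
}

face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  cr / sqrt(rowSums(cr^2))
}

# area-weighted average of incident face normals, unit length
vertex_normals <- function(mesh) {
  cr <- face_cross(mesh)  # cross product = 2*area*normal
  nv <- nrow(mesh$vertices)
  f <- mesh$faces
  n <- matrix(0, nv, 3)
  for (k in 1:3) {
    n[, 1] <- n[, 1] + unname(tapply2(cr[, 1], f[, k], nv))
    n[, 2] <- n[, 2] + unname(tapply2(cr[, 2], f[, k], nv))
    n[, 3] <- n[, 3] + unname(tapply2(cr[, 3], f[, k], nv))
  }
  n / sqrt(rowSums(n^2))
}

# fast grouped sum into a length-n vector
tapply2 <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Total surface area of a mesh
#' @param mesh a [triangle_mesh()].
#' @return scalar area in mm^2.
#' @export
total_area <- function(mesh) sum(face_areas(mesh))

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem volume: sum over faces of the signed tetrahedron
#' volume spanned by the origin and the face. Positive for outward,
#' counter-clockwise winding.
#'
#' @param mesh a closed [triangle_mesh()].
#' @return scalar volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Subdivided icosahedron sphere mesh
#'
#' Standard icosphere: each subdivision splits every face into four and
#' re-projects new vertices onto the sphere. Counter-clockwise winding seen
#' from outside.
#'
#' @param subdivisions number of 4-to-1 subdivisions (0 = icosahedron).
#'   Vertex count is `10 * 4^subdivisions + 2`.
#' @param radius sphere radius (mm).
#' @return a [triangle_mesh()].
#' @export
icosphere <- function(subdivisions = 4, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    uk <- !duplicated(key)
    mididx <- match(key, key[uk]) + nrow(v)
    mid <- (v[e[uk, 1], , drop = FALSE] + v[e[uk, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    v <- rbind(v, mid)
    nf <- nrow(f)
    m12 <- mididx[1:nf]; m23 <- mididx[nf + 1:nf]; m31 <- mididx[2 * nf + 1:nf]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  triangle_mesh(v * radius, f, validate = FALSE)
}

#' Triangulated regular planar grid
#'
#' Flat sheet in the z = 0 plane, `nx x ny` vertices at the given spacing,
#' each grid cell split into two triangles. Used for planar smoothing and
#' gradient oracles.
#'
#' @param nx,ny grid dimensions (vertices per side).
#' @param spacing vertex spacing (mm).
#' @return a [triangle_mesh()].
#' @export
planar_grid_mesh <- function(nx, ny, spacing = 1) {
  xy <- expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1)
  v <- cbind(xy$x * spacing, xy$y * spacing, 0)
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1), ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  f <- rbind(cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
             cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  triangle_mesh(v, f, validate = FALSE)
}

# mirror a mesh through the x = 0 plane, rewinding faces to keep outward
# counter-clockwise orientation
mirror_mesh <- function(mesh) {
  v <- mesh$vertices
  v[, 1] <- -v[, 1]
  triangle_mesh(v, mesh$faces[, c(1, 3, 2)], validate = FALSE)
}

# grid-interior vertex mask for planar_grid_mesh (full 1-ring)
planar_interior <- function(nx, ny) {
  xy <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  xy$x > 1 & xy$x < nx & xy$y > 1 & xy$y < ny
}
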