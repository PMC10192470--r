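# Shared fixtures, memoized so expensive phantoms are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

# a night-monkey-like spec with all four standard parcels
night_spec <- function(seed = 42L, subdivisions = 4L, ...) {
  default_species_specs(seed = seed, subdivisions = subdivisions)$night
}

# a single-parcel spec (MT+-like island at fraction 0.024)
one_parcel_spec <- function(seed = 7L, subdivisions = 4L, fraction = 0.024) {
  species_spec("toy", n_subjects = 1,
               target_fractions = c("MT+" = fraction),
               myelin_levels = c("MT+" = 0.6),
               mean_thickness_mm = 2.0, total_area_scale = 12.7,
               seed = seed, subdivisions = subdivisions,
               fraction_jitter_rel = 0, area_jitter_rel = 0,
               thickness_jitter_rel = 0)
}

# a parcel-free spherical pair (exact geometry, no jitter)
bare_sphere_spec <- function(thickness = 2.0, subdivisions = 3L) {
  species_spec("bare", n_subjects = 1, mean_thickness_mm = thickness,
               total_area_scale = 12.7, seed = 1L,
               subdivisions = subdivisions, fold_amplitude = 0,
               background_level = 1.0,
               area_jitter_rel = 0, fraction_jitter_rel = 0,
               thickness_jitter_rel = 0, thickness_wiggle = 0)
}

cached_night_hemi <- function() {
  cached("night_hemi", function() make_hemisphere(night_spec(), 1, "L"))
}

cached_one_parcel_hemi <- function() {
  cached("one_parcel_hemi", function() make_hemisphere(one_parcel_spec(), 1, "L"))
}

# random non-degenerate surface pair for oracle tests
random_pair <- function(seed = 1, subdivisions = 2) {
  set.seed(seed)
  base <- icosphere(subdivisions, 10)
  u <- base$vertices / 10
  r <- 10 * (1 + 0.1 * sin(3 * base$vertices[, 1] / 10) *
               cos(2 * base$vertices[, 2] / 10))
  mid <- u * r
  th <- 1 + 0.3 * sin(base$vertices[, 3] / 5)
  surface_pair(triangle_mesh(mid - u * th / 2, base$faces, validate = FALSE),
               triangle_mesh(mid + u * th / 2, base$faces, validate = FALSE))
}

# independent per-triangle area accumulation (brute-force oracle)
oracle_vertex_area_sum <- function(mesh, vertex_subset) {
  v <- mesh$vertices
  f <- mesh$faces
  total <- 0
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 2], ] - v[f[i, 1], ]
    b <- v[f[i, 3], ] - v[f[i, 1], ]
    ar <- 0.5 * sqrt(sum(crossprod_vec(a, b)^2))
    for (k in 1:3) if (f[i, k] %in% vertex_subset) total <- total + ar / 3
  }
  total
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# brute-force BFS flood fill over an adjacency list (oracle for grow_parcel)
oracle_flood_fill <- function(mesh, boundary, seed) {
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(3, 1)])
  nv <- nrow(mesh$vertices)
  adj <- lapply(seq_len(nv), function(i)
    unique(c(e[e[, 1] == i, 2], e[e[, 2] == i, 1])))
  blocked <- rep(FALSE, nv)
  blocked[boundary] <- TRUE
  seen <- rep(FALSE, nv)
  seen[seed] <- TRUE
  queue <- seed
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w] && !blocked[w]) {
      seen[w] <- TRUE
      queue <- c(queue, w)
    }
  }
  which(seen)
}

# rigid transform helper: rotate by random orthonormal matrix + translate
rigid_transform <- function(mesh, seed = 5) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- rnorm(3, 0, 20)
  triangle_mesh(sweep(mesh$vertices %*% q, 2, shift, "+"), mesh$faces,
                validate = FALSE)
}
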