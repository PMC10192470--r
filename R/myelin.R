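#' FWHM to Gaussian sigma
#'
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`.
#'
#' @param fwhm_mm full width at half maximum (mm), positive.
#' @return sigma in mm.
#' @export
fwhm_to_sigma <- function(fwhm_mm) {
  if (!is.numeric(fwhm_mm) || any(fwhm_mm <= 0))
    stop("fwhm_mm must be positive")
  fwhm_mm / (2 * sqrt(2 * log(2)))
}

#' Gaussian ribbon-sampling kernel
#'
#' Sampling points are spaced evenly along each white-to-pial segment and
#' combined with Gaussian weights centred at the segment midpoint, weighting
#' the T1w/T2w ratio toward the mid-thickness. The 1.8 mm FWHM default is
#' the night-monkey optimum (set by median cortical thickness).
#'
#' @param fwhm_mm kernel FWHM in mm.
#' @param n_samples number of points along each segment; odd and >= 3 so
#'   the midpoint itself is sampled.
#' @return object of class `sampling_kernel` with fields `fwhm_mm`,
#'   `n_samples`, `sigma_mm`.
#' @export
sampling_kernel <- function(fwhm_mm = 1.8, n_samples = 7L) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 3L || n_samples %% 2L == 0L)
    stop("n_samples must be odd and >= 3")
  structure(list(fwhm_mm = fwhm_mm, n_samples = n_samples,
                 sigma_mm = fwhm_to_sigma(fwhm_mm)),
            class = "sampling_kernel")
}

#' Voxelwise T1w/T2w ratio volume
#'
#' `t1w / max(t2w, epsilon)` per voxel; voxels with `t2w <= epsilon` are
#' masked non-finite and excluded downstream. The default epsilon is 1e-6
#' of the T2w robust (99th percentile) maximum.
#'
#' @param t1w,t2w [volume_image()]s on identical grids.
#' @param epsilon intensity floor for the denominator.
#' @return a [volume_image()] of the ratio.
#' @export
ratio_volume <- function(t1w, t2w, epsilon = NULL) {
  check_same_grid(t1w, t2w)
  if (is.null(epsilon))
    epsilon <- 1e-6 * stats::quantile(t2w$data, 0.99, names = FALSE)
  r <- t1w$data / pmax(t2w$data, epsilon)
  r[t2w$data <= epsilon] <- NA_real_
  volume_image(r, t1w$affine)
}

# vectorized trilinear interpolation at world-mm points; NA outside the
# grid or where any contributing voxel is non-finite
trilinear_sample <- function(vol, xyz) {
  v <- world_to_voxel(vol, xyz)
  d <- dim(vol$data)
  i0 <- floor(v)
  fr <- v - i0
  out <- numeric(nrow(v))
  oob <- i0[, 1] < 0 | i0[, 1] > d[1] - 2 |
         i0[, 2] < 0 | i0[, 2] > d[2] - 2 |
         i0[, 3] < 0 | i0[, 3] > d[3] - 2
  out[oob] <- NA_real_
  ok <- which(!oob)
  if (length(ok)) {
    i0k <- i0[ok, , drop = FALSE]
    frk <- fr[ok, , drop = FALSE]
    acc <- numeric(length(ok))
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) frk[, 1] else 1 - frk[, 1]) *
           (if (dy) frk[, 2] else 1 - frk[, 2]) *
           (if (dz) frk[, 3] else 1 - frk[, 3])
      lin <- (i0k[, 1] + dx) + d[1] * ((i0k[, 2] + dy) + d[2] * (i0k[, 3] + dz)) + 1
      acc <- acc + w * vol$data[lin]
    }
    out[ok] <- acc
  }
  out
}

#' Sample a volume onto the surface with mid-thickness Gaussian weighting
#'
#' Per vertex, the volume is sampled by trilinear interpolation at
#' `n_samples` points spaced evenly along the white-to-pial segment and
#' combined with Gaussian weights centred at the segment midpoint (sd =
#' `kernel$sigma_mm`, distance measured in mm along the segment). Weights
#' are renormalized over finite samples; a vertex with no finite sample is
#' masked. Vertices whose segment leaves the volume are masked and counted.
#'
#' @param vol a [volume_image()] (typically the T1w/T2w ratio).
#' @param pair a [surface_pair()].
#' @param kernel a [sampling_kernel()].
#' @return a [metric_map()] (ratio units) with attribute `n_masked`.
#' @export
sample_to_surface <- function(vol, pair, kernel = sampling_kernel()) {
  stopifnot(inherits(pair, "surface_pair"), inherits(kernel, "sampling_kernel"))
  W <- pair$white$vertices
  P <- pair$pial$vertices
  nv <- nrow(W)
  n <- kernel$n_samples
  tfrac <- seq(0, 1, length.out = n)
  seglen <- sqrt(rowSums((P - W)^2))

  vals <- matrix(NA_real_, nv, n)
  wts <- matrix(0, nv, n)
  for (s in seq_len(n)) {
    pos <- W + tfrac[s] * (P - W)
    vals[, s] <- trilinear_sample(vol, pos)
    dist_mid <- (tfrac[s] - 0.5) * seglen
    wts[, s] <- exp(-dist_mid^2 / (2 * kernel$sigma_mm^2))
  }
  wts[!is.finite(vals)] <- 0
  vals[!is.finite(vals)] <- 0
  tot <- rowSums(wts)
  out <- ifelse(tot > 0, rowSums(vals * wts) / tot, NA_real_)
  n_masked <- sum(tot == 0)
  if (n_masked > 0)
    warning(n_masked, " vertex(es) masked (no finite volume sample)")
  res <- metric_map(out, units = "ratio")
  attr(res, "n_masked") <- n_masked
  res
}

#' Template-referenced low-frequency bias correction
#'
#' Removes the spatially low-frequency (sigma = 5 mm by default) difference
#' between an individual myelin map and a symmetrized template:
#' `corrected = individual - smooth(individual - template, sigma)`.
#' Constants in the difference are removed exactly; sharp (areal) structure
#' in the individual map passes through. Masked vertices propagate.
#'
#' @param individual,template [metric_map()]s on the same mesh.
#' @param mesh the [triangle_mesh()] both maps live on.
#' @param sigma_mm smoothing sigma of the removed component (mm).
#' @return corrected [metric_map()].
#' @export
bias_correct <- function(individual, template, mesh, sigma_mm = 5) {
  stopifnot(sigma_mm > 0)
  check_same_mesh(individual, template)
  ind <- metric_values(individual, mesh)
  tem <- metric_values(template, mesh)
  diff <- ind - tem
  low <- smooth_metric(mesh, metric_map(diff, "ratio"), sigma_mm)$values
  metric_map(ind - low, units = "ratio")
}

#' Symmetrized group-average myelin template
#'
#' Vertexwise mean across subjects, then averaged with its mirrored
#' counterpart under the left/right vertex correspondence. The phantoms'
#' mirror correspondence is the identity map (right hemispheres are exact
#' mirror images sharing vertex indices), which is the default.
#'
#' @param maps list of [metric_map()]s (or numeric vectors) on a common mesh.
#' @param lr_correspondence integer vector mapping each vertex to its
#'   mirror-image vertex; defaults to the identity.
#' @return template [metric_map()].
#' @export
build_group_template <- function(maps, lr_correspondence = NULL) {
  stopifnot(length(maps) >= 1)
  vals <- vapply(maps, function(m) metric_values(m), numeric(length(metric_values(maps[[1]]))))
  avg <- rowMeans(vals)
  if (is.null(lr_correspondence)) lr_correspondence <- seq_along(avg)
  metric_map((avg + avg[lr_correspondence]) / 2, units = "ratio")
}
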