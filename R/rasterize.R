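#' Smooth multiplicative bias field generator
#'
#' Sum of three random low-order harmonic components: plane waves with unit
#' random directions, spatial scale `s` (= wavelength / 2*pi) at least 15 mm
#' so the field is separable from areal transitions by a 5 mm correction.
#' The field is `B(x) = 1 + amplitude * g(x)` with `|g| <= 1`.
#'
#' @param amplitude peak relative amplitude (fraction; < 1).
#' @param scale_mm smoothness scale of each component (mm, floor 15).
#' @param seed integer seed for directions and phases.
#' @return function mapping an `n x 3` matrix of world coordinates to the
#'   bias value at each point.
#' @export
make_bias_field <- function(amplitude, scale_mm = 20, seed = 1L) {
  stopifnot(amplitude >= 0, amplitude < 1)
  if (scale_mm < 15) stop("bias smoothness scale must be >= 15 mm")
  with_seed(derive_seed(seed, 77L), {
    dirs <- matrix(stats::rnorm(9), 3, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    phases <- stats::runif(3, 0, 2 * pi)
  })
  function(xyz) {
    xyz <- as.matrix(xyz)
    g <- 0
    for (j in 1:3)
      g <- g + sin((xyz %*% dirs[j, ]) / scale_mm + phases[j])
    as.numeric(1 + amplitude * g / 3)
  }
}

#' Rasterize a phantom hemisphere into T1w and T2w volumes
#'
#' Inverse model of the T1w/T2w contrast mechanism. Within the cortical
#' ribbon the noiseless, unbiased T1w/T2w ratio at a voxel equals the
#' ground-truth myelin field of the nearest correspondence segment:
#' `T1w = B(x) * sqrt(m)` and `T2w = B(x)^-1 / sqrt(m)` (monotone
#' increasing / decreasing in `m`), so the ratio carries the squared bias,
#' `ratio = m * B(x)^2`. Outside the ribbon both images take background
#' intensities distinct from cortex. A guard band of roughly one voxel of
#' cortex-valued samples beyond the white and pial boundaries limits
#' partial-volume contamination of trilinear samples taken near the
#' surfaces (the phantom's stand-in for ribbon-constrained partial-volume
#' handling).
#'
#' Ribbon membership and values are assigned by dense splatting: each
#' white/pial prism is sampled on a barycentric-by-depth grid finer than
#' half a voxel, and each voxel takes the value of the sample nearest its
#' center (ribbon samples preferred over guard samples). Assumes the
#' phantom's star-shaped geometry.
#'
#' @param pair a [surface_pair()].
#' @param truth phantom truth from [make_hemisphere()] (uses `myelin_field`).
#' @param voxel_mm isotropic voxel size; must be at most half the median
#'   correspondence thickness so at least two voxels span the ribbon.
#' @param bias_amplitude relative amplitude of the multiplicative bias.
#' @param noise_sd additive Gaussian noise sd applied per voxel to T1w and
#'   T2w (intensity units) before any ratio is taken.
#' @param seed integer seed for bias and noise.
#' @param bias_scale_mm smoothness scale of the bias components (mm).
#' @return list of [volume_image()]s `t1w`, `t2w`, `bias`, plus `ribbon`
#'   (logical array: voxels whose center value came from inside the
#'   ribbon) and `bias_fun` (the analytic bias function).
#' @export
rasterize_volumes <- function(pair, truth, voxel_mm, bias_amplitude = 0,
                              noise_sd = 0, seed = 1L, bias_scale_mm = 20) {
  stopifnot(inherits(pair, "surface_pair"))
  th <- correspondence_thickness(pair)$values
  if (voxel_mm > stats::median(th) / 2)
    stop("voxel_mm = ", voxel_mm, " exceeds half the median thickness (",
         round(stats::median(th) / 2, 3), " mm); need >= 2 voxels in the ribbon")

  W <- pair$white$vertices
  P <- pair$pial$vertices
  f <- pair$white$faces
  m <- metric_values(truth$myelin_field, pair$white)

  lo <- apply(pmin(W, P), 2, min) - 2 * voxel_mm
  hi <- apply(pmax(W, P), 2, max) + 2 * voxel_mm
  dims <- as.integer(ceiling((hi - lo) / voxel_mm)) + 1L
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- lo

  # barycentric pattern finer than half a voxel
  edges <- mesh_edges(pair$white)
  mid <- (W + P) / 2
  emax <- max(sqrt(rowSums((mid[edges[, 1], ] - mid[edges[, 2], ])^2)))
  nb <- max(2L, as.integer(ceiling(emax / (0.5 * voxel_mm))))
  bc <- expand.grid(i = 0:nb, j = 0:nb)
  bc <- bc[bc$i + bc$j <= nb, ]
  bary <- cbind(bc$i, bc$j, nb - bc$i - bc$j) / nb

  # depth pattern with ~1-voxel guard band beyond each surface
  guard <- 0.75 * voxel_mm / stats::median(th)
  tmax <- max(th)
  nt <- max(3L, as.integer(ceiling((1 + 2 * guard) * tmax / (0.5 * voxel_mm))))
  tt <- seq(-guard, 1 + guard, length.out = nt)

  nfc <- nrow(f)
  npat <- nrow(bary)
  # per (face, bary) endpoints and values
  wx <- matrix(0, nfc * npat, 3); px <- matrix(0, nfc * npat, 3)
  mv <- numeric(nfc * npat)
  for (k in 1:3) {
    wgt <- rep(bary[, k], each = nfc)
    vi <- rep(f[, k], npat)
    wx <- wx + wgt * W[vi, , drop = FALSE]
    px <- px + wgt * P[vi, , drop = FALSE]
    mv <- mv + wgt * m[vi]
  }

  nvox <- prod(dims)
  best_d2 <- rep(Inf, nvox)
  best_val <- rep(NA_real_, nvox)
  best_rib <- rep(FALSE, nvox)
  half <- voxel_mm / 2
  for (t in tt) {
    pos <- wx + t * (px - wx)
    ijk <- floor(sweep(pos, 2, lo, "-") / voxel_mm + 0.5)  # nearest voxel
    ctr <- sweep(ijk * voxel_mm, 2, lo, "+")
    d2 <- rowSums((pos - ctr)^2)
    rib <- t >= 0 && t <= 1
    lin <- as.integer(ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])) + 1L
    # rank ribbon samples above guard samples, then by distance
    key <- d2 + ifelse(rib, 0, 1e6)
    o <- order(lin, key)
    lin_o <- lin[o]
    first <- !duplicated(lin_o)
    li <- lin_o[first]
    cand_key <- key[o][first]
    cand_val <- mv[o][first]
    cur_key <- best_d2[li] + ifelse(best_rib[li], 0, 1e6)
    upd <- cand_key < cur_key
    li <- li[upd]
    best_d2[li] <- d2[o][first][upd]
    best_val[li] <- cand_val[upd]
    best_rib[li] <- rib
  }

  cortex <- !is.na(best_val)
  ribbon <- array(best_rib, dims)

  # voxel centers in world coordinates
  ii <- (seq_len(nvox) - 1L)
  vx <- ii %% dims[1]
  vy <- (ii %/% dims[1]) %% dims[2]
  vz <- ii %/% (dims[1] * dims[2])
  centers <- cbind(vx, vy, vz) * voxel_mm
  centers <- sweep(centers, 2, lo, "+")

  bias_fun <- make_bias_field(bias_amplitude, scale_mm = bias_scale_mm,
                              seed = seed)
  Bv <- bias_fun(centers)

  t1 <- rep(0.3, nvox)
  t2 <- rep(1.2, nvox)
  t1[cortex] <- sqrt(best_val[cortex])
  t2[cortex] <- 1 / sqrt(best_val[cortex])
  t1 <- t1 * Bv
  t2 <- t2 / Bv
  if (noise_sd > 0) {
    with_seed(derive_seed(seed, 3L), {
      t1 <- t1 + stats::rnorm(nvox, 0, noise_sd)
      t2 <- t2 + stats::rnorm(nvox, 0, noise_sd)
    })
  }

  list(t1w = volume_image(array(t1, dims), affine),
       t2w = volume_image(array(t2, dims), affine),
       bias = volume_image(array(Bv, dims), affine),
       ribbon = ribbon,
       bias_fun = bias_fun)
}
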