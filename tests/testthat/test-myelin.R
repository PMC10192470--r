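test_that("fwhm_to_sigma follows the Gaussian identity", {
  expect_equal(fwhm_to_sigma(2.3548), 1.0000, tolerance = 1e-4)
  expect_equal(fwhm_to_sigma(1.8), 0.7644, tolerance = 1e-4)
  expect_error(fwhm_to_sigma(0), "positive")
  expect_error(fwhm_to_sigma(-1), "positive")
})

test_that("sampling_kernel validates its sample count", {
  k <- sampling_kernel(1.8, 7)
  expect_equal(k$sigma_mm, 1.8 / (2 * sqrt(2 * log(2))))
  expect_error(sampling_kernel(1.8, 6), "odd")
  expect_error(sampling_kernel(1.8, 1), "odd")
})

test_that("ratio_volume matches the voxel-loop oracle and masks tiny T2w", {
  aff <- diag(4)
  set.seed(2)
  a <- volume_image(array(runif(4 * 5 * 6, 1, 2), c(4, 5, 6)), aff)
  b <- volume_image(array(runif(4 * 5 * 6, 1, 2), c(4, 5, 6)), aff)
  expect_true(all(ratio_volume(a, a)$data == 1))
  a2 <- volume_image(2 * b$data, aff)
  expect_equal(ratio_volume(a2, b)$data, array(2, c(4, 5, 6)), tolerance = 1e-12)

  r <- ratio_volume(a, b)
  oracle <- array(NA_real_, dim(a$data))
  for (i in seq_along(oracle)) oracle[i] <- a$data[i] / b$data[i]
  expect_equal(r$data, oracle, tolerance = 1e-12)

  b0 <- b
  b0$data[1, 1, 1] <- 0
  r0 <- ratio_volume(a, b0)
  expect_true(is.na(r0$data[1, 1, 1]))
  expect_error(ratio_volume(a, volume_image(array(1, c(2, 2, 2)), aff)),
               "grids differ")
})

test_that("surface sampling is exact for constant and linear fields", {
  # flat sheet pair: white at z = 1, pial at z = 2, in a volume of f = z
  g <- planar_grid_mesh(9, 9, 1)
  w <- g; w$vertices[, 3] <- 1
  p <- g; p$vertices[, 3] <- 2
  pair <- surface_pair(triangle_mesh(w$vertices, g$faces, validate = FALSE),
                       triangle_mesh(p$vertices, g$faces, validate = FALSE))
  aff <- diag(4); aff[1:3, 4] <- c(-2, -2, -2)
  d <- c(13, 13, 7)
  zval <- array(rep((0:(d[3] - 1)) - 2, each = d[1] * d[2]), d)
  vol <- volume_image(zval, aff)
  m <- sample_to_surface(vol, pair, sampling_kernel(1.8, 7))
  expect_equal(m$values, rep(1.5, length(m$values)), tolerance = 1e-9)

  cvol <- volume_image(array(4.2, d), aff)
  mc <- sample_to_surface(cvol, pair, sampling_kernel(1.8, 5))
  expect_equal(mc$values, rep(4.2, length(mc$values)), tolerance = 1e-12)
})

test_that("7-point Gaussian quadrature tracks a dense quadrature oracle", {
  g <- planar_grid_mesh(9, 9, 1)
  w <- triangle_mesh(cbind(g$vertices[, 1:2], 1), g$faces, validate = FALSE)
  p <- triangle_mesh(cbind(g$vertices[, 1:2], 2.6), g$faces, validate = FALSE)
  pair <- surface_pair(w, p)
  aff <- diag(4); aff[1:3, 4] <- c(-2, -2, -2)
  d <- c(13, 13, 8)
  idx <- expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1))
  xyz <- sweep(as.matrix(idx), 2, c(2, 2, 2), "-")
  f <- 1.5 + 0.3 * sin(0.8 * xyz[, 3]) + 0.1 * cos(0.5 * xyz[, 1]) * xyz[, 3]
  vol <- volume_image(array(f, d), aff)
  kernel <- sampling_kernel(1.8, 7)
  m7 <- sample_to_surface(vol, pair, kernel)$values

  # dense quadrature with the same weighting, independent trilinear code
  tril <- function(pt) {
    v <- pt + 2
    i0 <- floor(v); fr <- v - i0
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      wgt <- (if (dx) fr[1] else 1 - fr[1]) * (if (dy) fr[2] else 1 - fr[2]) *
             (if (dz) fr[3] else 1 - fr[3])
      acc <- acc + wgt * vol$data[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
    }
    acc
  }
  nvert <- nrow(w$vertices)
  oracle <- numeric(nvert)
  tfrac <- seq(0, 1, length.out = 1001)
  for (i in seq_len(nvert)) {
    seg <- sqrt(sum((p$vertices[i, ] - w$vertices[i, ])^2))
    wts <- exp(-((tfrac - 0.5) * seg)^2 / (2 * kernel$sigma_mm^2))
    vals <- vapply(tfrac, function(t)
      tril(w$vertices[i, ] + t * (p$vertices[i, ] - w$vertices[i, ])), 0)
    oracle[i] <- sum(vals * wts) / sum(wts)
  }
  expect_lt(sqrt(mean((m7 - oracle)^2)) / mean(abs(oracle)), 0.005)
})

test_that("sampling masks vertices outside the volume and is monotone", {
  g <- planar_grid_mesh(5, 5, 1)
  w <- triangle_mesh(cbind(g$vertices[, 1:2], 20), g$faces, validate = FALSE)
  p <- triangle_mesh(cbind(g$vertices[, 1:2], 30), g$faces, validate = FALSE)
  aff <- diag(4); aff[1:3, 4] <- c(-2, -2, -2)
  vol <- volume_image(array(1, c(9, 9, 6)), aff)
  expect_warning(m <- sample_to_surface(vol, surface_pair(w, p),
                                        sampling_kernel(40, 3)), "masked")
  expect_true(all(is.na(m$values)))

  set.seed(4)
  d <- c(9, 9, 6)
  base <- array(runif(prod(d), 1, 2), d)
  va <- volume_image(base + 0.3, aff)
  vb <- volume_image(base, aff)
  w2 <- triangle_mesh(cbind(g$vertices[, 1:2], 1), g$faces, validate = FALSE)
  p2 <- triangle_mesh(cbind(g$vertices[, 1:2], 3), g$faces, validate = FALSE)
  pr <- surface_pair(w2, p2)
  ma <- sample_to_surface(va, pr, sampling_kernel(1.8, 7))$values
  mb <- sample_to_surface(vb, pr, sampling_kernel(1.8, 7))$values
  expect_true(all(ma >= mb))
})

test_that("bias correction removes smooth differences and keeps templates fixed", {
  s <- icosphere(3, 12)
  set.seed(8)
  template <- metric_map(1.4 + 0.3 * sin(s$vertices[, 1] / 4), "ratio")
  same <- bias_correct(template, template, s, 5)
  expect_equal(same$values, template$values, tolerance = 1e-12)

  shifted <- metric_map(template$values + 0.25, "ratio")
  corr <- bias_correct(shifted, template, s, 5)
  expect_equal(corr$values, template$values, tolerance = 1e-9)
})

test_that("masked vertices propagate through bias correction", {
  s <- icosphere(2, 12)
  tem <- metric_map(rep(1.5, nrow(s$vertices)), "ratio")
  ind <- tem
  ind$values[3] <- NA
  out <- bias_correct(ind, tem, s, 3)
  expect_true(is.na(out$values[3]))
  expect_equal(out$values[-3], tem$values[-3], tolerance = 1e-9)
})

test_that("group templates are two-stage means with mirror symmetrization", {
  s <- icosphere(2, 10)
  nv <- nrow(s$vertices)
  # mirror correspondence on the icosphere: nearest vertex of x -> -x image
  mirr <- nearest_vertex(cbind(-s$vertices[, 1], s$vertices[, 2:3]),
                         s$vertices)
  sym <- metric_map(s$vertices[, 2]^2, "ratio")       # mirror-symmetric
  expect_equal(build_group_template(list(sym), mirr)$values, sym$values,
               tolerance = 1e-9)
  anti <- metric_map(s$vertices[, 1], "ratio")        # mirror-antisymmetric
  tpl <- build_group_template(list(anti), mirr)
  expect_equal(tpl$values, rep(0, nv), tolerance = 1e-9)

  set.seed(5)
  maps <- lapply(1:4, function(i) metric_map(rnorm(nv), "ratio"))
  got <- build_group_template(maps, mirr)$values
  avg <- rowMeans(vapply(maps, function(m) m$values, numeric(nv)))
  expect_equal(got, (avg + avg[mirr]) / 2, tolerance = 1e-12)
})

test_that("zero-noise phantom myelin is recovered within 2% away from borders", {
  hm <- cached_one_parcel_hemi()
  vols <- rasterize_volumes(hm$pair, hm$truth, voxel_mm = 0.7)
  r <- ratio_volume(vols$t1w, vols$t2w)
  m <- sample_to_surface(r, hm$pair, sampling_kernel(1.8, 7))
  lab <- hm$truth$labels$labels
  adj <- myeloparc:::vertex_neighbors(hm$pair$white)
  inside <- which(lab == 1L)
  # vertices within two edges of the label border, on either side
  border <- inside[vapply(inside, function(v) any(lab[adj[[v]]] == 0L), TRUE)]
  border <- union(border, setdiff(unique(unlist(adj[inside])), inside))
  zone <- unique(unlist(adj[unique(unlist(adj[border]))]))
  far <- setdiff(seq_along(lab), union(border, zone))
  truth <- hm$truth$myelin_field$values
  relerr <- abs(m$values[far] - truth[far]) / truth[far]
  expect_lt(max(relerr), 0.02)
})
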