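test_that("ridge extraction is empty for constants and localizes a step", {
  g <- planar_grid_mesh(25, 25, 1)
  flat <- metric_gradient(g, rep(1, nrow(g$vertices)), 0)
  expect_length(extract_ridges(g, flat, boundary_criteria()), 0)

  # step along the line x = 12
  f <- as.numeric(g$vertices[, 1] >= 12)
  gr <- metric_gradient(g, f, 0.6)
  ridge <- extract_ridges(g, gr, boundary_criteria(min_ridge_component = 5))
  expect_gt(length(ridge), 0)
  xs <- g$vertices[ridge, 1]
  expect_true(all(xs >= 10 & xs <= 13))        # band contains the step line
  expect_lte(length(unique(xs)), 3)            # band is <= 3 vertices wide
  expect_equal(nrow(attr(ridge, "components")), 1)
})

test_that("two myelin islands give two closed ridge components", {
  hm <- cached("two_island_hemi", function() {
    spec <- species_spec("twoisl", 1,
                         target_fractions = c(A = 0.05, B = 0.05),
                         myelin_levels = c(A = 0.6, B = 0.6),
                         mean_thickness_mm = 2, total_area_scale = 12.7,
                         seed = 5, subdivisions = 4, fraction_jitter_rel = 0)
    make_hemisphere(spec, 1, "L")
  })
  mesh <- compute_midthickness(hm$pair)
  gr <- metric_gradient(mesh, hm$truth$myelin_field, 0.5)
  ridge <- extract_ridges(mesh, gr, boundary_criteria(ridge_threshold = 0.25))
  expect_equal(nrow(attr(ridge, "components")), 2)
  # each loop is closed: flood fill from a seed stays inside its island
  for (nm in c("A", "B")) {
    seedv <- hm$truth$seeds[[nm]]
    grown <- grow_parcel(mesh, ridge, seedv, nm)
    expect_lt(sum(grown$labels > 0), 0.10 * length(grown$labels))
  }
})

test_that("ridge sets are monotone in the threshold", {
  hm <- cached_one_parcel_hemi()
  mesh <- compute_midthickness(hm$pair)
  gr <- metric_gradient(mesh, hm$truth$myelin_field, 0.5)
  lower <- extract_ridges(mesh, gr, boundary_criteria(ridge_threshold = 0.2,
                                                      min_ridge_component = 1))
  higher <- extract_ridges(mesh, gr, boundary_criteria(ridge_threshold = 0.6,
                                                       min_ridge_component = 1))
  expect_true(all(higher %in% lower))
})

test_that("grow_parcel matches the brute-force flood-fill oracle", {
  hm <- cached_one_parcel_hemi()
  mesh <- compute_midthickness(hm$pair)
  gr <- metric_gradient(mesh, hm$truth$myelin_field, 0.5)
  ridge <- extract_ridges(mesh, gr, boundary_criteria(ridge_threshold = 0.25))
  seedv <- hm$truth$seeds[["MT+"]]
  grown <- grow_parcel(mesh, ridge, seedv, "MT+")
  inside <- which(grown$labels == 1L)
  expect_identical(inside, oracle_flood_fill(mesh, ridge, seedv))
  expect_true(all(grown$labels[ridge] == 0L))

  # complement: a seed outside the loop reaches mesh minus interior minus ridge
  out_seed <- setdiff(seq_len(nrow(mesh$vertices)), c(inside, ridge))[1]
  expect_warning(outer <- grow_parcel(mesh, ridge, out_seed, "rest"), "leaky")
  expect_identical(which(outer$labels == 1L),
                   sort(setdiff(seq_len(nrow(mesh$vertices)),
                                c(inside, ridge))))

  expect_error(grow_parcel(mesh, ridge, ridge[1], "bad"), "boundary")
  expect_warning(all_mesh <- grow_parcel(mesh, integer(0), seedv, "all"),
                 "leaky")
  expect_true(all(all_mesh$labels == 1L))
})

test_that("label resampling is the identity on identical meshes and survives subdivision", {
  s3 <- icosphere(3, 10)
  set.seed(2)
  lab <- parcel_labels(sample(0:2, nrow(s3$vertices), replace = TRUE),
                       c(one = 1L, two = 2L))
  same <- resample_labels(s3, lab, s3)
  expect_identical(same$labels, lab$labels)

  s4 <- icosphere(4, 10)
  up <- resample_labels(s3, lab, s4)
  back <- resample_labels(s4, up, s3)
  expect_identical(back$labels, lab$labels)
  # parcel areas change < 5% under subdivision resampling
  a3 <- vertex_areas(s3)$values
  a4 <- vertex_areas(s4)$values
  for (k in 1:2) {
    f3 <- sum(a3[lab$labels == k]) / sum(a3)
    f4 <- sum(a4[up$labels == k]) / sum(a4)
    expect_lt(abs(f4 - f3) / f3, 0.05)
  }

  full <- parcel_labels(rep(1L, nrow(s3$vertices)), c(all = 1L))
  expect_true(all(resample_labels(s3, full, s4)$labels == 1L))
})

test_that("standard parcels are recovered from the phantom at zero noise", {
  hm <- cached_night_hemi()
  mesh <- compute_midthickness(hm$pair)
  lab <- delineate_standard_parcels(hm$truth$myelin_field,
                                    hm$truth$thickness, mesh,
                                    hm$truth$seeds)
  nv <- nrow(mesh$vertices)
  for (pn in names(hm$truth$seeds)) {
    a <- which(lab$labels == label_of(lab, pn))
    b <- which(hm$truth$labels$labels == label_of(hm$truth$labels, pn))
    expect_gte(dice_coefficient(a, b, n = nv), 0.90)
  }
  # the low-myelin island is recovered by the same machinery
  ba7 <- which(lab$labels == label_of(lab, "BA7"))
  expect_gt(length(ba7), 0)
  expect_lt(median(hm$truth$myelin_field$values[ba7]), 1.3)

  none <- delineate_standard_parcels(hm$truth$myelin_field,
                                     hm$truth$thickness, mesh,
                                     integer(0))
  expect_true(all(none$labels == 0L))
})

test_that("parcel recovery tolerates myelin noise", {
  hm <- cached_night_hemi()
  mesh <- compute_midthickness(hm$pair)
  nv <- nrow(mesh$vertices)
  set.seed(21)
  for (draw in 1:2) {
    noisy <- metric_map(hm$truth$myelin_field$values +
                          rnorm(nv, 0, 0.05 * 0.6), "ratio")
    lab <- delineate_standard_parcels(noisy, hm$truth$thickness, mesh,
                                      hm$truth$seeds)
    for (pn in names(hm$truth$seeds)) {
      a <- which(lab$labels == label_of(lab, pn))
      b <- which(hm$truth$labels$labels == label_of(hm$truth$labels, pn))
      expect_gte(dice_coefficient(a, b, n = nv), 0.80)
    }
  }
})
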