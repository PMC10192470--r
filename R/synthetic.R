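#' Species specification for the phantom generator
#'
#' Bundles the per-species parameters of the phantom population: hemisphere
#' size, cortical thickness, parcel area fractions and myelin contrasts, the
#' species' myelin-sampling kernel width, and the master seed. Defaults for
#' the biological variability knobs are set to the between-subject spreads
#' reported for real populations of this kind (total area sd ~6%, parcel
#' area sd ~5%).
#'
#' @param name species label (must be unique within a population).
#' @param n_subjects number of subjects (each contributes 2 hemispheres).
#' @param target_fractions named numeric vector, parcel name -> fraction of
#'   total surface area (0-1); the sum must be <= 1.
#' @param myelin_levels named numeric vector, parcel name -> contrast in
#'   ratio units relative to `background_level` (positive = more myelinated).
#' @param mean_thickness_mm mean cortical thickness (mm).
#' @param total_area_scale base hemisphere radius (mm); total surface area
#'   scales as its square.
#' @param sampling_fwhm_mm per-species Gaussian myelin-sampling kernel FWHM
#'   (mm); 1.8 mm is the night-monkey optimum.
#' @param seed integer master seed; everything derived from it.
#' @param subdivisions icosphere subdivisions of the hemisphere mesh.
#' @param fold_amplitude relative amplitude of the sinusoidal sulcal
#'   indentations (0 = perfect sphere).
#' @param background_level baseline myelin in ratio units.
#' @param thickness_factors optional named vector, parcel name -> relative
#'   thickness multiplier (e.g. a thin V1-like parcel).
#' @param area_jitter_rel between-subject sd of hemisphere linear scale
#'   (relative); total area jitter is about twice this.
#' @param fraction_jitter_rel between-subject sd of each parcel's target
#'   fraction (relative).
#' @param thickness_jitter_rel between-subject sd of mean thickness
#'   (relative).
#' @param thickness_wiggle relative amplitude of the smooth within-
#'   hemisphere thickness variation (0 = uniform thickness).
#' @return object of class `species_spec`.
#' @export
species_spec <- function(name, n_subjects, target_fractions = numeric(),
                         myelin_levels = numeric(),
                         mean_thickness_mm = 2.0,
                         total_area_scale = 12.7,
                         sampling_fwhm_mm = 1.8,
                         seed = 1L,
                         subdivisions = 4L,
                         fold_amplitude = 0.06,
                         background_level = 1.4,
                         thickness_factors = numeric(),
                         area_jitter_rel = 0.03,
                         fraction_jitter_rel = 0.03,
                         thickness_jitter_rel = 0.02,
                         thickness_wiggle = 0.04) {
  stopifnot(n_subjects >= 1, mean_thickness_mm > 0, total_area_scale > 0,
            sampling_fwhm_mm > 0)
  if (length(target_fractions)) {
    stopifnot(!is.null(names(target_fractions)),
              all(target_fractions > 0))
    if (sum(target_fractions) > 1)
      stop("target_fractions sum to ", sum(target_fractions), " > 1")
    missing_lv <- setdiff(names(target_fractions), names(myelin_levels))
    if (length(missing_lv))
      stop("no myelin level for parcel(s): ", paste(missing_lv, collapse = ", "))
  }
  structure(list(
    name = name, n_subjects = as.integer(n_subjects),
    target_fractions = target_fractions, myelin_levels = myelin_levels,
    mean_thickness_mm = mean_thickness_mm, total_area_scale = total_area_scale,
    sampling_fwhm_mm = sampling_fwhm_mm, seed = as.integer(seed),
    subdivisions = as.integer(subdivisions), fold_amplitude = fold_amplitude,
    background_level = background_level, thickness_factors = thickness_factors,
    area_jitter_rel = area_jitter_rel,
    fraction_jitter_rel = fraction_jitter_rel,
    thickness_jitter_rel = thickness_jitter_rel,
    thickness_wiggle = thickness_wiggle), class = "species_spec")
}

#' Default three-species phantom specifications
#'
#' Night-monkey-, macaque-, and marmoset-like specs whose hemisphere sizes,
#' thicknesses, sample sizes, and parcel area fractions follow the reported
#' group values for the three species (total mid-thickness area 2030, 9894,
#' and 1053 mm^2; 9, 32, and 20 subjects; MT+ fractions 2.4, 0.9, 1.2%;
#' auditory 2.5, 0.6, 1.5%; BA7 2.3, 3.2, 2.0%; V1 18.8, 11.7, 20.4%).
#'
#' @param seed master seed for the population.
#' @param subdivisions mesh resolution per hemisphere.
#' @param parcels subset of `c("MT+", "AC", "BA7", "V1")` to include.
#' @param n_subjects optional length-3 override of subject counts
#'   (night, macaque, marmoset), e.g. for a desk-scale run.
#' @return named list of three [species_spec()] objects.
#' @export
default_species_specs <- function(seed = 1L, subdivisions = 4L,
                                  parcels = c("MT+", "AC", "BA7", "V1"),
                                  n_subjects = c(9L, 32L, 20L)) {
  levels <- c("MT+" = 0.60, "AC" = 0.45, "BA7" = -0.25, "V1" = 0.55)
  thfac <- c("V1" = 0.78)  # V1-like parcel is thin (~1.5 vs 1.9 mm)
  fr <- list(
    night   = c("MT+" = 0.024, "AC" = 0.025, "BA7" = 0.023, "V1" = 0.188),
    macaque = c("MT+" = 0.009, "AC" = 0.006, "BA7" = 0.032, "V1" = 0.117),
    marmoset = c("MT+" = 0.012, "AC" = 0.015, "BA7" = 0.020, "V1" = 0.204))
  radius <- c(night = sqrt(2030 / (4 * pi)),
              macaque = sqrt(9894 / (4 * pi)),
              marmoset = sqrt(1053 / (4 * pi)))
  thick <- c(night = 1.91, macaque = 2.1, marmoset = 1.7)
  names(n_subjects) <- c("night", "macaque", "marmoset")
  out <- lapply(names(fr), function(sp) {
    species_spec(
      name = sp, n_subjects = n_subjects[[sp]],
      target_fractions = fr[[sp]][parcels],
      myelin_levels = levels[parcels],
      mean_thickness_mm = thick[[sp]],
      total_area_scale = radius[[sp]],
      sampling_fwhm_mm = 1.8,
      seed = derive_seed(seed, match(sp, names(fr))),
      subdivisions = subdivisions,
      thickness_factors = thfac[intersect("V1", parcels)])
  })
  names(out) <- names(fr)
  out
}

# canonical parcel center directions on the unit sphere (well separated);
# unknown names fall back to a golden-spiral sequence
parcel_direction <- function(name, k) {
  fixed <- list(
    "MT+" = c(sin(80 * pi / 180), 0, cos(80 * pi / 180)),
    "AC"  = c(sin(80 * pi / 180) * cos(2 * pi / 3),
              sin(80 * pi / 180) * sin(2 * pi / 3), cos(80 * pi / 180)),
    "BA7" = c(sin(80 * pi / 180) * cos(4 * pi / 3),
              sin(80 * pi / 180) * sin(4 * pi / 3), cos(80 * pi / 180)),
    "V1"  = c(0, 0, -1))
  if (!is.null(fixed[[name]])) return(fixed[[name]])
  ga <- pi * (3 - sqrt(5))
  z <- 1 - (k - 0.5) / 4
  r <- sqrt(1 - z^2)
  c(r * cos(k * ga), r * sin(k * ga), z)
}

# grow an edge-connected geodesic patch around `center` to a target area.
# Frontier-constrained greedy growth: repeatedly admit the frontier vertex
# closest (3-D Euclidean) to the center vertex, so the patch stays connected.
grow_patch <- function(adj, dist_to_center, areas, center, target_area,
                       blocked, parcel_name) {
  if (max(areas) / 2 > 0.1 * target_area)
    stop("target fraction for parcel '", parcel_name,
         "' unreachable at this mesh resolution")
  nv <- length(areas)
  in_patch <- rep(FALSE, nv)
  in_front <- rep(FALSE, nv)
  in_patch[center] <- TRUE
  acc <- areas[center]
  frontier <- setdiff(adj[[center]], which(blocked))
  in_front[frontier] <- TRUE
  while (acc < target_area) {
    if (!length(frontier))
      stop("growth for parcel '", parcel_name, "' exhausted the mesh")
    k <- which.min(dist_to_center[frontier])
    v <- frontier[k]
    if (acc + areas[v] - target_area > target_area - acc) break
    frontier <- frontier[-k]
    in_front[v] <- FALSE
    in_patch[v] <- TRUE
    acc <- acc + areas[v]
    nb <- adj[[v]]
    nb <- nb[!in_patch[nb] & !in_front[nb] & !blocked[nb]]
    in_front[nb] <- TRUE
    frontier <- c(frontier, nb)
  }
  which(in_patch)
}

#' Generate one phantom hemisphere with ground truth
#'
#' Builds a folded white/pial surface pair (radially perturbed icosphere
#' with three sinusoidal sulcal indentations), places the requested parcels
#' as geodesic patches grown to their target area fractions, and lays down
#' the ground-truth myelin field (background plus parcel contrasts with a
#' transition zone no wider than about two edge lengths). Deterministic
#' given `(spec$seed, subject_index, hemisphere)`; the right hemisphere is
#' the exact mirror image of the left.
#'
#' @param spec a [species_spec()].
#' @param subject_index subject number (1-based).
#' @param hemisphere `"L"` or `"R"`.
#' @return list with elements `pair` (a [surface_pair()]) and `truth`
#'   (labels, myelin_field, thickness field, per-parcel seed vertices,
#'   realized fractions and areas).
#' @export
make_hemisphere <- function(spec, subject_index = 1L, hemisphere = c("L", "R")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(inherits(spec, "species_spec"))
  seed <- derive_seed(spec$seed, subject_index)
  with_seed(seed, {
    base <- icosphere(spec$subdivisions, radius = 1)
    u <- base$vertices                      # unit directions
    nv <- nrow(u)

    # subject-level jitter
    scale <- spec$total_area_scale * (1 + stats::rnorm(1, 0, spec$area_jitter_rel))
    tbar <- spec$mean_thickness_mm * (1 + stats::rnorm(1, 0, spec$thickness_jitter_rel))
    fractions <- spec$target_fractions
    if (length(fractions))
      fractions <- fractions * (1 + stats::rnorm(length(fractions), 0,
                                                 spec$fraction_jitter_rel))

    # 3 sinusoidal sulcal indentations with random axes and phases
    r <- rep(1, nv)
    if (spec$fold_amplitude > 0) {
      for (k in 1:3) {
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        ph <- stats::runif(1, 0, 2 * pi)
        freq <- sample(3:5, 1)
        r <- r - (spec$fold_amplitude / 3) * sin(freq * acos(pmin(1, pmax(-1, u %*% ax))) + ph)^2
      }
    }
    mid_v <- u * (r * scale)
    mid <- triangle_mesh(mid_v, base$faces, validate = FALSE)

    # parcels as geodesic patches on the mid surface
    areas <- vertex_areas(mid)$values
    total <- sum(areas)
    adj <- vertex_neighbors(mid)
    labels <- integer(nv)
    seeds <- integer(0)
    pnames <- names(fractions)
    name_tab <- integer(0)
    if (length(fractions)) {
      name_tab <- stats::setNames(seq_along(pnames), pnames)
      for (k in seq_along(pnames)) {
        dir <- parcel_direction(pnames[k], k)
        center <- which.max(u %*% dir)
        d2c <- sqrt(rowSums((mid_v - matrix(mid_v[center, ], nv, 3, byrow = TRUE))^2))
        patch <- grow_patch(adj, d2c, areas, center,
                            fractions[k] * total, labels != 0L, pnames[k])
        if (any(labels[patch] != 0L))
          stop("parcel '", pnames[k], "' overlaps an earlier parcel")
        labels[patch] <- k
        seeds[pnames[k]] <- center
      }
    }
    plab <- parcel_labels(labels, name_tab)

    # ground-truth myelin field: background + contrasts, narrow transition
    m <- rep(spec$background_level, nv)
    for (k in seq_along(pnames))
      m[labels == k] <- spec$background_level + spec$myelin_levels[[pnames[k]]]
    ebar <- mean(sqrt(rowSums((mid_v[mesh_edges(mid)[, 1], ] -
                               mid_v[mesh_edges(mid)[, 2], ])^2)))
    myelin <- smooth_metric(mid, metric_map(m, "ratio"), 0.5 * ebar)

    # thickness field: smooth global variation + per-parcel factors
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    tfield <- tbar * (1 + spec$thickness_wiggle *
                        sin(2 * acos(pmin(1, pmax(-1, u %*% ax)))))
    tf <- rep(1, nv)
    for (nm in names(spec$thickness_factors))
      if (nm %in% pnames) tf[labels == name_tab[[nm]]] <- spec$thickness_factors[[nm]]
    tf <- smooth_metric(mid, metric_map(tf, "1"), 0.5 * ebar)$values
    tfield <- as.numeric(tfield) * tf

    white <- triangle_mesh(mid_v - u * (tfield / 2), base$faces, validate = FALSE)
    pial <- triangle_mesh(mid_v + u * (tfield / 2), base$faces, validate = FALSE)

    realized_areas <- if (length(pnames))
      stats::setNames(vapply(seq_along(pnames),
                             function(k) sum(areas[labels == k]), 0), pnames)
      else stats::setNames(numeric(0), character(0))

    pair <- surface_pair(white, pial)
    if (hemisphere == "R") {
      pair <- surface_pair(mirror_mesh(white), mirror_mesh(pial))
    }
    list(
      pair = pair,
      truth = list(
        labels = plab,
        myelin_field = myelin,
        thickness = metric_map(tfield, "mm"),
        seeds = seeds,
        true_fractions = realized_areas / total,
        true_parcel_areas_mm2 = realized_areas,
        total_area_mm2 = total))
  })
}

#' Generate a multi-species phantom population
#'
#' `n_subjects x 2` hemisphere records per species, with seeds derived
#' deterministically from each spec's seed. Volumes are rasterized on
#' demand by the mapping stage (see [rasterize_volumes()]); pass
#' `rasterize = TRUE` to attach them here.
#'
#' @param specs list of [species_spec()] objects (unique names).
#' @param rasterize also attach T1w/T2w/bias volumes to each record.
#' @param voxel_mm,bias_amplitude,noise_sd rasterization parameters,
#'   forwarded to [rasterize_volumes()] when `rasterize = TRUE`.
#' @return list of subject records: `species`, `subject`, `hemisphere`,
#'   `pair`, `truth`, and (optionally) `volumes`.
#' @export
make_population <- function(specs, rasterize = FALSE, voxel_mm = 0.8,
                            bias_amplitude = 0, noise_sd = 0) {
  stopifnot(length(specs) >= 1)
  nm <- vapply(specs, function(s) s$name, "")
  if (anyDuplicated(nm)) stop("duplicate species names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  records <- list()
  for (spec in specs) {
    for (subj in seq_len(spec$n_subjects)) {
      for (hemi in c("L", "R")) {
        hm <- make_hemisphere(spec, subj, hemi)
        rec <- list(species = spec$name,
                    subject = sprintf("%s%02d", spec$name, subj),
                    hemisphere = hemi, pair = hm$pair, truth = hm$truth,
                    spec = spec)
        if (rasterize)
          rec$volumes <- rasterize_volumes(
            hm$pair, hm$truth, voxel_mm = voxel_mm,
            bias_amplitude = bias_amplitude, noise_sd = noise_sd,
            seed = derive_seed(spec$seed, subj, match(hemi, c("L", "R"))))
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  records
}
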