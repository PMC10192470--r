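PIPELINE_VERSION <- "myeloparc-pipeline-v1"

#' Pipeline configuration
#'
#' Bundles the species specifications and the stage parameters (sampling
#' kernel, bias-correction sigma, gradient pre-smoothing sigma, ridge
#' criteria, rasterization settings) with the output layout and global
#' seed. Validates eagerly so a malformed config fails before any stage
#' runs.
#'
#' @param species list of [species_spec()]s (unique names).
#' @param out_dir output directory (created if needed).
#' @param seed global integer seed; all stage randomness derives from it.
#' @param parcel_seeds `"truth"` (use each phantom's ground-truth seed
#'   vertices) or a named list mapping species -> named vertex vector.
#' @param voxel_frac voxel size as a fraction of each species' mean
#'   thickness (the resolution criterion needs at most 0.5).
#' @param bias_amplitude,noise_sd,bias_scale_mm rasterization parameters.
#' @param fwhm_mm sampling-kernel FWHM; `NULL` uses each species'
#'   `sampling_fwhm_mm`.
#' @param n_samples samples along each white-pial segment (odd).
#' @param bias_sigma_mm low-frequency bias-correction sigma (mm).
#' @param criteria a [boundary_criteria()] for parcellation.
#' @param write_gifti also write surfaces, myelin maps and labels as GIFTI
#'   (slower; the metrics/stats outputs are always written).
#' @param save_volumes also write rasterized volumes as NIfTI (large).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(species, out_dir, seed = 1L,
                            parcel_seeds = "truth",
                            voxel_frac = 0.4,
                            bias_amplitude = 0.1, noise_sd = 0.02,
                            bias_scale_mm = 20,
                            fwhm_mm = NULL, n_samples = 7L,
                            bias_sigma_mm = 5,
                            criteria = boundary_criteria(ridge_threshold = 0.25),
                            write_gifti = FALSE, save_volumes = FALSE) {
  stopifnot(length(species) >= 1)
  if (!all(vapply(species, inherits, TRUE, "species_spec")))
    stop("species must be a list of species_spec objects")
  nm <- vapply(species, function(s) s$name, "")
  if (anyDuplicated(nm)) stop("duplicate species names")
  if (is.null(parcel_seeds))
    stop("parcel_seeds is missing: pass \"truth\" or a per-species seed table")
  if (!identical(parcel_seeds, "truth")) {
    if (!is.list(parcel_seeds) || is.null(names(parcel_seeds)) ||
        !all(nm %in% names(parcel_seeds)))
      stop("parcel_seeds table must name every species: ",
           paste(setdiff(nm, names(parcel_seeds)), collapse = ", "))
  }
  if (voxel_frac <= 0 || voxel_frac > 0.5)
    stop("voxel_frac must be in (0, 0.5] to keep >= 2 voxels in the ribbon")
  structure(list(species = species, out_dir = out_dir, seed = as.integer(seed),
                 parcel_seeds = parcel_seeds, voxel_frac = voxel_frac,
                 bias_amplitude = bias_amplitude, noise_sd = noise_sd,
                 bias_scale_mm = bias_scale_mm, fwhm_mm = fwhm_mm,
                 n_samples = as.integer(n_samples),
                 bias_sigma_mm = bias_sigma_mm, criteria = criteria,
                 write_gifti = write_gifti, save_volumes = save_volumes,
                 version = PIPELINE_VERSION),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' The file holds the scalar stage parameters plus a `species` block whose
#' entries are [species_spec()] arguments. Round-trips losslessly with
#' [save_pipeline_config()].
#'
#' @param path config file (`.yaml`/`.yml`/`.json`).
#' @param out_dir,seed optional overrides.
#' @return a [pipeline_config()].
#' @export
load_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  species <- lapply(raw$species, function(sp) {
    sp$target_fractions <- unlist(sp$target_fractions)
    sp$myelin_levels <- unlist(sp$myelin_levels)
    sp$thickness_factors <- unlist(sp$thickness_factors)
    do.call(species_spec, sp)
  })
  args <- raw[setdiff(names(raw), c("species", "version"))]
  args$species <- species
  if (!is.null(out_dir)) args$out_dir <- out_dir
  if (!is.null(seed)) args$seed <- seed
  if (!is.null(args$criteria)) args$criteria <- do.call(boundary_criteria, args$criteria)
  do.call(pipeline_config, args)
}

#' Save a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path output `.yaml` path.
#' @return the path, invisibly.
#' @export
save_pipeline_config <- function(config, path) {
  lst <- unclass(config)
  lst$species <- lapply(lst$species, function(s) {
    s <- unclass(s)
    s[c("target_fractions", "myelin_levels", "thickness_factors")] <-
      lapply(s[c("target_fractions", "myelin_levels", "thickness_factors")],
             as.list)
    s
  })
  lst$criteria <- unclass(lst$criteria)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Run the full phantom pipeline: simulate, map, parcellate, metrics, stats
#'
#' Executes the stages in order on an in-memory population, writing the
#' metrics table, statistics report, group summaries, and a provenance
#' manifest (config echo, seed, per-output md5 checksums, mask/inversion
#' counts) under `config$out_dir`. Identical config and seed give
#' bitwise-identical outputs.
#'
#' Stage order: (1) simulate phantom hemispheres; (2) rasterize T1w/T2w,
#' form the ratio volume, sample it to the surface with the species'
#' Gaussian kernel, build the symmetrized group template, and remove the
#' low-frequency individual-template difference; (3) delineate parcels on
#' each species' group-average corrected map and project them to subjects
#' through the shared phantom correspondence; (4) per-hemisphere native-
#' space areal metrics; (5) interspecies two-way ANOVA with post hoc tests.
#'
#' @param config a [pipeline_config()].
#' @param responses response columns analysed in the stats stage.
#' @return list: `metrics` (long table), `anova` (per response),
#'   `posthoc`, `summary`, `recovery` (per species/parcel recovered vs true
#'   mean fractions and group-level Dice), `manifest` (also written as
#'   JSON). Invisible.
#' @export
run_pipeline <- function(config, responses = c("rel_area", "mean_thickness_mm",
                                               "rel_volume")) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[myeloparc] ", sprintf(...))

  counts <- list(masked_vertices = 0L, inverted_wedges = 0L)
  t0 <- proc.time()[["elapsed"]]

  # ---- stage 1+2: simulate and map each hemisphere -------------------------
  per_species <- list()
  for (spec in config$species) {
    log_msg("simulate+map species '%s' (%d subjects x 2 hemispheres)",
            spec$name, spec$n_subjects)
    voxel <- config$voxel_frac * spec$mean_thickness_mm
    fwhm <- if (is.null(config$fwhm_mm)) spec$sampling_fwhm_mm else config$fwhm_mm
    kernel <- sampling_kernel(fwhm, config$n_samples)
    recs <- list()
    for (subj in seq_len(spec$n_subjects)) {
      for (hemi in c("L", "R")) {
        hm <- make_hemisphere(spec, subj, hemi)
        vols <- rasterize_volumes(
          hm$pair, hm$truth, voxel_mm = voxel,
          bias_amplitude = config$bias_amplitude,
          noise_sd = config$noise_sd,
          bias_scale_mm = config$bias_scale_mm,
          seed = derive_seed(config$seed, spec$seed, subj,
                             match(hemi, c("L", "R"))))
        ratio <- ratio_volume(vols$t1w, vols$t2w)
        map <- sample_to_surface(ratio, hm$pair, kernel)
        counts$masked_vertices <- counts$masked_vertices +
          (attr(map, "n_masked") %||% 0L)
        if (config$save_volumes) {
          vd <- file.path(out, spec$name, sprintf("%s%02d_%s", spec$name, subj, hemi))
          dir.create(vd, showWarnings = FALSE, recursive = TRUE)
          write_volume_nifti(vols$t1w, file.path(vd, "t1w.nii.gz"))
          write_volume_nifti(vols$t2w, file.path(vd, "t2w.nii.gz"))
        }
        recs[[length(recs) + 1L]] <- list(
          subject = sprintf("%s%02d", spec$name, subj), hemisphere = hemi,
          pair = hm$pair, truth = hm$truth, map = map)
      }
    }
    maps <- lapply(recs, `[[`, "map")
    template <- build_group_template(maps)
    mid1 <- compute_midthickness(recs[[1]]$pair)
    corrected <- lapply(seq_along(recs), function(i)
      bias_correct(maps[[i]], template,
                   compute_midthickness(recs[[i]]$pair),
                   sigma_mm = config$bias_sigma_mm))
    for (i in seq_along(recs)) recs[[i]]$corrected <- corrected[[i]]
    per_species[[spec$name]] <- list(spec = spec, records = recs,
                                     template = template)
  }

  # ---- stage 3: group-level parcellation per species -----------------------
  recovery <- list()
  for (nm in names(per_species)) {
    ps <- per_species[[nm]]
    recs <- ps$records
    log_msg("parcellate species '%s' on the group-average map", nm)
    nvert <- length(recs[[1]]$map$values)
    group_map <- metric_map(rowMeans(vapply(recs, function(r)
      r$corrected$values, numeric(nvert))), "ratio")
    group_th <- metric_map(rowMeans(vapply(recs, function(r)
      correspondence_thickness(r$pair)$values, numeric(nvert))), "mm")
    gmesh <- compute_midthickness(recs[[1]]$pair)
    seeds <- if (identical(config$parcel_seeds, "truth"))
      recs[[1]]$truth$seeds else unlist(config$parcel_seeds[[nm]])
    labels <- delineate_standard_parcels(group_map, group_th, gmesh, seeds,
                                         criteria = config$criteria)
    per_species[[nm]]$labels <- labels
    if (config$write_gifti) {
      sd_ <- file.path(out, nm)
      dir.create(sd_, showWarnings = FALSE, recursive = TRUE)
      write_surface_gii(gmesh, file.path(sd_, "group_midthickness.surf.gii"))
      write_metric_gii(group_map, file.path(sd_, "group_myelin.func.gii"))
      write_label_gii(labels, file.path(sd_, "group_parcels.label.gii"))
    }
    # recovery diagnostics vs ground truth
    for (pn in names(seeds)) {
      truth_lab <- recs[[1]]$truth$labels
      a <- which(labels$labels == label_of(labels, pn))
      b <- which(truth_lab$labels == label_of(truth_lab, pn))
      recovery[[length(recovery) + 1L]] <- data.frame(
        species = nm, parcel = pn,
        dice_group = dice_coefficient(a, b, n = nvert),
        true_fraction_target = unname(ps$spec$target_fractions[pn]))
    }
  }
  recovery <- do.call(rbind, recovery)

  # ---- stage 4: native-space metrics ---------------------------------------
  log_msg("native-space areal metrics")
  metrics <- list()
  for (nm in names(per_species)) {
    ps <- per_species[[nm]]
    for (r in ps$records) {
      wv <- withCallingHandlers(
        parcel_metrics(r$pair, ps$labels,
                       subject = r$subject, hemisphere = r$hemisphere,
                       species = nm),
        warning = function(w) {
          if (grepl("inverted", conditionMessage(w)))
            counts$inverted_wedges <<- counts$inverted_wedges + 1L
          invokeRestart("muffleWarning")
        })
      metrics[[length(metrics) + 1L]] <- wv
    }
  }
  metrics <- do.call(rbind, metrics)
  metrics_path <- file.path(out, "parcel_metrics.tsv")
  write_metrics_tsv(metrics, metrics_path)

  # recovered vs true mean fractions
  rec_mean <- stats::aggregate(rel_area ~ species + parcel, metrics, mean)
  names(rec_mean)[3] <- "recovered_mean_rel_area"
  recovery <- merge(recovery, rec_mean, by = c("species", "parcel"))

  # ---- stage 5: interspecies statistics ------------------------------------
  log_msg("interspecies statistics (%d observations)", nrow(metrics))
  anovas <- lapply(stats::setNames(responses, responses), function(r)
    two_way_anova(metrics, r))
  posthoc <- posthoc_bonferroni(metrics, responses[1])
  summ <- summary_report(metrics, responses)
  stats_path <- file.path(out, "stats_report.json")
  write_stats_json(anovas[[1]], posthoc, summ, stats_path)
  summary_path <- file.path(out, "group_summary.tsv")
  utils::write.table(summ, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    version = PIPELINE_VERSION,
    seed = config$seed,
    n_records = nrow(metrics) / length(unique(metrics$parcel)),
    counts = counts,
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2),
    outputs = as.list(tools::md5sum(c(metrics_path, stats_path, summary_path))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(metrics = metrics, anova = anovas, posthoc = posthoc,
                 summary = summ, recovery = recovery, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
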