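# Shared configuration for the analysis drivers. Desk-scale study: the
# three default species specs (night-monkey-, macaque-, and marmoset-like
# phantoms with the reported sizes, thicknesses, and parcel fractions) at
# reduced subject counts and mesh resolution so the whole workflow runs in
# minutes on one CPU.

library(myeloparc)

SEED <- 2026L
RESULTS <- file.path("results")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

desk_specs <- function(parcels = c("MT+", "AC", "BA7", "V1")) {
  default_species_specs(seed = SEED, subdivisions = 4, parcels = parcels,
                        n_subjects = c(3L, 3L, 3L))
}

desk_config <- function(out_dir = file.path(RESULTS, "pipeline")) {
  pipeline_config(desk_specs(), out_dir = out_dir, seed = SEED,
                  voxel_frac = 0.45, bias_amplitude = 0.1, noise_sd = 0.02,
                  write_gifti = TRUE)
}

say <- function(...) cat(sprintf(...), "\n")
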