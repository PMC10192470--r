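#!/usr/bin/env Rscript
# Stage 5: interspecies statistics on the pipeline's metrics table: two-way
# ANOVA (species x parcel, Type III) on relative area, thickness, and
# relative volume, Bonferroni-corrected post hoc Welch tests, and group
# summaries. Also prints the printed-arithmetic reference fractions the
# relative_fraction() convention reproduces.

source(file.path("analysis", "common.R"))

metrics <- read_metrics_tsv(file.path(RESULTS, "pipeline", "parcel_metrics.tsv"))

for (resp in c("rel_area", "mean_thickness_mm", "rel_volume")) {
  an <- two_way_anova(metrics, resp)
  say("\n== %s ==", resp)
  print(an)
}

ph <- posthoc_bonferroni(metrics, "rel_area")
say("\npost hoc Welch t tests (Bonferroni m = %d), MT+ rows:", ph$m[1])
print(ph[ph$parcel == "MT+", ], row.names = FALSE)

summ <- summary_report(metrics)
write_stats_json(two_way_anova(metrics, "rel_area"), ph, summ,
                 file.path(RESULTS, "stats_report.json"))
say("\nwrote results/stats_report.json")

say("\nreference printed arithmetic (parcel mean area / total area -> %%):")
say("  MT+: night %.1f  macaque %.1f  marmoset %.1f",
    relative_fraction(47.9, 2030), relative_fraction(89.8, 9894),
    relative_fraction(12.5, 1053))
say("  AC : night %.1f  macaque %.1f  marmoset %.1f",
    relative_fraction(51.2, 2030), relative_fraction(57.7, 9894),
    relative_fraction(16.1, 1053))
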