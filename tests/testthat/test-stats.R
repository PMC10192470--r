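test_that("whole-mesh parcels reproduce the totals exactly", {
  pr <- random_pair(5, subdivisions = 2)
  nv <- nrow(pr$white$vertices)
  lab <- parcel_labels(rep(1L, nv), c(all = 1L))
  tab <- parcel_metrics(pr, lab)
  mid <- compute_midthickness(pr)
  expect_identical(tab$area_mm2, tab$total_area_mm2)
  expect_equal(tab$area_mm2, total_area(mid), tolerance = 1e-12)
  expect_identical(tab$rel_area, 1)
  expect_identical(tab$rel_volume, 1)

  # uniform thickness: mean thickness equals it exactly
  w <- icosphere(2, 9)
  p <- icosphere(2, 10)
  t2 <- parcel_metrics(surface_pair(w, p),
                       parcel_labels(rep(1L, nrow(w$vertices)), c(all = 1L)))
  expect_equal(t2$mean_thickness_mm, 1, tolerance = 1e-9)
})

test_that("a spherical cap parcel has rel_area equal to its solid-angle fraction", {
  s <- icosphere(5, 10)
  costh <- 0.6
  lab <- parcel_labels(as.integer(s$vertices[, 3] / 10 > costh), c(cap = 1L))
  pair <- surface_pair(s, icosphere(5, 10.4))
  tab <- parcel_metrics(pair, lab)
  q <- (1 - costh) / 2                 # cap area fraction 2*pi*r^2(1-cos)/4*pi*r^2
  expect_equal(tab$rel_area[1], q, tolerance = 0.01)
})

test_that("empty parcels yield zero rows with a warning", {
  pr <- random_pair(7, subdivisions = 1)
  nv <- nrow(pr$white$vertices)
  lab <- parcel_labels(integer(nv), c(ghost = 1L))
  expect_warning(tab <- parcel_metrics(pr, lab), "empty parcel")
  expect_identical(tab$area_mm2, 0)
  expect_identical(tab$rel_area, 0)
})

test_that("relative fractions reproduce the printed interspecies arithmetic", {
  # MT+ complex, auditory cortex, BA7, V1 x night / macaque / marmoset
  expect_identical(relative_fraction(47.9, 2030), 2.4)
  expect_identical(relative_fraction(89.8, 9894), 0.9)
  expect_identical(relative_fraction(12.5, 1053), 1.2)
  expect_identical(relative_fraction(51.2, 2030), 2.5)
  expect_identical(relative_fraction(57.7, 9894), 0.6)
  expect_identical(relative_fraction(16.1, 1053), 1.5)
  expect_identical(relative_fraction(45.8, 2030), 2.3)
  expect_identical(relative_fraction(320, 9894), 3.2)
  expect_identical(relative_fraction(20.6, 1053), 2.0)
  expect_identical(relative_fraction(381, 2030), 18.8)
  expect_identical(relative_fraction(1160, 9894), 11.7)
  expect_identical(relative_fraction(215, 1053), 20.4)
  expect_identical(relative_fraction(7, 7), 100.0)
  expect_error(relative_fraction(1, 0), "positive")
})

make_design <- function(n_by_species, parcels, sd = 1, means = NULL) {
  rows <- list()
  for (sp in names(n_by_species)) {
    for (i in seq_len(n_by_species[[sp]])) {
      for (pc in parcels) {
        mu <- if (is.null(means)) 0 else means[[paste(sp, pc)]]
        rows[[length(rows) + 1L]] <- data.frame(
          subject = paste0(sp, i), hemisphere = "L", species = sp,
          parcel = pc, rel_area = rnorm(1, mu %||0% 0, sd))
      }
    }
  }
  do.call(rbind, rows)
}
`%||0%` <- function(a, b) if (is.null(a)) b else a

test_that("the interspecies design yields interaction df (6, 476)", {
  set.seed(10)
  tab <- make_design(c(macaque = 64, night = 18, marmoset = 40),
                     c("MT+", "AC", "BA7", "V1"))
  res <- two_way_anova(tab, "rel_area")
  inter <- res$factors[res$factors$effect == "species_x_parcel", ]
  expect_identical(inter$df1, 6L)
  expect_identical(inter$df2, 476L)
})

test_that("df2 = N - a*b for arbitrary designs and constants are flagged", {
  set.seed(11)
  for (i in 1:4) {
    ns <- sample(3:9, 3)
    np <- sample(2:4, 1)
    tab <- make_design(stats::setNames(ns, c("s1", "s2", "s3")),
                       paste0("p", seq_len(np)))
    res <- two_way_anova(tab, "rel_area")
    expect_identical(unique(res$factors$df2), as.integer(sum(ns) * np - 3 * np))
  }
  cst <- make_design(c(a = 4, b = 4), c("p", "q"), sd = 0,
                     means = list(`a p` = 1, `a q` = 1, `b p` = 1, `b q` = 1))
  res <- two_way_anova(cst, "rel_area")
  expect_true(res$zero_residual_variance)
  expect_true(all(is.na(res$factors$F)))
})

test_that("empty design cells fail naming the cell", {
  set.seed(3)
  tab <- make_design(c(a = 3, b = 3), c("p", "q"))
  tab <- tab[!(tab$species == "b" & tab$parcel == "q"), ]
  expect_error(two_way_anova(tab, "rel_area"), "b:q")
})

test_that("the single-factor balanced reduction satisfies F = t^2", {
  set.seed(14)
  tab <- make_design(c(g1 = 10, g2 = 10), "only")
  res <- two_way_anova(tab, "rel_area")
  tt <- t.test(rel_area ~ species, tab, var.equal = TRUE)
  expect_equal(res$factors$F[res$factors$effect == "species"],
               unname(tt$statistic)^2, tolerance = 1e-9)
})

test_that("native-space scaling leaves relative metrics untouched", {
  hm <- make_hemisphere(one_parcel_spec(subdivisions = 3), 1, "L")
  tab1 <- parcel_metrics(hm$pair, hm$truth$labels)
  s <- 1.7
  scaled <- surface_pair(
    triangle_mesh(hm$pair$white$vertices * s, hm$pair$white$faces,
                  validate = FALSE),
    triangle_mesh(hm$pair$pial$vertices * s, hm$pair$pial$faces,
                  validate = FALSE))
  tab2 <- parcel_metrics(scaled, hm$truth$labels)
  expect_equal(tab2$area_mm2, tab1$area_mm2 * s^2, tolerance = 1e-9)
  expect_equal(tab2$volume_mm3, tab1$volume_mm3 * s^3, tolerance = 1e-9)
  expect_equal(tab2$rel_area, tab1$rel_area, tolerance = 1e-12)
  expect_equal(tab2$rel_volume, tab1$rel_volume, tolerance = 1e-12)
})

test_that("hemisphere-wise relative areas sum to at most one", {
  hm <- cached_night_hemi()
  tab <- parcel_metrics(hm$pair, hm$truth$labels)
  expect_lte(sum(tab$rel_area), 1)
  expect_lte(sum(tab$rel_volume), 1 + 1e-12)
})

test_that("post hoc Welch tests carry the joint Bonferroni factor", {
  set.seed(15)
  tab <- make_design(c(a = 6, b = 6), "p")
  ph <- posthoc_bonferroni(tab, "rel_area")
  expect_identical(ph$m, 1L)
  expect_equal(ph$p_bonferroni, ph$p_raw)

  same <- make_design(c(a = 5, b = 5), "p", sd = 0,
                      means = list(`a p` = 2, `b p` = 2))
  ph2 <- posthoc_bonferroni(same, "rel_area")
  expect_identical(ph2$t, 0)
  expect_identical(ph2$p_raw, 1)

  tab3 <- make_design(c(a = 6, b = 6, c = 6), c("p", "q", "r", "s"))
  ph3 <- posthoc_bonferroni(tab3, "rel_area")
  expect_identical(unique(ph3$m), 12L)
  expect_equal(nrow(ph3), 12)
  expect_true(all(ph3$p_bonferroni == pmin(1, 12 * ph3$p_raw)))

  # n < 2 in a group flags the row
  small <- make_design(c(a = 1, b = 5), "p")
  ph4 <- posthoc_bonferroni(small, "rel_area")
  expect_true(ph4$flagged)
})

test_that("a 1.5-point group shift at sd 0.15 is detected after correction", {
  set.seed(16)
  hits <- 0
  for (i in 1:100) {
    a <- rnorm(18, 2.4, 0.15)
    b <- rnorm(64, 0.9, 0.15)
    tt <- t.test(a, b)
    if (min(1, 12 * tt$p.value) < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 99)
})

test_that("summary_report gives deterministic group means and flags singletons", {
  tab <- data.frame(subject = c("x", "x", "y"), hemisphere = c("L", "R", "L"),
                    species = c("a", "a", "b"), parcel = "p",
                    rel_area = c(1, 3, 5))
  s <- summary_report(tab, "rel_area")
  expect_equal(s$rel_area_mean[s$species == "a"], 2)
  expect_equal(s$rel_area_sd[s$species == "a"], sqrt(2))
  expect_identical(s$rel_area_sd[s$species == "b"], 0)
  expect_true(s$sd_flagged[s$species == "b"])
})
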