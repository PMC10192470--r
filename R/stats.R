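#' Per-parcel areal metrics in native space
#'
#' Per parcel: surface area = sum of vertex-wise areas on the mid-thickness
#' surface; mean thickness = unweighted mean of vertex-wise thickness;
#' volume = sum of vertex-wise wedge volumes from the white and pial
#' surfaces. Totals are over all vertices (labelled or not), and relative
#' fractions are parcel / total. One row per parcel.
#'
#' @param pair a [surface_pair()] in the subject's native space.
#' @param labels a [parcel_labels()] on the pair's mesh.
#' @param thickness optional thickness [metric_map()]; defaults to
#'   [correspondence_thickness()] of the pair.
#' @param subject,hemisphere,species identifiers copied into the rows.
#' @param area_weighted_thickness use the area-weighted mean instead of the
#'   unweighted vertex mean.
#' @return data frame with columns `subject`, `hemisphere`, `species`,
#'   `parcel`, `area_mm2`, `mean_thickness_mm`, `volume_mm3`,
#'   `total_area_mm2`, `total_volume_mm3`, `rel_area`, `rel_volume`.
#' @export
parcel_metrics <- function(pair, labels, thickness = NULL,
                           subject = "subj", hemisphere = "L",
                           species = "species",
                           area_weighted_thickness = FALSE) {
  stopifnot(inherits(pair, "surface_pair"), inherits(labels, "parcel_labels"))
  mid <- compute_midthickness(pair)
  va <- vertex_areas(mid)$values
  wv <- wedge_volumes(pair)$values
  th <- if (is.null(thickness)) correspondence_thickness(pair)$values
        else metric_values(thickness, mid)
  lab <- labels$labels
  stopifnot(length(lab) == length(va))

  total_area <- sum(va)
  total_vol <- sum(wv)
  rows <- lapply(names(labels$names), function(nm) {
    k <- label_of(labels, nm)
    sel <- lab == k
    if (!any(sel)) {
      warning("empty parcel '", nm, "'")
      return(data.frame(subject = subject, hemisphere = hemisphere,
                        species = species, parcel = nm, area_mm2 = 0,
                        mean_thickness_mm = 0, volume_mm3 = 0,
                        total_area_mm2 = total_area,
                        total_volume_mm3 = total_vol,
                        rel_area = 0, rel_volume = 0))
    }
    a <- sum(va[sel])
    v <- sum(wv[sel])
    t_ <- if (area_weighted_thickness) sum(th[sel] * va[sel]) / sum(va[sel])
          else mean(th[sel])
    data.frame(subject = subject, hemisphere = hemisphere, species = species,
               parcel = nm, area_mm2 = a, mean_thickness_mm = t_,
               volume_mm3 = v, total_area_mm2 = total_area,
               total_volume_mm3 = total_vol,
               rel_area = a / total_area, rel_volume = v / total_vol)
  })
  do.call(rbind, rows)
}

#' Relative area as a printed percentage
#'
#' `100 * area / total`, rounded half-up to one decimal — the printed
#' arithmetic convention (e.g. 47.9 / 2030 gives 2.4).
#'
#' @param area_mm2 parcel measurement.
#' @param total_mm2 whole-hemisphere total; must be positive.
#' @return percentage rounded to 1 decimal place.
#' @export
relative_fraction <- function(area_mm2, total_mm2) {
  if (any(total_mm2 <= 0)) stop("total must be positive")
  round_half_up(100 * area_mm2 / total_mm2, 1)
}

#' Two-way ANOVA of an areal response: species x parcel
#'
#' Fixed-effects linear model with species, parcel, and their interaction;
#' Type III sums of squares with sum-to-zero contrasts (the species samples
#' are unbalanced). Hemispheres are treated as independent observations,
#' matching the reported N accounting (so `df2 = N - a * b`). A factor with
#' a single level is dropped (one-way reduction).
#'
#' @param table a [parcel_metrics()]-style data frame with `species`,
#'   `parcel`, and the response column.
#' @param response one of `"rel_area"`, `"mean_thickness_mm"`,
#'   `"rel_volume"` (any numeric column name is accepted).
#' @param ss `"III"` (default) or `"II"` sums of squares.
#' @return list of class `anova_result`: `factors` (effect, F, df1, df2, p)
#'   and the fitted `model`.
#' @export
two_way_anova <- function(table, response = "rel_area", ss = c("III", "II")) {
  ss <- match.arg(ss)
  stopifnot(response %in% names(table))
  d <- data.frame(species = factor(table$species),
                  parcel = factor(table$parcel),
                  y = table[[response]])
  cells <- table(d$species, d$parcel)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(rownames(cells)[bad[, 1]], colnames(cells)[bad[, 2]],
               sep = ":", collapse = ", "))
  }
  two_species <- nlevels(d$species) > 1
  two_parcel <- nlevels(d$parcel) > 1
  if (!two_species && !two_parcel) stop("need >= 2 levels in some factor")
  form <- if (two_species && two_parcel) y ~ species * parcel
          else if (two_species) y ~ species else y ~ parcel
  fit <- stats::lm(form, data = d,
                   contrasts = list(species = "contr.sum",
                                    parcel = "contr.sum")[
                     c(two_species, two_parcel)])
  a <- nlevels(d$species)
  b <- nlevels(d$parcel)
  df2 <- nrow(d) - a * b
  zero_resid <- stats::deviance(fit) <=
    1e-16 * max(1, stats::var(d$y) * (nrow(d) - 1))
  if (zero_resid) {
    # degenerate fit (e.g. constant response): report the design dfs only
    eff <- c(if (two_species) "species", if (two_parcel) "parcel",
             if (two_species && two_parcel) "species_x_parcel")
    df1 <- c(if (two_species) a - 1L, if (two_parcel) b - 1L,
             if (two_species && two_parcel) (a - 1L) * (b - 1L))
    factors <- data.frame(effect = eff, F = NA_real_, df1 = as.integer(df1),
                          df2 = as.integer(df2), p = NA_real_)
  } else {
    at <- car::Anova(fit, type = ss)
    eff <- rownames(at)
    keep <- !eff %in% c("(Intercept)", "Residuals")
    factors <- data.frame(
      effect = gsub("species:parcel", "species_x_parcel", eff[keep]),
      F = at[keep, "F value"],
      df1 = as.integer(at[keep, "Df"]),
      df2 = as.integer(at["Residuals", "Df"]),
      p = at[keep, "Pr(>F)"])
  }
  rownames(factors) <- NULL
  structure(list(factors = factors, model = fit, response = response,
                 zero_residual_variance = zero_resid),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Two-way ANOVA (Type III, sum-to-zero) on", x$response, "\n")
  print(x$factors, row.names = FALSE)
  invisible(x)
}

#' Post hoc Welch t tests with Bonferroni correction
#'
#' Per parcel and species pair, a two-sample Welch t test on the response;
#' the Bonferroni factor is m = (number of species pairs) x (number of
#' parcels) — comparisons are corrected across species and parcels jointly
#' (m = 12 for 3 species and 4 parcels). Groups with fewer than 2
#' observations are flagged and not tested.
#'
#' @inheritParams two_way_anova
#' @return data frame with `parcel`, `species_pair`, `t`, `df`, `p_raw`,
#'   `p_bonferroni`, `m`, `flagged`.
#' @export
posthoc_bonferroni <- function(table, response = "rel_area") {
  stopifnot(response %in% names(table))
  sp <- unique(as.character(table$species))
  pc <- unique(as.character(table$parcel))
  pairs <- utils::combn(sort(sp), 2, simplify = FALSE)
  m <- length(pairs) * length(pc)
  rows <- list()
  for (parcel in pc) {
    for (pr in pairs) {
      a <- table[[response]][table$parcel == parcel & table$species == pr[1]]
      b <- table[[response]][table$parcel == parcel & table$species == pr[2]]
      if (length(a) < 2 || length(b) < 2) {
        rows[[length(rows) + 1L]] <- data.frame(
          parcel = parcel, species_pair = paste(pr, collapse = " vs "),
          t = NA_real_, df = NA_real_, p_raw = NA_real_,
          p_bonferroni = NA_real_, m = m, flagged = TRUE)
        next
      }
      tt <- if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
        list(statistic = c(t = 0), parameter = c(df = length(a) + length(b) - 2),
             p.value = 1)
      } else stats::t.test(a, b, var.equal = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        parcel = parcel, species_pair = paste(pr, collapse = " vs "),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p_raw = tt$p.value, p_bonferroni = min(1, m * tt$p.value),
        m = m, flagged = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Species-by-parcel summary of areal responses
#'
#' Mean, standard deviation across hemisphere observations, and group n for
#' each response, in deterministic (species, parcel) order. A single
#' observation yields sd = 0 with `sd_flagged = TRUE`.
#'
#' @param table a [parcel_metrics()]-style data frame.
#' @param responses numeric columns to summarize.
#' @return data frame of group summaries.
#' @export
summary_report <- function(table,
                           responses = c("rel_area", "mean_thickness_mm",
                                         "rel_volume")) {
  stopifnot(nrow(table) > 0)
  responses <- intersect(responses, names(table))
  sp <- sort(unique(as.character(table$species)))
  pc <- sort(unique(as.character(table$parcel)))
  rows <- list()
  for (s in sp) for (p in pc) {
    sel <- table$species == s & table$parcel == p
    if (!any(sel)) next
    row <- data.frame(species = s, parcel = p, n = sum(sel),
                      sd_flagged = sum(sel) < 2)
    for (r in responses) {
      v <- table[[r]][sel]
      row[[paste0(r, "_mean")]] <- mean(v)
      row[[paste0(r, "_sd")]] <- if (length(v) > 1) stats::sd(v) else 0
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
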