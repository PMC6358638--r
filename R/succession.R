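# Successional analysis: per-OTU abundance trends, CWM trajectories,
# cohort contrasts, and the three compositional time-course statistics
# (subsequent-sample variability, distance-to-final directional turnover,
# cross-infant convergence). Ages are binned as
# month = floor(age_days / 30.44) + 1, and 6-month periods are months
# 1-6, 7-12, ... .

#' @rdname age_month
#' @export
age_month <- function(age_days) as.integer(floor(age_days / 30.44) + 1)

#' Age binning conventions
#'
#' `age_month()` maps an age in days to a 1-based month of life using the
#' mean Gregorian month (30.44 days); `month_period()` maps months to
#' 6-month periods (1-6 -> 1, 7-12 -> 2, ...).
#'
#' @param age_days Age in days.
#' @param month 1-based month of life.
#' @name age_month
#' @export
month_period <- function(month) as.integer((month - 1) %/% 6 + 1)

#' Classify OTUs into successional groups by their abundance trend
#'
#' Ordinary least squares of relative abundance on age in months, pooled
#' over all samples of all infants (zeros included). OTUs with p < alpha
#' and negative slope are early successional; p < alpha with positive
#' slope, late; everything else (including constant-abundance OTUs, whose
#' p is undefined) is unclassified.
#'
#' @param dataset A [community_dataset()] (rarefied counts recommended).
#' @param alpha Significance level (default 0.05).
#' @return data.frame with columns `otu_id`, `slope` (relative abundance
#'   per month), `p_value`, `class` (`early`/`late`/`none`).
#' @export
classify_otus <- function(dataset, alpha = 0.05) {
  props <- relative_abundance(dataset)
  if (nrow(props) < 3L) stop("need >= 3 samples", call. = FALSE)
  age <- dataset$metadata$age_days / 30.44
  n <- length(age)
  xc <- age - mean(age)
  sxx <- sum(xc^2)
  rng <- apply(props, 2, function(z) diff(range(z)))
  slope <- as.numeric(crossprod(xc, props)) / sxx
  slope[rng == 0] <- 0  # constant abundance: no trend, p undefined
  fitted_dev <- outer(xc, slope)
  resid <- sweep(props, 2, colMeans(props)) - fitted_dev
  rss <- colSums(resid^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[rng == 0] <- NA_real_
  cls <- rep("none", ncol(props))
  cls[!is.na(p) & p < alpha & slope < 0] <- "early"
  cls[!is.na(p) & p < alpha & slope > 0] <- "late"
  data.frame(otu_id = colnames(props), slope = slope, p_value = p,
             class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

#' Monthly trajectory of community-weighted trait means
#'
#' Per trait and month of life: the mean CWM across samples with a normal
#' approximation 95% CI (mean +/- 1.96 SE; a single-sample month gets a
#' degenerate CI of +/- 0). Empty months are omitted.
#'
#' @param profile A [cwm_profile()] whose metadata carries `age_days`.
#' @return data.frame with columns `trait`, `month`, `mean`, `lo`, `hi`,
#'   `n`.
#' @export
monthly_cwm_trajectory <- function(profile) {
  stopifnot(!is.null(profile$metadata))
  month <- age_month(profile$metadata$age_days)
  out <- list()
  for (tr in colnames(profile$cwm)) {
    v <- profile$cwm[, tr]
    ok <- !is.na(v)
    if (!any(ok)) next  # trait gated out entirely
    agg <- split(v[ok], month[ok])
    m <- vapply(agg, mean, numeric(1))
    nn <- lengths(agg)
    se <- vapply(agg, function(z)
      if (length(z) > 1) stats::sd(z) / sqrt(length(z)) else 0, numeric(1))
    out[[tr]] <- data.frame(trait = tr, month = as.integer(names(agg)),
                            mean = m, lo = m - 1.96 * se, hi = m + 1.96 * se,
                            n = nn, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Assign infants to delivery-mode / antibiotic cohorts
#'
#' Cohort rules: `antibiotics` = vaginally delivered with at least 50 days
#' of antibiotic exposure; `csection` = C-section delivery with at most 2
#' antibiotic courses; `control` = vaginally delivered with no antibiotic
#' treatments; anything else (or missing delivery mode) is `unassigned`
#' and excluded from cohort contrasts. Unreported treatment durations are
#' imputed at 7 days per course.
#'
#' @param metadata Per-sample or per-infant data.frame with `infant_id`,
#'   `delivery_mode` (`"vaginal"`/`"csection"`), `abx_days` and optionally
#'   `abx_courses`.
#' @return data.frame with columns `infant_id`, `cohort`.
#' @export
assign_cohorts <- function(metadata) {
  inf <- metadata[!duplicated(metadata$infant_id), , drop = FALSE]
  courses <- if ("abx_courses" %in% names(inf)) inf$abx_courses else
    ceiling(ifelse(is.na(inf$abx_days), 0, inf$abx_days) / 7)
  days <- inf$abx_days
  days[is.na(days)] <- 7 * courses[is.na(days)]
  cohort <- rep("unassigned", nrow(inf))
  vag <- !is.na(inf$delivery_mode) & inf$delivery_mode == "vaginal"
  cs <- !is.na(inf$delivery_mode) & inf$delivery_mode == "csection"
  cohort[vag & days >= 50] <- "antibiotics"
  cohort[cs & courses <= 2] <- "csection"
  cohort[vag & courses == 0] <- "control"
  data.frame(infant_id = inf$infant_id, cohort = cohort,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Welch t contrasts of CWMs between treatment cohorts and controls
#'
#' Per trait and 6-month period: Welch's unequal-variance t test of sample
#' CWMs in each treatment cohort against the control cohort, with
#' Benjamini-Hochberg adjustment across all trait x period x treatment
#' tests. Tests with fewer than 2 samples on either side are skipped.
#'
#' @param profile A [cwm_profile()].
#' @param cohorts Output of [assign_cohorts()].
#' @param treatments Treatment cohort names (default both).
#' @return data.frame with `trait`, `period`, `group`, `t`, `p`, `p_adj`,
#'   `n_treat`, `n_control`.
#' @export
cohort_contrast <- function(profile, cohorts,
                            treatments = c("antibiotics", "csection")) {
  md <- profile$metadata
  coh <- cohorts$cohort[match(md$infant_id, cohorts$infant_id)]
  period <- month_period(age_month(md$age_days))
  rows <- list(); k <- 0L
  for (tr in colnames(profile$cwm)) for (pd in sort(unique(period)))
    for (g in treatments) {
      a <- profile$cwm[coh == g & period == pd, tr]
      b <- profile$cwm[coh == "control" & period == pd, tr]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      k <- k + 1L
      if (length(a) < 2L || length(b) < 2L ||
          (stats::sd(a) == 0 && stats::sd(b) == 0)) {
        tt <- c(NA_real_, NA_real_)
        if (length(a) >= 2L && length(b) >= 2L && mean(a) == mean(b))
          tt <- c(0, 1)  # identical groups: no difference
      } else {
        ht <- stats::t.test(a, b)
        tt <- c(unname(ht$statistic), ht$p.value)
      }
      rows[[k]] <- data.frame(trait = tr, period = pd, group = g,
                              t = tt[1], p = tt[2],
                              n_treat = length(a), n_control = length(b),
                              stringsAsFactors = FALSE)
    }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[c("trait", "period", "group", "t", "p", "p_adj", "n_treat",
        "n_control")]
}

# ---------------------------------------------------------------------
# binned series: the three compositional time-course statistics

.as_dist_matrix <- function(dataset, dist) {
  D <- if (is.function(dist)) dist(dataset) else dist
  D <- as.matrix(D)
  stopifnot(identical(rownames(D), dataset$metadata$sample_id))
  D
}

.series_units <- function(values, units, bins) {
  # mean within unit x bin
  key <- interaction(units, bins, drop = TRUE)
  agg <- tapply(values, key, mean, na.rm = TRUE)
  parts <- strsplit(names(agg), ".", fixed = TRUE)
  data.frame(unit = vapply(parts, function(p)
    paste(p[-length(p)], collapse = "."), character(1)),
    bin = as.integer(vapply(parts, function(p) p[length(p)], character(1))),
    value = as.numeric(agg), row.names = NULL, stringsAsFactors = FALSE)
}

.summarize_series <- function(units_df, measure) {
  units_df <- units_df[!is.na(units_df$value), , drop = FALSE]
  agg <- split(units_df$value, units_df$bin)
  m <- vapply(agg, mean, numeric(1))
  nn <- lengths(agg)
  se <- vapply(agg, function(z)
    if (length(z) > 1) stats::sd(z) / sqrt(length(z)) else 0, numeric(1))
  structure(list(summary = data.frame(bin = as.integer(names(agg)),
                                      mean = m, lo = m - 1.96 * se,
                                      hi = m + 1.96 * se, n = nn,
                                      row.names = NULL),
                 units = units_df, measure = measure),
            class = "binned_series")
}

#' @export
print.binned_series <- function(x, ...) {
  cat("binned_series (", x$measure, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# pair lists per statistic; bins are 6-month periods
.series_pair_table <- function(metadata, statistic) {
  month <- age_month(metadata$age_days)
  idx <- seq_len(nrow(metadata))
  if (statistic == "convergence") {
    rows <- list(); k <- 0L
    for (m in sort(unique(month))) {
      s <- idx[month == m]
      if (length(unique(metadata$infant_id[s])) < 2L) next
      pr <- t(utils::combn(s, 2))
      diff_inf <- metadata$infant_id[pr[, 1]] != metadata$infant_id[pr[, 2]]
      pr <- pr[diff_inf, , drop = FALSE]
      if (!nrow(pr)) next
      k <- k + 1L
      rows[[k]] <- data.frame(a = pr[, 1], b = pr[, 2],
                              unit = sprintf("month%02d", m),
                              bin = month_period(m))
    }
    return(do.call(rbind, rows))
  }
  rows <- list(); k <- 0L
  for (inf in unique(metadata$infant_id)) {
    s <- idx[metadata$infant_id == inf]
    if (length(s) < 2L) next
    s <- s[order(metadata$age_days[s])]
    if (statistic == "variability") {
      a <- s[-length(s)]; b <- s[-1L]
      bin <- month_period(month[b])  # realized at the later sample's age
    } else { # directional: each non-final sample vs the final sample
      a <- s[-length(s)]; b <- rep(s[length(s)], length(s) - 1L)
      bin <- month_period(month[a])
    }
    k <- k + 1L
    rows[[k]] <- data.frame(a = a, b = b, unit = inf, bin = bin)
  }
  do.call(rbind, rows)
}

.compositional_series <- function(dataset, dist, statistic) {
  D <- .as_dist_matrix(dataset, dist)
  pt <- .series_pair_table(dataset$metadata, statistic)
  if (is.null(pt) || !nrow(pt))
    stop("insufficient-data: no eligible sample pairs", call. = FALSE)
  vals <- D[cbind(pt$a, pt$b)]
  .summarize_series(.series_units(vals, pt$unit, pt$bin), statistic)
}

#' Short-term compositional variability over development
#'
#' Dissimilarity between chronologically adjacent samples of the same
#' infant, assigned to the 6-month period of the later sample, averaged
#' within infant x period and then across infants (mean and 95% CI; n =
#' contributing infants).
#'
#' @param dataset A [community_dataset()].
#' @param dist Square sample dissimilarity matrix (e.g.
#'   [bray_curtis_matrix()] or [trait_distance_matrix()]) or a function of
#'   the dataset returning one.
#' @return A `binned_series` (summary data.frame plus per-unit values).
#' @export
variability_series <- function(dataset, dist) {
  .compositional_series(dataset, dist, "variability")
}

#' Long-term directional turnover toward each infant's final sample
#'
#' Dissimilarity of every non-final sample to the same infant's final
#' sample, binned by the sample's own age; aggregation as in
#' [variability_series()]. The final sample is never paired with itself.
#'
#' @inheritParams variability_series
#' @return A `binned_series`.
#' @export
directional_series <- function(dataset, dist) {
  .compositional_series(dataset, dist, "directional")
}

#' Cross-infant compositional convergence over development
#'
#' Samples are sliced by month of life; within each month the mean
#' dissimilarity over all cross-infant sample pairs is taken (months with
#' fewer than 2 infants are omitted), and each 6-month period averages its
#' monthly means (n = contributing months, at most 6).
#'
#' @inheritParams variability_series
#' @return A `binned_series` whose units are months.
#' @export
convergence_series <- function(dataset, dist) {
  .compositional_series(dataset, dist, "convergence")
}
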