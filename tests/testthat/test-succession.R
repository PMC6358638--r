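# Successional statistics: OTU trend classification, CWM trajectories,
# cohort assignment and contrasts, and the three compositional series.

test_that("OTU classification follows the p/slope rule", {
  # otu1 declines linearly, otu2 rises, otu3 constant
  ds <- make_dataset(4, 1:12, function(i, m)
    c(100 - 5 * m, 40 + 5 * m, 60))
  cls <- classify_otus(ds)
  expect_identical(cls$class, c("early", "late", "none"))
  expect_lt(cls$slope[1], 0)
  expect_lt(cls$p_value[1], 1e-10)
  expect_true(is.na(cls$p_value[3]) || cls$p_value[3] > 0.05)

  # permuted abundances: type-I rate near the nominal 0.05
  set.seed(81)
  n_s <- 120
  counts <- matrix(rpois(n_s * 400, 20), n_s)
  colnames(counts) <- paste0("otu", 1:400)
  md <- data.frame(sample_id = paste0("s", 1:n_s),
                   infant_id = rep(paste0("i", 1:10), each = 12),
                   age_days = sample(30:1000, n_s, TRUE),
                   delivery_mode = "vaginal", abx_days = 0)
  rownames(counts) <- md$sample_id
  cls <- classify_otus(community_dataset(counts, md))
  rate <- mean(cls$class != "none")
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("monthly CWM trajectories report normal-approximation CIs", {
  cwm <- matrix(c(0, 2, 5), 3, 1, dimnames = list(c("s1", "s2", "s3"), "tr"))
  prof <- structure(list(
    cwm = cwm, cwv = cwm * 0, trait_sds = c(tr = 1),
    metadata = data.frame(sample_id = rownames(cwm),
                          age_days = c(10, 20, 40))), class = "cwm_profile")
  tj <- monthly_cwm_trajectory(prof)
  m1 <- tj[tj$month == 1, ]  # samples 0 and 2: mean 1, SE 1
  expect_equal(m1$mean, 1)
  expect_equal(m1$lo, 1 - 1.96, tolerance = 1e-12)
  expect_equal(m1$hi, 1 + 1.96, tolerance = 1e-12)
  m2 <- tj[tj$month == 2, ]  # single sample: degenerate CI
  expect_equal(c(m2$mean, m2$lo, m2$hi), c(5, 5, 5))
})

test_that("cohort assignment implements the delivery/antibiotic rules", {
  md <- data.frame(
    infant_id = c("a", "b", "c", "d", "e"),
    delivery_mode = c("vaginal", "csection", "vaginal", "csection", NA),
    abx_days = c(0, 10, NA, 14, 0),
    abx_courses = c(0, 3, 8, 2, 0))
  coh <- assign_cohorts(md)
  expect_identical(coh$cohort,
                   c("control",      # vaginal, no treatments
                     "unassigned",   # C-section but 3 courses
                     "antibiotics",  # 8 courses x 7 days = 56 >= 50
                     "csection",     # C-section, 2 courses
                     "unassigned"))  # missing delivery mode
})

test_that("cohort contrasts run Welch tests with BH adjustment", {
  set.seed(82)
  n <- 40
  md <- data.frame(sample_id = paste0("s", 1:n),
                   infant_id = paste0("i", 1:n),
                   age_days = rep(60, n), delivery_mode =
                     rep(c("vaginal", "csection"), each = n / 2),
                   abx_days = 0, abx_courses = 0)
  cwm <- cbind(tr = c(rnorm(n / 2, 0), rnorm(n / 2, 5)))
  rownames(cwm) <- md$sample_id
  prof <- structure(list(cwm = cwm, cwv = cwm * 0, trait_sds = c(tr = 1),
                         metadata = md), class = "cwm_profile")
  coh <- assign_cohorts(md)
  out <- cohort_contrast(prof, coh, treatments = "csection")
  expect_equal(nrow(out), 1)
  w <- welch_oracle(cwm[md$delivery_mode == "csection", 1],
                    cwm[md$delivery_mode == "vaginal", 1])
  expect_equal(out$t, w$t, tolerance = 1e-12)
  expect_equal(out$p, w$p, tolerance = 1e-12)
  expect_lt(out$p_adj, 0.001)

  # identical groups: t = 0, p = 1
  cwm2 <- cbind(tr = rep(c(1, 2), n / 2))
  rownames(cwm2) <- md$sample_id
  prof2 <- structure(list(cwm = cwm2, cwv = cwm2 * 0, trait_sds = c(tr = 1),
                          metadata = md), class = "cwm_profile")
  out2 <- cohort_contrast(prof2, coh, treatments = "csection")
  expect_equal(out2$t, 0)
  expect_equal(out2$p, 1)
})

test_that("constant-composition datasets give identically zero series", {
  ds <- make_dataset(3, 1:10, function(i, m) c(30, 30, 40))
  bc <- bray_curtis_matrix(ds)
  for (f in list(variability_series, directional_series, convergence_series)) {
    s <- f(ds, bc)
    expect_true(all(s$summary$mean == 0))
  }
})

test_that("variability series averages within infant then across infants", {
  # infant 1 alternates A/B compositions (adjacent BC = 0.5 at every step);
  # infant 2 is constant (BC = 0)
  ds <- make_dataset(2, 1:6, function(i, m) {
    if (i == 1) { if (m %% 2 == 0) c(20, 20, 0) else c(0, 20, 20) }
    else c(10, 10, 10)
  })
  bc <- bray_curtis_matrix(ds)
  s <- variability_series(ds, bc)
  expect_equal(s$summary$mean, 0.25)  # cross-infant mean of 0.5 and 0
  expect_equal(s$summary$n, 2L)

  # matches an explicit nested-loop oracle on a random dataset
  cfg <- sim_config(n_tips = 20, n_infants = 5, months = 12, depth = 150,
                    seed = 31)
  sim <- simulate_cohort(cfg)
  D <- bray_curtis_matrix(sim$dataset)
  got <- variability_series(sim$dataset, D)
  md <- sim$dataset$metadata
  per_bin <- list()
  for (inf in unique(md$infant_id)) {
    idx <- which(md$infant_id == inf)
    idx <- idx[order(md$age_days[idx])]
    for (k in 2:length(idx)) {
      bin <- month_period(age_month(md$age_days[idx[k]]))
      key <- paste(inf, bin)
      per_bin[[key]] <- c(per_bin[[key]], D[idx[k - 1], idx[k]])
    }
  }
  unit_means <- vapply(per_bin, mean, numeric(1))
  bins <- as.integer(sub(".* ", "", names(unit_means)))
  want <- tapply(unit_means, bins, mean)
  expect_equal(got$summary$mean,
               as.numeric(want[as.character(got$summary$bin)]),
               tolerance = 1e-12)
})

test_that("directional series measures distance to the final sample", {
  # compositions interpolate linearly toward the final state
  ds <- make_dataset(2, 1:12, function(i, m) {
    p <- (m - 1) / 11
    round(c(100 * (1 - p), 100 * p, 50))
  })
  bc <- bray_curtis_matrix(ds)
  s <- directional_series(ds, bc)
  expect_true(all(diff(s$summary$mean) < 0))  # monotone approach
  # final month's self-pair is excluded: last bin has no zero inflation
  md <- ds$metadata
  last_bin <- month_period(age_month(max(md$age_days)))
  expect_true(all(s$summary$mean[s$summary$bin == last_bin] > 0))

  # oracle: mean over non-final samples, binned by their own age
  D <- bc
  vals <- list()
  for (inf in unique(md$infant_id)) {
    idx <- which(md$infant_id == inf)
    idx <- idx[order(md$age_days[idx])]
    fin <- idx[length(idx)]
    for (k in idx[-length(idx)]) {
      bin <- month_period(age_month(md$age_days[k]))
      key <- paste(inf, bin)
      vals[[key]] <- c(vals[[key]], D[k, fin])
    }
  }
  unit_means <- vapply(vals, mean, numeric(1))
  bins <- as.integer(sub(".* ", "", names(unit_means)))
  want <- tapply(unit_means, bins, mean)
  expect_equal(s$summary$mean,
               as.numeric(want[as.character(s$summary$bin)]),
               tolerance = 1e-12)
})

test_that("convergence series averages monthly cross-infant pair means", {
  # two infants, one sample each in month 1, known Bray-Curtis
  ds <- make_dataset(2, 1, function(i, m)
    if (i == 1) c(2, 0, 1) else c(1, 1, 1))
  bc <- bray_curtis_matrix(ds)
  s <- convergence_series(ds, bc)
  expect_equal(s$summary$mean, 1 / 3)
  expect_equal(s$summary$n, 1L)  # one contributing month

  # planted convergence: compositions approach a common attractor
  ds2 <- make_dataset(4, 1:12, function(i, m) {
    p <- (m - 1) / 11
    base <- c(10, 20, 30, 40)
    own <- c(100, 0, 0, 0); own[i] <- 100
    round((1 - p) * own + p * base) + 1
  })
  s2 <- convergence_series(ds2, bray_curtis_matrix(ds2))
  expect_true(all(diff(s2$summary$mean) < 0))

  # oracle: all cross-infant pairs within each month
  md <- ds2$metadata
  D <- bray_curtis_matrix(ds2)
  month <- age_month(md$age_days)
  mm <- sort(unique(month))
  monthly <- vapply(mm, function(m) {
    idx <- which(month == m)
    prs <- t(combn(idx, 2))
    prs <- prs[md$infant_id[prs[, 1]] != md$infant_id[prs[, 2]], ,
               drop = FALSE]
    mean(D[prs])
  }, numeric(1))
  want <- tapply(monthly, month_period(mm), mean)
  expect_equal(s2$summary$mean,
               as.numeric(want[as.character(s2$summary$bin)]),
               tolerance = 1e-12)
})
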