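# Conservatism gating: pair sampling, the five-model competition, null
# expectation, 90%-of-null thresholds, gating and trait correlations.

test_that("pair sampling enumerates, bins and caps correctly", {
  tr3 <- ape::read.tree(text = "((A:0.01,B:0.01):0.04,C:0.05);")
  x <- c(A = 1, B = 3, C = 10)
  p <- sample_pair_differences(tr3, x)
  expect_equal(nrow(p), 3)
  key <- paste(pmin(p$tip_a, p$tip_b), pmax(p$tip_a, p$tip_b))
  want <- c("A B" = 2, "A C" = 9, "B C" = 7)
  expect_equal(unname(want[key]), p$abs_diff)

  # bin cap: 6 equidistant tips -> 15 pairs in one bin, capped to 10,
  # and the retained pairs are a subset of the full enumeration
  d <- matrix(0.1, 6, 6); diag(d) <- 0
  dimnames(d) <- list(letters[1:6], letters[1:6])
  teq <- agglomerative_tree(d)
  xx <- stats::setNames(rnorm(6), letters[1:6])
  full <- sample_pair_differences(teq, xx, max_per_bin = 100)
  capped <- sample_pair_differences(teq, xx, max_per_bin = 10, seed = 1)
  expect_equal(nrow(full), 15)
  expect_equal(nrow(capped), 10)
  expect_true(all(paste(capped$tip_a, capped$tip_b) %in%
                    paste(full$tip_a, full$tip_b)))
  expect_error(sample_pair_differences(teq, xx[1]), "insufficient-data")
})

test_that("null expectation averages strictly-distant pairs only", {
  pairs <- data.frame(x = c(0.2, 0.3), abs_diff = c(1, 3))
  expect_equal(null_expectation(pairs), 2)
  mixed <- data.frame(x = c(0.05, 0.1, 0.2, 0.4), abs_diff = c(9, 9, 1, 3))
  expect_equal(null_expectation(mixed), mean(c(1, 3)))  # x = 0.1 excluded
  expect_error(null_expectation(data.frame(x = 0.05, abs_diff = 1)),
               "insufficient-data")
})

test_that("model competition picks the generating model", {
  # flat data: null must win with the full 2-point AIC margin over linear
  flat <- data.frame(x = seq(0.001, 0.3, length.out = 1000),
                     abs_diff = rep(0.7, 1000))
  f <- fit_difference_models(flat)
  expect_identical(f$best_model, "null")
  expect_gte(f$fits$linear$aic - f$fits$null$aic, 2 - 1e-6)

  # exact line: linear wins with slope recovered to numerical precision
  lin <- data.frame(x = seq(0.001, 0.3, length.out = 500))
  lin$abs_diff <- 2 * lin$x
  f <- fit_difference_models(lin)
  expect_identical(f$best_model, "linear")
  expect_equal(unname(f$fits$linear$coef["b"]), 2, tolerance = 1e-6)

  # asymptotic self-consistency: a = 1, b = 3, small noise
  set.seed(61)
  a_hat <- replicate(30, {
    x <- runif(800, 0.001, 0.3)
    y <- 1 * (1 - exp(-exp(3) * x)) + rnorm(800, 0, 0.05)
    f <- fit_difference_models(data.frame(x = x, abs_diff = y))
    if (f$best_model == "asymptotic") unname(f$fits$asymptotic$coef["a"])
    else NA_real_
  })
  expect_gte(mean(!is.na(a_hat)), 0.9)
  expect_equal(mean(a_hat, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("thresholds come from the 90%-of-null crossing", {
  expect_equal(compute_threshold(function(x) x, null_exp = 1, max_x = 2),
               0.9, tolerance = 1e-6)
  # logistic crossing vs analytic inversion
  a <- 1; b <- 0.05; cc <- 0.02; ne <- 0.95
  pred <- function(x) a / (1 + exp((b - x) / cc))
  x_star <- b - cc * log(a / (0.9 * ne) - 1)
  expect_equal(compute_threshold(pred, ne, max_x = 0.5), x_star,
               tolerance = 1e-6)
  # curve that never reaches the target is capped at the max distance
  expect_equal(compute_threshold(function(x) 0.1 * x, 1, max_x = 0.3), 0.3)
  # already above at zero
  expect_equal(compute_threshold(function(x) rep(2, length(x)), 1,
                                 max_x = 0.3), 0)
})

test_that("conservatism discriminates Brownian from white-noise traits", {
  set.seed(62)
  res <- replicate(15, {
    tree <- random_test_tree(120)
    bm <- simulate_continuous_trait(tree, 1)
    wn <- stats::setNames(rnorm(120), tree$tip.label)
    m <- mask_traits(bm, 0.6)
    f_bm <- trait_conservatism(tree, bm[m])
    f_wn <- trait_conservatism(tree, wn[m])
    c(bm_pos = f_bm$best_model != "null" && f_bm$threshold > 0,
      wn_excluded = f_wn$threshold == 0)
  })
  expect_gte(mean(res["bm_pos", ]), 0.9)
  expect_gte(mean(res["wn_excluded", ]), 0.8)
})

test_that("thresholds are invariant to positive trait rescaling", {
  set.seed(63)
  tree <- random_test_tree(80)
  x <- simulate_continuous_trait(tree, 1)
  m <- mask_traits(x, 0.7)
  f1 <- trait_conservatism(tree, x[m], seed = 9)
  f10 <- trait_conservatism(tree, 10 * x[m], seed = 9)
  expect_identical(f1$best_model, f10$best_model)
  expect_equal(f1$threshold, f10$threshold, tolerance = 5e-3)
  expect_equal(f10$null_expectation, 10 * f1$null_expectation)
})

test_that("gating removes far predictions, never observed cells", {
  set.seed(64)
  tree <- random_test_tree(40)
  x <- simulate_continuous_trait(tree, 1)
  m <- mask_traits(x, 0.5)
  fit <- hsp(tree, x[m])

  g0 <- gate_predictions(fit, 0)
  expect_equal(sum(!is.na(g0$values)), sum(m))  # threshold 0: observed only
  gAll <- gate_predictions(fit, Inf)
  expect_equal(gAll$coverage, 1)

  # coverage is monotone non-decreasing in the threshold
  ths <- seq(0, 0.3, by = 0.05)
  covs <- vapply(ths, function(th) gate_predictions(fit, th)$coverage,
                 numeric(1))
  expect_true(all(diff(covs) >= 0))

  # a planted far outlier is exactly the tip gated at a threshold between
  # its nearest-observed distance and everyone else's
  nod <- fit$nearest_obs_dist[!m]
  far <- names(which.max(nod))
  th <- max(nod[names(nod) != far]) + 1e-9
  if (max(nod) > th) {
    g <- gate_predictions(fit, th)
    expect_true(is.na(g$values[far]))
    expect_equal(sum(is.na(g$values)), 1L)
  }
})

test_that("trait correlations are pairwise-complete with BH adjustment", {
  set.seed(65)
  v <- cbind(a = rnorm(50), b = rnorm(50))
  v <- cbind(v, c = -v[, "a"], d = c(rnorm(47), NA, NA, NA))
  out <- trait_correlations(v)
  expect_equal(diag(out$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(out$r["a", "c"], -1)
  expect_equal(out$n["a", "d"], 47L)
  expect_true(all(out$p_adj[upper.tri(out$p_adj)] >=
                    out$p[upper.tri(out$p)] - 1e-12, na.rm = TRUE))

  # independent traits rarely show |r| > 0.2 at n = 200
  set.seed(66)
  rr <- replicate(1000, cor(rnorm(200), rnorm(200)))
  expect_gte(mean(abs(rr) < 0.2), 0.95)
})
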