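# The synthetic-data generator: tree shape, trait evolution models,
# observation masking, and the longitudinal count simulator.

test_that("simulated trees are ultrametric and hit the target depth", {
  tr2 <- simulate_tree(2, depth_target = 0.2, seed = 1)
  expect_equal(sort(tr2$edge.length), c(0.1, 0.1))
  expect_equal(unname(cophenetic_matrix(tr2)[1, 2]), 0.2)

  for (s in 1:5) {
    tr <- simulate_tree(50, depth_target = 0.3, seed = s)
    rtt <- ape::node.depth.edgelength(tr)[1:50]
    expect_lt(diff(range(rtt)), 1e-9)       # all tips equidistant from root
    expect_equal(max(cophenetic_matrix(tr)), 0.3, tolerance = 1e-9)
  }
  expect_error(simulate_tree(1), "n_tips")
})

test_that("tree simulation is deterministic and matches a resimulation oracle", {
  expect_identical(simulate_tree(30, 0.3, seed = 42),
                   simulate_tree(30, 0.3, seed = 42))

  # mean pairwise distance across replicate trees vs an independent
  # brute-force Monte-Carlo of the same rescaled pure-birth process
  mean_pd <- function(n_rep, gen) {
    vapply(seq_len(n_rep), function(i) {
      tr <- gen()
      cm <- cophenetic_matrix(tr)
      mean(cm[upper.tri(cm)])
    }, numeric(1))
  }
  set.seed(11)
  ours <- mean_pd(150, function() simulate_tree(25, 0.3))
  set.seed(12)
  oracle <- mean_pd(150, function() {
    tr <- ape::rphylo(25, birth = 1, death = 0)
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * 0.3 / (2 * h)
    tr
  })
  se <- sqrt(var(ours) / length(ours) + var(oracle) / length(oracle))
  expect_lt(abs(mean(ours) - mean(oracle)), 3 * se)
})

test_that("Brownian trait variance matches the closed form", {
  tr <- simulate_tree(20, 0.3, seed = 3)
  expect_equal(unname(simulate_continuous_trait(tr, 0, root_value = 4)),
               rep(4, 20))
  expect_identical(simulate_continuous_trait(tr, 1, seed = 9),
                   simulate_continuous_trait(tr, 1, seed = 9))

  # two-tip tree: var(tipA - tipB) = sigma2 * pairwise distance
  tr2 <- simulate_tree(2, depth_target = 0.2, seed = 1)
  set.seed(5)
  diffs <- replicate(10000, {
    x <- simulate_continuous_trait(tr2, bm_sigma2 = 2)
    x[1] - x[2]
  })
  expect_equal(var(diffs), 2 * 0.2, tolerance = 0.05)
})

test_that("discrete trait switching matches the two-state Markov closed form", {
  tr <- simulate_tree(20, 0.3, seed = 4)
  expect_equal(unname(simulate_discrete_trait(tr, 0, root_state = 1)),
               rep(1L, 20))

  tr2 <- simulate_tree(2, depth_target = 0.2, seed = 1)
  r <- 5
  set.seed(6)
  dis <- replicate(10000, {
    x <- simulate_discrete_trait(tr2, rate = r)
    x[1] != x[2]
  })
  p_theory <- (1 - exp(-2 * r * 0.2)) / 2
  se <- sqrt(p_theory * (1 - p_theory) / 10000)
  expect_lt(abs(mean(dis) - p_theory), 3 * se)

  # very fast switching decorrelates sister tips
  tr4 <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);")
  set.seed(7)
  ab <- t(replicate(4000, simulate_discrete_trait(tr4, rate = 500)[c("A", "B")]))
  phi <- suppressWarnings(cor(ab[, 1], ab[, 2]))
  expect_lt(abs(phi), 3 / sqrt(4000))
})

test_that("trait masking hits the exact count and is uniform", {
  x <- stats::setNames(rnorm(100), paste0("t", 1:100))
  expect_true(all(mask_traits(x, 1)))
  expect_equal(sum(mask_traits(x, 0.5, seed = 1)), 50)
  expect_error(mask_traits(x, 0), "frac_observed")

  # overlap of two independent masks ~ hypergeometric(100, 50, 50)
  set.seed(8)
  overlap <- replicate(1000, sum(mask_traits(x, 0.5) & mask_traits(x, 0.5)))
  mu <- 50 * 50 / 100
  sd_h <- sqrt(50 * (50 / 100) * (50 / 100) * (100 - 50) / (100 - 1))
  expect_lt(abs(mean(overlap) - mu), 3 * sd_h / sqrt(1000))
})

test_that("infant series respects depth, determinism and planted trends", {
  cfg <- sim_config(n_tips = 40, n_infants = 8, months = 12, depth = 300,
                    seed = 21)
  sim <- simulate_cohort(cfg)
  expect_true(all(rowSums(sim$dataset$counts) == 300))
  expect_identical(simulate_cohort(cfg)$dataset$counts, sim$dataset$counts)

  md <- sim$dataset$metadata
  n_per_inf <- table(md$infant_id)
  expect_true(all(n_per_inf >= 4))  # months/3 floor at this scale
  expect_true(all(md$age_months > 0 & md$age_months <= 12))

  # neutral-only pool: per-OTU abundance slopes centered on zero
  cfg0 <- sim_config(n_tips = 200, n_infants = 10, months = 12, depth = 2000,
                     frac_early = 0, frac_late = 0, theta = Inf, seed = 22,
                     cohort_effects = list())
  sim0 <- simulate_cohort(cfg0)
  cls <- classify_otus(sim0$dataset)
  expect_lt(abs(mean(cls$slope > 0) - 0.5), 3 * 0.5 / sqrt(200))
  expect_lt(abs(mean(cls$slope)), 3 * sd(cls$slope) / sqrt(200))
})

test_that("steep planted declines are recovered as significant in most replicates", {
  hits <- vapply(1:20, function(r) {
    cfg <- sim_config(n_tips = 30, n_infants = 56, months = 24, depth = 500,
                      seed = 100 + r)
    sim <- simulate_cohort(cfg)
    cls <- classify_otus(sim$dataset)
    steep_early <- with(sim$roles, role == "early" & trend_steepness > 0.4)
    mean(cls$class[match(sim$roles$otu_id[steep_early], cls$otu_id)] == "early")
  }, numeric(1))
  expect_gte(mean(hits >= 0.95), 0.9)
})
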