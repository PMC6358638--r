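#' Configuration for the synthetic infant-cohort generator
#'
#' Bundles every tunable of the synthetic-data generator with defaults that
#' emulate the longitudinal infant-gut cohort the analysis is designed for:
#' 56 infants each sampled 12-36 times at semi-regular intervals over their
#' first 36 months, a shared species pool whose early taxa decline and late
#' taxa rise, phylogenetically conserved traits observed on only a fraction
#' of tips, and perturbed sub-cohorts (C-section delivery, heavy
#' antibiotics).
#'
#' @param n_tips Size of the shared OTU pool.
#' @param tree_depth_target Maximum tip-to-tip phylogenetic distance
#'   (16S V4 dissimilarity units).
#' @param bm_sigma2 Brownian-motion variance per unit distance for
#'   continuous traits.
#' @param discrete_switch_rate Switch rate for binary traits (events per
#'   unit distance).
#' @param frac_observed Fraction of tips with "known" (literature-style)
#'   trait values.
#' @param n_infants Number of hosts.
#' @param months Duration of sampling, months.
#' @param depth Reads per sample (sequencing depth before rarefaction).
#' @param theta Dirichlet concentration controlling compositional
#'   overdispersion around the expected relative abundances; `Inf` disables
#'   Dirichlet noise (multinomial sampling only).
#' @param frac_early,frac_late Fractions of the pool assigned declining /
#'   rising successional trends.
#' @param cohort_effects List of perturbations, each a list with elements
#'   `cohort` (`"csection"` or `"antibiotics"`), `trait` (trait name),
#'   `select` (`"high"` or `"low"` tail), `quantile` (tail cutoff),
#'   `mult` (abundance multiplier), `months` (length-2 age window).
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it (see [stage_seed()]), so identical configs give bit-identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tips = 150,
                       tree_depth_target = 0.3,
                       bm_sigma2 = 1,
                       discrete_switch_rate = 5,
                       frac_observed = 0.5,
                       n_infants = 56,
                       months = 36,
                       depth = 5000,
                       theta = 200,
                       frac_early = 0.3,
                       frac_late = 0.3,
                       cohort_effects = list(
                         list(cohort = "csection", trait = "oxygen_tolerance",
                              select = "high", quantile = 0.75, mult = 3,
                              months = c(0, 12)),
                         list(cohort = "antibiotics", trait = "gram_positive",
                              select = "high", quantile = 0.75, mult = 0.3,
                              months = c(0, 24))
                       ),
                       seed = 1L) {
  cfg <- list(n_tips = as.integer(n_tips),
              tree_depth_target = tree_depth_target,
              bm_sigma2 = bm_sigma2,
              discrete_switch_rate = discrete_switch_rate,
              frac_observed = frac_observed,
              n_infants = as.integer(n_infants),
              months = as.integer(months),
              depth = as.integer(depth),
              theta = theta,
              frac_early = frac_early, frac_late = frac_late,
              cohort_effects = cohort_effects,
              seed = as.integer(seed))
  stopifnot(cfg$n_tips >= 2, cfg$months >= 1, cfg$depth >= 1,
            cfg$frac_observed > 0, cfg$frac_observed <= 1,
            cfg$n_infants >= 1, cfg$theta > 0)
  structure(cfg, class = "sim_config")
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministic fan-out of one master seed to independent stage seeds, so
#' any pipeline stage can be re-run in isolation from its logged seed.
#'
#' @param master Master integer seed.
#' @param stage Stage name (any string; hashed by character codes).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}

#' Assign successional roles to a species pool
#'
#' Each OTU receives a role (`early`, `late`, `neutral`) plus the midpoint
#' (months) and steepness (per month) of its logistic abundance trend.
#' When `trait` is supplied, roles are linked to it: the top fraction of
#' the trait distribution becomes early and the bottom becomes late, which
#' plants a trait-driven successional signal (e.g., oxygen-tolerant taxa
#' declining). Without `trait`, roles are assigned at random
#' (trait-agnostic succession).
#'
#' @param otu_ids Character vector of OTU ids.
#' @param frac_early,frac_late Role fractions.
#' @param trait Optional named numeric vector over `otu_ids` linking roles
#'   to a trait.
#' @param midpoint_range,steepness_range Ranges for per-OTU trend midpoint
#'   (months) and steepness (per month).
#' @param seed Optional integer seed.
#' @return data.frame with columns `otu_id`, `role`, `trend_midpoint`,
#'   `trend_steepness`.
#' @export
succession_roles <- function(otu_ids, frac_early = 0.3, frac_late = 0.3,
                             trait = NULL,
                             midpoint_range = c(6, 18),
                             steepness_range = c(0.2, 0.6),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(otu_ids)
  n_early <- round(frac_early * n)
  n_late <- round(frac_late * n)
  role <- rep("neutral", n)
  if (is.null(trait)) {
    idx <- sample.int(n)
  } else {
    idx <- order(trait[otu_ids], decreasing = TRUE)
  }
  role[idx[seq_len(n_early)]] <- "early"
  if (n_late > 0) role[idx[n - seq_len(n_late) + 1L]] <- "late"
  data.frame(otu_id = otu_ids, role = role,
             trend_midpoint = stats::runif(n, midpoint_range[1], midpoint_range[2]),
             trend_steepness = stats::runif(n, steepness_range[1], steepness_range[2]),
             stringsAsFactors = FALSE)
}

#' Bundle an OTU count table with per-sample metadata
#'
#' @param counts Integer matrix, samples x OTUs, with row and column names.
#' @param metadata data.frame with one row per sample; must contain
#'   `sample_id`, `infant_id`, `age_days`, `delivery_mode`, `abx_days`.
#' @return Object of class `community_dataset`.
#' @export
community_dataset <- function(counts, metadata) {
  counts <- as.matrix(counts)
  req <- c("sample_id", "infant_id", "age_days", "delivery_mode", "abx_days")
  miss <- setdiff(req, names(metadata))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(metadata$sample_id))
    stop("sample ids must be unique", call. = FALSE)
  if (!identical(rownames(counts), as.character(metadata$sample_id)))
    stop("rownames(counts) must equal metadata$sample_id", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  structure(list(counts = counts, metadata = metadata),
            class = "community_dataset")
}

#' @export
print.community_dataset <- function(x, ...) {
  cat("community_dataset:", nrow(x$counts), "samples x", ncol(x$counts),
      "OTUs;", length(unique(x$metadata$infant_id)), "infants\n")
  invisible(x)
}

# expected (unnormalized) abundances of all OTUs at age t (months);
# early roles decline and late roles rise along per-OTU logistic trends,
# floored at 5% of baseline so no taxon vanishes entirely
.role_weights <- function(base, role, t, mid, steep, floor_frac = 0.05) {
  lg <- stats::plogis(steep * (t - mid))
  trend <- ifelse(role == "early", 1 - lg, ifelse(role == "late", lg, 1))
  base * (floor_frac + (1 - floor_frac) * trend)
}

#' Simulate a longitudinal infant-cohort community dataset
#'
#' Per infant, sampling ages are drawn on a jittered evenly spaced grid
#' over `(0, months]` (semi-regular intervals); the expected relative
#' abundance of each OTU follows a logistic trend determined by its
#' successional role; compositional noise is Dirichlet with concentration
#' `config$theta`; counts are multinomial at `config$depth`. Infants are
#' partitioned into delivery-mode / antibiotic sub-cohorts (6 C-section,
#' 18 heavy-antibiotic, 18 control, remainder intermediate at the default
#' cohort sizes), and `config$cohort_effects` multiply the expected
#' abundances of trait-selected taxa within age windows.
#'
#' @param tree `phylo` object for the OTU pool (tip labels = OTU ids).
#' @param roles data.frame from [succession_roles()].
#' @param traits Matrix (OTU x trait) of *true* trait values used by
#'   `cohort_effects` to select taxa.
#' @param config A [sim_config()].
#' @return A [community_dataset()] whose metadata also records
#'   `abx_courses` and `age_months`.
#' @export
simulate_infant_series <- function(tree, roles, traits, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(roles) || nrow(roles) == 0L)
    stop("`roles` must cover every tip", call. = FALSE)
  otus <- tree$tip.label
  if (!all(otus %in% roles$otu_id))
    stop("every tip needs a successional role", call. = FALSE)
  roles <- roles[match(otus, roles$otu_id), ]
  set.seed(stage_seed(config$seed, "infant_series"))
  n_otu <- length(otus)
  n_inf <- config$n_infants

  base <- stats::rlnorm(n_otu, 0, 1)

  # delivery-mode / antibiotic design: 6 C-section, 18 heavy-abx (vaginal),
  # 18 control (vaginal, none), remainder vaginal with light exposure
  n_cs <- min(6L, n_inf)
  n_abx <- min(18L, max(0L, n_inf - n_cs))
  n_ctl <- min(18L, max(0L, n_inf - n_cs - n_abx))
  grp <- c(rep("csection", n_cs), rep("antibiotics", n_abx),
           rep("control", n_ctl),
           rep("intermediate", max(0L, n_inf - n_cs - n_abx - n_ctl)))
  grp <- sample(grp)
  delivery <- ifelse(grp == "csection", "csection", "vaginal")
  courses <- integer(n_inf)
  courses[grp == "csection"] <- sample(0:2, sum(grp == "csection"), TRUE)
  courses[grp == "antibiotics"] <- sample(8:14, sum(grp == "antibiotics"), TRUE)
  courses[grp == "intermediate"] <- sample(1:5, sum(grp == "intermediate"), TRUE)
  abx_days <- courses * 7L # unreported durations imputed at 7 days/course

  # trait-stratum multipliers per cohort effect
  eff <- lapply(config$cohort_effects, function(e) {
    x <- traits[otus, e$trait]
    q <- stats::quantile(x, if (e$select == "high") e$quantile else 1 - e$quantile,
                         na.rm = TRUE)
    sel <- if (e$select == "high") x >= q else x <= q
    list(cohort = e$cohort, sel = !is.na(sel) & sel, mult = e$mult,
         window = e$months)
  })

  n_min <- max(2L, round(config$months / 3))
  n_max <- config$months
  rows <- list(); meta <- list(); k <- 0L
  for (i in seq_len(n_inf)) {
    n_s <- if (n_max > n_min) sample(n_min:n_max, 1L) else n_min
    spacing <- config$months / n_s
    ages <- seq(spacing, config$months, length.out = n_s) +
      stats::runif(n_s, -0.4 * spacing, 0.4 * spacing)
    ages <- sort(pmin(pmax(ages, 0.05), config$months))
    for (s in seq_len(n_s)) {
      t <- ages[s]
      w <- .role_weights(base, roles$role, t,
                         roles$trend_midpoint, roles$trend_steepness)
      for (e in eff)
        if (grp[i] == e$cohort && t >= e$window[1] && t <= e$window[2])
          w[e$sel] <- w[e$sel] * e$mult
      p <- w / sum(w)
      if (is.finite(config$theta)) {
        g <- stats::rgamma(n_otu, shape = p * config$theta)
        p <- if (sum(g) > 0) g / sum(g) else p
      }
      k <- k + 1L
      rows[[k]] <- as.integer(stats::rmultinom(1, config$depth, p))
      meta[[k]] <- data.frame(
        sample_id = sprintf("inf%02d_s%02d", i, s),
        infant_id = sprintf("inf%02d", i),
        age_days = round(t * 30.44), age_months = t,
        delivery_mode = delivery[i], abx_days = abx_days[i],
        abx_courses = courses[i], stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  metadata <- do.call(rbind, meta)
  dimnames(counts) <- list(metadata$sample_id, otus)
  community_dataset(counts, metadata)
}

#' Simulate a full synthetic cohort (tree, traits, observations, samples)
#'
#' Convenience wrapper running the whole generator from one [sim_config()]:
#' species tree, three phylogenetically conserved traits (two continuous
#' Brownian-motion traits named `oxygen_tolerance` and `temperature_optimum`
#' and one binary Markov trait `gram_positive`), a white-noise control trait
#' (`iga_binding`, no phylogenetic signal), observation masks, successional
#' roles linked to `oxygen_tolerance` (or random when
#' `trait_linked = FALSE`), and the longitudinal count dataset.
#'
#' @param config A [sim_config()].
#' @param trait_linked Link successional roles to `oxygen_tolerance`
#'   (`TRUE`, default) or assign them at random.
#' @return List with elements `tree`, `traits` (true values, OTU x trait),
#'   `observed` (logical OTU x trait mask), `trait_table` (a
#'   [trait_table()] with observed cells filled), `roles`, `dataset`,
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(), trait_linked = TRUE) {
  tree <- simulate_tree(config$n_tips, config$tree_depth_target,
                        seed = stage_seed(config$seed, "tree"))
  traits <- cbind(
    oxygen_tolerance = simulate_continuous_trait(
      tree, config$bm_sigma2, root_value = 2,
      seed = stage_seed(config$seed, "trait_oxygen")),
    temperature_optimum = simulate_continuous_trait(
      tree, config$bm_sigma2 * 25, root_value = 37,
      seed = stage_seed(config$seed, "trait_temp")),
    gram_positive = simulate_discrete_trait(
      tree, config$discrete_switch_rate,
      seed = stage_seed(config$seed, "trait_gram")),
    iga_binding = {
      set.seed(stage_seed(config$seed, "trait_iga"))
      stats::setNames(stats::rnorm(config$n_tips), tree$tip.label)
    })
  observed <- sapply(colnames(traits), function(tn)
    mask_traits(traits[, tn], config$frac_observed,
                seed = stage_seed(config$seed, paste0("mask_", tn))))
  rownames(observed) <- rownames(traits)
  vals <- traits
  vals[!observed] <- NA_real_
  prov <- ifelse(observed, "observed", "missing")
  tt <- trait_table(vals, provenance = prov)
  roles <- succession_roles(
    tree$tip.label, config$frac_early, config$frac_late,
    trait = if (trait_linked) traits[, "oxygen_tolerance"] else NULL,
    seed = stage_seed(config$seed, "roles"))
  dataset <- simulate_infant_series(tree, roles, traits, config)
  list(tree = tree, traits = traits, observed = observed, trait_table = tt,
       roles = roles, dataset = dataset, config = config)
}
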