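# Phylogenetic trait conservatism: how far across the tree can a trait be
# trusted? Absolute trait differences |y| between observed-tip pairs are
# modelled as a function of phylogenetic distance x; the best of five
# models (by AIC) is compared with the mean difference among distant pairs
# (x > 0.1, the "null expectation"), and the distance at which the fitted
# curve reaches 90% of that null is the trait's maximum prediction
# distance. Traits whose best model is the flat null get threshold 0 and
# are excluded from inference altogether.

#' Sample pairwise trait differences binned by phylogenetic distance
#'
#' Prunes the tree to observed tips, forms all tip pairs, bins them by
#' cophenetic distance in increments of `bin_width`, and uniformly
#' subsamples each bin to at most `max_per_bin` pairs without replacement.
#'
#' @param tree A `phylo` object.
#' @param observed_values Named numeric vector over observed tips.
#' @param bin_width Distance bin width (default 0.005).
#' @param max_per_bin Per-bin cap (default 10000).
#' @param seed Optional integer seed for the subsampling.
#' @return data.frame with columns `tip_a`, `tip_b`, `x` (distance),
#'   `abs_diff`, `bin` (integer bin index, `floor(x / bin_width)`).
#' @export
sample_pair_differences <- function(tree, observed_values,
                                    bin_width = 0.005, max_per_bin = 10000,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- observed_values[!is.na(observed_values)]
  if (length(obs) < 2L)
    stop("insufficient-data: need >= 2 observed tips", call. = FALSE)
  ptree <- if (length(obs) < length(tree$tip.label))
    ape::keep.tip(tree, names(obs)) else tree
  cm <- cophenetic_matrix(ptree)
  tipn <- ptree$tip.label
  ij <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- data.frame(tip_a = tipn[ij[, 1]], tip_b = tipn[ij[, 2]],
                      x = cm[ij], stringsAsFactors = FALSE)
  pairs$abs_diff <- abs(obs[pairs$tip_a] - obs[pairs$tip_b])
  pairs$bin <- as.integer(floor(pairs$x / bin_width))
  keep <- unlist(lapply(split(seq_len(nrow(pairs)), pairs$bin), function(idx) {
    if (length(idx) <= max_per_bin) idx else sample(idx, max_per_bin)
  }), use.names = FALSE)
  out <- pairs[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bin_width") <- bin_width
  out
}

#' Null expectation of trait difference among distant pairs
#'
#' Arithmetic mean of `abs_diff` over pairs strictly farther apart than
#' `cutoff` (default 0.1): the baseline trait difference between
#' effectively unrelated taxa.
#'
#' @param pairs Output of [sample_pair_differences()].
#' @param cutoff Strict distance cutoff (default 0.1).
#' @return Scalar mean difference.
#' @export
null_expectation <- function(pairs, cutoff = 0.1) {
  far <- pairs$abs_diff[pairs$x > cutoff]
  if (length(far) == 0L)
    stop("insufficient-data: no pairs beyond distance ", cutoff,
         call. = FALSE)
  mean(far)
}

# the five-model competition -------------------------------------------

.model_rank <- c(null = 1, linear = 2, log = 2, asymptotic = 2, logistic = 3)

.fit_models <- function(x, y, bin_width, w = NULL) {
  n <- length(y)
  if (is.null(w)) w <- rep(1, n)
  w <- w / mean(w)
  bins <- floor(x / bin_width)
  bm_x <- tapply(x, bins, mean)
  bm_y <- tapply(y, bins, mean)
  a0 <- max(bm_y)
  fits <- list()
  # RSS floor at the numerical noise scale of y, so exact fits (flat or
  # noiseless data) compare by parameter count instead of rounding error
  rss_floor <- n * (1e-9 * max(stats::sd(y), mean(abs(y)), 1e-300))^2
  aic_of <- function(rss, k) n * log(max(rss, rss_floor, 1e-300) / n) + 2 * k
  wrss <- function(m) sum(w * stats::resid(m)^2)

  m <- stats::lm(y ~ 1, weights = w)
  fits$null <- list(coef = c(a = unname(stats::coef(m))),
                    rss = wrss(m), k = 2,
                    pred = local({ a <- unname(stats::coef(m))
                      function(x) rep(a, length(x)) }))
  m <- stats::lm(y ~ x, weights = w)
  fits$linear <- list(coef = stats::setNames(stats::coef(m), c("a", "b")),
                      rss = wrss(m), k = 3,
                      pred = local({ cf <- unname(stats::coef(m))
                        function(x) cf[1] + cf[2] * x }))
  xf <- pmax(x, bin_width / 2)  # floor at half the bin width: smallest
  m <- stats::lm(y ~ log(xf), weights = w)  # resolvable distance scale
  fits$log <- list(coef = stats::setNames(stats::coef(m), c("a", "b")),
                   rss = wrss(m), k = 3,
                   pred = local({ cf <- unname(stats::coef(m)); bw <- bin_width
                     function(x) cf[1] + cf[2] * log(pmax(x, bw / 2)) }))

  # asymptotic a(1 - exp(-exp(b) x)), constrained through the origin;
  # deterministic self-start: a0 = max bin mean, rate from half-saturation
  half_idx <- which(bm_y >= a0 / 2)
  x_half <- if (length(half_idx)) bm_x[half_idx[1]] else stats::median(x)
  rate0 <- log(2) / max(x_half, bin_width / 2)
  fits$asymptotic <- tryCatch({
    m <- minpack.lm::nlsLM(y ~ a * (1 - exp(-exp(b) * x)),
                           start = list(a = a0, b = log(rate0)), weights = w,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(m)
    list(coef = cf, rss = wrss(m), k = 3,
         pred = local({ a <- cf[["a"]]; b <- cf[["b"]]
           function(x) a * (1 - exp(-exp(b) * x)) }))
  }, error = function(e) NULL)

  # logistic a / (1 + exp((b - x)/c)); b0 = distance at half max, c0 = 0.02
  b0 <- if (length(half_idx)) bm_x[half_idx[1]] else stats::median(x)
  fits$logistic <- tryCatch({
    m <- minpack.lm::nlsLM(y ~ a / (1 + exp((b - x) / c)),
                           start = list(a = a0, b = b0, c = 0.02), weights = w,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(m)
    list(coef = cf, rss = wrss(m), k = 4,
         pred = local({ a <- cf[["a"]]; b <- cf[["b"]]; cc <- cf[["c"]]
           function(x) a / (1 + exp((b - x) / cc)) }))
  }, error = function(e) NULL)

  fits <- Filter(Negate(is.null), fits)
  for (nm in names(fits)) fits[[nm]]$aic <- aic_of(fits[[nm]]$rss, fits[[nm]]$k)
  fits
}

# Simplest adequate model: candidates within `margin` AIC units of the
# minimum are treated as equivalent fits (the standard AIC equivalence
# band), and the structurally simplest of them wins. Under a true null
# this suppresses the irreducible spurious-selection rate of strict
# lowest-AIC among five models.
.select_model <- function(fits, margin = 2) {
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  cand <- names(fits)[aic <= min(aic) + margin]
  cand[order(.model_rank[cand], aic[cand])][1]
}

#' Fit the five candidate models of |trait difference| vs distance
#'
#' Gaussian least squares for the null (intercept-only), linear,
#' logarithmic (distance floored at half a bin width), origin-constrained
#' asymptotic `a (1 - exp(-exp(b) x))` and logistic
#' `a / (1 + exp((b - x)/c))` models, with deterministic self-start
#' initializations; AIC is `n log(RSS/n) + 2k` with `k` counting
#' parameters plus the error variance. Models within 2 AIC units of the
#' minimum are equivalent fits and the simplest of them is selected;
#' failed nonlinear fits drop out of the competition.
#'
#' @param pairs data.frame from [sample_pair_differences()] (columns `x`,
#'   `abs_diff`, `bin`).
#' @param bin_width Bin width used for the log-model floor and the bin
#'   means driving the self-starts.
#' @param fit_to Fit to pair-count-weighted bin means (default) or raw
#'   pair-level points.
#' @return List with `fits` (per model: `coef`, `rss`, `k`, `aic`,
#'   `pred`) and `best_model`.
#' @export
fit_difference_models <- function(pairs, bin_width = 0.005,
                                  fit_to = c("bin_means", "pairs")) {
  fit_to <- match.arg(fit_to)
  if (nrow(pairs) < 5L)
    stop("insufficient-data: need >= 5 pairs", call. = FALSE)
  if (is.null(pairs$bin)) pairs$bin <- floor(pairs$x / bin_width)
  if (fit_to == "pairs") {
    fits <- .fit_models(pairs$x, pairs$abs_diff, bin_width)
  } else {
    fx <- as.numeric(tapply(pairs$x, pairs$bin, mean))
    fy <- as.numeric(tapply(pairs$abs_diff, pairs$bin, mean))
    fw <- as.numeric(tapply(pairs$x, pairs$bin, length))
    fits <- .fit_models(fx, fy, bin_width, fw)
  }
  list(fits = fits, best_model = .select_model(fits))
}

#' Smallest distance at which a fitted curve reaches 90% of the null
#'
#' Bisection (to 1e-6) for the smallest `x >= 0` with
#' `curve(x) >= frac * null_exp`, capped at `max_x` when the curve never
#' gets there within the observed range.
#'
#' @param pred Prediction function of one argument (fitted curve), or a
#'   `conservatism_fit` (its best model's curve is used).
#' @param null_exp Null expectation (trait units).
#' @param max_x Maximum observed pair distance (the cap).
#' @param frac Fraction of the null (default 0.9).
#' @return Threshold distance in `[0, max_x]`.
#' @export
compute_threshold <- function(pred, null_exp, max_x, frac = 0.9) {
  if (inherits(pred, "conservatism_fit")) {
    fit <- pred
    if (fit$best_model == "null") return(0)
    pred <- fit$fits[[fit$best_model]]$pred
    if (missing(max_x)) max_x <- fit$max_distance
    if (missing(null_exp)) null_exp <- fit$null_expectation
  }
  target <- frac * null_exp
  if (pred(0) >= target) return(0)
  if (pred(max_x) < target) return(max_x)
  lo <- 0; hi <- max_x
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (pred(mid) >= target) hi <- mid else lo <- mid
  }
  hi
}

#' Fit the trait-conservatism model competition and threshold
#'
#' The full per-trait procedure: sample binned pairwise differences among
#' observed tips, fit the five candidate models of |difference| versus
#' distance (null, linear, logarithmic, origin-constrained asymptotic,
#' logistic) by Gaussian least squares, select by AIC
#' (`n log(RSS/n) + 2k`; models within 2 AIC units of the minimum count
#' as equivalent and the simplest wins; failed nonlinear fits drop out),
#' compute the far-pair null expectation, and
#' locate the 90%-of-null crossing. A trait whose best model is the null
#' gets threshold 0 — no prediction at any distance. A trait with no pairs
#' beyond the cutoff is flagged non-inferable (threshold 0).
#'
#' @param tree A `phylo` object.
#' @param observed_values Named numeric vector over observed tips (NAs
#'   dropped).
#' @param bin_width,max_per_bin Pair-sampling controls (defaults 0.005 and
#'   10000).
#' @param null_cutoff Strict distance cutoff for the null expectation
#'   (default 0.1).
#' @param threshold_frac Fraction of the null defining the crossing
#'   (default 0.9).
#' @param fit_to Fit models to per-bin mean differences (default,
#'   modelling the *average* difference at each distance) or to the
#'   sampled pair-level points (sensitivity switch; pair-level AIC is
#'   anticonservative because pairs sharing tips are dependent).
#' @param trait Optional trait name carried in the result.
#' @param seed Optional integer seed for pair subsampling.
#' @return Object of class `conservatism_fit`: `pairs`, `fits` (per-model
#'   coefficients, RSS, AIC, prediction function), `best_model`,
#'   `null_expectation`, `threshold`, `max_distance`, `non_inferable`.
#' @export
trait_conservatism <- function(tree, observed_values, bin_width = 0.005,
                               max_per_bin = 10000, null_cutoff = 0.1,
                               threshold_frac = 0.9,
                               fit_to = c("bin_means", "pairs"),
                               trait = NULL, seed = NULL) {
  fit_to <- match.arg(fit_to)
  pairs <- sample_pair_differences(tree, observed_values, bin_width,
                                   max_per_bin, seed = seed)
  if (nrow(pairs) < 5L || length(unique(pairs$bin)) < 2L)
    stop("insufficient-data: need >= 5 pairs spanning >= 2 bins",
         call. = FALSE)
  if (fit_to == "pairs") {
    fx <- pairs$x; fy <- pairs$abs_diff; fw <- NULL
  } else {
    # per-bin mean differences, weighted by pair count (the variance of a
    # bin mean scales as 1/count, so this is the matching WLS model)
    fx <- as.numeric(tapply(pairs$x, pairs$bin, mean))
    fy <- as.numeric(tapply(pairs$abs_diff, pairs$bin, mean))
    fw <- as.numeric(tapply(pairs$x, pairs$bin, length))
  }
  fits <- .fit_models(fx, fy, bin_width, fw)
  best <- .select_model(fits)
  max_x <- max(pairs$x)
  ne <- tryCatch(null_expectation(pairs, null_cutoff),
                 error = function(e) NA_real_)
  non_inferable <- is.na(ne)
  threshold <- if (non_inferable || best == "null") 0 else
    compute_threshold(fits[[best]]$pred, ne, max_x, threshold_frac)
  structure(list(trait = trait, pairs = pairs, fits = fits,
                 best_model = best, null_expectation = ne,
                 threshold = threshold, max_distance = max_x,
                 threshold_frac = threshold_frac,
                 non_inferable = non_inferable, call = match.call()),
            class = "conservatism_fit")
}

#' @export
print.conservatism_fit <- function(x, ...) {
  cat("Trait conservatism fit", if (!is.null(x$trait)) paste0("(", x$trait, ")"),
      "\n  best model:", x$best_model,
      "\n  null expectation:", format(x$null_expectation, digits = 4),
      "\n  max prediction distance:", format(x$threshold, digits = 4), "\n")
  invisible(x)
}

#' @export
summary.conservatism_fit <- function(object, ...) {
  aic <- vapply(object$fits, `[[`, numeric(1), "aic")
  data.frame(model = names(object$fits),
             aic = unname(aic), delta_aic = unname(aic - min(aic)),
             best = names(object$fits) == object$best_model,
             row.names = NULL)
}

#' @export
coef.conservatism_fit <- function(object, ...) object$fits[[object$best_model]]$coef

#' Fitted |difference| curve of the selected model
#' @param object A `conservatism_fit`.
#' @param newdata Numeric distances (default: the sampled pair distances).
#' @param ... Unused.
#' @export
predict.conservatism_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$pairs$x
  object$fits[[object$best_model]]$pred(newdata)
}

#' Diagnostic plot of pair differences, fitted curve and threshold
#' @param x A `conservatism_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.conservatism_fit <- function(x, ...) {
  bm_x <- tapply(x$pairs$x, x$pairs$bin, mean)
  bm_y <- tapply(x$pairs$abs_diff, x$pairs$bin, mean)
  plot(bm_x, bm_y, xlab = "phylogenetic distance",
       ylab = "mean |trait difference|",
       main = paste("best model:", x$best_model), ...)
  xs <- seq(0, x$max_distance, length.out = 200)
  graphics::lines(xs, x$fits[[x$best_model]]$pred(xs), col = "red")
  if (!is.na(x$null_expectation)) {
    graphics::abline(h = x$threshold_frac * x$null_expectation, lty = 2)
    graphics::abline(v = x$threshold, lty = 3)
  }
  invisible(x)
}

#' Discard predictions beyond a trait's conservatism threshold
#'
#' Predicted values whose nearest observed tip lies farther than the
#' threshold are set to missing; observed values are never gated.
#'
#' @param hsp_result An [hsp()] fit.
#' @param fit A `conservatism_fit`, or a numeric threshold.
#' @return List with `values` (named, gated predictions as `NA`),
#'   `provenance` (per tip), `coverage` (fraction of tips non-missing),
#'   `threshold`.
#' @export
gate_predictions <- function(hsp_result, fit) {
  threshold <- if (inherits(fit, "conservatism_fit")) fit$threshold else fit
  vals <- hsp_result$fitted
  prov <- ifelse(hsp_result$observed, "observed", "predicted")
  gate <- !hsp_result$observed & hsp_result$nearest_obs_dist > threshold
  vals[gate] <- NA_real_
  prov[gate] <- "missing"
  list(values = vals, provenance = prov, coverage = mean(!is.na(vals)),
       threshold = threshold)
}

#' Pairwise Pearson correlations among trait columns
#'
#' Pairwise-complete Pearson correlations with Benjamini-Hochberg adjusted
#' p-values across all trait pairs; pairs with fewer than 3 complete
#' observations are reported missing.
#'
#' @param values Numeric matrix, taxa x traits (NAs allowed).
#' @return List of matrices `r`, `p`, `p_adj`, `n`.
#' @export
trait_correlations <- function(values) {
  k <- ncol(values)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(values),
                                                   colnames(values)))
  n <- matrix(0L, k, k, dimnames = dimnames(r))
  diag(r) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    ok <- stats::complete.cases(values[, c(i, j)])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3L) next
    ct <- stats::cor.test(values[ok, i], values[ok, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  up <- upper.tri(p)
  padj <- p
  padj[up] <- stats::p.adjust(p[up], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  list(r = r, p = p, p_adj = padj, n = n)
}
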