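# Trait-shuffling null models: what would every trait-based statistic look
# like if traits were decoupled from taxon identity? Whole trait rows (an
# OTU's full trait vector including its missingness pattern) are permuted
# uniformly among OTUs, the trait-based series are recomputed with the
# scaling SDs frozen from the observed table, and observed values are
# tested against replicate-averaged null values per 6-month bin.

#' Shuffle trait vectors among OTUs
#'
#' Permutes whole rows of the trait matrix uniformly at random, preserving
#' each trait column's multiset of values (and the inter-trait correlation
#' and missingness structure of each row).
#'
#' @param traits Numeric matrix OTU x trait, or a [trait_table()].
#' @param seed Optional integer seed.
#' @param perm Optional explicit permutation (for reproducibility checks).
#' @return Same type as `traits`, rows reassigned to OTUs.
#' @export
shuffle_traits <- function(traits, seed = NULL, perm = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- inherits(traits, "trait_table")
  vals <- if (tt) traits$values else as.matrix(traits)
  if (nrow(vals) < 2L) stop("need >= 2 OTUs to shuffle", call. = FALSE)
  if (is.null(perm)) perm <- sample.int(nrow(vals))
  out <- vals[perm, , drop = FALSE]
  rownames(out) <- rownames(vals)
  if (tt) {
    prov <- traits$provenance[perm, , drop = FALSE]
    rownames(prov) <- rownames(traits$provenance)
    return(trait_table(out, prov, traits$meta))
  }
  out
}

# trait-space distances for an explicit pair list, vectorized over pairs
.pair_trait_dist <- function(C, sds, a, b) {
  use <- sds > 0 & !is.na(sds)
  A <- C[a, use, drop = FALSE]; B <- C[b, use, drop = FALSE]
  d2 <- sweep(A - B, 2, sds[use], "/")^2
  shared <- rowSums(!is.na(d2))
  v <- sqrt(rowSums(d2, na.rm = TRUE))
  v[shared == 0] <- NA_real_
  v
}

#' Observed trait-based compositional series
#'
#' Convenience wrapper computing one of the three trait-space series
#' (variability / directional / convergence) for a dataset and trait
#' matrix, with scaling SDs taken from that matrix.
#'
#' @param dataset A [community_dataset()].
#' @param traits OTU x trait matrix (gated values) or [trait_table()].
#' @param statistic One of `"variability"`, `"directional"`,
#'   `"convergence"`.
#' @param min_coverage Minimum covered abundance per CWM.
#' @return A `binned_series`.
#' @export
trait_series <- function(dataset, traits,
                         statistic = c("variability", "directional",
                                       "convergence"),
                         min_coverage = 0.5) {
  statistic <- match.arg(statistic)
  profile <- cwm_profile(dataset, traits, min_coverage)
  .compositional_series(dataset, trait_distance_matrix(profile), statistic)
}

#' Trait-shuffling null ensemble for a trait-based series
#'
#' Recomputes the chosen trait-space series for `n_reps` random
#' reassignments of trait vectors among OTUs. The per-trait scaling SDs
#' are frozen from the observed table (row shuffling preserves each
#' column's multiset anyway), so observed and null series live on the same
#' scale. Per-unit null values are averaged across replicates for the
#' matched-unit Welch tests of [observed_vs_null_test()].
#'
#' @inheritParams trait_series
#' @param n_reps Number of shuffles (default 1000).
#' @param seed Optional integer seed.
#' @param perms Optional list of explicit permutations overriding the
#'   random ones (length defines `n_reps`).
#' @return Object of class `null_ensemble`: `observed` (`binned_series`),
#'   `observed_units` / `null_units` (matched unit x bin observed values
#'   and replicate-averaged null means), `rep_bins` (replicate x bin
#'   matrix of null bin means), `statistic`, `n_reps`.
#' @export
null_series <- function(dataset, traits,
                        statistic = c("variability", "directional",
                                      "convergence"),
                        n_reps = 1000, seed = NULL, min_coverage = 0.5,
                        perms = NULL) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(perms)) n_reps <- length(perms)
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  vals <- if (inherits(traits, "trait_table")) traits$values else
    as.matrix(traits)
  props <- relative_abundance(dataset)
  vals <- vals[colnames(props), , drop = FALSE]
  sds <- apply(vals, 2, stats::sd, na.rm = TRUE)  # frozen scaling

  pt <- .series_pair_table(dataset$metadata, statistic)
  obs_C <- .cwm_matrix(props, vals, min_coverage)$cwm
  obs_units <- .series_units(.pair_trait_dist(obs_C, sds, pt$a, pt$b),
                             pt$unit, pt$bin)
  observed <- .summarize_series(obs_units, paste0("trait_", statistic))

  key <- paste(obs_units$unit, obs_units$bin)
  acc <- numeric(nrow(obs_units)); acc_n <- integer(nrow(obs_units))
  bins <- sort(unique(obs_units$bin))
  rep_bins <- matrix(NA_real_, n_reps, length(bins),
                     dimnames = list(NULL, bins))
  for (r in seq_len(n_reps)) {
    perm <- if (is.null(perms)) sample.int(nrow(vals)) else perms[[r]]
    pv <- vals[perm, , drop = FALSE]
    C <- .cwm_matrix(props, pv, min_coverage)$cwm
    u <- .series_units(.pair_trait_dist(C, sds, pt$a, pt$b),
                       pt$unit, pt$bin)
    stopifnot(identical(paste(u$unit, u$bin), key))
    ok <- !is.na(u$value)
    acc[ok] <- acc[ok] + u$value[ok]
    acc_n <- acc_n + ok
    bm <- tapply(u$value, u$bin, mean, na.rm = TRUE)
    rep_bins[r, names(bm)] <- bm
  }
  null_units <- obs_units
  null_units$value <- ifelse(acc_n > 0, acc / acc_n, NA_real_)
  structure(list(observed = observed, observed_units = obs_units,
                 null_units = null_units,
                 rep_bins = rep_bins, statistic = statistic,
                 n_reps = n_reps),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("null_ensemble:", x$statistic, "with", x$n_reps, "replicates\n")
  print(observed_vs_null_test(x), row.names = FALSE)
  invisible(x)
}

#' Welch tests of an observed series against its null ensemble
#'
#' Per 6-month bin: Welch's t test between the observed per-unit values
#' and the matched per-unit replicate-averaged null values (equal unit
#' counts; no pseudo-replication across replicates), with BH adjustment
#' across bins. Bins with fewer than 2 units are skipped.
#'
#' @param ensemble A [null_series()] result.
#' @return data.frame with `bin`, `observed_mean`, `null_mean`, `t`, `p`,
#'   `p_adj`, `n`.
#' @export
observed_vs_null_test <- function(ensemble) {
  ob <- ensemble$observed_units
  nu <- ensemble$null_units
  rows <- list(); k <- 0L
  for (b in sort(unique(ob$bin))) {
    x <- ob$value[ob$bin == b]
    y <- nu$value[nu$bin == b]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    k <- k + 1L
    if (length(x) < 2L) {
      rows[[k]] <- data.frame(bin = b, observed_mean = mean(x),
                              null_mean = mean(y), t = NA_real_,
                              p = NA_real_, n = length(x))
      next
    }
    tt <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      list(statistic = c(t = if (mean(x) == mean(y)) 0 else Inf),
           p.value = if (mean(x) == mean(y)) 1 else 0)
    } else stats::t.test(x, y)
    rows[[k]] <- data.frame(bin = b, observed_mean = mean(x),
                            null_mean = mean(y),
                            t = unname(tt$statistic), p = tt$p.value,
                            n = length(x))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[c("bin", "observed_mean", "null_mean", "t", "p", "p_adj", "n")]
}
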