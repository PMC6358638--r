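# Community-level machinery: rarefaction, community-weighted trait means
# and variances, and the two dissimilarity measures (Bray-Curtis on OTU
# composition; SD-scaled Euclidean distance in CWM trait space).

#' Rarefy an OTU count table to even depth
#'
#' Samples with fewer than `depth` reads are removed (their number is
#' recorded); the rest are subsampled without replacement (multivariate
#' hypergeometric) to exactly `depth` reads.
#'
#' @param x Count matrix (samples x OTUs) or [community_dataset()].
#' @param depth Rarefaction depth (default 5000).
#' @param seed Optional integer seed.
#' @return Same type as `x`, with attribute `removed` naming dropped
#'   samples.
#' @export
rarefy <- function(x, depth = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (depth <= 0) stop("`depth` must be positive", call. = FALSE)
  counts <- if (inherits(x, "community_dataset")) x$counts else as.matrix(x)
  if (any(counts != round(counts)))
    stop("counts must be integers", call. = FALSE)
  tot <- rowSums(counts)
  keep <- tot >= depth
  removed <- rownames(counts)[!keep]
  if (!any(keep))
    stop("every sample has fewer than ", depth, " reads", call. = FALSE)
  counts <- counts[keep, , drop = FALSE]
  out <- counts
  need <- rowSums(counts) > depth
  if (any(need))
    out[need, ] <- withCallingHandlers(
      vegan::rrarefy(counts[need, , drop = FALSE], depth),
      # vegan notes when every sample clears the depth; expected here
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  storage.mode(out) <- "integer"
  if (inherits(x, "community_dataset")) {
    res <- community_dataset(out, x$metadata[keep, , drop = FALSE])
  } else res <- out
  attr(res, "removed") <- removed
  res
}

#' Relative abundances from counts
#' @param counts Count matrix (samples x OTUs).
#' @return Matrix of row proportions.
#' @export
relative_abundance <- function(counts) {
  if (inherits(counts, "community_dataset")) counts <- counts$counts
  sweep(counts, 1, rowSums(counts), "/")
}

#' Community-weighted mean of a trait
#'
#' `sum(p_i * x_i)` over the OTUs in a sample, weighting each trait value
#' by relative abundance. OTUs with missing trait values are dropped and
#' the weights renormalized over the covered subset; if the covered
#' abundance falls below `min_coverage` the CWM is reported missing.
#'
#' @param sample_props Numeric vector of relative abundances (sums to 1
#'   over OTUs present).
#' @param trait_values Numeric vector of trait values (NAs = missing).
#' @param min_coverage Minimum covered abundance (default 0.5).
#' @param renormalize Renormalize weights over covered OTUs (default
#'   `TRUE`); `FALSE` gives the covered-abundance-weighted partial sum.
#' @return Scalar CWM, or `NA` under insufficient coverage.
#' @export
cwm <- function(sample_props, trait_values, min_coverage = 0.5,
                renormalize = TRUE) {
  ok <- !is.na(trait_values)
  cov <- sum(sample_props[ok])
  if (cov < min_coverage || cov == 0) return(NA_real_)
  w <- if (renormalize) sample_props[ok] / cov else sample_props[ok]
  sum(w * trait_values[ok])
}

#' Community-weighted variance of a trait
#'
#' `sum(p_i * (x_i - CWM)^2)` with the same coverage and renormalization
#' rules as [cwm()].
#'
#' @inheritParams cwm
#' @return Scalar CWV (>= 0), or `NA` under insufficient coverage.
#' @export
cwv <- function(sample_props, trait_values, min_coverage = 0.5,
                renormalize = TRUE) {
  ok <- !is.na(trait_values)
  cov <- sum(sample_props[ok])
  if (cov < min_coverage || cov == 0) return(NA_real_)
  w <- if (renormalize) sample_props[ok] / cov else sample_props[ok]
  m <- sum(w * trait_values[ok])
  sum(w * (trait_values[ok] - m)^2)
}

# vectorized CWM/CWV over all samples and traits (used by profiles and
# null ensembles; identical output to looping cwm()/cwv())
.cwm_matrix <- function(props, traits, min_coverage = 0.5) {
  M <- !is.na(traits)
  X <- ifelse(M, traits, 0)
  covered <- props %*% M
  num <- props %*% X
  cwm <- num / covered
  cwm[covered < min_coverage | covered == 0] <- NA_real_
  sq <- props %*% ifelse(M, traits^2, 0)
  cwv <- sq / covered - (num / covered)^2
  cwv[is.na(cwm)] <- NA_real_
  cwv <- pmax(cwv, 0)
  dimnames(cwm) <- dimnames(cwv) <- list(rownames(props), colnames(traits))
  list(cwm = cwm, cwv = cwv)
}

#' Sample-by-trait profile of community-weighted means
#'
#' Computes the CWM and CWV of every trait for every sample, plus the
#' per-trait scaling standard deviations (SD of each trait's values across
#' OTUs) used by [trait_distance()]. The SDs are computed here once and
#' frozen, so observed and null-model comparisons share the same scaling.
#'
#' @param dataset A [community_dataset()] (or count matrix).
#' @param traits Numeric matrix OTU x trait (gated values; NA = missing),
#'   or a [trait_table()].
#' @param min_coverage Minimum covered abundance per CWM (default 0.5).
#' @return Object of class `cwm_profile`: `cwm`, `cwv` (samples x traits),
#'   `trait_sds`, `metadata` (if available).
#' @export
cwm_profile <- function(dataset, traits, min_coverage = 0.5) {
  if (inherits(traits, "trait_table")) traits <- traits$values
  props <- relative_abundance(dataset)
  traits <- traits[colnames(props), , drop = FALSE]
  res <- .cwm_matrix(props, traits, min_coverage)
  structure(list(cwm = res$cwm, cwv = res$cwv,
                 trait_sds = apply(traits, 2, stats::sd, na.rm = TRUE),
                 metadata = if (inherits(dataset, "community_dataset"))
                   dataset$metadata else NULL),
            class = "cwm_profile")
}

#' @export
print.cwm_profile <- function(x, ...) {
  cat("cwm_profile:", nrow(x$cwm), "samples x", ncol(x$cwm), "traits\n")
  invisible(x)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `sum |p_i - q_i| / sum (p_i + q_i)`: 0 for identical compositions, 1
#' for disjoint supports.
#'
#' @param props_a,props_b Equal-length abundance vectors over the same OTU
#'   universe.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(props_a, props_b) {
  if (length(props_a) != length(props_b))
    stop("vectors must share the OTU universe", call. = FALSE)
  sum(abs(props_a - props_b)) / sum(props_a + props_b)
}

#' SD-scaled Euclidean distance between two communities in trait space
#'
#' Each trait's CWM is divided by that trait's OTU-level standard
#' deviation (equal weighting), and the Euclidean distance is taken over
#' the traits non-missing in both samples.
#'
#' @param cwm_a,cwm_b Named CWM vectors (one value per trait).
#' @param trait_sds Named per-trait scaling SDs (from [cwm_profile()]).
#' @return Nonnegative scalar; `NA` if no shared non-missing traits.
#' @export
trait_distance <- function(cwm_a, cwm_b, trait_sds) {
  ok <- !is.na(cwm_a) & !is.na(cwm_b) & trait_sds > 0
  if (!any(ok)) return(NA_real_)
  sqrt(sum(((cwm_a[ok] - cwm_b[ok]) / trait_sds[ok])^2))
}

#' All-pairs Bray-Curtis matrix
#' @param x Count matrix, proportions matrix or [community_dataset()].
#' @return Symmetric dissimilarity matrix.
#' @export
bray_curtis_matrix <- function(x) {
  props <- relative_abundance(x)
  as.matrix(vegan::vegdist(props, method = "bray"))
}

#' All-pairs trait-space distance matrix from a CWM profile
#' @param profile A [cwm_profile()].
#' @return Symmetric distance matrix over samples.
#' @export
trait_distance_matrix <- function(profile) {
  n <- nrow(profile$cwm)
  d <- matrix(0, n, n, dimnames = list(rownames(profile$cwm),
                                       rownames(profile$cwm)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- trait_distance(profile$cwm[i, ], profile$cwm[j, ],
                                         profile$trait_sds)
  d
}
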