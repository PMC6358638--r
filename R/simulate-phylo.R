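#' Simulate an ultrametric pure-birth species tree
#'
#' Generates a Yule (pure-birth) tree and rescales all branch lengths so the
#' maximum tip-to-tip cophenetic distance equals `depth_target`. Branch
#' lengths are therefore in the same dissimilarity units used for 16S V4
#' sequence comparisons, where a distance of 0.03 corresponds to the
#' conventional 97% OTU radius.
#'
#' @param n_tips Number of tips (>= 2).
#' @param depth_target Maximum tip-to-tip cophenetic distance after
#'   rescaling, in dissimilarity units.
#' @param seed Optional integer seed for reproducibility.
#' @return An ultrametric [ape::phylo] object with tip labels
#'   `otu0001, otu0002, ...`.
#' @examples
#' tr <- simulate_tree(10, depth_target = 0.3, seed = 1)
#' max(stats::cophenetic(tr)) # 0.3
#' @export
simulate_tree <- function(n_tips, depth_target = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(n_tips) != 1L || is.na(n_tips) || n_tips < 2)
    stop("`n_tips` must be a single integer >= 2", call. = FALSE)
  if (depth_target <= 0)
    stop("`depth_target` must be positive", call. = FALSE)
  tr <- ape::rphylo(n = as.integer(n_tips), birth = 1, death = 0)
  tr$tip.label <- sprintf("otu%04d", seq_len(n_tips))
  # ultrametric: max pairwise distance = 2 * tree height
  height <- max(ape::node.depth.edgelength(tr)[seq_len(n_tips)])
  tr$edge.length <- tr$edge.length * depth_target / (2 * height)
  tr
}

#' Simulate a continuous trait by Brownian motion on a tree
#'
#' Evolves a trait from `root_value` along each branch with independent
#' Gaussian increments of variance `bm_sigma2 * branch_length`, the standard
#' Brownian-motion model of a phylogenetically conserved continuous trait.
#'
#' @param tree A `phylo` object.
#' @param bm_sigma2 Trait variance accumulated per unit of branch length
#'   (>= 0).
#' @param root_value Trait value at the root.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_continuous_trait <- function(tree, bm_sigma2, root_value = 0,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (bm_sigma2 < 0) stop("`bm_sigma2` must be >= 0", call. = FALSE)
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise") # parents before children
  x <- numeric(ntip + tr$Nnode)
  x[ntip + 1L] <- root_value
  inc <- stats::rnorm(nrow(tr$edge), 0, sqrt(bm_sigma2 * tr$edge.length))
  for (e in seq_len(nrow(tr$edge)))
    x[tr$edge[e, 2L]] <- x[tr$edge[e, 1L]] + inc[e]
  stats::setNames(x[seq_len(ntip)], tr$tip.label)
}

#' Simulate a binary trait by a symmetric two-state Markov process
#'
#' The state flips along a branch of length `b` with probability
#' `(1 - exp(-2 * rate * b)) / 2`, the transition probability of the
#' symmetric two-state continuous-time Markov chain.
#'
#' @param tree A `phylo` object.
#' @param rate Switch rate in events per unit branch length (>= 0).
#' @param root_state Root state, 0 or 1.
#' @param seed Optional integer seed.
#' @return Named integer vector (0/1) of tip states.
#' @export
simulate_discrete_trait <- function(tree, rate, root_state = 0L,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (rate < 0) stop("`rate` must be >= 0", call. = FALSE)
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")
  x <- integer(ntip + tr$Nnode)
  x[ntip + 1L] <- as.integer(root_state)
  p_flip <- (1 - exp(-2 * rate * tr$edge.length)) / 2
  flips <- stats::runif(nrow(tr$edge)) < p_flip
  for (e in seq_len(nrow(tr$edge))) {
    par <- x[tr$edge[e, 1L]]
    x[tr$edge[e, 2L]] <- if (flips[e]) 1L - par else par
  }
  stats::setNames(x[seq_len(ntip)], tr$tip.label)
}

#' Mask trait values to emulate sparse literature coverage
#'
#' Marks a uniformly random subset of `round(frac_observed * n)` tips as
#' observed (at least one), mimicking the partial coverage of curated trait
#' databases.
#'
#' @param tip_values Named vector of true tip values.
#' @param frac_observed Fraction of tips observed, in (0, 1].
#' @param seed Optional integer seed.
#' @return Named logical vector, `TRUE` for observed tips. The observed
#'   values themselves are `tip_values[mask]`.
#' @export
mask_traits <- function(tip_values, frac_observed, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (frac_observed <= 0 || frac_observed > 1)
    stop("`frac_observed` must be in (0, 1]", call. = FALSE)
  n <- length(tip_values)
  if (n < 1L) stop("no tips to observe", call. = FALSE)
  k <- max(1L, round(frac_observed * n))
  mask <- rep(FALSE, n)
  mask[sample.int(n, k)] <- TRUE
  stats::setNames(mask, names(tip_values))
}
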