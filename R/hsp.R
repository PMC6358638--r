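# Hidden-state prediction: inferring unobserved tip trait values on a
# phylogeny from observed tips. Three algorithms are provided:
#
#   wscp     weighted squared-change parsimony — minimizes the sum over
#            edges of (parent - child)^2 / branch_length with observed tips
#            fixed and hidden tips free; solved exactly by a two-pass
#            recursion (rootward combination of locally parsimonious
#            states, then tipward finalization)
#   subtree  subtree averaging — each hidden tip takes the unweighted mean
#            of observed tips in the nearest ancestral clade containing any
#   pic      independent contrasts — Felsenstein's rootward
#            branch-length-weighted averaging on the observed-tip-pruned
#            tree; hidden tips take their nearest reconstructed ancestor
#
# All three are exact interpolators: observed tips keep their values.

# adjacency helpers -----------------------------------------------------

.tree_index <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  depth <- max(ape::node.depth.edgelength(tree))
  eps <- 1e-9 * max(depth, 1e-12)
  bl <- pmax(po$edge.length, eps)
  list(ntip = ntip, nnode = tree$Nnode, edge = po$edge, bl = bl,
       root = ntip + 1L)
}

# rootward + tipward pass of the quadratic (Gaussian) recursion
.wscp_values <- function(tree, obs) {
  ix <- .tree_index(tree)
  ntip <- ix$ntip
  nn <- ntip + ix$nnode
  x <- rep(NA_real_, nn)
  x[match(names(obs), tree$tip.label)] <- obs
  is_obs <- !is.na(x)

  W <- numeric(nn)   # combined precision of child messages at each node
  WH <- numeric(nn)  # precision-weighted sum of child message means
  # rootward: children appear before their parent edge in postorder
  for (e in seq_len(nrow(ix$edge))) {
    p <- ix$edge[e, 1L]; ch <- ix$edge[e, 2L]; b <- ix$bl[e]
    if (ch <= ntip) {
      if (is_obs[ch]) { w <- 1 / b; h <- x[ch] } else { w <- 0; h <- 0 }
    } else if (W[ch] > 0) {
      w <- 1 / (b + 1 / W[ch]); h <- WH[ch] / W[ch]
    } else { w <- 0; h <- 0 }
    W[p] <- W[p] + w
    WH[p] <- WH[p] + w * h
  }
  if (W[ix$root] <= 0) stop("insufficient-data: no observed tips", call. = FALSE)
  v <- numeric(nn)
  v[ix$root] <- WH[ix$root] / W[ix$root]
  # tipward: parents before children
  for (e in rev(seq_len(nrow(ix$edge)))) {
    p <- ix$edge[e, 1L]; ch <- ix$edge[e, 2L]; b <- ix$bl[e]
    if (ch <= ntip) {
      v[ch] <- if (is_obs[ch]) x[ch] else v[p]
    } else {
      v[ch] <- (WH[ch] + v[p] / b) / (W[ch] + 1 / b)
    }
  }
  stats::setNames(v[seq_len(ntip)], tree$tip.label)
}

.subtree_avg_values <- function(tree, obs) {
  ix <- .tree_index(tree)
  ntip <- ix$ntip
  nn <- ntip + ix$nnode
  x <- rep(NA_real_, nn)
  x[match(names(obs), tree$tip.label)] <- obs
  is_obs <- !is.na(x)
  osum <- numeric(nn); onum <- integer(nn)
  osum[is_obs] <- x[is_obs]; onum[is_obs] <- 1L
  parent <- integer(nn)
  for (e in seq_len(nrow(ix$edge))) {
    p <- ix$edge[e, 1L]; ch <- ix$edge[e, 2L]
    parent[ch] <- p
    osum[p] <- osum[p] + osum[ch]
    onum[p] <- onum[p] + onum[ch]
  }
  if (onum[ix$root] == 0L)
    stop("insufficient-data: no observed tips", call. = FALSE)
  out <- numeric(ntip)
  for (i in seq_len(ntip)) {
    if (is_obs[i]) { out[i] <- x[i]; next }
    a <- parent[i]
    while (onum[a] == 0L) a <- parent[a]
    out[i] <- osum[a] / onum[a]
  }
  stats::setNames(out, tree$tip.label)
}

# independent-contrasts node estimates on the pruned tree, with branch
# extension b' = b + 1 / sum(1 / b_child); generalizes the two-child
# formula x_k = (x_i/b_i + x_j/b_j) / (1/b_i + 1/b_j)
.pic_node_estimates <- function(ptree, tipvals) {
  ix <- .tree_index(ptree)
  ntip <- ix$ntip
  nn <- ntip + ix$nnode
  est <- rep(NA_real_, nn)
  est[seq_len(ntip)] <- tipvals[ptree$tip.label]
  ext <- numeric(nn)          # accumulated branch extension per node
  sw <- numeric(nn); swx <- numeric(nn)
  for (e in seq_len(nrow(ix$edge))) {
    p <- ix$edge[e, 1L]; ch <- ix$edge[e, 2L]
    b <- ix$bl[e] + ext[ch]
    sw[p] <- sw[p] + 1 / b
    swx[p] <- swx[p] + est[ch] / b
    if (sw[p] > 0) { est[p] <- swx[p] / sw[p]; ext[p] <- 1 / sw[p] }
  }
  est
}

.pic_values <- function(tree, obs) {
  if (length(obs) < 2L)
    stop("insufficient-data: independent contrasts needs >= 2 observed tips",
         call. = FALSE)
  ntip <- length(tree$tip.label)
  obs_tips <- names(obs)
  ptree <- ape::keep.tip(tree, obs_tips)
  est <- .pic_node_estimates(ptree, obs)

  # per original node: number of observed tips below, one observed
  # representative per node, and per-child observed representatives
  ix <- .tree_index(tree)
  nn <- ntip + ix$nnode
  is_obs <- tree$tip.label %in% obs_tips
  onum <- integer(nn); onum[seq_len(ntip)][is_obs] <- 1L
  rep1 <- character(nn)
  rep1[seq_len(ntip)][is_obs] <- tree$tip.label[is_obs]
  parent <- integer(nn)
  kids <- vector("list", nn)
  for (e in seq_len(nrow(ix$edge))) {
    p <- ix$edge[e, 1L]; ch <- ix$edge[e, 2L]
    parent[ch] <- p
    kids[[p]] <- c(kids[[p]], ch)
    onum[p] <- onum[p] + onum[ch]
    if (rep1[p] == "" && rep1[ch] != "") rep1[p] <- rep1[ch]
  }
  proot <- length(ptree$tip.label) + 1L
  out <- numeric(ntip)
  for (i in seq_len(ntip)) {
    if (is_obs[i]) { out[i] <- obs[tree$tip.label[i]]; next }
    a <- parent[i]
    node <- NA_integer_
    while (TRUE) {
      reps <- rep1[kids[[a]]]
      reps <- reps[reps != ""]
      if (length(reps) >= 2L) { # ancestor survives pruning: find its image
        node <- ape::getMRCA(ptree, reps[1:2])
        break
      }
      if (a == ix$root) { node <- proot; break }
      a <- parent[a]
    }
    out[i] <- est[node]
  }
  stats::setNames(out, tree$tip.label)
}

#' Distance from each tip to its nearest observed tip
#'
#' Minimum cophenetic distance from every tip to any member of the
#' observed set (0 for observed tips themselves); the quantity against
#' which trait-specific conservatism thresholds are applied.
#'
#' @param tree A `phylo` object.
#' @param observed_tips Character vector of observed tip labels.
#' @return Named numeric vector over all tips.
#' @export
nearest_observed_distance <- function(tree, observed_tips) {
  if (length(observed_tips) == 0L)
    stop("insufficient-data: observed set is empty", call. = FALSE)
  cm <- cophenetic_matrix(tree)
  apply(cm[, observed_tips, drop = FALSE], 1, min)
}

#' Predict hidden tip trait values on a phylogeny
#'
#' Fits one of three hidden-state-prediction algorithms (see Details) to a
#' partially observed tip trait and predicts the remaining tips. Discrete
#' traits encoded numerically yield fractional predictions, read as
#' probabilistic state estimates; nothing is rounded.
#'
#' @details `method = "wscp"` (the default, and the method of record for
#' downstream analysis) minimizes the branch-length-weighted sum of squared
#' changes over all edges, with observed tips clamped and hidden tips free;
#' a hidden tip's optimum equals its parent node's. `"subtree"` averages
#' observed tips within the nearest ancestral clade containing any.
#' `"pic"` runs the independent-contrasts rootward recursion on the tree
#' pruned to observed tips and assigns each hidden tip the estimate of its
#' nearest reconstructed ancestor. Zero-length branches are replaced by
#' 1e-9 of the tree depth (agglomerative trees can emit ties).
#'
#' @param tree A `phylo` object.
#' @param x Named numeric vector of trait values: either observed tips
#'   only, or all tips with `NA` marking hidden ones.
#' @param method One of `"wscp"`, `"subtree"`, `"pic"`.
#' @return An object of class `hsp` with components `fitted` (named values
#'   for every tip), `observed` (named logical), `nearest_obs_dist`,
#'   `method`. Use [fitted()] for all tips or [predict()] for hidden tips.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' fit <- hsp(tr, c(A = 0, B = 2), method = "wscp")
#' predict(fit)  # C = 1
#' @export
hsp <- function(tree, x, method = c("wscp", "subtree", "pic")) {
  method <- match.arg(method)
  if (is.null(names(x))) stop("`x` must be named by tip label", call. = FALSE)
  if (!all(names(x) %in% tree$tip.label))
    stop("`x` has names that are not tips", call. = FALSE)
  obs <- x[!is.na(x)]
  if (length(obs) == 0L)
    stop("insufficient-data: no observed tips", call. = FALSE)
  fitted <- switch(method,
                   wscp = .wscp_values(tree, obs),
                   subtree = .subtree_avg_values(tree, obs),
                   pic = .pic_values(tree, obs))
  observed <- stats::setNames(tree$tip.label %in% names(obs), tree$tip.label)
  structure(list(fitted = fitted, observed = observed,
                 nearest_obs_dist = nearest_observed_distance(tree, names(obs)),
                 method = method, call = match.call()),
            class = "hsp")
}

#' @export
print.hsp <- function(x, ...) {
  cat("Hidden-state prediction (", x$method, "): ",
      sum(x$observed), " observed, ", sum(!x$observed),
      " predicted tips\n", sep = "")
  invisible(x)
}

#' @export
fitted.hsp <- function(object, ...) object$fitted

#' Predicted values for hidden tips
#' @param object An `hsp` fit.
#' @param tips Tips to report (default: all hidden tips).
#' @param ... Unused.
#' @export
predict.hsp <- function(object, tips = NULL, ...) {
  if (is.null(tips)) tips <- names(object$observed)[!object$observed]
  object$fitted[tips]
}
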