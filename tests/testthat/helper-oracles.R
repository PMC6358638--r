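# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route (dense linear algebra, explicit loops,
# closed forms) and stays independent of the package internals.

# Dense solution of the weighted squared-change objective: minimize
# sum over edges of (v_parent - v_child)^2 / b with observed tips clamped,
# hidden tips and internal nodes free, by solving the normal equations of
# the full node-by-node quadratic form.
wscp_dense_oracle <- function(tree, obs) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  depth <- max(ape::node.depth.edgelength(tree))
  w <- 1 / pmax(tree$edge.length, 1e-9 * max(depth, 1e-12))
  L <- matrix(0, nn, nn)
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1]; j <- tree$edge[e, 2]
    L[i, i] <- L[i, i] + w[e]; L[j, j] <- L[j, j] + w[e]
    L[i, j] <- L[i, j] - w[e]; L[j, i] <- L[j, i] - w[e]
  }
  known <- match(names(obs), tree$tip.label)
  free <- setdiff(seq_len(nn), known)
  v <- numeric(nn)
  v[known] <- obs
  v[free] <- solve(L[free, free, drop = FALSE],
                   -L[free, known, drop = FALSE] %*% obs)
  stats::setNames(v[seq_len(ntip)], tree$tip.label)
}

# Tip-to-tip path length by breadth-first search over the edge list.
path_sum_oracle <- function(tree, tip_a, tip_b) {
  nn <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1]; j <- tree$edge[e, 2]; b <- tree$edge.length[e]
    adj[[i]] <- rbind(adj[[i]], c(j, b))
    adj[[j]] <- rbind(adj[[j]], c(i, b))
  }
  src <- match(tip_a, tree$tip.label)
  dst <- match(tip_b, tree$tip.label)
  dist <- rep(NA_real_, nn)
  dist[src] <- 0
  queue <- src
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (r in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][r, 1]
      if (is.na(dist[v])) {
        dist[v] <- dist[u] + adj[[u]][r, 2]
        queue <- c(queue, v)
      }
    }
  }
  dist[dst]
}

# Textbook Welch t statistic and p-value.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# A small random ultrametric tree for property tests.
random_test_tree <- function(n, depth = 0.3) {
  traitsuccession::simulate_tree(n, depth_target = depth)
}

# A tiny deterministic community dataset: `n_inf` infants, one sample per
# listed month, counts supplied per sample by `make_counts(infant, month)`.
make_dataset <- function(n_inf, months, make_counts, n_otu = 3) {
  rows <- list(); meta <- list(); k <- 0
  for (i in seq_len(n_inf)) for (m in months) {
    k <- k + 1
    rows[[k]] <- make_counts(i, m)
    meta[[k]] <- data.frame(sample_id = sprintf("i%02d_m%02d", i, m),
                            infant_id = sprintf("i%02d", i),
                            age_days = round((m - 0.5) * 30.44),
                            delivery_mode = "vaginal", abx_days = 0)
  }
  counts <- do.call(rbind, rows)
  md <- do.call(rbind, meta)
  colnames(counts) <- paste0("otu", seq_len(ncol(counts)))
  rownames(counts) <- md$sample_id
  traitsuccession::community_dataset(counts, md)
}
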