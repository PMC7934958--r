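# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: dense double loops, matrix
# exponentials and exhaustive enumeration at tiny sizes.

# naive O(n^2) double sum: sum_{i != j} W[i,j] z_i z_j
bruteforce_double_sum <- function(W, z) {
  n <- length(z)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) s <- s + W[i, j] * z[i] * z[j]
    }
  }
  s
}

# matrix exponential of the truncated linear birth-death generator
# (birth and death rate i * lam from state i)
bd_expm_oracle <- function(t, lam, N) {
  i <- 0:N
  Q <- matrix(0, N + 1, N + 1)
  Q[cbind(2:(N + 1), 1:N)] <- i[-1] * lam # deaths
  Q[cbind(1:N, 2:(N + 1))] <- i[-(N + 1)] * lam # births
  diag(Q) <- -rowSums(Q)
  as.matrix(Matrix::expm(Q * t))
}

# exhaustive sum over all internal-node state assignments
bruteforce_family_loglik <- function(counts, tree, model) {
  phy <- tree$phy
  n_tip <- ape::Ntip(phy)
  n_node <- phy$Nnode
  lam_edge <- immunevol:::edge_rates(tree, model)
  counts <- counts[phy$tip.label]
  N <- model$max_count
  internal <- (n_tip + 1):(n_tip + n_node)
  grids <- rep(list(0:N), n_node)
  assignments <- as.matrix(expand.grid(grids))
  total <- 0
  for (a in seq_len(nrow(assignments))) {
    states <- c(counts, assignments[a, ])
    root_state <- states[n_tip + 1]
    if (root_state < 1 || root_state > model$root_max) next
    p <- 1 / model$root_max
    for (e in seq_len(nrow(phy$edge))) {
      p <- p * bd_transition_prob(
        states[phy$edge[e, 1]], states[phy$edge[e, 2]],
        phy$edge.length[e], lam_edge[e]
      )
      if (p == 0) break
    }
    total <- total + p
  }
  log(total)
}

# exhaustive joint argmax over internal states (ties toward the
# lexicographically smaller assignment, i.e. smaller counts)
bruteforce_joint_argmax <- function(counts, tree, model) {
  phy <- tree$phy
  n_tip <- ape::Ntip(phy)
  n_node <- phy$Nnode
  lam_edge <- immunevol:::edge_rates(tree, model)
  counts <- counts[phy$tip.label]
  N <- model$max_count
  assignments <- as.matrix(expand.grid(rep(list(0:N), n_node)))
  best_p <- -Inf
  best <- NULL
  for (a in seq_len(nrow(assignments))) {
    states <- c(counts, assignments[a, ])
    root_state <- states[n_tip + 1]
    if (root_state < 1 || root_state > model$root_max) next
    p <- log(1 / model$root_max)
    for (e in seq_len(nrow(phy$edge))) {
      p <- p + log(bd_transition_prob(
        states[phy$edge[e, 1]], states[phy$edge[e, 2]],
        phy$edge.length[e], lam_edge[e]
      ))
      if (!is.finite(p)) break
    }
    if (is.finite(p) && p > best_p + 1e-12) {
      best_p <- p
      best <- states
    }
  }
  best
}

# random ultrametric test tree with unit-free branch lengths
random_coalescent_tree <- function(n, seed) {
  set.seed(seed)
  species_tree(ape::rcoal(n), ultrametric = TRUE, tol = 1e-6)
}

# random (generally non-ultrametric) tree for metric identities
random_rtree <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rtree(n)
  species_tree(phy, ultrametric = FALSE)
}

# node ids (tips + internal) of the subtree spanned by given tips
nodes_in_clade <- function(phy, tips) {
  mrca <- ape::getMRCA(phy, tips)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  out <- integer(0)
  stack <- mrca
  while (length(stack) > 0) {
    v <- stack[[1]]
    stack <- stack[-1]
    out <- c(out, v)
    ch <- kids[[as.character(v)]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  out
}

node_label_set <- function(phy, ids) {
  n_tip <- ape::Ntip(phy)
  ifelse(ids <= n_tip, phy$tip.label[ids], paste0("node", ids))
}
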