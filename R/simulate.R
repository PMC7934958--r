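## Synthetic-data generators: gene count matrices evolved under the
## birth-death model, continuous traits under Brownian motion with a known
## Pagel's lambda, and (in fixture.R) mock transcript-evidence bundles.

#' Synthetic 18-species cockroach/termite fixture tree
#'
#' A synthetic ultrametric phylogeny of 2 solitary cockroaches, 2 subsocial
#' wood roaches, 8 lower termites and 6 higher termites (Termitidae), with
#' plausible divergence times in million years (root at 150 My). Topology
#' and dates are invented for testing and simulation; they are not an
#' estimate for any real clade. Branch rate classes: the two solitary
#' cockroach lineages and the backbone are `"solitary"`, everything from
#' the wood roaches inwards is `"social"`.
#'
#' @return a [species_tree] with rate classes `"solitary"` and `"social"`.
#' @export
fixture_tree <- function() {
  k35 <- "(Nasutitermes_corniger:35,Cornitermes_cumulans:35)"
  j40 <- paste0("(Termes_hospes:40,", k35, ":5)")
  i45 <- paste0("(Microcerotermes_crassus:45,", j40, ":5)")
  tm50 <- paste0(
    "((Macrotermes_natalensis:30,Odontotermes_obesus:30):20,", i45, ":5)"
  )
  h60 <- paste0("(Coptotermes_formosanus:60,", tm50, ":10)")
  g70 <- paste0("(Reticulitermes_flavipes:70,", h60, ":10)")
  f80 <- paste0("(Prorhinotermes_simplex:80,", g70, ":10)")
  e90 <- paste0(
    "((Kalotermes_flavicollis:50,Cryptotermes_secundus:50):40,", f80, ":10)"
  )
  d100 <- paste0(
    "((Zootermopsis_nevadensis:60,Hodotermopsis_sjostedti:60):40,", e90, ":10)"
  )
  t110 <- paste0("(Mastotermes_darwiniensis:110,", d100, ":10)")
  c20 <- "(Cryptocercus_punctulatus:20,Cryptocercus_darwini:20)"
  nwk <- paste0(
    "(Blattella_germanica:150,(Blatta_orientalis:140,(",
    c20, ":100,", t110, ":10):20):10);"
  )
  tree <- species_tree(ape::read.tree(text = nwk))
  tips <- tree$phy$tip.label
  cls <- stats::setNames(
    ifelse(tips %in% c("Blattella_germanica", "Blatta_orientalis"),
      "solitary", "social"
    ),
    tips
  )
  assign_rate_classes(tree, cls, mixed = "solitary")
}

#' Reference per-class birth-death rates for simulations
#'
#' The default simulation truth: the solitary-lineage rate is higher than
#' the social-lineage rate (0.0037 vs 0.0016 events per gene per My),
#' mirroring the contrast reported for cockroach/termite immune gene
#' families.
#' @return named numeric vector with elements `solitary` and `social`.
#' @export
fixture_rates <- function() {
  c(solitary = 0.0037, social = 0.0016)
}

#' Tips of the higher-termite (Termitidae) clade of [fixture_tree()]
#' @return character vector of tip labels.
#' @export
fixture_termitidae_tips <- function() {
  c(
    "Macrotermes_natalensis", "Odontotermes_obesus",
    "Microcerotermes_crassus", "Termes_hospes",
    "Nasutitermes_corniger", "Cornitermes_cumulans"
  )
}

#' Replicated-cherry tree for covariance-parameter calibration
#'
#' An ultrametric tree of `n_pairs` two-species clades hanging off a
#' basal polytomy, each with a shared stem of length `stem` and pendant
#' branches of `1 - stem`. Pagel's lambda rescales off-diagonal
#' covariance, so its information content comes from replicated clades
#' with strong shared paths; on this shape the lambda MLE is close to
#' unbiased at moderate sizes, whereas on coalescent-like shapes the
#' profile likelihood is nearly flat and the estimator piles up on the
#' boundaries. Used for estimator-recovery simulations.
#'
#' @param n_pairs number of two-species clades (tips = `2 * n_pairs`).
#' @param stem shared fraction of each clade's unit depth, in (0, 1).
#' @return a [species_tree].
#' @export
replicated_cherry_tree <- function(n_pairs = 25, stem = 0.8) {
  stopifnot(n_pairs >= 2, stem > 0, stem < 1)
  tip <- 1 - stem
  cherries <- sprintf(
    "(c%da:%g,c%db:%g):%g", seq_len(n_pairs), tip, seq_len(n_pairs), tip, stem
  )
  nwk <- paste0("(", paste(cherries, collapse = ","), ");")
  species_tree(ape::read.tree(text = nwk))
}

rates_for_tree <- function(tree, rates) {
  classes <- levels(tree$rate_class)
  if (is.null(names(rates))) {
    if (length(rates) != 1L) stop("unnamed `rates` must be a single value")
    rates <- stats::setNames(rep(rates, length(classes)), classes)
  }
  missing_cls <- setdiff(classes, names(rates))
  if (length(missing_cls) > 0) {
    stop("no rate for class(es): ", paste(missing_cls, collapse = ", "))
  }
  rates
}

#' Simulate gene family counts under birth-death evolution on a tree
#'
#' For each family a root size is drawn uniformly from `root_range`, then
#' evolved down every branch under the linear birth-death process of
#' [bd_transition_prob()] with the branch's class rate. The default
#' (`method = "exact"`) samples each branch transition directly from the
#' closed-form transition law on a truncated support; `"gillespie"`
#' simulates individual birth/death events and serves as an independent
#' cross-check of the exact sampler.
#'
#' @param tree a [species_tree].
#' @param n_families number of families to simulate.
#' @param rates per-class birth = death rates (named by rate class, or a
#'   single unnamed value used for every class).
#' @param root_range integer interval `c(lo, hi)` for the uniform root
#'   size prior, `lo >= 0`.
#' @param seed optional integer seed.
#' @param max_count truncation bound of the exact sampler; default
#'   `4 * max(root_range) + 60`, generous enough that truncation loss is
#'   negligible for the rate regimes this package targets.
#' @param method `"exact"` or `"gillespie"`.
#' @return list with `tip_counts` (families x species integer matrix),
#'   `node_counts` (families x all-nodes matrix, columns named by tip
#'   label or `node<id>`), `root_states`, `tree`, `rates`.
#' @export
simulate_family_counts <- function(tree, n_families, rates,
                                   root_range = c(1, 10), seed = NULL,
                                   max_count = NULL,
                                   method = c("exact", "gillespie")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  rates <- rates_for_tree(tree, rates)
  phy <- as_phylo(tree)
  if (root_range[1] < 0 || root_range[2] < root_range[1]) {
    stop("invalid root_range")
  }
  N <- if (is.null(max_count)) 4L * max(root_range) + 60L else as.integer(max_count)
  n_tip <- ape::Ntip(phy)
  n_all <- n_tip + phy$Nnode
  lam_edge <- edge_rates(tree, bd_model(rates, N, 1L))
  # preorder: reverse of postorder guarantees parent states exist
  po <- ape::reorder.phylo(phy, "postorder")
  key <- function(E) paste(E[, 1], E[, 2])
  perm <- rev(match(key(po$edge), key(phy$edge)))
  node_counts <- matrix(0L, n_families, n_all)
  span <- root_range[2] - root_range[1] + 1L
  root_states <- root_range[1] + sample.int(span, n_families, replace = TRUE) - 1L
  node_counts[, n_tip + 1L] <- root_states
  Pcache <- list() # branches sharing (rate, length) share a matrix
  for (e in perm) {
    par <- phy$edge[e, 1L]
    ch <- phy$edge[e, 2L]
    t_e <- phy$edge.length[e]
    lam <- lam_edge[e]
    s_vec <- node_counts[, par]
    child <- integer(n_families)
    if (method == "exact") {
      pkey <- paste(lam, t_e)
      P <- Pcache[[pkey]]
      if (is.null(P)) {
        P <- bd_transition_matrix(t_e, lam, N)
        Pcache[[pkey]] <- P
      }
      for (s in unique(s_vec)) {
        rows <- which(s_vec == s)
        if (s == 0L) next
        child[rows] <- sample.int(N + 1L, length(rows),
          replace = TRUE, prob = P[s + 1L, ]
        ) - 1L
      }
    } else {
      for (i in seq_len(n_families)) {
        child[i] <- bd_branch_gillespie(s_vec[i], t_e, lam)
      }
    }
    node_counts[, ch] <- child
  }
  colnames(node_counts) <- c(phy$tip.label, paste0("node", (n_tip + 1L):n_all))
  rownames(node_counts) <- sprintf("fam%04d", seq_len(n_families))
  tip_counts <- node_counts[, seq_len(n_tip), drop = FALSE]
  list(
    tip_counts = tip_counts, node_counts = node_counts,
    root_states = root_states, tree = tree, rates = rates
  )
}

bd_branch_gillespie <- function(s, t, lam) {
  s <- as.integer(s)
  if (lam == 0) {
    return(s)
  }
  tt <- 0
  repeat {
    if (s == 0L) break
    rate <- 2 * s * lam
    tt <- tt + stats::rexp(1, rate)
    if (tt > t) break
    s <- s + sample(c(1L, -1L), 1L)
  }
  s
}

#' Sample single-branch birth-death transitions
#'
#' Draws from the transition law `P(. | s)` over one branch, either exactly
#' (inverse-CDF over the truncated support) or by event-driven (Gillespie)
#' simulation. Used to validate the two samplers against each other and
#' against [bd_transition_prob()].
#'
#' @inheritParams bd_transition_prob
#' @param n number of draws.
#' @param method `"exact"` or `"gillespie"`.
#' @param max_count truncation bound for the exact sampler.
#' @param seed optional seed.
#' @return integer vector of descendant sizes.
#' @export
bd_branch_sample <- function(s, t, lam, n, method = c("exact", "gillespie"),
                             max_count = NULL, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  s <- as.integer(s)
  if (method == "gillespie") {
    return(vapply(seq_len(n), function(i) bd_branch_gillespie(s, t, lam), integer(1)))
  }
  N <- if (is.null(max_count)) 4L * s + 60L else as.integer(max_count)
  if (s == 0L) {
    return(integer(n))
  }
  P <- bd_transition_matrix(t, lam, N)
  sample.int(N + 1L, n, replace = TRUE, prob = P[s + 1L, ]) - 1L
}

#' Simulate continuous traits under Brownian motion with Pagel's lambda
#'
#' Tip values are multivariate normal with mean 0 and covariance
#' `sigma2 * V_lambda`, where `V_lambda` is the shared-path covariance of
#' the tree with off-diagonal entries multiplied by `lambda_pagel`.
#' `lambda_pagel = 1` is pure Brownian motion; `0` gives independent tips
#' with variance `sigma2 * depth(i)`.
#'
#' @param tree a [species_tree].
#' @param sigma2 Brownian rate (trait variance per unit branch length).
#' @param lambda_pagel phylogenetic covariance multiplier in `[0, 1]`.
#' @param n number of independent replicate traits.
#' @param seed optional seed.
#' @return if `n == 1` a named vector over tips, else an `n x tips` matrix.
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, lambda_pagel = 1, n = 1,
                              seed = NULL) {
  if (lambda_pagel < 0 || lambda_pagel > 1) {
    stop("lambda_pagel must be in [0, 1]")
  }
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  phy <- as_phylo(tree)
  n_tip <- ape::Ntip(phy)
  tips <- phy$tip.label
  if (sigma2 == 0) {
    X <- matrix(0, n, n_tip, dimnames = list(NULL, tips))
  } else {
    V <- shared_path_covariance(tree)
    Vl <- V * lambda_pagel
    diag(Vl) <- diag(V)
    U <- chol(sigma2 * Vl)
    X <- matrix(stats::rnorm(n * n_tip), n, n_tip) %*% U
    colnames(X) <- tips
  }
  if (n == 1L) X[1L, ] else X
}

#' Simulate a count matrix with one clade evolving at an elevated rate
#'
#' Positive-control fixture for the expansion/contraction pipeline:
#' `n_background` families evolve under the two-class rates `rates`, and
#' `n_shifted` families additionally evolve at `shift_rate` on all branches
#' entirely inside the clade spanned by `clade_tips` (emulating episodic,
#' order-of-magnitude rate elevation of a few rapidly evolving families).
#'
#' @param tree a [species_tree] with tip-derived rate classes.
#' @param clade_tips tip labels spanning the elevated clade (must be
#'   monophyletic for the elevation to cover a connected subtree).
#' @param n_background,n_shifted family counts of the two kinds.
#' @param rates background per-class rates, default [fixture_rates()].
#' @param shift_rate elevated within-clade rate for shifted families.
#' @param root_range,seed,max_count as in [simulate_family_counts()].
#' @return as [simulate_family_counts()], plus `shifted` (logical per
#'   family) and `clade_tips`.
#' @export
simulate_positive_control <- function(tree, clade_tips,
                                      n_background = 60, n_shifted = 6,
                                      rates = fixture_rates(),
                                      shift_rate = 0.02,
                                      root_range = c(1, 10), seed = NULL,
                                      max_count = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- as_phylo(tree)
  bad <- setdiff(clade_tips, phy$tip.label)
  if (length(bad) > 0) stop("unknown clade tips: ", paste(bad, collapse = ", "))
  rates <- rates_for_tree(tree, rates)
  bg <- simulate_family_counts(tree, n_background, rates,
    root_range = root_range, max_count = max_count
  )
  # reclass the clade's internal branches as "elevated" for the shifted set
  tip_cls <- tip_classes_from_edges(tree)
  tip_cls[clade_tips] <- "elevated"
  backbone <- names(which.max(table(tip_cls[setdiff(names(tip_cls), clade_tips)])))
  tree_shift <- assign_rate_classes(tree, tip_cls, mixed = backbone)
  rates_shift <- c(rates, elevated = unname(shift_rate))
  sh <- simulate_family_counts(tree_shift, n_shifted, rates_shift,
    root_range = root_range, max_count = max_count
  )
  tip_counts <- rbind(bg$tip_counts, sh$tip_counts)
  node_counts <- rbind(bg$node_counts, sh$node_counts)
  rownames(tip_counts) <- rownames(node_counts) <-
    sprintf("fam%04d", seq_len(nrow(tip_counts)))
  list(
    tip_counts = tip_counts, node_counts = node_counts,
    root_states = c(bg$root_states, sh$root_states),
    shifted = rep(c(FALSE, TRUE), c(n_background, n_shifted)),
    clade_tips = clade_tips, tree = tree, rates = rates,
    shift_rate = shift_rate
  )
}

# recover per-tip classes from the classes of the pendant edges
tip_classes_from_edges <- function(tree) {
  phy <- tree$phy
  n_tip <- ape::Ntip(phy)
  pend <- match(seq_len(n_tip), phy$edge[, 2])
  stats::setNames(as.character(tree$rate_class)[pend], phy$tip.label)
}
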