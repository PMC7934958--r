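## Family- and branch-level inference under the fitted birth-death model:
## Monte Carlo family p-values, joint ML ancestral family sizes (Viterbi
## over the truncated state space), branch p-values localizing significant
## changes, and the starred expansion/contraction report.

#' Simulate families from a fitted birth-death model
#'
#' Draws root sizes from the model's uniform root prior and evolves them
#' along the tree with the model's class rates; the sampler lives on the
#' model's truncated state space, matching the likelihood.
#'
#' @param tree a [species_tree].
#' @param model a [bd_model].
#' @param n number of families.
#' @param seed optional seed.
#' @return as [simulate_family_counts()].
#' @export
simulate_from_model <- function(tree, model, n, seed = NULL) {
  simulate_family_counts(tree, n, model$rates,
    root_range = c(1L, model$root_max), seed = seed,
    max_count = model$max_count
  )
}

#' Null distribution of per-family log-likelihoods
#'
#' Simulates `n_sim` families from the model and returns their
#' log-likelihoods under that same model; shared by the Monte Carlo
#' family p-values of every family tested against one fitted model.
#'
#' @inheritParams simulate_from_model
#' @param n_sim number of simulated null families.
#' @export
null_family_logliks <- function(tree, model, n_sim, seed = NULL) {
  if (n_sim < 1) stop("n_sim must be >= 1")
  sim <- simulate_from_model(tree, model, n_sim, seed = seed)
  ctx <- pruning_context(tree, model)
  bd_loglik_matrix(t(sim$tip_counts), tree, model, ctx = ctx)
}

#' Monte Carlo family-wide p-value
#'
#' The test statistic is the family's log-likelihood under the fitted
#' model (lower = more extreme, i.e. a tip-count pattern the model finds
#' unlikely). `n_sim` families are simulated under the model from the same
#' root prior and `p = (b + 1) / (n_sim + 1)` with `b` the number of
#' simulated families at least as extreme as the observed one.
#'
#' @param counts named per-species counts of one family.
#' @param tree a [species_tree].
#' @param model a fitted [bd_model].
#' @param n_sim number of null simulations (>= 100 recommended).
#' @param seed optional seed.
#' @param null_logliks optional precomputed [null_family_logliks()]
#'   (the null does not depend on the family, so one set can be shared).
#' @return p-value in `(0, 1]`.
#' @export
family_pvalue <- function(counts, tree, model, n_sim = 1000, seed = NULL,
                          null_logliks = NULL) {
  if (is.null(null_logliks)) {
    if (n_sim < 1) stop("n_sim must be >= 1")
    null_logliks <- null_family_logliks(tree, model, n_sim, seed = seed)
  }
  obs <- family_loglik(counts, tree, model)
  (sum(null_logliks <= obs) + 1) / (length(null_logliks) + 1)
}

#' Family p-values for a whole count matrix (shared null)
#'
#' @param counts families x species matrix.
#' @inheritParams family_pvalue
#' @return named vector of p-values.
#' @export
family_pvalues <- function(counts, tree, model, n_sim = 1000, seed = NULL,
                           null_logliks = NULL) {
  if (is.null(null_logliks)) {
    null_logliks <- null_family_logliks(tree, model, n_sim, seed = seed)
  }
  obs <- bd_loglik_matrix(counts_to_species_matrix(counts, tree), tree, model)
  p <- vapply(
    obs,
    function(ll) (sum(null_logliks <= ll) + 1) / (length(null_logliks) + 1),
    numeric(1)
  )
  stats::setNames(p, rownames(counts))
}

node_names <- function(phy) {
  n_tip <- ape::Ntip(phy)
  c(phy$tip.label, paste0("node", (n_tip + 1L):(n_tip + phy$Nnode)))
}

#' Joint maximum-likelihood ancestral family sizes
#'
#' Dynamic programming (Viterbi analogue) over the truncated state space:
#' returns the jointly most probable assignment of family sizes to all
#' internal nodes given the tip counts, the model and the uniform root
#' prior. Ties are broken toward the smaller size.
#'
#' @inheritParams family_pvalue
#' @param ctx internal pruning context (precomputed log transition
#'   matrices), reusable when reconstructing many families under one model.
#' @return named integer vector over all nodes (tips included, under their
#'   labels; internal nodes as `node<id>`).
#' @export
ancestral_counts <- function(counts, tree, model, ctx = NULL) {
  if (is.null(ctx)) ctx <- pruning_context(tree, model, log = TRUE)
  phy <- ctx$phy
  cnt <- counts_to_species_matrix(counts, tree)[, 1]
  if (max(cnt) > model$max_count) {
    stop("observed count exceeds max_count; increase the truncation bound")
  }
  N1 <- model$max_count + 1L
  n_all <- ctx$n_tip + ctx$n_node
  M <- vector("list", n_all)
  ptr <- vector("list", nrow(ctx$edge))
  for (k in seq_len(nrow(ctx$edge))) {
    par <- ctx$edge[k, 1L]
    ch <- ctx$edge[k, 2L]
    if (ch <= ctx$n_tip) {
      msg <- ctx$P[[k]][, cnt[ch] + 1L]
    } else {
      T <- ctx$P[[k]] + rep(M[[ch]], each = N1)
      best <- max.col(T, ties.method = "first")
      ptr[[k]] <- best
      msg <- T[cbind(seq_len(N1), best)]
    }
    M[[par]] <- if (is.null(M[[par]])) msg else M[[par]] + msg
  }
  states <- integer(n_all)
  states[seq_len(ctx$n_tip)] <- cnt
  root_sc <- M[[ctx$root]][seq_len(model$root_max) + 1L]
  states[ctx$root] <- which.max(root_sc) # first max = smallest size
  if (!is.finite(max(root_sc))) {
    stop("no feasible ancestral assignment within the truncation bound")
  }
  for (k in rev(seq_len(nrow(ctx$edge)))) {
    ch <- ctx$edge[k, 2L]
    if (ch <= ctx$n_tip) next
    par <- ctx$edge[k, 1L]
    states[ch] <- ptr[[k]][states[par] + 1L] - 1L
  }
  stats::setNames(states, node_names(phy))
}

#' Branch-level p-values and change directions for one family
#'
#' For a family already flagged by [family_pvalue()], localizes which
#' branches drove the signal. On each branch the reconstructed
#' parent-to-child transition probability is compared against the null
#' distribution of that branch's transition probabilities: descendant
#' sizes are simulated from the transition law conditioned on the
#' reconstructed parent size, and `p = (b + 1) / (n_sim + 1)` with `b`
#' the number of simulated transitions at most as probable as the
#' observed one. An unchanged branch under small rates thus gets p near
#' 1; an improbable jump gets a small p. Direction is the sign of
#' (child - parent) reconstructed size: `"expansion"`, `"contraction"`
#' or `"none"`.
#'
#' @inheritParams family_pvalue
#' @param ctx_log,ctx_lin optional precomputed pruning contexts (log and
#'   linear transition matrices), reusable across families under one
#'   model.
#' @return data.frame with one row per branch: `parent`, `child` (node
#'   names), `parent_count`, `child_count`, `p`, `direction`.
#' @export
branch_pvalues <- function(counts, tree, model, n_sim = 1000, seed = NULL,
                           ctx_log = NULL, ctx_lin = NULL) {
  if (n_sim < 1) stop("n_sim must be >= 1")
  if (is.null(ctx_log)) ctx_log <- pruning_context(tree, model, log = TRUE)
  if (is.null(ctx_lin)) ctx_lin <- pruning_context(tree, model, log = FALSE)
  rec <- ancestral_counts(counts, tree, model, ctx = ctx_log)
  if (!is.null(seed)) set.seed(seed)
  states <- unname(rec)
  e <- ctx_lin$edge
  n_edge <- nrow(e)
  p <- numeric(n_edge)
  for (k in seq_len(n_edge)) {
    s <- states[e[k, 1L]]
    row <- ctx_lin$P[[k]][s + 1L, ]
    tp_obs <- row[states[e[k, 2L]] + 1L]
    draws <- sample.int(length(row), n_sim, replace = TRUE, prob = row)
    p[k] <- (sum(row[draws] <= tp_obs) + 1) / (n_sim + 1)
  }
  nn <- node_names(ctx_lin$phy)
  par_cnt <- states[e[, 1L]]
  ch_cnt <- states[e[, 2L]]
  delta <- ch_cnt - par_cnt
  data.frame(
    parent = nn[e[, 1L]],
    child = nn[e[, 2L]],
    parent_count = par_cnt,
    child_count = ch_cnt,
    p = p,
    direction = ifelse(delta > 0, "expansion",
      ifelse(delta < 0, "contraction", "none")
    ),
    stringsAsFactors = FALSE
  )
}

#' Star-annotated expansion/contraction report
#'
#' Applies the two-level reporting convention: a family must first pass
#' the family-wide gate (`family_p <= alpha_family`); its branches then
#' receive one star at the first significance level and two at the second
#' (defaults 0.05 and 0.01). Branches with no size change (`direction ==
#' "none"`) are never starred.
#'
#' @param branch_results data.frame stacking [branch_pvalues()] outputs
#'   with columns `family` and `family_p` added.
#' @param alpha_family family-wide gate.
#' @param alpha_levels two node-level significance levels (decreasing).
#' @return the input with a `stars` column (`""`, `"*"` or `"**"`).
#' @export
report_changes <- function(branch_results, alpha_family = 0.05,
                           alpha_levels = c(0.05, 0.01)) {
  stopifnot(all(c("family", "family_p", "p", "direction") %in%
    names(branch_results)))
  alpha_levels <- sort(alpha_levels, decreasing = TRUE)
  gate <- branch_results$family_p <= alpha_family &
    branch_results$direction != "none"
  stars <- character(nrow(branch_results))
  stars[gate & branch_results$p <= alpha_levels[1]] <- "*"
  stars[gate & branch_results$p <= alpha_levels[2]] <- "**"
  branch_results$stars <- stars
  branch_results
}

#' Full gene-family evolution analysis of a count matrix
#'
#' Fits clade-specific birth-death rates, computes Monte Carlo family-wide
#' p-values (shared null), localizes significant families with branch
#' p-values, and assembles the starred report.
#'
#' @param counts families x species integer matrix.
#' @param tree a [species_tree] with rate classes.
#' @param k number of rates (default: one per rate class).
#' @param n_sim Monte Carlo simulations for both p-value levels.
#' @param alpha_family family-wide gate for branch-level testing.
#' @param alpha_levels star levels.
#' @param seed seed for the Monte Carlo nulls.
#' @param max_count,root_max passed to [fit_rates()].
#' @return list with `fit` (from [fit_rates()]), `family_p`,
#'   `report` (starred branch table of gated families), `ancestral`
#'   (reconstructed sizes of gated families), and the settings used.
#' @export
family_evolution_analysis <- function(counts, tree,
                                      k = nlevels(tree$rate_class),
                                      n_sim = 1000, alpha_family = 0.05,
                                      alpha_levels = c(0.05, 0.01),
                                      seed = NULL, max_count = NULL,
                                      root_max = NULL) {
  fit <- fit_rates(counts, tree,
    k = k, max_count = max_count,
    root_max = root_max
  )
  if (!is.null(seed)) set.seed(seed)
  null_ll <- null_family_logliks(tree, fit$model, n_sim)
  fam_p <- family_pvalues(counts, tree, fit$model, null_logliks = null_ll)
  sig <- names(fam_p)[fam_p <= alpha_family]
  report <- NULL
  ancestral <- list()
  if (length(sig) > 0) {
    ctx_log <- pruning_context(tree, fit$model, log = TRUE)
    ctx_lin <- pruning_context(tree, fit$model, log = FALSE)
    pieces <- lapply(sig, function(fam) {
      br <- branch_pvalues(counts[fam, ], tree, fit$model,
        n_sim = n_sim, ctx_log = ctx_log, ctx_lin = ctx_lin
      )
      br$family <- fam
      br$family_p <- fam_p[[fam]]
      br
    })
    ancestral <- stats::setNames(
      lapply(sig, function(fam) ancestral_counts(counts[fam, ], tree, fit$model)),
      sig
    )
    report <- report_changes(do.call(rbind, pieces),
      alpha_family = alpha_family, alpha_levels = alpha_levels
    )
  }
  list(
    fit = fit, family_p = fam_p, report = report, ancestral = ancestral,
    settings = list(
      k = k, n_sim = n_sim, alpha_family = alpha_family,
      alpha_levels = alpha_levels, seed = seed
    )
  )
}
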