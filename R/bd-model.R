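## Birth-death model of gene family size evolution.
##
## Family size evolves along each branch as a linear birth-death Markov
## chain in which a family of size i gains or loses one member at rate
## i * lambda each (birth rate = death rate, the classic single-parameter
## gene gain/loss model). The single-branch transition law has a closed
## form in alpha = lambda * t / (1 + lambda * t):
##
##   P(c | s) = sum_{j=0}^{min(s,c)} C(s, j) C(s + c - j - 1, s - 1)
##              alpha^(s + c - 2j) (1 - 2 alpha)^j          (s >= 1)
##
## with state 0 absorbing. Likelihoods over a tree use Felsenstein pruning
## on a truncated state space {0, ..., max_count}; branches can carry
## different rates via the tree's rate classes.

# offspring distribution of a single gene after one branch: the linear
# birth-death process is a branching process, so the transition row for a
# parent of size s is the s-fold convolution of this distribution -- an
# all-positive computation that stays stable where the alternating
# closed-form sum loses precision (alpha > 1/2, i.e. lambda * t > 1)
bd_offspring_dist <- function(alpha, N) {
  if (alpha == 0) {
    return(c(0, 1, numeric(N - 1L)))
  }
  c(alpha, (1 - alpha)^2 * alpha^(0:(N - 1L)))
}

#' Single-branch transition probability of the gene birth-death process
#'
#' Probability that a family of size `s` at the top of a branch of
#' duration `t` has size `c` at the bottom, under a linear birth-death
#' process with equal per-gene birth and death rate `lam`
#' (events per gene per unit time). Size 0 is absorbing. Computed from the
#' closed form in `alpha = lam * t / (1 + lam * t)`.
#'
#' @param s parent (ancestral) family size, non-negative integer.
#' @param c child (descendant) family size, non-negative integer.
#' @param t branch duration, > 0 (same time unit as `lam`).
#' @param lam per-gene birth = death rate, >= 0.
#' @return probability in `[0, 1]`. Vectorized over `s` and `c`.
#' @examples
#' bd_transition_prob(1, 1, t = 1, lam = 1 / 3) # alpha = 0.25 -> 0.5625
#' @export
bd_transition_prob <- function(s, c, t, lam) {
  if (any(s < 0) || any(c < 0)) stop("family sizes must be non-negative")
  if (any(t <= 0)) stop("branch duration must be > 0")
  if (any(lam < 0)) stop("rate must be non-negative")
  n <- max(length(s), length(c))
  s <- rep_len(as.integer(s), n)
  c <- rep_len(as.integer(c), n)
  alpha <- bd_alpha(lam, t)
  vapply(seq_len(n), function(i) bd_tp_one(s[i], c[i], alpha), numeric(1))
}

bd_alpha <- function(lam, t) {
  lt <- lam * t
  lt / (1 + lt)
}

bd_tp_one <- function(s, c, alpha) {
  if (s == 0L) {
    return(as.numeric(c == 0L))
  }
  if (alpha == 0) {
    return(as.numeric(c == s))
  }
  if (alpha <= 0.5) {
    # closed form: alternating terms are benign here
    j <- 0:min(s, c)
    b <- 1 - 2 * alpha
    lterm <- lchoose(s, j) + lchoose(s + c - j - 1, s - 1) +
      (s + c - 2 * j) * log(alpha)
    if (b == 0) {
      return(sum(exp(lterm[j == 0])))
    }
    return(sum(exp(lterm + j * log(b))))
  }
  # large alpha: s-fold convolution of the single-gene offspring law
  g <- bd_offspring_dist(alpha, c)
  row <- g
  if (s > 1L) {
    for (i in 2:s) {
      row <- vapply(0:c, function(m) {
        sum(row[seq_len(m + 1L)] * g[(m + 1L):1L])
      }, numeric(1))
    }
  }
  row[c + 1L]
}

#' Transition matrix on a truncated state space
#'
#' `(max_count + 1) x (max_count + 1)` matrix with `P[s + 1, c + 1] =`
#' [bd_transition_prob]`(s, c, t, lam)`. Rows for large parent sizes lose
#' tail mass to the truncation; callers pick `max_count` generously (the
#' package default is twice the largest observed size plus 10).
#'
#' @inheritParams bd_transition_prob
#' @param max_count truncation bound (largest representable family size).
#' @export
bd_transition_matrix <- function(t, lam, max_count) {
  N <- as.integer(max_count)
  stopifnot(N >= 1, t > 0, lam >= 0)
  alpha <- bd_alpha(lam, t)
  P <- matrix(0, N + 1L, N + 1L)
  P[1L, 1L] <- 1
  if (alpha == 0) {
    diag(P) <- 1
    return(P)
  }
  g <- bd_offspring_dist(alpha, N)
  # Toeplitz convolution operator: row_s = row_{s-1} %*% Tm
  Tm <- matrix(0, N + 1L, N + 1L)
  keep <- col(Tm) >= row(Tm)
  Tm[keep] <- g[col(Tm)[keep] - row(Tm)[keep] + 1L]
  P[2L, ] <- g
  if (N >= 2L) {
    for (s in 2:N) P[s + 1L, ] <- P[s, ] %*% Tm
  }
  P
}

#' Construct a birth-death model for gene family evolution
#'
#' @param rates named numeric vector: one per-gene birth = death rate
#'   (events per gene per unit time) per branch rate class. Names must
#'   cover the rate classes of the tree the model is used with; a single
#'   unnamed rate is recycled to every class at use time.
#' @param max_count truncation bound of the state space.
#' @param root_max upper end of the uniform root prior on `{1, ...,
#'   root_max}` (a family present in the data is assumed present, with at
#'   least one copy, at the root).
#' @return object of class `bd_model`.
#' @export
bd_model <- function(rates, max_count, root_max) {
  if (any(rates < 0)) stop("rates must be non-negative")
  max_count <- as.integer(max_count)
  root_max <- as.integer(root_max)
  if (max_count < 1) stop("max_count must be >= 1")
  if (root_max < 1 || root_max > max_count) {
    stop("root_max must be in [1, max_count]")
  }
  structure(
    list(rates = rates, max_count = max_count, root_max = root_max),
    class = "bd_model"
  )
}

#' @export
print.bd_model <- function(x, ...) {
  cat("bd_model: birth = death rates per class\n")
  print(x$rates)
  cat(
    "state space {0..", x$max_count, "}, root prior uniform on {1..",
    x$root_max, "}\n",
    sep = ""
  )
  invisible(x)
}

default_max_count <- function(counts) {
  2L * as.integer(max(counts)) + 10L
}

default_root_max <- function(counts) {
  as.integer(max(counts)) + 5L
}

edge_rates <- function(tree, model) {
  classes <- as.character(tree$rate_class)
  rates <- model$rates
  if (is.null(names(rates)) && length(rates) == 1L) {
    return(rep(rates, length(classes)))
  }
  missing_cls <- setdiff(unique(classes), names(rates))
  if (length(missing_cls) > 0) {
    stop("model has no rate for class(es): ", paste(missing_cls, collapse = ", "))
  }
  unname(rates[classes])
}

# postorder traversal context shared by likelihood, simulation and
# reconstruction: edges in postorder, each with its branch length, rate and
# transition matrix
pruning_context <- function(tree, model, log = FALSE) {
  phy <- as_phylo(tree)
  po <- ape::reorder.phylo(phy, "postorder")
  key <- function(E) paste(E[, 1], E[, 2])
  perm <- match(key(po$edge), key(phy$edge))
  lam_edge <- edge_rates(tree, model)[perm]
  t_edge <- phy$edge.length[perm]
  # branches sharing (rate, length) share a transition matrix
  pkey <- paste(lam_edge, t_edge)
  uniq <- !duplicated(pkey)
  Pu <- lapply(which(uniq), function(k) {
    M <- bd_transition_matrix(t_edge[k], lam_edge[k], model$max_count)
    if (log) log(M) else M
  })
  names(Pu) <- pkey[uniq]
  P <- Pu[pkey]
  list(
    phy = phy, edge = po$edge, perm = perm, t = t_edge, lam = lam_edge,
    P = P, n_tip = ape::Ntip(phy), n_node = phy$Nnode,
    root = ape::Ntip(phy) + 1L, model = model
  )
}

col_max <- function(M) {
  tM <- t(M)
  j <- max.col(tM, ties.method = "first")
  tM[cbind(seq_len(nrow(tM)), j)]
}

# batched pruning likelihood: tipcounts is an n_species x n_families
# integer matrix (rownames = tip labels); returns one log-likelihood per
# family
bd_loglik_matrix <- function(tipcounts, tree, model, ctx = NULL) {
  if (is.null(ctx)) ctx <- pruning_context(tree, model)
  phy <- ctx$phy
  if (is.null(rownames(tipcounts))) {
    stop("tip count matrix must have species row names")
  }
  missing_sp <- setdiff(phy$tip.label, rownames(tipcounts))
  if (length(missing_sp) > 0) {
    stop("counts missing for species: ", paste(missing_sp, collapse = ", "))
  }
  if (max(tipcounts) > model$max_count) {
    stop(
      "observed count ", max(tipcounts), " exceeds max_count ",
    model$max_count, "; increase the truncation bound"
    )
  }
  tipcounts <- tipcounts[phy$tip.label, , drop = FALSE]
  n_fam <- ncol(tipcounts)
  N1 <- model$max_count + 1L
  L <- vector("list", ctx$n_tip + ctx$n_node)
  logscale <- numeric(n_fam)
  for (k in seq_len(nrow(ctx$edge))) {
    par <- ctx$edge[k, 1L]
    ch <- ctx$edge[k, 2L]
    if (ch <= ctx$n_tip) {
      msg <- ctx$P[[k]][, tipcounts[ch, ] + 1L, drop = FALSE]
    } else {
      msg <- ctx$P[[k]] %*% L[[ch]]
    }
    L[[par]] <- if (is.null(L[[par]])) msg else L[[par]] * msg
    # rescale only when underflow threatens: partial likelihoods on a few
    # dozen tips stay far above the denormal range in ordinary regimes
    if (max(L[[par]]) < 1e-220) {
      cm <- col_max(L[[par]])
      zero <- cm == 0
      if (any(zero)) {
        # impossible family under this model: flag, keep the rest
        cm[zero] <- 1
        logscale[zero] <- -Inf
      }
      L[[par]] <- L[[par]] / rep(cm, each = N1)
      logscale <- logscale + log(cm)
    }
  }
  root_states <- seq_len(model$root_max) + 1L
  lik <- colSums(L[[ctx$root]][root_states, , drop = FALSE]) / model$root_max
  unname(log(lik) + logscale)
}

#' Log-likelihood of one family's tip counts under a birth-death model
#'
#' Felsenstein pruning over the tree on the truncated state space, with the
#' branch rate chosen by each branch's rate class and the root summed over
#' the uniform prior on `{1, ..., root_max}`.
#'
#' @param counts named integer vector of per-species family sizes (names =
#'   tip labels), or a families x species matrix for several families at
#'   once.
#' @param tree a [species_tree].
#' @param model a [bd_model].
#' @return a log-likelihood (vector of them for a matrix input).
#' @export
family_loglik <- function(counts, tree, model) {
  tc <- counts_to_species_matrix(counts, tree)
  ll <- bd_loglik_matrix(tc, tree, model)
  if (!is.null(dim(counts)) && !is.null(rownames(counts))) {
    names(ll) <- rownames(counts)
  }
  if (length(ll) == 1L) ll <- ll[[1L]]
  ll
}

# accept a named vector (one family) or a families x species matrix and
# return the species x families orientation that pruning consumes
counts_to_species_matrix <- function(counts, tree) {
  phy <- as_phylo(tree)
  if (is.null(dim(counts))) {
    if (is.null(names(counts))) stop("counts must be named by species")
    m <- matrix(as.integer(counts),
      ncol = 1,
      dimnames = list(names(counts), NULL)
    )
  } else {
    m <- t(counts)
    storage.mode(m) <- "integer"
  }
  missing_sp <- setdiff(phy$tip.label, rownames(m))
  if (length(missing_sp) > 0) {
    stop("counts missing for species: ", paste(missing_sp, collapse = ", "))
  }
  m[phy$tip.label, , drop = FALSE]
}

#' Fit clade-specific birth-death rates by maximum likelihood
#'
#' Maximizes the summed [family_loglik()] over all families in the count
#' matrix, with one shared rate (`k = 1`) or one rate per branch rate
#' class of the tree (`k = n_classes`). Optimization is on the log-rate
#' scale: Brent for one rate, Nelder-Mead with multiple deterministic
#' starts for several.
#'
#' @param counts families x species integer matrix (rownames = families,
#'   colnames = species).
#' @param tree a [species_tree] whose `rate_class` defines the classes.
#' @param k number of rate parameters: 1 (global) or the number of rate
#'   classes on the tree.
#' @param max_count truncation bound; default `2 * max(counts) + 10`.
#' @param root_max root prior bound; default `max(counts) + 5`.
#' @param lower,upper box for each rate (events per gene per unit time).
#' @param n_starts number of Nelder-Mead starts for `k > 1`.
#' @return list with `model` (fitted [bd_model]), `loglik`,
#'   `rates`, `k`, and `convergence` (0 = converged).
#' @export
fit_rates <- function(counts, tree, k = nlevels(tree$rate_class),
                      max_count = NULL, root_max = NULL,
                      lower = 1e-8, upper = 10, n_starts = 5) {
  classes <- levels(tree$rate_class)
  if (!(k == 1L || k == length(classes))) {
    stop(
      "k must be 1 or the number of rate classes on the tree (",
      length(classes), ")"
    )
  }
  if (is.null(max_count)) max_count <- default_max_count(counts)
  if (is.null(root_max)) root_max <- default_root_max(counts)
  tc <- counts_to_species_matrix(counts, tree)
  obj <- function(log_rates) {
    rates <- exp(log_rates)
    if (k == 1L) {
      rates <- stats::setNames(rep(rates, length(classes)), classes)
    } else {
      names(rates) <- classes
    }
    model <- bd_model(rates, max_count, root_max)
    sum(bd_loglik_matrix(tc, tree, model))
  }
  if (k == 1L) {
    opt <- stats::optimize(obj,
      interval = log(c(lower, upper)),
      maximum = TRUE, tol = 1e-9
    )
    best <- list(par = opt$maximum, value = opt$objective, convergence = 0L)
  } else {
    # warm start: shared-rate Brent prefit, then Nelder-Mead from the
    # centre and tilted perturbations around it
    pre <- stats::optimize(function(lr) obj(rep(lr, k)),
      interval = log(c(lower, upper)), maximum = TRUE, tol = 1e-6
    )
    offsets <- list(rep(0, k))
    for (d in c(0.7, 1.4, 2.1)) {
      for (sgn in c(1, -1)) {
        o <- rep(-sgn * d / (k - 1), k)
        o[1] <- sgn * d
        offsets[[length(offsets) + 1L]] <- o
      }
    }
    offsets <- offsets[seq_len(min(n_starts, length(offsets)))]
    best <- NULL
    for (o in offsets) {
      fit <- stats::optim(pre$maximum + o, obj,
        method = "Nelder-Mead",
        control = list(fnscale = -1, reltol = 1e-10, maxit = 2000)
      )
      if (is.null(best) || fit$value > best$value + 1e-12) best <- fit
    }
  }
  rates <- exp(rep_len(best$par, length(classes)))
  if (k == 1L) rates <- rep(exp(best$par[1]), length(classes))
  names(rates) <- classes
  list(
    model = bd_model(rates, max_count, root_max),
    loglik = unname(best$value),
    rates = rates,
    k = k,
    convergence = best$convergence
  )
}
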