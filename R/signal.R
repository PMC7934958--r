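## Phylogenetic-signal battery: Abouheif's C_mean, Moran's I, Blomberg's K
## and K*, and Pagel's lambda, each with its null test. Permutation tests
## shuffle trait values across tips; lambda uses a likelihood-ratio test.

new_signal_result <- function(statistic, value, p_value, n_perm, trait,
                              ...) {
  structure(
    list(
      statistic = statistic, value = value, p_value = p_value,
      n_perm = n_perm, trait = trait, ...
    ),
    class = "signal_result"
  )
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf(
    "%s = %.4f, p-value = %.4g (%s, trait '%s')\n",
    x$statistic, x$value, x$p_value,
    if (x$n_perm > 0) paste0(x$n_perm, " permutations") else "likelihood ratio",
    x$trait
  ))
  invisible(x)
}

# align a named trait vector with the tree, pruning unused tips;
# errors on unknown names or (optionally) zero variance
align_trait <- function(trait, tree, require_variance = TRUE, min_n = 3L) {
  phy <- as_phylo(tree)
  if (is.null(names(trait))) stop("trait must be named by tip labels")
  unknown <- setdiff(names(trait), phy$tip.label)
  if (length(unknown) > 0) {
    stop("trait names not in tree: ", paste(unknown, collapse = ", "))
  }
  if (length(trait) < ape::Ntip(phy)) {
    phy <- ape::keep.tip(phy, names(trait))
    tree <- species_tree(phy, ultrametric = FALSE)
  }
  x <- trait[phy$tip.label]
  if (length(x) < min_n) stop("need at least ", min_n, " tips")
  if (require_variance && stats::var(x) == 0) {
    stop("degenerate trait: zero variance")
  }
  list(x = x, tree = tree, phy = phy)
}

# permutation matrix of the trait: one column per permuted replicate
permute_columns <- function(x, n_perm) {
  vapply(seq_len(n_perm), function(i) sample(x), numeric(length(x)))
}

# one-sided (signal = larger); n_perm = 0 means "value only", p = NA
perm_p_value <- function(obs, null) {
  if (length(null) == 0) {
    return(NA_real_)
  }
  (sum(null >= obs) + 1) / (length(null) + 1)
}

#' Abouheif's C_mean test of phylogenetic signal
#'
#' `C_mean = sum_{i != j} w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' trait and `w` the row-normalized Abouheif proximity matrix
#' ([abouheif_proximity()]); positive values mean related species resemble
#' each other. The p-value permutes trait values across tips (one-sided,
#' signal = larger).
#'
#' @param trait named numeric vector (names = tip labels).
#' @param tree a [species_tree].
#' @param n_perm number of permutations (default 999).
#' @param seed optional seed for the permutations.
#' @return a `signal_result`.
#' @export
cmean <- function(trait, tree, n_perm = 999, seed = NULL) {
  al <- align_trait(trait, tree)
  W <- row_normalize(abouheif_proximity(al$tree))
  if (!is.null(seed)) set.seed(seed)
  stat <- function(Z) colSums(Z * (W %*% Z)) / colSums(Z^2)
  z <- al$x - mean(al$x)
  obs <- stat(cbind(z))
  null <- if (n_perm > 0) stat(permute_columns(z, n_perm)) else numeric(0)
  new_signal_result("Cmean", unname(obs), perm_p_value(obs, null), n_perm,
    trait = trait_label(trait)
  )
}

#' Moran's I phylogenetic autocorrelation test
#'
#' `I = (n / S0) * sum_{i != j} w_ij z_i z_j / sum_i z_i^2` with `z` the
#' centred trait and `w` phylogenetic weights (default: inverse patristic
#' distance, row-normalized; see [moran_weights()]). Under no signal
#' `E[I] = -1/(n - 1)`. One-sided permutation p-value (signal = larger).
#'
#' @inheritParams cmean
#' @param scheme weighting scheme passed to [moran_weights()].
#' @param W optional explicit weight matrix overriding `scheme`.
#' @export
morans_i <- function(trait, tree, scheme = "inv_distance", W = NULL,
                     n_perm = 999, seed = NULL) {
  al <- align_trait(trait, tree, min_n = 3L)
  if (is.null(W)) {
    W <- moran_weights(al$tree, scheme = scheme)
  } else {
    W <- W[names(al$x), names(al$x)]
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(al$x)
  s0 <- sum(W)
  stat <- function(Z) (n / s0) * colSums(Z * (W %*% Z)) / colSums(Z^2)
  z <- al$x - mean(al$x)
  obs <- stat(cbind(z))
  null <- if (n_perm > 0) stat(permute_columns(z, n_perm)) else numeric(0)
  new_signal_result("I", unname(obs), perm_p_value(obs, null), n_perm,
    trait = trait_label(trait),
    expected = -1 / (n - 1)
  )
}

#' Blomberg's K (and K*) test of phylogenetic signal
#'
#' The variance-ratio statistic
#' `K = [(x - ctr)'(x - ctr) / (x - a 1)' V^-1 (x - a 1)] /
#'      [(tr V - n / (1' V^-1 1)) / (n - 1)]`
#' where `V` is the shared-path covariance, `a` the GLS (phylogenetic)
#' mean and `ctr` the centring of the numerator. The default
#' (`star = FALSE`) centres on the GLS mean `a`, the original definition
#' of the statistic, whose Brownian-motion expectation the denominator
#' correction term is derived for -- this variant calibrates to K = 1
#' under Brownian motion. `star = TRUE` gives the alternative convention
#' that centres the numerator on the raw mean; it runs systematically
#' below 1 under Brownian motion on most tree shapes because the raw sum
#' of squares has a different expectation than the correction assumes.
#' Both conventions circulate in the literature, which is why both are
#' implemented and clearly labelled. Larger K = more signal; one-sided
#' permutation p-value.
#'
#' @inheritParams cmean
#' @param star use the raw mean in the numerator centring (the
#'   alternative convention) instead of the GLS mean.
#' @export
blomberg_k <- function(trait, tree, n_perm = 999, seed = NULL, star = FALSE) {
  al <- align_trait(trait, tree)
  V <- shared_path_covariance(al$tree)
  Vi <- tryCatch(solve(V), error = function(e) {
    stop("shared-path covariance is singular: ", conditionMessage(e))
  })
  if (!is.null(seed)) set.seed(seed)
  n <- length(al$x)
  sum_vi <- sum(Vi)
  expected_ratio <- (sum(diag(V)) - n / sum_vi) / (n - 1)
  stat <- function(Z) {
    ViZ <- Vi %*% Z
    a <- colSums(ViZ) / sum_vi
    mse <- colSums(Z * ViZ) - sum_vi * a^2 # (z - a1)' Vi (z - a1)
    ss_num <- if (star) {
      colSums(scale(Z, scale = FALSE)^2) # raw-mean centring
    } else {
      colSums(Z^2) - 2 * a * colSums(Z) + n * a^2 # GLS centring
    }
    (ss_num / mse) / expected_ratio
  }
  z <- al$x
  obs <- stat(cbind(z))
  null <- if (n_perm > 0) stat(permute_columns(z, n_perm)) else numeric(0)
  new_signal_result(if (star) "Kstar" else "K", unname(obs),
    perm_p_value(obs, null), n_perm,
    trait = trait_label(trait)
  )
}

# profile log-likelihood of the lambda model: mean and sigma2 maximized
# analytically, V_lambda = V with off-diagonals scaled by lambda
lambda_profile_loglik <- function(lambda, x, V) {
  n <- length(x)
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  U <- chol(Vl)
  logdet <- 2 * sum(log(diag(U)))
  # solve via the Cholesky factor
  w <- backsolve(U, forwardsolve(t(U), cbind(x, rep(1, n))))
  Vix <- w[, 1]
  Vi1 <- w[, 2]
  mu <- sum(Vix) / sum(Vi1)
  r <- x - mu
  rr <- backsolve(U, forwardsolve(t(U), r))
  q <- sum(r * rr)
  sigma2 <- q / n
  -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
}

#' Pagel's lambda by maximum likelihood
#'
#' Maximizes the multivariate-normal log-likelihood of the trait with
#' covariance `sigma2 * V_lambda` (off-diagonal shared-path covariances
#' multiplied by `lambda`), profiling the mean and `sigma2` analytically.
#' `lambda` is searched on `[0, 1]` by a grid scan followed by Brent
#' refinement (tolerance 1e-8). The p-value is a likelihood-ratio test
#' against `lambda = 0` on a chi-squared(1) reference.
#'
#' @inheritParams cmean
#' @return a `signal_result` with extras `sigma2`, `loglik`, `loglik0`.
#' @export
pagel_lambda <- function(trait, tree) {
  al <- align_trait(trait, tree)
  V <- shared_path_covariance(al$tree)
  x <- al$x
  f <- function(l) lambda_profile_loglik(l, x, V)
  grid <- seq(0, 1, by = 0.1)
  ll_grid <- vapply(grid, f, numeric(1))
  if (any(!is.finite(ll_grid))) {
    stop("lambda likelihood not finite on the search grid")
  }
  i <- which.max(ll_grid)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  cand_l <- c(opt$maximum, grid[i], 0, 1)
  cand_ll <- c(opt$objective, ll_grid[i], ll_grid[1], ll_grid[length(grid)])
  best <- which.max(cand_ll)
  lam <- cand_l[best]
  ll <- cand_ll[best]
  ll0 <- ll_grid[1]
  lrt <- max(0, 2 * (ll - ll0))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  # sigma2 at the optimum, for reporting
  n <- length(x)
  Vl <- V * lam
  diag(Vl) <- diag(V)
  Vi <- solve(Vl)
  mu <- sum(Vi %*% x) / sum(Vi)
  sigma2 <- as.numeric(t(x - mu) %*% Vi %*% (x - mu)) / n
  new_signal_result("lambda", lam, p, 0L,
    trait = trait_label(trait),
    sigma2 = sigma2, loglik = ll, loglik0 = ll0, mu = mu
  )
}

trait_label <- function(trait) {
  lbl <- attr(trait, "trait_name")
  if (is.null(lbl)) "trait" else lbl
}

with_trait_name <- function(x, name) {
  attr(x, "trait_name") <- name
  x
}

#' Run the full signal battery over a family count matrix
#'
#' Applies all five statistics (C_mean, Moran's I, K, K*, lambda) to (a)
#' the per-species total gene count (column sums), (b) each family row and
#' (c) per-class aggregates if a family -> class map is given. Rows with
#' no variation across species are skipped with a notice.
#'
#' @param counts families x species numeric matrix.
#' @param tree a [species_tree]; matrix species must all be tips.
#' @param classes optional named vector mapping family -> class
#'   (e.g. effector/receptor/signalling) for class aggregates.
#' @param n_perm permutations per permutation test.
#' @param seed seed for the permutation tests.
#' @param transform `"none"` (counts used as-is) or `"log1p"`.
#' @return data.frame with columns `trait`, `statistic`, `value`,
#'   `p_value`, `n_perm`; skipped constant traits are recorded in the
#'   `"skipped"` attribute.
#' @export
signal_battery <- function(counts, tree, classes = NULL, n_perm = 999,
                           seed = 1, transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  phy <- as_phylo(tree)
  offenders <- setdiff(colnames(counts), phy$tip.label)
  if (length(offenders) > 0) {
    stop(
      "matrix species not on the tree: ",
      paste(offenders, collapse = ", ")
    )
  }
  traits <- list(total = colSums(counts))
  for (fam in rownames(counts)) traits[[fam]] <- counts[fam, ]
  if (!is.null(classes)) {
    unknown <- setdiff(rownames(counts), names(classes))
    if (length(unknown) > 0) {
      stop("no class for families: ", paste(unknown, collapse = ", "))
    }
    agg <- rowsum(counts, group = classes[rownames(counts)])
    for (cl in rownames(agg)) {
      traits[[paste0("class:", cl)]] <- agg[cl, ]
    }
  }
  rows <- list()
  skipped <- character(0)
  for (nm in names(traits)) {
    x <- traits[[nm]]
    if (transform == "log1p") x <- log1p(x)
    if (stats::var(x) == 0) {
      skipped <- c(skipped, nm)
      message("signal_battery: skipping constant trait '", nm, "'")
      next
    }
    x <- with_trait_name(x, nm)
    res <- list(
      cmean(x, tree, n_perm = n_perm, seed = seed),
      morans_i(x, tree, n_perm = n_perm, seed = seed),
      blomberg_k(x, tree, n_perm = n_perm, seed = seed),
      blomberg_k(x, tree, n_perm = n_perm, seed = seed, star = TRUE),
      pagel_lambda(x, tree)
    )
    for (r in res) {
      rows[[length(rows) + 1L]] <- data.frame(
        trait = nm, statistic = r$statistic, value = r$value,
        p_value = r$p_value, n_perm = r$n_perm,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
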