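test_that("autocorrelation statistics match brute-force double sums", {
  for (seed in c(1, 2, 3)) {
    n <- sample(4:8, 1)
    tr <- random_coalescent_tree(n, seed = 200 + seed)
    set.seed(seed)
    x <- setNames(rnorm(n), tr$phy$tip.label)
    z <- x - mean(x)

    Wc <- row_normalize(abouheif_proximity(tr))
    cm <- cmean(x, tr, n_perm = 0)
    expect_lt(abs(cm$value - bruteforce_double_sum(Wc, z) / sum(z^2)), 1e-12)

    Wm <- moran_weights(tr)
    mi <- morans_i(x, tr, n_perm = 0)
    expect_lt(
      abs(mi$value - (n / sum(Wm)) * bruteforce_double_sum(Wm, z) / sum(z^2)),
      1e-12
    )
  }
})

test_that("clade-clustered traits score positive on a balanced tree", {
  tr <- species_tree(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  x <- c(A = 1, B = 1, C = -1, D = -1)
  expect_gt(cmean(x, tr, n_perm = 0)$value, 0)
  mi <- morans_i(x, tr, n_perm = 0)
  expect_gt(mi$value, mi$expected) # above the null mean -1/(n-1)
})

test_that("iid traits give Moran's I centred on -1/(n-1)", {
  tr <- random_coalescent_tree(10, seed = 7)
  set.seed(7)
  vals <- replicate(1000, {
    x <- setNames(rnorm(10), tr$phy$tip.label)
    morans_i(x, tr, n_perm = 0)$value
  })
  expect_lt(abs(mean(vals) - (-1 / 9)), 0.03)
})

test_that("degenerate traits are rejected by every statistic", {
  tr <- random_coalescent_tree(6, seed = 3)
  x <- setNames(rep(2, 6), tr$phy$tip.label)
  expect_error(cmean(x, tr), "degenerate")
  expect_error(morans_i(x, tr), "degenerate")
  expect_error(blomberg_k(x, tr), "degenerate")
  expect_error(pagel_lambda(x, tr), "degenerate")
  # two-tip tree: permutation null is undefined
  two <- species_tree(ape::read.tree(text = "(A:1,B:1);"))
  expect_error(morans_i(c(A = 1, B = 2), two), "at least 3")
})

test_that("blomberg K matches a hand-computed 3-tip evaluation", {
  tr <- species_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  x <- c(A = 3, B = 5, C = 10)
  # explicit dense linear algebra, independent of the package path
  V <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  Vi <- solve(V)
  one <- rep(1, 3)
  a <- as.numeric(t(one) %*% Vi %*% x / (t(one) %*% Vi %*% one))
  mse <- as.numeric(t(x - a) %*% Vi %*% (x - a))
  expected <- (sum(diag(V)) - 3 / sum(Vi)) / 2
  k_hand <- (sum((x - a)^2) / mse) / expected # GLS-centred numerator
  expect_equal(blomberg_k(x, tr, n_perm = 0)$value, k_hand, tolerance = 1e-12)
  # the star variant centres the numerator on the raw mean instead
  kstar_hand <- (sum((x - mean(x))^2) / mse) / expected
  expect_equal(blomberg_k(x, tr, n_perm = 0, star = TRUE)$value, kstar_hand,
    tolerance = 1e-12
  )
})

test_that("blomberg K calibrates to 1 under BM and shrinks under white noise", {
  tr <- random_coalescent_tree(20, seed = 17)
  X <- simulate_bm_trait(tr, n = 150, seed = 18)
  ks <- apply(X, 1, function(x) blomberg_k(x, tr, n_perm = 0)$value)
  # K is a ratio statistic: its mean sits near, not exactly at, 1
  # (expectation of a ratio != ratio of expectations), with the offset
  # depending on tree shape
  expect_gt(mean(ks), 0.80)
  expect_lt(mean(ks), 1.25)
  # white noise on a deep tree: K well below 1
  set.seed(19)
  kw <- mean(replicate(50, {
    x <- setNames(rnorm(20), tr$phy$tip.label)
    blomberg_k(x, tr, n_perm = 0)$value
  }))
  expect_lt(kw, 0.6)
})

test_that("K matches an independent implementation", {
  # both centre the numerator sum of squares on the GLS mean
  tr <- random_coalescent_tree(15, seed = 23)
  x <- simulate_bm_trait(tr, seed = 24)
  ours <- blomberg_k(x, tr, n_perm = 0)$value
  theirs <- unname(phytools::phylosig(tr$phy, x, method = "K"))
  expect_equal(ours, as.numeric(theirs), tolerance = 1e-6)
})

test_that("pagel lambda hits its closed-form limits and recovers truth", {
  tr <- random_coalescent_tree(25, seed = 31)
  # at lambda = 0 the profile likelihood is the independent-normal form
  x <- simulate_bm_trait(tr, lambda_pagel = 0, seed = 32)
  V <- shared_path_covariance(tr)
  d <- diag(V)
  mu <- sum(x / d) / sum(1 / d) # GLS mean for diagonal covariance
  s2 <- sum((x - mu)^2 / d) / length(x)
  ll0_closed <- -0.5 * (length(x) * log(2 * pi * s2) + sum(log(d)) + length(x))
  res <- pagel_lambda(x, tr)
  expect_equal(res$loglik0, ll0_closed, tolerance = 1e-8)
  expect_lt(res$value, 0.35)
  # at lambda = 1 the likelihood equals dense GLS Brownian evaluation
  x1 <- simulate_bm_trait(tr, lambda_pagel = 1, seed = 33)
  Vi <- solve(V)
  mu1 <- sum(Vi %*% x1) / sum(Vi)
  q <- as.numeric(t(x1 - mu1) %*% Vi %*% (x1 - mu1))
  s21 <- q / length(x1)
  ll1_dense <- -0.5 * (length(x1) * log(2 * pi * s21) +
    determinant(V)$modulus[1] + length(x1))
  expect_equal(immunevol:::lambda_profile_loglik(1, x1[tr$phy$tip.label], V),
    ll1_dense,
    tolerance = 1e-8
  )
  # MLE agrees with an independent implementation
  # (their search box can exceed 1; ours is [0, 1] by construction)
  pl <- phytools::phylosig(tr$phy, x1, method = "lambda")
  ours <- pagel_lambda(x1, tr)
  expect_equal(ours$value, min(pl$lambda, 1), tolerance = 0.02)
})

test_that("signal values are invariant to affine trait transforms", {
  tr <- random_coalescent_tree(12, seed = 41)
  x <- simulate_bm_trait(tr, seed = 42)
  y <- 3 * x + 7
  expect_lt(abs(cmean(x, tr, n_perm = 0)$value - cmean(y, tr, n_perm = 0)$value), 1e-10)
  expect_lt(abs(morans_i(x, tr, n_perm = 0)$value - morans_i(y, tr, n_perm = 0)$value), 1e-10)
  expect_lt(abs(blomberg_k(x, tr, n_perm = 0)$value - blomberg_k(y, tr, n_perm = 0)$value), 1e-10)
  expect_lt(abs(pagel_lambda(x, tr)$value - pagel_lambda(y, tr)$value), 1e-6)
})

test_that("permutation p-values are seed-reproducible and tip-order invariant", {
  tr <- random_coalescent_tree(14, seed = 51)
  x <- simulate_bm_trait(tr, seed = 52)
  p1 <- cmean(x, tr, n_perm = 199, seed = 9)$p_value
  p2 <- cmean(x, tr, n_perm = 199, seed = 9)$p_value
  expect_identical(p1, p2)
  shuffled <- x[sample(length(x))]
  p3 <- cmean(shuffled, tr, n_perm = 199, seed = 9)$p_value
  expect_identical(p1, p3)
  expect_true(p1 > 0 && p1 <= 1)
})

test_that("signal battery covers totals, families and classes with skips", {
  tr <- fixture_tree()
  sim <- simulate_family_counts(tr, 5, fixture_rates(), seed = 61)
  counts <- sim$tip_counts
  rownames(counts) <- paste0("fam", 1:5)
  counts[3, ] <- 4L # constant row must be skipped with a notice
  classes <- setNames(
    c("effector", "effector", "receptor", "receptor", "signalling"),
    rownames(counts)
  )
  expect_message(
    sb <- signal_battery(counts, tr,
      classes = classes, n_perm = 49,
      seed = 1
    ),
    "constant trait"
  )
  n_variable_fams <- 4
  n_classes <- length(unique(classes))
  expect_equal(nrow(sb), 5 * (1 + n_variable_fams + n_classes))
  expect_setequal(
    unique(sb$statistic),
    c("Cmean", "I", "K", "Kstar", "lambda")
  )
  expect_equal(attr(sb, "skipped"), "fam3")
  bad <- counts
  colnames(bad)[1] <- "Unknown_species"
  expect_error(signal_battery(bad, tr), "Unknown_species")
})
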