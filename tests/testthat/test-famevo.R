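test_that("single-branch transition law matches its closed-form anchors", {
  # state 0 is absorbing
  expect_equal(bd_transition_prob(0, 0, t = 1, lam = 0.5), 1)
  expect_equal(bd_transition_prob(0, 3, t = 1, lam = 0.5), 0)
  # alpha = 0.25 (lam * t = 1/3): P(1 -> 1) = alpha^2 + (1 - 2 alpha)
  expect_equal(bd_transition_prob(1, 1, t = 1, lam = 1 / 3), 0.5625,
    tolerance = 1e-12
  )
  # alpha = 0.5 (lam * t = 1): geometric tail from one ancestor
  expect_equal(
    bd_transition_prob(1, 0:2, t = 1, lam = 1),
    c(0.5, 0.25, 0.125),
    tolerance = 1e-12
  )
  # rows are proper distributions once truncation is generous
  P <- bd_transition_matrix(t = 1, lam = 1, max_count = 400)
  expect_equal(unname(rowSums(P)[1:6]), rep(1, 6), tolerance = 1e-10)
  expect_error(bd_transition_prob(-1, 0, 1, 1), "non-negative")
})

test_that("transition probabilities equal the generator matrix exponential", {
  for (lt in c(0.01, 0.5)) {
    E <- bd_expm_oracle(t = lt, lam = 1, N = 90)
    P <- bd_transition_matrix(t = lt, lam = 1, max_count = 90)
    expect_lt(max(abs(E[1:11, 1:11] - P[1:11, 1:11])), 1e-8)
  }
})

test_that("transition matrices stay proper probabilities at large lam * t", {
  # the alternating closed-form sum is unstable here; the convolution
  # construction must keep everything in [0, 1]
  P <- bd_transition_matrix(t = 150, lam = 5, max_count = 60)
  expect_true(all(P >= 0 & P <= 1))
  expect_true(all(rowSums(P) <= 1 + 1e-12))
})

test_that("pruning likelihood agrees with direct and exhaustive summation", {
  # 2-tip closed form
  tr2 <- species_tree(ape::read.tree(text = "(A:3,B:3);"))
  m <- bd_model(c(all = 0.05), max_count = 12, root_max = 5)
  direct <- log(sum(vapply(1:5, function(r) {
    bd_transition_prob(r, 2, 3, 0.05) * bd_transition_prob(r, 3, 3, 0.05)
  }, numeric(1))) / 5)
  expect_equal(family_loglik(c(A = 2, B = 3), tr2, m), direct,
    tolerance = 1e-12
  )

  # lam = 0: all mass on the shared root count, likelihood 1 / root_max
  m0 <- bd_model(c(all = 0), max_count = 12, root_max = 5)
  expect_equal(family_loglik(c(A = 4, B = 4), tr2, m0), log(1 / 5))
  expect_equal(family_loglik(c(A = 4, B = 3), tr2, m0), -Inf)

  # exhaustive enumeration oracle on random small trees
  for (seed in c(11, 12)) {
    tr <- random_coalescent_tree(5, seed = seed)
    mm <- bd_model(c(all = 0.4), max_count = 5, root_max = 4)
    set.seed(seed)
    cnt <- setNames(sample(0:4, 5, replace = TRUE), tr$phy$tip.label)
    expect_equal(
      family_loglik(cnt, tr, mm),
      bruteforce_family_loglik(cnt, tr, mm),
      tolerance = 1e-10
    )
  }
})

test_that("likelihood is invariant to tip enumeration order", {
  tr <- fixture_tree()
  m <- bd_model(fixture_rates(), max_count = 30, root_max = 10)
  set.seed(8)
  cnt <- setNames(sample(1:8, 18, replace = TRUE), tr$phy$tip.label)
  ll1 <- family_loglik(cnt, tr, m)
  ll2 <- family_loglik(cnt[sample(18)], tr, m)
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("truncation convergence: enlarging max_count stops mattering", {
  tr <- fixture_tree()
  set.seed(3)
  cnt <- setNames(sample(2:9, 18, replace = TRUE), tr$phy$tip.label)
  base <- 2L * max(cnt) + 10L
  ll_a <- family_loglik(cnt, tr, bd_model(fixture_rates(), base, 10))
  ll_b <- family_loglik(cnt, tr, bd_model(fixture_rates(), base + 40L, 10))
  expect_lt(abs(ll_a - ll_b), 1e-6)
  # overflow is an error, not a silent clamp
  m_small <- bd_model(fixture_rates(), max_count = 5, root_max = 3)
  expect_error(family_loglik(cnt, tr, m_small), "max_count")
})

test_that("two-class fit nests the one-class fit", {
  tr <- fixture_tree()
  sim <- simulate_family_counts(tr, 60, fixture_rates(), seed = 21)
  f1 <- fit_rates(sim$tip_counts, tr, k = 1)
  f2 <- fit_rates(sim$tip_counts, tr, k = 2)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  expect_named(f2$rates, c("social", "solitary"))
  # monotone identifiability: higher simulated rate, higher fitted rate
  lams <- c(0.0005, 0.002, 0.008)
  fits <- vapply(seq_along(lams), function(i) {
    s <- simulate_family_counts(tr, 80, lams[i], seed = 100 + i)
    fit_rates(s$tip_counts, tr, k = 1)$rates[[1]]
  }, numeric(1))
  expect_true(all(diff(fits) > 0))
})

test_that("ancestral reconstruction matches the exhaustive joint argmax", {
  # lam = 0: internal nodes must equal the shared tip count
  tr2 <- species_tree(ape::read.tree(text = "(A:3,B:3);"))
  m0 <- bd_model(c(all = 0), max_count = 10, root_max = 6)
  rec <- ancestral_counts(c(A = 5, B = 5), tr2, m0)
  expect_equal(unname(rec["node3"]), 5)

  # small lam * t keeps the root at the shared tip count
  m_small <- bd_model(c(all = 1e-4), max_count = 10, root_max = 6)
  rec2 <- ancestral_counts(c(A = 5, B = 5), tr2, m_small)
  expect_equal(unname(rec2["node3"]), 5)

  # brute-force joint argmax oracle on random 5-tip instances
  for (seed in c(31, 32)) {
    tr <- random_coalescent_tree(5, seed = seed)
    mm <- bd_model(c(all = 0.3), max_count = 5, root_max = 5)
    set.seed(seed)
    cnt <- setNames(sample(1:4, 5, replace = TRUE), tr$phy$tip.label)
    rec <- ancestral_counts(cnt, tr, mm)
    oracle <- bruteforce_joint_argmax(cnt, tr, mm)
    expect_equal(unname(rec), unname(oracle))
  }
})

test_that("family p-values flag only model-implausible families", {
  tr <- fixture_tree()
  m <- bd_model(fixture_rates(), max_count = 60, root_max = 10)
  expect_error(family_pvalue(
    setNames(rep(3, 18), tr$phy$tip.label), tr, m,
    n_sim = 0
  ), "n_sim")
  null_ll <- null_family_logliks(tr, m, 300, seed = 5)
  # a family drawn from the model itself: unremarkable p
  sim <- simulate_from_model(tr, m, 1, seed = 9)
  p_null <- family_pvalue(sim$tip_counts[1, ], tr, m, null_logliks = null_ll)
  expect_gt(p_null, 0.05)
  # one tip forced far outside the null range: minimal attainable p
  extreme <- sim$tip_counts[1, ]
  extreme[1] <- 55
  p_ext <- family_pvalue(extreme, tr, m, null_logliks = null_ll)
  expect_lte(p_ext, 2 / (length(null_ll) + 1))
})

test_that("branch p-values localize changes with correct directions", {
  tr2 <- species_tree(ape::read.tree(text = "(A:3,B:3);"))
  m <- bd_model(c(all = 0.002), max_count = 40, root_max = 12)
  # no change under tiny lam * t: p near 1, direction none
  quiet <- branch_pvalues(c(A = 10, B = 10), tr2, m, n_sim = 300, seed = 2)
  expect_true(all(quiet$direction == "none"))
  expect_true(all(quiet$p > 0.5))
  # a 10 -> 2 drop under tiny lam * t: small p, contraction
  crash <- branch_pvalues(c(A = 2, B = 10), tr2, m, n_sim = 300, seed = 2)
  row <- crash[crash$child == "A", ]
  expect_equal(row$direction, "contraction")
  expect_lt(row$p, 0.05)
  # lam = 0 family: every direction none
  m0 <- bd_model(c(all = 0), max_count = 40, root_max = 12)
  flat <- branch_pvalues(c(A = 7, B = 7), tr2, m0, n_sim = 50, seed = 3)
  expect_true(all(flat$direction == "none"))
  expect_true(all(flat$p == 1))
})

test_that("star annotation applies the family gate then the node levels", {
  br <- data.frame(
    family = c("ctl", "ctl", "gnbp", "tpx"),
    family_p = c(0.011, 0.011, 0.2, 0.0),
    p = c(0.0173, 0.0012, 0.001, 0.0403),
    direction = c("contraction", "contraction", "expansion", "contraction"),
    stringsAsFactors = FALSE
  )
  rep <- report_changes(br)
  expect_equal(rep$stars, c("*", "**", "", "*"))
  # direction "none" is never starred even when p is tiny
  br2 <- br
  br2$direction[2] <- "none"
  expect_equal(report_changes(br2)$stars[2], "")
})
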