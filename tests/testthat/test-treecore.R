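test_that("newick parsing enforces the tree invariants", {
  tf <- withr::local_tempfile(lines = "((A:1,B:1):1,C:2);")
  tr <- read_species_tree(tf)
  expect_s3_class(tr, "species_tree")
  expect_equal(ape::Ntip(tr$phy), 3)
  expect_equal(tree_depth(tr), 2)

  bad <- withr::local_tempfile(lines = "((A:1,B:2):1,C:2);")
  expect_error(read_species_tree(bad), "not ultrametric")
  expect_silent(read_species_tree(bad, ultrametric = FALSE))

  dup <- withr::local_tempfile(lines = "((A:1,A:1):1,C:2);")
  expect_error(read_species_tree(dup), "duplicate tip labels")

  star <- withr::local_tempfile(lines = "(A:1,B:1,C:1);")
  st <- read_species_tree(star)
  expect_equal(st$phy$Nnode, 1) # polytomy preserved
})

test_that("patristic distances are path sums of branch lengths", {
  tr <- species_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  d <- patristic_matrix(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))

  star <- species_tree(ape::read.tree(text = "(A:1,B:1,C:1);"))
  ds <- patristic_matrix(star)
  expect_true(all(ds[upper.tri(ds)] == 2))

  two <- species_tree(ape::read.tree(text = "(A:3,B:3);"))
  expect_equal(patristic_matrix(two)["A", "B"], 6)
})

test_that("Abouheif proximity is the inverse product of node out-degrees", {
  star <- species_tree(ape::read.tree(text = "(A:1,B:1,C:1);"))
  a <- abouheif_proximity(star)
  expect_true(all(abs(a[upper.tri(a)] - 1 / 3) < 1e-15))

  tr <- species_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  a <- abouheif_proximity(tr)
  expect_equal(a["A", "B"], 1 / 2)
  expect_equal(a["A", "C"], 1 / 4)
  expect_equal(a["B", "C"], 1 / 4)

  two <- species_tree(ape::read.tree(text = "(A:3,B:3);"))
  expect_equal(abouheif_proximity(two)["A", "B"], 1 / 2)
})

test_that("Abouheif proximity on balanced binary trees is 2^-(path nodes)", {
  # fully balanced 8-tip tree: every internal node has out-degree 2, so
  # the proximity must equal 2^-(number of internal nodes on the path)
  nwk <- "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);"
  tr <- species_tree(ape::read.tree(text = nwk))
  a <- abouheif_proximity(tr)
  phy <- tr$phy
  n <- ape::Ntip(phy)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      path <- ape::nodepath(phy, i, j)
      k <- sum(path > n) # brute-force path enumeration
      expect_equal(a[i, j], 2^-k)
    }
  }
})

test_that("shared-path covariance matches its defining identities", {
  tr <- species_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  V <- shared_path_covariance(tr)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "A"], 2)
  expect_equal(V["A", "C"], 0)

  star <- species_tree(ape::read.tree(text = "(A:1,B:1,C:1);"))
  Vs <- shared_path_covariance(star)
  expect_equal(Vs[upper.tri(Vs)], rep(0, 3))

  # ultrametric tree: constant diagonal
  tr2 <- random_coalescent_tree(12, seed = 4)
  V2 <- shared_path_covariance(tr2)
  expect_lt(diff(range(diag(V2))) / max(diag(V2)), 1e-8)
})

test_that("d(i,j) = V(i,i) + V(j,j) - 2 V(i,j) on random trees", {
  for (seed in 1:5) {
    tr <- random_rtree(sample(5:12, 1), seed = seed)
    d <- patristic_matrix(tr)
    V <- shared_path_covariance(tr)
    lab <- rownames(d)
    D2 <- outer(diag(V), diag(V), "+") - 2 * V
    expect_equal(unname(d[lab, lab]), unname(D2[lab, lab]), tolerance = 1e-10)
  }
})

test_that("row normalization makes rows sum to one and keeps the diagonal", {
  tr <- random_coalescent_tree(10, seed = 2)
  W <- row_normalize(abouheif_proximity(tr))
  expect_equal(unname(rowSums(W)), rep(1, 10))
  expect_equal(unname(diag(W)), rep(0, 10))
  Z <- matrix(0, 2, 2)
  expect_error(row_normalize(Z), "all-zero")
})

test_that("rate classes derive from tips and require an explicit backbone label", {
  tr <- species_tree(ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);"))
  cls <- c(A = "x", B = "x", C = "y", D = "y")
  out <- assign_rate_classes(tr, cls, mixed = "x")
  # pendant edges carry their tip class
  pend <- match(1:4, out$phy$edge[, 2])
  expect_equal(
    as.character(out$rate_class)[pend],
    unname(cls[out$phy$tip.label])
  )
  # a class split that does not form clades leaves backbone branches
  # with mixed descendants: those need an explicit label
  cls_mixed <- c(A = "x", B = "y", C = "y", D = "y")
  expect_error(assign_rate_classes(tr, cls_mixed), "supply `mixed`")
  out2 <- assign_rate_classes(tr, cls_mixed, mixed = "y")
  expect_equal(nlevels(out2$rate_class), 2)
  expect_error(assign_rate_classes(tr, cls[-1]), "no class for tips")
})

test_that("labeled matrices round-trip through TSV", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, tf, row_label = "family")
  m2 <- read_matrix_tsv(tf)
  expect_equal(m2, m)
})
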