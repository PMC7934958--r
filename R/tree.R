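#' Species tree with branch rate classes
#'
#' Wraps a rooted, time-calibrated `ape::phylo` tree together with a
#' per-branch categorical rate class (for example `"solitary"` vs
#' `"social"`). The rate class is what the birth--death machinery in
#' [fit_rates()] uses to assign each branch one of its k rates; every other
#' computation in the package ignores it.
#'
#' @param phy an object of class `phylo` (rooted, with branch lengths).
#' @param rate_class `NULL` (single class `"all"`), or a character/factor
#'   vector with one entry per edge of `phy`, in `phy$edge` row order.
#' @param ultrametric logical; if `TRUE` (default) the tree must be
#'   ultrametric within `tol` (relative tip-depth spread), otherwise an
#'   error is raised. Set to `FALSE` for trees that are deliberately
#'   non-clock (the signal statistics remain defined).
#' @param tol relative ultrametricity tolerance (default `1e-6`): the
#'   spread of root-to-tip path lengths divided by the maximum depth.
#'
#' @return An object of class `species_tree`: a list with elements `phy`
#'   (the `phylo` object) and `rate_class` (factor, one level set shared by
#'   all edges).
#' @examples
#' tr <- species_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
#' tree_depth(tr)
#' @export
species_tree <- function(phy, rate_class = NULL, ultrametric = TRUE,
                         tol = 1e-6) {
  if (!inherits(phy, "phylo")) {
    stop("`phy` must be an ape 'phylo' object")
  }
  if (is.null(phy$edge.length) || anyNA(phy$edge.length)) {
    stop("tree has missing branch lengths")
  }
  # hierarchical Newick always carries a basal node; a basal polytomy
  # (star tree) is treated as rooted there
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (any(phy$edge.length <= 0)) {
    stop("all branch lengths must be > 0")
  }
  if (ultrametric) {
    depths <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
    spread <- diff(range(depths))
    if (spread / max(depths) > tol) {
      stop(sprintf(
        "tree is not ultrametric (relative tip-depth spread %.3g > tol %.3g)",
        spread / max(depths), tol
      ))
    }
  }
  n_edge <- nrow(phy$edge)
  if (is.null(rate_class)) {
    rate_class <- rep("all", n_edge)
  }
  if (length(rate_class) != n_edge) {
    stop("`rate_class` must have one entry per edge (", n_edge, ")")
  }
  structure(
    list(phy = phy, rate_class = factor(as.character(rate_class))),
    class = "species_tree"
  )
}

#' Read a species tree from a Newick file
#'
#' Branch lengths are required on every non-root edge; internal node labels
#' are tolerated and ignored. Polytomies are preserved.
#'
#' @param path path to a Newick file (single tree).
#' @param rate_class_file optional path to a two-column TSV
#'   (`species`, `class`) assigning each tip a rate class; branch classes
#'   are then derived with [assign_rate_classes()].
#' @param mixed class label for backbone branches whose descendant tips
#'   span several classes (passed to [assign_rate_classes()]).
#' @inheritParams species_tree
#' @return a [species_tree] object.
#' @export
read_species_tree <- function(path, rate_class_file = NULL, mixed = NULL,
                              ultrametric = TRUE, tol = 1e-6) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick file: ", path)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  tree <- species_tree(phy, ultrametric = ultrametric, tol = tol)
  if (!is.null(rate_class_file)) {
    tab <- utils::read.table(rate_class_file,
      header = TRUE, sep = "\t",
      stringsAsFactors = FALSE
    )
    classes <- stats::setNames(as.character(tab[[2]]), tab[[1]])
    tree <- assign_rate_classes(tree, classes, mixed = mixed)
  }
  tree
}

#' Write a species tree (with optional node annotations) to Newick
#'
#' @param tree a [species_tree] object or `phylo`.
#' @param path output file.
#' @export
write_species_tree <- function(tree, path) {
  phy <- if (inherits(tree, "species_tree")) tree$phy else tree
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Derive per-branch rate classes from tip classes
#'
#' A branch takes the class shared by all tips descending from it; branches
#' whose descendants span several classes (the backbone between clades)
#' take the `mixed` label, which must be supplied explicitly when such
#' branches exist -- there is no biologically neutral default for the
#' ancestral state.
#'
#' @param tree a [species_tree].
#' @param tip_classes named character vector, `names` = tip labels.
#' @param mixed class label for mixed-descendant branches.
#' @return the tree with `rate_class` replaced.
#' @export
assign_rate_classes <- function(tree, tip_classes, mixed = NULL) {
  stopifnot(inherits(tree, "species_tree"))
  phy <- tree$phy
  tips <- phy$tip.label
  missing_tips <- setdiff(tips, names(tip_classes))
  if (length(missing_tips) > 0) {
    stop("no class for tips: ", paste(missing_tips, collapse = ", "))
  }
  n_tip <- ape::Ntip(phy)
  n_node <- phy$Nnode
  # class sets propagated tips -> root over postorder edges
  class_of <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) class_of[[i]] <- tip_classes[[tips[i]]]
  eo <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1]; ch <- eo[k, 2]
    class_of[[p]] <- unique(c(class_of[[p]], class_of[[ch]]))
  }
  edge_class <- character(nrow(phy$edge))
  for (k in seq_len(nrow(phy$edge))) {
    cl <- class_of[[phy$edge[k, 2]]]
    if (length(cl) == 1) {
      edge_class[k] <- cl
    } else {
      if (is.null(mixed)) {
        stop(
          "tree has branches whose descendant tips span several classes; ",
          "supply `mixed` to label them"
        )
      }
      edge_class[k] <- mixed
    }
  }
  tree$rate_class <- factor(edge_class)
  tree
}

#' @export
print.species_tree <- function(x, ...) {
  cat(
    "species_tree:", ape::Ntip(x$phy), "tips,",
    x$phy$Nnode, "internal nodes, depth",
    format(tree_depth(x), digits = 6), "\n"
  )
  cat("rate classes:", paste(levels(x$rate_class), collapse = ", "), "\n")
  invisible(x)
}

#' Tree depth (maximum root-to-tip path length)
#' @param tree a [species_tree] or `phylo`.
#' @export
tree_depth <- function(tree) {
  phy <- if (inherits(tree, "species_tree")) tree$phy else tree
  max(ape::node.depth.edgelength(phy))
}

as_phylo <- function(tree) {
  if (inherits(tree, "species_tree")) tree$phy else tree
}

#' Patristic distance matrix
#'
#' Pairwise sum of branch lengths on the path between tips, used to build
#' the default inverse-distance weights of Moran's I.
#'
#' @param tree a [species_tree] or `phylo`.
#' @return symmetric n x n matrix with zero diagonal, tip labels as
#'   dimnames, tips in `tip.label` order.
#' @export
patristic_matrix <- function(tree) {
  phy <- as_phylo(tree)
  d <- ape::cophenetic.phylo(phy)
  d[phy$tip.label, phy$tip.label]
}

#' Abouheif phylogenetic proximity
#'
#' Off-diagonal proximity `a(i, j)` is the inverse of the product, over the
#' internal nodes on the path from tip i to tip j, of each node's number of
#' direct descendants. This is the topology-only weight matrix behind
#' Abouheif's C_mean; polytomies contribute their actual out-degree.
#'
#' @param tree a [species_tree] or `phylo`.
#' @return symmetric n x n matrix, zero diagonal, not row-normalized.
#' @export
abouheif_proximity <- function(tree) {
  phy <- as_phylo(tree)
  n <- ape::Ntip(phy)
  n_children <- tabulate(phy$edge[, 1], nbins = n + phy$Nnode)
  A <- matrix(0, n, n, dimnames = list(phy$tip.label, phy$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      path <- ape::nodepath(phy, i, j)
      internal <- path[path > n]
      A[i, j] <- A[j, i] <- 1 / prod(n_children[internal])
    }
  }
  A
}

#' Shared-path (phylogenetic) covariance matrix
#'
#' `V[i, j]` is the branch length shared between the root-to-tip paths of
#' tips i and j (the depth of their MRCA); `V[i, i]` is the depth of tip i.
#' On an ultrametric tree the diagonal is constant and V is the Brownian
#' motion trait covariance up to a rate constant.
#'
#' @param tree a [species_tree] or `phylo`.
#' @return symmetric positive semi-definite n x n matrix.
#' @export
shared_path_covariance <- function(tree) {
  phy <- as_phylo(tree)
  V <- ape::vcv.phylo(phy)
  V[phy$tip.label, phy$tip.label]
}

#' Row-normalize a proximity/weight matrix
#'
#' @param W square non-negative matrix with zero diagonal.
#' @return matrix whose rows each sum to 1; an all-zero row is an error
#'   (the corresponding observation would carry no neighbours).
#' @export
row_normalize <- function(W) {
  rs <- rowSums(W)
  if (any(rs == 0)) {
    bad <- rownames(W)[rs == 0]
    if (is.null(bad)) bad <- which(rs == 0)
    stop("cannot row-normalize: all-zero row(s): ", paste(bad, collapse = ", "))
  }
  W / rs
}

#' Moran spatial weights from a phylogeny
#'
#' Default scheme: off-diagonal weight `1/d(i, j)` from patristic
#' distances, then row-normalized. The weighting behind a Moran's I on a
#' phylogeny is a modelling choice, so it is exposed here rather than
#' hard-coded.
#'
#' @param tree a [species_tree] or `phylo`.
#' @param scheme `"inv_distance"` (default) or `"inv_distance_sq"`.
#' @param normalize row-normalize (default `TRUE`).
#' @export
moran_weights <- function(tree, scheme = c("inv_distance", "inv_distance_sq"),
                          normalize = TRUE) {
  scheme <- match.arg(scheme)
  d <- patristic_matrix(tree)
  W <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  off <- row(d) != col(d)
  W[off] <- switch(scheme,
    inv_distance = 1 / d[off],
    inv_distance_sq = 1 / d[off]^2
  )
  if (normalize) W <- row_normalize(W)
  W
}

#' Write a labeled matrix as TSV (row names in first column)
#' @param m matrix with dimnames.
#' @param path output path.
#' @param row_label header for the row-name column.
#' @export
write_matrix_tsv <- function(m, path, row_label = "row") {
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE, row = rownames(m))
  names(df) <- row_label
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a labeled matrix written by [write_matrix_tsv()]
#' @param path TSV path, first column = row labels.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t", check.names = FALSE,
    stringsAsFactors = FALSE
  )
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
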