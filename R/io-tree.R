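#' Read a rooted Newick tree with named branches
#'
#' Every branch of the tree is named after the node it leads to: tips keep
#' their tip label, internal branches take the internal-node label. Internal
#' nodes without a label are auto-named `b1..bk` in preorder so that branch
#' assignments are reproducible. The root itself carries no branch.
#'
#' @param path Path to a Newick file (exactly one tree).
#' @param text Newick string, as an alternative to `path`.
#' @return An [ape::read.tree()] `"phylo"` object with complete, unique
#'   node labels.
#' @examples
#' tr <- read_newick_tree(text = "((A,B)ab,(C,D)cd)root;")
#' branch_table(tr)
#' @export
read_newick_tree <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) {
    ape::read.tree(text = text)
  } else {
    ape::read.tree(file = path)
  }
  if (is.null(tree)) {
    stop("could not parse Newick input")
  }
  if (inherits(tree, "multiPhylo")) {
    stop("expected a single Newick tree, found ", length(tree))
  }
  if (anyDuplicated(tree$tip.label)) {
    stop(
      "duplicate tip names: ",
      paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")
    )
  }
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  lab[is.na(lab)] <- ""
  # preorder over internal nodes = order of first appearance as a parent
  # in the cladewise edge matrix, root first
  pre <- unique(tree$edge[, 1L])
  auto <- 0L
  for (nd in pre) {
    i <- nd - ntip
    if (!nzchar(lab[i])) {
      repeat {
        auto <- auto + 1L
        cand <- paste0("b", auto)
        if (!cand %in% c(tree$tip.label, lab)) break
      }
      lab[i] <- cand
    }
  }
  tree$node.label <- lab
  if (anyDuplicated(c(tree$tip.label, lab[-1L]))) {
    stop("branch names are not unique after labelling")
  }
  tree
}

#' Tabulate the named branches of a tree
#'
#' @param tree A `"phylo"` tree as returned by [read_newick_tree()].
#' @return A data.frame with one row per branch (edge): `branch` (name),
#'   `parent` and `child` (ape node numbers), `is_tip`.
#' @export
branch_table <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  child <- tree$edge[, 2L]
  name <- character(length(child))
  name[child <= ntip] <- tree$tip.label[child[child <= ntip]]
  name[child > ntip] <- tree$node.label[child[child > ntip] - ntip]
  if (anyDuplicated(name)) {
    stop("branch names are not unique; relabel the tree")
  }
  data.frame(
    branch = name,
    parent = tree$edge[, 1L],
    child = child,
    is_tip = child <= ntip,
    stringsAsFactors = FALSE
  )
}

#' Number of branches of a tree
#'
#' A rooted binary tree with n tips has 2n - 2 branches (the root carries
#' none).
#'
#' @param tree A `"phylo"` tree.
#' @return Integer branch count.
#' @export
n_branches <- function(tree) nrow(tree$edge)
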