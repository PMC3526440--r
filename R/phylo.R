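#' Read a rooted phylogeny with named ancestral nodes
#'
#' Wraps [ape::read.tree()]. The tree must be rooted with a bifurcating root
#' and have at least two leaves; leaves are the extant genomes and internal
#' nodes the inferred ancestors. Internal nodes without a label are named
#' deterministically `anc1`, `anc2`, ... in preorder (root first), so
#' auto-names are stable across runs.
#'
#' @param path Newick file.
#' @param reference Name of the reference leaf (coordinates of all windows
#'   refer to this genome). Defaults to the first leaf in the file.
#' @return A `phylogeny` object: list with `tree` (ape `phylo`), `reference`,
#'   and `branches` (tibble of `node`, `parent` for every non-root node).
#' @export
read_tree <- function(path, reference = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  phylogeny(tr, reference = reference)
}

#' Construct a phylogeny object from an ape tree
#'
#' @param tree An [ape::read.tree()] `phylo` object.
#' @inheritParams read_tree
#' @return A `phylogeny` object; see [read_tree()].
#' @export
phylogeny <- function(tree, reference = NULL) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape phylo object")
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have at least two leaves")
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted (multifurcating roots are not accepted); resolve upstream")
  }
  root <- ntip + 1L
  if (sum(tree$edge[, 1L] == root) > 2L) {
    stop("tree root is multifurcating; resolve upstream")
  }
  # Deterministic preorder auto-naming of unlabelled internal nodes.
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  lab[is.na(lab)] <- ""
  edge <- stats::reorder(tree, "cladewise")$edge
  pre_internal <- unique(c(root, edge[, 2L][edge[, 2L] > ntip]))
  blank <- which(lab == "")
  if (length(blank)) {
    rank <- match(blank + ntip, pre_internal)
    lab[blank[order(rank)]] <- paste0("anc", seq_along(blank))
  }
  tree$node.label <- lab
  nms <- c(tree$tip.label, tree$node.label)
  if (anyDuplicated(nms)) {
    stop("duplicate node names: ", paste(nms[duplicated(nms)], collapse = ", "))
  }
  reference <- reference %||% tree$tip.label[1L]
  if (!reference %in% tree$tip.label) {
    stop("reference leaf '", reference, "' not found among tips")
  }
  branches <- tibble::tibble(
    node = nms[tree$edge[, 2L]],
    parent = nms[tree$edge[, 1L]],
    length = if (is.null(tree$edge.length)) NA_real_ else tree$edge.length
  )
  structure(list(tree = tree, reference = reference, branches = branches),
            class = "phylogeny")
}

#' @export
print.phylogeny <- function(x, ...) {
  cat(sprintf("<phylogeny> %d leaves, %d ancestral nodes, reference = %s\n",
              length(x$tree$tip.label), x$tree$Nnode, x$reference))
  invisible(x)
}

#' Names of all nodes of a phylogeny
#'
#' @param phy A `phylogeny` object.
#' @param what `"all"`, `"leaves"` or `"ancestors"`.
#' @return Character vector of node names.
#' @export
node_names <- function(phy, what = c("all", "leaves", "ancestors")) {
  what <- match.arg(what)
  switch(what,
         leaves = phy$tree$tip.label,
         ancestors = phy$tree$node.label,
         all = c(phy$tree$tip.label, phy$tree$node.label))
}

root_name <- function(phy) {
  phy$tree$node.label[1L] # ape stores the root as the first internal node
}
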