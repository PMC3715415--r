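#' Read a rooted species tree from a Newick file
#'
#' Parses a Newick tree and validates it for use as the species tree of a
#' phylogenetic-profile analysis: leaf labels must be unique and, if a
#' species panel is supplied, must equal the panel exactly (a mismatch is an
#' error, not a warning). Unrooted input is rooted at a named outgroup or at
#' the midpoint; the rooting applied is recorded in the `"rooted_by"`
#' attribute.
#'
#' @param path path to a Newick file (single tree).
#' @param panel optional character vector of species identifiers that the
#'   leaf set must match exactly (order-insensitive).
#' @param root_at how to root an unrooted input tree: `NULL` (error on
#'   unrooted input), a leaf label to use as outgroup, or `"midpoint"`.
#' @return an [ape::phylo] rooted tree.
#' @export
read_newick <- function(path, panel = NULL, root_at = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: no tree parsed from ", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  validate_species_tree(tree, panel = panel, root_at = root_at)
}

#' @rdname read_newick
#' @param text a Newick string instead of a file.
#' @export
read_newick_text <- function(text, panel = NULL, root_at = NULL) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  validate_species_tree(tree, panel = panel, root_at = root_at)
}

validate_species_tree <- function(tree, panel = NULL, root_at = NULL) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  rooted_by <- "input"
  if (!ape::is.rooted(tree)) {
    if (is.null(root_at))
      stop("tree is unrooted; supply root_at = <outgroup leaf> or \"midpoint\"")
    if (identical(root_at, "midpoint")) {
      if (!requireNamespace("phangorn", quietly = TRUE))
        stop("midpoint rooting requires the phangorn package")
      tree <- phangorn::midpoint(tree)
      rooted_by <- "midpoint"
    } else {
      if (!root_at %in% tree$tip.label)
        stop("outgroup leaf not in tree: ", root_at)
      tree <- ape::root(tree, outgroup = root_at, resolve.root = TRUE)
      rooted_by <- paste0("outgroup:", root_at)
    }
  }
  if (!is.null(panel)) {
    if (!setequal(tree$tip.label, panel) ||
        length(tree$tip.label) != length(panel))
      stop("tree leaves do not match the species panel; missing: ",
           paste(setdiff(panel, tree$tip.label), collapse = ", "),
           "; extra: ",
           paste(setdiff(tree$tip.label, panel), collapse = ", "))
  }
  attr(tree, "rooted_by") <- rooted_by
  tree
}

# Branch indexing convention: every node v of the rooted tree (leaves
# 1..Ntip, internal Ntip+1..Ntip+Nnode in ape numbering) owns the branch
# directly above it; the root owns a virtual stem branch, so that a gain of
# a family present on both sides of the root has a branch to live on.
# Number of branches = number of nodes = Ntip + Nnode.

#' Precompute traversal structures for a rooted tree
#'
#' Internal workhorse shared by the Dollo reconstruction, LCA queries and
#' the simulator. Branches are identified with the node below them (the
#' root's branch is its virtual stem), so there are `Ntip + Nnode` branches.
#'
#' @param tree a rooted [ape::phylo].
#' @return a list with node counts, `parent` vector (0 at the root),
#'   `children` list, pre-/post-order node sequences, `depth` (root = 0) and
#'   leaf labels.
#' @keywords internal
tree_index <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  m <- ntip + nnode
  parent <- integer(m)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ntip + 1L
  if (any(parent[-root] == 0L)) {
    # non-standard node numbering; locate root as the node that is never a child
    root <- setdiff(seq_len(m), tree$edge[, 2L])
    if (length(root) != 1L) stop("tree has no unique root")
  }
  parent[root] <- 0L
  children <- vector("list", m)
  for (i in seq_len(nrow(tree$edge)))
    children[[tree$edge[i, 1L]]] <-
      c(children[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  n_child <- lengths(children)
  if (any(n_child[(ntip + 1L):m] < 2L))
    stop("internal node with fewer than 2 children (unresolved root?)")
  # preorder: parents before children
  preorder <- integer(m)
  preorder[1L] <- root
  k <- 1L
  for (i in seq_len(m)) {
    for (ch in children[[preorder[i]]]) {
      k <- k + 1L
      preorder[k] <- ch
    }
  }
  depth <- integer(m)
  for (v in preorder[-1L]) depth[v] <- depth[parent[v]] + 1L
  list(ntip = ntip, nnode = nnode, nbranch = m, root = root,
       parent = parent, children = children,
       preorder = preorder, postorder = rev(preorder),
       depth = depth, labels = tree$tip.label)
}

#' Number of branches of a rooted tree (one per node, incl. the root stem)
#' @param tree a rooted [ape::phylo].
#' @return integer branch count.
#' @export
n_branches <- function(tree) {
  length(tree$tip.label) + tree$Nnode
}

# LCA node id of a set of leaf indices (>=1), using a tree_index.
lca_node <- function(ti, leaves) {
  if (length(leaves) == 0L) stop("empty leaf set has no LCA")
  if (length(leaves) == 1L) return(leaves)
  # walk all leaves up to equal depth, then in lockstep
  v <- leaves
  repeat {
    if (all(v == v[1L])) return(v[1L])
    dmax <- max(ti$depth[v])
    up <- ti$depth[v] == dmax
    v[up] <- ti$parent[v[up]]
  }
}

# TRUE iff node u is a strict descendant of node v.
is_strict_descendant <- function(ti, u, v) {
  if (u == v) return(FALSE)
  while (ti$depth[u] > ti$depth[v]) {
    u <- ti$parent[u]
    if (u == v) return(TRUE)
  }
  FALSE
}
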