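# Trees are ape "phylo" objects: tips 1..n labeled by taxon, branch lengths
# in expected substitutions per site. Rooted (clock) trees have a bifurcating
# root; unrooted trees a trifurcating root node.

#' Parse a Newick string into a tree
#'
#' Missing branch lengths default to 0. Tip labels must be unique.
#'
#' @param text Newick string.
#' @return An `ape::phylo` tree.
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("malformed Newick string")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label: '",
         tree$tip.label[anyDuplicated(tree$tip.label)], "'")
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative")
  }
  tree
}

#' Serialize a tree to Newick
#'
#' @param tree An `ape::phylo` tree.
#' @param digits Significant digits for branch lengths.
#' @return Newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

#' Sum of all branch lengths
#' @param tree An `ape::phylo` tree.
#' @export
total_length <- function(tree) {
  if (is.null(tree$edge.length)) return(0)
  sum(tree$edge.length)
}

# Unroot, tolerating trees that are already unrooted or too small.
unroot_safely <- function(tree) {
  if (ape::Ntip(tree) > 2L && ape::is.rooted(tree)) ape::unroot(tree) else tree
}

#' Bipartitions (splits) of a tree
#'
#' Each edge of the unrooted tree induces a partition of the taxon set;
#' splits are keyed canonically by the side containing the alphabetically
#' first taxon, so equal splits compare equal across trees with the same
#' taxa. Rooted trees are unrooted first (the two root edges merge).
#'
#' @param tree An `ape::phylo` tree.
#' @param include_trivial Include the pendant (single-tip) splits?
#' @return A data frame with columns `split` (canonical key, taxa sorted and
#'   joined by `|`), `length` (the edge's branch length) and `trivial`.
#' @export
bipartitions <- function(tree, include_trivial = FALSE) {
  tree <- unroot_safely(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  labels <- tree$tip.label
  nnode <- ntip + tree$Nnode
  below <- matrix(FALSE, nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  parents <- tree$edge[, 1L]
  children <- tree$edge[, 2L]
  for (e in seq_along(parents)) {
    below[parents[e], ] <- below[parents[e], ] | below[children[e], ]
  }
  root <- parents[length(parents)]
  anchor <- order(labels)[1L]  # alphabetically first taxon
  keys <- character(length(parents))
  trivial <- logical(length(parents))
  for (e in seq_along(parents)) {
    side <- below[children[e], ]
    trivial[e] <- sum(side) == 1L || sum(side) == ntip - 1L
    if (!side[anchor]) side <- !side
    keys[e] <- paste(sort(labels[side]), collapse = "|")
  }
  lens <- if (is.null(tree$edge.length)) rep(0, length(parents)) else
    tree$edge.length
  keep <- if (include_trivial) rep(TRUE, length(parents)) else !trivial
  # drop the edge into the root's "whole taxon set" side never occurs:
  # every edge has a proper child side by construction
  data.frame(split = keys[keep], length = lens[keep],
             trivial = trivial[keep], stringsAsFactors = FALSE)
}

check_same_taxa <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different taxon sets")
  }
}

#' Robinson-Foulds topology distance
#'
#' The number of non-trivial bipartitions present in exactly one of the two
#' (unrooted) trees. Always an even, non-negative integer for binary trees;
#' an increase of 2 corresponds to one misplaced branch.
#'
#' @param t1,t2 Trees over the same taxon set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  check_same_taxa(t1, t2)
  b1 <- bipartitions(t1)$split
  b2 <- bipartitions(t2)$split
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Robinson-Foulds branch-length distance (RFL)
#'
#' Sum over the union of bipartitions of both trees (pendant splits
#' included) of the absolute difference in branch length, counting a split
#' absent from one tree as length 0 there. Trees are unrooted first.
#'
#' @param t1,t2 Trees over the same taxon set.
#' @return Non-negative real.
#' @export
rfl_distance <- function(t1, t2) {
  check_same_taxa(t1, t2)
  b1 <- bipartitions(t1, include_trivial = TRUE)
  b2 <- bipartitions(t2, include_trivial = TRUE)
  keys <- union(b1$split, b2$split)
  l1 <- b1$length[match(keys, b1$split)]
  l2 <- b2$length[match(keys, b2$split)]
  l1[is.na(l1)] <- 0
  l2[is.na(l2)] <- 0
  sum(abs(l1 - l2))
}

# ---- internal tree construction and surgery ----------------------------

# Build an ape phylo from parent/child id vectors with arbitrary integer
# ids. `tip_labels` is a named character vector mapping tip id -> label.
# Tips are numbered 1..ntip in the order their labels sort, internals in
# preorder from the root (root = ntip + 1), as ape requires.
build_phylo <- function(parent, child, len, tip_labels) {
  ids_child <- unique(child)
  ids_parent <- unique(parent)
  tip_ids <- as.integer(names(tip_labels))
  internal_ids <- setdiff(union(ids_parent, ids_child), tip_ids)
  root <- setdiff(ids_parent, ids_child)
  if (length(root) != 1L) stop("tree edges do not define a single root")
  # preorder over internal nodes
  kids <- split(child, factor(parent, levels = internal_ids))
  ord <- integer(0)
  stack <- root
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    ord <- c(ord, nd)
    ch <- kids[[as.character(nd)]]
    stack <- c(ch[ch %in% internal_ids], stack)
  }
  ntip <- length(tip_ids)
  tip_order <- order(unname(tip_labels))
  newid <- integer(max(c(tip_ids, internal_ids)))
  newid[tip_ids[tip_order]] <- seq_len(ntip)
  newid[ord] <- ntip + seq_along(ord)
  tree <- list(edge = cbind(newid[parent], newid[child]),
               edge.length = len,
               tip.label = unname(tip_labels[tip_order]),
               Nnode = length(internal_ids))
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  tree
}

# Attach a new tip by bisecting edge `edge_idx`: the edge (p -> c) of
# length L becomes p -> w (pos * L) and w -> c ((1-pos) * L), with a new
# pendant edge w -> tip of length `pendant`.
attach_tip <- function(tree, edge_idx, label, pendant, pos = 0.5) {
  ntot <- ape::Ntip(tree) + tree$Nnode
  w <- ntot + 1L
  newtip <- ntot + 2L
  p <- tree$edge[edge_idx, 1L]
  ch <- tree$edge[edge_idx, 2L]
  L <- tree$edge.length[edge_idx]
  parent <- c(tree$edge[-edge_idx, 1L], p, w, w)
  child <- c(tree$edge[-edge_idx, 2L], w, ch, newtip)
  len <- c(tree$edge.length[-edge_idx], pos * L, (1 - pos) * L, pendant)
  tips <- stats::setNames(c(tree$tip.label, label),
                          c(seq_len(ape::Ntip(tree)), newtip))
  build_phylo(parent, child, len, tips)
}

# The two nearest-neighbor-interchange neighbors around internal edge
# (u -> v): swap one child of v with one of u's other subtrees. Branch
# lengths stay attached to the moved subtrees. Returns a list of trees.
nni_neighbors <- function(tree, edge_idx) {
  u <- tree$edge[edge_idx, 1L]
  v <- tree$edge[edge_idx, 2L]
  ntip <- ape::Ntip(tree)
  if (v <= ntip) return(list())
  vkids <- which(tree$edge[, 1L] == v)
  ukids <- setdiff(which(tree$edge[, 1L] == u), edge_idx)
  if (length(vkids) < 2L) return(list())
  swap <- function(e_a, e_s) {
    tr <- tree
    tr$edge[e_a, 1L] <- u
    tr$edge[e_s, 1L] <- v
    attr(tr, "order") <- NULL
    tr
  }
  if (length(ukids) >= 2L) {
    # u is (typically) the unrooted trifurcating root: exchanging v's first
    # child with either other root subtree yields the two distinct neighbors
    list(swap(vkids[1L], ukids[1L]), swap(vkids[1L], ukids[2L]))
  } else if (length(ukids) == 1L) {
    list(swap(vkids[1L], ukids[1L]), swap(vkids[2L], ukids[1L]))
  } else {
    list()
  }
}
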