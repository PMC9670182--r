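# Internal tree helpers shared across modules.

# children indices of every node, as a list indexed by node id
node_children <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  kids
}

# tip labels below a node (the node itself if terminal)
tips_below <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  idx <- unlist(phangorn::Descendants(tree, node, type = "tips"))
  tree$tip.label[idx]
}

# list of tip-label sets, one per internal node, root excluded
clade_tip_sets <- function(tree, include_root = FALSE) {
  ntip <- ape::Ntip(tree)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  if (!include_root) nodes <- setdiff(nodes, ntip + 1L)
  desc <- phangorn::Descendants(tree, nodes, type = "tips")
  out <- lapply(desc, function(i) tree$tip.label[i])
  names(out) <- as.character(nodes)
  out
}

# parent node of each node (0 for the root)
node_parents <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  par <- integer(n_node)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

# terminal branch length of each tip (NA when the tree has no lengths)
terminal_lengths <- function(tree) {
  ntip <- ape::Ntip(tree)
  out <- rep(NA_real_, ntip)
  if (!is.null(tree$edge.length)) {
    tip_edges <- tree$edge[, 2L] <= ntip
    out[tree$edge[tip_edges, 2L]] <- tree$edge.length[tip_edges]
  }
  stats::setNames(out, tree$tip.label)
}

# heights above the tips for an ultrametric tree (tips at 0)
node_heights <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth) - depth
  tip_h <- h[seq_len(ape::Ntip(tree))]
  if (diff(range(tip_h)) > tol * max(1, max(depth))) {
    stop("tree is not ultrametric")
  }
  h
}
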