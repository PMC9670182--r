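# Independent brute-force oracles used to cross-check the package's
# quartet, restriction and concordance machinery. These deliberately use
# different primitives (keep.tip + cherry detection, ape::prop.part) than
# the implementation under test.

# topology code of a 4-taxon subset q (sorted): 1 = q1q2|q3q4, 2 = q1q3|q2q4,
# 3 = q1q4|q2q3, 0 = unresolved, NA = taxon absent
oracle_quartet_topology <- function(tree, q) {
  q <- sort(q)
  if (!all(q %in% tree$tip.label)) return(NA_integer_)
  tr <- ape::unroot(ape::keep.tip(tree, q))
  pairing <- NULL
  for (nd in unique(tr$edge[, 1])) {
    ch <- tr$edge[tr$edge[, 1] == nd, 2]
    if (length(ch) == 2 && all(ch <= 4)) {
      pairing <- sort(tr$tip.label[ch])
      break
    }
  }
  if (is.null(pairing)) return(0L)
  if (setequal(pairing, q[c(1, 2)]) || setequal(pairing, q[c(3, 4)])) return(1L)
  if (setequal(pairing, q[c(1, 3)]) || setequal(pairing, q[c(2, 4)])) return(2L)
  3L
}

# quartet set of a tree on a taxon subset, as a named integer vector
oracle_quartet_set <- function(tree, taxa = sort(tree$tip.label)) {
  taxa <- sort(taxa)
  combs <- utils::combn(taxa, 4)
  topo <- apply(combs, 2, function(q) oracle_quartet_topology(tree, q))
  names(topo) <- apply(combs, 2, paste, collapse = "|")
  topo
}

oracle_quartet_score <- function(candidate, gene_trees) {
  taxa <- sort(candidate$tip.label)
  combs <- utils::combn(taxa, 4)
  total <- 0L
  for (k in seq_len(ncol(combs))) {
    q <- combs[, k]
    ct <- oracle_quartet_topology(candidate, q)
    if (is.na(ct) || ct == 0L) next
    for (g in gene_trees) {
      gt <- oracle_quartet_topology(g, q)
      if (!is.na(gt) && gt == ct) total <- total + 1L
    }
  }
  total
}

# per-(tree, clade) classifier built on ape::prop.part
oracle_classify <- function(gene_tree, ref_clade, ref_taxa) {
  shared <- intersect(gene_tree$tip.label, ref_taxa)
  cp <- intersect(ref_clade, shared)
  if (length(cp) < 2 || length(setdiff(shared, cp)) < 1) {
    return("uninformative")
  }
  g <- ape::keep.tip(gene_tree, shared)
  pp <- ape::prop.part(g)
  labs <- attr(pp, "labels")
  sets <- lapply(pp, function(i) labs[i])
  has_conflict <- FALSE
  for (s in sets) {
    if (setequal(s, cp)) return("concordant")
    ov <- length(intersect(s, cp))
    if (ov > 0 && ov < length(cp) && ov < length(s)) has_conflict <- TRUE
  }
  if (has_conflict) "conflicting" else "uninformative"
}

# random rooted tree whose tips look like species__gene labels
random_gene_family_tree <- function(taxa, n_extra_copies = 0) {
  labs <- paste0(taxa, "__g", seq_along(taxa))
  if (n_extra_copies > 0) {
    extra <- sample(taxa, n_extra_copies, replace = TRUE)
    labs <- c(labs, paste0(extra, "__x", seq_len(n_extra_copies)))
  }
  ape::rtree(length(labs), tip.label = sample(labs))
}

# a small random MUL dataset: a rooted reference over MUL-labeled taxa and
# gene trees over random taxon subsets
random_mul_dataset <- function(n_taxa = 7, n_trees = 6) {
  taxa <- c(paste0("t", seq_len(n_taxa - 2)), "A-H", "B-H")
  ref <- ape::rtree(length(taxa), tip.label = sample(taxa))
  gene_trees <- lapply(seq_len(n_trees), function(i) {
    keep <- sample(taxa, sample(4:length(taxa), 1))
    ape::rtree(length(keep), tip.label = sample(keep))
  })
  class(gene_trees) <- "multiPhylo"
  list(ref = ref, gene_trees = gene_trees, taxa = taxa)
}

two_hybrid_toy <- function() {
  ape::read.tree(
    text = "(((mid__a1,(col__x1,col__x2)),((wbg__b1,cae__y1),mid__a2)),amb__z1);")
}

two_hybrid_hypotheses <- function() {
  list(hybrid_hypothesis("mid", "col", "cae"),
       hybrid_hypothesis("wbg", "col", "cae"))
}

# topology equality for rooted trees (ignores rotation and branch lengths)
same_topology <- function(a, b) {
  isTRUE(all.equal(a, b, use.edge.length = FALSE, use.tip.label = TRUE))
}

# unrooted topology equality via Robinson-Foulds distance
same_unrooted <- function(a, b) {
  phangorn::RF.dist(ape::unroot(a), ape::unroot(b)) == 0
}
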