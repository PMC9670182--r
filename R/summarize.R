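# Quartet machinery ----------------------------------------------------------
#
# The induced topology of a 4-taxon subset {a,b,c,d} (a<b<c<d) is encoded as
#   1 = ab|cd, 2 = ac|bd, 3 = ad|bc, 0 = unresolved (polytomy).
# With unit branch lengths the topology is the pairing with the strictly
# smallest sum of path distances (four-point condition); ties mean the
# quartet crosses a polytomy.

# pairwise path distances with every edge set to length 1
unit_dist <- function(tree) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  stats::cophenetic(tree)
}

# all 4-subsets of a taxon vector, as a 4 x K index matrix over sort(taxa)
quartet_subsets <- function(taxa) {
  taxa <- sort(unique(taxa))
  if (length(taxa) < 4L) {
    return(structure(matrix(integer(0), nrow = 4L), taxa = taxa))
  }
  structure(utils::combn(length(taxa), 4L), taxa = taxa)
}

# topology code of each subset on one tree; NA when a taxon is absent
quartet_topologies <- function(tree, subsets) {
  taxa <- attr(subsets, "taxa")
  K <- ncol(subsets)
  out <- rep(NA_integer_, K)
  if (!K) return(out)
  present <- taxa %in% tree$tip.label
  ok <- present[subsets[1L, ]] & present[subsets[2L, ]] &
    present[subsets[3L, ]] & present[subsets[4L, ]]
  if (!any(ok)) return(out)
  d <- unit_dist(tree)
  pos <- match(taxa, rownames(d))
  a <- pos[subsets[1L, ok]]; b <- pos[subsets[2L, ok]]
  c_ <- pos[subsets[3L, ok]]; d_ <- pos[subsets[4L, ok]]
  s1 <- d[cbind(a, b)] + d[cbind(c_, d_)]
  s2 <- d[cbind(a, c_)] + d[cbind(b, d_)]
  s3 <- d[cbind(a, d_)] + d[cbind(b, c_)]
  m <- pmin(s1, s2, s3)
  topo <- integer(sum(ok))
  tie <- (abs(s1 - m) < 1e-9) + (abs(s2 - m) < 1e-9) + (abs(s3 - m) < 1e-9)
  topo[tie > 1L] <- 0L
  single <- tie == 1L
  topo[single & abs(s1 - m) < 1e-9] <- 1L
  topo[single & abs(s2 - m) < 1e-9] <- 2L
  topo[single & abs(s3 - m) < 1e-9] <- 3L
  out[ok] <- topo
  out
}

#' Tally quartet topologies across gene trees
#'
#' For each 4-taxon subset of `taxa`, counts how many gene trees induce each
#' of the three unrooted topologies. Subsets crossing a polytomy or missing a
#' taxon in a gene tree are not counted for that tree.
#'
#' @param gene_trees `multiPhylo` (or list) of trees; MUL labels are distinct
#'   taxa.
#' @param taxa taxon set to tally over (default: union of gene-tree taxa).
#' @return list with `subsets` (4 x K index matrix with a `taxa` attribute)
#'   and `counts` (K x 3 integer matrix).
#' @export
quartet_tally <- function(gene_trees, taxa = NULL) {
  if (inherits(gene_trees, "phylo")) gene_trees <- c(gene_trees)
  if (is.null(taxa)) {
    taxa <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  }
  subsets <- quartet_subsets(taxa)
  counts <- matrix(0L, ncol(subsets), 3L)
  for (g in gene_trees) {
    topo <- quartet_topologies(g, subsets)
    hit <- !is.na(topo) & topo > 0L
    if (any(hit)) {
      idx <- cbind(which(hit), topo[hit])
      counts[idx] <- counts[idx] + 1L
    }
  }
  list(subsets = subsets, counts = counts)
}

#' Quartet score of a candidate species tree
#'
#' The number of (gene tree, 4-subset) pairs whose induced quartet topology
#' equals the candidate's.
#'
#' @param candidate an (un)rooted `phylo`; its taxa must be a subset of the
#'   union of gene-tree taxa.
#' @param gene_trees `multiPhylo` (or list) of gene trees, or a precomputed
#'   [quartet_tally()] over the candidate's taxa.
#' @return integer score.
#' @export
quartet_score <- function(candidate, gene_trees) {
  tal <- if (is.list(gene_trees) && !is.null(gene_trees$subsets))
    gene_trees else quartet_tally(gene_trees, taxa = candidate$tip.label)
  score_from_tally(candidate, tal)
}

score_from_tally <- function(candidate, tal) {
  topo <- quartet_topologies(candidate, tal$subsets)
  hit <- !is.na(topo) & topo > 0L
  if (!any(hit)) return(0L)
  sum(tal$counts[cbind(which(hit), topo[hit])])
}

# quartet-mismatch distance matrix between taxa, from a tally:
# d(i,j) = fraction of resolved gene quartets containing i and j that do NOT
# place i and j on the same side
quartet_mismatch_dist <- function(tal) {
  taxa <- attr(tal$subsets, "taxa")
  n <- length(taxa)
  mism <- tot <- matrix(0, n, n, dimnames = list(taxa, taxa))
  K <- ncol(tal$subsets)
  rs <- rowSums(tal$counts)
  for (k in seq_len(K)) {
    if (!rs[[k]]) next
    q <- tal$subsets[, k]
    cnt <- tal$counts[k, ]
    # pairing 1 = q1q2|q3q4, 2 = q1q3|q2q4, 3 = q1q4|q2q3
    pairs <- list(c(1L, 2L), c(3L, 4L), c(1L, 3L), c(2L, 4L),
                  c(1L, 4L), c(2L, 3L))
    topo_of_pair <- c(1L, 1L, 2L, 2L, 3L, 3L)
    for (p in seq_along(pairs)) {
      i <- q[pairs[[p]][1L]]; j <- q[pairs[[p]][2L]]
      tot[i, j] <- tot[i, j] + rs[[k]]
      mism[i, j] <- mism[i, j] + rs[[k]] - cnt[[topo_of_pair[[p]]]]
    }
  }
  d <- ifelse(tot > 0, mism / tot, 0.5)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Infer a summary species tree by quartet-score maximization
#'
#' The coalescent-summary step: combines (MUL-labeled) gene trees into a
#' single unrooted species tree maximizing the quartet score. Exact mode
#' enumerates all unrooted topologies (feasible up to 8 taxa, `(2n-5)!!`
#' trees, in the fixed `phangorn::allTrees` order; ties are broken by the
#' first maximizer and reported). Heuristic mode starts from neighbor joining
#' on quartet-mismatch distances and hill-climbs by nearest-neighbor
#' interchange to a local optimum. Each internal branch is annotated with the
#' fraction of resolved gene-tree quartets spanning it that agree with it.
#'
#' @param gene_trees `multiPhylo` (or list) of gene trees.
#' @param mode `"auto"` (exact up to 8 taxa, else heuristic), `"exact"` or
#'   `"heuristic"`.
#' @param max_iter maximum NNI hill-climbing sweeps.
#' @return list with `tree` (unrooted `phylo`, branch agreement fractions as
#'   node labels), `score`, `mode`, `tie` (logical: exact maximizer not
#'   unique), `branch_agreement` (data.frame) and `note`.
#' @export
infer_summary_tree <- function(gene_trees, mode = c("auto", "exact",
                                                    "heuristic"),
                               max_iter = 100L) {
  mode <- match.arg(mode)
  if (inherits(gene_trees, "phylo")) gene_trees <- c(gene_trees)
  if (!length(gene_trees)) stop("at least one gene tree is required")
  taxa <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  if (length(taxa) < 4L) {
    star <- ape::stree(length(taxa), type = "star", tip.label = taxa)
    return(list(tree = star, score = 0L, mode = "degenerate", tie = FALSE,
                branch_agreement = NULL,
                note = "fewer than 4 taxa; returning a star tree"))
  }
  tal <- quartet_tally(gene_trees, taxa = taxa)
  if (mode == "auto") mode <- if (length(taxa) <= 8L) "exact" else "heuristic"
  tie <- FALSE
  if (mode == "exact") {
    if (length(taxa) > 8L) {
      stop("exact mode enumerates all unrooted topologies and requires <= 8 ",
           "taxa; use heuristic mode")
    }
    cands <- phangorn::allTrees(length(taxa), rooted = FALSE,
                                tip.label = taxa)
    scores <- vapply(cands, score_from_tally, numeric(1L), tal = tal)
    best <- which.max(scores)
    tie <- sum(scores == scores[[best]]) > 1L
    tree <- cands[[best]]
    score <- scores[[best]]
  } else {
    d <- quartet_mismatch_dist(tal)
    tree <- ape::unroot(ape::nj(stats::as.dist(d)))
    score <- score_from_tally(tree, tal)
    for (it in seq_len(max_iter)) {
      nbrs <- phangorn::nni(tree)
      nscores <- vapply(nbrs, score_from_tally, numeric(1L), tal = tal)
      if (max(nscores) <= score) break
      pick <- which.max(nscores)
      tree <- nbrs[[pick]]
      score <- nscores[[pick]]
    }
  }
  ba <- branch_agreement(tree, tal)
  tree <- annotate_agreement(tree, ba)
  list(tree = tree, score = score, mode = mode, tie = tie,
       branch_agreement = ba, note = if (tie)
         "multiple topologies attain the maximum score; first reported"
       else NA_character_)
}

# per internal branch: fraction of resolved gene quartets spanning the
# branch (2 taxa on each side) that agree with the split
branch_agreement <- function(tree, tal) {
  taxa <- attr(tal$subsets, "taxa")
  ntip <- ape::Ntip(tree)
  internal <- which(tree$edge[, 2L] > ntip)
  if (!length(internal)) return(NULL)
  rs <- rowSums(tal$counts)
  rows <- lapply(internal, function(e) {
    node <- tree$edge[e, 2L]
    side <- taxa %in% tips_below(tree, node)
    ss <- side[tal$subsets[1L, ]] + side[tal$subsets[2L, ]] +
      side[tal$subsets[3L, ]] + side[tal$subsets[4L, ]]
    span <- which(ss == 2L)
    if (!length(span)) {
      return(data.frame(node = node, agree = 0, resolved = 0,
                        fraction = NA_real_))
    }
    # agreeing pairing groups the two same-side taxa together
    s1 <- side[tal$subsets[1L, span]]
    s2 <- side[tal$subsets[2L, span]]
    s3 <- side[tal$subsets[3L, span]]
    topo <- ifelse(s1 & s2 | !s1 & !s2, 1L, ifelse(s1 & s3 | s2 & !s3, 2L, 3L))
    agree <- sum(tal$counts[cbind(span, topo)])
    resolved <- sum(rs[span])
    data.frame(node = node, agree = agree, resolved = resolved,
               fraction = if (resolved) agree / resolved else NA_real_)
  })
  do.call(rbind, rows)
}

annotate_agreement <- function(tree, ba) {
  ntip <- ape::Ntip(tree)
  lab <- rep("", tree$Nnode)
  if (!is.null(ba)) {
    lab[ba$node - ntip] <- ifelse(is.na(ba$fraction), "",
                                  sprintf("%.3f", ba$fraction))
  }
  tree$node.label <- lab
  tree
}
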