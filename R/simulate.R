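# Lightweight nested-list tree representation used by the simulator.
# A node is list(label = <tip label or NULL>, len = <branch to parent>,
# children = <list of nodes or NULL>). The root has len 0.

phylo_to_plist <- function(tree) {
  kids <- node_children(tree)
  ntip <- ape::Ntip(tree)
  len_by_child <- rep(0, ntip + tree$Nnode)
  if (!is.null(tree$edge.length)) {
    len_by_child[tree$edge[, 2L]] <- tree$edge.length
  }
  rec <- function(node) {
    if (node <= ntip) {
      list(label = tree$tip.label[[node]], len = len_by_child[[node]],
           children = NULL)
    } else {
      list(label = NULL, len = len_by_child[[node]],
           children = lapply(kids[[node]], rec))
    }
  }
  rec(ntip + 1L)
}

plist_ntips <- function(pl) {
  if (is.null(pl$children)) return(1L)
  sum(vapply(pl$children, plist_ntips, integer(1L)))
}

plist_to_phylo <- function(pl) {
  n_tip <- plist_ntips(pl)
  env <- new.env()
  env$tip <- 0L
  env$int <- n_tip
  env$lab <- character(n_tip)
  env$from <- env$to <- integer(0)
  env$len <- numeric(0)
  build <- function(x) {
    if (is.null(x$children)) {
      env$tip <- env$tip + 1L
      env$lab[[env$tip]] <- x$label
      return(env$tip)
    }
    env$int <- env$int + 1L
    id <- env$int
    for (ch in x$children) {
      cid <- build(ch)
      env$from <- c(env$from, id)
      env$to <- c(env$to, cid)
      env$len <- c(env$len, ch$len)
    }
    id
  }
  build(pl)
  tr <- list(edge = cbind(env$from, env$to), edge.length = env$len,
             tip.label = env$lab, Nnode = env$int - n_tip)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

# paths (integer child-index vectors) to every non-root node, preorder
plist_paths <- function(pl, prefix = integer(0)) {
  out <- list()
  if (!is.null(pl$children)) {
    for (i in seq_along(pl$children)) {
      out <- c(out, list(c(prefix, i)),
               plist_paths(pl$children[[i]], c(prefix, i)))
    }
  }
  out
}

plist_get <- function(pl, path) {
  for (i in path) pl <- pl$children[[i]]
  pl
}

plist_replace <- function(pl, path, value) {
  if (!length(path)) return(value)
  pl$children[[path[[1L]]]] <-
    plist_replace(pl$children[[path[[1L]]]], path[-1L], value)
  pl
}

plist_tips <- function(pl) {
  if (is.null(pl$children)) return(pl$label)
  unlist(lapply(pl$children, plist_tips))
}

plist_find_tip <- function(pl, label, prefix = integer(0)) {
  if (is.null(pl$children)) {
    if (identical(pl$label, label)) return(prefix) else return(NULL)
  }
  for (i in seq_along(pl$children)) {
    hit <- plist_find_tip(pl$children[[i]], label, c(prefix, i))
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' An allopolyploidy event for the simulator
#'
#' Both subgenomes of the hybrid diverge from their respective donor lineages
#' at `t_hyb` coalescent units before the present.
#'
#' @param hybrid name of the new hybrid taxon.
#' @param donor_A,donor_B extant leaf taxa donating the A and B subgenomes.
#' @param t_hyb time of the hybridization, in coalescent units (>= 0).
#' @param prefix_A,prefix_B label prefixes for the two subgenome tips.
#' @return object of class `allopolyploidy_event`.
#' @export
allopolyploidy_event <- function(hybrid, donor_A, donor_B, t_hyb,
                                 prefix_A = "A-", prefix_B = "B-") {
  stopifnot(is.character(hybrid), length(hybrid) == 1L,
            is.numeric(t_hyb), t_hyb >= 0, donor_A != donor_B)
  structure(list(hybrid = hybrid, donor_A = donor_A, donor_B = donor_B,
                 t_hyb = t_hyb, prefix_A = prefix_A, prefix_B = prefix_B),
            class = "allopolyploidy_event")
}

# attach a new tip at height t on the path from `donor` to the root;
# `new_tips` are labels created by earlier attachments (they do not bound t)
attach_at_height <- function(pl, donor, t, new_label, new_tips = character(0)) {
  path <- plist_find_tip(pl, donor)
  if (is.null(path)) stop("donor tip not found: ", donor)
  # heights along the path, tip at height 0 (ultrametric species tree)
  nodes <- lapply(seq_along(path), function(k) plist_get(pl, path[seq_len(k)]))
  lens <- vapply(nodes, `[[`, numeric(1L), "len")
  heights <- rev(cumsum(rev(lens))) - lens  # height of each path node's BOTTOM
  # height of top of edge above path node k is heights[k] + lens[k]
  tip_k <- length(path)
  # bound: height of the lowest ancestor holding a pre-existing non-donor tip
  bound <- Inf
  for (k in rev(seq_len(length(path)))) {
    if (k == tip_k) next
    other <- setdiff(plist_tips(nodes[[k]]), c(donor, new_tips))
    if (length(other)) { bound <- heights[[k]]; break }
  }
  if (t >= bound) {
    stop("t_hyb (", t, ") is older than the donor edge (parent node at ",
         bound, ")")
  }
  for (k in rev(seq_len(length(path)))) {
    bottom <- heights[[k]]
    top <- bottom + lens[[k]]
    if (t >= bottom && t <= top) {
      sub <- nodes[[k]]
      sub$len <- t - bottom
      newnode <- list(label = NULL, len = top - t,
                      children = list(sub, list(label = new_label, len = t,
                                                children = NULL)))
      return(plist_replace(pl, path[seq_len(k)], newnode))
    }
  }
  stop("t_hyb (", t, ") exceeds the height of the tree root path")
}

#' Build a MUL species tree by applying allopolyploidy events
#'
#' Each event adds two tips: `A-hybrid` attached at `t_hyb` on the A donor's
#' lineage and `B-hybrid` at `t_hyb` on the B donor's; all other structure is
#' unchanged. Events are applied in order; the species tree must be
#' ultrametric with branch lengths in coalescent units.
#'
#' @param tree ultrametric rooted `phylo` species tree.
#' @param events an [allopolyploidy_event()] or list thereof.
#' @return the MUL species `phylo` (two more tips per event).
#' @export
build_mul_species_tree <- function(tree, events) {
  if (inherits(events, "allopolyploidy_event")) events <- list(events)
  node_heights(tree)  # validates ultrametricity
  pl <- phylo_to_plist(tree)
  new_tips <- character(0)
  for (ev in events) {
    stopifnot(inherits(ev, "allopolyploidy_event"))
    a_tip <- paste0(ev$prefix_A, ev$hybrid)
    b_tip <- paste0(ev$prefix_B, ev$hybrid)
    pl <- attach_at_height(pl, ev$donor_A, ev$t_hyb, a_tip, new_tips)
    pl <- attach_at_height(pl, ev$donor_B, ev$t_hyb, b_tip, new_tips)
    new_tips <- c(new_tips, a_tip, b_tip)
  }
  plist_to_phylo(pl)
}

# multispecies-coalescent simulation on a MUL species tree; one lineage per
# tip, Kingman coalescent (pairwise rate 1) within each branch; consumes the
# current RNG stream
msc_sim <- function(mul_tree, tip_labels) {
  ntip <- ape::Ntip(mul_tree)
  kids <- node_children(mul_tree)
  h <- node_heights(mul_tree)
  coalesce_in <- function(lins, bottom, top) {
    k <- length(lins)
    t_now <- bottom
    while (k >= 2L) {
      t_now <- t_now + stats::rexp(1L, k * (k - 1L) / 2)
      if (t_now >= top) break
      pair <- sort(sample.int(k, 2L))
      x <- lins[[pair[[1L]]]]; y <- lins[[pair[[2L]]]]
      x$pl$len <- t_now - x$h
      y$pl$len <- t_now - y$h
      merged <- list(pl = list(label = NULL, len = 0,
                               children = list(x$pl, y$pl)), h = t_now)
      lins <- c(lins[-pair], list(merged))
      k <- k - 1L
    }
    lins
  }
  rec <- function(node, top) {
    if (node <= ntip) {
      lins <- list(list(pl = list(label = tip_labels[[node]], len = 0,
                                  children = NULL), h = 0))
      return(coalesce_in(lins, 0, top))
    }
    lins <- unlist(lapply(kids[[node]], rec, top = h[[node]]),
                   recursive = FALSE)
    coalesce_in(lins, h[[node]], top)
  }
  root <- ntip + 1L
  lins <- rec(root, Inf)
  stopifnot(length(lins) == 1L)
  plist_to_phylo(lins[[1L]]$pl)
}

#' Simulate one gene tree under the multispecies coalescent
#'
#' One gene lineage is sampled per MUL-tree tip; the two subgenome tips of a
#' hybrid (`A-H`, `B-H`) each contribute one copy, emitted as tips of taxon
#' `H` with distinct gene ids. Within each branch lineages coalesce as a
#' Kingman coalescent (pairwise rate 1 per coalescent unit); the remaining
#' lineages merge above the root. The same seed yields the identical tree.
#'
#' @param mul_tree ultrametric `phylo`, branch lengths in coalescent units,
#'   possibly with `A-`/`B-` prefixed hybrid tips.
#' @param seed integer seed.
#' @param gene_index index used to form gene ids (`og<index>_s<k>`).
#' @param mul_prefixes subgenome prefixes recognized on tips.
#' @return ultrametric `phylo` gene tree with tips `species__geneid` and a
#'   `truth` attribute (data.frame: tip, mul_tip, species, subgenome).
#' @export
simulate_gene_tree <- function(mul_tree, seed, gene_index = 1L,
                               mul_prefixes = c(A = "A-", B = "B-")) {
  set.seed(seed)
  simulate_gene_tree_impl(mul_tree, gene_index, mul_prefixes)
}

simulate_gene_tree_impl <- function(mul_tree, gene_index = 1L,
                                    mul_prefixes = c(A = "A-", B = "B-")) {
  mul_tips <- mul_tree$tip.label
  sub <- rep(NA_character_, length(mul_tips))
  species <- mul_tips
  for (lab in names(mul_prefixes)) {
    pre <- mul_prefixes[[lab]]
    hit <- startsWith(mul_tips, pre)
    sub[hit] <- lab
    species[hit] <- substring(mul_tips[hit], nchar(pre) + 1L)
  }
  gid <- sprintf("og%d_s%d", gene_index, seq_along(mul_tips))
  tip_labels <- paste0(species, "__", gid)
  gt <- msc_sim(mul_tree, tip_labels)
  attr(gt, "truth") <- data.frame(tip = tip_labels, mul_tip = mul_tips,
                                  species = species, subgenome = sub,
                                  stringsAsFactors = FALSE)
  gt
}

#' Inject random paralog duplications into a gene tree
#'
#' The number of duplications is Poisson(`dup_rate`); each picks a uniform
#' random edge and grafts a copy of the subtree below it as its sister, at the
#' midpoint of the edge, with fresh gene ids (`<geneid>.d<k>`). Restricting
#' the output to the original tips recovers the original tree.
#'
#' @param gene_tree a `phylo` with `species__geneid` tip labels.
#' @param dup_rate expected number of duplications (>= 0).
#' @param seed integer seed.
#' @return `phylo` with a `paralog_truth` attribute (data.frame: tip,
#'   parent_tip) mapping each injected copy to the tip it was copied from.
#' @export
inject_paralogs <- function(gene_tree, dup_rate, seed) {
  set.seed(seed)
  inject_paralogs_impl(gene_tree, dup_rate)
}

inject_paralogs_impl <- function(gene_tree, dup_rate) {
  stopifnot(dup_rate >= 0)
  n_dup <- stats::rpois(1L, dup_rate)
  truth <- data.frame(tip = character(0), parent_tip = character(0),
                      stringsAsFactors = FALSE)
  if (n_dup == 0L) {
    attr(gene_tree, "paralog_truth") <- truth
    return(gene_tree)
  }
  pl <- phylo_to_plist(gene_tree)
  relabel <- function(x, k) {
    if (is.null(x$children)) {
      x$label <- paste0(x$label, ".d", k)
      return(x)
    }
    x$children <- lapply(x$children, relabel, k = k)
    x
  }
  for (k in seq_len(n_dup)) {
    paths <- plist_paths(pl)
    pick <- paths[[sample.int(length(paths), 1L)]]
    sub <- plist_get(pl, pick)
    half <- sub$len / 2
    orig <- sub; orig$len <- half
    copy <- relabel(sub, k); copy$len <- half
    truth <- rbind(truth, data.frame(tip = plist_tips(copy),
                                     parent_tip = plist_tips(orig),
                                     stringsAsFactors = FALSE))
    newnode <- list(label = NULL, len = half, children = list(orig, copy))
    pl <- plist_replace(pl, pick, newnode)
  }
  out <- plist_to_phylo(pl)
  attr(out, "paralog_truth") <- truth
  out
}

# deterministic 32-bit sub-seed for gene i, independent of n_genes
gene_seed <- function(seed, i) {
  ((as.numeric(seed) %% 1000003) * 2017 + i * 7919) %% 2147483647
}

#' Configuration for a simulated multi-copy gene family dataset
#'
#' @param species_tree ultrametric rooted `phylo`, branch lengths in
#'   coalescent units.
#' @param events an [allopolyploidy_event()] or list thereof.
#' @param n_genes number of gene family trees to simulate.
#' @param dup_rate expected paralog duplications per gene tree.
#' @param missing_rate per-tip dropout probability (the outgroup is never
#'   dropped).
#' @param length_mean,length_sd mean and sd (bp) of simulated sequence
#'   lengths.
#' @param seed integer master seed; each gene uses a fixed sub-stream so
#'   per-gene results do not depend on `n_genes`.
#' @param outgroup outgroup taxa, protected from dropout.
#' @param bias_truth_longest make injected paralog/isoform copies shorter than
#'   their source copy, so that longest-copy pruning recovers the truth.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(species_tree, events, n_genes, dup_rate = 0,
                       missing_rate = 0, length_mean = 900, length_sd = 200,
                       seed = 1L, outgroup = character(),
                       bias_truth_longest = TRUE) {
  if (inherits(events, "allopolyploidy_event")) events <- list(events)
  stopifnot(inherits(species_tree, "phylo"), n_genes >= 0, dup_rate >= 0,
            missing_rate >= 0, missing_rate < 1, length_mean > 0,
            length_sd >= 0)
  for (ev in events) stopifnot(inherits(ev, "allopolyploidy_event"))
  structure(list(species_tree = species_tree, events = events,
                 n_genes = as.integer(n_genes), dup_rate = dup_rate,
                 missing_rate = missing_rate, length_mean = length_mean,
                 length_sd = length_sd, seed = as.integer(seed),
                 outgroup = outgroup,
                 bias_truth_longest = isTRUE(bias_truth_longest)),
            class = "sim_config")
}

#' Simulate a multi-copy gene family dataset with truth records
#'
#' For each gene: a coalescent gene tree on the MUL species tree, paralog
#' injection, per-tip dropout (outgroup protected), and sequence-length
#' assignment (injected copies biased shorter when
#' `bias_truth_longest`). Identical configurations yield identical output.
#'
#' @param config a [sim_config()].
#' @return list with `trees` (named `multiPhylo`), `lengths` (named numeric,
#'   gene id -> bp), `truth` (list: `mul_tree`, `events`, per-gene `genes`
#'   data.frames with tip/species/subgenome/parent assignments) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mul <- build_mul_species_tree(config$species_tree, config$events)
  trees <- vector("list", config$n_genes)
  lengths <- numeric(0)
  genes <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    set.seed(gene_seed(config$seed, i))
    gt <- simulate_gene_tree_impl(mul, gene_index = i)
    truth <- attr(gt, "truth")
    gt2 <- inject_paralogs_impl(gt, config$dup_rate)
    ptruth <- attr(gt2, "paralog_truth")
    info <- parse_tip_labels(gt2$tip.label)
    # lengths before dropout so copies can inherit from their source
    len <- round(stats::rnorm(length(gt2$tip.label), config$length_mean,
                              config$length_sd))
    len <- pmax(len, 100)
    names(len) <- info$gene_id
    if (config$bias_truth_longest && nrow(ptruth)) {
      src_gid <- parse_tip_labels(ptruth$parent_tip)$gene_id
      cp_gid <- parse_tip_labels(ptruth$tip)$gene_id
      len[cp_gid] <- pmax(100, round(len[src_gid] *
                                       stats::runif(length(cp_gid), 0.4, 0.9)))
    }
    # per-tip dropout; the outgroup is never dropped
    protected <- info$species %in% config$outgroup
    drop <- stats::runif(length(gt2$tip.label)) < config$missing_rate &
      !protected
    if (sum(!drop) < 2L) drop[] <- FALSE
    kept <- gt2$tip.label[!drop]
    gt3 <- if (length(kept) < length(gt2$tip.label))
      restrict_tree(gt2, kept) else gt2
    rec <- data.frame(tip = gt2$tip.label, species = info$species,
                      gene_id = info$gene_id, stringsAsFactors = FALSE)
    rec$subgenome <- truth$subgenome[match(rec$tip, truth$tip)]
    rec$parent_tip <- ptruth$parent_tip[match(rec$tip, ptruth$tip)]
    # injected copies inherit the subgenome of their source copy
    has_parent <- !is.na(rec$parent_tip)
    rec$subgenome[has_parent] <-
      truth$subgenome[match(rec$parent_tip[has_parent], truth$tip)]
    rec$is_paralog <- has_parent
    rec$dropped <- drop
    trees[[i]] <- gt3
    lengths <- c(lengths, len)
    genes[[i]] <- rec
  }
  names(trees) <- sprintf("og%d", seq_len(config$n_genes))
  names(genes) <- names(trees)
  class(trees) <- "multiPhylo"
  list(trees = trees, lengths = lengths,
       truth = list(mul_tree = mul, events = config$events, genes = genes),
       config = config)
}

#' Write a simulated dataset to disk
#'
#' Trees as a multi-tree newick file, lengths as TSV, truth as JSON.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sim_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_trees <- file.path(dir, "gene_trees.nwk")
  p_len <- file.path(dir, "lengths.tsv")
  p_truth <- file.path(dir, "truth.json")
  write_gene_trees(sim$trees, p_trees)
  utils::write.table(data.frame(gene_id = names(sim$lengths),
                                length = unname(sim$lengths)),
                     p_len, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(mul_tree = ape::write.tree(sim$truth$mul_tree),
                events = lapply(sim$truth$events, unclass),
                genes = sim$truth$genes)
  jsonlite::write_json(truth, p_truth, auto_unbox = TRUE, digits = NA)
  invisible(c(trees = p_trees, lengths = p_len, truth = p_truth))
}

#' The built-in water-lily study scenario
#'
#' An 18-taxon Nymphaeales-like sampling: 15 Nymphaeaceae water lilies, two
#' Cabombaceae, and one outgroup, with two hybrid cultivars formed by
#' allopolyploidy from the *N. colorata* and *N. caerulea* lineages. Internal
#' branches of the species tree are multiples of `units` coalescent units, so
#' `units` directly controls the intensity of incomplete lineage sorting
#' (e.g. `units = 5` is a low-ILS regime, `units = 0.5` a moderate one). The
#' two hybridization events occur at `1 * units` and `2 * units` before
#' present. Also returns the nine taxon groups used for representation
#' filtering, the filtering criteria, and the hybridization hypotheses.
#'
#' @param units coalescent-unit scale of the species-tree branches.
#' @return list with `species_tree`, `events`, `hypotheses`, `groups`,
#'   `criteria`, `outgroup`, `universe`, `hybrids`.
#' @export
waterlily_scenario <- function(units = 5) {
  stopifnot(units > 0)
  u <- function(x) x * units
  nwk <- sprintf(paste0(
    "(((((Nymphaea_mexicana:%g,Nymphaea_tetragona:%g):%g,",
    "((Nymphaea_gigantea_Albert:%g,Nymphaea_gigantea_Hybrid1:%g):%g,",
    "((Nymphaea_colorata:%g,Nymphaea_caerulea:%g):%g,",
    "((Nymphaea_potamophila:%g,(Nymphaea_prolifera:%g,Nymphaea_rubra:%g):%g):%g,",
    "(Victoria_cruziana:%g,Euryale_ferox:%g):%g):%g):%g):%g):%g,",
    "(Nuphar_lutea:%g,Nuphar_advena:%g):%g):%g,",
    "(Cabomba_caroliniana:%g,Brasenia_schreberi:%g):%g):%g,",
    "Amborella_trichopoda:%g);"),
    u(1), u(1), u(5),
    u(1), u(1), u(4),
    u(3), u(3), u(1),
    u(2), u(1), u(1), u(1), u(1),
    u(1), u(1), u(2), u(1), u(1), u(1), u(1),
    u(1), u(1), u(6), u(1),
    u(1), u(1), u(7), u(1),
    u(9))
  tree <- ape::read.tree(text = nwk)
  col <- "Nymphaea_colorata"; cae <- "Nymphaea_caerulea"
  mid <- "Nymphaea_Midnight"; wbg <- "Nymphaea_Woods_blue_goddess"
  events <- list(
    allopolyploidy_event(mid, donor_A = col, donor_B = cae, t_hyb = u(1)),
    allopolyploidy_event(wbg, donor_A = col, donor_B = cae, t_hyb = u(2)))
  hypotheses <- list(
    hybrid_hypothesis(mid, lineage_A = col, lineage_B = cae),
    hybrid_hypothesis(wbg, lineage_A = col, lineage_B = cae))
  groups <- list(
    a = c(mid, col, wbg),
    b = c(wbg, cae, mid),
    c = c("Nymphaea_gigantea_Albert", "Nymphaea_gigantea_Hybrid1"),
    d = c("Nymphaea_mexicana", "Nymphaea_tetragona"),
    e = c("Nymphaea_potamophila", "Nymphaea_prolifera", "Nymphaea_rubra"),
    f = c("Victoria_cruziana", "Euryale_ferox"),
    g = c("Nuphar_lutea", "Nuphar_advena"),
    h = c("Cabomba_caroliniana", "Brasenia_schreberi"),
    i = "Amborella_trichopoda")
  outgroup <- "Amborella_trichopoda"
  universe <- c(tree$tip.label, mid, wbg)
  criteria <- filter_criteria(min_coverage = 0.5, require_outgroup = TRUE,
                              outgroup = outgroup, groups = groups)
  list(species_tree = tree, events = events, hypotheses = hypotheses,
       groups = groups, criteria = criteria, outgroup = outgroup,
       universe = universe, hybrids = c(mid, wbg))
}
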