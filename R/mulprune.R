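#' A hybridization hypothesis: one putative hybrid and two parental lineages
#'
#' @param hybrid taxon name of the putative hybrid (cultivar).
#' @param lineage_A,lineage_B disjoint candidate parental-lineage taxon sets;
#'   the hybrid must not belong to either.
#' @param prefix_A,prefix_B label prefixes attached to the hybrid's kept
#'   copies ("A-" / "B-").
#' @return object of class `hybrid_hypothesis`.
#' @export
hybrid_hypothesis <- function(hybrid, lineage_A, lineage_B,
                              prefix_A = "A-", prefix_B = "B-") {
  stopifnot(is.character(hybrid), length(hybrid) == 1L,
            length(lineage_A) >= 1L, length(lineage_B) >= 1L)
  if (length(intersect(lineage_A, lineage_B))) {
    stop("lineage_A and lineage_B must be disjoint")
  }
  if (hybrid %in% c(lineage_A, lineage_B)) {
    stop("the hybrid cannot belong to a parental lineage")
  }
  structure(list(hybrid = hybrid, lineage_A = lineage_A,
                 lineage_B = lineage_B, prefix_A = prefix_A,
                 prefix_B = prefix_B),
            class = "hybrid_hypothesis")
}

# copy length used for "longest" selection: sequence length when a length
# table is given, else terminal branch length, else 0; used with the
# lexicographic gene-id tie-break
copy_lengths <- function(tree, tips, gene_ids, lengths) {
  if (!is.null(lengths)) {
    len <- unname(lengths[gene_ids])
    len[is.na(len)] <- 0
    return(len)
  }
  term <- terminal_lengths(tree)[tips]
  term[is.na(term)] <- 0
  unname(term)
}

#' Best (longest) copy of a species in a gene family tree
#'
#' If the species' tips are monophyletic, returns the longest copy (by the
#' sequence-length table when given, else by terminal branch length). If they
#' are paraphyletic, the globally longest copy is returned and the result
#' carries a `paraphyletic` attribute. Ties are broken by the
#' lexicographically smallest gene id.
#'
#' @param tree a rooted `phylo`.
#' @param species taxon whose copies are compared.
#' @param lengths optional named numeric vector gene id -> length (bp).
#' @inheritParams parse_tip_labels
#' @return the selected tip label, with attribute `paraphyletic` (logical).
#' @export
best_copy <- function(tree, species, lengths = NULL, delim = "__",
                      mul_prefixes = c(A = "A-", B = "B-"),
                      taxon_map = NULL) {
  info <- parse_tip_labels(tree$tip.label, delim = delim,
                           mul_prefixes = mul_prefixes, taxon_map = taxon_map)
  idx <- which(info$species == species)
  if (!length(idx)) stop("species absent from tree: ", species)
  tips <- tree$tip.label[idx]
  para <- FALSE
  if (length(tips) > 1L) {
    # the species' tips themselves must form a clade (stricter than the
    # taxon-set monophyly used for family constraints)
    sets <- clade_tip_sets(tree, include_root = TRUE)
    para <- !any(vapply(sets, setequal, logical(1L), y = tips))
    if (para) {
      warning("paraphyletic-copies: tips of ", species,
              " are not monophyletic; keeping the globally longest copy")
    }
  }
  len <- copy_lengths(tree, tips, info$gene_id[idx], lengths)
  pick <- order(-len, info$gene_id[idx])[1L]
  structure(tips[[pick]], paraphyletic = para)
}

#' Prune a gene family tree to one best copy per non-hybrid species
#'
#' Every non-hybrid species is reduced to its [best_copy()]; ALL copies of
#' hybrid taxa are retained. The output topology equals
#' `restrict_tree(tree, kept tips)` — no rearrangement is introduced.
#'
#' @param tree a rooted `phylo` (root on the outgroup first).
#' @param hybrids taxa whose copies are all retained.
#' @param lengths optional named numeric vector gene id -> length (bp).
#' @inheritParams parse_tip_labels
#' @return the pruned `phylo`, with attribute `pruned_tips` listing removals.
#' @export
prune_paralogs <- function(tree, hybrids = character(), lengths = NULL,
                           delim = "__", mul_prefixes = c(A = "A-", B = "B-"),
                           taxon_map = NULL) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  info <- parse_tip_labels(tree$tip.label, delim = delim,
                           mul_prefixes = mul_prefixes, taxon_map = taxon_map)
  keep <- character(0)
  for (sp in unique(info$species)) {
    tips <- tree$tip.label[info$species == sp]
    if (sp %in% hybrids || length(tips) == 1L) {
      keep <- c(keep, tips)
    } else {
      keep <- c(keep, as.character(
        best_copy(tree, sp, lengths = lengths, delim = delim,
                  mul_prefixes = mul_prefixes, taxon_map = taxon_map)))
    }
  }
  out <- restrict_tree(tree, keep)
  attr(out, "pruned_tips") <- setdiff(tree$tip.label, keep)
  out
}

#' Assign a hybrid gene copy to a parental lineage
#'
#' Walks rootward from the hybrid tip to the first ancestor whose descendants
#' include at least one NON-hybrid taxon (tips of any hybrid taxon are skipped
#' as witnesses, breaking the circularity of co-occurring hybrids). With `W`
#' the witness taxa: returns `"A"` if `W` lies within `lineage_A`, `"B"` if
#' within `lineage_B`, else `"unassigned"`.
#'
#' @param tree a pruned, rooted `phylo`.
#' @param hybrid_tip tip label of a copy of the hypothesis' hybrid.
#' @param hyp a [hybrid_hypothesis()].
#' @param hybrid_taxa all taxa to treat as hybrids when collecting witnesses
#'   (defaults to the hypothesis' own hybrid).
#' @inheritParams parse_tip_labels
#' @return `"A"`, `"B"` or `"unassigned"`, with attribute `witness` holding
#'   the witness taxon set.
#' @export
assign_parent_lineage <- function(tree, hybrid_tip, hyp,
                                  hybrid_taxa = hyp$hybrid, delim = "__",
                                  mul_prefixes = c(A = "A-", B = "B-"),
                                  taxon_map = NULL) {
  stopifnot(inherits(hyp, "hybrid_hypothesis"))
  info <- parse_tip_labels(tree$tip.label, delim = delim,
                           mul_prefixes = mul_prefixes, taxon_map = taxon_map)
  tip_idx <- match(hybrid_tip, tree$tip.label)
  if (is.na(tip_idx)) stop("tip not in tree: ", hybrid_tip)
  if (!identical(info$species[[tip_idx]], hyp$hybrid)) {
    stop("tip ", hybrid_tip, " does not belong to hybrid ", hyp$hybrid)
  }
  if (all(info$species %in% hybrid_taxa)) {
    stop("tree contains no non-hybrid tip; cannot find witnesses")
  }
  sp_by_tip <- stats::setNames(info$species, tree$tip.label)
  parents <- node_parents(tree)
  node <- parents[[tip_idx]]
  repeat {
    w <- unique(sp_by_tip[tips_below(tree, node)])
    w <- setdiff(w, hybrid_taxa)
    if (length(w)) break
    node <- parents[[node]]
  }
  lab <- if (all(w %in% hyp$lineage_A)) "A" else
    if (all(w %in% hyp$lineage_B)) "B" else "unassigned"
  structure(lab, witness = sort(unname(w)))
}

#' Convert a multi-copy gene family tree to a MUL-labeled single-copy tree
#'
#' The tree is rooted on the outgroup, pruned to one best copy per non-hybrid
#' species ([prune_paralogs()]), and every copy of every hypothesized hybrid
#' is assigned to a parental lineage ([assign_parent_lineage()]). Within each
#' label the longest copy is kept; unassigned copies are dropped. Kept hybrid
#' tips are renamed `prefix + taxon` (e.g. `A-Midnight`); all other tips are
#' renamed to the bare taxon. A hybrid that ends up with fewer than two
#' distinct labels is flagged uninformative (the tree is still returned).
#'
#' @param tree a `phylo` gene family tree.
#' @param hypotheses a [hybrid_hypothesis()] or list thereof.
#' @param outgroup outgroup taxon set used for rooting.
#' @param lengths optional named numeric vector gene id -> length (bp).
#' @param min_support optional numeric; internal edges with support below it
#'   are collapsed to polytomies before assignment.
#' @inheritParams parse_tip_labels
#' @return list with `tree` (the MUL-labeled `phylo`), `log` (a data.frame
#'   recording every removal and assignment) and `flags` (character vector of
#'   uninformative-hybrid flags).
#' @export
mul_convert <- function(tree, hypotheses, outgroup, lengths = NULL,
                        min_support = NULL, delim = "__",
                        mul_prefixes = c(A = "A-", B = "B-"),
                        taxon_map = NULL) {
  if (inherits(hypotheses, "hybrid_hypothesis")) hypotheses <- list(hypotheses)
  popts <- list(delim = delim, mul_prefixes = mul_prefixes,
                taxon_map = taxon_map)
  hybrid_taxa <- vapply(hypotheses, `[[`, character(1L), "hybrid")
  rooted <- do.call(root_on_outgroup, c(list(tree, outgroup), popts))
  if (!is.null(min_support)) rooted <- collapse_low_support(rooted, min_support)
  pruned <- do.call(prune_paralogs,
                    c(list(rooted, hybrids = hybrid_taxa, lengths = lengths),
                      popts))
  info <- do.call(parse_tip_labels, c(list(pruned$tip.label), popts))
  removed <- attr(pruned, "pruned_tips")
  n_rm <- length(removed)
  log <- data.frame(tip = removed,
                    species = if (n_rm)
                      do.call(parse_tip_labels, c(list(removed), popts))$species
                    else character(0),
                    action = rep("pruned_paralog", n_rm),
                    label = rep(NA_character_, n_rm),
                    witness = rep(NA_character_, n_rm),
                    stringsAsFactors = FALSE)
  keep <- pruned$tip.label[!(info$species %in% hybrid_taxa)]
  new_names <- stats::setNames(info$species[!(info$species %in% hybrid_taxa)],
                               keep)
  flags <- character(0)
  add_log <- function(log, tip, species, action, label, witness) {
    rbind(log, data.frame(tip = tip, species = species, action = action,
                          label = label, witness = witness,
                          stringsAsFactors = FALSE))
  }
  for (hyp in hypotheses) {
    copies <- pruned$tip.label[info$species == hyp$hybrid]
    if (!length(copies)) {
      flags <- c(flags, paste0("uninformative for ", hyp$hybrid, ": no copy"))
      next
    }
    calls <- lapply(copies, function(tp) {
      do.call(assign_parent_lineage,
              c(list(pruned, tp, hyp, hybrid_taxa = hybrid_taxa), popts))
    })
    assign <- vapply(calls, as.character, character(1L))
    witnesses <- vapply(calls, function(x)
      paste(attr(x, "witness"), collapse = ","), character(1L))
    gid <- info$gene_id[match(copies, pruned$tip.label)]
    len <- copy_lengths(pruned, copies, gid, lengths)
    kept_labels <- character(0)
    for (lab in c("A", "B")) {
      in_lab <- which(assign == lab)
      if (!length(in_lab)) next
      pick <- in_lab[order(-len[in_lab], gid[in_lab])[1L]]
      keep <- c(keep, copies[[pick]])
      prefix <- if (lab == "A") hyp$prefix_A else hyp$prefix_B
      new_names[copies[[pick]]] <- paste0(prefix, hyp$hybrid)
      kept_labels <- c(kept_labels, lab)
      log <- add_log(log, copies[[pick]], hyp$hybrid, "labeled", lab,
                     witnesses[[pick]])
      for (drop in setdiff(in_lab, pick)) {
        log <- add_log(log, copies[[drop]], hyp$hybrid,
                       "dropped_duplicate_label", lab, witnesses[[drop]])
      }
    }
    for (drop in which(assign == "unassigned")) {
      log <- add_log(log, copies[[drop]], hyp$hybrid, "dropped_unassigned",
                     NA_character_, witnesses[[drop]])
    }
    if (length(kept_labels) < 2L) {
      flags <- c(flags, paste0("uninformative for ", hyp$hybrid, ": labels {",
                               paste(kept_labels, collapse = ","), "}"))
    }
  }
  out <- restrict_tree(pruned, keep)
  out$tip.label <- unname(new_names[out$tip.label])
  list(tree = out, log = log, flags = flags)
}

#' Collapse weakly supported internal edges to polytomies
#'
#' Internal node labels are read as numeric support values; edges subtending a
#' node with support below `min_support` are contracted.
#'
#' @param tree a `phylo` with numeric node labels.
#' @param min_support support threshold.
#' @return a `phylo`, possibly with polytomies.
#' @export
collapse_low_support <- function(tree, min_support) {
  if (is.null(tree$node.label)) return(tree)
  supp <- suppressWarnings(as.numeric(tree$node.label))
  ntip <- ape::Ntip(tree)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  weak_nodes <- ntip + which(!is.na(supp) & supp < min_support)
  weak_nodes <- setdiff(weak_nodes, ntip + 1L)   # never collapse the root
  if (!length(weak_nodes)) return(tree)
  target <- tree$edge[, 2L] %in% weak_nodes
  tree$edge.length[target] <- 0
  ape::di2multi(tree, tol = 1e-12)
}
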