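#' Classify a gene tree against one reference clade
#'
#' Both trees are restricted to their shared taxa `S` (MUL labels such as
#' `A-Midnight` are treated as distinct taxa). With `C' = ref_clade` on `S`:
#' the pair is uninformative when fewer than two clade members or no
#' non-member survive; concordant when some clade of the restricted gene tree
#' equals `C'`; conflicting when some clade properly overlaps `C'` (nonempty
#' intersection, neither containment). An unresolved gene tree that neither
#' matches nor properly overlaps is uninformative — polytomies are soft.
#'
#' @param gene_tree rooted `phylo` whose tips are (MUL-labeled) taxa; must be
#'   rooted on the outgroup shared with the reference.
#' @param ref_clade character vector, a clade of the reference tree.
#' @param ref_taxa character vector, all taxa of the reference tree.
#' @return `"concordant"`, `"conflicting"` or `"uninformative"`.
#' @export
classify_clade <- function(gene_tree, ref_clade, ref_taxa) {
  if (!all(ref_clade %in% ref_taxa)) {
    stop("ref_clade must be a subset of ref_taxa")
  }
  shared <- intersect(gene_tree$tip.label, ref_taxa)
  gsets <- restricted_clade_sets(gene_tree, shared)
  classify_sets(gsets, shared, ref_clade)
}

# clade tip sets of a gene tree restricted to the shared taxa
restricted_clade_sets <- function(gene_tree, shared) {
  if (length(shared) < 3L) return(list())
  g <- restrict_tree(gene_tree, shared)
  clade_tip_sets(g, include_root = FALSE)
}

# core classification on precomputed restricted clade sets
classify_sets <- function(gsets, shared, ref_clade) {
  cp <- intersect(ref_clade, shared)
  if (length(cp) < 2L || length(setdiff(shared, cp)) < 1L) {
    return("uninformative")
  }
  conflict <- FALSE
  for (s in gsets) {
    ni <- length(intersect(s, cp))
    if (ni == length(cp) && ni == length(s)) return("concordant")
    if (ni > 0L && ni < length(cp) && ni < length(s)) conflict <- TRUE
  }
  if (conflict) "conflicting" else "uninformative"
}

#' Count per-clade gene-tree support on a reference tree
#'
#' For every internal clade of the rooted reference tree (root excluded),
#' classifies every gene tree as concordant, conflicting or uninformative.
#' At every clade the three counts sum to the number of gene trees.
#'
#' @param gene_trees `multiPhylo` (or list) of MUL-labeled gene trees, rooted
#'   on the shared outgroup.
#' @param ref rooted reference `phylo` (may itself be MUL-labeled).
#' @return data.frame of class `node_support_table` with columns `node` (ape
#'   node id in `ref`), `clade` (comma-joined members), `n_concordant`,
#'   `n_conflicting`, `n_uninformative`, plus a list-column `supporting` of
#'   concordant gene-tree indices.
#' @export
count_support <- function(gene_trees, ref) {
  if (inherits(gene_trees, "phylo")) gene_trees <- c(gene_trees)
  if (!ape::is.rooted(ref)) stop("reference tree must be rooted")
  clades <- clade_tip_sets(ref, include_root = FALSE)
  n_clade <- length(clades)
  ref_taxa <- ref$tip.label
  con <- conf <- uninf <- integer(n_clade)
  supporting <- rep(list(integer(0)), n_clade)
  for (i in seq_along(gene_trees)) {
    g <- gene_trees[[i]]
    shared <- intersect(g$tip.label, ref_taxa)
    gsets <- restricted_clade_sets(g, shared)
    for (j in seq_len(n_clade)) {
      cls <- classify_sets(gsets, shared, clades[[j]])
      if (cls == "concordant") {
        con[[j]] <- con[[j]] + 1L
        supporting[[j]] <- c(supporting[[j]], i)
      } else if (cls == "conflicting") {
        conf[[j]] <- conf[[j]] + 1L
      } else {
        uninf[[j]] <- uninf[[j]] + 1L
      }
    }
  }
  out <- data.frame(node = as.integer(names(clades)),
                    clade = vapply(clades, function(s)
                      paste(sort(s), collapse = ","), character(1L)),
                    n_concordant = con, n_conflicting = conf,
                    n_uninformative = uninf, stringsAsFactors = FALSE,
                    row.names = NULL)
  out$supporting <- supporting
  attr(out, "n_trees") <- length(gene_trees)
  class(out) <- c("node_support_table", class(out))
  out
}

#' Summarize the hybridization signal per hypothesis
#'
#' For each (hybrid, label) pair, reports the smallest reference clade that
#' contains the labeled hybrid tip together with at least one taxon of the
#' corresponding parental lineage — the attachment clade — with its
#' concordant/conflicting counts and the fraction of informative gene trees
#' that are concordant. A hypothesis is "supported" when both labels'
#' attachment clades have more concordant than conflicting trees. When the
#' conversion logs of [mul_convert()] are supplied, the modal witness taxon
#' set observed across gene trees is reported per label as a data-driven
#' donor estimate.
#'
#' @param table a `node_support_table` from [count_support()].
#' @param hypotheses a [hybrid_hypothesis()] or list thereof.
#' @param ref the rooted MUL-labeled reference `phylo` used for counting.
#' @param logs optional list of `log` data.frames from [mul_convert()].
#' @return list with `per_label` (data.frame, one row per hybrid x label) and
#'   `verdicts` (named character vector per hybrid: "supported",
#'   "unsupported" or "untestable").
#' @export
hybridization_report <- function(table, hypotheses, ref, logs = NULL) {
  if (inherits(hypotheses, "hybrid_hypothesis")) hypotheses <- list(hypotheses)
  clades <- clade_tip_sets(ref, include_root = FALSE)
  n_trees <- attr(table, "n_trees")
  rows <- list()
  verdicts <- character(0)
  for (hyp in hypotheses) {
    ok <- c(A = FALSE, B = FALSE)
    testable <- TRUE
    for (lab in c("A", "B")) {
      prefix <- if (lab == "A") hyp$prefix_A else hyp$prefix_B
      lineage <- if (lab == "A") hyp$lineage_A else hyp$lineage_B
      tip <- paste0(prefix, hyp$hybrid)
      if (!(tip %in% ref$tip.label)) {
        rows[[length(rows) + 1L]] <- data.frame(
          hybrid = hyp$hybrid, label = lab, tip = tip,
          attachment = NA_character_, n_concordant = NA_integer_,
          n_conflicting = NA_integer_, n_uninformative = NA_integer_,
          support_fraction = NA_real_, modal_witness = NA_character_,
          status = "untestable", stringsAsFactors = FALSE)
        testable <- FALSE
        next
      }
      cand <- Filter(function(s) tip %in% s && length(intersect(s, lineage)),
                     clades)
      if (!length(cand)) {
        rows[[length(rows) + 1L]] <- data.frame(
          hybrid = hyp$hybrid, label = lab, tip = tip,
          attachment = NA_character_, n_concordant = NA_integer_,
          n_conflicting = NA_integer_, n_uninformative = NA_integer_,
          support_fraction = NA_real_, modal_witness = NA_character_,
          status = "untestable", stringsAsFactors = FALSE)
        testable <- FALSE
        next
      }
      best <- cand[[order(lengths(cand))[1L]]]
      node <- as.integer(names(cand)[order(lengths(cand))[1L]])
      row <- table[table$node == node, , drop = FALSE]
      frac <- row$n_concordant /
        max(1L, row$n_concordant + row$n_conflicting)
      ok[[lab]] <- row$n_concordant > row$n_conflicting
      modal <- NA_character_
      if (!is.null(logs)) {
        wit <- unlist(lapply(logs, function(lg) {
          lg$witness[lg$species == hyp$hybrid & !is.na(lg$label) &
                       lg$label == lab & lg$action == "labeled"]
        }))
        wit <- wit[!is.na(wit) & nzchar(wit)]
        if (length(wit)) modal <- names(sort(table(wit), decreasing = TRUE))[1L]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        hybrid = hyp$hybrid, label = lab, tip = tip,
        attachment = paste(sort(best), collapse = ","),
        n_concordant = row$n_concordant, n_conflicting = row$n_conflicting,
        n_uninformative = row$n_uninformative, support_fraction = frac,
        modal_witness = modal, status = "tested", stringsAsFactors = FALSE)
    }
    verdicts[[hyp$hybrid]] <- if (!testable) "untestable" else
      if (all(ok)) "supported" else "unsupported"
  }
  list(per_label = do.call(rbind, rows), verdicts = verdicts,
       n_trees = n_trees)
}

#' Write a node support table as TSV, JSON and/or annotated newick
#'
#' The annotated newick carries the concordant counts as internal node labels
#' on the reference tree.
#'
#' @param table a `node_support_table`.
#' @param ref the reference tree used to build it (for the newick output).
#' @param path_tsv,path_json,path_newick output paths; `NULL` skips a format.
#' @export
write_support_table <- function(table, ref = NULL, path_tsv = NULL,
                                path_json = NULL, path_newick = NULL) {
  flat <- table[, c("node", "clade", "n_concordant", "n_conflicting",
                    "n_uninformative")]
  if (!is.null(path_tsv)) {
    utils::write.table(flat, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(flat, path_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(path_newick)) {
    if (is.null(ref)) stop("annotated newick output needs the reference tree")
    ntip <- ape::Ntip(ref)
    lab <- rep("", ref$Nnode)
    lab[table$node - ntip] <- as.character(table$n_concordant)
    ref$node.label <- lab
    ape::write.tree(ref, file = path_newick)
  }
  invisible(table)
}
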