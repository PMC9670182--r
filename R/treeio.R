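#' Parse tip labels into species, gene id and MUL label
#'
#' Tip labels of multi-copy gene family trees encode a species name and a gene
#' identifier, separated by a delimiter (default `"__"`), optionally preceded
#' by a subgenome prefix (`"A-"` / `"B-"`) on labeled hybrid tips. When labels
#' do not contain the delimiter, an external taxon map (gene id -> taxon) can
#' be supplied instead.
#'
#' @param labels character vector of raw tip labels.
#' @param delim delimiter between species and gene id; the split is on the
#'   FIRST occurrence.
#' @param mul_prefixes named character vector `c(A = "A-", B = "B-")` giving
#'   the subgenome label prefixes stripped from labeled tips.
#' @param taxon_map optional named character vector mapping gene id -> taxon,
#'   used for labels lacking the delimiter (see [read_taxon_map()]).
#' @return data.frame with columns `raw`, `species`, `gene_id`, `mul_label`
#'   (`NA` when the tip carries no subgenome prefix).
#' @examples
#' parse_tip_labels("Nymphaea_colorata__g12")
#' parse_tip_labels("A-Midnight__c1")
#' @export
parse_tip_labels <- function(labels, delim = "__",
                             mul_prefixes = c(A = "A-", B = "B-"),
                             taxon_map = NULL) {
  stopifnot(is.character(labels), length(labels) >= 1L, nchar(delim) >= 1L)
  if (any(!nzchar(labels))) stop("empty tip label")
  mul <- rep(NA_character_, length(labels))
  rest <- labels
  for (lab in names(mul_prefixes)) {
    pre <- mul_prefixes[[lab]]
    hit <- is.na(mul) & startsWith(rest, pre)
    mul[hit] <- lab
    rest[hit] <- substring(rest[hit], nchar(pre) + 1L)
  }
  pos <- regexpr(delim, rest, fixed = TRUE)
  species <- gene_id <- character(length(labels))
  has_delim <- pos > 0L
  species[has_delim] <- substr(rest[has_delim], 1L, pos[has_delim] - 1L)
  gene_id[has_delim] <- substring(rest[has_delim],
                                  pos[has_delim] + nchar(delim))
  if (any(!has_delim)) {
    bad <- rest[!has_delim]
    if (is.null(taxon_map)) {
      stop("unparseable tip label(s) (no '", delim,
           "' and no taxon map): ", paste(bad, collapse = ", "))
    }
    unknown <- setdiff(bad, names(taxon_map))
    if (length(unknown)) {
      stop("tip label(s) absent from taxon map: ",
           paste(unknown, collapse = ", "))
    }
    species[!has_delim] <- unname(taxon_map[bad])
    gene_id[!has_delim] <- bad
  }
  if (any(!nzchar(species)) || any(!nzchar(gene_id))) {
    stop("tip label(s) with empty species or gene id: ",
         paste(labels[!nzchar(species) | !nzchar(gene_id)], collapse = ", "))
  }
  data.frame(raw = labels, species = species, gene_id = gene_id,
             mul_label = mul, stringsAsFactors = FALSE)
}

#' Species of each tip of a tree
#'
#' @param tree a `phylo` object.
#' @inheritParams parse_tip_labels
#' @return character vector of taxon names, one per tip, in tip order.
#' @export
tip_species <- function(tree, delim = "__",
                        mul_prefixes = c(A = "A-", B = "B-"),
                        taxon_map = NULL) {
  parse_tip_labels(tree$tip.label, delim = delim, mul_prefixes = mul_prefixes,
                   taxon_map = taxon_map)$species
}

#' Read gene family trees from a newick file
#'
#' One tree per line; multi-tree files are supported. Quoted labels and
#' bracketed comments are handled by the ape newick reader.
#'
#' @param path path to a newick file.
#' @return a `multiPhylo` object (even for a single tree).
#' @export
read_gene_trees <- function(path) {
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (is.null(trees)) stop("no trees read from ", path)
  trees
}

#' Write trees to a newick file, one per line
#'
#' Labels are made unquoted-safe: spaces are replaced with underscores.
#'
#' @param trees a `phylo` or `multiPhylo` object.
#' @param path output file path.
#' @export
write_gene_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  trees <- lapply(trees, function(tr) {
    tr$tip.label <- gsub(" ", "_", tr$tip.label, fixed = TRUE)
    tr
  })
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = path)
  invisible(path)
}

#' Read a two-column taxon map (gene id, taxon) from TSV
#'
#' @param path TSV file with columns gene id and taxon (no header required;
#'   a header line `gene_id<TAB>taxon` is tolerated).
#' @return named character vector mapping gene id -> taxon.
#' @export
read_taxon_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2L) stop("taxon map must have two columns")
  if (identical(tolower(tab[1L, 1L]), "gene_id")) tab <- tab[-1L, , drop = FALSE]
  if (anyDuplicated(tab[[1L]])) stop("duplicated gene id in taxon map")
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Root a gene family tree on its outgroup taxa
#'
#' The tree is rooted on the edge separating all outgroup tips from the
#' ingroup. If the outgroup tips are not separable (non-monophyletic in the
#' unrooted tree), the tree is rooted above the largest outgroup-only clade
#' (ties broken by the clade containing the lexicographically smallest tip
#' label) and a warning is recorded in the `rooting_warning` attribute.
#'
#' @param tree a `phylo` object.
#' @param outgroup character vector of outgroup taxon names.
#' @inheritParams parse_tip_labels
#' @return rooted `phylo`; the unrooted topology (bipartition set) is never
#'   changed.
#' @export
root_on_outgroup <- function(tree, outgroup, delim = "__",
                             mul_prefixes = c(A = "A-", B = "B-"),
                             taxon_map = NULL) {
  sp <- tip_species(tree, delim = delim, mul_prefixes = mul_prefixes,
                    taxon_map = taxon_map)
  og_tips <- tree$tip.label[sp %in% outgroup]
  if (!length(og_tips)) {
    stop("missing outgroup: no tip belongs to ",
         paste(outgroup, collapse = ", "))
  }
  if (ape::is.rooted(tree)) {
    # already rooted with the outgroup basal? keep as-is
    root_node <- ape::Ntip(tree) + 1L
    kids <- tree$edge[tree$edge[, 1L] == root_node, 2L]
    for (k in kids) {
      kt <- tips_below(tree, k)
      if (setequal(kt, og_tips) || setequal(setdiff(tree$tip.label, kt), og_tips)) {
        return(tree)
      }
    }
  }
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  rooted <- tryCatch(
    ape::root(utree, outgroup = og_tips, resolve.root = TRUE),
    error = function(e) NULL)
  if (!is.null(rooted)) return(rooted)
  # non-monophyletic outgroup: root above the largest outgroup-only clade
  tmp <- ape::root(utree, outgroup = og_tips[[1L]], resolve.root = TRUE)
  sets <- clade_tip_sets(tmp)
  cand <- Filter(function(s) all(s %in% og_tips), sets)
  cand <- c(cand, as.list(og_tips))      # singleton tips always available
  sizes <- lengths(cand)
  best <- cand[sizes == max(sizes)]
  keyed <- vapply(best, function(s) min(sort(s)), character(1L))
  pick <- best[[order(keyed)[1L]]]
  warn <- paste0("outgroup not monophyletic; rooted above clade {",
                 paste(sort(pick), collapse = ","), "}")
  warning(warn)
  rooted <- ape::root(utree, outgroup = pick, resolve.root = TRUE)
  attr(rooted, "rooting_warning") <- warn
  rooted
}

#' Restrict a tree to a subset of its tips
#'
#' Returns the induced tree on `keep`: unary nodes are suppressed with branch
#' lengths summed, and the root is retained when at least two children remain.
#' The quartet topologies induced on `keep` equal the original tree's.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (non-empty subset of
#'   the tree's tips).
#' @return the induced `phylo`.
#' @export
restrict_tree <- function(tree, keep) {
  if (!length(keep)) stop("keep must contain at least one tip")
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("tips not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}
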