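#' Fraction of a taxon universe represented in a tree
#'
#' Multiple copies of one taxon count once.
#'
#' @param tree a `phylo` object with species-encoding tip labels.
#' @param universe character vector of taxon names defining 100% coverage.
#' @inheritParams parse_tip_labels
#' @return fraction in `[0, 1]`.
#' @export
taxon_coverage <- function(tree, universe, delim = "__",
                           mul_prefixes = c(A = "A-", B = "B-"),
                           taxon_map = NULL) {
  stopifnot(length(universe) >= 1L)
  sp <- tip_species(tree, delim = delim, mul_prefixes = mul_prefixes,
                    taxon_map = taxon_map)
  length(intersect(unique(sp), universe)) / length(universe)
}

#' Is a taxon set monophyletic on a rooted tree?
#'
#' True iff some clade's tip-taxon set equals the members of `taxa` present in
#' the tree. Absent members are ignored; when no member is present the check
#' is vacuously true with a warning. Singletons are monophyletic.
#'
#' @param tree a rooted `phylo`.
#' @param taxa character vector of taxon names.
#' @inheritParams parse_tip_labels
#' @return logical.
#' @export
is_clade_monophyletic <- function(tree, taxa, delim = "__",
                                  mul_prefixes = c(A = "A-", B = "B-"),
                                  taxon_map = NULL) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted; root on the outgroup first")
  sp <- tip_species(tree, delim = delim, mul_prefixes = mul_prefixes,
                    taxon_map = taxon_map)
  present <- intersect(taxa, unique(sp))
  if (!length(present)) {
    warning("no member of the taxon set is present; vacuously monophyletic")
    return(TRUE)
  }
  if (length(present) == 1L) return(TRUE)
  sets <- clade_tip_sets(tree, include_root = TRUE)
  sp_by_tip <- stats::setNames(sp, tree$tip.label)
  for (s in sets) {
    if (setequal(unique(sp_by_tip[s]), present)) return(TRUE)
  }
  FALSE
}

#' Criteria for selecting gene family trees
#'
#' Bundles the selection rules applied by [select_trees()]: minimum species
#' coverage (strictly greater-than by default, matching a "more than 50%"
#' rule), outgroup presence, at-least-one-representative per required taxon
#' group, and monophyly constraints evaluated on the outgroup-rooted tree.
#'
#' @param min_coverage minimum coverage fraction in `[0, 1]`.
#' @param require_outgroup must at least one outgroup tip be present?
#' @param outgroup character vector of outgroup taxa.
#' @param groups named list of taxon-name vectors; groups may overlap.
#' @param required_groups names of groups that must each have >= 1 member
#'   present (default: all groups).
#' @param monophyly list of taxon sets that must each be monophyletic on the
#'   outgroup-rooted tree.
#' @param evaluate_after_pruning evaluate monophyly after pruning paralogs of
#'   non-hybrid taxa (default TRUE; isoform tips otherwise trivially break
#'   monophyly).
#' @param min_alignment_length optional minimum alignment length (bp), applied
#'   only when a per-orthogroup length table is supplied to [select_trees()].
#' @param coverage_strict use strict `>` for the coverage rule (default).
#' @return an object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_coverage = 0.5, require_outgroup = TRUE,
                            outgroup = character(), groups = list(),
                            required_groups = names(groups),
                            monophyly = list(),
                            evaluate_after_pruning = TRUE,
                            min_alignment_length = NULL,
                            coverage_strict = TRUE) {
  stopifnot(is.numeric(min_coverage), min_coverage >= 0, min_coverage <= 1)
  if (length(groups) && is.null(names(groups))) {
    names(groups) <- letters[seq_along(groups)]
  }
  structure(list(min_coverage = min_coverage,
                 require_outgroup = isTRUE(require_outgroup),
                 outgroup = outgroup, groups = groups,
                 required_groups = required_groups,
                 monophyly = monophyly,
                 evaluate_after_pruning = isTRUE(evaluate_after_pruning),
                 min_alignment_length = min_alignment_length,
                 coverage_strict = isTRUE(coverage_strict)),
            class = "filter_criteria")
}

#' Select gene family trees suitable for MUL conversion
#'
#' A tree is kept iff its coverage exceeds `min_coverage`, the outgroup is
#' present when required, every required group has at least one member, every
#' monophyly constraint holds on the outgroup-rooted (optionally pruned) tree,
#' and — when an orthogroup length table is supplied — its alignment length
#' exceeds `min_alignment_length`. The report lists every failed criterion per
#' tree.
#'
#' @param trees `multiPhylo` (or list) of gene family trees.
#' @param criteria a [filter_criteria()] object.
#' @param universe character vector of all known taxa.
#' @param hybrids taxa allowed to keep multiple copies when pruning for the
#'   monophyly checks.
#' @param lengths optional named numeric vector of per-gene sequence lengths
#'   (gene id -> bp), used to pick best copies during pruning.
#' @param og_lengths optional named numeric vector of per-orthogroup alignment
#'   lengths (tree name -> bp) for the `min_alignment_length` rule; when
#'   absent the rule is skipped with a notice.
#' @inheritParams parse_tip_labels
#' @return list with elements `kept` (`multiPhylo`), `report` (data.frame with
#'   columns `tree`, `pass`, `failed`) and `counts` (failures per criterion).
#' @export
select_trees <- function(trees, criteria, universe, hybrids = character(),
                         lengths = NULL, og_lengths = NULL, delim = "__",
                         mul_prefixes = c(A = "A-", B = "B-"),
                         taxon_map = NULL) {
  stopifnot(inherits(criteria, "filter_criteria"), length(universe) >= 1L)
  if (inherits(trees, "phylo")) trees <- c(trees)
  unknown <- setdiff(unique(unlist(criteria$groups)), universe)
  if (length(unknown)) {
    stop("configuration error: unknown taxa in group definitions: ",
         paste(unknown, collapse = ", "))
  }
  unknown <- setdiff(unique(unlist(criteria$monophyly)), universe)
  if (length(unknown)) {
    stop("configuration error: unknown taxa in monophyly constraints: ",
         paste(unknown, collapse = ", "))
  }
  check_length <- !is.null(criteria$min_alignment_length)
  if (check_length && is.null(og_lengths)) {
    message("no orthogroup length table supplied; skipping the ",
            "min_alignment_length rule")
    check_length <- FALSE
  }
  ids <- names(trees)
  if (is.null(ids)) ids <- as.character(seq_along(trees))
  popts <- list(delim = delim, mul_prefixes = mul_prefixes,
                taxon_map = taxon_map)
  fails <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    failed <- character(0)
    sp <- unique(do.call(tip_species, c(list(tr), popts)))
    cov <- length(intersect(sp, universe)) / length(universe)
    cov_ok <- if (criteria$coverage_strict) cov > criteria$min_coverage else
      cov >= criteria$min_coverage
    if (!cov_ok) failed <- c(failed, "coverage")
    og_present <- length(intersect(sp, criteria$outgroup)) > 0L
    if (criteria$require_outgroup && !og_present) failed <- c(failed, "outgroup")
    for (g in criteria$required_groups) {
      if (!length(intersect(sp, criteria$groups[[g]]))) {
        failed <- c(failed, paste0("group:", g))
      }
    }
    if (length(criteria$monophyly)) {
      rooted <- if (og_present) {
        tryCatch(suppressWarnings(do.call(root_on_outgroup,
          c(list(tr, criteria$outgroup), popts))), error = function(e) NULL)
      } else NULL
      if (is.null(rooted)) {
        failed <- c(failed, "monophyly:unrootable")
      } else {
        eval_tree <- rooted
        if (criteria$evaluate_after_pruning) {
          eval_tree <- suppressWarnings(do.call(prune_paralogs,
            c(list(rooted, hybrids = hybrids, lengths = lengths), popts)))
        }
        mono_names <- names(criteria$monophyly)
        if (is.null(mono_names)) mono_names <- as.character(seq_along(criteria$monophyly))
        for (j in seq_along(criteria$monophyly)) {
          ok <- suppressWarnings(do.call(is_clade_monophyletic,
            c(list(eval_tree, criteria$monophyly[[j]]), popts)))
          if (!ok) failed <- c(failed, paste0("monophyly:", mono_names[[j]]))
        }
      }
    }
    if (check_length) {
      len <- og_lengths[ids[[i]]]
      if (is.na(len) || len <= criteria$min_alignment_length) {
        failed <- c(failed, "alignment_length")
      }
    }
    fails[[i]] <- failed
  }
  pass <- lengths(fails) == 0L
  kept <- trees[pass]
  class(kept) <- "multiPhylo"
  report <- data.frame(tree = ids, pass = pass,
                       failed = vapply(fails, paste, character(1L),
                                       collapse = ","),
                       stringsAsFactors = FALSE)
  counts <- table(unlist(fails))
  list(kept = kept, report = report,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Write a filter report as TSV and JSON
#'
#' @param result the list returned by [select_trees()].
#' @param path_tsv,path_json output paths (either may be `NULL` to skip).
#' @export
write_filter_report <- function(result, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    utils::write.table(result$report, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(list(report = result$report,
                              counts = as.list(result$counts)),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
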