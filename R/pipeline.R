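#' Read a pipeline run configuration from YAML
#'
#' Recognized keys: `gene_trees`, `reference`, `taxon_map`, `lengths`
#' (paths); `outgroup` (list); `universe` (list); `hybrids`; `hypotheses`
#' (list of maps with `hybrid`, `lineage_A`, `lineage_B`); `filter` (map with
#' [filter_criteria()] fields, `groups` as a map of lists); `summary_mode`;
#' `min_support`; `delimiter`; `out_dir`; `seed`.
#'
#' @param path YAML file path.
#' @return a named list (class `run_config`) ready for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full hybridization-detection pipeline
#'
#' Filter gene family trees, convert each to a MUL-labeled tree, count
#' per-clade support on the reference tree, summarize the hybridization
#' signal per hypothesis, and infer a quartet-based summary tree. All
#' intermediate artifacts are written to `out_dir` when given.
#'
#' @param config a `run_config` (from [read_run_config()]) or an equivalent
#'   named list. Instead of `gene_trees`/`reference` paths, in-memory
#'   `trees` (`multiPhylo`) and `ref` (`phylo`) entries may be supplied.
#' @param out_dir output directory overriding `config$out_dir`; `NULL` for no
#'   file output.
#' @return list with `filter` (selection result), `mul_trees`, `logs`,
#'   `flags`, `support` (node support table), `report` (hybridization
#'   report), `summary` (quartet summary), and `text` (human-readable
#'   summary lines).
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  delim <- config$delimiter %||% "__"
  taxon_map <- if (!is.null(config$taxon_map))
    read_taxon_map(config$taxon_map) else NULL
  trees <- stage("load", {
    if (!is.null(config[["trees"]])) config[["trees"]] else
      read_gene_trees(config[["gene_trees"]])
  })
  ref <- stage("load", {
    if (!is.null(config[["ref"]])) config[["ref"]] else
      ape::read.tree(config[["reference"]])
  })
  if (!ape::is.rooted(ref)) stop("pipeline stage 'load' failed: ",
                                 "reference tree must be rooted")
  lengths <- NULL
  if (!is.null(config$lengths)) {
    lengths <- if (is.numeric(config$lengths)) config$lengths else {
      tab <- utils::read.table(config$lengths, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
      stats::setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]]))
    }
  }
  hypotheses <- stage("configure", {
    lapply(config$hypotheses, function(hh) {
      if (inherits(hh, "hybrid_hypothesis")) hh else
        hybrid_hypothesis(hh$hybrid, unlist(hh$lineage_A),
                          unlist(hh$lineage_B),
                          prefix_A = hh$prefix_A %||% "A-",
                          prefix_B = hh$prefix_B %||% "B-")
    })
  })
  hybrids <- vapply(hypotheses, `[[`, character(1L), "hybrid")
  outgroup <- unlist(config$outgroup)
  universe <- unlist(config$universe)
  criteria <- stage("configure", {
    if (inherits(config$filter, "filter_criteria")) config$filter else {
      f <- config$filter %||% list()
      filter_criteria(
        min_coverage = f$min_coverage %||% 0.5,
        require_outgroup = f$require_outgroup %||% TRUE,
        outgroup = outgroup,
        groups = lapply(f$groups %||% list(), unlist),
        monophyly = lapply(f$monophyly %||% list(), unlist),
        min_alignment_length = f$min_alignment_length)
    }
  })
  filt <- stage("filter", {
    suppressWarnings(select_trees(trees, criteria, universe,
                                  hybrids = hybrids, lengths = lengths,
                                  delim = delim, taxon_map = taxon_map))
  })
  if (!length(filt$kept)) {
    stop("pipeline stage 'filter' failed: no trees passed filtering",
         call. = FALSE)
  }
  mulified <- stage("mulify", {
    lapply(filt$kept, function(tr) {
      suppressWarnings(mul_convert(tr, hypotheses, outgroup,
                                   lengths = lengths,
                                   min_support = config$min_support,
                                   delim = delim, taxon_map = taxon_map))
    })
  })
  mul_trees <- lapply(mulified, `[[`, "tree")
  class(mul_trees) <- "multiPhylo"
  logs <- lapply(mulified, `[[`, "log")
  flags <- lapply(mulified, `[[`, "flags")
  support <- stage("count", count_support(mul_trees, ref))
  report <- stage("report",
                  hybridization_report(support, hypotheses, ref, logs = logs))
  summary_mode <- config$summary_mode %||% "auto"
  summ <- stage("summarize", infer_summary_tree(mul_trees, mode = summary_mode))
  text <- report_text(report, filt, summ)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_filter_report(filt, file.path(out_dir, "filter_report.tsv"),
                        file.path(out_dir, "filter_report.json"))
    write_gene_trees(mul_trees, file.path(out_dir, "mul_trees.nwk"))
    utils::write.table(do.call(rbind, Map(function(lg, id) {
      if (nrow(lg)) cbind(tree = id, lg) else NULL
    }, logs, names(logs) %||% seq_along(logs))),
    file.path(out_dir, "conversion_log.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
    write_support_table(support, ref,
                        path_tsv = file.path(out_dir, "node_support.tsv"),
                        path_json = file.path(out_dir, "node_support.json"),
                        path_newick = file.path(out_dir,
                                                "annotated_reference.nwk"))
    jsonlite::write_json(list(per_label = report$per_label,
                              verdicts = as.list(report$verdicts),
                              quartet_score = summ$score,
                              summary_mode = summ$mode),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    ape::write.tree(summ$tree, file.path(out_dir, "summary_tree.nwk"))
    writeLines(text, file.path(out_dir, "report.txt"))
  }
  list(filter = filt, mul_trees = mul_trees, logs = logs, flags = flags,
       support = support, report = report, summary = summ, text = text)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

report_text <- function(report, filt, summ) {
  lines <- c(sprintf("%d of %d gene family trees passed filtering.",
                     sum(filt$report$pass), nrow(filt$report)))
  pl <- report$per_label
  for (i in seq_len(nrow(pl))) {
    r <- pl[i, ]
    if (identical(r$status, "untestable")) {
      lines <- c(lines, sprintf("%s (%s): untestable on this reference.",
                                r$tip, r$label))
    } else {
      lines <- c(lines, sprintf(
        paste0("The number of multi-labeled gene family trees supporting ",
               "%s clustering with {%s} is %d (%d conflicting, %d ",
               "uninformative; support fraction %.2f)."),
        r$tip, r$attachment, r$n_concordant, r$n_conflicting,
        r$n_uninformative, r$support_fraction))
    }
  }
  for (h in names(report$verdicts)) {
    lines <- c(lines, sprintf("Hybridization hypothesis for %s: %s.",
                              h, report$verdicts[[h]]))
  }
  lines <- c(lines, sprintf(
    "Quartet summary tree (%s mode) score: %d.", summ$mode, summ$score))
  lines
}
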