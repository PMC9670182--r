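universe18 <- paste0("sp", 1:18)

tree_over <- function(taxa, copies = NULL) {
  labs <- paste0(taxa, "__g", seq_along(taxa))
  if (!is.null(copies)) labs <- c(labs, paste0(copies, "__c",
                                               seq_along(copies)))
  ape::rtree(length(labs), tip.label = sample(labs))
}

test_that("coverage counts distinct taxa once", {
  set.seed(1)
  expect_equal(taxon_coverage(tree_over(universe18[1:9]), universe18), 0.5)
  expect_equal(taxon_coverage(tree_over(universe18,
                                        copies = rep("sp1", 3)), universe18),
               1.0)
  expect_equal(taxon_coverage(tree_over(c("zz1", "zz2")), universe18), 0.0)
})

test_that("monophyly follows rooted clade membership", {
  tr <- ape::read.tree(text = "((A__1,B__1),(C__1,D__1));")
  expect_true(is_clade_monophyletic(tr, c("A", "B")))
  expect_false(is_clade_monophyletic(tr, c("A", "C")))
  expect_true(is_clade_monophyletic(tr, "A"))
  expect_warning(ok <- is_clade_monophyletic(tr, "Z"), "vacuously")
  expect_true(ok)
  expect_error(is_clade_monophyletic(ape::unroot(tr), c("A", "B")),
               "rooted")
})

test_that("select_trees applies every rule and reports failures", {
  set.seed(2)
  groups <- list(g1 = c("sp1", "sp2"), g2 = c("sp3", "sp4"))
  crit <- filter_criteria(min_coverage = 0.5, require_outgroup = TRUE,
                          outgroup = "sp18", groups = groups)
  keep_tree <- tree_over(c(paste0("sp", 1:10), "sp18"))
  drop_group <- tree_over(c(paste0("sp", c(1, 2, 5:12)), "sp18"))
  drop_cov <- tree_over(c("sp1", "sp3", "sp18"))
  drop_og <- tree_over(paste0("sp", 1:10))
  res <- select_trees(c(keep_tree, drop_group, drop_cov, drop_og),
                      crit, universe18)
  expect_equal(res$report$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$report$failed[2], "group:g2")
  expect_match(res$report$failed[3], "coverage")
  expect_match(res$report$failed[4], "outgroup")
  expect_length(res$kept, 1)

  expect_error(select_trees(c(keep_tree),
                            filter_criteria(groups = list(g = "nope")),
                            universe18),
               "configuration error")
})

test_that("exact 50% coverage fails a strict more-than-50% rule", {
  set.seed(3)
  tr <- tree_over(universe18[1:9])
  crit <- filter_criteria(min_coverage = 0.5, require_outgroup = FALSE)
  expect_false(select_trees(c(tr), crit, universe18)$report$pass)
  loose <- filter_criteria(min_coverage = 0.5, require_outgroup = FALSE,
                           coverage_strict = FALSE)
  expect_true(select_trees(c(tr), loose, universe18)$report$pass)
})

test_that("monophyly constraints are evaluated on the rooted, pruned tree", {
  # a short sp4 isoform nested inside the {sp1,sp2,sp3} family region breaks
  # raw monophyly; pruning sp4 to its longest copy (outside) restores it
  tr <- ape::read.tree(text = paste0(
    "((((sp1__a:0.2,sp4__x:0.1):0.1,(sp2__b:0.2,sp3__c:0.2):0.1):0.1,",
    "sp4__d:0.5):1,out__z:1);"))
  uni <- c("sp1", "sp2", "sp3", "sp4", "out")
  crit <- filter_criteria(min_coverage = 0, require_outgroup = TRUE,
                          outgroup = "out",
                          monophyly = list(fam = c("sp1", "sp2", "sp3")))
  res <- select_trees(c(tr), crit, uni)
  expect_true(res$report$pass)
  crit_raw <- filter_criteria(min_coverage = 0, require_outgroup = TRUE,
                              outgroup = "out",
                              monophyly = list(fam = c("sp1", "sp2", "sp3")),
                              evaluate_after_pruning = FALSE)
  res_raw <- select_trees(c(tr), crit_raw, uni)
  expect_false(res_raw$report$pass)
  expect_equal(res_raw$report$failed, "monophyly:fam")
})

test_that("kept set matches an independent predicate on simulated trees", {
  scen <- waterlily_scenario(units = 1)
  cfg <- sim_config(scen$species_tree, scen$events, n_genes = 50,
                    dup_rate = 0.5, missing_rate = 0.25, seed = 77,
                    outgroup = scen$outgroup)
  sim <- simulate_dataset(cfg)
  res <- select_trees(sim$trees, scen$criteria, scen$universe,
                      hybrids = scen$hybrids, lengths = sim$lengths)
  expected <- vapply(sim$trees, function(tr) {
    sp <- unique(tip_species(tr))
    cov <- length(intersect(sp, scen$universe)) / length(scen$universe)
    cov > 0.5 && "Amborella_trichopoda" %in% sp &&
      all(vapply(scen$groups, function(g)
        length(intersect(g, sp)) > 0, logical(1)))
  }, logical(1))
  expect_equal(res$report$pass, unname(expected))
  expect_true(any(expected) && !all(expected))  # the fixture discriminates
})

test_that("tightening a criterion never grows the kept set", {
  scen <- waterlily_scenario(units = 1)
  cfg <- sim_config(scen$species_tree, scen$events, n_genes = 30,
                    missing_rate = 0.3, seed = 5, outgroup = scen$outgroup)
  sim <- simulate_dataset(cfg)
  base <- filter_criteria(min_coverage = 0, require_outgroup = FALSE,
                          outgroup = scen$outgroup, groups = scen$groups,
                          required_groups = character(0))
  kept0 <- select_trees(sim$trees, base, scen$universe)$report$pass
  expect_true(all(kept0))  # no-op criteria keep everything
  for (cov in c(0.3, 0.6, 0.9)) {
    crit <- filter_criteria(min_coverage = cov, require_outgroup = FALSE,
                            outgroup = scen$outgroup)
    kept <- select_trees(sim$trees, crit, scen$universe)$report$pass
    expect_true(all(kept0 | !kept))
    kept0 <- kept
  }
})
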