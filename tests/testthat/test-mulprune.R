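test_that("best_copy prefers sequence length, then branch length, then id", {
  tr <- ape::read.tree(
    text = "((sp1__g1:0.1,sp1__g2:0.3),(sp2__g1:0.2,out__g1:0.5));")
  expect_equal(as.character(best_copy(tr, "sp1", lengths = c(g1 = 500,
                                                             g2 = 800))),
               "sp1__g2")
  expect_equal(as.character(best_copy(tr, "sp1")), "sp1__g2")  # 0.3 > 0.1
  tie <- ape::read.tree(text = "((sp1__g1:0.2,sp1__g2:0.2),out__g1:0.5);")
  expect_equal(as.character(best_copy(tie, "sp1")), "sp1__g1")
  expect_error(best_copy(tr, "nope"), "absent")
})

test_that("best_copy flags paraphyletic copies", {
  tr <- ape::read.tree(
    text = "((sp1__g1:0.1,sp2__g1:0.2),(sp1__g2:0.4,out__g1:0.5));")
  expect_warning(bc <- best_copy(tr, "sp1"), "paraphyletic")
  expect_equal(as.character(bc), "sp1__g2")
  expect_true(attr(bc, "paraphyletic"))
})

test_that("prune_paralogs keeps one best copy per non-hybrid species", {
  toy <- two_hybrid_toy()
  rooted <- root_on_outgroup(toy, "amb")
  pruned <- prune_paralogs(rooted, hybrids = c("mid", "wbg"),
                           lengths = c(x1 = 900, x2 = 700))
  expect_setequal(pruned$tip.label,
                  c("mid__a1", "col__x1", "wbg__b1", "cae__y1", "mid__a2",
                    "amb__z1"))
  expect_equal(attr(pruned, "pruned_tips"), "col__x2")
  # already single-copy: identity
  again <- prune_paralogs(pruned, hybrids = c("mid", "wbg"))
  expect_true(same_topology(pruned, again))
})

test_that("pruning equals independent restriction on simulated paralog trees", {
  scen <- waterlily_scenario(units = 2)
  cfg <- sim_config(scen$species_tree, scen$events, n_genes = 60,
                    dup_rate = 1.5, seed = 13, outgroup = scen$outgroup)
  sim <- simulate_dataset(cfg)
  for (i in seq_along(sim$trees)) {
    tr <- root_on_outgroup(sim$trees[[i]], scen$outgroup)
    pruned <- suppressWarnings(
      prune_paralogs(tr, hybrids = scen$hybrids, lengths = sim$lengths))
    # independently recompute the kept tips: all hybrid copies + the longest
    # copy per other species (ties by gene id)
    info <- parse_tip_labels(tr$tip.label)
    keep <- unlist(lapply(split(seq_along(tr$tip.label), info$species),
                          function(idx) {
      sp <- info$species[idx[1]]
      if (sp %in% scen$hybrids) return(tr$tip.label[idx])
      len <- sim$lengths[info$gene_id[idx]]
      tr$tip.label[idx[order(-len, info$gene_id[idx])[1]]]
    }))
    expect_true(same_topology(pruned, ape::keep.tip(tr, keep)))
  }
})

test_that("parental-lineage assignment follows the nearest non-hybrid witness", {
  hyp <- hybrid_hypothesis("H", "P1", "P2")
  tr <- ape::read.tree(text = "((H__c1,P1__g),((H__c2,P2__g),Out__g));")
  expect_equal(as.character(assign_parent_lineage(tr, "H__c1", hyp)), "A")
  expect_equal(as.character(assign_parent_lineage(tr, "H__c2", hyp)), "B")

  mixed <- ape::read.tree(text = "((H__c1,(P1__g,P2__g)),Out__g);")
  a <- assign_parent_lineage(mixed, "H__c1", hyp)
  expect_equal(as.character(a), "unassigned")
  expect_setequal(attr(a, "witness"), c("P1", "P2"))

  # witnesses skip tips of ALL hybrid taxa, not only the focal one
  nested <- ape::read.tree(text = "(((H__c1,H2__z1),P2__g),Out__g);")
  b <- assign_parent_lineage(nested, "H__c1", hyp,
                             hybrid_taxa = c("H", "H2"))
  expect_equal(as.character(b), "B")

  allhyb <- ape::read.tree(text = "(H__c1,H__c2);")
  expect_error(assign_parent_lineage(allhyb, "H__c1", hyp), "no non-hybrid")
})

test_that("mul_convert reproduces the worked two-hybrid example", {
  res <- mul_convert(two_hybrid_toy(), two_hybrid_hypotheses(), outgroup = "amb",
                     lengths = c(x1 = 900, x2 = 700))
  expected <- ape::read.tree(text = "(((A-mid,col),((B-wbg,cae),B-mid)),amb);")
  expect_true(same_topology(res$tree, expected))
  expect_match(res$flags, "uninformative for wbg")
  expect_true(all(c("pruned_paralog", "labeled") %in% res$log$action))
})

test_that("trees without hybrid tips become bare single-copy taxon trees", {
  tr <- ape::read.tree(text = "((sp1__a:1,(sp2__b:1,sp2__c:2):1):1,out__z:1);")
  res <- mul_convert(tr, two_hybrid_hypotheses(), outgroup = "out")
  expect_setequal(res$tree$tip.label, c("sp1", "sp2", "out"))
  expect_length(res$flags, 2)  # both hybrids absent -> uninformative
})

test_that("MUL output invariants hold and order of hypotheses is irrelevant", {
  scen <- waterlily_scenario(units = 2)
  cfg <- sim_config(scen$species_tree, scen$events, n_genes = 40,
                    dup_rate = 1, seed = 99, outgroup = scen$outgroup)
  sim <- simulate_dataset(cfg)
  for (i in seq_along(sim$trees)) {
    res <- suppressWarnings(
      mul_convert(sim$trees[[i]], scen$hypotheses, scen$outgroup,
                  lengths = sim$lengths))
    labs <- res$tree$tip.label
    expect_equal(anyDuplicated(labs), 0)
    bare <- labs[!grepl("^[AB]-", labs)]
    expect_false(any(bare %in% scen$hybrids))
    rev_res <- suppressWarnings(
      mul_convert(sim$trees[[i]], rev(scen$hypotheses), scen$outgroup,
                  lengths = sim$lengths))
    expect_true(same_topology(res$tree, rev_res$tree))
  }
})

test_that("labels match the simulator's true subgenomes in a no-ILS regime", {
  scen <- waterlily_scenario(units = 10)
  cfg <- sim_config(scen$species_tree, scen$events, n_genes = 40,
                    dup_rate = 0.5, seed = 4, outgroup = scen$outgroup)
  sim <- simulate_dataset(cfg)
  n_checked <- 0
  for (i in seq_along(sim$trees)) {
    res <- suppressWarnings(
      mul_convert(sim$trees[[i]], scen$hypotheses, scen$outgroup,
                  lengths = sim$lengths))
    lab_rows <- res$log[res$log$action == "labeled", ]
    truth <- sim$truth$genes[[i]]
    for (j in seq_len(nrow(lab_rows))) {
      true_sub <- truth$subgenome[truth$tip == lab_rows$tip[j]]
      expect_equal(lab_rows$label[j], true_sub)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 100)
})
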