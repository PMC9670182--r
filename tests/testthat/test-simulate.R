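test_that("MUL species tree construction places both subgenome tips", {
  sp <- ape::read.tree(text = "((P1:2,P2:2):1,Out:3);")
  ev <- allopolyploidy_event("H", "P1", "P2", t_hyb = 1)
  mul <- build_mul_species_tree(sp, ev)
  expected <- ape::read.tree(
    text = "(((A-H:1,P1:1):1,(B-H:1,P2:1):1):1,Out:3);")
  expect_true(isTRUE(all.equal(mul, expected, use.edge.length = TRUE)))
  expect_equal(ape::Ntip(mul), ape::Ntip(sp) + 2)

  # t = 0: zero-length sister branches at the donor tips
  mul0 <- build_mul_species_tree(sp, allopolyploidy_event("H", "P1", "P2", 0))
  h <- ape::node.depth.edgelength(mul0)
  expect_equal(max(h) - h[match("A-H", mul0$tip.label)], 0)

  expect_error(build_mul_species_tree(
    sp, allopolyploidy_event("H", "P1", "P2", 2.5)), "older")
})

test_that("sequential events nest along the donor lineage", {
  scen <- waterlily_scenario(units = 1)
  mul <- build_mul_species_tree(scen$species_tree, scen$events)
  expect_equal(ape::Ntip(mul), 20)
  sets <- lapply((ape::Ntip(mul) + 1):(ape::Ntip(mul) + mul$Nnode),
                 function(n) mul$tip.label[unlist(
                   phangorn::Descendants(mul, n, "tips"))])
  has <- function(x) any(vapply(sets, setequal, logical(1), y = x))
  expect_true(has(c("Nymphaea_colorata", "A-Nymphaea_Midnight")))
  expect_true(has(c("Nymphaea_colorata", "A-Nymphaea_Midnight",
                    "A-Nymphaea_Woods_blue_goddess")))
  expect_true(has(c("Nymphaea_caerulea", "B-Nymphaea_Midnight")))
})

test_that("two-taxon coalescent trees are forced and ultrametric", {
  sp <- ape::read.tree(text = "(A:1,B:1);")
  for (s in 1:5) {
    gt <- simulate_gene_tree(sp, seed = s)
    expect_setequal(tip_species(gt), c("A", "B"))
    d <- ape::node.depth.edgelength(gt)
    expect_equal(d[1], d[2], tolerance = 1e-9)
  }
})

test_that("long branches suppress discordance (no-ILS limit)", {
  sp <- ape::read.tree(text = "(((A:150,B:150):50,C:200):50,D:250);")
  for (s in 1:30) {
    gt <- simulate_gene_tree(sp, seed = s)
    gt$tip.label <- tip_species(gt)
    expect_true(same_unrooted(gt, sp))
  }
})

test_that("gene trees are ultrametric and reproducible", {
  scen <- waterlily_scenario(units = 2)
  mul <- build_mul_species_tree(scen$species_tree, scen$events)
  g1 <- simulate_gene_tree(mul, seed = 10)
  g2 <- simulate_gene_tree(mul, seed = 10)
  expect_equal(ape::write.tree(g1), ape::write.tree(g2))
  d <- ape::node.depth.edgelength(g1)
  tipd <- d[seq_len(ape::Ntip(g1))]
  expect_lt(diff(range(tipd)) / max(tipd), 1e-8)
  truth <- attr(g1, "truth")
  expect_setequal(truth$subgenome[!is.na(truth$subgenome)],
                  c("A", "B"))
  expect_equal(sum(!is.na(truth$subgenome)), 4)  # 2 hybrids x 2 subgenomes
})

test_that("MSC discordance matches the (2/3)exp(-T) law", {
  # asymmetric 4-taxon tree; internal branch T between the (A,B) ancestor
  # and its parent
  T_int <- 1
  sp <- ape::read.tree(text = sprintf(
    "(((A:1,B:1):%g,C:%g):1,D:%g);", T_int, 1 + T_int, 2 + T_int))
  n <- 2000
  disc <- vapply(seq_len(n), function(s) {
    gt <- simulate_gene_tree(sp, seed = 1000 + s)
    gt$tip.label <- tip_species(gt)
    oracle_quartet_topology(gt, c("A", "B", "C", "D")) != 1L
  }, logical(1))
  p_hat <- mean(disc)
  p_exp <- (2 / 3) * exp(-T_int)
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(p_hat - p_exp), 3 * se)
})

test_that("paralog injection is deterministic and restriction-invertible", {
  scen <- waterlily_scenario(units = 2)
  mul <- build_mul_species_tree(scen$species_tree, scen$events)
  gt <- simulate_gene_tree(mul, seed = 3)

  none <- inject_paralogs(gt, dup_rate = 0, seed = 1)
  expect_equal(ape::write.tree(none), ape::write.tree(gt))
  expect_equal(nrow(attr(none, "paralog_truth")), 0)

  a <- inject_paralogs(gt, dup_rate = 1, seed = 8)
  b <- inject_paralogs(gt, dup_rate = 1, seed = 8)
  expect_equal(ape::write.tree(a), ape::write.tree(b))

  for (s in 1:100) {
    out <- inject_paralogs(gt, dup_rate = 1.5, seed = s)
    back <- restrict_tree(out, gt$tip.label)
    expect_true(isTRUE(all.equal(back, gt, use.edge.length = TRUE,
                                 tolerance = 1e-8)))
    tr <- attr(out, "paralog_truth")
    expect_true(all(tr$parent_tip %in% gt$tip.label |
                      tr$parent_tip %in% out$tip.label))
  }
})

test_that("datasets are deterministic and per-gene independent of n_genes", {
  scen <- waterlily_scenario(units = 2)
  cfg <- function(n) sim_config(scen$species_tree, scen$events, n_genes = n,
                                dup_rate = 0.5, missing_rate = 0.1,
                                seed = 17, outgroup = scen$outgroup)
  s1 <- simulate_dataset(cfg(5))
  s2 <- simulate_dataset(cfg(5))
  expect_equal(vapply(s1$trees, ape::write.tree, character(1)),
               vapply(s2$trees, ape::write.tree, character(1)))
  expect_equal(s1$lengths, s2$lengths)
  s10 <- simulate_dataset(cfg(10))
  expect_equal(vapply(s1$trees, ape::write.tree, character(1)),
               vapply(s10$trees[1:5], ape::write.tree, character(1)))

  empty <- simulate_dataset(cfg(0))
  expect_length(empty$trees, 0)
  expect_length(empty$lengths, 0)
})

test_that("dropout never removes the outgroup", {
  scen <- waterlily_scenario(units = 2)
  cfg <- sim_config(scen$species_tree, scen$events, n_genes = 30,
                    missing_rate = 0.35, seed = 23,
                    outgroup = scen$outgroup)
  sim <- simulate_dataset(cfg)
  og_present <- vapply(sim$trees, function(tr)
    "Amborella_trichopoda" %in% tip_species(tr), logical(1))
  expect_true(all(og_present))
  n_tips <- vapply(sim$trees, ape::Ntip, integer(1))
  expect_true(any(n_tips < 20))  # dropout actually happened
})

test_that("datasets round-trip to disk as newick + TSV + JSON", {
  scen <- waterlily_scenario(units = 2)
  cfg <- sim_config(scen$species_tree, scen$events, n_genes = 4,
                    dup_rate = 0.5, seed = 2, outgroup = scen$outgroup)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_sim_dataset(sim, dir)
  back <- read_gene_trees(paths[["trees"]])
  expect_length(back, 4)
  expect_true(same_topology(back[[1]], sim$trees[[1]]))
  lens <- utils::read.table(paths[["lengths"]], header = TRUE, sep = "\t")
  expect_equal(nrow(lens), length(sim$lengths))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_true(!is.null(truth$mul_tree))
})
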