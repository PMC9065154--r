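test_that("TNT xread parsing handles polymorphism, missing, and ccode", {
  f <- withr::local_tempfile(fileext = ".tnt")
  writeLines(c("xread 'toy' 3 4",
               "taxA 001",
               "taxB 0[01]1",
               "taxC 1?0",
               "taxD 12-",
               ";",
               "ccode + 0 ] 2 ;",
               "proc /;"), f)
  cm <- read_character_matrix(f)
  expect_equal(cm$ntax, 4)
  expect_equal(cm$nchar, 3)
  expect_equal(cm$taxa, c("taxA", "taxB", "taxC", "taxD"))
  expect_equal(cm$mask[2, 2], bitwOr(1L, 2L))        # [01] -> {0,1}
  expect_equal(cm$mask[3, 2], 0L)                    # '?' missing
  expect_equal(cm$mask[4, 3], 0L)                    # '-' inapplicable
  expect_true(cm$ordered[1])                         # ccode + 0 (0-based)
  expect_false(cm$active[3])                         # ccode ] 2
})

test_that("matrix parse errors are informative", {
  f <- withr::local_tempfile(fileext = ".tnt")
  writeLines(c("xread 3 2", "taxA 001", "taxB 01", ";"), f)
  expect_error(read_character_matrix(f), "taxB")
  writeLines(c("xread 3 2", "taxA 001", "taxA 010", ";"), f)
  expect_error(read_character_matrix(f), "2 taxa but 1 found|duplicate")
  expect_error(character_matrix(rbind("0", "!"), c("a", "b")),
               "unknown state symbol")
  expect_error(character_matrix(rbind("0", "1"), c("a", "a")), "duplicate")
})

test_that("NEXUS matrices parse with assumptions blocks", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS",
               "BEGIN DATA;",
               "DIMENSIONS NTAX=4 NCHAR=5;",
               "FORMAT MISSING=? GAP=- SYMBOLS=\"0123\";",
               "MATRIX",
               "taxA 00110",
               "taxB 01(12)10",
               "taxC 11?21",
               "taxD 10-21",
               ";",
               "END;",
               "BEGIN ASSUMPTIONS;",
               "TYPESET * UNTITLED = ord: 2 4-5;",
               "EXSET * EXCLUDED = 3;",
               "END;"), f)
  cm <- read_character_matrix(f)
  expect_equal(cm$ntax, 4)
  expect_equal(cm$nchar, 5)
  expect_equal(which(cm$ordered), c(2L, 4L, 5L))
  expect_equal(which(!cm$active), 3L)
  expect_equal(cm$mask[2, 3], bitwOr(2L, 4L))        # (12) -> {1,2}
})

test_that("TNT write/read round-trips the matrix and flags", {
  tr <- random_topology(6, seed = 2)
  sim <- generate_character_matrix(tr, nchar = 25, change_prob = 0.15,
                                   ordered_fraction = 0.3,
                                   missing_prob = 0.25, seed = 4)
  f <- withr::local_tempfile(fileext = ".tnt")
  write_tnt(sim$matrix, f)
  cm2 <- read_character_matrix(f)
  expect_identical(cm2$mask, sim$matrix$mask)
  expect_identical(cm2$ordered, sim$matrix$ordered)
  expect_identical(cm2$active, sim$matrix$active)
  expect_identical(cm2$taxa, sim$matrix$taxa)
})

test_that("character lengths match the textbook examples", {
  cells <- cbind(c("0", "0", "1", "1"))
  cm <- toy_matrix(cells, c("a", "b", "c", "d"))
  t_ab <- ape::read.tree(text = "((a,b),(c,d));")
  t_ac <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(character_length(t_ab, cm), 1L)
  expect_equal(character_length(t_ac, cm), 2L)

  # additive states (0,2) on a three-leaf tree: 2 ordered steps vs 1 unordered
  cells3 <- cbind(c("0", "2", "0"))
  cm_uno <- toy_matrix(cells3, c("a", "b", "c"))
  cm_ord <- toy_matrix(cells3, c("a", "b", "c"), ordered = TRUE)
  t3 <- ape::read.tree(text = "(a,b,c);")
  expect_equal(character_length(t3, cm_uno), 1L)
  expect_equal(character_length(t3, cm_ord), 2L)
})

test_that("tree_length computes the worked CI/RI identity", {
  cells <- cbind(c("0", "0", "1", "1"))
  cm <- toy_matrix(cells, c("a", "b", "c", "d"))
  sc <- tree_length(ape::read.tree(text = "((a,c),(b,d));"), cm)
  expect_equal(sc$S, 2)
  expect_equal(sc$M, 1)
  expect_equal(sc$G, 2)
  expect_equal(sc$CI, 0.5)
  expect_equal(sc$RI, 0)
  # invariant matrix: S = 0, CI reported 1 by convention and flagged
  cm0 <- toy_matrix(cbind(rep("0", 4), rep("1", 4)), letters[1:4])
  sc0 <- tree_length(ape::read.tree(text = "((a,b),(c,d));"), cm0)
  expect_equal(sc0$S, 0)
  expect_equal(sc0$CI, 1)
  expect_false(sc0$ci_defined)
  # excluded characters contribute nothing
  cmx <- toy_matrix(cells, c("a", "b", "c", "d"), active = FALSE)
  expect_equal(tree_length(ape::read.tree(text = "((a,c),(b,d));"), cmx)$S, 0)
})

test_that("Fitch/additive lengths equal the exhaustive-assignment oracle", {
  set.seed(20)
  for (case in 1:60) {
    ntip <- sample(4:6, 1)
    max_state <- sample(1:3, 1)
    topo <- enumerate_topologies(ntip)
    e <- topo[[sample(length(topo), 1)]]
    col <- random_char_column(ntip, max_state)
    for (ordered in c(FALSE, TRUE)) {
      cm <- toy_matrix(cbind(col$cells), paste0("t", seq_len(ntip)),
                       ordered = ordered)
      got <- character_length(edges_phylo(e, ntip), cm)
      want <- brute_force_char_length(e, ntip, col$sets, ordered, max_state)
      expect_equal(got, as.integer(want),
                   info = paste("case", case, "ordered", ordered))
    }
  }
})

test_that("tree length is invariant to re-rooting and taxon order", {
  tr <- random_topology(7, seed = 5)
  sim <- generate_character_matrix(tr, nchar = 20, change_prob = 0.2,
                                   ordered_fraction = 0.25, seed = 6)
  cm <- sim$matrix
  s0 <- tree_length(tr, cm)$S
  rooted <- ape::root(tr, outgroup = "t4", resolve.root = FALSE)
  expect_equal(tree_length(rooted, cm)$S, s0)
  perm <- sample(cm$ntax)
  cm2 <- character_matrix(cm$cells[perm, , drop = FALSE], cm$taxa[perm],
                          ordered = cm$ordered)
  expect_equal(tree_length(tr, cm2)$S, s0)
})

test_that("per-character S stays within [M, G] on random trees", {
  set.seed(21)
  for (i in 1:10) {
    tr <- random_topology(8)
    sim <- generate_character_matrix(tr, nchar = 15, change_prob = 0.3,
                                     ordered_fraction = 0.3,
                                     missing_prob = 0.2)
    other <- random_topology(8)
    sc <- tree_length(other, sim$matrix)
    pc <- sc$per_character
    expect_true(all(pc$length >= pc$min_steps))
    expect_true(all(pc$length <= pc$max_steps))
    expect_gte(sc$CI, 0); expect_lte(sc$CI, 1)
    expect_gte(sc$RI, 0); expect_lte(sc$RI, 1)
  }
})

test_that("Wagner builds recover unambiguous signal for any addition order", {
  cells <- cbind(c("0", "0", "1", "1"), c("0", "0", "1", "1"),
                 c("1", "1", "0", "0"), c("0", "0", "1", "1"))
  cm <- toy_matrix(cells, c("a", "b", "c", "d"))
  want <- clawmorph:::tree_signature(
    clawmorph:::phylo_to_edges(ape::read.tree(text = "((a,b),(c,d));"),
                               cm$taxa), 4)
  orders <- list(1:4, 4:1, c(2, 4, 1, 3), c(3, 1, 4, 2))
  for (ord in orders) {
    tr <- wagner_build(cm, addition_order = ord)
    got <- clawmorph:::tree_signature(
      clawmorph:::phylo_to_edges(tr, cm$taxa), 4)
    expect_equal(got, want)
  }
  # three taxa: the unique unrooted tree
  cm3 <- toy_matrix(cbind(c("0", "1", "0")), c("a", "b", "c"))
  expect_equal(sort(wagner_build(cm3, 1:3)$tip.label), c("a", "b", "c"))
})

test_that("the search attains the exhaustive minimum on 6-taxon matrices", {
  set.seed(22)
  topo6 <- enumerate_topologies(6)
  expect_length(topo6, 105)
  prep_score <- function(cm) {
    prep <- clawmorph:::prep_matrix(cm)
    vapply(topo6, clawmorph:::score_edges, numeric(1), prep = prep)
  }
  for (trial in 1:3) {
    tr <- random_topology(6)
    sim <- generate_character_matrix(tr, nchar = 8, change_prob = 0.35,
                                     ordered_fraction = 0.25)
    best_exhaustive <- min(prep_score(sim$matrix))
    res <- branch_swap_search(sim$matrix, replicates = 5, strategy = "tbr",
                              hold = 5, seed = trial)
    expect_equal(res$best_length, best_exhaustive)
    # spr and nni from more starts also reach it on these small problems
    res_spr <- branch_swap_search(sim$matrix, replicates = 10,
                                  strategy = "spr", hold = 5, seed = trial)
    expect_equal(res_spr$best_length, best_exhaustive)
  }
})

test_that("search honors determinism and the hold contract", {
  tr <- random_topology(7, seed = 9)
  sim <- generate_character_matrix(tr, nchar = 12, change_prob = 0.3, seed = 10)
  r1 <- branch_swap_search(sim$matrix, replicates = 4, seed = 42)
  r2 <- branch_swap_search(sim$matrix, replicates = 4, seed = 42)
  expect_equal(lapply(r1$trees, ape::write.tree),
               lapply(r2$trees, ape::write.tree))
  r_hold1 <- branch_swap_search(sim$matrix, replicates = 1, hold = 1, seed = 1)
  expect_lte(length(r_hold1$trees), 1)
  # an already-optimal start tree is returned unchanged in length
  r_start <- branch_swap_search(sim$matrix, replicates = 1, hold = 3,
                                start_trees = r1$trees[1], seed = 2)
  expect_equal(r_start$best_length, r1$best_length)
})

test_that("consensus operators obey their defining rules", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,c),(b,d),e);")
  t3 <- ape::read.tree(text = "((a,b),(c,d),e);")
  # identical trees: the tree itself
  st_same <- strict_consensus(list(t1, t3))
  expect_equal(ape::dist.topo(ape::unroot(st_same), ape::unroot(t1)), 0,
               ignore_attr = TRUE)
  # resolved conflict: star on the conflicting part
  st <- strict_consensus(list(t1, t2))
  expect_equal(st$Nnode, 1)
  # star tree is absorbing
  star <- ape::read.tree(text = "(a,b,c,d,e);")
  st2 <- strict_consensus(list(t1, t2, star))
  expect_equal(st2$Nnode, 1)
  # majority rule: clade in 2 of 3 kept with frequency 2/3
  mj <- majority_rule_consensus(list(t1, t2, t3))
  expect_true(any(abs(as.numeric(mj$node.label) - 2 / 3) < 1e-9, na.rm = TRUE))
  # threshold 0.5 on unanimous input equals strict consensus
  mj_u <- majority_rule_consensus(list(t1, t3))
  expect_equal(ape::dist.topo(ape::unroot(mj_u), ape::unroot(t1)), 0,
               ignore_attr = TRUE)
  # clade in exactly half of an even set is excluded (strict majority)
  mj_h <- majority_rule_consensus(list(t1, t2))
  expect_equal(mj_h$Nnode, 1)
  expect_error(strict_consensus(list(t1, ape::read.tree(text = "(a,b,x);"))),
               "leaf sets")
})

test_that("consensus operators are idempotent and order-invariant", {
  set.seed(23)
  trees <- replicate(5, random_topology(7), simplify = FALSE)
  st <- strict_consensus(trees)
  st_rev <- strict_consensus(rev(trees))
  expect_equal(ape::write.tree(st), ape::write.tree(st_rev))
  expect_equal(ape::write.tree(strict_consensus(list(st, st))),
               ape::write.tree(st))
  mj <- majority_rule_consensus(trees)
  mj_rev <- majority_rule_consensus(rev(trees))
  expect_equal(ape::write.tree(mj), ape::write.tree(mj_rev))
})

test_that("consensus and tree length agree with ape and phangorn", {
  skip_if_not_installed("phangorn")
  set.seed(24)
  trees <- replicate(6, random_topology(8), simplify = FALSE)
  class(trees) <- "multiPhylo"
  st <- strict_consensus(trees)
  st_ape <- ape::consensus(trees, p = 1)
  expect_equal(ape::dist.topo(ape::unroot(st), ape::unroot(st_ape)), 0,
               ignore_attr = TRUE)
  mj <- majority_rule_consensus(trees)
  mj_ape <- ape::consensus(trees, p = 0.5)
  expect_equal(ape::dist.topo(ape::unroot(mj), ape::unroot(mj_ape)), 0,
               ignore_attr = TRUE)

  # unordered tree length cross-check against phangorn's Fitch engine
  tr <- random_topology(8, seed = 31)
  sim <- generate_character_matrix(tr, nchar = 30, change_prob = 0.25,
                                   missing_prob = 0.15, seed = 32)
  cm <- sim$matrix
  states <- apply(cm$cells, c(1, 2), function(x) if (is.na(x)) "?" else x)
  rownames(states) <- cm$taxa
  pd <- phangorn::phyDat(states, type = "USER",
                         levels = as.character(0:3), ambiguity = "?")
  expect_equal(tree_length(tr, cm)$S, phangorn::parsimony(tr, pd))
})

test_that("zero-length-branch collapsing never changes tree length", {
  tr <- random_topology(7, seed = 12)
  sim <- generate_character_matrix(tr, nchar = 6, change_prob = 0.1, seed = 13)
  other <- random_topology(7, seed = 14)
  col <- collapse_zero_branches(other, sim$matrix)
  expect_equal(tree_length(col, sim$matrix)$S,
               tree_length(other, sim$matrix)$S)
  expect_lte(col$Nnode, other$Nnode)
})
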