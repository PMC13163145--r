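# seven-leaf tree with three named strata on the path to focal leaf L1;
# other internal nodes are unnamed
seven_leaf_tree <- function() {
  ape::read.tree(text = "(((L1,L2)S3,(L3,L4))S2,((L5,L6),L7))S1;")
}

test_that("stratified_tree validates ladder nesting and focal placement", {
  tree <- seven_leaf_tree()
  st <- stratified_tree(tree, c("S1", "S2", "S3"), "L1")
  expect_s3_class(st, "stratified_tree")
  # youngest-to-oldest order violates strict nesting
  expect_error(stratified_tree(tree, c("S3", "S2", "S1"), "L1"),
               "not strictly nested")
  expect_error(stratified_tree(tree, c("S1", "S2", "S3"), "L7"),
               "not on the root-to-focal path")
  expect_error(stratified_tree(tree, c("S1", "S2", "S3"), "Lx"),
               "not a leaf")
})

test_that("orthogroup ages follow the smallest named clade containing the MRCA", {
  tree <- ape::read.tree(text = "((A,B)Crustacea,C)Metazoa;")
  st <- stratified_tree(tree, c("Metazoa", "Crustacea"), "A")
  ogs <- orthogroup_table(list(
    OG_all = list(A = "a1", B = "b1", C = "c1"),
    OG_focal = list(A = "a2", B = character(0), C = character(0)),
    OG_ab = list(A = "a3", B = "b2", C = character(0)),
    OG_ac = list(A = "a4", B = character(0), C = "c2"),
    OG_nofocal = list(A = character(0), B = "b3", C = "c3")
  ), species = c("A", "B", "C"))
  assign <- assign_strata(ogs, st)
  strat <- stats::setNames(as.character(assign$orthogroups$stratum),
                           assign$orthogroups$orthogroup_id)
  expect_equal(unname(strat["OG_all"]), "Metazoa")
  expect_equal(unname(strat["OG_focal"]), "Crustacea")
  expect_equal(unname(strat["OG_ab"]), "Crustacea")
  expect_equal(unname(strat["OG_ac"]), "Metazoa")  # MRCA(A,C) is the root
  expect_true(is.na(strat["OG_nofocal"]))
  # the per-gene view only covers focal-containing orthogroups
  expect_setequal(assign$genes$gene_id, c("a1", "a2", "a3", "a4"))
})

test_that("assignment matches the exhaustive clade-containment oracle on all presence subsets", {
  tree <- seven_leaf_tree()
  focal <- "L1"
  st <- stratified_tree(tree, c("S1", "S2", "S3"), focal)
  leaves <- tree$tip.label
  others <- setdiff(leaves, focal)
  # all subsets containing the focal leaf
  subsets <- lapply(0:(2^length(others) - 1), function(mask) {
    c(focal, others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0])
  })
  members <- lapply(subsets, function(p) {
    m <- lapply(stats::setNames(leaves, leaves), function(sp)
      if (sp %in% p) paste0(sp, "_x") else character(0))
    m
  })
  names(members) <- sprintf("OG%03d", seq_along(members))
  # unique gene ids per orthogroup
  for (i in seq_along(members))
    members[[i]] <- lapply(members[[i]], function(g)
      if (length(g)) paste0(g, "_", i) else g)
  ogs <- orthogroup_table(members, species = leaves)
  assign <- assign_strata(ogs, st)

  # oracle: the smallest named clade whose tip set contains the presence set
  clades <- lapply(c(S1 = "S1", S2 = "S2", S3 = "S3"), function(lbl) {
    nd <- which(tree$node.label == lbl) + ape::Ntip(tree)
    ape::extract.clade(tree, nd)$tip.label
  })
  oracle <- vapply(subsets, function(p) {
    containing <- names(clades)[vapply(clades, function(cl)
      all(p %in% cl), logical(1))]
    sizes <- vapply(clades[containing], length, integer(1))
    containing[which.min(sizes)]
  }, character(1))
  expect_equal(as.character(assign$orthogroups$stratum), unname(oracle))
})

test_that("enlarging the presence set never yields a younger stratum", {
  tree <- seven_leaf_tree()
  st <- stratified_tree(tree, c("S1", "S2", "S3"), "L1")
  leaves <- tree$tip.label
  set.seed(5)
  for (rep in 1:30) {
    p <- c("L1", sample(setdiff(leaves, "L1"), sample(0:5, 1)))
    q <- unique(c(p, sample(leaves, sample(1:6, 1))))
    build <- function(pres) {
      m <- list(lapply(stats::setNames(leaves, leaves), function(sp)
        if (sp %in% pres) paste0(sp, "_g") else character(0)))
      names(m) <- "OG1"
      orthogroup_table(m, species = leaves)
    }
    s_p <- assign_strata(build(p), st)$orthogroups$stratum
    s_q <- assign_strata(build(q), st)$orthogroups$stratum
    # ordered factor levels run oldest -> youngest
    expect_lte(as.integer(s_q), as.integer(s_p))
  }
})

test_that("stratum counts partition the assigned orthogroups and genes", {
  set.seed(17)
  cfg <- sim_config(seed = 17, strata_births = c(stratum_1 = 40L,
                                                 stratum_2 = 30L,
                                                 stratum_3 = 30L,
                                                 stratum_4 = 20L,
                                                 stratum_5 = 20L))
  orth <- simulate_orthology(cfg)
  assign <- assign_strata(orth$ogs, orth$stree)
  counts <- stratum_gene_counts(assign)
  expect_equal(sum(counts$n_orthogroups),
               sum(!is.na(assign$orthogroups$stratum)))
  expect_equal(sum(counts$n_genes), nrow(assign$genes))
  expect_false(anyDuplicated(assign$genes$gene_id) > 0)
})

test_that("planted orthogroup births are recovered exactly without presence noise", {
  cfg <- sim_config(seed = 23, strata_births = c(stratum_1 = 40L,
                                                 stratum_2 = 30L,
                                                 stratum_3 = 30L,
                                                 stratum_4 = 10L,
                                                 stratum_5 = 10L))
  orth <- simulate_orthology(cfg)
  assign <- assign_strata(orth$ogs, orth$stree)
  expect_identical(as.character(assign$orthogroups$stratum),
                   orth$truth$stratum)
  counts <- stratum_gene_counts(assign)
  expect_equal(counts$n_orthogroups, c(40L, 30L, 30L, 10L, 10L))
})

test_that("tree-ortholog filters reproduce occupancy and single-copy criteria", {
  ogs <- orthogroup_table(list(
    OG1 = list(A = "a1", B = "b1", C = "c1", D = "d1", E = "e1",
               F = c("f1", "f2")),
    OG2 = list(A = c("a2", "a3"), B = c("b2", "b3"), C = "c2", D = "d2",
               E = "e2", F = "f3"),
    OG3 = list(A = "a4", B = "b4", C = "c3", D = "d3", E = "e3",
               F = character(0)),
    OG4 = list(A = c("a5", "a6"), B = c("b5", "b6"), C = c("c4", "c5"),
               D = c("d4", "d5"), E = "e4", F = "f4")
  ), species = LETTERS[1:6])
  sel <- select_tree_orthologs(ogs)
  # OG1: occupancy 6/6, single-copy 5/6 -> in; OG2: single-copy 4/6 -> in
  # OG3: occupancy 5/6 -> out; OG4: single-copy 2/6 -> out
  expect_identical(sel, c("OG1", "OG2"))
})

test_that("filter selection equals an independent per-row reimplementation", {
  set.seed(29)
  ogs <- random_og_table(200, paste0("s", 1:6), p_present = 0.85,
                         lambda = 0.8)
  sel <- select_tree_orthologs(ogs, min_occupancy = 1.0,
                               min_single_copy_fraction = 0.5)
  oracle <- character(0)
  for (og in ogs$orthogroup_id) {
    sizes <- vapply(ogs$members[[og]], length, integer(1))
    if (mean(sizes >= 1) >= 1.0 && mean(sizes == 1) >= 0.5)
      oracle <- c(oracle, og)
  }
  expect_identical(sel, oracle)
})
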