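make_de_stub <- function(genes, classes) {
  data.frame(gene_id = genes, baseMean = 10, log2fc = 0, se = 1,
             pvalue = 0.5, fdr = 0.5, class = classes, expressed = TRUE,
             stringsAsFactors = FALSE)
}

test_that("conserved orthogroups require presence in every listed species", {
  ogs <- toy_og_table()
  expect_identical(conserved_orthogroups(ogs, c("A", "B", "C")), "OG1")
  expect_identical(conserved_orthogroups(ogs, c("A", "C")), c("OG1", "OG2"))
  expect_identical(conserved_orthogroups(ogs, character(0)),
                   c("OG1", "OG2", "OG3"))
  expect_error(conserved_orthogroups(ogs, "Z"), "unknown species")

  set.seed(19)
  big <- random_og_table(120, paste0("s", 1:5))
  got <- conserved_orthogroups(big, paste0("s", 1:5))
  oracle <- big$orthogroup_id[vapply(big$orthogroup_id, function(og)
    all(vapply(big$members[[og]], length, integer(1)) >= 1), logical(1))]
  expect_identical(got, oracle)
})

test_that("representative selection picks longest gene with lexical ties", {
  ogs <- orthogroup_table(list(
    OG1 = list(A = c("g1", "g2"), B = c("gA", "gB")),
    OG2 = list(A = "g3", B = character(0))
  ), species = c("A", "B"))
  lens <- c(g1 = 300, g2 = 500, gA = 400, gB = 400, g3 = 100)
  reps <- pick_representatives(ogs, lens)
  expect_equal(reps$gene_id[reps$orthogroup_id == "OG1" &
                            reps$species_id == "A"], "g2")
  expect_equal(reps$gene_id[reps$orthogroup_id == "OG1" &
                            reps$species_id == "B"], "gA")
  # absent cell yields no row; missing length is a hard error naming the gene
  expect_equal(nrow(reps[reps$orthogroup_id == "OG2" &
                         reps$species_id == "B", ]), 0L)
  expect_error(pick_representatives(ogs, lens[-5]), "g3")
})

test_that("representative selection equals brute-force argmax on random fixtures", {
  set.seed(37)
  ogs <- random_og_table(60, paste0("s", 1:4), lambda = 1.2)
  genes <- unlist(ogs$members, use.names = FALSE)
  lens <- stats::setNames(sample(100:5000, length(genes), replace = TRUE),
                          genes)
  reps <- pick_representatives(ogs, lens)
  for (i in sample(nrow(reps), 25)) {
    row <- reps[i, ]
    mem <- ogs$members[[row$orthogroup_id]][[row$species_id]]
    best <- mem[lens[mem] == max(lens[mem])]
    expect_identical(row$gene_id, min(best))
  }
})

test_that("orthogroup response statuses follow the up/down/mixed rules", {
  ogs <- orthogroup_table(list(
    OG1 = list(A = c("a1", "a2"), B = "b1"),
    OG2 = list(A = "a3", B = "b2"),
    OG3 = list(A = "a4", B = character(0)),
    OG4 = list(A = c("a5", "a6"), B = "b3")
  ), species = c("A", "B"))
  de <- list(
    A = make_de_stub(paste0("a", 1:6),
                     c("DEG_up", "NS", "HDEG_down", "NS", "DEG_up",
                       "DEG_down")),
    B = make_de_stub(paste0("b", 1:3), c("NS", "NS", "HDEG_up")))
  st <- build_sharing(ogs, de)
  expect_equal(st$A, c("up", "down", "tested_NS", "mixed"))
  expect_equal(st$B, c("tested_NS", "tested_NS", "absent", "up"))
  expect_equal(st$n_species_responsive, c(1L, 1L, 0L, 2L))
  expect_equal(st$conserved, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("statuses equal independent recomputation on a synthetic run", {
  set.seed(43)
  ogs <- random_og_table(100, paste0("s", 1:3), lambda = 1)
  cls_pool <- c("NS", "NS", "NS", "DEG_up", "DEG_down", "HDEG_up",
                "HDEG_down")
  de <- lapply(stats::setNames(ogs$species, ogs$species), function(sp) {
    genes <- unlist(lapply(ogs$members, `[[`, sp), use.names = FALSE)
    make_de_stub(genes, sample(cls_pool, length(genes), replace = TRUE))
  })
  st <- build_sharing(ogs, de)
  for (i in sample(100, 30)) {
    for (sp in ogs$species) {
      genes <- ogs$members[[i]][[sp]]
      expected <- if (length(genes) == 0) "absent" else {
        cls <- de[[sp]]$class[match(genes, de[[sp]]$gene_id)]
        up <- any(cls %in% c("DEG_up", "HDEG_up"))
        dn <- any(cls %in% c("DEG_down", "HDEG_down"))
        if (up && dn) "mixed" else if (up) "up" else if (dn) "down"
        else "tested_NS"
      }
      expect_identical(st[[sp]][i], expected)
    }
  }
})

test_that("sharing counts match brute-force subset enumeration", {
  set.seed(47)
  sp <- paste0("s", 1:5)
  ogs <- random_og_table(300, sp, p_present = 0.8)
  de <- lapply(stats::setNames(sp, sp), function(s) {
    genes <- unlist(lapply(ogs$members, `[[`, s), use.names = FALSE)
    make_de_stub(genes, sample(c("NS", "DEG_up", "DEG_down"),
                               length(genes), replace = TRUE,
                               prob = c(0.6, 0.2, 0.2)))
  })
  st <- build_sharing(ogs, de)
  sc <- sharing_counts(st, k_min = 4)

  resp <- sapply(sp, function(s) st[[s]] %in% c("up", "down", "mixed"))
  for (j in seq_len(nrow(sc$exact))) {
    sub <- strsplit(sc$exact$subset[j], "+", fixed = TRUE)[[1]]
    in_sub <- rowSums(resp[, sub, drop = FALSE]) == length(sub)
    none_out <- rowSums(resp[, setdiff(sp, sub), drop = FALSE]) == 0
    expect_equal(sc$exact$n_orthogroups[j], sum(in_sub & none_out))
    expect_equal(sc$at_least$n_orthogroups[j], sum(in_sub))
  }
  # conservation: exact counts partition the responsive-anywhere set
  expect_equal(sum(sc$exact$n_orthogroups), sum(rowSums(resp) > 0))
  expect_equal(sc$by_k$n_at_least[1], sum(rowSums(resp) > 0))
  expect_equal(sc$by_k$n_exact[5], sc$by_k$n_at_least[5])
  expect_equal(sc$n_at_least_k_min, sum(rowSums(resp) >= 4))
  # sankey rows correspond to responsive cells
  expect_equal(nrow(sc$sankey), sum(resp))
})

test_that("degenerate sharing configurations give the expected corner counts", {
  sp <- paste0("s", 1:5)
  members <- lapply(1:10, function(i)
    lapply(stats::setNames(sp, sp), function(s) paste0(s, "_g", i)))
  names(members) <- paste0("OG", 1:10)
  ogs <- orthogroup_table(members, species = sp)
  # all species responsive in the same 10 orthogroups
  de_all <- lapply(stats::setNames(sp, sp), function(s)
    make_de_stub(paste0(s, "_g", 1:10), rep("DEG_up", 10)))
  sc <- sharing_counts(build_sharing(ogs, de_all), k_min = 5)
  expect_equal(sc$by_k$n_exact[5], 10L)
  expect_equal(sc$n_at_least_k_min, 10L)
  # pairwise-disjoint responsive sets: no sharing at k >= 2
  de_disj <- lapply(stats::setNames(seq_along(sp), sp), function(i) {
    cls <- rep("NS", 10); cls[i] <- "DEG_up"  # species i responds in OG i only
    make_de_stub(paste0(sp[i], "_g", 1:10), cls)
  })
  sc2 <- sharing_counts(build_sharing(ogs, de_disj), k_min = 2)
  expect_equal(sc2$n_at_least_k_min, 0L)
})

test_that("orthogroup PCA separates species more than conditions by design", {
  set.seed(59)
  sp <- c("spA", "spB")
  members <- lapply(1:40, function(i)
    lapply(stats::setNames(sp, sp), function(s) paste0(s, "_g", i)))
  names(members) <- sprintf("OG%02d", 1:40)
  ogs <- orthogroup_table(members, species = sp)
  lens <- stats::setNames(rep(500, 80), unlist(members, use.names = FALSE))
  reps <- pick_representatives(ogs, lens)
  conserved <- conserved_orthogroups(ogs, sp)
  # strong species offset, weak condition offset
  expr <- lapply(stats::setNames(sp, sp), function(s) {
    base <- if (s == "spA") 6 else 60
    m <- matrix(rnbinom(40 * 6, mu = base, size = 20), nrow = 40,
                dimnames = list(paste0(s, "_g", 1:40),
                                paste0(s, "_", c("c1", "c2", "c3",
                                                 "k1", "k2", "k3"))))
    m
  })
  pca <- orthogroup_pca(expr, reps, conserved)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  expect_lte(sum(pca$var_explained), 1 + 1e-9)
  pc1 <- pca$coords$PC1
  is_a <- pca$coords$species_id == "spA"
  between <- abs(mean(pc1[is_a]) - mean(pc1[!is_a]))
  within <- max(stats::sd(pc1[is_a]), stats::sd(pc1[!is_a]))
  expect_gt(between, 2 * within)
})

test_that("duplicated samples land on identical PCA coordinates", {
  set.seed(61)
  sp <- "spA"
  members <- lapply(1:20, function(i) list(spA = paste0("g", i)))
  names(members) <- sprintf("OG%02d", 1:20)
  ogs <- orthogroup_table(members, species = sp)
  reps <- pick_representatives(ogs, stats::setNames(rep(100, 20),
                                                    paste0("g", 1:20)))
  m <- matrix(rnbinom(20 * 4, mu = 50, size = 10), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
  m <- cbind(m, dup = m[, "s1"])
  pca <- orthogroup_pca(list(spA = m), reps, conserved_orthogroups(ogs, sp))
  c1 <- unlist(pca$coords[pca$coords$sample_id == "s1", -(1:2)])
  c2 <- unlist(pca$coords[pca$coords$sample_id == "dup", -(1:2)])
  expect_equal(unname(c1), unname(c2), tolerance = 1e-9)
})
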