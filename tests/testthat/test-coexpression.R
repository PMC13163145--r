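test_that("TOM similarity is symmetric, bounded and unit-diagonal", {
  set.seed(2)
  expr <- matrix(rnorm(40 * 10), nrow = 40,
                 dimnames = list(paste0("g", 1:40), paste0("s", 1:10)))
  adj <- adjacency_matrix(expr, 6)
  expect_true(all(adj >= 0 & adj <= 1))
  expect_equal(unname(diag(adj)), rep(1, 40))
  tom <- tom_similarity(adj)
  expect_equal(tom, t(tom), tolerance = 1e-10)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(unname(diag(tom)), rep(1, 40))
})

test_that("soft power selection is deterministic and respects r2_target = 0", {
  set.seed(4)
  sim <- simulate_counts(sim_config(seed = 4, n_control = 6, n_cold = 6,
                                    p_responsive = rep(0, 5)),
                         sprintf("g%03d", 1:200))
  expr <- log2(sweep(sim$counts, 2, size_factors(sim$counts), "/") + 1)
  expect_equal(suppressWarnings(pick_soft_power(expr, r2_target = 0)), 1L)
  p1 <- suppressWarnings(pick_soft_power(expr))
  p2 <- suppressWarnings(pick_soft_power(expr))
  expect_identical(p1, p2)
})

test_that("identical genes collapse into a single module", {
  v <- c(1, 3, 2, 5, 4, 6, 2, 4, 3, 5)
  expr <- matrix(rep(v, times = 40), nrow = 40, byrow = TRUE,
                 dimnames = list(paste0("g", 1:40), paste0("s", 1:10)))
  net <- detect_modules(expr, 6, min_module_size = 10)
  expect_equal(length(setdiff(names(net$modules), "unassigned")), 1L)
  expect_equal(length(net$modules$M1), 40L)
})

test_that("planted module structure is recovered and order-invariant", {
  cfg <- sim_config(seed = 77, n_modules = 2, module_size = 50,
                    module_rho = 0.6, n_control = 15, n_cold = 15,
                    p_responsive = rep(0, 5))
  sim <- simulate_counts(cfg, sprintf("g%04d", 1:600))
  expr <- log2(sweep(sim$counts, 2, size_factors(sim$counts), "/") + 1)
  net <- suppressWarnings(detect_modules(expr, 7, min_module_size = 30))
  truth <- sim$truth$module
  truth[is.na(truth)] <- "background"
  ri <- rand_index(truth, unname(net$module_of[rownames(expr)]))
  expect_gt(ri, 0.9)

  perm <- sample(nrow(expr))
  net2 <- suppressWarnings(detect_modules(expr[perm, ], 7,
                                          min_module_size = 30))
  ri_perm <- rand_index(unname(net$module_of[rownames(expr)]),
                        unname(net2$module_of[rownames(expr)]))
  expect_equal(ri_perm, 1)
})

test_that("module eigengene captures the leading variance direction", {
  cfg <- sim_config(seed = 88, n_modules = 1, module_size = 40,
                    module_rho = 0.6, n_control = 8, n_cold = 8,
                    p_responsive = rep(0, 5))
  sim <- simulate_counts(cfg, sprintf("g%03d", 1:120))
  expr <- log2(sim$counts + 1)
  inmod <- !is.na(sim$truth$module)
  net <- suppressWarnings(detect_modules(expr[inmod, ], 6,
                                         min_module_size = 10))
  eig <- net$eigengenes["M1", ]
  x <- t(scale(t(expr[net$modules$M1, ])))
  # explained sum of squares of a unit-norm sample-combination w is ||Xw||^2,
  # maximized by the leading eigenvector of X^T X
  var_eig <- sum((x %*% eig)^2)
  lead <- eigen(t(x) %*% x)$vectors[, 1]
  expect_equal(var_eig, sum((x %*% lead)^2), tolerance = 1e-6)
  set.seed(1)
  for (i in 1:10) {
    u <- rnorm(length(eig)); u <- u / sqrt(sum(u^2))
    expect_gte(var_eig + 1e-9, sum((x %*% u)^2))
  }
  # orientation: genes correlate positively with their eigengene on average
  expect_gte(mean(stats::cor(t(expr[net$modules$M1, ]), eig)), 0)
})

test_that("module enrichment p-values equal exact hypergeometric tails", {
  # universe 20 genes, 5 DEGs, module of 4 containing 3 of them
  genes <- sprintf("g%02d", 1:20)
  net <- list(genes = genes,
              modules = list(M1 = genes[1:4], unassigned = genes[5:20]),
              tom = NULL)
  class(net) <- "coexpression_network"
  de <- data.frame(gene_id = genes, class = c(rep("DEG_up", 3), "NS",
                                              rep("DEG_up", 2),
                                              rep("NS", 14)),
                   stringsAsFactors = FALSE)
  enr <- module_deg_enrichment(net, de, direction = "any")
  expect_equal(enr$pvalue[enr$module_id == "M1"], 155 / 4845,
               tolerance = 1e-12)
  # a module with zero DEGs has p = P(X >= 0) = 1
  de0 <- de; de0$class <- "NS"
  enr0 <- module_deg_enrichment(net, de0, direction = "any")
  expect_equal(enr0$pvalue, 1)
})

test_that("hypergeometric tails match enumeration across exhaustive small cases", {
  for (N in c(5, 10, 17, 30)) {
    for (K in c(0, 2, floor(N / 2), N)) {
      for (n in c(1, 3, min(N, 7))) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_upper(k, K, n, N),
                       hyper_tail_enum(k, K, n, N), tolerance = 1e-10)
        }
      }
    }
  }
  expect_error(hypergeom_upper(5, 3, 4, 10), "invalid")
})

test_that("hub ranking follows within-module TOM connectivity with ties on gene id", {
  set.seed(6)
  sim <- simulate_counts(sim_config(seed = 6, n_modules = 1,
                                    module_size = 40, n_control = 8,
                                    n_cold = 8, p_responsive = rep(0, 5)),
                         sprintf("g%03d", 1:120))
  expr <- log2(sim$counts + 1)
  net <- suppressWarnings(detect_modules(expr, 6, min_module_size = 20))
  m <- setdiff(names(net$modules), "unassigned")[1]
  hubs <- hub_genes(net, m, top_n = 10)
  idx <- net$modules[[m]]
  k_oracle <- rowSums(net$tom[idx, idx]) - 1
  expected <- idx[order(-k_oracle, idx)][1:10]
  expect_identical(hubs$gene_id, expected)
  expect_equal(hubs$connectivity, unname(k_oracle[expected]))

  whole <- hub_genes(net, m, top_n = 10000)
  expect_equal(nrow(whole), length(idx))
  expect_error(hub_genes(net, "M99"), "unknown module")

  # annotation filter keeps only annotated genes
  ann <- data.frame(gene_id = idx[1:5], term_id = "T1",
                    stringsAsFactors = FALSE)
  class(ann) <- c("annotation_table", class(ann))
  hubs_ann <- hub_genes(net, m, top_n = 40, annot = ann)
  expect_true(all(hubs_ann$gene_id %in% idx[1:5]))
})

test_that("network edge export writes the strongest edges", {
  set.seed(8)
  expr <- matrix(rnorm(30 * 10), nrow = 30,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  net <- suppressWarnings(detect_modules(expr, 4, min_module_size = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  edges <- export_network_edges(net, path, top_edges = 20,
                                graphml_path = gml)
  expect_equal(nrow(edges), 20)
  expect_true(all(diff(edges$weight) <= 1e-12))
  expect_true(file.exists(gml))
  expect_match(readLines(gml, n = 2)[2], "graphml")
})
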