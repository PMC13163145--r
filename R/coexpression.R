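#' Co-expression adjacency from a gene x sample matrix
#'
#' Soft-threshold adjacency: `|cor|^power` (unsigned, the default) or
#' `((1 + cor)/2)^power` (signed) over Pearson correlations of genes.
#'
#' @param expr Gene x sample numeric matrix (log scale recommended).
#' @param power Positive integer soft-threshold exponent.
#' @param signed Use the signed transform instead of the unsigned one.
#' @return Symmetric adjacency matrix in \[0, 1\] with unit diagonal.
#' @export
adjacency_matrix <- function(expr, power, signed = FALSE) {
  if (power < 1) stop("power must be a positive integer")
  cc <- stats::cor(t(expr))
  a <- if (signed) ((1 + cc) / 2)^power else abs(cc)^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' TOM similarity: two genes overlap strongly when they are connected to
#' each other and share neighbors. For adjacency A with zeroed diagonal,
#' `TOM_ij = (L_ij + A_ij) / (min(k_i, k_j) + 1 - A_ij)` where
#' `L = A %*% A` and `k` is connectivity; the diagonal is 1.
#'
#' @param adj Symmetric adjacency matrix in \[0, 1\].
#' @return Symmetric TOM matrix in \[0, 1\] with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  num <- l + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom
}

# scale-free topology fit: R^2 of log10 p(k) ~ log10 k over connectivity bins,
# zeroed when the slope is not negative
scale_free_fit <- function(adj, n_bins = 10L) {
  k <- rowSums(adj) - 1
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(0)
  bin <- cut(k, breaks = n_bins, include.lowest = TRUE)  # equal-width bins
  logk <- log10(tapply(k, bin, mean))
  logp <- log10(tapply(k, bin, length) / length(k))
  ok <- is.finite(logk) & is.finite(logp)
  if (sum(ok) < 3L) return(0)
  r <- stats::cor(logk[ok], logp[ok])
  if (is.na(r) || r >= 0) 0 else r^2
}

#' Choose the soft-threshold power
#'
#' Sweeps powers 1..`max_power` and returns the smallest whose scale-free
#' topology fit R^2 reaches `r2_target`; if none qualifies, the power with
#' the best fit is returned with a warning. Constant genes are dropped
#' before fitting.
#'
#' @param expr Gene x sample matrix.
#' @param r2_target Scale-free fit threshold, default 0.8.
#' @param max_power Largest power tried, default 20.
#' @param signed Signed adjacency, default FALSE.
#' @return Positive integer power.
#' @export
pick_soft_power <- function(expr, r2_target = 0.8, max_power = 20L,
                            signed = FALSE) {
  if (ncol(expr) < 8L)
    warning("fewer than 8 samples; soft-power selection will be unstable")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped before power selection")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  fits <- numeric(max_power)
  for (p in seq_len(max_power)) {
    fits[p] <- scale_free_fit(adjacency_matrix(expr, p, signed = signed))
    if (fits[p] >= r2_target) return(p)
  }
  warning("no power reached scale-free R^2 of ", r2_target,
          "; returning best fit (R^2 = ", round(max(fits), 3), ")")
  which.max(fits)
}

# first principal component of a module's standardized expression across
# samples, oriented so the mean gene-eigengene correlation is non-negative
module_eigengene <- function(expr_mod) {
  x <- t(scale(t(expr_mod)))
  x[is.na(x)] <- 0
  sv <- svd(x, nu = 0, nv = 1)
  eig <- sv$v[, 1]
  ori <- mean(stats::cor(t(expr_mod), eig), na.rm = TRUE)
  if (!is.na(ori) && ori < 0) eig <- -eig
  stats::setNames(eig, colnames(expr_mod))
}

#' Detect co-expression modules
#'
#' The classic weighted-network recipe: soft-threshold adjacency,
#' topological-overlap dissimilarity (1 - TOM), average-linkage
#' hierarchical clustering, a static tree cut at `cut_height`, assignment
#' of undersized clusters to an "unassigned" bin, and iterative merging of
#' modules whose eigengenes correlate above `1 - merge_threshold`. Modules
#' are labelled M1, M2, ... in decreasing size order.
#'
#' @param expr Gene x sample matrix, already filtered to expressed genes.
#' @param power Soft-threshold power (see [pick_soft_power()]).
#' @param min_module_size Smallest retained module, default 30.
#' @param merge_threshold Eigengene dissimilarity below which modules merge,
#'   default 0.25 (i.e. merge when eigengene correlation > 0.75).
#' @param cut_height Static cut height on the 1 - TOM dendrogram,
#'   default 0.99.
#' @param signed Signed adjacency, default FALSE.
#' @return Object of class `coexpression_network`: `genes`, `soft_power`,
#'   `adjacency`, `tom`, `modules` (named list module -> genes; the
#'   `unassigned` bin holds leftovers), `module_of`, `eigengenes`
#'   (module x sample), `connectivity` (within-module TOM row sums).
#' @export
detect_modules <- function(expr, power, min_module_size = 30L,
                           merge_threshold = 0.25, cut_height = 0.99,
                           signed = FALSE) {
  genes <- rownames(expr)
  if (is.null(genes)) stop("expression matrix must have gene row names")
  adj <- adjacency_matrix(expr, power, signed = signed)
  tom <- tom_similarity(adj)
  if (length(genes) < min_module_size) {
    warning("fewer than min_module_size genes; returning a single module")
    labels <- rep(1L, length(genes))
  } else {
    hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
    labels <- stats::cutree(hc, h = min(cut_height, max(hc$height)))
  }
  # drop undersized clusters to the unassigned bin
  sizes <- table(labels)
  keep <- names(sizes)[sizes >= min_module_size]
  if (length(keep) == 0L) {
    warning("no cluster reached min_module_size; returning a single module")
    labels <- rep(1L, length(genes))
    keep <- "1"
  }
  member <- ifelse(labels %in% as.integer(keep), as.character(labels),
                   "unassigned")
  names(member) <- genes

  # merge modules with near-identical eigengenes
  repeat {
    mods <- setdiff(unique(member), "unassigned")
    if (length(mods) < 2L) break
    eig <- sapply(mods, function(m)
      module_eigengene(expr[member == m, , drop = FALSE]))
    ec <- stats::cor(eig)
    diag(ec) <- -Inf
    top <- which(ec == max(ec), arr.ind = TRUE)[1, ]
    if (ec[top[1], top[2]] <= 1 - merge_threshold) break
    member[member == mods[top[2]]] <- mods[top[1]]
  }

  mods <- setdiff(unique(member), "unassigned")
  mods <- mods[order(-vapply(mods, function(m) sum(member == m), integer(1)),
                     mods)]
  relabel <- stats::setNames(paste0("M", seq_along(mods)), mods)
  member[member != "unassigned"] <- relabel[member[member != "unassigned"]]

  module_list <- split(names(member), member)
  real_mods <- setdiff(names(module_list), "unassigned")
  real_mods <- real_mods[order(as.integer(sub("^M", "", real_mods)))]
  eigengenes <- t(sapply(real_mods, function(m)
    module_eigengene(expr[module_list[[m]], , drop = FALSE])))
  colnames(eigengenes) <- colnames(expr)

  connectivity <- stats::setNames(numeric(length(genes)), genes)
  for (m in real_mods) {
    idx <- module_list[[m]]
    tm <- tom[idx, idx, drop = FALSE]
    connectivity[idx] <- rowSums(tm) - 1  # exclude self (diagonal = 1)
  }
  structure(list(genes = genes, soft_power = power, adjacency = adj,
                 tom = tom, modules = module_list[c(real_mods,
                   intersect("unassigned", names(module_list)))],
                 module_of = member, eigengenes = eigengenes,
                 connectivity = connectivity, signed = signed),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  sizes <- vapply(x$modules, length, integer(1))
  cat("coexpression_network:", length(x$genes), "genes, power",
      x$soft_power, "\n")
  print(sizes)
  invisible(x)
}

#' Hypergeometric enrichment of DEGs within modules
#'
#' Tests each module for overrepresentation of significant genes with an
#' upper-tail hypergeometric test; the sampling universe is the set of
#' genes in the network. BH adjustment is applied across modules.
#'
#' @param net A `coexpression_network`.
#' @param de A `de_result` data.frame covering the network genes.
#' @param direction Which DEGs to test: `"any"`, `"up"` or `"down"`.
#' @param fdr_threshold Module significance cut on the BH-adjusted p,
#'   default 0.05.
#' @return data.frame `module_id`, `n_module`, `n_deg_in_module`,
#'   `n_deg_total`, `n_universe`, `pvalue`, `fdr`, `direction_tested`,
#'   `significant`.
#' @export
module_deg_enrichment <- function(net, de, direction = c("any", "up", "down"),
                                  fdr_threshold = 0.05) {
  direction <- match.arg(direction)
  universe <- net$genes
  miss <- setdiff(universe, de$gene_id)
  if (length(miss))
    stop("DE results missing for network gene(s): ",
         paste(utils::head(miss, 3), collapse = ", "))
  cls <- stats::setNames(de$class, de$gene_id)[universe]
  hit <- switch(direction,
                any = is_deg(cls),
                up = cls %in% c("DEG_up", "HDEG_up"),
                down = cls %in% c("DEG_down", "HDEG_down"))
  mods <- setdiff(names(net$modules), "unassigned")
  n_universe <- length(universe)
  n_deg <- sum(hit)
  rows <- lapply(mods, function(m) {
    idx <- universe %in% net$modules[[m]]
    k <- sum(hit & idx)
    data.frame(module_id = m, n_module = sum(idx), n_deg_in_module = k,
               n_deg_total = n_deg, n_universe = n_universe,
               pvalue = hypergeom_upper(k, n_deg, sum(idx), n_universe),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pvalue)
  out$direction_tested <- direction
  out$significant <- out$fdr < fdr_threshold
  out[order(out$pvalue), , drop = FALSE]
}

#' Rank a module's hub genes by intramodular connectivity
#'
#' Connectivity is each gene's within-module TOM row sum (self excluded).
#' Ties break on gene ID so rankings are deterministic. Optionally keeps
#' only genes with a non-empty annotation, mirroring "key genes with
#' homologous annotations".
#'
#' @param net A `coexpression_network`.
#' @param module_id Module to rank.
#' @param top_n Number of genes to return, default 40.
#' @param annot Optional `annotation_table`; when given, only annotated
#'   genes are eligible.
#' @return data.frame `gene_id`, `connectivity`, `rank`.
#' @export
hub_genes <- function(net, module_id, top_n = 40L, annot = NULL) {
  if (!module_id %in% names(net$modules))
    stop("unknown module: ", module_id)
  genes <- net$modules[[module_id]]
  if (!is.null(annot)) {
    annotated <- unique(annot$gene_id[!is.na(annot$term_id) & annot$term_id != ""])
    genes <- intersect(genes, annotated)
  }
  k <- net$connectivity[genes]
  ord <- order(-k, genes)
  genes <- genes[ord]
  k <- k[ord]
  n <- min(top_n, length(genes))
  data.frame(gene_id = genes[seq_len(n)], connectivity = unname(k[seq_len(n)]),
             rank = seq_len(n), stringsAsFactors = FALSE)
}

#' Export the strongest network edges
#'
#' Writes the top TOM edges as an edge-list TSV and (optionally) GraphML
#' for external graph viewers.
#'
#' @param net A `coexpression_network`.
#' @param path Output TSV path.
#' @param top_edges Number of strongest edges to keep, default 500.
#' @param graphml_path Optional GraphML output path.
#' @return Invisibly, the edge data.frame.
#' @export
export_network_edges <- function(net, path, top_edges = 500L,
                                 graphml_path = NULL) {
  tom <- net$tom
  ut <- upper.tri(tom)
  idx <- which(ut, arr.ind = TRUE)
  w <- tom[ut]
  ord <- order(-w)[seq_len(min(top_edges, length(w)))]
  edges <- data.frame(source = net$genes[idx[ord, 1]],
                      target = net$genes[idx[ord, 2]],
                      weight = w[ord], stringsAsFactors = FALSE)
  write_tsv(edges, path)
  if (!is.null(graphml_path)) {
    nodes <- unique(c(edges$source, edges$target))
    xml <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
             '<key id="w" for="edge" attr.name="weight" attr.type="double"/>',
             '<graph edgedefault="undirected">',
             sprintf('<node id="%s"/>', nodes),
             sprintf('<edge source="%s" target="%s"><data key="w">%.6g</data></edge>',
                     edges$source, edges$target, edges$weight),
             '</graph>', '</graphml>')
    writeLines(xml, graphml_path)
  }
  invisible(edges)
}
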