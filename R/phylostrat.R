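#' Assign each orthogroup to a phylostratum
#'
#' For every orthogroup containing at least one gene of the focal species,
#' the presence set is the set of species with >= 1 member. The orthogroup's
#' age is the smallest named clade (youngest stratum on the ladder) that
#' contains the MRCA of the presence set: a gene shared across the whole
#' tree maps to the oldest stratum, a gene found only in the focal lineage
#' maps to the youngest stratum containing it. Orthogroups without focal
#' genes get stratum `NA` and are excluded from the per-gene view; they
#' still appear in the orthogroup-level output so cross-species
#' presence/absence summaries can use them.
#'
#' @param ogs An `orthogroup_table`.
#' @param stree A `stratified_tree` whose leaves cover `ogs$species`.
#' @return An object of class `stratum_assignment`: list with
#'   `orthogroups` (data.frame orthogroup_id, mrca_node, stratum),
#'   `genes` (data.frame gene_id, orthogroup_id, stratum for the focal
#'   species), `strata` (ordered names) and `focal_species`.
#' @export
assign_strata <- function(ogs, stree) {
  stopifnot(inherits(ogs, "orthogroup_table"), inherits(stree, "stratified_tree"))
  tree <- stree$tree
  missing_sp <- setdiff(ogs$species, tree$tip.label)
  if (length(missing_sp))
    stop("species in orthogroup table but not in tree: ",
         paste(missing_sp, collapse = ", "))
  focal <- stree$focal_species
  if (!focal %in% ogs$species)
    stop("focal species ", focal, " absent from orthogroup table")
  strata_names <- stree$strata$name
  strata_nodes <- stree$strata$node

  n <- length(ogs$orthogroup_id)
  mrca <- integer(n)
  stratum <- rep(NA_character_, n)
  has_focal <- ogs$gene_counts[, focal] > 0L
  presence_mat <- ogs$gene_counts > 0L
  for (i in seq_len(n)) {
    if (!has_focal[i]) { mrca[i] <- NA_integer_; next }
    pres <- ogs$species[presence_mat[i, ]]
    nd <- mrca_node(tree, pres)
    mrca[i] <- nd
    anc <- ancestors_or_self(stree$parent, nd)
    on_ladder <- strata_nodes %in% anc
    if (!any(on_ladder))
      stop("no named stratum contains the MRCA of orthogroup ",
           ogs$orthogroup_id[i], "; is the ladder misconfigured?")
    stratum[i] <- strata_names[max(which(on_ladder))]
  }
  og_df <- data.frame(orthogroup_id = ogs$orthogroup_id,
                      mrca_node = mrca,
                      stratum = factor(stratum, levels = strata_names),
                      stringsAsFactors = FALSE)
  focal_members <- species_members(ogs, focal)
  n_gene <- vapply(focal_members, length, integer(1))
  genes <- data.frame(
    gene_id = unlist(focal_members, use.names = FALSE),
    orthogroup_id = rep(ogs$orthogroup_id, n_gene),
    stratum = factor(rep(stratum, n_gene), levels = strata_names),
    stringsAsFactors = FALSE)
  structure(list(orthogroups = og_df, genes = genes,
                 strata = strata_names, focal_species = focal),
            class = "stratum_assignment")
}

#' @export
print.stratum_assignment <- function(x, ...) {
  cat("stratum_assignment: focal =", x$focal_species, "\n")
  print(table(x$orthogroups$stratum, useNA = "ifany"))
  invisible(x)
}

#' Orthogroup and gene counts per phylostratum
#'
#' Tabulates, for the focal species, how many orthogroups and genes fall in
#' each age class (the shape of a per-species phylostratum census table).
#'
#' @param assign A `stratum_assignment`.
#' @return data.frame with `stratum` (oldest to youngest), `n_orthogroups`,
#'   `n_genes`.
#' @export
stratum_gene_counts <- function(assign) {
  stopifnot(inherits(assign, "stratum_assignment"))
  og_tab <- table(assign$orthogroups$stratum)
  gene_tab <- table(assign$genes$stratum)
  data.frame(stratum = assign$strata,
             n_orthogroups = as.integer(og_tab[assign$strata]),
             n_genes = as.integer(gene_tab[assign$strata]),
             stringsAsFactors = FALSE)
}

#' Select well-conserved, mostly single-copy orthogroups
#'
#' Applies the tree-ortholog selection filters: keep orthogroups whose
#' taxon occupancy (fraction of species with >= 1 gene) reaches
#' `min_occupancy` and whose single-copy fraction (fraction of species
#' contributing exactly one gene) reaches `min_single_copy_fraction`. With
#' the defaults this is "present in every species, single-copy in at least
#' half of them" — the usual criterion for phylogenomic marker sets.
#'
#' @param ogs An `orthogroup_table`.
#' @param min_occupancy Minimum fraction of species present, default 1.0.
#' @param min_single_copy_fraction Minimum fraction of species with exactly
#'   one gene, default 0.5.
#' @return Character vector of orthogroup IDs in input order.
#' @export
select_tree_orthologs <- function(ogs, min_occupancy = 1.0,
                                  min_single_copy_fraction = 0.5) {
  stopifnot(inherits(ogs, "orthogroup_table"))
  n_sp <- length(ogs$species)
  occ <- rowSums(ogs$gene_counts > 0L) / n_sp
  sc <- rowSums(ogs$gene_counts == 1L) / n_sp
  ogs$orthogroup_id[occ >= min_occupancy & sc >= min_single_copy_fraction]
}
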