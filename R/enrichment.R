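#' Upper-tail hypergeometric probability
#'
#' P(X >= k) when drawing `n` genes from a universe of `N` containing `K`
#' marked genes — the one-sided overrepresentation test used for both term
#' and module enrichment.
#'
#' @param k Observed overlap.
#' @param K Marked genes in the universe.
#' @param n Drawn genes (query set size).
#' @param N Universe size.
#' @return Probability in (0, 1\].
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("invalid hypergeometric configuration (k=", k, ", K=", K,
         ", n=", n, ", N=", N, ")")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term enrichment of a gene set against an annotation table
#'
#' Flat (no ontology propagation) hypergeometric enrichment: for each term
#' annotating at least `min_term_size` universe genes, tests whether the
#' query set overlaps it more than expected under sampling without
#' replacement from the universe. BH adjustment is applied across the
#' tested terms.
#'
#' @param genes Character vector, the query set (must be inside `universe`).
#' @param universe Character vector, the background gene set (typically all
#'   expressed genes of the run).
#' @param annot An `annotation_table` (columns `gene_id`, `term_id`,
#'   optional `name`, `namespace`).
#' @param min_term_size Smallest term (in universe genes) tested, default 3.
#' @return data.frame `term_id`, `name`, `namespace`, `k`, `K`, `n`, `N`,
#'   `pvalue`, `fdr`, sorted by p-value.
#' @export
term_enrichment <- function(genes, universe, annot, min_term_size = 3L) {
  genes <- unique(genes)
  universe <- unique(universe)
  outside <- setdiff(genes, universe)
  if (length(outside))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  ann <- annot[annot$gene_id %in% universe, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id")])
  term_genes <- split(ann$gene_id, ann$term_id)
  term_genes <- term_genes[lengths(term_genes) >= min_term_size]
  if (length(term_genes) == 0L)
    return(data.frame(term_id = character(0), name = character(0),
                      namespace = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), pvalue = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE))
  N <- length(universe)
  n <- length(genes)
  rows <- lapply(names(term_genes), function(tid) {
    tg <- term_genes[[tid]]
    data.frame(term_id = tid, k = length(intersect(genes, tg)),
               K = length(tg), n = n, N = N, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pvalue <- mapply(hypergeom_upper, out$k, out$K, out$n, MoreArgs = list(N = N))
  out$fdr <- bh_adjust(out$pvalue)
  meta <- unique(annot[, intersect(c("term_id", "name", "namespace"),
                                   names(annot)), drop = FALSE])
  out$name <- meta$name[match(out$term_id, meta$term_id)]
  out$name[is.na(out$name)] <- out$term_id[is.na(out$name)]
  out$namespace <- if ("namespace" %in% names(meta))
    meta$namespace[match(out$term_id, meta$term_id)] else NA_character_
  out <- out[order(out$pvalue, out$term_id),
             c("term_id", "name", "namespace", "k", "K", "n", "N",
               "pvalue", "fdr")]
  rownames(out) <- NULL
  out
}

#' Terms significantly enriched in several species
#'
#' Cross-tabulates per-species enrichment tables and keeps the terms that
#' pass the per-species FDR threshold in at least `min_species` species,
#' marking each species' direction (`up`, `down`, `both`, or `ns`). Input
#' tables may carry a `direction` column (from testing up- and
#' down-regulated sets separately); without one the direction is reported
#' as `any`.
#'
#' @param per_species Named list species_id -> enrichment data.frame (as
#'   from [term_enrichment()], optionally with a `direction` column).
#' @param min_species Minimum number of species a term must be significant
#'   in, default 3.
#' @param fdr_threshold Per-species significance cut, default 0.05.
#' @return data.frame with `term_id`, `name`, `n_species_significant` and
#'   one direction column per species.
#' @export
shared_term_summary <- function(per_species, min_species = 3L,
                                fdr_threshold = 0.05) {
  if (length(per_species) < 2L)
    stop("need enrichment tables for at least 2 species")
  sp_list <- names(per_species)
  sig_rows <- lapply(per_species, function(df) {
    if (is.null(df$direction)) df$direction <- "any"
    df[df$fdr < fdr_threshold, c("term_id", "name", "direction"), drop = FALSE]
  })
  all_terms <- unique(unlist(lapply(sig_rows, `[[`, "term_id")))
  if (length(all_terms) == 0L)
    return(data.frame(term_id = character(0), name = character(0),
                      n_species_significant = integer(0),
                      stringsAsFactors = FALSE))
  dir_mat <- sapply(sp_list, function(sp) {
    df <- sig_rows[[sp]]
    vapply(all_terms, function(tid) {
      d <- unique(df$direction[df$term_id == tid])
      if (length(d) == 0L) "ns"
      else if (all(c("up", "down") %in% d)) "both"
      else paste(sort(d), collapse = "/")
    }, character(1))
  })
  dir_mat <- matrix(dir_mat, nrow = length(all_terms),
                    dimnames = list(all_terms, sp_list))
  n_sig <- rowSums(dir_mat != "ns")
  name_map <- unique(do.call(rbind, lapply(sig_rows, function(d)
    d[, c("term_id", "name")])))
  out <- data.frame(term_id = all_terms,
                    name = name_map$name[match(all_terms, name_map$term_id)],
                    n_species_significant = as.integer(n_sig),
                    dir_mat, stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[out$n_species_significant >= min_species, , drop = FALSE]
  out <- out[order(-out$n_species_significant, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
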