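#' Load and normalize a run configuration
#'
#' Accepts a YAML file path or a list. Fills defaults, validates required
#' fields, and computes a short hash of the canonical configuration that is
#' embedded in every output header so results are traceable to their
#' settings.
#'
#' @param config YAML path or list.
#' @return Normalized config list with a `config_hash` element.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(seed = 1L, out_dir = "orthostress_out",
                   input_dir = NULL, simulate = FALSE, sim = list(),
                   focal_species = NULL, strata = NULL,
                   expressed_min_mean = 1.0,
                   thresholds = de_thresholds(),
                   k_min = 4L,
                   min_occupancy = 1.0, min_single_copy_fraction = 0.5,
                   modules = list(power = NULL, min_module_size = 30L,
                                  merge_threshold = 0.25, max_genes = 300L,
                                  r2_target = 0.8),
                   enrichment = list(min_term_size = 3L, min_species = 3L,
                                     fdr_threshold = 0.05))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$input_dir)) cfg$input_dir <- file.path(cfg$out_dir, "sim")
  # hash the scientific settings only: where the run lives on disk must not
  # change its content
  canon <- cfg[setdiff(names(cfg), c("config_hash", "out_dir", "input_dir"))]
  canon <- canon[order(names(canon))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(canon, tmp, auto_unbox = TRUE, digits = NA)
  cfg$config_hash <- substr(unname(tools::md5sum(tmp)), 1, 8)
  cfg
}

output_comment <- function(cfg) {
  paste0("orthostress ", as.character(utils::packageVersion("orthostress")),
         " config=", cfg$config_hash)
}

read_inputs <- function(cfg) {
  list(ogs = read_orthogroups(file.path(cfg$input_dir, "orthogroups.tsv")),
       tree = read_tree(file.path(cfg$input_dir, "tree.nwk")),
       samples = read_sample_sheet(file.path(cfg$input_dir, "samples.tsv")))
}

counts_path <- function(cfg, sp) file.path(cfg$input_dir,
                                           paste0("counts_", sp, ".tsv"))

read_de_output <- function(cfg, sp) {
  path <- file.path(cfg$out_dir, paste0("de_", sp, ".tsv"))
  if (!file.exists(path))
    stop("DE results for ", sp, " not found (run the 'de' stage first): ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  class(df) <- c("de_result", class(df))
  df
}

stage_strata <- function(cfg) {
  inp <- read_inputs(cfg)
  if (is.null(cfg$strata)) stop("config field 'strata' (node-label ladder) is required")
  focal <- cfg$focal_species
  if (is.null(focal)) stop("config field 'focal_species' is required")
  stree <- stratified_tree(inp$tree, cfg$strata, focal)
  assign <- assign_strata(inp$ogs, stree)
  cm <- output_comment(cfg)
  og_df <- assign$orthogroups
  og_df$stratum <- as.character(og_df$stratum)
  write_tsv(og_df, file.path(cfg$out_dir, "strata.tsv"), comment = cm)
  write_tsv(stratum_gene_counts(assign),
            file.path(cfg$out_dir, "stratum_counts.tsv"), comment = cm)
  write_tsv(data.frame(orthogroup_id = select_tree_orthologs(
              inp$ogs, cfg$min_occupancy, cfg$min_single_copy_fraction)),
            file.path(cfg$out_dir, "tree_orthologs.tsv"), comment = cm)
  invisible(assign)
}

stage_de <- function(cfg) {
  inp <- read_inputs(cfg)
  cm <- output_comment(cfg)
  for (sp in unique(inp$samples$species_id)) {
    sheet <- inp$samples[inp$samples$species_id == sp, , drop = FALSE]
    counts <- read_counts(counts_path(cfg, sp), sheet)
    res <- de_test(counts, sheet, expressed_min_mean = cfg$expressed_min_mean,
                   thresholds = cfg$thresholds)
    write_tsv(res, file.path(cfg$out_dir, paste0("de_", sp, ".tsv")),
              comment = cm)
  }
  invisible(NULL)
}

stage_compare <- function(cfg) {
  inp <- read_inputs(cfg)
  cm <- output_comment(cfg)
  sp_list <- unique(inp$samples$species_id)
  de <- lapply(stats::setNames(sp_list, sp_list),
               function(sp) read_de_output(cfg, sp))
  st <- build_sharing(inp$ogs, de)
  write_tsv(st, file.path(cfg$out_dir, "sharing.tsv"), comment = cm)
  sc <- sharing_counts(st, k_min = min(cfg$k_min, length(sp_list)))
  venn <- merge(sc$exact, sc$at_least, by = c("subset", "k"),
                suffixes = c("_exact", "_at_least"))
  venn <- venn[order(venn$k, venn$subset), ]
  write_tsv(venn, file.path(cfg$out_dir, "venn_counts.tsv"), comment = cm)
  write_tsv(sc$sankey, file.path(cfg$out_dir, "sankey.tsv"), comment = cm)

  lengths_file <- file.path(cfg$input_dir, "lengths.tsv")
  if (file.exists(lengths_file)) {
    lens <- read_lengths(lengths_file)
    conserved <- conserved_orthogroups(inp$ogs, sp_list)
    if (length(conserved) >= 2L) {
      reps <- pick_representatives(inp$ogs, lens)
      expr <- lapply(stats::setNames(sp_list, sp_list), function(sp)
        read_counts(counts_path(cfg, sp),
                    inp$samples[inp$samples$species_id == sp, , drop = FALSE]))
      pca <- orthogroup_pca(expr, reps, conserved)
      n_pc <- min(5L, ncol(pca$coords) - 2L)
      write_tsv(pca$coords[, c("sample_id", "species_id",
                               paste0("PC", seq_len(n_pc)))],
                file.path(cfg$out_dir, "pca_coords.tsv"), comment = cm)
      write_tsv(data.frame(component = seq_along(pca$var_explained),
                           var_explained = pca$var_explained),
                file.path(cfg$out_dir, "pca_variance.tsv"), comment = cm)
    }
  }
  invisible(st)
}

stage_modules <- function(cfg) {
  inp <- read_inputs(cfg)
  cm <- output_comment(cfg)
  sp <- cfg$focal_species
  if (is.null(sp)) stop("config field 'focal_species' is required")
  sheet <- inp$samples[inp$samples$species_id == sp, , drop = FALSE]
  counts <- read_counts(counts_path(cfg, sp), sheet)
  de <- read_de_output(cfg, sp)
  sf <- size_factors(counts)
  nc <- sweep(counts, 2, sf, "/")
  expressed <- de$gene_id[de$expressed]
  expr <- log2(nc[rownames(nc) %in% expressed, , drop = FALSE] + 1)
  vars <- apply(expr, 1, stats::var)
  keep <- order(-vars)[seq_len(min(cfg$modules$max_genes, nrow(expr)))]
  expr <- expr[sort(keep), , drop = FALSE]
  power <- cfg$modules$power
  if (is.null(power))
    power <- pick_soft_power(expr, r2_target = cfg$modules$r2_target)
  net <- detect_modules(expr, power,
                        min_module_size = cfg$modules$min_module_size,
                        merge_threshold = cfg$modules$merge_threshold)
  write_tsv(data.frame(gene_id = names(net$module_of),
                       module = unname(net$module_of)),
            file.path(cfg$out_dir, paste0("modules_", sp, ".tsv")),
            comment = cm)
  eig <- data.frame(module = rownames(net$eigengenes), net$eigengenes,
                    check.names = FALSE)
  write_tsv(eig, file.path(cfg$out_dir, paste0("eigengenes_", sp, ".tsv")),
            comment = cm)
  enr <- module_deg_enrichment(net, de, direction = "any",
                               fdr_threshold = cfg$enrichment$fdr_threshold)
  write_tsv(enr, file.path(cfg$out_dir,
                           paste0("module_enrichment_", sp, ".tsv")),
            comment = cm)
  ann_file <- file.path(cfg$input_dir, "annotations.tsv")
  annot <- if (file.exists(ann_file)) read_annotations(ann_file) else NULL
  hubs <- do.call(rbind, lapply(setdiff(names(net$modules), "unassigned"),
    function(m) {
      h <- hub_genes(net, m, top_n = 40L, annot = annot)
      if (nrow(h)) cbind(module = m, h) else NULL
    }))
  write_tsv(hubs, file.path(cfg$out_dir, paste0("hubs_", sp, ".tsv")),
            comment = cm)
  export_network_edges(net,
                       file.path(cfg$out_dir, paste0("edges_", sp, ".tsv")),
                       graphml_path = file.path(cfg$out_dir,
                                                paste0("network_", sp,
                                                       ".graphml")))
  invisible(net)
}

stage_enrich <- function(cfg) {
  inp <- read_inputs(cfg)
  cm <- output_comment(cfg)
  ann_file <- file.path(cfg$input_dir, "annotations.tsv")
  if (!file.exists(ann_file)) stop("annotations.tsv not found in ",
                                   cfg$input_dir)
  annot <- read_annotations(ann_file)
  sp_list <- unique(inp$samples$species_id)
  tables <- list()
  for (sp in sp_list) {
    de <- read_de_output(cfg, sp)
    universe <- de$gene_id[de$expressed]
    if (!any(universe %in% annot$gene_id)) next
    per_dir <- lapply(c(up = "up", down = "down"), function(d) {
      genes <- de$gene_id[de$class %in% paste0(c("DEG_", "HDEG_"), d)]
      et <- term_enrichment(genes, universe, annot,
                            min_term_size = cfg$enrichment$min_term_size)
      if (nrow(et)) cbind(et, direction = d) else NULL
    })
    tab <- do.call(rbind, per_dir)
    if (is.null(tab)) next
    rownames(tab) <- NULL
    tables[[sp]] <- tab
    write_tsv(tab, file.path(cfg$out_dir, paste0("enrichment_", sp, ".tsv")),
              comment = cm)
  }
  if (length(tables) >= 2L) {
    shared <- shared_term_summary(tables,
                                  min_species = cfg$enrichment$min_species,
                                  fdr_threshold = cfg$enrichment$fdr_threshold)
    write_tsv(shared, file.path(cfg$out_dir, "shared_terms.tsv"),
              comment = cm)
  }
  invisible(tables)
}

stage_plasticity <- function(cfg) {
  inp <- read_inputs(cfg)
  cm <- output_comment(cfg)
  stree <- stratified_tree(inp$tree, cfg$strata, cfg$focal_species)
  assign <- assign_strata(inp$ogs, stree)
  de <- read_de_output(cfg, cfg$focal_species)
  pt <- plasticity_table(assign, de)
  write_tsv(pt, file.path(cfg$out_dir, "plasticity.tsv"), comment = cm)
  trends <- do.call(rbind, lapply(c("deg", "hdeg"), function(mt) {
    tr <- age_trend_test(pt, metric = mt)
    data.frame(metric = mt, statistic = tr$statistic, pvalue = tr$pvalue,
               direction = tr$direction, monotone = tr$monotone_flag,
               stringsAsFactors = FALSE)
  }))
  write_tsv(trends, file.path(cfg$out_dir, "trend.tsv"), comment = cm)
  write_tsv(stratum_fold_change(pt, "deg"),
            file.path(cfg$out_dir, "stratum_fold.tsv"), comment = cm)
  invisible(pt)
}

stage_simulate <- function(cfg) {
  sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$sim)
  scfg <- do.call(sim_config, sim_args)
  simulate_study(scfg, cfg$input_dir)
  invisible(NULL)
}

#' Run one pipeline stage (or the whole pipeline)
#'
#' Stages: `simulate` (emit a synthetic input bundle), `strata` (gene-age
#' assignment), `de` (per-species NB differential expression), `compare`
#' (orthogroup-level sharing, Venn/Sankey tables, orthogroup PCA),
#' `modules` (co-expression network of the focal species), `enrich` (term
#' enrichment per species plus the cross-species shared-term summary),
#' `plasticity` (age x plasticity table, trend test, fold table), and
#' `all` (everything in dependency order, preceded by `simulate` when the
#' config sets `simulate: true`). After the stage completes, a
#' `manifest.json` with MD5 checksums of every file in the output
#' directory is (re)written. On failure, files newly created by the failed
#' stage are removed.
#'
#' @param stage Stage name.
#' @param config YAML path or config list (see [load_run_config()]).
#' @return Invisibly, the manifest data.frame.
#' @export
run_stage <- function(stage = c("simulate", "strata", "de", "compare",
                                "modules", "enrich", "plasticity", "all"),
                      config) {
  stage <- match.arg(stage)
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  before <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  run_one <- function(s) switch(s,
    simulate = stage_simulate(cfg),
    strata = stage_strata(cfg),
    de = stage_de(cfg),
    compare = stage_compare(cfg),
    modules = stage_modules(cfg),
    enrich = stage_enrich(cfg),
    plasticity = stage_plasticity(cfg))
  result <- tryCatch({
    if (stage == "all") {
      if (isTRUE(cfg$simulate)) run_one("simulate")
      for (s in c("strata", "de", "compare", "modules", "enrich",
                  "plasticity"))
        run_one(s)
    } else run_one(stage)
    TRUE
  }, error = function(e) {
    after <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
    unlink(setdiff(after, before))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  manifest <- write_manifest(cfg$out_dir)
  invisible(manifest)
}

#' Write a checksum manifest of an output directory
#'
#' @param out_dir Directory to index.
#' @return data.frame `file` (relative path), `md5`, also written to
#'   `manifest.json` inside `out_dir`.
#' @export
write_manifest <- function(out_dir) {
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  md5 <- unname(tools::md5sum(file.path(out_dir, files)))
  manifest <- data.frame(file = files, md5 = md5, stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
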