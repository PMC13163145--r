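#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults mirror
#' the shape of a multi-species cold-stress study at desk scale: six
#' species on a ladder-shaped (pectinate) tree giving five nested strata,
#' about 2000 orthogroups born mostly on the oldest stratum, five control
#' and five cold replicates per species, log-normal baseline expression
#' with NB dispersion 0.1, and an age-dependent probability of responding
#' to cold that rises from the oldest stratum to the youngest.
#'
#' @param seed Integer master seed; all stage streams derive from it.
#' @param species Tip labels, ordered focal-first along the ladder.
#' @param focal_species Focal species (defaults to the first).
#' @param strata_births Named integer vector: orthogroups born per stratum,
#'   oldest to youngest; names become stratum names.
#' @param genes_per_cell_lambda Extra genes per orthogroup x species beyond
#'   the first follow Poisson(lambda).
#' @param loss_rate Probability a non-focal descendant species loses an
#'   orthogroup (0 = noise-free presence).
#' @param n_control,n_cold Replicates per condition.
#' @param mu_meanlog,mu_sdlog Log-normal parameters of baseline means.
#' @param dispersion NB dispersion (1/size).
#' @param p_responsive Per-stratum probability that a gene responds to
#'   cold, oldest to youngest.
#' @param lfc_magnitude Planted |log2 fold change| of responsive genes
#'   (sign random).
#' @param sf_range Range of log-uniform sample size factors.
#' @param n_modules,module_size,module_rho Co-expression module structure:
#'   number of planted modules, genes per module, target within-module
#'   expression correlation.
#' @param module_min_mu Smallest baseline mean eligible for module
#'   membership; below it count noise would hide the latent factor.
#' @param n_terms,term_size_range,n_enriched_terms Annotation model: number
#'   of terms, range of term sizes, and how many terms are planted as
#'   enriched among responsive genes.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       species = paste0("sp", 1:6),
                       focal_species = species[1],
                       strata_births = c(stratum_1 = 1000L, stratum_2 = 200L,
                                         stratum_3 = 150L, stratum_4 = 150L,
                                         stratum_5 = 500L),
                       genes_per_cell_lambda = 0.3,
                       loss_rate = 0,
                       n_control = 5L, n_cold = 5L,
                       mu_meanlog = 4, mu_sdlog = 1.5,
                       dispersion = 0.1,
                       p_responsive = c(0.05, 0.08, 0.10, 0.15, 0.20),
                       lfc_magnitude = 3,
                       sf_range = c(0.7, 1.4),
                       n_modules = 4L, module_size = 50L, module_rho = 0.6,
                       module_min_mu = 50,
                       n_terms = 40L, term_size_range = c(10L, 50L),
                       n_enriched_terms = 4L) {
  n_strata <- length(species) - 1L
  if (length(strata_births) != n_strata)
    stop("strata_births must have one entry per stratum (", n_strata, ")")
  if (length(p_responsive) != n_strata)
    stop("p_responsive must have one entry per stratum (", n_strata, ")")
  if (any(p_responsive < 0 | p_responsive > 1))
    stop("p_responsive entries must lie in [0, 1]")
  if (any(strata_births < 1)) stop("strata_births must be positive")
  if (!focal_species %in% species) stop("focal species must be a tip")
  cfg <- list(seed = as.integer(seed), species = species,
              focal_species = focal_species,
              strata_births = strata_births,
              genes_per_cell_lambda = genes_per_cell_lambda,
              loss_rate = loss_rate,
              n_control = as.integer(n_control), n_cold = as.integer(n_cold),
              mu_meanlog = mu_meanlog, mu_sdlog = mu_sdlog,
              dispersion = dispersion,
              p_responsive = stats::setNames(p_responsive, names(strata_births)),
              lfc_magnitude = lfc_magnitude, sf_range = sf_range,
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              module_rho = module_rho, module_min_mu = module_min_mu,
              n_terms = as.integer(n_terms),
              term_size_range = as.integer(term_size_range),
              n_enriched_terms = as.integer(n_enriched_terms))
  class(cfg) <- "sim_config"
  cfg
}

#' Derive a reproducible per-stage seed from a master seed
#'
#' A named-stream splitter: each pipeline stage draws its randomness from
#' `stage_seed(seed, stage)`, so partial reruns of one stage reproduce the
#' full-run output.
#'
#' @param seed Integer master seed.
#' @param stage Stage name string.
#' @return Integer seed in \[0, 2^31).
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483629
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# variance of log2(X + 1) for X ~ NB(mu, size = 1/disp), computed from the
# pmf on a log-mu grid and interpolated; first-order delta approximations
# undershoot badly at small means
nb_log2_var <- function(mu, disp) {
  grid_mu <- exp(seq(log(max(min(mu), 1e-3)), log(max(mu)), length.out = 60L))
  grid_var <- vapply(grid_mu, function(m) {
    kmax <- max(20, stats::qnbinom(1 - 1e-8, mu = m, size = 1 / disp))
    k <- 0:kmax
    p <- stats::dnbinom(k, mu = m, size = 1 / disp)
    lx <- log2(k + 1)
    sum(p * lx^2) - sum(p * lx)^2
  }, numeric(1))
  stats::approx(log(grid_mu), grid_var, xout = log(mu), rule = 2)$y
}

# ladder (pectinate) tree over cfg$species with internal nodes labelled by
# the stratum names, oldest (root) to youngest
sim_tree <- function(cfg) {
  sp <- cfg$species
  strata <- names(cfg$strata_births)
  n <- length(sp)
  nwk <- paste0("(", sp[1], ",", sp[2], ")", strata[n - 1])
  if (n > 2L) {
    for (i in 3:n)
      nwk <- paste0("(", nwk, ",", sp[i], ")", strata[n - i + 1L])
  }
  tree <- ape::read.tree(text = paste0(nwk, ";"))
  stratified_tree(tree, strata, cfg$focal_species)
}

#' Simulate orthogroup births on a stratified species tree
#'
#' Each orthogroup is born on one stratum's branch and is present in all
#' (and, with `loss_rate = 0`, only) species descending from that node,
#' with per-species gene counts of 1 + Poisson(lambda). The focal species
#' never loses an orthogroup, so every simulated orthogroup is age-assignable.
#'
#' @param cfg A `sim_config`.
#' @return List with `ogs` (an `orthogroup_table`), `stree` (a
#'   `stratified_tree`) and `truth` (data.frame `orthogroup_id`,
#'   `stratum`).
#' @export
simulate_orthology <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "orthology"))
  stree <- sim_tree(cfg)
  strata <- names(cfg$strata_births)
  n_og <- sum(cfg$strata_births)
  og_ids <- sprintf("OG%05d", seq_len(n_og))
  og_stratum <- rep(strata, cfg$strata_births)
  clade_of <- lapply(stree$strata$node, function(nd) clade_tips(stree$tree, nd))
  names(clade_of) <- strata
  gene_counter <- stats::setNames(integer(length(cfg$species)), cfg$species)
  members <- vector("list", n_og)
  for (i in seq_len(n_og)) {
    present <- clade_of[[og_stratum[i]]]
    if (cfg$loss_rate > 0) {
      lost <- present != cfg$focal_species &
        stats::runif(length(present)) < cfg$loss_rate
      present <- present[!lost]
    }
    m <- stats::setNames(vector("list", length(cfg$species)), cfg$species)
    for (sp in cfg$species) {
      if (!sp %in% present) { m[[sp]] <- character(0); next }
      n_gene <- 1L + stats::rpois(1, cfg$genes_per_cell_lambda)
      ids <- sprintf("%s_g%05d", sp, gene_counter[sp] + seq_len(n_gene))
      gene_counter[sp] <- gene_counter[sp] + n_gene
      m[[sp]] <- ids
    }
    members[[i]] <- m
  }
  names(members) <- og_ids
  ogs <- orthogroup_table(members, species = cfg$species)
  truth <- data.frame(orthogroup_id = og_ids, stratum = og_stratum,
                      stringsAsFactors = FALSE)
  list(ogs = ogs, stree = stree, truth = truth)
}

#' Simulate an NB count matrix with planted condition effects and modules
#'
#' Counts follow `NB(mu_g * s_j * 2^(+/- lfc_g / 2), dispersion)`: the
#' planted fold change is split symmetrically between conditions. Size
#' factors are log-uniform over `sf_range`. A gene responds to cold with
#' the probability of its stratum (or, without strata, the mean of
#' `p_responsive`). Planted co-expression modules share a per-sample latent
#' factor whose per-gene loading is calibrated so the expected
#' within-module log-expression correlation is `module_rho`.
#'
#' @param cfg A `sim_config`.
#' @param genes Character vector of gene IDs to simulate.
#' @param strata_of Optional named character vector gene_id -> stratum
#'   controlling per-gene response probability.
#' @param species_id Species label for the sample sheet, default the focal.
#' @param stream Extra string mixed into the seed so each species gets an
#'   independent stream.
#' @return List with `counts` (gene x sample integer matrix, unit counts),
#'   `samples` (sample-sheet data.frame) and `truth` (data.frame `gene_id`,
#'   `responsive`, `true_lfc`, `module`).
#' @export
simulate_counts <- function(cfg, genes, strata_of = NULL,
                            species_id = cfg$focal_species,
                            stream = species_id) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, paste0("counts:", stream)))
  n_gene <- length(genes)
  n_samp <- cfg$n_control + cfg$n_cold
  cond <- rep(c("control", "cold"), c(cfg$n_control, cfg$n_cold))
  samples <- data.frame(
    sample_id = paste0(species_id, "_", cond, "_",
                       c(seq_len(cfg$n_control), seq_len(cfg$n_cold))),
    species_id = species_id, condition = cond,
    replicate = c(seq_len(cfg$n_control), seq_len(cfg$n_cold)),
    stringsAsFactors = FALSE)

  p_resp <- if (is.null(strata_of)) rep(mean(cfg$p_responsive), n_gene)
            else unname(cfg$p_responsive[strata_of[genes]])
  if (anyNA(p_resp)) stop("missing stratum for some genes in strata_of")
  responsive <- stats::runif(n_gene) < p_resp
  true_lfc <- ifelse(responsive,
                     sample(c(-1, 1), n_gene, replace = TRUE) * cfg$lfc_magnitude,
                     0)
  mu <- stats::rlnorm(n_gene, cfg$mu_meanlog, cfg$mu_sdlog)
  sf <- exp(stats::runif(n_samp, log(cfg$sf_range[1]), log(cfg$sf_range[2])))

  module <- rep(NA_character_, n_gene)
  n_mod_gene <- cfg$n_modules * cfg$module_size
  if (cfg$n_modules > 0L && n_mod_gene <= n_gene) {
    # modules live among well-expressed, non-responsive genes: at low means
    # count noise swamps the latent factor, and planted condition effects add
    # variance orthogonal to it; either washes out the configured correlation
    eligible <- which(mu >= cfg$module_min_mu & !responsive)
    if (length(eligible) < n_mod_gene)
      eligible <- setdiff(order(-mu), which(responsive))
    if (length(eligible) >= n_mod_gene) {
      picked <- eligible[sample.int(length(eligible), n_mod_gene)]
      module[picked] <- rep(paste0("mod", seq_len(cfg$n_modules)),
                            each = cfg$module_size)
    } else {
      warning("too few eligible genes to plant ", cfg$n_modules,
              " modules; module structure skipped for this matrix")
    }
  }
  # latent factor per module x sample; per-gene loading calibrated so that
  # on the log2(x+1) scale factor variance / total variance ~ module_rho
  factor_mat <- if (cfg$n_modules > 0L)
    matrix(stats::rnorm(cfg$n_modules * n_samp),
           nrow = cfg$n_modules, ncol = n_samp,
           dimnames = list(paste0("mod", seq_len(cfg$n_modules)), NULL))
  loading <- if (any(!is.na(module))) {
    noise_var <- nb_log2_var(mu, cfg$dispersion)
    log(2) * sqrt(cfg$module_rho / (1 - cfg$module_rho) * noise_var)
  } else numeric(n_gene)

  counts <- matrix(0L, nrow = n_gene, ncol = n_samp,
                   dimnames = list(genes, samples$sample_id))
  half <- ifelse(cond == "cold", 0.5, -0.5)
  for (j in seq_len(n_samp)) {
    m <- mu * sf[j] * 2^(half[j] * true_lfc)
    in_mod <- !is.na(module)
    if (any(in_mod)) {
      f <- factor_mat[module[in_mod], j]
      m[in_mod] <- m[in_mod] *
        exp(loading[in_mod] * f - loading[in_mod]^2 / 2)
    }
    counts[, j] <- stats::rnbinom(n_gene, mu = m, size = 1 / cfg$dispersion)
  }
  attr(counts, "unit") <- "counts"
  truth <- data.frame(gene_id = genes, responsive = responsive,
                      true_lfc = true_lfc, module = module,
                      stringsAsFactors = FALSE)
  list(counts = counts, samples = samples, truth = truth)
}

#' Simulate a gene annotation table with planted enriched terms
#'
#' Background terms sample genes uniformly; planted enriched terms draw 70%
#' of their genes from the responsive set, so downstream term enrichment of
#' the DEG set has known positives.
#'
#' @param cfg A `sim_config`.
#' @param genes All gene IDs of the annotated species.
#' @param responsive Logical vector parallel to `genes`.
#' @return List `annotations` (data.frame gene_id, term_id, name,
#'   namespace) and `truth` (data.frame term_id, enriched).
#' @export
simulate_annotations <- function(cfg, genes, responsive) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "annotations"))
  term_ids <- sprintf("T%04d", seq_len(cfg$n_terms))
  enriched <- seq_len(cfg$n_terms) <= cfg$n_enriched_terms
  resp_genes <- genes[responsive]
  rows <- lapply(seq_len(cfg$n_terms), function(i) {
    size <- sample(seq(cfg$term_size_range[1], cfg$term_size_range[2]), 1)
    if (enriched[i] && length(resp_genes) >= 2L) {
      n_resp <- min(length(resp_genes), ceiling(0.7 * size))
      g <- c(sample(resp_genes, n_resp),
             sample(setdiff(genes, resp_genes), size - n_resp))
    } else {
      g <- sample(genes, size)
    }
    data.frame(gene_id = g, term_id = term_ids[i],
               name = paste0("term ", term_ids[i]),
               namespace = "synthetic", stringsAsFactors = FALSE)
  })
  list(annotations = do.call(rbind, rows),
       truth = data.frame(term_id = term_ids, enriched = enriched,
                          stringsAsFactors = FALSE))
}

#' Emit a complete synthetic input bundle with truth files
#'
#' Writes everything a full pipeline run consumes — orthogroups.tsv,
#' tree.nwk, samples.tsv, one counts_<species>.tsv per species,
#' lengths.tsv, annotations.tsv — plus `truth/` tables recording every
#' planted quantity. Byte-identical for a fixed config (same seed
#' included).
#'
#' @param cfg A `sim_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`ogs`, `stree`,
#'   `counts` per species, `samples`, `truths`).
#' @export
simulate_study <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  orth <- simulate_orthology(cfg)
  write_orthogroups(orth$ogs, file.path(dir, "orthogroups.tsv"))
  write_tree(orth$stree$tree, file.path(dir, "tree.nwk"))
  write_tsv(orth$truth, file.path(dir, "truth", "strata.tsv"))

  og_stratum <- stats::setNames(orth$truth$stratum, orth$truth$orthogroup_id)
  all_samples <- list()
  counts_list <- list()
  de_truths <- list()
  for (sp in cfg$species) {
    mem <- species_members(orth$ogs, sp)
    n_per_og <- vapply(mem, length, integer(1))
    genes <- unlist(mem, use.names = FALSE)
    strata_of <- stats::setNames(
      rep(unname(og_stratum[orth$ogs$orthogroup_id]), n_per_og), genes)
    sim <- simulate_counts(cfg, genes, strata_of = strata_of, species_id = sp)
    write_counts(sim$counts, file.path(dir, paste0("counts_", sp, ".tsv")))
    write_tsv(sim$truth, file.path(dir, "truth", paste0("de_", sp, ".tsv")))
    all_samples[[sp]] <- sim$samples
    counts_list[[sp]] <- sim$counts
    de_truths[[sp]] <- sim$truth
  }
  samples <- do.call(rbind, all_samples)
  rownames(samples) <- NULL
  write_tsv(samples, file.path(dir, "samples.tsv"))

  set.seed(stage_seed(cfg$seed, "lengths"))
  all_genes <- unlist(lapply(cfg$species,
                             function(sp) rownames(counts_list[[sp]])),
                      use.names = FALSE)
  lengths_df <- data.frame(gene_id = all_genes,
                           length = sample(300:3000, length(all_genes),
                                           replace = TRUE),
                           stringsAsFactors = FALSE)
  write_tsv(lengths_df, file.path(dir, "lengths.tsv"))

  focal_truth <- de_truths[[cfg$focal_species]]
  ann <- simulate_annotations(cfg, focal_truth$gene_id, focal_truth$responsive)
  write_tsv(ann$annotations, file.path(dir, "annotations.tsv"))
  write_tsv(ann$truth, file.path(dir, "truth", "terms.tsv"))

  invisible(list(ogs = orth$ogs, stree = orth$stree, truth_strata = orth$truth,
                 counts = counts_list, samples = samples,
                 de_truths = de_truths, annotations = ann$annotations,
                 truth_terms = ann$truth))
}
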