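#' Orthogroups conserved across a species set
#'
#' @param ogs An `orthogroup_table`.
#' @param species Character vector of species that must all be present
#'   (>= 1 gene each). An empty vector imposes no condition and returns
#'   every orthogroup.
#' @return Character vector of orthogroup IDs in input order.
#' @export
conserved_orthogroups <- function(ogs, species) {
  stopifnot(inherits(ogs, "orthogroup_table"))
  unknown <- setdiff(species, ogs$species)
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "))
  if (length(species) == 0L) return(ogs$orthogroup_id)
  keep <- rowSums(ogs$gene_counts[, species, drop = FALSE] > 0L) == length(species)
  ogs$orthogroup_id[keep]
}

#' Pick the longest gene as each orthogroup's species representative
#'
#' For every orthogroup x species cell with at least one member, selects the
#' gene with the greatest transcript length; ties go to the
#' lexicographically smallest gene ID so the choice is deterministic.
#'
#' @param ogs An `orthogroup_table`.
#' @param lengths Named numeric vector gene_id -> length (bp); every member
#'   gene must have an entry.
#' @return data.frame `orthogroup_id`, `species_id`, `gene_id`.
#' @export
pick_representatives <- function(ogs, lengths) {
  stopifnot(inherits(ogs, "orthogroup_table"))
  out <- vector("list", length(ogs$orthogroup_id) * length(ogs$species))
  k <- 0L
  for (i in seq_along(ogs$orthogroup_id)) {
    for (sp in ogs$species) {
      genes <- ogs$members[[i]][[sp]]
      if (length(genes) == 0L) next
      miss <- genes[!genes %in% names(lengths)]
      if (length(miss))
        stop("no length for gene(s): ", paste(miss, collapse = ", "))
      len <- lengths[genes]
      best <- genes[len == max(len)]
      k <- k + 1L
      out[[k]] <- data.frame(orthogroup_id = ogs$orthogroup_id[i],
                             species_id = sp,
                             gene_id = min(best),
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Lift gene-level DE calls to orthogroup-level response statuses
#'
#' Per orthogroup and species: `up` when at least one member is significantly
#' up and none down, `down` symmetrically, `mixed` when both directions
#' occur, `tested_NS` when members exist but none is significant, and
#' `absent` when the species has no members. An orthogroup is "responsive"
#' in a species when its status is up, down or mixed.
#'
#' @param ogs An `orthogroup_table`.
#' @param de Named list species_id -> `de_result` data.frame.
#' @return data.frame of class `sharing_table`: `orthogroup_id`, one status
#'   column per species, `n_species_responsive`, `conserved` (present in
#'   all species with DE results).
#' @export
build_sharing <- function(ogs, de) {
  stopifnot(inherits(ogs, "orthogroup_table"))
  sp_list <- names(de)
  if (is.null(sp_list) || !all(sp_list %in% ogs$species))
    stop("DE results must be a named list keyed by species in the table")
  gene_class <- lapply(de, function(d) stats::setNames(d$class, d$gene_id))
  status <- matrix("absent", nrow = length(ogs$orthogroup_id),
                   ncol = length(sp_list),
                   dimnames = list(ogs$orthogroup_id, sp_list))
  for (i in seq_along(ogs$orthogroup_id)) {
    for (sp in sp_list) {
      genes <- ogs$members[[i]][[sp]]
      if (length(genes) == 0L) next
      cls <- gene_class[[sp]][genes]
      cls <- cls[!is.na(cls)]
      any_up <- any(cls %in% c("DEG_up", "HDEG_up"))
      any_down <- any(cls %in% c("DEG_down", "HDEG_down"))
      status[i, sp] <-
        if (any_up && any_down) "mixed"
        else if (any_up) "up"
        else if (any_down) "down"
        else "tested_NS"
    }
  }
  responsive <- status %in% c("up", "down", "mixed")
  dim(responsive) <- dim(status)
  out <- data.frame(orthogroup_id = ogs$orthogroup_id, status,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$n_species_responsive <- rowSums(responsive)
  out$conserved <- rowSums(status == "absent") == 0L
  attr(out, "species") <- sp_list
  class(out) <- c("sharing_table", class(out))
  out
}

#' Cross-species sharing counts (Venn/upset view) and Sankey export
#'
#' Counts orthogroups by the exact set of species in which they are
#' responsive, and by superset ("responsive in at least these species"),
#' plus the cumulative count of orthogroups responsive in >= `k_min`
#' species. Both subset readings are reported because published Venn
#' diagrams are ambiguous between them. Also emits a long
#' (orthogroup, species, direction) table for Sankey-style flow plots.
#'
#' @param st A `sharing_table` from [build_sharing()].
#' @param k_min Minimum number of responsive species for the cumulative
#'   count, in `[1, n_species]`. Default 1.
#' @return List with `exact` (subset, k, n_orthogroups), `at_least`
#'   (subset, n_orthogroups with responsive set containing the subset),
#'   `by_k` (k, n_exact, n_at_least), `n_at_least_k_min`, `members`
#'   (named list subset -> orthogroup IDs) and `sankey`
#'   (orthogroup_id, species_id, direction).
#' @export
sharing_counts <- function(st, k_min = 1L) {
  sp_list <- attr(st, "species")
  n_sp <- length(sp_list)
  if (k_min < 1L || k_min > n_sp) stop("k_min must lie in [1, n_species]")
  status <- as.matrix(st[, sp_list, drop = FALSE])
  resp <- status == "up" | status == "down" | status == "mixed"
  key <- apply(resp, 1, function(r) paste(sp_list[r], collapse = "+"))

  subsets <- unlist(lapply(seq_len(n_sp), function(k)
    utils::combn(sp_list, k, paste, collapse = "+", simplify = FALSE)))
  exact_n <- vapply(subsets, function(s) sum(key == s), integer(1))
  subset_members <- strsplit(subsets, "+", fixed = TRUE)
  at_least_n <- vapply(subset_members, function(s)
    sum(rowSums(resp[, s, drop = FALSE]) == length(s)), integer(1))
  k_of <- lengths(subset_members)
  n_resp <- rowSums(resp)
  by_k <- data.frame(k = seq_len(n_sp),
                     n_exact = vapply(seq_len(n_sp), function(k)
                       sum(n_resp == k), integer(1)),
                     n_at_least = vapply(seq_len(n_sp), function(k)
                       sum(n_resp >= k), integer(1)))
  members <- lapply(subsets, function(s) st$orthogroup_id[key == s])
  names(members) <- subsets

  sankey_idx <- which(resp, arr.ind = TRUE)
  sankey <- data.frame(
    orthogroup_id = st$orthogroup_id[sankey_idx[, 1]],
    species_id = sp_list[sankey_idx[, 2]],
    direction = status[sankey_idx],
    stringsAsFactors = FALSE)
  sankey <- sankey[order(sankey$orthogroup_id, sankey$species_id), ,
                   drop = FALSE]
  rownames(sankey) <- NULL

  list(exact = data.frame(subset = subsets, k = k_of, n_orthogroups = exact_n,
                          stringsAsFactors = FALSE),
       at_least = data.frame(subset = subsets, k = k_of,
                             n_orthogroups = at_least_n,
                             stringsAsFactors = FALSE),
       by_k = by_k,
       n_at_least_k_min = sum(n_resp >= k_min),
       members = members,
       sankey = sankey)
}

#' PCA of samples over conserved-orthogroup representatives
#'
#' Stacks all species' samples into one matrix whose features are conserved
#' orthogroups, each species contributing the expression of its
#' representative gene. Expression is log2(x + 1) transformed and each
#' orthogroup feature is z-scored across samples before the PCA, so species
#' and condition structure — not expression scale — drives the components.
#' Component signs follow the convention that the largest-magnitude loading
#' is positive.
#'
#' @param expr Named list species_id -> expression matrix (samples in
#'   columns; TPM recommended).
#' @param reps Representative map from [pick_representatives()].
#' @param conserved Character vector of conserved orthogroup IDs to use.
#' @return List with `coords` (data.frame sample_id, species_id, PC
#'   columns) and `var_explained` (fraction per component, non-increasing).
#' @export
orthogroup_pca <- function(expr, reps, conserved) {
  sp_list <- names(expr)
  blocks <- lapply(sp_list, function(sp) {
    r <- reps[reps$species_id == sp & reps$orthogroup_id %in% conserved, ,
              drop = FALSE]
    r <- r[match(conserved, r$orthogroup_id), , drop = FALSE]
    if (anyNA(r$gene_id))
      stop("species ", sp, " lacks representatives for some conserved orthogroups")
    miss <- setdiff(r$gene_id, rownames(expr[[sp]]))
    if (length(miss))
      stop("representative gene(s) absent from ", sp, " matrix: ",
           paste(utils::head(miss, 3), collapse = ", "))
    m <- t(log2(expr[[sp]][r$gene_id, , drop = FALSE] + 1))
    colnames(m) <- conserved
    data.frame(sample_id = rownames(m), species_id = sp, m,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  stacked <- do.call(rbind, blocks)
  x <- as.matrix(stacked[, conserved, drop = FALSE])
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples")
  x <- scale(x)
  keep <- !is.na(colSums(x))  # drop zero-variance features
  x <- x[, keep, drop = FALSE]
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  # orient each component so its largest-|loading| feature is positive
  for (j in seq_len(ncol(pc$rotation))) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- data.frame(stacked[, c("sample_id", "species_id")], pc$x,
                       stringsAsFactors = FALSE, row.names = NULL)
  list(coords = coords, var_explained = var_explained)
}
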