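#' Construct an orthogroup membership table
#'
#' The central homology container: for each orthogroup, the gene IDs each
#' species contributes. Every downstream stage (gene-age assignment,
#' cross-species sharing, conserved-set selection) keys on this object.
#'
#' @param members Named list, one element per orthogroup. Each element is a
#'   named list mapping `species_id` to a character vector of gene IDs
#'   (possibly empty). The species name set must be identical across
#'   orthogroups.
#' @param species Optional character vector fixing species column order.
#'   Defaults to the order seen in the first orthogroup.
#' @return An object of class `orthogroup_table` with components
#'   `orthogroup_id`, `species`, `members` and a `gene_counts` integer matrix
#'   (orthogroups x species).
#' @export
orthogroup_table <- function(members, species = NULL) {
  if (length(members) == 0L) stop("orthogroup table must contain at least one orthogroup")
  og_ids <- names(members)
  if (is.null(og_ids) || anyNA(og_ids) || any(og_ids == ""))
    stop("every orthogroup must be named")
  if (anyDuplicated(og_ids))
    stop("duplicate orthogroup IDs: ", paste(unique(og_ids[duplicated(og_ids)]), collapse = ", "))
  if (is.null(species)) species <- names(members[[1]])
  if (is.null(species) || anyDuplicated(species))
    stop("species names must be present and unique")
  members <- lapply(members, function(m) {
    if (!setequal(names(m), species))
      stop("species set differs across orthogroups; expected {",
           paste(species, collapse = ", "), "}")
    lapply(m[species], as.character)
  })
  all_genes <- unlist(members, use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    dup <- unique(all_genes[duplicated(all_genes)])
    stop("gene(s) assigned to more than one orthogroup: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  counts <- matrix(0L, nrow = length(members), ncol = length(species),
                   dimnames = list(og_ids, species))
  for (i in seq_along(members))
    counts[i, ] <- vapply(members[[i]], length, integer(1))
  structure(list(orthogroup_id = og_ids, species = species,
                 members = members, gene_counts = counts),
            class = "orthogroup_table")
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat("orthogroup_table:", length(x$orthogroup_id), "orthogroups x",
      length(x$species), "species\n")
  cat("species:", paste(x$species, collapse = ", "), "\n")
  cat("total genes:", sum(x$gene_counts), "\n")
  invisible(x)
}

#' Genes of one species across all orthogroups
#'
#' @param ogs An `orthogroup_table`.
#' @param species_id Species to extract.
#' @return Named list orthogroup_id -> character vector of gene IDs.
#' @export
species_members <- function(ogs, species_id) {
  stopifnot(inherits(ogs, "orthogroup_table"))
  if (!species_id %in% ogs$species)
    stop("unknown species: ", species_id)
  lapply(ogs$members, `[[`, species_id)
}

split_member_cell <- function(cell) {
  # OrthoFinder writes "g1, g2"; tolerate bare commas and stray whitespace
  cell <- trimws(cell)
  if (is.na(cell) || cell == "") return(character(0))
  trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
}

#' Read an OrthoFinder-style orthogroups table
#'
#' Parses the `Orthogroups.tsv` dialect: first column is the orthogroup ID,
#' remaining columns are per-species comma-separated gene lists. Empty cells
#' become empty member lists. Species column order is taken from the header
#' and preserved in all outputs.
#'
#' @param path Path to a TSV file.
#' @param dialect Input dialect; only `"orthofinder_tsv"` is supported.
#' @return An `orthogroup_table`.
#' @export
read_orthogroups <- function(path, dialect = "orthofinder_tsv") {
  dialect <- match.arg(dialect, "orthofinder_tsv")
  if (!file.exists(path)) stop("orthogroups file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stop("orthogroups file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 2L) stop("orthogroups header must name at least one species")
  species <- header[-1]
  ncol_expect <- length(header)
  members <- vector("list", length(fields) - 1L)
  og_ids <- character(length(members))
  for (i in seq_along(members)) {
    row <- fields[[i + 1L]]
    # trailing empty cells are dropped by strsplit; pad them back
    if (length(row) < ncol_expect) row <- c(row, rep("", ncol_expect - length(row)))
    if (length(row) != ncol_expect)
      stop("ragged row at line ", i + 1L, ": expected ", ncol_expect,
           " columns, found ", length(row))
    og_ids[i] <- row[1]
    m <- lapply(row[-1], split_member_cell)
    names(m) <- species
    members[[i]] <- m
  }
  names(members) <- og_ids
  orthogroup_table(members, species = species)
}

#' Write an orthogroup table in OrthoFinder TSV dialect
#'
#' @param ogs An `orthogroup_table`.
#' @param path Output path.
#' @param comment Optional header comment (written as `# ...` first line).
#' @export
write_orthogroups <- function(ogs, path, comment = NULL) {
  stopifnot(inherits(ogs, "orthogroup_table"))
  rows <- vapply(seq_along(ogs$orthogroup_id), function(i) {
    cells <- vapply(ogs$members[[i]], paste, character(1), collapse = ", ")
    paste(c(ogs$orthogroup_id[i], cells), collapse = "\t")
  }, character(1))
  header <- paste(c("Orthogroup", ogs$species), collapse = "\t")
  out <- c(if (!is.null(comment)) paste0("# ", comment), header, rows)
  writeLines(out, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Expects columns `sample_id`, `species_id`, `condition`, `replicate`.
#' Conditions must be `control` or `cold`; each species must have both
#' conditions with at least `min_replicates` replicates each.
#'
#' @param path TSV path.
#' @param min_replicates Minimum replicates required per species x condition.
#' @return A data.frame with validated columns.
#' @export
read_sample_sheet <- function(path, min_replicates = 2L) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_sample_sheet(df, min_replicates = min_replicates)
}

#' Validate a sample-sheet data.frame
#'
#' @param df data.frame with `sample_id`, `species_id`, `condition`, `replicate`.
#' @param min_replicates Minimum replicates per species x condition.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_sample_sheet <- function(df, min_replicates = 2L) {
  need <- c("sample_id", "species_id", "condition", "replicate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("sample sheet missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample IDs: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$condition), c("control", "cold"))
  if (length(bad))
    stop("condition must be 'control' or 'cold'; found: ", paste(bad, collapse = ", "))
  if (any(df$replicate < 1)) stop("replicate must be a positive integer")
  tab <- table(df$species_id, df$condition)
  for (sp in rownames(tab)) {
    for (cond in c("control", "cold")) {
      n <- if (cond %in% colnames(tab)) tab[sp, cond] else 0L
      if (n < min_replicates)
        stop("species ", sp, " has ", n, " '", cond, "' replicates; need >= ",
             min_replicates)
    }
  }
  df
}

#' Read a gene x sample count (or TPM) matrix
#'
#' First column must hold gene IDs; remaining columns are samples. Columns
#' are checked against, and reordered to, the sample sheet.
#'
#' @param path TSV path.
#' @param samples Sample-sheet data.frame (only its `sample_id` column is
#'   used; pass the full sheet or a subset for one species).
#' @param unit `"counts"` (default) or `"tpm"`. DE testing requires counts;
#'   TPM matrices are accepted for PCA-style analyses only.
#' @return Numeric matrix (genes x samples) with attribute `unit`.
#' @export
read_counts <- function(path, samples, unit = c("counts", "tpm")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("expression matrix not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs in matrix: ",
         paste(unique(gene_ids[duplicated(gene_ids)])[1:3], collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- gene_ids
  missing_samp <- setdiff(samples$sample_id, colnames(mat))
  if (length(missing_samp))
    stop("sample(s) declared in sheet but absent from matrix: ",
         paste(missing_samp, collapse = ", "))
  mat <- mat[, samples$sample_id, drop = FALSE]
  if (anyNA(mat)) stop("expression matrix contains missing values")
  if (any(mat < 0)) stop("expression matrix contains negative values")
  if (unit == "counts" && any(mat != round(mat)))
    stop("unit 'counts' requires integer values; use unit = 'tpm' for reals")
  attr(mat, "unit") <- unit
  mat
}

#' Write an expression matrix as TSV
#'
#' @param mat Gene x sample matrix.
#' @param path Output path.
#' @param comment Optional `#` header comment.
#' @export
write_counts <- function(mat, path, comment = NULL) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, comment = comment)
}

#' Write a data.frame as TSV with an optional comment header
#'
#' @param df data.frame.
#' @param path Output path.
#' @param comment Optional comment string written as a `# ` first line.
#' @export
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-length table
#'
#' @param path TSV with columns `gene_id`, `length`.
#' @return Named numeric vector of lengths.
#' @export
read_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("gene_id", "length") %in% names(df)))
    stop("lengths table needs columns gene_id, length")
  if (any(df$length <= 0)) stop("gene lengths must be positive")
  stats::setNames(df$length, df$gene_id)
}

#' Read a gene-to-term annotation table
#'
#' @param path TSV with columns `gene_id`, `term_id` and optional `name`,
#'   `namespace`.
#' @return data.frame of class `annotation_table`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("gene_id", "term_id") %in% names(df)))
    stop("annotation table needs columns gene_id, term_id")
  if (is.null(df$name)) df$name <- df$term_id
  if (is.null(df$namespace)) df$namespace <- NA_character_
  class(df) <- c("annotation_table", class(df))
  df
}
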