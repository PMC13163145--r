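#' Read a rooted species tree from a Newick file
#'
#' Leaf labels must be unique; internal node labels are optional but are
#' what the phylostratum ladder refers to. An unrooted or root-multifurcating
#' tree is accepted with a warning.
#'
#' @param path Newick file path.
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable Newick file: ", path,
                                            " (", conditionMessage(e), ")"))
  if (is.null(tree)) stop("unparseable Newick file: ", path)
  validate_species_tree(tree)
}

#' Validate a species tree object
#'
#' @param tree An `ape::phylo`.
#' @return The tree, invisibly unchanged.
#' @export
validate_species_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!is.null(tree$node.label)) {
    nl <- tree$node.label[tree$node.label != ""]
    if (anyDuplicated(nl))
      stop("duplicate internal node label(s): ",
           paste(unique(nl[duplicated(nl)]), collapse = ", "))
  }
  if (!ape::is.rooted(tree))
    warning("tree is not strictly rooted (root multifurcation); proceeding")
  tree
}

#' Write a tree to Newick
#'
#' @param tree `ape::phylo`.
#' @param path Output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# parent node of every node (0 for the root), as an integer vector
node_parents <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

# ancestors of a node from itself up to the root (inclusive of the node)
ancestors_or_self <- function(parent, node) {
  out <- node
  while (parent[node] != 0L) {
    node <- parent[node]
    out <- c(out, node)
  }
  out
}

# internal node id for a node label
node_id_for_label <- function(tree, label) {
  if (is.null(tree$node.label)) stop("tree has no internal node labels")
  hit <- which(tree$node.label == label)
  if (length(hit) == 0L) stop("internal node label not found in tree: ", label)
  hit[1] + ape::Ntip(tree)
}

#' Build a stratified species tree
#'
#' Attaches an ordered phylostratum ladder to a rooted tree. Strata are
#' named internal nodes along the path from the root to the focal species,
#' ordered oldest (most inclusive clade) to youngest. Each gene age class is
#' "the smallest named clade containing the orthogroup's MRCA", so the
#' ladder must be strictly nested; this is checked here.
#'
#' @param tree Rooted `ape::phylo` with labelled internal nodes.
#' @param strata Character vector of internal node labels, ordered oldest to
#'   youngest, or a data.frame with columns `name` and `node_label` when the
#'   stratum display name differs from the tree label.
#' @param focal_species Tip label of the focal species whose genes get ages.
#' @return An object of class `stratified_tree`.
#' @export
stratified_tree <- function(tree, strata, focal_species) {
  validate_species_tree(tree)
  if (!focal_species %in% tree$tip.label)
    stop("focal species not a leaf of the tree: ", focal_species)
  if (is.character(strata))
    strata <- data.frame(name = strata, node_label = strata,
                         stringsAsFactors = FALSE)
  if (!all(c("name", "node_label") %in% names(strata)))
    stop("strata must be a character vector or data.frame(name, node_label)")
  if (nrow(strata) == 0L) stop("at least one stratum is required")
  if (anyDuplicated(strata$name)) stop("stratum names must be unique")
  strata$node <- vapply(strata$node_label, node_id_for_label,
                        integer(1), tree = tree)
  parent <- node_parents(tree)
  focal_tip <- match(focal_species, tree$tip.label)
  path_nodes <- ancestors_or_self(parent, focal_tip)
  off_path <- setdiff(strata$node, path_nodes)
  if (length(off_path))
    stop("stratum node(s) not on the root-to-focal path: ",
         paste(strata$node_label[strata$node %in% off_path], collapse = ", "))
  # oldest-to-youngest must mean strictly shrinking clades (strict nesting)
  sizes <- vapply(strata$node, function(nd) length(clade_tips(tree, nd)),
                  integer(1))
  if (any(diff(sizes) >= 0))
    stop("strata are not strictly nested oldest to youngest; clade sizes: ",
         paste(sizes, collapse = ", "))
  structure(list(tree = tree, strata = strata, focal_species = focal_species,
                 parent = parent),
            class = "stratified_tree")
}

#' @export
print.stratified_tree <- function(x, ...) {
  cat("stratified_tree:", ape::Ntip(x$tree), "species, focal =",
      x$focal_species, "\n")
  cat("strata (oldest -> youngest):", paste(x$strata$name, collapse = " > "),
      "\n")
  invisible(x)
}

#' Tip labels of the clade under a node
#'
#' @param tree `ape::phylo`.
#' @param node Node id (tip ids are their own single-leaf clade).
#' @return Character vector of tip labels.
#' @export
clade_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

#' MRCA node of a species set
#'
#' @param tree `ape::phylo`.
#' @param species Character vector of tip labels (length >= 1).
#' @return Node id; for a single species, the tip itself.
#' @export
mrca_node <- function(tree, species) {
  missing_sp <- setdiff(species, tree$tip.label)
  if (length(missing_sp))
    stop("species not in tree: ", paste(missing_sp, collapse = ", "))
  if (length(species) == 1L) return(match(species, tree$tip.label))
  ape::getMRCA(tree, species)
}
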