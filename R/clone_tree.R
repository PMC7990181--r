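MUT_CLASSES <- c("snv", "indel", "cna", "sv")

#' Construct a clonal lineage tree
#'
#' A clone tree is the rooted lineage of inferred subclonal populations of
#' one tumor: the root is the normal/diploid founder, each edge carries the
#' counts of somatic events (by class) acquired along it, and each clone has
#' a cellular prevalence. This is the summary-level object that phylogenetic
#' deconvolution tools produce; the package consumes it, it does not infer
#' it.
#'
#' @param nodes Character vector of clone identifiers (including the root).
#' @param root Identifier of the normal founder clone.
#' @param parent Named character vector mapping each non-root node to its
#'   parent.
#' @param edge_counts Numeric matrix, rows named by child node, columns
#'   `snv`, `indel`, `cna`, `sv`; counts of events acquired on the edge
#'   parent -> child. All counts must be `>= 0`.
#' @param prevalence Named numeric vector of clone prevalences in `[0, 1]`;
#'   non-root prevalences must sum to at most `1 + tol`.
#' @param tol Tolerance for the prevalence-sum invariant.
#' @return A list of class `clone_tree`.
#' @export
clone_tree <- function(nodes, root, parent, edge_counts, prevalence = NULL,
                       tol = 1e-6) {
  tr <- structure(list(nodes = as.character(nodes), root = as.character(root),
                       parent = parent, edge_counts = edge_counts,
                       prevalence = prevalence),
                  class = "clone_tree")
  validate_clone_tree(tr, tol = tol)
}

#' @rdname clone_tree
#' @param tree A `clone_tree` object.
#' @export
validate_clone_tree <- function(tree, tol = 1e-6) {
  nodes <- tree$nodes
  if (anyDuplicated(nodes))
    abort_evorisk("duplicate clone identifiers", "evorisk_structure_error")
  if (!tree$root %in% nodes)
    abort_evorisk("root is not among the nodes", "evorisk_structure_error")
  children <- setdiff(nodes, tree$root)
  if (!setequal(names(tree$parent), children))
    abort_evorisk("parent map must cover exactly the non-root nodes",
                  "evorisk_structure_error")
  if (!all(tree$parent %in% nodes))
    abort_evorisk("parent map points outside the node set",
                  "evorisk_structure_error")
  # Walk each node to the root; a cycle or self-parent never terminates there.
  for (nd in children) {
    seen <- character()
    cur <- nd
    while (cur != tree$root) {
      if (cur %in% seen)
        abort_evorisk(sprintf("cycle in parent map at node '%s'", nd),
                      "evorisk_structure_error")
      seen <- c(seen, cur)
      cur <- tree$parent[[cur]]
    }
  }
  ec <- tree$edge_counts
  if (length(children)) {
    if (!is.matrix(ec) || !setequal(rownames(ec), children) ||
        !all(MUT_CLASSES %in% colnames(ec)))
      abort_evorisk("edge_counts must be a child-by-class matrix",
                    "evorisk_structure_error")
    if (any(ec < 0) || any(is.na(ec)))
      abort_evorisk("edge counts must be nonnegative",
                    "evorisk_validation_error")
  }
  if (!is.null(tree$prevalence)) {
    pv <- tree$prevalence
    if (!all(names(pv) %in% nodes) || any(pv < -tol) || any(pv > 1 + tol))
      abort_evorisk("prevalences must be named by node and lie in [0, 1]",
                    "evorisk_validation_error")
    if (sum(pv) > 1 + tol)
      abort_evorisk("prevalences must sum to <= 1",
                    "evorisk_validation_error")
  }
  tree
}

#' Read / write clone trees
#'
#' Clone trees are stored one per file in a documented JSON schema (fields
#' `nodes`, `root`, `parent`, `edge_counts`, `prevalence`). JSON rather
#' than Newick because per-edge multi-class counts and per-clone
#' prevalences do not fit Newick cleanly. `read_clone_tree()` and
#' [write_clone_tree()] are mutually inverse on valid trees.
#'
#' @param path File path.
#' @return A validated `clone_tree`.
#' @export
read_clone_tree <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ec <- NULL
  if (!is.null(x$edge_counts) && length(x$edge_counts)) {
    ec <- as.matrix(as.data.frame(lapply(x$edge_counts[MUT_CLASSES],
                                         as.numeric)))
    rownames(ec) <- x$edge_counts$child
  }
  prev <- NULL
  if (!is.null(x$prevalence))
    prev <- stats::setNames(as.numeric(x$prevalence$value),
                            x$prevalence$node)
  parent <- stats::setNames(as.character(x$parent$parent), x$parent$child)
  clone_tree(nodes = x$nodes, root = x$root, parent = parent,
             edge_counts = ec, prevalence = prev)
}

#' @rdname read_clone_tree
#' @param tree A `clone_tree` object.
#' @export
write_clone_tree <- function(tree, path) {
  validate_clone_tree(tree)
  children <- setdiff(tree$nodes, tree$root)
  out <- list(
    nodes = tree$nodes, root = tree$root,
    parent = data.frame(child = names(tree$parent),
                        parent = unname(tree$parent)),
    edge_counts = if (length(children)) cbind(
      data.frame(child = rownames(tree$edge_counts)),
      as.data.frame(tree$edge_counts[, MUT_CLASSES, drop = FALSE])),
    prevalence = if (!is.null(tree$prevalence)) data.frame(
      node = names(tree$prevalence), value = unname(tree$prevalence)))
  jsonlite::write_json(out[!vapply(out, is.null, logical(1L))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Depth-first ancestry path from a node up to (excluding) the root.
path_to_root <- function(tree, node) {
  path <- character()
  cur <- node
  while (cur != tree$root) {
    path <- c(path, cur)
    cur <- tree$parent[[cur]]
  }
  path
}
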