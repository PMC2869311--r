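#' Build the binary hierarchy of master-regulator gene modules
#'
#' Cellular identities live on a complete binary tree (a Cayley tree with
#' branching factor 2): the root module governs the embryonic-stem (ES)
#' state and each node has two children representing the two lineages a
#' state can differentiate into. Nodes are numbered `0 .. 2^levels - 2`
#' in breadth-first order (root = 0, children of `i` are `2i+1`, `2i+2`),
#' so all relations reduce to O(1) index arithmetic.
#'
#' @param levels Depth of the hierarchy (integer >= 1). `levels = 1` is
#'   the degenerate single-module tree.
#' @param genes_per_module Number of individual genes per module
#'   (integer >= 1); 1 for the base model, >1 for the multi-gene variant.
#' @return An object of class `hierarchy_topology` with fields `levels`,
#'   `n_nodes`, `genes_per_module`, and precomputed `parent`, `sibling`
#'   and `children` relations (module ids are 0-based throughout).
#' @examples
#' topo <- build_hierarchy(4)
#' topo$n_nodes            # 15
#' nearest_neighbors(topo, 0)
#' @export
build_hierarchy <- function(levels, genes_per_module = 1L) {
  if (length(levels) != 1L || !is.finite(levels) || levels < 1 ||
      levels != as.integer(levels)) {
    stop("'levels' must be a single integer >= 1")
  }
  if (length(genes_per_module) != 1L || !is.finite(genes_per_module) ||
      genes_per_module < 1 || genes_per_module != as.integer(genes_per_module)) {
    stop("'genes_per_module' must be a single integer >= 1")
  }
  levels <- as.integer(levels)
  n <- 2L^levels - 1L
  ids <- 0:(n - 1L)
  parent <- ifelse(ids == 0L, NA_integer_, (ids - 1L) %/% 2L)
  sibling <- ifelse(ids == 0L, NA_integer_,
                    ifelse(ids %% 2L == 1L, ids + 1L, ids - 1L))
  children <- lapply(ids, function(i) {
    ch <- c(2L * i + 1L, 2L * i + 2L)
    ch[ch < n]
  })
  structure(
    list(levels = levels, n_nodes = n,
         genes_per_module = as.integer(genes_per_module),
         parent = as.integer(parent), sibling = as.integer(sibling),
         children = children),
    class = "hierarchy_topology")
}

.check_node <- function(topology, node) {
  if (length(node) != 1L || !is.finite(node) || node != as.integer(node) ||
      node < 0 || node >= topology$n_nodes) {
    stop("invalid module id: ", node)
  }
  as.integer(node)
}

#' Parent, sibling and children of a module
#'
#' @param topology A [build_hierarchy()] object.
#' @param node 0-based module id.
#' @return `parent_of()`/`sibling_of()` return a single id or
#'   `NA_integer_` for the root; `children_of()` an integer vector
#'   (empty for leaves).
#' @export
parent_of <- function(topology, node) {
  node <- .check_node(topology, node)
  topology$parent[node + 1L]
}

#' @rdname parent_of
#' @export
sibling_of <- function(topology, node) {
  node <- .check_node(topology, node)
  topology$sibling[node + 1L]
}

#' @rdname parent_of
#' @export
children_of <- function(topology, node) {
  node <- .check_node(topology, node)
  topology$children[[node + 1L]]
}

#' Nearest neighbours of a module in the hierarchy
#'
#' The nearest neighbours of a module are its immediate progenitor
#' (parent), its sibling (the competing lineage with the same
#' progenitor) and its immediate progeny (children) — the targets of the
#' short-range epigenetic rules and of mutual expression repression.
#'
#' @inheritParams parent_of
#' @return Integer vector of module ids (boundary members omitted where
#'   they do not exist: the root has no parent or sibling, leaves no
#'   children).
#' @export
nearest_neighbors <- function(topology, node) {
  node <- .check_node(topology, node)
  out <- c(parent_of(topology, node), sibling_of(topology, node),
           children_of(topology, node))
  sort(out[!is.na(out)])
}

#' Descendants and ancestors of a module
#'
#' @inheritParams parent_of
#' @return Integer vector of 0-based ids, excluding `node` itself.
#' @export
descendants_of <- function(topology, node) {
  node <- .check_node(topology, node)
  acc <- integer(0)
  frontier <- children_of(topology, node)
  while (length(frontier) > 0L) {
    acc <- c(acc, frontier)
    frontier <- unlist(lapply(frontier, children_of, topology = topology))
  }
  sort(acc)
}

#' @rdname descendants_of
#' @export
ancestors_of <- function(topology, node) {
  node <- .check_node(topology, node)
  acc <- integer(0)
  p <- parent_of(topology, node)
  while (!is.na(p)) {
    acc <- c(acc, p)
    p <- parent_of(topology, p)
  }
  sort(acc)
}

#' Distal set of a module: the long-range methylation targets
#'
#' Proteins expressed by a module favour DNA methylation (silencing) of
#' every module regulating a competing lineage or a less differentiated
#' state in the same lineage: all modules that are neither the module
#' itself nor one of its descendants. The parent and sibling belong to
#' this set as well as to the nearest-neighbour set, so they receive
#' both the short-range histone field and the methylation field.
#'
#' @inheritParams parent_of
#' @return Sorted integer vector of module ids.
#' @export
distal_set <- function(topology, node) {
  node <- .check_node(topology, node)
  all_ids <- 0:(topology$n_nodes - 1L)
  sort(setdiff(all_ids, c(node, descendants_of(topology, node))))
}

#' Leaf queries
#'
#' @inheritParams parent_of
#' @return `is_leaf()` a logical; `leaf_nodes()` the ids of all
#'   terminally differentiated modules.
#' @export
is_leaf <- function(topology, node) {
  node <- .check_node(topology, node)
  length(children_of(topology, node)) == 0L
}

#' @rdname is_leaf
#' @export
leaf_nodes <- function(topology) {
  n <- topology$n_nodes
  if (n == 1L) return(0L)
  (2L^(topology$levels - 1L) - 1L):(n - 1L)
}

#' @export
print.hierarchy_topology <- function(x, ...) {
  cat(sprintf(
    "hierarchy_topology: %d levels, %d modules (%d leaves), %d gene(s)/module\n",
    x$levels, x$n_nodes, length(leaf_nodes(x)), x$genes_per_module))
  invisible(x)
}
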