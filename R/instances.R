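#' Find all induced occurrences of a motif pattern
#'
#' Enumerates every induced occurrence of \code{pattern} in \code{network}:
#' the subgraph induced by the mapped nodes must carry exactly the pattern's
#' edges and no others. Occurrences are deduplicated up to pattern
#' automorphism, so each node set hosts at most one instance per pattern, and
#' the result is sorted by node set for determinism.
#'
#' @param network A directed simple \code{igraph} (see [read_network()]).
#' @param pattern A \code{motif_pattern}.
#' @return An object of class \code{motif_instances}: a list of instances,
#'   each a list with elements \code{pattern} (name), \code{roles} (named
#'   character vector role -> node), and \code{nodes} (sorted node names).
#' @examples
#' g <- igraph::graph_from_literal(a --+ b, a --+ c, b --+ c)
#' find_instances(g, motif_ffl())
#' @export
find_instances <- function(network, pattern) {
  network <- as_network(network)
  stopifnot(inherits(pattern, "motif_pattern"))
  pg <- pattern$graph
  empty <- structure(list(), class = "motif_instances",
                     pattern = pattern$name)
  if (igraph::vcount(network) < igraph::vcount(pg) ||
      igraph::ecount(network) < igraph::ecount(pg)) {
    return(empty)
  }
  maps <- igraph::subgraph_isomorphisms(pg, network, method = "lad",
                                        induced = TRUE)
  if (!length(maps)) return(empty)
  vnames <- igraph::V(network)$name
  roles <- igraph::V(pg)$name
  inst <- lapply(maps, function(m) {
    nodes_in_role_order <- vnames[as.integer(m)]
    names(nodes_in_role_order) <- roles
    list(pattern = pattern$name,
         roles = nodes_in_role_order,
         nodes = sort(unname(nodes_in_role_order), method = "radix"))
  })
  # Automorphism dedup: one instance per node set. Among automorphic role
  # maps keep the lexicographically smallest node vector (deterministic).
  keys <- vapply(inst, function(x) paste(x$nodes, collapse = "\r"),
                 character(1))
  repr <- vapply(inst, function(x) paste(unname(x$roles), collapse = "\r"),
                 character(1))
  keep <- !logical(length(inst))
  ord <- order(keys, repr, method = "radix")
  inst <- inst[ord]
  keys <- keys[ord]
  keep <- !duplicated(keys)
  structure(unname(inst[keep]), class = "motif_instances",
            pattern = pattern$name)
}

#' Count induced occurrences of a motif pattern
#'
#' @inheritParams find_instances
#' @return Integer count of distinct instances.
#' @export
count_instances <- function(network, pattern) {
  length(find_instances(network, pattern))
}

#' @export
print.motif_instances <- function(x, ...) {
  cat(length(x), "instance(s) of pattern '", attr(x, "pattern"), "'\n",
      sep = "")
  n_show <- min(length(x), 10L)
  for (i in seq_len(n_show)) {
    cat("  {", paste(x[[i]]$nodes, collapse = ", "), "}\n", sep = "")
  }
  if (length(x) > n_show) cat("  ...\n")
  invisible(x)
}

# Internal: find instances for every pattern in a validated list; returns a
# flat list of instances each tagged with its pattern name.
find_all_instances <- function(network, patterns) {
  patterns <- as_pattern_list(patterns)
  out <- list()
  for (p in patterns) {
    out <- c(out, unclass(find_instances(network, p)))
  }
  out
}

# Internal: the directed edges of an instance (2-column character matrix),
# i.e. the pattern's edges mapped through the role assignment.
instance_edges <- function(inst, patterns) {
  p <- patterns[[inst$pattern]]
  el <- igraph::as_edgelist(p$graph)
  cbind(unname(inst$roles[el[, 1]]), unname(inst$roles[el[, 2]]))
}
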