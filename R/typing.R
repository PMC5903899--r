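#' Enumerate the catalog of pairwise motif clustering types
#'
#' Builds the set of all distinct union graphs obtainable by overlapping two
#' motif copies on one or more shared nodes such that each copy remains an
#' induced occurrence in the union. Candidates are deduplicated by graph
#' isomorphism (canonical labeling), so motif symmetries never produce
#' repeated entries. For the FFL there are exactly 12 types: 6 sharing one
#' node (union graphs with 5 nodes / 6 edges) and 6 sharing two nodes
#' (4 nodes / 5 edges). For the 3-cycle feedback loop there are 2.
#'
#' When the pattern set is a single FFL-shaped motif, type ids follow the
#' conventional numbering anchored on node roles (input A, intermediate B,
#' output C): one-node-sharing types ordered by shared role pair
#' (C,C)=1, (B,C)=2, (A,C)=3, (B,B)=4, (A,B)=5, (A,A)=6; two-node-sharing
#' types by shared role sets (BC,BC)=7, (AB,AC)=8, (AB,BC)=9, (AC,AC)=10,
#' (AC,BC)=11, (AB,AB)=12. Types 7, 10 and 12 are the unions produced by
#' duplicating the input, intermediate and output node respectively. For any
#' other pattern set, types are ordered by shared-node count and canonical
#' certificate.
#'
#' @param patterns A \code{motif_pattern} or list of patterns.
#' @param which Restrict enumeration to \code{"homologous"} pairs (two copies
#'   of the same pattern), \code{"heterologous"} pairs (copies of different
#'   patterns), or \code{"all"} (default).
#' @return An object of class \code{type_catalog}: a list with \code{table}
#'   (data frame of id, pattern pair, shared-node count, shared role sets,
#'   union size), \code{graphs} (the union graphs), \code{keys} (canonical
#'   certificates), and \code{patterns}.
#' @examples
#' cat12 <- enumerate_types(motif_ffl())
#' nrow(cat12$table)  # 12
#' @export
enumerate_types <- function(patterns,
                            which = c("all", "homologous", "heterologous")) {
  which <- match.arg(which)
  patterns <- as_pattern_list(patterns)
  np <- length(patterns)
  cand <- list()
  for (i in seq_len(np)) {
    for (j in i:np) {
      if (which == "homologous" && i != j) next
      if (which == "heterologous" && i == j) next
      cand <- c(cand, overlap_candidates(patterns[[i]], patterns[[j]], i, j))
    }
  }
  if (!length(cand)) {
    return(structure(list(patterns = patterns,
                          table = empty_catalog_table(),
                          graphs = list(), keys = character(0),
                          config2id = integer(0)),
                     class = "type_catalog"))
  }
  all_keys <- vapply(cand, `[[`, character(1), "key")
  all_configs <- vapply(cand, `[[`, character(1), "config")
  keep <- !duplicated(all_keys)
  cand <- cand[keep]
  keys <- all_keys[keep]

  if (np == 1L && which != "heterologous" && is_ffl_shaped(patterns[[1]])) {
    ord <- ffl_anchor_order(patterns[[1]], keys)
  } else {
    shared <- vapply(cand, `[[`, integer(1), "shared")
    pair_idx <- vapply(cand, function(x) x$pair_i * 1000L + x$pair_j,
                       integer(1))
    ord <- order(pair_idx, shared, keys, method = "radix")
  }
  cand <- cand[ord]
  keys <- keys[ord]
  tab <- data.frame(
    id = seq_along(cand),
    pattern_a = vapply(cand, function(x) names(patterns)[x$pair_i],
                       character(1)),
    pattern_b = vapply(cand, function(x) names(patterns)[x$pair_j],
                       character(1)),
    shared = vapply(cand, `[[`, integer(1), "shared"),
    roles_a = vapply(cand, `[[`, character(1), "roles_a"),
    roles_b = vapply(cand, `[[`, character(1), "roles_b"),
    n_nodes = vapply(cand, function(x) igraph::vcount(x$graph), numeric(1)),
    n_edges = vapply(cand, function(x) igraph::ecount(x$graph), numeric(1)),
    stringsAsFactors = FALSE
  )
  # overlap-configuration lookup: every enumerated candidate (including
  # isomorphic duplicates) maps its role-identification signature to the
  # id of its isomorphism class, giving O(1) pair classification
  config2id <- stats::setNames(tab$id[match(all_keys, keys)], all_configs)
  config2id <- config2id[!duplicated(names(config2id))]
  structure(list(patterns = patterns, table = tab,
                 graphs = lapply(cand, `[[`, "graph"), keys = keys,
                 config2id = config2id),
            class = "type_catalog")
}

empty_catalog_table <- function() {
  data.frame(id = integer(0), pattern_a = character(0),
             pattern_b = character(0), shared = integer(0),
             roles_a = character(0), roles_b = character(0),
             n_nodes = integer(0), n_edges = integer(0),
             stringsAsFactors = FALSE)
}

#' @export
print.type_catalog <- function(x, ...) {
  cat("Motif clustering type catalog: ", nrow(x$table), " type(s) for {",
      paste(names(x$patterns), collapse = ", "), "}\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# Internal: canonical key for one overlap configuration: which roles of the
# two copies are identified, irrespective of the order of the two
# instances. Shared node t carries role roles1[t] in copy 1 and roles2[t]
# in copy 2.
config_key <- function(pat1, roles1, pat2, roles2) {
  k12 <- paste(pat1, pat2,
               paste(sort(paste(roles1, roles2, sep = ">")),
                     collapse = "|"))
  k21 <- paste(pat2, pat1,
               paste(sort(paste(roles2, roles1, sep = ">")),
                     collapse = "|"))
  min(k12, k21)
}

# Internal: canonical isomorphism certificate of a small digraph.
canonical_key <- function(g) {
  cp <- igraph::canonical_permutation(g)
  h <- igraph::permute(g, cp$labeling)
  el <- igraph::as_edgelist(h, names = FALSE)
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste0(igraph::vcount(g), ":",
         paste(el[, 1], el[, 2], sep = ">", collapse = ","))
}

# Internal: all permutations of a vector (patterns are tiny, <= 4 roles).
all_perms <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- list()
  for (k in seq_len(n)) {
    for (rest in all_perms(v[-k])) out[[length(out) + 1L]] <- c(v[k], rest)
  }
  out
}

# Internal: build the union graph of two pattern copies identified through
# `map` (names = shared roles of copy 1, values = matched roles of copy 2).
# Returns NULL when either copy fails to stay induced in the union.
union_of_copies <- function(p1, p2, map) {
  n1 <- paste0("a.", p1$roles)
  names(n1) <- p1$roles
  n2 <- paste0("b.", p2$roles)
  names(n2) <- p2$roles
  n2[map] <- n1[names(map)]  # identify shared nodes
  el1 <- igraph::as_edgelist(p1$graph)
  el2 <- igraph::as_edgelist(p2$graph)
  e1 <- cbind(unname(n1[el1[, 1]]), unname(n1[el1[, 2]]))
  e2 <- cbind(unname(n2[el2[, 1]]), unname(n2[el2[, 2]]))
  edges <- unique(rbind(e1, e2))
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  # induced check: the union must add no edges among either copy's nodes
  # beyond that copy's own (every copy edge is already present, so an edge
  # count match implies set equality)
  sub1 <- igraph::induced_subgraph(g, unique(unname(n1)))
  if (igraph::ecount(sub1) != nrow(el1)) return(NULL)
  sub2 <- igraph::induced_subgraph(g, unique(unname(n2)))
  if (igraph::ecount(sub2) != nrow(el2)) return(NULL)
  g
}

# Internal: all valid overlap candidates for one (ordered) pattern pair.
overlap_candidates <- function(p1, p2, pair_i, pair_j) {
  r1 <- p1$roles
  r2 <- p2$roles
  out <- list()
  for (s in seq_len(min(length(r1), length(r2)))) {
    subs1 <- utils::combn(r1, s, simplify = FALSE)
    subs2 <- utils::combn(r2, s, simplify = FALSE)
    for (a in subs1) {
      for (b in subs2) {
        for (bp in all_perms(b)) {
          map <- stats::setNames(bp, a)
          g <- union_of_copies(p1, p2, map)
          if (is.null(g)) next
          # skip the degenerate case where the two copies coincide
          if (s == length(r1) && s == length(r2) &&
              igraph::ecount(g) == igraph::ecount(p1$graph)) next
          out[[length(out) + 1L]] <- list(
            graph = g, key = canonical_key(g), shared = s,
            pair_i = pair_i, pair_j = pair_j,
            config = config_key(p1$name, a, p2$name, bp),
            roles_a = paste(sort(a), collapse = "+"),
            roles_b = paste(sort(bp), collapse = "+"))
        }
      }
    }
  }
  out
}

# Internal: TRUE when a 3-node pattern is isomorphic to the FFL.
is_ffl_shaped <- function(p) {
  igraph::vcount(p$graph) == 3L && igraph::ecount(p$graph) == 3L &&
    igraph::isomorphic(p$graph, motif_ffl()$graph)
}

# Internal: structural FFL roles of a pattern (A = source, B = relay,
# C = sink), by degree signature.
ffl_structural_roles <- function(p) {
  g <- p$graph
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  c(A = igraph::V(g)$name[indeg == 0][1],
    B = igraph::V(g)$name[indeg == 1 & outdeg == 1][1],
    C = igraph::V(g)$name[outdeg == 0][1])
}

# Internal: order an enumerated FFL catalog by the conventional ids 1..12.
ffl_anchor_order <- function(p, keys) {
  sr <- ffl_structural_roles(p)
  one_node <- list(c("C", "C"), c("B", "C"), c("A", "C"),
                   c("B", "B"), c("A", "B"), c("A", "A"))
  two_node <- list(list(c("B", "C"), c("B", "C")),
                   list(c("A", "B"), c("A", "C")),
                   list(c("A", "B"), c("B", "C")),
                   list(c("A", "C"), c("A", "C")),
                   list(c("A", "C"), c("B", "C")),
                   list(c("A", "B"), c("A", "B")))
  anchor_keys <- character(12)
  for (t in 1:6) {
    map <- stats::setNames(sr[one_node[[t]][2]], sr[one_node[[t]][1]])
    g <- union_of_copies(p, p, map)
    stopifnot(!is.null(g))
    anchor_keys[t] <- canonical_key(g)
  }
  for (t in 1:6) {
    a <- sr[two_node[[t]][[1]]]
    b <- sr[two_node[[t]][[2]]]
    g <- union_of_copies(p, p, stats::setNames(b, a))
    if (is.null(g)) {
      g <- union_of_copies(p, p, stats::setNames(rev(b), a))
    }
    stopifnot(!is.null(g))
    anchor_keys[6 + t] <- canonical_key(g)
  }
  ord <- match(anchor_keys, keys)
  if (anyNA(ord) || length(keys) != 12L) {
    stop("internal error: FFL catalog does not match the 12 anchored types")
  }
  ord
}

#' Classify a pair of motif instances by clustering type
#'
#' Builds the union of the two instances' own edges (pattern edges mapped
#' through their role assignments; bystander edges of the host network are
#' ignored) and matches it against the catalog by graph isomorphism.
#'
#' @param inst1,inst2 Instances as returned in a [find_instances()] list.
#' @param catalog A \code{type_catalog} from [enumerate_types()] built for
#'   the instances' patterns.
#' @return The integer type id, or the string \code{"disjoint"} when the
#'   instances share no nodes.
#' @export
classify_pair <- function(inst1, inst2, catalog) {
  stopifnot(inherits(catalog, "type_catalog"))
  shared <- intersect(inst1$nodes, inst2$nodes)
  if (!length(shared)) return("disjoint")
  # fast path: the shared nodes' role identifications determine the union
  # graph up to isomorphism, so look the configuration up directly
  r1 <- names(inst1$roles)[match(shared, inst1$roles)]
  r2 <- names(inst2$roles)[match(shared, inst2$roles)]
  id <- catalog$config2id[config_key(inst1$pattern, r1,
                                     inst2$pattern, r2)]
  if (!is.na(id)) return(unname(id))
  # fallback: isomorphism match of the pair's union graph
  e1 <- instance_edges(inst1, catalog$patterns)
  e2 <- instance_edges(inst2, catalog$patterns)
  g <- igraph::graph_from_edgelist(unique(rbind(e1, e2)), directed = TRUE)
  idx <- match(canonical_key(g), catalog$keys)
  if (is.na(idx)) {
    stop("internal consistency error: clustered pair matches no catalog type")
  }
  catalog$table$id[idx]
}

# Internal: find instances, enumerate clustered pairs and classify them.
# Returns list(instances, pairs = data.frame(i, j, type)).
pair_classification <- function(network, patterns, catalog = NULL) {
  patterns <- as_pattern_list(patterns)
  if (is.null(catalog)) catalog <- enumerate_types(patterns)
  inst <- find_all_instances(network, patterns)
  n <- length(inst)
  pairs <- matrix(integer(0), ncol = 2)
  if (n >= 2L) {
    # index instances by node; only pairs sharing >= 1 node can cluster
    node_vec <- unlist(lapply(inst, `[[`, "nodes"), use.names = FALSE)
    inst_vec <- rep(seq_len(n),
                    vapply(inst, function(x) length(x$nodes), integer(1)))
    by_node <- split(inst_vec, node_vec)
    plist <- lapply(by_node, function(ks) {
      if (length(ks) >= 2L) t(utils::combn(sort(ks), 2L))
      else matrix(integer(0), ncol = 2)
    })
    pairs <- do.call(rbind, plist)
    if (nrow(pairs)) {
      pairs <- pairs[!duplicated(pairs[, 1] * (n + 1) + pairs[, 2]), ,
                     drop = FALSE]
    }
  }
  types <- integer(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    types[r] <- classify_pair(inst[[pairs[r, 1]]], inst[[pairs[r, 2]]],
                              catalog)
  }
  list(instances = inst, catalog = catalog,
       pairs = data.frame(i = pairs[, 1], j = pairs[, 2], type = types))
}

#' Motif clustering type distribution
#'
#' Classifies every clustered (node-sharing) unordered pair of motif
#' instances by its catalog type and reports counts and fractions. Disjoint
#' pairs are neglected; fractions are normalized over clustered pairs only
#' and sum to 1 whenever at least one clustered pair exists.
#'
#' @inheritParams motif_clustering
#' @param catalog Optional precomputed \code{type_catalog} (saves repeated
#'   enumeration in simulation loops).
#' @return An object of class \code{type_distribution}: a list with
#'   \code{table} (data frame id, count, fraction over the full catalog),
#'   \code{n_pairs_clustered}, and \code{n_instances}.
#' @export
type_distribution <- function(network, patterns = motif_ffl(),
                              catalog = NULL) {
  network <- as_network(network)
  pc <- pair_classification(network, patterns, catalog)
  ids <- pc$catalog$table$id
  counts <- vapply(ids, function(id) sum(pc$pairs$type == id), integer(1))
  n_pairs <- nrow(pc$pairs)
  fractions <- if (n_pairs > 0) counts / n_pairs else rep(0, length(counts))
  structure(list(table = data.frame(id = ids, count = counts,
                                    fraction = fractions),
                 n_pairs_clustered = n_pairs,
                 n_instances = length(pc$instances),
                 catalog = pc$catalog),
            class = "type_distribution")
}

#' @export
print.type_distribution <- function(x, ...) {
  cat("Motif clustering type distribution (", x$n_instances,
      " instance(s), ", x$n_pairs_clustered, " clustered pair(s))\n",
      sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Per-node motif clustering diversity (MCD)
#'
#' The MCD of a node is the number of distinct clustering types among all
#' pairs of motif instances that contain the node (a node belongs to a pair
#' when it lies in the intersection of the two instances' node sets). Nodes
#' in no such pair score 0. A hub shared by many same-type pairs scores 1:
#' diversity counts types, not pairs.
#'
#' @inheritParams type_distribution
#' @return A data frame of class \code{mcd_table} with columns \code{node}
#'   and \code{mcd}, one row per network node.
#' @export
mcd <- function(network, patterns = motif_ffl(), catalog = NULL) {
  network <- as_network(network)
  pc <- pair_classification(network, patterns, catalog)
  types_by_node <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(pc$pairs))) {
    shared <- intersect(pc$instances[[pc$pairs$i[r]]]$nodes,
                        pc$instances[[pc$pairs$j[r]]]$nodes)
    for (v in shared) {
      assign(v, union(get0(v, envir = types_by_node,
                           ifnotfound = integer(0)),
                      pc$pairs$type[r]),
             envir = types_by_node)
    }
  }
  nodes <- igraph::V(network)$name
  vals <- vapply(nodes, function(v) {
    length(get0(v, envir = types_by_node, ifnotfound = integer(0)))
  }, integer(1))
  structure(data.frame(node = nodes, mcd = unname(vals),
                       stringsAsFactors = FALSE),
            class = c("mcd_table", "data.frame"))
}

#' Extract the motif-cluster subnetwork
#'
#' Returns the union of all motif instances: their node sets and their own
#' edges, together with node and edge coverage fractions relative to the
#' whole network.
#'
#' @inheritParams motif_clustering
#' @return An object of class \code{motif_subnetwork}: a list with
#'   \code{subnetwork} (igraph), \code{node_coverage},
#'   \code{edge_coverage}, and \code{n_instances}.
#' @export
extract_motif_subnetwork <- function(network, patterns = motif_ffl()) {
  network <- as_network(network)
  patterns <- as_pattern_list(patterns)
  inst <- find_all_instances(network, patterns)
  if (!length(inst)) {
    sub <- igraph::make_empty_graph(n = 0, directed = TRUE)
    nv <- igraph::vcount(network)
    ne <- igraph::ecount(network)
    return(structure(list(subnetwork = sub,
                          node_coverage = if (nv > 0) 0 else 0,
                          edge_coverage = if (ne > 0) 0 else 0,
                          n_instances = 0L),
                     class = "motif_subnetwork"))
  }
  edges <- unique(do.call(rbind, lapply(inst, instance_edges,
                                        patterns = patterns)))
  sub <- igraph::graph_from_edgelist(edges, directed = TRUE)
  structure(list(subnetwork = sub,
                 node_coverage = igraph::vcount(sub) /
                   igraph::vcount(network),
                 edge_coverage = igraph::ecount(sub) /
                   igraph::ecount(network),
                 n_instances = length(inst)),
            class = "motif_subnetwork")
}

#' @export
print.motif_subnetwork <- function(x, ...) {
  cat("Motif-cluster subnetwork: ", igraph::vcount(x$subnetwork),
      " nodes, ", igraph::ecount(x$subnetwork), " edges from ",
      x$n_instances, " instance(s)\n", sep = "")
  cat(sprintf("  coverage: %.1f%% of nodes, %.1f%% of edges\n",
              100 * x$node_coverage, 100 * x$edge_coverage))
  invisible(x)
}
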