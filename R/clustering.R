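#' Motif clustering coefficient
#'
#' Quantifies how strongly the occurrences of a motif set aggregate by
#' sharing nodes. With found instances \eqn{F = \{f_1, ..., f_n\}} (node
#' sets), the coefficient is \eqn{M_c = S/T} where
#' \eqn{S = \sum_{i<j} |f_i \cap f_j|} is the observed number of shared
#' nodes over all unordered instance pairs and
#' \eqn{T = \sum_{i<j} (\min(|f_i|,|f_j|) - 1)} is the maximum attainable:
#' two distinct instances of a size-\eqn{m} motif can share at most
#' \eqn{m - 1} nodes. For a single pattern of size \eqn{|M|},
#' \eqn{T = \binom{n}{2}(|M|-1)}. \eqn{M_c = 0} means all instances are
#' node-disjoint; \eqn{M_c = 1} means every pair is fully clustered.
#'
#' @param network A directed simple \code{igraph}.
#' @param patterns A \code{motif_pattern} or list of patterns; the set must
#'   contain no pattern that is a subgraph isomorph of another.
#' @return An object of class \code{motif_clustering} with fields \code{Mc}
#'   (NaN when fewer than two instances exist), \code{S}, \code{T}, and
#'   \code{n} (instance count).
#' @examples
#' g <- igraph::graph_from_literal(a --+ b, a --+ c, b --+ c,
#'                                 a --+ d, b --+ d)
#' motif_clustering(g, motif_ffl())  # two FFLs sharing two nodes: Mc = 1
#' @export
motif_clustering <- function(network, patterns = motif_ffl()) {
  network <- as_network(network)
  patterns <- as_pattern_list(patterns)
  inst <- find_all_instances(network, patterns)
  n <- length(inst)
  node_sets <- lapply(inst, `[[`, "nodes")
  st <- shared_node_stats(node_sets)
  Mc <- if (st$T > 0) st$S / st$T else NaN
  if (n < 2L) {
    warning("fewer than two motif instances found; Mc is undefined (NaN)")
    Mc <- NaN
  }
  structure(list(Mc = Mc, S = st$S, T = st$T, n = n,
                 patterns = names(patterns)),
            class = "motif_clustering")
}

# Internal: S and T for a list of node sets.
#  S via per-node incidence counts: sum_v C(m_v, 2) where m_v is the number
#  of instances containing v -- identical to pairwise intersection sums.
#  T via sorted sizes: the smaller set of each pair contributes (size - 1).
shared_node_stats <- function(node_sets) {
  n <- length(node_sets)
  if (n < 2L) return(list(S = 0L, T = 0L))
  m_v <- table(unlist(node_sets, use.names = FALSE))
  S <- sum(choose(as.integer(m_v), 2))
  sizes <- sort(vapply(node_sets, length, integer(1)))
  T <- sum((sizes - 1L) * (n - seq_len(n)))
  list(S = as.integer(S), T = as.integer(T))
}

#' @export
print.motif_clustering <- function(x, ...) {
  cat("Motif clustering (patterns: ",
      paste(x$patterns, collapse = ", "), ")\n", sep = "")
  cat("  instances n =", x$n, "\n")
  cat("  shared nodes S =", x$S, " max possible T =", x$T, "\n")
  cat("  Mc =", format(x$Mc, digits = 4), "\n")
  invisible(x)
}

#' Homologous and heterologous motif clustering
#'
#' Splits the motif clustering coefficient by pattern type: the homologous
#' coefficient \eqn{M_c^+} pools shared-node and maximum counts over pairs of
#' instances of the same pattern, while the heterologous coefficient
#' \eqn{M_c^\pm} pools them over pairs of instances of different patterns.
#' Undefined ratios (empty pair sets) are reported as NaN, never 0, since 0
#' is the meaningful "fully isolated" value.
#'
#' @inheritParams motif_clustering
#' @return An object of class \code{motif_clustering_split} with fields
#'   \code{Mc_plus}, \code{Mc_minus}, the pooled numerators/denominators
#'   \code{S_plus}, \code{T_plus}, \code{S_minus}, \code{T_minus}, and
#'   per-pattern instance counts.
#' @export
motif_clustering_split <- function(network, patterns) {
  network <- as_network(network)
  patterns <- as_pattern_list(patterns)
  per_type <- lapply(patterns, function(p) {
    lapply(unclass(find_instances(network, p)), `[[`, "nodes")
  })
  np <- length(per_type)
  # homologous: same-type pairs
  S_plus <- 0L
  T_plus <- 0L
  for (i in seq_len(np)) {
    st <- shared_node_stats(per_type[[i]])
    S_plus <- S_plus + st$S
    T_plus <- T_plus + st$T
  }
  # heterologous: cross-type pairs
  S_minus <- 0L
  T_minus <- 0L
  if (np >= 2L) {
    for (i in seq_len(np - 1L)) {
      for (j in (i + 1L):np) {
        cs <- cross_shared_stats(per_type[[i]], per_type[[j]])
        S_minus <- S_minus + cs$S
        T_minus <- T_minus + cs$T
      }
    }
  }
  Mc_plus <- if (T_plus > 0) S_plus / T_plus else NaN
  Mc_minus <- if (np >= 2L && T_minus > 0) S_minus / T_minus else NaN
  structure(list(Mc_plus = Mc_plus, Mc_minus = Mc_minus,
                 S_plus = S_plus, T_plus = T_plus,
                 S_minus = S_minus, T_minus = T_minus,
                 n_per_pattern = vapply(per_type, length, integer(1))),
            class = "motif_clustering_split")
}

# Internal: S_ij and T_ij across two families of node sets.
cross_shared_stats <- function(sets_a, sets_b) {
  if (!length(sets_a) || !length(sets_b)) return(list(S = 0L, T = 0L))
  cnt_a <- table(unlist(sets_a, use.names = FALSE))
  cnt_b <- table(unlist(sets_b, use.names = FALSE))
  common <- intersect(names(cnt_a), names(cnt_b))
  S <- sum(as.integer(cnt_a[common]) * as.integer(cnt_b[common]))
  sa <- vapply(sets_a, length, integer(1))
  sb <- vapply(sets_b, length, integer(1))
  T <- sum(outer(sa, sb, pmin) - 1L)
  list(S = as.integer(S), T = as.integer(T))
}

#' @export
print.motif_clustering_split <- function(x, ...) {
  cat("Homologous / heterologous motif clustering\n")
  cat("  instances per pattern:",
      paste(names(x$n_per_pattern), x$n_per_pattern, sep = "=",
            collapse = ", "), "\n")
  cat("  Mc+ =", format(x$Mc_plus, digits = 4),
      " (S =", x$S_plus, ", T =", x$T_plus, ")\n")
  cat("  Mc+/- =", format(x$Mc_minus, digits = 4),
      " (S =", x$S_minus, ", T =", x$T_minus, ")\n")
  invisible(x)
}
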