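# Null models and randomization machinery.
#
# All generators accept a `seed`; when non-NULL the global RNG is seeded so
# repeated calls with the same seed are reproducible.

seed_if_given <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
}

#' Erdos-Renyi random digraph
#'
#' Every ordered node pair (u, v), u != v, is an edge independently with
#' probability \code{p}.
#'
#' @param n Number of nodes.
#' @param p Edge probability in \code{[0, 1]}.
#' @param seed Optional integer seed for reproducibility.
#' @return A directed simple \code{igraph} with nodes \code{n1..nN}.
#' @export
erdos_renyi <- function(n, p, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("'p' must be a probability in [0, 1]")
  }
  seed_if_given(seed)
  g <- igraph::sample_gnp(n, p, directed = TRUE, loops = FALSE)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g$name <- sprintf("erdos_renyi(n=%d, p=%g)", n, p)
  g
}

#' Duplication growth from a template motif
#'
#' Grows a network by node duplication: starting from the template motif, a
#' node is repeatedly chosen at random and duplicated together with all of
#' its incoming and outgoing edges (pure neighborhood copying; the duplicate
#' gains no edge to its originator), until the target size is reached.
#' Duplicates inherit the template role of their originator, and the choice
#' can be biased per role via \code{role_bias}. Duplicating any motif-member
#' node creates a new instance of the same pattern fully clustered with the
#' original, so this model generates the duplication signature of two-node
#' sharing clustering types.
#'
#' @param template A \code{motif_pattern} used as the seed graph.
#' @param target_n Final node count (>= template size).
#' @param seed Optional integer seed.
#' @param role_bias Optional named non-negative weights over the template
#'   roles; duplication picks nodes proportionally to the weight of their
#'   role lineage. All-zero weights are an error.
#' @return A directed simple \code{igraph} with a \code{role} vertex
#'   attribute recording each node's template lineage.
#' @export
duplication_growth <- function(template, target_n, seed = NULL,
                               role_bias = NULL) {
  stopifnot(inherits(template, "motif_pattern"))
  stopifnot(is.numeric(target_n), length(target_n) == 1L)
  target_n <- as.integer(target_n)
  if (target_n < igraph::vcount(template$graph)) {
    stop("'target_n' must be at least the template size (",
         igraph::vcount(template$graph), ")")
  }
  roles <- template$roles
  if (is.null(role_bias)) {
    role_bias <- stats::setNames(rep(1, length(roles)), roles)
  }
  if (is.null(names(role_bias)) || !all(roles %in% names(role_bias))) {
    stop("'role_bias' must be a named vector covering every template role")
  }
  if (any(role_bias < 0) || sum(role_bias[roles]) <= 0) {
    stop("'role_bias' weights must be non-negative with a positive sum")
  }
  seed_if_given(seed)
  g <- template$graph
  igraph::V(g)$role <- roles
  dup_counter <- 0L
  while (igraph::vcount(g) < target_n) {
    w <- role_bias[igraph::V(g)$role]
    pick <- sample.int(igraph::vcount(g), 1L, prob = w)
    dup_counter <- dup_counter + 1L
    new_name <- paste0(igraph::V(g)$name[pick], ".d", dup_counter)
    ins <- igraph::neighbors(g, pick, mode = "in")
    outs <- igraph::neighbors(g, pick, mode = "out")
    role <- igraph::V(g)$role[pick]
    g <- igraph::add_vertices(g, 1L, name = new_name, role = role)
    new_id <- igraph::vcount(g)
    new_edges <- integer(0)
    if (length(ins)) {
      new_edges <- c(new_edges,
                     rbind(as.integer(ins), rep(new_id, length(ins))))
    }
    if (length(outs)) {
      new_edges <- c(new_edges,
                     rbind(rep(new_id, length(outs)), as.integer(outs)))
    }
    if (length(new_edges)) g <- igraph::add_edges(g, new_edges)
  }
  g$name <- sprintf("duplication_growth(%s, n=%d)", template$name, target_n)
  g
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Rewires the network with directed double-edge swaps
#' (a->b, c->d) => (a->d, c->b), rejecting swaps that would create
#' self-loops or duplicate edges, so every node's in- and out-degree is
#' preserved exactly.
#'
#' @param network A directed simple \code{igraph} with at least 2 edges.
#' @param n_swaps_per_edge Attempted swaps per edge (default 10).
#' @param seed Optional integer seed.
#' @return A randomized \code{igraph} with identical degree sequences.
#' @export
degree_preserving_randomize <- function(network, n_swaps_per_edge = 10,
                                        seed = NULL) {
  network <- as_network(network)
  if (igraph::ecount(network) < 2L) {
    stop("'network' must have at least 2 edges to rewire")
  }
  seed_if_given(seed)
  niter <- ceiling(n_swaps_per_edge * igraph::ecount(network))
  igraph::rewire(network, igraph::keeping_degseq(loops = FALSE,
                                                 niter = niter))
}

#' Motif-count-preserving rejection sampler
#'
#' Generates a random network with exactly the same node count, edge count,
#' and motif instance count as the original. Starting from an empty graph on
#' the same nodes, motif copies are placed on uniformly drawn distinct node
#' tuples (already-present edges are reused) until the original instance
#' count is reached; remaining edges are then placed uniformly at random.
#' Whenever the motif count or edge count exceeds the original's the
#' candidate is rejected and the process restarts. Because added edges can
#' also destroy induced instances, a completed candidate whose final count
#' differs from the target is likewise rejected.
#'
#' @param network A directed simple \code{igraph}.
#' @param pattern The \code{motif_pattern} whose count must be preserved.
#' @param seed Optional integer seed.
#' @param max_restarts Restart budget; the sampler errors once it is
#'   exhausted.
#' @return A directed simple \code{igraph}; the number of restarts used is
#'   stored in the graph attribute \code{restarts}.
#' @export
motif_preserving_sample <- function(network, pattern, seed = NULL,
                                    max_restarts = 10000L) {
  network <- as_network(network)
  stopifnot(inherits(pattern, "motif_pattern"))
  seed_if_given(seed)
  n_nodes <- igraph::vcount(network)
  e0 <- igraph::ecount(network)
  m0 <- count_instances(network, pattern)
  psize <- igraph::vcount(pattern$graph)
  pedges <- igraph::as_edgelist(pattern$graph)
  role_idx <- match(pedges, igraph::V(pattern$graph)$name)
  dim(role_idx) <- dim(pedges)
  nodes <- igraph::V(network)$name

  attempts <- max_restarts + 1L
  for (attempt in seq_len(attempts)) {
    g <- igraph::make_empty_graph(n = n_nodes, directed = TRUE)
    igraph::V(g)$name <- nodes
    ok <- TRUE
    # phase 1: place motifs until the census matches
    m <- 0L
    while (m < m0) {
      pick <- sample.int(n_nodes, psize)
      new_e <- cbind(pick[role_idx[, 1]], pick[role_idx[, 2]])
      el <- igraph::as_edgelist(g, names = FALSE)
      have <- paste(el[, 1], el[, 2])
      add <- new_e[!(paste(new_e[, 1], new_e[, 2]) %in% have), ,
                   drop = FALSE]
      if (nrow(add)) g <- igraph::add_edges(g, t(add))
      m <- count_instances(g, pattern)
      if (m > m0 || igraph::ecount(g) > e0) {
        ok <- FALSE
        break
      }
    }
    # phase 2: place outstanding edges
    while (ok && igraph::ecount(g) < e0) {
      u <- sample.int(n_nodes, 1L)
      v <- sample.int(n_nodes, 1L)
      if (u == v || igraph::are_adjacent(g, u, v)) next
      g <- igraph::add_edges(g, c(u, v))
      m <- count_instances(g, pattern)
      if (m > m0) {
        ok <- FALSE
        break
      }
    }
    if (ok && m == m0 && igraph::ecount(g) == e0) {
      g$restarts <- attempt - 1L
      g$name <- "motif_preserving_sample"
      return(g)
    }
  }
  stop("motif_preserving_sample: restart budget exhausted (max_restarts = ",
       max_restarts, ")")
}

#' Significance of a motif statistic against a null model
#'
#' Computes the observed statistic (induced motif count or motif clustering
#' coefficient Mc), generates \code{n_samples} networks from the chosen null
#' model, and reports a standard z score
#' \eqn{(observed - \bar{x}_{null}) / s_{null}} (sample standard deviation,
#' n-1 denominator) plus an upper-tail empirical P value
#' \eqn{(r + 1)/(n + 1)} with \eqn{r} the number of null samples at or above
#' the observed value. By default motif counts are tested against
#' degree-preserving randomization and Mc against the
#' motif-count-preserving rejection sampler, so the Mc significance is
#' relative to networks with the same number of motifs.
#'
#' @param network A directed simple \code{igraph}.
#' @param statistic \code{"motif_count"} or \code{"Mc"}.
#' @param null \code{"degree_preserving"} or \code{"motif_preserving"};
#'   defaults depend on \code{statistic} as above.
#' @param pattern The \code{motif_pattern} of interest.
#' @param n_samples Number of null samples (>= 2).
#' @param seed Optional integer seed.
#' @param ... Passed to the null generator
#'   ([degree_preserving_randomize()] or [motif_preserving_sample()]).
#' @return An object of class \code{motif_significance} with fields
#'   \code{observed}, \code{null_mean}, \code{null_sd}, \code{z} (a signed
#'   infinite sentinel when the null is degenerate), \code{p_upper},
#'   \code{n_samples}, \code{n_rejected} and \code{seed}.
#' @export
motif_significance <- function(network,
                               statistic = c("motif_count", "Mc"),
                               null = NULL,
                               pattern = motif_ffl(),
                               n_samples = 1000L,
                               seed = NULL, ...) {
  statistic <- match.arg(statistic)
  network <- as_network(network)
  stopifnot(n_samples >= 2L)
  if (is.null(null)) {
    null <- if (statistic == "motif_count") "degree_preserving"
            else "motif_preserving"
  }
  null <- match.arg(null, c("degree_preserving", "motif_preserving"))
  seed_if_given(seed)
  stat_fun <- switch(statistic,
    motif_count = function(g) count_instances(g, pattern),
    Mc = function(g) {
      suppressWarnings(motif_clustering(g, pattern)$Mc)
    })
  observed <- stat_fun(network)
  samples <- numeric(n_samples)
  n_rejected <- 0L
  for (k in seq_len(n_samples)) {
    gk <- if (null == "degree_preserving") {
      degree_preserving_randomize(network, ...)
    } else {
      motif_preserving_sample(network, pattern, ...)
    }
    if (!is.null(gk$restarts)) n_rejected <- n_rejected + gk$restarts
    samples[k] <- stat_fun(gk)
  }
  null_mean <- mean(samples)
  null_sd <- stats::sd(samples)
  if (is.na(null_sd) || null_sd == 0) {
    warning("null distribution is degenerate (sd = 0); ",
            "z reported as a signed infinity sentinel")
    diffs <- observed - null_mean
    z <- if (diffs > 0) Inf else if (diffs < 0) -Inf else 0
  } else {
    z <- (observed - null_mean) / null_sd
  }
  p_upper <- (sum(samples >= observed) + 1) / (n_samples + 1)
  structure(list(observed = observed, null_mean = null_mean,
                 null_sd = null_sd, z = z, p_upper = p_upper,
                 n_samples = n_samples, n_rejected = n_rejected,
                 seed = seed, statistic = statistic, null = null),
            class = "motif_significance")
}

#' @export
print.motif_significance <- function(x, ...) {
  cat("Motif significance (", x$statistic, " vs ", x$null, " null)\n",
      sep = "")
  cat("  observed =", format(x$observed, digits = 4),
      " null mean =", format(x$null_mean, digits = 4),
      " sd =", format(x$null_sd, digits = 4), "\n")
  cat("  z =", format(x$z, digits = 4),
      " empirical P(upper) =", format(x$p_upper, digits = 4),
      " (", x$n_samples, "samples,", x$n_rejected, "restarts )\n")
  invisible(x)
}

#' Robustness of the clustering-type distribution to edge removal
#'
#' For each removal fraction, removes that share of edges uniformly at
#' random (distinct edges, \code{round(fraction * E)} of them), recomputes
#' the motif clustering type distribution, and averages the per-type
#' fractions over trials. Trials where no clustered pair survives contribute
#' a zero vector to the average. Also reports the mean motif instance count
#' per fraction.
#'
#' @param network A directed simple \code{igraph}.
#' @param fractions Numeric vector of removal fractions in \code{(0, 1]}
#'   (a fraction that rounds to zero edges leaves the network unperturbed).
#' @param trials Trials per fraction (>= 1).
#' @param patterns Motif pattern(s), default FFL.
#' @param seed Optional integer seed.
#' @return An object of class \code{edge_removal_robustness}: a list with
#'   \code{fractions}, \code{mean_distribution} (matrix fraction x type id),
#'   \code{mean_motif_count}, and \code{trials}.
#' @export
edge_removal_robustness <- function(network, fractions, trials = 500L,
                                    patterns = motif_ffl(), seed = NULL) {
  network <- as_network(network)
  stopifnot(is.numeric(fractions), all(fractions > 0), all(fractions <= 1),
            trials >= 1L)
  patterns <- as_pattern_list(patterns)
  catalog <- enumerate_types(patterns)
  seed_if_given(seed)
  E <- igraph::ecount(network)
  ids <- catalog$table$id
  mean_dist <- matrix(0, nrow = length(fractions), ncol = length(ids),
                      dimnames = list(format(fractions), ids))
  mean_count <- numeric(length(fractions))
  for (fi in seq_along(fractions)) {
    k <- round(fractions[fi] * E)
    acc <- numeric(length(ids))
    cnt <- 0
    for (t in seq_len(trials)) {
      sub <- if (k > 0) {
        igraph::delete_edges(network, sample.int(E, k))
      } else {
        network
      }
      td <- type_distribution(sub, patterns, catalog)
      acc <- acc + td$table$fraction
      cnt <- cnt + td$n_instances
    }
    mean_dist[fi, ] <- acc / trials
    mean_count[fi] <- cnt / trials
  }
  structure(list(fractions = fractions, mean_distribution = mean_dist,
                 mean_motif_count = mean_count, trials = trials,
                 catalog = catalog),
            class = "edge_removal_robustness")
}

#' @export
print.edge_removal_robustness <- function(x, ...) {
  cat("Edge-removal robustness (", x$trials, " trial(s) per fraction)\n",
      sep = "")
  df <- data.frame(fraction = x$fractions,
                   mean_motifs = x$mean_motif_count)
  print(cbind(df, round(x$mean_distribution, 3)), row.names = FALSE)
  invisible(x)
}
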