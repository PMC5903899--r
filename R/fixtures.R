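# Deterministic synthetic fixtures with ground truth known by construction.
#
# Every recipe assembles FFL copies so that each clustered pair realizes one
# prescribed clustering type, and records the exact expected motif count,
# Mc, type distribution, and per-node MCD arithmetic derived from the
# construction -- never from the library's own detector.

#' Build a pure-type FFL fixture
#'
#' Constructs \code{k} FFLs arranged so that every clustered pair of
#' instances realizes exactly clustering type \code{type_id}, together with
#' the ground truth implied by the construction. One-node-sharing types use
#' a star (types 1, 4, 6: one node shared by all copies) or a chain (types
#' 2, 3, 5: consecutive copies share one node, non-consecutive pairs are
#' disjoint); two-node-sharing types 7, 10, 12 use a star on the shared node
#' pair. Types 8, 9, 11 admit no pairwise-pure arrangement beyond two
#' motifs, because their shared roles differ between the two copies and a
#' third copy would create pairs of another type, so they require
#' \code{k = 2}.
#'
#' @param type_id Clustering type 1-12 (FFL catalog numbering, see
#'   [enumerate_types()]).
#' @param k Number of FFL copies (>= 2).
#' @param seed Optional integer seed; when given, node names are replaced by
#'   a seeded random relabeling (useful for testing label invariance).
#' @return An object of class \code{motif_fixture}: a list with
#'   \code{network} (igraph) and \code{spec}, where \code{spec} holds the
#'   constructed ground truth: \code{motif_count},
#'   \code{n_pairs_clustered}, \code{S}, \code{T}, \code{Mc},
#'   \code{distribution} (named fractions over types 1-12), and \code{mcd}
#'   (named per-node values).
#' @examples
#' fx <- make_type_fixture(6, k = 3)
#' fx$spec$Mc  # 0.5
#' @export
make_type_fixture <- function(type_id, k, seed = NULL) {
  stopifnot(length(type_id) == 1L, type_id %in% 1:12,
            is.numeric(k), length(k) == 1L)
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be at least 2")
  if (type_id %in% c(8L, 9L, 11L) && k != 2L) {
    stop("type ", type_id, " admits no pairwise-pure construction for k > 2",
         " (its two copies share different role sets, so any third copy",
         " would form pairs of another type); use k = 2")
  }
  b <- build_type_blocks(type_id, k)
  g <- igraph::graph_from_edgelist(b$edges, directed = TRUE)
  g$name <- sprintf("fixture(type=%d, k=%d)", type_id, k)
  # pair count and shared-node sums follow from the arrangement
  if (type_id %in% c(2L, 3L, 5L)) {
    n_pairs <- k - 1L
    S <- k - 1L
  } else if (type_id %in% c(1L, 4L, 6L)) {
    n_pairs <- choose(k, 2)
    S <- choose(k, 2)
  } else {
    n_pairs <- choose(k, 2)
    S <- 2 * choose(k, 2)
  }
  T <- 2 * choose(k, 2)
  distribution <- stats::setNames(numeric(12), as.character(1:12))
  distribution[as.character(type_id)] <- 1
  mcd_truth <- stats::setNames(integer(igraph::vcount(g)),
                               igraph::V(g)$name)
  mcd_truth[b$shared_nodes] <- 1L
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    new_names <- paste0("v", sample.int(igraph::vcount(g)))
    names(mcd_truth) <- new_names[match(names(mcd_truth),
                                        igraph::V(g)$name)]
    igraph::V(g)$name <- new_names
  }
  spec <- list(recipe = "pure_type", type_id = type_id, k = k,
               motif_count = k, n_pairs_clustered = as.integer(n_pairs),
               S = as.integer(S), T = as.integer(T), Mc = S / T,
               distribution = distribution, mcd = mcd_truth)
  structure(list(network = g, spec = spec), class = "motif_fixture")
}

# Internal: edge list and shared-node set for each pure-type arrangement.
build_type_blocks <- function(type_id, k) {
  i <- seq_len(k)
  a <- paste0("a", i); b <- paste0("b", i); cc <- paste0("c", i)
  edges <- switch(as.character(type_id),
    "1" = rbind(cbind(a, b), cbind(a, rep("c", k)), cbind(b, rep("c", k))),
    "2" = {
      x <- paste0("x", seq_len(k + 1))
      rbind(cbind(a, x[i]), cbind(a, x[i + 1]), cbind(x[i], x[i + 1]))
    },
    "3" = {
      y <- paste0("y", seq_len(k + 1))
      rbind(cbind(y[i], b), cbind(y[i], y[i + 1]), cbind(b, y[i + 1]))
    },
    "4" = rbind(cbind(a, "b"), cbind(a, cc), cbind("b", cc)),
    "5" = {
      z <- paste0("z", seq_len(k + 1))
      rbind(cbind(z[i], z[i + 1]), cbind(z[i], cc), cbind(z[i + 1], cc))
    },
    "6" = rbind(cbind("a", b), cbind("a", cc), cbind(b, cc)),
    "7" = rbind(cbind(a, "b"), cbind(a, "c"), c("b", "c")),
    "8" = rbind(c("x", "y"), c("x", "c1"), c("y", "c1"),
                c("x", "b2"), c("b2", "y")),
    "9" = rbind(c("y", "z"), c("y", "c1"), c("z", "c1"),
                c("a2", "y"), c("a2", "z")),
    "10" = rbind(cbind("a", b), cbind("a", "c"), cbind(b, "c")),
    "11" = rbind(c("x", "b1"), c("x", "z"), c("b1", "z"),
                 c("a2", "x"), c("a2", "z")),
    "12" = rbind(cbind("a", "b"), cbind("a", cc), cbind("b", cc))
  )
  shared <- switch(as.character(type_id),
    "1" = "c",
    "2" = paste0("x", 2:k),
    "3" = paste0("y", 2:k),
    "4" = "b",
    "5" = paste0("z", 2:k),
    "6" = "a",
    "7" = c("b", "c"),
    "8" = c("x", "y"),
    "9" = c("y", "z"),
    "10" = c("a", "c"),
    "11" = c("x", "z"),
    "12" = c("a", "b")
  )
  list(edges = unique(edges), shared_nodes = shared)
}

#' @export
print.motif_fixture <- function(x, ...) {
  s <- x$spec
  cat("Motif fixture (", s$recipe, "): ", igraph::vcount(x$network),
      " nodes, ", igraph::ecount(x$network), " edges\n", sep = "")
  cat("  ground truth: ", s$motif_count, " motif(s), Mc = ",
      format(s$Mc, digits = 4), ", ", s$n_pairs_clustered,
      " clustered pair(s)\n", sep = "")
  nz <- s$distribution[s$distribution > 0]
  if (length(nz)) {
    cat("  type distribution:",
        paste(names(nz), format(nz, digits = 3), sep = ": ",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build a mixed-composition FFL fixture
#'
#' Assembles node-disjoint pure-type blocks (each a two-motif pair) so that
#' the clustered-pair type distribution matches the requested composition
#' exactly. Cross-block pairs are node-disjoint, hence neglected, and never
#' pollute the composition.
#'
#' @param composition Named numeric vector: names are type ids (1-12),
#'   values are fractions summing to 1 (or non-negative integer block
#'   counts). An empty composition yields an empty network.
#' @param seed Optional integer seed forwarded to block relabeling.
#' @return A \code{motif_fixture} (see [make_type_fixture()]); the spec
#'   records the exact achieved distribution.
#' @examples
#' fx <- make_mixed_fixture(c("6" = 0.5, "12" = 0.5))
#' fx$spec$distribution[c("6", "12")]
#' @export
make_mixed_fixture <- function(composition, seed = NULL) {
  if (!length(composition)) {
    g <- igraph::make_empty_graph(0, directed = TRUE)
    spec <- list(recipe = "mixed", composition = composition,
                 motif_count = 0L, n_pairs_clustered = 0L,
                 S = 0L, T = 0L, Mc = NaN,
                 distribution = stats::setNames(numeric(12),
                                                as.character(1:12)),
                 mcd = stats::setNames(integer(0), character(0)))
    return(structure(list(network = g, spec = spec),
                     class = "motif_fixture"))
  }
  stopifnot(is.numeric(composition), !is.null(names(composition)),
            all(composition >= 0))
  ids <- as.integer(names(composition))
  if (anyNA(ids) || !all(ids %in% 1:12)) {
    stop("composition names must be type ids 1-12")
  }
  if (all(composition == round(composition)) && sum(composition) >= 1 &&
      sum(composition) != 1) {
    counts <- as.integer(composition)
  } else {
    if (abs(sum(composition) - 1) > 1e-9) {
      stop("composition fractions must sum to 1")
    }
    L <- NA_integer_
    for (cand in 1:1000) {
      if (all(abs(composition * cand - round(composition * cand)) < 1e-9)) {
        L <- cand
        break
      }
    }
    if (is.na(L)) {
      stop("infeasible composition: fractions have no common denominator ",
           "up to 1000 blocks")
    }
    counts <- as.integer(round(composition * L))
  }
  blocks <- rep(ids, counts)
  n_blocks <- length(blocks)
  if (!n_blocks) stop("composition requests zero blocks")
  edges <- NULL
  mcd_truth <- integer(0)
  S <- 0L
  for (bi in seq_len(n_blocks)) {
    fx <- make_type_fixture(blocks[bi], 2L)
    pre <- paste0("g", bi, ".")
    el <- igraph::as_edgelist(fx$network)
    edges <- rbind(edges, cbind(paste0(pre, el[, 1]),
                                paste0(pre, el[, 2])))
    m <- fx$spec$mcd
    names(m) <- paste0(pre, names(m))
    mcd_truth <- c(mcd_truth, m)
    S <- S + fx$spec$S
  }
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    new_names <- paste0("v", sample.int(igraph::vcount(g)))
    names(mcd_truth) <- new_names[match(names(mcd_truth),
                                        igraph::V(g)$name)]
    igraph::V(g)$name <- new_names
  }
  g$name <- sprintf("fixture(mixed, %d block(s))", n_blocks)
  n_motifs <- 2L * n_blocks
  T <- 2 * choose(n_motifs, 2)
  distribution <- stats::setNames(numeric(12), as.character(1:12))
  tab <- table(blocks)
  distribution[names(tab)] <- as.numeric(tab) / n_blocks
  spec <- list(recipe = "mixed", composition = composition,
               motif_count = n_motifs,
               n_pairs_clustered = n_blocks,
               S = as.integer(S), T = as.integer(T), Mc = S / T,
               distribution = distribution, mcd = mcd_truth)
  structure(list(network = g, spec = spec), class = "motif_fixture")
}
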