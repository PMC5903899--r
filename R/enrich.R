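# Enrichment of a binary node label across MCD strata, and comparison of
# MCD against degree/betweenness as predictors.

# Internal: coerce label input (data.frame node/label or named vector) to a
# named logical vector. Accepts logicals, "true"/"false", "yes"/"no", 0/1.
as_label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("node", "label") %in% names(labels)))
    lv <- stats::setNames(labels$label, labels$node)
  } else if (!is.null(names(labels))) {
    lv <- labels
  } else {
    stop("'labels' must be a data frame with node/label columns or a ",
         "named vector")
  }
  if (is.logical(lv)) return(lv)
  lo <- tolower(as.character(lv))
  out <- lo %in% c("true", "yes", "1", "t", "essential")
  bad <- !(lo %in% c("true", "yes", "1", "t", "essential",
                     "false", "no", "0", "f", "nonessential"))
  if (any(bad)) {
    stop("unrecognized label value(s): ",
         paste(unique(lv[bad]), collapse = ", "))
  }
  stats::setNames(out, names(lv))
}

#' Group-size-adjusted enrichment of a label across MCD values
#'
#' For each MCD value, models the number of positively labeled nodes in that
#' group under fixed-margin random selection: drawing the group (size
#' \eqn{n_g}) from a population of \eqn{N} nodes of which \eqn{K} carry the
#' label gives a hypergeometric count with mean \eqn{n_g K / N}. The
#' reported z score is \eqn{(obs - n_g K/N)/sd}. This adjusts for the very
#' different group sizes at each MCD value. A permutation null (label
#' shuffling) is available as a cross-check and gives the empirical mean/sd
#' in place of the exact hypergeometric moments.
#'
#' @param mcd_table An \code{mcd_table} from [mcd()] (or any data frame with
#'   columns \code{node} and \code{mcd}).
#' @param labels A data frame with columns \code{node}, \code{label}, or a
#'   named vector; values are interpreted as logical (true/false, yes/no,
#'   0/1). Every scored node must be labeled; label keys that match no
#'   scored node are reported with a warning.
#' @param method \code{"hypergeometric"} (exact moments, default) or
#'   \code{"permutation"}.
#' @param n_perm Number of label permutations for the permutation method.
#' @param seed Optional integer seed (permutation method).
#' @return An object of class \code{mcd_enrichment}: a data frame with one
#'   row per MCD value (\code{mcd}, \code{size}, \code{labeled},
#'   \code{expected}, \code{sd}, \code{z}) plus attributes \code{N},
#'   \code{K}, and \code{method}.
#' @export
mcd_enrichment <- function(mcd_table, labels,
                           method = c("hypergeometric", "permutation"),
                           n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(mcd_table),
            all(c("node", "mcd") %in% names(mcd_table)))
  lv <- as_label_vector(labels)
  extra <- setdiff(names(lv), mcd_table$node)
  if (length(extra)) {
    warning("label table has ", length(extra),
            " key(s) matching no scored node: ",
            paste(utils::head(extra, 10), collapse = ", "),
            if (length(extra) > 10) ", ..." else "")
  }
  missing <- setdiff(mcd_table$node, names(lv))
  if (length(missing)) {
    stop("scored node(s) without a label: ",
         paste(utils::head(missing, 20), collapse = ", "),
         if (length(missing) > 20) ", ..." else "")
  }
  lab <- unname(lv[mcd_table$node])
  N <- nrow(mcd_table)
  K <- sum(lab)
  groups <- sort(unique(mcd_table$mcd))
  size <- vapply(groups, function(gv) sum(mcd_table$mcd == gv), integer(1))
  observed <- vapply(groups, function(gv) sum(lab[mcd_table$mcd == gv]),
                     integer(1))
  if (method == "hypergeometric") {
    expected <- size * K / N
    vr <- if (N > 1) {
      size * (K / N) * (1 - K / N) * (N - size) / (N - 1)
    } else {
      rep(0, length(size))
    }
    sdv <- sqrt(vr)
  } else {
    seed_if_given(seed)
    perm <- matrix(0, nrow = n_perm, ncol = length(groups))
    for (b in seq_len(n_perm)) {
      pl <- sample(lab)
      perm[b, ] <- vapply(seq_along(groups), function(gi) {
        sum(pl[mcd_table$mcd == groups[gi]])
      }, numeric(1))
    }
    expected <- colMeans(perm)
    sdv <- apply(perm, 2, stats::sd)
  }
  degenerate <- sdv == 0 | is.na(sdv)
  if (any(degenerate)) {
    warning("degenerate group(s) with zero selection variance; ",
            "z reported as 0 for: MCD = ",
            paste(groups[degenerate], collapse = ", "))
  }
  z <- ifelse(degenerate, 0, (observed - expected) / sdv)
  out <- data.frame(mcd = groups, size = size, labeled = observed,
                    expected = expected, sd = sdv, z = z)
  structure(out, class = c("mcd_enrichment", "data.frame"),
            N = N, K = K, method = method)
}

#' Compare top-k node selections by MCD, degree, and betweenness
#'
#' Selects the top \code{k} nodes under each importance measure and compares
#' how many positively labeled nodes each captures, including pairwise
#' overlaps and the labeled nodes uniquely identified by a single measure.
#' Ties at the selection threshold are all included (threshold-inclusive
#' selection), so the effective set size can exceed \code{k} and is
#' reported per measure.
#'
#' @param metrics A data frame with columns \code{node}, \code{label}
#'   (logical or coercible), and one column per measure (see
#'   \code{measures}).
#' @param k Target set size (1 <= k <= number of nodes).
#' @param measures Character vector of metric column names; default
#'   \code{c("mcd", "degree", "betweenness")}.
#' @return An object of class \code{top_set_comparison}: a list with
#'   \code{per_measure} (data frame measure, effective_k, labeled_hits,
#'   unique_hits), \code{overlap} (matrix of selected-set overlaps),
#'   \code{venn} (labeled-hit counts per membership region), and the
#'   selected node sets.
#' @export
top_set_comparison <- function(metrics, k,
                               measures = c("mcd", "degree", "betweenness")) {
  stopifnot(is.data.frame(metrics), "node" %in% names(metrics),
            "label" %in% names(metrics),
            all(measures %in% names(metrics)))
  if (k < 1L || k > nrow(metrics)) {
    stop("'k' must be between 1 and the number of nodes (", nrow(metrics),
         ")")
  }
  lab <- as_label_vector(stats::setNames(metrics$label, metrics$node))
  sets <- lapply(measures, function(ms) {
    v <- metrics[[ms]]
    thr <- sort(v, decreasing = TRUE)[k]
    metrics$node[v >= thr]
  })
  names(sets) <- measures
  eff_k <- vapply(sets, length, integer(1))
  hits <- vapply(sets, function(s) sum(lab[s]), integer(1))
  unique_hits <- vapply(measures, function(ms) {
    others <- unlist(sets[setdiff(measures, ms)], use.names = FALSE)
    sum(lab[setdiff(sets[[ms]], others)])
  }, integer(1))
  overlap <- outer(measures, measures,
                   Vectorize(function(a, b) {
                     length(intersect(sets[[a]], sets[[b]]))
                   }))
  dimnames(overlap) <- list(measures, measures)
  # labeled-hit counts per Venn region (membership pattern over measures)
  labeled_nodes <- metrics$node[lab[metrics$node]]
  membership <- vapply(sets, function(s) labeled_nodes %in% s,
                       logical(length(labeled_nodes)))
  if (length(labeled_nodes) == 1L) membership <- matrix(membership, nrow = 1)
  pattern_key <- apply(membership, 1, function(r) paste(as.integer(r),
                                                        collapse = ""))
  in_any <- rowSums(membership) > 0
  venn <- table(pattern_key[in_any])
  structure(list(per_measure = data.frame(measure = measures,
                                          effective_k = eff_k,
                                          labeled_hits = hits,
                                          unique_hits = unique_hits),
                 overlap = overlap, venn = venn, sets = sets, k = k),
            class = "top_set_comparison")
}

#' @export
print.top_set_comparison <- function(x, ...) {
  cat("Top-", x$k, " selection comparison (threshold-inclusive)\n", sep = "")
  print(x$per_measure, row.names = FALSE)
  cat("Selected-set overlaps:\n")
  print(x$overlap)
  invisible(x)
}

#' Per-node metrics table for importance comparison
#'
#' Computes MCD, total degree, and normalized directed betweenness for every
#' node, optionally joined with a label table.
#'
#' @param network A directed simple \code{igraph}.
#' @param patterns Motif pattern(s) for the MCD computation (default FFL).
#' @param labels Optional label table (data frame \code{node}, \code{label}).
#' @return A data frame with columns \code{node}, \code{mcd}, \code{degree},
#'   \code{betweenness}, and (when labels are given) \code{label}.
#' @export
node_metrics <- function(network, patterns = motif_ffl(), labels = NULL) {
  network <- as_network(network)
  mt <- mcd(network, patterns)
  out <- data.frame(node = mt$node, mcd = mt$mcd,
                    degree = as.numeric(
                      igraph::degree(network, v = mt$node, mode = "all")),
                    betweenness = as.numeric(
                      igraph::betweenness(network, v = mt$node,
                                          directed = TRUE,
                                          normalized = TRUE)),
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    lv <- as_label_vector(labels)
    out$label <- unname(lv[out$node])
  }
  out
}
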