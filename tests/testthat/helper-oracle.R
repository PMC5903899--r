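# Independent brute-force oracles. These deliberately avoid the package's
# matching and canonicalization machinery: graphs are handled as adjacency
# matrices, isomorphism is tested by exhaustive permutation, and motif
# occurrences are enumerated over all node triples.

oracle_adjacency <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

.perm_cache <- new.env(parent = emptyenv())
oracle_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  res <- if (n == 1L) list(1L) else {
    out <- list()
    for (k in seq_len(n)) {
      for (rest in oracle_perms(n - 1L)) {
        v <- seq_len(n)[-k]
        out[[length(out) + 1L]] <- c(k, v[rest])
      }
    }
    out
  }
  .perm_cache[[key]] <- res
  res
}

# Exhaustive-permutation digraph isomorphism on adjacency matrices.
oracle_iso <- function(A, B) {
  if (nrow(A) != nrow(B) || sum(A) != sum(B)) return(FALSE)
  degA <- paste(sort(paste(rowSums(A), colSums(A))), collapse = ";")
  degB <- paste(sort(paste(rowSums(B), colSums(B))), collapse = ";")
  if (degA != degB) return(FALSE)
  for (p in oracle_perms(nrow(A))) {
    if (all(A[p, p, drop = FALSE] == B)) return(TRUE)
  }
  FALSE
}

# All induced occurrences of a 3-node pattern: every node triple, every
# role assignment, induced-submatrix equality. Returns a list of instances
# (sorted node names + one role map).
oracle_find_instances <- function(g, pattern) {
  A <- oracle_adjacency(g)
  nodes <- igraph::V(g)$name
  P <- oracle_adjacency(pattern$graph)
  roles <- igraph::V(pattern$graph)$name
  n <- nrow(A)
  out <- list()
  seen <- character(0)
  if (n < 3L) return(out)
  for (trip in utils::combn(n, 3, simplify = FALSE)) {
    for (p in oracle_perms(3L)) {
      sel <- trip[p]
      if (all(A[sel, sel] == P)) {
        key <- paste(sort(nodes[trip]), collapse = "|")
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          out[[length(out) + 1L]] <- list(
            pattern = pattern$name,
            roles = stats::setNames(nodes[sel], roles),
            nodes = sort(nodes[sel]))
        }
        break
      }
    }
  }
  out
}

# Pairwise S and T by direct double loop (Eqs. as written).
oracle_shared_stats <- function(node_sets) {
  n <- length(node_sets)
  S <- 0L
  T <- 0L
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        S <- S + length(intersect(node_sets[[i]], node_sets[[j]]))
        T <- T + min(length(node_sets[[i]]), length(node_sets[[j]])) - 1L
      }
    }
  }
  list(S = S, T = T)
}

# Brute-force enumeration of all union graphs of two overlapping pattern
# copies (each copy staying induced), deduplicated by oracle_iso. Returns a
# list of adjacency matrices.
oracle_enumerate_types <- function(p1, p2 = p1) {
  A1 <- oracle_adjacency(p1$graph)
  A2 <- oracle_adjacency(p2$graph)
  n1 <- nrow(A1)
  n2 <- nrow(A2)
  found <- list()
  for (s in seq_len(min(n1, n2))) {
    for (sub1 in utils::combn(n1, s, simplify = FALSE)) {
      for (sub2 in utils::combn(n2, s, simplify = FALSE)) {
        for (p in oracle_perms(s)) {
          m2 <- sub2[p]  # sub1[t] identified with m2[t]
          # build union on n1 + (n2 - s) nodes
          map2 <- integer(n2)
          map2[m2] <- sub1
          map2[setdiff(seq_len(n2), m2)] <-
            n1 + seq_len(n2 - s)
          nt <- n1 + n2 - s
          U <- matrix(0L, nt, nt)
          U[seq_len(n1), seq_len(n1)] <- A1
          for (i in seq_len(n2)) {
            for (j in seq_len(n2)) {
              if (A2[i, j] == 1L) U[map2[i], map2[j]] <- 1L
            }
          }
          # induced: no extra union edges inside either copy
          if (sum(U[seq_len(n1), seq_len(n1)]) != sum(A1)) next
          c2 <- map2
          if (sum(U[c2, c2]) != sum(A2)) next
          # skip coincident copies
          if (s == n1 && s == n2 && sum(U) == sum(A1)) next
          if (!any(vapply(found, oracle_iso, logical(1), B = U))) {
            found[[length(found) + 1L]] <- U
          }
        }
      }
    }
  }
  found
}

# Classify one clustered pair by exhaustive isomorphism against the catalog
# graphs (independent of canonical keys). Instances must carry role maps.
oracle_classify_pair <- function(inst1, inst2, catalog) {
  if (!length(intersect(inst1$nodes, inst2$nodes))) return("disjoint")
  pe <- function(inst) {
    p <- catalog$patterns[[inst$pattern]]
    el <- igraph::as_edgelist(p$graph)
    cbind(unname(inst$roles[el[, 1]]), unname(inst$roles[el[, 2]]))
  }
  edges <- unique(rbind(pe(inst1), pe(inst2)))
  verts <- sort(unique(as.vector(edges)))
  U <- matrix(0L, length(verts), length(verts))
  U[cbind(match(edges[, 1], verts), match(edges[, 2], verts))] <- 1L
  for (t in seq_along(catalog$graphs)) {
    if (oracle_iso(U, oracle_adjacency(catalog$graphs[[t]]))) {
      return(catalog$table$id[t])
    }
  }
  stop("oracle: clustered pair matches no catalog type")
}

# Full oracle pass: instances, clustered pairs, per-type counts, per-node
# MCD (pairs of instances both containing the node).
oracle_type_analysis <- function(g, pattern, catalog) {
  inst <- oracle_find_instances(g, pattern)
  n <- length(inst)
  counts <- stats::setNames(integer(nrow(catalog$table)),
                            catalog$table$id)
  mcd_env <- new.env(parent = emptyenv())
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ty <- oracle_classify_pair(inst[[i]], inst[[j]], catalog)
        if (!identical(ty, "disjoint")) {
          counts[as.character(ty)] <- counts[as.character(ty)] + 1L
          for (v in intersect(inst[[i]]$nodes, inst[[j]]$nodes)) {
            assign(v, union(get0(v, envir = mcd_env,
                                 ifnotfound = integer(0)), ty),
                   envir = mcd_env)
          }
        }
      }
    }
  }
  mcd_vals <- stats::setNames(integer(igraph::vcount(g)),
                              igraph::V(g)$name)
  for (v in ls(mcd_env)) mcd_vals[v] <- length(get(v, envir = mcd_env))
  list(instances = inst, counts = counts, mcd = mcd_vals)
}
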