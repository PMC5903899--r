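#' Define a motif pattern
#'
#' A motif pattern is a small role-labeled directed graph used as a search
#' template, such as the feed-forward loop. Patterns must be simple, weakly
#' connected, and free of self-loops.
#'
#' @param name Short identifier for the pattern (e.g. \code{"ffl"}).
#' @param edges A two-column character matrix or data frame of directed role
#'   pairs (source role, target role).
#' @param roles Optional ordered character vector of role labels; defaults to
#'   the roles in order of first appearance in \code{edges}.
#' @return An object of class \code{motif_pattern} with fields \code{name},
#'   \code{roles}, and \code{graph} (an igraph whose vertex names are the
#'   roles).
#' @seealso [motif_ffl()], [motif_fbl()], [read_pattern()]
#' @export
motif_pattern <- function(name, edges, roles = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  stopifnot(is.character(name), length(name) == 1L,
            is.matrix(edges), ncol(edges) >= 2L)
  edges <- cbind(as.character(edges[, 1]), as.character(edges[, 2]))
  if (is.null(roles)) roles <- unique(as.vector(t(edges)))
  if (!all(edges %in% roles)) {
    stop("pattern '", name, "': edge endpoints must all be listed roles")
  }
  if (any(edges[, 1] == edges[, 2])) {
    stop("pattern '", name, "' contains a self-loop")
  }
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) {
    stop("pattern '", name, "' contains duplicate edges")
  }
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(roles), name = roles)
  g <- igraph::add_edges(g, as.vector(t(edges)))
  if (!igraph::is_connected(g, mode = "weak")) {
    stop("pattern '", name, "' must be weakly connected")
  }
  structure(list(name = name, roles = roles, graph = g),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  el <- igraph::as_edgelist(x$graph)
  cat("Motif pattern '", x$name, "': roles [",
      paste(x$roles, collapse = ", "), "]\n", sep = "")
  cat("  edges:", paste(el[, 1], "->", el[, 2], collapse = ", "), "\n")
  invisible(x)
}

#' Built-in feed-forward loop pattern
#'
#' The FFL has an input regulating an intermediate and an output, with the
#' intermediate also regulating the output (edges input->intermediate,
#' input->output, intermediate->output).
#'
#' @return A \code{motif_pattern}.
#' @export
motif_ffl <- function() {
  motif_pattern("ffl",
                rbind(c("input", "intermediate"),
                      c("input", "output"),
                      c("intermediate", "output")),
                roles = c("input", "intermediate", "output"))
}

#' Built-in three-node feedback loop pattern
#'
#' A directed 3-cycle A->B->C->A.
#'
#' @return A \code{motif_pattern}.
#' @export
motif_fbl <- function() {
  motif_pattern("fbl",
                rbind(c("A", "B"), c("B", "C"), c("C", "A")),
                roles = c("A", "B", "C"))
}

#' Read a custom motif pattern from a file
#'
#' The file format is a tiny edge list with a role header: the first
#' non-comment line must read \code{roles: r1 r2 ...}; every following
#' non-comment line gives one directed edge as two whitespace-separated
#' roles. Lines starting with \code{#} are comments.
#'
#' @param path Path to the pattern file.
#' @param name Pattern name; defaults to the file name without extension.
#' @return A \code{motif_pattern}.
#' @export
read_pattern <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) < 2L || !startsWith(lines[[1]], "roles:")) {
    stop("pattern file '", path,
         "' must start with a 'roles: ...' header line followed by edges")
  }
  roles <- strsplit(sub("^roles:\\s*", "", lines[[1]]), "[ \t]+")[[1]]
  edges <- t(vapply(lines[-1], function(ln) {
    toks <- strsplit(ln, "[ \t]+")[[1]]
    if (length(toks) < 2L) stop("bad edge line in pattern file: '", ln, "'")
    toks[1:2]
  }, character(2)))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  motif_pattern(name, edges, roles = roles)
}

# Internal: normalize a pattern or list of patterns to a named list and
# validate the set.
as_pattern_list <- function(patterns) {
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  if (!is.list(patterns) || !length(patterns) ||
      !all(vapply(patterns, inherits, logical(1), "motif_pattern"))) {
    stop("'patterns' must be a motif_pattern or a list of motif_pattern objects")
  }
  names(patterns) <- vapply(patterns, `[[`, character(1), "name")
  validate_pattern_set(patterns)
  patterns
}

#' Validate a set of motif patterns
#'
#' Checks that pattern names are unique and that no pattern is a subgraph
#' isomorph of another (which would make shared instances ambiguous).
#'
#' @param patterns List of \code{motif_pattern} objects.
#' @return Invisibly, the validated list.
#' @export
validate_pattern_set <- function(patterns) {
  nms <- vapply(patterns, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("pattern names must be unique")
  np <- length(patterns)
  if (np > 1L) {
    for (i in seq_len(np)) {
      for (j in seq_len(np)) {
        if (i == j) next
        gi <- patterns[[i]]$graph
        gj <- patterns[[j]]$graph
        if (igraph::vcount(gi) <= igraph::vcount(gj) &&
            igraph::subgraph_isomorphic(gi, gj, method = "lad",
                                        induced = FALSE)) {
          stop("invalid pattern set: '", nms[i],
               "' is a subgraph isomorph of '", nms[j], "'")
        }
      }
    }
  }
  invisible(patterns)
}

# Internal: resolve pattern names like "ffl,fbl" (used by the CLI).
patterns_from_names <- function(spec) {
  nms <- strsplit(spec, ",")[[1]]
  lapply(nms, function(nm) {
    switch(nm,
      ffl = motif_ffl(),
      fbl = motif_fbl(),
      {
        if (file.exists(nm)) read_pattern(nm)
        else stop("unknown motif '", nm,
                  "' (use 'ffl', 'fbl', or a pattern file path)")
      }
    )
  })
}
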