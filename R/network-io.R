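#' Read a directed network from a file
#'
#' Reads a directed network from a whitespace-delimited edge list, GraphML, or
#' GML file and sanitizes it to a simple digraph (self-loops and duplicate
#' edges are dropped with a message reporting the counts).
#'
#' The edge-list dialect is: one edge per line, first two whitespace-separated
#' tokens are source and target, extra tokens are ignored, lines starting with
#' \code{#} and blank lines are skipped. Node labels are kept as opaque
#' strings and never coerced to numbers, so \code{"1"} and \code{"01"} remain
#' distinct nodes.
#'
#' @param path Path to the network file.
#' @param format One of \code{"auto"} (guess from the file extension),
#'   \code{"edgelist"}, \code{"graphml"}, or \code{"gml"}.
#' @param name Optional name stored as the graph's \code{name} attribute;
#'   defaults to the file name.
#' @return A directed, simple \code{igraph} object with character vertex
#'   names.
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' writeLines(c("a b", "b c", "a c"), tf)
#' g <- read_network(tf)
#' igraph::vcount(g)  # 3
#' @export
read_network <- function(path, format = c("auto", "edgelist", "graphml", "gml"),
                         name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read network file: '", path, "' does not exist")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      graphml = "graphml",
      gml = "gml",
      "edgelist"
    )
  }
  g <- switch(format,
    edgelist = read_edgelist_file(path),
    graphml = igraph::read_graph(path, format = "graphml"),
    gml = igraph::read_graph(path, format = "gml")
  )
  if (!igraph::is_directed(g)) {
    stop("network in '", path, "' is undirected; a directed network is required")
  }
  g <- ensure_names(g)
  g <- sanitize_network(g)
  g$name <- if (is.null(name)) basename(path) else name
  g
}

read_edgelist_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  src <- character(0)
  dst <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    toks <- strsplit(ln, "[ \t]+")[[1]]
    if (length(toks) < 2L) {
      stop("parse error in edge list '", path, "' at line ", i,
           ": expected at least two tokens, got '", ln, "'")
    }
    src <- c(src, toks[[1]])
    dst <- c(dst, toks[[2]])
  }
  if (length(src) == 0L) {
    return(igraph::make_empty_graph(n = 0, directed = TRUE))
  }
  igraph::graph_from_edgelist(cbind(src, dst), directed = TRUE)
}

ensure_names <- function(g) {
  nm <- igraph::vertex_attr(g, "name")
  if (is.null(nm)) {
    # GraphML/GML files may carry labels under other attribute names
    for (cand in c("label", "id")) {
      v <- igraph::vertex_attr(g, cand)
      if (!is.null(v)) {
        nm <- as.character(v)
        break
      }
    }
    if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
    igraph::V(g)$name <- nm
  } else {
    igraph::V(g)$name <- as.character(nm)
  }
  if (anyDuplicated(igraph::V(g)$name)) {
    stop("network has duplicated node labels after reading")
  }
  g
}

#' Sanitize a directed network to a simple digraph
#'
#' Removes self-loops and duplicate edges, reporting how many of each were
#' dropped. All downstream motif definitions assume a simple digraph, so this
#' runs automatically inside [read_network()]; it is idempotent.
#'
#' @param network A directed \code{igraph} object.
#' @return A simple directed \code{igraph} with the same vertices.
#' @export
sanitize_network <- function(network) {
  stopifnot(igraph::is_igraph(network))
  if (!igraph::is_directed(network)) {
    stop("network must be directed")
  }
  n_loops <- sum(igraph::which_loop(network))
  # which_multiple flags every copy beyond the first of a repeated edge
  n_dup <- sum(igraph::which_multiple(network))
  if (n_loops > 0L || n_dup > 0L) {
    message("sanitize_network: dropped ", n_loops, " self-loop(s) and ",
            n_dup, " duplicate edge(s)")
    network <- igraph::simplify(network, remove.multiple = TRUE,
                                remove.loops = TRUE)
  }
  network
}

# Internal: validate/normalize user-supplied network arguments.
as_network <- function(network) {
  if (!igraph::is_igraph(network)) {
    stop("'network' must be an igraph object (see read_network())")
  }
  if (!igraph::is_directed(network)) stop("'network' must be directed")
  if (is.null(igraph::vertex_attr(network, "name"))) {
    network <- ensure_names(network)
  }
  network
}

#' Write a directed network to a file
#'
#' @param network A directed \code{igraph} object.
#' @param path Output path.
#' @param format One of \code{"edgelist"}, \code{"graphml"}, \code{"gml"}.
#' @return Invisibly, \code{path}.
#' @export
write_network <- function(network, path,
                          format = c("edgelist", "graphml", "gml")) {
  format <- match.arg(format)
  network <- as_network(network)
  if (format == "edgelist") {
    el <- igraph::as_edgelist(network, names = TRUE)
    lines <- if (nrow(el)) paste(el[, 1], el[, 2]) else character(0)
    writeLines(lines, path)
  } else {
    igraph::write_graph(network, path, format = format)
  }
  invisible(path)
}

#' Read a two-column node label table
#'
#' Reads a CSV with columns \code{node,label} mapping node names to a
#' categorical label (for example essentiality \code{true}/\code{false}).
#'
#' @param path Path to a CSV file with a header row.
#' @return A data frame with character columns \code{node} and \code{label}.
#' @export
read_node_labels <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("label table '", path, "' must have at least two columns (node,label)")
  }
  out <- data.frame(node = df[[1]], label = df[[2]],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$node)) {
    stop("label table '", path, "' has duplicated node keys")
  }
  out
}

#' Match a label table against a network's node set
#'
#' Label keys that do not correspond to any network node are reported with a
#' warning (never silently dropped); the returned table is restricted to
#' matching nodes.
#'
#' @param network A directed \code{igraph}.
#' @param labels Data frame with columns \code{node} and \code{label}.
#' @return The subset of \code{labels} whose nodes exist in the network.
#' @export
match_node_labels <- function(network, labels) {
  network <- as_network(network)
  stopifnot(is.data.frame(labels), all(c("node", "label") %in% names(labels)))
  unknown <- setdiff(labels$node, igraph::V(network)$name)
  if (length(unknown)) {
    warning("label table has ", length(unknown),
            " key(s) not present in the network: ",
            paste(utils::head(unknown, 10), collapse = ", "),
            if (length(unknown) > 10) ", ..." else "")
  }
  labels[labels$node %in% igraph::V(network)$name, , drop = FALSE]
}

#' Write a result table as CSV or JSON
#'
#' CSV output always carries a header row; JSON output is an array with one
#' object per record. An empty record set yields a header-only CSV or an
#' empty JSON array, and a write/read round trip preserves values.
#'
#' @param records A data frame of results.
#' @param path Output path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return Invisibly, \code{path}.
#' @export
write_table <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (is.null(records)) stop("'records' must be non-null")
  records <- as.data.frame(records)
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}
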