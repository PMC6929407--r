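#' @importFrom stats setNames
NULL

#' Construct a weighted PPI network
#'
#' Builds an undirected weighted graph from an edge table. Edges are stored
#' canonically (endpoint pair sorted lexicographically, one row per unordered
#' pair); an adjacency list is precomputed for fast neighbourhood queries.
#'
#' @param edges data.frame with columns `from`, `to` (character) and `weight`
#'   (numeric in \[0,1\]). Duplicate unordered pairs are collapsed keeping the
#'   maximum weight; self-loops are dropped.
#' @param nodes optional character vector of node identifiers; defaults to the
#'   union of edge endpoints. Extra names declare isolated nodes.
#' @param quiet suppress messages about dropped self-loops.
#'
#' @return An object of class `ppi_network` with elements `nodes` (sorted
#'   character vector), `edges` (canonical edge data.frame) and `adj`
#'   (named list mapping each node to a named numeric vector of
#'   neighbour weights).
#' @export
ppi_network <- function(edges = NULL, nodes = NULL, quiet = FALSE) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (anyNA(edges$weight)) {
    stop("edge weights must be numeric and non-missing")
  }
  if (any(edges$weight < 0 | edges$weight > 1)) {
    bad <- which(edges$weight < 0 | edges$weight > 1)[1L]
    stop(sprintf("edge weight outside [0,1]: %s -- %s (%g)",
                 edges$from[bad], edges$to[bad], edges$weight[bad]))
  }
  nodes <- c(nodes, edges$from, edges$to)   # loop endpoints stay as nodes
  loops <- edges$from == edges$to
  if (any(loops)) {
    if (!quiet) message(sprintf("dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical orientation, collapse duplicates keeping max weight
  flip <- edges$from > edges$to
  tmp <- edges$from[flip]
  edges$from[flip] <- edges$to[flip]
  edges$to[flip] <- tmp
  if (nrow(edges)) {
    key <- paste(edges$from, edges$to, sep = "\r")
    ord <- order(key, -edges$weight)
    edges <- edges[ord, , drop = FALSE]
    edges <- edges[!duplicated(key[ord]), , drop = FALSE]
  }
  all_nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  adj <- setNames(vector("list", length(all_nodes)), all_nodes)
  for (v in all_nodes) adj[[v]] <- numeric(0)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges$from[i]; b <- edges$to[i]; w <- edges$weight[i]
      adj[[a]][b] <- w
      adj[[b]][a] <- w
    }
    adj <- lapply(adj, function(x) {
      if (length(x)) x[order(names(x))] else x
    })
  }
  structure(list(nodes = all_nodes, edges = edges, adj = adj),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(sprintf("  weights in [%.3g, %.3g]\n",
                min(x$edges$weight), max(x$edges$weight)))
  }
  invisible(x)
}

#' Weighted degree of nodes
#'
#' Sum of incident edge weights per node.
#'
#' @param g a `ppi_network`.
#' @param v nodes to query (default all).
#' @return named numeric vector.
#' @export
weighted_degree <- function(g, v = g$nodes) {
  vapply(g$adj[v], sum, numeric(1))
}

#' Unweighted degree of nodes
#' @param g a `ppi_network`.
#' @param v nodes to query (default all).
#' @return named integer vector of neighbour counts.
#' @export
node_degree <- function(g, v = g$nodes) {
  vapply(g$adj[v], length, integer(1))
}

#' Neighbours of a node
#' @param g a `ppi_network`.
#' @param v a node identifier.
#' @return character vector of adjacent nodes.
#' @export
neighbors_of <- function(g, v) {
  nm <- names(g$adj[[v]])
  if (is.null(nm)) character(0) else nm
}

#' Read a weighted edge list
#'
#' Parses a tab-separated network file with three columns (nodeA, nodeB,
#' weight), no header. Lines starting with `#` and blank lines are ignored.
#' Duplicate unordered pairs keep the maximum weight; self-loops are dropped
#' with a message.
#'
#' @param path file path.
#' @param quiet suppress drop messages.
#' @return a `ppi_network`.
#' @export
read_network <- function(path, quiet = FALSE) {
  fields <- parse_tsv3(path, what = "network")
  w <- suppressWarnings(as.numeric(fields$x3))
  if (anyNA(w)) {
    stop(sprintf("%s: non-numeric weight at line %d", path,
                 fields$line[which(is.na(w))[1L]]))
  }
  bad <- w < 0 | w > 1
  if (any(bad)) {
    stop(sprintf("%s: weight outside [0,1] at line %d (%g)", path,
                 fields$line[which(bad)[1L]], w[which(bad)[1L]]))
  }
  ppi_network(data.frame(from = fields$x1, to = fields$x2, weight = w,
                         stringsAsFactors = FALSE), quiet = quiet)
}

#' Write a network edge list
#'
#' Inverse of [read_network()]: canonical edges, tab-separated, no header.
#' @param g a `ppi_network`.
#' @param path output file path.
#' @export
write_network <- function(g, path) {
  lines <- sprintf("%s\t%s\t%s", g$edges$from, g$edges$to,
                   format(g$edges$weight, digits = 15, trim = TRUE,
                          scientific = FALSE))
  writeLines(lines, path)
  invisible(NULL)
}

# shared 3-column TSV parser: returns fields + original line numbers
parse_tsv3 <- function(path, what = "input") {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  idx <- which(keep)
  if (!length(idx)) {
    return(list(x1 = character(), x2 = character(), x3 = character(),
                line = integer()))
  }
  parts <- strsplit(raw[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop(sprintf("%s: line %d has %d field(s), expected >= 3 (tab-separated)",
                 path, idx[which(nf < 3L)[1L]], nf[which(nf < 3L)[1L]]))
  }
  list(x1 = vapply(parts, `[[`, "", 1L),
       x2 = vapply(parts, `[[`, "", 2L),
       x3 = vapply(parts, `[[`, "", 3L),
       line = idx)
}

#' Read cross-network sequence-similarity links
#'
#' Parses a TSV of `node1 <tab> node2 <tab> score` (score >= 0, e.g. -log
#' BLAST e-value) linking nodes of two networks. Pairs whose endpoints are
#' missing from the respective networks are dropped with a message; duplicate
#' pairs keep the maximum score.
#'
#' @param path file path, or `NULL` when constructing from `entries`.
#' @param g1,g2 the two `ppi_network`s the links connect.
#' @param entries optional data.frame(node1, node2, score) used instead of a
#'   file (programmatic construction).
#' @param quiet suppress drop messages.
#' @return object of class `crosslinks`: data.frame with columns `node1`,
#'   `node2`, `score`, sorted, one row per pair.
#' @export
read_crosslinks <- function(path = NULL, g1, g2, entries = NULL,
                            quiet = FALSE) {
  if (is.null(entries)) {
    fields <- parse_tsv3(path, what = "crosslink")
    score <- suppressWarnings(as.numeric(fields$x3))
    if (anyNA(score)) {
      stop(sprintf("%s: non-numeric score at line %d", path,
                   fields$line[which(is.na(score))[1L]]))
    }
    if (any(score < 0)) {
      stop(sprintf("%s: negative score at line %d", path,
                   fields$line[which(score < 0)[1L]]))
    }
    entries <- data.frame(node1 = fields$x1, node2 = fields$x2,
                          score = score, stringsAsFactors = FALSE)
  } else {
    entries <- data.frame(node1 = as.character(entries$node1),
                          node2 = as.character(entries$node2),
                          score = as.numeric(entries$score),
                          stringsAsFactors = FALSE)
    if (any(entries$score < 0)) stop("negative crosslink score")
  }
  known <- entries$node1 %in% g1$nodes & entries$node2 %in% g2$nodes
  if (any(!known) && !quiet) {
    message(sprintf("dropped %d crosslink line(s) with unknown node IDs",
                    sum(!known)))
  }
  entries <- entries[known, , drop = FALSE]
  if (nrow(entries)) {
    key <- paste(entries$node1, entries$node2, sep = "\r")
    ord <- order(key, -entries$score)
    entries <- entries[ord, , drop = FALSE]
    entries <- entries[!duplicated(key[ord]), , drop = FALSE]
    entries <- entries[order(entries$node1, entries$node2), , drop = FALSE]
  }
  rownames(entries) <- NULL
  class(entries) <- c("crosslinks", "data.frame")
  entries
}

#' @export
print.crosslinks <- function(x, ...) {
  cat(sprintf("crosslinks: %d pair(s)", nrow(x)))
  if (nrow(x)) cat(sprintf(", scores in [%.3g, %.3g]",
                           min(x$score), max(x$score)))
  cat("\n")
  invisible(x)
}

#' Write crosslinks to TSV
#' @param xl a `crosslinks` object.
#' @param path output file path.
#' @export
write_crosslinks <- function(xl, path) {
  lines <- sprintf("%s\t%s\t%s", xl$node1, xl$node2,
                   format(xl$score, digits = 15, trim = TRUE,
                          scientific = FALSE))
  writeLines(lines, path)
  invisible(NULL)
}

#' Write aligned cluster pairs
#'
#' Emits the standard two-file output: row i of `path1` lists the members of
#' the network-1 cluster of pair i (tab-separated, sorted), row i of `path2`
#' the members of its aligned network-2 cluster. Both files always have the
#' same number of rows.
#'
#' @param pairs list of cluster pairs, each a list with `members1` and
#'   `members2` character vectors (as produced by [leprimalign()]).
#' @param path1,path2 output file paths for the two networks.
#' @export
write_cluster_pairs <- function(pairs, path1, path2) {
  rows1 <- vapply(pairs, function(p)
    paste(sort(p$members1), collapse = "\t"), "")
  rows2 <- vapply(pairs, function(p)
    paste(sort(p$members2), collapse = "\t"), "")
  writeLines(rows1, path1)
  writeLines(rows2, path2)
  invisible(NULL)
}
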