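#' f-score of a predicted cluster against a known complex
#'
#' Harmonic mean of recall (share of the complex recovered) and precision
#' (share of the cluster inside the complex):
#' \deqn{\rho = |C \cap P|/|P|, \quad \pi = |C \cap P|/|C|, \quad
#'       f = 2\pi\rho/(\pi+\rho)}
#' Disjoint sets score 0.
#'
#' @param cluster,complex non-empty character vectors of member IDs.
#' @return numeric in \[0,1\]; 1 iff the sets are equal.
#' @export
fscore <- function(cluster, complex) {
  if (!length(cluster) || !length(complex)) {
    stop("fscore requires non-empty sets")
  }
  common <- length(intersect(cluster, complex))
  if (common == 0) return(0)
  rho <- common / length(unique(complex))
  pi_ <- common / length(unique(cluster))
  2 * pi_ * rho / (pi_ + rho)
}

#' Mean best-match f-score of a clustering
#'
#' For each predicted cluster, the best [fscore()] over all catalog
#' complexes; returns the mean over clusters. The standard accuracy summary
#' for protein-complex prediction.
#'
#' @param clusters non-empty list of character vectors.
#' @param catalog non-empty list of character vectors (known complexes).
#' @return numeric in \[0,1\].
#' @export
mean_best_fscore <- function(clusters, catalog) {
  if (!length(clusters)) stop("no clusters to evaluate")
  if (!length(catalog)) stop("empty complex catalog")
  best <- vapply(clusters, function(cl) {
    max(vapply(catalog, function(p) fscore(cl, p), numeric(1)))
  }, numeric(1))
  mean(best)
}

#' Read a complex catalog
#'
#' One complex per line, tab-separated member IDs, optionally preceded by a
#' complex name. Complexes with fewer than two members after restriction to
#' the network's nodes are dropped with a message.
#'
#' @param path file path.
#' @param nodes optional character vector to restrict members to (e.g.
#'   `g$nodes`); `NULL` keeps all members.
#' @param named whether the first column is a complex name.
#' @param quiet suppress drop messages.
#' @return named list of character vectors.
#' @export
read_complexes <- function(path, nodes = NULL, named = FALSE,
                           quiet = FALSE) {
  if (!file.exists(path)) stop(sprintf("catalog file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  parts <- strsplit(raw, "\t", fixed = TRUE)
  if (named) {
    nm <- vapply(parts, `[[`, "", 1L)
    parts <- lapply(parts, `[`, -1L)
  } else {
    nm <- paste0("complex", seq_along(parts))
  }
  cx <- lapply(parts, unique)
  if (!is.null(nodes)) cx <- lapply(cx, intersect, y = nodes)
  keep <- lengths(cx) >= 2L
  if (any(!keep) && !quiet) {
    message(sprintf("dropped %d complex(es) with < 2 members in the network",
                    sum(!keep)))
  }
  setNames(cx[keep], nm[keep])
}

#' Read a pairwise semantic-similarity table
#'
#' TSV of `node1 <tab> node2 <tab> similarity` with values in \[0,1\].
#' Missing pairs are treated as similarity 0 by the metrics.
#'
#' @param path file path, or `NULL` when constructing from `entries`.
#' @param entries optional data.frame(node1, node2, similarity).
#' @return object of class `ss_table` (data.frame) with a fast lookup
#'   attribute.
#' @export
read_sstable <- function(path = NULL, entries = NULL) {
  if (is.null(entries)) {
    fields <- parse_tsv3(path, what = "semantic-similarity")
    sim <- suppressWarnings(as.numeric(fields$x3))
    if (anyNA(sim)) {
      stop(sprintf("%s: non-numeric similarity at line %d", path,
                   fields$line[which(is.na(sim))[1L]]))
    }
    entries <- data.frame(node1 = fields$x1, node2 = fields$x2,
                          similarity = sim, stringsAsFactors = FALSE)
  } else {
    entries <- data.frame(node1 = as.character(entries$node1),
                          node2 = as.character(entries$node2),
                          similarity = as.numeric(entries$similarity),
                          stringsAsFactors = FALSE)
  }
  if (any(entries$similarity < 0 | entries$similarity > 1)) {
    stop("semantic similarity outside [0,1]")
  }
  key <- paste(entries$node1, entries$node2, sep = "\r")
  entries <- entries[!duplicated(key), , drop = FALSE]
  rownames(entries) <- NULL
  lookup <- new.env(parent = emptyenv(), size = nrow(entries))
  for (i in seq_len(nrow(entries))) {
    assign(paste(entries$node1[i], entries$node2[i], sep = "\r"),
           entries$similarity[i], envir = lookup)
  }
  structure(entries, lookup = lookup, class = c("ss_table", "data.frame"))
}

ss_of <- function(ss, a, b) {
  if (is.null(ss)) return(0)
  val <- get0(paste(a, b, sep = "\r"), envir = attr(ss, "lookup"),
              ifnotfound = 0)
  val
}

#' Inter-species semantic similarity of an aligned cluster pair
#'
#' Mean semantic similarity over the full cross product of the two clusters:
#' \deqn{ISS(C_1,C_2) = \sum_{v_i \in C_1}\sum_{v_j \in C_2}
#'       SS(v_i,v_j) / (|C_1||C_2|)}
#' Pairs absent from the table contribute 0.
#'
#' @param c1,c2 non-empty character vectors (cluster members, c1 in the
#'   network the table's first column refers to).
#' @param ss an `ss_table`.
#' @return numeric in \[0,1\].
#' @export
iss <- function(c1, c2, ss) {
  stopifnot(length(c1) > 0, length(c2) > 0)
  total <- 0
  for (a in c1) for (b in c2) total <- total + ss_of(ss, a, b)
  total / (length(c1) * length(c2))
}

# enumerate conserved (c1-edge, c2-edge) pairs; returns a data.frame of
# endpoint correspondences for downstream SS filtering
conserved_edge_pairs <- function(members1, members2, g1, g2, xl) {
  e1 <- cluster_edges(members1, g1)
  e2 <- cluster_edges(members2, g2)
  out <- list()
  if (!nrow(e1) || !nrow(e2) || !nrow(xl)) {
    return(data.frame(vi = character(), vj = character(),
                      vi2 = character(), vj2 = character()))
  }
  linked <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(xl))) {
    assign(paste(xl$node1[i], xl$node2[i], sep = "\r"), TRUE, envir = linked)
  }
  has_link <- function(a, b) {
    !is.null(get0(paste(a, b, sep = "\r"), envir = linked))
  }
  for (i in seq_len(nrow(e1))) {
    vi <- e1$from[i]; vj <- e1$to[i]
    for (j in seq_len(nrow(e2))) {
      a <- e2$from[j]; b <- e2$to[j]
      # an unordered c2 edge conserves the c1 edge via either orientation
      if (has_link(vi, a) && has_link(vj, b)) {
        out[[length(out) + 1L]] <- c(vi, vj, a, b)
      } else if (has_link(vi, b) && has_link(vj, a)) {
        out[[length(out) + 1L]] <- c(vi, vj, b, a)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(vi = character(), vj = character(),
                      vi2 = character(), vj2 = character()))
  }
  m <- do.call(rbind, out)
  data.frame(vi = m[, 1], vj = m[, 2], vi2 = m[, 3], vj2 = m[, 4],
             stringsAsFactors = FALSE)
}

#' Count conserved edges between two aligned clusters
#'
#' An edge of the first cluster is conserved by an edge of the second when
#' both endpoint pairs are crosslinked (orthologous). An edge conserved by
#' several partner edges counts once per distinct partner edge.
#'
#' @param members1,members2 member sets of the aligned clusters.
#' @param g1,g2 the two networks.
#' @param xl `crosslinks` (ortholog pairs).
#' @return non-negative integer.
#' @export
conserved_edges <- function(members1, members2, g1, g2, xl) {
  nrow(conserved_edge_pairs(members1, members2, g1, g2, xl))
}

#' Count functionally consistent conserved edges
#'
#' As [conserved_edges()], additionally requiring the semantic similarity of
#' both endpoint correspondences to exceed `ss_threshold` (strictly).
#'
#' @inheritParams conserved_edges
#' @param ss an `ss_table` of inter-species semantic similarities.
#' @param ss_threshold strict lower bound on both endpoint similarities.
#' @return non-negative integer, never more than [conserved_edges()].
#' @export
functionally_consistent_ce <- function(members1, members2, g1, g2, xl, ss,
                                       ss_threshold = 0.2) {
  cp <- conserved_edge_pairs(members1, members2, g1, g2, xl)
  if (!nrow(cp)) return(0L)
  ok <- vapply(seq_len(nrow(cp)), function(i) {
    ss_of(ss, cp$vi[i], cp$vi2[i]) > ss_threshold &&
      ss_of(ss, cp$vj[i], cp$vj2[i]) > ss_threshold
  }, logical(1))
  sum(ok)
}

#' Remove highly overlapping clusters
#'
#' Greedy size-ranked filtering: clusters are visited in decreasing size
#' (ties broken lexicographically by sorted membership) and kept iff their
#' Jaccard index with every already-kept cluster is at most
#' `jaccard_threshold`. Idempotent.
#'
#' @param clusters list of character vectors.
#' @param jaccard_threshold overlap bound (Jaccard index
#'   `|A n B| / |A u B|`).
#' @return filtered list, in the greedy visiting order.
#' @export
filter_overlapping <- function(clusters, jaccard_threshold = 0.4) {
  if (!length(clusters)) return(clusters)
  clusters <- lapply(clusters, function(x) sort(unique(x)))
  key <- vapply(clusters, paste, "", collapse = "\r")
  ord <- order(-lengths(clusters), key)
  kept <- list()
  for (i in ord) {
    a <- clusters[[i]]
    ok <- TRUE
    for (b in kept) {
      jac <- length(intersect(a, b)) / length(union(a, b))
      if (jac > jaccard_threshold) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1L]] <- a
  }
  kept
}

#' Per-pair evaluation report for an alignment
#'
#' Computes, for every emitted cluster pair, the sizes, best-match f-scores
#' against the per-network complex catalogs (when given), the inter-species
#' semantic similarity (when a table is given), and conserved-edge counts in
#' both directions.
#'
#' @param fit a `leprimalign` object.
#' @param g1,g2 the aligned networks.
#' @param xl the `crosslinks` used for the alignment.
#' @param catalog1,catalog2 optional complex catalogs (lists of character
#'   vectors) for networks 1 and 2.
#' @param ss optional `ss_table` of inter-species semantic similarities.
#' @param ss_threshold strict bound for functionally consistent conserved
#'   edges.
#' @return data.frame with one row per pair plus a `summary` attribute of
#'   column means.
#' @export
evaluate_alignment <- function(fit, g1, g2, xl, catalog1 = NULL,
                               catalog2 = NULL, ss = NULL,
                               ss_threshold = 0.2) {
  pairs <- fit$pairs
  n <- length(pairs)
  res <- data.frame(
    pair = seq_len(n),
    size1 = vapply(pairs, function(p) length(p$members1), integer(1)),
    size2 = vapply(pairs, function(p) length(p$members2), integer(1)))
  if (!is.null(catalog1)) {
    res$f1 <- vapply(pairs, function(p)
      max(vapply(catalog1, function(cx) fscore(p$members1, cx),
                 numeric(1))), numeric(1))
  }
  if (!is.null(catalog2)) {
    res$f2 <- vapply(pairs, function(p)
      max(vapply(catalog2, function(cx) fscore(p$members2, cx),
                 numeric(1))), numeric(1))
  }
  if (!is.null(ss)) {
    res$iss <- vapply(pairs, function(p) iss(p$members1, p$members2, ss),
                      numeric(1))
  }
  res$ce_12 <- vapply(pairs, function(p)
    conserved_edges(p$members1, p$members2, g1, g2, xl), numeric(1))
  res$ce_21 <- vapply(pairs, function(p)
    conserved_edges(p$members2, p$members1, g2, g1,
                    flip_crosslinks(xl)), numeric(1))
  if (!is.null(ss)) {
    res$fce_12 <- vapply(pairs, function(p)
      functionally_consistent_ce(p$members1, p$members2, g1, g2, xl, ss,
                                 ss_threshold), numeric(1))
  }
  means <- if (n) colMeans(res[, -1, drop = FALSE]) else numeric(0)
  attr(res, "summary") <- means
  res
}

# swap the two sides of a crosslinks table (for direction-2 CE counting)
flip_crosslinks <- function(xl) {
  out <- data.frame(node1 = xl$node2, node2 = xl$node1, score = xl$score,
                    stringsAsFactors = FALSE)
  class(out) <- c("crosslinks", "data.frame")
  out
}
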