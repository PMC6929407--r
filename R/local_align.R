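#' Alignment parameters
#'
#' Bundles the tunable parameters of the local alignment stage.
#'
#' @param theta seed threshold: node pairs with global score strictly above
#'   `theta` nucleate cluster pairs.
#' @param beta gap penalty in \[0,1\]; weight given to indirectly conserved
#'   (gap) edges in the intra-network score.
#' @param gamma mixing weight in \[0,1\]: local score =
#'   `gamma * S_inter + (1 - gamma) * S_intra`.
#' @param min_size minimum cluster size for an emitted pair.
#' @param discard_threshold minimum directional local score for an emitted
#'   pair (both directions must reach it).
#' @return a list of class `leprimalign_params`.
#' @export
align_params <- function(theta = 1.0, beta = 1.0, gamma = 0.25,
                         min_size = 2L, discard_threshold = 0.02) {
  stopifnot(theta >= 0, beta >= 0, beta <= 1, gamma >= 0, gamma <= 1,
            min_size >= 1, discard_threshold >= 0)
  structure(list(theta = theta, beta = beta, gamma = gamma,
                 min_size = as.integer(min_size),
                 discard_threshold = discard_threshold),
            class = "leprimalign_params")
}

# fast lookup structures over a normalized global alignment:
#  partners1[[v1]] -> named numeric s_norm by node2 (only s_global > 0 pairs
#  define "aligned"; s_norm kept for all pairs for the inter score)
ga_index <- function(ga) {
  has_norm <- !is.null(ga$s_norm)
  sp1 <- split(seq_len(nrow(ga)), ga$node1)
  sp2 <- split(seq_len(nrow(ga)), ga$node2)
  norm1 <- lapply(sp1, function(i) setNames(ga$s_norm[i], ga$node2[i]))
  norm2 <- lapply(sp2, function(i) setNames(ga$s_norm[i], ga$node1[i]))
  pos <- ga$s_global > 0
  al1 <- lapply(sp1, function(i) ga$node2[i[pos[i]]])
  al2 <- lapply(sp2, function(i) ga$node1[i[pos[i]]])
  list(norm1 = norm1, norm2 = norm2, aligned1 = al1, aligned2 = al2,
       has_norm = has_norm)
}

#' Select seed node pairs
#'
#' All crosslinked pairs with `s_global > theta`, in descending score order;
#' ties broken lexicographically by node IDs.
#'
#' @param ga a `global_alignment`.
#' @param theta threshold on the raw global score.
#' @return data.frame with columns `node1`, `node2`, `s_global`.
#' @export
select_seeds <- function(ga, theta) {
  keep <- ga$s_global > theta
  out <- as.data.frame(ga)[keep, c("node1", "node2", "s_global"),
                           drop = FALSE]
  out <- out[order(-out$s_global, out$node1, out$node2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# internal edges of a member set: rows of g$edges with both endpoints inside
cluster_edges <- function(members, g) {
  e <- g$edges
  e[e$from %in% members & e$to %in% members, , drop = FALSE]
}

#' Classify a cluster's edges as matches or gaps
#'
#' An edge (vi, vj) of the first cluster is a *match* when vi and vj are
#' aligned to two nodes of the second cluster that are directly connected
#' there; it is a *gap* when it is not a match but such aligned partners are
#' connected through exactly one intermediate node of the second cluster that
#' is itself aligned to no node of the first cluster. "Aligned" means the
#' pair carries a positive global alignment score.
#'
#' @param members1,members2 member sets of the two clusters.
#' @param g1,g2 the two networks (first cluster lives in `g1`).
#' @param ga a `global_alignment` (defines the aligned-pair universe).
#' @param direction 1 if `members1` is in network 1, 2 if in network 2.
#' @return list with data.frames `match` and `gap` (disjoint subsets of the
#'   first cluster's internal edges).
#' @export
classify_edges <- function(members1, members2, g1, g2, ga, direction = 1L) {
  classify_edges_idx(members1, members2, g1, g2, ga_index(ga), direction)
}

classify_edges_idx <- function(members1, members2, g1, g2, idx,
                               direction = 1L) {
  aligned_fwd <- if (direction == 1L) idx$aligned1 else idx$aligned2
  aligned_bwd <- if (direction == 1L) idx$aligned2 else idx$aligned1
  e1 <- cluster_edges(members1, g1)
  if (!nrow(e1)) {
    return(list(match = e1, gap = e1))
  }
  # nodes of the partner cluster that are aligned to someone in members1
  partner_aligned <- vapply(members2, function(u) {
    any(aligned_bwd[[u]] %in% members1)
  }, logical(1))
  unaligned2 <- members2[!partner_aligned]

  is_match <- logical(nrow(e1))
  is_gap <- logical(nrow(e1))
  for (k in seq_len(nrow(e1))) {
    pa <- intersect(aligned_fwd[[e1$from[k]]], members2)
    pb <- intersect(aligned_fwd[[e1$to[k]]], members2)
    if (!length(pa) || !length(pb)) next
    hit <- FALSE
    for (a in pa) {
      nb_a <- names(g2$adj[[a]])
      if (any(pb %in% nb_a)) { hit <- TRUE; break }
    }
    if (hit) { is_match[k] <- TRUE; next }
    # gap: a -- z -- b with z in the partner cluster and unaligned
    for (a in pa) {
      zs <- intersect(names(g2$adj[[a]]), unaligned2)
      if (!length(zs)) next
      for (z in zs) {
        if (any(pb %in% names(g2$adj[[z]]))) { is_gap[k] <- TRUE; break }
      }
      if (is_gap[k]) break
    }
  }
  list(match = e1[is_match, , drop = FALSE],
       gap = e1[is_gap, , drop = FALSE])
}

#' Intra-network conservation score
#'
#' \deqn{S_{intra}(C_1,C_2) = (\sum_{match} w + \beta \sum_{gap} w)/|E_1|}
#' Matched edge weights count in full; gap edges are discounted by `beta`;
#' unconserved edges count only in the denominator. A cluster with no
#' internal edges scores 0.
#'
#' @param cls classification from [classify_edges()].
#' @param n_edges number of internal edges of the first cluster.
#' @param beta gap penalty.
#' @return numeric in \[0,1\].
#' @export
intra_score <- function(cls, n_edges, beta) {
  if (n_edges == 0) return(0)
  (sum(cls$match$weight) + beta * sum(cls$gap$weight)) / n_edges
}

#' Inter-network score of a cluster pair
#'
#' Mean over the first cluster's nodes of the best normalized global
#' alignment score into the second cluster; nodes with no crosslink into the
#' partner contribute 0. All crosslinked pairs count, with no threshold.
#'
#' @param members1,members2 member sets of the two clusters.
#' @param ga a normalized `global_alignment`.
#' @param direction 1 if `members1` is in network 1.
#' @return numeric in \[0,1\].
#' @export
inter_score <- function(members1, members2, ga, direction = 1L) {
  inter_score_idx(members1, members2, ga_index(ga), direction)
}

inter_score_idx <- function(members1, members2, idx, direction = 1L) {
  norm_fwd <- if (direction == 1L) idx$norm1 else idx$norm2
  best <- vapply(members1, function(v) {
    s <- norm_fwd[[v]]
    s <- s[names(s) %in% members2]
    if (length(s)) max(s) else 0
  }, numeric(1))
  mean(best)
}

# full directional local score (Eq. 12-14 from scratch)
local_score_dir <- function(members1, members2, g_own, g_other, idx,
                            direction, beta, gamma) {
  cls <- classify_edges_idx(members1, members2, g_own, g_other, idx,
                            direction)
  n_e <- nrow(cluster_edges(members1, g_own))
  s_intra <- intra_score(cls, n_e, beta)
  s_inter <- inter_score_idx(members1, members2, idx, direction)
  gamma * s_inter + (1 - gamma) * s_intra
}

#' Local alignment score of a cluster pair
#'
#' Convex combination of the inter- and intra-network scores,
#' \deqn{S_{local}(C_1,C_2) = \gamma S_{inter} + (1-\gamma) S_{intra}}
#' evaluated directionally: the first cluster's edges and nodes set the
#' denominators.
#'
#' @param members1 member set whose edges/nodes are scored.
#' @param members2 partner member set.
#' @param g1,g2 the two networks.
#' @param ga a normalized `global_alignment`.
#' @param beta,gamma scoring parameters (see [align_params()]).
#' @param direction 1 if `members1` lives in network 1, else 2.
#' @return numeric in \[0,1\].
#' @export
local_score <- function(members1, members2, g1, g2, ga, beta = 1.0,
                        gamma = 0.25, direction = 1L) {
  idx <- ga_index(ga)
  if (direction == 1L) {
    local_score_dir(members1, members2, g1, g2, idx, 1L, beta, gamma)
  } else {
    local_score_dir(members1, members2, g2, g1, idx, 2L, beta, gamma)
  }
}

# boundary of a member set: outside nodes with at least one edge into it,
# ordered by decreasing (unweighted) degree, ties lexicographic
boundary_nodes <- function(members, g) {
  cand <- unique(unlist(lapply(members, neighbors_of, g = g),
                        use.names = FALSE))
  cand <- setdiff(cand, members)
  if (!length(cand)) return(character(0))
  deg <- node_degree(g, cand)
  cand[order(-deg, cand)]
}

#' Expand an aligned cluster pair
#'
#' Greedy boundary expansion: passes alternate over the two clusters; in each
#' pass the cluster's outer-boundary nodes (outside nodes with at least one
#' edge into the cluster) are tried in descending degree order, and a node is
#' kept iff it strictly increases that cluster's own directional local score.
#' Expansion stops when a full pass over both clusters accepts nothing.
#'
#' @param members1,members2 initial member sets (from
#'   [form_initial_cluster()]).
#' @param g1,g2 the two networks.
#' @param ga normalized `global_alignment`.
#' @param params an [align_params()] object.
#' @return list with final `members1`, `members2`, directional scores
#'   `s_local_12`, `s_local_21`, and the initial scores
#'   `s_initial_12`, `s_initial_21`.
#' @export
expand_pair <- function(members1, members2, g1, g2, ga, params) {
  idx <- ga_index(ga)
  s1 <- local_score_dir(members1, members2, g1, g2, idx, 1L,
                        params$beta, params$gamma)
  s2 <- local_score_dir(members2, members1, g2, g1, idx, 2L,
                        params$beta, params$gamma)
  s1_init <- s1; s2_init <- s2
  repeat {
    accepted <- FALSE
    for (u in boundary_nodes(members1, g1)) {
      trial <- local_score_dir(c(members1, u), members2, g1, g2, idx, 1L,
                               params$beta, params$gamma)
      if (trial > s1) {
        members1 <- c(members1, u)
        s1 <- trial
        accepted <- TRUE
      }
    }
    # partner cluster grew or shrank candidates: rescore direction 2 base
    s2 <- local_score_dir(members2, members1, g2, g1, idx, 2L,
                          params$beta, params$gamma)
    for (u in boundary_nodes(members2, g2)) {
      trial <- local_score_dir(c(members2, u), members1, g2, g1, idx, 2L,
                               params$beta, params$gamma)
      if (trial > s2) {
        members2 <- c(members2, u)
        s2 <- trial
        accepted <- TRUE
      }
    }
    # direction 1 score may have risen with the enlarged partner
    s1 <- local_score_dir(members1, members2, g1, g2, idx, 1L,
                          params$beta, params$gamma)
    if (!accepted) break
  }
  list(members1 = sort(members1), members2 = sort(members2),
       s_local_12 = s1, s_local_21 = s2,
       s_initial_12 = s1_init, s_initial_21 = s2_init)
}

#' Local network alignment of two PPI networks
#'
#' The main entry point. Runs the Markov-chain global alignment
#' ([global_align()]) as preprocessing, normalizes its scores, then processes
#' seed pairs in descending global-score order: a seed pair whose endpoints
#' are both already covered by emitted clusters is skipped; otherwise an
#' initial cluster is grown around each seed by graph-entropy pruning
#' ([form_initial_cluster()]), the pair is greedily expanded
#' ([expand_pair()]), and it is emitted if both clusters have at least
#' `min_size` members and both directional local scores reach the discard
#' threshold. Emitted member nodes are marked visited.
#'
#' @param g1,g2 the two `ppi_network`s (or file paths, read with
#'   [read_network()]).
#' @param xl `crosslinks` between them (or a file path).
#' @param params an [align_params()] object.
#' @param cross_weight,alpha,tol,max_iter global-stage settings, see
#'   [global_align()].
#' @param quiet suppress progress messages.
#' @return object of class `leprimalign`: list with `pairs` (list of emitted
#'   cluster pairs, each carrying `members1`, `members2`, directional scores
#'   and the seed pair), the normalized `global` alignment, `params`, and
#'   the `call`.
#' @examples
#' g1 <- ppi_network(data.frame(from = c("a", "a", "b"),
#'                              to = c("b", "c", "c"),
#'                              weight = c(0.8, 0.8, 0.8)))
#' g2 <- ppi_network(data.frame(from = c("x", "x", "y"),
#'                              to = c("y", "z", "z"),
#'                              weight = c(0.8, 0.8, 0.8)))
#' xl <- read_crosslinks(entries = data.frame(
#'   node1 = c("a", "b", "c"), node2 = c("x", "y", "z"), score = 10),
#'   g1 = g1, g2 = g2)
#' fit <- leprimalign(g1, g2, xl, params = align_params(theta = 1))
#' summary(fit)
#' @export
leprimalign <- function(g1, g2, xl, params = align_params(),
                        cross_weight = 1.0, alpha = 0.85, tol = 1e-10,
                        max_iter = 1000L, quiet = TRUE) {
  cl <- match.call()
  if (is.character(g1)) g1 <- read_network(g1, quiet = quiet)
  if (is.character(g2)) g2 <- read_network(g2, quiet = quiet)
  if (is.character(xl)) xl <- read_crosslinks(xl, g1, g2, quiet = quiet)
  stopifnot(inherits(g1, "ppi_network"), inherits(g2, "ppi_network"),
            inherits(xl, "crosslinks"), inherits(params, "leprimalign_params"))

  ga <- global_align(g1, g2, xl, cross_weight = cross_weight, alpha = alpha,
                     tol = tol, max_iter = max_iter)
  seeds <- if (nrow(ga)) select_seeds(ga, params$theta) else
    data.frame(node1 = character(), node2 = character(),
               s_global = numeric())
  if (!nrow(seeds)) {
    warning("no seed pairs above theta; empty alignment")
  }
  visited1 <- new.env(parent = emptyenv())
  visited2 <- new.env(parent = emptyenv())
  pairs <- list()
  for (k in seq_len(nrow(seeds))) {
    v1 <- seeds$node1[k]; v2 <- seeds$node2[k]
    if (exists(v1, envir = visited1) && exists(v2, envir = visited2)) next
    c1 <- form_initial_cluster(v1, g1)
    c2 <- form_initial_cluster(v2, g2)
    res <- expand_pair(c1$members, c2$members, g1, g2, ga, params)
    if (length(res$members1) >= params$min_size &&
        length(res$members2) >= params$min_size &&
        res$s_local_12 >= params$discard_threshold &&
        res$s_local_21 >= params$discard_threshold) {
      res$seed1 <- v1
      res$seed2 <- v2
      res$s_seed <- seeds$s_global[k]
      pairs[[length(pairs) + 1L]] <- res
      for (m in res$members1) assign(m, TRUE, envir = visited1)
      for (m in res$members2) assign(m, TRUE, envir = visited2)
    }
  }
  structure(list(pairs = pairs, global = ga, params = params,
                 n1 = length(g1$nodes), n2 = length(g2$nodes),
                 call = cl),
            class = "leprimalign")
}

#' @export
print.leprimalign <- function(x, ...) {
  cat("Local PPI network alignment (LePrimAlign)\n")
  cat(sprintf("  networks: %d and %d nodes; %d crosslinked pair(s) scored\n",
              x$n1, x$n2, nrow(x$global)))
  cat(sprintf("  theta = %g, beta = %g, gamma = %g\n",
              x$params$theta, x$params$beta, x$params$gamma))
  cat(sprintf("  conserved module pairs emitted: %d\n", length(x$pairs)))
  invisible(x)
}

#' @export
summary.leprimalign <- function(object, ...) {
  df <- as.data.frame(object)
  structure(list(params = object$params, table = df), class =
              "summary.leprimalign")
}

#' @export
print.summary.leprimalign <- function(x, ...) {
  cat(sprintf("%d aligned cluster pair(s)  [theta=%g beta=%g gamma=%g]\n",
              nrow(x$table), x$params$theta, x$params$beta, x$params$gamma))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.leprimalign <- function(x, ...) {
  if (!length(x$pairs)) {
    return(data.frame(pair = integer(), seed1 = character(),
                      seed2 = character(), size1 = integer(),
                      size2 = integer(), s_local_12 = numeric(),
                      s_local_21 = numeric()))
  }
  data.frame(
    pair = seq_along(x$pairs),
    seed1 = vapply(x$pairs, `[[`, "", "seed1"),
    seed2 = vapply(x$pairs, `[[`, "", "seed2"),
    size1 = vapply(x$pairs, function(p) length(p$members1), integer(1)),
    size2 = vapply(x$pairs, function(p) length(p$members2), integer(1)),
    s_local_12 = vapply(x$pairs, `[[`, numeric(1), "s_local_12"),
    s_local_21 = vapply(x$pairs, `[[`, numeric(1), "s_local_21"))
}
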