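# Independent oracles and random-instance builders used across the suite.
# Everything here works from plain data.frames and dense matrices so it does
# not share code paths with the package internals it checks.

# random weighted network on n nodes with edge probability p
rand_network <- function(n, p, seed, prefix = "v", wmin = 0.05, wmax = 1) {
  set.seed(seed)
  nodes <- sprintf("%s%02d", prefix, seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                      weight = runif(sum(keep), wmin, wmax),
                      stringsAsFactors = FALSE)
  ppi_network(edges, nodes = nodes, quiet = TRUE)
}

rand_crosslinks <- function(g1, g2, rate, seed, smax = 20) {
  set.seed(seed)
  cross <- expand.grid(node1 = g1$nodes, node2 = g2$nodes,
                       stringsAsFactors = FALSE)
  keep <- runif(nrow(cross)) < rate
  read_crosslinks(entries = data.frame(node1 = cross$node1[keep],
                                       node2 = cross$node2[keep],
                                       score = runif(sum(keep), 0.5, smax)),
                  g1 = g1, g2 = g2, quiet = TRUE)
}

# dense brute-force stationary distribution: builds the full transition
# matrix with base-R dense algebra straight from the edge/crosslink tables
dense_stationary <- function(g1, g2, xl, cross_weight = 1, alpha = 0.85,
                             tol = 1e-13, max_iter = 20000) {
  nodes <- c(g1$nodes, g2$nodes)
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(g1$edges))) {
    a <- g1$edges$from[i]; b <- g1$edges$to[i]; w <- g1$edges$weight[i]
    M[a, b] <- M[a, b] + w; M[b, a] <- M[b, a] + w
  }
  for (i in seq_len(nrow(g2$edges))) {
    a <- g2$edges$from[i]; b <- g2$edges$to[i]; w <- g2$edges$weight[i]
    M[a, b] <- M[a, b] + w; M[b, a] <- M[b, a] + w
  }
  for (i in seq_len(nrow(xl))) {
    a <- xl$node1[i]; b <- xl$node2[i]; s <- cross_weight * xl$score[i]
    M[a, b] <- M[a, b] + s; M[b, a] <- M[b, a] + s
  }
  rs <- rowSums(M)
  q <- as.numeric(rs == 0)
  Tm <- M / ifelse(rs == 0, 1, rs)
  Tm[rs == 0, ] <- 0
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    pt <- alpha * as.numeric(p %*% Tm) + (alpha * sum(p * q) + 1 - alpha) / n
    pt <- pt / sum(abs(pt))
    if (sum(abs(pt - p)) < tol) break
    p <- pt
  }
  names(pt) <- nodes
  pt
}

# full-recomputation greedy seed clustering (mirrors the published
# procedure but recomputes the whole entropy sum at every trial)
oracle_initial_cluster <- function(seed_node, g) {
  nbrs <- neighbors_of(g, seed_node)
  members <- c(seed_node, nbrs)
  wd <- weighted_degree(g, nbrs)
  current <- graph_entropy(members, g)
  for (v in nbrs[order(-wd, nbrs)]) {
    trial <- setdiff(members, v)
    e_trial <- graph_entropy(trial, g)
    if (e_trial < current) {
      members <- trial
      current <- e_trial
    }
  }
  list(members = sort(members), entropy = current)
}

# the four-node worked instance used throughout the entropy tests:
# s-a, s-b, a-b, b-x, unit weights
square_graph <- function() {
  ppi_network(data.frame(from = c("s", "s", "a", "b"),
                         to = c("a", "b", "b", "x"),
                         weight = 1), quiet = TRUE)
}

# tiny global alignment object with prescribed scores (for scoring tests)
fake_ga <- function(node1, node2, s_global) {
  ga <- data.frame(node1 = node1, node2 = node2, s_global = s_global,
                   stringsAsFactors = FALSE)
  class(ga) <- c("global_alignment", "data.frame")
  normalize_scores(ga)
}

# internal edges of a member set, straight off the edge table
cluster_edges_for_test <- function(members, g) {
  g$edges[g$edges$from %in% members & g$edges$to %in% members, ,
          drop = FALSE]
}

# serialize a fit deterministically for byte-identity comparisons
fit_fingerprint <- function(fit) {
  paste(vapply(fit$pairs, function(p) {
    paste(c(p$seed1, p$seed2,
            sprintf("%.15g", c(p$s_local_12, p$s_local_21)),
            paste(p$members1, collapse = ","),
            paste(p$members2, collapse = ",")), collapse = "|")
  }, ""), collapse = "\n")
}
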