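#' Build the two-network Markov transition matrix
#'
#' Stacks both networks into a single state space of size
#' `n = n_G1 + n_G2` and builds the block transition matrix
#' \deqn{T = [T_{11} T_{12}; T_{21} T_{22}]}
#' where the within-network blocks carry edge weights and the cross blocks
#' carry `cross_weight * score` for every crosslinked pair. Each row is then
#' divided by its sum; rows with no outgoing mass (dangling nodes) are left
#' zero and flagged in `q`.
#'
#' @param g1,g2 the two `ppi_network`s.
#' @param xl `crosslinks` between them.
#' @param cross_weight positive multiplier applied to crosslink scores before
#'   row normalization (weighting of sequence similarity vs interaction
#'   confidence).
#' @return object of class `transition_matrix`: list with sparse matrix `T`
#'   (`Matrix::dgCMatrix`, row-stochastic where defined), logical dangling
#'   indicator `q`, node index maps `nodes1`/`nodes2`, sizes `n1`, `n2`, `n`.
#' @export
build_transition_matrix <- function(g1, g2, xl, cross_weight = 1.0) {
  stopifnot(length(g1$nodes) > 0, length(g2$nodes) > 0, cross_weight > 0)
  n1 <- length(g1$nodes); n2 <- length(g2$nodes); n <- n1 + n2
  i1 <- setNames(seq_len(n1), g1$nodes)
  i2 <- setNames(n1 + seq_len(n2), g2$nodes)

  # within-network blocks: both orientations of each undirected edge
  ii <- c(i1[g1$edges$from], i1[g1$edges$to],
          i2[g2$edges$from], i2[g2$edges$to])
  jj <- c(i1[g1$edges$to], i1[g1$edges$from],
          i2[g2$edges$to], i2[g2$edges$from])
  ww <- c(g1$edges$weight, g1$edges$weight, g2$edges$weight, g2$edges$weight)
  # cross blocks: weighted sequence-similarity scores, both directions
  if (nrow(xl)) {
    ii <- c(ii, i1[xl$node1], i2[xl$node2])
    jj <- c(jj, i2[xl$node2], i1[xl$node1])
    ww <- c(ww, cross_weight * xl$score, cross_weight * xl$score)
  }
  T <- Matrix::sparseMatrix(i = unname(ii), j = unname(jj), x = ww,
                            dims = c(n, n))
  rs <- Matrix::rowSums(T)
  q <- rs == 0
  scale <- ifelse(q, 0, 1 / rs)
  T <- Matrix::Diagonal(n, scale) %*% T
  structure(list(T = methods::as(T, "CsparseMatrix"), q = q,
                 nodes1 = g1$nodes, nodes2 = g2$nodes,
                 i1 = i1, i2 = i2, n1 = n1, n2 = n2, n = n),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix: %d + %d states, %d nonzeros, %d dangling\n",
              x$n1, x$n2, length(x$T@x), sum(x$q)))
  invisible(x)
}

#' Stationary distribution of the interconnected networks
#'
#' Damped power iteration over the joint transition matrix with the standard
#' teleport correction for dangling rows:
#' \deqn{p' = \alpha p T + (\alpha p q + 1 - \alpha) u / n}
#' followed by L1 renormalization, iterated until the L1 change drops below
#' `tol`.
#'
#' @param tm a `transition_matrix`.
#' @param alpha damping factor in (0,1).
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; a warning is raised if reached.
#' @return numeric probability vector of length `n` (sums to 1), named by
#'   node with network-1 nodes first.
#' @export
stationary_distribution <- function(tm, alpha = 0.85, tol = 1e-10,
                                    max_iter = 1000L) {
  stopifnot(alpha > 0, alpha < 1, tol > 0)
  n <- tm$n
  p <- rep(1 / n, n)
  Tt <- Matrix::t(tm$T)           # column access = row products
  q <- as.numeric(tm$q)
  for (it in seq_len(max_iter)) {
    pt <- as.numeric(Tt %*% p)
    pt <- alpha * pt + (alpha * sum(p * q) + 1 - alpha) / n
    pt <- pt / sum(abs(pt))
    if (sum(abs(pt - p)) < tol) {
      p <- pt
      names(p) <- c(tm$nodes1, tm$nodes2)
      return(p)
    }
    p <- pt
  }
  warning(sprintf("power iteration did not converge in %d iterations",
                  max_iter))
  names(p) <- c(tm$nodes1, tm$nodes2)
  p
}

#' Global alignment scores for crosslinked node pairs
#'
#' For each crosslinked pair (v1, v2) the score combines the stationary
#' probability of each endpoint with that endpoint's share of cross-network
#' transition mass going to its partner:
#' \deqn{S_{global}(v_1,v_2) = (p(v_1) T_{12}[v_1,v_2]/||T_{12}[v_1,]||_1 +
#'       p(v_2) T_{21}[v_2,v_1]/||T_{21}[v_2,]||_1) \cdot n}
#'
#' @param p stationary distribution from [stationary_distribution()].
#' @param tm the `transition_matrix` used to compute `p`.
#' @param xl the `crosslinks` (defines which pairs are scored).
#' @return object of class `global_alignment`: data.frame with columns
#'   `node1`, `node2`, `s_global` plus attributes filled in by
#'   [normalize_scores()].
#' @export
global_scores <- function(p, tm, xl) {
  if (!nrow(xl)) {
    ga <- data.frame(node1 = character(), node2 = character(),
                     s_global = numeric(), stringsAsFactors = FALSE)
    class(ga) <- c("global_alignment", "data.frame")
    return(ga)
  }
  # cross-block share of each node: since rows of T are uniformly scaled,
  # score / (sum of that node's crosslink scores) equals the normalized share
  tot1 <- tapply(xl$score, xl$node1, sum)
  tot2 <- tapply(xl$score, xl$node2, sum)
  share1 <- xl$score / as.numeric(tot1[xl$node1])
  share2 <- xl$score / as.numeric(tot2[xl$node2])
  s <- (p[xl$node1] * share1 + p[xl$node2] * share2) * tm$n
  ga <- data.frame(node1 = xl$node1, node2 = xl$node2,
                   s_global = as.numeric(s), stringsAsFactors = FALSE)
  ga <- ga[order(ga$node1, ga$node2), , drop = FALSE]
  rownames(ga) <- NULL
  class(ga) <- c("global_alignment", "data.frame")
  ga
}

#' Log-normalize global alignment scores into \[0,1\]
#'
#' Adds `s_norm = log_b(1 + s_global)` with base
#' `b = ceiling(1 + max(s_global))`, floored at 2 so the logarithm is valid
#' when all scores are below 1.
#'
#' @param ga a `global_alignment` (with `s_global`).
#' @return the same object with an `s_norm` column and attribute `base`.
#' @export
normalize_scores <- function(ga) {
  if (!nrow(ga)) stop("no global scores to normalize")
  b <- max(2, ceiling(1 + max(ga$s_global)))
  ga$s_norm <- log(1 + ga$s_global, base = b)
  attr(ga, "base") <- b
  ga
}

#' @export
print.global_alignment <- function(x, ...) {
  cat(sprintf("global_alignment: %d scored pair(s)", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(", S_global in [%.4g, %.4g]", min(x$s_global),
                max(x$s_global)))
    if (!is.null(x$s_norm)) cat(sprintf(", base %d", attr(x, "base")))
  }
  cat("\n")
  invisible(x)
}

#' Run the full global alignment stage
#'
#' Convenience wrapper: transition matrix, stationary distribution, pair
#' scores, and log normalization in one call.
#'
#' @inheritParams build_transition_matrix
#' @inheritParams stationary_distribution
#' @return normalized `global_alignment`.
#' @export
global_align <- function(g1, g2, xl, cross_weight = 1.0, alpha = 0.85,
                         tol = 1e-10, max_iter = 1000L) {
  tm <- build_transition_matrix(g1, g2, xl, cross_weight = cross_weight)
  p <- stationary_distribution(tm, alpha = alpha, tol = tol,
                               max_iter = max_iter)
  ga <- global_scores(p, tm, xl)
  if (nrow(ga)) ga <- normalize_scores(ga)
  ga
}

#' Dump global scores to TSV
#'
#' Writes one row per scored pair: node1, node2, S_global, S_norm.
#' @param ga a normalized `global_alignment`.
#' @param path output file path.
#' @export
write_global_scores <- function(ga, path) {
  utils::write.table(
    data.frame(ga$node1, ga$node2,
               signif(ga$s_global, 10),
               if (is.null(ga$s_norm)) NA else signif(ga$s_norm, 10)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}
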