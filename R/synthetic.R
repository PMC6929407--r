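#' Specification for a synthetic paired-network instance
#'
#' Describes two PPI networks with planted conserved modules: each module is
#' a dense weighted subgraph in network 1 whose relabeled copy (with edge
#' dropout) is planted in network 2. Both networks get additional background
#' nodes and sparse low-weight background edges; crosslinks connect planted
#' counterpart nodes at a high ortholog-like score, plus a sprinkling of
#' spurious pairs at a low score.
#'
#' @param n_modules number of planted conserved modules.
#' @param module_size integer range `c(min, max)` for module sizes.
#' @param p_in within-module edge probability (must exceed `p_bg`).
#' @param n_bg background (non-module) nodes per network.
#' @param p_bg background edge probability over non-module pairs.
#' @param w_module range of module edge weights (confidence-like, high).
#' @param w_bg range of background edge weights (low).
#' @param dropout per-edge probability that a module edge is missing from
#'   network 2's copy.
#' @param ortholog_score crosslink score for planted counterpart pairs
#'   (-log e-value scale).
#' @param spurious_rate probability that a non-counterpart cross pair gets a
#'   spurious crosslink.
#' @param spurious_score score of spurious crosslinks (must be below
#'   `ortholog_score`).
#' @param seed integer seed driving all randomness of [generate_pair()].
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_modules = 3L, module_size = c(6L, 6L),
                           p_in = 0.9, n_bg = 20L, p_bg = 0.05,
                           w_module = c(0.6, 1.0), w_bg = c(0.05, 0.4),
                           dropout = 0.1, ortholog_score = 100,
                           spurious_rate = 0.02, spurious_score = 5,
                           seed = 1L) {
  stopifnot(n_modules >= 1, length(module_size) == 2,
            module_size[1] >= 2, module_size[2] >= module_size[1],
            p_in > p_bg, p_bg >= 0, dropout >= 0, dropout < 1,
            ortholog_score > spurious_score, spurious_rate >= 0,
            spurious_rate < 1, n_bg >= 0)
  structure(list(n_modules = as.integer(n_modules),
                 module_size = as.integer(module_size),
                 p_in = p_in, n_bg = as.integer(n_bg), p_bg = p_bg,
                 w_module = w_module, w_bg = w_bg, dropout = dropout,
                 ortholog_score = ortholog_score,
                 spurious_rate = spurious_rate,
                 spurious_score = spurious_score,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# run expr with a private RNG stream; global .Random.seed untouched
with_private_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Bernoulli edges over the pair set `pairs` (2-column matrix), weights
# uniform in w_range
draw_edges <- function(pairs, prob, w_range) {
  if (!nrow(pairs)) {
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  keep <- stats::runif(nrow(pairs)) < prob
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(from = pairs[, 1], to = pairs[, 2],
             weight = stats::runif(nrow(pairs), w_range[1], w_range[2]),
             stringsAsFactors = FALSE)
}

all_pairs <- function(nodes) {
  if (length(nodes) < 2) {
    return(matrix(character(0), ncol = 2))
  }
  t(utils::combn(nodes, 2))
}

#' Generate a paired synthetic instance with planted conserved modules
#'
#' Deterministic given `spec$seed`. Network 1 holds the planted modules plus
#' background; network 2 holds relabeled copies of the modules (with edge
#' dropout) plus its own background. Module realizations whose within-module
#' edge density does not exceed the background density are redrawn (with a
#' message). Crosslinks join counterpart module nodes at the ortholog score
#' plus spurious random pairs at the low score.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `g1`, `g2` (`ppi_network`s), `xl` (`crosslinks`), and
#'   `truth`: list of planted module pairs, each with `members1`,
#'   `members2`.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_private_rng(spec$seed, {
    size_range <- seq(spec$module_size[1], spec$module_size[2])
    sizes <- if (length(size_range) == 1L) {
      rep(size_range, spec$n_modules)
    } else {
      sample(size_range, spec$n_modules, replace = TRUE)
    }
    mod1 <- mod2 <- vector("list", spec$n_modules)
    for (i in seq_len(spec$n_modules)) {
      mod1[[i]] <- sprintf("s1_m%d_%02d", i, seq_len(sizes[i]))
      mod2[[i]] <- sprintf("s2_m%d_%02d", i, seq_len(sizes[i]))
    }
    bg1 <- if (spec$n_bg) sprintf("s1_bg_%02d", seq_len(spec$n_bg))
           else character(0)
    bg2 <- if (spec$n_bg) sprintf("s2_bg_%02d", seq_len(spec$n_bg))
           else character(0)
    nodes1 <- c(unlist(mod1), bg1)
    nodes2 <- c(unlist(mod2), bg2)

    # planted module subgraphs, redrawn until denser than background
    module_edges <- vector("list", spec$n_modules)
    for (i in seq_len(spec$n_modules)) {
      pr <- all_pairs(mod1[[i]])
      for (try in 1:50) {
        e <- draw_edges(pr, spec$p_in, spec$w_module)
        if (nrow(e) / nrow(pr) > spec$p_bg) break
        message(sprintf("redrawing module %d (density below background)", i))
      }
      module_edges[[i]] <- e
    }
    in_same_module <- function(pairs, mods) {
      mid <- function(v) {
        m <- rep(NA_integer_, length(v))
        for (i in seq_along(mods)) m[v %in% mods[[i]]] <- i
        m
      }
      a <- mid(pairs[, 1]); b <- mid(pairs[, 2])
      !is.na(a) & !is.na(b) & a == b
    }
    pr1 <- all_pairs(nodes1)
    bg_edges1 <- draw_edges(pr1[!in_same_module(pr1, mod1), , drop = FALSE],
                            spec$p_bg, spec$w_bg)
    g1 <- ppi_network(rbind(do.call(rbind, module_edges), bg_edges1),
                      nodes = nodes1, quiet = TRUE)

    # network 2: relabeled module copies with dropout + own background
    relabel <- function(v) sub("^s1_", "s2_", v)
    m2_edges <- do.call(rbind, module_edges)
    if (nrow(m2_edges)) {
      keep <- stats::runif(nrow(m2_edges)) >= spec$dropout
      m2_edges <- m2_edges[keep, , drop = FALSE]
      m2_edges$from <- relabel(m2_edges$from)
      m2_edges$to <- relabel(m2_edges$to)
    }
    pr2 <- all_pairs(nodes2)
    bg_edges2 <- draw_edges(pr2[!in_same_module(pr2, mod2), , drop = FALSE],
                            spec$p_bg, spec$w_bg)
    g2 <- ppi_network(rbind(m2_edges, bg_edges2), nodes = nodes2,
                      quiet = TRUE)

    # crosslinks: counterparts high, spurious low
    counterpart <- data.frame(node1 = unlist(mod1),
                              node2 = relabel(unlist(mod1)),
                              score = spec$ortholog_score,
                              stringsAsFactors = FALSE)
    spurious <- data.frame(node1 = character(), node2 = character(),
                           score = numeric(), stringsAsFactors = FALSE)
    if (spec$spurious_rate > 0) {
      cross <- expand.grid(node1 = nodes1, node2 = nodes2,
                           stringsAsFactors = FALSE)
      is_cp <- paste(cross$node1, cross$node2) %in%
        paste(counterpart$node1, counterpart$node2)
      cross <- cross[!is_cp, , drop = FALSE]
      keep <- stats::runif(nrow(cross)) < spec$spurious_rate
      if (any(keep)) {
        spurious <- data.frame(node1 = cross$node1[keep],
                               node2 = cross$node2[keep],
                               score = spec$spurious_score,
                               stringsAsFactors = FALSE)
      }
    }
    xl <- read_crosslinks(entries = rbind(counterpart, spurious),
                          g1 = g1, g2 = g2, quiet = TRUE)
    truth <- lapply(seq_len(spec$n_modules), function(i) {
      list(members1 = mod1[[i]], members2 = mod2[[i]])
    })
    list(g1 = g1, g2 = g2, xl = xl, truth = truth)
  })
}

#' Recovery accuracy of an alignment against planted modules
#'
#' Mean best-match [fscore()] of the emitted clusters against the planted
#' modules, pooled over both network sides.
#'
#' @param fit a `leprimalign` object.
#' @param truth ground-truth module pairs from [generate_pair()].
#' @return numeric in \[0,1\] (`NA` if no pairs were emitted).
#' @export
recovery_fscore <- function(fit, truth) {
  if (!length(fit$pairs)) return(NA_real_)
  cat1 <- lapply(truth, `[[`, "members1")
  cat2 <- lapply(truth, `[[`, "members2")
  f1 <- mean_best_fscore(lapply(fit$pairs, `[[`, "members1"), cat1)
  f2 <- mean_best_fscore(lapply(fit$pairs, `[[`, "members2"), cat2)
  (f1 + f2) / 2
}
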