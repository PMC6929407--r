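# two-cluster fixtures for match/gap classification
two_cluster_nets <- function(edges2) {
  g1 <- ppi_network(data.frame(from = "vA1", to = "vA2", weight = 0.9))
  g2 <- ppi_network(edges2)
  xl <- read_crosslinks(entries = data.frame(
    node1 = c("vA1", "vA2"), node2 = c("vB1", "vB2"), score = 5),
    g1 = g1, g2 = g2, quiet = TRUE)
  ga <- fake_ga(xl$node1, xl$node2, xl$score)
  list(g1 = g1, g2 = g2, ga = ga)
}

test_that("seed selection thresholds, orders and breaks ties", {
  ga <- fake_ga(c("a", "b", "c"), c("x", "y", "z"), c(2.5, 1.2, 0.7))
  s <- select_seeds(ga, 1)
  expect_equal(s$node1, c("a", "b"))
  expect_equal(select_seeds(ga, 10)$node1, character(0))
  ga2 <- fake_ga(c("a", "a"), c("y", "x"), c(1.5, 1.5))
  s2 <- select_seeds(ga2, 1)
  expect_equal(s2$node2, c("x", "y"))   # lexicographic tie-break
})

test_that("directly conserved edges classify as matches", {
  # aligned partners vB1, vB2 adjacent in the second cluster
  f <- two_cluster_nets(data.frame(from = "vB1", to = "vB2", weight = 0.8))
  cls <- classify_edges(c("vA1", "vA2"), c("vB1", "vB2"), f$g1, f$g2, f$ga)
  expect_equal(nrow(cls$match), 1)
  expect_equal(nrow(cls$gap), 0)
})

test_that("edges conserved through one unaligned intermediate are gaps", {
  # vB1 - vB4 - vB2 with vB4 aligned to nothing
  f <- two_cluster_nets(data.frame(from = c("vB1", "vB4"),
                                   to = c("vB4", "vB2"), weight = 0.8))
  cls <- classify_edges(c("vA1", "vA2"), c("vB1", "vB2", "vB4"),
                        f$g1, f$g2, f$ga)
  expect_equal(nrow(cls$match), 0)
  expect_equal(nrow(cls$gap), 1)

  # the intermediate must lie inside the partner cluster
  cls2 <- classify_edges(c("vA1", "vA2"), c("vB1", "vB2"),
                         f$g1, f$g2, f$ga)
  expect_equal(nrow(cls2$match) + nrow(cls2$gap), 0)
})

test_that("partners three or more hops apart are neither match nor gap", {
  f <- two_cluster_nets(data.frame(from = c("vB1", "vB4", "vB5"),
                                   to = c("vB4", "vB5", "vB2"),
                                   weight = 0.8))
  cls <- classify_edges(c("vA1", "vA2"), c("vB1", "vB2", "vB4", "vB5"),
                        f$g1, f$g2, f$ga)
  expect_equal(nrow(cls$match), 0)
  expect_equal(nrow(cls$gap), 0)
})

test_that("an aligned intermediate does not create a gap", {
  f <- two_cluster_nets(data.frame(from = c("vB1", "vB4"),
                                   to = c("vB4", "vB2"), weight = 0.8))
  # align vB4 to vA1 as well: no longer an unaligned intermediate
  ga <- fake_ga(c("vA1", "vA2", "vA1"), c("vB1", "vB2", "vB4"),
                c(5, 5, 5))
  cls <- classify_edges(c("vA1", "vA2"), c("vB1", "vB2", "vB4"),
                        f$g1, f$g2, ga)
  expect_equal(nrow(cls$gap), 0)
})

test_that("intra-network score mixes matches and penalized gaps", {
  cls <- list(match = data.frame(weight = 0.5),
              gap = data.frame(weight = 0.4))
  expect_equal(intra_score(cls, 3, beta = 1), 0.3)
  expect_equal(round(intra_score(cls, 3, beta = 0), 4), 0.1667)
  expect_equal(intra_score(cls, 0, beta = 1), 0)   # no internal edges
  # perfect conservation, unit weights
  cls2 <- list(match = data.frame(weight = c(1, 1, 1)),
               gap = data.frame(weight = numeric()))
  expect_equal(intra_score(cls2, 3, beta = 1), 1)
})

test_that("inter-network score averages best normalized partners", {
  # engineer s_norm values 0.8 and 0.6: base 2, s_norm = log2(1+s)
  ga <- fake_ga(c("u1", "u1", "u2"), c("w1", "w2", "w1"),
                c(2^0.8 - 1, 0.1, 2^0.6 - 1))
  expect_equal(inter_score(c("u1", "u2"), c("w1", "w2"), ga), 0.7,
               tolerance = 1e-12)
  # node with no crosslink into the partner contributes 0
  expect_equal(inter_score(c("u1", "zz"), c("w1"), ga),
               0.8 / 2, tolerance = 1e-12)
  expect_equal(inter_score(c("u1"), c("zz"), ga), 0)
})

test_that("local score is the stated convex combination", {
  g1 <- ppi_network(data.frame(from = "a", to = "b", weight = 1))
  g2 <- ppi_network(data.frame(from = "x", to = "y", weight = 1))
  # S_inter and S_intra both computable by hand: single matched edge
  ga <- fake_ga(c("a", "b"), c("x", "y"), c(3, 3))
  s_gamma1 <- local_score(c("a", "b"), c("x", "y"), g1, g2, ga,
                          beta = 1, gamma = 1)
  expect_equal(s_gamma1, inter_score(c("a", "b"), c("x", "y"), ga))
  s_gamma0 <- local_score(c("a", "b"), c("x", "y"), g1, g2, ga,
                          beta = 1, gamma = 0)
  expect_equal(s_gamma0, 1)   # matched edge of weight 1
  s_mix <- local_score(c("a", "b"), c("x", "y"), g1, g2, ga,
                       beta = 1, gamma = 0.25)
  expect_equal(s_mix, 0.25 * s_gamma1 + 0.75 * s_gamma0)
})

test_that("a mixed match/gap/unconserved instance scores 0.4", {
  # engineered so S_inter = 0.7 and S_intra = 0.3 exactly (gamma = 0.25):
  # edge u1-u2 is a match (w 0.5), u1-u3 a gap via w4 (w 0.4), u2-u3
  # unconserved (w 0.9); best normalized partners 0.8, 0.6, 0.7
  g1 <- ppi_network(data.frame(from = c("u1", "u1", "u2"),
                               to = c("u2", "u3", "u3"),
                               weight = c(0.5, 0.4, 0.9)),
                    nodes = c("u1", "u2", "u3", "u9"))
  g2 <- ppi_network(data.frame(from = c("w1", "w1", "w4"),
                               to = c("w2", "w4", "w3"),
                               weight = 0.8),
                    nodes = c("w1", "w2", "w3", "w4", "w9"))
  # base 4 (max score 3 on an uninvolved pair): s_norm = log4(1 + s)
  ga <- fake_ga(c("u1", "u2", "u3", "u9"), c("w1", "w2", "w3", "w9"),
                c(4^0.8 - 1, 4^0.6 - 1, 4^0.7 - 1, 3))
  c1 <- c("u1", "u2", "u3"); c2 <- c("w1", "w2", "w3", "w4")

  cls <- classify_edges(c1, c2, g1, g2, ga)
  expect_equal(cls$match$weight, 0.5)
  expect_equal(cls$gap$weight, 0.4)
  expect_equal(intra_score(cls, 3, beta = 1), 0.3)
  expect_equal(inter_score(c1, c2, ga), 0.7, tolerance = 1e-12)
  expect_equal(local_score(c1, c2, g1, g2, ga, beta = 1, gamma = 0.25),
               0.4, tolerance = 1e-12)
})

test_that("expansion leaves a perfectly conserved pair unchanged", {
  # two mirrored triangles plus unaligned, unconnected-to-module outsiders
  g1 <- ppi_network(data.frame(from = c("a", "a", "b", "o1"),
                               to = c("b", "c", "c", "o2"),
                               weight = c(0.9, 0.9, 0.9, 0.2)))
  g2 <- ppi_network(data.frame(from = c("x", "x", "y", "p1"),
                               to = c("y", "z", "z", "p2"),
                               weight = c(0.9, 0.9, 0.9, 0.2)))
  ga <- fake_ga(c("a", "b", "c"), c("x", "y", "z"), c(5, 5, 5))
  res <- expand_pair(c("a", "b", "c"), c("x", "y", "z"), g1, g2, ga,
                     align_params())
  expect_equal(res$members1, c("a", "b", "c"))
  expect_equal(res$members2, c("x", "y", "z"))
  expect_equal(res$s_local_12, res$s_initial_12)
})

test_that("expansion absorbs a strongly linked missing member", {
  # planted 4-cliques; the first initial cluster misses member d, whose
  # counterpart w is already in the partner cluster and whose edges are
  # heavier than the core's, so absorbing d raises the matched-weight mean
  cl4 <- t(combn(c("a", "b", "c", "d"), 2))
  w1 <- ifelse(cl4[, 1] == "d" | cl4[, 2] == "d", 1.0, 0.8)
  g1 <- ppi_network(data.frame(from = cl4[, 1], to = cl4[, 2], weight = w1))
  cl4b <- t(combn(c("w", "x", "y", "z"), 2))
  w2 <- ifelse(cl4b[, 1] == "w" | cl4b[, 2] == "w", 1.0, 0.8)
  g2 <- ppi_network(data.frame(from = cl4b[, 1], to = cl4b[, 2],
                               weight = w2))
  ga <- fake_ga(c("a", "b", "c", "d"), c("x", "y", "z", "w"),
                c(5, 5, 5, 5))
  params <- align_params()
  res <- expand_pair(c("a", "b", "c"), c("w", "x", "y", "z"), g1, g2, ga,
                     params)
  expect_equal(res$members1, c("a", "b", "c", "d"))
  expect_equal(res$members2, c("w", "x", "y", "z"))
  expect_gt(res$s_local_12, res$s_initial_12)
  # exhaustive check: the accepted addition is exactly the candidate that
  # raises the directional score of the initial pair
  for (u in setdiff(g1$nodes, c("a", "b", "c"))) {
    gain <- local_score(c("a", "b", "c", u), c("w", "x", "y", "z"),
                        g1, g2, ga, direction = 1L) -
      local_score(c("a", "b", "c"), c("w", "x", "y", "z"), g1, g2, ga,
                  direction = 1L)
    expect_equal(gain > 0, u %in% res$members1)
  }
})

test_that("mutually missing counterparts cannot be absorbed greedily", {
  # when BOTH clusters lack the counterpart pair, neither side's own
  # directional score improves by adding its member alone, so the greedy
  # expansion (correctly, per its acceptance rule) leaves both out
  cl4 <- t(combn(c("a", "b", "c", "d"), 2))
  g1 <- ppi_network(data.frame(from = cl4[, 1], to = cl4[, 2], weight = 0.9))
  cl4b <- t(combn(c("w", "x", "y", "z"), 2))
  g2 <- ppi_network(data.frame(from = cl4b[, 1], to = cl4b[, 2],
                               weight = 0.9))
  ga <- fake_ga(c("a", "b", "c", "d"), c("x", "y", "z", "w"),
                c(5, 5, 5, 5))
  res <- expand_pair(c("a", "b", "c"), c("x", "y", "z"), g1, g2, ga,
                     align_params())
  expect_equal(res$members1, c("a", "b", "c"))
  expect_equal(res$members2, c("x", "y", "z"))
})

test_that("identity alignment of two triangles recovers one exact pair", {
  g1 <- ppi_network(data.frame(from = c("a", "a", "b"),
                               to = c("b", "c", "c"), weight = 0.8))
  g2 <- ppi_network(data.frame(from = c("x", "x", "y"),
                               to = c("y", "z", "z"), weight = 0.8))
  xl <- read_crosslinks(entries = data.frame(
    node1 = c("a", "b", "c"), node2 = c("x", "y", "z"), score = 10),
    g1 = g1, g2 = g2, quiet = TRUE)
  fit <- leprimalign(g1, g2, xl, params = align_params(theta = 1))
  expect_length(fit$pairs, 1)
  p <- fit$pairs[[1]]
  expect_equal(p$members1, c("a", "b", "c"))
  expect_equal(p$members2, c("x", "y", "z"))
  # all matches: S_intra = mean edge weight; S_inter = 1 (scores at max)
  expect_equal(p$s_local_12, 0.25 * 1 + 0.75 * 0.8)
  expect_equal(p$s_local_21, p$s_local_12)

  # theta above every global score: no seeds, empty result with warning
  expect_warning(fit0 <- leprimalign(g1, g2, xl,
                                     params = align_params(theta = 10)),
                 "no seed")
  expect_length(fit0$pairs, 0)
})

test_that("pairs collapsing to singletons are discarded", {
  # second cluster side has an isolated seed: cluster stays a singleton
  g1 <- ppi_network(data.frame(from = "a", to = "b", weight = 1))
  g2 <- ppi_network(data.frame(from = "x", to = "y", weight = 1),
                    nodes = c("x", "y", "lone"))
  xl <- read_crosslinks(entries = data.frame(
    node1 = c("a", "b"), node2 = c("lone", "lone"), score = 10),
    g1 = g1, g2 = g2, quiet = TRUE)
  fit <- leprimalign(g1, g2, xl, params = align_params(theta = 0.01))
  expect_length(fit$pairs, 0)
})

test_that("alignment output is deterministic", {
  spec <- synthetic_spec(seed = 11L)
  inst <- generate_pair(spec)
  f1 <- leprimalign(inst$g1, inst$g2, inst$xl)
  f2 <- leprimalign(inst$g1, inst$g2, inst$xl)
  expect_identical(fit_fingerprint(f1), fit_fingerprint(f2))
})

test_that("scores stay within [0,1] on random inputs", {
  draws <- 0
  for (seed in 1:12) {
    g1 <- rand_network(10, 0.35, seed, prefix = "a")
    g2 <- rand_network(10, 0.35, seed + 30, prefix = "b")
    xl <- rand_crosslinks(g1, g2, 0.08, seed + 60)
    if (!nrow(xl)) next
    ga <- global_align(g1, g2, xl)
    expect_true(all(ga$s_norm >= 0 & ga$s_norm <= 1))
    set.seed(seed)
    for (k in 1:8) {
      m1 <- sample(g1$nodes, sample(2:5, 1))
      m2 <- sample(g2$nodes, sample(2:5, 1))
      beta <- runif(1); gamma <- runif(1)
      s12 <- local_score(m1, m2, g1, g2, ga, beta, gamma, direction = 1L)
      s21 <- local_score(m2, m1, g1, g2, ga, beta, gamma, direction = 2L)
      expect_true(s12 >= 0 && s12 <= 1)
      expect_true(s21 >= 0 && s21 <= 1)
      draws <- draws + 2
    }
  }
  expect_gte(draws, 100)
})
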