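test_that("pearson_r matches the closed-form sample correlation", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  ## independent formula evaluation on random input
  set.seed(3)
  x <- rnorm(10); y <- rnorm(10)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), manual)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:2, 1:2), "3 time points")
})

test_that("correlation significance follows the two-sided t-test on n-2 df", {
  expect_true(is_significant(1.0, 10, 0.05))
  expect_false(is_significant(0.0, 10, 0.05))
  ## boundary case: r = 0.632, n = 10 gives p = 0.04995 < 0.05
  ## (frozen from an independent t CDF evaluation)
  expect_true(is_significant(0.632, 10, 0.05))
  expect_false(is_significant(0.631, 10, 0.05))
  ## agreement with cor.test on random data
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    r <- cor(x, y)
    p <- stats::cor.test(x, y)$p.value
    expect_equal(is_significant(r, 8, 0.05), p < 0.05)
  }
})

test_that("term graphs connect exactly the significantly correlated annotated genes", {
  tp <- seq(0, 70, 7)
  base <- sin(2 * pi * tp / 70)
  vals <- rbind(g1 = base, g2 = 2 * base + 1, g3 = base * 1.5,
                g4 = vector_with_cor(base, 0))
  colnames(vals) <- tp
  expr <- tc_matrix(vals)
  annot <- annotation_map(cbind(c("g1", "g2", "g3"), "T1"))
  g <- build_term_graph("T1", annot, expr)
  expect_setequal(g$vertices, c("g1", "g2", "g3"))
  expect_equal(nrow(g$edges), 3L)             # perfect triangle

  annot2 <- annotation_map(cbind(c("g1", "g2", "g4"), "T1"))
  g2 <- build_term_graph("T1", annot2, expr)
  expect_equal(nrow(g2$edges), 1L)            # only g1-g2 survives
  expect_false(g2$adjacency["g1", "g4"])

  annot3 <- annotation_map(cbind("g1", "T1"))
  g3 <- build_term_graph("T1", annot3, expr)
  expect_equal(g3$vertices, "g1")
  expect_equal(nrow(g3$edges), 0L)

  ## genes annotated but absent from the expression matrix are ignored
  annot4 <- annotation_map(rbind(c("g1", "T1"), c("ghost", "T1")))
  expect_setequal(build_term_graph("T1", annot4, expr)$vertices, "g1")
})

test_that("edge sets grow monotonically with alpha", {
  set.seed(9)
  tp <- seq(0, 77, 7)
  vals <- matrix(rnorm(8 * length(tp)), 8,
                 dimnames = list(paste0("g", 1:8), tp))
  expr <- tc_matrix(vals)
  annot <- annotation_map(cbind(paste0("g", 1:8), "T1"))
  prev <- NULL
  for (alpha in c(0.01, 0.05, 0.2, 0.5)) {
    g <- build_term_graph("T1", annot, expr, alpha = alpha)
    key <- apply(g$edges, 1, paste, collapse = "|")
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("greedy clique selection returns deterministic maximal cliques", {
  complete <- random_graph(4, 1.01)
  expect_setequal(greedy_clique(complete), complete$vertices)

  ## star: centre g01 adjacent to all leaves, leaves mutually non-adjacent
  ids <- sprintf("g%02d", 1:4)
  adj <- matrix(FALSE, 4, 4, dimnames = list(ids, ids))
  adj[1, 2:4] <- adj[2:4, 1] <- TRUE
  star <- structure(list(vertices = ids, adjacency = adj),
                    class = "cor_graph")
  cl <- greedy_clique(star)
  expect_equal(length(cl), 2L)
  expect_true("g01" %in% cl)
  expect_equal(cl, greedy_clique(star))       # deterministic

  empty <- random_graph(3, -1)
  expect_equal(length(greedy_clique(empty)), 1L)
  expect_equal(length(greedy_clique(random_graph(0, 0.5))), 0L)
})

test_that("greedy cliques are valid, maximal and bounded by the exact maximum", {
  set.seed(13)
  for (i in 1:40) {
    g <- random_graph(sample(2:10, 1), runif(1, 0.2, 0.9))
    cl <- greedy_clique(g)
    expect_true(is_clique(g$adjacency, cl))
    expect_true(is_maximal_clique(g$adjacency, cl))
    expect_lte(length(cl), brute_max_clique_size(g$adjacency))
  }
})

test_that("the non-noise system keeps per-term cliques and restricts E* and A*", {
  tp <- seq(0, 77, 7)
  n_tp <- length(tp)
  base <- sin(2 * pi * tp / 70)
  set.seed(21)
  vals <- rbind(a1 = base + rnorm(n_tp, sd = 0.02),
                a2 = base + rnorm(n_tp, sd = 0.02),
                a3 = base + rnorm(n_tp, sd = 0.02),
                u1 = vector_with_cor(base, 0),
                u2 = vector_with_cor(base, 0, z = seq_along(tp)^3),
                shared = base + rnorm(n_tp, sd = 0.02))
  colnames(vals) <- tp
  expr <- tc_matrix(vals)
  annot <- annotation_map(rbind(
    c("a1", "T1"), c("a2", "T1"), c("a3", "T1"), c("shared", "T1"),
    c("u1", "T2"), c("u2", "T2"), c("shared", "T2")))
  nns <- build_non_noise_system(expr, annot, min_clique = 2)
  expect_setequal(nns$cliques$T1, c("a1", "a2", "a3", "shared"))
  ## clique property: every retained pair is significantly correlated
  for (tm in names(nns$cliques)) {
    cl <- nns$cliques[[tm]]
    if (length(cl) < 2) next
    for (i in seq_along(cl)[-1]) for (j in seq_len(i - 1))
      expect_true(is_significant(
        pearson_r(nns$expr$values[cl[i], ], nns$expr$values[cl[j], ]),
        ncol(nns$expr$values), 0.05))
  }
  ## a gene shared by two retained terms appears once in E*
  expect_equal(sum(gene_ids(nns$expr) == "shared"), 1L)
  expect_setequal(nns$genes, rownames(nns$expr$values))

  ## three mutually uncorrelated genes: term dropped entirely
  annot_u <- annotation_map(rbind(c("u1", "T2"), c("u2", "T2"), c("a1", "T2")))
  expect_error(build_non_noise_system(expr, annot_u, min_clique = 3),
               "larger alpha|smaller min_clique")
})
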