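## small diamond DAG:  root -> a -> c, root -> b -> d -> c
## c is reachable in 2 steps (via a) and 3 steps (via b, d)
diamond_dag <- function() {
  go_dag(c("root", "a", "b", "c", "d"),
         rbind(c("a", "root"), c("b", "root"),
               c("c", "a"), c("d", "b"), c("c", "d")))
}

test_that("term levels are shortest is_a paths from the root", {
  dag <- diamond_dag()
  expect_equal(term_level(dag, "root"), 0L)
  expect_equal(term_level(dag, "a"), 1L)
  expect_equal(term_level(dag, "c"), 2L)      # BFS: shorter of paths 2 and 3
  expect_equal(term_level(dag, "d"), 2L)
  expect_error(term_level(dag, "nope"), "unknown term")
  ## BFS oracle on a random DAG built by forward edges
  set.seed(17)
  n <- 12
  ids <- paste0("t", seq_len(n))
  edges <- NULL
  for (i in 2:n)
    for (p in sample(seq_len(i - 1), min(i - 1, sample(1:2, 1))))
      edges <- rbind(edges, c(ids[i], ids[p]))
  dag2 <- go_dag(ids, unique(edges))
  lv <- term_levels(dag2)
  for (tm in ids) {
    parents <- dag2$parents[[tm]]
    if (!length(parents)) expect_equal(lv[[tm]], 0L)
    else expect_equal(lv[[tm]], min(lv[parents]) + 1L)
  }
})

test_that("GNC up-propagates under-populated terms and enforces the lambda floor", {
  dag <- go_dag(c("root", "mid", "leaf"),
                rbind(c("mid", "root"), c("leaf", "mid")))
  annot <- annotation_map(cbind(paste0("g", 1:5), "leaf"))
  ## leaf(5) < 10 -> mid(5) < 10 -> root(5) < 10 -> nothing survives
  expect_error(gnc(annot, dag, lam = 10), "no class")
  ## with lambda = 5 the leaf is already a fixed point and survives alone
  sys <- gnc(annot, dag, lam = 5)
  expect_equal(names(sys$classes), "leaf")
  expect_setequal(sys$classes$leaf$genes, paste0("g", 1:5))
  ## with lambda = 6 genes propagate to mid where another gene waits
  annot2 <- annotation_map(rbind(cbind(paste0("g", 1:5), "leaf"),
                                 c("g6", "mid")))
  sys2 <- gnc(annot2, dag, lam = 6)
  expect_equal(names(sys2$classes), "mid")
  expect_setequal(sys2$classes$mid$genes, paste0("g", 1:6))

  ## multi-parent fan-out: an under-populated leaf copies its genes to all
  ## parents (duplication across classes is allowed)
  dag3 <- go_dag(c("root", "p1", "p2", "leaf"),
                 rbind(c("p1", "root"), c("p2", "root"),
                       c("leaf", "p1"), c("leaf", "p2")))
  annot3 <- annotation_map(rbind(cbind(paste0("g", 1:5), "leaf"),
                                 c("x1", "p1"), c("x2", "p2")))
  sys3 <- gnc(annot3, dag3, lam = 6)
  expect_setequal(names(sys3$classes), c("p1", "p2"))
  expect_true(all(paste0("g", 1:5) %in% sys3$classes$p1$genes))
  expect_true(all(paste0("g", 1:5) %in% sys3$classes$p2$genes))
  ## every surviving class respects the floor
  expect_true(all(colSums(sys3$label_matrix) >= 6))

  ## genes stranded at an under-populated root are reported unplaced
  sys4 <- gnc(annot2, dag, lam = 6)
  expect_length(attr(sys4, "unplaced"), 0L)
  annot5 <- annotation_map(rbind(cbind(paste0("g", 1:6), "leaf"),
                                 cbind(paste0("h", 1:3), "root")))
  sys5 <- gnc(annot5, dag, lam = 6)
  expect_equal(names(sys5$classes), "leaf")
  expect_setequal(attr(sys5, "unplaced"), paste0("h", 1:3))
})

test_that("GOLC re-assigns annotations to every ancestor at the target level", {
  dag <- diamond_dag()
  annot <- annotation_map(cbind("g1", "c"))
  sys <- golc(annot, dag, iota = 1)
  ## c reaches level-1 ancestors a (via a) and b (via d, b)
  expect_setequal(names(sys$classes), c("a", "b"))
  expect_equal(sys$classes$a$genes, "g1")
  expect_equal(sys$classes$b$genes, "g1")
  ## annotation already at the target level stays put
  sys2 <- golc(annotation_map(cbind("g2", "a")), dag, iota = 1)
  expect_equal(names(sys2$classes), "a")
  ## annotation above the target level contributes nothing
  expect_error(golc(annotation_map(cbind("g3", "root")), dag, iota = 1),
               "no level")
  ## level-2 targets: c maps to itself and d
  sys3 <- golc(annot, dag, iota = 2)
  expect_setequal(names(sys3$classes), c("c", "d"))
  ## postcondition: classes sit exactly at the target level
  expect_true(all(term_levels(dag)[names(sys3$classes)] == 2L))
})

test_that("bag distances follow the Hausdorff-family definitions", {
  tp <- seq(0, 44, 4)
  p <- sin(tp / 3) + tp / 20
  q <- vector_with_cor(p, 0.6)             # d(p, q) = 0.4 exactly
  bag_p <- rbind(p = p)
  bag_pq <- rbind(p = p, q = q)
  for (mode in c("avg_hausdorff", "max_hausdorff", "min_hausdorff")) {
    expect_equal(bag_distance(bag_pq, bag_pq, mode), 0)
    ## singleton bags reduce to the instance distance in every mode
    expect_equal(bag_distance(rbind(p), rbind(q), mode), 0.4)
    ## symmetry
    expect_equal(bag_distance(bag_pq, bag_p, mode),
                 bag_distance(bag_p, bag_pq, mode))
  }
  ## avg_hausdorff of {p,q} vs {p}: (0 + 0.4 + 0) / 3
  expect_equal(bag_distance(bag_pq, bag_p), 0.4 / 3)
  expect_equal(bag_distance(bag_pq, bag_p, "max_hausdorff"), 0.4)
  expect_equal(bag_distance(bag_pq, bag_p, "min_hausdorff"), 0)
  ## constant profiles take the maximum instance distance
  expect_equal(bag_distance(rbind(rep(1, 12)), rbind(p)), 2)
  ## independent double-loop evaluation on random bags
  set.seed(23)
  a <- matrix(rnorm(4 * 12), 4); b <- matrix(rnorm(3 * 12), 3)
  d <- matrix(0, 4, 3)
  for (i in 1:4) for (j in 1:3) d[i, j] <- 1 - cor(a[i, ], b[j, ])
  expect_equal(bag_distance(a, b),
               (sum(apply(d, 1, min)) + sum(apply(d, 2, min))) / 7)
  expect_gte(bag_distance(a, b), 0)
})

test_that("MIHC merges the closest bags, honours the terminal factor and conserves genes", {
  fix <- make_two_group_nns()
  nns <- fix$nns
  ## tau = 0: no merges, one class per term
  res0 <- mihc(nns, stop_tau = 0)
  expect_equal(length(res0$system$classes), length(nns$cliques))
  expect_equal(nrow(res0$dendrogram$merges), 0L)
  ## tau = Inf: complete agglomeration into a single class
  res_inf <- mihc(nns, stop_tau = Inf)
  expect_equal(length(res_inf$system$classes), 1L)
  expect_setequal(res_inf$system$classes[[1]]$genes, nns$genes)
  ## two planted groups at tau = 0.5 recover exactly the planted partition
  res <- mihc(nns, stop_tau = 0.5)
  expect_equal(length(res$system$classes), 2L)
  grp <- unname(lapply(res$system$classes, function(cl) sort(cl$terms)))
  expect_true(identical(sort(vapply(grp, paste, "", collapse = "+")),
                        c("A1+A2", "B1+B2")))
  ## data-derived default terminal factor finds the same two groups
  res_def <- mihc(nns)
  expect_equal(length(res_def$system$classes), 2L)
  ## gene conservation in every case
  for (r in list(res0, res_inf, res, res_def))
    expect_setequal(unique(unlist(class_genes(r$system))), nns$genes)
  ## every merge height equals the naive matrix minimum at its step
  oracle <- naive_mihc_merges(lapply(nns$cliques,
                                     function(g) profiles(nns$expr, g)),
                              tau = 0.5)
  expect_equal(res$dendrogram$merges, oracle)
})

test_that("MIHC merge sequences match a from-scratch oracle on random bag sets", {
  set.seed(29)
  for (trial in 1:5) {
    n_bags <- sample(3:6, 1)
    bags <- lapply(seq_len(n_bags), function(i) {
      m <- matrix(rnorm(sample(2:5, 1) * 10), ncol = 10)
      rownames(m) <- paste0("b", i, "_", seq_len(nrow(m)))
      m
    })
    tau <- runif(1, 0.3, 1.5)
    ## package path: wrap bags in a minimal non-noise system
    expr <- tc_matrix(do.call(rbind, bags),
                      time_points = seq(0, 63, 7))
    cliques <- lapply(bags, rownames)
    names(cliques) <- paste0("T", seq_len(n_bags))
    nns <- structure(list(cliques = cliques, expr = expr,
                          genes = rownames(expr$values)),
                     class = "non_noise_system")
    got <- mihc(nns, stop_tau = tau)$dendrogram$merges
    expect_equal(got, naive_mihc_merges(bags, tau))
  }
})

test_that("single-term systems and Newick export behave", {
  fix <- make_two_group_nns()
  nns1 <- fix$nns
  nns1$cliques <- nns1$cliques["A1"]
  nns1$genes <- nns1$cliques$A1
  res1 <- mihc(nns1)
  expect_equal(length(res1$system$classes), 1L)
  expect_equal(nrow(res1$dendrogram$merges), 0L)

  res <- mihc(fix$nns, stop_tau = 0.5)
  nwk <- write_dendrogram_newick(res$dendrogram)
  expect_length(nwk, 2L)                      # a two-tree forest
  expect_true(all(grepl(";$", nwk)))
  ## ape can parse each tree and sees the right leaves
  trees <- lapply(nwk, function(s) ape::read.tree(text = s))
  expect_setequal(unlist(lapply(trees, `[[`, "tip.label")),
                  names(fix$nns$cliques))
})
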