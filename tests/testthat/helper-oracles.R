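# Independent oracles and fixture builders used across the suite.

## exhaustive maximum-clique size by subset enumeration (n <= 12)
brute_max_clique_size <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(0L)
  best <- 1L
  for (code in seq_len(2^n - 1L)) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0L)
    if (length(members) <= best) next
    ok <- TRUE
    for (i in seq_along(members)[-1L]) for (j in seq_len(i - 1L))
      if (!adj[members[i], members[j]]) { ok <- FALSE; break }
    if (ok) best <- length(members)
  }
  best
}

is_clique <- function(adj, members) {
  if (length(members) <= 1L) return(TRUE)
  all(adj[members, members][upper.tri(diag(length(members)))])
}

is_maximal_clique <- function(adj, members) {
  others <- setdiff(rownames(adj), members)
  !any(vapply(others, function(v) all(adj[v, members]), logical(1)))
}

## random Erdos-Renyi cor_graph-shaped object over <= 12 vertices
random_graph <- function(n, p) {
  ids <- sprintf("g%02d", seq_len(n))
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      adj[i, j] <- adj[j, i] <- stats::runif(1) < p
  }
  structure(list(vertices = ids, adjacency = adj), class = "cor_graph")
}

## naive multi-instance agglomeration: recompute the whole distance matrix
## from the cluster instance sets at every step
naive_mihc_merges <- function(bags, tau, mode = "avg_hausdorff") {
  merges <- data.frame(a = integer(0), b = integer(0), height = numeric(0),
                       new_id = integer(0))
  alive <- rep(TRUE, length(bags))
  repeat {
    idx <- which(alive)
    if (length(idx) < 2L) break
    best <- NULL
    for (ai in seq_along(idx)[-length(idx)]) {
      for (bi in (ai + 1L):length(idx)) {
        d <- bag_distance(bags[[idx[ai]]], bags[[idx[bi]]], mode)
        if (is.null(best) || d < best$d)
          best <- list(d = d, i = idx[ai], j = idx[bi])
      }
    }
    if (best$d > tau) break
    merged <- rbind(bags[[best$i]], bags[[best$j]])
    merged <- merged[!duplicated(rownames(merged)), , drop = FALSE]
    bags[[length(bags) + 1L]] <- merged
    alive[c(best$i, best$j)] <- FALSE
    alive <- c(alive, TRUE)
    merges <- rbind(merges,
                    data.frame(a = best$i, b = best$j, height = best$d,
                               new_id = length(bags)))
  }
  merges
}

## exhaustive MLKNN: neighbours, scores and labels by direct loops
naive_mlknn <- function(Xtr, Ytr, x, k) {
  d <- numeric(nrow(Xtr))
  for (i in seq_len(nrow(Xtr))) d[i] <- 1 - stats::cor(x, Xtr[i, ])
  nb <- order(d)[seq_len(k)]
  sim <- (1 + vapply(nb, function(i) stats::cor(x, Xtr[i, ]), numeric(1))) / 2
  scores <- stats::setNames(numeric(ncol(Ytr)), colnames(Ytr))
  for (cl in colnames(Ytr))
    for (m in seq_along(nb))
      if (Ytr[nb[m], cl] == 1) scores[cl] <- scores[cl] + sim[m]
  cand <- colnames(Ytr)[colSums(Ytr[nb, , drop = FALSE]) > 0]
  labels <- names(scores)[scores > sum(sim) / 2]
  list(neighbours = nb, scores = scores, candidates = sort(cand),
       labels = sort(labels), total_mass = sum(sim))
}

## pairwise brute-force AUC with half credit for ties
brute_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## vector with an exact Pearson correlation r to x (length >= 3)
vector_with_cor <- function(x, r, z = NULL) {
  xc <- (x - mean(x)) / stats::sd(x)
  if (is.null(z)) {
    z <- seq_along(x)^2
  }
  zc <- stats::residuals(stats::lm(z ~ x))
  zc <- zc / stats::sd(zc)
  r * xc + sqrt(1 - r^2) * zc
}

## fixed imbalanced toy set: one positive at (1,1), nine negatives below
imbalanced_toy <- function() {
  X <- rbind(c(1, 1),
             c(-1, -1), c(-2, -2), c(-1.5, -1), c(-1, -1.5), c(-0.5, -0.7),
             c(-0.7, -0.5), c(-1.2, -0.8), c(-0.8, -1.2), c(-0.3, -0.4))
  Y <- matrix(c(1, rep(0, 9)), ncol = 1, dimnames = list(NULL, "c1"))
  list(X = X, Y = Y)
}

## tiny OBO chain fixture: leaf is_a mid is_a root (plus extras via `extra`)
write_chain_obo <- function(path, extra = character(0)) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: mid",
    "namespace: biological_process", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: leaf",
    "namespace: biological_process", "is_a: GO:0000002 ! mid", "",
    extra), path)
  path
}

## expression fixture with exact values
write_expr_fixture <- function(path, values, gene_ids, time_points) {
  rownames(values) <- gene_ids
  colnames(values) <- time_points
  write_expression(tc_matrix(values), path)
  path
}

## small two-group non-noise system built through the real pipeline:
## `groups` named list group -> term ids; genes per term correlated within
## group, anti/un-correlated across groups
make_two_group_nns <- function(genes_per_term = 3, n_tp = 12, seed = 42) {
  set.seed(seed)
  tp <- seq(0, by = 7, length.out = n_tp)
  base1 <- sin(2 * pi * tp / max(tp))
  base2 <- cos(2 * pi * tp / max(tp))
  terms <- c(A1 = 1, A2 = 1, B1 = 2, B2 = 2)
  vals <- NULL; ids <- character(0); pairs <- NULL
  for (tm in names(terms)) {
    base <- if (terms[[tm]] == 1) base1 else base2
    for (g in seq_len(genes_per_term)) {
      gid <- paste0(tm, "_g", g)
      ids <- c(ids, gid)
      vals <- rbind(vals, base + stats::rnorm(n_tp, sd = 0.05))
      pairs <- rbind(pairs, c(gid, tm))
    }
  }
  rownames(vals) <- ids
  expr <- preprocess(tc_matrix(vals, gene_ids = ids, time_points = tp))
  nns <- build_non_noise_system(expr, annotation_map(pairs))
  list(nns = nns, groups = terms)
}
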