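#' Multi-label learning system
#'
#' Internal constructor shared by [gnc()], [golc()] and [mihc()].  A learning
#' system is an ordered list of classes -- each a set of original GO terms
#' with its member gene set -- plus the binary genes x classes label matrix.
#'
#' @param class_terms named list: class id -> character vector of term ids.
#' @param class_genes named list: class id -> character vector of gene ids.
#' @param method one of `"GNC"`, `"GOLC"`, `"MIHC"`.
#' @param params named list of method parameters.
#' @return object of class `learning_system` with elements `classes`,
#'   `label_matrix`, `method`, `params`.
#' @export
learning_system <- function(class_terms, class_genes, method, params = list()) {
  stopifnot(length(class_terms) == length(class_genes))
  keep <- lengths(class_genes) > 0L
  class_terms <- class_terms[keep]
  class_genes <- lapply(class_genes[keep], function(g) sort(unique(g)))
  if (!length(class_genes)) stop("learning system has no non-empty class")
  genes <- sort(unique(unlist(class_genes, use.names = FALSE)))
  lab <- matrix(0L, length(genes), length(class_genes),
                dimnames = list(genes, names(class_genes)))
  for (j in seq_along(class_genes)) lab[class_genes[[j]], j] <- 1L
  structure(list(classes = Map(function(tm, gn) list(terms = tm, genes = gn),
                               class_terms, class_genes),
                 label_matrix = lab, method = method, params = params),
            class = "learning_system")
}

#' @export
print.learning_system <- function(x, ...) {
  cat(sprintf("learning_system [%s]: %d classes, %d genes\n", x$method,
              ncol(x$label_matrix), nrow(x$label_matrix)))
  invisible(x)
}

#' Genes of every class of a learning system
#' @param system a [learning_system()].
#' @return named list class id -> gene ids.
#' @export
class_genes <- function(system) lapply(system$classes, `[[`, "genes")

#' Gene-number clustering (GNC)
#'
#' Builds a learning system by up-propagating annotations along the GO DAG
#' until every surviving term holds at least `lam` genes.  Terms are
#' processed bottom-up (deepest level first, ties broken lexicographically);
#' an under-populated term passes its genes to all of its parents and is
#' removed (genes routed through already-removed parents continue upwards).
#' A root left with fewer than `lam` genes is dropped and its genes are
#' reported in the `unplaced` attribute.
#'
#' @param annot an [annotation_map()].
#' @param dag a [go_dag()].
#' @param lam minimum number of genes per class (>= 1).
#' @return a [learning_system()] with `method = "GNC"`; attribute `unplaced`
#'   lists genes lost at under-populated roots.
#' @export
gnc <- function(annot, dag, lam = 10) {
  stopifnot(lam >= 1)
  gene_sets <- stats::setNames(vector("list", length(dag$term_ids)),
                               dag$term_ids)
  for (tm in intersect(names(annot$term2gene), dag$term_ids))
    gene_sets[[tm]] <- annot$term2gene[[tm]]
  lv <- dag$levels
  order_terms <- dag$term_ids[order(-lv, dag$term_ids)]
  alive <- stats::setNames(rep(TRUE, length(dag$term_ids)), dag$term_ids)
  unplaced <- character(0)
  ## route genes upwards through removed terms to the nearest alive ancestors
  transfer_up <- function(term, genes) {
    for (p in dag$parents[[term]]) {
      if (alive[[p]]) gene_sets[[p]] <<- union(gene_sets[[p]], genes)
      else transfer_up(p, genes)
    }
    if (!length(dag$parents[[term]]))
      unplaced <<- union(unplaced, genes)
  }
  for (tm in order_terms) {
    genes <- gene_sets[[tm]]
    if (length(genes) >= lam) next
    alive[[tm]] <- FALSE
    gene_sets[[tm]] <- NULL
    if (length(genes)) transfer_up(tm, genes)
  }
  survivors <- dag$term_ids[alive[dag$term_ids]]
  survivors <- survivors[lengths(gene_sets[survivors]) >= lam]
  if (!length(survivors))
    stop("GNC produced no class; all terms fell below lambda = ", lam)
  sys <- learning_system(as.list(stats::setNames(survivors, survivors)),
                         gene_sets[survivors], "GNC", list(lambda = lam))
  attr(sys, "unplaced") <- sort(unplaced)
  sys
}

#' GO-level clustering (GOLC)
#'
#' Builds a learning system by re-assigning every annotation to all
#' ancestors of its term (including the term itself) that sit exactly at DAG
#' level `iota`.  Annotations at terms shallower than `iota` contribute
#' nothing; classes are the level-`iota` terms with at least one gene.
#'
#' @param annot an [annotation_map()].
#' @param dag a [go_dag()].
#' @param iota target GO level (>= 1).
#' @return a [learning_system()] with `method = "GOLC"`.
#' @export
golc <- function(annot, dag, iota = 1) {
  stopifnot(iota >= 1)
  lv <- dag$levels
  gene_sets <- list()
  for (tm in intersect(names(annot$term2gene), dag$term_ids)) {
    anc <- term_ancestors(dag, tm, include_self = TRUE)
    targets <- anc[lv[anc] == iota]
    for (tg in targets)
      gene_sets[[tg]] <- union(gene_sets[[tg]], annot$term2gene[[tm]])
  }
  if (!length(gene_sets))
    stop("GOLC found no level-", iota, " ancestor for any annotation")
  gene_sets <- gene_sets[sort(names(gene_sets))]
  learning_system(as.list(stats::setNames(names(gene_sets),
                                          names(gene_sets))),
                  gene_sets, "GOLC", list(iota = iota))
}

#' Hausdorff-family distance between two multi-instance bags
#'
#' Instances are preprocessed expression profiles; the instance distance is
#' `d(x, y) = 1 - pearson_r(x, y)` (range 0-2).  A constant profile has an
#' undefined correlation and its pairwise distances are taken as the maximum
#' (2).  The bag distance aggregates per-instance nearest-neighbour
#' distances:
#' \describe{
#'   \item{avg_hausdorff}{`(sum_x min_y d + sum_y min_x d) / (|a| + |b|)`}
#'   \item{max_hausdorff}{`max(max_x min_y d, max_y min_x d)`}
#'   \item{min_hausdorff}{`min_{x, y} d`}
#' }
#' All modes are symmetric and non-negative; `avg_hausdorff` is zero on
#' identical bags.
#'
#' @param a,b numeric matrices, instances in rows (equal column count).
#' @param mode one of `"avg_hausdorff"`, `"max_hausdorff"`, `"min_hausdorff"`.
#' @return non-negative scalar distance.
#' @export
bag_distance <- function(a, b,
                         mode = c("avg_hausdorff", "max_hausdorff",
                                  "min_hausdorff")) {
  mode <- match.arg(mode)
  a <- rbind(a); b <- rbind(b)
  stopifnot(nrow(a) >= 1L, nrow(b) >= 1L, ncol(a) == ncol(b))
  d <- instance_distances(a, b)
  row_min <- apply(d, 1L, min)
  col_min <- apply(d, 2L, min)
  switch(mode,
         avg_hausdorff = (sum(row_min) + sum(col_min)) / (nrow(a) + nrow(b)),
         max_hausdorff = max(max(row_min), max(col_min)),
         min_hausdorff = min(d))
}

## pairwise 1 - Pearson r between rows of a and rows of b; constant rows get
## the maximum distance 2
instance_distances <- function(a, b) {
  const_a <- apply(a, 1L, stats::sd) == 0
  const_b <- apply(b, 1L, stats::sd) == 0
  d <- matrix(2, nrow(a), nrow(b))
  if (any(!const_a) && any(!const_b)) {
    r <- suppressWarnings(stats::cor(t(a[!const_a, , drop = FALSE]),
                                     t(b[!const_b, , drop = FALSE])))
    d[!const_a, !const_b] <- 1 - r
  }
  d
}

#' Multi-instance hierarchical clustering of GO terms (MIHC)
#'
#' Treats each retained term of the non-noise system as a multi-instance bag
#' whose instances are its clique genes' expression profiles, and
#' agglomeratively merges the closest pair of bags under a Hausdorff-family
#' bag distance.  A merged cluster is the union of the two instance sets (the
#' cluster is itself a multi-instance sample, not a linkage summary).
#' Merging stops when the minimum pairwise distance exceeds the terminal
#' factor `stop_tau`, or when one cluster remains.  The default terminal
#' factor is derived from the data, keeping the method free of tuned
#' parameters: the complete merge sequence is computed once and `stop_tau`
#' is set to the midpoint of the largest gap between consecutive merge
#' heights (the knee of the dendrogram; when the sequence has no interior
#' gap the mean of the initial distance matrix is used instead).  Ties are
#' broken by the lowest pair of cluster indices.  The union of class gene
#' sets always equals the non-noise gene set.
#'
#' @param nns a [build_non_noise_system()] result.
#' @param stop_tau terminal factor; `NULL` (default) uses the largest-gap
#'   rule above.
#' @param mode bag-distance mode, see [bag_distance()].
#' @return list with elements `system` (a [learning_system()], classes named
#'   `MIHC1`, `MIHC2`, ...) and `dendrogram` (class `mihc_dendrogram`:
#'   data.frame of merges `a`, `b`, `height`, `new_id`, plus the terminal
#'   factor used and final cluster membership).
#' @export
mihc <- function(nns, stop_tau = NULL,
                 mode = c("avg_hausdorff", "max_hausdorff", "min_hausdorff")) {
  mode <- match.arg(mode)
  terms <- names(nns$cliques)
  n0 <- length(terms)
  bags <- lapply(nns$cliques, function(g) profiles(nns$expr, g))
  cluster_terms <- as.list(terms)
  if (n0 == 1L) {
    if (is.null(stop_tau)) stop_tau <- NA_real_
    sys <- learning_system(list(MIHC1 = terms), list(MIHC1 = nns$cliques[[1L]]),
                           "MIHC", list(tau = stop_tau, mode = mode))
    dend <- structure(list(merges = data.frame(a = integer(0), b = integer(0),
                                               height = numeric(0),
                                               new_id = integer(0)),
                           tau = stop_tau, mode = mode,
                           members = list(terms), labels = terms),
                      class = "mihc_dendrogram")
    return(list(system = sys, dendrogram = dend))
  }
  D <- matrix(NA_real_, n0, n0)
  for (i in seq_len(n0 - 1L)) for (j in (i + 1L):n0)
    D[i, j] <- D[j, i] <- bag_distance(bags[[i]], bags[[j]], mode)
  if (is.null(stop_tau)) {
    full <- agglomerate_bags(bags, D, Inf, mode)
    h <- full$merges$height
    gaps <- diff(h)
    stop_tau <- if (length(gaps))
      (h[which.max(gaps)] + h[which.max(gaps) + 1L]) / 2
    else mean(D[upper.tri(D)])
  }
  stopifnot(stop_tau >= 0)
  run <- agglomerate_bags(bags, D, stop_tau, mode)
  final <- run$final
  ids <- paste0("MIHC", seq_along(final))
  cg <- lapply(final, function(k) rownames(run$bags[[k]]))
  ct <- lapply(final, function(k) terms[unlist(run$members[[k]])])
  sys <- learning_system(stats::setNames(ct, ids),
                         stats::setNames(cg, ids), "MIHC",
                         list(tau = stop_tau, mode = mode))
  dend <- structure(list(merges = run$merges, tau = stop_tau, mode = mode,
                         members = ct, labels = terms),
                    class = "mihc_dendrogram")
  list(system = sys, dendrogram = dend)
}

## sequential agglomeration under a bag distance: merge the closest alive
## pair (ties: lowest index pair) while the minimum distance <= tau
agglomerate_bags <- function(bags, D, tau, mode) {
  n0 <- length(bags)
  members <- lapply(seq_len(n0), identity)
  alive <- rep(TRUE, n0)
  merges <- data.frame(a = integer(0), b = integer(0), height = numeric(0),
                       new_id = integer(0))
  repeat {
    idx <- which(alive)
    if (length(idx) < 2L) break
    sub <- D[idx, idx, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- NA
    h <- min(sub, na.rm = TRUE)
    if (h > tau) break
    hit <- which(sub == h, arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]   # lowest pair
    i <- idx[hit[1L, 1L]]; j <- idx[hit[1L, 2L]]
    new_bag <- rbind(bags[[i]], bags[[j]])
    new_bag <- new_bag[!duplicated(rownames(new_bag)), , drop = FALSE]
    bags[[length(bags) + 1L]] <- new_bag
    members[[length(members) + 1L]] <- c(members[[i]], members[[j]])
    alive[c(i, j)] <- FALSE
    alive <- c(alive, TRUE)
    new_id <- length(bags)
    D <- rbind(cbind(D, NA_real_), NA_real_)
    for (k in which(alive[-new_id]))
      D[k, new_id] <- D[new_id, k] <- bag_distance(bags[[k]], new_bag, mode)
    merges <- rbind(merges, data.frame(a = i, b = j, height = h,
                                       new_id = new_id))
  }
  list(bags = bags, merges = merges, final = which(alive),
       members = members)
}

#' @export
print.mihc_dendrogram <- function(x, ...) {
  cat(sprintf("mihc_dendrogram: %d leaves, %d merges, tau = %.4g (%s)\n",
              length(x$labels), nrow(x$merges), x$tau, x$mode))
  invisible(x)
}

#' Export an MIHC dendrogram in Newick format
#'
#' Each final cluster becomes one tree; branch lengths are merge heights
#' (leaf edges run from height zero to the parent's merge height).  The
#' forest is written one Newick string per line.
#'
#' @param dend a `mihc_dendrogram` from [mihc()].
#' @param path output file path, or `NULL` to return the strings.
#' @return character vector of Newick strings, invisibly if written.
#' @export
write_dendrogram_newick <- function(dend, path = NULL) {
  n0 <- length(dend$labels)
  height <- c(rep(0, n0), dend$merges$height)
  node_str <- as.list(dend$labels)
  for (m in seq_len(nrow(dend$merges))) {
    a <- dend$merges$a[m]; b <- dend$merges$b[m]
    h <- dend$merges$height[m]
    node_str[[dend$merges$new_id[m]]] <-
      sprintf("(%s:%g,%s:%g)", node_str[[a]], h - height[a],
              node_str[[b]], h - height[b])
  }
  roots <- setdiff(seq_along(node_str),
                   c(dend$merges$a, dend$merges$b))
  out <- paste0(unlist(node_str[roots]), ";")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
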