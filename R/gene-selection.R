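#' Pearson correlation of two profiles
#'
#' Sample Pearson correlation, with an explicit error on constant input so
#' callers can treat such pairs as non-significant (the convention used by
#' the clique selection and the bag distance).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) < 3L) stop("need at least 3 time points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant profile")
  stats::cor(x, y)
}

#' Significance of a correlation coefficient
#'
#' Two-sided t-test on the Pearson correlation: `t = r * sqrt((n-2)/(1-r^2))`
#' on `n - 2` degrees of freedom.  `|r| = 1` is always significant.
#'
#' @param r correlation coefficient.
#' @param n number of paired observations (>= 3).
#' @param alpha significance level in (0, 1).
#' @return `TRUE` iff the two-sided p-value is below `alpha`.
#' @export
is_significant <- function(r, n, alpha = 0.05) {
  stopifnot(n >= 3, alpha > 0, alpha < 1)
  if (abs(r) >= 1) return(TRUE)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  p < alpha
}

#' Significant-correlation graph of a term's genes
#'
#' Vertices are the genes annotated to `term` that are present in `expr`; an
#' edge joins two genes whose profiles are significantly correlated at level
#' `alpha` (two-sided t-test on Pearson r).  Pairs with an undefined
#' correlation (constant profile) get no edge.
#'
#' @param term GO term identifier.
#' @param annot an [annotation_map()].
#' @param expr a preprocessed [tc_matrix()].
#' @param alpha per-pair significance level.
#' @param bonferroni if `TRUE`, `alpha` is divided by the number of gene
#'   pairs of the term.
#' @return object of class `cor_graph`: `vertices`, `edges` (2-column
#'   matrix), `r_values`, `adjacency`.
#' @export
build_term_graph <- function(term, annot, expr, alpha = 0.05,
                             bonferroni = FALSE) {
  genes <- sort(intersect(annot$term2gene[[term]], gene_ids(expr)))
  n_g <- length(genes)
  adj <- matrix(FALSE, n_g, n_g, dimnames = list(genes, genes))
  edges <- matrix(character(0), 0L, 2L)
  r_values <- numeric(0)
  if (n_g >= 2L) {
    n_tp <- ncol(expr$values)
    a <- if (bonferroni) alpha / choose(n_g, 2L) else alpha
    prof <- profiles(expr, genes)
    for (i in seq_len(n_g - 1L)) for (j in (i + 1L):n_g) {
      r <- tryCatch(pearson_r(prof[i, ], prof[j, ]), error = function(e) NA)
      if (!is.na(r) && is_significant(r, n_tp, a)) {
        adj[i, j] <- adj[j, i] <- TRUE
        edges <- rbind(edges, c(genes[i], genes[j]))
        r_values <- c(r_values, r)
      }
    }
  }
  structure(list(term = term, vertices = genes, edges = edges,
                 r_values = r_values, adjacency = adj),
            class = "cor_graph")
}

#' Greedy maximal clique of a correlation graph
#'
#' The maximum-clique problem is NP-hard, so the selection uses a
#' deterministic greedy heuristic: seed with the highest-degree vertex, then
#' repeatedly add the candidate vertex (adjacent to all current members) of
#' highest degree within the remaining candidate set, breaking ties
#' lexicographically by gene id.  The result is always a maximal clique, not
#' necessarily a maximum one.
#'
#' @param g a `cor_graph` from [build_term_graph()].
#' @return character vector of clique gene ids (empty for an empty graph).
#' @export
greedy_clique <- function(g) {
  verts <- g$vertices
  if (!length(verts)) return(character(0))
  adj <- g$adjacency
  deg <- rowSums(adj)
  pick <- function(cands, degrees) {
    d <- degrees[cands]
    cands[order(-d, cands)][1L]
  }
  clique <- pick(verts, deg)
  cands <- verts[adj[clique, ]]
  while (length(cands)) {
    sub_deg <- if (length(cands) > 1L)
      rowSums(adj[cands, cands, drop = FALSE]) else stats::setNames(0, cands)
    nxt <- pick(cands, sub_deg)
    clique <- c(clique, nxt)
    cands <- cands[adj[nxt, cands] & cands != nxt]
  }
  sort(clique)
}

#' Build the non-noise system
#'
#' For every annotated term, restricts the term's gene set to the greedy
#' maximal clique of its significant-correlation graph; terms whose clique is
#' smaller than `min_clique` are dropped.  The result bundles the retained
#' term -> clique map, the expression submatrix over the union of retained
#' genes (`E*`), and the correspondingly restricted annotation map (`A*`).
#'
#' @param expr preprocessed [tc_matrix()].
#' @param annot [annotation_map()].
#' @param alpha per-pair significance level for the correlation test.
#' @param min_clique minimum clique size for a term to be retained.
#' @param bonferroni per-term Bonferroni correction flag (see
#'   [build_term_graph()]).
#' @return object of class `non_noise_system`: `cliques` (named list
#'   term -> genes), `expr` (`E*`), `annot` (`A*`), `genes`.
#' @export
build_non_noise_system <- function(expr, annot, alpha = 0.05, min_clique = 2,
                                   bonferroni = FALSE) {
  terms <- sort(names(annot$term2gene))
  cliques <- list()
  for (tm in terms) {
    cl <- greedy_clique(build_term_graph(tm, annot, expr, alpha, bonferroni))
    if (length(cl) >= min_clique) cliques[[tm]] <- cl
  }
  if (!length(cliques))
    stop("no term retained any clique; consider a larger alpha or ",
         "a smaller min_clique")
  genes <- sort(unique(unlist(cliques, use.names = FALSE)))
  pairs <- do.call(rbind, lapply(names(cliques), function(tm)
    cbind(cliques[[tm]], tm)))
  sub <- tc_matrix(profiles(expr, genes), time_points = expr$time_points)
  structure(list(cliques = cliques, expr = sub,
                 annot = annotation_map(pairs), genes = genes),
            class = "non_noise_system")
}

#' @export
print.non_noise_system <- function(x, ...) {
  cat(sprintf("non_noise_system: %d terms, %d genes (clique sizes %d-%d)\n",
              length(x$cliques), length(x$genes),
              min(lengths(x$cliques)), max(lengths(x$cliques))))
  invisible(x)
}
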