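#' Gene Ontology DAG
#'
#' Builds a `go_dag` from a table of child -> parent `is_a` edges.  The graph
#' must be acyclic and every non-root term must reach a root; term depth
#' ([term_level()]) is the shortest `is_a` path from a root.
#'
#' @param term_ids character vector of term identifiers.
#' @param parent_edges two-column character matrix or data.frame of
#'   (child, parent) `is_a` pairs; both ends must appear in `term_ids`.
#' @param namespace named character vector giving each term's namespace
#'   (e.g. `biological_process`); defaults to one shared namespace.
#' @param term_names optional named character vector of human-readable names.
#' @return an object of class `go_dag` with elements `term_ids`,
#'   `parent_edges`, `parents`, `children`, `namespace`, `roots`.
#' @export
go_dag <- function(term_ids, parent_edges,
                   namespace = NULL, term_names = NULL) {
  term_ids <- as.character(term_ids)
  if (anyDuplicated(term_ids)) stop("duplicate term ids")
  pe <- as.matrix(parent_edges)
  if (length(pe) == 0L) pe <- matrix(character(0), 0L, 2L)
  if (ncol(pe) != 2L) stop("parent_edges must have two columns (child, parent)")
  mode(pe) <- "character"
  colnames(pe) <- c("child", "parent")
  unknown <- setdiff(c(pe), term_ids)
  if (length(unknown))
    stop("edge endpoint not among term_ids: ", unknown[1L])
  if (any(pe[, 1L] == pe[, 2L])) stop("self is_a edge")
  pe <- unique(pe)
  parents <- split(pe[, "parent"], factor(pe[, "child"], levels = term_ids))
  children <- split(pe[, "child"], factor(pe[, "parent"], levels = term_ids))
  roots <- term_ids[lengths(parents) == 0L]
  if (nrow(pe)) {
    g <- igraph::graph_from_edgelist(pe, directed = TRUE)
    if (!igraph::is_dag(g)) {
      cyc <- igraph::feedback_arc_set(g)
      member <- igraph::ends(g, cyc[1L])[1L, 1L]
      stop("is_a cycle detected involving term ", member)
    }
  }
  if (length(roots) == 0L && length(term_ids))
    stop("DAG has no root term")
  if (is.null(namespace))
    namespace <- stats::setNames(rep("biological_process", length(term_ids)),
                                 term_ids)
  dag <- structure(list(term_ids = term_ids, parent_edges = pe,
                        parents = parents, children = children,
                        namespace = namespace[term_ids], roots = roots,
                        term_names = term_names),
                   class = "go_dag")
  lv <- term_levels(dag)
  if (anyNA(lv))
    stop("term(s) cannot reach a root: ", names(lv)[is.na(lv)][1L])
  dag$levels <- lv
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms, %d is_a edges, %d root(s), max level %d\n",
              length(x$term_ids), nrow(x$parent_edges), length(x$roots),
              if (length(x$levels)) max(x$levels) else 0L))
  invisible(x)
}

#' Depth of every term in the DAG
#'
#' The level of a term is the length of the shortest `is_a` path from a root
#' of its namespace; roots are at level 0.
#'
#' @param dag a [go_dag()].
#' @return named integer vector over all terms (`NA` if unreachable).
#' @export
term_levels <- function(dag) {
  lv <- stats::setNames(rep(NA_integer_, length(dag$term_ids)), dag$term_ids)
  lv[dag$roots] <- 0L
  frontier <- dag$roots
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(dag$children[frontier], use.names = FALSE))
    nxt <- nxt[!is.na(nxt)]
    nxt <- nxt[is.na(lv[nxt])]
    lv[nxt] <- d
    frontier <- nxt
  }
  lv
}

#' Level of a single term
#' @param dag a [go_dag()].
#' @param term term identifier.
#' @return non-negative integer.
#' @export
term_level <- function(dag, term) {
  if (!term %in% dag$term_ids) stop("unknown term: ", term)
  lv <- dag$levels[[term]]
  if (is.na(lv)) stop("term unreachable from any root: ", term)
  lv
}

#' Ancestors of a term
#' @param dag a [go_dag()].
#' @param term term identifier.
#' @param include_self include `term` itself (default `TRUE`).
#' @return character vector of ancestor term ids.
#' @export
term_ancestors <- function(dag, term, include_self = TRUE) {
  if (!term %in% dag$term_ids) stop("unknown term: ", term)
  seen <- character(0)
  frontier <- term
  while (length(frontier)) {
    up <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    up <- setdiff(up, seen)
    seen <- c(seen, up)
    frontier <- up
  }
  if (include_self) unique(c(term, seen)) else seen
}

#' Read an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas, keeping `id`, `name`, `namespace` and `is_a`
#' lines.  Obsolete terms are excluded; only `is_a` edges are retained
#' (`part_of` and other relationships are ignored); `is_a` references to
#' terms not defined in the file are dropped with a warning.
#'
#' @param path OBO file path.
#' @return a [go_dag()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  term_starts <- which(trimws(lines) == "[Term]")
  stanza_starts <- which(grepl("^\\[.*\\]$", trimws(lines)))
  ids <- character(0); nms <- character(0); ns <- character(0)
  edges <- list(); obsolete <- logical(0)
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    block <- lines[(s + 1L):(if (length(nxt)) nxt[1L] - 1L else length(lines))]
    get1 <- function(key) {
      hit <- grep(paste0("^", key, ":"), block, value = TRUE)
      if (!length(hit)) return(NA_character_)
      trimws(sub(paste0("^", key, ":"), "", hit[1L]))
    }
    id <- get1("id")
    if (is.na(id)) next
    isa <- grep("^is_a:", block, value = TRUE)
    isa <- trimws(sub("!.*$", "", sub("^is_a:", "", isa)))
    ids <- c(ids, id)
    nms <- c(nms, get1("name"))
    ns <- c(ns, get1("namespace"))
    obsolete <- c(obsolete, identical(get1("is_obsolete"), "true"))
    edges[[id]] <- isa
  }
  if (anyDuplicated(ids)) stop("duplicate term stanza: ", ids[duplicated(ids)][1L])
  keep <- !obsolete
  ids_k <- ids[keep]
  edge_mat <- do.call(rbind, lapply(ids_k, function(id) {
    if (length(edges[[id]])) cbind(id, edges[[id]]) else NULL
  }))
  if (is.null(edge_mat)) edge_mat <- matrix(character(0), 0L, 2L)
  dangling <- !(edge_mat[, 2L] %in% ids_k)
  if (any(dangling)) {
    warning(sum(dangling), " is_a edge(s) to undefined/obsolete terms dropped")
    edge_mat <- edge_mat[!dangling, , drop = FALSE]
  }
  ns_k <- stats::setNames(ifelse(is.na(ns[keep]), "biological_process",
                                 ns[keep]), ids_k)
  go_dag(ids_k, edge_mat, namespace = ns_k,
         term_names = stats::setNames(nms[keep], ids_k))
}

#' Write a minimal OBO 1.2 file
#' @param dag a [go_dag()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (id in dag$term_ids) {
    nm <- if (!is.null(dag$term_names)) dag$term_names[[id]] else id
    parents <- dag$parents[[id]]
    isa_lines <- if (length(parents)) paste0("is_a: ", parents) else character(0)
    writeLines(c("[Term]", paste0("id: ", id), paste0("name: ", nm),
                 paste0("namespace: ", dag$namespace[[id]]),
                 isa_lines, ""), con)
  }
  invisible(path)
}

gaf_aspect <- c(biological_process = "P", molecular_function = "F",
                cellular_component = "C")

#' Gene annotation map
#'
#' A bipartite gene/term incidence kept in two mutually consistent views.
#'
#' @param pairs two-column character matrix or data.frame of (gene, term)
#'   annotation pairs.
#' @return object of class `annotation_map` with named lists `gene2term` and
#'   `term2gene`.
#' @export
annotation_map <- function(pairs) {
  if (is.null(pairs)) pairs <- matrix(character(0), 0L, 2L)
  pm <- as.matrix(pairs)
  if (length(pm) == 0L) pm <- matrix(character(0), 0L, 2L)
  mode(pm) <- "character"
  pm <- unique(pm)
  structure(list(
    gene2term = lapply(split(pm[, 2L], pm[, 1L]), unique),
    term2gene = lapply(split(pm[, 1L], pm[, 2L]), unique),
    pairs = pm), class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d genes, %d terms, %d pairs\n",
              length(x$gene2term), length(x$term2gene), nrow(x$pairs)))
  invisible(x)
}

#' Read a GAF 2.x annotation file
#'
#' Keeps one (gene, term) pair per row, using the DB Object ID column as the
#' gene identifier.  Rows with a `NOT` qualifier, rows outside the requested
#' aspect/namespace, rows with an excluded evidence code, and rows whose term
#' is absent from `dag` (counted in a warning) are dropped.
#'
#' @param path GAF file path (lines starting with `!` are comments).
#' @param dag the companion [go_dag()].
#' @param namespace aspect to keep: `"P"`/`"biological_process"` (default),
#'   `"F"`, or `"C"`.
#' @param exclude_evidence evidence codes to drop (e.g. `"IEA"`); default none.
#' @return an [annotation_map()].
#' @export
read_gaf <- function(path, dag, namespace = "biological_process",
                     exclude_evidence = character(0)) {
  aspect <- if (namespace %in% names(gaf_aspect)) gaf_aspect[[namespace]]
            else toupper(namespace)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(trimws(lines))]
  if (!length(lines)) return(annotation_map(NULL))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 9L)
  if (length(short))
    stop("unparseable GAF line ", short[1L], ": fewer than 9 columns")
  gene <- vapply(fields, `[[`, character(1), 2L)
  qualifier <- vapply(fields, `[[`, character(1), 4L)
  term <- vapply(fields, `[[`, character(1), 5L)
  evidence <- vapply(fields, `[[`, character(1), 7L)
  asp <- vapply(fields, `[[`, character(1), 9L)
  keep <- !grepl("\\bNOT\\b", qualifier) & asp == aspect &
    !(evidence %in% exclude_evidence)
  in_dag <- term %in% dag$term_ids
  n_missing <- sum(keep & !in_dag)
  if (n_missing)
    warning(n_missing, " annotation(s) to terms absent from the DAG dropped")
  keep <- keep & in_dag
  annotation_map(cbind(gene[keep], term[keep]))
}

#' Write an annotation map as GAF 2.2
#' @param annot an [annotation_map()].
#' @param dag companion [go_dag()] (used for the aspect column).
#' @param path output path.
#' @param db database label for column 1.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annot, dag, path, db = "mihclust") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  pm <- annot$pairs
  if (nrow(pm)) {
    asp <- gaf_aspect[dag$namespace[pm[, 2L]]]
    asp[is.na(asp)] <- "P"
    rows <- paste(db, pm[, 1L], pm[, 1L], "involved_in", pm[, 2L],
                  "PMID:0000000", "IDA", "", asp, "", "", "gene", "taxon:4932",
                  "20260101", db, sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Restrict an annotation map
#' @param annot an [annotation_map()].
#' @param genes,terms optional vectors; pairs outside them are dropped.
#' @return an [annotation_map()].
#' @export
restrict_annotation <- function(annot, genes = NULL, terms = NULL) {
  pm <- annot$pairs
  if (!is.null(genes)) pm <- pm[pm[, 1L] %in% genes, , drop = FALSE]
  if (!is.null(terms)) pm <- pm[pm[, 2L] %in% terms, , drop = FALSE]
  annotation_map(pm)
}
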