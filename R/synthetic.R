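#' Generate a synthetic time-course dataset with planted modules
#'
#' Emulates the structure of a yeast cell-cycle study at desk scale.  Each
#' module receives a smooth periodic latent profile: a sinusoid over the
#' sampled span with period equal to half the span (about two cell cycles,
#' ~63 min for the default 18 x 7-min grid).  Modules are assigned to
#' orthogonal harmonic/quadrature pairs -- `sin`, `cos` of the base period,
#' then of its second harmonic, and so on -- with one shared random phase, so
#' that distinct modules are mutually near-uncorrelated while genes within a
#' module are strongly co-expressed.  Every module gene is its latent profile
#' plus i.i.d. Gaussian noise; background genes are pure noise and carry no
#' annotation.
#'
#' The companion ontology is a small random DAG with one root,
#' `n_modules` mid-level terms, and `terms_per_module` leaf terms per
#' module.  Each leaf is annotated with `genes_per_term` distinct genes of
#' one module, but is attached to a uniformly random mid-level parent: as in
#' the real Gene Ontology, the ontology's upper structure carries no
#' information about co-expression, so up-propagating annotations mixes
#' expression patterns while clustering terms by their gene profiles does
#' not.
#'
#' @param n_modules number of planted co-expression modules.
#' @param terms_per_module leaf terms per module.
#' @param genes_per_term genes annotated to each leaf.
#' @param n_timepoints number of samples along the time course (7-min grid).
#' @param within_noise_sd standard deviation of the per-gene Gaussian noise
#'   (log-ratio units).
#' @param background_genes number of unannotated pure-noise genes.
#' @param amplitude peak log-ratio amplitude of the latent sinusoids.
#' @param phase_offsets optional numeric vector (length `n_modules`) of
#'   module phase offsets in radians, overriding the orthogonal
#'   harmonic/quadrature assignment (all modules then share the base
#'   period).
#' @param seed integer seed; equal seeds give bit-identical output.
#' @return list with `expr` (raw [tc_matrix()]), `dag` ([go_dag()]), `annot`
#'   ([annotation_map()]), `modules` (named integer vector gene -> planted
#'   module, `NA` for background genes) and `params`.
#' @export
generate_synthetic <- function(n_modules = 4, terms_per_module = 3,
                               genes_per_term = 8, n_timepoints = 18,
                               within_noise_sd = 0.3, background_genes = 20,
                               amplitude = 0.85, phase_offsets = NULL,
                               seed = 1) {
  stopifnot(n_modules >= 1, terms_per_module >= 1, genes_per_term >= 1,
            n_timepoints >= 3, within_noise_sd >= 0, background_genes >= 0)
  rng <- local_rng(seed)
  tp <- 7 * (0:(n_timepoints - 1))
  period <- (max(tp) - min(tp)) / 2
  psi <- rng$runif(1) * 2 * pi
  latent <- matrix(0, n_modules, n_timepoints)
  for (m in seq_len(n_modules)) {
    if (is.null(phase_offsets)) {
      harmonic <- ceiling(m / 2)
      offset <- if (m %% 2 == 1) 0 else pi / 2
      latent[m, ] <- amplitude * sin(2 * pi * harmonic * tp / period +
                                       psi + offset)
    } else {
      latent[m, ] <- amplitude * sin(2 * pi * tp / period + psi +
                                       phase_offsets[m])
    }
  }
  n_module_genes <- terms_per_module * genes_per_term
  gene_rows <- list(); gene_id <- character(0); module_of <- integer(0)
  pairs <- NULL
  term_ids <- "GO:0000001"
  term_names <- c("GO:0000001" = "biological_process_root")
  edges <- NULL
  mids <- sprintf("GO:%07d", 100 + seq_len(n_modules))
  for (m in seq_len(n_modules)) {
    term_ids <- c(term_ids, mids[m])
    term_names[mids[m]] <- sprintf("process_group_%d", m)
    edges <- rbind(edges, c(mids[m], "GO:0000001"))
  }
  for (m in seq_len(n_modules)) {
    for (j in seq_len(terms_per_module)) {
      leaf <- sprintf("GO:%07d", 1000 + 10 * m + j)
      parent <- mids[ceiling(rng$runif(1) * n_modules)]
      term_ids <- c(term_ids, leaf)
      term_names[leaf] <- sprintf("module_%d_subprocess_%d", m, j)
      edges <- rbind(edges, c(leaf, parent))
      for (g in seq_len(genes_per_term)) {
        gid <- sprintf("M%dT%dG%02d", m, j, g)
        gene_id <- c(gene_id, gid)
        module_of <- c(module_of, m)
        gene_rows[[gid]] <- latent[m, ] +
          rng$rnorm(n_timepoints, sd = within_noise_sd)
        pairs <- rbind(pairs, c(gid, leaf))
      }
    }
  }
  for (b in seq_len(background_genes)) {
    gid <- sprintf("BG%03d", b)
    gene_id <- c(gene_id, gid)
    module_of <- c(module_of, NA_integer_)
    gene_rows[[gid]] <- rng$rnorm(n_timepoints, sd = within_noise_sd)
  }
  values <- do.call(rbind, gene_rows)
  rownames(values) <- gene_id
  ns <- stats::setNames(rep("biological_process", length(term_ids)), term_ids)
  list(expr = tc_matrix(values, gene_ids = gene_id, time_points = tp),
       dag = go_dag(term_ids, edges, namespace = ns, term_names = term_names),
       annot = annotation_map(pairs),
       modules = stats::setNames(module_of, gene_id),
       params = list(n_modules = n_modules,
                     terms_per_module = terms_per_module,
                     genes_per_term = genes_per_term,
                     n_timepoints = n_timepoints,
                     within_noise_sd = within_noise_sd,
                     background_genes = background_genes,
                     amplitude = amplitude, seed = seed))
}

#' Randomly reassign annotations to other terms
#'
#' Stress input for the non-noise selection: each (gene, term) pair is moved,
#' independently with probability `flip_rate`, to a uniformly chosen other
#' term of the map.
#'
#' @param annot an [annotation_map()].
#' @param flip_rate probability in `[0, 1)` of moving each pair.
#' @param seed integer seed.
#' @return a perturbed [annotation_map()].
#' @export
perturb_labels <- function(annot, flip_rate, seed = 1) {
  stopifnot(flip_rate >= 0, flip_rate < 1)
  pm <- annot$pairs
  terms <- sort(unique(pm[, 2L]))
  if (flip_rate == 0 || nrow(pm) == 0L || length(terms) < 2L)
    return(annotation_map(pm))
  rng <- local_rng(seed)
  flip <- rng$runif(nrow(pm)) < flip_rate
  for (i in which(flip)) {
    others <- setdiff(terms, pm[i, 2L])
    pm[i, 2L] <- others[ceiling(rng$runif(1) * length(others))]
  }
  annotation_map(pm)
}
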