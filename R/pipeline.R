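# End-to-end conveniences chaining the module operations; used by the
# command-line script and by calibration studies.

#' Recurrent breakpoint gene analysis, end to end
#'
#' Derives breakpoints from segmented profiles, maps them to genes, pools
#' genes sharing breakpoint probes, fits the baseline probability model on
#' the pooled entities and runs the Poisson-binomial recurrence test with
#' discrete FDR.
#'
#' @param profiles `segmented_profiles`.
#' @param genes gene `data.frame`.
#' @param pm a [probe_map].
#' @param alpha FDR level (default 0.1).
#' @param mode breakpoint-to-gene assignment mode (see
#'   [map_breakpoints_to_genes]).
#' @param pool merge genes sharing breakpoint probes before testing
#'   (default TRUE, matching the reporting of pooled entities).
#' @param refit run a second pass in which the baseline model is refitted
#'   with first-pass discoveries excluded from the likelihood (default
#'   TRUE).  Recurrent genes carry real signal; leaving them in the
#'   baseline fit inflates the null for every gene and costs power.
#' @return list: `breakpoints`, `bp_counts`, `gene_matrix` (pre-pooling),
#'   `matrix` (tested rows), `registry` (NULL when `pool = FALSE`), `model`,
#'   `table` (the `recurrence_table`).
#' @export
recurrent_breakpoint_genes <- function(profiles, genes, pm, alpha = 0.1,
                                       mode = "interval", pool = TRUE,
                                       refit = TRUE) {
  bps <- derive_breakpoints(profiles, pm)
  bp_counts <- table(factor(bps$sample, levels = names(profiles)))
  bp_counts <- setNames(as.integer(bp_counts), names(profiles))
  mapped <- map_breakpoints_to_genes(bps, genes, pm,
                                     samples = names(profiles), mode = mode)
  gpi <- gene_probe_index(genes, pm)
  registry <- NULL
  m <- mapped$matrix
  # the baseline model is always fitted on individual genes; pooled
  # entities then inherit the complement-product null
  np_out <- gpi$n_probes
  if (pool) {
    pooled <- pool_shared_probe_genes(m, mapped$probe_sets)
    registry <- pooled$registry
    pooled_gpi <- pool_gene_index(gpi, registry, pm)
    np_out <- pooled_gpi$n_probes
    memb <- setNames(strsplit(registry$members, ",", fixed = TRUE),
                     registry$pool_id)
  }
  run_pass <- function(excluded) {
    gene_model <- fit_breakpoint_probability_model(m, gpi, bp_counts,
                                                   exclude = excluded)
    model <- if (pool)
      pool_probability_model(gene_model, registry, pooled_gpi, bp_counts)
    else gene_model
    tested <- if (pool) pooled$matrix else m
    list(model = model,
         table = gene_recurrence_test(tested, model, alpha = alpha))
  }
  pass <- run_pass(character())
  if (refit) {
    sig <- pass$table$gene[pass$table$significant]
    contaminating <- if (pool) unique(unlist(memb[sig])) else sig
    if (length(contaminating)) pass <- run_pass(contaminating)
  }
  tab <- pass$table
  tab$n_probes <- as.integer(np_out[tab$gene])
  list(breakpoints = bps, bp_counts = bp_counts, gene_matrix = mapped$matrix,
       matrix = if (pool) pooled$matrix else m, registry = registry,
       model = pass$model, table = tab)
}

#' Baseline probabilities for pooled entities
#'
#' A pool is one entity occupying the union of its members' breakpoint
#' territories (members share probes, so their footprints largely
#' coincide).  Its per-profile null probability is therefore predicted from
#' the fitted gene-level coefficients at the pool's union covariates
#' (union probe count, union covered length).  For models without
#' coefficients (e.g. the closed-form fallback) the complement product over
#' members `1 - prod_m (1 - p_ms)` is used instead — an upper bound, hence
#' conservative.
#'
#' @param model a `bp_prob_model` fitted on individual genes.
#' @param registry pool registry from [pool_shared_probe_genes].
#' @param pooled_index union footprints from [pool_gene_index].
#' @param bp_counts named per-sample breakpoint counts.
#' @return a `bp_prob_model` over the pooled entities.
#' @export
pool_probability_model <- function(model, registry, pooled_index = NULL,
                                   bp_counts = NULL) {
  pools <- registry$pool_id
  p <- matrix(0, length(pools), ncol(model$p),
              dimnames = list(pools, colnames(model$p)))
  if (identical(model$method, "logistic_pooled") &&
      !is.null(pooled_index) && !is.null(bp_counts)) {
    b <- model$coefficients
    np <- pooled_index$n_probes[pools]
    cov_len <- pooled_index$covered_length[pools]
    lb <- log(bp_counts[colnames(model$p)] + 1)
    eta <- b[1] + b[2] * log(np + 1) + b[3] * log(pmax(cov_len, 1))
    p[] <- stats::plogis(outer(eta, b[4] * lb, "+"))
    p[np == 0, ] <- 0
    testable <- pools[np > 0]
  } else {
    testable <- character()
    for (i in seq_along(pools)) {
      members <- strsplit(registry$members[i], ",", fixed = TRUE)[[1L]]
      p[i, ] <- 1 - apply(1 - model$p[members, , drop = FALSE], 2, prod)
      if (any(members %in% model$testable))
        testable <- c(testable, pools[i])
    }
  }
  structure(list(p = p, coefficients = model$coefficients, se = model$se,
                 testable = testable,
                 untestable = setdiff(pools, testable),
                 converged = model$converged, loglik = model$loglik,
                 method = paste0(model$method, "_pooled_entities")),
            class = "bp_prob_model")
}

#' Union footprints of pooled entities
#'
#' Probe count, probe-covered length and boundary set of each pool are
#' computed over the union of its members' footprints (members share
#' breakpoint probes; summing per-member quantities would double-count the
#' shared territory).
#'
#' @param gpi a [gene_probe_index].
#' @param registry pool registry.
#' @param pm the [probe_map] (for inter-probe interval widths).
#' @return list shaped like [gene_probe_index] output, named by pool id.
#' @export
pool_gene_index <- function(gpi, registry, pm) {
  pos <- split(pm$position, pm$chromosome)
  n <- nrow(registry)
  n_probes <- integer(n)
  span <- covered <- numeric(n)
  probes <- bounds <- vector("list", n)
  chrom <- character(n)
  for (i in seq_len(n)) {
    members <- strsplit(registry$members[i], ",", fixed = TRUE)[[1L]]
    probes[[i]] <- sort(unique(unlist(gpi$probes[members])))
    bounds[[i]] <- sort(unique(unlist(gpi$boundaries[members])))
    n_probes[i] <- length(probes[[i]])
    span[i] <- max(gpi$span_length[members])
    chrom[i] <- gpi$chromosome[[members[1L]]]
    p <- pos[[chrom[i]]]
    covered[i] <- if (length(bounds[[i]]))
      sum(p[bounds[[i]] + 2L] - p[bounds[[i]] + 1L]) else 0
  }
  list(probes = setNames(probes, registry$pool_id),
       boundaries = setNames(bounds, registry$pool_id),
       chromosome = setNames(chrom, registry$pool_id),
       n_probes = setNames(n_probes, registry$pool_id),
       span_length = setNames(span, registry$pool_id),
       covered_length = setNames(covered, registry$pool_id))
}

#' Score one planted-scenario replicate of the recurrence stage
#'
#' Simulates a cohort, runs the full recurrence stage and scores discoveries
#' against the planted truth: a discovered pool counts as a true positive
#' when it contains a planted gene, and a planted gene counts as recovered
#' when any significant pool contains it.
#'
#' @param config a [simulation_config] with planted genes.
#' @param alpha FDR level (default 0.1).
#' @return list: `fdp` (false discovery proportion, 0 when nothing is
#'   discovered), `sensitivity`, `n_discoveries`, `n_planted`.
#' @export
planted_recurrence_metrics <- function(config, alpha = 0.1) {
  sim <- simulate_cohort(config)
  res <- recurrent_breakpoint_genes(sim$profiles, sim$genes, sim$probe_map,
                                    alpha = alpha)
  planted <- sim$truth$planted_genes$gene_id
  memb <- setNames(strsplit(res$registry$members, ",", fixed = TRUE),
                   res$registry$pool_id)
  sig <- res$table$gene[res$table$significant]
  tp <- vapply(sig, function(pool) any(memb[[pool]] %in% planted),
               logical(1))
  recovered <- vapply(planted, function(g)
    any(vapply(sig, function(pool) g %in% memb[[pool]], logical(1))),
    logical(1))
  list(fdp = if (length(sig)) mean(!tp) else 0,
       sensitivity = if (length(planted)) mean(recovered) else NA_real_,
       n_discoveries = length(sig), n_planted = length(planted))
}

#' Select prevalent recurrent breakpoint genes for stratification
#'
#' Stratification consumes the breakpoint status of the recurrent breakpoint
#' genes observed above a prevalence floor (the convention is > 3% of
#' samples), not of every gene: rows of the unpooled gene matrix are kept
#' when the gene belongs to a significant pool and its own prevalence
#' exceeds the floor.
#'
#' @param result output of [recurrent_breakpoint_genes] (with pooling).
#' @param min_prevalence prevalence floor (default 0.03, exclusive).
#' @return binary genes x samples matrix restricted to the selected genes.
#' @export
prevalent_breakpoint_genes <- function(result, min_prevalence = 0.03) {
  sig_pools <- result$table$gene[result$table$significant]
  members <- unlist(strsplit(
    result$registry$members[result$registry$pool_id %in% sig_pools], ",",
    fixed = TRUE))
  prev <- breakpoint_frequencies(result$gene_matrix)
  keep <- intersect(members, names(prev)[prev > min_prevalence])
  result$gene_matrix[keep, , drop = FALSE]
}

#' Network-based stratification, end to end
#'
#' Merges breakpoint and mutation events, drops samples with no event,
#' propagates over the network, quantile-normalizes, consensus-clusters and
#' extracts gene aberration scores.
#'
#' @param breakpoint_matrix,mutation_matrix binary genes x samples matrices.
#' @param network_edges edge `data.frame` or a [gene_network].
#' @param config an [nbs_config].
#' @return list: `merged`, `dropped_samples`, `smoothed`, `run`, `labels`,
#'   `scores`.
#' @export
nbs_stratify <- function(breakpoint_matrix, mutation_matrix, network_edges,
                         config = nbs_config()) {
  merged <- merge_events(breakpoint_matrix, mutation_matrix)
  zero <- attr(merged, "zero_event_samples")
  if (length(zero)) {
    message("dropping ", length(zero), " sample(s) with no events")
    merged <- merged[, setdiff(colnames(merged), zero), drop = FALSE]
  }
  net <- if (inherits(network_edges, "gene_network")) network_edges
         else gene_network(network_edges)
  smoothed <- propagate(merged, net, alpha = config$alpha)
  run <- consensus_cluster(smoothed, net, config)
  list(merged = merged, dropped_samples = zero, smoothed = smoothed,
       run = run, labels = run$labels, scores = extract_gene_scores(run))
}
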