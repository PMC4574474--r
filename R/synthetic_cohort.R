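# ---------------------------------------------------------------------------
# Synthetic array-CGH cohort generator with known ground truth.
#
# Emulates the structure of a segmented, state-called array-CGH cohort: a
# uniform probe grid (~17 kb spacing), genes with log-normal span lengths,
# per-sample breakpoint counts that vary over orders of magnitude (negative
# binomial), planted recurrent breakpoint genes, a small mutation panel, a
# modular gene-interaction network, and subtype-dependent exponential
# survival.  Breakpoints are simulated as inter-probe boundary events and
# converted to segments whose call states alternate between neutral and
# non-neutral, so no simulated boundary is ever a neutral-neutral boundary
# and the breakpoint-derivation rule recovers exactly the simulated set.
# ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' @param seed RNG seed; all outputs are byte-identical under the same seed.
#' @param n_samples cohort size.
#' @param n_chromosomes,probes_per_chromosome probe grid shape.
#' @param probe_spacing_bp inter-probe spacing (default 17000 bp, the
#'   emulated platform's resolution).
#' @param n_genes number of gene models.
#' @param gene_length_meanlog,gene_length_sdlog log-normal span-length
#'   parameters (defaults give a ~60 kb median, so a typical gene covers a
#'   few probes and some short genes carry none).
#' @param bg_mean,bg_dispersion negative-binomial mean and size of the
#'   per-sample background breakpoint count.
#' @param planted_genes `data.frame(gene_id, theta)` of recurrent breakpoint
#'   genes and their per-sample hit probabilities; `gene_id = NA` rows are
#'   assigned to randomly chosen genes with at least one fully-internal
#'   probe boundary.  An explicit gene without such a boundary is a
#'   configuration error.
#' @param mutation_freqs named or unnamed numeric vector of panel mutation
#'   frequencies (default: eight genes at frequencies typical of commonly
#'   mutated colorectal-cancer genes).
#' @param n_network_genes genes placed on the interaction network (first
#'   `n_network_genes` gene models; must include the planted drivers).
#' @param n_modules,p_within,p_between stochastic-block-model network:
#'   module count and within/between edge probabilities.
#' @param k_groups number of planted subtypes (1 = no subtype structure).
#' @param group_hazards per-group exponential death hazards (per day).
#' @param censor_hazard independent exponential censoring hazard.
#' @param drivers_per_group,driver_theta,driver_bg_theta subtype drivers:
#'   each group gets `drivers_per_group` genes from its own network module,
#'   hit with probability `driver_theta` in member samples and
#'   `driver_bg_theta` elsewhere.
#' @param msi_probs per-group probability of microsatellite instability.
#' @param mutation_group_enrich optional list(`panel_index`, `group`,
#'   `freq_in`, `freq_out`) making one panel gene subtype-enriched.
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_samples = 100,
                              n_chromosomes = 20,
                              probes_per_chromosome = 1000,
                              probe_spacing_bp = 17000,
                              n_genes = 2000,
                              gene_length_meanlog = log(6e4),
                              gene_length_sdlog = 0.8,
                              bg_mean = 40,
                              bg_dispersion = 0.7,
                              planted_genes = data.frame(
                                gene_id = character(), theta = numeric()),
                              mutation_freqs = c(
                                TP53 = 0.55, APC = 0.50, KRAS = 0.40,
                                PIK3CA = 0.15, FBXW7 = 0.10, SMAD4 = 0.10,
                                BRAF = 0.08, NRAS = 0.04),
                              n_network_genes = 0,
                              n_modules = 4,
                              p_within = 0.08,
                              p_between = 0.002,
                              k_groups = 1,
                              group_hazards = log(2) / 610,
                              censor_hazard = log(2) / 1500,
                              drivers_per_group = 0,
                              driver_theta = 0.4,
                              driver_bg_theta = 0.05,
                              msi_probs = 0.05,
                              mutation_group_enrich = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_samples > 0, cfg$n_chromosomes > 0,
            cfg$probes_per_chromosome > 1, cfg$probe_spacing_bp > 0,
            cfg$n_genes > 0, cfg$bg_mean >= 0, cfg$bg_dispersion > 0,
            all(cfg$planted_genes$theta >= 0),
            all(cfg$planted_genes$theta <= 1),
            all(cfg$mutation_freqs >= 0), all(cfg$mutation_freqs <= 1),
            cfg$p_within >= 0, cfg$p_within <= 1,
            cfg$p_between >= 0, cfg$p_between <= 1,
            cfg$k_groups >= 1,
            cfg$driver_theta >= 0, cfg$driver_theta <= 1,
            cfg$driver_bg_theta >= 0, cfg$driver_bg_theta <= 1,
            all(cfg$group_hazards > 0), cfg$censor_hazard >= 0,
            all(cfg$msi_probs >= 0), all(cfg$msi_probs <= 1))
  if (length(cfg$group_hazards) == 1)
    cfg$group_hazards <- rep(cfg$group_hazards, cfg$k_groups)
  if (length(cfg$msi_probs) == 1)
    cfg$msi_probs <- rep(cfg$msi_probs, cfg$k_groups)
  stopifnot(length(cfg$group_hazards) == cfg$k_groups,
            length(cfg$msi_probs) == cfg$k_groups)
  class(cfg) <- "sim_config"
  cfg
}

#' Preset simulation scenarios
#'
#' * `"null"` — no planted signal; FDR / calibration studies.
#' * `"planted"` — 20 recurrent breakpoint genes with per-sample hit
#'   probability 0.08 on a 100-sample, 2,000-gene, 20,000-probe grid;
#'   power and FDR studies.
#' * `"subtypes"` — 200 samples, 4 survival-separated groups whose driver
#'   genes align with the 4 modules of a 1,000-gene network; stratification
#'   recovery studies.  The poor-prognosis group has a ~2.2-fold hazard,
#'   carries most MSI samples, and one panel gene is mutation-enriched in
#'   it, mirroring the structure reported for advanced colorectal cancer.
#'
#' @param name scenario name.
#' @param seed RNG seed forwarded to the config.
#' @return a [simulation_config].
#' @export
scenario <- function(name = c("null", "planted", "subtypes"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    null = simulation_config(seed = seed),
    planted = simulation_config(
      seed = seed,
      planted_genes = data.frame(gene_id = rep(NA_character_, 20),
                                 theta = rep(0.08, 20))),
    subtypes = simulation_config(
      seed = seed,
      n_samples = 200,
      n_chromosomes = 10,
      probes_per_chromosome = 1000,
      n_genes = 1000,
      n_network_genes = 1000,
      n_modules = 4,
      k_groups = 4,
      group_hazards = log(2) / 610 * c(1, 1, 2.2, 1),
      drivers_per_group = 40,
      driver_theta = 0.35,
      msi_probs = c(0.01, 0.01, 0.30, 0.01),
      mutation_group_enrich = list(panel_index = 7L, group = 3L,
                                   freq_in = 0.33, freq_out = 0.05)))
}

#' Simulate a cohort with known ground truth
#'
#' Generates a probe map, gene models, segmented state-called profiles, a
#' panel mutation matrix, a modular gene network, and a clinical table, all
#' consistent with one hidden truth (planted recurrent genes, subtype
#' labels, subtype drivers, hazards, and the exact simulated breakpoint
#' set).  When `out_dir` is given, the standard files are written there
#' (`probes.tsv`, `genes.bed`, `segments.tsv`, `mutations.tsv`,
#' `network.tsv`, `clinical.tsv`).
#'
#' @param config a [simulation_config].
#' @param out_dir optional output directory.
#' @return list with `probe_map`, `genes`, `profiles`, `mutations`,
#'   `network` (edge data.frame), `clinical`, and `truth` (list:
#'   `breakpoints` data.frame, `planted_genes`, `subtype_labels`,
#'   `drivers`, `group_hazards`, `modules`, `mutation_panel`).
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- as.character(seq_len(config$n_chromosomes))
  m <- config$probes_per_chromosome
  sp <- config$probe_spacing_bp
  chrom_len <- (m + 1L) * sp

  pm <- probe_map(
    probe_id = sprintf("p_%s_%04d", rep(chroms, each = m),
                       rep(seq_len(m) - 1L, times = length(chroms))),
    chromosome = rep(chroms, each = m),
    position = rep(sp * seq_len(m), times = length(chroms)))

  # gene models: log-normal lengths, uniform placement
  g_chr <- sample(chroms, config$n_genes, replace = TRUE)
  g_len <- pmax(1000L, pmin(as.integer(round(stats::rlnorm(
    config$n_genes, config$gene_length_meanlog, config$gene_length_sdlog))),
    chrom_len %/% 2L))
  g_start <- vapply(g_len, function(l)
    sample.int(chrom_len - l, 1L), integer(1))
  genes <- data.frame(gene_id = sprintf("g%04d", seq_len(config$n_genes)),
                      chromosome = g_chr, start = g_start,
                      end = g_start + g_len - 1L,
                      strand = sample(c("+", "-"), config$n_genes, TRUE),
                      stringsAsFactors = FALSE)

  # per-gene internal boundaries: consecutive probe pairs fully inside the
  # span (a breakpoint planted there always overlaps the gene)
  gpi <- gene_probe_index(genes, pm)
  internal <- lapply(gpi$probes, function(j)
    if (length(j) >= 2) j[which(diff(j) == 1L)] else integer())
  plantable <- genes$gene_id[lengths(internal) > 0]

  planted <- config$planted_genes
  if (nrow(planted)) {
    auto <- is.na(planted$gene_id)
    pool <- setdiff(plantable, planted$gene_id[!auto])
    if (sum(auto) > length(pool))
      stop("not enough genes with internal probe boundaries to plant")
    planted$gene_id[auto] <- sample(pool, sum(auto))
    bad <- setdiff(planted$gene_id, plantable)
    if (length(bad))
      stop("planted gene(s) without an internal probe boundary: ",
           paste(bad, collapse = ", "))
  }

  # subtype structure
  samples <- sprintf("s%03d", seq_len(config$n_samples))
  groups <- setNames(sample.int(config$k_groups, config$n_samples,
                                replace = TRUE), samples)
  n_net <- config$n_network_genes
  modules <- NULL
  drivers <- data.frame(gene_id = character(), group = integer(),
                        theta = numeric(), stringsAsFactors = FALSE)
  if (n_net > 0) {
    stopifnot(n_net <= config$n_genes)
    net_genes <- genes$gene_id[seq_len(n_net)]
    modules <- setNames(sort(rep(seq_len(config$n_modules),
                                 length.out = n_net)), net_genes)
    if (config$drivers_per_group > 0) {
      stopifnot(config$k_groups <= config$n_modules)
      for (k in seq_len(config$k_groups)) {
        cand <- intersect(names(modules)[modules == k], plantable)
        cand <- setdiff(cand, planted$gene_id)
        if (length(cand) < config$drivers_per_group)
          stop("module ", k, " lacks plantable genes for drivers")
        drivers <- rbind(drivers, data.frame(
          gene_id = sample(cand, config$drivers_per_group),
          group = k, theta = config$driver_theta,
          stringsAsFactors = FALSE))
      }
    }
  }

  # breakpoint events: background boundaries + planted/driver gene hits
  boundary_chr <- rep(chroms, each = m - 1L)
  boundary_left <- rep(seq_len(m - 1L) - 1L, times = length(chroms))
  n_bound <- length(boundary_chr)
  gene_chr <- setNames(genes$chromosome, genes$gene_id)
  bp_rows <- vector("list", config$n_samples)
  b_bg <- pmin(stats::rnbinom(config$n_samples, size = config$bg_dispersion,
                              mu = config$bg_mean), n_bound)
  for (si in seq_along(samples)) {
    bg <- sample.int(n_bound, b_bg[si])
    chr <- boundary_chr[bg]
    left <- boundary_left[bg]
    hit_gene <- function(gid, theta) {
      if (stats::runif(1) < theta) {
        cand <- internal[[gid]]
        j <- if (length(cand) == 1L) cand else sample(cand, 1L)
        chr <<- c(chr, gene_chr[[gid]])
        left <<- c(left, j)
      }
    }
    if (nrow(planted))
      for (r in seq_len(nrow(planted)))
        hit_gene(planted$gene_id[r], planted$theta[r])
    if (nrow(drivers))
      for (r in seq_len(nrow(drivers))) {
        th <- if (groups[si] == drivers$group[r]) drivers$theta[r]
              else config$driver_bg_theta
        hit_gene(drivers$gene_id[r], th)
      }
    keep <- !duplicated(paste(chr, left))
    bp_rows[[si]] <- data.frame(sample = rep(samples[si], sum(keep)),
                                chromosome = as.character(chr[keep]),
                                left_probe = as.integer(left[keep]),
                                stringsAsFactors = FALSE)
  }
  truth_bps <- do.call(rbind, bp_rows)
  truth_bps$right_probe <- truth_bps$left_probe + 1L
  truth_bps <- truth_bps[order(truth_bps$sample, truth_bps$chromosome,
                               truth_bps$left_probe), ]
  rownames(truth_bps) <- NULL

  # segments: alternate neutral / non-neutral calls so every simulated
  # boundary is detectable and no spurious neutral-neutral boundary exists
  profiles <- setNames(vector("list", config$n_samples), samples)
  for (si in seq_along(samples)) {
    bp <- bp_rows[[si]]
    seg_rows <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      lefts <- sort(bp$left_probe[bp$chromosome == chroms[ci]])
      starts <- c(0L, lefts + 1L)
      ends <- c(lefts, m - 1L)
      k <- length(starts)
      call <- integer(k)
      nz <- seq_len(k) %% 2L == 0L
      call[nz] <- sample(c(-1L, 1L), sum(nz), replace = TRUE)
      seg_rows[[ci]] <- data.frame(
        chromosome = chroms[ci], start_probe = starts, end_probe = ends,
        mean_log2 = round(0.35 * call + stats::rnorm(k, 0, 0.03), 4),
        call = call, stringsAsFactors = FALSE)
    }
    profiles[[si]] <- do.call(rbind, seg_rows)
    rownames(profiles[[si]]) <- NULL
  }
  class(profiles) <- "segmented_profiles"

  # mutation panel: Bernoulli per sample; panel genes are network genes
  # (when a network exists) so that mutations propagate
  n_panel <- length(config$mutation_freqs)
  panel_pool <- if (n_net > 0) genes$gene_id[seq_len(n_net)]
                else genes$gene_id
  panel_pool <- setdiff(panel_pool, c(planted$gene_id, drivers$gene_id))
  panel_genes <- sample(panel_pool, n_panel)
  mutations <- matrix(0L, n_panel, config$n_samples,
                      dimnames = list(panel_genes, samples))
  freqs <- unname(config$mutation_freqs)
  for (i in seq_len(n_panel)) {
    f <- rep(freqs[i], config$n_samples)
    en <- config$mutation_group_enrich
    if (!is.null(en) && en$panel_index == i)
      f <- ifelse(groups == en$group, en$freq_in, en$freq_out)
    mutations[i, ] <- stats::rbinom(config$n_samples, 1L, f)
  }

  # interaction network: stochastic block model over the network genes
  network <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  if (n_net > 0) {
    sizes <- as.integer(table(factor(modules, seq_len(config$n_modules))))
    pref <- matrix(config$p_between, config$n_modules, config$n_modules)
    diag(pref) <- config$p_within
    g <- igraph::sample_sbm(n_net, pref.matrix = pref, block.sizes = sizes)
    igraph::V(g)$name <- names(sort(modules))
    el <- igraph::as_edgelist(g)
    network <- data.frame(from = el[, 1], to = el[, 2], weight = 1,
                          stringsAsFactors = FALSE)
  }

  # clinical: per-group exponential survival, independent censoring
  death <- stats::rexp(config$n_samples,
                       rate = config$group_hazards[groups])
  cens <- if (config$censor_hazard > 0)
    stats::rexp(config$n_samples, rate = config$censor_hazard)
  else rep(Inf, config$n_samples)
  clinical <- data.frame(
    sample = samples,
    os_days = as.integer(ceiling(pmin(death, cens))),
    event = as.integer(death <= cens),
    msi_status = stats::rbinom(config$n_samples, 1L,
                               config$msi_probs[groups]),
    stringsAsFactors = FALSE)

  out <- list(probe_map = pm, genes = genes, profiles = profiles,
              mutations = mutations, network = network, clinical = clinical,
              truth = list(breakpoints = truth_bps,
                           planted_genes = planted,
                           subtype_labels = groups,
                           drivers = drivers,
                           group_hazards = config$group_hazards,
                           modules = modules,
                           mutation_panel = data.frame(
                             gene_id = panel_genes, freq = freqs,
                             stringsAsFactors = FALSE)),
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_probe_map(pm, file.path(out_dir, "probes.tsv"))
    write_genes(genes, file.path(out_dir, "genes.bed"))
    write_segments(profiles, file.path(out_dir, "segments.tsv"))
    write_matrix(mutations, file.path(out_dir, "mutations.tsv"))
    write_network(network, file.path(out_dir, "network.tsv"))
    write_clinical(clinical, file.path(out_dir, "clinical.tsv"))
  }
  out
}
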