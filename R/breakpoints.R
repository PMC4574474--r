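# ---------------------------------------------------------------------------
# CNA-associated chromosomal breakpoints from segmented profiles.
#
# A breakpoint is the boundary between two consecutive segments of one
# chromosome, i.e. the genomic start position of a new copy-number segment.
# The first segment of each chromosome never yields a breakpoint, and
# boundaries flanked by two copy-number neutral segments (both calls 0) are
# excluded.  The true break is only localized to the gap between the last
# probe of the preceding segment and the first probe of the new one
# (~17 kb on the emulated platform), so each breakpoint carries the
# uncertainty interval (position(left_probe), position(right_probe)].
# ---------------------------------------------------------------------------

#' Derive CNA-associated breakpoints from segmented profiles
#'
#' @param profiles a `segmented_profiles` list (see [read_segments]) or a
#'   single per-sample segment `data.frame`.
#' @param pm the [probe_map] the probe indices refer to.
#' @param sample_id sample name used when `profiles` is a single data.frame.
#' @return `data.frame` with one row per breakpoint: `sample`, `chromosome`,
#'   `left_probe`, `right_probe` (= left + 1), `left_call`, `right_call`,
#'   `left_pos`, `right_pos` (bp of the flanking probes).  Sorted by
#'   (sample, chromosome, left_probe).
#' @export
derive_breakpoints <- function(profiles, pm, sample_id = "sample") {
  if (is.data.frame(profiles))
    profiles <- structure(setNames(list(profiles), sample_id),
                          class = "segmented_profiles")
  pos <- split(pm$position, pm$chromosome)
  out <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    s <- names(profiles)[i]
    seg <- profiles[[i]]
    seg <- seg[order(seg$chromosome, seg$start_probe), , drop = FALSE]
    # boundary rows: every segment but the first of its chromosome
    first <- !duplicated(seg$chromosome)
    idx <- which(!first)
    if (!length(idx)) next
    left_call <- seg$call[idx - 1L]
    right_call <- seg$call[idx]
    keep <- !(left_call == 0L & right_call == 0L)
    idx <- idx[keep]
    if (!length(idx)) next
    chr <- seg$chromosome[idx]
    left <- seg$end_probe[idx - 1L]
    right <- seg$start_probe[idx]
    out[[i]] <- data.frame(
      sample = s, chromosome = chr,
      left_probe = left, right_probe = right,
      left_call = seg$call[idx - 1L],
      right_call = seg$call[idx],
      left_pos = as.integer(mapply(function(ch, j) pos[[ch]][j + 1L],
                                   chr, left)),
      right_pos = as.integer(mapply(function(ch, j) pos[[ch]][j + 1L],
                                    chr, right)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(sample = character(), chromosome = character(),
                      left_probe = integer(), right_probe = integer(),
                      left_call = integer(), right_call = integer(),
                      left_pos = integer(), right_pos = integer(),
                      stringsAsFactors = FALSE)
  res <- res[order(res$sample, res$chromosome, res$left_probe), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Index the probes covered by each gene
#'
#' @param genes gene `data.frame` ([read_genes]).
#' @param pm a [probe_map].
#' @return list with `probes` (per gene, 0-based within-chromosome indices of
#'   probes with position inside the gene span, genomic order), `n_probes`,
#'   `span_length` (end - start + 1, bp), `covered_length` (the gene's
#'   length at probe resolution: total bp width of the inter-probe intervals
#'   `(pos_j, pos_j+1]` overlapping the span — the genomic territory within
#'   which a breakpoint is attributable to the gene), `boundaries` (per
#'   gene, the 0-based left-probe indices of those intervals) and
#'   `chromosome`; all named by gene id.
#' @export
gene_probe_index <- function(genes, pm) {
  pos <- split(pm$position, pm$chromosome)
  probes <- boundaries <- vector("list", nrow(genes))
  names(probes) <- names(boundaries) <- genes$gene_id
  covered <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    p <- pos[[genes$chromosome[i]]]
    boundaries[[i]] <- integer()
    if (is.null(p)) { probes[[i]] <- integer(); next }
    j <- which(p >= genes$start[i] & p <= genes$end[i])
    probes[[i]] <- j - 1L
    if (length(p) > 1) {
      ov <- which(p[-length(p)] < genes$end[i] & p[-1L] >= genes$start[i])
      boundaries[[i]] <- ov - 1L   # 0-based left-probe index of the interval
      covered[i] <- sum((p[-1L] - p[-length(p)])[ov])
    }
  }
  list(probes = probes,
       boundaries = boundaries,
       chromosome = setNames(genes$chromosome, genes$gene_id),
       n_probes = vapply(probes, length, integer(1)),
       span_length = setNames(genes$end - genes$start + 1, genes$gene_id),
       covered_length = setNames(covered, genes$gene_id))
}

#' Map breakpoints to genes
#'
#' By default a breakpoint is assigned to every gene whose span overlaps its
#' uncertainty interval `(left_pos, right_pos]` — the break can lie anywhere
#' between the two flanking probes.  `mode = "point"` instead assigns the
#' breakpoint only to genes containing `right_pos` (the genomic start of the
#' new segment).
#'
#' @param bps breakpoint `data.frame` from [derive_breakpoints].
#' @param genes gene `data.frame`.
#' @param pm a [probe_map] (defines the sample-independent probe grid).
#' @param samples optional character vector fixing the sample set (columns);
#'   defaults to the samples present in `bps`.
#' @param mode `"interval"` (default) or `"point"`.
#' @return list with `matrix` (binary genes x samples incidence) and
#'   `probe_sets` (per gene, the character set of supporting
#'   `"chrom:left:right"` probe pairs).  Genes on chromosomes absent from the
#'   probe map keep an all-zero row (with a warning).
#' @export
map_breakpoints_to_genes <- function(bps, genes, pm, samples = NULL,
                                     mode = c("interval", "point")) {
  mode <- match.arg(mode)
  if (is.null(samples)) samples <- unique(bps$sample)
  m <- matrix(0L, nrow = nrow(genes), ncol = length(samples),
              dimnames = list(genes$gene_id, samples))
  probe_sets <- setNames(vector("list", nrow(genes)), genes$gene_id)
  probe_sets[] <- list(character())
  off_map <- setdiff(genes$chromosome, pm$chromosome)
  if (length(off_map))
    warning("gene(s) on chromosome(s) absent from the probe map kept as ",
            "all-zero rows: ", paste(off_map, collapse = ", "))
  for (chr in intersect(unique(genes$chromosome), unique(bps$chromosome))) {
    gi <- which(genes$chromosome == chr)
    bi <- which(bps$chromosome == chr)
    if (!length(gi) || !length(bi)) next
    if (mode == "interval") {
      # interval (left_pos, right_pos] == [left_pos + 1, right_pos] in bp
      q <- IRanges::IRanges(start = bps$left_pos[bi] + 1L,
                            end = bps$right_pos[bi])
    } else {
      q <- IRanges::IRanges(start = bps$right_pos[bi],
                            end = bps$right_pos[bi])
    }
    subj <- IRanges::IRanges(start = genes$start[gi], end = genes$end[gi])
    ov <- IRanges::findOverlaps(q, subj)
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    g <- gi[sh]
    s <- match(bps$sample[bi][qh], samples)
    m[cbind(g, s)] <- 1L
    pair <- sprintf("%s:%d:%d", chr, bps$left_probe[bi][qh],
                    bps$right_probe[bi][qh])
    sp <- split(pair, genes$gene_id[g])
    for (id in names(sp))
      probe_sets[[id]] <- union(probe_sets[[id]], unique(sp[[id]]))
  }
  list(matrix = m, probe_sets = probe_sets)
}

#' Pool genes sharing breakpoint-supporting probes
#'
#' Genes whose breakpoint uncertainty intervals are supported by intersecting
#' probe pairs are indistinguishable at probe resolution; they are merged
#' (transitively) into pools — the connected components of the gene-probe
#' bipartite graph.  A pooled row is the element-wise OR of its members'
#' rows.  Multi-gene pools are named after the alphabetically first (or a
#' user-chosen representative) member with a `"*"` suffix.
#'
#' @param m binary genes x samples matrix.
#' @param probe_sets per-gene supporting probe-pair sets
#'   ([map_breakpoints_to_genes]).
#' @param representative optional named character vector `pool member ->
#'   preferred representative` applied after pooling.
#' @return list with `matrix` (pooled rows) and `registry` (`data.frame`
#'   `pool_id`, `representative`, `members` (comma-separated), `n_members`).
#' @export
pool_shared_probe_genes <- function(m, probe_sets, representative = NULL) {
  genes <- rownames(m)
  probe_sets <- probe_sets[genes]
  all_pairs <- unique(unlist(probe_sets, use.names = FALSE))
  if (length(all_pairs)) {
    edges <- do.call(rbind, lapply(seq_along(genes), function(i) {
      ps <- probe_sets[[i]]
      if (!length(ps)) return(NULL)
      cbind(genes[i], paste0("probe|", ps))  # avoid gene/probe name clashes
    }))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    comp <- igraph::components(g)$membership
    membership <- comp[genes]
    # genes without any supporting probes form their own singleton pools
    iso <- is.na(membership)
    membership[iso] <- max(comp, 0) + seq_len(sum(iso))
  } else {
    membership <- seq_along(genes)
  }
  pools <- split(genes, membership)
  rep_of <- function(members) {
    r <- sort(members)[1L]
    if (!is.null(representative)) {
      hit <- intersect(representative, members)
      if (length(hit)) r <- hit[1L]
    }
    r
  }
  reps <- vapply(pools, rep_of, character(1))
  pool_names <- ifelse(lengths(pools) > 1L, paste0(reps, "*"), reps)
  pooled <- matrix(0L, nrow = length(pools), ncol = ncol(m),
                   dimnames = list(pool_names, colnames(m)))
  for (i in seq_along(pools))
    pooled[i, ] <- as.integer(colSums(m[pools[[i]], , drop = FALSE]) > 0)
  ord <- order(pool_names)
  registry <- data.frame(
    pool_id = pool_names,
    representative = reps,
    members = vapply(pools, function(x) paste(sort(x), collapse = ","),
                     character(1)),
    n_members = lengths(pools),
    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(registry) <- NULL
  list(matrix = pooled[ord, , drop = FALSE], registry = registry)
}

#' Per-row breakpoint prevalence
#'
#' @param m binary features x samples matrix.
#' @return named numeric vector: fraction of samples with an event per row.
#' @export
breakpoint_frequencies <- function(m) {
  if (ncol(m) == 0) stop("matrix has zero samples")
  rowMeans(m)
}

#' Probe-level breakpoint incidence matrix
#'
#' Marks, for each breakpoint, the first probe of the new segment (the
#' genomic start position defining the breakpoint).
#'
#' @param bps breakpoint `data.frame`.
#' @param pm a [probe_map].
#' @param samples optional fixed sample set.
#' @return binary probes x samples matrix (row names = probe ids).
#' @export
probe_breakpoint_matrix <- function(bps, pm, samples = NULL) {
  if (is.null(samples)) samples <- unique(bps$sample)
  m <- matrix(0L, nrow = nrow(pm), ncol = length(samples),
              dimnames = list(pm$probe_id, samples))
  if (nrow(bps)) {
    key_pm <- paste(pm$chromosome,
                    stats::ave(seq_len(nrow(pm)), pm$chromosome,
                               FUN = seq_along) - 1L)
    key_bp <- paste(bps$chromosome, bps$right_probe)
    ri <- match(key_bp, key_pm)
    ci <- match(bps$sample, samples)
    m[cbind(ri, ci)] <- 1L
  }
  m
}
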