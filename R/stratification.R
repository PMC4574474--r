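# ---------------------------------------------------------------------------
# Network-based stratification (NBS) of samples from merged breakpoint and
# mutation events: propagate sparse binary events over a gene-interaction
# network, quantile-normalize across samples, then consensus-cluster with
# graph-regularized non-negative matrix factorization over subsampled
# iterations.  Per-sample network-based gene aberration scores R_s are
# recovered from the factorization by averaging the reconstructions
# V_i = W_i H_i over iterations, normalized by each sample's selection
# count C_s.
# ---------------------------------------------------------------------------

#' Merge two binary event matrices
#'
#' Union of gene sets over the shared samples; a gene present in both (e.g.
#' one acquiring both breakpoints and mutations) gets the element-wise OR of
#' its rows.  Samples present in only one matrix are dropped with a warning;
#' disjoint sample sets are an error.  Samples with no event in any gene are
#' retained but flagged in the `"zero_event_samples"` attribute — NBS drops
#' them before clustering.
#'
#' @param a,b binary genes x samples matrices.
#' @return merged binary matrix.
#' @export
merge_events <- function(a, b) {
  samples <- intersect(colnames(a), colnames(b))
  if (!length(samples)) stop("matrices have disjoint sample sets")
  if (length(samples) < ncol(a) || length(samples) < ncol(b))
    warning("sample sets differ; using the ", length(samples),
            " shared samples")
  genes <- union(rownames(a), rownames(b))
  m <- matrix(0L, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  m[rownames(a), ] <- a[, samples]
  m[rownames(b), ] <- as.integer(m[rownames(b), ] | b[, samples])
  zero <- samples[colSums(m) == 0]
  attr(m, "zero_event_samples") <- zero
  m
}

#' Build a gene network object
#'
#' @param edges edge `data.frame` (`from`, `to`, optional `weight`), or an
#'   `igraph` object.  Self-loops are an error; duplicate edges are summed.
#' @return object of class `gene_network`: `genes`, sparse symmetric
#'   `adjacency`, symmetric degree-normalized `a_norm`
#'   (`D^{-1/2} A D^{-1/2}`), `laplacian` (`D - A`) and `laplacian_norm`
#'   (`I - D^{-1/2} A D^{-1/2}`, the one used by the factorization).
#' @export
gene_network <- function(edges) {
  if (inherits(edges, "igraph")) {
    g <- edges
  } else {
    if (!"weight" %in% names(edges)) edges$weight <- 1
    g <- igraph::graph_from_data_frame(edges[, c("from", "to", "weight")],
                                       directed = FALSE)
  }
  if (any(igraph::which_loop(g))) stop("self-loops are not allowed")
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  if (any(w < 0)) stop("edge weights must be non-negative")
  a <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = TRUE)
  a <- (a + Matrix::t(a)) / 2  # enforce exact symmetry
  deg <- Matrix::rowSums(a)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  a_norm <- Matrix::Diagonal(x = dinv) %*% a %*% Matrix::Diagonal(x = dinv)
  dimnames(a_norm) <- dimnames(a)
  lap <- Matrix::Diagonal(x = deg) - a
  dimnames(lap) <- dimnames(a)
  # normalized Laplacian I - D^{-1/2} A D^{-1/2}: eigenvalues in [0, 2], so
  # the factorization penalty is on the scale of the loadings regardless of
  # network density; this is the Laplacian the NBS step uses
  lap_norm <- Matrix::Diagonal(x = as.numeric(deg > 0)) - a_norm
  dimnames(lap_norm) <- dimnames(a)
  structure(list(genes = rownames(a), adjacency = a, a_norm = a_norm,
                 laplacian = lap, laplacian_norm = lap_norm),
            class = "gene_network")
}

#' Propagate binary events over the gene network
#'
#' Random-walk-with-restart smoothing: iterate
#' `F <- alpha * F %*% A_norm + (1 - alpha) * F0` to its fixed point, where
#' `F0` is the samples x network-genes event matrix and `A_norm` the
#' symmetric degree-normalized adjacency.  For `alpha < 1` the map is a
#' contraction and converges for every input.  Afterwards each sample's
#' smoothed vector is quantile-normalized across samples (rank-mapped to the
#' mean empirical distribution) so that profiles with very different event
#' burdens become comparable.
#'
#' @param events binary genes x samples matrix; genes absent from the
#'   network are dropped (a message reports the count).
#' @param network a [gene_network].
#' @param alpha restart smoothing weight in (0, 1); default 0.7.
#' @param tol fixed-point tolerance on `max |F_new - F|` (default 1e-6).
#' @param max_iter iteration cap.
#' @param quantile_normalize apply the rank-mapping step (default TRUE).
#' @return samples x network-genes numeric matrix; attribute `"residual"`
#'   holds the final fixed-point residual (pre-normalization).
#' @export
propagate <- function(events, network, alpha = 0.7, tol = 1e-6,
                      max_iter = 2000, quantile_normalize = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  shared <- intersect(rownames(events), network$genes)
  if (!length(shared))
    stop("no overlap between event genes and the network")
  dropped <- setdiff(rownames(events), network$genes)
  if (length(dropped))
    message(length(dropped), " event gene(s) absent from the network dropped")
  f0 <- matrix(0, nrow = ncol(events), ncol = length(network$genes),
               dimnames = list(colnames(events), network$genes))
  f0[, shared] <- t(events[shared, , drop = FALSE])
  f <- f0
  a_norm <- network$a_norm
  resid <- Inf
  for (i in seq_len(max_iter)) {
    f_new <- alpha * as.matrix(f %*% a_norm) + (1 - alpha) * f0
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid <= tol) break
  }
  dimnames(f) <- dimnames(f0)
  if (quantile_normalize) {
    dn <- dimnames(f)
    f <- t(limma::normalizeQuantiles(t(f)))
    dimnames(f) <- dn
  }
  attr(f, "residual") <- resid
  f
}

#' Graph-regularized non-negative matrix factorization
#'
#' Minimizes `||V - W H||_F^2 + lambda * tr(H L H^T)` over non-negative
#' `W` (samples x k) and `H` (k x genes) by multiplicative updates, where
#' `L = D - A` is the graph Laplacian on the genes.  The regularizer pulls
#' the gene loadings of network-adjacent genes together.  The objective is
#' non-increasing under the updates; iteration stops when its relative
#' change drops below `tol` or at `max_iter`.
#'
#' @param v non-negative samples x genes matrix.
#' @param laplacian gene-graph Laplacian restricted to `colnames(v)` (order
#'   must match); `NULL` for plain NMF.
#' @param k factorization rank (>= 2, <= min(dim(v))).
#' @param lambda regularization strength (default 1).
#' @param max_iter update cap (default 500).
#' @param tol relative-objective convergence tolerance (default 1e-5).
#' @param seed optional seed for the uniform random initialization.
#' @return list with `w`, `h`, `objective` (trajectory), `iterations`,
#'   `converged`.
#' @export
netnmf <- function(v, laplacian = NULL, k, lambda = 1, max_iter = 500,
                   tol = 1e-5, seed = NULL) {
  if (any(v < 0)) stop("v must be non-negative")
  if (k > min(dim(v))) stop("k exceeds matrix dimensions")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(v); m <- ncol(v)
  eps <- 1e-10
  if (is.null(laplacian)) {
    a <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(m, m))
    d <- a
    lambda <- 0
  } else {
    stopifnot(nrow(laplacian) == m)
    d <- Matrix::Diagonal(x = Matrix::diag(laplacian))
    a <- d - laplacian
  }
  w <- matrix(stats::runif(n * k), n, k)
  h <- matrix(stats::runif(k * m), k, m)
  obj <- function() {
    r <- v - w %*% h
    pen <- if (lambda > 0) lambda * sum((h %*% laplacian) * h) else 0
    sum(r * r) + pen
  }
  # the objective (as costly as one update) is tracked every `stride`
  # updates; convergence is judged on the per-update relative change
  stride <- 10L
  trace <- obj()
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    steps <- min(stride, max_iter - it)
    for (u in seq_len(steps)) {
      w <- w * (v %*% t(h)) / (w %*% tcrossprod(h) + eps)
      num <- crossprod(w, v) + lambda * as.matrix(h %*% a)
      den <- crossprod(w) %*% h + lambda * as.matrix(h %*% d) + eps
      h <- h * num / den
    }
    it <- it + steps
    trace <- c(trace, obj())
    nt <- length(trace)
    rel <- abs(trace[nt - 1L] - trace[nt]) /
      max(abs(trace[nt - 1L]), eps) / steps
    if (rel <= tol) { converged <- TRUE; break }
  }
  list(w = w, h = h, objective = trace, iterations = it,
       converged = converged,
       dimnames = list(rownames(v), colnames(v)))
}

#' NBS configuration
#'
#' @param k number of subtypes (default 4).
#' @param n_iter consensus iterations (default 1000).
#' @param alpha propagation restart weight (default 0.7).
#' @param lambda graph-regularization strength (default 1).
#' @param sample_frac,gene_frac subsample fractions per iteration
#'   (default 0.8).
#' @param seed master RNG seed.
#' @param tol netnmf convergence tolerance (default 1e-5).
#' @param max_iter netnmf update cap (default 500).
#' @param store_factors keep every iteration's `W_i`, `H_i` (memory-heavy;
#'   the streaming score accumulator gives identical `R_s` without it).
#' @return validated list of class `nbs_config`.
#' @export
nbs_config <- function(k = 4, n_iter = 1000, alpha = 0.7, lambda = 1,
                       sample_frac = 0.8, gene_frac = 0.8, seed = 1,
                       tol = 1e-5, max_iter = 500, store_factors = FALSE) {
  stopifnot(k >= 2, n_iter >= 1, alpha > 0, alpha < 1,
            sample_frac > 0, sample_frac <= 1,
            gene_frac > 0, gene_frac <= 1, lambda >= 0)
  structure(list(k = k, n_iter = n_iter, alpha = alpha, lambda = lambda,
                 sample_frac = sample_frac, gene_frac = gene_frac,
                 seed = seed, tol = tol, max_iter = max_iter,
                 store_factors = store_factors),
            class = "nbs_config")
}

#' Consensus clustering of smoothed profiles
#'
#' Runs `n_iter` iterations, each subsampling samples and genes, factorizing
#' the sub-matrix with [netnmf] and assigning each selected sample to the
#' arg-max column of its `W` row (ties to the lowest cluster index).
#' Co-clustering counts normalized by co-selection counts give the
#' sample-similarity matrix; final subtype labels come from average-linkage
#' hierarchical clustering of `1 - similarity` cut into `k` clusters.
#' Reconstruction rows `W_i H_i` are accumulated for [extract_gene_scores].
#'
#' @param smoothed samples x genes non-negative matrix (from [propagate]).
#' @param network a [gene_network] supplying the Laplacian (or `NULL`).
#' @param config an [nbs_config].
#' @return object of class `nbs_run`: `labels` (named integer subtype per
#'   sample, NA for never-selected samples), `similarity`, `coclust`,
#'   `coselect`, `c_s` (selection counts), `v_accum` (running sum of
#'   reconstructions), `factors` (if stored), `config`.
#' @export
consensus_cluster <- function(smoothed, network = NULL, config = nbs_config()) {
  stopifnot(inherits(config, "nbs_config"))
  n <- nrow(smoothed); m <- ncol(smoothed)
  samples <- rownames(smoothed)
  lap_full <- if (!is.null(network)) {
    stopifnot(all(colnames(smoothed) %in% network$genes))
    idx <- match(colnames(smoothed), network$genes)
    network$laplacian_norm[idx, idx, drop = FALSE]
  } else NULL
  set.seed(config$seed)
  iter_seeds <- sample.int(.Machine$integer.max, config$n_iter)
  n_sub <- max(config$k, round(config$sample_frac * n))
  m_sub <- max(config$k, round(config$gene_frac * m))
  coclust <- matrix(0, n, n, dimnames = list(samples, samples))
  coselect <- matrix(0, n, n, dimnames = list(samples, samples))
  c_s <- setNames(numeric(n), samples)
  v_accum <- matrix(0, n, m, dimnames = dimnames(smoothed))
  factors <- if (config$store_factors) vector("list", config$n_iter)
  for (i in seq_len(config$n_iter)) {
    set.seed(iter_seeds[i])
    si <- sort(sample.int(n, n_sub))
    gi <- sort(sample.int(m, m_sub))
    v <- smoothed[si, gi, drop = FALSE]
    if (all(v == 0)) {
      warning("iteration ", i, " skipped: all-zero subsample")
      next
    }
    fit <- netnmf(v, lap_full[gi, gi, drop = FALSE], k = config$k,
                  lambda = config$lambda, max_iter = config$max_iter,
                  tol = config$tol)
    # columns of W carry arbitrary scales (WH is invariant to diagonal
    # rescaling); normalize before the arg-max assignment
    wn <- sweep(fit$w, 2, pmax(colSums(fit$w), 1e-12), "/")
    lab <- max.col(wn, ties.method = "first")
    same <- outer(lab, lab, "==")
    coclust[si, si] <- coclust[si, si] + same
    coselect[si, si] <- coselect[si, si] + 1
    c_s[si] <- c_s[si] + 1
    v_accum[si, gi] <- v_accum[si, gi] + fit$w %*% fit$h
    if (config$store_factors)
      factors[[i]] <- list(samples = si, genes = gi, w = fit$w, h = fit$h)
  }
  similarity <- ifelse(coselect > 0, coclust / pmax(coselect, 1), 0)
  diag(similarity)[c_s > 0] <- 1
  selected <- c_s > 0
  labels <- setNames(rep(NA_integer_, n), samples)
  if (sum(selected) >= config$k) {
    d <- stats::as.dist(1 - similarity[selected, selected, drop = FALSE])
    hc <- stats::hclust(d, method = "average")
    labels[selected] <- stats::cutree(hc, k = config$k)
  }
  structure(list(labels = labels, similarity = similarity,
                 coclust = coclust, coselect = coselect, c_s = c_s,
                 v_accum = v_accum, factors = factors, config = config),
            class = "nbs_run")
}

#' Extract network-based gene aberration scores
#'
#' `R_s = (1 / C_s) * sum_i V_is`, where `V_is` is sample `s`'s row of the
#' iteration-`i` reconstruction `W_i H_i` (zero when `s` was not selected in
#' iteration `i`) and `C_s` is the number of iterations that selected `s`.
#' Uses the streaming accumulator when available; recomputes from stored
#' factors otherwise — both paths give identical scores.
#'
#' @param run an `nbs_run`.
#' @param from `"accumulator"` (default) or `"factors"`; the two routes are
#'   algebraically identical.
#' @return samples x genes numeric matrix; samples never selected have an
#'   all-zero row and are listed in the `"never_selected"` attribute.
#' @export
extract_gene_scores <- function(run, from = c("accumulator", "factors")) {
  from <- match.arg(from)
  if (from == "accumulator" && !is.null(run$v_accum)) {
    v <- run$v_accum
  } else {
    if (is.null(run$factors) || !length(run$factors))
      stop("nbs_run carries no stored factors; rerun with store_factors")
    v <- array(0, dim = dim(run$v_accum), dimnames = dimnames(run$v_accum))
    for (f in run$factors) {
      if (is.null(f)) next
      v[f$samples, f$genes] <- v[f$samples, f$genes] + f$w %*% f$h
    }
  }
  c_s <- run$c_s
  r <- v / ifelse(c_s > 0, c_s, 1)
  r[c_s == 0, ] <- 0
  attr(r, "never_selected") <- names(c_s)[c_s == 0]
  r
}

#' Gene-subtype association by Mann-Whitney U tests
#'
#' For every gene and subtype, a two-sided rank-sum test of the gene's
#' aberration scores in the subtype versus all other samples.
#'
#' @param scores samples x genes score matrix ([extract_gene_scores]).
#' @param subtypes named subtype labels (1..k) per sample.
#' @param adjust `"none"` (default) or `"BH"` — BH across the genes x
#'   subtypes grid is an artifact addition, not part of the original
#'   procedure.
#' @return genes x subtypes matrix of p-values (NA column, with a warning,
#'   for subtypes with fewer than 2 samples on either side).
#' @export
subtype_gene_association <- function(scores, subtypes,
                                     adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  subtypes <- subtypes[rownames(scores)]
  ks <- sort(unique(subtypes[!is.na(subtypes)]))
  out <- matrix(NA_real_, ncol(scores), length(ks),
                dimnames = list(colnames(scores), paste0("subtype", ks)))
  for (j in seq_along(ks)) {
    inside <- !is.na(subtypes) & subtypes == ks[j]
    outside <- !is.na(subtypes) & subtypes != ks[j]
    if (sum(inside) < 2 || sum(outside) < 2) {
      warning("subtype ", ks[j], " has fewer than 2 samples on a side; NA")
      next
    }
    out[, j] <- vapply(seq_len(ncol(scores)), function(g)
      stats::wilcox.test(scores[inside, g], scores[outside, g],
                         alternative = "two.sided", exact = FALSE,
                         correct = TRUE)$p.value,
      numeric(1))
  }
  if (adjust == "BH")
    out[] <- stats::p.adjust(out, method = "BH")
  out
}
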