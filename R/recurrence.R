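# ---------------------------------------------------------------------------
# Recurrence statistics for breakpoint genes.
#
# Three-step test:
#   1. a logistic regression over all (testable gene, profile) pairs gives a
#      gene- and profile-specific baseline probability p_gs of >=1 breakpoint
#      falling in gene g of profile s at random, from the profile's
#      breakpoint burden, the gene's length at probe resolution and its
#      probe count;
#   2. the test statistic T_g is the number of profiles with at least one
#      breakpoint in g; its null is the Poisson-binomial convolution of
#      independent Bernoulli(p_gs) across profiles, and the p-value is the
#      exact tail P0(T_g >= t_obs);
#   3. a discrete Benjamini-Hochberg-type step-up that uses each gene's
#      attainable p-value distribution (the null is discrete and differs per
#      gene) converts p-values to q-values; FDR < 0.1 is the conventional
#      significance call.
# The probe-level variant assumes a uniform breakpoint probability across
# probes, so all probes share one null and standard BH applies.
# ---------------------------------------------------------------------------

#' Poisson-binomial distribution
#'
#' Exact probability mass and upper-tail of a sum of independent Bernoulli
#' variables with heterogeneous success probabilities, via the standard
#' dynamic-programming convolution (numerically stable at cohort scale).
#'
#' @param p numeric vector of success probabilities, each in \[0, 1\].
#' @return `poisson_binomial_pmf`: numeric vector of length `length(p) + 1`
#'   with `P(T = t)` for `t = 0..n`.
#' @export
poisson_binomial_pmf <- function(p) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  poisbinom_pmf_cpp(as.numeric(p))
}

#' @rdname poisson_binomial_pmf
#' @param t integer count (vectorized); `P(T >= t)` is 1 for `t <= 0` and 0
#'   for `t > length(p)`.
#' @export
poisson_binomial_tail <- function(p, t) {
  tails <- pmf_to_tail(poisson_binomial_pmf(p))
  n <- length(p)
  t <- as.integer(t)
  out <- numeric(length(t))
  out[t <= 0] <- 1
  inside <- t >= 1 & t <= n
  out[inside] <- tails[t[inside] + 1L]
  out
}

# tail vector P(T >= t), t = 0..n, from a pmf; guards against tiny negative
# rounding in the cumulative sum
pmf_to_tail <- function(pmf) {
  pmax(rev(cumsum(rev(pmf))), 0)
}

#' Fit the per-gene, per-profile baseline breakpoint probability model
#'
#' One pooled logistic regression over all (testable gene, profile) pairs:
#' response `1{>=1 breakpoint in gene g of profile s}`, covariates
#' `log(n_probes_g + 1)`, `log(covered_length_g)` (the gene's length at
#' probe resolution, see [gene_probe_index]) and `log(B_s + 1)` where
#' `B_s` is the profile's total breakpoint count.  The covered length,
#' rather than the raw bp span, is the length that determines how much
#' breakpoint-attributable territory a gene exposes at inter-probe
#' resolution.  Pooling the profiles with
#' their burden as a covariate yields profile-specific baselines without
#' fitting hundreds of per-profile regressions on sparse events;
#' `per_profile = TRUE` instead fits one regression per profile (gene
#' covariates only) and requires every profile to carry events.
#'
#' Genes without any associated probes cannot harbor a detectable breakpoint
#' and are excluded from the fit; their fitted probability is exactly 0.
#'
#' @param gene_matrix binary genes x samples breakpoint incidence.
#' @param gene_index output of [gene_probe_index] covering the matrix rows.
#' @param bp_counts named per-sample total breakpoint counts `B_s`.
#' @param per_profile fit one regression per profile instead of the pooled
#'   model.
#' @param exclude gene ids left out of the likelihood (but still predicted
#'   from the fitted coefficients).  Used by the two-pass scheme in
#'   [recurrent_breakpoint_genes] to keep genes with established recurrent
#'   signal from inflating the baseline.
#' @return object of class `bp_prob_model`: `p` (genes x samples fitted
#'   probabilities, zero rows for untestable genes), `coefficients`,
#'   `testable`, `untestable`, `converged`, `loglik`, `method`.
#' @export
fit_breakpoint_probability_model <- function(gene_matrix, gene_index,
                                             bp_counts,
                                             per_profile = FALSE,
                                             exclude = character()) {
  genes <- rownames(gene_matrix)
  samples <- colnames(gene_matrix)
  if (length(samples) < 2) stop("need at least 2 samples")
  bp_counts <- bp_counts[samples]
  n_probes <- gene_index$n_probes[genes]
  span <- gene_index$covered_length[genes]
  testable <- genes[n_probes > 0]
  if (length(testable) < 2) stop("need at least 2 testable genes")
  y <- gene_matrix[testable, , drop = FALSE]
  if (sum(y) == 0)
    stop("degenerate fit: no breakpoint events in the cohort; ",
         "use fallback_probability_model()")
  lp <- log(n_probes[testable] + 1)   # varies over rows, constant over cols
  ls <- log(pmax(span[testable], 1))
  lb <- log(bp_counts + 1)            # varies over cols
  p_fit <- matrix(0, nrow = length(genes), ncol = length(samples),
                  dimnames = dimnames(gene_matrix))
  if (!per_profile) {
    x <- cbind(`(Intercept)` = 1,
               log_n_probes = rep(lp, times = length(samples)),
               log_covered = rep(ls, times = length(samples)),
               log_burden = rep(lb, each = length(testable)))
    keep <- rep(!(testable %in% exclude), times = length(samples))
    if (sum(y[keep]) == 0)
      stop("degenerate fit: no breakpoint events left after exclusions")
    fit <- stats::glm.fit(x[keep, , drop = FALSE], as.vector(y)[keep],
                          family = stats::binomial())
    check_degenerate_fit(fit)
    p_fit[testable, ] <- stats::plogis(x %*% stats::coef(fit))
    coefs <- stats::coef(fit)
    se <- sqrt(diag(chol2inv(fit$qr$qr[seq_len(ncol(x)), , drop = FALSE])))
    names(se) <- names(coefs)
    conv <- fit$converged
    ll <- -fit$deviance / 2
  } else {
    coefs <- vector("list", length(samples))
    ll <- 0
    conv <- TRUE
    for (j in seq_along(samples)) {
      if (sum(y[, j]) == 0)
        stop("degenerate fit: profile ", samples[j], " has no events; ",
             "per-profile mode needs events in every profile")
      x <- cbind(`(Intercept)` = 1, log_n_probes = lp, log_covered = ls)
      fit <- stats::glm.fit(x, y[, j], family = stats::binomial())
      check_degenerate_fit(fit)
      p_fit[testable, j] <- fit$fitted.values
      coefs[[j]] <- stats::coef(fit)
      ll <- ll - fit$deviance / 2
      conv <- conv && fit$converged
    }
    names(coefs) <- samples
  }
  structure(list(p = p_fit, coefficients = coefs,
                 se = if (!per_profile) se, testable = testable,
                 untestable = setdiff(genes, testable), converged = conv,
                 loglik = ll,
                 method = if (per_profile) "logistic_per_profile"
                          else "logistic_pooled"),
            class = "bp_prob_model")
}

check_degenerate_fit <- function(fit) {
  eps <- 1e-10
  if (!fit$converged ||
      all(fit$fitted.values > 1 - eps | fit$fitted.values < eps))
    stop("degenerate fit (separation or non-convergence); ",
         "use fallback_probability_model()")
  invisible(fit)
}

#' Closed-form fallback baseline probability model
#'
#' A uniform-placement null requiring no fitting: each of profile `s`'s
#' `B_s` breakpoints falls on one of the `N` inter-probe boundaries uniformly
#' at random, so a gene overlapped by `n_intervals_g` boundaries escapes all
#' of them with probability `(1 - B_s / N)^{n_intervals_g}`.  Intended for
#' cohorts where the logistic fit is degenerate; the model is flagged via
#' `method = "uniform_fallback"`.
#'
#' @param genes gene `data.frame`.
#' @param pm a [probe_map].
#' @param bp_counts named per-sample breakpoint counts.
#' @return a `bp_prob_model`.
#' @export
fallback_probability_model <- function(genes, pm, bp_counts) {
  pos <- split(pm$position, pm$chromosome)
  n_boundaries <- sum(vapply(pos, function(p) length(p) - 1L, integer(1)))
  n_int <- vapply(seq_len(nrow(genes)), function(i) {
    p <- pos[[genes$chromosome[i]]]
    if (is.null(p) || length(p) < 2) return(0L)
    # boundary j spans (p[j], p[j+1]]; overlap with [start, end]
    sum(p[-length(p)] < genes$end[i] & p[-1L] >= genes$start[i])
  }, integer(1))
  names(n_int) <- genes$gene_id
  if (any(bp_counts > n_boundaries))
    stop("a profile has more breakpoints than inter-probe boundaries")
  p_miss <- outer(n_int, bp_counts[names(bp_counts)],
                  function(k, b) (1 - b / n_boundaries)^k)
  p_fit <- 1 - p_miss
  testable <- genes$gene_id[n_int > 0]
  structure(list(p = p_fit, coefficients = NULL, testable = testable,
                 untestable = setdiff(genes$gene_id, testable),
                 converged = TRUE, loglik = NA_real_,
                 method = "uniform_fallback"),
            class = "bp_prob_model")
}

#' Gene-level recurrence test
#'
#' For each candidate gene the observed statistic is the number of profiles
#' with at least one breakpoint in the gene; the p-value is the exact
#' Poisson-binomial upper tail under the fitted per-profile baseline
#' probabilities, and q-values come from the discrete FDR step-up
#' ([discrete_fdr]).
#'
#' @param gene_matrix binary genes (or pools) x samples incidence; rows must
#'   match the model.
#' @param model a `bp_prob_model` fitted on the same cohort.
#' @param candidates `"observed"` (default: genes with >= 1 observed
#'   breakpoint, the candidate breakpoint genes) or `"testable"` (all genes
#'   with probe coverage).  Restricting the tested set to genes with
#'   observed events is a selection on the test statistic, so in
#'   `"observed"` mode both the p-values and the null distributions fed to
#'   the FDR step are conditioned on `T >= 1`
#'   (`P0(T >= t | T >= 1) = P0(T >= t) / P0(T >= 1)`); without this
#'   conditioning the selected nulls are anticonservative and the FDR level
#'   is not held.
#' @param alpha FDR significance level (default 0.1).
#' @return `data.frame` of class `recurrence_table` with columns `gene`,
#'   `n_probes` (NA when unknown), `t_obs`, `prevalence`, `p_value`,
#'   `q_value`, `significant`; attribute `null_cdfs` holds each tested
#'   gene's attainable tail vector (`t = 0..n` unconditional in
#'   `"testable"` mode, `t = 1..n` conditional in `"observed"` mode).
#' @export
gene_recurrence_test <- function(gene_matrix, model,
                                 candidates = c("observed", "testable"),
                                 alpha = 0.1) {
  candidates <- match.arg(candidates)
  genes <- rownames(gene_matrix)
  stopifnot(identical(genes, rownames(model$p)),
            identical(colnames(gene_matrix), colnames(model$p)))
  t_obs <- rowSums(gene_matrix)
  keep <- genes %in% model$testable
  if (candidates == "observed") keep <- keep & t_obs >= 1
  tested <- genes[keep]
  null_cdfs <- vector("list", length(tested))
  names(null_cdfs) <- tested
  p_value <- numeric(length(tested))
  for (i in seq_along(tested)) {
    tails <- pmf_to_tail(poisson_binomial_pmf(model$p[tested[i], ]))
    if (candidates == "observed") {
      # condition on the selection event T >= 1
      tails <- tails[-1L] / tails[2L]
      null_cdfs[[i]] <- tails
      p_value[i] <- tails[t_obs[tested[i]]]
    } else {
      null_cdfs[[i]] <- tails
      p_value[i] <- tails[t_obs[tested[i]] + 1L]
    }
  }
  fdr <- discrete_fdr(p_value, null_cdfs, alpha = alpha)
  out <- data.frame(gene = tested,
                    n_probes = NA_integer_,
                    t_obs = as.integer(t_obs[tested]),
                    prevalence = t_obs[tested] / ncol(gene_matrix),
                    p_value = p_value,
                    q_value = fdr$q_values,
                    significant = fdr$significant,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "null_cdfs") <- null_cdfs
  class(out) <- c("recurrence_table", "data.frame")
  out
}

#' Discrete Benjamini-Hochberg-type FDR correction
#'
#' Step-up correction for hypotheses with heterogeneous *discrete* null
#' distributions.  At a candidate threshold `t` the expected number of null
#' p-values at or below `t` is `sum_g P0(P_g <= t)`, evaluated exactly on
#' each hypothesis's attainable p-value support, giving
#' `FDRhat(t) = sum_g P0(P_g <= t) / max(1, #\{p_g <= t\})`; the q-value of
#' hypothesis `g` is the minimum of `FDRhat` over attainable thresholds
#' `>= p_g`.  When all hypotheses share one null this reduces exactly to the
#' standard Benjamini-Hochberg step-up.
#'
#' @param p_values observed p-values (each attainable under its own null).
#' @param null_cdfs list, one per hypothesis, of the attainable tail
#'   probabilities `P0(T >= t), t = 0..n` (a decreasing vector; its values
#'   are the attainable p-values).
#' @param alpha significance level (default 0.1).
#' @return list with `q_values` and logical `significant` (`q < alpha`).
#' @export
discrete_fdr <- function(p_values, null_cdfs, alpha = 0.1) {
  G <- length(p_values)
  if (length(null_cdfs) != G)
    stop("p_values and null_cdfs lengths differ")
  if (G == 0) return(list(q_values = numeric(), significant = logical()))
  # P0(P_g <= u) is a step function jumping to a at each attainable value a
  ev <- lapply(null_cdfs, function(cdf) sort(unique(cdf)))
  vals <- unlist(ev, use.names = FALSE)
  dels <- unlist(lapply(ev, function(a) diff(c(0, a))), use.names = FALSE)
  o <- order(vals)
  vals <- vals[o]
  cum <- cumsum(dels[o])
  last <- !duplicated(vals, fromLast = TRUE)
  thr <- vals[last]               # unique attainable thresholds, ascending
  num <- cum[last]                # sum_g P0(P_g <= thr)
  denom <- pmax(1, findInterval(thr, sort(p_values)))
  fdr_hat <- num / denom
  q_at_thr <- pmin(1, rev(cummin(rev(fdr_hat))))  # step-up over t >= thr
  idx <- findInterval(p_values, thr)  # observed p is attainable, so exact hit
  q <- q_at_thr[idx]
  list(q_values = q, significant = q < alpha)
}

#' Probe-level recurrence test
#'
#' Assumes the probability of being a breakpoint probe is uniform across
#' probes within a profile: `p_s = B_s / N_probes`.  All probes then share
#' one Poisson-binomial null, and the discrete FDR correction reduces to the
#' standard Benjamini-Hochberg step-up, which is what is applied.
#'
#' @param probe_matrix binary probes x samples incidence
#'   ([probe_breakpoint_matrix]).
#' @param bp_counts named per-sample breakpoint counts `B_s`.
#' @param n_probes number of probes on the array (default `nrow`).
#' @param alpha FDR level.
#' @return `recurrence_table` over probes (all probes reported; the shared
#'   null makes untested rows meaningless to exclude).
#' @export
probe_recurrence_test <- function(probe_matrix, bp_counts,
                                  n_probes = nrow(probe_matrix),
                                  alpha = 0.1) {
  samples <- colnames(probe_matrix)
  bp_counts <- bp_counts[samples]
  if (any(bp_counts > n_probes))
    stop("a profile has more breakpoints than probes")
  p_s <- bp_counts / n_probes
  tails <- pmf_to_tail(poisson_binomial_pmf(p_s))
  t_obs <- rowSums(probe_matrix)
  p_value <- tails[t_obs + 1L]
  q_value <- stats::p.adjust(p_value, method = "BH")
  out <- data.frame(gene = rownames(probe_matrix),
                    n_probes = 1L,
                    t_obs = as.integer(t_obs),
                    prevalence = t_obs / length(samples),
                    p_value = p_value,
                    q_value = q_value,
                    significant = q_value < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "null_cdf") <- tails
  class(out) <- c("recurrence_table", "data.frame")
  out
}
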