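# ---------------------------------------------------------------------------
# Survival and enrichment analyses linking subtypes and gene events to
# outcome: Kaplan-Meier curves with k-group log-rank tests, Cox hazard
# ratios for binary contrasts, a per-gene log-rank screen with Bonferroni
# correction, and Fisher exact enrichment of binary features in subtypes.
# ---------------------------------------------------------------------------

#' Kaplan-Meier curves and log-rank test across groups
#'
#' @param groups named group labels per sample (>= 2 groups, each with >= 1
#'   sample).
#' @param clinical clinical `data.frame` (`sample`, `os_days`, `event`).
#' @return list of class `survival_summary`: `groups` (per group `n`,
#'   `events`, `median_os` — first time the KM curve drops to <= 0.5, NA
#'   while it stays above), `curves` (per group `time`, `surv`, `n_risk`),
#'   `chisq`, `df`, `p_value`.
#' @export
km_logrank <- function(groups, clinical) {
  d <- clinical[match(names(groups), clinical$sample), ]
  if (any(is.na(d$sample))) stop("samples missing from the clinical table")
  g <- factor(unlist(groups))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) == 0)) stop("group with zero samples")
  sv <- survival::Surv(d$os_days, d$event)
  sd <- survival::survdiff(sv ~ g)
  fit <- survival::survfit(sv ~ g)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- lapply(setNames(nm = levels(g)), function(lv) {
    i <- strata == paste0("g=", lv)
    data.frame(time = fit$time[i], surv = fit$surv[i], n_risk = fit$n.risk[i])
  })
  med <- vapply(curves, function(cv) {
    j <- which(cv$surv <= 0.5)
    if (length(j)) cv$time[min(j)] else NA_real_
  }, numeric(1))
  structure(list(
    groups = data.frame(group = levels(g), n = as.vector(table(g)),
                        events = as.vector(tapply(d$event, g, sum)),
                        median_os = med, stringsAsFactors = FALSE),
    curves = curves,
    chisq = sd$chisq, df = length(sd$n) - 1L,
    p_value = stats::pchisq(sd$chisq, length(sd$n) - 1L, lower.tail = FALSE)),
    class = "survival_summary")
}

#' Hazard ratio for a binary grouping
#'
#' Cox proportional-hazards fit with the single binary covariate
#' `group = 1` vs `0`.
#'
#' @param group named 0/1 vector per sample.
#' @param clinical clinical `data.frame`.
#' @return list with `hr`, `ci_lower`, `ci_upper` (95%), `p_value`, `n`.
#' @export
cox_hr <- function(group, clinical) {
  d <- clinical[match(names(group), clinical$sample), ]
  if (any(is.na(d$sample))) stop("samples missing from the clinical table")
  x <- as.integer(unlist(group))
  if (!all(x %in% c(0L, 1L))) stop("group must be binary 0/1")
  ev <- tapply(d$event, x, sum)
  if (length(ev) < 2 || any(ev == 0))
    stop("both groups must contain observed events")
  fit <- survival::coxph(survival::Surv(d$os_days, d$event) ~ x)
  s <- summary(fit)
  list(hr = unname(s$conf.int[1, "exp(coef)"]),
       ci_lower = unname(s$conf.int[1, "lower .95"]),
       ci_upper = unname(s$conf.int[1, "upper .95"]),
       p_value = unname(s$coefficients[1, "Pr(>|z|)"]),
       n = length(x))
}

#' Per-gene survival screen
#'
#' Log-rank test of carriers vs non-carriers for every gene, with Bonferroni
#' correction over the genes actually tested.  Genes with fewer than
#' `min_carriers` carriers (or non-carriers) are skipped with a reason.
#'
#' @param gene_matrix binary genes x samples matrix.
#' @param clinical clinical `data.frame` covering the columns.
#' @param min_carriers minimum group size on each side (default 5).
#' @param level family-wise significance level (default 0.05).
#' @return `data.frame`: `gene`, `n_carriers`, `p_value`,
#'   `p_bonferroni` (capped at 1), `significant`, `skipped`, `reason`.
#' @export
per_gene_survival_screen <- function(gene_matrix, clinical,
                                     min_carriers = 5, level = 0.05) {
  samples <- colnames(gene_matrix)
  d <- clinical[match(samples, clinical$sample), ]
  if (any(is.na(d$sample))) stop("samples missing from the clinical table")
  sv <- survival::Surv(d$os_days, d$event)
  n <- nrow(gene_matrix)
  p <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  carriers <- rowSums(gene_matrix)
  for (i in seq_len(n)) {
    x <- gene_matrix[i, ]
    if (carriers[i] < min_carriers || sum(x == 0) < min_carriers) {
      reason[i] <- sprintf("fewer than %d carriers or non-carriers",
                           min_carriers)
      next
    }
    sd <- survival::survdiff(sv ~ x)
    p[i] <- stats::pchisq(sd$chisq, 1, lower.tail = FALSE)
  }
  tested <- sum(!is.na(p))
  out <- data.frame(gene = rownames(gene_matrix),
                    n_carriers = as.integer(carriers),
                    p_value = p,
                    p_bonferroni = pmin(1, p * tested),
                    skipped = is.na(p),
                    reason = reason,
                    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni < level
  out
}

#' Fisher exact enrichment of a binary feature in a subtype
#'
#' @param feature named 0/1 vector (e.g. MSI status, a gene's events).
#' @param subtype_indicator named 0/1 vector (in subtype vs not), same
#'   samples.
#' @param sided `"two"` (default) or `"one"` (enrichment, i.e. greater).
#' @return list with `table` (2x2, feature x subtype), `odds_ratio`,
#'   `p_value`.  Degenerate margins (a vector constant across samples) give
#'   `p = 1` with a warning.
#' @export
fisher_enrichment <- function(feature, subtype_indicator,
                              sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(length(feature) == length(subtype_indicator))
  keep <- !is.na(feature) & !is.na(subtype_indicator)
  f <- factor(feature[keep], levels = c(1, 0))
  s <- factor(subtype_indicator[keep], levels = c(1, 0))
  tab <- table(feature = f, subtype = s)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin; p set to 1")
    return(list(table = tab, odds_ratio = NA_real_, p_value = 1))
  }
  ft <- stats::fisher.test(tab, alternative = switch(sided,
                                                     two = "two.sided",
                                                     one = "greater"))
  list(table = tab, odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}
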