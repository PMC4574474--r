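test_that("Poisson-binomial tail matches closed forms and the enumeration oracle", {
  expect_equal(poisson_binomial_tail(c(0.5, 0.5, 0.5), 3), 0.125)
  expect_equal(poisson_binomial_tail(runif(5), 0), 1)
  expect_equal(poisson_binomial_tail(c(0.2, 0.9), 3), 0)
  expect_error(poisson_binomial_tail(c(0.5, 1.2), 1), "\\[0, 1\\]")

  set.seed(3)
  p <- runif(12)
  tails <- vapply(0:12, function(t) poisson_binomial_tail(p, t), numeric(1))
  oracle <- vapply(0:12, function(t) enum_poisbinom_tail(p, t), numeric(1))
  expect_equal(tails, oracle, tolerance = 1e-12)
  expect_true(all(diff(tails) <= 1e-15))  # monotone non-increasing in t

  p352 <- runif(352)
  expect_equal(sum(poisson_binomial_pmf(p352)), 1, tolerance = 1e-10)
})

test_that("the pooled logistic fit recovers a known generating law", {
  beta <- c(-4.5, 0.9, 0.25, 0.8)  # intercept, log probes, log length, log burden
  set.seed(19)
  n_g <- 200; n_s <- 100
  covered <- matrix(FALSE, 10, 4)
  for (rep in 1:10) {
    n_probes <- sample(1:30, n_g, TRUE)
    len <- as.numeric(sample(2000:200000, n_g, TRUE))
    b_s <- sample(5:120, n_s, TRUE)
    eta <- beta[1] + beta[2] * log(n_probes + 1) + beta[3] * log(len)
    eta <- outer(eta, beta[4] * log(b_s + 1), "+")
    y <- matrix(rbinom(n_g * n_s, 1, plogis(eta)), n_g,
                dimnames = list(sprintf("g%03d", 1:n_g),
                                sprintf("s%03d", 1:n_s)))
    gi <- list(probes = NULL,
               n_probes = setNames(n_probes, rownames(y)),
               span_length = setNames(len, rownames(y)),
               covered_length = setNames(len, rownames(y)))
    fit <- fit_breakpoint_probability_model(y, gi, setNames(b_s, colnames(y)))
    covered[rep, ] <- abs(fit$coefficients - beta) <= 1.96 * fit$se
    expect_true(all(fit$p[, 1] > 0 & fit$p[, 1] < 1))
    # calibration in the large: mean fitted probability ~ event rate
    expect_equal(mean(fit$p), mean(y), tolerance = 1e-6)
  }
  expect_true(all(colMeans(covered) >= 0.8))
})

test_that("a cohort without events is a degenerate fit, with a working fallback", {
  pm <- toy_probe_map(n = 100)
  genes <- data.frame(gene_id = c("gA", "gB"), chromosome = "1",
                      start = c(5000L, 50000L), end = c(9000L, 70000L),
                      strand = "+", stringsAsFactors = FALSE)
  y <- matrix(0L, 2, 3, dimnames = list(genes$gene_id, c("s1", "s2", "s3")))
  gi <- gene_probe_index(genes, pm)
  expect_error(
    fit_breakpoint_probability_model(y, gi, c(s1 = 0L, s2 = 0L, s3 = 0L)),
    "degenerate")

  fb <- fallback_probability_model(genes, pm, c(s1 = 10L, s2 = 0L, s3 = 50L))
  expect_s3_class(fb, "bp_prob_model")
  expect_true(all(fb$p >= 0 & fb$p < 1))
  expect_equal(unname(fb$p[, "s2"]), c(0, 0)) # no breakpoints, no risk
  # wider gene overlaps more boundaries => higher probability
  expect_gt(fb$p["gB", "s3"], fb$p["gA", "s3"])
  # closed form: 1 - (1 - B/N)^k with N = 99 boundaries
  k_gA <- sum(pm$position[-100] < 9000 & pm$position[-1] >= 5000)
  expect_equal(fb$p["gA", "s1"], 1 - (1 - 10 / 99)^k_gA)
})

test_that("gene recurrence p-values equal direct convolution of the fitted null", {
  set.seed(5)
  n_s <- 5
  p <- matrix(runif(3 * n_s, 0.05, 0.5), 3,
              dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:n_s)))
  model <- structure(list(p = p, testable = rownames(p), untestable = NULL,
                          method = "logistic_pooled"),
                     class = "bp_prob_model")
  y <- matrix(c(1L, 1L, 0L, 0L, 0L,
                1L, 1L, 1L, 1L, 0L,
                0L, 0L, 0L, 0L, 0L), 3, byrow = TRUE,
              dimnames = dimnames(p))
  tab <- gene_recurrence_test(y, model, candidates = "testable")
  for (g in c("g1", "g2", "g3")) {
    t_obs <- sum(y[g, ])
    expect_equal(tab$p_value[tab$gene == g],
                 enum_poisbinom_tail(p[g, ], t_obs), tolerance = 1e-12)
  }
  expect_equal(tab$p_value[tab$gene == "g3"], 1)  # t_obs = 0
  expect_equal(tab$prevalence, c(0.4, 0.8, 0))
})

test_that("discrete FDR reduces to standard BH under a shared null", {
  set.seed(8)
  shared_tail <- pmf_shared <- poisson_binomial_pmf(runif(30, 0.02, 0.2))
  tails <- pmax(rev(cumsum(rev(pmf_shared))), 0)
  t_obs <- sample(0:8, 40, TRUE)
  p <- tails[t_obs + 1]
  fdr <- discrete_fdr(p, replicate(40, tails, simplify = FALSE))
  expect_equal(fdr$q_values, p.adjust(p, method = "BH"), tolerance = 1e-12)

  # single hypothesis: q equals the observed (attainable) p
  one <- discrete_fdr(tails[4], list(tails))
  expect_equal(one$q_values, tails[4])

  expect_error(discrete_fdr(c(0.1, 0.2), list(tails)), "lengths")

  # q monotone non-decreasing in p among heterogeneous nulls
  het <- lapply(1:25, function(i)
    pmax(rev(cumsum(rev(poisson_binomial_pmf(runif(20, 0.01, 0.4))))), 0))
  pv <- vapply(het, function(tl) tl[sample(1:6, 1)], numeric(1))
  q <- discrete_fdr(pv, het)$q_values
  ord <- order(pv)
  expect_true(all(diff(q[ord]) >= -1e-12))
})

test_that("null cohorts give super-uniform p-values and rare discoveries", {
  cfg <- simulation_config(seed = 101, n_samples = 50, n_chromosomes = 4,
                           probes_per_chromosome = 250, n_genes = 300,
                           bg_mean = 15)
  sim <- simulate_cohort(cfg)
  res <- suppressWarnings(
    recurrent_breakpoint_genes(sim$profiles, sim$genes, sim$probe_map))
  p <- res$table$p_value
  for (u in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    mc <- 3 * sqrt(u * (1 - u) / length(p))
    expect_lte(mean(p <= u), u + mc)
  }
})

test_that("planted recurrent genes rank above background genes", {
  cfg <- simulation_config(seed = 55, n_samples = 60, n_chromosomes = 4,
                           probes_per_chromosome = 500, n_genes = 400,
                           bg_mean = 15,
                           planted_genes = data.frame(
                             gene_id = rep(NA_character_, 8),
                             theta = rep(0.15, 8)))
  sim <- simulate_cohort(cfg)
  res <- recurrent_breakpoint_genes(sim$profiles, sim$genes, sim$probe_map)
  planted <- sim$truth$planted_genes$gene_id
  memb <- setNames(strsplit(res$registry$members, ","), res$registry$pool_id)
  is_planted <- vapply(res$table$gene, function(pool)
    any(memb[[pool]] %in% planted), logical(1))
  expect_true(any(is_planted))
  expect_lt(median(res$table$p_value[is_planted]),
            median(res$table$p_value[!is_planted]))
})

test_that("the probe-level test matches hand computation and the discrete FDR", {
  pm <- toy_probe_map(n = 20)
  bps <- data.frame(sample = c("s1", "s1", "s2", "s3", "s4"),
                    chromosome = "1",
                    left_probe = c(4L, 9L, 4L, 4L, 14L),
                    stringsAsFactors = FALSE)
  bps$right_probe <- bps$left_probe + 1L
  pmat <- probe_breakpoint_matrix(bps, pm)
  counts <- setNames(c(2L, 1L, 1L, 1L), c("s1", "s2", "s3", "s4"))
  tab <- probe_recurrence_test(pmat, counts, n_probes = 20)
  p_s <- counts / 20
  # probe 5 (index 4) broken in 3 of 4 profiles
  expect_equal(tab$t_obs[tab$gene == "p_1_005"], 3L)
  expect_equal(tab$p_value[tab$gene == "p_1_005"],
               enum_poisbinom_tail(p_s, 3), tolerance = 1e-12)
  expect_equal(tab$p_value[tab$gene == "p_1_000"], 1)

  # BH on the shared null equals the general discrete correction
  tails <- pmax(rev(cumsum(rev(poisson_binomial_pmf(p_s)))), 0)
  fdr <- discrete_fdr(tab$p_value, replicate(nrow(tab), tails,
                                             simplify = FALSE))
  expect_equal(tab$q_value, fdr$q_values, tolerance = 1e-12)

  # a cohort without breakpoints: every probe p-value is 1
  none <- probe_recurrence_test(pmat * 0L, counts * 0L, n_probes = 20)
  expect_true(all(none$p_value == 1))

  expect_error(probe_recurrence_test(pmat, counts * 100L, n_probes = 20),
               "more breakpoints than probes")
})
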