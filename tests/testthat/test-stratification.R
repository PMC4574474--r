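test_that("event merging ORs shared genes and keeps zero-event samples flagged", {
  bp <- matrix(c(1L, 0L, 0L, 0L, 0L, 0L), 2,
               dimnames = list(c("SMAD4", "FHIT"), c("sA", "sB", "sC")))
  mut <- matrix(c(0L, 1L, 0L), 1, dimnames = list("SMAD4", c("sA", "sB", "sC")))
  m <- merge_events(bp, mut)
  expect_equal(unname(m["SMAD4", ]), c(1L, 1L, 0L))  # breakpoint OR mutation
  expect_equal(attr(m, "zero_event_samples"), "sC")

  # disjoint gene sets concatenate
  mut2 <- matrix(1L, 1, 3, dimnames = list("KRAS", c("sA", "sB", "sC")))
  m2 <- merge_events(bp, mut2)
  expect_setequal(rownames(m2), c("SMAD4", "FHIT", "KRAS"))

  # idempotence
  expect_equal(unname(merge_events(m, m)), unname(m))

  mut3 <- matrix(1L, 1, 1, dimnames = list("KRAS", "sZ"))
  expect_error(merge_events(bp, mut3), "disjoint")
})

test_that("propagation matches the closed-form linear solve on a path graph", {
  edges <- data.frame(from = c("a", "b"), to = c("b", "c"), weight = 1)
  net <- gene_network(edges)
  f0 <- matrix(c(1, 0, 0, 0, 0, 1), 2, 3, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  events <- t(f0)
  alpha <- 0.6
  sm <- propagate(events, net, alpha = alpha, tol = 1e-12,
                  quantile_normalize = FALSE)
  a_norm <- as.matrix(net$a_norm)
  closed <- (1 - alpha) * f0[, net$genes] %*%
    solve(diag(3) - alpha * a_norm)
  expect_equal(unname(as.matrix(sm)), unname(closed), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lte(attr(sm, "residual"), 1e-12)

  # alpha -> 0 limit returns the input
  sm0 <- propagate(events, net, alpha = 1e-9, quantile_normalize = FALSE)
  expect_equal(unname(as.matrix(sm0)), unname(f0[, net$genes]),
               tolerance = 1e-6, ignore_attr = TRUE)

  off <- matrix(1L, 1, 2, dimnames = list("zz", c("s1", "s2")))
  expect_error(propagate(off, net), "no overlap")
})

test_that("netnmf decreases its objective and recovers exact low-rank input", {
  set.seed(21)
  w0 <- matrix(runif(30), 15, 2)
  h0 <- matrix(runif(40), 2, 20)
  v <- w0 %*% h0
  fit <- netnmf(v, NULL, k = 2, lambda = 0, tol = 1e-12, max_iter = 5000,
                seed = 1)
  expect_true(all(diff(fit$objective) <= 1e-8))   # monotone non-increasing
  expect_true(all(fit$w >= 0) && all(fit$h >= 0))
  expect_lte(sum((v - fit$w %*% fit$h)^2), 1e-6)

  expect_error(netnmf(v, NULL, k = 40), "exceeds")
  expect_error(netnmf(-v, NULL, k = 2), "non-negative")

  # regularized: objective still monotone
  edges <- data.frame(from = sprintf("g%d", 1:19), to = sprintf("g%d", 2:20))
  net <- gene_network(edges)
  colnames(v) <- sprintf("g%d", 1:20)
  fit2 <- netnmf(v, net$laplacian_norm, k = 2, lambda = 1, seed = 2,
                 max_iter = 300, tol = 1e-10)
  expect_true(all(diff(fit2$objective) <= 1e-8))
})

test_that("consensus clustering is deterministic and recovers planted blocks", {
  set.seed(9)
  n_per <- 12; k <- 3
  blocks <- rep(1:k, each = n_per)
  base <- matrix(0.05, k, 24)
  for (b in 1:k) base[b, ((b - 1) * 8 + 1):(b * 8)] <- 1
  sm <- base[blocks, ] + matrix(runif(36 * 24, 0, 0.25), 36)
  rownames(sm) <- sprintf("s%02d", 1:36)
  colnames(sm) <- sprintf("g%02d", 1:24)
  cfg <- nbs_config(k = k, n_iter = 40, seed = 13, tol = 1e-7,
                    max_iter = 500)
  run1 <- consensus_cluster(sm, NULL, cfg)
  run2 <- consensus_cluster(sm, NULL, cfg)
  expect_identical(run1$labels, run2$labels)       # seeded reproducibility
  expect_equal(run1$similarity, t(run1$similarity))
  expect_true(all(diag(run1$similarity)[run1$c_s > 0] == 1))
  expect_true(all(run1$similarity >= 0 & run1$similarity <= 1))
  ari <- mclust::adjustedRandIndex(run1$labels, blocks)
  expect_gte(ari, 0.9)
})

test_that("co-clustering accumulation ignores cluster label permutations", {
  set.seed(4)
  lab <- sample(1:4, 30, TRUE)
  perm <- sample(1:4)
  expect_identical(outer(lab, lab, "=="),
                   outer(perm[lab], perm[lab], "=="))
})

test_that("gene scores average the reconstructions over selecting iterations", {
  # three mock iterations over 3 samples x 2 genes; sample 3 never selected
  w1 <- matrix(c(1, 0, 0, 1), 2); h1 <- matrix(c(2, 0, 1, 1), 2)
  w2 <- matrix(c(0.5, 2), 1);    h2 <- matrix(c(1, 0, 0, 3), 2)
  run <- list(
    c_s = c(s1 = 2, s2 = 1, s3 = 0),
    v_accum = matrix(0, 3, 2, dimnames = list(c("s1", "s2", "s3"),
                                              c("gA", "gB"))),
    factors = list(list(samples = 1:2, genes = 1:2, w = w1, h = h1),
                   list(samples = 1L, genes = 1:2, w = matrix(c(0.5, 2), 1),
                        h = h2)),
    coclust = matrix(0, 3, 3))
  v1 <- w1 %*% h1
  v2 <- matrix(c(0.5, 2), 1) %*% h2
  run$v_accum[1:2, ] <- v1
  run$v_accum[1, ] <- run$v_accum[1, ] + v2
  r_acc <- extract_gene_scores(run)
  r_fac <- extract_gene_scores(run, from = "factors")
  expect_equal(r_acc, r_fac)                       # both routes identical
  expect_equal(unname(r_acc["s1", ]), unname((v1[1, ] + v2[1, ]) / 2))
  expect_equal(unname(r_acc["s2", ]), unname(v1[2, ]))  # single-term average
  expect_equal(unname(r_acc["s3", ]), c(0, 0))
  expect_equal(attr(r_acc, "never_selected"), "s3")
})

test_that("subtype-gene association matches a direct rank-sum computation", {
  set.seed(31)
  n1 <- 20; n2 <- 40
  scores <- matrix(rnorm(60 * 3), 60,
                   dimnames = list(sprintf("s%02d", 1:60),
                                   c("flat", "shifted", "flat2")))
  scores[1:n1, "shifted"] <- scores[1:n1, "shifted"] + 5
  subtypes <- setNames(rep(c(1L, 2L), c(n1, n2)), rownames(scores))
  p <- subtype_gene_association(scores, subtypes)
  expect_equal(dim(p), c(3L, 2L))
  expect_lt(p["shifted", "subtype1"], 1e-6)
  expect_gt(p["flat", "subtype1"], 0.05)

  # independent normal-approximation rank-sum oracle (no ties here)
  x <- scores[1:n1, "shifted"]; y <- scores[(n1 + 1):60, "shifted"]
  r <- rank(c(x, y))
  u <- sum(r[1:n1]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sg <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  p_oracle <- 2 * pnorm((abs(u - mu) - 0.5) / sg, lower.tail = FALSE)
  expect_equal(p["shifted", "subtype1"], p_oracle, tolerance = 1e-10)

  # one-sample subtype: both columns degenerate (1 vs 59 and 59 vs 1)
  tiny <- setNames(rep(c(1L, 2L), c(1, 59)), rownames(scores))
  wn <- capture_warnings(p2 <- subtype_gene_association(scores, tiny))
  expect_match(wn, "fewer than 2", all = TRUE)
  expect_true(all(is.na(p2[, "subtype1"])))
})
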