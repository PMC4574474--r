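test_that("breakpoints sit at segment starts, minus the excluded boundaries", {
  pm <- toy_probe_map(n = 40)
  prof <- toy_segments(c(0, 10, 25), c(9, 24, 39), c(0, 1, 0))
  bps <- derive_breakpoints(prof, pm, sample_id = "s1")
  expect_equal(nrow(bps), 2L)
  expect_equal(bps$left_probe, c(9L, 24L))
  expect_equal(bps$right_probe, c(10L, 25L))
  expect_equal(bps$left_pos, c(10000L, 25000L))

  # neutral-neutral boundary excluded even when log2 means differ
  flat <- toy_segments(c(0, 10), c(9, 39), c(0, 0), log2 = c(-0.05, 0.07))
  expect_equal(nrow(derive_breakpoints(flat, pm)), 0L)

  # single segment: the chromosome's first segment never yields a breakpoint
  single <- toy_segments(0, 39, -1)
  expect_equal(nrow(derive_breakpoints(single, pm)), 0L)

  empty <- as_profiles()
  expect_equal(nrow(derive_breakpoints(empty, pm)), 0L)
})

test_that("per chromosome, k segments yield at most k - 1 breakpoints", {
  pm <- toy_probe_map(n = 60)
  set.seed(42)
  for (rep in 1:20) {
    n_seg <- sample(2:8, 1)
    cuts <- sort(sample(1:59, n_seg - 1))
    starts <- c(0L, cuts)
    ends <- c(cuts - 1L, 59L)
    calls <- sample(c(-2L, -1L, 0L, 1L, 2L), n_seg, replace = TRUE)
    prof <- toy_segments(starts, ends, calls)
    bps <- derive_breakpoints(prof, pm)
    nn <- sum(calls[-n_seg] == 0 & calls[-1] == 0)
    expect_equal(nrow(bps), (n_seg - 1L) - nn)
  }
})

test_that("interval mapping equals the all-pairs brute force", {
  set.seed(7)
  pm <- toy_probe_map(chroms = c("1", "2"), n = 50, spacing = 1000L)
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:50),
    chromosome = sample(c("1", "2"), 50, TRUE),
    start = sample(1:45000, 50), stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(500:8000, 50)
  genes$strand <- "+"
  bps <- data.frame(
    sample = sample(sprintf("s%d", 1:5), 30, TRUE),
    chromosome = sample(c("1", "2"), 30, TRUE),
    left_probe = sample(0:48, 30, TRUE), stringsAsFactors = FALSE)
  bps$right_probe <- bps$left_probe + 1L
  bps$left_pos <- (bps$left_probe + 1L) * 1000L
  bps$right_pos <- bps$left_pos + 1000L
  mapped <- map_breakpoints_to_genes(bps, genes, pm,
                                     samples = sprintf("s%d", 1:5))
  brute <- matrix(0L, nrow(genes), 5,
                  dimnames = list(genes$gene_id, sprintf("s%d", 1:5)))
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(bps))) {
    same_chr <- genes$chromosome[i] == bps$chromosome[j]
    overlap <- genes$start[i] <= bps$right_pos[j] &&
      genes$end[i] >= bps$left_pos[j] + 1L
    if (same_chr && overlap) brute[i, bps$sample[j]] <- 1L
  }
  expect_identical(mapped$matrix, brute)
})

test_that("point-mode mapping flags only genes containing the right probe", {
  pm <- toy_probe_map(n = 40, spacing = 1000L)
  bps <- data.frame(sample = "s1", chromosome = "1", left_probe = 9L,
                    right_probe = 10L, left_pos = 10000L, right_pos = 11000L,
                    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("in_interval", "at_point", "outside"),
                      chromosome = "1",
                      start = c(10200L, 10900L, 20000L),
                      end = c(10800L, 11500L, 30000L),
                      strand = "+", stringsAsFactors = FALSE)
  interval <- map_breakpoints_to_genes(bps, genes, pm)
  point <- map_breakpoints_to_genes(bps, genes, pm, mode = "point")
  expect_equal(unname(interval$matrix[, 1]), c(1L, 1L, 0L))
  expect_equal(unname(point$matrix[, 1]), c(0L, 1L, 0L))
})

test_that("pooling merges genes sharing breakpoint probes, transitively", {
  m <- matrix(c(1L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 1L), 3,
              dimnames = list(c("B", "A", "C"), c("s1", "s2", "s3")))
  probe_sets <- list(B = c("1:17:18"), A = c("1:17:18"), C = c("1:30:31"))
  pooled <- pool_shared_probe_genes(m, probe_sets)
  expect_setequal(pooled$registry$pool_id, c("A*", "C"))
  expect_equal(pooled$registry$members[pooled$registry$pool_id == "A*"],
               "A,B")
  expect_equal(unname(pooled$matrix["A*", ]), c(1L, 1L, 0L))
  expect_equal(unname(pooled$matrix["C", ]), c(0L, 0L, 1L))
})

test_that("pooling equals connected components from a union-find oracle", {
  set.seed(11)
  for (rep in 1:10) {
    n_gene <- 20
    genes <- sprintf("g%02d", seq_len(n_gene))
    pairs <- sprintf("1:%d:%d", 1:8, 2:9)
    probe_sets <- setNames(lapply(seq_len(n_gene), function(i)
      sample(pairs, sample(0:3, 1))), genes)
    m <- matrix(rbinom(n_gene * 4, 1, 0.3), n_gene,
                dimnames = list(genes, sprintf("s%d", 1:4)))
    # some genes have probe sets but all-zero rows; keep consistent anyway
    pooled <- pool_shared_probe_genes(m, probe_sets)

    # union-find over genes joined via shared probe pairs
    parent <- seq_len(n_gene)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (pp in pairs) {
      members <- which(vapply(probe_sets, function(x) pp %in% x, logical(1)))
      if (length(members) > 1)
        for (j in members[-1]) {
          a <- find(members[1]); b <- find(j)
          if (a != b) parent[b] <- a
        }
    }
    roots <- vapply(seq_len(n_gene), find, integer(1))
    oracle <- unname(split(genes, roots))
    got <- unname(lapply(strsplit(pooled$registry$members, ","), sort))
    expect_setequal(lapply(oracle, sort), got)
    # pooling never decreases prevalence (OR-monotonicity)
    prev <- breakpoint_frequencies(m)
    prev_pool <- breakpoint_frequencies(pooled$matrix)
    for (r in seq_len(nrow(pooled$registry))) {
      mem <- strsplit(pooled$registry$members[r], ",")[[1]]
      expect_gte(prev_pool[[pooled$registry$pool_id[r]]], max(prev[mem]))
    }
  }
})

test_that("prevalences and the probe matrix conserve breakpoint counts", {
  m <- matrix(0L, 1, 352, dimnames = list("macro", sprintf("s%03d", 1:352)))
  m[1, 1:144] <- 1L
  expect_equal(unname(breakpoint_frequencies(m)), 144 / 352)
  expect_equal(round(unname(breakpoint_frequencies(m)), 3), 0.409)
  expect_equal(unname(breakpoint_frequencies(m * 0L)), 0)
  expect_error(breakpoint_frequencies(m[, 0, drop = FALSE]), "zero samples")

  pm <- toy_probe_map(n = 40)
  prof <- as_profiles(
    s1 = segments_from_boundaries(c(4, 9, 20), 40),
    s2 = segments_from_boundaries(c(9), 40))
  bps <- derive_breakpoints(prof, pm)
  pmat <- probe_breakpoint_matrix(bps, pm)
  expect_equal(unname(colSums(pmat)), c(3L, 1L))
  expect_equal(sum(pmat[, "s1"]), nrow(bps[bps$sample == "s1", ]))
  # marks exactly the right probe
  expect_equal(pmat["p_1_010", "s2"], 1L)
})
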