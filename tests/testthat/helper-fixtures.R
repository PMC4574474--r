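# Small in-code fixtures shared across test files.

# probe map: `n` probes per chromosome at fixed spacing
toy_probe_map <- function(chroms = "1", n = 40, spacing = 1000L) {
  probe_map(
    probe_id = sprintf("p_%s_%03d", rep(chroms, each = n),
                       rep(seq_len(n) - 1L, length(chroms))),
    chromosome = rep(chroms, each = n),
    position = rep(spacing * seq_len(n), length(chroms)))
}

# one chromosome's segments from vectors of (start, end, call)
toy_segments <- function(starts, ends, calls, chromosome = "1",
                         log2 = 0.35 * calls) {
  data.frame(chromosome = chromosome, start_probe = as.integer(starts),
             end_probe = as.integer(ends), mean_log2 = log2,
             call = as.integer(calls), stringsAsFactors = FALSE)
}

as_profiles <- function(...) {
  structure(list(...), class = "segmented_profiles")
}

# segments for one chromosome built from boundary left-probe indices,
# alternating neutral / non-neutral calls (first segment neutral)
segments_from_boundaries <- function(lefts, n_probes, chromosome = "1") {
  lefts <- sort(unique(as.integer(lefts)))
  starts <- c(0L, lefts + 1L)
  ends <- c(lefts, n_probes - 1L)
  calls <- rep_len(c(0L, 1L), length(starts))
  toy_segments(starts, ends, calls, chromosome)
}

# brute-force Poisson-binomial tail by complete enumeration (oracle, n <= 15)
enum_poisbinom_tail <- function(p, t) {
  n <- length(p)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask)[seq_len(n)])
    if (sum(bits) >= t)
      total <- total + prod(ifelse(bits == 1, p, 1 - p))
  }
  total
}
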