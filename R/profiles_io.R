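#' @useDynLib breakgene, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
NULL

# ---------------------------------------------------------------------------
# Data model and file I/O.
#
# Internal coordinate conventions (all other modules rely on these):
#   * probe positions and gene spans are 1-based, inclusive, in bp;
#   * probe indices are 0-based *within chromosome* and follow genomic order;
#   * call states are integers with 0 = copy-number neutral, negative = loss,
#     positive = gain/amplification (the CGHcall {-2,-1,0,1,2} vocabulary is
#     the expected coding, but any integer coding with 0 = neutral works:
#     downstream only "neutral vs not" matters);
#   * BED input is 0-based half-open and is converted at the boundary.
# ---------------------------------------------------------------------------

#' Construct and validate a probe map
#'
#' A probe map lists the genomic positions of the array probes.  Probes are
#' sorted by (chromosome, position); positions must be strictly increasing
#' within each chromosome and probe ids unique.
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param chromosome character vector of chromosome labels.
#' @param position integer vector of 1-based bp positions.
#' @return A `data.frame` of class `probe_map` with columns `probe_id`,
#'   `chromosome`, `position`, sorted by (chromosome, position).
#' @export
probe_map <- function(probe_id, chromosome, position) {
  pm <- data.frame(probe_id = as.character(probe_id),
                   chromosome = as.character(chromosome),
                   position = as.integer(position),
                   stringsAsFactors = FALSE)
  pm <- pm[order(pm$chromosome, pm$position), , drop = FALSE]
  rownames(pm) <- NULL
  validate_probe_map(pm)
  class(pm) <- c("probe_map", "data.frame")
  pm
}

validate_probe_map <- function(pm) {
  stopifnot(all(c("probe_id", "chromosome", "position") %in% names(pm)))
  if (anyDuplicated(pm$probe_id))
    stop("probe ids must be unique")
  bad <- tapply(pm$position, pm$chromosome, function(p) any(diff(p) <= 0))
  if (any(unlist(bad)))
    stop("probe positions must be strictly increasing within each chromosome")
  invisible(pm)
}

#' Read / write a probe map (TSV with columns probe_id, chromosome, position)
#' @param path file path.
#' @return `read_probe_map`: a [probe_map]. `write_probe_map`: `path`,
#'   invisibly.
#' @export
read_probe_map <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "character", "integer"),
                         stringsAsFactors = FALSE)
  probe_map(d$probe_id, d$chromosome, d$position)
}

#' @rdname read_probe_map
#' @param pm a [probe_map].
#' @export
write_probe_map <- function(pm, path) {
  utils::write.table(as.data.frame(pm)[, c("probe_id", "chromosome", "position")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# per-chromosome probe counts, in the probe map's chromosome order
probe_counts <- function(pm) {
  tab <- table(pm$chromosome)
  setNames(as.integer(tab), names(tab))
}

#' Read segmented, state-called copy-number profiles
#'
#' Parses a SEG-like TSV with columns `sample`, `chromosome`, `start_probe`,
#' `end_probe`, `mean_log2`, `call`.  `start_probe`/`end_probe` are 0-based
#' within-chromosome probe indices, inclusive on both ends.  Each sample's
#' segments must tile every chromosome of the probe map exactly: the first
#' segment starts at probe 0, consecutive segments satisfy
#' `start = previous end + 1`, and the last segment ends at the chromosome's
#' final probe.  Violations raise an error naming the sample and chromosome.
#'
#' @param path path to the segments TSV.
#' @param pm a [probe_map] the indices refer to.
#' @return A named list of per-sample segment `data.frame`s (columns
#'   `chromosome`, `start_probe`, `end_probe`, `mean_log2`, `call`), class
#'   `segmented_profiles`.
#' @export
read_segments <- function(path, pm) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sample", "chromosome", "start_probe", "end_probe",
            "mean_log2", "call")
  if (!all(need %in% names(d)))
    stop("segments file must have columns: ", paste(need, collapse = ", "))
  d$start_probe <- as.integer(d$start_probe)
  d$end_probe <- as.integer(d$end_probe)
  d$call <- as.integer(d$call)
  profiles <- lapply(split(d[setdiff(names(d), "sample")], d$sample),
                     function(x) { rownames(x) <- NULL; x })
  profiles <- profiles[unique(d$sample)]
  out <- structure(profiles, class = "segmented_profiles")
  validate_profiles(out, pm)
  out
}

validate_profiles <- function(profiles, pm) {
  counts <- probe_counts(pm)
  for (s in names(profiles)) {
    seg <- profiles[[s]]
    if (any(seg$start_probe > seg$end_probe))
      stop(sprintf("sample %s: segment with start_probe > end_probe", s))
    for (chr in unique(seg$chromosome)) {
      if (!chr %in% names(counts))
        stop(sprintf("sample %s: chromosome %s absent from probe map", s, chr))
      x <- seg[seg$chromosome == chr, , drop = FALSE]
      x <- x[order(x$start_probe), , drop = FALSE]
      if (x$start_probe[1L] != 0L)
        stop(sprintf("sample %s chromosome %s: first segment must start at probe 0",
                     s, chr))
      if (nrow(x) > 1L &&
          any(x$start_probe[-1L] != x$end_probe[-nrow(x)] + 1L))
        stop(sprintf("sample %s chromosome %s: segments have a gap or overlap",
                     s, chr))
      if (x$end_probe[nrow(x)] != counts[[chr]] - 1L)
        stop(sprintf("sample %s chromosome %s: segments do not cover all %d probes",
                     s, chr, counts[[chr]]))
    }
    missing_chr <- setdiff(names(counts), unique(seg$chromosome))
    if (length(missing_chr))
      stop(sprintf("sample %s: no segments for chromosome(s) %s",
                   s, paste(missing_chr, collapse = ", ")))
  }
  invisible(profiles)
}

#' @rdname read_segments
#' @param profiles a `segmented_profiles` list.
#' @export
write_segments <- function(profiles, path) {
  rows <- lapply(names(profiles), function(s)
    cbind(sample = s, profiles[[s]][, c("chromosome", "start_probe",
                                        "end_probe", "mean_log2", "call")]))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene models from a BED file
#'
#' BED intervals are 0-based half-open; they are converted to the package's
#' 1-based inclusive convention (`start = BED start + 1`, `end = BED end`).
#' The 4th column is the gene id (required, unique); a 6th column, when
#' present, is kept as the strand but ignored by breakpoint mapping.
#'
#' @param path BED4+ file.
#' @return `data.frame` with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @export
read_genes <- function(path) {
  empty <- data.frame(gene_id = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  d <- utils::read.delim(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (nrow(d) == 0) return(empty)
  if (ncol(d) < 4) stop("BED file must have at least 4 columns (BED4)")
  g <- data.frame(gene_id = as.character(d[[4]]),
                  chromosome = as.character(d[[1]]),
                  start = as.integer(d[[2]]) + 1L,
                  end = as.integer(d[[3]]),
                  strand = if (ncol(d) >= 6) as.character(d[[6]]) else "+",
                  stringsAsFactors = FALSE)
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene_id in BED file: ",
         paste(unique(g$gene_id[duplicated(g$gene_id)]), collapse = ", "))
  if (any(g$start > g$end))
    stop("gene with start > end after BED conversion: ",
         paste(g$gene_id[g$start > g$end], collapse = ", "))
  g
}

#' @rdname read_genes
#' @param genes gene `data.frame` as returned by `read_genes`.
#' @export
write_genes <- function(genes, path) {
  bed <- data.frame(genes$chromosome, genes$start - 1L, genes$end,
                    genes$gene_id, 0L, genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a binary event matrix
#'
#' Carrier for gene-breakpoint and gene-mutation incidence: rows are features
#' (genes or probes), columns are samples, entries are 0/1.  The TSV layout is
#' row labels in the first column, sample ids in the header.
#'
#' @param path TSV file path.
#' @return `read_matrix`: an integer matrix with unique row and column names.
#' @export
read_matrix <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d)
  if (length(m)) mode(m) <- "integer"
  else m <- matrix(integer(), nrow = nrow(d), ncol = ncol(d),
                   dimnames = dimnames(d))
  validate_binary_matrix(m)
  m
}

validate_binary_matrix <- function(m) {
  if (is.null(rownames(m)) && nrow(m) > 0)
    stop("matrix must have row labels")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("matrix row/column labels must be unique")
  if (length(m) && !all(m %in% c(0L, 1L)))
    stop("matrix entries must be 0 or 1")
  invisible(m)
}

#' @rdname read_matrix
#' @param m binary integer matrix with row and column names.
#' @export
write_matrix <- function(m, path) {
  validate_binary_matrix(m)
  d <- cbind(feature = rownames(m), as.data.frame(m, check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-interaction network edge list
#'
#' Two-column (plus optional weight) TSV with a header; weights default to 1.
#'
#' @param path edge-list file.
#' @return `data.frame` with columns `from`, `to`, `weight`.
#' @export
read_network <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  out <- data.frame(from = as.character(d[[1]]), to = as.character(d[[2]]),
                    weight = if (ncol(d) >= 3) as.numeric(d[[3]]) else 1,
                    stringsAsFactors = FALSE)
  if (any(out$weight < 0)) stop("negative edge weights are not allowed")
  if (any(out$from == out$to)) stop("self-loops are not allowed")
  out
}

#' @rdname read_network
#' @param edges edge `data.frame` (`from`, `to`, `weight`).
#' @export
write_network <- function(edges, path) {
  utils::write.table(edges[, c("from", "to", "weight")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clinical table
#'
#' One row per sample with overall survival in days (`os_days` >= 0), an
#' event indicator (`event`, 1 = death observed) and a binary `msi_status`
#' (NA allowed).  Extra columns are kept as covariates.
#'
#' @param path TSV file.
#' @return `data.frame` with at least `sample`, `os_days`, `event`,
#'   `msi_status`.
#' @export
read_clinical <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sample", "os_days", "event")
  if (!all(need %in% names(d)))
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$sample)) stop("duplicate sample in clinical table")
  if (any(d$os_days < 0)) stop("os_days must be non-negative")
  if (!all(d$event %in% c(0L, 1L))) stop("event must be 0/1")
  if (!"msi_status" %in% names(d)) d$msi_status <- NA_integer_
  d
}

#' @rdname read_clinical
#' @param clinical clinical `data.frame`.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
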