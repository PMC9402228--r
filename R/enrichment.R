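#' Normalize per-gene chromatin-profiling counts to 1x genome coverage
#'
#' Scales raw read counts so that libraries are comparable at one-fold
#' mean genome coverage (the RPGC convention): normalized = raw *
#' genome_size / total_aligned_bases. The scale factor is 1 when the
#' total aligned bases equal the genome size, and the transform is linear
#' in the raw counts.
#'
#' @param raw_counts non-negative numeric vector (optionally named by
#'   gene).
#' @param total_aligned_bases library size in aligned bases (reads x read
#'   length), positive.
#' @param genome_size genome length in bases, positive.
#' @return data.frame with columns `raw_count`, `normalized`, and
#'   `arcsinh_normalized`.
#' @examples
#' normalize_1x(40, total_aligned_bases = 4e6, genome_size = 1e6)
#' @export
normalize_1x <- function(raw_counts, total_aligned_bases, genome_size) {
  if (!is.numeric(raw_counts) || any(!is.finite(raw_counts)) ||
      any(raw_counts < 0))
    stop("raw_counts must be finite and non-negative")
  if (length(total_aligned_bases) != 1L || !is.finite(total_aligned_bases) ||
      total_aligned_bases <= 0)
    stop("total_aligned_bases must be a single positive number")
  if (length(genome_size) != 1L || !is.finite(genome_size) ||
      genome_size <= 0)
    stop("genome_size must be a single positive number")
  normalized <- raw_counts * (genome_size / total_aligned_bases)
  out <- data.frame(raw_count = raw_counts, normalized = normalized,
                    arcsinh_normalized = arcsinh_transform(normalized))
  if (!is.null(names(raw_counts))) rownames(out) <- names(raw_counts)
  out
}

#' Inverse hyperbolic sine display transform
#'
#' \eqn{\mathrm{arcsinh}(x) = \ln(x + \sqrt{x^2 + 1})}: linear near zero,
#' logarithmic for large values, defined at 0 — the conventional display
#' transform for TPM and coverage-normalized enrichment values.
#'
#' @param x finite numeric vector.
#' @return elementwise arcsinh of `x`.
#' @export
arcsinh_transform <- function(x) {
  if (any(!is.finite(x))) stop("inputs must be finite")
  asinh(x)
}

#' Read a BED interval file as GRanges
#'
#' BED 3+ columns, 0-based half-open coordinates (converted to the
#' 1-based closed convention of GRanges by the importer; overlap lengths
#' are unaffected).
#'
#' @param path BED file path.
#' @return a `GRanges` with interval names when a name column is present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}

#' Associate peaks with genes by fractional overlap
#'
#' A peak is considered to associate with a gene when their overlap
#' covers at least half of the peak's length (boundary inclusive). A
#' peak may associate with several genes; a gene is flagged
#' peak-overlapping when it has at least one association. Strand is
#' ignored.
#'
#' @param peaks,genes `GRanges` objects, or BED-style data.frames with
#'   columns chrom, start, end (0-based half-open) and optionally name.
#' @param min_fraction minimum overlap as a fraction of peak length
#'   (default 0.5, inclusive).
#' @return list with `associations` (data.frame: gene_id, peak_id,
#'   overlap_bp, overlap_fraction_of_peak) and `gene_overlaps_peak`
#'   (named logical over all genes).
#' @export
associate_peaks <- function(peaks, genes, min_fraction = 0.5) {
  peaks <- .as_granges(peaks, "peak")
  genes <- .as_granges(genes, "gene")
  hits <- GenomicRanges::findOverlaps(peaks, genes, ignore.strand = TRUE)
  ov <- GenomicRanges::pintersect(
    peaks[S4Vectors::queryHits(hits)],
    genes[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE
  )
  ov_bp <- GenomicRanges::width(ov)
  frac <- ov_bp / GenomicRanges::width(peaks)[S4Vectors::queryHits(hits)]
  keep <- frac >= min_fraction
  associations <- data.frame(
    gene_id = names(genes)[S4Vectors::subjectHits(hits)][keep],
    peak_id = names(peaks)[S4Vectors::queryHits(hits)][keep],
    overlap_bp = ov_bp[keep],
    overlap_fraction_of_peak = frac[keep],
    stringsAsFactors = FALSE
  )
  flag <- stats::setNames(names(genes) %in% associations$gene_id,
                          names(genes))
  list(associations = associations, gene_overlaps_peak = flag)
}

.as_granges <- function(x, prefix) {
  if (methods::is(x, "GRanges")) {
    gr <- x
  } else if (is.data.frame(x)) {
    cols <- names(x)
    if (!all(c("chrom", "start", "end") %in% cols))
      stop("data.frame intervals need chrom, start, end columns")
    if (any(x$start >= x$end))
      stop("intervals must satisfy start < end (0-based half-open)")
    gr <- GenomicRanges::GRanges(
      seqnames = x$chrom,
      ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
      strand = if ("strand" %in% cols) x$strand else "*"
    )
    if ("name" %in% cols) names(gr) <- x$name
  } else {
    stop("intervals must be GRanges or a BED-style data.frame")
  }
  if (is.null(names(gr)) || any(is.na(names(gr))) ||
      any(names(gr) == ""))
    names(gr) <- paste0(prefix, seq_along(gr))
  gr
}

#' Chi-squared test of regulation vs peak overlap
#'
#' Pearson chi-squared test on the 2x2 contingency table of
#' {regulated, not regulated} x {peak-overlapping, not}, one degree of
#' freedom, Yates continuity correction off by default.
#'
#' @param table2x2 2x2 numeric matrix (or coercible) of non-negative
#'   counts with positive margins.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @examples
#' chisq_overlap_test(matrix(c(30, 10, 10, 30), 2))  # statistic 20
#' @export
chisq_overlap_test <- function(table2x2, correct = FALSE) {
  tab <- as.matrix(table2x2)
  if (!identical(dim(tab), c(2L, 2L)))
    stop("table2x2 must be a 2 x 2 table")
  if (any(!is.finite(tab)) || any(tab < 0))
    stop("cells must be finite and non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has a zero margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}
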