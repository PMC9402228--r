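#' @title Allele-resolved count tables
#' @description
#' An allele count table is a data.frame with one row per gene x replicate
#' and columns `gene_id`, `replicate`, `maternal_count`, `paternal_count`,
#' `sample_role` (embryo | maternal_control | paternal_control) and
#' `assay` (rna | cutrun). Counts may be fractional: quantifiers that
#' distribute multi-mapping reads emit expected counts, and the pipeline
#' keeps the non-rounded values for ratio estimation, rounding down only
#' inside the exact binomial and G tests.
#' @name allele_count_table
NULL

.ASSAYS <- c("rna", "cutrun")
.ROLES <- c("embryo", "maternal_control", "paternal_control")
.COUNT_COLS <- c("gene_id", "replicate", "maternal_count",
                 "paternal_count", "sample_role", "assay")

#' Validate an allele count table
#'
#' Checks column presence, finite non-negative counts, known assay and
#' sample-role labels, and uniqueness of (gene_id, replicate) pairs within
#' each sample role.
#'
#' @param counts data.frame as described in [allele_count_table].
#' @return the validated data.frame, invisibly unchanged.
#' @export
validate_allele_counts <- function(counts) {
  if (!is.data.frame(counts)) stop("counts must be a data.frame")
  missing_cols <- setdiff(.COUNT_COLS, names(counts))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  for (col in c("maternal_count", "paternal_count")) {
    v <- counts[[col]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop(col, " must be finite numeric")
    bad <- which(v < 0)
    if (length(bad))
      stop("negative ", col, " at row ", bad[1L])
  }
  if (!all(counts$assay %in% .ASSAYS))
    stop("unknown assay value; expected one of: ",
         paste(.ASSAYS, collapse = ", "))
  if (!all(counts$sample_role %in% .ROLES))
    stop("unknown sample_role value; expected one of: ",
         paste(.ROLES, collapse = ", "))
  key <- paste(counts$sample_role, counts$gene_id, counts$replicate,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated (gene_id, replicate) pair: gene ",
         counts$gene_id[dup[1L]], ", replicate ",
         counts$replicate[dup[1L]])
  invisible(counts)
}

#' Read an allele-resolved count table from TSV
#'
#' Expects a header line with the columns described in
#' [allele_count_table]. Malformed rows, negative counts, unknown assay
#' labels and duplicated (gene, replicate) pairs raise errors.
#'
#' @param path TSV file path.
#' @param assay optional; when given ("rna" or "cutrun"), every row must
#'   carry this assay label.
#' @return validated data.frame.
#' @export
read_allele_counts <- function(path, assay = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  counts <- utils::read.delim(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE,
                              colClasses = "character")
  missing_cols <- setdiff(.COUNT_COLS, names(counts))
  if (length(missing_cols))
    stop("malformed header in ", path, ": missing ",
         paste(missing_cols, collapse = ", "))
  for (col in c("maternal_count", "paternal_count")) {
    v <- suppressWarnings(as.numeric(counts[[col]]))
    bad <- which(is.na(v) & !is.na(counts[[col]]))
    if (length(bad))
      stop("malformed ", col, " at line ", bad[1L] + 1L, " of ", path)
    counts[[col]] <- v
  }
  if (!is.null(assay)) {
    assay <- match.arg(assay, .ASSAYS)
    off <- which(counts$assay != assay)
    if (length(off))
      stop("assay mismatch at line ", off[1L] + 1L, " of ", path,
           ": expected ", assay)
  }
  validate_allele_counts(counts)
  counts
}

#' Write an allele-resolved count table as TSV
#'
#' @param counts validated count table.
#' @param path output file path.
#' @param digits significant digits for fractional counts (default 6).
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(counts, path, digits = 6) {
  validate_allele_counts(counts)
  out <- counts[.COUNT_COLS]
  out$maternal_count <- signif(out$maternal_count, digits)
  out$paternal_count <- signif(out$paternal_count, digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Maternal ratio from allele counts
#'
#' \eqn{p_m} = maternal / (maternal + paternal), computed on the
#' non-rounded counts. Vectorized; zero totals raise an error (the ratio
#' is undefined).
#'
#' @param maternal,paternal non-negative numeric vectors.
#' @return numeric vector of ratios in \[0,1\].
#' @examples
#' maternal_ratio(75, 25)    # 0.75
#' maternal_ratio(7.8, 2.3)  # 7.8 / 10.1
#' @export
maternal_ratio <- function(maternal, paternal) {
  n_len <- max(length(maternal), length(paternal))
  maternal <- rep_len(as.numeric(maternal), n_len)
  paternal <- rep_len(as.numeric(paternal), n_len)
  if (any(!is.finite(maternal) | !is.finite(paternal) |
          maternal < 0 | paternal < 0))
    stop("counts must be finite and non-negative")
  tot <- maternal + paternal
  if (any(tot <= 0))
    stop("maternal ratio undefined for zero total counts")
  maternal / tot
}

#' Read-depth filter on allele counts
#'
#' RNA-seq mode keeps genes with 50 or more reads in total across all
#' replicates (boundary inclusive). CUT&RUN mode keeps genes with more
#' than 10 total reads in every replicate (strictly more). Totals are the
#' non-rounded maternal + paternal counts.
#'
#' @param counts allele count table (one sample role).
#' @param assay "rna" or "cutrun"; defaults to the table's own label when
#'   unique.
#' @param rna_min_total inclusive minimum summed across replicates
#'   (default 50).
#' @param cutrun_min_per_replicate exclusive per-replicate minimum
#'   (default 10).
#' @return list with `kept` (filtered table) and `dropped` (data.frame of
#'   gene_id + reason).
#' @export
apply_depth_filter <- function(counts, assay = NULL,
                               rna_min_total = 50,
                               cutrun_min_per_replicate = 10) {
  validate_allele_counts(counts)
  if (is.null(assay)) {
    assay <- unique(counts$assay)
    if (length(assay) != 1L)
      stop("table carries multiple assay labels; pass assay explicitly")
  }
  assay <- match.arg(assay, .ASSAYS)
  tot <- counts$maternal_count + counts$paternal_count
  if (assay == "rna") {
    gene_tot <- tapply(tot, counts$gene_id, sum)
    keep_genes <- names(gene_tot)[gene_tot >= rna_min_total]
    reason <- "rna_total_below_50"
  } else {
    gene_min <- tapply(tot, counts$gene_id, min)
    keep_genes <- names(gene_min)[gene_min > cutrun_min_per_replicate]
    reason <- "cutrun_replicate_at_or_below_10"
  }
  all_genes <- unique(counts$gene_id)
  dropped_genes <- setdiff(all_genes, keep_genes)
  list(
    kept = counts[counts$gene_id %in% keep_genes, , drop = FALSE],
    dropped = data.frame(gene_id = dropped_genes,
                         reason = rep(reason, length(dropped_genes)),
                         stringsAsFactors = FALSE)
  )
}

#' Parental-contamination filter from pure-parent control samples
#'
#' A gene is excluded when the maternal control (pure maternal parent) is
#' not completely maternal (\eqn{p_m < 0.95}) or the paternal control
#' (pure paternal parent) is not completely paternal (\eqn{p_m > 0.05}),
#' in each case provided that control measured at least 5 reads for the
#' gene (counts pooled across control replicates). Genes absent from a
#' control table are not excluded by that control.
#'
#' @param counts embryo allele count table.
#' @param maternal_control,paternal_control control count tables (either
#'   may be NULL to skip that criterion).
#' @param min_reads control-read qualifier (default 5, inclusive).
#' @param maternal_min,paternal_max control purity bounds
#'   (defaults 0.95 / 0.05).
#' @return list with `kept` and `excluded` (gene_id + reason).
#' @export
apply_parental_control_filter <- function(counts,
                                          maternal_control = NULL,
                                          paternal_control = NULL,
                                          min_reads = 5,
                                          maternal_min = 0.95,
                                          paternal_max = 0.05) {
  validate_allele_counts(counts)
  flag_impure <- function(control, check) {
    if (is.null(control)) return(character(0))
    validate_allele_counts(control)
    m <- tapply(control$maternal_count, control$gene_id, sum)
    p <- tapply(control$paternal_count, control$gene_id, sum)
    tot <- m + p
    ratio <- ifelse(tot > 0, m / tot, NA_real_)
    enough <- tot >= min_reads
    names(m)[enough & check(ratio)]
  }
  bad_m <- flag_impure(maternal_control, function(r) r < maternal_min)
  bad_p <- flag_impure(paternal_control, function(r) r > paternal_max)
  excluded <- rbind(
    data.frame(gene_id = bad_m,
               reason = rep("maternal_control_impure", length(bad_m)),
               stringsAsFactors = FALSE),
    data.frame(gene_id = bad_p,
               reason = rep("paternal_control_impure", length(bad_p)),
               stringsAsFactors = FALSE)
  )
  list(
    kept = counts[!(counts$gene_id %in% excluded$gene_id), ,
                  drop = FALSE],
    excluded = excluded[excluded$gene_id %in% counts$gene_id, ,
                        drop = FALSE]
  )
}
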