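#' Run the full imprinting classification on a count table
#'
#' End-to-end reproducible run: read (or accept) an allele count table,
#' apply the assay-specific depth filter, optionally the
#' parental-control contamination filter, classify every gene, and write
#' per-gene results, the category summary, dropped/excluded gene lists
#' and a JSON run manifest (thresholds, versions, input checksums) to
#' the output directory. Floats are written at 6 significant digits.
#'
#' @param counts allele count table (data.frame) or path to a counts
#'   TSV.
#' @param out_dir output directory (created if needed); NULL skips all
#'   file output.
#' @param assay "rna" or "cutrun"; defaults to the table's unique label.
#' @param maternal_control,paternal_control optional control tables or
#'   TSV paths.
#' @param scheme an [imprint_scheme()].
#' @return (invisibly when writing) list with `results`, `summary`,
#'   `dropped`, `excluded`, `replicate_tests`, `heterogeneity`,
#'   `manifest`.
#' @export
run_classify <- function(counts, out_dir = NULL, assay = NULL,
                         maternal_control = NULL,
                         paternal_control = NULL,
                         scheme = imprint_scheme()) {
  input_paths <- character(0)
  load_tab <- function(x) {
    if (is.character(x) && length(x) == 1L) {
      input_paths <<- c(input_paths, x)
      read_allele_counts(x)
    } else x
  }
  counts <- load_tab(counts)
  maternal_control <- load_tab(maternal_control)
  paternal_control <- load_tab(paternal_control)
  validate_allele_counts(counts)
  if (is.null(assay)) {
    assay <- unique(counts$assay)
    if (length(assay) != 1L)
      stop("table carries multiple assay labels; pass assay explicitly")
  }
  assay <- match.arg(assay, .ASSAYS)

  depth <- apply_depth_filter(counts, assay)
  ctrl <- apply_parental_control_filter(depth$kept, maternal_control,
                                        paternal_control)
  cls <- classify_imprinting(ctrl$kept, assay, scheme)
  summary_tab <- summarize_categories(cls$results)

  manifest <- list(
    package = "imprintr",
    version = as.character(utils::packageVersion("imprintr")),
    assay = assay,
    alpha = scheme$alpha,
    category_bounds = list(maternal_min = scheme$maternal_min,
                           biased_min = scheme$biased_min),
    depth_filter = list(rna_min_total = 50,
                        cutrun_min_per_replicate = 10),
    control_filter = list(min_reads = 5, maternal_min = 0.95,
                          paternal_max = 0.05),
    heterogeneity_p_threshold = 0.05,
    bonferroni_families = list(
      replicate = "genes testable within each replicate",
      final = "kept genes"),
    final_family_size = cls$final_family_size,
    filter_order = c("depth", "parental_control"),
    n_genes_input = length(unique(counts$gene_id)),
    n_genes_kept = sum(cls$results$kept),
    input_checksums = as.list(tools::md5sum(input_paths))
  )

  out <- list(results = cls$results, summary = summary_tab,
              dropped = depth$dropped, excluded = ctrl$excluded,
              replicate_tests = cls$replicate_tests,
              heterogeneity = cls$heterogeneity, manifest = manifest)
  if (is.null(out_dir)) return(out)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(cls$results, "gene_results.tsv")
  write_tsv(summary_tab, "category_summary.tsv")
  write_tsv(rbind(depth$dropped, ctrl$excluded), "dropped_genes.tsv")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Compare two classification runs (e.g. wild type vs mutant)
#'
#' Tabulates category shares and their deltas, mean final maternal
#' ratios, Cohen's d of the per-gene ratios between the two conditions
#' (with its qualitative band), and optionally the Spearman correlation
#' between paired per-gene metrics on the shared gene set.
#'
#' @param results_a,results_b `results` data.frames from
#'   [run_classify()] / [classify_imprinting()] (or those lists).
#' @param labels length-2 condition names for the report.
#' @param paired_metric optional; when "p_m", computes the Spearman
#'   correlation of final ratios across the genes kept in both runs.
#' @return list with `category_shares` (per-condition percentages and
#'   delta), `mean_p_m`, `cohens_d`, `band`, `spearman_rho` (NA unless
#'   requested), `n_shared_genes`.
#' @export
run_report <- function(results_a, results_b,
                       labels = c("condition_a", "condition_b"),
                       paired_metric = NULL) {
  grab <- function(x) {
    if (is.list(x) && !is.data.frame(x) && !is.null(x$results))
      x$results else x
  }
  a <- grab(results_a); b <- grab(results_b)
  sa <- summarize_categories(a)
  sb <- summarize_categories(b)
  shares <- data.frame(category = imprint_categories(),
                       stringsAsFactors = FALSE)
  shares[[paste0(labels[1], "_percent")]] <- sa$percent[
    match(shares$category, sa$category)]
  shares[[paste0(labels[2], "_percent")]] <- sb$percent[
    match(shares$category, sb$category)]
  shares$delta_percent <- shares[[3]] - shares[[2]]

  pa <- a$final_p_m[a$kept %in% TRUE]
  pb <- b$final_p_m[b$kept %in% TRUE]
  d <- cohens_d(pa, pb)

  shared <- intersect(a$gene_id[a$kept %in% TRUE],
                      b$gene_id[b$kept %in% TRUE])
  if (length(shared) == 0L)
    warning("conditions share no kept genes; paired metrics skipped")
  rho <- NA_real_
  if (!is.null(paired_metric) && length(shared)) {
    paired_metric <- match.arg(paired_metric, "p_m")
    rho <- stats::cor(a$final_p_m[match(shared, a$gene_id)],
                      b$final_p_m[match(shared, b$gene_id)],
                      method = "spearman")
  }
  list(category_shares = shares,
       mean_p_m = stats::setNames(c(mean(pa), mean(pb)), labels),
       cohens_d = d$d, band = d$band, spearman_rho = rho,
       n_shared_genes = length(shared))
}
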