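#' Per-replicate exact binomial tests with Bonferroni correction
#'
#' Runs the two-sided exact binomial test (null 0.5, counts rounded down)
#' for every gene x replicate, Bonferroni-adjusts within each replicate's
#' family (all testable genes in that replicate), and classifies each
#' replicate's non-rounded ratio under the scheme.
#'
#' @param counts allele count table (single sample role).
#' @param scheme an [imprint_scheme()].
#' @return data.frame with one row per gene x replicate: raw and rounded
#'   counts, `p_value`, `p_adjusted`, `significant`, `p_m` (non-rounded
#'   ratio), `category`, `testable`.
#' @export
replicate_tests <- function(counts, scheme = imprint_scheme()) {
  validate_allele_counts(counts)
  bt <- exact_binom_test(counts$maternal_count, counts$paternal_count)
  out <- data.frame(
    gene_id = counts$gene_id,
    replicate = counts$replicate,
    maternal_count = counts$maternal_count,
    paternal_count = counts$paternal_count,
    rounded_maternal = bt$rounded_maternal,
    rounded_paternal = bt$rounded_paternal,
    p_value = bt$p_value,
    testable = bt$testable,
    stringsAsFactors = FALSE
  )
  out$p_adjusted <- NA_real_
  for (rep_id in unique(out$replicate)) {
    idx <- which(out$replicate == rep_id & out$testable)
    if (length(idx))
      out$p_adjusted[idx] <- bonferroni_adjust(out$p_value[idx],
                                               length(idx))
  }
  out$significant <- !is.na(out$p_adjusted) &
    out$p_adjusted < scheme$alpha
  tot <- counts$maternal_count + counts$paternal_count
  out$p_m <- ifelse(tot > 0,
                    counts$maternal_count / tot, NA_real_)
  cat <- classify_ratio(ifelse(is.na(out$p_m), 0.5, out$p_m),
                        out$significant, scheme)
  cat[is.na(out$p_m)] <- NA
  out$category <- cat
  out
}

#' Resolve one gene's replicate tests into a final imprinting call
#'
#' Implements the replicate-consistency rules: genes without significant
#' heterogeneity (G-test p > 0.05) are automatically kept; significantly
#' heterogeneous genes are kept only if every replicate's significance
#' call agrees and every replicate's category is identical (calls taken
#' from Bonferroni-adjusted per-replicate tests). For kept genes the
#' maternal and paternal counts of all replicates are pooled, a final
#' exact binomial test is run on the pooled (floored) counts, and the
#' final ratio is the pooled non-rounded ratio in RNA mode or the mean of
#' the per-replicate ratios in CUT&RUN mode; final significance comes
#' from the pooled-count test in both modes.
#'
#' @param gene_tests rows of [replicate_tests()] for a single gene.
#' @param het result of [g_test_heterogeneity()] for that gene.
#' @param assay "rna" or "cutrun".
#' @param scheme an [imprint_scheme()].
#' @param final_family_size Bonferroni family size for the final pooled
#'   test (the number of kept genes in the calling analysis; default 1 =
#'   no correction, for standalone use).
#' @return one-row data.frame: `gene_id`, `kept`, `final_p_m`,
#'   `p_value`, `p_adjusted`, `significant`, `category`, `flags`
#'   (comma-separated provenance flags).
#' @export
resolve_gene <- function(gene_tests, het, assay,
                         scheme = imprint_scheme(),
                         final_family_size = 1) {
  assay <- match.arg(assay, .ASSAYS)
  gene_id <- unique(gene_tests$gene_id)
  stopifnot(length(gene_id) == 1L)
  flags <- character(0)
  if (!isTRUE(het$testable)) flags <- c(flags, "het_untestable")

  kept <- TRUE
  if (isTRUE(het$heterogeneous)) {
    usable <- gene_tests[gene_tests$testable, , drop = FALSE]
    unanimous <- nrow(usable) > 0L &&
      length(unique(usable$significant)) <= 1L &&
      length(unique(as.character(usable$category))) <= 1L
    kept <- unanimous
    flags <- c(flags,
               if (kept) "heterogeneous_kept" else "heterogeneous_dropped")
  }

  if (!kept) {
    return(data.frame(gene_id = gene_id, kept = FALSE,
                      final_p_m = NA_real_, p_value = NA_real_,
                      p_adjusted = NA_real_, significant = NA,
                      category = factor(NA, levels = imprint_categories()),
                      flags = paste(flags, collapse = ","),
                      stringsAsFactors = FALSE))
  }

  m_pool <- sum(gene_tests$maternal_count)
  p_pool <- sum(gene_tests$paternal_count)
  final_test <- exact_binom_test(m_pool, p_pool)
  p_adj <- if (final_test$testable)
    bonferroni_adjust(final_test$p_value, final_family_size)
  else NA_real_
  significant <- !is.na(p_adj) && p_adj < scheme$alpha

  if (assay == "cutrun") {
    per_rep <- gene_tests$p_m[!is.na(gene_tests$p_m)]
    final_p_m <- mean(per_rep)
    flags <- c(flags, "pooled", "mean_of_replicates")
  } else {
    final_p_m <- maternal_ratio(m_pool, p_pool)
    flags <- c(flags, "pooled")
  }

  data.frame(gene_id = gene_id, kept = TRUE,
             final_p_m = final_p_m,
             p_value = final_test$p_value,
             p_adjusted = p_adj,
             significant = significant,
             category = classify_ratio(final_p_m, significant, scheme),
             flags = paste(flags, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Full per-gene imprinting classification
#'
#' Orchestrates the classification procedure on a (filtered) allele count
#' table: per-replicate exact binomial tests with within-replicate
#' Bonferroni correction, per-gene G-test heterogeneity filtering with
#' the unanimity rescue rule, pooling of kept genes, final pooled exact
#' tests Bonferroni-corrected over the kept-gene family, and category
#' assignment. Depth and parental-control filters are applied beforehand
#' by the caller (see [apply_depth_filter()],
#' [apply_parental_control_filter()] and [run_classify()]).
#'
#' @param counts allele count table (single sample role).
#' @param assay "rna" or "cutrun"; defaults to the table's unique label.
#' @param scheme an [imprint_scheme()].
#' @return list with `results` (one row per gene, see [resolve_gene()]),
#'   `replicate_tests`, and `heterogeneity` (per-gene G-test table).
#' @export
classify_imprinting <- function(counts, assay = NULL,
                                scheme = imprint_scheme()) {
  validate_allele_counts(counts)
  if (is.null(assay)) {
    assay <- unique(counts$assay)
    if (length(assay) != 1L)
      stop("table carries multiple assay labels; pass assay explicitly")
  }
  assay <- match.arg(assay, .ASSAYS)

  tests <- replicate_tests(counts, scheme)
  genes <- unique(tests$gene_id)
  split_tests <- split(tests, tests$gene_id)

  het_list <- lapply(genes, function(g) {
    gt <- split_tests[[g]]
    h <- g_test_heterogeneity(gt$maternal_count, gt$paternal_count)
    data.frame(gene_id = g, G = h$G, df = h$df, p_value = h$p_value,
               heterogeneous = h$heterogeneous, testable = h$testable,
               stringsAsFactors = FALSE)
  })
  het_tab <- do.call(rbind, het_list)
  rownames(het_tab) <- het_tab$gene_id

  # first pass: keep/drop decisions determine the final Bonferroni family
  het_of <- function(g) as.list(het_tab[g, ])
  prelim <- lapply(genes, function(g)
    resolve_gene(split_tests[[g]], het_of(g), assay, scheme,
                 final_family_size = 1))
  kept_genes <- genes[vapply(prelim, function(r) r$kept, logical(1))]
  fam <- max(1L, length(kept_genes))

  results <- do.call(rbind, lapply(genes, function(g)
    resolve_gene(split_tests[[g]], het_of(g), assay, scheme,
                 final_family_size = fam)))
  rownames(results) <- NULL

  list(results = results, replicate_tests = tests,
       heterogeneity = het_tab, assay = assay,
       final_family_size = fam)
}

#' Category composition of an imprinting analysis
#'
#' Counts and percentages of kept genes per category, plus the number of
#' genes per category whose final pooled test significantly deviates from
#' the Mendelian ratio 0.5.
#'
#' @param results the `results` data.frame of [classify_imprinting()] (or
#'   the list itself).
#' @return data.frame with columns `category`, `n`, `percent`,
#'   `n_significant`; zero rows when no genes are kept.
#' @export
summarize_categories <- function(results) {
  if (is.list(results) && !is.data.frame(results) &&
      !is.null(results$results))
    results <- results$results
  kept <- results[results$kept %in% TRUE, , drop = FALSE]
  if (nrow(kept) == 0L) {
    return(data.frame(category = character(0), n = integer(0),
                      percent = numeric(0), n_significant = integer(0),
                      stringsAsFactors = FALSE))
  }
  cat <- factor(as.character(kept$category),
                levels = imprint_categories())
  n <- as.integer(table(cat))
  n_sig <- as.integer(table(cat[kept$significant %in% TRUE]))
  data.frame(category = imprint_categories(), n = n,
             percent = 100 * n / nrow(kept),
             n_significant = n_sig, stringsAsFactors = FALSE)
}
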