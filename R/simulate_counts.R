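#' Configuration for allele-count simulation
#'
#' Describes the generative model for allele-resolved count tables: a
#' mixture over the five bias categories, per-category distributions of
#' the true maternal ratio, a negative-binomial read-depth model, and an
#' optional beta-binomial overdispersion of the allele draws.
#'
#' Defaults emulate a wild-type embryo transcriptome: category mixture
#' (0.25, 0.73, 0.02, 0, 0) over (maternal, maternally biased, unbiased,
#' paternally biased, paternal), 11 replicates; the companion mutant
#' mixture (0.15, 0.47, 0.30, 0.08, 0) is available via
#' `mutant_category_mix()`. True ratios are drawn uniformly inside a
#' trimmed sub-interval of each category so that sampled truths respect
#' the scheme's boundaries.
#'
#' @param n_genes number of genes.
#' @param n_replicates number of replicates (11 for wild-type RNA-seq,
#'   17 for mutant RNA-seq, 2 for CUT&RUN in the emulated study design).
#' @param category_mix numeric length-5 vector of category proportions in
#'   the order of [imprint_categories()], summing to 1.
#' @param ratio_bounds 5 x 2 matrix of per-category \[lower, upper\]
#'   bounds for the true ratio; must lie inside the scheme's intervals.
#' @param depth_mean mean informative reads per gene per replicate.
#' @param depth_dispersion negative-binomial size (shape) parameter of
#'   per-gene x replicate depth; larger = less dispersed.
#' @param overdispersion_rho within-gene between-replicate correlation of
#'   allele draws in \[0, 1); 0 reduces exactly to the binomial.
#' @param assay "rna" or "cutrun".
#' @param seed integer seed.
#' @param scheme an [imprint_scheme()] (defines the category intervals).
#' @return list of class `count_sim_config`.
#' @export
count_sim_config <- function(n_genes = 2000,
                             n_replicates = 11,
                             category_mix = c(0.25, 0.73, 0.02, 0, 0),
                             ratio_bounds = default_ratio_bounds(),
                             depth_mean = 500,
                             depth_dispersion = 5,
                             overdispersion_rho = 0,
                             assay = "rna",
                             seed = 1L,
                             scheme = imprint_scheme()) {
  stopifnot(n_genes >= 1, n_replicates >= 1, depth_mean > 0,
            depth_dispersion > 0)
  if (length(category_mix) != 5L || any(category_mix < 0) ||
      abs(sum(category_mix) - 1) > 1e-9)
    stop("category_mix must be 5 non-negative proportions summing to 1")
  if (!(overdispersion_rho >= 0 && overdispersion_rho < 1))
    stop("overdispersion_rho must lie in [0, 1)")
  assay <- match.arg(assay, .ASSAYS)
  iv <- scheme_intervals(scheme)
  if (!is.matrix(ratio_bounds) || !identical(dim(ratio_bounds), c(5L, 2L)))
    stop("ratio_bounds must be a 5 x 2 matrix")
  for (i in seq_len(5L)) {
    if (ratio_bounds[i, 1] < iv$lower[i] - 1e-12 ||
        ratio_bounds[i, 2] > iv$upper[i] + 1e-12)
      stop("ratio_bounds for ", iv$category[i],
           " fall outside the category interval")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 category_mix = category_mix,
                 ratio_bounds = ratio_bounds,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 overdispersion_rho = overdispersion_rho,
                 assay = assay, seed = as.integer(seed),
                 scheme = scheme),
            class = "count_sim_config")
}

#' Default per-category true-ratio bounds
#'
#' Uniform supports trimmed away from the category boundaries so that a
#' deeply sequenced gene is classifiable to its true category with high
#' probability.
#'
#' @return 5 x 2 numeric matrix (rows in [imprint_categories()] order).
#' @export
default_ratio_bounds <- function() {
  matrix(c(0.96, 1.00,
           0.68, 0.92,
           0.40, 0.60,
           0.08, 0.32,
           0.00, 0.04),
         ncol = 2, byrow = TRUE,
         dimnames = list(imprint_categories(), c("lower", "upper")))
}

#' Category mixture of the emulated mutant condition
#'
#' Proportions (0.15, 0.47, 0.30, 0.08, 0): transcription shifted toward
#' biallelic expression relative to the wild-type mixture.
#'
#' @return numeric length-5 vector.
#' @export
mutant_category_mix <- function() c(0.15, 0.47, 0.30, 0.08, 0)

#' Simulate an allele-resolved count table with known ground truth
#'
#' Each gene draws a category from the configured mixture and a true
#' maternal ratio uniformly inside that category's bounds. Per gene x
#' replicate, total depth is negative-binomial (mean `depth_mean`, size
#' `depth_dispersion`) and the maternal count is binomial — or
#' beta-binomial when `overdispersion_rho > 0`, with the replicate-level
#' success probability drawn from a Beta distribution with mean equal to
#' the true ratio and intra-class correlation rho. Deterministic given
#' the config seed.
#'
#' @param config a [count_sim_config()].
#' @return list with `counts` (allele count table, sample_role "embryo")
#'   and `truth` (gene_id, true_category, true_p_m).
#' @export
simulate_allele_counts <- function(config) {
  stopifnot(inherits(config, "count_sim_config"))
  with_config_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(config$seed)
    code
  }
  with_config_seed({
    ng <- config$n_genes
    nr <- config$n_replicates
    gene_id <- sprintf("gene%05d", seq_len(ng))
    cat_idx <- sample.int(5L, ng, replace = TRUE,
                          prob = config$category_mix)
    lb <- config$ratio_bounds[cat_idx, 1]
    ub <- config$ratio_bounds[cat_idx, 2]
    true_pm <- stats::runif(ng, lb, ub)

    depth <- matrix(stats::rnbinom(ng * nr, mu = config$depth_mean,
                                   size = config$depth_dispersion),
                    nrow = ng)
    rho <- config$overdispersion_rho
    pm_mat <- matrix(rep(true_pm, nr), nrow = ng)
    if (rho > 0) {
      nu <- 1 / rho - 1  # Beta concentration a + b
      a <- pm_mat * nu
      b <- (1 - pm_mat) * nu
      inner <- a > 0 & b > 0  # degenerate at p in {0, 1}
      draw <- pm_mat
      draw[inner] <- stats::rbeta(sum(inner), a[inner], b[inner])
      pm_mat <- draw
    }
    m_mat <- matrix(stats::rbinom(ng * nr, size = as.vector(depth),
                                  prob = as.vector(pm_mat)),
                    nrow = ng)
    p_mat <- depth - m_mat

    counts <- data.frame(
      gene_id = rep(gene_id, nr),
      replicate = rep(sprintf("rep%02d", seq_len(nr)), each = ng),
      maternal_count = as.vector(m_mat),
      paternal_count = as.vector(p_mat),
      sample_role = "embryo",
      assay = config$assay,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(gene_id = gene_id,
                        true_category = imprint_categories()[cat_idx],
                        true_p_m = true_pm,
                        stringsAsFactors = FALSE)
    list(counts = counts, truth = truth)
  })
}

#' Simulate pure-parental control samples
#'
#' Emulates RNA-seq of the pure maternal and paternal parents used to
#' detect contamination: a maternal control emits reads with per-gene
#' maternal fraction `1 - contamination_rate` (symmetrically paternal
#' fraction for the paternal control). Only the genes listed in
#' `contaminated_genes` (default: all genes when the rate is positive)
#' receive contamination; contaminated genes are recorded in the ground
#' truth.
#'
#' @param config a [count_sim_config()]; `n_replicates` is ignored
#'   (controls are single samples), depth model reused.
#' @param contamination_rate fraction in \[0, 0.5).
#' @param contaminated_genes optional character vector of gene ids to
#'   contaminate.
#' @return list with `maternal_control`, `paternal_control` (allele
#'   count tables) and `truth` (gene_id, contaminated).
#' @export
simulate_parental_controls <- function(config, contamination_rate = 0,
                                       contaminated_genes = NULL) {
  stopifnot(inherits(config, "count_sim_config"))
  if (!(contamination_rate >= 0 && contamination_rate < 0.5))
    stop("contamination_rate must lie in [0, 0.5)")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 104729L)  # offset: independent of embryo draws

  ng <- config$n_genes
  gene_id <- sprintf("gene%05d", seq_len(ng))
  if (is.null(contaminated_genes)) {
    contaminated <- rep(contamination_rate > 0, ng)
  } else {
    contaminated <- gene_id %in% contaminated_genes
  }
  rate <- ifelse(contaminated, contamination_rate, 0)

  one_control <- function(role) {
    depth <- stats::rnbinom(ng, mu = config$depth_mean,
                            size = config$depth_dispersion)
    pm <- if (role == "maternal_control") 1 - rate else rate
    m <- stats::rbinom(ng, size = depth, prob = pm)
    data.frame(gene_id = gene_id, replicate = "ctrl01",
               maternal_count = m, paternal_count = depth - m,
               sample_role = role, assay = config$assay,
               stringsAsFactors = FALSE)
  }
  list(maternal_control = one_control("maternal_control"),
       paternal_control = one_control("paternal_control"),
       truth = data.frame(gene_id = gene_id, contaminated = contaminated,
                          stringsAsFactors = FALSE))
}
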