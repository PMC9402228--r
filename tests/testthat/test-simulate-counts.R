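test_that("simulation is reproducible and conserves counts", {
  cfg <- count_sim_config(n_genes = 50, n_replicates = 3, seed = 5L)
  a <- simulate_allele_counts(cfg)
  b <- simulate_allele_counts(cfg)
  expect_identical(a, b)
  expect_true(all(a$counts$maternal_count >= 0))
  expect_true(all(a$counts$paternal_count >= 0))
  expect_equal(nrow(a$counts), 150)
  # true ratios respect their category's interval
  iv <- scheme_intervals()
  for (i in seq_len(nrow(a$truth))) {
    row <- iv[iv$category == a$truth$true_category[i], ]
    expect_gte(a$truth$true_p_m[i], row$lower)
    expect_lte(a$truth$true_p_m[i], row$upper)
  }
})

test_that("degenerate maternal mixture yields near-pure maternal ratios", {
  cfg <- count_sim_config(n_genes = 200, n_replicates = 2,
                          category_mix = c(1, 0, 0, 0, 0),
                          depth_mean = 1000, seed = 2L)
  sim <- simulate_allele_counts(cfg)
  tot <- sim$counts$maternal_count + sim$counts$paternal_count
  ratio <- sim$counts$maternal_count[tot > 0] / tot[tot > 0]
  expect_gt(mean(ratio >= 0.95), 0.99)
})

test_that("an unbiased gene draws symmetric allele counts", {
  bounds <- default_ratio_bounds()
  bounds["unbiased", ] <- c(0.5, 0.5)
  cfg <- count_sim_config(n_genes = 400, n_replicates = 4,
                          category_mix = c(0, 0, 1, 0, 0),
                          ratio_bounds = bounds, depth_mean = 200,
                          seed = 3L)
  sim <- simulate_allele_counts(cfg)
  m <- sum(sim$counts$maternal_count)
  n <- sum(sim$counts$maternal_count + sim$counts$paternal_count)
  se <- sqrt(0.25 / n)
  expect_lt(abs(m / n - 0.5), 3 * se)
})

test_that("category frequencies follow the configured mixture at 3 sigma", {
  mix <- c(0.25, 0.73, 0.02, 0, 0)
  cfg <- count_sim_config(n_genes = 4000, n_replicates = 1,
                          category_mix = mix, seed = 9L)
  sim <- simulate_allele_counts(cfg)
  freq <- table(factor(sim$truth$true_category,
                       levels = imprint_categories())) / 4000
  for (i in 1:5) {
    se <- sqrt(mix[i] * (1 - mix[i]) / 4000)
    expect_lte(abs(freq[[i]] - mix[i]), 3 * se + 1e-12)
  }
})

test_that("beta-binomial overdispersion inflates between-replicate spread", {
  base <- count_sim_config(n_genes = 300, n_replicates = 8,
                           category_mix = c(0, 1, 0, 0, 0),
                           depth_mean = 400, seed = 21L)
  over <- count_sim_config(n_genes = 300, n_replicates = 8,
                           category_mix = c(0, 1, 0, 0, 0),
                           depth_mean = 400,
                           overdispersion_rho = 0.3, seed = 21L)
  spread <- function(sim) {
    tot <- sim$counts$maternal_count + sim$counts$paternal_count
    r <- sim$counts$maternal_count / tot
    mean(tapply(r, sim$counts$gene_id, var), na.rm = TRUE)
  }
  expect_gt(spread(simulate_allele_counts(over)),
            2 * spread(simulate_allele_counts(base)))
})

test_that("invalid configurations are rejected", {
  expect_error(count_sim_config(category_mix = c(0.5, 0.5, 0.5, 0, 0)),
               "summing to 1")
  expect_error(count_sim_config(overdispersion_rho = 1), "rho")
  bad_bounds <- default_ratio_bounds()
  bad_bounds["maternal", 1] <- 0.5
  expect_error(count_sim_config(ratio_bounds = bad_bounds), "interval")
})

test_that("pure parental controls are pure at zero contamination", {
  cfg <- count_sim_config(n_genes = 100, seed = 4L)
  ctrl <- simulate_parental_controls(cfg, contamination_rate = 0)
  m <- ctrl$maternal_control
  tot <- m$maternal_count + m$paternal_count
  expect_true(all(m$paternal_count == 0))
  expect_true(all(m$maternal_count[tot > 0] / tot[tot > 0] == 1))
  p <- ctrl$paternal_control
  expect_true(all(p$maternal_count == 0))
  expect_false(any(ctrl$truth$contaminated))
})

test_that("contamination shifts control ratios by the configured rate", {
  cfg <- count_sim_config(n_genes = 500, depth_mean = 100, seed = 6L)
  ctrl <- simulate_parental_controls(cfg, contamination_rate = 0.2)
  m <- ctrl$maternal_control
  tot <- m$maternal_count + m$paternal_count
  pat_frac <- sum(m$paternal_count) / sum(tot)
  expect_lt(abs(pat_frac - 0.2), 0.02)
  expect_true(all(ctrl$truth$contaminated))
})

test_that("contaminated genes with enough control reads are excluded downstream", {
  cfg <- count_sim_config(n_genes = 50, depth_mean = 100, seed = 8L)
  sim <- simulate_allele_counts(cfg)
  ctrl <- simulate_parental_controls(cfg, contamination_rate = 0.2,
                                     contaminated_genes = "gene00001")
  res <- apply_parental_control_filter(sim$counts,
                                       ctrl$maternal_control,
                                       ctrl$paternal_control)
  mc <- ctrl$maternal_control
  row <- mc[mc$gene_id == "gene00001", ]
  tot <- row$maternal_count + row$paternal_count
  if (tot >= 5 && row$maternal_count / tot < 0.95) {
    expect_true("gene00001" %in% res$excluded$gene_id)
  }
  expect_false(any(setdiff(sim$counts$gene_id, "gene00001") %in%
                     res$excluded$gene_id))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_allele_counts(count_sim_config(n_genes = 10,
                                                    seed = 1L)))
  expect_identical(.Random.seed, before)
})
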