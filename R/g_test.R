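#' G-test for replicate heterogeneity of allele counts
#'
#' Likelihood-ratio test of homogeneity of the maternal/paternal split
#' across replicates of one gene: \eqn{G = 2 \sum O \ln(O/E)} over the
#' replicates x {maternal, paternal} contingency table, with expected
#' counts from the pooled margins. Zero observed cells contribute 0.
#' Counts are rounded down to integers (consistent with the exact test's
#' round-down rule); replicates whose rounded total is 0 are excluded and
#' the degrees of freedom reduced accordingly. No Williams correction is
#' applied. The p-value comes from the chi-squared distribution with
#' (usable replicates - 1) degrees of freedom; a gene is called
#' heterogeneous when p <= 0.05 (unadjusted).
#'
#' With fewer than 2 usable replicates the gene is untestable and treated
#' as non-heterogeneous, flagged via `testable = FALSE`.
#'
#' @param maternal,paternal numeric vectors of per-replicate counts for
#'   one gene (equal length).
#' @param p_threshold heterogeneity call threshold on the unadjusted
#'   p-value (default 0.05).
#' @return list with `G`, `df`, `p_value`, `heterogeneous`, `testable`,
#'   `n_replicates_used`.
#' @examples
#' g_test_heterogeneity(c(10, 0), c(0, 10))   # G = 40 log 2, heterogeneous
#' g_test_heterogeneity(c(50, 50), c(50, 50)) # G = 0
#' @export
g_test_heterogeneity <- function(maternal, paternal, p_threshold = 0.05) {
  if (length(maternal) != length(paternal))
    stop("maternal and paternal must have equal length")
  m <- floor(as.numeric(maternal))
  p <- floor(as.numeric(paternal))
  if (any(!is.finite(m) | !is.finite(p) | m < 0 | p < 0))
    stop("counts must be finite and non-negative")
  tot <- m + p
  use <- tot > 0
  m <- m[use]; p <- p[use]; tot <- tot[use]
  r <- length(tot)
  if (r < 2L) {
    return(list(G = NA_real_, df = NA_integer_, p_value = NA_real_,
                heterogeneous = FALSE, testable = FALSE,
                n_replicates_used = r))
  }
  grand <- sum(tot)
  pm_pool <- sum(m) / grand
  e_m <- tot * pm_pool
  e_p <- tot * (1 - pm_pool)
  term <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  G <- 2 * sum(term(m, e_m) + term(p, e_p))
  G <- max(G, 0)  # guard tiny negative round-off
  df <- r - 1L
  pv <- stats::pchisq(G, df = df, lower.tail = FALSE)
  list(G = G, df = df, p_value = pv,
       heterogeneous = pv <= p_threshold, testable = TRUE,
       n_replicates_used = r)
}
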