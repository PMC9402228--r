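#' Exact binomial test against Mendelian expression
#'
#' Two-sided exact binomial test of the maternal read count against the
#' null of equal parental contribution (success probability 0.5).
#' Fractional counts (e.g. expected counts from probabilistic read
#' assignment) are rounded down to integers before testing; the maternal
#' ratio itself is always estimated from the non-rounded counts elsewhere.
#'
#' The two-sided p-value is the minimum-likelihood sum: the total
#' probability of all outcomes no more likely than the observed one. Under
#' the symmetric 0.5 null this equals the two-tail sum
#' \eqn{\min(1,\ 2 P(X \le \min(k, n-k)))} with
#' \eqn{X \sim \mathrm{Binomial}(n, 0.5)}, which is how it is computed
#' (vectorized, closed form).
#'
#' @param maternal,paternal non-negative numeric vectors of allele-resolved
#'   read counts (recycled to common length).
#' @return data.frame with columns `rounded_maternal`, `rounded_paternal`,
#'   `n` (rounded total), `p_value`, and `testable` (FALSE where the
#'   rounded total is 0; such cases carry `p_value = NA` and are flagged,
#'   not errors).
#' @examples
#' exact_binom_test(10, 0)$p_value      # 2 * 0.5^10
#' exact_binom_test(7.8, 2.3)           # tests (7, 2), n = 9
#' @export
exact_binom_test <- function(maternal, paternal) {
  n_len <- max(length(maternal), length(paternal))
  maternal <- rep_len(as.numeric(maternal), n_len)
  paternal <- rep_len(as.numeric(paternal), n_len)
  if (any(!is.finite(maternal) | !is.finite(paternal) |
          maternal < 0 | paternal < 0))
    stop("counts must be finite and non-negative")
  k <- floor(maternal)
  j <- floor(paternal)
  n <- k + j
  m <- pmin(k, j)
  p <- pmin(1, 2 * stats::pbinom(m, n, 0.5))
  testable <- n >= 1
  p[!testable] <- NA_real_
  data.frame(rounded_maternal = k, rounded_paternal = j, n = n,
             p_value = p, testable = testable)
}

#' Bonferroni adjustment over an explicit family size
#'
#' Multiplies each p-value by the family size and caps at 1. The family
#' size may exceed the number of p-values supplied (e.g. when a subset of
#' a per-replicate family is adjusted).
#'
#' @param p numeric vector of p-values (NA passed through).
#' @param family_size positive integer, at least `sum(!is.na(p))`.
#' @return adjusted p-values, same length as `p`.
#' @export
bonferroni_adjust <- function(p, family_size = sum(!is.na(p))) {
  if (length(family_size) != 1L || !is.finite(family_size) ||
      family_size < 1)
    stop("family_size must be a single integer >= 1")
  if (family_size < sum(!is.na(p)))
    stop("family_size smaller than the number of tests supplied")
  pmin(1, p * family_size)
}

#' Cohen's d standardized mean difference with qualitative band
#'
#' \eqn{d = (\bar a - \bar b)/s_p} with the pooled standard deviation
#' \eqn{s_p^2 = ((n_a-1)s_a^2 + (n_b-1)s_b^2)/(n_a+n_b-2)}. Bands follow
#' the conventional cutpoints: |d| < 0.2 no effect, < 0.5 small, < 0.8
#' medium, otherwise large (boundaries assigned to the larger band).
#'
#' @param a,b numeric vectors, each of length >= 2 with finite variance.
#' @return list with elements `d` and `band`.
#' @export
cohens_d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples must have length >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("samples must be finite")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop("pooled standard deviation is zero; d undefined")
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  band <- if (abs(d) < 0.2) "no effect"
          else if (abs(d) < 0.5) "small"
          else if (abs(d) < 0.8) "medium"
          else "large"
  list(d = d, band = band)
}
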