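#' Five-category maternal-ratio classification scheme
#'
#' Builds the category scheme used to classify the maternal ratio \eqn{p_m}
#' of a gene (fraction of allele-informative reads of maternal origin).
#' Significant genes are binned as: maternal (\eqn{p_m \ge 0.95}),
#' maternally biased (\eqn{0.65 \le p_m < 0.95}), unbiased
#' (\eqn{0.35 < p_m < 0.65}), paternally biased
#' (\eqn{0.05 < p_m \le 0.35}) and paternal (\eqn{p_m \le 0.05}).
#' Non-significant genes are always classed as unbiased. The five intervals
#' tile \[0,1\] exactly under the stated open/closed boundaries.
#'
#' @param maternal_min lower (closed) bound of the maternal category.
#' @param biased_min lower (closed) bound of the maternally biased category;
#'   by symmetry `1 - biased_min` is the upper (closed) bound of the
#'   paternally biased category.
#' @param alpha significance level applied to Bonferroni-adjusted p-values.
#' @return An object of class `imprint_scheme`.
#' @examples
#' sc <- imprint_scheme()
#' classify_ratio(c(0.99, 0.7, 0.5, 0.2, 0.01), TRUE, sc)
#' @export
imprint_scheme <- function(maternal_min = 0.95, biased_min = 0.65,
                           alpha = 0.05) {
  stopifnot(is.numeric(maternal_min), is.numeric(biased_min),
            is.numeric(alpha), length(alpha) == 1L)
  if (!(0.5 < biased_min && biased_min < maternal_min && maternal_min <= 1))
    stop("require 0.5 < biased_min < maternal_min <= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  structure(
    list(maternal_min = maternal_min, biased_min = biased_min, alpha = alpha),
    class = "imprint_scheme"
  )
}

#' Ordered category levels of the classification scheme
#'
#' @return Character vector of the five categories, maternal first.
#' @export
imprint_categories <- function() {
  c("maternal", "maternally_biased", "unbiased", "paternally_biased",
    "paternal")
}

#' Classify maternal ratios into bias categories
#'
#' Bins significant maternal ratios by the scheme's intervals;
#' non-significant cases are classed as unbiased regardless of the ratio.
#'
#' @param p_m numeric vector of maternal ratios in \[0,1\].
#' @param significant logical vector (recycled) of significance calls from
#'   Bonferroni-adjusted exact binomial tests.
#' @param scheme an [imprint_scheme()].
#' @return factor with levels [imprint_categories()].
#' @export
classify_ratio <- function(p_m, significant, scheme = imprint_scheme()) {
  stopifnot(inherits(scheme, "imprint_scheme"))
  p_m <- as.numeric(p_m)
  if (any(!is.finite(p_m) | p_m < 0 | p_m > 1))
    stop("p_m values must lie in [0, 1]")
  significant <- rep_len(as.logical(significant), length(p_m))
  hi <- scheme$maternal_min
  lo <- scheme$biased_min
  cat <- ifelse(p_m >= hi, "maternal",
         ifelse(p_m >= lo, "maternally_biased",
         ifelse(p_m > 1 - lo, "unbiased",
         ifelse(p_m > 1 - hi, "paternally_biased", "paternal"))))
  cat[!significant] <- "unbiased"
  factor(cat, levels = imprint_categories())
}

#' Interval bounds of each category
#'
#' Returns the \[lower, upper\] bounds of the scheme's five intervals with
#' their open/closed status, mainly for simulation (drawing true ratios
#' inside a category) and documentation.
#'
#' @param scheme an [imprint_scheme()].
#' @return data.frame with columns category, lower, upper,
#'   lower_closed, upper_closed.
#' @export
scheme_intervals <- function(scheme = imprint_scheme()) {
  hi <- scheme$maternal_min
  lo <- scheme$biased_min
  data.frame(
    category = imprint_categories(),
    lower = c(hi, lo, 1 - lo, 1 - hi, 0),
    upper = c(1, hi, lo, 1 - lo, 1 - hi),
    lower_closed = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    upper_closed = c(TRUE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}
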