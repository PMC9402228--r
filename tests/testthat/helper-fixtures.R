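# shared fixture builders; everything is generated in code at test time

make_counts <- function(gene_id, replicate, maternal, paternal,
                        role = "embryo", assay = "rna") {
  data.frame(gene_id = gene_id, replicate = replicate,
             maternal_count = maternal, paternal_count = paternal,
             sample_role = role, assay = assay,
             stringsAsFactors = FALSE)
}

# counts table for one gene across replicates
gene_counts <- function(maternal, paternal, gene = "g1", assay = "rna") {
  make_counts(gene, sprintf("rep%02d", seq_along(maternal)),
              maternal, paternal, assay = assay)
}

# brute-force minimum-likelihood two-sided exact binomial p-value
oracle_binom_p <- function(k, n, p0 = 0.5) {
  pmf <- stats::dbinom(0:n, n, p0)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

# textbook Pearson chi-square statistic
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# exhaustive plateau search: same d_thr schedule, runs found by scanning
# every candidate window
oracle_plateau <- function(diffs, min_len = 7, start_factor = 0.1,
                           growth = 2) {
  d_thr <- mean(diffs) * start_factor
  repeat {
    best <- NULL
    for (s in seq_along(diffs)) {
      for (e in s:length(diffs)) {
        if (all(diffs[s:e] <= d_thr)) {
          len <- e - s + 1L
          if (is.null(best) || len > best$len)
            best <- list(start = s, end = e, len = len)
        }
      }
    }
    if (!is.null(best) && best$len >= min_len)
      return(list(plateau_start = best$start,
                  plateau_end = best$end + 1L,
                  center_index = (best$start + best$end + 1L) %/% 2L,
                  d_thr = d_thr))
    d_thr <- d_thr * growth
  }
}

# solid ellipsoid fixture volume with given interior/exterior values
ellipsoid_volume <- function(dim3 = c(16, 24, 24), semi = c(5, 8, 8),
                             inside = 100, outside = 10) {
  ctr <- (dim3 + 1) / 2
  z <- (seq_len(dim3[1]) - ctr[1]) / semi[1]
  y <- (seq_len(dim3[2]) - ctr[2]) / semi[2]
  x <- (seq_len(dim3[3]) - ctr[3]) / semi[3]
  mask <- outer(outer(z^2, y^2, `+`), x^2, `+`) <= 1
  vol <- array(outside, dim3)
  vol[mask] <- inside
  list(volume = vol, mask = mask)
}
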