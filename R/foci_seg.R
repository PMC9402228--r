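#' Segment heterochromatic foci inside a nucleus by k-means thresholding
#'
#' Runs 1-D k-means on the channel intensities of the voxels inside the
#' nucleus mask. For single-valued data, classification in k classes
#' specifies k-1 threshold values (midpoints between adjacent sorted
#' cluster centers); the foci mask is the volume thresholded at the
#' highest of these, restricted to the nucleus. Connected components are
#' then size-filtered: only the largest foci, bigger than
#' `size_fraction` (default 20%) of the nucleus size, are kept. Size is
#' measured on maximum-intensity-projection areas by default (the same
#' convention the nucleus size curve uses); set
#' `size_measure = "voxels"` for 3D voxel counts.
#'
#' k-means is initialized at deterministic intensity quantiles, so
#' results are reproducible without a seed.
#'
#' @param volume numeric 3D array (z, y, x) of the channel to segment.
#' @param nucleus a `nucleus_segmentation` or logical 3D mask.
#' @param k number of classes, 2, 3 (default) or 4.
#' @param size_fraction minimum focus size as a fraction of nucleus size
#'   (strictly bigger; default 0.20).
#' @param size_measure "projection" (default) or "voxels".
#' @param connectivity component connectivity (default 26).
#' @return list of class `foci_segmentation`: `foci_mask` (kept union),
#'   `labels` (kept components relabeled 1..n), `n_foci`,
#'   `components` (data.frame: id, voxels, projected_area, size, kept),
#'   `class_thresholds` (ascending), `threshold` (the one applied),
#'   `k`, `size_fraction`, `size_measure`, `nucleus_size`,
#'   `adjust_iterations`.
#' @export
segment_foci <- function(volume, nucleus, k = 3, size_fraction = 0.20,
                         size_measure = c("projection", "voxels"),
                         connectivity = 26) {
  size_measure <- match.arg(size_measure)
  nucleus_mask <- if (inherits(nucleus, "nucleus_segmentation"))
    nucleus$mask else nucleus > 0
  stopifnot(identical(dim(volume), dim(nucleus_mask)))
  if (!any(nucleus_mask)) stop("nucleus mask is empty")
  if (!(k %in% 2:4)) stop("k must be 2, 3 or 4")
  x <- volume[nucleus_mask]
  if (length(unique(x)) < k)
    stop("degenerate clustering: fewer than k distinct intensities ",
         "inside the nucleus")
  thresholds <- .kmeans_thresholds(x, k)
  .build_foci(volume, nucleus_mask, threshold = max(thresholds),
              class_thresholds = thresholds, k = k,
              size_fraction = size_fraction, size_measure = size_measure,
              connectivity = connectivity, adjust_iterations = 0L)
}

# deterministic 1-D Lloyd k-means: quantile initialization, ties to the
# lowest-index center, empty clusters reseeded at the costliest point.
# Noise-free synthetic volumes produce few distinct intensities, which
# breaks generic k-means initializations (duplicate centers, empty
# clusters); this specialized routine handles them and needs no seed.
.kmeans_lloyd_1d <- function(x, k, max_iter = 200) {
  centers <- stats::quantile(x, probs = (seq_len(k) * 2 - 1) / (2 * k),
                             names = FALSE)
  for (iter in seq_len(max_iter)) {
    dist2 <- vapply(centers, function(c) (x - c)^2, numeric(length(x)))
    assign <- max.col(-dist2, ties.method = "first")
    empty <- setdiff(seq_len(k), unique(assign))
    if (length(empty)) {
      # reseed empty clusters at the costliest points, one point each
      cost_order <- order(dist2[cbind(seq_along(x), assign)],
                          decreasing = TRUE)
      for (j in seq_along(empty)) {
        worst <- cost_order[j]
        centers[empty[j]] <- x[worst]
        assign[worst] <- empty[j]
      }
    }
    new_centers <- vapply(seq_len(k), function(j) mean(x[assign == j]),
                          numeric(1))
    if (max(abs(new_centers - centers)) < 1e-10) {
      centers <- new_centers
      break
    }
    centers <- new_centers
  }
  centers
}

.kmeans_thresholds <- function(x, k) {
  cs <- sort(.kmeans_lloyd_1d(x, k))
  (cs[-length(cs)] + cs[-1]) / 2
}

.build_foci <- function(volume, nucleus_mask, threshold,
                        class_thresholds, k, size_fraction,
                        size_measure, connectivity, adjust_iterations) {
  raw <- (volume > threshold) & nucleus_mask
  cc <- label_components_3d(raw, connectivity)
  nucleus_size <- if (size_measure == "projection")
    .mip_area(nucleus_mask) else sum(nucleus_mask)
  comp <- data.frame(id = integer(0), voxels = integer(0),
                     projected_area = integer(0), size = numeric(0),
                     kept = logical(0))
  labels <- array(0L, dim(volume))
  kept_ids <- integer(0)
  if (cc$n > 0L) {
    voxels <- cc$sizes
    projected <- vapply(seq_len(cc$n), function(i)
      .mip_area(cc$labels == i), numeric(1))
    size <- if (size_measure == "projection") projected else voxels
    kept <- size > size_fraction * nucleus_size
    comp <- data.frame(id = seq_len(cc$n), voxels = voxels,
                       projected_area = projected, size = size,
                       kept = kept)
    kept_ids <- comp$id[kept]
    for (j in seq_along(kept_ids))
      labels[cc$labels == kept_ids[j]] <- j
  }
  structure(list(foci_mask = labels > 0L, labels = labels,
                 n_foci = length(kept_ids), components = comp,
                 class_thresholds = class_thresholds,
                 threshold = threshold, k = k,
                 size_fraction = size_fraction,
                 size_measure = size_measure,
                 nucleus_size = nucleus_size,
                 adjust_iterations = adjust_iterations),
            class = "foci_segmentation")
}

#' Adjust a foci segmentation toward an expected focus count
#'
#' When the base segmentation found too few foci, the intensity
#' threshold and the minimum size fraction are both repeatedly
#' multiplied by a coefficient < 1 (decreasing the threshold and the
#' expected focus size) until the desired number of foci is reached or
#' the iteration cap is hit. When it found too many or oversized foci,
#' classification in four classes is used instead, which raises the
#' highest threshold and shrinks the foci; if that still leaves too few,
#' the multiplicative loop is applied on top.
#'
#' @param volume channel 3D array.
#' @param nucleus a `nucleus_segmentation` or logical mask.
#' @param target_n_foci integer in 1..3.
#' @param base `foci_segmentation` to adjust (returned unchanged, with 0
#'   recorded iterations, when already at the target).
#' @param coefficient multiplicative shrink factor (default 0.9).
#' @param max_iterations iteration cap (default 25).
#' @return a `foci_segmentation` achieving the target count, with
#'   `adjust_iterations` recorded.
#' @export
adjust_foci <- function(volume, nucleus, target_n_foci, base,
                        coefficient = 0.9, max_iterations = 25) {
  stopifnot(inherits(base, "foci_segmentation"))
  if (!(target_n_foci %in% 1:3)) stop("target_n_foci must lie in 1..3")
  if (!(coefficient > 0 && coefficient < 1))
    stop("coefficient must lie in (0, 1)")
  nucleus_mask <- if (inherits(nucleus, "nucleus_segmentation"))
    nucleus$mask else nucleus > 0

  current <- base
  current$adjust_iterations <- 0L
  if (current$n_foci == target_n_foci) return(current)

  iterations <- 0L
  if (current$n_foci > target_n_foci && current$k < 4) {
    current <- segment_foci(volume, nucleus_mask, k = 4,
                            size_fraction = base$size_fraction,
                            size_measure = base$size_measure)
    iterations <- 1L
    current$adjust_iterations <- iterations
    if (current$n_foci == target_n_foci) return(current)
  }

  thr <- current$threshold
  sf <- current$size_fraction
  best <- current
  while (iterations < max_iterations) {
    iterations <- iterations + 1L
    thr <- thr * coefficient
    sf <- sf * coefficient
    current <- .build_foci(volume, nucleus_mask, threshold = thr,
                           class_thresholds = base$class_thresholds,
                           k = base$k, size_fraction = sf,
                           size_measure = base$size_measure,
                           connectivity = 26,
                           adjust_iterations = iterations)
    if (abs(current$n_foci - target_n_foci) <
        abs(best$n_foci - target_n_foci)) best <- current
    if (current$n_foci == target_n_foci) return(current)
  }
  cond <- structure(
    class = c("foci_adjustment_failure", "error", "condition"),
    list(message = paste0("could not reach ", target_n_foci,
                          " foci within ", max_iterations,
                          " iterations (best attempt: ", best$n_foci,
                          " foci)"),
         call = sys.call(-1), best_attempt = best))
  stop(cond)
}

#' Overlap statistics between foci, a signal domain and the nucleus
#'
#' Computes the fraction of channel signal contained within the foci
#' (intensity-weighted: summed intensity over foci / summed intensity
#' over the nucleus, plus a binary-mask variant), the fraction of foci
#' area contained within the signal domain, and the fraction of nucleus
#' area covered by foci.
#'
#' @param signal_volume channel 3D intensity array.
#' @param foci `foci_segmentation` or logical mask (intersected with the
#'   nucleus).
#' @param signal_domain `foci_segmentation` or logical mask of the
#'   signal's own domains (e.g. H3K27me3 domains), or NULL to skip
#'   `foci_in_domain`.
#' @param nucleus `nucleus_segmentation` or logical mask.
#' @return list with `signal_in_foci` (intensity-weighted),
#'   `signal_in_foci_binary` (fraction of the signal domain's area
#'   inside foci; NA without a domain), `foci_in_domain` (NA when the
#'   foci mask is empty or no domain is given), `foci_area_fraction`.
#' @export
overlap_fractions <- function(signal_volume, foci, signal_domain,
                              nucleus) {
  as_mask <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "foci_segmentation")) x$foci_mask
    else if (inherits(x, "nucleus_segmentation")) x$mask
    else x > 0
  }
  nucleus_mask <- as_mask(nucleus)
  foci_mask <- as_mask(foci) & nucleus_mask
  domain_mask <- as_mask(signal_domain)
  stopifnot(identical(dim(signal_volume), dim(nucleus_mask)))
  if (!any(nucleus_mask)) stop("nucleus mask is empty")

  total_signal <- sum(signal_volume[nucleus_mask])
  signal_in_foci <- if (total_signal > 0)
    sum(signal_volume[foci_mask]) / total_signal else NA_real_

  # binary variant: fraction of the signal's own domain area inside foci
  signal_in_foci_binary <- NA_real_
  if (!is.null(domain_mask) && any(domain_mask))
    signal_in_foci_binary <- sum(domain_mask & foci_mask) /
      sum(domain_mask)

  foci_in_domain <- NA_real_
  if (!is.null(domain_mask) && any(foci_mask))
    foci_in_domain <- sum(foci_mask & domain_mask) / sum(foci_mask)

  list(signal_in_foci = signal_in_foci,
       signal_in_foci_binary = signal_in_foci_binary,
       foci_in_domain = foci_in_domain,
       foci_area_fraction = sum(foci_mask) / sum(nucleus_mask))
}
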