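#' Size curve of a 3D stack over an adaptive threshold sequence
#'
#' Thresholds the DAPI volume at a sequence of `n_thresholds` equally
#' spaced intensity values spanning a clearly-too-low to clearly-too-high
#' range (by default the 2nd to 99.8th intensity percentiles, robust to
#' hot pixels), computes the maximum intensity projection of each 3D
#' mask, and records the projected mask area at each threshold. For a
#' nucleus image the curve decreases rapidly, crosses a wide plateau
#' where only the nucleus survives, and decays in a tail at high
#' thresholds.
#'
#' @param volume numeric 3D array (z, y, x), non-constant.
#' @param n_thresholds number of thresholds (default 20).
#' @param probs length-2 percentile bounds of the threshold range.
#' @return list of class `size_curve` with `thresholds` (ascending),
#'   `mip_sizes` (non-increasing projected areas) and `diffs` (absolute
#'   neighbor differences).
#' @export
build_size_curve <- function(volume, n_thresholds = 20,
                             probs = c(0.02, 0.998)) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L,
            n_thresholds >= 2)
  if (any(!is.finite(volume))) stop("volume must be finite")
  q <- stats::quantile(volume, probs = probs, names = FALSE)
  if (diff(q) <= 0)
    stop("degenerate input: volume is (near-)constant over the ",
         "threshold range")
  thresholds <- seq(q[1], q[2], length.out = n_thresholds)
  mip_sizes <- vapply(thresholds,
                      function(t) .mip_area(volume > t), numeric(1))
  structure(list(thresholds = thresholds, mip_sizes = mip_sizes,
                 diffs = abs(diff(mip_sizes))),
            class = "size_curve")
}

#' Detect the plateau of a size curve
#'
#' Thresholds the absolute neighbor differences of the size curve with an
#' increasing sequence of difference-thresholds \eqn{d_{thr}}, starting
#' at 1/10 of the mean difference and doubling, until the longest run of
#' consecutive differences at or below \eqn{d_{thr}} is longer than 6
#' (i.e. at least `min_plateau_len` = 7 differences). The selected
#' segmentation is the middle of that plateau (even-length runs take the
#' lower-middle index). Ties between equally long runs go to the first.
#'
#' @param curve a `size_curve` from [build_size_curve()].
#' @param min_plateau_len minimum run length in differences (default 7,
#'   "length larger than 6").
#' @param start_factor starting threshold as a fraction of the mean
#'   difference (default 1/10).
#' @param growth multiplicative schedule of the difference threshold
#'   (default 2).
#' @return list with `plateau_start`, `plateau_end` (size indices),
#'   `center_index`, `d_thr` (final difference threshold),
#'   `threshold` (intensity at the center), `iterations`.
#' @export
detect_plateau <- function(curve, min_plateau_len = 7,
                           start_factor = 0.1, growth = 2) {
  stopifnot(inherits(curve, "size_curve") || is.list(curve))
  diffs <- curve$diffs
  if (length(diffs) < 1) stop("size curve needs at least 2 sizes")
  if (length(diffs) < min_plateau_len)
    stop("plateau failure: curve too short to host a run of ",
         min_plateau_len, " differences (has ", length(diffs), ")")
  d_max <- max(diffs)
  d_thr <- mean(diffs) * start_factor
  if (d_thr <= 0) d_thr <- max(d_max * start_factor, .Machine$double.eps)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    run <- .longest_run(diffs <= d_thr)
    if (!is.null(run) && run$length >= min_plateau_len) break
    if (d_thr > d_max)
      stop("plateau failure: no run of ", min_plateau_len,
           " consecutive differences <= d_thr up to max(diffs) = ",
           signif(d_max, 6))
    d_thr <- d_thr * growth
  }
  ps <- run$start           # size indices covered: run$start .. run$end + 1
  pe <- run$end + 1L
  center <- (ps + pe) %/% 2L
  list(plateau_start = ps, plateau_end = pe, center_index = center,
       d_thr = d_thr,
       threshold = curve$thresholds[center], iterations = iterations)
}

.longest_run <- function(flag) {
  if (!any(flag)) return(NULL)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]  # first on ties
  list(start = starts[best], end = ends[best],
       length = r$lengths[best])
}

#' Segment a nucleus from a DAPI 3D stack
#'
#' Adaptive-threshold segmentation: build the 20-threshold size curve,
#' detect its plateau, threshold the volume in 3D at the plateau-center
#' intensity, fill enclosed holes, apply binary closing (radius-1 ball),
#' and retain the largest connected component (flagged when more than
#' one component was present).
#'
#' @param volume numeric 3D array (z, y, x).
#' @param n_thresholds,probs passed to [build_size_curve()].
#' @param min_plateau_len passed to [detect_plateau()].
#' @param connectivity component connectivity (default 26).
#' @return list of class `nucleus_segmentation`: `mask`, `threshold`,
#'   `threshold_index`, `curve`, `plateau`, `flags` (character vector,
#'   e.g. "multiple_components").
#' @export
segment_nucleus <- function(volume, n_thresholds = 20,
                            probs = c(0.02, 0.998),
                            min_plateau_len = 7, connectivity = 26) {
  curve <- build_size_curve(volume, n_thresholds, probs)
  plateau <- detect_plateau(curve, min_plateau_len)
  mask <- volume > plateau$threshold
  mask <- fill_holes_3d(mask)
  mask <- binary_closing_3d(mask)
  cc <- label_components_3d(mask, connectivity)
  flags <- character(0)
  if (cc$n > 1L) {
    mask <- cc$labels == 1L
    flags <- "multiple_components"
  }
  structure(list(mask = mask, threshold = plateau$threshold,
                 threshold_index = plateau$center_index,
                 curve = curve, plateau = plateau, flags = flags),
            class = "nucleus_segmentation")
}
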