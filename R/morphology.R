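# 3D binary-mask utilities used by the segmentation stack. Volumes are
# logical or numeric arrays in (z, y, x) order. Connectivity defaults to
# 26-neighborhood for foreground objects and 6-neighborhood for the
# background complement (hole filling), the standard complementary pair.

.offsets_3d <- function(connectivity) {
  # half-space neighbor offsets (each unordered pair once)
  if (connectivity == 6) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else if (connectivity == 26) {
    off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    off <- off[!(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0), ]
    off[off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0) |
          (off[, 1] == 0 & off[, 2] == 0 & off[, 3] > 0), , drop = FALSE]
  } else stop("connectivity must be 6 or 26")
}

.shift_ranges <- function(d, off) {
  # index ranges of the two aligned sub-arrays for an offset
  rng <- function(n, o) {
    if (o >= 0) list(a = seq_len(n - o), b = seq_len(n - o) + o)
    else list(a = seq_len(n + o) - o, b = seq_len(n + o))
  }
  list(z = rng(d[1], off[1]), y = rng(d[2], off[2]), x = rng(d[3], off[3]))
}

#' Label connected components of a 3D mask
#'
#' @param mask logical 3D array (z, y, x).
#' @param connectivity 26 (default) or 6.
#' @return list with `labels` (integer array, 0 = background, components
#'   numbered by decreasing size), `n` and `sizes` (voxels per label).
#' @export
label_components_3d <- function(mask, connectivity = 26) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  mask <- mask > 0
  d <- dim(mask)
  fg <- which(mask)
  if (!length(fg))
    return(list(labels = array(0L, d), n = 0L, sizes = integer(0)))
  idx <- array(seq_len(prod(d)), d)
  edges <- list()
  offs <- .offsets_3d(connectivity)
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    sr <- .shift_ranges(d, off)
    a <- idx[sr$z$a, sr$y$a, sr$x$a]
    b <- idx[sr$z$b, sr$y$b, sr$x$b]
    sel <- mask[a] & mask[b]
    if (any(sel)) edges[[length(edges) + 1L]] <- cbind(a[sel], b[sel])
  }
  comp_of <- integer(length(fg))
  vid <- match(seq_len(prod(d)), fg)  # voxel index -> vertex id
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::make_graph(rbind(vid[e[, 1]], vid[e[, 2]]),
                            n = length(fg), directed = FALSE)
    comp_of <- igraph::components(g)$membership
  } else {
    comp_of <- seq_along(fg)
  }
  sizes <- tabulate(comp_of)
  ord <- order(sizes, decreasing = TRUE)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(ord)
  labels <- array(0L, d)
  labels[fg] <- relabel[comp_of]
  list(labels = labels, n = length(sizes), sizes = sizes[ord])
}

#' Fill enclosed cavities in a 3D mask
#'
#' Background voxels (6-connected complement) not reachable from the
#' volume border are considered holes and set to foreground.
#'
#' @param mask logical 3D array.
#' @return logical 3D array with holes filled.
#' @export
fill_holes_3d <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  mask <- mask > 0
  d <- dim(mask)
  bg <- label_components_3d(!mask, connectivity = 6)
  if (bg$n == 0L) return(mask)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  outside <- unique(bg$labels[border & !mask])
  hole <- bg$labels > 0 & !(bg$labels %in% outside)
  mask | hole
}

.dilate_3d <- function(mask, connectivity = 6) {
  d <- dim(mask)
  out <- mask
  full <- .offsets_3d(connectivity)
  for (r in seq_len(nrow(full))) {
    for (sgn in c(1, -1)) {
      off <- sgn * full[r, ]
      sr <- .shift_ranges(d, off)
      sub <- out[sr$z$a, sr$y$a, sr$x$a] | mask[sr$z$b, sr$y$b, sr$x$b]
      out[sr$z$a, sr$y$a, sr$x$a] <- sub
    }
  }
  out
}

.erode_3d <- function(mask, connectivity = 6) {
  !.dilate_3d(!mask, connectivity)
}

#' Morphological closing of a 3D mask
#'
#' Dilation followed by erosion with a radius-1 structuring element
#' (6-neighborhood ball by default), bridging thin gaps. Voxels outside
#' the volume are treated as background.
#'
#' @param mask logical 3D array.
#' @param connectivity structuring-element connectivity, 6 or 26.
#' @return logical 3D array.
#' @export
binary_closing_3d <- function(mask, connectivity = 6) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  .erode_3d(.dilate_3d(mask > 0, connectivity), connectivity)
}

#' Maximum intensity projection along z
#'
#' @param volume numeric or logical 3D array (z, y, x).
#' @return 2D matrix (y, x) of per-column maxima.
#' @export
max_intensity_projection <- function(volume) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  apply(volume, c(2, 3), max)
}

.mip_area <- function(mask) sum(max_intensity_projection(mask > 0) > 0)
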