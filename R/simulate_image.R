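#' Configuration for synthetic nucleus-image simulation
#'
#' Describes a two-channel (DAPI + antibody) 3D immunofluorescence stack
#' containing one ellipsoidal nucleus and 0-3 dense heterochromatic foci
#' with elevated signal in both channels. Foci are flattened ellipsoids
#' placed inside the eroded nucleus by rejection sampling, mutually
#' separated so each remains its own connected component.
#'
#' `focus_area_fraction` is the per-focus fraction of the nucleus
#' maximum-intensity-projection area (the size convention the
#' segmentation stack measures masks in); recycled across foci.
#'
#' @param volume_shape integer length-3 (z, y, x) voxel dimensions.
#' @param nucleus_semiaxes numeric length-3 ellipsoid semi-axes (z, y, x)
#'   in voxels; nucleus centered in the volume.
#' @param n_foci integer in 0..3.
#' @param focus_area_fraction per-focus projected-area fraction of the
#'   nucleus (scalar or length `n_foci`).
#' @param focus_thickness focus semi-axis along z, voxels.
#' @param channel_gains list with elements `dapi` and `antibody`, each a
#'   named numeric vector `c(background=, nucleus=, focus=)` with
#'   background < nucleus in DAPI; foci add elevated signal.
#' @param noise_sd additive Gaussian noise scale (clipped at 0).
#' @param seed integer seed.
#' @return list of class `image_sim_config`.
#' @export
image_sim_config <- function(volume_shape = c(34, 64, 64),
                             nucleus_semiaxes = c(12, 24, 24),
                             n_foci = 2,
                             focus_area_fraction = 0.25,
                             focus_thickness = 2,
                             channel_gains = list(
                               dapi = c(background = 20, nucleus = 180,
                                        focus = 230),
                               antibody = c(background = 20, nucleus = 60,
                                            focus = 180)),
                             noise_sd = 10,
                             seed = 1L) {
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 4),
            length(nucleus_semiaxes) == 3L, all(nucleus_semiaxes > 1),
            focus_thickness >= 1, noise_sd >= 0)
  if (!(n_foci %in% 0:3)) stop("n_foci must lie in 0..3")
  if (any(2 * nucleus_semiaxes + 2 > volume_shape))
    stop("nucleus does not fit inside the volume")
  focus_area_fraction <- rep_len(focus_area_fraction, max(n_foci, 1L))
  if (any(focus_area_fraction <= 0 | focus_area_fraction >= 1))
    stop("focus_area_fraction must lie in (0, 1)")
  for (ch in c("dapi", "antibody")) {
    g <- channel_gains[[ch]]
    if (is.null(g) || !all(c("background", "nucleus", "focus") %in%
                           names(g)))
      stop("channel_gains$", ch,
           " needs background, nucleus and focus entries")
  }
  g <- channel_gains$dapi
  if (!(g["background"] < g["nucleus"] && g["nucleus"] < g["focus"]))
    stop("DAPI gains must be ordered background < nucleus < focus")
  structure(list(volume_shape = as.integer(volume_shape),
                 nucleus_semiaxes = nucleus_semiaxes,
                 n_foci = as.integer(n_foci),
                 focus_area_fraction = focus_area_fraction,
                 focus_thickness = focus_thickness,
                 channel_gains = channel_gains,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "image_sim_config")
}

.ellipsoid_mask <- function(dim3, center, semiaxes) {
  z <- (seq_len(dim3[1]) - center[1]) / semiaxes[1]
  y <- (seq_len(dim3[2]) - center[2]) / semiaxes[2]
  x <- (seq_len(dim3[3]) - center[3]) / semiaxes[3]
  outer(outer(z^2, y^2, `+`), x^2, `+`) <= 1
}

#' Simulate a two-channel 3D nucleus image with ground truth
#'
#' Rasterizes the nucleus ellipsoid, places the requested foci inside the
#' eroded nucleus (rejection sampling; foci pairwise separated by at
#' least 2 voxels so they are distinct 26-connected components), paints
#' the channel intensities and adds Gaussian noise clipped at 0.
#' Deterministic given the config seed.
#'
#' @param config an [image_sim_config()].
#' @return list with `image` (list of `dapi` and `antibody` 3D arrays),
#'   `nucleus_mask`, `foci_masks` (list of per-focus logical arrays),
#'   `foci_mask` (their union) and `config`.
#' @export
simulate_nucleus_image <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  d <- config$volume_shape
  center <- (d + 1) / 2
  ax <- config$nucleus_semiaxes
  nucleus <- .ellipsoid_mask(d, center, ax)
  inner <- .ellipsoid_mask(d, center, ax - 1)  # eroded placement region
  nucleus_area <- .mip_area(nucleus)

  n_foci <- config$n_foci
  foci_masks <- list()
  if (n_foci > 0) {
    rz <- config$focus_thickness
    # stratified z offsets keep stacked foci separable along z
    z_base <- switch(n_foci,
                     0,
                     c(-(2 * rz + 1), 2 * rz + 1),
                     c(-(2 * rz + 3), 0, 2 * rz + 3))
    occupied <- array(FALSE, d)
    for (i in seq_len(n_foci)) {
      r_xy <- sqrt(config$focus_area_fraction[i] * nucleus_area / pi)
      placed <- FALSE
      for (attempt in seq_len(400L)) {
        jitter_scale <- max(0, 1 - attempt / 200)  # shrink jitter late
        cz <- center[1] + z_base[i] + stats::runif(1, -1, 1) * jitter_scale
        cy <- center[2] + stats::runif(1, -6, 6) * jitter_scale
        cx <- center[3] + stats::runif(1, -6, 6) * jitter_scale
        cand <- .ellipsoid_mask(d, c(cz, cy, cx), c(rz, r_xy, r_xy))
        if (any(cand & !inner)) next
        if (any(.dilate_3d(cand, 26) & occupied)) next
        foci_masks[[i]] <- cand
        occupied <- occupied | cand
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place focus ", i,
             " inside the nucleus; reduce focus_area_fraction or ",
             "n_foci, or enlarge the nucleus")
    }
  }
  foci_union <- if (length(foci_masks))
    Reduce(`|`, foci_masks) else array(FALSE, d)

  paint <- function(gains) {
    img <- array(gains[["background"]], d)
    img[nucleus] <- gains[["nucleus"]]
    img[foci_union] <- gains[["focus"]]
    if (config$noise_sd > 0)
      img <- img + stats::rnorm(prod(d), sd = config$noise_sd)
    img[img < 0] <- 0
    img
  }
  image <- list(dapi = paint(config$channel_gains$dapi),
                antibody = paint(config$channel_gains$antibody))

  list(image = image, nucleus_mask = nucleus, foci_masks = foci_masks,
       foci_mask = foci_union, config = config)
}

#' Write a simulated image and its truth masks as TIFF stacks
#'
#' Each channel and each mask is written as a multi-page (z-major)
#' 16-bit TIFF; intensities are scaled by `scale` into \[0,1\] as the
#' TIFF writer requires.
#'
#' @param sim result of [simulate_nucleus_image()].
#' @param dir output directory (created if needed).
#' @param scale intensity divisor mapping the image into \[0,1\].
#' @return named character vector of the written paths, invisibly.
#' @export
write_image_tiff <- function(sim, dir, scale = 1024) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  as_pages <- function(a) {
    lapply(seq_len(dim(a)[1]), function(z) a[z, , ] / scale)
  }
  paths <- c(dapi = file.path(dir, "dapi.tif"),
             antibody = file.path(dir, "antibody.tif"),
             nucleus_mask = file.path(dir, "nucleus_mask.tif"))
  tiff::writeTIFF(as_pages(sim$image$dapi), paths["dapi"],
                  bits.per.sample = 16)
  tiff::writeTIFF(as_pages(sim$image$antibody), paths["antibody"],
                  bits.per.sample = 16)
  tiff::writeTIFF(as_pages(sim$nucleus_mask * (scale / 2)),
                  paths["nucleus_mask"], bits.per.sample = 16)
  for (i in seq_along(sim$foci_masks)) {
    p <- file.path(dir, sprintf("focus_mask_%d.tif", i))
    tiff::writeTIFF(as_pages(sim$foci_masks[[i]] * (scale / 2)), p,
                    bits.per.sample = 16)
    paths[sprintf("focus_mask_%d", i)] <- p
  }
  invisible(paths)
}

#' Read a multi-page TIFF stack as a 3D array
#'
#' @param path TIFF path written by [write_image_tiff()].
#' @param scale intensity multiplier undoing the writer's scaling.
#' @return numeric 3D array (z, y, x).
#' @export
read_image_tiff <- function(path, scale = 1024) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  arr * scale
}
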