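# builds a nucleus volume with rectangular "foci" regions at given
# intensities; returns volume, nucleus mask and the focus index boxes
boxed_nucleus <- function(dim3 = c(16, 30, 30), nucleus_level = 50) {
  fix <- ellipsoid_volume(dim3 = dim3,
                          semi = (dim3 - 4) / 2,
                          inside = nucleus_level, outside = 0)
  fix
}

test_that("a 30% bimodal high region is kept as a single focus at k = 2", {
  fix <- boxed_nucleus()
  vol <- fix$volume
  # carve a bright block covering ~30% of the projected nucleus area
  proj <- sum(max_intensity_projection(fix$mask) > 0)
  side <- ceiling(sqrt(0.3 * proj))
  box <- list(z = 6:11, y = 12:(12 + side - 1), x = 12:(12 + side - 1))
  sel <- array(FALSE, dim(vol))
  sel[box$z, box$y, box$x] <- TRUE
  sel <- sel & fix$mask
  vol[sel] <- 200
  seg <- segment_foci(vol, fix$mask, k = 2)
  expect_equal(seg$n_foci, 1)
  expect_gt(seg$threshold, 50)
  expect_lt(seg$threshold, 200)
  expect_equal(sum(seg$foci_mask), sum(sel))
})

test_that("a high region under 20% of the nucleus is filtered out", {
  fix <- boxed_nucleus()
  vol <- fix$volume
  sel <- array(FALSE, dim(vol))
  sel[7:9, 13:17, 13:17] <- TRUE   # tiny bright block, ~3% projected
  sel <- sel & fix$mask
  vol[sel] <- 200
  seg <- segment_foci(vol, fix$mask, k = 2)
  expect_equal(seg$n_foci, 0)
  expect_false(any(seg$foci_mask))
  expect_true(any(seg$components$size > 0))
})

test_that("uniform nuclei cannot be clustered into k classes", {
  fix <- boxed_nucleus()
  expect_error(segment_foci(fix$volume, fix$mask, k = 3),
               "degenerate clustering")
  expect_error(segment_foci(fix$volume, fix$mask, k = 5), "k must be")
})

test_that("foci masks stay inside the nucleus and sizes obey the filter", {
  cfg <- image_sim_config(n_foci = 2, focus_area_fraction = 0.25,
                          seed = 31L)
  sim <- simulate_nucleus_image(cfg)
  ns <- segment_nucleus(sim$image$dapi)
  fs <- segment_foci(sim$image$antibody, ns)
  expect_true(all(ns$mask[fs$foci_mask]))
  kept <- fs$components[fs$components$kept, ]
  expect_true(all(kept$size > 0.2 * fs$nucleus_size))
  # the voxel-count size measure is also available; flat foci occupy a
  # much smaller volume fraction, so the cutoff must be scaled down
  fs_vox <- segment_foci(sim$image$antibody, ns,
                         size_measure = "voxels", size_fraction = 0.02)
  expect_equal(fs_vox$n_foci, 2)
  expect_identical(fs_vox$foci_mask, fs$foci_mask)
})

test_that("adjustment returns the base unchanged when already at target", {
  cfg <- image_sim_config(n_foci = 1, focus_area_fraction = 0.3,
                          seed = 8L)
  sim <- simulate_nucleus_image(cfg)
  ns <- segment_nucleus(sim$image$dapi)
  base <- segment_foci(sim$image$antibody, ns)
  adj <- adjust_foci(sim$image$antibody, ns, target_n_foci = 1, base)
  expect_equal(adj$adjust_iterations, 0)
  expect_identical(adj$foci_mask, base$foci_mask)
})

test_that("the shrink loop recovers a dim focus missed at k = 3", {
  fix <- boxed_nucleus()
  vol <- fix$volume
  bright <- array(FALSE, dim(vol)); bright[4:7, 4:15, 4:15] <- TRUE
  dim_f <- array(FALSE, dim(vol)); dim_f[10:13, 16:25, 16:25] <- TRUE
  bright <- bright & fix$mask; dim_f <- dim_f & fix$mask
  vol[bright] <- 200
  vol[dim_f] <- 120
  base <- segment_foci(vol, fix$mask, k = 3)
  # the top k-means threshold sits between 120 and 200: only the bright
  # focus is found
  expect_equal(base$n_foci, 1)
  expect_gt(base$threshold, 120)
  adj <- adjust_foci(vol, fix$mask, target_n_foci = 2, base)
  expect_equal(adj$n_foci, 2)
  expect_gt(adj$adjust_iterations, 0)
  expect_lt(adj$threshold, 120)
  # matches a direct scan: the first coefficient power that drops the
  # threshold below the dim focus intensity
  n_steps <- ceiling(log(120 / base$threshold) / log(0.9))
  expect_equal(adj$adjust_iterations, n_steps)
})

test_that("four classes raise the top threshold and shrink foci", {
  fix <- boxed_nucleus()
  vol <- fix$volume
  # nucleus background split in two levels; focus with bright core and
  # dimmer rim (single connected component at k = 3)
  vol[fix$mask] <- rep(c(40, 60), length.out = sum(fix$mask))
  sel <- array(FALSE, dim(vol)); sel[5:12, 8:21, 8:21] <- TRUE
  sel <- sel & fix$mask
  core <- array(FALSE, dim(vol)); core[7:10, 11:18, 11:18] <- TRUE
  core <- core & fix$mask
  vol[sel] <- 190
  vol[core] <- 210
  k3 <- segment_foci(vol, fix$mask, k = 3)
  k4 <- segment_foci(vol, fix$mask, k = 4)
  expect_gt(k4$threshold, k3$threshold)
  expect_lt(sum(k4$foci_mask), sum(k3$foci_mask))
})

test_that("adjustment failure carries the best attempt", {
  fix <- boxed_nucleus()
  vol <- fix$volume
  sel <- array(FALSE, dim(vol)); sel[6:10, 10:20, 10:20] <- TRUE
  sel <- sel & fix$mask
  vol[sel] <- 200
  base <- segment_foci(vol, fix$mask, k = 2)
  expect_error(adjust_foci(vol, fix$mask, target_n_foci = 3, base,
                           max_iterations = 5),
               "could not reach")
  cond <- tryCatch(
    adjust_foci(vol, fix$mask, target_n_foci = 3, base,
                max_iterations = 5),
    foci_adjustment_failure = function(e) e)
  expect_s3_class(cond$best_attempt, "foci_segmentation")
})

test_that("overlap fractions are exact on constructed geometries", {
  d <- c(8, 12, 12)
  nucleus <- array(FALSE, d); nucleus[2:7, 2:11, 2:11] <- TRUE
  foci <- array(FALSE, d); foci[3:4, 3:6, 3:6] <- TRUE
  domain_sup <- array(FALSE, d); domain_sup[2:6, 2:8, 2:8] <- TRUE
  uniform <- array(1, d)
  # nested: foci entirely inside the domain
  nested <- overlap_fractions(uniform, foci, domain_sup, nucleus)
  expect_equal(nested$foci_in_domain, 1.0)
  # disjoint domain
  domain_far <- array(FALSE, d); domain_far[6:7, 9:11, 9:11] <- TRUE
  disjoint <- overlap_fractions(uniform, foci, domain_far, nucleus)
  expect_equal(disjoint$foci_in_domain, 0.0)
  # uniform intensity: signal fraction equals the area fraction
  quarter <- array(FALSE, d); quarter[2:7, 2:11, 2:6] <- TRUE
  half <- overlap_fractions(uniform, quarter, NULL, nucleus)
  expect_equal(half$signal_in_foci, sum(quarter & nucleus) / sum(nucleus))
  expect_equal(half$signal_in_foci, half$foci_area_fraction)
  # empty foci: containment is missing, not zero
  none <- overlap_fractions(uniform, array(FALSE, d), domain_sup,
                            nucleus)
  expect_true(is.na(none$foci_in_domain))
  expect_true(all(unlist(nested[c("signal_in_foci",
                                  "foci_area_fraction")]) >= 0))
})

test_that("foci area fraction is monotone in the size filter", {
  cfg <- image_sim_config(n_foci = 2,
                          focus_area_fraction = c(0.22, 0.33),
                          seed = 12L)
  sim <- simulate_nucleus_image(cfg)
  ns <- segment_nucleus(sim$image$dapi)
  fracs <- vapply(c(0.05, 0.2, 0.3), function(sf) {
    fs <- segment_foci(sim$image$antibody, ns, size_fraction = sf)
    overlap_fractions(sim$image$antibody, fs, NULL,
                      ns)$foci_area_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})
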