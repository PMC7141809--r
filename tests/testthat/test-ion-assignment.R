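# Peak extraction, cross-condition matching and site classification.

# one Gaussian blob at a known center, no model atoms
blob_map <- function(center = c(10.3, 12.7, 9.1), amp = 5, width = 1,
                     n = 24, noise = 0, seed = 1) {
  g <- array(0, dim = rep(n, 3))
  xs <- seq_len(n) - 1
  gx <- exp(-(xs - center[1])^2 / (2 * width^2))
  gy <- exp(-(xs - center[2])^2 / (2 * width^2))
  gz <- exp(-(xs - center[3])^2 / (2 * width^2))
  g <- amp * (gx %o% gy %o% gz)
  if (noise > 0) {
    set.seed(seed)
    g <- g + array(rnorm(n^3, 0, noise), dim = rep(n, 3))
  }
  density_map(g, voxel_size = 1, origin = c(0, 0, 0))
}

test_that("a single blob is found with sub-voxel centroid accuracy", {
  truth <- c(10.3, 12.7, 9.1)
  m <- sigma_scale(blob_map(truth))
  peaks <- find_nonprotein_peaks(m, threshold = 5)
  expect_equal(nrow(peaks), 1)
  expect_lt(point_distance(c(peaks$cx, peaks$cy, peaks$cz), truth), 0.5)
  expect_gt(peaks$volume, 0)

  # threshold above the map maximum -> nothing
  expect_equal(nrow(find_nonprotein_peaks(m, threshold = 1e6)), 0)
  # unscaled map is refused
  expect_error(find_nonprotein_peaks(blob_map(truth), threshold = 5),
               class = "ionpore_precondition_error")
})

test_that("raising the threshold never adds peaks or grows volumes", {
  tc <- make_toy_channel(seed = 31)$structure
  sim <- paired_ion_maps(tc, seed = 31)
  s1 <- sigma_scale(sim$map_primary)
  thr <- sim$truth$threshold_primary
  reg <- cylinder_region(sim$truth$axis$origin, sim$truth$axis$direction, 8)
  lo <- find_nonprotein_peaks(s1, tc, thr, region = reg)
  hi <- find_nonprotein_peaks(s1, tc, thr * 1.15, region = reg)
  expect_lte(nrow(hi), nrow(lo))
  expect_lte(max(hi$volume), max(lo$volume))
  expect_lte(sum(hi$volume), sum(lo$volume))
})

test_that("peak voxels respect the protein exclusion radius", {
  tc <- make_toy_channel(seed = 33)$structure
  sim <- paired_ion_maps(tc, seed = 33)
  s1 <- sigma_scale(sim$map_primary)
  p <- find_nonprotein_peaks(s1, tc, sim$truth$threshold_primary,
                             exclusion_radius = 1.8)
  expect_true(all(p$nearest_protein_atom >= 1.8))
  # a model in a different frame is caught
  far <- tc
  far$x <- far$x + 500
  far <- new_structure(tibble::as_tibble(far), label = "far")
  expect_error(
    find_nonprotein_peaks(s1, far, sim$truth$threshold_primary),
    class = "ionpore_frame_error")
})

test_that("matching is one-to-one, symmetric and conserves counts", {
  tc <- make_toy_channel(seed = 35)$structure
  sim <- paired_ion_maps(tc, seed = 35)
  s1 <- sigma_scale(sim$map_primary)
  reg <- cylinder_region(sim$truth$axis$origin, sim$truth$axis$direction, 8)
  p1 <- find_nonprotein_peaks(s1, tc, sim$truth$threshold_primary,
                              region = reg)

  # identical lists match fully at distance zero
  self <- match_peaks(p1, p1, criterion = "centroid_distance", cutoff = 1)
  expect_equal(nrow(self$matches), nrow(p1))
  expect_equal(max(self$matches$centroid_distance), 0)

  # displaced beyond cutoff: no matches
  shifted <- p1
  shifted$cx <- shifted$cx + 5
  none <- match_peaks(p1, shifted, criterion = "centroid_distance",
                      cutoff = 1.5)
  expect_equal(nrow(none$matches), 0)
  expect_equal(length(none$unmatched_a), nrow(p1))

  # count conservation and injectivity on the real pair
  p2 <- find_nonprotein_peaks(sigma_scale(sim$map_partner), tc,
                              sim$truth$threshold_partner, region = reg)
  mt <- match_peaks(p1, p2)
  expect_equal(nrow(mt$matches) + length(mt$unmatched_a), nrow(p1))
  expect_equal(nrow(mt$matches) + length(mt$unmatched_b), nrow(p2))
  expect_false(anyDuplicated(mt$matches$idx_a) > 0)
  expect_false(anyDuplicated(mt$matches$idx_b) > 0)
  # symmetry: swapping the arguments swaps the pairing
  rev <- match_peaks(p2, p1)
  expect_equal(nrow(rev$matches), nrow(mt$matches))
  expect_setequal(paste(rev$matches$idx_b, rev$matches$idx_a),
                  paste(mt$matches$idx_a, mt$matches$idx_b))

  expect_error(match_peaks(p1, p2, cutoff = -1),
               class = "ionpore_parameter_error")
})

test_that("classification splits matched ions from unmatched waters", {
  tc <- make_toy_channel(seed = 37)$structure
  sim <- paired_ion_maps(tc, seed = 37)
  reg <- cylinder_region(sim$truth$axis$origin, sim$truth$axis$direction, 8)
  p1 <- find_nonprotein_peaks(sigma_scale(sim$map_primary), tc,
                              sim$truth$threshold_primary, region = reg)
  p2 <- find_nonprotein_peaks(sigma_scale(sim$map_partner), tc,
                              sim$truth$threshold_partner, region = reg)
  mt <- match_peaks(p1, p2)
  sites <- classify_sites(mt, p1, p2, axis = sim$truth$axis)
  expect_equal(sum(sites$classification == "ion"), 4)
  expect_equal(sum(sites$classification == "water"), 12)
  expect_equal(nrow(sites), nrow(p1))
  # ion labels follow z order along the axis
  ions <- sites[sites$classification == "ion", ]
  expect_equal(ions$label[order(ions$cz)], paste0("K", 1:4))
  expect_true(all(is.na(
    sites$amplitude_ratio[sites$classification == "water"])))

  # empty match list -> everything is water
  all_water <- classify_sites(list(matches = mt$matches[0, ],
                                   unmatched_a = seq_len(nrow(p1)),
                                   unmatched_b = integer(0)),
                              p1, p2)
  expect_true(all(all_water$classification == "water"))
})

test_that("assignments are invariant under joint map+model translation", {
  tc <- make_toy_channel(seed = 39)$structure
  sim <- paired_ion_maps(tc, seed = 39)
  shift <- c(7, -3, 12)
  shift_map <- function(m) {
    m$origin <- m$origin + shift
    m
  }
  moved <- tc
  moved$x <- moved$x + shift[1]
  moved$y <- moved$y + shift[2]
  moved$z <- moved$z + shift[3]
  moved <- new_structure(tibble::as_tibble(moved), label = "moved")
  reg0 <- cylinder_region(sim$truth$axis$origin, sim$truth$axis$direction, 8)
  reg1 <- cylinder_region(sim$truth$axis$origin + shift,
                          sim$truth$axis$direction, 8)
  p_ref <- find_nonprotein_peaks(sigma_scale(sim$map_primary), tc,
                                 sim$truth$threshold_primary, region = reg0)
  p_mov <- find_nonprotein_peaks(sigma_scale(shift_map(sim$map_primary)),
                                 moved, sim$truth$threshold_primary,
                                 region = reg1)
  expect_equal(nrow(p_mov), nrow(p_ref))
  expect_equal(cbind(p_mov$cx, p_mov$cy, p_mov$cz),
               cbind(p_ref$cx, p_ref$cy, p_ref$cz) +
                 matrix(shift, nrow(p_ref), 3, byrow = TRUE),
               tolerance = 1e-9)
})

test_that("site geometry reports coordination distances within the shell", {
  model <- new_structure(tibble::tibble(
    element = c("K", "O", "O"),
    atom_name = c("K", "O", "O"),
    residue_name = c("K", "HOH", "HOH"),
    residue_number = 1:3, chain_id = "A",
    x = c(0, 2.8, 9), y = 0, z = 0
  ), label = "site-fixture")
  sites <- tibble::tibble(label = "K1", classification = "ion",
                          cx = 0, cy = 0, cz = 0,
                          max_sigma_primary = 12, max_sigma_partner = 20,
                          centroid_distance = 0.2, amplitude_ratio = 3)
  rep4 <- site_geometry_report(sites, model, shell = 4)
  expect_equal(nrow(rep4), 1)          # only the 2.8 A water; K1 itself skipped
  expect_equal(rep4$distance, 2.8)
  expect_equal(rep4$contact_type, "water")
  rep0 <- site_geometry_report(sites, model, shell = 1)
  expect_equal(nrow(rep0), 0)
})
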