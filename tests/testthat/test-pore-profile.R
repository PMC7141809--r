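# Probe-radius profiler against analytic geometries.

z_axis <- function() list(origin = c(0, 0, 0), direction = c(0, 0, 1))

test_that("profiler matches the analytic clearance on rings", {
  # ring of vdW-1.7 atoms at radius 5: probe radius 5 - 1.7 = 3.3 exactly
  ring <- ring_structure(ring_radius = 5)
  p <- compute_pore_profile(ring, axis = z_axis(), z_range = c(0, 0),
                            step = 0.5, seed = 2)
  expect_equal(p$radius, 3.3, tolerance = 0.05)

  # 20 generated ring/cylinder cases across radii and atom counts
  set.seed(1401)
  cases <- expand.grid(radius = c(2.2, 3.0, 4.1, 5.5, 7.0),
                       n = c(8, 10, 12, 16))
  for (k in seq_len(nrow(cases))) {
    rr <- cases$radius[k]; n <- cases$n[k]
    ring <- ring_structure(ring_radius = rr, n = n)
    p <- compute_pore_profile(ring, axis = z_axis(), z_range = c(0, 0),
                              step = 0.5, seed = k)
    expect_equal(p$radius, rr - 1.7, tolerance = 0.05,
                 label = sprintf("ring r=%.1f n=%d", rr, n))
  }
})

test_that("a uniform cylinder gives a flat profile", {
  cyl <- cylinder_structure(ring_radius = 5, zs = seq(-6, 6, 1))
  p <- compute_pore_profile(cyl, axis = z_axis(), z_range = c(-3, 3),
                            step = 0.5, seed = 3)
  expect_lt(max(p$radius) - min(p$radius), 0.05)
  expect_true(all(abs(p$radius - 3.3) < 0.35))
})

test_that("probe spheres never overlap obstacles and shrink with vdW", {
  tc <- make_toy_channel(seed = 21)$structure
  p <- compute_pore_profile(tc, z_range = c(-8, 8), step = 1, seed = 5)
  xyz <- coords(select_atoms(tc, record_class == "protein"))
  vdw <- vdw_radius(tc$element[tc$record_class == "protein"])
  for (i in seq_len(nrow(p))) {
    ctr <- c(p$cx[i], p$cy[i], p$cz[i])
    gap <- min(sqrt((xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 +
                      (xyz[, 3] - ctr[3])^2) - vdw) - p$radius[i]
    expect_gte(gap, -1e-6)
  }

  # monotonicity: shrinking every obstacle sphere by delta (modeling the
  # atoms as smaller elements is not possible, so compare two rings whose
  # center-line radii differ by delta) grows the pore by exactly delta
  r1 <- compute_pore_profile(ring_structure(5.0), axis = z_axis(),
                             z_range = c(0, 0), seed = 2)$radius
  r2 <- compute_pore_profile(ring_structure(5.4), axis = z_axis(),
                             z_range = c(0, 0), seed = 2)$radius
  expect_equal(r2 - r1, 0.4, tolerance = 0.02)
})

test_that("profiles are deterministic for a fixed seed", {
  tc <- make_toy_channel(seed = 8)$structure
  a <- compute_pore_profile(tc, z_range = c(-5, 5), step = 0.5, seed = 17)
  b <- compute_pore_profile(tc, z_range = c(-5, 5), step = 0.5, seed = 17)
  expect_identical(a$radius, b$radius)
  expect_identical(a$cx, b$cx)
})

test_that("open funnels are capped and flagged", {
  ring <- ring_structure(ring_radius = 5)
  p <- compute_pore_profile(ring, axis = z_axis(), z_range = c(30, 30),
                            step = 0.5, seed = 1)
  expect_equal(p$radius, 10)
  expect_true(p$capped)
  expect_error(compute_pore_profile(
    select_atoms(three_atom_structure(), record_class == "water")),
    class = "ionpore_no_protein")
})

test_that("min_constriction finds the vertex and breaks ties low", {
  prof <- structure(
    tibble::tibble(z = c(-2, -1, 0, 1, 2),
                   cx = 0, cy = 0, cz = c(-2, -1, 0, 1, 2),
                   radius = c(3, 2, 1, 2, 3), capped = FALSE,
                   lining_residues = replicate(5, "X", simplify = FALSE)),
    class = c("pore_profile", class(tibble::tibble())))
  mc <- min_constriction(prof)
  expect_equal(mc$z, 0)
  expect_equal(mc$radius, 1)

  tied <- prof
  tied$radius <- c(3, 1, 2, 1, 3)
  expect_equal(min_constriction(tied)$z, -1)   # smaller z wins
  expect_error(min_constriction(prof, z_window = c(10, 20)),
               class = "ionpore_window_error")
  expect_equal(min_constriction(prof, z_window = c(0.5, 2.5))$radius, 2)
})

test_that("toy channel constriction radii match their construction", {
  for (cr in c(1.7, 0.5)) {
    tc <- make_toy_channel(constriction_radius = cr, seed = 19)
    p <- compute_pore_profile(tc$structure, z_range = c(-4, 4), step = 0.5,
                              seed = 3)
    mc <- min_constriction(p)
    expect_equal(mc$radius, cr, tolerance = 0.05)
    # the gate is lined by the isoleucine rings
    expect_true(all(grepl("^ILE", mc$lining_residues[[1]])))
  }
})

test_that("hydrophobicity annotation averages the lining scale values", {
  # all-leucine lining: every sample scores the leucine value
  cyl <- cylinder_structure(ring_radius = 5, zs = seq(-4, 4, 1),
                            residue_name = "LEU")
  p <- compute_pore_profile(cyl, axis = z_axis(), z_range = c(-2, 2),
                            step = 1, seed = 4)
  h <- hydrophobicity_annotation(cyl, p, lining_cutoff = 7)
  expect_true(all(h$hydrophobicity == kyte_doolittle[["LEU"]]))

  # alternating Ser/Leu rings: mixed planes average the two scale values
  rows <- lapply(0:3, function(i) {
    rn <- if (i %% 2 == 0) "SER" else "LEU"
    tibble::as_tibble(ring_structure(5, z = i, residue_name = rn)) |>
      dplyr::mutate(residue_number = residue_number + i * 100)
  })
  alt <- new_structure(dplyr::bind_rows(rows), label = "alt")
  p2 <- compute_pore_profile(alt, axis = z_axis(), z_range = c(1.5, 1.5),
                             step = 1, seed = 4)
  h2 <- hydrophobicity_annotation(alt, p2, lining_cutoff = 6)
  # cutoff 6 around (0,0,1.5) reaches all four rings: 2 Ser + 2 Leu
  expect_equal(h2$hydrophobicity,
               mean(kyte_doolittle[c("SER", "SER", "LEU", "LEU")]))

  # hydrophobic vestibule vs polar entrance in the toy channel: the
  # ILE/LEU-rich center scores above the Ser-containing flanks
  tc <- make_toy_channel(seed = 23)$structure
  prof <- compute_pore_profile(tc, z_range = c(-15, 15), step = 1, seed = 6)
  prof <- hydrophobicity_annotation(tc, prof, lining_cutoff = 6.5)
  center <- mean(prof$hydrophobicity[abs(prof$z) <= 2])
  flank <- mean(prof$hydrophobicity[abs(prof$z) >= 12])
  expect_gt(center, flank)

  # unknown residues fall back to neutral with a warning
  odd <- ring_structure(5, residue_name = "XYZ")
  odd$record_class <- "protein"
  odd <- new_structure(tibble::as_tibble(odd), label = "odd")
  p3 <- compute_pore_profile(odd, axis = z_axis(), z_range = c(0, 0), seed = 1)
  expect_warning(h3 <- hydrophobicity_annotation(odd, p3),
                 "not in hydropathy scale")
  expect_equal(h3$hydrophobicity, 0)
})
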