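# Ground-truth generators emulating the study's three input kinds: a
# pseudo-symmetric two-protomer channel with a tunable hydrophobic
# constriction, paired density maps in two cation conditions (partner ion
# blobs ~3x the primary amplitude, water blobs equal), and bi-ionic
# voltage-clamp families from a known permeability ratio.

#' Generate a toy channel structure with a known constriction
#'
#' Stacked rings of carbon "side-chain" atoms around the z axis, flaring
#' parabolically away from a central constriction so the analytic minimum
#' pore radius equals \code{constriction_radius}. Angular positions are
#' divided between chains so the bundle has the requested rotational
#' symmetry (2 chains = two-fold, 4 chains = four-fold); rings carry a small
#' seeded helical twist. Constriction rings are isoleucine, the flanks
#' alternate leucine/serine, mimicking a hydrophobic gate between more polar
#' segments.
#'
#' @param n_chains 2 or 4.
#' @param constriction_radius Target minimum pore radius in Angstrom
#'   (default 1.7, the open-gate value; 0.5 mimics the closed gate).
#' @param length Pore length in Angstrom (default 45).
#' @param seed Integer seed (ring twist jitter).
#' @param atoms_per_ring Atoms per ring (default 8; must be divisible by
#'   \code{n_chains}).
#' @return List with \code{structure} (an \code{ion_structure}) and
#'   \code{truth} (constriction radius, ring model parameters, seed).
#' @export
make_toy_channel <- function(n_chains = 2, constriction_radius = 1.7,
                             length = 45, seed = 1, atoms_per_ring = 8) {
  if (!n_chains %in% c(2, 4)) {
    abort("n_chains must be 2 or 4", class = "ionpore_parameter_error")
  }
  if (constriction_radius < 0) {
    abort("constriction_radius must be non-negative",
          class = "ionpore_parameter_error")
  }
  if (constriction_radius > 6) {
    abort("constriction_radius larger than the helix bundle",
          class = "ionpore_geometry_error")
  }
  if (atoms_per_ring %% n_chains != 0) {
    abort("atoms_per_ring must be divisible by n_chains",
          class = "ionpore_parameter_error")
  }
  vdw_c <- vdw_radius("C")
  half <- length / 2
  zs <- seq(-half, half, by = 1.5)
  flare <- 4.6                    # extra ring radius at the pore mouths
  kq <- flare / half^2
  ring_radius <- constriction_radius + vdw_c + kq * zs^2
  twist <- with_seed(seed, runif(length(zs), -0.2, 0.2))
  chains <- LETTERS[seq_len(n_chains)]
  per_chain <- atoms_per_ring / n_chains
  rows <- list()
  for (ri in seq_along(zs)) {
    resname <- if (abs(zs[ri]) < 1.5) "ILE" else
      if (ri %% 2 == 0) "LEU" else "SER"
    for (j in seq_len(atoms_per_ring)) {
      theta <- 2 * pi * (j - 1) / atoms_per_ring + twist[ri]
      chain <- chains[((j - 1) %/% per_chain) + 1]
      rows[[length(rows) + 1]] <- tibble(
        element = "C",
        atom_name = paste0("C", ((j - 1) %% per_chain) + 1),
        residue_name = resname,
        residue_number = ri,
        chain_id = chain,
        x = ring_radius[ri] * cos(theta),
        y = ring_radius[ri] * sin(theta),
        z = zs[ri],
        occupancy = 1, b_factor = 20
      )
    }
  }
  structure_tbl <- new_structure(dplyr::bind_rows(rows),
                                 label = "toy-channel",
                                 condition = "synthetic")
  list(
    structure = structure_tbl,
    truth = list(constriction_radius = constriction_radius,
                 length = length, n_chains = n_chains,
                 flare = flare, seed = seed)
  )
}

# additive Gaussian blob density on a map grid
add_blobs <- function(grid, origin, voxel, centers, amps, width) {
  d <- dim(grid)
  xs <- origin[1] + (seq_len(d[1]) - 1) * voxel[1]
  ys <- origin[2] + (seq_len(d[2]) - 1) * voxel[2]
  zs <- origin[3] + (seq_len(d[3]) - 1) * voxel[3]
  for (b in seq_len(nrow(centers))) {
    ctr <- centers[b, ]
    # limit to a 4-width neighborhood for speed
    ix <- which(abs(xs - ctr[1]) <= 4 * width)
    iy <- which(abs(ys - ctr[2]) <= 4 * width)
    iz <- which(abs(zs - ctr[3]) <= 4 * width)
    if (length(ix) == 0 || length(iy) == 0 || length(iz) == 0) {
      abort("blob position outside the map grid",
            class = "ionpore_placement_error")
    }
    gx <- exp(-(xs[ix] - ctr[1])^2 / (2 * width^2))
    gy <- exp(-(ys[iy] - ctr[2])^2 / (2 * width^2))
    gz <- exp(-(zs[iz] - ctr[3])^2 / (2 * width^2))
    blob <- amps[b] * (gx %o% gy %o% gz)
    grid[ix, iy, iz] <- grid[ix, iy, iz] + blob
  }
  grid
}

#' Generate paired density maps in two cation conditions
#'
#' Both maps contain Gaussian density for the structure's atoms plus solvent
#' blobs at shared positions: \code{n_ions} on the pore axis and
#' \code{n_waters} off-axis. Ion blobs in the partner map are scaled by
#' \code{amplitude_ratio} (default 3, the heavier cation's scattering
#' advantage); water blobs are equal in both maps. Each map gets independent
#' additive Gaussian noise. The returned truth records the solvent
#' positions and per-map sigma thresholds at which waters are suprathreshold
#' only in the primary map — the operating point of the dual-cation
#' comparison.
#'
#' @param structure An \code{ion_structure} (e.g. from
#'   \code{\link{make_toy_channel}}).
#' @param n_ions,n_waters Solvent blob counts (defaults 4 and 12).
#' @param amplitude_ratio Partner/primary ion amplitude (default 3).
#' @param voxel Voxel size in Angstrom (default 1).
#' @param blob_width Gaussian width in Angstrom (default 0.8).
#' @param noise_sd Additive noise sd as a fraction of the solvent blob
#'   amplitude (default 0.02).
#' @param box Grid dimension (default 64 voxels per axis).
#' @param seed Integer seed.
#' @return List with \code{map_primary}, \code{map_partner} (raw
#'   \code{density_map}s) and \code{truth} (positions, amplitude ratio,
#'   suggested per-map thresholds, seed).
#' @export
paired_ion_maps <- function(structure, n_ions = 4, n_waters = 12,
                            amplitude_ratio = 3, voxel = 1.0,
                            blob_width = 0.8, noise_sd = 0.02,
                            box = 64, seed = 1) {
  stopifnot(n_ions >= 0, n_waters >= 0, voxel > 0, amplitude_ratio > 0)
  ctr <- colMeans(coords(structure))
  origin <- ctr - (box - 1) / 2 * voxel
  vox3 <- rep(voxel, 3)
  # solvent layout: ions on the axis, waters in two off-axis shells
  # Solvent layout in half-integer offsets from the box center, i.e. exactly
  # on voxel centers (origin puts voxel centers at ctr + k - (box-1)/2):
  # ions on the axis in the central 15 A, waters off-axis in the outer pore
  # with >= 3 A separation between any two blobs so connected components
  # never merge at the operating thresholds.
  ion_pos <- if (n_ions > 0) {
    cbind(ctr[1], ctr[2], ctr[3] + seq(-7.5, 7.5, length.out = n_ions))
  } else matrix(numeric(0), ncol = 3)
  wat_pos <- if (n_waters > 0) {
    zshells <- as.vector(rbind(-(10.5 + 2 * (0:5)), 10.5 + 2 * (0:5)))
    zoff <- rep(zshells, length.out = n_waters)
    xy <- matrix(c(1.5, 0.5, -1.5, -0.5, -0.5, 1.5), ncol = 2, byrow = TRUE)
    xyk <- xy[(seq_len(n_waters) - 1) %% 3 + 1, , drop = FALSE]
    cbind(ctr[1] + xyk[, 1], ctr[2] + xyk[, 2], ctr[3] + zoff)
  } else matrix(numeric(0), ncol = 3)
  amp_solvent <- 1.0
  amp_protein <- 1.5
  pxyz <- coords(select_atoms(structure, .data$record_class == "protein"))

  base <- array(0, dim = rep(box, 3))
  base <- add_blobs(base, origin, vox3, pxyz,
                    rep(amp_protein, nrow(pxyz)), width = 0.8)
  solvent <- rbind(ion_pos, wat_pos)
  amps_primary <- c(rep(amp_solvent, nrow(ion_pos)),
                    rep(amp_solvent, nrow(wat_pos)))
  amps_partner <- c(rep(amp_solvent * amplitude_ratio, nrow(ion_pos)),
                    rep(amp_solvent, nrow(wat_pos)))
  g1 <- if (nrow(solvent) > 0)
    add_blobs(base, origin, vox3, solvent, amps_primary, blob_width) else base
  g2 <- if (nrow(solvent) > 0)
    add_blobs(base, origin, vox3, solvent, amps_partner, blob_width) else base
  noise <- with_seed(seed, list(
    a = array(rnorm(box^3, 0, noise_sd * amp_solvent), dim = rep(box, 3)),
    b = array(rnorm(box^3, 0, noise_sd * amp_solvent), dim = rep(box, 3))
  ))
  map1 <- density_map(g1 + noise$a, voxel_size = vox3, origin = origin)
  map2 <- density_map(g2 + noise$b, voxel_size = vox3, origin = origin)

  # operating thresholds, in sigma units of each map
  value_at <- function(map, pos) {
    s <- sigma_scale(map)
    ijk <- round(sweep(pos, 2, map$origin) / voxel) + 1
    s$grid[cbind(ijk[, 1], ijk[, 2], ijk[, 3])]
  }
  thr1 <- thr2 <- NA_real_
  if (nrow(solvent) > 0) {
    # 0.8 x the weakest solvent peak: suprathreshold components are compact
    # (single voxels) so nearby blobs never fuse, yet every solvent site is
    # comfortably above threshold
    s1 <- value_at(map1, solvent)
    thr1 <- 0.8 * min(s1)
    if (nrow(ion_pos) > 0 && nrow(wat_pos) > 0) {
      s2i <- value_at(map2, ion_pos)
      s2w <- value_at(map2, wat_pos)
      thr2 <- (max(s2w) + min(s2i)) / 2
    } else if (nrow(ion_pos) > 0) {
      thr2 <- 0.8 * min(value_at(map2, ion_pos))
    }
  }
  list(
    map_primary = map1, map_partner = map2,
    truth = list(
      ion_positions = ion_pos, water_positions = wat_pos,
      amplitude_ratio = amplitude_ratio,
      threshold_primary = thr1, threshold_partner = thr2,
      axis = list(origin = ctr, direction = c(0, 0, 1)),
      blob_width = blob_width, noise_sd = noise_sd, seed = seed
    )
  )
}

#' Simulate a bi-ionic I-V family with known permeability ratio
#'
#' The true reversal potential follows from the bi-ionic relation,
#' Erev = -(RT/F) ln(ratio * [X+]int / [Y+]ext); currents are linear,
#' I(V) = conductance * (V - Erev) * (1 + eps) with multiplicative
#' zero-mean Gaussian noise of relative sd \code{noise_frac}, sampled at the
#' standard 11-step protocol (-100 to +100 mV in 20 mV increments).
#'
#' @param condition A \code{\link{bi_ionic_condition}}.
#' @param true_ratio True P_X/P_Y (> 0).
#' @param conductance Slope in pA/mV (default 10).
#' @param noise_frac Relative current noise sd (default 0.05).
#' @param n_replicates Cells recorded (default 3).
#' @param seed Integer seed.
#' @return List with \code{family} (an \code{iv_family}) and \code{truth}
#'   (true ratio, true Erev in mV, parameters, seed).
#' @export
simulate_iv <- function(condition = bi_ionic_condition(), true_ratio = 9,
                        conductance = 10, noise_frac = 0.05,
                        n_replicates = 3, seed = 1) {
  if (true_ratio <= 0) {
    abort("true_ratio must be positive", class = "ionpore_parameter_error")
  }
  rt_f_mv <- 1000 * .GAS_CONSTANT * condition$temperature / .FARADAY
  erev_true <- -rt_f_mv *
    log(true_ratio * condition$conc_internal / condition$conc_external)
  volts <- seq(-100, 100, by = 20)
  records <- with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_replicates), function(r) {
      eps <- rnorm(length(volts), 0, noise_frac)
      tibble(voltage = volts,
             current = conductance * (volts - erev_true) * (1 + eps),
             replicate = paste0("cell", r))
    }))
  })
  list(
    family = iv_family(records, condition = condition),
    truth = list(true_ratio = true_ratio, true_erev_mv = erev_true,
                 conductance = conductance, noise_frac = noise_frac,
                 n_replicates = n_replicates, seed = seed)
  )
}
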