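# Small programmatic fixtures shared across test files.

# three atoms covering the protein / ion / water record classes
three_atom_structure <- function() {
  new_structure(tibble::tibble(
    element = c("C", "K", "O"),
    atom_name = c("CA", "K", "O"),
    residue_name = c("ALA", "K", "HOH"),
    residue_number = c(1L, 101L, 201L),
    chain_id = c("A", "A", "A"),
    x = c(0, 1, 2), y = c(0, 0, 0), z = c(0, 1, 2),
    occupancy = c(1, 1, 1), b_factor = c(10, 20, 30)
  ), label = "fixture-3atom")
}

# planar ring of n carbon atoms, analytic pore radius = ring_radius - vdW(C)
ring_structure <- function(ring_radius = 5, n = 8, z = 0,
                           residue_name = "LEU") {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  new_structure(tibble::tibble(
    element = "C", atom_name = paste0("C", seq_len(n)),
    residue_name = residue_name, residue_number = seq_len(n),
    chain_id = "A",
    x = ring_radius * cos(ang), y = ring_radius * sin(ang), z = z
  ), label = "ring")
}

# stack of rings = uniform cylinder of obstacle atoms
cylinder_structure <- function(ring_radius = 5, n = 8, zs = seq(-5, 5, 1),
                               residue_name = "LEU") {
  rows <- lapply(seq_along(zs), function(i) {
    ang <- 2 * pi * (seq_len(n) - 1) / n + (i %% 2) * pi / n
    tibble::tibble(
      element = "C", atom_name = paste0("C", seq_len(n)),
      residue_name = residue_name, residue_number = i,
      chain_id = "A",
      x = ring_radius * cos(ang), y = ring_radius * sin(ang), z = zs[i]
    )
  })
  new_structure(dplyr::bind_rows(rows), label = "cylinder")
}

# random rigid transform built from a fixed seed
random_rotation <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0.1, pi - 0.1)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

z_protocol <- seq(-100, 100, by = 20)

linear_family <- function(erev, g = 10, replicates = 1) {
  recs <- dplyr::bind_rows(lapply(seq_len(replicates), function(r) {
    tibble::tibble(voltage = z_protocol,
                   current = g * (z_protocol - erev),
                   replicate = paste0("cell", r))
  }))
  iv_family(recs)
}
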