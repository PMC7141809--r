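# Dual-cation ion-site assignment: non-protein density peaks are extracted
# from sigma-scaled maps in each cation condition; peaks present in both maps
# (the heavier cation scatters ~3x more strongly, so its sites survive a
# stringent threshold) are classified as ions, the remainder as ordered
# waters.

# 26-connected component labeling of a logical 3-D mask (BFS flood fill).
label_components_26 <- function(mask) {
  dims <- dim(mask)
  L <- array(0L, dims)
  seeds <- which(mask)
  if (length(seeds) == 0) return(L)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nxy <- dims[1] * dims[2]
  lab <- 0L
  for (v in seeds) {
    if (L[v] != 0L) next
    lab <- lab + 1L
    L[v] <- lab
    frontier <- v
    while (length(frontier) > 0) {
      ci <- arrayInd(frontier, dims)
      nxt <- integer(0)
      for (r in seq_len(nrow(offs))) {
        ni <- ci[, 1] + offs[r, 1]
        nj <- ci[, 2] + offs[r, 2]
        nk <- ci[, 3] + offs[r, 3]
        ok <- ni >= 1 & ni <= dims[1] & nj >= 1 & nj <= dims[2] &
          nk >= 1 & nk <= dims[3]
        if (!any(ok)) next
        lin <- ni[ok] + (nj[ok] - 1L) * dims[1] + (nk[ok] - 1L) * nxy
        new <- lin[mask[lin] & L[lin] == 0L]
        if (length(new) > 0) {
          L[new] <- lab
          nxt <- c(nxt, new)
        }
      }
      frontier <- unique(nxt)
    }
  }
  L
}

#' Cylindrical region mask around a pore axis
#'
#' @param origin,direction Axis origin and direction (Angstrom).
#' @param radius Cylinder radius in Angstrom (default 8, covering the
#'   permeation pathway).
#' @param z_range Optional interval along the axis.
#' @return A predicate function over an n x 3 world-coordinate matrix, for
#'   use as the \code{region} argument of \code{\link{find_nonprotein_peaks}}.
#' @export
cylinder_region <- function(origin, direction, radius = 8, z_range = NULL) {
  u <- direction / sqrt(sum(direction^2))
  force(origin); force(radius); force(z_range)
  function(world) {
    rel <- sweep(world, 2, origin)
    zloc <- as.numeric(rel %*% u)
    perp2 <- rowSums(rel^2) - zloc^2
    ok <- perp2 <= radius^2
    if (!is.null(z_range)) ok <- ok & zloc >= z_range[1] & zloc <= z_range[2]
    ok
  }
}

#' Find non-protein density peaks above a sigma threshold
#'
#' Voxels at or above \code{threshold} (sigma units) are retained, voxels
#' within \code{exclusion_radius} of any protein (or other non-solvent) model
#' atom are removed, and the remainder is segmented into 26-connected
#' components. Each component becomes one peak with an intensity-weighted
#' centroid.
#'
#' @param map A sigma-scaled \code{density_map}.
#' @param model Optional \code{ion_structure} in the same frame as the map;
#'   its protein/other atoms define the exclusion zone.
#' @param threshold Sigma threshold (e.g. 12 for a K+ map, 8 for a Cs+ map).
#' @param exclusion_radius Angstrom (default 1.8).
#' @param region Optional predicate over world coordinates (see
#'   \code{\link{cylinder_region}}) restricting the search, e.g. to the pore.
#' @return A tibble of peaks sorted by \code{max_sigma} descending:
#'   \code{peak_id}, centroid \code{cx, cy, cz} (world Angstrom),
#'   \code{max_sigma}, \code{raw_amplitude} (max_sigma times the map's raw
#'   sd), \code{volume} (Angstrom^3 above threshold), \code{n_voxels},
#'   \code{nearest_protein_atom} (Angstrom, Inf without a model) and
#'   \code{voxels} (list column of linear voxel indices).
#' @export
find_nonprotein_peaks <- function(map, model = NULL, threshold,
                                  exclusion_radius = 1.8, region = NULL) {
  stopifnot(inherits(map, "density_map"))
  if (!isTRUE(map$sigma_scaled)) {
    abort("map must be sigma-scaled (see sigma_scale())",
          class = "ionpore_precondition_error")
  }
  mask <- map$grid >= threshold
  idx <- which(mask)
  mind <- rep(Inf, length(idx))
  if (length(idx) > 0 && (!is.null(model) || !is.null(region))) {
    world <- voxel_to_world(map, arrayInd(idx, dim(map$grid)))
    if (!is.null(region)) {
      keep <- region(world)
      mask[idx[!keep]] <- FALSE
      idx <- idx[keep]
      world <- world[keep, , drop = FALSE]
      mind <- mind[keep]
    }
    if (!is.null(model) && length(idx) > 0) {
      excl <- select_atoms(model, .data$record_class %in% c("protein", "other"))
      if (nrow(excl) > 0) {
        pxyz <- coords(excl)
        # frame sanity: the model must overlap the map box
        lo <- map$origin - 2
        hi <- map$origin + (dim(map$grid) - 1) * map$voxel_size + 2
        inside <- pxyz[, 1] >= lo[1] & pxyz[, 1] <= hi[1] &
          pxyz[, 2] >= lo[2] & pxyz[, 2] <= hi[2] &
          pxyz[, 3] >= lo[3] & pxyz[, 3] <= hi[3]
        if (!any(inside)) {
          abort("model lies entirely outside the map box; frame mismatch?",
                class = "ionpore_frame_error")
        }
        for (start in seq(1, length(idx), by = 4096)) {
          rows <- start:min(start + 4095, length(idx))
          w <- world[rows, , drop = FALSE]
          d2 <- outer(rowSums(w^2), rep(1, nrow(pxyz))) +
            outer(rep(1, nrow(w)), rowSums(pxyz^2)) -
            2 * w %*% t(pxyz)
          mind[rows] <- sqrt(pmax(apply(d2, 1, min), 0))
        }
        drop <- mind < exclusion_radius
        mask[idx[drop]] <- FALSE
        idx <- idx[!drop]
        mind <- mind[!drop]
      }
    }
  }
  if (length(idx) == 0) {
    return(tibble(peak_id = integer(0), cx = numeric(0), cy = numeric(0),
                  cz = numeric(0), max_sigma = numeric(0),
                  raw_amplitude = numeric(0), volume = numeric(0),
                  n_voxels = integer(0), nearest_protein_atom = numeric(0),
                  voxels = list()))
  }
  L <- label_components_26(mask)
  labs <- L[idx]
  world <- voxel_to_world(map, arrayInd(idx, dim(map$grid)))
  vals <- map$grid[idx]
  vvol <- prod(map$voxel_size)
  peaks <- lapply(sort(unique(labs)), function(l) {
    sel <- labs == l
    w <- vals[sel]
    ctr <- colSums(world[sel, , drop = FALSE] * w) / sum(w)
    list(cx = ctr[1], cy = ctr[2], cz = ctr[3],
         max_sigma = max(w), volume = sum(sel) * vvol,
         n_voxels = sum(sel),
         nearest_protein_atom = min(mind[sel]),
         voxels = idx[sel])
  })
  out <- tibble(
    peak_id = seq_along(peaks),
    cx = vapply(peaks, `[[`, numeric(1), "cx"),
    cy = vapply(peaks, `[[`, numeric(1), "cy"),
    cz = vapply(peaks, `[[`, numeric(1), "cz"),
    max_sigma = vapply(peaks, `[[`, numeric(1), "max_sigma"),
    raw_amplitude = vapply(peaks, `[[`, numeric(1), "max_sigma") * map$raw_sd,
    volume = vapply(peaks, `[[`, numeric(1), "volume"),
    n_voxels = vapply(peaks, `[[`, integer(1), "n_voxels"),
    nearest_protein_atom = vapply(peaks, `[[`, numeric(1),
                                  "nearest_protein_atom"),
    voxels = lapply(peaks, `[[`, "voxels")
  )
  out <- out[order(-out$max_sigma), ]
  out$peak_id <- seq_len(nrow(out))
  out
}

#' Match density peaks between two conditions
#'
#' One-to-one matching of peaks from the primary (e.g. K+) and partner
#' (e.g. Cs+) maps. \code{"voxel_overlap"} (the default, both maps on the
#' same grid) pairs peaks sharing at least one suprathreshold voxel, largest
#' overlap first; \code{"centroid_distance"} pairs mutual nearest neighbors
#' within \code{cutoff}, smallest distance first with ties to the higher
#' partner \code{max_sigma}.
#'
#' @param peaks_a,peaks_b Peak tibbles from
#'   \code{\link{find_nonprotein_peaks}} in the same world frame.
#' @param criterion "voxel_overlap" or "centroid_distance".
#' @param cutoff Angstrom centroid cutoff (default 1.5).
#' @return List with \code{matches} (tibble: \code{idx_a}, \code{idx_b},
#'   \code{centroid_distance}, \code{shared_voxels}) and integer vectors
#'   \code{unmatched_a}, \code{unmatched_b} (row indices).
#' @export
match_peaks <- function(peaks_a, peaks_b,
                        criterion = c("voxel_overlap", "centroid_distance"),
                        cutoff = 1.5) {
  criterion <- match.arg(criterion)
  if (cutoff < 0) {
    abort("cutoff must be non-negative", class = "ionpore_parameter_error")
  }
  na <- nrow(peaks_a); nb <- nrow(peaks_b)
  cda <- function(i, j) {
    point_distance(c(peaks_a$cx[i], peaks_a$cy[i], peaks_a$cz[i]),
                   c(peaks_b$cx[j], peaks_b$cy[j], peaks_b$cz[j]))
  }
  cand <- NULL
  if (na > 0 && nb > 0) {
    if (criterion == "voxel_overlap") {
      cand <- dplyr::bind_rows(lapply(seq_len(na), function(i) {
        ov <- vapply(seq_len(nb), function(j) {
          length(intersect(peaks_a$voxels[[i]], peaks_b$voxels[[j]]))
        }, integer(1))
        j <- which(ov > 0)
        if (length(j) == 0) return(NULL)
        tibble(idx_a = i, idx_b = j, shared_voxels = ov[j],
               centroid_distance = vapply(j, function(jj) cda(i, jj),
                                          numeric(1)))
      }))
      if (!is.null(cand) && nrow(cand) > 0) {
        cand <- cand[order(-cand$shared_voxels, cand$centroid_distance), ]
      }
    } else {
      cand <- dplyr::bind_rows(lapply(seq_len(na), function(i) {
        d <- vapply(seq_len(nb), function(j) cda(i, j), numeric(1))
        j <- which(d <= cutoff)
        if (length(j) == 0) return(NULL)
        tibble(idx_a = i, idx_b = j, shared_voxels = NA_integer_,
               centroid_distance = d[j],
               sigma_b = peaks_b$max_sigma[j])
      }))
      if (!is.null(cand) && nrow(cand) > 0) {
        cand <- cand[order(cand$centroid_distance, -cand$sigma_b), ]
        cand$sigma_b <- NULL
      }
    }
  }
  matches <- tibble(idx_a = integer(0), idx_b = integer(0),
                    centroid_distance = numeric(0),
                    shared_voxels = integer(0))
  if (!is.null(cand) && nrow(cand) > 0) {
    used_a <- logical(na); used_b <- logical(nb)
    for (r in seq_len(nrow(cand))) {
      i <- cand$idx_a[r]; j <- cand$idx_b[r]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      matches <- dplyr::bind_rows(matches, cand[r, names(matches)])
    }
  }
  list(matches = matches,
       unmatched_a = setdiff(seq_len(na), matches$idx_a),
       unmatched_b = setdiff(seq_len(nb), matches$idx_b))
}

#' Classify matched peaks as ions and unmatched primary peaks as waters
#'
#' Peaks of the primary map with a partner in the second cation condition are
#' ions (labelled \code{K1, K2, ...} in order of position along the pore
#' axis); unmatched primary peaks are ordered waters (\code{W1, ...}). The
#' amplitude ratio of a matched pair is the partner peak's raw amplitude
#' (max sigma times that map's raw sd) over the primary peak's — about 3 for
#' Cs+ over K+.
#'
#' @param match_result Output of \code{\link{match_peaks}}.
#' @param peaks_primary,peaks_partner The peak tibbles that were matched.
#' @param axis Optional pore axis (list with origin, direction) used to
#'   order site labels; defaults to the world z axis.
#' @param ion_prefix Label prefix for ion sites (default "K").
#' @return A tibble of site assignments: \code{label},
#'   \code{classification} ("ion"/"water"), primary centroid
#'   \code{cx, cy, cz}, \code{max_sigma_primary}, \code{max_sigma_partner},
#'   \code{centroid_distance}, \code{amplitude_ratio}.
#' @export
classify_sites <- function(match_result, peaks_primary, peaks_partner = NULL,
                           axis = NULL, ion_prefix = "K") {
  m <- match_result$matches
  zg <- function(p) {
    if (is.null(axis)) return(p$cz)
    u <- axis$direction / sqrt(sum(axis$direction^2))
    as.numeric(sweep(cbind(p$cx, p$cy, p$cz), 2, axis$origin) %*% u)
  }
  rows <- list()
  if (nrow(m) > 0) {
    ion <- peaks_primary[m$idx_a, ]
    ord <- order(zg(ion))
    for (k in seq_along(ord)) {
      r <- ord[k]
      partner <- if (!is.null(peaks_partner)) peaks_partner[m$idx_b[r], ] else NULL
      rows[[length(rows) + 1]] <- tibble(
        label = paste0(ion_prefix, k),
        classification = "ion",
        cx = ion$cx[r], cy = ion$cy[r], cz = ion$cz[r],
        max_sigma_primary = ion$max_sigma[r],
        max_sigma_partner = if (!is.null(partner)) partner$max_sigma else NA_real_,
        centroid_distance = m$centroid_distance[r],
        amplitude_ratio = if (!is.null(partner))
          partner$raw_amplitude / ion$raw_amplitude[r] else NA_real_
      )
    }
  }
  um <- match_result$unmatched_a
  if (length(um) > 0) {
    wat <- peaks_primary[um, ]
    ord <- order(zg(wat))
    for (k in seq_along(ord)) {
      r <- ord[k]
      rows[[length(rows) + 1]] <- tibble(
        label = paste0("W", k),
        classification = "water",
        cx = wat$cx[r], cy = wat$cy[r], cz = wat$cz[r],
        max_sigma_primary = wat$max_sigma[r],
        max_sigma_partner = NA_real_,
        centroid_distance = NA_real_,
        amplitude_ratio = NA_real_
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(label = character(0), classification = character(0),
                  cx = numeric(0), cy = numeric(0), cz = numeric(0),
                  max_sigma_primary = numeric(0),
                  max_sigma_partner = numeric(0),
                  centroid_distance = numeric(0),
                  amplitude_ratio = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

#' Coordination geometry around assigned sites
#'
#' For each site, lists model atoms within \code{shell} of the site centroid
#' with their distances, flagged as direct protein contacts or
#' water/ion-mediated ones.
#'
#' @param assignments Site tibble from \code{\link{classify_sites}}.
#' @param model An \code{ion_structure} containing the solvent model.
#' @param shell Shell radius in Angstrom (default 4).
#' @return Tibble: \code{site}, \code{classification}, contacted atom
#'   columns, \code{distance}, \code{contact_type} ("direct" for protein,
#'   otherwise the solvent record class).
#' @export
site_geometry_report <- function(assignments, model, shell = 4) {
  xyz <- coords(model)
  out <- list()
  for (i in seq_len(nrow(assignments))) {
    ctr <- c(assignments$cx[i], assignments$cy[i], assignments$cz[i])
    d <- sqrt((xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 +
                (xyz[, 3] - ctr[3])^2)
    sel <- which(d <= shell & d > 1e-6)
    if (length(sel) == 0) next
    out[[length(out) + 1]] <- tibble(
      site = assignments$label[i],
      classification = assignments$classification[i],
      atom_name = model$atom_name[sel],
      residue_name = model$residue_name[sel],
      residue_number = model$residue_number[sel],
      chain_id = model$chain_id[sel],
      distance = d[sel],
      contact_type = ifelse(model$record_class[sel] == "protein",
                            "direct", model$record_class[sel])
    )
  }
  if (length(out) == 0) {
    return(tibble(site = character(0), classification = character(0),
                  atom_name = character(0), residue_name = character(0),
                  residue_number = integer(0), chain_id = character(0),
                  distance = numeric(0), contact_type = character(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$site, .data$distance)
}

#' Plot site assignments along the pore axis
#'
#' @param object Assignment tibble from \code{\link{classify_sites}}.
#' @param ... Unused.
#' @return A ggplot of peak sigma vs axial position, ions vs waters.
#' @export
plot_ion_sites <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$cz, y = .data$max_sigma_primary,
                               color = .data$classification)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -1,
                       show.legend = FALSE) +
    ggplot2::labs(x = "position along pore axis (Å)",
                  y = "peak height (σ, primary map)", color = NULL) +
    ggplot2::theme_minimal()
}
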