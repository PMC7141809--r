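# Probe-radius pore profiling: at each position along the channel axis, the
# radius of the largest sphere centered in that plane that touches no protein
# van der Waals sphere. Waters and ions are never obstacles, so the profile
# describes the protein-lined conduction pathway itself.

#' Van der Waals radii (Bondi-style)
#'
#' Single fixed table used for all profiling; elements not listed fall back
#' to the carbon radius.
#' @param element Character vector of element symbols.
#' @return Radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  tbl <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
  r <- tbl[toupper(trimws(element))]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Kyte-Doolittle residue hydropathy scale
#'
#' Named vector over the 20 standard residues; positive = hydrophobic.
#' @export
kyte_doolittle <- c(
  ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
  ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3,
  PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
  LYS = -3.9, ARG = -4.5
)

# run code under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Compute a pore radius profile along a channel axis
#'
#' At each step along the axis the probe center is optimized within the
#' perpendicular plane (multi-start Nelder-Mead, deterministic for a fixed
#' seed) to maximize clearance from the protein van der Waals surface. The
#' clearance at the optimum is the pore radius. Radii are capped at
#' \code{cap} (bulk solvent sentinel) and flagged \code{capped} there.
#'
#' @param structure An \code{ion_structure}; only protein atoms are
#'   obstacles.
#' @param axis List with \code{origin} and unit \code{direction}, or NULL to
#'   use the z axis through the protein centroid (use
#'   \code{\link{estimate_pore_axis}} for dimer structures).
#' @param z_range Length-2 Angstrom interval along the axis (relative to
#'   \code{axis$origin}); defaults to the protein extent.
#' @param step Sampling step in Angstrom (default 0.5).
#' @param cap Maximum reported radius in Angstrom (default 10).
#' @param max_offset Maximum in-plane distance of the probe center from the
#'   axis in Angstrom (default 4): keeps the probe inside the pore rather
#'   than escaping around the outside of the protein.
#' @param n_starts In-plane optimization restarts per step (default 8).
#' @param seed Integer seed for the restart positions.
#' @return A \code{pore_profile} tibble: \code{z}, probe center
#'   (\code{cx, cy, cz}), \code{radius}, \code{capped},
#'   \code{lining_residues} (list column of "RES<number>.<chain>" labels for
#'   the residues realizing the contact).
#' @export
compute_pore_profile <- function(structure, axis = NULL, z_range = NULL,
                                 step = 0.5, cap = 10, max_offset = 4,
                                 n_starts = 8, seed = 1) {
  stopifnot(step > 0, cap > 0, max_offset > 0)
  prot <- select_atoms(structure, .data$record_class == "protein")
  if (nrow(prot) == 0) {
    abort("no protein atoms to profile against", class = "ionpore_no_protein")
  }
  if (is.null(axis)) {
    axis <- list(origin = colMeans(coords(prot)), direction = c(0, 0, 1))
  }
  u <- axis$direction / sqrt(sum(axis$direction^2))
  # orthonormal in-plane basis
  e1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  xyz <- coords(prot)
  rel <- sweep(xyz, 2, axis$origin)
  az <- as.numeric(rel %*% u)
  a1 <- as.numeric(rel %*% e1)
  a2 <- as.numeric(rel %*% e2)
  vdw <- vdw_radius(prot$element)
  res_label <- paste0(prot$residue_name, prot$residue_number, ".",
                      prot$chain_id)
  if (is.null(z_range)) z_range <- range(az)
  zs <- seq(z_range[1], z_range[2], by = step)

  starts <- with_seed(seed, {
    ang <- runif(max(n_starts - 1, 0), 0, 2 * pi)
    rad <- sqrt(runif(max(n_starts - 1, 0))) * min(2, max_offset / 2)
    rbind(c(0, 0), cbind(rad * cos(ang), rad * sin(ang)))
  })

  one_plane <- function(z) {
    # obstacles whose sphere can constrain a probe of radius <= cap here
    sel <- abs(az - z) <= cap + vdw + 0.5
    if (!any(sel)) {
      return(list(center2d = c(0, 0), radius = cap, capped = TRUE,
                  lining = character(0)))
    }
    o1 <- a1[sel]; o2 <- a2[sel]; dz2 <- (az[sel] - z)^2; ov <- vdw[sel]
    clearance <- function(p) {
      min(sqrt((p[1] - o1)^2 + (p[2] - o2)^2 + dz2) - ov)
    }
    # clearance grows without bound outside the protein: cap the objective,
    # reject centers beyond max_offset, and nudge ties toward the axis
    objective <- function(p) {
      off <- sqrt(sum(p^2))
      if (off > max_offset) return(-(1e3 + off))
      min(clearance(p), cap + 1) - 1e-3 * off
    }
    best <- NULL; best_val <- -Inf
    for (s in seq_len(nrow(starts))) {
      fit <- optim(starts[s, ], objective,
                   control = list(fnscale = -1, reltol = 1e-10, maxit = 300))
      if (fit$value > best_val) { best_val <- fit$value; best <- fit$par }
    }
    r0 <- clearance(best)
    capped <- r0 >= cap
    r <- max(min(r0, cap), 0)
    gaps <- sqrt((best[1] - o1)^2 + (best[2] - o2)^2 + dz2) - ov - r0
    lining <- unique(res_label[sel][gaps < 0.2])
    list(center2d = best, radius = r, capped = capped, lining = lining)
  }

  planes <- lapply(zs, one_plane)
  centers <- t(vapply(seq_along(zs), function(i) {
    p <- planes[[i]]$center2d
    axis$origin + zs[i] * u + p[1] * e1 + p[2] * e2
  }, numeric(3)))
  out <- tibble(
    z = zs,
    cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
    radius = vapply(planes, `[[`, numeric(1), "radius"),
    capped = vapply(planes, `[[`, logical(1), "capped"),
    lining_residues = lapply(planes, `[[`, "lining")
  )
  structure(out,
            class = c("pore_profile", class(out)),
            axis = list(origin = axis$origin, direction = u),
            label = attr(structure, "label"))
}

#' Narrowest point of a pore profile
#'
#' @param profile A \code{pore_profile}.
#' @param z_window Length-2 interval restricting the search (default: all
#'   samples). Ties are broken toward the smaller z (cytoplasmic end).
#' @return One-row tibble: \code{z}, \code{radius}, \code{lining_residues}.
#' @export
min_constriction <- function(profile, z_window = NULL) {
  stopifnot(inherits(profile, "pore_profile"))
  s <- profile
  if (!is.null(z_window)) {
    s <- s[s$z >= z_window[1] & s$z <= z_window[2], ]
  }
  if (nrow(s) == 0) {
    abort("z window contains no profile samples", class = "ionpore_window_error")
  }
  i <- which(s$radius == min(s$radius))[1]  # smallest z wins ties
  tibble(z = s$z[i], radius = s$radius[i],
         lining_residues = s$lining_residues[i])
}

#' Annotate a pore profile with lining hydrophobicity
#'
#' Each sample is scored with the mean hydropathy of the residues having an
#' atom within \code{lining_cutoff} of the probe center; those residues
#' replace the contact-based lining list. Residues absent from the scale get
#' a neutral value of 0 with a warning.
#'
#' @param structure The profiled \code{ion_structure} (protein atoms only
#'   are considered; ions and waters never contribute).
#' @param profile A \code{pore_profile} from the same structure.
#' @param scale Named residue->value vector (default Kyte-Doolittle).
#' @param lining_cutoff Angstrom distance from probe center (default 6).
#' @return The profile with columns \code{hydrophobicity} and updated
#'   \code{lining_residues}.
#' @export
hydrophobicity_annotation <- function(structure, profile,
                                      scale = kyte_doolittle,
                                      lining_cutoff = 6) {
  stopifnot(inherits(profile, "pore_profile"))
  prot <- select_atoms(structure, .data$record_class == "protein")
  xyz <- coords(prot)
  res_label <- paste0(prot$residue_name, prot$residue_number, ".",
                      prot$chain_id)
  res_name <- prot$residue_name
  warned <- FALSE
  vals <- vector("list", nrow(profile))
  lining <- vector("list", nrow(profile))
  for (i in seq_len(nrow(profile))) {
    ctr <- c(profile$cx[i], profile$cy[i], profile$cz[i])
    d2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 +
      (xyz[, 3] - ctr[3])^2
    near <- d2 <= lining_cutoff^2
    labs <- unique(res_label[near])
    lining[[i]] <- labs
    nm <- res_name[near][!duplicated(res_label[near])]
    v <- scale[nm]
    if (anyNA(v) && !warned) {
      warn(paste0("residue(s) not in hydropathy scale, using 0: ",
                  paste(unique(nm[is.na(v)]), collapse = ", ")))
      warned <- TRUE
    }
    v[is.na(v)] <- 0
    vals[[i]] <- if (length(v) > 0) mean(v) else NA_real_
  }
  out <- profile
  out$hydrophobicity <- unlist(vals)
  out$lining_residues <- lining
  out
}

#' Plot a pore profile
#'
#' Radius along the axis, colored by hydrophobicity when annotated.
#' @param object A \code{pore_profile}.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pore_profile <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$z,
                                                       y = .data$radius))
  if ("hydrophobicity" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(color = .data$hydrophobicity),
                                linewidth = 1) +
      ggplot2::scale_color_gradient2(low = "steelblue", mid = "grey80",
                                     high = "orange", midpoint = 0,
                                     name = "hydropathy")
  } else {
    p <- p + ggplot2::geom_line(linewidth = 1)
  }
  p + ggplot2::labs(x = "position along pore axis (Å)",
                    y = "pore radius (Å)") +
    ggplot2::theme_minimal()
}
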