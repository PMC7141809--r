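# Rigid-body superposition and RMSD: the machinery behind the repeat I vs
# repeat II comparison and the open/closed (class 1 vs class 2) comparison.

#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets, via SVD of the covariance matrix with the usual
#' sign correction so the rotation is never a reflection.
#'
#' @param mobile,reference n x 3 matrices (or data frames with x, y, z) of
#'   paired coordinates, n >= 3 and not collinear.
#' @return A \code{superposition} object with \code{rotation} (3 x 3,
#'   det = +1), \code{translation}, \code{rmsd} (Angstrom) and \code{n_pairs}.
#'   Applying it maps \code{mobile} onto \code{reference}:
#'   \code{x %*% t(rotation) + translation} for row vectors.
#' @export
kabsch_superpose <- function(mobile, reference) {
  P <- as_xyz_matrix(mobile)
  Q <- as_xyz_matrix(reference)
  if (nrow(P) != nrow(Q)) {
    abort("mobile and reference must pair the same number of atoms",
          class = "ionpore_pairing_error")
  }
  n <- nrow(P)
  if (n < 3) {
    abort("superposition needs at least 3 paired points",
          class = "ionpore_underdetermined")
  }
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  # collinear clouds leave a free rotation about the line
  if (qr(Pc)$rank < 2 || qr(Qc)$rank < 2) {
    abort("superposition is underdetermined for collinear points",
          class = "ionpore_underdetermined")
  }
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  translation <- as.numeric(cq - R %*% cp)
  resid <- Pc %*% t(R) - Qc
  rmsd <- sqrt(mean(rowSums(resid^2)))
  structure(
    list(rotation = R, translation = translation, rmsd = rmsd, n_pairs = n),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: %d pairs, rmsd %.3f A>\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sup A \code{superposition}.
#' @param x n x 3 matrix of coordinates.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, x) {
  m <- as_xyz_matrix(x)
  sweep(m %*% t(sup$rotation), 2, sup$translation, "+")
}

#' @exportS3Method generics::tidy
tidy.superposition <- function(x, ...) {
  tibble(
    term = c(paste0("rotation[", rep(1:3, each = 3), ",", rep(1:3, 3), "]"),
             paste0("translation[", 1:3, "]")),
    estimate = c(as.vector(t(x$rotation)), x$translation)
  )
}

#' @exportS3Method generics::glance
glance.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_pairs = x$n_pairs,
         rotation_det = det(x$rotation))
}

as_xyz_matrix <- function(x) {
  if (inherits(x, "ion_structure") ||
      (is.data.frame(x) && all(c("x", "y", "z") %in% names(x)))) {
    x <- as.matrix(as.data.frame(x)[, c("x", "y", "z")])
  }
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (ncol(m) != 3 || !all(is.finite(m))) {
    abort("coordinates must be a finite n x 3 matrix",
          class = "ionpore_format_error")
  }
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Superposed RMSD between two models
#'
#' Pairs atoms between the two structures, superposes the shared set, and
#' returns the minimized RMSD. The default scope is "all-atom" in the sense
#' used for model-vs-model comparisons: protein atoms only, since solvent
#' placement differs between independently built models. Pass
#' \code{scope = "all"} to include ions and waters that are present in both.
#'
#' @param a,b \code{ion_structure} tables.
#' @param pairing "by_identity" pairs on (chain, residue number, atom name);
#'   "by_sequence_map" pairs residue ranges via \code{pair_map}.
#' @param scope "protein" (default) or "all".
#' @param pair_map For "by_sequence_map": a data frame with columns
#'   \code{chain_a, start_a, end_a, chain_b, start_b} mapping residue
#'   \code{i} in \code{[start_a, end_a]} of chain_a to residue
#'   \code{start_b + (i - start_a)} of chain_b, paired atom-name to
#'   atom-name within residues (falling back to CA-only when side-chain
#'   composition differs).
#' @return The superposed RMSD in Angstrom. The full \code{superposition}
#'   is attached as attribute \code{"superposition"}.
#' @export
rmsd_between_models <- function(a, b,
                                pairing = c("by_identity", "by_sequence_map"),
                                scope = c("protein", "all"),
                                pair_map = NULL) {
  pairing <- match.arg(pairing)
  scope <- match.arg(scope)
  if (scope == "protein") {
    a <- select_atoms(a, .data$record_class == "protein")
    b <- select_atoms(b, .data$record_class == "protein")
  }
  if (pairing == "by_identity") {
    ka <- paste(a$chain_id, a$residue_number, a$atom_name)
    kb <- paste(b$chain_id, b$residue_number, b$atom_name)
    shared <- intersect(ka, kb)
    if (length(shared) < 3) {
      abort("fewer than 3 shared atoms between models",
            class = "ionpore_pairing_error")
    }
    P <- coords(a)[match(shared, ka), , drop = FALSE]
    Q <- coords(b)[match(shared, kb), , drop = FALSE]
  } else {
    if (is.null(pair_map)) {
      abort("pair_map required for by_sequence_map pairing",
            class = "ionpore_pairing_error")
    }
    pm <- pair_residues(a, b, pair_map)
    if (nrow(pm$P) < 3) {
      abort("sequence map yields fewer than 3 atom pairs",
            class = "ionpore_pairing_error")
    }
    P <- pm$P; Q <- pm$Q
  }
  sup <- kabsch_superpose(P, Q)
  structure(sup$rmsd, superposition = sup)
}

# Pair atoms across residue ranges related by a fixed offset; atom-name
# matching within each residue pair, CA-only fallback for mismatched residues.
pair_residues <- function(a, b, pair_map) {
  P <- NULL; Q <- NULL
  for (r in seq_len(nrow(pair_map))) {
    row <- pair_map[r, ]
    for (res_a in seq(row$start_a, row$end_a)) {
      res_b <- row$start_b + (res_a - row$start_a)
      at_a <- a[a$chain_id == row$chain_a & a$residue_number == res_a, ]
      at_b <- b[b$chain_id == row$chain_b & b$residue_number == res_b, ]
      if (nrow(at_a) == 0 || nrow(at_b) == 0) next
      shared <- intersect(at_a$atom_name, at_b$atom_name)
      same_res <- length(unique(at_a$residue_name)) == 1 &&
        length(unique(at_b$residue_name)) == 1 &&
        at_a$residue_name[1] == at_b$residue_name[1]
      if (!same_res) shared <- intersect(shared, "CA")
      if (length(shared) == 0) next
      P <- rbind(P, as.matrix(at_a[match(shared, at_a$atom_name),
                                   c("x", "y", "z")]))
      Q <- rbind(Q, as.matrix(at_b[match(shared, at_b$atom_name),
                                   c("x", "y", "z")]))
    }
  }
  list(P = P, Q = Q)
}

#' Euclidean distance between two points
#'
#' @param a,b Finite 3-vectors (Angstrom).
#' @return Distance in Angstrom.
#' @export
point_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 3, length(b) == 3, all(is.finite(c(a, b))))
  sqrt(sum((a - b)^2))
}

#' Estimate the two-fold pore axis of a homodimer
#'
#' Superposes one chain onto the other (pairing residue number + atom name)
#' and extracts the rotation axis — for a two-fold symmetric dimer this is
#' the pore axis. The axis passes through the midpoint of the two chain
#' centroids; direction is normalized with a positive z component.
#'
#' @param structure An \code{ion_structure} with exactly two protein chains.
#' @return List with \code{origin} and unit \code{direction}.
#' @export
estimate_pore_axis <- function(structure) {
  prot <- select_atoms(structure, .data$record_class == "protein")
  chains <- sort(unique(prot$chain_id))
  if (length(chains) != 2) {
    abort("axis estimation needs exactly two protein chains",
          class = "ionpore_geometry_error")
  }
  a <- prot[prot$chain_id == chains[1], ]
  b <- prot[prot$chain_id == chains[2], ]
  ka <- paste(a$residue_number, a$atom_name)
  kb <- paste(b$residue_number, b$atom_name)
  shared <- intersect(ka, kb)
  if (length(shared) < 3) {
    abort("chains share too few atoms for axis estimation",
          class = "ionpore_pairing_error")
  }
  P <- coords(a)[match(shared, ka), , drop = FALSE]
  Q <- coords(b)[match(shared, kb), , drop = FALSE]
  sup <- kabsch_superpose(P, Q)
  ev <- eigen(sup$rotation)
  k <- which.min(abs(ev$values - 1))
  axis <- Re(ev$vectors[, k])
  axis <- axis / sqrt(sum(axis^2))
  if (axis[3] < 0) axis <- -axis
  origin <- (colMeans(P) + colMeans(Q)) / 2
  list(origin = as.numeric(origin), direction = axis)
}
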