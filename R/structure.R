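# Atom tables: the shared coordinate model for all pipeline stages.

# Residue-name -> record class lookup. Fixed table; unknown hetero residues
# fall through to "other".
.ION_RESIDUES <- c("K", "CS", "NA", "MG", "CA", "ZN", "CL", "RB", "LI", "MN")
.WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")
.AMINO_ACIDS <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)

.ELEMENTS <- c(
  "H", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE", "NA", "MG", "AL",
  "SI", "P", "S", "CL", "AR", "K", "CA", "MN", "FE", "CO", "NI", "CU",
  "ZN", "SE", "BR", "RB", "SR", "MO", "I", "CS", "BA", "W", "PT", "AU", "HG"
)

#' Classify a residue name as protein, ion, water or other
#'
#' @param residue_name Character vector of 3-letter (or ion) residue codes.
#' @return Character vector over \code{c("protein", "ion", "water", "other")}.
#' @export
record_class_of <- function(residue_name) {
  rn <- toupper(trimws(residue_name))
  dplyr::case_when(
    rn %in% .WATER_RESIDUES ~ "water",
    rn %in% .ION_RESIDUES ~ "ion",
    rn %in% .AMINO_ACIDS ~ "protein",
    TRUE ~ "other"
  )
}

#' Build a structure (tidy atom table)
#'
#' A structure is a tibble with one row per atom and columns
#' \code{element}, \code{atom_name}, \code{residue_name}, \code{residue_number},
#' \code{chain_id}, \code{x}, \code{y}, \code{z} (Angstrom), \code{occupancy},
#' \code{b_factor} and \code{record_class}. The \code{label} and
#' \code{condition} attributes carry provenance (e.g. "class1-K", condition
#' "K", "Cs" or "synthetic").
#'
#' @param atoms Data frame with at least element, atom_name, residue_name,
#'   residue_number, chain_id, x, y, z. Missing occupancy defaults to 1,
#'   missing b_factor to 0; record_class is derived from residue_name when
#'   absent.
#' @param label Free-text label for the model.
#' @param condition One of "K", "Cs", "synthetic".
#' @return A tibble of class \code{ion_structure}.
#' @export
new_structure <- function(atoms, label = "structure", condition = "synthetic") {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) == 0) {
    abort("structure must contain at least one atom", class = "ionpore_empty_structure")
  }
  needed <- c("element", "atom_name", "residue_name", "residue_number",
              "chain_id", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "ionpore_format_error")
  }
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"b_factor" %in% names(atoms)) atoms$b_factor <- 0
  if (!"record_class" %in% names(atoms)) {
    atoms$record_class <- record_class_of(atoms$residue_name)
  }
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) {
    abort("atom coordinates must be finite", class = "ionpore_format_error")
  }
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1)) {
    abort("occupancy must lie in [0, 1]", class = "ionpore_format_error")
  }
  bad_el <- setdiff(unique(toupper(trimws(atoms$element))), .ELEMENTS)
  if (length(bad_el) > 0) {
    abort(paste0("unknown element symbol(s): ", paste(bad_el, collapse = ", ")),
          class = "ionpore_format_error")
  }
  atoms <- atoms[, c(needed[1:5], "x", "y", "z", "occupancy", "b_factor",
                     "record_class")]
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name,
               atoms$residue_name)
  if (anyDuplicated(key)) {
    abort("duplicate (chain, residue, atom) triples in atom table",
          class = "ionpore_format_error")
  }
  structure(atoms,
            class = c("ion_structure", class(atoms)),
            label = label, condition = condition)
}

#' @export
print.ion_structure <- function(x, ...) {
  cat(sprintf("<ion_structure '%s' (%s): %d atoms, %d chains>\n",
              attr(x, "label"), attr(x, "condition"), nrow(x),
              length(unique(x$chain_id))))
  NextMethod()
}

restore_structure <- function(new, template) {
  structure(as_tibble(new),
            class = c("ion_structure", class(as_tibble(new))),
            label = attr(template, "label"),
            condition = attr(template, "condition"))
}

#' Read a coordinate file into a structure table
#'
#' Parses PDB or mmCIF via bio3d and returns a tidy atom table. Only the
#' highest-occupancy alternate location of each atom is kept; coordinates are
#' Angstrom in the deposition frame with author residue numbering.
#'
#' @param path Path to a .pdb or .cif file.
#' @param format "pdb" or "mmcif"; guessed from the extension by default.
#' @param label,condition Provenance attributes for the returned structure.
#' @return An \code{ion_structure} tibble.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           label = basename(path), condition = "synthetic") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("coordinate file not found: ", path),
          class = "ionpore_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) {
      abort(paste0("failed to parse ", format, " file '", path, "': ",
                   conditionMessage(e)),
            class = "ionpore_format_error")
    }
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) {
    abort(paste0("no atoms in ", path), class = "ionpore_empty_structure")
  }
  # keep highest-occupancy altloc per atom site
  o <- if ("o" %in% names(at)) ifelse(is.na(at$o), 1, at$o) else rep(1, nrow(at))
  key <- paste(at$chain, at$resno, at$elety, at$resid)
  keep <- !duplicated(key[order(-o)])[order(order(-o))]
  at <- at[keep, , drop = FALSE]
  o <- o[keep]
  elem <- if ("elesy" %in% names(at) && !all(is.na(at$elesy)) &&
              !all(trimws(at$elesy) == "")) {
    trimws(at$elesy)
  } else {
    # fall back to first letter(s) of the atom name
    sub("^([A-Za-z]{1,2}).*", "\\1", trimws(at$elety))
  }
  elem <- ifelse(is.na(elem) | elem == "",
                 substr(trimws(at$elety), 1, 1), elem)
  # single-letter fallback when the guess is not a known element
  elem_up <- toupper(elem)
  bad <- !(elem_up %in% .ELEMENTS)
  elem_up[bad] <- substr(toupper(trimws(at$elety[bad])), 1, 1)
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  new_structure(
    tibble(
      element = elem_up,
      atom_name = trimws(at$elety),
      residue_name = trimws(at$resid),
      residue_number = as.integer(at$resno),
      chain_id = chain,
      x = at$x, y = at$y, z = at$z,
      occupancy = pmin(pmax(o, 0), 1),
      b_factor = ifelse(is.na(at$b), 0, at$b)
    ),
    label = label, condition = condition
  )
}

#' Write a structure to a PDB file
#'
#' @param structure An \code{ion_structure}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "ion_structure"))
  type <- ifelse(structure$record_class == "protein", "ATOM", "HETATM")
  xyz <- as.vector(t(as.matrix(structure[, c("x", "y", "z")])))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz, type = type,
    resno = structure$residue_number,
    resid = structure$residue_name,
    eleno = seq_len(nrow(structure)),
    elety = structure$atom_name,
    chain = structure$chain_id,
    o = structure$occupancy,
    b = structure$b_factor,
    elesy = structure$element
  )
  invisible(path)
}

#' Select atoms with a tidy predicate
#'
#' The selection grammar is an R expression over the atom-table columns
#' (\code{element}, \code{atom_name}, \code{residue_name},
#' \code{residue_number}, \code{chain_id}, \code{x}, \code{y}, \code{z},
#' \code{occupancy}, \code{b_factor}, \code{record_class}), evaluated with
#' tidy semantics as in \code{dplyr::filter()}. Row order is preserved and an
#' empty selection is allowed.
#'
#' @param structure An \code{ion_structure}.
#' @param predicate Logical expression over atom columns, e.g.
#'   \code{record_class == "water"} or
#'   \code{chain_id == "A" & dplyr::between(residue_number, 30, 173)}.
#' @return The selected subset, still an \code{ion_structure}.
#' @examples
#' s <- make_toy_channel(seed = 1)$structure
#' select_atoms(s, record_class == "protein")
#' @export
select_atoms <- function(structure, predicate) {
  stopifnot(inherits(structure, "ion_structure"))
  quo <- enquo(predicate)
  keep <- tryCatch(
    eval_tidy(quo, data = as.data.frame(structure)),
    error = function(e) {
      abort(paste0("malformed selection predicate: ", conditionMessage(e)),
            class = "ionpore_selection_error")
    }
  )
  if (is.logical(keep) && length(keep) == 1) {
    keep <- rep(keep, nrow(structure))
  }
  if (!is.logical(keep) || length(keep) != nrow(structure)) {
    abort("selection predicate must yield one logical per atom",
          class = "ionpore_selection_error")
  }
  keep[is.na(keep)] <- FALSE
  restore_structure(structure[keep, , drop = FALSE], structure)
}

#' Atom coordinates as a numeric matrix
#'
#' @param structure An \code{ion_structure}.
#' @return An n x 3 matrix of Angstrom coordinates.
#' @export
coords <- function(structure) {
  m <- as.matrix(structure[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}
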