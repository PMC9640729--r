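#' Atom tables
#'
#' An atom table is an ordinary tibble with one row per atom and columns
#' `serial` (integer, unique within a frame), `name`, `element`,
#' `residue_name`, `residue_id`, `chain_id`, `x`, `y`, `z` (coordinates, in
#' angstroms), `weight` (the nonnegative contact weight `w` of the weighted
#' point `a = (p, w)`) and `is_ligand`.  A trajectory is the same table with
#' leading `frame` (0-based) and `time_ps` columns; every frame shares one
#' topology (same serials, names, residues and ligand flags in the same
#' order).
#'
#' @param serial integer atom serials.
#' @param x,y,z coordinates in angstroms.
#' @param element element symbols; used to assign default weights.
#' @param name,residue_name,residue_id,chain_id,is_ligand optional metadata.
#' @param weight explicit weights; by default assigned from `element` via
#'   [atom_weights()].
#' @param weight_scheme `"vdw_radius"` (default) or `"mass"`.
#' @return a tibble with the atom-table columns above.
#' @examples
#' atom_table(serial = 1:4, x = c(0, 1, 0, 0), y = c(0, 0, 1, 0),
#'            z = c(0, 0, 0, 1), element = "C")
#' @export
atom_table <- function(serial, x, y, z, element = "C",
                       name = element, residue_name = "UNK",
                       residue_id = 1L, chain_id = "A",
                       is_ligand = FALSE, weight = NULL,
                       weight_scheme = c("vdw_radius", "mass")) {
  weight_scheme <- match.arg(weight_scheme)
  tb <- tibble(
    serial = as.integer(serial),
    name = as.character(name),
    element = toupper(as.character(element)),
    residue_name = as.character(residue_name),
    residue_id = as.integer(residue_id),
    chain_id = as.character(chain_id),
    x = as.double(x), y = as.double(y), z = as.double(z),
    is_ligand = as.logical(is_ligand)
  )
  tb$weight <- if (is.null(weight)) atom_weights(tb$element, weight_scheme)
               else as.double(weight)
  validate_atoms(tb)
}

#' Default atom weights by element
#'
#' The weighted-point formulation takes each atom as a pair `a = (p, w)`.
#' The default weight is the element's van der Waals radius in angstroms,
#' which makes the orthogonality predicates (sphere tangency/overlap)
#' geometrically meaningful; atomic mass is available as an alternative
#' scheme and is recorded in downstream metadata when chosen.
#'
#' @param element character vector of element symbols.
#' @param scheme `"vdw_radius"` (angstroms, default) or `"mass"` (amu).
#' @return numeric vector of weights.
#' @examples
#' atom_weights(c("C", "N", "O"))
#' @export
atom_weights <- function(element, scheme = c("vdw_radius", "mass")) {
  scheme <- match.arg(scheme)
  el <- toupper(as.character(element))
  tab <- if (scheme == "vdw_radius") .vdw_radii else .atomic_masses
  w <- unname(tab[el])
  w[is.na(w)] <- if (scheme == "vdw_radius") 1.70 else 12.011
  w
}

# Bondi van der Waals radii, angstroms
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
  NA. = 2.27, K = 2.75, MG = 1.73, ZN = 1.39, FE = 1.70, CA = 2.31
)
names(.vdw_radii)[names(.vdw_radii) == "NA."] <- "NA"

.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, SE = 78.971,
  NA. = 22.990, K = 39.098, MG = 24.305, ZN = 65.38, FE = 55.845, CA = 40.078
)
names(.atomic_masses)[names(.atomic_masses) == "NA."] <- "NA"

validate_atoms <- function(atoms, arg = "atoms") {
  req <- c("serial", "x", "y", "z", "weight", "is_ligand")
  missing <- setdiff(req, names(atoms))
  if (length(missing) > 0)
    abort(paste0(arg, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  if (nrow(atoms) < 1) abort(paste0(arg, " must contain at least one atom"))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    abort("atom coordinates must be finite")
  if (any(atoms$weight < 0) || !all(is.finite(atoms$weight)))
    abort("atom weights must be finite and nonnegative")
  if (anyDuplicated(atoms$serial))
    abort("atom serials must be unique within a frame")
  atoms
}

validate_trajectory <- function(traj) {
  if (!"frame" %in% names(traj))
    abort("trajectory must have a 'frame' column")
  frames <- split(traj, traj$frame)
  if (length(frames) < 1) abort("trajectory must contain at least one frame")
  key <- topology_key(frames[[1]])
  for (f in frames) {
    validate_atoms(f, arg = "frame")
    if (!identical(topology_key(f), key))
      abort("inconsistent topology: frames do not share one atom list")
  }
  traj
}

#' @keywords internal
topology_key <- function(frame) {
  nm <- if ("name" %in% names(frame)) frame$name else rep("", nrow(frame))
  ri <- if ("residue_id" %in% names(frame)) frame$residue_id else rep(1L, nrow(frame))
  ch <- if ("chain_id" %in% names(frame)) frame$chain_id else rep("A", nrow(frame))
  paste(frame$serial, nm, ri, ch, frame$is_ligand, sep = "|")
}

#' Number of frames in a trajectory table
#' @param traj a trajectory tibble (atom table with a `frame` column).
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  if (!"frame" %in% names(traj)) return(1L)
  length(unique(traj$frame))
}

#' Split a trajectory into a list of single-frame atom tables
#' @inheritParams n_frames
#' @return named list of atom tibbles, in frame order.
#' @export
trajectory_frames <- function(traj) {
  if (!"frame" %in% names(traj)) return(list(`0` = traj))
  split(traj, traj$frame)  # split() on an integer orders levels numerically
}

#' Turn a single frame into a one-frame trajectory
#' @param frame an atom tibble.
#' @param time_ps frame time in picoseconds.
#' @return trajectory tibble with `frame = 0`.
#' @export
as_trajectory <- function(frame, time_ps = 0) {
  if ("frame" %in% names(frame)) return(frame)
  bind_cols(tibble(frame = 0L, time_ps = as.double(time_ps)), frame)
}
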