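#' Drug-target interface sets
#'
#' Surface atoms are extracted three times: `A` for the whole complex, `B`
#' for the isolated target (receptor atoms only) and `C` for the isolated
#' drug (ligand atoms only).  Atoms that are surface in an isolated
#' structure but buried in the complex are the interacting atoms:
#' `I = (B U C) - A`, split into target side `I_t = I ^ B` and drug side
#' `I_d = I ^ C`.
#'
#' Sub-structures with fewer than 4 atoms, or with coplanar positions, have
#' no tetrahedral alpha complex; all their atoms are trivially exposed and
#' are reported as surface.  Other geometry failures propagate with the
#' sub-structure named.
#'
#' @param frame single-frame atom tibble containing both receptor and
#'   ligand atoms.
#' @param alpha alpha parameter passed to [alpha_surface()].
#' @return list of sorted integer serial vectors `A`, `B`, `C`, `I`, `I_t`,
#'   `I_d`.
#' @export
interface_sets <- function(frame, alpha = 0) {
  if ("frame" %in% names(frame)) {
    fr <- trajectory_frames(frame)
    if (length(fr) > 1) abort("interface_sets() takes a single frame")
    frame <- fr[[1]]
  }
  validate_atoms(frame)
  rec <- frame[!frame$is_ligand, ]
  lig <- frame[frame$is_ligand, ]
  if (nrow(rec) == 0 || nrow(lig) == 0)
    abort("frame must contain both receptor and ligand atoms")
  A <- surface_serials(frame, alpha, "complex")
  B <- surface_serials(rec, alpha, "target")
  C <- surface_serials(lig, alpha, "drug")
  I <- sort(setdiff(union(B, C), A))
  list(A = A, B = B, C = C, I = I,
       I_t = sort(intersect(I, B)), I_d = sort(intersect(I, C)))
}

# surface serials with the small/degenerate fallback (all atoms exposed)
surface_serials <- function(atoms, alpha, label) {
  if (nrow(atoms) < 4) return(sort(atoms$serial))
  rep <- tryCatch(alpha_surface(atoms, alpha), error = function(e) {
    if (grepl("coplanar", conditionMessage(e))) return(NULL)
    abort(paste0("alpha_surface failed on ", label, ": ",
                 conditionMessage(e)))
  })
  if (is.null(rep)) return(sort(atoms$serial))
  sort(rep$serial[rep$on_surface])
}

#' Match predicate for an interface atom pair
#'
#' A target-side / drug-side surface-atom pair is matched (strong
#' interaction) when one atom is convex and the other concave, i.e. when
#' the product of their convexity scores `cos(omega)/4` is strictly
#' negative.  Pairs with equal-signed or zero scores are unmatched.
#'
#' @param omega_b,omega_c solid angles (steradians) of the target-side and
#'   drug-side atoms; vectorized.
#' @return integer 0/1 vector (`NA` angles give 0).
#' @details A score of exactly zero (within the same 1e-12 tolerance used by
#'   [classify_convexity()]) never matches: the product must be strictly
#'   negative.
#' @examples
#' pair_match(acos(0.8), acos(-0.4))  # opposite curvature: matched
#' @export
pair_match <- function(omega_b, omega_c) {
  zero <- function(v) ifelse(!is.na(v) & abs(v) <= 1e-12, 0, v)
  prod <- zero(cos(omega_b) / 4) * zero(cos(omega_c) / 4)
  as.integer(!is.na(prod) & prod < 0)
}

#' Trajectory matching rate
#'
#' For each frame, interface sets are built and every target-side /
#' drug-side pair `(i in I_t, j in I_d)` whose inter-atom distance is at
#' most `contact_cutoff` is tested with [pair_match()], using the solid
#' angles of each atom in its isolated structure.  The matching rate is the
#' total matched-pair count over the trajectory divided by the number of
#' frames (a per-frame matched count, not a fraction); the fraction of
#' considered pairs that matched is reported alongside.
#'
#' @param traj trajectory tibble.
#' @param alpha alpha parameter for surface extraction.
#' @param contact_cutoff maximum pair distance in angstroms (default 5;
#'   `Inf` enumerates all interface pairs).
#' @return one-row tibble: `matching_rate`, `matched_fraction` (`NA` when no
#'   pair was considered), `n_frames`, plus a `per_frame` attribute with
#'   matched counts per frame.
#' @export
matching_rate <- function(traj, alpha = 0, contact_cutoff = 5) {
  traj <- as_trajectory(traj)
  frames <- trajectory_frames(traj)
  if (length(frames) < 1) abort("empty trajectory")
  matched <- integer(length(frames))
  considered <- integer(length(frames))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    sets <- interface_sets(f, alpha)
    if (length(sets$I_t) == 0 || length(sets$I_d) == 0) next
    rec <- f[!f$is_ligand, ]
    lig <- f[f$is_ligand, ]
    om_b <- atom_omegas(rec, alpha)
    om_c <- atom_omegas(lig, alpha)
    it <- sets$I_t; id <- sets$I_d
    pi_t <- match(it, f$serial); pi_d <- match(id, f$serial)
    dmat <- cross_distances(f[pi_t, ], f[pi_d, ])
    keep <- dmat <= contact_cutoff
    considered[k] <- sum(keep)
    if (!any(keep)) next
    fb <- om_b[as.character(it)]
    fc <- om_c[as.character(id)]
    mm <- outer(fb, fc, function(ob, oc) pair_match(ob, oc))
    matched[k] <- sum(mm[keep], na.rm = TRUE)
  }
  out <- tibble(
    matching_rate = sum(matched) / length(frames),
    matched_fraction = if (sum(considered) > 0) sum(matched) / sum(considered)
                       else NA_real_,
    n_frames = length(frames)
  )
  attr(out, "per_frame") <- matched
  out
}

# named vector serial -> omega within an isolated structure
atom_omegas <- function(atoms, alpha) {
  if (nrow(atoms) < 4)
    return(setNames(rep(NA_real_, nrow(atoms)), as.character(atoms$serial)))
  rep <- tryCatch(alpha_surface(atoms, alpha), error = function(e) NULL)
  if (is.null(rep))
    return(setNames(rep(NA_real_, nrow(atoms)), as.character(atoms$serial)))
  setNames(rep$omega, as.character(rep$serial))
}

cross_distances <- function(a, b) {
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Convex atoms at the complex interface
#'
#' Counts surface atoms of the whole complex labeled convex within the
#' interface neighbourhood: atoms in the interacting set `I` plus atoms
#' within `contact_cutoff` of any ligand atom.
#'
#' @param frame single-frame atom tibble.
#' @param alpha alpha parameter.
#' @param contact_cutoff neighbourhood radius around the ligand, angstroms.
#' @return integer count.
#' @export
convex_interface_count <- function(frame, alpha = 0, contact_cutoff = 5) {
  if ("frame" %in% names(frame)) {
    fr <- trajectory_frames(frame)
    if (length(fr) > 1) abort("convex_interface_count() takes a single frame")
    frame <- fr[[1]]
  }
  sets <- interface_sets(frame, alpha)
  lig <- frame[frame$is_ligand, ]
  dmin <- apply(cross_distances(frame, lig), 1, min)
  nb_serials <- union(sets$I, frame$serial[dmin <= contact_cutoff])
  surf <- alpha_surface(frame, alpha)
  sum(surf$on_surface & !is.na(surf$shape_label) &
        surf$shape_label == "convex" & surf$serial %in% nb_serials)
}
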