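#' Receptor-drug connectivity over a trajectory
#'
#' In frame `k`, receptor atom `i` and drug atom `j` are connected when
#' their Euclidean distance is at most `threshold` (inclusive).  `C_{k,i}`
#' counts the drug atoms connected to receptor atom `i`; `D_k` counts
#' receptor atoms with at least one connection; the trajectory summary
#' `E_k` is the mean of `D_k` over frames.  Atoms connected in every frame
#' ("throughout the simulation") are reported as `d_persistent`.
#'
#' @param traj trajectory tibble.
#' @param threshold distance threshold in angstroms (default 40, the local
#'   threshold used for this descriptor; inclusive comparison).
#' @return list with `d_k` (tibble `frame`, `d_k`), `e_k` (mean connected
#'   receptor atoms per frame) and `d_persistent` (receptor atoms connected
#'   in every frame).
#' @export
connectivity <- function(traj, threshold = 40) {
  if (!is.numeric(threshold) || threshold <= 0)
    abort("threshold must be a positive number")
  traj <- as_trajectory(traj)
  frames <- trajectory_frames(traj)
  f1 <- frames[[1]]
  if (!any(f1$is_ligand) || !any(!f1$is_ligand))
    abort("trajectory must contain both receptor and ligand atoms")
  connected <- matrix(FALSE, nrow = sum(!f1$is_ligand), ncol = length(frames))
  d_k <- integer(length(frames))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    rec <- f[!f$is_ligand, ]
    lig <- f[f$is_ligand, ]
    c_ki <- rowSums(cross_distances(rec, lig) <= threshold)
    connected[, k] <- c_ki > 0
    d_k[k] <- sum(c_ki > 0)
  }
  list(
    d_k = tibble(frame = as.integer(names(frames)), d_k = d_k),
    e_k = mean(d_k),
    d_persistent = sum(rowSums(connected) == length(frames))
  )
}

#' Binding-site positioning distances
#'
#' Euclidean distances between binding-site alpha-carbon atoms and the
#' drug-center atoms, per frame.  With `n_ca` CA atoms and `n_c` center
#' atoms the result is an `n_frames x (n_ca * n_c)` matrix, pairs ordered
#' CA-major; `d_avg` is the mean of all entries.
#'
#' @param traj trajectory tibble.
#' @param ca_serials serials of the binding-site CA atoms (see
#'   [select_binding_site()]).
#' @param center_serials serials of the drug-center atoms (see
#'   [drug_center_atoms()]).
#' @return list with `distances` (matrix, columns named
#'   `ca<serial>_c<serial>`) and `d_avg`.
#' @export
binding_site_distances <- function(traj, ca_serials, center_serials) {
  traj <- as_trajectory(traj)
  if (length(ca_serials) == 0 || length(center_serials) == 0)
    abort("ca_serials and center_serials must be nonempty")
  frames <- trajectory_frames(traj)
  f1 <- frames[[1]]
  missing <- setdiff(c(ca_serials, center_serials), f1$serial)
  if (length(missing) > 0)
    abort(paste0("unknown serial(s): ", paste(missing, collapse = ", ")))
  pairs <- expand.grid(center = center_serials, ca = ca_serials)[, c("ca", "center")]
  mat <- matrix(NA_real_, nrow = length(frames), ncol = nrow(pairs),
                dimnames = list(NULL, paste0("ca", pairs$ca, "_c", pairs$center)))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    ia <- match(pairs$ca, f$serial)
    ib <- match(pairs$center, f$serial)
    mat[k, ] <- sqrt((f$x[ia] - f$x[ib])^2 + (f$y[ia] - f$y[ib])^2 +
                       (f$z[ia] - f$z[ib])^2)
  }
  list(distances = mat, d_avg = mean(mat))
}

#' Default binding-site CA selection
#'
#' Selects the CA atoms of receptor residues having any atom within
#' `cutoff` of any ligand atom in the first frame.  Structures without CA
#' atoms (coarse or toy models) fall back to the contact receptor atoms
#' themselves.
#'
#' @param traj trajectory tibble.
#' @param cutoff residue-contact cutoff in angstroms (default 5).
#' @return integer vector of CA serials.
#' @export
select_binding_site <- function(traj, cutoff = 5) {
  f <- trajectory_frames(as_trajectory(traj))[[1]]
  rec <- f[!f$is_ligand, ]
  lig <- f[f$is_ligand, ]
  dmin <- apply(cross_distances(rec, lig), 1, min)
  res <- unique(rec[dmin <= cutoff, c("chain_id", "residue_id")])
  ca <- rec[rec$name == "CA" &
              paste(rec$chain_id, rec$residue_id) %in%
                paste(res$chain_id, res$residue_id), ]
  if (nrow(ca) == 0) ca <- rec[dmin <= cutoff, ]
  sort(ca$serial)
}

#' Drug-center atoms
#'
#' The `k` ligand atoms nearest the ligand centroid in the first frame
#' (default 2, the worked-example convention); `method = "centroid"` instead
#' returns no serials and callers should use the centroid directly.
#'
#' @param traj trajectory tibble.
#' @param k number of center atoms.
#' @return integer vector of ligand serials, length `k`.
#' @export
drug_center_atoms <- function(traj, k = 2) {
  f <- trajectory_frames(as_trajectory(traj))[[1]]
  lig <- f[f$is_ligand, ]
  if (nrow(lig) < k) abort("fewer ligand atoms than requested centers")
  ctr <- c(mean(lig$x), mean(lig$y), mean(lig$z))
  d <- sqrt((lig$x - ctr[1])^2 + (lig$y - ctr[2])^2 + (lig$z - ctr[3])^2)
  sort(lig$serial[order(d, lig$serial)][seq_len(k)])
}

#' Geometric hydrogen-bond count over a trajectory
#'
#' Per frame, donor-acceptor pairs across the receptor-drug interface are
#' counted when the heavy-atom (donor-acceptor) distance is at most
#' `dist_cutoff` and, when the donor carries a resolvable hydrogen (within
#' 1.25 angstrom of the donor on the same side), the D-H...A angle is at
#' least `angle_cutoff`.  Structures without hydrogens fall back to the
#' distance-only criterion, flagged in the output.  Donors and acceptors
#' are N and O atoms (and S when `include_sulfur`).  The trajectory total
#' is the primary value (per-frame mean reported alongside).
#'
#' @param traj trajectory tibble.
#' @param dist_cutoff heavy-atom distance cutoff, angstroms (default 3.0).
#' @param angle_cutoff D-H...A angle cutoff, degrees (default 135).
#' @param include_sulfur also allow S as donor/acceptor.
#' @param between `"interface"` (default: donor and acceptor on opposite
#'   sides of the receptor/ligand split) or `"all"` pairs.
#' @return one-row tibble: `hb_total`, `hb_per_frame_mean`, `n_frames`,
#'   `used_hydrogens`.
#' @export
count_hydrogen_bonds <- function(traj, dist_cutoff = 3.0, angle_cutoff = 135,
                                 include_sulfur = FALSE,
                                 between = c("interface", "all")) {
  between <- match.arg(between)
  traj <- as_trajectory(traj)
  frames <- trajectory_frames(traj)
  elements <- c("N", "O", if (include_sulfur) "S")
  f1 <- frames[[1]]
  polar <- f1$element %in% elements
  if (!any(polar)) {
    warn("no donor/acceptor atoms found")
    return(tibble(hb_total = 0L, hb_per_frame_mean = 0,
                  n_frames = length(frames), used_hydrogens = FALSE))
  }
  has_h <- any(f1$element == "H")
  total <- 0L
  for (f in frames) {
    pol <- f[f$element %in% elements, ]
    dmat <- cross_distances(pol, pol)
    ok <- dmat <= dist_cutoff
    diag(ok) <- FALSE
    if (between == "interface")
      ok <- ok & outer(pol$is_ligand, pol$is_ligand, "!=")
    if (!has_h) {
      # distance-only: each unordered qualifying pair counts once
      total <- total + sum(ok & upper.tri(ok))
    } else {
      hyd <- f[f$element == "H", ]
      # attach each hydrogen to its nearest heavy polar atom within 1.25 A
      dh <- cross_distances(pol, hyd)
      n_bonds <- 0L
      for (d in seq_len(nrow(pol))) {
        hs <- which(dh[d, ] <= 1.25 & hyd$is_ligand == pol$is_ligand[d])
        if (length(hs) == 0) next
        acc <- which(ok[d, ])
        for (a in acc) {
          for (h in hs) {
            v1 <- c(pol$x[d] - hyd$x[h], pol$y[d] - hyd$y[h],
                    pol$z[d] - hyd$z[h])
            v2 <- c(pol$x[a] - hyd$x[h], pol$y[a] - hyd$y[h],
                    pol$z[a] - hyd$z[h])
            ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                       (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))))
            if (ang * 180 / pi >= angle_cutoff) {
              n_bonds <- n_bonds + 1L
              break  # one bond per donor-acceptor pair
            }
          }
        }
      }
      total <- total + n_bonds
    }
  }
  total <- as.integer(round(total))
  tibble(hb_total = total, hb_per_frame_mean = total / length(frames),
         n_frames = length(frames), used_hydrogens = has_h)
}

#' One-call geometric feature extraction for a trajectory
#'
#' Computes the geometric feature block for one receptor-drug trajectory:
#' matching rate, convex interface atoms (mean over frames), connectivity,
#' binding-site positioning distance and hydrogen-bond count, with the
#' parameters used recorded as provenance columns.
#'
#' @param traj trajectory tibble.
#' @param alpha alpha parameter for surface extraction.
#' @param threshold connectivity threshold, angstroms.
#' @param contact_cutoff interface-pair cutoff for the matching rate and
#'   convex-atom neighbourhood, angstroms.
#' @param hb_dist,hb_angle hydrogen-bond cutoffs.
#' @param ca_serials,center_serials binding-site selection; defaults via
#'   [select_binding_site()] and [drug_center_atoms()].
#' @return one-row tibble with columns `matching_rate`, `convex_atoms`,
#'   `connectivity`, `euclidean_distance`, `hydrogen_bonds` plus provenance
#'   (`alpha`, `threshold`, `contact_cutoff`, `hb_dist`, `hb_angle`).
#' @export
extract_geometric_features <- function(traj, alpha = 0, threshold = 40,
                                       contact_cutoff = 5, hb_dist = 3.0,
                                       hb_angle = 135,
                                       ca_serials = NULL,
                                       center_serials = NULL) {
  traj <- as_trajectory(traj)
  frames <- trajectory_frames(traj)
  mr <- matching_rate(traj, alpha, contact_cutoff)
  conv <- mean(vapply(frames, convex_interface_count, numeric(1),
                      alpha = alpha, contact_cutoff = contact_cutoff))
  conn <- connectivity(traj, threshold)
  if (is.null(ca_serials)) ca_serials <- select_binding_site(traj)
  if (is.null(center_serials)) center_serials <- drug_center_atoms(traj)
  bsd <- if (length(ca_serials) > 0)
    binding_site_distances(traj, ca_serials, center_serials)
  else list(d_avg = NA_real_)
  hb <- count_hydrogen_bonds(traj, hb_dist, hb_angle)
  tibble(
    matching_rate = mr$matching_rate,
    convex_atoms = conv,
    connectivity = conn$e_k,
    euclidean_distance = bsd$d_avg,
    hydrogen_bonds = hb$hb_total,
    alpha = alpha, threshold = threshold, contact_cutoff = contact_cutoff,
    hb_dist = hb_dist, hb_angle = hb_angle
  )
}
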