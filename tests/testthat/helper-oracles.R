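# Independent brute-force oracles used to validate the geometry pipeline.
# These deliberately use a different formulation than the package: plain
# enumeration of all 4-subsets with a vectorized Cramer solve for the
# orthocenter, and the Van Oosterom-Strackee closed form for per-tetrahedron
# vertex solid angles (the package sums dihedral angles).

# deterministic symbolic-perturbation jitter; part of the documented input
# canonicalization, reproduced here so both paths resolve degeneracies the
# same way
oracle_jitter <- function(pos, serial) {
  scale <- 1e-7 * (max(apply(pos, 2, function(v) diff(range(v)))) + 1)
  for (d in 1:3) pos[, d] <- pos[, d] + scale * sin(0.5 + serial * 12.9898 +
                                                      d * 78.233)
  pos
}

# solid angle subtended at v by triangle (a, b, c): Van Oosterom-Strackee
oracle_vertex_solid_angle <- function(v, a, b, c) {
  A <- a - v; B <- b - v; C <- c - v
  la <- sqrt(sum(A^2)); lb <- sqrt(sum(B^2)); lc <- sqrt(sum(C^2))
  num <- abs(A[1] * (B[2] * C[3] - B[3] * C[2]) -
               A[2] * (B[1] * C[3] - B[3] * C[1]) +
               A[3] * (B[1] * C[2] - B[2] * C[1]))
  den <- la * lb * lc + sum(A * B) * lc + sum(A * C) * lb + sum(B * C) * la
  ang <- 2 * atan2(num, den)
  if (ang < 0) ang <- ang + 4 * pi
  ang
}

# alpha complex by exhaustive enumeration: a tetrahedron is kept iff its
# orthosphere is empty and its orthoradius^2 <= alpha
oracle_alpha_complex <- function(atoms, alpha) {
  n <- nrow(atoms)
  stopifnot(n >= 4)
  pos0 <- cbind(atoms$x, atoms$y, atoms$z)
  pos <- oracle_jitter(pos0, atoms$serial)
  w2 <- atoms$weight^2
  x <- pos[, 1]; y <- pos[, 2]; z <- pos[, 3]
  q <- x^2 + y^2 + z^2 - w2

  quads <- t(combn(n, 4))
  i1 <- quads[, 1]; i2 <- quads[, 2]; i3 <- quads[, 3]; i4 <- quads[, 4]
  a11 <- x[i2] - x[i1]; a12 <- y[i2] - y[i1]; a13 <- z[i2] - z[i1]
  a21 <- x[i3] - x[i1]; a22 <- y[i3] - y[i1]; a23 <- z[i3] - z[i1]
  a31 <- x[i4] - x[i1]; a32 <- y[i4] - y[i1]; a33 <- z[i4] - z[i1]
  b1 <- (q[i2] - q[i1]) / 2; b2 <- (q[i3] - q[i1]) / 2
  b3 <- (q[i4] - q[i1]) / 2
  det <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  sc <- abs(a11) + abs(a12) + abs(a13) + abs(a21) + abs(a22) + abs(a23) +
    abs(a31) + abs(a32) + abs(a33)
  nondeg <- abs(det) >= 1e-13 * sc^3 + 1e-300
  cx <- (b1 * (a22 * a33 - a23 * a32) - a12 * (b2 * a33 - a23 * b3) +
           a13 * (b2 * a32 - a22 * b3)) / det
  cy <- (a11 * (b2 * a33 - a23 * b3) - b1 * (a21 * a33 - a23 * a31) +
           a13 * (a21 * b3 - b2 * a31)) / det
  cz <- (a11 * (a22 * b3 - b2 * a32) - a12 * (a21 * b3 - b2 * a31) +
           b1 * (a21 * a32 - a22 * a31)) / det
  r2 <- (cx - x[i1])^2 + (cy - y[i1])^2 + (cz - z[i1])^2 - w2[i1]
  keep <- which(nondeg & r2 <= alpha)

  cells <- matrix(integer(0), 0, 4)
  if (length(keep) > 0) {
    empty <- vapply(keep, function(t) {
      pw <- (x - cx[t])^2 + (y - cy[t])^2 + (z - cz[t])^2 - w2
      pw[quads[t, ]] <- Inf
      all(pw >= r2[t])
    }, logical(1))
    cells <- quads[keep[empty], , drop = FALSE]
  }

  # boundary facets: triangles incident to exactly one kept tetrahedron
  facets <- character(0)
  if (nrow(cells) > 0) {
    facets <- unlist(lapply(seq_len(nrow(cells)), function(t) {
      cc <- sort(cells[t, ])
      apply(combn(cc, 3), 2, paste, collapse = "-")
    }))
  }
  fc <- table(facets)
  boundary <- if (length(fc) > 0) names(fc)[fc == 1] else character(0)
  bverts <- unique(as.integer(unlist(strsplit(boundary, "-"))))

  n_inc <- tabulate(as.vector(cells), nbins = n)
  on_surface <- seq_len(n) %in% bverts | n_inc == 0

  omega <- rep(NA_real_, n)
  if (nrow(cells) > 0) {
    omega[] <- 0
    for (t in seq_len(nrow(cells))) {
      cc <- cells[t, ]
      for (vi in 1:4) {
        v <- cc[vi]; rest <- cc[-vi]
        omega[v] <- omega[v] +
          oracle_vertex_solid_angle(pos0[v, ], pos0[rest[1], ],
                                    pos0[rest[2], ], pos0[rest[3], ])
      }
    }
    omega[n_inc == 0] <- NA_real_
  }

  list(on_surface = on_surface, omega = omega, n_incident = n_inc,
       cells = cells)
}

# surface serial set with the same small/degenerate fallback the package
# documents (fewer than 4 atoms, or coplanar, means all atoms exposed)
oracle_surface_serials <- function(atoms, alpha) {
  if (nrow(atoms) < 4) return(sort(atoms$serial))
  sv <- svd(scale(cbind(atoms$x, atoms$y, atoms$z), scale = FALSE))$d
  if (sv[3] < 1e-9 * (sv[1] + 1e-300)) return(sort(atoms$serial))
  res <- oracle_alpha_complex(atoms, alpha)
  sort(atoms$serial[res$on_surface])
}

oracle_interface_sets <- function(frame, alpha) {
  rec <- frame[!frame$is_ligand, ]
  lig <- frame[frame$is_ligand, ]
  A <- oracle_surface_serials(frame, alpha)
  B <- oracle_surface_serials(rec, alpha)
  C <- oracle_surface_serials(lig, alpha)
  I <- sort(setdiff(union(B, C), A))
  list(A = A, B = B, C = C, I = I,
       I_t = sort(intersect(I, B)), I_d = sort(intersect(I, C)))
}

oracle_omegas <- function(atoms, alpha) {
  if (nrow(atoms) < 4)
    return(setNames(rep(NA_real_, nrow(atoms)), atoms$serial))
  sv <- svd(scale(cbind(atoms$x, atoms$y, atoms$z), scale = FALSE))$d
  if (sv[3] < 1e-9 * (sv[1] + 1e-300))
    return(setNames(rep(NA_real_, nrow(atoms)), atoms$serial))
  res <- oracle_alpha_complex(atoms, alpha)
  setNames(res$omega, atoms$serial)
}

# naive per-frame double loop over all interface pairs
oracle_matching_rate <- function(traj, alpha, contact_cutoff) {
  frames <- trajectory_frames(traj)
  total <- 0
  for (f in frames) {
    sets <- oracle_interface_sets(f, alpha)
    if (length(sets$I_t) == 0 || length(sets$I_d) == 0) next
    om_b <- oracle_omegas(f[!f$is_ligand, ], alpha)
    om_c <- oracle_omegas(f[f$is_ligand, ], alpha)
    for (i in sets$I_t) for (j in sets$I_d) {
      pi_ <- match(i, f$serial); pj <- match(j, f$serial)
      d <- sqrt((f$x[pi_] - f$x[pj])^2 + (f$y[pi_] - f$y[pj])^2 +
                  (f$z[pi_] - f$z[pj])^2)
      if (d > contact_cutoff) next
      ob <- om_b[[as.character(i)]]; oc <- om_c[[as.character(j)]]
      if (is.na(ob) || is.na(oc)) next
      sb <- cos(ob) / 4; sc_ <- cos(oc) / 4
      if (abs(sb) <= 1e-12) sb <- 0
      if (abs(sc_) <= 1e-12) sc_ <- 0
      if (sb * sc_ < 0) total <- total + 1
    }
  }
  total / length(frames)
}

oracle_connectivity <- function(traj, threshold) {
  frames <- trajectory_frames(traj)
  d_k <- integer(0)
  for (f in frames) {
    rec <- f[!f$is_ligand, ]; lig <- f[f$is_ligand, ]
    cnt <- 0L
    for (i in seq_len(nrow(rec))) {
      hit <- FALSE
      for (j in seq_len(nrow(lig))) {
        d <- sqrt((rec$x[i] - lig$x[j])^2 + (rec$y[i] - lig$y[j])^2 +
                    (rec$z[i] - lig$z[j])^2)
        if (d <= threshold) { hit <- TRUE; break }
      }
      if (hit) cnt <- cnt + 1L
    }
    d_k <- c(d_k, cnt)
  }
  list(d_k = d_k, e_k = mean(d_k))
}

# naive hydrogen-bond count, interface pairs, hydrogens required
oracle_hbond_count <- function(traj, dist_cutoff, angle_cutoff) {
  frames <- trajectory_frames(traj)
  total <- 0
  for (f in frames) {
    pol <- f[f$element %in% c("N", "O"), ]
    hyd <- f[f$element == "H", ]
    for (d in seq_len(nrow(pol))) for (a in seq_len(nrow(pol))) {
      if (d == a) next
      if (pol$is_ligand[d] == pol$is_ligand[a]) next
      dda <- sqrt((pol$x[d] - pol$x[a])^2 + (pol$y[d] - pol$y[a])^2 +
                    (pol$z[d] - pol$z[a])^2)
      if (dda > dist_cutoff) next
      if (nrow(hyd) == 0) { total <- total + 0.5; next }
      found <- FALSE
      for (h in seq_len(nrow(hyd))) {
        if (hyd$is_ligand[h] != pol$is_ligand[d]) next
        dh <- sqrt((pol$x[d] - hyd$x[h])^2 + (pol$y[d] - hyd$y[h])^2 +
                     (pol$z[d] - hyd$z[h])^2)
        if (dh > 1.25) next
        v1 <- c(pol$x[d] - hyd$x[h], pol$y[d] - hyd$y[h],
                pol$z[d] - hyd$z[h])
        v2 <- c(pol$x[a] - hyd$x[h], pol$y[a] - hyd$y[h],
                pol$z[a] - hyd$z[h])
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2)))))
        if (ang * 180 / pi >= angle_cutoff) { found <- TRUE; break }
      }
      if (found) total <- total + 1
    }
  }
  as.integer(round(total))
}

# random weighted point cloud for oracle-equivalence fixtures
random_atoms <- function(n, seed, spread = 6, wmin = 0.8, wmax = 2.0) {
  set.seed(seed)
  atom_table(
    serial = seq_len(n),
    x = runif(n, -spread, spread),
    y = runif(n, -spread, spread),
    z = runif(n, -spread, spread),
    weight = runif(n, wmin, wmax))
}

# two-cluster receptor/ligand fixture for interface and matching oracles
random_complex <- function(n_rec, n_lig, seed, gap = 2.5) {
  set.seed(seed)
  rec <- tibble::tibble(
    serial = seq_len(n_rec),
    x = runif(n_rec, -4, 4), y = runif(n_rec, -4, 4),
    z = runif(n_rec, -4, 4), w = runif(n_rec, 1.2, 2.0))
  lig <- tibble::tibble(
    serial = n_rec + seq_len(n_lig),
    x = runif(n_lig, -2, 2) + gap, y = runif(n_lig, -2, 2),
    z = runif(n_lig, -2, 2), w = runif(n_lig, 1.2, 2.0))
  atom_table(
    serial = c(rec$serial, lig$serial),
    x = c(rec$x, lig$x), y = c(rec$y, lig$y), z = c(rec$z, lig$z),
    residue_name = rep(c("REC", "LIG"), c(n_rec, n_lig)),
    residue_id = rep(c(1L, 2L), c(n_rec, n_lig)),
    is_ligand = rep(c(FALSE, TRUE), c(n_rec, n_lig)),
    weight = c(rec$w, lig$w))
}

rotate_frame <- function(frame, seed = 1) {
  set.seed(seed)
  m <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(m) < 0) m[, 1] <- -m[, 1]
  shift <- rnorm(3, 0, 10)
  pos <- cbind(frame$x, frame$y, frame$z) %*% t(m)
  frame$x <- pos[, 1] + shift[1]
  frame$y <- pos[, 2] + shift[2]
  frame$z <- pos[, 3] + shift[3]
  frame
}
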