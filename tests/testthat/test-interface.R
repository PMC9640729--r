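test_that("interface set identities hold and match the generator's ground truth", {
  tc <- make_toy_complex()
  sets <- interface_sets(tc$frame, tc$alpha)
  gt <- tc$ground_truth
  expect_setequal(sets$I, setdiff(union(sets$B, sets$C), sets$A))
  expect_setequal(sets$I_t, intersect(sets$I, sets$B))
  expect_setequal(sets$I_d, intersect(sets$I, sets$C))
  expect_length(intersect(sets$I_t, sets$I_d), 0)
  expect_setequal(sets$A, gt$surface_complex)
  expect_setequal(sets$B, gt$surface_receptor)
  expect_setequal(sets$C, gt$surface_ligand)
  expect_setequal(sets$I, gt$I)
  # the interacting set is nonempty and contains only pocket-lining atoms
  expect_gt(length(sets$I), 0)
  expect_true(all(sets$I %in% gt$buried))
})

test_that("a ligand far from the receptor gives an empty interface", {
  tc <- make_toy_complex(pocket_depth = 0, ligand_offset = 100)
  sets <- interface_sets(tc$frame, tc$alpha)
  expect_length(sets$I, 0)
  expect_setequal(sets$A, union(sets$B, sets$C))
})

test_that("generator convexity markers carry the forced solid-angle labels", {
  tc <- make_toy_complex()
  rec <- tc$frame[!tc$frame$is_ligand, ]
  s <- alpha_surface(rec, tc$alpha)
  gt <- tc$ground_truth
  conv <- s$shape_label[match(gt$convex_markers, s$serial)]
  conc <- s$shape_label[match(gt$concave_markers, s$serial)]
  expect_true(all(conv == "convex"))
  expect_true(all(conc == "concave"))
  expect_equal(unique(round(s$omega[match(gt$convex_markers, s$serial)], 9)),
               round(2 * pi, 9))
})

test_that("interface sets agree with the brute-force oracle on random complexes", {
  for (seed in 1:10) {
    frame <- random_complex(n_rec = sample(15:25, 1),
                            n_lig = sample(5:10, 1), seed = seed + 40)
    sets <- interface_sets(frame, alpha = 0)
    osets <- oracle_interface_sets(frame, alpha = 0)
    expect_equal(sets, osets, info = paste("seed", seed))
  }
})

test_that("pair matching requires opposite-sign convexity scores", {
  om_convex <- 0.2      # cos > 0
  om_concave <- pi      # cos < 0
  expect_equal(pair_match(om_convex, om_concave), 1L)
  expect_equal(pair_match(om_convex, 0.3), 0L)
  expect_equal(pair_match(pi / 2, om_concave), 0L)  # zero score never matches
  expect_equal(pair_match(NA, om_concave), 0L)
})

test_that("matching rate is the per-frame matched-pair count", {
  tc <- make_toy_complex()
  one <- matching_rate(as_trajectory(tc$frame), tc$alpha, contact_cutoff = 5)
  # constant frames: trajectory MR equals the single-frame count
  traj <- jitter_trajectory(tc$frame, n_frames = 5, sigma = 0, seed = 1)
  five <- matching_rate(traj, tc$alpha, contact_cutoff = 5)
  expect_equal(five$matching_rate, one$matching_rate)
  expect_equal(five$n_frames, 5)
  expect_gt(one$matching_rate, 0)
})

test_that("matching rate agrees with the naive double-loop oracle", {
  for (seed in 1:6) {
    frame <- random_complex(n_rec = 18, n_lig = 8, seed = seed + 70,
                            gap = 2)
    traj <- jitter_trajectory(frame, n_frames = 2, sigma = 0.15,
                              seed = seed)
    mr <- matching_rate(traj, alpha = 0, contact_cutoff = 5)
    expect_equal(mr$matching_rate, oracle_matching_rate(traj, 0, 5),
                 info = paste("seed", seed))
  }
})

test_that("convex interface count is rotation invariant and zero without convex atoms", {
  tc <- make_toy_complex(n_receptor = 60, n_ligand = 9)
  c1 <- convex_interface_count(tc$frame, tc$alpha)
  c2 <- convex_interface_count(rotate_frame(tc$frame, 5), tc$alpha)
  expect_equal(c1, c2)
})

test_that("connectivity counts receptor atoms within the threshold", {
  f <- atom_table(1:2, c(0, 39), c(0, 0), c(0, 0),
                  residue_name = c("REC", "LIG"),
                  is_ligand = c(FALSE, TRUE))
  r <- connectivity(as_trajectory(f), threshold = 40)
  expect_equal(r$d_k$d_k, 1L)
  expect_equal(r$e_k, 1)
  expect_equal(r$d_persistent, 1L)

  f40 <- atom_table(1:2, c(0, 40), c(0, 0), c(0, 0),
                    is_ligand = c(FALSE, TRUE))
  expect_equal(connectivity(as_trajectory(f40), 40)$e_k, 1)  # inclusive

  tc <- make_toy_complex(n_receptor = 40, n_ligand = 9)
  n_rec <- sum(!tc$frame$is_ligand)
  expect_equal(connectivity(as_trajectory(tc$frame), 1e9)$e_k, n_rec)
  expect_error(connectivity(as_trajectory(f), -1), "positive")
})

test_that("connectivity is monotone in the threshold and matches the naive oracle", {
  frame <- random_complex(20, 8, seed = 99, gap = 6)
  traj <- jitter_trajectory(frame, 3, sigma = 0.3, seed = 2)
  prev <- -1
  for (th in c(2, 5, 10, 20)) {
    r <- connectivity(traj, th)
    o <- oracle_connectivity(traj, th)
    expect_equal(r$d_k$d_k, o$d_k)
    expect_equal(r$e_k, o$e_k)
    expect_gte(r$e_k, prev)
    prev <- r$e_k
  }
})

test_that("binding-site distance matrix has the worked-example shape", {
  # 14 CA atoms and 2 center atoms over 200 frames -> a 200 x 28 matrix
  set.seed(8)
  n_ca <- 14
  frame <- atom_table(
    serial = 1:(n_ca + 4),
    x = c(runif(n_ca, -20, 20), 1, -1, 0.5, -0.5),
    y = c(runif(n_ca, -20, 20), 0, 0, 8, -8),
    z = c(runif(n_ca, -20, 20), 0, 0, 0, 0),
    name = c(rep("CA", n_ca), rep("C1", 4)),
    is_ligand = rep(c(FALSE, TRUE), c(n_ca, 4)))
  traj <- jitter_trajectory(frame, 200, sigma = 0.2, seed = 3)
  centers <- drug_center_atoms(traj, k = 2)
  expect_length(centers, 2)
  bsd <- binding_site_distances(traj, ca_serials = 1:n_ca,
                                center_serials = centers)
  expect_equal(dim(bsd$distances), c(200, 28))
  expect_equal(bsd$d_avg, mean(bsd$distances))
  expect_error(binding_site_distances(traj, 999, centers), "unknown serial")
})

test_that("binding-site distances reproduce simple closed forms", {
  f <- atom_table(1:2, c(0, 3), c(0, 4), c(0, 0), name = c("CA", "C1"),
                  is_ligand = c(FALSE, TRUE))
  b <- binding_site_distances(as_trajectory(f), 1, 2)
  expect_equal(as.vector(b$distances), 5)

  t2 <- dplyr::bind_rows(
    dplyr::mutate(f, frame = 0L, time_ps = 0, x = c(0, 2)),
    dplyr::mutate(f, frame = 1L, time_ps = 10, x = c(0, 4)))[,
      c("frame", "time_ps", names(f))]
  b2 <- binding_site_distances(t2, 1, 2)
  expect_equal(b2$d_avg, mean(c(sqrt(4 + 16), sqrt(16 + 16))))
})

test_that("hydrogen bonds require distance and, when present, angle", {
  # donor N (receptor, with H), acceptor O (ligand) at 2.8 A, angle ~172deg
  mk <- function(d_na) atom_table(
    1:3,
    x = c(0, 1.0, d_na),
    y = 0, z = 0,
    element = c("N", "H", "O"),
    name = c("N", "H", "O1"),
    is_ligand = c(FALSE, FALSE, TRUE))
  expect_equal(count_hydrogen_bonds(as_trajectory(mk(2.8)))$hb_total, 1L)
  expect_equal(count_hydrogen_bonds(as_trajectory(mk(3.6)))$hb_total, 0L)
  # bent geometry fails the angle cutoff
  bent <- mk(2.8); bent$y[2] <- 1.0; bent$x[2] <- 0
  expect_equal(count_hydrogen_bonds(as_trajectory(bent))$hb_total, 0L)
  # no polar atoms: warning and zero
  apol <- atom_table(1:2, c(0, 3), 0, 0, element = "C",
                     is_ligand = c(FALSE, TRUE))
  expect_warning(r <- count_hydrogen_bonds(as_trajectory(apol)),
                 "no donor")
  expect_equal(r$hb_total, 0L)
})

test_that("hydrogen-bond totals aggregate over frames and match the oracle", {
  # three qualifying pairs per frame, five frames -> 15
  f <- atom_table(
    serial = 1:9,
    x = c(0, 1, 2.8, 10, 11, 12.8, 20, 21, 22.8),
    y = 0, z = 0,
    element = rep(c("N", "H", "O"), 3),
    is_ligand = rep(c(FALSE, FALSE, TRUE), 3))
  traj <- jitter_trajectory(f, 5, sigma = 0, seed = 1)
  r <- count_hydrogen_bonds(traj)
  expect_equal(r$hb_total, 15L)
  expect_equal(r$hb_per_frame_mean, 3)
  expect_true(r$used_hydrogens)
  expect_equal(r$hb_total, oracle_hbond_count(traj, 3.0, 135))

  jit <- jitter_trajectory(f, 4, sigma = 0.25, seed = 9)
  expect_equal(count_hydrogen_bonds(jit)$hb_total,
               oracle_hbond_count(jit, 3.0, 135))
})

test_that("trajectory descriptors are invariant under rigid motion of whole frames", {
  frame <- random_complex(16, 8, seed = 123, gap = 2)
  traj <- jitter_trajectory(frame, 2, sigma = 0.1, seed = 4)
  rot <- dplyr::bind_rows(lapply(trajectory_frames(traj), function(f) {
    rf <- rotate_frame(f, 55)
    rf
  }))
  expect_equal(matching_rate(traj, 0, 5)$matching_rate,
               matching_rate(rot, 0, 5)$matching_rate)
  expect_equal(connectivity(traj, 10)$e_k, connectivity(rot, 10)$e_k)
  ca <- traj$serial[!traj$is_ligand][1:3]
  ce <- drug_center_atoms(traj, 2)
  expect_equal(binding_site_distances(traj, ca, ce)$d_avg,
               binding_site_distances(rot, ca, ce)$d_avg, tolerance = 1e-9)
})

test_that("one-call geometric extraction returns the full feature block", {
  tc <- make_toy_complex(n_receptor = 60, n_ligand = 9)
  traj <- jitter_trajectory(tc$frame, 3, sigma = 0.05, seed = 6)
  g <- extract_geometric_features(traj)
  expect_true(all(c("matching_rate", "convex_atoms", "connectivity",
                    "euclidean_distance", "hydrogen_bonds", "alpha",
                    "threshold") %in% names(g)))
  expect_equal(nrow(g), 1)
  expect_gte(g$connectivity, 0)
})
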