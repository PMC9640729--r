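#' Toy receptor-ligand complex with combinatorial ground truth
#'
#' Builds a cubic-lattice block of receptor atoms (spacing `spacing`, equal
#' weights `w`) with a square pocket sunk into the centre of its top face,
#' and a ligand that fills the pocket sites from the bottom up.  Because
#' ligand atoms occupy exact lattice sites, surface and interface
#' membership are decidable combinatorially: with `w` chosen so that every
#' lattice cell (including cells with missing corners) is fully
#' tetrahedralized at `alpha = 0`, an atom is interior to the alpha complex
#' exactly when all six face-neighbour sites are occupied.  The ground
#' truth records surface atoms of the complex and of each isolated part,
#' the interacting sets `I`, `I_t`, `I_d`, and convexity labels for marker
#' atoms whose local solid angle is forced by construction: pocket-floor
#' footprint corners sit at the base of two pocket walls (solid angle
#' `2.892*pi`, score `cos(omega)/4 < 0`, concave), while interior
#' bottom-face atoms see a half-space (solid angle `2*pi`, score `+0.25`,
#' convex).  With `pocket_depth = 0` no pocket is carved and the ligand is
#' placed as a free block `ligand_offset` angstroms away, giving an empty
#' interface.
#'
#' @param n_receptor minimum receptor atom count (>= 8); the block is grown
#'   to the smallest near-cubic lattice holding this many sites after the
#'   pocket is carved.
#' @param n_ligand ligand atom count (>= 2), at most the pocket volume.
#' @param pocket_depth pocket depth in angstroms (rounded to lattice
#'   layers, at least one layer).
#' @param pocket_width pocket width in sites per side (odd, default 3).
#' @param spacing lattice spacing, angstroms (default 2.2).
#' @param w atom weight, angstroms (default 2.0; must exceed the worst-case
#'   lattice-cell circumradius `spacing * sqrt(3)/2` for the combinatorial
#'   surface rule to hold at `alpha = 0`).
#' @param seed seed for the optional coordinate jitter.
#' @param jitter_sd coordinate noise sd, angstroms; keep well below
#'   `spacing / 10` or the combinatorial ground truth is voided.
#' @param ligand_offset with `pocket_depth = 0` (no pocket) the ligand is
#'   built as a free block this far along x from the receptor, angstroms.
#' @return list with `frame` (atom tibble), `alpha` (the alpha at which the
#'   ground truth holds, 0) and `ground_truth`: serial vectors
#'   `surface_complex`, `surface_receptor`, `surface_ligand`, `I`, `I_t`,
#'   `I_d`, `buried`, `convex_markers`, `concave_markers`, plus pocket
#'   bookkeeping.
#' @export
make_toy_complex <- function(n_receptor = 150, n_ligand = 18,
                             pocket_depth = 4.4, pocket_width = 3,
                             spacing = 2.2, w = 2.0, seed = 1,
                             jitter_sd = 0, ligand_offset = 100) {
  if (n_receptor < 8) abort("n_receptor must be >= 8")
  if (n_ligand < 2) abort("n_ligand must be >= 2")
  if (pocket_width %% 2 != 1) abort("pocket_width must be odd")
  depth_layers <- if (pocket_depth < spacing / 2) 0L
                  else as.integer(round(pocket_depth / spacing))
  pocket_volume <- pocket_width^2 * depth_layers

  # near-cubic block with at least n_receptor sites after carving
  side <- ceiling((n_receptor + pocket_volume)^(1 / 3))
  nz <- max(side, depth_layers + 2)         # keep floor below the pocket
  nxy <- side
  while (nxy^2 * nz - pocket_volume < n_receptor ||
         nxy < pocket_width + 2) nxy <- nxy + 1
  if (nz - depth_layers < 1)
    abort("infeasible geometry: pocket deeper than the receptor body")

  half_w <- (pocket_width - 1) %/% 2
  off <- (nxy - 1) / 2                       # centre the block on the origin
  sites <- expand.grid(i = seq_len(nxy) - 1, j = seq_len(nxy) - 1,
                       k = seq_len(nz) - 1)
  z_top <- nz - 1
  ci <- floor(off)                           # pocket centre column
  in_pocket <- abs(sites$i - ci) <= half_w & abs(sites$j - ci) <= half_w &
    sites$k > z_top - depth_layers
  pocket_sites <- sites[in_pocket, ]
  receptor_sites <- sites[!in_pocket, ]

  if (depth_layers > 0) {
    if (n_ligand > nrow(pocket_sites))
      abort(paste0("n_ligand exceeds pocket volume (",
                   nrow(pocket_sites), ")"))
    # ligand occupies the deepest pocket sites first
    pocket_sites <- pocket_sites[order(pocket_sites$k, pocket_sites$i,
                                       pocket_sites$j), ]
    ligand_sites <- pocket_sites[seq_len(n_ligand), ]
  } else {
    # no pocket: free near-cubic ligand block offset along x
    ls <- ceiling(n_ligand^(1 / 3))
    lg <- expand.grid(i = seq_len(ls) - 1, j = seq_len(ls) - 1,
                      k = seq_len(ceiling(n_ligand / ls^2)) - 1)
    lg <- lg[order(lg$k, lg$j, lg$i), ][seq_len(n_ligand), ]
    lg$i <- lg$i + nxy + as.integer(ceiling(ligand_offset / spacing))
    ligand_sites <- lg
  }

  all_sites <- bind_rows(
    mutate(as_tibble(receptor_sites), is_ligand = FALSE),
    mutate(as_tibble(ligand_sites), is_ligand = TRUE))
  all_sites$serial <- seq_len(nrow(all_sites))

  key <- function(s) paste(s$i, s$j, s$k)
  on_surface_of <- function(s, occ) {
    !(paste(s$i + 1, s$j, s$k) %in% occ) |
      !(paste(s$i - 1, s$j, s$k) %in% occ) |
      !(paste(s$i, s$j + 1, s$k) %in% occ) |
      !(paste(s$i, s$j - 1, s$k) %in% occ) |
      !(paste(s$i, s$j, s$k + 1) %in% occ) |
      !(paste(s$i, s$j, s$k - 1) %in% occ)
  }

  rec <- all_sites[!all_sites$is_ligand, ]
  lig <- all_sites[all_sites$is_ligand, ]
  A <- sort(all_sites$serial[on_surface_of(all_sites, key(all_sites))])
  B <- sort(rec$serial[on_surface_of(rec, key(rec))])
  C <- if (nrow(lig) < 4 || length(unique(lig$i)) == 1 ||
           length(unique(lig$j)) == 1 || length(unique(lig$k)) == 1)
    sort(lig$serial) else sort(lig$serial[on_surface_of(lig, key(lig))])
  I <- sort(setdiff(union(B, C), A))

  # convexity markers refer to the isolated receptor's surface, the
  # structure whose solid angles drive the matching rate.  Forced values:
  # interior face atoms see a half-space (omega = 2*pi, score +0.25,
  # convex); pocket-floor footprint corners sit at the base of two walls
  # (omega = 2.892*pi, score cos(0.892*pi)/4 < 0, concave).
  concave <- if (depth_layers > 0)
    rec$serial[abs(rec$i - ci) == half_w & abs(rec$j - ci) == half_w &
                 rec$k == z_top - depth_layers]
  else integer(0)
  convex <- rec$serial[rec$k == 0 & rec$i > 0 & rec$i < nxy - 1 &
                         rec$j > 0 & rec$j < nxy - 1]

  set.seed(seed)
  noise <- function(n) if (jitter_sd > 0) stats::rnorm(n, 0, jitter_sd)
                       else rep(0, n)
  n_all <- nrow(all_sites)
  # pocket-lining receptor atoms (face neighbours of pocket sites) are
  # oxygen so the hydrogen-bond counter sees polar contacts; the ligand is
  # nitrogen, the rest carbon
  pocket_keys <- key(pocket_sites)
  lines_pocket <- !all_sites$is_ligand & depth_layers > 0 &
    (paste(all_sites$i + 1, all_sites$j, all_sites$k) %in% pocket_keys |
       paste(all_sites$i - 1, all_sites$j, all_sites$k) %in% pocket_keys |
       paste(all_sites$i, all_sites$j + 1, all_sites$k) %in% pocket_keys |
       paste(all_sites$i, all_sites$j - 1, all_sites$k) %in% pocket_keys |
       paste(all_sites$i, all_sites$j, all_sites$k + 1) %in% pocket_keys |
       paste(all_sites$i, all_sites$j, all_sites$k - 1) %in% pocket_keys)
  elem <- ifelse(all_sites$is_ligand, "N",
                 ifelse(lines_pocket, "O", "C"))
  frame <- atom_table(
    serial = all_sites$serial,
    x = (all_sites$i - off) * spacing + noise(n_all),
    y = (all_sites$j - off) * spacing + noise(n_all),
    z = (all_sites$k - (nz - 1) / 2) * spacing + noise(n_all),
    element = elem,
    name = elem,
    residue_name = ifelse(all_sites$is_ligand, "LIG", "REC"),
    residue_id = ifelse(all_sites$is_ligand, 2L, 1L),
    is_ligand = all_sites$is_ligand,
    weight = w)

  list(
    frame = frame, alpha = 0,
    ground_truth = list(
      surface_complex = A, surface_receptor = B, surface_ligand = C,
      I = I, I_t = sort(intersect(I, B)), I_d = sort(intersect(I, C)),
      buried = I,
      convex_markers = sort(convex),
      concave_markers = sort(concave),
      pocket_volume = nrow(pocket_sites),
      depth_layers = depth_layers))
}

#' Jittered rigid trajectory from a single frame
#'
#' Repeats a frame `n_frames` times with seeded Gaussian coordinate noise
#' (standard deviation `sigma`) and an optional constant rigid drift per
#' frame, emulating snapshot-to-snapshot thermal motion.  `sigma = 0`
#' yields identical frames.
#'
#' @param frame atom tibble.
#' @param n_frames number of frames (>= 1).
#' @param sigma coordinate noise sd, angstroms.
#' @param seed RNG seed.
#' @param drift length-3 rigid translation applied cumulatively per frame.
#' @param dt_ps frame spacing in picoseconds.
#' @return trajectory tibble.
#' @export
jitter_trajectory <- function(frame, n_frames, sigma = 0.1, seed = 1,
                              drift = c(0, 0, 0), dt_ps = 10) {
  if (n_frames < 1) abort("n_frames must be >= 1")
  if (sigma < 0) abort("sigma must be nonnegative")
  if ("frame" %in% names(frame)) frame <- trajectory_frames(frame)[[1]]
  validate_atoms(frame)
  set.seed(seed)
  purrr::map(seq_len(n_frames) - 1L, function(k) {
    f <- frame
    n <- nrow(f)
    if (sigma > 0) {
      f$x <- f$x + stats::rnorm(n, 0, sigma)
      f$y <- f$y + stats::rnorm(n, 0, sigma)
      f$z <- f$z + stats::rnorm(n, 0, sigma)
    }
    f$x <- f$x + k * drift[1]; f$y <- f$y + k * drift[2]
    f$z <- f$z + k * drift[3]
    bind_cols(tibble(frame = k, time_ps = k * dt_ps), f)
  }) %>% bind_rows()
}

# feature ranges the cohort generator emulates (an emulation of realistic
# per-complex values, not a real-data claim)
.cohort_ranges <- list(
  vdw = c(-60, -45), eel = c(-23, 11), esurf = c(-45, -1), epb = c(27, 40),
  matching_rate = c(0, 17), convex_atoms = c(0, 43), connectivity = c(0, 23),
  euclidean_distance = c(30, 39), hydrogen_bonds = c(775, 1650)
)
.discrete_features <- c("matching_rate", "convex_atoms", "connectivity",
                        "hydrogen_bonds")

#' Synthetic labeled cohort
#'
#' Draws one row per patient with DCI codes, energy components and
#' geometric features uniformly within their emulated ranges, then shifts
#' the geometric columns per response class according to the effect size,
#' mirroring a cohort in which the geometric descriptors carry the class
#' signal.  `effect_size = "none"` makes labels independent of all
#' features; `"well-separated"` spaces adjacent class means by three
#' within-class standard deviations per geometric feature; `"weak"` by
#' one.  Shifts act on raw (pre-normalization) features.  Discrete
#' features are rounded to integers; shifted values may leave the nominal
#' range (never clipped).
#'
#' @param class_counts patients per response class 0..3 (default
#'   `c(19, 118, 30, 34)`, the emulated cohort's class imbalance).
#' @param effect_size `"well-separated"` (default), `"weak"` or `"none"`.
#' @param seed RNG seed.
#' @return feature tibble with `patient_id`, `age_years`, `age_code`,
#'   `sex_code`, `smoking_code`, `survival_months`, `response_label`,
#'   energy and geometric columns, rows in seeded shuffled order.
#' @export
make_cohort <- function(class_counts = c(19, 118, 30, 34),
                        effect_size = c("well-separated", "weak", "none"),
                        seed = 1) {
  effect_size <- match.arg(effect_size)
  if (length(class_counts) != 4 || any(class_counts < 0))
    abort("class_counts must be 4 nonnegative integers")
  n <- sum(class_counts)
  if (n < 8) abort("cohort too small: need at least 8 patients")
  delta <- c(none = 0, weak = 1, `well-separated` = 3)[[effect_size]]

  set.seed(seed)
  label <- rep(0:3, times = class_counts)
  out <- tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    age_years = sample(30:85, n, replace = TRUE),
    sex_code = sample(0:2, n, replace = TRUE, prob = c(0.35, 0.62, 0.03)),
    smoking_code = sample(0:2, n, replace = TRUE, prob = c(0.75, 0.15, 0.1)),
    survival_months = round(stats::rlnorm(n, meanlog = 3, sdlog = 0.5), 1),
    response_label = label
  )
  out$age_code <- encode_age(out$age_years)

  geo <- feature_groups()$geometric
  for (f in names(.cohort_ranges)) {
    rg <- .cohort_ranges[[f]]
    v <- stats::runif(n, rg[1], rg[2])
    if (f %in% geo) {
      sd_u <- diff(rg) / sqrt(12)
      v <- v + delta * sd_u * (label - 1.5)
    }
    if (f %in% .discrete_features) v <- round(v)
    out[[f]] <- v
  }
  out[sample.int(n), ]
}

#' Write a cohort out as the three pipeline input CSV tables
#'
#' Splits a [make_cohort()] table into the clinical, energy and geometric
#' CSV files consumed by [read_clinical_table()], [read_energy_table()]
#' and [assemble_features()].
#'
#' @param cohort tibble from [make_cohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_cohort_tables <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  clinical <- tibble(patient_id = cohort$patient_id, age = cohort$age_years,
                     sex = cohort$sex_code, smoking = cohort$smoking_code,
                     survival_months = cohort$survival_months,
                     response = cohort$response_label)
  energy <- select(cohort, "patient_id", dplyr::all_of(feature_groups()$energy))
  names(energy) <- c("patient_id", toupper(feature_groups()$energy))
  geometric <- select(cohort, "patient_id",
                      dplyr::all_of(feature_groups()$geometric))
  paths <- c(clinical = file.path(dir, "clinical.csv"),
             energy = file.path(dir, "energy.csv"),
             geometric = file.path(dir, "geometric.csv"))
  readr::write_csv(clinical, paths["clinical"])
  readr::write_csv(energy, paths["energy"])
  readr::write_csv(geometric, paths["geometric"])
  invisible(paths)
}
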