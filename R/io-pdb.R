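#' Read a multi-model PDB file as a trajectory table
#'
#' Parses ATOM/HETATM records of a fixed-column PDB file.  Each `MODEL` /
#' `ENDMDL` block becomes one frame; a file without MODEL records is read as
#' a single frame.  Frames are re-indexed 0-based in file order regardless of
#' the MODEL numbers, and `time_ps` is assigned as `frame * dt_ps`.  Atoms
#' whose residue name matches `ligand` are flagged `is_ligand`.
#'
#' @param path path to a PDB file.
#' @param ligand character vector of ligand residue names (e.g. `"GEF"`), or
#'   a predicate function taking the residue-name vector and returning a
#'   logical vector.
#' @param dt_ps sampling interval between frames, picoseconds (default 10, a
#'   2-ns run sampled every 10 ps gives 200 frames).
#' @param weight_scheme weight assignment passed to [atom_weights()].
#' @return a trajectory tibble (see [atom_table()]) with `frame`, `time_ps`
#'   and the atom columns, carrying attributes `weight_scheme` and
#'   `source_path`.
#' @seealso [write_multiframe_pdb()]
#' @export
read_multiframe_pdb <- function(path, ligand, dt_ps = 10,
                                weight_scheme = c("vdw_radius", "mass")) {
  weight_scheme <- match.arg(weight_scheme)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)

  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  is_model_open <- startsWith(lines, "MODEL")

  # frame id per line: cumulative MODEL count (0 if no MODEL records at all)
  frame_of_line <- cumsum(is_model_open)
  has_models <- any(is_model_open)
  atom_idx <- which(is_atom)
  if (length(atom_idx) == 0) abort("no ATOM/HETATM records found")
  if (has_models && any(frame_of_line[atom_idx] == 0))
    atom_idx <- atom_idx[frame_of_line[atom_idx] > 0]

  al <- lines[atom_idx]
  too_short <- nchar(al) < 54
  if (any(too_short))
    abort(paste0("malformed ATOM record (line ",
                 atom_idx[which(too_short)[1]],
                 "): fewer than 54 columns"))

  num <- function(s, from, to) suppressWarnings(as.numeric(substr(s, from, to)))
  xs <- num(al, 31, 38); ys <- num(al, 39, 46); zs <- num(al, 47, 54)
  serial <- suppressWarnings(as.integer(substr(al, 7, 11)))
  bad <- which(!is.finite(xs) | !is.finite(ys) | !is.finite(zs) | is.na(serial))
  if (length(bad) > 0)
    abort(paste0("malformed ATOM record (line ", atom_idx[bad[1]],
                 "): non-numeric coordinate or serial field"))

  name <- trimws(substr(al, 13, 16))
  resname <- trimws(substr(al, 18, 20))
  chain <- trimws(substr(al, 22, 22))
  chain[chain == ""] <- "A"
  resid <- suppressWarnings(as.integer(substr(al, 23, 26)))
  resid[is.na(resid)] <- 1L
  element <- trimws(substr(al, 77, 78))
  element[element == ""] <- guess_element(name[element == ""])
  element <- toupper(element)

  lig <- if (is.function(ligand)) as.logical(ligand(resname))
         else resname %in% as.character(ligand)
  if (!any(lig))
    abort("ligand selector matched zero atoms")

  frame_raw <- if (has_models) frame_of_line[atom_idx] else rep(1L, length(al))
  frame <- match(frame_raw, sort(unique(frame_raw))) - 1L

  traj <- tibble(
    frame = as.integer(frame),
    time_ps = frame * as.double(dt_ps),
    serial = serial, name = name, element = element,
    residue_name = resname, residue_id = resid, chain_id = chain,
    x = xs, y = ys, z = zs,
    weight = atom_weights(element, weight_scheme),
    is_ligand = lig
  )
  counts <- table(traj$frame)
  if (length(unique(as.integer(counts))) > 1)
    abort(paste0("topology error: frames have differing atom counts (",
                 paste(unique(as.integer(counts)), collapse = ", "), ")"))
  validate_trajectory(traj)
  attr(traj, "weight_scheme") <- weight_scheme
  attr(traj, "source_path") <- path
  traj
}

guess_element <- function(name) {
  # strip leading digits (e.g. "1HG1"), then take letters; two-letter
  # elements only when they match a known symbol
  core <- toupper(gsub("^[0-9']+", "", name))
  two <- substr(core, 1, 2)
  one <- substr(core, 1, 1)
  ifelse(two %in% c("CL", "BR", "SE", "NA", "MG", "ZN", "FE"), two, one)
}

#' Write a trajectory table as a multi-model PDB file
#'
#' Coordinates are written at the PDB fixed-width precision (3 decimals), so
#' a read/write round trip reproduces them to 0.001 angstrom.
#'
#' @param traj trajectory tibble from [read_multiframe_pdb()] or built in
#'   code.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multiframe_pdb <- function(traj, path) {
  traj <- as_trajectory(traj)
  validate_trajectory(traj)
  frames <- trajectory_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (multi) writeLines(sprintf("MODEL %8d", i), con)
    rectype <- ifelse(f$is_ligand, "HETATM", "ATOM  ")
    nm <- ifelse(nchar(f$name) <= 3, sprintf(" %-3s", f$name),
                 sprintf("%-4s", f$name))
    writeLines(sprintf(
      "%s%5d %s %-3s%2s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rectype, f$serial, nm, f$residue_name,
      substr(f$chain_id, 1, 1), f$residue_id,
      f$x, f$y, f$z, 1, 0, substr(f$element, 1, 2)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
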