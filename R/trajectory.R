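#' Trajectory ensembles
#'
#' `allodyn` stores a molecular trajectory as a `trajectory_ensemble`: a
#' topology table (one row per atom) plus a 3-D coordinate array in
#' nanometres. All analysis functions in the package consume this container.
#'
#' Internal coordinates are always in nm (the GROMACS convention); PDB input
#' and output convert from/to Angstrom at the boundary, so cutoffs expressed
#' in nm (contact cutoff 0.6 nm, cluster cutoff 0.2 nm) apply directly.
#'
#' @param topology A data frame with columns `chain_id`, `residue_id`,
#'   `residue_name`, `atom_name`, `element`. Derived columns `is_backbone`
#'   (atom name in N/CA/C/O) and `is_heavy` (element != H) are filled in.
#' @param coords Numeric array of dimension `c(n_atoms, 3, n_frames)`, nm.
#' @param times Per-frame time stamps in ns, strictly increasing.
#' @param replica_id Label identifying the replica this trajectory came from.
#'
#' @return A `trajectory_ensemble` object.
#' @export
trajectory_ensemble <- function(topology, coords, times = NULL,
                                replica_id = "rep1") {
  topology <- as_tibble(topology)
  req <- c("chain_id", "residue_id", "residue_name", "atom_name", "element")
  missing_cols <- setdiff(req, names(topology))
  if (length(missing_cols) > 0L) {
    stop_allodyn(
      paste0("topology is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "allodyn_format_error"
    )
  }
  topology$chain_id <- as.character(topology$chain_id)
  topology$residue_id <- as.integer(topology$residue_id)
  topology$residue_name <- as.character(topology$residue_name)
  topology$atom_name <- as.character(topology$atom_name)
  topology$element <- as.character(topology$element)
  topology$is_backbone <- topology$atom_name %in% c("N", "CA", "C", "O")
  topology$is_heavy <- toupper(topology$element) != "H"

  key <- paste(topology$chain_id, topology$residue_id, topology$atom_name)
  if (anyDuplicated(key)) {
    stop_allodyn(
      "duplicate (chain, residue, atom name) in topology",
      class = "allodyn_format_error"
    )
  }

  if (length(dim(coords)) == 2L) {
    coords <- array(coords, dim = c(dim(coords), 1L))
  }
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop_allodyn("`coords` must be an (atoms x 3 x frames) array",
                 class = "allodyn_format_error")
  }
  if (dim(coords)[1] != nrow(topology)) {
    stop_allodyn(
      sprintf("coordinate array has %d atoms but topology has %d",
              dim(coords)[1], nrow(topology)),
      class = "allodyn_format_error"
    )
  }
  n_frames <- dim(coords)[3]
  if (n_frames == 0L) {
    stop_allodyn("trajectory has zero frames", class = "allodyn_empty_input")
  }
  if (is.null(times)) times <- seq_len(n_frames) - 1
  if (length(times) != n_frames || any(diff(times) <= 0)) {
    stop_allodyn("`times` must be strictly increasing, one per frame",
                 class = "allodyn_format_error")
  }

  structure(
    list(topology = topology, coords = coords, times = as.numeric(times),
         replica_id = as.character(replica_id)),
    class = "trajectory_ensemble"
  )
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf(
    "<trajectory_ensemble> %d atoms, %d frames, chains: %s (replica %s)\n",
    n_atoms(x), n_frames(x),
    paste(unique(x$topology$chain_id), collapse = ", "), x$replica_id
  ))
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param ensemble A `trajectory_ensemble`.
#' @return Integer count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(ensemble) dim(ensemble$coords)[1]

#' Extract one frame's coordinates
#' @param ensemble A `trajectory_ensemble`.
#' @param i Frame index (1-based).
#' @return An `n_atoms x 3` matrix, nm.
#' @export
frame_coords <- function(ensemble, i) {
  ensemble$coords[, , i, drop = TRUE]
}

#' Restrict an ensemble to a subset of frames
#' @param ensemble A `trajectory_ensemble`.
#' @param frames Integer frame indices to keep, in order.
#' @return A `trajectory_ensemble`.
#' @export
subset_frames <- function(ensemble, frames) {
  trajectory_ensemble(ensemble$topology,
                      ensemble$coords[, , frames, drop = FALSE],
                      times = ensemble$times[frames],
                      replica_id = ensemble$replica_id)
}

guess_element <- function(atom_name) {
  # MD topologies rarely carry an element column; fall back on the atom-name
  # convention that the element is the leading alphabetic character(s)
  nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", atom_name))
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "CA") &
           nchar(nm) > 1 & !grepl("^C[A-Z]", atom_name),
         two, toupper(substr(nm, 1, 1)))
}

#' Read a structure/trajectory into a trajectory ensemble
#'
#' Reads a topology (PDB or GRO) and, optionally, a separate trajectory file
#' (DCD, or a multi-model PDB). If `topology_path` is a multi-model PDB and no
#' trajectory is given, every MODEL becomes a frame.
#'
#' @param topology_path Path to a PDB or GRO file.
#' @param trajectory_path Optional path to a DCD or multi-model PDB
#'   trajectory whose atom count matches the topology. XTC/TRR are not
#'   readable here; convert to DCD or multi-model PDB first (e.g. with
#'   `mdconvert` or `gmx trjconv`).
#' @param dt Time step between frames in ns, used when the files carry no
#'   time information (default 0.1 ns).
#' @param replica_id Label stored on the returned ensemble.
#'
#' @return A [trajectory_ensemble()].
#' @export
read_trajectory <- function(topology_path, trajectory_path = NULL,
                            dt = 0.1, replica_id = "rep1") {
  ext <- tolower(tools::file_ext(topology_path))
  if (ext %in% c("pdb", "ent")) {
    top <- read_pdb_frames(topology_path)
  } else if (ext == "gro") {
    top <- read_gro_frame(topology_path)
  } else {
    stop_allodyn(sprintf("unsupported topology format '.%s' (need PDB or GRO)", ext),
                 class = "allodyn_format_error")
  }

  coords <- top$coords
  if (!is.null(trajectory_path)) {
    text <- tolower(tools::file_ext(trajectory_path))
    if (text == "dcd") {
      xyz <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
      frames <- aperm(array(t(xyz) / 10, dim = c(3, ncol(xyz) / 3, nrow(xyz))),
                      c(2, 1, 3))
    } else if (text %in% c("pdb", "ent")) {
      frames <- read_pdb_frames(trajectory_path)$coords
    } else if (text %in% c("xtc", "trr")) {
      stop_allodyn(
        sprintf("'.%s' trajectories are not readable here; convert to DCD or multi-model PDB first", text),
        class = "allodyn_format_error"
      )
    } else {
      stop_allodyn(sprintf("unsupported trajectory format '.%s'", text),
                   class = "allodyn_format_error")
    }
    if (dim(frames)[1] != nrow(top$topology)) {
      stop_allodyn(
        sprintf("atom-count mismatch: topology has %d atoms, trajectory frames have %d",
                nrow(top$topology), dim(frames)[1]),
        class = "allodyn_format_error"
      )
    }
    coords <- frames
  }

  if (is.null(coords) || dim(coords)[3] == 0L) {
    stop_allodyn("no frames found in input", class = "allodyn_empty_input")
  }
  trajectory_ensemble(top$topology, coords,
                      times = (seq_len(dim(coords)[3]) - 1) * dt,
                      replica_id = replica_id)
}

read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  if (!is.null(atom$insert) && any(!is.na(atom$insert) & atom$insert != "")) {
    stop_allodyn("PDB insertion codes are not supported (renumber the structure)",
                 class = "allodyn_format_error")
  }
  alt <- atom$alt
  keep <- is.na(alt) | alt == "" | alt == "A"
  atom <- atom[keep, , drop = FALSE]

  elem <- atom$elesy
  if (is.null(elem) || all(is.na(elem)) || all(trimws(elem) == "")) {
    elem <- guess_element(atom$elety)
  } else {
    blank <- is.na(elem) | trimws(elem) == ""
    elem[blank] <- guess_element(atom$elety[blank])
  }
  chain <- atom$chain
  chain[is.na(chain) | chain == ""] <- "A"

  topology <- tibble(
    chain_id = chain,
    residue_id = as.integer(atom$resno),
    residue_name = atom$resid,
    atom_name = atom$elety,
    element = trimws(elem)
  )

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  xyz <- xyz[, bio3d::atom2xyz(which(keep)), drop = FALSE]
  # bio3d gives Angstrom, row-per-model; reshape to (atoms x 3 x frames) in nm
  coords <- aperm(array(t(xyz) / 10, dim = c(3, ncol(xyz) / 3, nrow(xyz))),
                  c(2, 1, 3))
  list(topology = topology, coords = coords)
}

read_gro_frame <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) {
    stop_allodyn("GRO file too short", class = "allodyn_format_error")
  }
  n <- as.integer(trimws(lines[2]))
  if (is.na(n) || length(lines) < 2L + n) {
    stop_allodyn("malformed GRO file: bad atom count", class = "allodyn_format_error")
  }
  body <- lines[3:(2 + n)]
  resid <- as.integer(substr(body, 1, 5))
  resname <- trimws(substr(body, 6, 10))
  aname <- trimws(substr(body, 11, 15))
  x <- as.numeric(substr(body, 21, 28))
  y <- as.numeric(substr(body, 29, 36))
  z <- as.numeric(substr(body, 37, 44))
  topology <- tibble(
    chain_id = "A", residue_id = resid, residue_name = resname,
    atom_name = aname, element = guess_element(aname)
  )
  list(topology = topology,
       coords = array(cbind(x, y, z), dim = c(n, 3, 1)))
}

#' Write an ensemble as a multi-model PDB
#'
#' Each frame becomes one MODEL; coordinates are converted from nm to
#' Angstrom at 0.001 A precision (the PDB format limit).
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param path Output file path.
#' @param frames Optional frame indices to write (default all).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(ensemble, path, frames = seq_len(n_frames(ensemble))) {
  top <- ensemble$topology
  name_field <- ifelse(nchar(top$atom_name) < 4L,
                       sprintf(" %-3s", top$atom_name),
                       sprintf("%-4s", top$atom_name))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    xyz <- frame_coords(ensemble, f) * 10  # nm -> Angstrom
    writeLines(sprintf("MODEL     %4d", match(f, frames)), con)
    writeLines(sprintf(
      "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(top)), name_field, substr(top$residue_name, 1, 3),
      substr(top$chain_id, 1, 1), top$residue_id,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, top$element
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
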