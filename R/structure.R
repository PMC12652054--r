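# Structures, trajectories and atom-group resolution.
#
# Atoms are addressed throughout by the label "chain/resid/atom", e.g.
# "A/797/OG1". Groups are matched by label, never by file index, so group
# resolution is independent of atom order in the input files.

#' Construct a molecular structure
#'
#' @param atoms data.frame with columns `atom` (name), `resname`, `resid`
#'   (integer), `chain`, `element`, `x`, `y`, `z` (Angstrom).
#' @return Object of class `cts_structure`.
#' @export
cts_structure <- function(atoms) {
  need <- c("atom", "resname", "resid", "chain", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop_cts("invalid_input", "atoms must have columns: %s", paste(need, collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  atoms$resid <- as.integer(atoms$resid)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop_cts("invalid_input", "non-finite atom coordinates")
  lab <- atom_labels_of(atoms)
  if (anyDuplicated(lab))
    stop_cts("invalid_input", "duplicate atom identity: %s", lab[duplicated(lab)][1])
  structure(list(atoms = atoms), class = "cts_structure")
}

atom_labels_of <- function(atoms) paste(atoms$chain, atoms$resid, atoms$atom, sep = "/")

#' Atom labels of a structure
#' @param structure A `cts_structure`.
#' @return Character vector `"chain/resid/atom"`, one per atom.
#' @export
atom_labels <- function(structure) atom_labels_of(structure$atoms)

#' Resolve atom labels to row indices
#' @noRd
atom_indices <- function(structure, labels, context = "selection") {
  idx <- match(labels, atom_labels(structure))
  if (anyNA(idx))
    stop_cts("configuration_error", "%s references absent atom(s): %s",
             context, paste(labels[is.na(idx)], collapse = ", "))
  idx
}

#' Coordinates of selected atoms
#'
#' @param structure A `cts_structure`.
#' @param labels Optional character vector of atom labels; default all atoms.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
structure_coords <- function(structure, labels = NULL) {
  at <- structure$atoms
  if (!is.null(labels)) at <- at[atom_indices(structure, labels), , drop = FALSE]
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- atom_labels_of(at)
  m
}

#' @export
print.cts_structure <- function(x, ...) {
  cat(sprintf("cts_structure: %d atoms, %d residues, chains %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records via `bio3d::read.pdb`. Insertion codes are
#' rejected; when alternate locations are present only the first altloc of
#' each atom is kept (with a warning). A file without MODEL records yields a
#' single structure; for multi-model files the first model is returned.
#'
#' @param path Path to a PDB file.
#' @return A [cts_structure].
#' @export
read_structure_pdb <- function(path) {
  if (!file.exists(path)) stop_cts("io_error", "file not found: %s", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                                   rm.alt = FALSE)),
                  error = function(e) stop_cts("parse_error", "cannot parse %s: %s",
                                               path, conditionMessage(e)))
  at <- pdb$atom
  if (any(rowSums(is.na(at[, c("x", "y", "z")])) > 0)) {
    bad <- which(rowSums(is.na(at[, c("x", "y", "z")])) > 0)[1]
    ln <- grep("^(ATOM|HETATM)", readLines(path))[bad]
    stop_cts("parse_error", "malformed coordinate field at line %d of %s", ln, path)
  }
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop_cts("parse_error", "insertion codes present in %s; not supported", path)
  has_alt <- !is.na(at$alt) & nzchar(at$alt)
  if (any(has_alt)) {
    key <- paste(at$chain, at$resno, at$elety)
    keep <- !duplicated(key)
    if (any(!keep)) {
      warning(sprintf("%d altloc duplicate atom(s) dropped; first altloc kept",
                      sum(!keep)))
      at <- at[keep, , drop = FALSE]
    }
  }
  cts_structure(data.frame(
    atom = at$elety, resname = at$resid, resid = at$resno, chain = at$chain,
    element = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                     substr(gsub("[0-9']", "", at$elety), 1, 1), at$elesy),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE))
}

#' Construct a trajectory
#'
#' @param topology A [cts_structure].
#' @param coords Numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param frame_spacing Time between frames, ns (> 0).
#' @param metadata Named list of system descriptors (e.g. `ligand`,
#'   `stereochemistry` ("alpha"/"beta"), `ions` ("2xK", "1xMg", "none"),
#'   `repeat_id`).
#' @return Object of class `cts_trajectory`.
#' @export
cts_trajectory <- function(topology, coords, frame_spacing = 1, metadata = list()) {
  if (!inherits(topology, "cts_structure"))
    stop_cts("invalid_input", "topology must be a cts_structure")
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop_cts("invalid_input", "coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != nrow(topology$atoms))
    stop_cts("atom_count_mismatch", "coords have %d atoms but topology has %d",
             dim(coords)[1], nrow(topology$atoms))
  if (!is.numeric(frame_spacing) || frame_spacing <= 0)
    stop_cts("invalid_input", "frame_spacing must be > 0 (ns)")
  structure(list(topology = topology, coords = coords,
                 frame_spacing = frame_spacing, metadata = metadata),
            class = "cts_trajectory")
}

#' Number of frames in a trajectory
#' @param trajectory A `cts_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Coordinates of one frame
#' @param trajectory A `cts_trajectory`.
#' @param i Frame index (1-based).
#' @return n_atoms x 3 matrix.
#' @export
frame_coords <- function(trajectory, i) {
  m <- trajectory$coords[, , i, drop = TRUE]
  dim(m) <- c(dim(trajectory$coords)[1], 3)
  m
}

#' @export
print.cts_trajectory <- function(x, ...) {
  cat(sprintf("cts_trajectory: %d atoms x %d frames, %.3g ns/frame\n",
              dim(x$coords)[1], n_frames(x), x$frame_spacing))
  invisible(x)
}

#' Read a trajectory (and optionally an atom-group map)
#'
#' The canonical interchange format is multi-model PDB: `topology_path` may
#' itself hold the MODEL blocks, or a separate multi-model `coordinates_path`
#' may supply them over the topology's atoms. Frames are assumed pre-imaged;
#' no periodic-boundary treatment is performed.
#'
#' @param topology_path PDB file defining atoms (first MODEL used as topology).
#' @param coordinates_path Optional multi-model PDB with the frames; defaults
#'   to `topology_path`.
#' @param groups_config_path Optional YAML group configuration, resolved
#'   against the topology (see [read_group_config()]).
#' @param frame_spacing ns per frame (metadata only).
#' @param metadata Named list of system descriptors.
#' @return List with `trajectory` (a [cts_trajectory]) and `groups` (an
#'   `atom_group_map` or NULL).
#' @export
read_trajectory <- function(topology_path, coordinates_path = NULL,
                            groups_config_path = NULL,
                            frame_spacing = 1, metadata = list()) {
  topo <- read_structure_pdb(topology_path)
  cpath <- coordinates_path %||% topology_path
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(cpath, multi = TRUE, verbose = FALSE)),
                  error = function(e) stop_cts("parse_error", "cannot parse %s: %s",
                                               cpath, conditionMessage(e)))
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  nat <- ncol(xyz) / 3
  if (nat != nrow(topo$atoms))
    stop_cts("atom_count_mismatch",
             "coordinate file has %d atoms per model, topology has %d",
             nat, nrow(topo$atoms))
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nat, 3, nf))
  for (i in seq_len(nf))
    coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  traj <- cts_trajectory(topo, coords, frame_spacing, metadata)
  groups <- if (!is.null(groups_config_path))
    read_group_config(groups_config_path, topo) else NULL
  list(trajectory = traj, groups = groups)
}

#' Write a trajectory as multi-model PDB
#'
#' One MODEL block per frame; fixed-width formatting, bit-stable across
#' runs. Coordinates are written at the format's 1e-3 Angstrom precision.
#'
#' @param trajectory A [cts_trajectory].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_multimodel_pdb <- function(trajectory, path) {
  if (n_frames(trajectory) < 1)
    stop_cts("invalid_input", "empty trajectory")
  at <- trajectory$topology$atoms
  aname <- ifelse(nchar(at$atom) < 4, paste0(" ", at$atom), at$atom)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_cts("io_error", "cannot write %s", path))
  on.exit(close(con))
  for (f in seq_len(n_frames(trajectory))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(trajectory, f)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)) %% 100000L, aname, substr(at$resname, 1, 3), at$chain,
      at$resid, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read and resolve an atom-group configuration
#'
#' The YAML file has two top-level maps. `groups` names ligand/ion atom
#' groups (each a list of `"chain/resid/atom"` labels, or a single label for
#' `sugar_marker`): `core_ring_atoms` (steroid C1-C17, >= 10 atoms),
#' `beta_methyls` (C18, C19; exactly 2 when present), `lactone_atoms`,
#' `hydroxyl_oxygens`, `sugar_marker`, `ion_site_I`, `ion_site_II`.
#' `partners` maps residue labels (e.g. `T797`) to their hydrogen-bond
#' donor/acceptor heavy atoms (`atoms`) and, optionally, `hydrogens`.
#'
#' @param path YAML file path, or a pre-parsed list with the same shape.
#' @param topology A [cts_structure] every referenced atom must exist in.
#' @return Object of class `atom_group_map`: list with `groups` (name ->
#'   label vector) and `partners` (residue -> list(atoms, hydrogens)).
#' @export
read_group_config <- function(path, topology) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  groups <- lapply(cfg$groups, function(g) as.character(unlist(g)))
  partners <- lapply(cfg$partners, function(p) {
    if (is.character(p) || is.null(names(p))) p <- list(atoms = unlist(p))
    list(atoms = as.character(unlist(p$atoms)),
         hydrogens = as.character(unlist(p$hydrogens %||% character())))
  })
  for (nm in names(groups))
    atom_indices(topology, groups[[nm]], context = sprintf("group '%s'", nm))
  for (nm in names(partners)) {
    atom_indices(topology, partners[[nm]]$atoms,
                 context = sprintf("partner '%s'", nm))
    if (length(partners[[nm]]$hydrogens))
      atom_indices(topology, partners[[nm]]$hydrogens,
                   context = sprintf("partner '%s' hydrogens", nm))
  }
  if (!is.null(groups$core_ring_atoms) && length(groups$core_ring_atoms) < 10)
    stop_cts("configuration_error", "core_ring_atoms needs >= 10 atoms, got %d",
             length(groups$core_ring_atoms))
  if (!is.null(groups$beta_methyls) && length(groups$beta_methyls) != 2)
    stop_cts("configuration_error", "beta_methyls must contain exactly 2 atoms")
  structure(list(groups = groups, partners = partners), class = "atom_group_map")
}

#' Write an atom-group configuration to YAML
#' @param group_map An `atom_group_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_group_config <- function(group_map, path) {
  yaml::write_yaml(list(groups = group_map$groups,
                        partners = group_map$partners), path)
  invisible(path)
}
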