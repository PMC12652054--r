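# Per-frame observables over a classified trajectory: hydrogen-bond
# detection and binding-mode-resolved interaction-prevalence matrices,
# lactone--ion distance series, tilt/vertical-displacement stability
# series, and in-plane sugar-site clustering.

#' Hydrogen-bond geometric criteria
#'
#' Defaults follow standard MD practice: donor-acceptor distance <= 3.5 A
#' and donor-hydrogen-acceptor angle >= 150 degrees. With
#' `hydrogen_optional = TRUE` (default) the angle test is skipped for pairs
#' without hydrogen atoms, leaving a distance-only criterion -- which also
#' supports hydrogen-free synthetic systems.
#'
#' @param dist_max Maximum donor-acceptor distance, Angstrom (> 0).
#' @param angle_min Minimum D-H-A angle, degrees, in (0, 180].
#' @param hydrogen_optional Allow the distance-only fallback?
#' @return Object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(dist_max = 3.5, angle_min = 150,
                           hydrogen_optional = TRUE) {
  if (dist_max <= 0) stop_cts("invalid_input", "dist_max must be > 0")
  if (angle_min <= 0 || angle_min > 180)
    stop_cts("invalid_input", "angle_min must be in (0, 180]")
  structure(list(dist_max = dist_max, angle_min = angle_min,
                 hydrogen_optional = hydrogen_optional),
            class = "hbond_criteria")
}

#' Candidate donor/acceptor pair for hydrogen-bond analysis
#'
#' Evaluation is symmetric over the listed heavy atoms: a bond is recorded
#' if any atom of side `a` and any atom of side `b` satisfy the criteria,
#' so either side may donate.
#'
#' @param name Pair name, conventionally `"<ligand group>:<residue>"`.
#' @param a,b Atom labels of the two heavy-atom groups.
#' @param hydrogens_a,hydrogens_b Optional hydrogen labels attached to each
#'   side (needed unless the criteria allow the distance-only fallback).
#' @return Object of class `hbond_pair`.
#' @export
hbond_pair <- function(name, a, b, hydrogens_a = character(),
                       hydrogens_b = character()) {
  structure(list(name = name, a = a, b = b,
                 hydrogens_a = hydrogens_a, hydrogens_b = hydrogens_b),
            class = "hbond_pair")
}

angle_deg <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(min(max(cosang, -1), 1)) * 180 / pi
}

hbond_one <- function(coords, ia, ib, iha, ihb, criteria) {
  pa <- coords[ia, , drop = FALSE]; pb <- coords[ib, , drop = FALSE]
  d2max <- criteria$dist_max^2
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb))) {
    d2 <- sum((pa[i, ] - pb[j, ])^2)
    if (d2 > d2max) next
    ih <- c(iha, ihb)
    if (!length(ih)) {
      if (!criteria$hydrogen_optional)
        stop_cts("criteria_error",
                 "no hydrogens for pair and hydrogen_optional is FALSE")
      return(TRUE)
    }
    for (h in ih) {
      # H bonded to whichever heavy atom it sits on; test D-H-A both ways
      if (angle_deg(pa[i, ], coords[h, ], pb[j, ]) >= criteria$angle_min)
        return(TRUE)
    }
  }
  FALSE
}

#' Detect hydrogen bonds in one frame
#'
#' @param coords Frame coordinates (n_atoms x 3).
#' @param topology A [cts_structure] matching the coordinates.
#' @param pairs List of [hbond_pair]s.
#' @param criteria An [hbond_criteria].
#' @return Named logical vector, one entry per pair.
#' @export
detect_hbonds <- function(coords, topology, pairs, criteria = hbond_criteria()) {
  out <- vapply(pairs, function(p) {
    hbond_one(coords,
              atom_indices(topology, p$a, p$name),
              atom_indices(topology, p$b, p$name),
              if (length(p$hydrogens_a)) atom_indices(topology, p$hydrogens_a, p$name) else integer(),
              if (length(p$hydrogens_b)) atom_indices(topology, p$hydrogens_b, p$name) else integer(),
              criteria)
  }, logical(1))
  names(out) <- vapply(pairs, `[[`, "", "name")
  out
}

#' Binding-mode-resolved interaction-prevalence matrix
#'
#' For every candidate pair and every retained binding mode, the fraction
#' of that mode's frames in which the hydrogen bond is formed. Modes
#' observed for no more than `threshold` of the total (pooled) simulation
#' time are dropped from the matrix. Multiple trajectories (repeats) are
#' pooled frame-by-frame.
#'
#' @param trajectory A [cts_trajectory], or list of them (repeats).
#' @param trace Matching `binding_mode_trace`, or list of them.
#' @param pairs List of [hbond_pair]s.
#' @param criteria An [hbond_criteria].
#' @param threshold Mode-inclusion threshold on total-time prevalence
#'   (default 0.05).
#' @return Object of class `prevalence_matrix`: `matrix` (pairs x retained
#'   modes, fractions), `mode_prevalence` (all modes), `threshold`,
#'   `n_frames`.
#' @export
interaction_prevalence <- function(trajectory, trace, pairs,
                                   criteria = hbond_criteria(),
                                   threshold = 0.05) {
  trajs <- if (inherits(trajectory, "cts_trajectory")) list(trajectory) else trajectory
  traces <- if (inherits(trace, "binding_mode_trace")) list(trace) else trace
  if (length(trajs) != length(traces))
    stop_cts("invalid_input", "trajectory and trace counts differ")
  labels <- character(); bonded <- NULL
  for (r in seq_along(trajs)) {
    tj <- trajs[[r]]; tc <- traces[[r]]
    if (n_frames(tj) != nrow(tc$frames))
      stop_cts("invalid_input", "trace length %d != trajectory frames %d",
               nrow(tc$frames), n_frames(tj))
    bmat <- t(vapply(seq_len(n_frames(tj)), function(i)
      detect_hbonds(frame_coords(tj, i), tj$topology, pairs, criteria),
      logical(length(pairs))))
    bonded <- rbind(bonded, matrix(bmat, ncol = length(pairs)))
    labels <- c(labels, tc$frames$label)
  }
  prev_all <- vapply(BM_LABELS, function(m) mean(labels == m), numeric(1))
  keep <- names(prev_all)[prev_all > threshold]
  mat <- matrix(NA_real_, length(pairs), length(keep),
                dimnames = list(vapply(pairs, `[[`, "", "name"), keep))
  for (m in keep) {
    sel <- labels == m
    mat[, m] <- colMeans(bonded[sel, , drop = FALSE])
  }
  structure(list(matrix = mat, mode_prevalence = prev_all,
                 threshold = threshold, n_frames = length(labels)),
            class = "prevalence_matrix")
}

#' @export
print.prevalence_matrix <- function(x, ...) {
  cat(sprintf("prevalence_matrix: %d pairs x %d modes (> %.0f%% of %d frames)\n",
              nrow(x$matrix), ncol(x$matrix), 100 * x$threshold, x$n_frames))
  print(round(100 * x$matrix, 1))
  invisible(x)
}

#' Lactone--ion distance series
#'
#' Distance per frame from the lactone's representative atom to the site-II
#' ion, tagged with the frame's binding mode. By default the representative
#' atom is the lactone oxygen nearest the ion in each frame; a fixed atom
#' label may be configured instead.
#'
#' @param trajectory A [cts_trajectory].
#' @param groups `atom_group_map` with `lactone_atoms` and `ion_site_II`.
#' @param trace Optional `binding_mode_trace` for mode tags.
#' @param lactone_atom Optional fixed atom label to use as the lactone
#'   representative instead of the per-frame nearest oxygen.
#' @return data.frame (`frame`, `distance` in Angstrom, `mode`); zero rows
#'   with attribute `ion_absent = TRUE` when no site-II ion is configured.
#' @export
ion_distance_series <- function(trajectory, groups, trace = NULL,
                                lactone_atom = NULL) {
  if (is.null(groups$groups$ion_site_II) || !length(groups$groups$ion_site_II)) {
    out <- data.frame(frame = integer(), distance = numeric(), mode = character())
    attr(out, "ion_absent") <- TRUE
    return(out)
  }
  topo <- trajectory$topology
  ion_idx <- atom_indices(topo, groups$groups$ion_site_II, "ion_site_II")
  lac_idx <- if (!is.null(lactone_atom)) atom_indices(topo, lactone_atom, "lactone")
  else {
    idx <- atom_indices(topo, groups$groups$lactone_atoms, "lactone_atoms")
    ox <- idx[topo$atoms$element[idx] %in% c("O", "o")]
    if (length(ox)) ox else idx
  }
  nf <- n_frames(trajectory)
  d <- vapply(seq_len(nf), function(i) {
    xyz <- frame_coords(trajectory, i)
    ion <- colMeans(xyz[ion_idx, , drop = FALSE])
    min(sqrt(rowSums(sweep(xyz[lac_idx, , drop = FALSE], 2, ion)^2)))
  }, numeric(1))
  data.frame(frame = seq_len(nf), distance = d,
             mode = if (!is.null(trace)) trace$frames$label else NA_character_,
             stringsAsFactors = FALSE)
}

# Superpose every frame onto the topology's own coordinates over the given
# selection, so results live in the frame the reference frame was built in
# and a rigid motion of the whole trajectory cancels exactly.
align_frames_to_topology <- function(trajectory, align_labels) {
  topo <- trajectory$topology
  idx <- atom_indices(topo, align_labels, "alignment selection")
  ref_xyz <- structure_coords(topo)[idx, , drop = FALSE]
  lapply(seq_len(n_frames(trajectory)), function(i) {
    xyz <- frame_coords(trajectory, i)
    tr <- kabsch_superpose(xyz[idx, , drop = FALSE], ref_xyz)
    apply_transform(tr$transform, xyz)
  })
}

#' C-alpha atom labels of configured transmembrane helices
#'
#' Convenience selector for the alignment anchor: the C-alpha atoms of the
#' configured helix residue ranges (used to superpose frames "on alphaM1-6").
#'
#' @param structure A [cts_structure].
#' @param helix_ranges Named list of helix ranges (`chain`, `start`, `end`).
#' @param helices Which helices to include (default all configured).
#' @return Character vector of atom labels.
#' @export
helix_ca_labels <- function(structure, helix_ranges,
                            helices = names(helix_ranges)) {
  at <- structure$atoms
  lab <- character()
  for (h in helices) {
    rg <- helix_ranges[[h]]
    sel <- at$chain == rg$chain & at$resid >= rg$start & at$resid <= rg$end &
      at$atom == "CA"
    lab <- c(lab, atom_labels_of(at[sel, , drop = FALSE]))
  }
  lab
}

#' Pose-stability series: tilt and vertical displacement
#'
#' Tilt is the angle (degrees, 0-180) between the core long axis and the
#' membrane normal; vertical displacement is the z shift of the core
#' centroid relative to frame 1. When `align_labels` are given (typically
#' the alphaM1-6 C-alpha atoms, see [helix_ca_labels()]) every frame is
#' first superposed onto the topology coordinates over that selection,
#' making both series invariant to rigid motion of the whole system.
#'
#' @param trajectory A [cts_trajectory].
#' @param groups `atom_group_map` with `core_ring_atoms`.
#' @param ref A `reference_frame`.
#' @param align_labels Optional atom labels for per-frame superposition.
#' @return data.frame (`frame`, `tilt` deg, `displacement` Angstrom).
#' @export
stability_series <- function(trajectory, groups, ref, align_labels = NULL) {
  topo <- trajectory$topology
  core_idx <- atom_indices(topo, groups$groups$core_ring_atoms, "core_ring_atoms")
  frames <- if (!is.null(align_labels))
    align_frames_to_topology(trajectory, align_labels)
  else lapply(seq_len(n_frames(trajectory)), function(i) frame_coords(trajectory, i))
  z0 <- NULL
  out <- t(vapply(frames, function(xyz) {
    core <- xyz[core_idx, , drop = FALSE]
    c3 <- core[which.min(core[, 3]), ]; c17 <- core[which.max(core[, 3]), ]
    ax <- principal_axis(core, c3, c17)
    tilt <- acos(min(max(sum(ax * ref$z_axis), -1), 1)) * 180 / pi
    c(tilt = tilt, z = mean(core[, 3]))
  }, numeric(2)))
  data.frame(frame = seq_len(nrow(out)), tilt = out[, "tilt"],
             displacement = out[, "z"] - out[1, "z"])
}

#' Sugar-site clustering of the para-hydroxyl marker
#'
#' For each binding mode with enough frames, the in-plane (x, y) positions
#' of the sugar marker atom -- after optional superposition of every frame
#' onto the topology over `align_labels` -- are clustered with k-means (k = 2 by
#' default). Clusters whose centroids lie closer than `merge_dist` are
#' merged into one site. The higher-occupancy site is labeled `X`, the
#' other `Y`.
#'
#' @param trajectory A [cts_trajectory].
#' @param trace Matching `binding_mode_trace`.
#' @param groups `atom_group_map` with `sugar_marker`.
#' @param ref A `reference_frame` (origin subtracted from positions).
#' @param k Sites sought per mode (default 2).
#' @param merge_dist Centroid merge distance, Angstrom (default
#'   `cts_tolerances$merge_dist`).
#' @param min_frames Modes with fewer frames are skipped with a warning
#'   (default 20).
#' @param align_labels Optional atom labels for per-frame superposition.
#' @param seed k-means seed.
#' @return Object of class `sugar_sites`: per mode a list with `centroids`
#'   (site x 2 matrix, Angstrom, rows named X/Y), `occupancy` (fractions
#'   summing to 1) and `n` (frames).
#' @export
sugar_site_clusters <- function(trajectory, trace, groups, ref, k = 2,
                                merge_dist = cts_tolerances$merge_dist,
                                min_frames = 20, align_labels = NULL, seed = 1) {
  topo <- trajectory$topology
  sm <- groups$groups$sugar_marker
  if (is.null(sm)) stop_cts("configuration_error", "no sugar_marker configured")
  sm_idx <- atom_indices(topo, sm, "sugar_marker")[1]
  frames <- if (!is.null(align_labels))
    align_frames_to_topology(trajectory, align_labels)
  else lapply(seq_len(n_frames(trajectory)), function(i) frame_coords(trajectory, i))
  xy <- t(vapply(frames, function(f) f[sm_idx, 1:2] - ref$origin[1:2], numeric(2)))
  lab <- trace$frames$label
  res <- list()
  for (m in BM_LABELS) {
    sel <- lab == m
    if (!any(sel)) next
    if (sum(sel) < min_frames) {
      warning(sprintf("mode %s has %d frames (< %d); skipped", m, sum(sel), min_frames))
      next
    }
    pts <- xy[sel, , drop = FALSE]
    set.seed(seed)
    km <- stats::kmeans(pts, centers = min(k, nrow(unique(pts))), nstart = 10)
    cen <- km$centers; size <- km$size
    # merge centroids closer than merge_dist
    repeat {
      if (nrow(cen) < 2) break
      dd <- as.matrix(stats::dist(cen)); diag(dd) <- Inf
      ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      if (dd[ij[1], ij[2]] >= merge_dist) break
      w <- size[ij]
      merged <- colSums(cen[ij, , drop = FALSE] * w) / sum(w)
      keep <- setdiff(seq_len(nrow(cen)), ij)
      cen <- rbind(cen[keep, , drop = FALSE], merged)
      size <- c(size[keep], sum(w))
    }
    ord <- order(size, decreasing = TRUE)
    cen <- cen[ord, , drop = FALSE]; size <- size[ord]
    rownames(cen) <- c("X", "Y", "Z")[seq_len(nrow(cen))]
    res[[m]] <- list(centroids = cen, occupancy = size / sum(size), n = sum(sel))
  }
  structure(res, class = "sugar_sites")
}

#' @export
print.sugar_sites <- function(x, ...) {
  for (m in names(x)) {
    cat(sprintf("%s (%d frames):\n", m, x[[m]]$n))
    cen <- x[[m]]$centroids
    for (i in seq_len(nrow(cen)))
      cat(sprintf("  site %s: (%.2f, %.2f) A, occupancy %.2f\n",
                  rownames(cen)[i], cen[i, 1], cen[i, 2], x[[m]]$occupancy[i]))
  }
  invisible(x)
}
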