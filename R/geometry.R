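# Geometric primitives: principal axes, Kabsch superposition, rigid
# transforms, and the binding-site reference frame that defines the
# rotational binding modes.

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix (det +1, orthonormal).
#' @param translation Length-3 numeric translation (Angstrom).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3)
    stop_cts("invalid_input", "rigid_transform needs a 3x3 rotation and length-3 translation")
  tol <- cts_tolerances$orthonormal_tol
  if (max(abs(crossprod(rotation) - diag(3))) > sqrt(tol))
    stop_cts("invalid_input", "rotation matrix is not orthonormal")
  if (det(rotation) < 0)
    stop_cts("invalid_input", "rotation matrix is a reflection (det < 0)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform A `rigid_transform`.
#' @param coords n x 3 matrix of coordinates (Angstrom).
#' @return Transformed n x 3 matrix `coords %*% t(R) + t`.
#' @export
apply_transform <- function(transform, coords) {
  coords <- rbind(coords)
  sweep(coords %*% t(transform$rotation), 2, -transform$translation)
}

#' Principal (long) axis of a point cloud
#'
#' Largest-variance eigenvector of the coordinate covariance, with its sign
#' fixed so the axis points from `orient_from` toward `orient_to`. Used for
#' the long axis of the steroid core (the rotational axis of the binding
#' modes runs along the core).
#'
#' @param points n x 3 matrix of coordinates, n >= 3.
#' @param orient_from,orient_to Length-3 points fixing the axis sign; the
#'   returned axis has positive dot product with `orient_to - orient_from`.
#' @return Unit length-3 vector.
#' @export
principal_axis <- function(points, orient_from, orient_to) {
  points <- rbind(points)
  if (nrow(points) < 3)
    stop_cts("invalid_input", "principal_axis needs at least 3 points, got %d", nrow(points))
  if (!all(is.finite(points)))
    stop_cts("invalid_input", "principal_axis: non-finite coordinates")
  centred <- sweep(points, 2, colMeans(points))
  cv <- crossprod(centred) / nrow(points)
  if (sum(diag(cv)) < .Machine$double.eps * 100)
    stop_cts("degenerate_geometry", "principal_axis: zero total variance")
  axis <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  ref <- as.numeric(orient_to) - as.numeric(orient_from)
  s <- sum(axis * ref)
  if (s < 0) axis <- -axis
  axis / sqrt(sum(axis^2))
}

#' Kabsch least-squares superposition
#'
#' Optimal proper-rotation superposition of `mobile` onto `reference` over a
#' set of paired atoms, e.g. the alphaM1-6 C-alpha atoms used to align
#' trajectory frames before extracting positions in the binding-site frame.
#' A reflection is never returned: the smallest singular direction is
#' negated when the naive solution has det -1.
#'
#' @param mobile,reference n x 3 coordinate matrices of paired atoms
#'   (same order), or `cts_structure` objects when `selection` is given.
#' @param selection Optional character vector of atom labels
#'   (`"chain/resid/atom"`) used to pair atoms between two structures.
#' @return List with `transform` (a [rigid_transform] mapping mobile onto
#'   reference) and `rmsd` (Angstrom, after superposition).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  if (!is.null(selection)) {
    mobile <- structure_coords(mobile, selection)
    reference <- structure_coords(reference, selection)
  }
  mobile <- rbind(mobile); reference <- rbind(reference)
  if (nrow(mobile) != nrow(reference))
    stop_cts("pairing_error", "kabsch_superpose: %d mobile vs %d reference atoms",
             nrow(mobile), nrow(reference))
  if (nrow(mobile) < 3)
    stop_cts("invalid_input", "kabsch_superpose needs >= 3 paired atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  s <- svd(crossprod(A, B))          # H = A'B; R = V D U' with det guard
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- cr - as.numeric(R %*% cm)
  tr <- rigid_transform(R, t_vec)
  moved <- apply_transform(tr, mobile)
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  list(transform = tr, rmsd = rmsd)
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop_cts("degenerate_geometry", "zero-length vector cannot be normalized")
  v / n
}

#' Signed angle between in-plane vectors
#'
#' Counterclockwise angle (degrees, in (-180, 180]) from `a` to `b` viewed
#' from the extracellular (+z) side of the membrane.
#' @noRd
signed_angle_xy <- function(a, b) {
  ang <- atan2(a[1] * b[2] - a[2] * b[1], a[1] * b[1] + a[2] * b[2]) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  unname(ang)
}

#' Build the binding-site reference frame
#'
#' Defines the frame in which rotational binding modes are measured: the
#' origin is the centroid of configured binding-site atoms, the z axis is
#' the membrane normal (extracellular positive, as in OPM-aligned starting
#' structures), and each transmembrane helix contributes an in-plane unit
#' direction from the origin toward its C-alpha centroid.
#'
#' @param structure A `cts_structure`.
#' @param helix_ranges Named list, one entry per helix label (e.g. `"aM1"`),
#'   each a list with `chain`, `start`, `end` (residue numbers, inclusive).
#' @param site_atoms Character vector of atom labels (`"chain/resid/atom"`)
#'   whose centroid is the site origin.
#' @param z_axis Membrane normal, default `c(0, 0, 1)`.
#' @param mode_map Named character vector helix -> mode label; default
#'   [default_mode_map()]. Keys must be a subset of `names(helix_ranges)`.
#' @return Object of class `reference_frame` with fields `origin`, `z_axis`,
#'   `helix_directions` (named list of unit in-plane vectors), `azimuths`
#'   (degrees from the first mode helix, for reporting) and `mode_map`.
#' @export
build_reference_frame <- function(structure, helix_ranges, site_atoms,
                                  z_axis = c(0, 0, 1),
                                  mode_map = default_mode_map()) {
  if (!all(names(mode_map) %in% names(helix_ranges)))
    stop_cts("configuration_error", "mode_map helices missing from helix_ranges: %s",
             paste(setdiff(names(mode_map), names(helix_ranges)), collapse = ", "))
  z_axis <- unit(as.numeric(z_axis))
  origin <- unname(colMeans(structure_coords(structure, site_atoms)))

  dirs <- list()
  for (h in names(helix_ranges)) {
    rg <- helix_ranges[[h]]
    at <- structure$atoms
    sel <- at$chain == rg$chain & at$resid >= rg$start & at$resid <= rg$end &
      at$atom == "CA"
    if (sum(sel) < 4) {
      missing_res <- setdiff(seq(rg$start, rg$end),
                             at$resid[at$chain == rg$chain & at$atom == "CA"])
      stop_cts("configuration_error",
               "helix %s: %d CA atoms found (need >= 4); absent residues: %s",
               h, sum(sel),
               if (length(missing_res)) paste(missing_res, collapse = ",") else
                 sprintf("chain %s not present", rg$chain))
    }
    cen <- unname(colMeans(as.matrix(at[sel, c("x", "y", "z")])))
    v <- cen - origin
    v_inplane <- v - sum(v * z_axis) * z_axis
    if (sqrt(sum(v_inplane^2)) < cts_tolerances$degenerate_dist)
      stop_cts("degenerate_direction",
               "helix %s centroid projects within 0.1 A of the site origin", h)
    dirs[[h]] <- unit(v_inplane)
  }

  ref_h <- names(mode_map)[1]
  azimuths <- vapply(dirs, function(d) signed_angle_xy(dirs[[ref_h]], d),
                     numeric(1))
  structure(list(origin = origin, z_axis = z_axis, helix_directions = dirs,
                 azimuths = azimuths, mode_map = mode_map),
            class = "reference_frame")
}

#' @export
print.reference_frame <- function(x, ...) {
  cat("Binding-site reference frame\n")
  cat(sprintf("  origin: (%.2f, %.2f, %.2f) A\n", x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  helices: %s\n", paste(names(x$helix_directions), collapse = ", ")))
  for (h in names(x$mode_map))
    cat(sprintf("  %s -> %s (azimuth %.1f deg)\n", h, x$mode_map[[h]], x$azimuths[[h]]))
  invisible(x)
}
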