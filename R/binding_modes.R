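# Rotational binding-mode classification. The steroid core's rotation
# about its long axis is summarized by the signed in-plane angle phi from
# the alphaM2 direction to the ligand's beta-surface vector (the direction
# from the core centroid toward the beta-methyl centroid), counterclockwise
# positive viewed from the extracellular (+z) side. The beta-surface facing
# alphaM2 / alphaM1 / alphaM4 / alphaM6 defines BM0 / BM1 / BM2 / BM3.

beta_vector_xy <- function(coords, groups, ref) {
  core <- coords[groups$idx$core_ring_atoms, , drop = FALSE]
  meth <- coords[groups$idx$beta_methyls, , drop = FALSE]
  c3 <- core[which.min(core[, 3]), ]
  c17 <- core[which.max(core[, 3]), ]
  axis <- principal_axis(core, c3, c17)
  bv <- colMeans(meth) - colMeans(core)
  bv <- bv - sum(bv * axis) * axis                     # orthogonalize vs long axis
  bv <- bv - sum(bv * ref$z_axis) * ref$z_axis          # project to membrane plane
  bv
}

resolve_group_indices <- function(groups, topology) {
  groups$idx <- lapply(groups$groups, function(lab)
    atom_indices(topology, lab, context = "group"))
  groups
}

#' Rotation angle of the steroid core in one frame
#'
#' @param coords Frame coordinates (n_atoms x 3) in the same atom order as
#'   the topology `groups` was resolved against.
#' @param groups An `atom_group_map` (with `core_ring_atoms` and
#'   `beta_methyls`) resolved against the topology via the `trajectory`
#'   argument of [rotation_angles()], or carrying an `idx` field.
#' @param ref A [build_reference_frame()] result.
#' @param topology Optional [cts_structure] used to resolve `groups` when
#'   they have not been resolved yet.
#' @return Signed angle phi in degrees, in (-180, 180]; `NA` with a
#'   `degenerate_orientation` warning when the beta vector projects to
#'   < 0.1 Angstrom in the membrane plane.
#' @export
rotation_angle <- function(coords, groups, ref, topology = NULL) {
  if (is.null(groups$idx)) {
    if (is.null(topology))
      stop_cts("invalid_input", "groups are unresolved; supply `topology`")
    groups <- resolve_group_indices(groups, topology)
  }
  bv <- beta_vector_xy(coords, groups, ref)
  if (sqrt(sum(bv^2)) < cts_tolerances$degenerate_dist) {
    warning("degenerate orientation: beta vector < 0.1 A in plane; frame unassigned")
    return(NA_real_)
  }
  signed_angle_xy(ref$helix_directions[["aM2"]], bv)
}

#' Rotation angles for every frame of a trajectory
#'
#' @param trajectory A [cts_trajectory].
#' @param groups An `atom_group_map`.
#' @param ref A `reference_frame`.
#' @return Numeric vector of per-frame angles (degrees), NA for degenerate
#'   frames.
#' @export
rotation_angles <- function(trajectory, groups, ref) {
  groups <- resolve_group_indices(groups, trajectory$topology)
  vapply(seq_len(n_frames(trajectory)), function(i)
    suppressWarnings(rotation_angle(frame_coords(trajectory, i), groups, ref)),
    numeric(1))
}

wrap180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}

mode_azimuths <- function(ref) {
  helices <- names(ref$mode_map)
  az <- vapply(helices, function(h)
    signed_angle_xy(ref$helix_directions[["aM2"]], ref$helix_directions[[h]]),
    numeric(1))
  names(az) <- ref$mode_map[helices]
  az[order(names(az))]   # BM0, BM1, BM2, BM3 order
}

# Wrapped-normal density (radians), truncated wrap sum.
dwrapnorm <- function(theta, mu, sd) {
  out <- 0
  for (j in -3:3) out <- out + stats::dnorm(theta + 2 * pi * j, mu, sd)
  out
}

# Circular (wrapped-Gaussian) mixture EM on angles in radians.
em_wrapped_1d <- function(theta, k, init_mu, tol, max_iter) {
  n <- length(theta); w <- rep(1 / k, k); mu <- init_mu; sd <- rep(0.5, k)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    comp <- vapply(seq_len(k), function(j) w[j] * dwrapnorm(theta, mu[j], sd[j]),
                   numeric(n))
    comp <- matrix(comp, nrow = n)
    tot <- pmax(rowSums(comp), .Machine$double.xmin)
    ll <- sum(log(tot))
    if (is.finite(ll_old) && ll - ll_old < tol) { ll_old <- ll; break }
    ll_old <- ll
    r <- comp / tot
    nk <- pmax(colSums(r), 1e-12)
    w <- nk / n
    for (j in seq_len(k)) {
      # circular mean/sd via first trigonometric moment
      C <- sum(r[, j] * cos(theta)) / nk[j]
      S <- sum(r[, j] * sin(theta)) / nk[j]
      mu[j] <- atan2(S, C)
      R <- min(sqrt(C^2 + S^2), 1 - 1e-12)
      sd[j] <- max(sqrt(-2 * log(R)), 0.02)
    }
  }
  list(w = w, mu = mu, sd = sd, loglik = ll_old)
}

#' Assign binding-mode labels from rotation angles
#'
#' `method = "nearest"` labels each frame by the mode-defining helix whose
#' direction has maximal cosine with the beta vector (equivalently, minimal
#' circular distance between phi and the helix azimuth); ties break toward
#' the lower BM index. `method = "cluster"` first fits a wrapped-Gaussian
#' mixture to phi (component count by BIC, capped at 4) and labels every
#' frame of a cluster by the helix nearest the cluster's circular mean.
#'
#' @param angles Per-frame rotation angles (degrees); NA means degenerate.
#' @param ref A `reference_frame`.
#' @param method `"nearest"` (default) or `"cluster"`.
#' @param min_cos Optional: frames whose best cosine falls below this are
#'   left `"unassigned"`. Default NULL (always assign).
#' @param seed Seed for clustering restarts (method "cluster").
#' @return Object of class `binding_mode_trace`: data.frame `frames`
#'   (`phi`, `label`), plus `prevalence` (named fractions over BM0-BM3 and
#'   `unassigned`), `transitions` (4x4 counts) and `dwell` (mean dwell
#'   frames per mode) computed via [mode_transitions()].
#' @export
assign_modes <- function(angles, ref, method = c("nearest", "cluster"),
                         min_cos = NULL, seed = 1) {
  method <- match.arg(method)
  if (!length(angles)) stop_cts("invalid_input", "empty angle sequence")
  az <- mode_azimuths(ref)     # named BM0..BM3, degrees from aM2
  modes <- names(az)
  lab <- rep("unassigned", length(angles))
  ok <- is.finite(angles)

  if (method == "nearest") {
    cosd <- vapply(az, function(a) cos((angles[ok] - a) * pi / 180), numeric(sum(ok)))
    cosd <- matrix(cosd, nrow = sum(ok))
    # ties (within numerical noise) break toward the lower BM index
    best <- apply(cosd, 1, function(v) which(v >= max(v) - 1e-9)[1])
    l <- modes[best]
    if (!is.null(min_cos))
      l[cosd[cbind(seq_along(best), best)] < min_cos] <- "unassigned"
    lab[ok] <- l
  } else {
    theta <- angles[ok] * pi / 180
    n <- length(theta)
    best_by_k <- list()
    set.seed(seed)
    for (k in 1:4) {
      best <- NULL
      for (r in 1:5) {
        init <- sort(stats::runif(k, -pi, pi))
        fit <- em_wrapped_1d(theta, k, init, 1e-8, 300)
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
      best_by_k[[k]] <- best
    }
    bic <- (3 * (1:4) - 1) * log(n) - 2 * vapply(best_by_k, `[[`, 0, "loglik")
    fit <- best_by_k[[which.min(bic)]]
    # posterior-most-probable component per frame, then label by helix
    comp <- vapply(seq_along(fit$w), function(j)
      fit$w[j] * dwrapnorm(theta, fit$mu[j], fit$sd[j]), numeric(n))
    comp <- matrix(comp, nrow = n)
    cl <- apply(comp, 1, which.max)
    mu_deg <- fit$mu * 180 / pi
    cl_mode <- vapply(mu_deg, function(m)
      modes[which.max(cos((m - az) * pi / 180))], "")
    lab[ok] <- cl_mode[cl]
  }

  trace <- structure(list(frames = data.frame(phi = angles, label = lab,
                                              stringsAsFactors = FALSE)),
                     class = "binding_mode_trace")
  trace$prevalence <- mode_prevalence(trace)
  tr <- mode_transitions(trace)
  trace$transitions <- tr$counts
  trace$dwell <- tr$dwell
  trace
}

#' Binding-mode prevalence
#'
#' Fraction of pooled frames per mode. Several traces (repeat simulations)
#' are pooled with every frame weighted equally, matching prevalences
#' reported over combined simulation time.
#'
#' @param traces A `binding_mode_trace` or list of them.
#' @return Named numeric vector over BM0-BM3 and `unassigned`, summing to 1.
#' @export
mode_prevalence <- function(traces) {
  if (inherits(traces, "binding_mode_trace")) traces <- list(traces)
  if (!length(traces)) stop_cts("invalid_input", "no traces")
  lab <- unlist(lapply(traces, function(t) t$frames$label))
  lev <- c(BM_LABELS, "unassigned")
  tab <- table(factor(lab, levels = lev))
  p <- as.numeric(tab) / length(lab)
  names(p) <- lev
  p
}

#' Transition counts and dwell times of a binding-mode trace
#'
#' Counts label changes between consecutive assigned frames; unassigned
#' frames break runs and contribute no transitions. Dwell times are mean
#' run lengths (frames) per mode.
#'
#' @param trace A `binding_mode_trace`.
#' @return List: `counts` (4x4 matrix, from-row to-column, diagonal =
#'   self-transitions), `dwell` (named mean run length per mode, NA when a
#'   mode never occurs).
#' @export
mode_transitions <- function(trace) {
  lab <- trace$frames$label
  counts <- matrix(0L, 4, 4, dimnames = list(BM_LABELS, BM_LABELS))
  ok <- lab %in% BM_LABELS
  prev <- NULL
  runs_label <- character(); runs_len <- integer()
  cur_lab <- NULL; cur_len <- 0L
  for (i in seq_along(lab)) {
    if (!ok[i]) {
      if (!is.null(cur_lab)) { runs_label <- c(runs_label, cur_lab); runs_len <- c(runs_len, cur_len) }
      cur_lab <- NULL; cur_len <- 0L; prev <- NULL
      next
    }
    if (!is.null(prev)) counts[prev, lab[i]] <- counts[prev, lab[i]] + 1L
    if (identical(cur_lab, lab[i])) cur_len <- cur_len + 1L
    else {
      if (!is.null(cur_lab)) { runs_label <- c(runs_label, cur_lab); runs_len <- c(runs_len, cur_len) }
      cur_lab <- lab[i]; cur_len <- 1L
    }
    prev <- lab[i]
  }
  if (!is.null(cur_lab)) { runs_label <- c(runs_label, cur_lab); runs_len <- c(runs_len, cur_len) }
  dwell <- vapply(BM_LABELS, function(m)
    if (any(runs_label == m)) mean(runs_len[runs_label == m]) else NA_real_,
    numeric(1))
  list(counts = counts, dwell = dwell)
}

#' Classify a trajectory into binding modes
#'
#' Convenience wrapper: computes per-frame rotation angles and assigns
#' modes in one call.
#'
#' @inheritParams rotation_angles
#' @inheritParams assign_modes
#' @return A `binding_mode_trace`.
#' @export
classify_binding_modes <- function(trajectory, groups, ref,
                                   method = "nearest", min_cos = NULL, seed = 1) {
  assign_modes(rotation_angles(trajectory, groups, ref), ref,
               method = method, min_cos = min_cos, seed = seed)
}

#' @export
print.binding_mode_trace <- function(x, ...) {
  cat(sprintf("binding_mode_trace: %d frames\n", nrow(x$frames)))
  p <- x$prevalence[x$prevalence > 0]
  cat("  prevalence:", paste(sprintf("%s %.1f%%", names(p), 100 * p), collapse = ", "), "\n")
  invisible(x)
}
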