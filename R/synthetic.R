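# Synthetic-data generators with known ground truth. Frames are
# statistical emulations of the study's observables -- Markov-switching
# rotational modes, Bernoulli hydrogen-bond contacts at set prevalences,
# mixture-distributed lactone--ion distances, planted sugar sites -- not
# molecular dynamics: there is no force field and no integrator.

# Deterministic per-stream sub-seeds from one global seed, so adding a new
# stream never perturbs existing ones. Kept below 2^31.
sub_seed <- function(seed, stream) {
  streams <- c(modes = 1L, jitter = 2L, tilt = 3L, vertical = 4L,
               contacts = 5L, ion = 6L, sugar = 7L, assay = 8L, torsion = 9L)
  (as.integer(seed) %% 1000003L) * 1009L + streams[[stream]]
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_axis <- function(axis, deg) {
  a <- deg * pi / 180; u <- unit(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

random_unit <- function(n = 1) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

#' Default per-mode contact-prevalence table
#'
#' Ligand-group/residue hydrogen-bond prevalences per binding mode used by
#' the default synthetic system; values are loosely patterned on the kind
#' of interaction matrix seen for a bufadienolide aglycone (a dominant
#' core-to-T797 bond in BM1, C3-substituent contacts in BM2).
#'
#' @return data.frame with columns `group`, `residue`, `BM0`..`BM3`.
#' @export
default_contact_prevalences <- function() {
  data.frame(
    group   = c("hydroxyl_C14", "hydroxyl_C14", "hydroxyl_C3", "hydroxyl_C3"),
    residue = c("T797", "N122", "Q111", "N122"),
    BM0 = c(0.95, 0.00, 0.10, 0.00),
    BM1 = c(0.91, 0.07, 0.00, 0.00),
    BM2 = c(0.00, 0.03, 0.36, 0.39),
    BM3 = c(0.00, 0.00, 0.00, 0.00),
    stringsAsFactors = FALSE)
}

default_ion_mixture <- function() {
  # bound component at the K+ coordination distance (2.8 A) plus an
  # unbound component at 6-8 A; mixing varies by mode
  list(
    BM0 = data.frame(weight = c(0.8, 0.2), mean = c(2.8, 6.5), sd = c(0.2, 0.5)),
    BM1 = data.frame(weight = c(0.9, 0.1), mean = c(2.8, 6.0), sd = c(0.2, 0.5)),
    BM2 = data.frame(weight = c(0.3, 0.7), mean = c(2.8, 7.0), sd = c(0.2, 0.6)),
    BM3 = data.frame(weight = c(0.1, 0.9), mean = c(2.8, 7.5), sd = c(0.2, 0.6)))
}

default_sugar_sites <- function() {
  # two in-plane sites 4 A apart, sd 0.5 A; the major site dominates so the
  # X/Y occupancy ordering is well defined in every mode
  lapply(stats::setNames(c(0.7, 0.7, 0.65, 0.65), BM_LABELS), function(w)
    list(centers = rbind(X = c(2, 0), Y = c(-2, 0)), sd = 0.5,
         weights = c(w, 1 - w)))
}

#' A sticky Markov transition matrix with a given stationary distribution
#'
#' `P = stickiness * I + (1 - stickiness) * 1 pi'`, which has stationary
#' distribution `pi` for any stickiness in [0, 1).
#'
#' @param pi Stationary distribution over BM0-BM3 (sums to 1).
#' @param stickiness Diagonal persistence weight (default 0.9).
#' @return 4x4 row-stochastic matrix with BM dimnames.
#' @export
sticky_transition_matrix <- function(pi = rep(0.25, 4), stickiness = 0.9) {
  if (abs(sum(pi) - 1) > 1e-9 || any(pi < 0))
    stop_cts("invalid_input", "pi must be a distribution")
  P <- stickiness * diag(4) + (1 - stickiness) * matrix(pi, 4, 4, byrow = TRUE)
  dimnames(P) <- list(BM_LABELS, BM_LABELS)
  P
}

#' Stationary distribution of a transition matrix
#' @param P Row-stochastic matrix.
#' @return Stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(P))
}

#' Specification of a synthetic binding-mode trajectory
#'
#' @param n_frames Number of frames.
#' @param transition 4x4 row-stochastic mode transition matrix
#'   (rows/columns BM0-BM3; rows must sum to 1 within 1e-12).
#' @param start_mode Initial mode label; default drawn from the stationary
#'   distribution.
#' @param contact_prevalences data.frame (`group`, `residue`,
#'   `BM0`..`BM3`), per-mode hydrogen-bond prevalences in [0, 1].
#' @param ion_mixture Named list per mode: data.frame (`weight`, `mean` A,
#'   `sd` A); weights sum to 1.
#' @param jitter_sd Wrapped-Gaussian rotational jitter sd, degrees.
#' @param tilt_sd Core tilt noise sd, degrees.
#' @param vertical_sd Vertical (z) displacement noise sd, Angstrom.
#' @param helix_azimuths Named azimuths (degrees) of the pseudo-helices;
#'   any two closer than 20 degrees on the circle are rejected.
#' @param sugar_sites Named list per mode: list(`centers` (site x 2 matrix,
#'   A), `sd`, `weights`).
#' @param frame_spacing ns per frame (metadata).
#' @param seed Global seed fanned out to per-stream sub-seeds.
#' @return Object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_frames = 5000,
                            transition = sticky_transition_matrix(),
                            start_mode = NULL,
                            contact_prevalences = default_contact_prevalences(),
                            ion_mixture = default_ion_mixture(),
                            jitter_sd = 15, tilt_sd = 5, vertical_sd = 0.5,
                            helix_azimuths = c(aM2 = 0, aM1 = 90, aM4 = 180,
                                               aM6 = 270, aM5 = 315),
                            sugar_sites = default_sugar_sites(),
                            frame_spacing = 0.1, seed = 1) {
  if (any(abs(rowSums(transition) - 1) > 1e-12) || any(transition < 0))
    stop_cts("invalid_input", "transition rows must be nonnegative and sum to 1")
  dimnames(transition) <- list(BM_LABELS, BM_LABELS)
  pv <- as.matrix(contact_prevalences[, BM_LABELS])
  if (any(pv < 0 | pv > 1))
    stop_cts("invalid_input", "contact prevalences must lie in [0, 1]")
  for (m in names(ion_mixture))
    if (abs(sum(ion_mixture[[m]]$weight) - 1) > 1e-9)
      stop_cts("invalid_input", "ion mixture weights for %s must sum to 1", m)
  az <- helix_azimuths
  for (i in seq_along(az)) for (j in seq_along(az)) {
    if (i >= j) next
    sep <- abs(wrap180(az[i] - az[j]))
    if (sep < 20)
      stop_cts("ambiguous_geometry",
               "helix azimuths %s and %s are %.1f deg apart (< 20)",
               names(az)[i], names(az)[j], sep)
  }
  structure(list(n_frames = as.integer(n_frames), transition = transition,
                 start_mode = start_mode,
                 contact_prevalences = contact_prevalences,
                 ion_mixture = ion_mixture, jitter_sd = jitter_sd,
                 tilt_sd = tilt_sd, vertical_sd = vertical_sd,
                 helix_azimuths = helix_azimuths, sugar_sites = sugar_sites,
                 frame_spacing = frame_spacing, seed = seed),
            class = "trajectory_spec")
}

# ligand template: atom name, element, local coordinates (long axis = z,
# beta face = +x, C3 end at low z, C17/lactone end at high z)
ligand_template <- function() {
  i <- 1:17
  # lateral offsets complete one full period so the core's xy centroid is
  # exactly at the rotation axis (and hence at the site origin)
  core <- data.frame(atom = paste0("C", i), element = "C",
                     x = 0.6 * cos(2 * pi * (i - 1) / 17),
                     y = 0.6 * sin(2 * pi * (i - 1) / 17),
                     z = seq(-4, 4, length.out = 17))
  extra <- data.frame(
    atom = c("C18", "C19", "C20", "C21", "O23", "O3L", "O14"),
    element = c("C", "C", "C", "C", "O", "O", "O"),
    x = c(1.8, 1.8, 0.4, -0.4, 0.0, -0.5, -1.0),
    y = c(0.0, 0.0, 0.3, -0.3, 0.0, 0.3, 0.5),
    z = c(1.0, 2.5, 4.4, 4.6, 4.9, -4.3, 1.5))
  rbind(core, extra)
}

residue_number <- function(res_label) as.integer(gsub("[^0-9]", "", res_label))

#' Generate a synthetic system with known ground truth
#'
#' Builds a pseudo-protein (straight C-alpha helices on a 12 A circle at
#' the configured azimuths), a rigid steroid-core template with two
#' beta-methyl marker atoms on one face, single-atom hydrogen-bond partner
#' residues, a site-II ion and a sugar-marker atom; then emits frames in
#' which the binding mode follows the Markov chain, the core is rotated to
#' the mode helix's azimuth plus wrapped-Gaussian jitter (with tilt and
#' vertical noise), partner atoms satisfy or violate hydrogen-bond
#' geometry by Bernoulli draws at the configured prevalences, the ion sits
#' at a mixture-distributed distance from the lactone oxygen, and the
#' sugar marker falls in planted in-plane sites. Deterministic under the
#' spec's seed.
#'
#' @param spec A [trajectory_spec].
#' @return List: `structure` ([cts_structure] topology), `trajectory`
#'   ([cts_trajectory]), `groups` (`atom_group_map`), `pairs` (list of
#'   [hbond_pair]s for the configured contacts), `helix_ranges`,
#'   `site_atoms`, and `truth` (list: `modes`, `phi`, `contacts`
#'   (frame x pair logical matrix), `ion_component`,
#'   `mode_prevalence` (stationary distribution), `spec`).
#' @export
generate_system <- function(spec) {
  if (!inherits(spec, "trajectory_spec")) stop_cts("invalid_input", "need a trajectory_spec")
  az <- spec$helix_azimuths
  nf <- spec$n_frames

  # ---- topology ------------------------------------------------------
  helix_rows <- NULL
  helix_ranges <- list()
  base_res <- c(aM1 = 100L, aM2 = 200L, aM4 = 400L, aM5 = 500L, aM6 = 600L)
  for (h in names(az)) {
    zs <- seq(-15, 15, length.out = 21)
    res <- base_res[[h]] + seq_along(zs)
    helix_rows <- rbind(helix_rows, data.frame(
      atom = "CA", resname = "ALA", resid = res, chain = "A", element = "C",
      x = 12 * cos(az[[h]] * pi / 180), y = 12 * sin(az[[h]] * pi / 180), z = zs))
    helix_ranges[[h]] <- list(chain = "A", start = min(res), end = max(res))
  }
  lig <- ligand_template()
  lig_rows <- data.frame(atom = lig$atom, resname = "CTS", resid = 1L,
                         chain = "L", element = lig$element,
                         x = lig$x, y = lig$y, z = lig$z)
  # one donor/acceptor atom per contact, so contacts sharing a residue
  # (e.g. N122 reachable from both OH-C3 and OH-C14) stay independent
  cp0 <- spec$contact_prevalences
  part_atom <- stats::ave(seq_len(nrow(cp0)), cp0$residue,
                          FUN = seq_along)
  part_rows <- data.frame(atom = paste0("OD", part_atom),
                          resname = substr(cp0$residue, 1, 1),
                          resid = residue_number(cp0$residue), chain = "P",
                          element = "O",
                          x = 8 * cos(seq_len(nrow(cp0))),
                          y = 8 * sin(seq_len(nrow(cp0))), z = 0)
  residues <- unique(cp0$residue)
  sugar_row <- data.frame(atom = "O4S", resname = "GLC", resid = 2L,
                          chain = "L", element = "O", x = 2, y = 0, z = -6)
  ion_row <- data.frame(atom = "K", resname = "K", resid = 901L, chain = "I",
                        element = "K", x = 0, y = 0, z = 7)
  atoms <- rbind(helix_rows, lig_rows, part_rows, sugar_row, ion_row)
  topo <- cts_structure(atoms)
  labs <- atom_labels(topo)

  lig_idx <- which(atoms$chain == "L" & atoms$resid == 1L)
  lig_names <- atoms$atom[lig_idx]
  idx_of <- function(name) lig_idx[match(name, lig_names)]
  group_atom <- c(hydroxyl_C14 = "O14", hydroxyl_C3 = "O3L", lactone = "O23",
                  sugar = "O4S")
  sugar_idx <- which(atoms$atom == "O4S")
  ion_idx <- which(atoms$chain == "I")
  part_idx <- nrow(helix_rows) + nrow(lig_rows) + seq_len(nrow(cp0))
  stopifnot(all(atoms$chain[part_idx] == "P"))

  # ---- per-frame streams --------------------------------------------
  set.seed(sub_seed(spec$seed, "modes"))
  pi_stat <- stationary_distribution(spec$transition)
  modes <- character(nf)
  modes[1] <- spec$start_mode %||% sample(BM_LABELS, 1, prob = pi_stat)
  for (f in seq_len(nf - 1))
    modes[f + 1] <- sample(BM_LABELS, 1, prob = spec$transition[modes[f], ])

  mode_helix <- stats::setNames(names(default_mode_map()), default_mode_map())
  mode_az <- az[mode_helix[modes]]
  set.seed(sub_seed(spec$seed, "jitter"))
  phi <- wrap180(mode_az + stats::rnorm(nf, 0, spec$jitter_sd))
  set.seed(sub_seed(spec$seed, "tilt"))
  tilt_angle <- stats::rnorm(nf, 0, spec$tilt_sd)
  tilt_axis_az <- stats::runif(nf, 0, 360)
  set.seed(sub_seed(spec$seed, "vertical"))
  dz <- stats::rnorm(nf, 0, spec$vertical_sd)

  cp <- spec$contact_prevalences
  pair_names <- paste(cp$group, cp$residue, sep = ":")
  set.seed(sub_seed(spec$seed, "contacts"))
  pmat <- as.matrix(cp[, BM_LABELS])          # pairs x modes
  contact_on <- matrix(stats::runif(nf * nrow(cp)), nf, nrow(cp)) <
    t(pmat[, match(modes, BM_LABELS), drop = FALSE])
  dimnames(contact_on) <- list(NULL, pair_names)
  d_on <- matrix(stats::runif(nf * nrow(cp), 2.6, 3.3), nf, nrow(cp))
  d_off <- matrix(stats::runif(nf * nrow(cp), 4.5, 8.0), nf, nrow(cp))
  contact_dir <- array(random_unit(nf * nrow(cp)), c(nf, nrow(cp), 3))

  set.seed(sub_seed(spec$seed, "ion"))
  ion_comp <- integer(nf); ion_d <- numeric(nf)
  for (f in seq_len(nf)) {
    mix <- spec$ion_mixture[[modes[f]]]
    j <- sample.int(nrow(mix), 1, prob = mix$weight)
    ion_comp[f] <- j
    ion_d[f] <- max(stats::rnorm(1, mix$mean[j], mix$sd[j]), 0.1)
  }
  ion_dir <- random_unit(nf)

  set.seed(sub_seed(spec$seed, "sugar"))
  sugar_xy <- matrix(0, nf, 2)
  for (f in seq_len(nf)) {
    ss <- spec$sugar_sites[[modes[f]]]
    j <- sample.int(nrow(ss$centers), 1, prob = ss$weights)
    sugar_xy[f, ] <- ss$centers[j, ] + stats::rnorm(2, 0, ss$sd)
  }

  # ---- assemble coordinates -----------------------------------------
  lig_template_xyz <- as.matrix(lig[, c("x", "y", "z")])
  coords <- array(NA_real_, c(nrow(atoms), 3, nf))
  static_xyz <- as.matrix(atoms[, c("x", "y", "z")])
  for (f in seq_len(nf)) {
    xyz <- static_xyz
    R <- rot_axis(c(cos(tilt_axis_az[f] * pi / 180),
                    sin(tilt_axis_az[f] * pi / 180), 0), tilt_angle[f]) %*%
      rot_z(phi[f])
    lg <- lig_template_xyz %*% t(R)
    lg[, 3] <- lg[, 3] + dz[f]
    xyz[lig_idx, ] <- lg
    for (p in seq_len(nrow(cp))) {
      donor <- xyz[idx_of(group_atom[[cp$group[p]]]), ]
      d <- if (contact_on[f, p]) d_on[f, p] else d_off[f, p]
      xyz[part_idx[p], ] <- donor + d * contact_dir[f, p, ]
    }
    xyz[ion_idx, ] <- xyz[idx_of("O23"), ] + ion_d[f] * ion_dir[f, ]
    xyz[sugar_idx, ] <- c(sugar_xy[f, ], -6)
    coords[, , f] <- xyz
  }

  traj <- cts_trajectory(topo, coords, spec$frame_spacing,
                         metadata = list(ligand = "synthetic-CTS",
                                         stereochemistry = "beta",
                                         ions = "2xK", repeat_id = 1L))

  # ---- groups, pairs, truth -----------------------------------------
  lab_of <- function(i) labs[i]
  groups_cfg <- list(
    groups = list(
      core_ring_atoms = lab_of(idx_of(paste0("C", 1:17))),
      beta_methyls = lab_of(idx_of(c("C18", "C19"))),
      lactone_atoms = lab_of(idx_of(c("C20", "C21", "O23"))),
      hydroxyl_oxygens = lab_of(idx_of(c("O3L", "O14"))),
      sugar_marker = labs[sugar_idx],
      ion_site_II = labs[ion_idx]),
    partners = lapply(stats::setNames(residues, residues), function(r)
      list(atoms = labs[part_idx[cp$residue == r]])))
  groups <- read_group_config(groups_cfg, topo)

  pairs <- lapply(seq_len(nrow(cp)), function(p)
    hbond_pair(pair_names[p],
               a = lab_of(idx_of(group_atom[[cp$group[p]]])),
               b = labs[part_idx[p]]))

  site_atoms <- lab_of(idx_of(paste0("C", 1:17)))
  list(structure = topo, trajectory = traj, groups = groups, pairs = pairs,
       helix_ranges = helix_ranges, site_atoms = site_atoms,
       truth = list(modes = modes, phi = phi, contacts = contact_on,
                    ion_component = ion_comp, ion_distance = ion_d,
                    mode_prevalence = vapply(BM_LABELS, function(m)
                      mean(modes == m), numeric(1)),
                    stationary = pi_stat, spec = spec))
}

#' Generate a synthetic tight-binding inhibition dataset
#'
#' Percent inhibition from the equilibrium solver plus Gaussian noise. The
#' default noise model is multiplicative (a constant coefficient of
#' variation, as enzyme-activity readings typically show):
#' `y * (1 + N(0, noise_sd_percent/100))`. `noise_type = "additive"` adds
#' `N(0, noise_sd_percent)` percentage points instead.
#'
#' @param model A [tight_binding_model] (the ground truth).
#' @param L_grid Total ligand concentrations, uM.
#' @param noise_sd_percent Noise scale: CV in percent (multiplicative) or
#'   percentage points (additive).
#' @param seed Seed.
#' @param noise_type `"multiplicative"` (default) or `"additive"`.
#' @return List: `dataset` (data.frame `L_total`, `inhibition`, with
#'   `E_total` attribute), `truth` (the model).
#' @export
generate_inhibition_dataset <- function(model, L_grid, noise_sd_percent = 0,
                                        seed = 1,
                                        noise_type = c("multiplicative",
                                                       "additive")) {
  noise_type <- match.arg(noise_type)
  if (any(L_grid < 0)) stop_cts("invalid_input", "negative concentrations")
  y <- predict_inhibition(model, L_grid)
  set.seed(sub_seed(seed, "assay"))
  eps <- stats::rnorm(length(y), 0, 1)
  y <- if (noise_type == "multiplicative")
    y * (1 + eps * noise_sd_percent / 100) else y + eps * noise_sd_percent
  d <- data.frame(L_total = L_grid, inhibition = y)
  attr(d, "E_total") <- model$E_total
  list(dataset = d, truth = model)
}

#' Generate synthetic AO-competition fluorescence readings
#'
#' Bound amounts come from the exact two-ligand equilibrium solver;
#' fluorescence = baseline + span x AO-bound fraction + noise. The free-AO
#' reference reading emulates displacement by 1 mM unlabeled ouabain.
#' Defaults follow the assay conditions: enzyme 0.1 uM incubated with
#' equimolar AO and competitor at 0.2 uM each.
#'
#' @param K_ratio True K_X / K_AO (> 0).
#' @param E_total,AO_total,X_total Totals, uM.
#' @param noise_sd Additive fluorescence noise sd.
#' @param seed Seed.
#' @param K_AO Absolute AO dissociation constant, uM (default 1e-4, i.e.
#'   0.1 nM, the reported affinity scale of AO for the phosphoenzyme).
#' @param baseline,span Fluorescence of free AO and the span to the fully
#'   bound signal.
#' @return List: `measurement` (list `F_AO`, `F_mix`, `F_ref`, totals),
#'   `truth` (list `K_ratio`, `K_AO`, bound amounts).
#' @export
generate_competition_readings <- function(K_ratio, E_total = 0.1,
                                          AO_total = 0.2, X_total = 0.2,
                                          noise_sd = 0, seed = 1,
                                          K_AO = 1e-4, baseline = 100,
                                          span = 1000) {
  if (K_ratio <= 0) stop_cts("invalid_input", "K_ratio must be > 0")
  if (E_total <= 0 || AO_total <= 0 || X_total < 0)
    stop_cts("invalid_input", "concentrations must be positive")
  K_X <- K_ratio * K_AO
  alone <- competition_equilibrium(E_total, AO_total, 0, K_AO, Inf)
  mix <- if (X_total > 0)
    competition_equilibrium(E_total, AO_total, X_total, K_AO, K_X) else alone
  ref <- competition_equilibrium(E_total, AO_total, 1000, K_AO, K_AO)
  set.seed(sub_seed(seed, "assay"))
  noise <- stats::rnorm(3, 0, noise_sd)
  F_of <- function(eq) baseline + span * eq$bound_AO / AO_total
  measurement <- list(F_AO = F_of(alone) + noise[1],
                      F_mix = F_of(mix) + noise[2],
                      F_ref = F_of(ref) + noise[3],
                      E_total = E_total, AO_total = AO_total, X_total = X_total)
  list(measurement = measurement,
       truth = list(K_ratio = K_ratio, K_AO = K_AO,
                    bound_AO_alone = alone$bound_AO, bound_AO_mix = mix$bound_AO,
                    bound_X_mix = mix$bound_X))
}

#' Generate noisy torsional energy profiles from known dihedral terms
#'
#' @param true_terms A [dihedral_term_set]; one profile is generated per
#'   dihedral, using the term set's stored offset for that name (or 0).
#' @param grid Scan angles, degrees (default [scan_grid()], i.e. the
#'   10-degree circle).
#' @param noise_sd Additive Gaussian noise sd, kcal/mol.
#' @param seed Seed.
#' @return List: `profiles` (list of [dihedral_profile]), `truth`
#'   (the term set).
#' @export
generate_torsion_profiles <- function(true_terms, grid = scan_grid(),
                                      noise_sd = 0, seed = 1) {
  if (!length(grid)) stop_cts("invalid_input", "empty grid")
  if (any(grid <= -180 - 1e-9) || any(grid > 180 + 1e-9))
    stop_cts("invalid_input", "grid must lie within (-180, 180]")
  set.seed(sub_seed(seed, "torsion"))
  profiles <- lapply(names(true_terms$terms), function(nm) {
    e <- dihedral_energy(true_terms, nm, grid) +
      stats::rnorm(length(grid), 0, noise_sd)
    dihedral_profile(nm, grid, e)
  })
  names(profiles) <- names(true_terms$terms)
  list(profiles = profiles, truth = true_terms)
}
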