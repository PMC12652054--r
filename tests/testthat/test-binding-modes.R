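# A hand-built single frame: core along z, beta methyls displaced along a
# chosen in-plane direction, embedded in the standard synthetic topology.
frame_with_beta_direction <- function(sys, azimuth_deg) {
  xyz <- frame_coords(sys$trajectory, 1)
  topo <- sys$structure
  core_idx <- match(sys$groups$groups$core_ring_atoms, atom_labels(topo))
  meth_idx <- match(sys$groups$groups$beta_methyls, atom_labels(topo))
  core <- cbind(0, 0, seq(-4, 4, length.out = 17))   # axis exactly along z
  xyz[core_idx, ] <- core
  u <- c(cos(azimuth_deg * pi / 180), sin(azimuth_deg * pi / 180), 0)
  xyz[meth_idx[1], ] <- colMeans(core) + 2 * u + c(0, 0, 1)
  xyz[meth_idx[2], ] <- colMeans(core) + 2 * u + c(0, 0, 2)
  xyz
}

test_that("rotation_angle is zero when the beta face points at alphaM2", {
  sys <- small_system(); ref <- small_ref(sys)
  xyz <- frame_with_beta_direction(sys, 0)
  expect_equal(rotation_angle(xyz, sys$groups, ref, topology = sys$structure),
               0, tolerance = 1e-6)
})

test_that("rotation_angle sign follows the counterclockwise-from-extracellular convention", {
  sys <- small_system(); ref <- small_ref(sys)
  for (az in c(90, -90, 45, 170)) {
    xyz <- frame_with_beta_direction(sys, az)
    phi <- rotation_angle(xyz, sys$groups, ref, topology = sys$structure)
    # oracle: explicit atan2 of the constructed in-plane direction against
    # the aM2 helix direction
    a <- ref$helix_directions[["aM2"]]
    b <- c(cos(az * pi / 180), sin(az * pi / 180))
    want <- atan2(a[1] * b[2] - a[2] * b[1], a[1] * b[1] + a[2] * b[2]) * 180 / pi
    expect_equal(phi, want, tolerance = 1e-6)
  }
})

test_that("rotation_angle is invariant under rigid motion of the frame after alignment", {
  sys <- small_system(); ref <- small_ref(sys)
  xyz <- frame_with_beta_direction(sys, 30)
  phi0 <- rotation_angle(xyz, sys$groups, ref, topology = sys$structure)
  R <- random_rotation(8); tv <- c(4, -7, 2)
  moved <- sweep(xyz %*% t(R), 2, -tv)
  # align back on all atoms (exact rigid copy), then re-measure
  fit <- kabsch_superpose(moved, xyz)
  back <- apply_transform(fit$transform, moved)
  phi1 <- rotation_angle(back, sys$groups, ref, topology = sys$structure)
  expect_equal(phi1, phi0, tolerance = 1e-6)
})

test_that("degenerate beta vectors mark the frame unassigned", {
  sys <- small_system(); ref <- small_ref(sys)
  xyz <- frame_coords(sys$trajectory, 1)
  topo <- sys$structure
  core_idx <- match(sys$groups$groups$core_ring_atoms, atom_labels(topo))
  meth_idx <- match(sys$groups$groups$beta_methyls, atom_labels(topo))
  xyz[core_idx, ] <- cbind(0.3 * cos(1:17), 0.3 * sin(1:17),
                           seq(-4, 4, length.out = 17))
  xyz[meth_idx, ] <- rep(colMeans(xyz[core_idx, ]), each = 2) +
    cbind(0, 0, c(1, 2))   # beta offset purely along the axis
  expect_warning(phi <- rotation_angle(xyz, sys$groups, ref, topology = topo),
                 "degenerate")
  expect_true(is.na(phi))
  tr <- assign_modes(c(0, phi, 0), ref)
  expect_equal(tr$frames$label, c("BM0", "unassigned", "BM0"))
})

test_that("nearest-direction assignment labels angles and breaks ties low", {
  ref <- small_ref()
  tr <- assign_modes(rep(0, 10), ref)
  expect_equal(unname(tr$prevalence["BM0"]), 1)
  # exactly between BM0 (0 deg) and BM1 (90 deg): lower BM index wins
  tie <- assign_modes(45, ref)
  expect_equal(tie$frames$label, "BM0")
  # min_cos strictness: 45 deg off every direction fails min_cos = 0.9
  strict <- assign_modes(45, ref, min_cos = 0.9)
  expect_equal(strict$frames$label, "unassigned")
})

test_that("synthetic traces are labeled to ground truth at jitter sd 15", {
  sys <- small_system(); ref <- small_ref(sys)
  tr <- classify_binding_modes(sys$trajectory, sys$groups, ref)
  agree <- mean(tr$frames$label == sys$truth$modes)
  expect_gte(agree, 0.98)
})

test_that("clustering and nearest assignment agree on well-separated angles", {
  sys <- small_system(); ref <- small_ref(sys)
  phi <- rotation_angles(sys$trajectory, sys$groups, ref)
  near <- assign_modes(phi, ref, method = "nearest")
  clus <- assign_modes(phi, ref, method = "cluster", seed = 2)
  expect_gte(mean(near$frames$label == clus$frames$label), 0.95)
})

test_that("a circular cluster straddling +/-180 is recovered as one state", {
  ref <- small_ref()
  set.seed(6)
  # all mass at the alphaM4 azimuth (180 deg): wrapped draws land near +180
  # and -180; a linear clusterer would split them
  phi <- ctsbind:::wrap180(180 + rnorm(400, 0, 12))
  expect_gt(sum(phi > 170), 10); expect_gt(sum(phi < -170), 10)
  tr <- assign_modes(phi, ref, method = "cluster", seed = 3)
  expect_equal(unname(tr$prevalence["BM2"]), 1)
})

test_that("prevalence pools repeats frame-weighted and is permutation invariant", {
  ref <- small_ref()
  t1 <- assign_modes(rep(0, 100), ref)     # all BM0
  t2 <- assign_modes(rep(90, 100), ref)    # all BM1
  p <- mode_prevalence(list(t1, t2))
  expect_equal(unname(p[c("BM0", "BM1")]), c(0.5, 0.5))
  set.seed(1)
  phi <- runif(300, -180, 180)
  expect_equal(mode_prevalence(assign_modes(phi, ref)),
               mode_prevalence(assign_modes(sample(phi), ref)))
})

test_that("transition counting matches hand counts and breaks runs at unassigned frames", {
  ref <- small_ref()
  const <- mode_transitions(assign_modes(rep(0, 20), ref))
  expect_equal(sum(const$counts) - const$counts["BM0", "BM0"], 0)
  alt <- assign_modes(rep(c(0, 90), 5), ref)   # BM0/BM1 alternating, length 10
  tra <- mode_transitions(alt)
  expect_equal(sum(tra$counts[tra$counts > 0 & row(tra$counts) != col(tra$counts)]), 9)
  # NA angle breaks the run: no transition spans it
  broken <- assign_modes(c(0, 0, NA, 90, 90), ref)
  trb <- mode_transitions(broken)
  expect_equal(trb$counts["BM0", "BM1"], 0)
  expect_equal(trb$counts["BM0", "BM0"], 1)
  expect_equal(trb$counts["BM1", "BM1"], 1)
})

test_that("empirical transition probabilities recover the generating chain", {
  P <- sticky_transition_matrix(pi = c(0.4, 0.3, 0.2, 0.1), stickiness = 0.85)
  sys <- generate_system(trajectory_spec(n_frames = 5000, transition = P, seed = 12))
  ref <- build_reference_frame(sys$structure, sys$helix_ranges, sys$site_atoms)
  tr <- classify_binding_modes(sys$trajectory, sys$groups, ref)
  counts <- mode_transitions(tr)$counts
  Phat <- counts / pmax(rowSums(counts), 1)
  visited <- rowSums(counts) > 200
  expect_lt(max(abs(Phat[visited, ] - P[visited, ])), 0.05)
})
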