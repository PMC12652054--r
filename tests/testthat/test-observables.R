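toy_hbond_frame <- function() {
  # donor-acceptor pairs at controlled distances; single-atom sides
  atoms <- data.frame(
    atom = c("O1", "O2", "O3", "O4", "N1", "N2", "H1"),
    resname = "X", resid = 1:7, chain = "A",
    element = c("O", "O", "O", "O", "N", "N", "H"),
    x = c(0, 2.9, 4.0, 0, 10, 10, 1.0),
    y = c(0, 0, 0, 3.2, 0, 2.8, 0),
    z = 0)
  cts_structure(atoms)
}

test_that("distance-only hydrogen-bond detection matches a brute-force scan", {
  topo <- toy_hbond_frame()
  xyz <- structure_coords(topo)
  crit <- hbond_criteria(dist_max = 3.5, angle_min = 150)
  labels <- atom_labels(topo)
  pairs <- list()
  combos <- utils::combn(6, 2)
  for (i in seq_len(ncol(combos)))
    pairs[[i]] <- hbond_pair(paste0("p", i), labels[combos[1, i]], labels[combos[2, i]])
  got <- detect_hbonds(xyz, topo, pairs, crit)
  # oracle: independent all-pairs distance scan
  want <- apply(combos, 2, function(ij)
    sqrt(sum((xyz[ij[1], ] - xyz[ij[2], ])^2)) <= 3.5)
  expect_equal(unname(got), want)
  expect_true(got[["p1"]])     # O1-O2 at 2.9 A
  expect_false(any(xyz[1, ] != 0) && got[[which(combos[1, ] == 1 & combos[2, ] == 3)]]) # O1-O3 at 4.0 A
})

test_that("the D-H-A angle criterion gates bonds when hydrogens are given", {
  topo <- toy_hbond_frame()
  xyz <- structure_coords(topo)
  crit <- hbond_criteria(dist_max = 3.5, angle_min = 150, hydrogen_optional = FALSE)
  # H1 at (1,0,0) lies between O1 (0,0,0) and O2 (2.9,0,0): angle 180
  p_in <- hbond_pair("in", "A/1/O1", "A/2/O2", hydrogens_a = "A/7/H1")
  expect_true(detect_hbonds(xyz, topo, list(p_in), crit)[["in"]])
  # same donor pair but acceptor O4 at (0,3.2,0): O1-H1-O4 angle is 90
  p_out <- hbond_pair("out", "A/1/O1", "A/4/O4", hydrogens_a = "A/7/H1")
  expect_false(detect_hbonds(xyz, topo, list(p_out), crit)[["out"]])
  # strict criteria without hydrogens must error
  p_noh <- hbond_pair("noh", "A/1/O1", "A/2/O2")
  expect_error(detect_hbonds(xyz, topo, list(p_noh), crit),
               class = "criteria_error")
})

test_that("interaction prevalence is exact on constructed traces and drops rare modes", {
  sys <- small_system(); ref <- small_ref(sys)
  # constructed trace: call every frame BM1 -> always-on pair reads 100%
  nf <- n_frames(sys$trajectory)
  tr_all <- assign_modes(rep(90, nf), ref)
  always_on <- hbond_pair("self", sys$groups$groups$core_ring_atoms[1],
                          sys$groups$groups$core_ring_atoms[2])
  pm <- interaction_prevalence(sys$trajectory, tr_all, list(always_on))
  expect_equal(unname(pm$matrix["self", "BM1"]), 1)
  expect_equal(colnames(pm$matrix), "BM1")   # other modes at 0% are dropped
})

test_that("a planted 4%-prevalence mode is excluded by the 5% filter", {
  P <- sticky_transition_matrix(pi = c(0.48, 0.48, 0.04, 0), stickiness = 0.9)
  sys <- generate_system(trajectory_spec(n_frames = 5000, transition = P, seed = 21))
  ref <- build_reference_frame(sys$structure, sys$helix_ranges, sys$site_atoms)
  tr <- classify_binding_modes(sys$trajectory, sys$groups, ref)
  expect_lt(unname(tr$prevalence["BM2"]), 0.05)
  expect_gt(unname(tr$prevalence["BM2"]), 0.02)
  pm <- interaction_prevalence(sys$trajectory, tr, sys$pairs)
  expect_false("BM2" %in% colnames(pm$matrix))
  expect_setequal(colnames(pm$matrix), c("BM0", "BM1"))
})

test_that("prevalence cells are frame-order invariant and pooling is frame-weighted", {
  sys <- generate_system(trajectory_spec(n_frames = 200, seed = 31))
  ref <- build_reference_frame(sys$structure, sys$helix_ranges, sys$site_atoms)
  tr <- classify_binding_modes(sys$trajectory, sys$groups, ref)
  pm <- interaction_prevalence(sys$trajectory, tr, sys$pairs, threshold = 0)
  perm <- sample(200)
  traj_p <- cts_trajectory(sys$structure, sys$trajectory$coords[, , perm],
                           sys$trajectory$frame_spacing)
  tr_p <- tr; tr_p$frames <- tr$frames[perm, ]
  pm_p <- interaction_prevalence(traj_p, tr_p, sys$pairs, threshold = 0)
  expect_equal(pm_p$matrix[, colnames(pm$matrix)], pm$matrix)
  # pooling two copies equals the single-trajectory matrix
  pm2 <- interaction_prevalence(list(sys$trajectory, sys$trajectory),
                                list(tr, tr), sys$pairs, threshold = 0)
  expect_equal(pm2$matrix[, colnames(pm$matrix)], pm$matrix)
})

test_that("ion distances are exact on constructed frames and flagged when absent", {
  sys <- small_system()
  ds <- ion_distance_series(sys$trajectory, sys$groups)
  expect_equal(nrow(ds), n_frames(sys$trajectory))
  # constructed: move the ion 2.8 A straight above the lactone oxygen
  topo <- sys$structure
  o23 <- match(paste0("L/1/O23"), atom_labels(topo))
  ion <- match(sys$groups$groups$ion_site_II, atom_labels(topo))
  xyz <- frame_coords(sys$trajectory, 1)
  xyz[ion, ] <- xyz[o23, ] + c(0, 0, 2.8)
  coords <- array(xyz, c(nrow(xyz), 3, 1))
  t1 <- cts_trajectory(topo, coords)
  expect_equal(ion_distance_series(t1, sys$groups)$distance, 2.8, tolerance = 1e-9)
  xyz[ion, ] <- xyz[o23, ]
  t0 <- cts_trajectory(topo, array(xyz, c(nrow(xyz), 3, 1)))
  expect_equal(ion_distance_series(t0, sys$groups)$distance, 0)
  g2 <- sys$groups; g2$groups$ion_site_II <- NULL
  empty <- ion_distance_series(sys$trajectory, g2)
  expect_equal(nrow(empty), 0)
  expect_true(attr(empty, "ion_absent"))
})

test_that("per-mode ion distances reflect the generating mixtures", {
  sys <- small_system(); ref <- small_ref(sys)
  tr <- classify_binding_modes(sys$trajectory, sys$groups, ref)
  ds <- ion_distance_series(sys$trajectory, sys$groups, tr)
  mix <- sys$truth$spec$ion_mixture
  for (m in c("BM0", "BM1")) {
    v <- ds$distance[ds$mode == m]
    want <- sum(mix[[m]]$weight * mix[[m]]$mean)
    expect_equal(mean(v), want, tolerance = 3 * sd(v) / sqrt(length(v)) + 0.05)
  }
})

test_that("mixture EM with BIC selects the right component count", {
  set.seed(101)
  one <- rnorm(2000, 2.8, 0.2)
  f1 <- mixture_fit_bic(one)
  expect_equal(f1$k, 1)
  expect_equal(f1$components$mean, mean(one), tolerance = 0.05)

  two <- c(rnorm(1000, 2.8, 0.2), rnorm(1000, 6.0, 0.5))
  f2 <- mixture_fit_bic(two)
  expect_equal(f2$k, 2)
  expect_equal(f2$components$mean, c(2.8, 6.0), tolerance = 0.1)
  expect_equal(f2$components$weight, c(0.5, 0.5), tolerance = 0.05)
})

test_that("mixture fits agree with mclust as an independent reference", {
  skip_if_not_installed("mclust")
  suppressMessages(require(mclust, quietly = TRUE))  # Mclust needs attachment
  set.seed(55)
  x <- c(rnorm(700, 2.8, 0.2), rnorm(300, 6.5, 0.4))
  ours <- mixture_fit_bic(x)
  mc <- mclust::Mclust(x, G = 1:4, modelNames = "V", verbose = FALSE)
  expect_equal(ours$k, mc$G)
  expect_equal(sort(ours$components$mean), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  expect_equal(ours$loglik, mc$loglik, tolerance = 1e-4)
})

test_that("degenerate samples collapse to one floored component", {
  f <- mixture_fit_bic(rep(2.8, 50))
  expect_equal(f$k, 1)
  expect_equal(f$components$sd, cts_tolerances$sd_floor)
  expect_error(mixture_fit_bic(rnorm(5)), class = "insufficient_data")
})

test_that("BIC selection sharpens with sample size on separated components", {
  hits <- function(n) {
    mean(vapply(1:10, function(s) {
      set.seed(s)
      x <- c(rnorm(n / 2, 2.8, 0.2), rnorm(n / 2, 6.0, 0.5))
      mixture_fit_bic(x)$k == 2
    }, logical(1)))
  }
  expect_gte(hits(2000), hits(200))
  expect_equal(hits(2000), 1)
})

test_that("stability series report tilt and vertical displacement exactly on constructed frames", {
  sys <- small_system(); ref <- small_ref(sys)
  topo <- sys$structure
  core_idx <- match(sys$groups$groups$core_ring_atoms, atom_labels(topo))
  xyz <- frame_coords(sys$trajectory, 1)
  xyz[core_idx, ] <- cbind(0, 0, seq(-4, 4, length.out = 17))  # axis along z
  xyz2 <- xyz; xyz2[core_idx, 3] <- xyz2[core_idx, 3] + 1.5
  traj <- cts_trajectory(topo, array(c(xyz, xyz2), c(nrow(xyz), 3, 2)))
  ss <- stability_series(traj, sys$groups, ref)
  expect_equal(ss$tilt[1], 0, tolerance = 1e-6)
  expect_equal(ss$displacement, c(0, 1.5), tolerance = 1e-9)
})

test_that("stability is invariant to rigid motion when alignment is enabled", {
  sys <- generate_system(trajectory_spec(n_frames = 30, seed = 41))
  ref <- build_reference_frame(sys$structure, sys$helix_ranges, sys$site_atoms)
  al <- helix_ca_labels(sys$structure, sys$helix_ranges)
  ss0 <- stability_series(sys$trajectory, sys$groups, ref, align_labels = al)
  R <- random_rotation(3); tv <- c(5, 5, -3)
  coords <- sys$trajectory$coords
  for (f in seq_len(dim(coords)[3]))
    coords[, , f] <- sweep(coords[, , f] %*% t(R), 2, -tv)
  moved <- cts_trajectory(sys$structure, coords)
  ss1 <- stability_series(moved, sys$groups, ref, align_labels = al)
  expect_equal(ss1$tilt, ss0$tilt, tolerance = 1e-6)
  expect_equal(ss1$displacement, ss0$displacement, tolerance = 1e-6)
})

test_that("generated tilt noise is recovered at roughly the configured scale", {
  sys <- generate_system(trajectory_spec(n_frames = 800, tilt_sd = 5, seed = 17))
  ref <- build_reference_frame(sys$structure, sys$helix_ranges, sys$site_atoms)
  ss <- stability_series(sys$trajectory, sys$groups, ref)
  # tilt is the absolute angle off z; its mean for half-normal(5) is 5*sqrt(2/pi)
  expect_equal(sd(c(ss$tilt, -ss$tilt)), 5, tolerance = 1)
})

test_that("sugar-site clustering recovers planted sites and merges tight ones", {
  sys <- small_system(); ref <- small_ref(sys)
  tr <- classify_binding_modes(sys$trajectory, sys$groups, ref)
  sg <- sugar_site_clusters(sys$trajectory, tr, sys$groups, ref, seed = 5)
  planted <- sys$truth$spec$sugar_sites
  for (m in names(sg)) {
    cen <- sg[[m]]$centroids
    expect_equal(sum(sg[[m]]$occupancy), 1, tolerance = 1e-9)
    expect_equal(nrow(cen), 2)
    # X = higher-occupancy site = the planted major center
    major <- planted[[m]]$centers[which.max(planted[[m]]$weights), ]
    minor <- planted[[m]]$centers[which.min(planted[[m]]$weights), ]
    expect_lt(sqrt(sum((cen["X", ] - major)^2)), 0.2)
    expect_lt(sqrt(sum((cen["Y", ] - minor)^2)), 0.2)
    expect_gte(sg[[m]]$occupancy[1], sg[[m]]$occupancy[2])
  }
  # single tight site: k-means 2 clusters then merge to one
  one_site <- lapply(planted, function(p) {
    p$centers <- rbind(X = c(1, 0), Y = c(1.4, 0)); p$weights <- c(0.5, 0.5); p
  })
  sys1 <- generate_system(trajectory_spec(n_frames = 300, sugar_sites = one_site,
                                          seed = 6))
  ref1 <- build_reference_frame(sys1$structure, sys1$helix_ranges, sys1$site_atoms)
  tr1 <- classify_binding_modes(sys1$trajectory, sys1$groups, ref1)
  sg1 <- sugar_site_clusters(sys1$trajectory, tr1, sys1$groups, ref1, seed = 5)
  for (m in names(sg1)) expect_equal(nrow(sg1[[m]]$centroids), 1)
  # modes with too few frames are skipped with a warning
  few <- tr; few$frames$label[-(1:10)] <- "BM0"; few$frames$label[1:10] <- "BM3"
  expect_warning(sugar_site_clusters(sys$trajectory, few, sys$groups, ref),
                 "skipped")
})
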