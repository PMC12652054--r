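test_that("dihedral energies evaluate the cosine series exactly", {
  zero <- dihedral_term_set(list(d = data.frame(n = c(1, 3), k = 0, delta = 0)))
  expect_equal(dihedral_energy(zero, "d", scan_grid()), rep(0, 36))
  one <- dihedral_term_set(list(d = data.frame(n = 1, k = 2.5, delta = 0)))
  expect_equal(dihedral_energy(one, "d", c(0, 180)), c(5, 0), tolerance = 1e-12)
  # random term set vs independent naive summation
  set.seed(4)
  tt <- data.frame(n = 1:6, k = runif(6, 0, 3), delta = sample(c(0, 180), 6, TRUE))
  ts <- dihedral_term_set(list(d = tt))
  ang <- runif(25, -180, 180)
  naive <- vapply(ang, function(a) {
    s <- 0
    for (i in 1:6) s <- s + tt$k[i] * (1 + cos(tt$n[i] * a * pi / 180 -
                                                 tt$delta[i] * pi / 180))
    s
  }, numeric(1))
  expect_equal(dihedral_energy(ts, "d", ang), naive, tolerance = 1e-12)
})

test_that("a 180-degree phase equals a sign-flipped cosine contribution", {
  a <- dihedral_term_set(list(d = data.frame(n = 2, k = 1.3, delta = 180)))
  phi <- scan_grid() * pi / 180
  expect_equal(dihedral_energy(a, "d", scan_grid()),
               1.3 * (1 - cos(2 * phi)), tolerance = 1e-12)
})

test_that("noiseless profiles are recovered exactly", {
  truth <- dihedral_term_set(
    list(d1 = data.frame(n = c(1, 2, 3), k = c(1.5, 0.8, 2.2), delta = c(0, 180, 0)),
         d2 = data.frame(n = c(1, 6), k = c(0.4, 1.1), delta = c(180, 0))),
    offsets = c(d1 = 1.0, d2 = -2.0))
  g <- generate_torsion_profiles(truth, noise_sd = 0)
  fit <- fit_dihedral_terms(g$profiles)
  expect_lt(fit$rmse, 1e-6)
  for (nm in c("d1", "d2")) {
    got <- fit$term_set$terms[[nm]]
    want <- truth$terms[[nm]]
    got <- got[order(got$n), ]; want <- want[order(want$n), ]
    expect_equal(got$n, want$n)
    expect_equal(got$k, want$k, tolerance = 1e-6)
    expect_equal(got$delta, want$delta)
  }
  # round trip: fitted terms reproduce the target through dihedral_energy
  for (nm in c("d1", "d2"))
    expect_equal(dihedral_energy(fit$term_set, nm, g$profiles[[nm]]$angles,
                                 profile = nm),
                 g$profiles[[nm]]$energies, tolerance = 1e-6)
})

test_that("fitted RMSE tracks the noise level", {
  truth <- dihedral_term_set(
    list(d1 = data.frame(n = c(1, 3), k = c(2, 1), delta = c(0, 0))))
  rmses <- vapply(1:20, function(s) {
    g <- generate_torsion_profiles(truth, noise_sd = 0.2, seed = s)
    fit_dihedral_terms(g$profiles)$rmse
  }, numeric(1))
  expect_true(all(rmses >= 0.1 & rmses <= 0.3))
})

test_that("offset-only targets give zero force constants", {
  p <- dihedral_profile("d", scan_grid(), rep(4.2, 36))
  fit <- fit_dihedral_terms(list(p))
  expect_equal(nrow(fit$term_set$terms$d), 0)
  expect_equal(unname(fit$term_set$offsets["d"]), 4.2, tolerance = 1e-9)
  expect_lt(fit$rmse, 1e-9)
})

test_that("the fit never beats the data but always beats the offset-only model", {
  set.seed(12)
  p <- dihedral_profile("d", scan_grid(),
                        2 * (1 + cos(2 * scan_grid() * pi / 180)) + rnorm(36, 0, 0.3))
  fit <- fit_dihedral_terms(list(p))
  rmse_offset_only <- sqrt(mean((p$energies - mean(p$energies))^2))
  expect_lte(fit$rmse, rmse_offset_only)
})

test_that("a constant shift of one profile is absorbed by its offset", {
  truth <- dihedral_term_set(
    list(d1 = data.frame(n = 2, k = 1.4, delta = 0)), offsets = c(d1 = 0))
  g <- generate_torsion_profiles(truth, noise_sd = 0)
  f0 <- fit_dihedral_terms(g$profiles)
  shifted <- g$profiles
  shifted$d1$energies <- shifted$d1$energies + 7.7
  f1 <- fit_dihedral_terms(shifted)
  expect_equal(f1$term_set$terms$d1$k, f0$term_set$terms$d1$k, tolerance = 1e-9)
  expect_equal(unname(f1$term_set$offsets["d1"] - f0$term_set$offsets["d1"]),
               7.7, tolerance = 1e-9)
})

test_that("a restricted phase dictionary enforces nonnegative constants", {
  # target built from a delta=180 term; with only delta=0 allowed the
  # fitter cannot go negative and must approximate with other multiplicities
  truth <- dihedral_term_set(list(d = data.frame(n = 1, k = 2, delta = 180)))
  g <- generate_torsion_profiles(truth, noise_sd = 0)
  fit <- fit_dihedral_terms(g$profiles, phases = 0)
  expect_true(all(fit$term_set$terms$d$k >= 0))
  full <- fit_dihedral_terms(g$profiles)
  expect_lte(full$rmse, fit$rmse + 1e-9)
  expect_lt(full$rmse, 1e-6)
})

test_that("underdetermined systems name the deficient profile", {
  p <- dihedral_profile("d", c(-60, 60), c(1, 2), name = "tiny")
  expect_error(fit_dihedral_terms(list(p)), "tiny")
})

test_that("profiles round-trip through the TSV reader and CHARMM stream writer", {
  truth <- dihedral_term_set(
    list(`CA-CB-NL-OL` = data.frame(n = c(1, 2), k = c(1.1, 0.6),
                                    delta = c(0, 180))),
    offsets = c(`CA-CB-NL-OL` = 0.5))
  g <- generate_torsion_profiles(truth, noise_sd = 0)
  tsv <- tempfile(fileext = ".tsv")
  d <- data.frame(dihedral = "CA-CB-NL-OL", angle = g$profiles[[1]]$angles,
                  energy = g$profiles[[1]]$energies)
  write.table(d, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  profs <- read_dihedral_profiles(tsv)
  fit <- fit_dihedral_terms(profs)
  expect_lt(fit$rmse, 1e-6)
  str_path <- tempfile(fileext = ".str")
  write_charmm_dihedrals(fit$term_set, str_path)
  lines <- readLines(str_path)
  expect_true(any(grepl("^DIHEDRALS$", lines)))
  expect_equal(sum(grepl("^CA\\s+CB\\s+NL\\s+OL", lines)), 2)
})
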