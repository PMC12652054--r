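test_that("the Morrison closed form matches the bisection mass-balance oracle", {
  expect_equal(bound_fraction_single(0.1, 0.2, 0.01), 0.915571122978,
               tolerance = 1e-9)
  grid <- expand.grid(E = 10^seq(-3, 0, length.out = 10),
                      L = c(0, 10^seq(-3, 1, length.out = 10)),
                      Kd = 10^seq(-5, 1, length.out = 9))
  got <- mapply(bound_fraction_single, grid$E, grid$L, grid$Kd)
  want <- mapply(bisect_bound_fraction, grid$E, grid$L, grid$Kd)
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("bound fraction limits and monotonicity hold", {
  expect_equal(bound_fraction_single(0.1, 0, 0.05), 0)
  expect_equal(bound_fraction_single(0.1, 0.1, 0), 1)       # stoichiometric
  expect_equal(bound_fraction_single(0.1, 5, 1e-12), 1, tolerance = 1e-9)
  L <- seq(0, 2, by = 0.05)
  expect_true(all(diff(bound_fraction_single(0.1, L, 0.03)) >= 0))
  Kd <- 10^seq(-4, 1, length.out = 30)
  expect_true(all(diff(vapply(Kd, function(k)
    bound_fraction_single(0.1, 0.2, k), 0)) <= 0))
  expect_error(bound_fraction_single(-1, 1, 1), class = "invalid_input")
})

test_that("multi-species equilibrium reduces to and conserves mass", {
  m1 <- tight_binding_model(0.1, 0.02)
  for (L in c(0.01, 0.1, 0.5)) {
    eq <- equilibrium_bound_multi(m1, L)
    expect_equal(eq$bound_fraction, bound_fraction_single(0.1, L, 0.02),
                 tolerance = 1e-9)
  }
  set.seed(2)
  for (i in 1:20) {
    m <- tight_binding_model(runif(1, 0.01, 1), Kd = runif(2, 1e-4, 5),
                             fractions = { a <- runif(1, 0.05, 0.95); c(a, 1 - a) })
    L <- runif(1, 0, 10)
    eq <- equilibrium_bound_multi(m, L)
    expect_lt(abs(eq$free + sum(eq$bound) - L), 1e-9 * max(1, L))
  }
})

test_that("noiseless inhibition fits recover Kd essentially exactly", {
  truth <- tight_binding_model(0.1, 0.015)
  L <- c(0.01, 0.025, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6)
  g <- generate_inhibition_dataset(truth, L, noise_sd_percent = 0)
  fit <- fit_inhibition_curve(g$dataset, n_species = 1, n_boot = 0)
  expect_equal(fit$model$Kd, 0.015, tolerance = 1e-3)
  expect_false(fit$non_binding)
})

test_that("flat data are flagged non-binding instead of erroring", {
  d <- data.frame(L_total = c(0.01, 0.05, 0.1, 0.5, 1, 2),
                  inhibition = rep(1, 6))
  attr(d, "E_total") <- 0.1
  fit <- fit_inhibition_curve(d, n_boot = 0)
  expect_true(fit$non_binding)
})

test_that("AIC prefers the heterogeneous model when the truth is two-species", {
  truth <- tight_binding_model(0.1, Kd = c(0.002, 0.2), fractions = c(0.5, 0.5))
  L <- c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.4, 0.8, 1.5, 3, 6, 12)
  g <- generate_inhibition_dataset(truth, L, noise_sd_percent = 1, seed = 3)
  fit <- fit_inhibition_curve(g$dataset, n_species = 2, n_boot = 0)
  expect_lt(fit$compare[["aic_2species"]], fit$compare[["aic_1species"]])
  expect_equal(sort(fit$model$Kd), c(0.002, 0.2), tolerance = 0.5)
})

test_that("bootstrap intervals cover the generating Kd", {
  truth <- tight_binding_model(0.1, 0.02)
  L <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6, 3, 6)
  g <- generate_inhibition_dataset(truth, L, noise_sd_percent = 3, seed = 7)
  fit <- fit_inhibition_curve(g$dataset, n_boot = 60, seed = 7)
  expect_lt(fit$bootstrap[1, "Kd1"], 0.02)
  expect_gt(fit$bootstrap[2, "Kd1"], 0.02)
})

test_that("competition equilibrium honors limits and conservation", {
  # K_X -> Inf reduces to the single-ligand closed form
  eq <- competition_equilibrium(0.1, 0.2, 0.2, 1e-3, Inf)
  expect_equal(eq$bound_AO / 0.1, bound_fraction_single(0.1, 0.2, 1e-3),
               tolerance = 1e-9)
  # equal K and totals: bound AO = bound X (the 50%-decrease condition)
  eq2 <- competition_equilibrium(0.1, 0.2, 0.2, 1e-3, 1e-3)
  expect_equal(eq2$bound_AO, eq2$bound_X, tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    E <- runif(1, 0.01, 1); AO <- runif(1, 0.01, 2); X <- runif(1, 0, 2)
    KA <- 10^runif(1, -5, 0); KX <- 10^runif(1, -5, 0)
    eq <- competition_equilibrium(E, AO, X, KA, KX)
    expect_lt(abs(eq$free_E + eq$bound_AO + eq$bound_X - E), 1e-9)
    expect_lt(abs(eq$free_AO * (1 + eq$free_E / KA) - AO), 1e-9)
    if (X > 0) expect_lt(abs(eq$free_X * (1 + eq$free_E / KX) - X), 1e-9)
    # equilibrium ratio identity
    if (X > 0)
      expect_equal(eq$bound_AO / eq$bound_X,
                   (eq$free_AO / KA) / (eq$free_X / KX), tolerance = 1e-6)
  }
})

test_that("the residual-fraction estimator is exact algebra", {
  # f = 0.5 at equal totals: equal affinities
  ra <- relative_affinity_ratio(F_AO = 200, F_mix = 150, F_ref = 100)
  expect_identical(ra$ratio, 1)
  expect_identical(ra$f, 0.5)
  # f = 0.2 at equal totals: ratio f/(1-f) = 0.25
  ra2 <- relative_affinity_ratio(F_AO = 200, F_mix = 120, F_ref = 100)
  expect_equal(ra2$ratio, 0.25, tolerance = 1e-12)
})

test_that("the estimator round-trips readings from the exact solver", {
  g <- generate_competition_readings(K_ratio = 1, noise_sd = 0)
  ra <- relative_affinity_ratio(g$measurement$F_AO, g$measurement$F_mix,
                                g$measurement$F_ref)
  expect_equal(ra$ratio, 1, tolerance = 0.05)
  # tighter and weaker competitors keep the ordering
  r_tight <- relative_affinity_ratio(
    F_AO = generate_competition_readings(0.2, noise_sd = 0)$measurement$F_AO,
    F_mix = generate_competition_readings(0.2, noise_sd = 0)$measurement$F_mix,
    F_ref = generate_competition_readings(0.2, noise_sd = 0)$measurement$F_ref)
  expect_lt(r_tight$ratio, 0.5)
})

test_that("estimator accuracy improves toward the ligand-excess regime", {
  # the total-concentration approximation sharpens as totals/K grow
  err_at <- function(K_AO) {
    g <- generate_competition_readings(K_ratio = 1, noise_sd = 0, K_AO = K_AO)
    abs(relative_affinity_ratio(g$measurement$F_AO, g$measurement$F_mix,
                                g$measurement$F_ref)$ratio - 1)
  }
  errs <- vapply(c(1e-2, 1e-3, 1e-4, 1e-5), err_at, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("no-displacement and full-displacement readings are reported as bounds", {
  ra_hi <- relative_affinity_ratio(F_AO = 200, F_mix = 199.9, F_ref = 100)
  expect_equal(ra_hi$censored, "upper")
  expect_true(is.finite(ra_hi$ratio))
  ra_lo <- relative_affinity_ratio(F_AO = 200, F_mix = 100.01, F_ref = 100)
  expect_equal(ra_lo$censored, "lower")
  expect_warning(relative_affinity_ratio(200, 210, 100), "clamped")
  expect_error(relative_affinity_ratio(100, 150, 200), class = "invalid_input")
})
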