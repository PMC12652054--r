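# Equilibrium binding models: Morrison ("square-root") tight-binding
# inhibition with ligand depletion, heterogeneous multi-species binding,
# exact two-ligand competition, and the anthroylouabain (AO) displacement
# estimator of relative affinity.
#
# Concentrations are in micromolar throughout; inhibition in percent.

#' Tight-binding model specification
#'
#' One enzyme population split into species with distinct dissociation
#' constants sharing the free-ligand pool. Heterogeneous (biphasic) binding
#' -- coexisting fast- and slow-dissociating enzyme-ligand complexes -- is
#' realized as two species.
#'
#' @param E_total Total enzyme concentration, uM (> 0).
#' @param Kd Vector of dissociation constants, uM (> 0), one per species.
#' @param fractions Species fractions, summing to 1; default single species.
#' @param amplitude Maximal percent inhibition at full occupancy (default 100).
#' @return Object of class `tight_binding_model`.
#' @export
tight_binding_model <- function(E_total, Kd, fractions = rep(1 / length(Kd), length(Kd)),
                                amplitude = 100) {
  if (!is.numeric(E_total) || E_total <= 0) stop_cts("invalid_input", "E_total must be > 0")
  if (any(Kd <= 0)) stop_cts("invalid_input", "all Kd must be > 0")
  if (length(fractions) != length(Kd))
    stop_cts("invalid_input", "fractions and Kd lengths differ")
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions <= 0))
    stop_cts("invalid_input", "fractions must be positive and sum to 1")
  structure(list(E_total = E_total, Kd = as.numeric(Kd),
                 fractions = as.numeric(fractions), amplitude = amplitude),
            class = "tight_binding_model")
}

#' Morrison tight-binding bound fraction (closed form)
#'
#' Fraction of enzyme occupied at equilibrium when ligand depletion matters
#' (enzyme and ligand concentrations comparable): the root of the
#' single-site mass-balance quadratic,
#' bound = ((E+L+Kd) - sqrt((E+L+Kd)^2 - 4*E*L)) / (2*E).
#' Evaluated in the conjugate form 2L / (S + sqrt(S^2 - 4EL)), S = E+L+Kd,
#' which is stable when the discriminant approaches its root.
#'
#' @param E_total Enzyme concentration, uM (> 0).
#' @param L_total Total ligand concentration(s), uM (>= 0); vectorized.
#' @param Kd Dissociation constant, uM (>= 0).
#' @return Bound-enzyme fraction(s) in `[0, 1]`.
#' @export
bound_fraction_single <- function(E_total, L_total, Kd) {
  if (E_total <= 0) stop_cts("invalid_input", "E_total must be > 0")
  if (any(L_total < 0) || Kd < 0) stop_cts("invalid_input", "L_total and Kd must be >= 0")
  S <- E_total + L_total + Kd
  disc <- pmax(S^2 - 4 * E_total * L_total, 0)
  pmin(2 * L_total / (S + sqrt(disc)), 1)
}

#' Multi-species equilibrium binding
#'
#' Solves for the shared free-ligand concentration Lf in
#' sum_i a_i * E * Lf / (Kd_i + Lf) + Lf = L_total
#' by bracketed root finding, then reports bound ligand per species.
#'
#' @param model A [tight_binding_model].
#' @param L_total Total ligand, uM (>= 0).
#' @return List: `free` (uM), `bound` (uM per species), `bound_fraction`
#'   (total bound-enzyme fraction).
#' @export
equilibrium_bound_multi <- function(model, L_total) {
  if (L_total < 0) stop_cts("invalid_input", "L_total must be >= 0")
  if (L_total == 0)
    return(list(free = 0, bound = rep(0, length(model$Kd)), bound_fraction = 0))
  E <- model$E_total; a <- model$fractions; Kd <- model$Kd
  g <- function(Lf) Lf + sum(a * E * Lf / (Kd + Lf)) - L_total
  gprime <- function(Lf) 1 + sum(a * E * Kd / (Kd + Lf)^2)
  Lf <- stats::uniroot(g, c(0, L_total), tol = .Machine$double.eps^0.75)$root
  for (i in 1:3) {   # Newton polish to machine precision
    step <- g(Lf) / gprime(Lf)
    Lf <- min(max(Lf - step, 0), L_total)
  }
  bound <- a * E * Lf / (Kd + Lf)
  if (abs(Lf + sum(bound) - L_total) > 1e-6 * max(1, L_total))
    stop_cts("numerical_error", "mass balance not satisfied (residual %.3g)",
             Lf + sum(bound) - L_total)
  list(free = Lf, bound = bound, bound_fraction = sum(bound) / E)
}

#' Percent inhibition predicted by a tight-binding model
#' @param model A [tight_binding_model].
#' @param L_total Vector of total ligand concentrations, uM.
#' @return Percent inhibition (amplitude x total bound-enzyme fraction).
#' @export
predict_inhibition <- function(model, L_total) {
  if (length(model$Kd) == 1)   # closed form; equals the solver to ~1e-9
    return(model$amplitude *
             bound_fraction_single(model$E_total, L_total, model$Kd))
  model$amplitude * vapply(L_total, function(L)
    equilibrium_bound_multi(model, L)$bound_fraction, numeric(1))
}

#' Fit a tight-binding ("square-root") inhibition curve
#'
#' Least-squares fit of percent inhibition = amplitude x bound-enzyme
#' fraction against total ligand concentration, with Kd log-parameterized
#' (and the species split logit-parameterized for the heterogeneous model).
#' Reports AIC for 1- vs 2-species model selection and seeded
#' case-resampling bootstrap confidence intervals.
#'
#' @param dataset data.frame with columns `L_total` (uM) and `inhibition`
#'   (percent), plus an `E_total` attribute or explicit argument.
#' @param E_total Enzyme concentration, uM.
#' @param n_species 1 or 2.
#' @param amplitude Fixed maximal inhibition (default 100); set
#'   `fit_amplitude = TRUE` to estimate it instead.
#' @param fit_amplitude Estimate the amplitude? Default FALSE.
#' @param n_boot Bootstrap resamples for CIs (default 1000; 0 disables).
#' @param seed Bootstrap seed.
#' @param conf_level CI level (default 0.95).
#' @param weights `NULL` (unweighted, default), `"inverse_variance"`
#'   (weights 1/y^2, the efficient choice for constant-CV readings), or a
#'   numeric vector of per-point weights.
#' @return List of class `inhibition_fit`: `model` (fitted
#'   [tight_binding_model]), `rss`, `aic`, `n`, `non_binding` flag,
#'   `bootstrap` (Kd quantiles per species, or NULL), `compare` (AIC of the
#'   1- and 2-species fits when `n_species = 2`).
#' @export
fit_inhibition_curve <- function(dataset, E_total = attr(dataset, "E_total"),
                                 n_species = 1, amplitude = 100,
                                 fit_amplitude = FALSE,
                                 n_boot = 1000, seed = 1, conf_level = 0.95,
                                 weights = NULL) {
  if (is.null(E_total)) stop_cts("invalid_input", "E_total is required")
  L <- dataset$L_total; y <- dataset$inhibition
  w_all <- if (is.null(weights)) rep(1, length(y))
  else if (identical(weights, "inverse_variance")) 1 / pmax(abs(y), 1)^2
  else as.numeric(weights)
  if (length(w_all) != length(y))
    stop_cts("invalid_input", "weights length differs from data")
  if (any(L < 0)) stop_cts("invalid_input", "negative concentrations")
  n_distinct <- length(unique(L))
  need <- if (n_species == 2) 7 else 5
  if (n_distinct < need)
    stop_cts("invalid_input", "need >= %d distinct L values for %d species, got %d",
             need, n_species, n_distinct)

  if (diff(range(y)) < 5) {   # flat data: flag, do not throw
    return(structure(list(model = NULL, rss = NA_real_, aic = NA_real_,
                          n = length(y), non_binding = TRUE,
                          bootstrap = NULL, compare = NULL),
                     class = "inhibition_fit"))
  }

  fit_one <- function(L, y, k, w = w_all) {
    # parameters: log Kd (k of them), logit fraction (k-1), log amplitude (opt)
    split_frac <- function(theta) {
      p <- min(max(stats::plogis(theta), 1e-9), 1 - 1e-9)
      c(p, 1 - p)
    }
    predict_p <- function(par) {
      Kd <- exp(par[seq_len(k)])
      fr <- if (k == 2) split_frac(par[k + 1]) else 1
      amp <- if (fit_amplitude) exp(par[length(par)]) else amplitude
      m <- tight_binding_model(E_total, Kd, fr, amp)
      predict_inhibition(m, L)
    }
    obj <- function(par) sum(w * (y - predict_p(par))^2)
    starts <- expand.grid(lk1 = log(c(1e-3, 1e-2, 1e-1, 1) * max(E_total, 1e-6)),
                          lk2 = if (k == 2) log(c(1e-2, 1) * max(E_total, 1e-6)) else 0)
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      par0 <- c(starts$lk1[i], if (k == 2) c(starts$lk2[i], 0))
      if (fit_amplitude) par0 <- c(par0, log(max(y)))
      if (length(par0) == 1) {
        o <- stats::optim(par0, obj, method = "Brent", lower = -40, upper = 12,
                          control = list(reltol = 1e-15))
      } else {
        o <- stats::optim(par0, obj, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-14))
        o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-14))
      }
      if (is.null(best) || o$value < best$value) best <- o
    }
    Kd <- exp(best$par[seq_len(k)])
    fr <- if (k == 2) split_frac(best$par[k + 1]) else 1
    amp <- if (fit_amplitude) exp(best$par[length(best$par)]) else amplitude
    ord <- order(Kd)
    mdl <- tight_binding_model(E_total, Kd[ord],
                               if (k == 2) fr[ord] else 1, amp)
    n <- length(y); p <- length(best$par)
    list(model = mdl, rss = best$value,
         aic = n * log(best$value / n) + 2 * (p + 1))
  }

  fit <- fit_one(L, y, n_species)
  compare <- NULL
  if (n_species == 2) {
    f1 <- fit_one(L, y, 1)
    compare <- c(aic_1species = f1$aic, aic_2species = fit$aic)
  }

  boot <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    kd_mat <- matrix(NA_real_, n_boot, n_species)
    for (b in seq_len(n_boot)) {
      idx <- sample(length(L), replace = TRUE)
      if (length(unique(L[idx])) < need) next
      fb <- try(fit_one(L[idx], y[idx], n_species, w_all[idx]), silent = TRUE)
      if (!inherits(fb, "try-error")) kd_mat[b, ] <- fb$model$Kd
    }
    al <- (1 - conf_level) / 2
    boot <- apply(kd_mat, 2, stats::quantile, probs = c(al, 1 - al), na.rm = TRUE)
    colnames(boot) <- paste0("Kd", seq_len(n_species))
  }

  structure(list(model = fit$model, rss = fit$rss, aic = fit$aic,
                 n = length(y), non_binding = FALSE,
                 bootstrap = boot, compare = compare, seed = seed),
            class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  if (x$non_binding) { cat("inhibition_fit: non-binding (flat data)\n"); return(invisible(x)) }
  cat(sprintf("inhibition_fit: %d species, RSS %.4g, AIC %.2f\n",
              length(x$model$Kd), x$rss, x$aic))
  for (i in seq_along(x$model$Kd))
    cat(sprintf("  species %d: Kd = %.4g uM (fraction %.3f)\n",
                i, x$model$Kd[i], x$model$fractions[i]))
  invisible(x)
}

#' Exact two-ligand single-site competition equilibrium
#'
#' AO and a competitor X compete for one site on E. Solved by bracketed
#' root finding on the free-enzyme concentration Ef in
#' Ef * (1 + AOf/K_AO + Xf/K_X) = E_total with
#' AOf = AO_total / (1 + Ef/K_AO), Xf = X_total / (1 + Ef/K_X).
#' At equilibrium bound-AO / bound-X = (AOf/K_AO) / (Xf/K_X).
#'
#' @param E_total,AO_total,X_total Totals, uM (E, AO > 0; X >= 0).
#' @param K_AO,K_X Dissociation constants, uM (> 0; `K_X = Inf` means no
#'   competitor binding).
#' @return List: `bound_AO`, `bound_X`, `free_E`, `free_AO`, `free_X` (uM).
#' @export
competition_equilibrium <- function(E_total, AO_total, X_total, K_AO, K_X) {
  if (E_total <= 0 || AO_total <= 0 || X_total < 0)
    stop_cts("invalid_input", "concentrations must be positive (X_total >= 0)")
  if (K_AO <= 0 || K_X <= 0) stop_cts("invalid_input", "K values must be > 0")
  xterm <- function(Ef) if (is.finite(K_X) && X_total > 0)
    (X_total / (1 + Ef / K_X)) / K_X else 0
  h <- function(Ef) Ef * (1 + (AO_total / (1 + Ef / K_AO)) / K_AO + xterm(Ef)) - E_total
  sol <- stats::uniroot(h, c(0, E_total), tol = .Machine$double.eps^0.9)
  Ef <- sol$root
  AOf <- AO_total / (1 + Ef / K_AO)
  Xf <- if (is.finite(K_X)) X_total / (1 + Ef / K_X) else X_total
  list(bound_AO = Ef * AOf / K_AO,
       bound_X = if (is.finite(K_X)) Ef * Xf / K_X else 0,
       free_E = Ef, free_AO = AOf, free_X = Xf)
}

#' Relative affinity from AO-displacement fluorescence
#'
#' The residual AO-specific fluorescence fraction after adding competitor X
#' in equal concentration, f = (F_mix - F_ref) / (F_AO - F_ref), estimates
#' the relative dissociation constant via
#' K_X / K_AO = (X_total / AO_total) * f / (1 - f);
#' f = 0.5 at equal totals means equal affinities. F_ref is the free-AO
#' reference (AO + saturating unlabeled ouabain).
#'
#' @param F_AO,F_mix,F_ref Fluorescence of AO alone, AO + X, and the free-AO
#'   reference (F_AO > F_ref required).
#' @param AO_total,X_total Totals, uM (defaults 0.2 and 0.2).
#' @param detection_f Residual fractions closer than this to 0 or 1 are
#'   reported as censored bounds rather than ratios (default 0.02).
#' @return List of class `relative_affinity`: `ratio` (K_X/K_AO), `f`
#'   (residual fraction), `censored` ("none", "upper" or "lower").
#' @export
relative_affinity_ratio <- function(F_AO, F_mix, F_ref,
                                    AO_total = 0.2, X_total = 0.2,
                                    detection_f = 0.02) {
  if (F_AO <= F_ref) stop_cts("invalid_input", "F_AO must exceed F_ref")
  f <- (F_mix - F_ref) / (F_AO - F_ref)
  if (f < 0 || f > 1) {
    warning(sprintf("residual fraction %.3f outside [0,1]; clamped", f))
    f <- min(max(f, 0), 1)
  }
  scale <- X_total / AO_total
  if (f >= 1 - detection_f) {
    ratio <- scale * (1 - detection_f) / detection_f
    censored <- "upper"            # no measurable displacement
  } else if (f <= detection_f) {
    ratio <- scale * detection_f / (1 - detection_f)
    censored <- "lower"            # complete displacement
  } else {
    ratio <- scale * f / (1 - f)
    censored <- "none"
  }
  structure(list(ratio = ratio, f = f, censored = censored),
            class = "relative_affinity")
}

#' @export
print.relative_affinity <- function(x, ...) {
  bound <- switch(x$censored, none = "", upper = " (lower bound; no displacement)",
                  lower = " (upper bound; complete displacement)")
  cat(sprintf("K_X/K_AO = %.4g (residual AO fraction f = %.3f)%s\n",
              x$ratio, x$f, bound))
  invisible(x)
}
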