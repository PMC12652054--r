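# One-dimensional Gaussian mixture fitting by EM with BIC model selection,
# used for lactone--ion distance distributions. BIC = p*ln(n) - 2*lnL with
# p = 3k - 1 free parameters for k components; the minimizing k wins, ties
# to the smaller k.

em_gaussian_1d <- function(x, k, init_mu, tol, max_iter, sd_floor) {
  n <- length(x)
  w <- rep(1 / k, k)
  mu <- init_mu
  sd <- rep(max(stats::sd(x), sd_floor), k)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    # E step
    comp <- vapply(seq_len(k), function(j) w[j] * stats::dnorm(x, mu[j], sd[j]),
                   numeric(n))
    comp <- matrix(comp, nrow = n)
    tot <- pmax(rowSums(comp), .Machine$double.xmin)
    r <- comp / tot
    ll <- sum(log(tot))
    # EM monotonicity is a structural property of the algorithm; guard it.
    if (ll < ll_old - 1e-8)
      stop_cts("numerical_error", "EM log-likelihood decreased (%.6g -> %.6g)",
               ll_old, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { ll_old <- ll; break }
    ll_old <- ll
    # M step
    nk <- pmax(colSums(r), 1e-12)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sd <- sqrt(colSums(r * (outer(x, mu, "-")^2)) / nk)
    sd <- pmax(sd, sd_floor)
  }
  list(w = w, mu = mu, sd = sd, loglik = ll_old)
}

#' Fit a 1-D Gaussian mixture with BIC component selection
#'
#' EM fits for k = 1..`k_max`, each the best of several quantile-anchored
#' restarts; the returned fit minimizes BIC = p*ln(n) - 2*lnL with
#' p = 3k - 1, ties resolved toward the smaller k. Component collapse is
#' prevented by a standard-deviation floor.
#'
#' @param values Numeric sample (e.g. distances, Angstrom); n >= 10.
#' @param k_max Maximum component count (default 4).
#' @param restarts EM restarts per k (default `cts_tolerances$em_restarts`).
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param sd_floor Minimum component standard deviation.
#' @param seed Seed for restart jitter (default 1).
#' @return Object of class `mixture_fit`: `components` data.frame
#'   (`weight`, `mean`, `sd`, sorted by mean), `k`, `loglik`, `bic`, `n`,
#'   and `bic_by_k`.
#' @export
mixture_fit_bic <- function(values, k_max = 4,
                            restarts = cts_tolerances$em_restarts,
                            tol = cts_tolerances$em_tol,
                            max_iter = cts_tolerances$em_max_iter,
                            sd_floor = cts_tolerances$sd_floor,
                            seed = 1) {
  x <- as.numeric(values)
  if (length(x) < 10)
    stop_cts("insufficient_data", "mixture fit needs n >= 10, got %d", length(x))
  if (!all(is.finite(x))) stop_cts("invalid_input", "non-finite values")
  n <- length(x)
  rng <- local({ set.seed(seed); function(n, s) stats::rnorm(n, 0, s) })
  spread <- max(stats::sd(x), sd_floor)

  best_by_k <- list()
  for (k in seq_len(k_max)) {
    best <- NULL
    for (r in seq_len(restarts)) {
      q <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
      init_mu <- q + if (r == 1) 0 else rng(k, spread / 2)
      fit <- em_gaussian_1d(x, k, init_mu, tol, max_iter, sd_floor)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    best_by_k[[k]] <- best
  }
  p <- 3 * seq_len(k_max) - 1
  bic <- p * log(n) - 2 * vapply(best_by_k, `[[`, 0, "loglik")
  k_sel <- which.min(bic)  # which.min takes the first (smallest k) on ties
  fit <- best_by_k[[k_sel]]
  ord <- order(fit$mu)
  structure(list(components = data.frame(weight = fit$w[ord], mean = fit$mu[ord],
                                         sd = fit$sd[ord]),
                 k = k_sel, loglik = fit$loglik, bic = bic[k_sel], n = n,
                 bic_by_k = bic),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: k = %d (BIC %.1f, n = %d)\n", x$k, x$bic, x$n))
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  component %d: weight %.3f, mean %.3f A, sd %.3f A\n",
                i, x$components$weight[i], x$components$mean[i], x$components$sd[i]))
  invisible(x)
}
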