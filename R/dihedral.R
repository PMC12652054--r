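# CHARMM-style cosine-series dihedral terms fitted to torsional energy
# scans (QM target minus unfitted-MM baseline, supplied as angle/energy
# tables). V(phi) = sum_n k_n * (1 + cos(n*phi - delta_n)) + offset,
# k_n >= 0, delta_n in {0, 180} degrees.

#' Construct a dihedral term set
#'
#' @param terms Named list: one data.frame per dihedral name with columns
#'   `n` (integer multiplicity >= 1), `k` (force constant >= 0, kcal/mol),
#'   `delta` (phase, 0 or 180 degrees).
#' @param offsets Named numeric vector of per-profile constant offsets
#'   (kcal/mol); may be empty.
#' @return Object of class `dihedral_term_set`.
#' @export
dihedral_term_set <- function(terms, offsets = numeric()) {
  for (nm in names(terms)) {
    tt <- terms[[nm]]
    if (!all(c("n", "k", "delta") %in% names(tt)))
      stop_cts("invalid_input", "terms for %s need columns n, k, delta", nm)
    if (any(tt$n < 1) || any(tt$n != round(tt$n)))
      stop_cts("invalid_input", "multiplicities must be positive integers (%s)", nm)
    if (any(tt$k < 0))
      stop_cts("invalid_input", "force constants must be >= 0 (%s)", nm)
    if (!all(tt$delta %in% c(0, 180)))
      stop_cts("invalid_input", "phases must be 0 or 180 degrees (%s)", nm)
  }
  structure(list(terms = terms, offsets = offsets), class = "dihedral_term_set")
}

#' Evaluate a cosine-series dihedral energy
#'
#' @param term_set A [dihedral_term_set].
#' @param dihedral Dihedral name (must be present in the term set).
#' @param angles Angles in degrees.
#' @param offset Constant offset, kcal/mol; default the term set's offset
#'   for `profile` (or 0).
#' @param profile Optional profile name whose stored offset to use.
#' @return Energies, kcal/mol.
#' @export
dihedral_energy <- function(term_set, dihedral, angles, offset = NULL,
                            profile = dihedral) {
  tt <- term_set$terms[[dihedral]]
  if (is.null(tt)) stop_cts("invalid_input", "no terms for dihedral '%s'", dihedral)
  if (is.null(offset))
    offset <- if (profile %in% names(term_set$offsets))
      term_set$offsets[[profile]] else 0
  phi <- angles * pi / 180
  v <- rep(offset, length(angles))
  for (i in seq_len(nrow(tt)))
    v <- v + tt$k[i] * (1 + cos(tt$n[i] * phi - tt$delta[i] * pi / 180))
  v
}

#' Construct a torsional energy profile
#'
#' @param dihedral Dihedral name (e.g. four atom labels joined by "-").
#' @param angles Grid angles, degrees, strictly increasing in (-180, 180].
#' @param energies Target energies, kcal/mol.
#' @param name Profile name; defaults to the dihedral name.
#' @return Object of class `dihedral_profile`.
#' @export
dihedral_profile <- function(dihedral, angles, energies, name = dihedral) {
  if (length(angles) == 0) stop_cts("invalid_input", "empty angle grid")
  if (length(angles) != length(energies))
    stop_cts("invalid_input", "angles and energies lengths differ")
  if (any(diff(angles) <= 0) || any(angles <= -180) || any(angles > 180))
    stop_cts("invalid_input", "angles must be strictly increasing within (-180, 180]")
  if (!all(is.finite(energies))) stop_cts("invalid_input", "non-finite energies")
  structure(list(dihedral = dihedral, angles = as.numeric(angles),
                 energies = as.numeric(energies), name = name),
            class = "dihedral_profile")
}

#' The standard scan grid: -180 to 180 degrees in 10-degree increments
#' @return Numeric vector of angles (degrees), -170 to 180 (36 points as a
#'   non-redundant circle) by default; set `closed = TRUE` for -180..180.
#' @param step Grid step, degrees (default 10).
#' @param closed Include both -180 and 180 (redundant on the circle)?
#' @export
scan_grid <- function(step = 10, closed = FALSE) {
  if (closed) seq(-180, 180, by = step) else seq(-180 + step, 180, by = step)
}

# Least squares with nonnegativity constraints on the leading columns
# (active-set; free columns always stay in the passive set).
nnls_mixed <- function(A, y, n_constrained) {
  p <- ncol(A)
  passive <- rep(TRUE, p)
  repeat {
    x <- rep(0, p)
    if (any(passive)) {
      fit <- stats::lm.fit(A[, passive, drop = FALSE], y)
      x[passive] <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    }
    neg <- which(passive & seq_len(p) <= n_constrained & x < -1e-12)
    if (!length(neg)) return(x)
    passive[neg[which.min(x[neg])]] <- FALSE
  }
}

#' Fit dihedral terms to torsional energy profiles
#'
#' Joint least-squares fit across profiles: profiles whose `dihedral` names
#' coincide share cosine terms; each profile gets its own free constant
#' offset. With the full phase set {0, 180} the model is an exact linear
#' reparameterization of the cosine basis `c_n cos(n phi)` plus a constant,
#' so the fit is solved in that basis and converted to nonnegative force
#' constants (`k = |c|`, phase by sign); with a restricted phase set an
#' active-set nonnegative least-squares solve is used. Terms with fitted
#' `k` below the pruning threshold are removed and the system refitted.
#'
#' @param profiles List of [dihedral_profile]s.
#' @param multiplicities Candidate multiplicities (default 1:6).
#' @param phases Allowed phases in degrees, subset of c(0, 180).
#' @param prune_k Pruning threshold on k, kcal/mol (default
#'   `cts_tolerances$prune_k`).
#' @return List of class `dihedral_fit`: `term_set` (a
#'   [dihedral_term_set] with per-profile offsets), `rmse` (kcal/mol,
#'   pooled over all grid points), `residuals` (per profile).
#' @export
fit_dihedral_terms <- function(profiles, multiplicities = 1:6,
                               phases = c(0, 180),
                               prune_k = cts_tolerances$prune_k) {
  if (!length(profiles)) stop_cts("invalid_input", "no profiles supplied")
  if (!all(phases %in% c(0, 180)))
    stop_cts("invalid_input", "phases must be a subset of {0, 180}")
  dihedrals <- unique(vapply(profiles, `[[`, "", "dihedral"))
  pnames <- vapply(profiles, `[[`, "", "name")
  if (anyDuplicated(pnames)) stop_cts("invalid_input", "duplicate profile names")
  full_phase <- all(c(0, 180) %in% phases)

  build <- function(active) {
    # active: data.frame(dihedral, n [, delta]) of candidate terms
    nrow_tot <- sum(vapply(profiles, function(p) length(p$angles), 0L))
    ncol_terms <- nrow(active)
    A <- matrix(0, nrow_tot, ncol_terms + length(profiles))
    y <- numeric(nrow_tot)
    r0 <- 0
    for (j in seq_along(profiles)) {
      p <- profiles[[j]]
      rows <- r0 + seq_along(p$angles)
      phi <- p$angles * pi / 180
      for (i in seq_len(ncol_terms)) {
        if (active$dihedral[i] != p$dihedral) next
        A[rows, i] <- if (full_phase) cos(active$n[i] * phi)
        else 1 + cos(active$n[i] * phi - active$delta[i] * pi / 180)
      }
      A[rows, ncol_terms + j] <- 1
      y[rows] <- p$energies
      if (length(p$angles) < 2 * sum(active$dihedral == p$dihedral))
        stop_cts("underdetermined",
                 "profile '%s' has %d points for %d candidate terms",
                 p$name, length(p$angles), sum(active$dihedral == p$dihedral))
      r0 <- r0 + length(p$angles)
    }
    list(A = A, y = y)
  }

  solve_terms <- function(active) {
    d <- build(active)
    if (full_phase) {
      fit <- stats::lm.fit(d$A, d$y)
      coef <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    } else {
      coef <- nnls_mixed(d$A, d$y, n_constrained = nrow(active))
    }
    resid <- d$y - d$A %*% coef
    list(coef = coef, rmse = sqrt(mean(resid^2)), resid = as.numeric(resid))
  }

  active <- if (full_phase)
    expand.grid(dihedral = dihedrals, n = multiplicities,
                delta = NA_real_, stringsAsFactors = FALSE)
  else
    expand.grid(dihedral = dihedrals, n = multiplicities, delta = phases,
                stringsAsFactors = FALSE)

  sol <- solve_terms(active)
  # prune small terms and refit once per removal round
  repeat {
    k_abs <- abs(sol$coef[seq_len(nrow(active))])
    drop <- which(k_abs < prune_k)
    if (!length(drop) || length(drop) == nrow(active) && all(k_abs < prune_k)) {
      if (length(drop)) { active <- active[-drop, , drop = FALSE]; sol <- solve_terms(active) }
      break
    }
    active <- active[-drop, , drop = FALSE]
    sol <- solve_terms(active)
  }

  nterm <- nrow(active)
  coef_terms <- sol$coef[seq_len(nterm)]
  offsets_raw <- sol$coef[nterm + seq_along(profiles)]
  terms <- list(); offsets <- numeric()
  for (dn in dihedrals) {
    rows <- which(active$dihedral == dn)
    if (!length(rows)) {
      terms[[dn]] <- data.frame(n = integer(), k = numeric(), delta = numeric())
      next
    }
    if (full_phase) {
      terms[[dn]] <- data.frame(n = as.integer(active$n[rows]),
                                k = abs(coef_terms[rows]),
                                delta = ifelse(coef_terms[rows] >= 0, 0, 180))
    } else {
      terms[[dn]] <- data.frame(n = as.integer(active$n[rows]),
                                k = pmax(coef_terms[rows], 0),
                                delta = active$delta[rows])
    }
  }
  # offsets: with the cosine basis the raw intercept is offset + sum(k);
  # with the explicit 1+cos basis it is the offset directly.
  r0 <- 0; resid <- list()
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    ksum <- if (full_phase) sum(terms[[p$dihedral]]$k) else 0
    offsets[[p$name]] <- offsets_raw[j] - ksum
    resid[[p$name]] <- sol$resid[r0 + seq_along(p$angles)]
    r0 <- r0 + length(p$angles)
  }
  structure(list(term_set = dihedral_term_set(terms, unlist(offsets)),
                 rmse = sol$rmse, residuals = resid),
            class = "dihedral_fit")
}

#' @export
print.dihedral_fit <- function(x, ...) {
  cat(sprintf("dihedral_fit: %d dihedral(s), pooled RMSE %.4g kcal/mol\n",
              length(x$term_set$terms), x$rmse))
  for (nm in names(x$term_set$terms)) {
    tt <- x$term_set$terms[[nm]]
    for (i in seq_len(nrow(tt)))
      cat(sprintf("  %s  n=%d  k=%.4f  delta=%d\n", nm, tt$n[i], tt$k[i], tt$delta[i]))
  }
  invisible(x)
}

#' Read torsional profiles from a TSV table
#'
#' Expected columns: `dihedral`, `angle` (deg), `energy` (kcal/mol), and
#' optionally `profile` (defaults to the dihedral name).
#'
#' @param path TSV file path.
#' @return List of [dihedral_profile]s.
#' @export
read_dihedral_profiles <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("dihedral", "angle", "energy") %in% names(d)))
    stop_cts("parse_error", "%s needs columns dihedral, angle, energy", path)
  if (is.null(d$profile)) d$profile <- d$dihedral
  lapply(split(d, d$profile), function(s)
    dihedral_profile(s$dihedral[1], s$angle, s$energy, name = s$profile[1]))
}

#' Serialize fitted terms as a CHARMM parameter stream DIHEDRALS block
#'
#' @param term_set A [dihedral_term_set] whose dihedral names are four atom
#'   types joined by "-".
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_charmm_dihedrals <- function(term_set, path) {
  lines <- c("read para card flex append", "", "DIHEDRALS")
  for (nm in names(term_set$terms)) {
    types <- strsplit(nm, "-", fixed = TRUE)[[1]]
    if (length(types) != 4) types <- c(types, rep("X", 4 - length(types)))
    tt <- term_set$terms[[nm]]
    for (i in seq_len(nrow(tt)))
      lines <- c(lines, sprintf("%-8s%-8s%-8s%-8s%10.4f%3d%9.2f",
                                types[1], types[2], types[3], types[4],
                                tt$k[i], tt$n[i], tt$delta[i]))
  }
  lines <- c(lines, "", "END", "RETURN")
  writeLines(lines, path)
  invisible(path)
}
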