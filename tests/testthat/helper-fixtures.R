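# Shared fixtures and independent oracles, built in code at test time.

# Independent mass-balance oracle for single-site tight binding:
# plain bisection on Lf + E*Lf/(Kd+Lf) = L, never the closed form.
bisect_bound_fraction <- function(E, L, Kd, iters = 200) {
  if (L == 0) return(0)
  g <- function(Lf) Lf + E * Lf / (Kd + Lf) - L
  lo <- 0; hi <- L
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  Lf <- (lo + hi) / 2
  Lf / (Kd + Lf)
}

# Independent dominant-eigenvector oracle: power iteration on the covariance.
power_iteration_axis <- function(points, iters = 1000) {
  centred <- sweep(points, 2, colMeans(points))
  C <- crossprod(centred) / nrow(points)
  v <- c(1, 1, 1) / sqrt(3)
  for (i in seq_len(iters)) v <- { w <- C %*% v; w / sqrt(sum(w^2)) }
  as.numeric(v)
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- svd(matrix(rnorm(9), 3))
  R <- q$u %*% t(q$v)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Minimal in-code structure: atoms on a grid, two chains.
tiny_structure <- function() {
  cts_structure(data.frame(
    atom = c("N", "CA", "C", "CA", "O"),
    resname = c("GLY", "GLY", "GLY", "ALA", "HOH"),
    resid = c(1L, 1L, 1L, 2L, 1L),
    chain = c("A", "A", "A", "A", "B"),
    element = c("N", "C", "C", "C", "O"),
    x = c(0, 1.5, 2.1, 4.0, 8.0), y = c(0, 0, 1.2, 1.2, 2.0),
    z = c(0, 0, 0, 0.5, 1.0)))
}

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.100   1.200   0.000  1.00  0.00           C",
    "END"), path)
  path
}

# Default small synthetic system shared across tests (cached per session).
small_system <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_system(trajectory_spec(n_frames = 600, seed = 11))
    cache
  }
})

small_ref <- function(sys = small_system())
  build_reference_frame(sys$structure, sys$helix_ranges, sys$site_atoms)
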