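# Independent oracles used to pin down expected values. These deliberately
# avoid the package's own computational paths.

# Concentric-sphere boundary-value oracle: solve the electrostatics of a
# two-interface shelled sphere in a uniform applied field directly (4x4
# complex linear system for the potential coefficients) and read the CM
# factor off the induced-dipole term.
oracle_shell_cm <- function(cell, med, f) {
  # dimensionless units (eps in multiples of eps0, radii in multiples of the
  # outer radius) keep the linear system well-conditioned
  eps <- function(mat) complex(real = mat$relative_permittivity,
                               imaginary = -mat$conductivity /
                                 (2 * pi * f * depspring::EPS0))
  e1 <- eps(cell$cytoplasm)            # core
  e2 <- eps(cell$membrane)             # shell
  e3 <- eps(med)                       # medium
  a <- 1 - cell$membrane_thickness / cell$outer_radius
  R <- 1
  # potentials (E0 = 1): phi1 = -A r cos; phi2 = (-B r + C/r^2) cos;
  # phi3 = (-r + D/r^2) cos. Unknowns (A, B, C, D).
  M <- matrix(0 + 0i, 4, 4)
  rhs <- complex(4)
  M[1, ] <- c(-a, a, -1 / a^2, 0)                 # phi continuous at a
  M[2, ] <- c(-e1, e2, 2 * e2 / a^3, 0)           # eps dphi/dr at a
  M[3, ] <- c(0, -R, 1 / R^2, -1 / R^2); rhs[3] <- -R
  M[4, ] <- c(0, -e2, -2 * e2 / R^3, 2 * e3 / R^3); rhs[4] <- -e3
  sol <- solve(M, rhs)
  sol[4] / R^3                                    # CM = D / (E0 R^3)
}

# Equivalent homogeneous permittivity implied by the oracle CM.
oracle_equivalent_permittivity <- function(cell, med, f) {
  cm <- oracle_shell_cm(cell, med, f)
  e3 <- complex(real = depspring::EPS0 * med$relative_permittivity,
                imaginary = -med$conductivity / (2 * pi * f))
  e3 * (1 + 2 * cm) / (1 - cm)
}
# Brute-force pairwise remaining-set oracle (double loop, no matrix tricks).
oracle_remaining <- function(ref, re_cm, freq_idx, rel_tol, cm_min) {
  out <- integer(0)
  for (i in seq_len(nrow(re_cm))) {
    if (i == ref) next
    stays <- TRUE
    for (j in freq_idx) {
      ref_cm <- re_cm[ref, j]
      tol <- abs(ref_cm) * rel_tol
      both_measurable <- (ref_cm <= -cm_min) && (re_cm[i, j] <= -cm_min)
      if (both_measurable && abs(re_cm[i, j] - ref_cm) > tol) {
        stays <- FALSE
        break
      }
    }
    if (stays) out <- c(out, i)
  }
  out
}

# Exhaustive 0-1-loss linear oracle: try every grid direction and every
# threshold candidate by direct counting.
oracle_best_linear_accuracy <- function(x, y01, res_deg = 1) {
  x <- as.matrix(x)
  k <- ncol(x)
  dirs <- if (k == 1) matrix(1, 1, 1) else {
    ang <- seq(0, 180 - res_deg, by = res_deg) * pi / 180
    cbind(cos(ang), sin(ang))
  }
  best <- 0
  for (i in seq_len(nrow(dirs))) {
    z <- drop(x %*% dirs[i, ])
    zs <- sort(z)
    thr <- c(zs[1] - 1, (zs[-1] + zs[-length(zs)]) / 2, zs[length(zs)] + 1)
    for (t in thr) {
      acc <- mean((z > t) == (y01 == 1))
      best <- max(best, acc, 1 - acc)
    }
  }
  best
}

# Default-device constants used in several numeric fixtures.
default_fixture_device <- function() depspring::device_state()

ranges_degenerate <- function() {
  depspring::parameter_ranges(
    cytoplasm_conductivity = c(0.7, 0.7),
    cytoplasm_permittivity = c(50, 50),
    membrane_conductivity = c(5e-7, 5e-7),
    membrane_permittivity = c(11, 11),
    radius = c(5e-6, 5e-6))
}
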