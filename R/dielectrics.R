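# Complex permittivities and single-shell Clausius-Mossotti factors.
#
# Time convention is e^{+j w t}, so the complex permittivity of a lossy
# dielectric is eps* = eps - j sigma / w.  Re[CM] is independent of this
# convention; Im[CM] changes sign under e^{-j w t}.

#' Vacuum permittivity (F/m)
#'
#' @export
EPS0 <- 8.8541878128e-12

#' Dielectric material
#'
#' A homogeneous lossy dielectric described by its relative permittivity
#' (dimensionless multiple of the vacuum permittivity) and conductivity.
#'
#' @param relative_permittivity Relative permittivity (> 0, dimensionless).
#' @param conductivity Conductivity in S/m (>= 0).
#' @return An object of class `dielectric_material`.
#' @examples
#' cytoplasm <- dielectric_material(60, 0.5)
#' @export
dielectric_material <- function(relative_permittivity, conductivity) {
  stopifnot(is.numeric(relative_permittivity), is.numeric(conductivity),
            length(relative_permittivity) == 1L, length(conductivity) == 1L)
  if (!is.finite(relative_permittivity) || relative_permittivity <= 0)
    stop("relative_permittivity must be a positive finite number", call. = FALSE)
  if (!is.finite(conductivity) || conductivity < 0)
    stop("conductivity must be a finite non-negative number", call. = FALSE)
  structure(list(relative_permittivity = relative_permittivity,
                 conductivity = conductivity),
            class = "dielectric_material")
}

#' Suspending medium
#'
#' The aqueous suspending medium. Defaults to the reference conditions used
#' throughout: 1.5 S/m, 78.5 eps0.
#'
#' @param relative_permittivity Relative permittivity (default 78.5).
#' @param conductivity Conductivity in S/m (default 1.5; must be > 0).
#' @return A `dielectric_material` that also carries class `medium`.
#' @export
medium <- function(relative_permittivity = 78.5, conductivity = 1.5) {
  if (conductivity <= 0)
    stop("medium conductivity must be > 0", call. = FALSE)
  m <- dielectric_material(relative_permittivity, conductivity)
  class(m) <- c("medium", class(m))
  m
}

#' Single-shell cell model
#'
#' A mammalian cell idealized as a conducting cytoplasm sphere wrapped in a
#' thin, poorly conducting membrane shell of fixed thickness (default 10 nm,
#' the phospholipid bilayer).
#'
#' @param outer_radius Outer (membrane) radius in m.
#' @param cytoplasm,membrane `dielectric_material` objects.
#' @param membrane_thickness Shell thickness in m (default 10e-9).
#' @return An object of class `shelled_cell`.
#' @export
shelled_cell <- function(outer_radius, cytoplasm, membrane,
                         membrane_thickness = 10e-9) {
  stopifnot(inherits(cytoplasm, "dielectric_material"),
            inherits(membrane, "dielectric_material"))
  if (!is.finite(membrane_thickness) || membrane_thickness <= 0)
    stop("membrane_thickness must be > 0", call. = FALSE)
  if (!is.finite(outer_radius) || outer_radius <= membrane_thickness)
    stop("outer_radius must exceed membrane_thickness", call. = FALSE)
  structure(list(outer_radius = outer_radius,
                 membrane_thickness = membrane_thickness,
                 cytoplasm = cytoplasm, membrane = membrane),
            class = "shelled_cell")
}

check_frequency <- function(f) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f <= 0))
    stop("frequency must be positive and finite", call. = FALSE)
  invisible(f)
}

#' Complex permittivity of a lossy dielectric
#'
#' eps*(f) = eps0 * eps_r - j sigma / (2 pi f), in F/m.
#'
#' @param material A `dielectric_material`.
#' @param f Frequency in Hz (vectorized, all > 0).
#' @return Complex permittivity in F/m (same length as `f`).
#' @export
complex_permittivity <- function(material, f) {
  stopifnot(inherits(material, "dielectric_material"))
  check_frequency(f)
  complex(real = EPS0 * material$relative_permittivity,
          imaginary = -material$conductivity / (2 * pi * f))
}

#' Equivalent homogeneous permittivity of a shelled sphere
#'
#' Reduces the concentric-sphere (cytoplasm + membrane shell) particle to the
#' equivalent homogeneous sphere using the standard single-shell formula
#' with radius ratio g = R / (R - d):
#' eps_eq = eps_mem * (g^3 + 2 K) / (g^3 - K),
#' K = (eps_cyt - eps_mem) / (eps_cyt + 2 eps_mem),
#' all permittivities complex.
#'
#' @param cell A `shelled_cell`.
#' @param f Frequency in Hz (vectorized).
#' @return Complex equivalent permittivity in F/m.
#' @export
equivalent_cell_permittivity <- function(cell, f) {
  stopifnot(inherits(cell, "shelled_cell"))
  check_frequency(f)
  ec <- complex_permittivity(cell$cytoplasm, f)
  em <- complex_permittivity(cell$membrane, f)
  g3 <- (cell$outer_radius / (cell$outer_radius - cell$membrane_thickness))^3
  K <- (ec - em) / (ec + 2 * em)
  em * (g3 + 2 * K) / (g3 - K)
}

#' Clausius-Mossotti factor
#'
#' CM(f) = (eps*_p - eps*_m) / (eps*_p + 2 eps*_m) for a (possibly shelled)
#' spherical particle in a medium. Re[CM] lies in [-0.5, 1]; negative values
#' produce negative DEP (repulsion from high-field regions).
#'
#' @param particle A `shelled_cell`, a `dielectric_material` (homogeneous
#'   sphere), or a complex particle permittivity (F/m) already evaluated at
#'   `f`.
#' @param med The suspending [medium()].
#' @param f Frequency in Hz (vectorized).
#' @return Complex CM factor (same length as `f`).
#' @export
cm_factor <- function(particle, med, f) {
  stopifnot(inherits(med, "dielectric_material"))
  check_frequency(f)
  ep <- if (inherits(particle, "shelled_cell")) {
    equivalent_cell_permittivity(particle, f)
  } else if (inherits(particle, "dielectric_material")) {
    complex_permittivity(particle, f)
  } else if (is.complex(particle) || is.numeric(particle)) {
    particle
  } else stop("unsupported particle specification", call. = FALSE)
  em <- complex_permittivity(med, f)
  (ep - em) / (ep + 2 * em)
}

#' Logarithmic frequency grid
#'
#' @param fmin,fmax Range endpoints in Hz (0 < fmin < fmax).
#' @param n Number of points (default 100).
#' @return Strictly increasing numeric vector of frequencies in Hz.
#' @export
log_frequency_grid <- function(fmin, fmax, n = 100) {
  check_frequency(c(fmin, fmax))
  if (fmin >= fmax) stop("fmin must be < fmax", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (n == 1) return(fmin)
  exp(seq(log(fmin), log(fmax), length.out = n))
}

check_grid <- function(grid) {
  check_frequency(grid)
  if (is.unsorted(grid, strictly = TRUE))
    stop("frequency grid must be strictly increasing", call. = FALSE)
  invisible(grid)
}

#' CM spectrum of one particle
#'
#' @param particle A `shelled_cell` or `dielectric_material`.
#' @param med The suspending [medium()].
#' @param grid Strictly increasing frequencies in Hz
#'   (see [log_frequency_grid()]).
#' @return A data frame of class `cm_spectrum` with columns `frequency_hz`,
#'   `re_cm`, `im_cm`.
#' @export
cm_spectrum <- function(particle, med, grid) {
  check_grid(grid)
  cm <- cm_factor(particle, med, grid)
  structure(data.frame(frequency_hz = grid, re_cm = Re(cm), im_cm = Im(cm)),
            class = c("cm_spectrum", "data.frame"))
}

#' CM factor matrix for a cell population
#'
#' Vectorized evaluation of the single-shell CM factor for every cell of a
#' sampled population (rows) on a frequency grid (columns).
#'
#' @param population A `cell_population` (see [sample_population()]) or a
#'   data frame with columns `cytoplasm_conductivity`,
#'   `cytoplasm_permittivity`, `membrane_conductivity`,
#'   `membrane_permittivity`, `radius` and optionally `membrane_thickness`.
#' @param med The suspending [medium()].
#' @param grid Frequencies in Hz (any positive vector; need not be ordered).
#' @return Complex matrix, `nrow(population)` x `length(grid)`.
#' @export
cm_spectrum_matrix <- function(population, med, grid) {
  stopifnot(is.data.frame(population), inherits(med, "dielectric_material"))
  check_frequency(grid)
  n <- nrow(population)
  m <- length(grid)
  d <- population$membrane_thickness
  if (is.null(d)) d <- rep(10e-9, n)
  w_inv <- 1 / (2 * pi * grid)
  ec <- matrix(complex(real = EPS0 * population$cytoplasm_permittivity), n, m) -
    1i * (population$cytoplasm_conductivity %o% w_inv)
  em <- matrix(complex(real = EPS0 * population$membrane_permittivity), n, m) -
    1i * (population$membrane_conductivity %o% w_inv)
  emed <- matrix(complex(real = EPS0 * med$relative_permittivity) -
                   1i * med$conductivity * w_inv, n, m, byrow = TRUE)
  g3 <- (population$radius / (population$radius - d))^3
  K <- (ec - em) / (ec + 2 * em)
  ep <- em * (g3 + 2 * K) / (g3 - K)
  (ep - emed) / (ep + 2 * emed)
}

#' Count dispersions of a Re[CM] spectrum
#'
#' A dispersion is a frequency band over which Re[CM] transitions between
#' plateaus (interfacial polarization of one compartment). Counted as the
#' number of local maxima of |d Re[CM] / d log f| whose height exceeds
#' `min_slope`.
#'
#' @param spectrum A `cm_spectrum` data frame.
#' @param min_slope Minimum |d Re[CM]/d log10 f| for a transition to count
#'   (default 0.02 per decade).
#' @return Integer dispersion count.
#' @export
count_dispersions <- function(spectrum, min_slope = 0.02) {
  stopifnot(is.data.frame(spectrum), nrow(spectrum) >= 3)
  s <- diff(spectrum$re_cm) / diff(log10(spectrum$frequency_hz))
  a <- abs(s)
  peaks <- which(diff(sign(diff(a))) < 0) + 1L
  sum(a[peaks] > min_slope)
}

#' Write a CM spectrum to CSV
#'
#' Columns `frequency_hz`, `re_cm`, `im_cm`.
#'
#' @param spectrum A `cm_spectrum`.
#' @param path Output file path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum)[c("frequency_hz", "re_cm", "im_cm")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.cm_spectrum <- function(x, ...) {
  graphics::plot(x$frequency_hz, x$re_cm, type = "l", log = "x",
                 xlab = "frequency (Hz)", ylab = "Re[CM]", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
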