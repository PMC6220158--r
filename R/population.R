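# Monte Carlo sampling of single-shell cell populations.

#' Parameter ranges for cell sampling
#'
#' Uniform sampling ranges for the five free single-shell parameters, plus
#' the fixed membrane thickness and medium. Defaults are the literature-derived
#' reference ranges used throughout the simulations: cytoplasm conductivity
#' 0.2-1.2 S/m, cytoplasm permittivity 20-80 eps0, membrane conductivity
#' 10 nS/m - 1 uS/m, membrane permittivity 2-20 eps0, outer radius 2-8 um,
#' membrane thickness 10 nm, medium 1.5 S/m and 78.5 eps0.
#'
#' @param cytoplasm_conductivity,cytoplasm_permittivity,membrane_conductivity,membrane_permittivity,radius
#'   Length-2 numeric `c(low, high)` bounds (low <= high).
#' @param membrane_thickness Fixed shell thickness in m.
#' @param med Fixed suspending [medium()].
#' @param log_membrane_conductivity If `TRUE`, sample membrane conductivity
#'   log-uniformly over its range (it spans two decades); the default `FALSE`
#'   samples all parameters uniformly on a linear scale.
#' @return An object of class `parameter_ranges`.
#' @export
parameter_ranges <- function(cytoplasm_conductivity = c(0.2, 1.2),
                             cytoplasm_permittivity = c(20, 80),
                             membrane_conductivity = c(10e-9, 1e-6),
                             membrane_permittivity = c(2, 20),
                             radius = c(2e-6, 8e-6),
                             membrane_thickness = 10e-9,
                             med = medium(),
                             log_membrane_conductivity = FALSE) {
  rng <- list(cytoplasm_conductivity = cytoplasm_conductivity,
              cytoplasm_permittivity = cytoplasm_permittivity,
              membrane_conductivity = membrane_conductivity,
              membrane_permittivity = membrane_permittivity,
              radius = radius)
  for (nm in names(rng)) {
    b <- rng[[nm]]
    if (!is.numeric(b) || length(b) != 2L || any(!is.finite(b)) || b[1] > b[2])
      stop("invalid range for ", nm, ": need finite c(low, high), low <= high",
           call. = FALSE)
  }
  if (rng$radius[1] <= membrane_thickness)
    stop("radius range must exceed the membrane thickness", call. = FALSE)
  stopifnot(inherits(med, "dielectric_material"))
  structure(c(rng, list(membrane_thickness = membrane_thickness, medium = med,
                        log_membrane_conductivity =
                          isTRUE(log_membrane_conductivity))),
            class = "parameter_ranges")
}

#' Sample a cell population
#'
#' Draws `n` single-shell cells with each parameter independently uniform on
#' its range (marginal uniformity on a linear scale; membrane conductivity
#' optionally log-uniform, see [parameter_ranges()]). Reproducible for a
#' given seed: one RNG stream per population.
#'
#' @param n Number of cells (>= 1).
#' @param ranges A [parameter_ranges()] object.
#' @param seed Integer seed recorded with the population.
#' @return A data frame of class `cell_population` with one row per cell and
#'   columns `cytoplasm_conductivity`, `cytoplasm_permittivity`,
#'   `membrane_conductivity`, `membrane_permittivity`, `radius`,
#'   `membrane_thickness`; attributes `seed` and `ranges`.
#' @export
sample_population <- function(n, ranges = parameter_ranges(), seed = 1L) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  stopifnot(inherits(ranges, "parameter_ranges"))
  n <- as.integer(n)
  draw <- function(b) stats::runif(n, b[1], b[2])
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(as.integer(seed))
  pop <- data.frame(
    cytoplasm_conductivity = draw(ranges$cytoplasm_conductivity),
    cytoplasm_permittivity = draw(ranges$cytoplasm_permittivity),
    membrane_conductivity = if (ranges$log_membrane_conductivity)
      exp(stats::runif(n, log(ranges$membrane_conductivity[1]),
                       log(ranges$membrane_conductivity[2])))
    else draw(ranges$membrane_conductivity),
    membrane_permittivity = draw(ranges$membrane_permittivity),
    radius = draw(ranges$radius),
    membrane_thickness = ranges$membrane_thickness)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  structure(pop, seed = as.integer(seed), ranges = ranges,
            class = c("cell_population", "data.frame"))
}

#' Extract one cell of a population as a `shelled_cell`
#'
#' @param population A `cell_population`.
#' @param i Row index.
#' @return A [shelled_cell()].
#' @export
as_shelled_cell <- function(population, i) {
  stopifnot(i >= 1, i <= nrow(population))
  r <- population[i, ]
  shelled_cell(r$radius,
               dielectric_material(r$cytoplasm_permittivity,
                                   r$cytoplasm_conductivity),
               dielectric_material(r$membrane_permittivity,
                                   r$membrane_conductivity),
               r$membrane_thickness)
}

#' The midpoint cell of a set of ranges
#'
#' Convenience: the fully determined cell at the center of every sampled range.
#'
#' @param ranges A [parameter_ranges()] object.
#' @return A [shelled_cell()].
#' @export
midpoint_cell <- function(ranges = parameter_ranges()) {
  mid <- function(b) mean(b)
  shelled_cell(mid(ranges$radius),
               dielectric_material(mid(ranges$cytoplasm_permittivity),
                                   mid(ranges$cytoplasm_conductivity)),
               dielectric_material(mid(ranges$membrane_permittivity),
                                   mid(ranges$membrane_conductivity)),
               ranges$membrane_thickness)
}

#' Write a population to CSV
#'
#' One row per cell; the generation seed is recorded in a `# seed:` header
#' comment line.
#'
#' @param population A `cell_population`.
#' @param path Output file path.
#' @export
write_population_csv <- function(population, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", attr(population, "seed") %||% NA_integer_),
             con)
  utils::write.csv(as.data.frame(population), con, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
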