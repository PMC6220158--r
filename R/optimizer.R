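# Greedy selection of optimal discriminating measurement frequencies.
#
# For a randomly chosen reference cell, a frequency discriminates a
# neighboring cell when BOTH cells attain a measurable balance position
# there (Re[CM] <= -min_measurable_cm, i.e. nDEP strong enough that the
# spring argument u <= 1) AND their Re[CM] differ by more than the
# position-uncertainty-derived tolerance. Cells not discriminated at any
# chosen frequency "remain". The greedy search adds, one at a time, the
# grid frequency that minimizes the number of remaining cells.

#' Balance-position-derived CM tolerance model
#'
#' Under the exponential force decay q_R(delta) = exp(-delta/lambda), the
#' balance position is delta = lambda log|Re CM| + const, so a position
#' uncertainty Delta-delta maps to a relative CM tolerance
#' Delta-delta / lambda:
#' tol(CM_ref) = |CM_ref| * Delta-delta / lambda. The tolerance therefore
#' vanishes as Re[CM] approaches 0, where the balance position is most
#' sensitive to CM. Frequencies at which a cell's Re[CM] is above
#' `-min_measurable_cm` give no measurable balance position (the spring
#' argument exceeds 1 at the reference operating point) and cannot
#' discriminate that cell.
#'
#' @param position_uncertainty Balance-position uncertainty Delta-delta in m
#'   (default 0.5 um, about twice the standard deviation of measured
#'   balance-position noise).
#' @param decay_length Force decay length lambda in m (default
#'   [DEFAULT_DECAY_LENGTH], shared with [device_state()]).
#' @param min_measurable_cm Weakest |Re CM| that still yields an on-scale
#'   balance position (default 0.05, the u = 1 point of the default device
#'   for a mid-size cell). Set to 0 to disable the measurability window.
#' @param constant_tolerance If non-`NULL`, use this constant CM tolerance
#'   instead of the position-mapped proportional rule.
#' @return An object of class `tolerance_model`.
#' @export
tolerance_model <- function(position_uncertainty = 0.5e-6,
                            decay_length = DEFAULT_DECAY_LENGTH,
                            min_measurable_cm = 0.05,
                            constant_tolerance = NULL) {
  if (!is.finite(position_uncertainty) || position_uncertainty < 0)
    stop("position_uncertainty must be >= 0", call. = FALSE)
  if (!is.finite(decay_length) || decay_length <= 0)
    stop("decay_length must be > 0", call. = FALSE)
  if (!is.finite(min_measurable_cm) || min_measurable_cm < 0)
    stop("min_measurable_cm must be >= 0", call. = FALSE)
  structure(list(position_uncertainty = position_uncertainty,
                 decay_length = decay_length,
                 min_measurable_cm = min_measurable_cm,
                 constant_tolerance = constant_tolerance),
            class = "tolerance_model")
}

#' CM tolerance around a reference value
#'
#' tol = |re_cm_ref| * Delta-delta / lambda (or the model's constant
#' tolerance if set). Zero at re_cm_ref = 0: the balance position is
#' maximally sensitive there.
#'
#' @param re_cm_ref Reference Re[CM] (vectorized).
#' @param model A [tolerance_model()].
#' @return Non-negative tolerance(s) on Re[CM].
#' @export
cm_tolerance <- function(re_cm_ref, model = tolerance_model()) {
  stopifnot(inherits(model, "tolerance_model"))
  if (!is.null(model$constant_tolerance))
    return(rep_len(model$constant_tolerance, length(re_cm_ref)))
  abs(re_cm_ref) * model$position_uncertainty / model$decay_length
}

# n x m logical: TRUE where cell i is NOT discriminated from the reference
# at frequency j.
indistinct_matrix <- function(re_cm, ref_index, model) {
  n <- nrow(re_cm)
  tol <- cm_tolerance(re_cm[ref_index, ], model)
  close <- abs(sweep(re_cm, 2, re_cm[ref_index, ])) <= rep(tol, each = n)
  if (model$min_measurable_cm > 0) {
    meas <- re_cm <= -model$min_measurable_cm
    close <- close | !meas | rep(!meas[ref_index, ], each = n)
  }
  close[ref_index, ] <- FALSE  # the reference is never its own neighbor
  close
}

resolve_freq_indices <- function(chosen_freqs, grid) {
  if (length(chosen_freqs) == 0) return(integer(0))
  idx <- match(chosen_freqs, grid)
  if (anyNA(idx)) {
    # tolerate floating-point representations of grid members
    idx <- vapply(chosen_freqs, function(f) {
      j <- which.min(abs(grid - f))
      if (abs(grid[j] - f) > 1e-9 * f)
        stop("chosen frequency ", f, " is not a member of the candidate grid",
             call. = FALSE)
      j
    }, integer(1))
  }
  idx
}

#' Cells remaining within tolerance of a reference
#'
#' Indices of the cells not discriminated from the reference at EVERY one of
#' the chosen frequencies. With no chosen frequencies, all non-reference
#' cells remain.
#'
#' @param ref_index Row index of the reference cell in `re_cm`.
#' @param re_cm Numeric matrix of Re[CM], cells x grid frequencies (e.g.
#'   `Re(cm_spectrum_matrix(...))`).
#' @param grid Candidate frequency grid (columns of `re_cm`), Hz.
#' @param chosen_freqs Frequencies (members of `grid`) already measured.
#' @param model A [tolerance_model()].
#' @return Integer vector of remaining cell indices.
#' @export
remaining_set <- function(ref_index, re_cm, grid, chosen_freqs = numeric(0),
                          model = tolerance_model()) {
  stopifnot(is.matrix(re_cm), length(grid) == ncol(re_cm))
  if (ref_index < 1 || ref_index > nrow(re_cm))
    stop("ref_index out of range", call. = FALSE)
  idx <- resolve_freq_indices(chosen_freqs, grid)
  keep <- rep(TRUE, nrow(re_cm))
  keep[ref_index] <- FALSE
  if (length(idx)) {
    ind <- indistinct_matrix(re_cm, ref_index, model)
    for (j in idx) keep <- keep & ind[, j]
  }
  which(keep)
}

#' Greedy selection of discriminating frequencies
#'
#' At each step, appends the candidate grid frequency minimizing the number
#' of remaining cells given all previously chosen frequencies (ties broken
#' toward the lowest frequency). Stops at `max_steps`, or as soon as the
#' best achievable count no longer improves on the current one (when
#' `stop_when_no_improvement`).
#'
#' @inheritParams remaining_set
#' @param max_steps Maximum number of frequencies to select (default 5).
#' @param stop_when_no_improvement Stop early when no candidate reduces the
#'   remaining count (default `TRUE`).
#' @return An object of class `selection_run`: list with `ref_index`,
#'   `chosen_freqs` (Hz), `chosen_idx`, `remaining_counts` (after each
#'   selection), `n_cells`.
#' @export
greedy_select <- function(ref_index, re_cm, grid, model = tolerance_model(),
                          max_steps = 5, stop_when_no_improvement = TRUE) {
  stopifnot(is.matrix(re_cm), length(grid) == ncol(re_cm))
  if (length(grid) == 0) stop("empty candidate grid", call. = FALSE)
  if (max_steps < 1) stop("max_steps must be >= 1", call. = FALSE)
  if (ref_index < 1 || ref_index > nrow(re_cm))
    stop("ref_index out of range", call. = FALSE)
  ind <- indistinct_matrix(re_cm, ref_index, model)
  mask <- rep(TRUE, nrow(re_cm))
  mask[ref_index] <- FALSE
  current <- sum(mask)
  chosen <- integer(0)
  counts <- integer(0)
  for (s in seq_len(max_steps)) {
    cnt <- colSums(ind & mask)
    j <- which.min(cnt)        # first minimum = lowest frequency on ties
    # a first frequency is always chosen; afterwards stop on zero improvement
    if (s > 1 && stop_when_no_improvement && cnt[j] >= current) break
    chosen <- c(chosen, j)
    counts <- c(counts, as.integer(cnt[j]))
    current <- cnt[j]
    mask <- mask & ind[, j]
  }
  structure(list(ref_index = ref_index, chosen_freqs = grid[chosen],
                 chosen_idx = chosen, remaining_counts = counts,
                 n_cells = nrow(re_cm)),
            class = "selection_run")
}

#' Monte Carlo frequency-selection study
#'
#' Repeats the greedy frequency selection over independently sampled cell
#' populations, each run with its own random reference cell. Fractions are
#' reported over the n - 1 non-reference cells. Each run always selects
#' `max_steps` frequencies so per-step summaries are complete; remaining
#' counts are non-increasing by construction.
#'
#' @param n_runs Number of independent runs (default 100).
#' @param n_cells Cells per population (default 1000).
#' @param ranges [parameter_ranges()] for the population sampler.
#' @param grid Candidate frequency grid in Hz (default 100 log-spaced points
#'   over 10 kHz - 1 GHz).
#' @param model A [tolerance_model()].
#' @param max_steps Frequencies selected per run (default 4).
#' @param seed Master seed; per-run population seeds and reference choices
#'   derive from it.
#' @return An object of class `mc_summary`: list with per-step
#'   `mean_fraction` / `median_fraction`, the runs x steps `fraction_matrix`
#'   and `chosen` frequency matrix (Hz), `first_freq_table`,
#'   `modal_combination` (most frequent full chosen sequence),
#'   `mean_sweep` (steps x grid matrix: mean remaining fraction if the
#'   step's selection were forced to each candidate, earlier selections held
#'   at their greedy choices), plus the configuration.
#' @export
run_monte_carlo <- function(n_runs = 100, n_cells = 1000,
                            ranges = parameter_ranges(),
                            grid = log_frequency_grid(1e4, 1e9, 100),
                            model = tolerance_model(),
                            max_steps = 4, seed = 1L) {
  stopifnot(n_runs >= 1, n_cells >= 2)
  check_grid(grid)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(as.integer(seed))
  run_seeds <- sample.int(2^31 - 2, n_runs)
  ref_draw <- stats::runif(n_runs)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  m <- length(grid)
  frac <- matrix(NA_real_, n_runs, max_steps)
  chosen <- matrix(NA_real_, n_runs, max_steps)
  sweep_sum <- matrix(0, max_steps, m)
  for (r in seq_len(n_runs)) {
    pop <- sample_population(n_cells, ranges, seed = run_seeds[r])
    ref <- 1L + as.integer(floor(ref_draw[r] * n_cells))
    re_cm <- Re(cm_spectrum_matrix(pop, ranges$medium, grid))
    ind <- indistinct_matrix(re_cm, ref, model)
    mask <- rep(TRUE, n_cells)
    mask[ref] <- FALSE
    for (s in seq_len(max_steps)) {
      cnt <- colSums(ind & mask)
      sweep_sum[s, ] <- sweep_sum[s, ] + cnt / (n_cells - 1)
      j <- which.min(cnt)
      chosen[r, s] <- grid[j]
      frac[r, s] <- cnt[j] / (n_cells - 1)
      mask <- mask & ind[, j]
    }
  }
  combos <- apply(chosen, 1, function(z) paste(signif(z, 6), collapse = ","))
  tab <- sort(table(combos), decreasing = TRUE)
  modal <- as.numeric(strsplit(names(tab)[1], ",")[[1]])
  structure(list(
    mean_fraction = colMeans(frac),
    median_fraction = apply(frac, 2, stats::median),
    fraction_matrix = frac,
    chosen = chosen,
    first_freq_table = sort(table(chosen[, 1]), decreasing = TRUE),
    modal_combination = modal,
    mean_sweep = sweep_sum / n_runs,
    grid = grid, n_runs = n_runs, n_cells = n_cells, max_steps = max_steps,
    seed = as.integer(seed), run_seeds = run_seeds, model = model,
    ranges = ranges),
    class = "mc_summary")
}

#' Modal frequency selected at a given step
#'
#' @param summary An `mc_summary`.
#' @param step Selection step (1 = first frequency).
#' @return The most frequent frequency chosen at that step across runs, Hz.
#' @export
modal_frequency <- function(summary, step = 1) {
  stopifnot(inherits(summary, "mc_summary"), step >= 1,
            step <= summary$max_steps)
  tab <- sort(table(summary$chosen[, step]), decreasing = TRUE)
  as.numeric(names(tab)[1])
}

#' Sweep spread of the mean remaining fraction at a step
#'
#' Max minus min, over candidate frequencies, of the mean (across runs)
#' remaining fraction when the given step's selection is forced to each
#' candidate with all earlier selections held at their per-run greedy
#' choices. Measures how sensitive the step is to the exact frequency.
#'
#' @inheritParams modal_frequency
#' @return Dimensionless spread (fraction).
#' @export
sweep_spread <- function(summary, step) {
  stopifnot(inherits(summary, "mc_summary"), step >= 1,
            step <= summary$max_steps)
  curve <- summary$mean_sweep[step, ]
  max(curve) - min(curve)
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("Monte Carlo frequency-selection study: %d runs x %d cells\n",
              x$n_runs, x$n_cells))
  cat(sprintf("grid: %d points, %.3g Hz - %.3g Hz\n", length(x$grid),
              min(x$grid), max(x$grid)))
  cat("mean fraction remaining by step:",
      paste(sprintf("%.3f%%", 100 * x$mean_fraction), collapse = ", "), "\n")
  cat("modal combination (MHz):",
      paste(sprintf("%.3g", x$modal_combination / 1e6), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.mc_summary <- function(x, ...) {
  graphics::matplot(x$grid, t(x$mean_sweep), type = "l", log = "xy",
                    xlab = "frequency (Hz)",
                    ylab = "mean fraction remaining", ...)
  graphics::legend("bottomleft", legend = seq_len(x$max_steps), lty = 1,
                   col = seq_len(x$max_steps), title = "step", bty = "n")
  invisible(x)
}
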