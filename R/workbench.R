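# End-to-end orchestration: the two-range frequency-selection study and the
# fully synthetic multi-frequency discrimination experiment, plus run
# configuration and JSON export.

#' Run configuration
#'
#' Bundles every module-level setting of an experiment behind one master
#' seed; serializes losslessly through YAML.
#'
#' @param seed Master seed; every stochastic step derives its seed from it.
#' @param n_runs,n_cells Monte Carlo study size (defaults 100 x 1000).
#' @param max_steps Frequencies selected per run (default 4).
#' @param n_grid Candidate grid density per range (default 100).
#' @param wide_range,narrow_range `c(fmin, fmax)` in Hz.
#' @param ranges [parameter_ranges()].
#' @param model [tolerance_model()].
#' @param device [device_state()].
#' @param schedule [frequency_schedule()].
#' @param res_deg Classifier direction resolution, degrees.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_runs = 100, n_cells = 1000,
                       max_steps = 4, n_grid = 100,
                       wide_range = c(1e4, 1e9),
                       narrow_range = c(5e5, 25e6),
                       ranges = parameter_ranges(),
                       model = tolerance_model(),
                       device = device_state(),
                       schedule = frequency_schedule(),
                       res_deg = 1) {
  structure(list(seed = as.integer(seed), n_runs = n_runs, n_cells = n_cells,
                 max_steps = max_steps, n_grid = n_grid,
                 wide_range = wide_range, narrow_range = narrow_range,
                 ranges = ranges, model = model, device = device,
                 schedule = schedule, res_deg = res_deg),
            class = "run_config")
}

#' Read / write a run configuration
#'
#' Structured-text (YAML) serialization; round-trips losslessly.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config` returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  rng <- config$ranges
  x <- list(
    seed = config$seed, n_runs = config$n_runs, n_cells = config$n_cells,
    max_steps = config$max_steps, n_grid = config$n_grid,
    wide_range = config$wide_range, narrow_range = config$narrow_range,
    res_deg = config$res_deg,
    ranges = list(
      cytoplasm_conductivity = rng$cytoplasm_conductivity,
      cytoplasm_permittivity = rng$cytoplasm_permittivity,
      membrane_conductivity = rng$membrane_conductivity,
      membrane_permittivity = rng$membrane_permittivity,
      radius = rng$radius, membrane_thickness = rng$membrane_thickness,
      log_membrane_conductivity = rng$log_membrane_conductivity,
      medium = list(
        relative_permittivity = rng$medium$relative_permittivity,
        conductivity = rng$medium$conductivity)),
    model = unclass(config$model),
    schedule = list(frequency_hz = config$schedule$frequency_hz,
                    duration_s = config$schedule$duration_s))
  yaml::write_yaml(x, path, precision = 17)  # lossless double round-trip
  dev_path <- sub("(\\.ya?ml)?$", ".device\\1", path)
  write_device_yaml(config$device, dev_path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  rng <- x$ranges
  dev_path <- sub("(\\.ya?ml)?$", ".device\\1", path)
  run_config(
    seed = x$seed, n_runs = x$n_runs, n_cells = x$n_cells,
    max_steps = x$max_steps, n_grid = x$n_grid,
    wide_range = unlist(x$wide_range), narrow_range = unlist(x$narrow_range),
    res_deg = x$res_deg,
    ranges = parameter_ranges(
      cytoplasm_conductivity = unlist(rng$cytoplasm_conductivity),
      cytoplasm_permittivity = unlist(rng$cytoplasm_permittivity),
      membrane_conductivity = unlist(rng$membrane_conductivity),
      membrane_permittivity = unlist(rng$membrane_permittivity),
      radius = unlist(rng$radius),
      membrane_thickness = rng$membrane_thickness,
      med = medium(rng$medium$relative_permittivity,
                   rng$medium$conductivity),
      log_membrane_conductivity = rng$log_membrane_conductivity),
    model = tolerance_model(
      position_uncertainty = x$model$position_uncertainty,
      decay_length = x$model$decay_length,
      min_measurable_cm = x$model$min_measurable_cm,
      constant_tolerance = x$model$constant_tolerance),
    device = if (file.exists(dev_path)) read_device_yaml(dev_path)
             else device_state(),
    schedule = frequency_schedule(unlist(x$schedule$frequency_hz),
                                  unlist(x$schedule$duration_s)))
}

#' Stable hash of a configuration
#'
#' @param config Any R object.
#' @return Character hash.
#' @export
config_hash <- function(config) rlang::hash(config)

derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(as.integer(master))
  s <- sample.int(2^31 - 2, n)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  s
}

#' Two-range Monte Carlo frequency-selection study
#'
#' Runs [run_monte_carlo()] over both the wide (10 kHz - 1 GHz) and narrow
#' (500 kHz - 25 MHz) candidate ranges of the study design. The narrow-range
#' study selects `max_steps - 1` frequencies (three at the default four):
#' the narrower range saturates earlier.
#'
#' @param config A [run_config()].
#' @return List of class `frequency_study` with elements `wide` and
#'   `narrow` (each an `mc_summary`), `config` and `config_hash`.
#' @export
run_frequency_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 2)
  wide <- run_monte_carlo(
    n_runs = config$n_runs, n_cells = config$n_cells, ranges = config$ranges,
    grid = log_frequency_grid(config$wide_range[1], config$wide_range[2],
                              config$n_grid),
    model = config$model, max_steps = config$max_steps, seed = seeds[1])
  narrow <- run_monte_carlo(
    n_runs = config$n_runs, n_cells = config$n_cells, ranges = config$ranges,
    grid = log_frequency_grid(config$narrow_range[1], config$narrow_range[2],
                              config$n_grid),
    model = config$model, max_steps = max(config$max_steps - 1, 1),
    seed = seeds[2])
  structure(list(wide = wide, narrow = narrow, config = config,
                 config_hash = config_hash(config)),
            class = "frequency_study")
}

#' Export a frequency study as JSON (+ per-run CSV)
#'
#' The JSON carries the config hash and seed, per-step mean/median
#' fractions, the per-range sweep curves, modal combinations and first-
#' frequency tables; an optional CSV holds the per-run chosen sequences.
#'
#' @param study A `frequency_study`.
#' @param path JSON output path.
#' @param runs_csv Optional path for the per-run CSV export.
#' @export
export_study_json <- function(study, path, runs_csv = NULL) {
  stopifnot(inherits(study, "frequency_study"))
  pack <- function(s) list(
    grid_hz = s$grid,
    mean_fraction = s$mean_fraction,
    median_fraction = s$median_fraction,
    modal_combination_hz = s$modal_combination,
    first_frequency_table = as.list(s$first_freq_table),
    mean_sweep = apply(s$mean_sweep, 1, identity, simplify = FALSE))
  jsonlite::write_json(
    list(config_hash = study$config_hash, seed = study$config$seed,
         wide = pack(study$wide), narrow = pack(study$narrow)),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(runs_csv)) {
    per_run <- function(s, range) data.frame(
      range = range, run = seq_len(s$n_runs),
      step = rep(seq_len(s$max_steps), each = s$n_runs),
      frequency_hz = as.vector(s$chosen),
      fraction_remaining = as.vector(s$fraction_matrix))
    utils::write.csv(rbind(per_run(study$wide, "wide"),
                           per_run(study$narrow, "narrow")),
                     runs_csv, row.names = FALSE)
  }
  invisible(path)
}

#' Synthetic end-to-end multi-frequency discrimination experiment
#'
#' Generates three cell populations with graded dielectric offsets
#' (emulating increasing drug exposure), simulates their trajectories under
#' the multi-frequency schedule, validates balance positions, size-corrects
#' and inverts them to Re[CM] features, and reports 0-1-loss discrimination
#' accuracies using one, two and three frequencies, pairwise and
#' three-class.
#'
#' @param config A [run_config()]; `n_cells` is the per-class size here
#'   (use a small value, e.g. 40).
#' @param class_shift Per-class additive shifts applied to the centers of
#'   the cytoplasm-conductivity (S/m) and membrane-permittivity ranges;
#'   matrix 3 x 2 (default: graded shifts producing separable but
#'   overlapping classes).
#' @param half_width Half-widths of the per-class parameter ranges around
#'   their shifted centers: cytoplasm conductivity (S/m), membrane
#'   permittivity (eps0), radius (m).
#' @param tau,noise_sd Trajectory settling time (s) and position noise (m).
#' @return List of class `endtoend_result`: `features` (per validated cell:
#'   Re[CM] at the schedule frequencies, radius, class), `accuracies` (data
#'   frame: comparison, n_frequencies, accuracy), `n_valid`, `n_total`,
#'   `config_hash`.
#' @export
run_endtoend <- function(config = run_config(n_cells = 40),
                         class_shift = cbind(c(0, 0.15, 0.3),
                                             c(0, 2, 4)),
                         half_width = c(0.1, 1.5, 1e-6),
                         tau = 0.15, noise_sd = 0.25e-6) {
  stopifnot(inherits(config, "run_config"))
  schedule <- config$schedule
  device <- config$device
  n_per_class <- config$n_cells
  seeds <- derive_seeds(config$seed, 3 + 3 * n_per_class)
  base_sig <- 0.6
  base_epsm <- 8
  base_r <- 5e-6
  classes <- c("control", "low_dose", "high_dose")
  feats <- list()
  n_total <- 0
  for (ci in seq_along(classes)) {
    rng <- parameter_ranges(
      cytoplasm_conductivity = base_sig + class_shift[ci, 1] +
        c(-1, 1) * half_width[1],
      membrane_permittivity = base_epsm + class_shift[ci, 2] +
        c(-1, 1) * half_width[2],
      radius = base_r + c(-1, 1) * half_width[3])
    pop <- sample_population(n_per_class, rng, seed = seeds[ci])
    recm <- Re(cm_spectrum_matrix(pop, rng$medium, schedule$frequency_hz))
    for (i in seq_len(n_per_class)) {
      n_total <- n_total + 1
      traj <- simulate_trajectory(recm[i, ], pop$radius[i], device, schedule,
                                  n_cycles = 1, tau = tau,
                                  noise_sd = noise_sd,
                                  seed = seeds[3 + (ci - 1) * n_per_class + i])
      traj <- moving_average(traj)
      rec <- validate_balance(traj)
      if (!all(rec$valid)) next
      # observation noise can push a near-center balance slightly negative;
      # the physical position is clipped at the electrode center
      balances <- pmax(rec$balance_m, 0)
      corrected <- vapply(seq_len(nrow(rec)), function(k)
        size_correct(balances[k], pop$radius[i], base_r, device,
                     rec$frequency_hz[k]), numeric(1))
      cm_hat <- vapply(seq_len(nrow(rec)), function(k)
        invert_cm(corrected[k], base_r, device, rec$frequency_hz[k]),
        numeric(1))
      feats[[length(feats) + 1]] <- data.frame(
        t(stats::setNames(cm_hat,
                          paste0("re_cm_f", seq_len(nrow(schedule))))),
        radius_m = pop$radius[i], label = classes[ci])
    }
  }
  features <- do.call(rbind, feats)
  fcols <- paste0("re_cm_f", seq_len(nrow(schedule)))
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  acc <- list()
  for (k in seq_along(fcols)) {
    use <- fcols[seq_len(k)]
    x <- as.matrix(features[use])
    for (p in pairs) {
      sel <- features$label %in% p
      fit <- fit_01_linear(x[sel, , drop = FALSE], features$label[sel],
                           config$res_deg)
      acc[[length(acc) + 1]] <- data.frame(
        comparison = paste(p, collapse = " vs "), n_frequencies = k,
        accuracy = fit$accuracy)
    }
    mc <- classify_multiclass(x, features$label, config$res_deg)
    acc[[length(acc) + 1]] <- data.frame(
      comparison = "three-class", n_frequencies = k, accuracy = mc$accuracy)
  }
  structure(list(features = features, accuracies = do.call(rbind, acc),
                 n_valid = nrow(features), n_total = n_total,
                 config_hash = config_hash(config)),
            class = "endtoend_result")
}

#' @export
print.endtoend_result <- function(x, ...) {
  cat(sprintf("end-to-end synthetic experiment: %d/%d cells validated\n",
              x$n_valid, x$n_total))
  print(x$accuracies, row.names = FALSE)
  invisible(x)
}
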