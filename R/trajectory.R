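# Trajectory segmentation by the applied frequency schedule, balance-position
# validation, duration truncation analysis, and synthetic trajectories.

#' Frequency schedule
#'
#' The ordered sequence of (frequency, duration) entries applied to the
#' channel, cyclically repeated. The default is the reference three-frequency
#' schedule: 25 MHz for 1.3 s, 1.2 MHz for 1.8 s, 2 MHz for 0.7 s.
#'
#' @param frequencies Frequencies in Hz.
#' @param durations Dwell durations in s (> 0), same length.
#' @return A data frame of class `frequency_schedule` with columns
#'   `frequency_hz`, `duration_s`.
#' @export
frequency_schedule <- function(frequencies = c(25e6, 1.2e6, 2e6),
                               durations = c(1.3, 1.8, 0.7)) {
  check_frequency(frequencies)
  if (length(durations) != length(frequencies) || any(durations <= 0))
    stop("durations must be positive and match frequencies", call. = FALSE)
  structure(data.frame(frequency_hz = frequencies, duration_s = durations),
            class = c("frequency_schedule", "data.frame"))
}

#' Construct a trajectory
#'
#' A uniformly sampled position time series for one cell, y measured from
#' the electrode-pair center.
#'
#' @param t_s Strictly increasing timestamps in s, uniform to within 1%.
#' @param y_m y positions in m.
#' @param x_m Optional x positions in m.
#' @return A data frame of class `trajectory` with attribute
#'   `frame_interval`.
#' @export
trajectory <- function(t_s, y_m, x_m = NULL) {
  stopifnot(is.numeric(t_s), is.numeric(y_m), length(t_s) == length(y_m))
  if (length(t_s) >= 2) {
    dt <- diff(t_s)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing",
                           call. = FALSE)
    if ((max(dt) - min(dt)) > 0.01 * stats::median(dt))
      stop("timestamps must be uniform to within 1%", call. = FALSE)
  }
  out <- data.frame(t_s = t_s, y_m = y_m)
  if (!is.null(x_m)) out$x_m <- x_m
  structure(out,
            frame_interval = if (length(t_s) >= 2) stats::median(diff(t_s))
                             else NA_real_,
            class = c("trajectory", "data.frame"))
}

#' Trailing moving-average filter
#'
#' Four-point (by default) trailing moving average applied to the y
#' positions; length is preserved by shrinking the window at the start
#' (the k-th of the first `window - 1` points averages the first k samples).
#'
#' @param traj A `trajectory` (or any data frame with `y_m`).
#' @param window Window length in samples (default 4).
#' @return The trajectory with smoothed `y_m`.
#' @export
moving_average <- function(traj, window = 4L) {
  stopifnot(is.data.frame(traj), window >= 1)
  n <- nrow(traj)
  if (n < window)
    stop("trajectory shorter than the averaging window", call. = FALSE)
  cs <- cumsum(traj$y_m)
  out <- numeric(n)
  k <- seq_len(min(window, n))
  out[k] <- cs[k] / k
  if (n > window)
    out[(window + 1):n] <- (cs[(window + 1):n] - cs[1:(n - window)]) / window
  traj$y_m <- out
  traj
}

#' Segment a trajectory by the frequency schedule
#'
#' Assigns every sample to the schedule entry active at its timestamp
#' (boundaries at cumulative schedule times, cyclically repeated). A sample
#' exactly on a boundary closes the ending segment: it is that dwell's
#' final position measurement. Segments are renumbered consecutively from
#' the trajectory start, so shifting the schedule origin by a whole number
#' of cycles leaves the segmentation unchanged.
#'
#' @param traj A `trajectory`.
#' @param schedule A [frequency_schedule()].
#' @param t0 Time at which the schedule's first entry starts, s (default 0).
#' @return The trajectory with added columns `segment` (1-based consecutive
#'   index) and `frequency_hz`.
#' @export
segment_by_schedule <- function(traj, schedule, t0 = 0) {
  stopifnot(is.data.frame(traj), inherits(schedule, "frequency_schedule"))
  cycle <- sum(schedule$duration_s)
  bounds <- cumsum(schedule$duration_s)
  eps <- 1e-9 * cycle                   # absorbs timestamp rounding
  rel <- traj$t_s - t0
  cyc <- floor((rel - eps) / cycle)
  within <- rel - cyc * cycle
  entry <- findInterval(within - eps, c(0, bounds[-length(bounds)]))
  entry <- pmin(pmax(entry, 1L), nrow(schedule))
  raw <- cyc * nrow(schedule) + entry
  traj$segment <- cumsum(c(1L, diff(raw) != 0))
  traj$frequency_hz <- schedule$frequency_hz[entry]
  traj
}

#' Validate balance positions of one segmented trajectory
#'
#' A segment's balance position is the final y of the segment. The cell's
#' reference scale D is the mean absolute difference between consecutive
#' segment balance positions (computed per cell by default; pass
#' `reference_scale` to use a population-wide value). A segment is valid if
#' every sample in its final `final_window` seconds lies within
#' `rel_tol * D` of the segment's final y and that window holds at least
#' `min_samples` samples. At least two segments are required for a
#' difference to exist.
#'
#' @param traj A segmented trajectory (see [segment_by_schedule()]).
#' @param final_window Length of the settling window, s (default 0.25).
#' @param rel_tol Fraction of D the cell must stay within (default 0.1).
#' @param reference_scale Optional externally supplied D in m (e.g. a
#'   population-wide mean difference); default `NULL` computes D per cell.
#' @param min_samples Minimum samples in the final window (default 2).
#' @return A data frame of class `balance_record` with columns `segment`,
#'   `frequency_hz`, `balance_m`, `valid`, `reason`.
#' @export
validate_balance <- function(traj, final_window = 0.25, rel_tol = 0.1,
                             reference_scale = NULL, min_samples = 2L) {
  stopifnot(is.data.frame(traj), "segment" %in% names(traj))
  segs <- split(traj, factor(traj$segment, levels = unique(traj$segment)))
  if (length(segs) < 2)
    stop("at least two segments are required to define the reference scale",
         call. = FALSE)
  finals <- vapply(segs, function(s) s$y_m[nrow(s)], numeric(1))
  D <- reference_scale %||% mean(abs(diff(finals)))
  rec <- lapply(seq_along(segs), function(i) {
    s <- segs[[i]]
    t_end <- s$t_s[nrow(s)]
    tail_idx <- which(s$t_s >= t_end - final_window)
    if (length(tail_idx) < min_samples)
      return(data.frame(segment = as.integer(names(segs)[i]),
                        frequency_hz = s$frequency_hz[1],
                        balance_m = finals[i], valid = FALSE,
                        reason = "insufficient samples"))
    settled <- all(abs(s$y_m[tail_idx] - finals[i]) <= rel_tol * D)
    data.frame(segment = as.integer(names(segs)[i]),
               frequency_hz = s$frequency_hz[1], balance_m = finals[i],
               valid = settled, reason = if (settled) "" else "unsettled")
  })
  structure(do.call(rbind, rec), reference_scale = D,
            class = c("balance_record", "data.frame"))
}

#' Truncation analysis of the frequency schedule
#'
#' For each duration scale factor, every segment of every trajectory is
#' truncated to `factor * duration` (samples beyond the scaled dwell time,
#' measured from the segment start, are dropped) and the balance validation
#' is re-run on the truncated trajectories. Factor 1 reproduces the
#' untruncated validation exactly.
#'
#' @param trajectories List of segmented trajectories.
#' @param schedule The [frequency_schedule()] used for segmentation.
#' @param factors Duration scale factors in (0, 1].
#' @param ... Passed on to [validate_balance()].
#' @return Data frame with columns `factor`, `total_duration_s`,
#'   `fraction_valid` (over all segments of all cells) and
#'   `fraction_cells_all_valid`.
#' @export
truncation_analysis <- function(trajectories, schedule,
                                factors = seq(0.5, 1, by = 0.1), ...) {
  stopifnot(is.list(trajectories), inherits(schedule, "frequency_schedule"),
            all(factors > 0), all(factors <= 1))
  res <- lapply(factors, function(fac) {
    valid <- logical(0)
    all_valid <- logical(0)
    for (traj in trajectories) {
      keep <- unlist(lapply(split(seq_len(nrow(traj)), traj$segment),
        function(ix) {
          dwell <- schedule$duration_s[
            match(traj$frequency_hz[ix[1]], schedule$frequency_hz)]
          ix[traj$t_s[ix] - traj$t_s[ix[1]] <= fac * dwell + 1e-12]
        }))
      cut <- traj[sort(keep), , drop = FALSE]
      rec <- tryCatch(validate_balance(cut, ...), error = function(e) NULL)
      if (is.null(rec)) next
      valid <- c(valid, rec$valid)
      all_valid <- c(all_valid, all(rec$valid))
    }
    data.frame(factor = fac,
               total_duration_s = fac * sum(schedule$duration_s),
               fraction_valid = if (length(valid)) mean(valid) else 0,
               fraction_cells_all_valid =
                 if (length(all_valid)) mean(all_valid) else 0)
  })
  do.call(rbind, res)
}

#' Simulate a multi-frequency DEP-spring trajectory
#'
#' First-order relaxation (time constant `tau`) toward the balance position
#' of the active schedule frequency, plus additive Gaussian position noise
#' on the observations. Balance positions come from the forward spring
#' model.
#'
#' @param re_cm Re[CM] of the cell at each schedule entry (same length as
#'   the schedule, all < 0).
#' @param cell_radius Cell radius in m.
#' @param device A [device_state()].
#' @param schedule A [frequency_schedule()].
#' @param n_cycles Number of schedule cycles to simulate (default 1).
#' @param tau Settling time constant in s (> 0, default 0.3).
#' @param noise_sd Observation noise standard deviation in m
#'   (default 0.25 um).
#' @param frame_rate Sampling rate in Hz (default 20).
#' @param y0 Initial y position in m (default: the first entry's balance
#'   position, i.e. the cell arrives settled).
#' @param seed Seed for the observation noise.
#' @return A segmented `trajectory` (columns `t_s`, `y_m`, `segment`,
#'   `frequency_hz`).
#' @export
simulate_trajectory <- function(re_cm, cell_radius, device,
                                schedule = frequency_schedule(),
                                n_cycles = 1, tau = 0.3, noise_sd = 0.25e-6,
                                frame_rate = 20, y0 = NULL, seed = 1L) {
  stopifnot(inherits(schedule, "frequency_schedule"),
            length(re_cm) == nrow(schedule))
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  targets <- vapply(seq_len(nrow(schedule)), function(k)
    balance_position(cell_radius, re_cm[k], device,
                     schedule$frequency_hz[k])$position_m, numeric(1))
  dt <- 1 / frame_rate
  total <- n_cycles * sum(schedule$duration_s)
  t_s <- seq(dt, total, by = dt)
  cycle <- sum(schedule$duration_s)
  bounds <- cumsum(schedule$duration_s)
  entry_at <- function(t) {
    within <- t - floor((t - 1e-12) / cycle) * cycle
    min(findInterval(within - 1e-12, c(0, bounds[-length(bounds)])),
        nrow(schedule))
  }
  y <- numeric(length(t_s))
  state <- y0 %||% targets[1]
  decay <- exp(-dt / tau)
  for (i in seq_along(t_s)) {
    tgt <- targets[entry_at(t_s[i])]
    state <- tgt + (state - tgt) * decay
    y[i] <- state
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(as.integer(seed))
  y <- y + stats::rnorm(length(y), sd = noise_sd)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  segment_by_schedule(trajectory(t_s, y), schedule)
}

#' Read / write trajectories as CSV
#'
#' Columns `t_s`, `y_m`, optional `x_m`, optional `segment`/`frequency_hz`.
#'
#' @param traj A `trajectory`.
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  out <- trajectory(d$t_s, d$y_m, d$x_m)
  for (col in intersect(c("segment", "frequency_hz"), names(d)))
    out[[col]] <- d[[col]]
  out
}
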