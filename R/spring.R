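# The DEP-spring force-balance model: forward, inverse, bead calibration and
# size correction.
#
# A cell flowing past a pair of slanted coplanar electrodes experiences a
# negative-DEP force opposing the fluid drag. Equating the two gives a
# dimensionless spring argument
#
#   u = 3 eta sin(theta) [6 Q / (w h^3) (h - R)] g^3
#       / (R eps_m |Re[CM]| V_RMS^2 p(f, sigma_m)),
#
# where g is the electrode gap length scale that normalizes the field
# gradient (grad E^2 ~ V^2 / g^3 near the electrodes). The position
# dependence of the DEP force is modelled as exponential decay
# q_R(delta) = exp(-delta / lambda), so the balance position is
# delta = q_R^{-1}(u) = -lambda log(u), with u > 1 clamped to delta = 0
# (the cell balances at the electrode center). q_R is a plug-in: supply
# `q_r_inverse` / `q_r` to substitute another decay model.

#' Default force decay length (m)
#'
#' The decay length lambda of the exponential position model
#' q_R(delta) = exp(-delta/lambda). Its default is set by the package's one
#' calibration: with the 0.5 um balance-position uncertainty, the relative
#' Re[CM] tolerance Delta-delta / lambda that reproduces the reference
#' single-frequency discrimination level of the wide-range Monte Carlo study
#' is 0.12, giving lambda = 0.5 um / 0.12 (about 4.17 um).
#'
#' @export
DEFAULT_DECAY_LENGTH <- 0.5e-6 / 0.12

#' DEP-spring device state
#'
#' Geometry, flow, drive and field-normalization parameters of the coplanar
#' slanted-electrode DEP spring channel.
#'
#' @param channel_width Channel width w in m.
#' @param channel_height Channel height h in m.
#' @param electrode_angle Angle theta between electrodes and flow, rad
#'   (0 < theta < pi/2).
#' @param flow_rate Volumetric flow rate Q in m^3/s.
#' @param rms_voltage Drive voltage V_RMS in V.
#' @param viscosity Medium viscosity eta in Pa s.
#' @param med Suspending [medium()] (supplies eps_m and sigma_m).
#' @param decay_length Decay length lambda of the exponential q_R model, m.
#' @param gap Electrode gap length scale g in m (field-gradient
#'   normalization).
#' @param normalization Optional data frame (`frequency_hz`, `p`) of
#'   dimensionless field-normalization factors p(f, sigma_m); interpolated
#'   log-linearly in frequency, p = 1 where absent. See [calibrate_p()].
#' @return An object of class `device_state`.
#' @export
device_state <- function(channel_width = 500e-6,
                         channel_height = 20e-6,
                         electrode_angle = 15 * pi / 180,
                         flow_rate = 1e-11,
                         rms_voltage = 4,
                         viscosity = 1e-3,
                         med = medium(),
                         decay_length = DEFAULT_DECAY_LENGTH,
                         gap = 25e-6,
                         normalization = NULL) {
  num <- c(channel_width = channel_width, channel_height = channel_height,
           flow_rate = flow_rate, rms_voltage = rms_voltage,
           viscosity = viscosity, decay_length = decay_length, gap = gap)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all geometric/flow/voltage device quantities must be > 0",
         call. = FALSE)
  if (!is.finite(electrode_angle) || electrode_angle <= 0 ||
      electrode_angle >= pi / 2)
    stop("electrode_angle must lie in (0, pi/2)", call. = FALSE)
  stopifnot(inherits(med, "dielectric_material"))
  if (!is.null(normalization)) {
    stopifnot(is.data.frame(normalization),
              all(c("frequency_hz", "p") %in% names(normalization)))
    if (any(normalization$p <= 0))
      stop("normalization factors p must be > 0", call. = FALSE)
    normalization <- normalization[order(normalization$frequency_hz), ]
  }
  structure(list(channel_width = channel_width,
                 channel_height = channel_height,
                 electrode_angle = electrode_angle, flow_rate = flow_rate,
                 rms_voltage = rms_voltage, viscosity = viscosity,
                 medium = med, decay_length = decay_length, gap = gap,
                 normalization = normalization),
            class = "device_state")
}

#' Field normalization factor at a frequency
#'
#' Interpolates the device's calibrated p(f, sigma_m) table log-linearly in
#' frequency; constant extrapolation beyond the calibrated range; p = 1 when
#' no table is attached.
#'
#' @param device A [device_state()].
#' @param f Frequency in Hz (vectorized).
#' @return Dimensionless normalization factor(s).
#' @export
normalization_at <- function(device, f) {
  check_frequency(f)
  tab <- device$normalization
  if (is.null(tab)) return(rep(1, length(f)))
  if (nrow(tab) == 1L) return(rep(tab$p, length(f)))
  stats::approx(log(tab$frequency_hz), tab$p, xout = log(f), rule = 2)$y
}

#' Dimensionless spring argument
#'
#' The argument u passed to the inverse position model: the ratio of the
#' drag-side to the DEP-side force scale (see the model description above).
#' Requires negative DEP (re_cm < 0) and a cell smaller than the channel.
#'
#' @param cell_radius Cell radius R in m.
#' @param re_cm Re[CM] at the operating frequency (must be < 0).
#' @param device A [device_state()].
#' @param f Frequency in Hz (used for the p(f) normalization lookup).
#' @return Dimensionless u > 0.
#' @export
spring_argument <- function(cell_radius, re_cm, device, f) {
  stopifnot(inherits(device, "device_state"))
  check_frequency(f)
  if (any(!is.finite(cell_radius)) || any(cell_radius <= 0))
    stop("cell_radius must be > 0", call. = FALSE)
  if (any(cell_radius >= device$channel_height))
    stop("geometry error: cell radius must be smaller than the channel height",
         call. = FALSE)
  if (any(!is.finite(re_cm)) || any(re_cm >= 0))
    stop("no-balance: re_cm must be negative (nDEP) for an equilibrium",
         call. = FALSE)
  eps_m <- EPS0 * device$medium$relative_permittivity
  drag <- 3 * device$viscosity * sin(device$electrode_angle) *
    (6 * device$flow_rate / (device$channel_width * device$channel_height^3)) *
    (device$channel_height - cell_radius) * device$gap^3
  dep <- cell_radius * eps_m * abs(re_cm) * device$rms_voltage^2 *
    normalization_at(device, f)
  drag / dep
}

#' Balance position of a cell
#'
#' delta = q_R^{-1}(u) with the exponential decay model:
#' delta = -lambda log(u). Arguments u > 1 (DEP too weak to push the cell
#' away from the electrode center) are clamped to delta = 0 with a warning.
#'
#' @inheritParams spring_argument
#' @param q_r_inverse Optional replacement inverse position model,
#'   a function(u, device) -> delta in m.
#' @return A data frame of class `balance_prediction` with columns
#'   `position_m` (delta >= 0, distance from the electrode-pair center along
#'   y), `frequency_hz` and `cell_radius_m`.
#' @export
balance_position <- function(cell_radius, re_cm, device, f,
                             q_r_inverse = NULL) {
  u <- spring_argument(cell_radius, re_cm, device, f)
  if (is.null(q_r_inverse)) {
    clamped <- u > 1
    if (any(clamped))
      warning(sum(clamped),
              " cell(s) with spring argument > 1: balance position clamped ",
              "to the electrode center (delta = 0)", call. = FALSE)
    delta <- ifelse(clamped, 0, -device$decay_length * log(u))
  } else {
    delta <- q_r_inverse(u, device)
  }
  structure(data.frame(position_m = delta,
                       frequency_hz = rep_len(f, length(delta)),
                       cell_radius_m = rep_len(cell_radius, length(delta))),
            class = c("balance_prediction", "data.frame"))
}

#' Invert a balance position to Re[CM]
#'
#' Closed-form inverse of [balance_position()] under the exponential q_R:
#' u = exp(-delta/lambda), Re[CM] = -u_num / u where u_num collects the
#' device terms. Round-trips with the forward model to machine precision.
#' Values below -0.5 (outside the physical CM range) trigger a warning, not
#' an error.
#'
#' @param delta Balance position in m (>= 0).
#' @param cell_radius Cell radius in m.
#' @param device A [device_state()].
#' @param f Frequency in Hz.
#' @return Re[CM] (negative).
#' @export
invert_cm <- function(delta, cell_radius, device, f) {
  stopifnot(inherits(device, "device_state"))
  if (any(!is.finite(delta)) || any(delta < 0))
    stop("delta must be >= 0", call. = FALSE)
  u <- exp(-delta / device$decay_length)
  # spring_argument with |re_cm| = 1 gives the numerator scale
  scale <- spring_argument(cell_radius, -1, device, f)
  re_cm <- -scale / u
  if (any(re_cm < -0.5))
    warning("inverted Re[CM] below -0.5: outside the physical range",
            call. = FALSE)
  re_cm
}

#' Calibrate the field normalization p(f) with beads
#'
#' Polystyrene beads of known CM factor are measured at each frequency; the
#' normalization factor p(f) is solved so the forward model reproduces each
#' bead balance position exactly, then the table is normalized to p = 1 at
#' the lowest calibrated frequency.
#'
#' @param bead_positions Data frame with columns `frequency_hz`, `delta_m`.
#' @param bead_material A `dielectric_material` (e.g. polystyrene: relative
#'   permittivity 2.5, conductivity ~ 0).
#' @param bead_radius Bead radius in m.
#' @param device A [device_state()] (its current normalization is ignored).
#' @return Data frame (`frequency_hz`, `p`) suitable for
#'   [device_state()]'s `normalization`.
#' @export
calibrate_p <- function(bead_positions, bead_material, bead_radius, device) {
  stopifnot(is.data.frame(bead_positions),
            all(c("frequency_hz", "delta_m") %in% names(bead_positions)),
            nrow(bead_positions) >= 1,
            inherits(bead_material, "dielectric_material"),
            inherits(device, "device_state"))
  bead_positions <- bead_positions[order(bead_positions$frequency_hz), ]
  f <- bead_positions$frequency_hz
  delta <- bead_positions$delta_m
  cm <- Re(cm_factor(bead_material, device$medium, f))
  if (any(cm >= 0))
    stop("calibration failure: bead Re[CM] must be negative", call. = FALSE)
  dev1 <- device
  dev1$normalization <- NULL            # solve for p against p = 1
  u_at_p1 <- spring_argument(bead_radius, cm, dev1, f)
  p <- u_at_p1 * exp(delta / device$decay_length)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("calibration failure: solved p is not positive", call. = FALSE)
  data.frame(frequency_hz = f, p = p / p[1])
}

#' Correct a balance position for cell size
#'
#' Maps a measured balance position at the cell's optically measured radius
#' to the position an identical-CM cell of the reference radius would have:
#' invert at `r_measured`, re-apply the forward model at `r_reference`.
#' Cells differing only in radius map to identical corrected positions.
#'
#' @param delta Measured balance position in m.
#' @param r_measured Optically measured cell radius in m.
#' @param r_reference Reference radius in m.
#' @param device A [device_state()].
#' @param f Frequency in Hz.
#' @return Corrected balance position in m.
#' @export
size_correct <- function(delta, r_measured, r_reference, device, f) {
  cm <- invert_cm(delta, r_measured, device, f)
  balance_position(r_reference, cm, device, f)$position_m
}

#' Read / write a device configuration
#'
#' Devices serialize as structured `key: value` text (YAML) with SI units;
#' the normalization table round-trips as a nested list.
#'
#' @param device A [device_state()].
#' @param path File path.
#' @return `read_device_yaml` returns a [device_state()].
#' @export
write_device_yaml <- function(device, path) {
  stopifnot(inherits(device, "device_state"))
  x <- unclass(device)
  x$medium <- list(relative_permittivity = device$medium$relative_permittivity,
                   conductivity = device$medium$conductivity)
  if (!is.null(x$normalization)) x$normalization <- as.list(x$normalization)
  yaml::write_yaml(x, path, precision = 17)  # lossless double round-trip
  invisible(path)
}

#' @rdname write_device_yaml
#' @export
read_device_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  norm <- if (!is.null(x$normalization))
    data.frame(frequency_hz = unlist(x$normalization$frequency_hz),
               p = unlist(x$normalization$p))
  device_state(channel_width = x$channel_width,
               channel_height = x$channel_height,
               electrode_angle = x$electrode_angle,
               flow_rate = x$flow_rate, rms_voltage = x$rms_voltage,
               viscosity = x$viscosity,
               med = medium(x$medium$relative_permittivity,
                            x$medium$conductivity),
               decay_length = x$decay_length, gap = x$gap,
               normalization = norm)
}
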