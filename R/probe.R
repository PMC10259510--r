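#' Cantilever probe specification
#'
#' Describes the elastic probe: spring constant, geometry of the tip and, for
#' axial measurements, of the aluminium foil glued to the tip. The foil turns a
#' ~30 um tip into a flat paddle wide enough to block a whole tissue
#' cross-section; fabricated foils are 100-400 um wide and ~15 um thick.
#'
#' @param spring_constant spring constant k (N/m). AFM-style probes for soft
#'   embryonic tissue span roughly 0.01-0.2 N/m.
#' @param probe_length cantilever length L (um).
#' @param tip_width width of the bare tip at its base (um).
#' @param tip_thickness thickness of the bare tip (um).
#' @param tip_shape `"sharp"`, `"triangular"` or `"foil"`.
#' @param foil_width,foil_height,foil_thickness foil dimensions (um); required
#'   exactly when `tip_shape = "foil"`.
#' @param label `"none"` or `"fluorescent"` (a dyed tip rendered as a bright
#'   spot in the fluorescence channel).
#' @return an object of class `probe_spec`.
#' @examples
#' probe_spec(0.2, tip_shape = "foil",
#'            foil_width = 200, foil_height = 200, foil_thickness = 15)
#' @export
probe_spec <- function(spring_constant,
                       probe_length = 200,
                       tip_width = 30,
                       tip_thickness = 1,
                       tip_shape = c("sharp", "triangular", "foil"),
                       foil_width = NULL,
                       foil_height = NULL,
                       foil_thickness = NULL,
                       label = c("none", "fluorescent")) {
  tip_shape <- match.arg(tip_shape)
  label <- match.arg(label)
  stop_if_not_scalar(spring_constant, "spring_constant", positive = TRUE)
  stop_if_not_scalar(probe_length, "probe_length", positive = TRUE)
  stop_if_not_scalar(tip_width, "tip_width", positive = TRUE)
  stop_if_not_scalar(tip_thickness, "tip_thickness", positive = TRUE)

  has_foil <- !is.null(foil_width) || !is.null(foil_height) ||
    !is.null(foil_thickness)
  if (tip_shape == "foil") {
    if (is.null(foil_width) || is.null(foil_height) || is.null(foil_thickness)) {
      stop("foil_width, foil_height and foil_thickness are required when ",
           "tip_shape = \"foil\"", call. = FALSE)
    }
    stop_if_not_scalar(foil_width, "foil_width", positive = TRUE)
    stop_if_not_scalar(foil_height, "foil_height", positive = TRUE)
    stop_if_not_scalar(foil_thickness, "foil_thickness", positive = TRUE)
    if (foil_width < 100 || foil_width > 400) {
      stop("foil_width must lie in the fabrication range [100, 400] um",
           call. = FALSE)
    }
  } else if (has_foil) {
    stop("foil dimensions are only meaningful when tip_shape = \"foil\"",
         call. = FALSE)
  }

  structure(
    list(
      spring_constant = spring_constant,
      probe_length = probe_length,
      tip_width = tip_width,
      tip_thickness = tip_thickness,
      tip_shape = tip_shape,
      foil_width = foil_width,
      foil_height = foil_height,
      foil_thickness = foil_thickness,
      label = label
    ),
    class = "probe_spec"
  )
}

#' @export
print.probe_spec <- function(x, ...) {
  cat(sprintf("<probe_spec> k = %g N/m, L = %g um, tip = %s (%g um wide)\n",
              x$spring_constant, x$probe_length, x$tip_shape, x$tip_width))
  if (x$tip_shape == "foil") {
    cat(sprintf("  foil %g x %g um, %g um thick\n",
                x$foil_width, x$foil_height, x$foil_thickness))
  }
  invisible(x)
}

#' Piezo actuator and capacitive sensor model
#'
#' The probe holder ("chip") sits on a piezo bender flanked by a pair of plate
#' capacitors. Chip position is `gain * voltage` plus a slow random-walk drift;
#' the capacitance pair `C1 = c0 / (g0 - x)`, `C2 = c0 / (g0 + x)` encodes the
#' chip position `x`, and their difference is strictly increasing in `x`.
#'
#' @param gain piezo gain (um/V).
#' @param voltage_range length-2 numeric, admissible controller voltages (V).
#' @param drift_rate random-walk scale of piezo/chip drift (um per sqrt(s));
#'   each step of `dt` seconds adds a zero-mean increment with s.d.
#'   `drift_rate * sqrt(dt)`.
#' @param readout_noise_pF s.d. of independent capacitance readout noise (pF).
#' @param gap_um capacitor plate gap g0 at chip zero (um); must exceed the
#'   largest commanded excursion.
#' @param coefficient_pF_um capacitor coefficient c0 (pF*um).
#' @return an object of class `piezo_model`.
#' @export
piezo_model <- function(gain = 2,
                        voltage_range = c(-75, 75),
                        drift_rate = 0.02,
                        readout_noise_pF = 0.004,
                        gap_um = 200,
                        coefficient_pF_um = 2000) {
  stop_if_not_scalar(gain, "gain", positive = TRUE)
  stopifnot(length(voltage_range) == 2L, voltage_range[1] < voltage_range[2])
  stop_if_not_scalar(drift_rate, "drift_rate")
  if (drift_rate < 0) stop("drift_rate must be >= 0", call. = FALSE)
  stop_if_not_scalar(readout_noise_pF, "readout_noise_pF")
  if (readout_noise_pF < 0) stop("readout_noise_pF must be >= 0", call. = FALSE)
  stop_if_not_scalar(gap_um, "gap_um", positive = TRUE)
  stop_if_not_scalar(coefficient_pF_um, "coefficient_pF_um", positive = TRUE)
  max_excursion <- gain * max(abs(voltage_range))
  if (gap_um <= max_excursion) {
    stop(sprintf(
      "capacitor gap (%g um) must exceed the maximal chip excursion (%g um)",
      gap_um, max_excursion), call. = FALSE)
  }
  structure(
    list(
      gain = gain,
      voltage_range = as.numeric(voltage_range),
      drift_rate = drift_rate,
      readout_noise_pF = readout_noise_pF,
      gap_um = gap_um,
      coefficient_pF_um = coefficient_pF_um
    ),
    class = "piezo_model"
  )
}

#' Phenomenological active-tissue model
#'
#' One-dimensional stand-in for a pushing embryonic tissue. The advancing
#' front follows a linear (Hill-like, degree 1) force-velocity law
#' `v = v0 * (1 - sigma_r / sigma_a)`, clamped at zero once the resisting
#' stress reaches the active capacity (the stall condition); an assisting
#' (negative) resisting stress speeds the front up. The active capacity can
#' dissipate exponentially with timescale `dissipation_h`, and a finite
#' passive viscous coefficient lets an over-stressed front relax backwards at
#' `(sigma_r - sigma_a) / passive_viscous`, so the measured stress follows
#' the decaying capacity instead of freezing at its peak.
#'
#' @param active_stress_Pa active stress capacity sigma_a0 (Pa).
#' @param free_velocity_um_h unloaded front speed v0 (um/h).
#' @param dissipation_h exponential decay timescale of the active capacity
#'   (h); `Inf` disables dissipation.
#' @param passive_viscous viscous coefficient eta (Pa*h per um/h of retreat);
#'   `Inf` (default) disables passive retreat and yields the pure clamped law.
#' @param contact_mode `"blocking"` (probe blocks the advancing front) or
#'   `"lateral"` (probe loaded sideways by a converging tissue).
#' @return an object of class `tissue_model`.
#' @export
tissue_model <- function(active_stress_Pa = 100,
                         free_velocity_um_h = 150,
                         dissipation_h = Inf,
                         passive_viscous = Inf,
                         contact_mode = c("blocking", "lateral")) {
  contact_mode <- match.arg(contact_mode)
  if (!is.numeric(active_stress_Pa) || active_stress_Pa < 0) {
    stop("active_stress_Pa must be >= 0", call. = FALSE)
  }
  if (!is.numeric(free_velocity_um_h) || free_velocity_um_h < 0) {
    stop("free_velocity_um_h must be >= 0", call. = FALSE)
  }
  if (!is.numeric(dissipation_h) || dissipation_h <= 0) {
    stop("dissipation_h must be > 0 (use Inf for no dissipation)",
         call. = FALSE)
  }
  if (!is.numeric(passive_viscous) || passive_viscous <= 0) {
    stop("passive_viscous must be > 0 (use Inf to disable)", call. = FALSE)
  }
  structure(
    list(
      active_stress_Pa = active_stress_Pa,
      free_velocity_um_h = free_velocity_um_h,
      dissipation_h = dissipation_h,
      passive_viscous = passive_viscous,
      contact_mode = contact_mode
    ),
    class = "tissue_model"
  )
}
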