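#' Force from cantilever deflection
#'
#' `F = k (X_T - X_C)`, with positions in um and k in N/m, returned in nN
#' (1 N/m x 1 um = 1000 nN).
#'
#' @param k spring constant (N/m).
#' @param X_T_um tip position (um).
#' @param X_C_um chip position (um).
#' @return force in nN (vectorized).
#' @examples
#' force_from_deflection(0.01, 10, 0) # 100 nN
#' @export
force_from_deflection <- function(k, X_T_um, X_C_um) {
  stopifnot(is.finite(k), all(is.finite(X_T_um)), all(is.finite(X_C_um)))
  nN_from_deflection(k, X_T_um - X_C_um)
}

#' Contact geometry of the inserted probe
#'
#' @param insertion_depth_um insertion depth D (um).
#' @param depth_uncertainty_um uncertainty on D (um); the focal-plane protocol
#'   carries +/- 20 um in practice.
#' @param insertion_angle_rad insertion angle theta_I from vertical (rad).
#' @param angle_uncertainty_rad uncertainty on theta_I (rad).
#' @param imaging_depth_um imaging depth D_I (um).
#' @param tissue_span_um lateral tissue extent available for contact (um).
#' @return an object of class `contact_geometry`.
#' @export
contact_geometry <- function(insertion_depth_um,
                             depth_uncertainty_um = 20,
                             insertion_angle_rad = 0,
                             angle_uncertainty_rad = 0,
                             imaging_depth_um = insertion_depth_um,
                             tissue_span_um = Inf) {
  stopifnot(insertion_depth_um >= 0, depth_uncertainty_um >= 0,
            insertion_angle_rad >= 0, insertion_angle_rad < pi / 2,
            angle_uncertainty_rad >= 0)
  structure(
    list(insertion_depth_um = insertion_depth_um,
         depth_uncertainty_um = depth_uncertainty_um,
         insertion_angle_rad = insertion_angle_rad,
         angle_uncertainty_rad = angle_uncertainty_rad,
         imaging_depth_um = imaging_depth_um,
         tissue_span_um = tissue_span_um),
    class = "contact_geometry"
  )
}

# projected contact area at a given depth, cos(theta) applied to the
# projection; foil: width x min(D, height); triangle: similar triangles,
# width at depth d is tip_width * d / probe_length
contact_area_at_depth <- function(probe, D_um, theta_rad) {
  if (D_um <= 0) return(0)
  if (probe$tip_shape == "foil") {
    a <- probe$foil_width * min(D_um, probe$foil_height)
  } else {
    d <- min(D_um, probe$probe_length)
    a <- 0.5 * (probe$tip_width * d / probe$probe_length) * d
  }
  a * cos(theta_rad)
}

#' Tissue contact area from probe geometry and insertion depth
#'
#' Foil probes contact over `foil_width x min(D, foil_height)`; bare
#' (sharp/triangular) tips over the triangular cross-section below depth D
#' (similar triangles from `tip_width` and `probe_length`, so halving D
#' quarters the area). The projected area is scaled by `cos(theta_I)`.
#'
#' @param probe a [probe_spec()].
#' @param geom a [contact_geometry()].
#' @return area in um^2 with attributes `relative_uncertainty` (from the
#'   depth uncertainty) and `clipped` (TRUE when D exceeded the probe/foil
#'   vertical extent and was clipped to it).
#' @examples
#' p <- probe_spec(0.2, tip_shape = "foil",
#'                 foil_width = 200, foil_height = 200, foil_thickness = 15)
#' contact_area(p, contact_geometry(200)) # 4e4 um^2
#' @export
contact_area <- function(probe, geom) {
  stopifnot(inherits(probe, "probe_spec"), inherits(geom, "contact_geometry"))
  D <- geom$insertion_depth_um
  if (D <= 0) stop("insertion depth is zero: no tissue contact", call. = FALSE)
  th <- geom$insertion_angle_rad
  a <- contact_area_at_depth(probe, D, th)
  extent <- if (probe$tip_shape == "foil") probe$foil_height else probe$probe_length
  clipped <- D > extent
  dD <- geom$depth_uncertainty_um
  a_lo <- contact_area_at_depth(probe, max(D - dD, 0), th)
  a_hi <- contact_area_at_depth(probe, D + dD, th)
  rel <- if (a > 0) max(abs(a_hi - a), abs(a - a_lo)) / a else Inf
  structure(a, relative_uncertainty = rel, clipped = clipped)
}

#' Stress from force and contact area
#'
#' `sigma = F / A`, returned in Pa (1 nN / 1 um^2 = 1000 Pa).
#'
#' @param force_nN force (nN).
#' @param area_um2 contact area (um^2); must be positive.
#' @return stress in Pa (vectorized).
#' @examples
#' stress_estimate(100, 1e3) # 100 Pa
#' stress_estimate(100, 1e4) # 10 Pa
#' @export
stress_estimate <- function(force_nN, area_um2) {
  if (any(!is.finite(area_um2)) || any(area_um2 <= 0)) {
    stop("contact area must be positive", call. = FALSE)
  }
  Pa_from_force(force_nN, as.numeric(area_um2))
}

#' Relative uncertainty budget for a stress measurement
#'
#' Decomposes the relative uncertainty of `sigma = k (X_T - X_C) / A` into:
#' \describe{
#'   \item{angle}{projected-area bound `1 - cos(theta_I + d_theta)`; the
#'     off-axis force fraction `sin(theta_I)` is reported separately and not
#'     folded into the stress total.}
#'   \item{depth}{relative area change over `D +/- dD` (zero for a fully
#'     inserted foil, whose area no longer depends on D).}
#'   \item{fabrication}{foil cutting tolerance (10-20 percent, default 15);
#'     bare narrow tips get a geometric tolerance and, when the depth band
#'     spans a large area ratio, an order-of-magnitude flag.}
#'   \item{tracking}{`k * tracking_rmse / F`.}
#' }
#' Components combine by worst-case sum (default; a bound) or in quadrature.
#'
#' @param probe a [probe_spec()].
#' @param geom a [contact_geometry()].
#' @param tracking_rmse_um tip localization RMSE (um).
#' @param force_nN the measured force the tracking error is referenced to.
#' @param combination_rule `"worst_case"` or `"quadrature"`.
#' @param fabrication_frac relative area tolerance from probe/foil
#'   fabrication; default 0.15 for foils, 0.10 for bare tips.
#' @return an object of class `uncertainty_budget`: list with `components`
#'   (named numeric, relative fractions), `total`, `rule`,
#'   `off_axis_force_fraction`, `order_of_magnitude_flag`,
#'   `tracking_unbounded`.
#' @export
uncertainty_budget <- function(probe, geom, tracking_rmse_um, force_nN,
                               combination_rule = c("worst_case", "quadrature"),
                               fabrication_frac = NULL) {
  combination_rule <- match.arg(combination_rule)
  stopifnot(inherits(probe, "probe_spec"), inherits(geom, "contact_geometry"),
            tracking_rmse_um >= 0)
  if (is.null(fabrication_frac)) {
    fabrication_frac <- if (probe$tip_shape == "foil") 0.15 else 0.10
  }
  th <- geom$insertion_angle_rad + geom$angle_uncertainty_rad
  angle <- 1 - cos(th)

  D <- geom$insertion_depth_um
  dD <- geom$depth_uncertainty_um
  a_mid <- contact_area_at_depth(probe, D, 0)
  a_lo <- contact_area_at_depth(probe, max(D - dD, 0), 0)
  a_hi <- contact_area_at_depth(probe, D + dD, 0)
  depth <- if (a_mid > 0) max(abs(a_hi - a_mid), abs(a_mid - a_lo)) / a_mid else Inf
  oom <- FALSE
  if (a_lo <= 0 || a_hi / max(a_lo, .Machine$double.eps) >= 10) {
    oom <- probe$tip_shape != "foil" || a_mid == 0
  }

  tracking_unbounded <- FALSE
  if (force_nN == 0 && tracking_rmse_um > 0) {
    tracking <- Inf
    tracking_unbounded <- TRUE
  } else if (force_nN == 0) {
    tracking <- 0
  } else {
    tracking <- abs(nN_from_deflection(probe$spring_constant, tracking_rmse_um) /
                      force_nN)
  }

  comp <- c(angle = angle, depth = depth,
            fabrication = fabrication_frac, tracking = tracking)
  total <- if (combination_rule == "worst_case") sum(comp) else sqrt(sum(comp^2))
  structure(
    list(components = comp, total = total, rule = combination_rule,
         off_axis_force_fraction = sin(geom$insertion_angle_rad),
         order_of_magnitude_flag = oom || total >= 1,
         tracking_unbounded = tracking_unbounded),
    class = "uncertainty_budget"
  )
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("<uncertainty_budget> total = %.1f%% (%s)\n",
              100 * x$total, x$rule))
  for (nm in names(x$components)) {
    cat(sprintf("  %-12s %6.2f%%\n", nm, 100 * x$components[[nm]]))
  }
  cat(sprintf("  off-axis force fraction sin(theta_I) = %.3f\n",
              x$off_axis_force_fraction))
  if (x$order_of_magnitude_flag) {
    cat("  NOTE: stress accurate only to an order of magnitude\n")
  }
  invisible(x)
}

#' Full stress estimate with decomposed uncertainty
#'
#' Bundles force, area, stress and the propagated uncertainty budget;
#' `sigma * A == 1000 * F` holds to machine precision.
#'
#' @inheritParams uncertainty_budget
#' @param force_nN measured force (nN).
#' @return an object of class `stress_breakdown`: list with `force_nN`,
#'   `area_um2`, `sigma_Pa`, `budget`.
#' @export
stress_breakdown <- function(force_nN, probe, geom, tracking_rmse_um = 0.05,
                             combination_rule = c("worst_case", "quadrature"),
                             fabrication_frac = NULL) {
  area <- contact_area(probe, geom)
  budget <- uncertainty_budget(probe, geom, tracking_rmse_um, force_nN,
                               combination_rule, fabrication_frac)
  structure(
    list(force_nN = force_nN,
         area_um2 = as.numeric(area),
         sigma_Pa = stress_estimate(force_nN, as.numeric(area)),
         budget = budget),
    class = "stress_breakdown"
  )
}

#' @export
print.stress_breakdown <- function(x, ...) {
  cat(sprintf(
    "<stress_breakdown> F = %.1f nN over A = %.0f um^2 -> sigma = %.2f Pa +/- %.0f%%\n",
    x$force_nN, x$area_um2, x$sigma_Pa, 100 * x$budget$total))
  invisible(x)
}

#' Insertion depth from recorded objective z positions
#'
#' `D = |z_target - z_surface|`; the focal-plane recognition protocol carries
#' a practical +/- 20 um uncertainty, attached as an attribute and consumed
#' by [contact_geometry()].
#'
#' @param z_surface_um objective z at the tissue surface (um).
#' @param z_target_um objective z at the insertion target plane (um).
#' @param uncertainty_um attached depth uncertainty (um).
#' @return depth in um with attribute `uncertainty_um`.
#' @export
insertion_depth <- function(z_surface_um, z_target_um, uncertainty_um = 20) {
  stop_if_not_scalar(z_surface_um, "z_surface_um")
  stop_if_not_scalar(z_target_um, "z_target_um")
  structure(abs(z_target_um - z_surface_um), uncertainty_um = uncertainty_um)
}
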