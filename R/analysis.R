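#' Stress-time series from an experiment record
#'
#' `sigma(t) = k * deflection(t) / A` per row; the area uncertainty travels
#' along as metadata.
#'
#' @param record an `experiment_record` (needs a `deflection_um` column) or
#'   any data.frame with `time_s` and `deflection_um`.
#' @param k spring constant (N/m); defaults to the record's.
#' @param A_um2 contact area (um^2); defaults to the record's.
#' @param area_relative_uncertainty optional relative uncertainty attached as
#'   an attribute.
#' @return data.frame with `time_s`, `sigma_Pa`; attribute
#'   `area_relative_uncertainty`.
#' @export
stress_trace <- function(record, k = NULL, A_um2 = NULL,
                         area_relative_uncertainty = NA_real_) {
  if (!all(c("time_s", "deflection_um") %in% names(record))) {
    stop("record must contain `time_s` and `deflection_um` columns",
         call. = FALSE)
  }
  if (is.null(k)) k <- attr(record, "spring_constant")
  if (is.null(A_um2)) A_um2 <- attr(record, "contact_area_um2")
  stop_if_not_scalar(k, "k", positive = TRUE)
  stop_if_not_scalar(A_um2, "A_um2", positive = TRUE)
  out <- data.frame(time_s = record$time_s,
                    sigma_Pa = Pa_from_deflection(k, record$deflection_um, A_um2))
  attr(out, "area_relative_uncertainty") <- area_relative_uncertainty
  out
}

moving_average <- function(x, width) {
  if (width <= 1L || length(x) < width) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
  # fill the ends with the raw values
  na <- is.na(sm)
  sm[na] <- x[na]
  sm
}

#' Initial stress, stalling stress and dissipation from a stress trace
#'
#' Initial stress is the mean over the first `initial_window_min` after
#' insertion; the plateau is the trailing contiguous region of the smoothed
#' trace where `|d sigma / dt|` stays below `rate_threshold`, and the
#' stalling stress its mean. Dissipation is flagged when the post-peak
#' stress falls by more than 20 percent, in which case an exponential decay
#' timescale is fitted (log-linear least squares) to the declining segment.
#'
#' @param sigma data.frame with `time_s`, `sigma_Pa` (e.g. from
#'   [stress_trace()]).
#' @param initial_window_min initial-stress window (min).
#' @param rate_threshold_Pa_min plateau criterion on the smoothed derivative
#'   (Pa/min).
#' @param smooth_width moving-average width (samples).
#' @return an object of class `stall_metrics`: list with
#'   `initial_stress_Pa`, `stall_stress_Pa` (NA with a warning when no
#'   plateau exists), `time_to_stall_min`, `dissipation` (logical),
#'   `dissipation_timescale_h` (NA unless fitted).
#' @export
stall_metrics <- function(sigma, initial_window_min = 30,
                          rate_threshold_Pa_min = 0.05,
                          smooth_width = 5L) {
  stopifnot(all(c("time_s", "sigma_Pa") %in% names(sigma)), nrow(sigma) >= 3)
  t_min <- sigma$time_s / 60
  if (max(t_min) < initial_window_min) {
    stop("trace must span at least the initial-stress window", call. = FALSE)
  }
  s <- moving_average(sigma$sigma_Pa, smooth_width)
  initial <- mean(sigma$sigma_Pa[t_min <= initial_window_min])

  rate <- c(NA, diff(s) / diff(t_min)) # Pa/min
  flat <- abs(rate) < rate_threshold_Pa_min
  flat[is.na(flat)] <- FALSE
  n <- length(flat)
  # latest contiguous flat run spanning at least min_span_min
  min_span_min <- 5
  runs <- rle(flat)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  plateau_idx <- integer(0)
  for (r in rev(which(runs$values))) {
    if (diff(range(t_min[starts[r]:ends[r]])) >= min_span_min) {
      plateau_idx <- starts[r]:ends[r]
      break
    }
  }
  if (length(plateau_idx) < 2L ||
      diff(range(t_min[plateau_idx])) < min_span_min) {
    warning("no stall plateau found in the stress trace")
    stall <- NA_real_
    t_stall <- NA_real_
  } else {
    stall <- mean(sigma$sigma_Pa[plateau_idx])
    t_stall <- t_min[plateau_idx[1]]
  }

  # dissipation: post-peak decline by > 20 %
  peak_i <- which.max(s)
  dissipation <- FALSE
  tau_h <- NA_real_
  if (peak_i < n && min(s[peak_i:n]) < 0.8 * s[peak_i] && s[peak_i] > 0) {
    dissipation <- TRUE
    seg <- seq(peak_i, n)
    seg <- seg[s[seg] > 0.02 * s[peak_i]]
    if (length(seg) >= 3L) {
      fit <- stats::lm(log(s[seg]) ~ t_min[seg])
      slope <- unname(stats::coef(fit)[2]) # per minute
      if (is.finite(slope) && slope < 0) tau_h <- -1 / slope / 60
    }
  }
  structure(
    list(initial_stress_Pa = initial, stall_stress_Pa = stall,
         time_to_stall_min = t_stall, dissipation = dissipation,
         dissipation_timescale_h = tau_h),
    class = "stall_metrics"
  )
}

#' @export
print.stall_metrics <- function(x, ...) {
  cat(sprintf(
    "<stall_metrics> initial %.1f Pa, stall %s Pa (t_stall %s min)%s\n",
    x$initial_stress_Pa,
    ifelse(is.na(x$stall_stress_Pa), "NA", sprintf("%.1f", x$stall_stress_Pa)),
    ifelse(is.na(x$time_to_stall_min), "NA", sprintf("%.0f", x$time_to_stall_min)),
    if (x$dissipation) sprintf(", dissipating (tau ~ %.2f h)",
                               x$dissipation_timescale_h) else ""))
  invisible(x)
}

#' Elongation (front) speed by least squares
#'
#' @param time_s sample times (s).
#' @param position_um front positions (um).
#' @return slope in um/h.
#' @export
elongation_speed <- function(time_s, position_um) {
  stopifnot(length(time_s) == length(position_um), length(time_s) >= 2)
  if (stats::sd(time_s) == 0) stop("degenerate time axis", call. = FALSE)
  unname(stats::coef(stats::lm(position_um ~ time_s))[2]) * 3600
}

#' Welch two-sample comparison of speed samples
#'
#' Unpaired two-tailed Welch t-test with per-group mean and dispersion
#' (s.d. or s.e.m.). Two groups with zero variance and equal means return
#' `t = 0, p = 1` by convention.
#'
#' @param samples_a,samples_b numeric vectors (each n >= 2).
#' @param dispersion `"sd"` or `"sem"`.
#' @return list with `mean_a`, `dispersion_a`, `mean_b`, `dispersion_b`,
#'   `t`, `df`, `p`, `dispersion_type`.
#' @export
compare_groups <- function(samples_a, samples_b, dispersion = c("sd", "sem")) {
  dispersion <- match.arg(dispersion)
  stopifnot(length(samples_a) >= 2, length(samples_b) >= 2)
  disp <- function(x) {
    if (dispersion == "sd") stats::sd(x) else stats::sd(x) / sqrt(length(x))
  }
  base <- list(mean_a = mean(samples_a), dispersion_a = disp(samples_a),
               mean_b = mean(samples_b), dispersion_b = disp(samples_b),
               dispersion_type = dispersion)
  if (stats::sd(samples_a) == 0 && stats::sd(samples_b) == 0) {
    if (mean(samples_a) == mean(samples_b)) {
      return(c(base, list(t = 0, df = NA_real_, p = 1)))
    }
    return(c(base, list(t = Inf, df = NA_real_, p = 0)))
  }
  ht <- stats::t.test(samples_a, samples_b, var.equal = FALSE,
                      alternative = "two.sided")
  c(base, list(t = unname(ht$statistic), df = unname(ht$parameter),
               p = ht$p.value))
}

#' Summarize an experiment into tidy outputs
#'
#' Convenience wrapper: stress trace + stall metrics + summary JSON/CSV
#' export.
#'
#' @param record an `experiment_record`.
#' @param out_dir optional directory; when given, writes
#'   `stress_trace.csv` and `summary.json` there.
#' @param ... passed to [stall_metrics()].
#' @return list with `trace` and `metrics`.
#' @export
analyze_record <- function(record, out_dir = NULL, ...) {
  tr <- stress_trace(record)
  m <- stall_metrics(tr, ...)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(tr, file.path(out_dir, "stress_trace.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(m), file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(trace = tr, metrics = m)
}
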