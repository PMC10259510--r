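#' Imaging model configuration
#'
#' Camera and optics parameters for rendering synthetic frames of the probe
#' tip in tissue. Contrast degradation with imaging depth is modelled as a
#' Gaussian blur whose s.d. grows linearly with the depth of tissue the light
#' traverses; sensor noise is Gaussian read noise plus Poisson-scaled shot
#' noise. Intensities are kept as fractions of full scale in `[0, 1]` and
#' written as 16-bit TIFF.
#'
#' @param pixel_size_um pixel size (um/px).
#' @param frame_rate_max_hz camera frame-rate ceiling (Hz).
#' @param fov_px integer length-2, field of view `c(nx, ny)` in pixels.
#' @param imaging_depth_um imaging depth D_I through the tissue (um).
#' @param blur_px_per_100um Gaussian blur s.d. (px) added per 100 um of
#'   imaging depth.
#' @param background_level mean background intensity (fraction of full scale).
#' @param texture_amplitude s.d. of the smooth static background texture.
#' @param texture_seed seed of the (static) background texture; frames of one
#'   movie share it.
#' @param read_noise_sd Gaussian read noise s.d.
#' @param shot_noise_scale shot-noise coefficient; per-pixel s.d. is
#'   `shot_noise_scale * sqrt(intensity)`.
#' @param tip_contrast intensity depth (brightfield) or height (fluorescence)
#'   of the tip profile.
#' @param channel `"brightfield"` (dark tip) or `"fluorescent"` (bright spot).
#' @param supersample sub-row sampling factor for non-separable profiles.
#' @return an object of class `optics_config`.
#' @export
optics_config <- function(pixel_size_um = 0.5,
                          frame_rate_max_hz = 200,
                          fov_px = c(128L, 128L),
                          imaging_depth_um = 30,
                          blur_px_per_100um = 2,
                          background_level = 0.45,
                          texture_amplitude = 0.02,
                          texture_seed = 1234,
                          read_noise_sd = 0.004,
                          shot_noise_scale = 0.006,
                          tip_contrast = 0.35,
                          channel = c("brightfield", "fluorescent"),
                          supersample = 4L) {
  channel <- match.arg(channel)
  stop_if_not_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  stop_if_not_scalar(frame_rate_max_hz, "frame_rate_max_hz", positive = TRUE)
  stopifnot(length(fov_px) == 2L, all(fov_px >= 16))
  stopifnot(imaging_depth_um >= 0, blur_px_per_100um >= 0,
            read_noise_sd >= 0, shot_noise_scale >= 0,
            texture_amplitude >= 0, tip_contrast > 0)
  structure(
    list(pixel_size_um = pixel_size_um,
         frame_rate_max_hz = frame_rate_max_hz,
         fov_px = as.integer(fov_px),
         imaging_depth_um = imaging_depth_um,
         blur_px_per_100um = blur_px_per_100um,
         background_level = background_level,
         texture_amplitude = texture_amplitude,
         texture_seed = texture_seed,
         read_noise_sd = read_noise_sd,
         shot_noise_scale = shot_noise_scale,
         tip_contrast = tip_contrast,
         channel = channel,
         supersample = as.integer(supersample)),
    class = "optics_config"
  )
}

blur_sigma_px <- function(optics) {
  optics$blur_px_per_100um * optics$imaging_depth_um / 100
}

# overlap length of [lo, hi] with unit pixels centred at `centers` (px units)
interval_coverage <- function(lo, hi, centers) {
  pmax(0, pmin(hi, centers + 0.5) - pmax(lo, centers - 0.5))
}

# static smooth background texture, deterministic in the texture seed
background_texture <- function(optics) {
  if (optics$texture_amplitude <= 0) {
    return(matrix(0, optics$fov_px[2], optics$fov_px[1]))
  }
  with_seed(optics$texture_seed, {
    raw <- matrix(stats::rnorm(prod(optics$fov_px)),
                  optics$fov_px[2], optics$fov_px[1])
    sm <- as.matrix(EBImage::gblur(EBImage::Image(raw), sigma = 3))
    sm * optics$texture_amplitude / stats::sd(sm)
  })
}

# tip/foil coverage profile (ny x nx matrix in [0,1]); x centroid of every
# profile equals x0 by construction (all profiles symmetric in x)
tip_profile <- function(x0_px, y0_px, probe, optics) {
  nx <- optics$fov_px[1]; ny <- optics$fov_px[2]
  xc <- seq_len(nx) - 0.5
  yc <- seq_len(ny) - 0.5
  px <- optics$pixel_size_um
  fluorescent <- optics$channel == "fluorescent"
  if (fluorescent) {
    sigma <- max(probe$tip_width / 6 / px, 1.2)
    ix <- stats::pnorm((xc + 0.5 - x0_px) / sigma) -
      stats::pnorm((xc - 0.5 - x0_px) / sigma)
    iy <- stats::pnorm((yc + 0.5 - y0_px) / sigma) -
      stats::pnorm((yc - 0.5 - y0_px) / sigma)
    prof <- outer(iy, ix)
    return(prof / max(prof))
  }
  if (probe$tip_shape == "foil") {
    wx <- max(probe$foil_thickness / px, 2)
    wy <- probe$foil_width / px
    covx <- interval_coverage(x0_px - wx / 2, x0_px + wx / 2, xc)
    covy <- interval_coverage(y0_px - wy / 2, y0_px + wy / 2, yc)
    return(outer(covy, covx))
  }
  # sharp / triangular: filled triangle, apex up (-y), base width tip_width,
  # height 2 x tip_width, symmetric in x about x0
  W <- probe$tip_width / px
  H <- 2 * W
  ss <- optics$supersample
  prof <- matrix(0, ny, nx)
  sub <- (seq_len(ss) - 0.5) / ss - 0.5
  for (r in seq_len(ny)) {
    acc <- numeric(nx)
    for (s in sub) {
      y <- yc[r] + s
      frac <- (y - (y0_px - H / 2)) / H
      if (frac <= 0 || frac > 1) next
      w <- W * frac
      acc <- acc + interval_coverage(x0_px - w / 2, x0_px + w / 2, xc)
    }
    prof[r, ] <- acc / ss
  }
  prof
}

#' Render one synthetic frame of the tip in tissue
#'
#' Draws the tip/foil profile centred at the true tip position, adds the
#' static background texture (and optionally a projected cell-density field),
#' applies depth-dependent Gaussian blur, then sensor noise. The ground-truth
#' position is stored in the frame metadata.
#'
#' @param tip_x_um true tip position along the measurement axis (um), or a
#'   `plant_state` whose `X_T_true_um` (and density field) is used.
#' @param probe a [probe_spec()].
#' @param optics an [optics_config()].
#' @param tip_y_um tip position across the axis (um); defaults to the frame
#'   centre.
#' @param density optional density field (list `x`, `rho`) projected onto the
#'   image as added intensity per column.
#' @param density_contrast intensity per unit linear density.
#' @param time_s frame timestamp (s).
#' @param texture optional precomputed background texture (shared by a movie).
#' @param rng_seed optional seed for the sensor noise; the same seed and
#'   configuration give a bit-identical frame.
#' @return an object of class `tifm_frame`: list with `pixels` (ny x nx
#'   matrix in `[0,1]`), `time_s`, `truth_x_um`, `truth_y_um`,
#'   `pixel_size_um`, `channel`, `out_of_view`.
#' @export
render_frame <- function(tip_x_um, probe, optics, tip_y_um = NULL,
                         density = NULL, density_contrast = 0.02,
                         time_s = 0, texture = NULL, rng_seed = NULL) {
  stopifnot(inherits(probe, "probe_spec"), inherits(optics, "optics_config"))
  if (inherits(tip_x_um, "plant_state")) {
    st <- tip_x_um
    if (is.null(density)) density <- st$density
    time_s <- st$time_s
    tip_x_um <- st$X_T_true_um
  }
  nx <- optics$fov_px[1]; ny <- optics$fov_px[2]
  px <- optics$pixel_size_um
  if (is.null(tip_y_um)) tip_y_um <- ny * px / 2
  x0_px <- tip_x_um / px
  y0_px <- tip_y_um / px
  out_of_view <- x0_px < 0 || x0_px > nx || y0_px < 0 || y0_px > ny

  if (is.null(texture)) texture <- background_texture(optics)
  scene <- optics$background_level + texture
  if (!is.null(density) && density_contrast > 0) {
    xc_um <- (seq_len(nx) - 0.5) * px
    rho <- stats::approx(density$x, density$rho, xout = xc_um,
                         yleft = 0, yright = 0)$y
    scene <- scene + matrix(rho * density_contrast, ny, nx, byrow = TRUE)
  }
  prof <- tip_profile(x0_px, y0_px, probe, optics)
  scene <- if (optics$channel == "brightfield") {
    scene - optics$tip_contrast * prof
  } else {
    scene + optics$tip_contrast * prof
  }
  sig <- blur_sigma_px(optics)
  if (sig > 0) {
    scene <- as.matrix(EBImage::gblur(EBImage::Image(scene), sigma = sig))
  }
  img <- with_seed(rng_seed, {
    n <- length(scene)
    noisy <- scene
    if (optics$read_noise_sd > 0) {
      noisy <- noisy + stats::rnorm(n, 0, optics$read_noise_sd)
    }
    if (optics$shot_noise_scale > 0) {
      noisy <- noisy + stats::rnorm(n) * optics$shot_noise_scale *
        sqrt(pmax(scene, 0))
    }
    noisy
  })
  img <- matrix(pmin(pmax(img, 0), 1), ny, nx)
  structure(
    list(pixels = img, time_s = time_s,
         truth_x_um = tip_x_um, truth_y_um = tip_y_um,
         pixel_size_um = px, channel = optics$channel,
         out_of_view = out_of_view),
    class = "tifm_frame"
  )
}

#' Render a time-lapse movie from a plant trajectory
#'
#' One frame per trajectory sample at the requested interval; frame
#' timestamps equal the trajectory times, and the ground-truth track is kept
#' alongside the frames (and written as a CSV sidecar by [write_movie()]).
#'
#' @param trajectory data.frame with `time_s` and `X_T_true_um` columns
#'   (e.g. from [simulate_plant()]).
#' @param probe a [probe_spec()].
#' @param optics an [optics_config()].
#' @param sampling_interval_s frame spacing (s); must be at least
#'   `1 / frame_rate_max_hz`. `NULL` renders every trajectory row.
#' @param density_snapshots optional list of density fields parallel to the
#'   trajectory rows.
#' @param rng_seed optional seed for all per-frame sensor noise.
#' @inheritParams render_frame
#' @return an object of class `tifm_movie`: list with `frames` (list of
#'   `tifm_frame`), `truth` (data.frame `frame`, `time_s`, `x_um`, `y_um`),
#'   `optics`, `probe`.
#' @export
render_movie <- function(trajectory, probe, optics,
                         sampling_interval_s = NULL,
                         tip_y_um = NULL, density_snapshots = NULL,
                         density_contrast = 0.02, rng_seed = NULL) {
  stopifnot(is.data.frame(trajectory),
            all(c("time_s", "X_T_true_um") %in% names(trajectory)))
  if (nrow(trajectory) == 0L) stop("empty trajectory", call. = FALSE)
  if (!is.null(sampling_interval_s)) {
    if (sampling_interval_s < 1 / optics$frame_rate_max_hz) {
      stop("sampling interval is below the camera frame-rate limit",
           call. = FALSE)
    }
    t0 <- trajectory$time_s[1]
    wanted <- seq(t0, max(trajectory$time_s), by = sampling_interval_s)
    idx <- vapply(wanted, function(t) which.min(abs(trajectory$time_s - t)),
                  integer(1))
    idx <- unique(idx)
  } else {
    idx <- seq_len(nrow(trajectory))
  }
  texture <- background_texture(optics)
  with_seed(rng_seed, {
    frames <- vector("list", length(idx))
    for (j in seq_along(idx)) {
      i <- idx[j]
      frames[[j]] <- render_frame(
        trajectory$X_T_true_um[i], probe, optics, tip_y_um = tip_y_um,
        density = if (!is.null(density_snapshots)) density_snapshots[[i]],
        density_contrast = density_contrast,
        time_s = trajectory$time_s[i], texture = texture)
    }
    truth <- data.frame(
      frame = seq_along(idx),
      time_s = trajectory$time_s[idx],
      x_um = trajectory$X_T_true_um[idx],
      y_um = vapply(frames, `[[`, numeric(1), "truth_y_um"))
    structure(list(frames = frames, truth = truth,
                   optics = optics, probe = probe),
              class = "tifm_movie")
  })
}

#' @export
print.tifm_movie <- function(x, ...) {
  cat(sprintf("<tifm_movie> %d frames, %dx%d px, %s channel\n",
              length(x$frames), x$optics$fov_px[1], x$optics$fov_px[2],
              x$optics$channel))
  invisible(x)
}

#' Write a movie as a 16-bit multi-page TIFF with sidecars
#'
#' Writes `<basename>.tif` (one page per frame), `<basename>_truth.csv`
#' (ground-truth track) and `<basename>_meta.json` (timestamps, pixel size,
#' channel).
#'
#' @param movie a `tifm_movie`.
#' @param dir output directory (created if missing).
#' @param basename file stem.
#' @return the TIFF path, invisibly.
#' @export
write_movie <- function(movie, dir, basename = "movie") {
  stopifnot(inherits(movie, "tifm_movie"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tif <- file.path(dir, paste0(basename, ".tif"))
  pages <- lapply(movie$frames, `[[`, "pixels")
  tiff::writeTIFF(pages, tif, bits.per.sample = 16)
  utils::write.csv(movie$truth, file.path(dir, paste0(basename, "_truth.csv")),
                   row.names = FALSE)
  meta <- list(
    n_frames = length(movie$frames),
    timestamps_s = movie$truth$time_s,
    pixel_size_um = movie$optics$pixel_size_um,
    channel = movie$optics$channel,
    fov_px = movie$optics$fov_px
  )
  jsonlite::write_json(meta, file.path(dir, paste0(basename, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(tif)
}

#' Read a movie written by [write_movie()]
#'
#' @param dir directory holding the files.
#' @param basename file stem used at write time.
#' @return a `tifm_movie` (frame pixels quantized to 16-bit).
#' @export
read_movie <- function(dir, basename = "movie") {
  tif <- file.path(dir, paste0(basename, ".tif"))
  meta <- jsonlite::read_json(file.path(dir, paste0(basename, "_meta.json")),
                              simplifyVector = TRUE)
  truth <- utils::read.csv(file.path(dir, paste0(basename, "_truth.csv")))
  pages <- tiff::readTIFF(tif, all = TRUE)
  frames <- lapply(seq_along(pages), function(i) {
    structure(
      list(pixels = pages[[i]], time_s = meta$timestamps_s[i],
           truth_x_um = truth$x_um[i], truth_y_um = truth$y_um[i],
           pixel_size_um = meta$pixel_size_um, channel = meta$channel,
           out_of_view = FALSE),
      class = "tifm_frame")
  })
  optics <- optics_config(pixel_size_um = meta$pixel_size_um,
                          fov_px = meta$fov_px,
                          channel = meta$channel)
  structure(list(frames = frames, truth = truth, optics = optics,
                 probe = NULL),
            class = "tifm_movie")
}
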