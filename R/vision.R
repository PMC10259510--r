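#' Sub-pixel tip localization in a single frame
#'
#' Two interchangeable estimators:
#' \describe{
#'   \item{centroid}{Otsu threshold, connected components, component nearest
#'     the prior (largest if no prior), then an intensity-weighted sub-pixel
#'     centroid of the background-subtracted component.}
#'   \item{template}{normalized cross-correlation against a reference patch
#'     within a search window around the prior, with parabolic sub-pixel
#'     refinement of the correlation peak.}
#' }
#' Brightfield frames are inverted first (dark tip); fluorescence frames are
#' used as-is.
#'
#' @param frame a `tifm_frame` (or a plain pixel matrix plus `pixel_size_um`).
#' @param prior_um optional prior position `c(x, y)` or scalar x (um).
#' @param method `"centroid"` or `"template"`.
#' @param template reference patch matrix (required for `"template"`;
#'   same polarity as the working image, i.e. bright tip).
#' @param search_radius_px half-width of the template search window.
#' @param pixel_size_um pixel size, needed only when `frame` is a bare matrix.
#' @param min_contrast frames whose full-scale intensity range falls below
#'   this are declared lost (no tip visible).
#' @return list with `x_um`, `y_um` (NA when lost), `confidence` in `[0, 1]`
#'   and `lost` (logical).
#' @export
locate_tip <- function(frame, prior_um = NULL,
                       method = c("centroid", "template"),
                       template = NULL, search_radius_px = 12,
                       pixel_size_um = NULL, min_contrast = 0.02) {
  method <- match.arg(method)
  if (inherits(frame, "tifm_frame")) {
    img <- frame$pixels
    px <- frame$pixel_size_um
    dark_tip <- identical(frame$channel, "brightfield")
  } else {
    img <- frame
    if (is.null(pixel_size_um)) stop("pixel_size_um required for a bare matrix",
                                     call. = FALSE)
    px <- pixel_size_um
    dark_tip <- TRUE
  }
  stopifnot(is.matrix(img), all(is.finite(img)))
  lost <- list(x_um = NA_real_, y_um = NA_real_, confidence = 0, lost = TRUE)

  work <- if (dark_tip) max(img) - img else img
  rng <- diff(range(work))
  if (rng < min_contrast) return(lost)
  w <- (work - min(work)) / rng

  if (method == "centroid") {
    thr <- EBImage::otsu(EBImage::Image(w), range = c(0, 1))
    mask <- w > thr
    if (sum(mask) < 3L) return(lost)
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    lab <- as.matrix(lab)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= max(3, 0.25 * max(sizes)))
    cents <- t(vapply(keep, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      c(mean(idx[, 2]), mean(idx[, 1])) # x (col), y (row), px centres - 0.5
    }, numeric(2)))
    pick <- if (!is.null(prior_um) && nrow(cents) > 1L) {
      pr <- if (length(prior_um) == 1L) c(prior_um, NA) else prior_um
      d <- (cents[, 1] - 0.5 - pr[1] / px)^2
      if (!is.na(pr[2])) d <- d + (cents[, 2] - 0.5 - pr[2] / px)^2
      keep[which.min(d)]
    } else {
      keep[which.max(sizes[keep])]
    }
    sel <- lab == pick
    cols <- matrix(rep(seq_len(ncol(w)) - 0.5, each = nrow(w)), nrow(w))
    rows <- matrix(rep(seq_len(nrow(w)) - 0.5, ncol(w)), nrow(w))
    # subtract a local background plane (fitted to non-tip pixels around the
    # component) so smooth background texture does not bias the centroid
    idx <- which(sel, arr.ind = TRUE)
    margin <- 6L
    r_rng <- max(1L, min(idx[, 1]) - margin):min(nrow(w), max(idx[, 1]) + margin)
    c_rng <- max(1L, min(idx[, 2]) - margin):min(ncol(w), max(idx[, 2]) + margin)
    box <- matrix(FALSE, nrow(w), ncol(w))
    box[r_rng, c_rng] <- TRUE
    bgpix <- box & !mask
    w2 <- w
    if (sum(bgpix) > 12L) {
      X <- cbind(1, cols[bgpix], rows[bgpix])
      beta <- tryCatch(qr.solve(crossprod(X), crossprod(X, w[bgpix])),
                       error = function(e) NULL)
      if (!is.null(beta)) {
        w2 <- w - (beta[1] + beta[2] * cols + beta[3] * rows)
      }
    }
    base <- stats::median(w2[bgpix])
    ww <- pmax(w2 - base - (thr - stats::median(w[bgpix])), 0) * sel
    tot <- sum(ww)
    if (tot <= 0) return(lost)
    x_px <- sum(ww * cols) / tot
    y_px <- sum(ww * rows) / tot
    bg <- w[!mask]
    snr <- (mean(w[sel]) - mean(bg)) / max(stats::sd(bg), 1e-6)
    conf <- min(1, 1 - exp(-snr / 5))
    return(list(x_um = x_px * px, y_um = y_px * px,
                confidence = conf, lost = FALSE))
  }

  # template matching
  if (is.null(template)) stop("template patch required for method = \"template\"",
                              call. = FALSE)
  p <- dim(template)
  if (is.null(prior_um)) {
    ctr <- c(ncol(w), nrow(w)) / 2 * px
  } else {
    ctr <- if (length(prior_um) == 1L) c(prior_um, nrow(w) / 2 * px) else prior_um
  }
  cx <- round(ctr[1] / px + 0.5) # pixel index of the prior
  cy <- round(ctr[2] / px + 0.5)
  hr <- floor(p[1] / 2); hc <- floor(p[2] / 2)
  tmpl <- as.vector(template - mean(template))
  tnorm <- sqrt(sum(tmpl^2))
  if (tnorm <= 0) return(lost)
  sr <- search_radius_px
  offs <- (-sr):sr
  score <- matrix(-Inf, length(offs), length(offs)) # rows: dy, cols: dx
  for (iy in seq_along(offs)) {
    r0 <- cy + offs[iy] - hr
    if (r0 < 1L || r0 + p[1] - 1L > nrow(w)) next
    for (ix in seq_along(offs)) {
      c0 <- cx + offs[ix] - hc
      if (c0 < 1L || c0 + p[2] - 1L > ncol(w)) next
      patch <- w[r0:(r0 + p[1] - 1L), c0:(c0 + p[2] - 1L)]
      pv <- as.vector(patch - mean(patch))
      pn <- sqrt(sum(pv^2))
      if (pn <= 0) next
      score[iy, ix] <- sum(pv * tmpl) / (pn * tnorm)
    }
  }
  if (!any(is.finite(score))) return(lost)
  pk <- which(score == max(score), arr.ind = TRUE)[1, ]
  if (score[pk[1], pk[2]] < 0.5) return(lost)
  refine <- function(sm1, s0, sp1) {
    den <- sm1 - 2 * s0 + sp1
    if (!is.finite(den) || den >= 0) return(0)
    d <- 0.5 * (sm1 - sp1) / den
    max(min(d, 0.5), -0.5)
  }
  dy <- dx <- 0
  if (pk[1] > 1L && pk[1] < nrow(score)) {
    dy <- refine(score[pk[1] - 1L, pk[2]], score[pk[1], pk[2]],
                 score[pk[1] + 1L, pk[2]])
  }
  if (pk[2] > 1L && pk[2] < ncol(score)) {
    dx <- refine(score[pk[1], pk[2] - 1L], score[pk[1], pk[2]],
                 score[pk[1], pk[2] + 1L])
  }
  x_px <- cx - 0.5 + offs[pk[2]] + dx
  y_px <- cy - 0.5 + offs[pk[1]] + dy
  # honour the sub-pixel offset the template was extracted with, if recorded
  cofs <- attr(template, "center_offset_um")
  if (is.null(cofs)) cofs <- c(0, 0)
  list(x_um = x_px * px + cofs[1], y_um = y_px * px + cofs[2],
       confidence = max(0, min(1, score[pk[1], pk[2]])), lost = FALSE)
}

#' Extract a template patch around a position
#'
#' Cuts a patch (polarity-corrected to bright tip) for the template tracker.
#'
#' @param frame a `tifm_frame`.
#' @param center_um position `c(x, y)` in um (y defaults to frame centre).
#' @param half_width_px patch half-width in pixels.
#' @return a `(2*half_width_px + 1)` square matrix.
#' @export
extract_template <- function(frame, center_um, half_width_px = 10) {
  img <- frame$pixels
  px <- frame$pixel_size_um
  if (identical(frame$channel, "brightfield")) img <- max(img) - img
  if (length(center_um) == 1L) center_um <- c(center_um, nrow(img) * px / 2)
  cx <- round(center_um[1] / px + 0.5)
  cy <- round(center_um[2] / px + 0.5)
  r <- half_width_px
  stopifnot(cx - r >= 1, cx + r <= ncol(img), cy - r >= 1, cy + r <= nrow(img))
  patch <- img[(cy - r):(cy + r), (cx - r):(cx + r)]
  # sub-pixel offset between the requested centre and the patch centre pixel
  attr(patch, "center_offset_um") <- c(center_um[1] - (cx - 0.5) * px,
                                       center_um[2] - (cy - 0.5) * px)
  patch
}

#' Track the tip through a movie
#'
#' Runs [locate_tip()] frame by frame, seeding each search with a
#' constant-velocity prediction from the previous fixes. Runs of up to
#' `max_gap` lost frames are bridged by constant-velocity interpolation
#' between the flanking fixes; longer runs stay lost. Traces losing more than
#' half their frames are flagged `quality_fail`.
#'
#' @param movie a `tifm_movie`.
#' @param initial_um starting position `c(x, y)` or scalar x (um), inside the
#'   first frame.
#' @param method `"centroid"` or `"template"`.
#' @param max_gap longest bridgeable run of lost frames.
#' @param template_half_width_px template patch half-width (template method).
#' @return a `tracked_trace`: data.frame with `time_s`, `x_um`, `y_um`,
#'   `confidence`, `lost`, `bridged`; attributes `method` and `quality_fail`.
#' @export
track_movie <- function(movie, initial_um, method = c("centroid", "template"),
                        max_gap = 3L, template_half_width_px = 10) {
  method <- match.arg(method)
  stopifnot(inherits(movie, "tifm_movie"), length(movie$frames) >= 1L)
  n <- length(movie$frames)
  px <- movie$frames[[1]]$pixel_size_um
  if (length(initial_um) == 1L) {
    initial_um <- c(initial_um, nrow(movie$frames[[1]]$pixels) * px / 2)
  }
  fx <- initial_um[1] / px
  if (fx < 0 || fx > ncol(movie$frames[[1]]$pixels)) {
    stop("initial position outside the first frame", call. = FALSE)
  }
  template <- if (method == "template") {
    extract_template(movie$frames[[1]], initial_um, template_half_width_px)
  }
  t_s <- vapply(movie$frames, `[[`, numeric(1), "time_s")
  x <- y <- conf <- rep(NA_real_, n)
  lost <- rep(TRUE, n)
  prev <- initial_um
  vel <- c(0, 0) # um per frame
  last_fix <- NA_integer_
  for (i in seq_len(n)) {
    gap_len <- if (is.na(last_fix)) 0L else i - last_fix - 1L
    prior <- prev + vel * (gap_len + 1L)
    fit <- locate_tip(movie$frames[[i]], prior_um = prior, method = method,
                      template = template)
    if (!fit$lost) {
      x[i] <- fit$x_um; y[i] <- fit$y_um; conf[i] <- fit$confidence
      lost[i] <- FALSE
      if (!is.na(last_fix)) {
        vel <- (c(x[i], y[i]) - prev) / (i - last_fix)
      }
      prev <- c(x[i], y[i])
      last_fix <- i
    }
  }
  bridged <- rep(FALSE, n)
  runs <- rle(lost)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    s <- starts[r]; e <- ends[r]
    if (e - s + 1L <= max_gap && s > 1L && e < n && !lost[s - 1L] && !lost[e + 1L]) {
      frac <- (t_s[s:e] - t_s[s - 1L]) / (t_s[e + 1L] - t_s[s - 1L])
      x[s:e] <- x[s - 1L] + frac * (x[e + 1L] - x[s - 1L])
      y[s:e] <- y[s - 1L] + frac * (y[e + 1L] - y[s - 1L])
      conf[s:e] <- 0.5 * (conf[s - 1L] + conf[e + 1L])
      bridged[s:e] <- TRUE
      lost[s:e] <- FALSE
    }
  }
  trace <- data.frame(time_s = t_s, x_um = x, y_um = y,
                      confidence = conf, lost = lost, bridged = bridged)
  attr(trace, "method") <- method
  attr(trace, "quality_fail") <- mean(lost) > 0.5
  class(trace) <- c("tracked_trace", "data.frame")
  trace
}

#' Mean intensity in a region of interest over a movie
#'
#' The fluorescence ROI mean is used as a relative cell-density proxy (e.g.
#' one ROI anterior and one posterior to the foil).
#'
#' @param movie a `tifm_movie`.
#' @param roi list with `x_um`, `y_um` (centre) and either `w_um`, `h_um`
#'   (rectangle) or `r_um` (disc).
#' @return data.frame with `frame`, `time_s`, `intensity` (arbitrary units).
#' @export
roi_mean_intensity <- function(movie, roi) {
  stopifnot(inherits(movie, "tifm_movie"))
  f1 <- movie$frames[[1]]
  px <- f1$pixel_size_um
  nr <- nrow(f1$pixels); nc <- ncol(f1$pixels)
  cols <- matrix(rep((seq_len(nc) - 0.5) * px, each = nr), nr)
  rows <- matrix(rep((seq_len(nr) - 0.5) * px, nc), nr)
  sel <- if (!is.null(roi$r_um)) {
    (cols - roi$x_um)^2 + (rows - roi$y_um)^2 <= roi$r_um^2
  } else {
    abs(cols - roi$x_um) <= roi$w_um / 2 & abs(rows - roi$y_um) <= roi$h_um / 2
  }
  if (!any(sel)) stop("ROI selects no pixels inside the field of view",
                      call. = FALSE)
  vals <- vapply(movie$frames, function(f) mean(f$pixels[sel]), numeric(1))
  data.frame(frame = seq_along(movie$frames),
             time_s = vapply(movie$frames, `[[`, numeric(1), "time_s"),
             intensity = vals)
}

#' Signed speeds over fixed intervals along an axis
#'
#' One signed speed per consecutive window: the cell displacement projected
#' on `axis` divided by the elapsed time, in um/h. The default axis
#' `c(0, 1)` is medial-to-lateral positive.
#'
#' @param track data.frame with `t_s`, `x_um`, `y_um` and optionally
#'   `cell_id` (speeds are computed per cell).
#' @param window_s interval length (s); default 300 (5 min).
#' @param axis length-2 unit vector (normalized internally).
#' @return data.frame with `cell_id`, `t_mid_s`, `speed_um_h` (zero rows when
#'   a track is shorter than one window).
#' @export
interval_speeds <- function(track, window_s = 300, axis = c(0, 1)) {
  stopifnot(all(c("t_s", "x_um", "y_um") %in% names(track)))
  axis <- axis / sqrt(sum(axis^2))
  if (is.null(track$cell_id)) track$cell_id <- 1L
  out <- lapply(split(track, track$cell_id), function(tr) {
    tr <- tr[order(tr$t_s), ]
    if (nrow(tr) < 2L) return(NULL)
    spacing <- stats::median(diff(tr$t_s))
    step <- max(1L, round(window_s / spacing))
    if (nrow(tr) <= step) return(NULL)
    i0 <- seq(1L, nrow(tr) - step, by = step)
    i1 <- i0 + step
    dt <- tr$t_s[i1] - tr$t_s[i0]
    proj <- (tr$x_um[i1] - tr$x_um[i0]) * axis[1] +
      (tr$y_um[i1] - tr$y_um[i0]) * axis[2]
    data.frame(cell_id = tr$cell_id[1],
               t_mid_s = (tr$t_s[i0] + tr$t_s[i1]) / 2,
               speed_um_h = proj / dt * 3600)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(cell_id = integer(0), t_mid_s = numeric(0),
                      speed_um_h = numeric(0))
  }
  rownames(out) <- NULL
  out
}
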