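#' Two-channel XY-T image stack
#'
#' @param green,red Integer arrays of dimension `c(ny, nx, nt)` (rows are
#'   y, columns x, slices time), in counts of a declared bit depth.
#' @param pixel_um Pixel size in micrometres.
#' @param dt_s Frame interval in seconds.
#' @param field Optional field label.
#' @param bit_depth Bit depth of the pixel values (default 16).
#' @return An object of class `"image_stack"`.
#' @export
image_stack <- function(green, red, pixel_um, dt_s, field = "field_1",
                        bit_depth = 16L) {
  if (!identical(dim(green), dim(red))) stop("channel shapes differ")
  if (length(dim(green)) != 3L) stop("expected a 3D (y, x, t) array")
  if (!is.numeric(pixel_um) || pixel_um <= 0) stop("pixel_um must be > 0")
  if (!is.numeric(dt_s) || dt_s <= 0) stop("dt_s must be > 0")
  storage.mode(green) <- "integer"
  storage.mode(red) <- "integer"
  structure(list(green = green, red = red, pixel_um = pixel_um, dt_s = dt_s,
                 field = field, bit_depth = as.integer(bit_depth)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$green)
  cat(sprintf("<image stack '%s': %d x %d px, %d frames, %.3g um/px, %.3g s/frame, %d-bit>\n",
              x$field, d[2L], d[1L], d[3L], x$pixel_um, x$dt_s, x$bit_depth))
  invisible(x)
}

#' Render a two-channel image stack from tracks and seeded transients
#'
#' Rasterizes simulated recordings: the red channel holds Gaussian cell
#' footprints following track positions; the green channel holds a dim
#' per-cell baseline plus Gaussian event blobs with a rectangular temporal
#' profile; stationary bright blobs appear in both channels at
#' `n_autofluorescent` fixed sites. Shot noise is approximated per the
#' generator's noise model (Gaussian with variance equal to the mean above
#' 20 counts, Poisson below), and pixels are integer-valued 16-bit counts.
#'
#' Event blobs are scaled so that the area enclosed by the half-maximum
#' contour equals the requested `area_um2`; with the default amplitude
#' convention (peak amplitude twice the detection margin) the
#' suprathreshold footprint of a detected event matches its nominal area.
#'
#' @param tracks A [track_set()] or `NULL` for a cell-free field.
#' @param events Data frame of seeded transients with columns `x_um`,
#'   `y_um`, `t_start_s`, `duration_s`, `area_um2`, `amplitude` (peak
#'   counts above local background) and optionally `class`; `NULL` for
#'   none.
#' @param pixel_um Pixel size (default 0.65 um, fast-imaging geometry).
#' @param dt_s Frame interval (default 0.5 s).
#' @param size_px Field size in pixels, `c(nx, ny)` (default 462, a
#'   300 um x 300 um field at 0.65 um/px).
#' @param duration_s Recording length in seconds (default 300).
#' @param n_autofluorescent Number of stationary bright bodies.
#' @param background Background offset counts in both channels (default 100).
#' @param cell_red_amp Peak red counts of a cell footprint (default 400).
#' @param cell_green_amp Peak baseline green counts of a cell (default 20).
#' @param cell_radius_um Gaussian sigma of a cell footprint (default 2.5).
#' @param noise Add shot noise (default `TRUE`).
#' @param seed RNG seed.
#' @return List with `stack` (an [image_stack()]) and `truth` (the event
#'   table augmented with pixel coordinates, plus autofluorescent sites).
#' @export
render_image_stack <- function(tracks = NULL, events = NULL, pixel_um = 0.65,
                               dt_s = 0.5, size_px = c(462L, 462L),
                               duration_s = 300, n_autofluorescent = 0L,
                               background = 100, cell_red_amp = 400,
                               cell_green_amp = 20, cell_radius_um = 2.5,
                               noise = TRUE, seed = 1L) {
  nx <- as.integer(size_px[[1L]])
  ny <- as.integer(size_px[[if (length(size_px) > 1L) 2L else 1L]])
  nt <- as.integer(floor(duration_s / dt_s))
  if (nt < 1L) stop("duration shorter than one frame")
  sigma_cell_px <- cell_radius_um / pixel_um
  if (4 * sigma_cell_px > min(nx, ny)) stop("field smaller than one cell footprint")
  set.seed(as.integer(seed))
  frame_t <- (seq_len(nt) - 1L) * dt_s

  if (!is.null(events) && nrow(events)) {
    ev <- as.data.frame(events)
    need <- c("x_um", "y_um", "t_start_s", "duration_s", "area_um2", "amplitude")
    if (!all(need %in% names(ev))) {
      stop("events must have columns ", paste(need, collapse = ", "))
    }
    if (any(ev$x_um < 0 | ev$x_um > nx * pixel_um |
            ev$y_um < 0 | ev$y_um > ny * pixel_um)) {
      stop("events lie outside the field")
    }
    if (any(ev$t_start_s < 0 | ev$t_start_s + ev$duration_s > duration_s + dt_s)) {
      stop("events lie outside the recording")
    }
    # half-maximum contour of the Gaussian blob encloses area_um2
    ev$sigma_px <- sqrt(ev$area_um2 / pi) / sqrt(2 * log(2)) / pixel_um
  } else {
    ev <- NULL
  }

  af <- NULL
  if (n_autofluorescent > 0L) {
    af <- data.frame(x_px = stats::runif(n_autofluorescent, 5, nx - 5),
                     y_px = stats::runif(n_autofluorescent, 5, ny - 5),
                     sigma_px = 2 / pixel_um / 2,
                     amp = 500)
  }

  # static per-frame base image for autofluorescent bodies
  af_img <- matrix(0, ny, nx)
  if (!is.null(af)) {
    for (j in seq_len(nrow(af))) {
      af_img <- add_blob(af_img, af$x_px[j], af$y_px[j], af$sigma_px[j], af$amp[j])
    }
  }

  green <- array(0L, c(ny, nx, nt))
  red <- array(0L, c(ny, nx, nt))
  maxval <- 65535L
  for (k in seq_len(nt)) {
    g <- matrix(background, ny, nx) + af_img
    r <- matrix(background, ny, nx) + af_img
    if (!is.null(tracks)) {
      for (tr in tracks) {
        fi <- which.min(abs(tr$t_s - frame_t[k]))
        if (abs(tr$t_s[fi] - frame_t[k]) > stats::median(diff(tr$t_s))) next
        x_px <- tr$pos_um[fi, 1L] / pixel_um
        y_px <- tr$pos_um[fi, 2L] / pixel_um
        r <- add_blob(r, x_px, y_px, sigma_cell_px, cell_red_amp)
        g <- add_blob(g, x_px, y_px, sigma_cell_px, cell_green_amp)
      }
    }
    if (!is.null(ev)) {
      live <- which(frame_t[k] >= ev$t_start_s &
                    frame_t[k] < ev$t_start_s + ev$duration_s)
      for (j in live) {
        g <- add_blob(g, ev$x_um[j] / pixel_um, ev$y_um[j] / pixel_um,
                      ev$sigma_px[j], ev$amplitude[j])
      }
    }
    if (noise) {
      g <- add_shot_noise(g)
      r <- add_shot_noise(r)
    }
    green[, , k] <- pmin(as.integer(round(g)), maxval)
    red[, , k] <- pmin(as.integer(round(r)), maxval)
  }
  truth <- list(events = ev, autofluorescent = af)
  list(stack = image_stack(green, red, pixel_um, dt_s), truth = truth)
}

# Add a Gaussian blob (peak `amp`) centred at 0-based pixel coordinates
# (x_px, y_px) into image `img` (rows y, cols x), within a +-4 sigma patch.
add_blob <- function(img, x_px, y_px, sigma_px, amp) {
  ny <- nrow(img); nx <- ncol(img)
  hw <- max(2L, ceiling(4 * sigma_px))
  xlo <- max(1L, floor(x_px + 1 - hw)); xhi <- min(nx, ceiling(x_px + 1 + hw))
  ylo <- max(1L, floor(y_px + 1 - hw)); yhi <- min(ny, ceiling(y_px + 1 + hw))
  if (xlo > xhi || ylo > yhi) return(img)  # blob entirely outside the field
  xs <- xlo:xhi
  ys <- ylo:yhi
  gx <- exp(-((xs - 1) - x_px)^2 / (2 * sigma_px^2))
  gy <- exp(-((ys - 1) - y_px)^2 / (2 * sigma_px^2))
  img[ys, xs] <- img[ys, xs] + amp * outer(gy, gx)
  img
}

# Shot-noise model: Gaussian with variance = mean above 20 counts, Poisson
# below (cheap but realistic for 16-bit detector counts).
add_shot_noise <- function(img) {
  hi <- img > 20
  out <- img
  out[hi] <- img[hi] + stats::rnorm(sum(hi), sd = sqrt(img[hi]))
  if (any(!hi)) out[!hi] <- stats::rpois(sum(!hi), lambda = pmax(img[!hi], 0))
  pmax(out, 0)
}
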