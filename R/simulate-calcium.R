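#' Simulate Salsa6f green/red fluorescence series for simulated tracks
#'
#' The red (tdTomato) series declines linearly by `bleach_fraction` over
#' the recording with multiplicative noise. The green (GCaMP6f) series is a
#' flat dim baseline (only tdTomato bleaches appreciably, so the raw G/R
#' ratio drifts upward until the red trend is corrected) plus transient
#' terms: for each pause selected with
#' probability `ca_coupled_fraction`, a flat-topped global transient whose
#' peak precedes the pause's velocity minimum by `ca_lead_s` and whose
#' elevation tracks the pause duration; plus brief Gaussian sparkle
#' transients at `sparkle_rate_per_cell_min`, uncoupled to motility. The
#' true peak normalized ratio of a transient is `1 + transient_amplitude`.
#'
#' @param sim A `"sim_result"` from [simulate_tracks()] (its `tracks` and
#'   `truth` must belong together).
#' @param config Optional [sim_config()]; defaults to `sim$config`.
#' @return The `"sim_result"` with green/red series attached to each track
#'   and `truth$events` added: a data frame with `cell_id`, `class`
#'   (`"cell_wide"` or `"sparkle"`), `onset_s`, `peak_s`, `duration_s`,
#'   `area_um2`, `x_um`, `y_um`, `amplitude`, `pause_start_s`.
#' @export
simulate_calcium <- function(sim, config = NULL) {
  if (!inherits(sim, "sim_result")) stop("sim must come from simulate_tracks()")
  config <- config %||% sim$config
  stopifnot(inherits(config, "sim_config"))
  ts <- sim$tracks
  ids <- vapply(ts, `[[`, character(1), "cell_id")
  if (!identical(sort(ids), sort(names(sim$truth$states)))) {
    stop("track/truth mismatch: cell ids disagree")
  }
  edge <- config$dt_s  # smoothstep edge width of global transients
  g_baseline <- 50     # arbitrary units; ratio analysis is scale free
  r_baseline <- 500
  tracks <- vector("list", length(ts))
  events <- list()
  for (i in seq_along(ts)) {
    tr <- ts[[i]]
    set.seed(cell_seed(config$seed, i) + 1L)
    t <- tr$t_s
    Tdur <- max(t)
    shape <- 1 - config$bleach_fraction * t / Tdur
    v <- instantaneous_velocities(tr)
    w <- numeric(length(t))
    # pause-coupled global transients
    pz <- sim$truth$pauses
    pz <- pz[pz$cell_id == tr$cell_id, , drop = FALSE]
    if (nrow(pz)) {
      coupled <- stats::runif(nrow(pz)) < config$ca_coupled_fraction
      for (j in which(coupled)) {
        # velocity minimum within the pause (by construction at its onset)
        step_t <- t[-length(t)]
        in_pause <- step_t >= pz$start_s[j] & step_t < pz$end_s[j]
        t_min <- step_t[in_pause][which.min(v[in_pause])]
        peak <- t_min - config$ca_lead_s
        wf <- flat_top_wave(t, peak, pz$end_s[j], edge)
        w <- pmax(w, config$transient_amplitude * wf)
        pk_frame <- which.min(abs(t - peak))
        events[[length(events) + 1L]] <- data.frame(
          cell_id = tr$cell_id, class = "cell_wide",
          onset_s = peak - edge, peak_s = peak,
          duration_s = (pz$end_s[j] - peak) + edge,
          area_um2 = 40,
          x_um = tr$pos_um[pk_frame, 1L], y_um = tr$pos_um[pk_frame, 2L],
          amplitude = config$transient_amplitude,
          pause_start_s = pz$start_s[j], stringsAsFactors = FALSE)
      }
    }
    # uncoupled sparkles, Poisson in time
    n_sp <- stats::rpois(1, config$sparkle_rate_per_cell_min * Tdur / 60)
    if (n_sp > 0) {
      sd_t <- config$sparkle_duration_s / 2.355  # FWHM -> Gaussian sd
      for (tc in stats::runif(n_sp, 0, Tdur)) {
        w <- pmax(w, config$transient_amplitude * exp(-(t - tc)^2 / (2 * sd_t^2)))
        pk_frame <- which.min(abs(t - tc))
        events[[length(events) + 1L]] <- data.frame(
          cell_id = tr$cell_id, class = "sparkle",
          onset_s = tc - config$sparkle_duration_s / 2, peak_s = tc,
          duration_s = config$sparkle_duration_s,
          area_um2 = config$sparkle_area_um2 * stats::rlnorm(1, sdlog = 0.2),
          x_um = tr$pos_um[pk_frame, 1L], y_um = tr$pos_um[pk_frame, 2L],
          amplitude = config$transient_amplitude,
          pause_start_s = NA_real_, stringsAsFactors = FALSE)
      }
    }
    noise <- function(n) {
      if (config$trace_noise_cv > 0) {
        1 + stats::rnorm(n, sd = config$trace_noise_cv)
      } else rep(1, n)
    }
    # only tdTomato bleaches appreciably; GCaMP6f baseline stays flat, so
    # the raw G/R ratio drifts up by 1/(1 - bleach_fraction) over the
    # recording and flattens once the red trend is corrected
    R <- r_baseline * shape * noise(length(t))
    G <- g_baseline * (1 + w) * noise(length(t))
    tracks[[i]] <- track(tr$cell_id, tr$t_s, tr$pos_um, green = G, red = R)
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(cell_id = character(0), class = character(0), onset_s = numeric(0),
               peak_s = numeric(0), duration_s = numeric(0), area_um2 = numeric(0),
               x_um = numeric(0), y_um = numeric(0), amplitude = numeric(0),
               pause_start_s = numeric(0), stringsAsFactors = FALSE)
  sim$tracks <- track_set(tracks, group = attr(ts, "group"))
  sim$truth$events <- ev
  sim
}

# Flat-topped waveform: smoothstep rise over [peak - edge, peak], plateau at
# 1 until t_end, smoothstep fall over [t_end, t_end + edge].
flat_top_wave <- function(t, peak, t_end, edge) {
  s <- function(x) {
    x <- pmin(1, pmax(0, x))
    x * x * (3 - 2 * x)
  }
  up <- s((t - (peak - edge)) / edge)
  down <- 1 - s((t - t_end) / edge)
  pmin(up, down)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
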