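#' Simulate stop-and-go persistent-random-walk tracks
#'
#' Each cell alternates between two states. In GO the heading performs a
#' persistent random walk (heading decorrelation time `persistence_s`) at a
#' per-cell speed drawn around `mean_speed_um_min` with coefficient of
#' variation `speed_cv`. Pauses are entered as a Poisson process at
#' `pause_rate_per_min` and exited after an exponential dwell with mean
#' `pause_mean_s`; during a pause the cell jitters at under 1 um/min, with
#' the slowest step pinned to the first pause frame so every pause has a
#' well-defined velocity minimum at its onset. Positions are sampled every
#' `dt_s` seconds.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_result"` with elements
#'   \describe{
#'     \item{tracks}{a [track_set()] of `n_cells` tracks;}
#'     \item{truth}{ground truth: `pauses` (data frame `cell_id`,
#'       `start_s`, `end_s`, `duration_s`), `states` (per-cell character
#'       vectors, one state per step, `"go"` or `"pause"`), and
#'       `speeds_um_min` (per-cell intended step speeds);}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_steps <- floor(config$duration_s / config$dt_s)
  n_frames <- n_steps + 1L
  dt <- config$dt_s
  t_s <- seq(0, by = dt, length.out = n_frames)
  p_enter <- 1 - exp(-(config$pause_rate_per_min / 60) * dt)
  p_exit <- 1 - exp(-dt / config$pause_mean_s)
  sdlog <- sqrt(log(1 + config$speed_cv^2))
  kappa <- if (config$dim == 3L && is.finite(config$persistence_s)) {
    vmf_kappa(exp(-dt / max(config$persistence_s, 1e-12)))
  } else NULL

  tracks <- vector("list", config$n_cells)
  states <- vector("list", config$n_cells)
  speeds <- vector("list", config$n_cells)
  pauses <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    set.seed(cell_seed(config$seed, i))
    cid <- sprintf("cell_%03d", i)
    v_cell <- config$mean_speed_um_min *
      stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    st <- character(n_steps)
    sp <- numeric(n_steps)
    pos <- matrix(0, n_frames, config$dim)
    pos[1L, ] <- stats::runif(config$dim, 0, 100)
    head <- random_unit(config$dim)
    state <- "go"
    just_entered <- FALSE
    for (k in seq_len(n_steps)) {
      if (state == "go" && config$pause_rate_per_min > 0 &&
          stats::runif(1) < p_enter) {
        state <- "pause"; just_entered <- TRUE
      } else if (state == "pause" && stats::runif(1) < p_exit) {
        state <- "go"
        # pauses coincide with turning: motion resumes in a fresh direction,
        # so more pausing means faster directionality decay and sharper turns
        head <- random_unit(config$dim)
      }
      st[k] <- state
      if (state == "go") {
        head <- perturb_heading(head, dt, config$persistence_s, kappa)
        sp[k] <- v_cell
        step_dir <- head
      } else {
        # pause jitter in [0, 1] um/min; the entry step is the slowest so
        # the pause's velocity minimum sits at its first frame
        sp[k] <- if (just_entered) stats::runif(1, 0, 0.05) else stats::runif(1, 0.1, 1)
        just_entered <- FALSE
        step_dir <- random_unit(config$dim)
      }
      pos[k + 1L, ] <- pos[k, ] + step_dir * (sp[k] / 60) * dt
    }
    tracks[[i]] <- track(cid, t_s, pos)
    states[[i]] <- st
    speeds[[i]] <- sp
    pauses[[i]] <- pause_truth(cid, st, t_s)
  }
  names(states) <- names(speeds) <- vapply(tracks, `[[`, character(1), "cell_id")
  truth <- list(pauses = do.call(rbind, pauses), states = states,
                speeds_um_min = speeds)
  if (is.null(truth$pauses)) {
    truth$pauses <- data.frame(cell_id = character(0), start_s = numeric(0),
                               end_s = numeric(0), duration_s = numeric(0),
                               stringsAsFactors = FALSE)
  }
  structure(list(tracks = track_set(tracks), truth = truth, config = config),
            class = "sim_result")
}

# Pause intervals from a per-step state sequence. Step k covers
# [t_s[k], t_s[k + 1]); a pause of m consecutive steps starting at step k
# spans [t_s[k], t_s[k + m]].
pause_truth <- function(cell_id, states, t_s) {
  r <- rle(states == "pause")
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  data.frame(cell_id = cell_id,
             start_s = t_s[starts[idx]],
             end_s = t_s[ends[idx] + 1L],
             duration_s = t_s[ends[idx] + 1L] - t_s[starts[idx]],
             stringsAsFactors = FALSE)
}

random_unit <- function(dim) {
  v <- stats::rnorm(dim)
  v / sqrt(sum(v^2))
}

# One heading-update step of the persistent random walk. In 2D the heading
# angle receives Gaussian noise of variance 2 * dt / persistence, giving
# <cos(theta(t) - theta(0))> = exp(-t / persistence) exactly. In 3D the new
# heading is drawn from a von Mises-Fisher distribution around the old one
# whose concentration is chosen so the per-step correlation is exactly
# exp(-dt / persistence); successive rotations are independent and
# azimuthally symmetric, so the heading autocorrelation is exactly
# exponential in every regime, including the Brownian limit.
perturb_heading <- function(head, dt, persistence_s, kappa = NULL) {
  if (!is.finite(persistence_s)) return(head)
  if (length(head) == 2L) {
    if (persistence_s <= 0) return(random_unit(2L))
    ang <- atan2(head[2L], head[1L]) +
      stats::rnorm(1, sd = sqrt(2 * dt / persistence_s))
    c(cos(ang), sin(ang))
  } else {
    if (is.null(kappa)) kappa <- vmf_kappa(exp(-dt / max(persistence_s, 1e-12)))
    if (!is.finite(kappa)) return(head)
    if (kappa <= 0) return(random_unit(3L))
    # Ulrich/Wood sampler, d = 3
    u <- stats::runif(1)
    w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
    w <- min(1, max(-1, w))
    phi <- stats::runif(1, 0, 2 * pi)
    # orthonormal basis perpendicular to head
    a <- if (abs(head[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * head) * head
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(head[2L] * e1[3L] - head[3L] * e1[2L],
            head[3L] * e1[1L] - head[1L] * e1[3L],
            head[1L] * e1[2L] - head[2L] * e1[1L])
    w * head + sqrt(max(0, 1 - w^2)) * (cos(phi) * e1 + sin(phi) * e2)
  }
}

# Concentration of a 3D von Mises-Fisher whose mean resultant
# (Langevin function coth(k) - 1/k) equals the target correlation rho.
vmf_kappa <- function(rho) {
  if (rho <= 0) return(0)
  if (rho >= 1 - 1e-12) return(Inf)
  f <- function(k) 1 / tanh(k) - 1 / k - rho
  stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-12)$root
}
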