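# Synthetic ganglion-cell populations and spike-train simulation.
#
# The generative model mirrors, factor by factor, the seven measured response
# parameters: polarity gates which stimulus transitions drive the cell, an
# isotropic Gaussian receptive field sets the spatial gain, a calibrated
# rise-decay temporal kernel sets latency and transience, log-Gaussian speed
# and width tunings set the preferred-speed/width indices, and a von
# Mises-shaped direction gain sets the DS index. Spiking is inhomogeneous
# Poisson with an optional absolute refractory period.

# Gaussian receptive-field SD as a fraction of the nominal diameter, chosen so
# the 33%-of-maximum contour of the noiseless response profile has the nominal
# diameter: d = 2 * sigma * sqrt(2 * log(3)).
RF_SIGMA_FACTOR <- 1 / (2 * sqrt(2 * log(3)))

# The mapping procedure broadens the measured field: the 100 um square
# convolves the map with its footprint and the 9x bilinear upsampling widens
# narrow peaks. The generator SD is therefore calibrated numerically against
# the full estimator -- a noiseless response map is built on the 9x9 grid,
# run through receptive_field(), and the SD producing a measured diameter
# equal to the nominal one is found by inverting a phase-averaged
# calibration curve (cached per session).
rf_sigma_env <- new.env(parent = emptyenv())

measured_map_diameter <- function(sigma, map_side = 100) {
  centers <- seq(50, 850, by = 100)
  phases <- rbind(c(0, 0), c(50, 0), c(0, 50), c(25, 25), c(50, 50))
  mean(apply(phases, 1, function(ph) {
    g <- outer(centers, centers, function(y, x) {
      square_gain(x, y, map_side, 450 + ph[1], 450 + ph[2], sigma)
    })
    receptive_field(g, centers, centers)$diameter
  }))
}

rf_sigma_from_diameter <- function(diameter) {
  curve <- rf_sigma_env$inverse
  if (is.null(curve)) {
    sig <- seq(22, 175, by = 8.5)
    d_meas <- vapply(sig, measured_map_diameter, numeric(1))
    stopifnot(all(diff(d_meas) > 0))
    curve <- stats::splinefun(d_meas, sig, method = "hyman")
    rf_sigma_env$inverse <- curve
    rf_sigma_env$range <- range(d_meas)
  }
  rng <- rf_sigma_env$range
  pmax(curve(pmin(pmax(diameter, rng[1]), rng[2])), 20)
}

# ON/OFF gain asymmetry for ON_OFF cells: the ON lobe is slightly dominant so
# the larger-peak rule picks the ON window deterministically.
ONOFF_OFF_GAIN <- 1 / 1.1

#' Default ganglion-cell archetype table
#'
#' One row per functional type the pipeline is designed to recover: OFF brisk
#' transient, OFF sluggish transient, ON-OFF brisk transient, ON-OFF sluggish
#' sustained, ON-OFF DS, ON brisk transient and ON DS. Latency means follow
#' the brisk/sluggish naming (0.12 s vs 0.30 s); transience targets follow
#' transient/sustained (0.15 vs 0.25, see the methods vignette for why the
#' sustained target is bounded by the 1 s polarity window); the two DS types
#' use a von Mises concentration of 1.5, giving a noiseless DS index of about
#' 0.6 over eight directions. These defaults are artifacts of this package,
#' used for property-based and recovery tests; they are not measured values.
#'
#' @return A tibble with one row per archetype and columns `name`, `polarity`
#'   (`"ON"`, `"OFF"` or `"ON_OFF"`), `latency_mean`, `latency_sd` (s),
#'   `transience_target` (dimensionless in (0, 1]), `is_ds`,
#'   `ds_concentration`, `preferred_direction` (deg; `NA` = randomized per
#'   cell), `speed_pref`, `speed_bw`, `width_pref`, `width_bw` (um/s, log
#'   units, um, log units), `rf_diameter_mean`, `rf_diameter_sd` (um),
#'   `peak_rate`, `baseline_rate` (Hz).
#' @examples
#' rgc_archetypes()
#' @export
rgc_archetypes <- function() {
  tibble::tribble(
    ~name,                       ~polarity, ~latency_mean, ~transience_target, ~is_ds, ~ds_concentration, ~speed_pref, ~width_pref,
    "OFF brisk transient",       "OFF",     0.12,          0.15,               FALSE,  0,                 900,         300,
    "OFF sluggish transient",    "OFF",     0.30,          0.15,               FALSE,  0,                 300,         300,
    "ON-OFF brisk transient",    "ON_OFF",  0.12,          0.15,               FALSE,  0,                 900,         600,
    "ON-OFF sluggish sustained", "ON_OFF",  0.30,          0.25,               FALSE,  0,                 300,         600,
    "ON-OFF DS",                 "ON_OFF",  0.15,          0.20,               TRUE,   1.5,               600,         300,
    "ON brisk transient",        "ON",      0.12,          0.15,               FALSE,  0,                 900,         300,
    "ON DS",                     "ON",      0.20,          0.20,               TRUE,   1.5,               450,         300
  ) |>
    dplyr::mutate(
      latency_sd = 0.015,
      preferred_direction = NA_real_,
      speed_bw = 0.7, width_bw = 1.2,
      rf_diameter_mean = 270, rf_diameter_sd = 60,
      peak_rate = 60, baseline_rate = 0.2
    )
}

# ---- temporal kernel -------------------------------------------------------

# Peak-normalized rise-decay kernel: K(t) = c (1 - exp(-t/tau_r)) exp(-t/tau_d)
# for t >= 0, zero before. The saturating rise (tau_r fixed, 20 ms) gives a
# smooth onset; the decay constant tau_d is calibrated per archetype so the
# measured transience index of a noiseless PSTH equals the archetype target.

kernel_peak_time <- function(tau_r, tau_d) tau_r * log((tau_r + tau_d) / tau_r)

kernel_peak_value <- function(tau_r, tau_d) {
  ts <- kernel_peak_time(tau_r, tau_d)
  (1 - exp(-ts / tau_r)) * exp(-ts / tau_d)
}

# K evaluated at times t (t < 0 -> 0), peak normalized to 1
kernel_eval <- function(t, tau_r, tau_d) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (1 - exp(-t[pos] / tau_r)) * exp(-t[pos] / tau_d) /
    kernel_peak_value(tau_r, tau_d)
  out
}

# integral of the peak-normalized kernel over [a, b] (clamped at 0)
kernel_integral <- function(tau_r, tau_d, a, b) {
  a <- pmax(a, 0)
  b <- pmax(b, 0)
  rate_sum <- 1 / tau_r + 1 / tau_d
  raw <- function(x) {
    -tau_d * exp(-x / tau_d) + exp(-x * rate_sum) / rate_sum
  }
  (raw(b) - raw(a)) / kernel_peak_value(tau_r, tau_d)
}

# Noiseless measured transience for a flashing-square response: model PSTH
# over the 1.5 s polarity window, peak-normalized, integrated, divided by 1.5.
# ON_OFF cells are measured in the ON window, which also contains the partial
# OFF lobe arriving at square offset (bright phase length `phase`).
model_transience <- function(tau_d, latency, polarity, tau_r = 0.02,
                             phase = 1, bin = 0.005) {
  t <- seq(bin / 2, 1.5 - bin / 2, by = bin)
  t0 <- latency - kernel_peak_time(tau_r, tau_d)
  rate <- kernel_eval(t - t0, tau_r, tau_d)
  if (polarity == "ON_OFF") {
    rate <- rate + ONOFF_OFF_GAIN * kernel_eval(t - t0 - phase, tau_r, tau_d)
  }
  sum(rate / max(rate)) * bin / 1.5
}

#' Calibrate the temporal decay constant of an archetype
#'
#' Root-finds the kernel decay constant so that the transience index measured
#' on a noiseless flashing-square PSTH (1.5 s window, 5 ms bins,
#' peak-normalized) equals `transience_target`. This is the calibration
#' contract that makes parameter recovery well-posed.
#'
#' @param latency Kernel peak delay (s).
#' @param transience_target Target measured transience in (0, 1].
#' @param polarity `"ON"`, `"OFF"` or `"ON_OFF"` (the ON window of an ON_OFF
#'   cell also contains the partial OFF lobe).
#' @param tau_r Rise time constant (s).
#' @return Decay constant `tau_d` (s).
#' @export
calibrate_tau_d <- function(latency, transience_target, polarity = "ON",
                            tau_r = 0.02) {
  check_number(transience_target, "transience_target", lower = 1e-3, upper = 1)
  f <- function(td) {
    model_transience(td, latency, polarity, tau_r) - transience_target
  }
  upper <- 50
  if (f(upper) < 0) {
    stop(sprintf(
      "transience target %.3g is not attainable with latency %.3g s: the 1.5 s measurement window caps the measured index at %.3g",
      transience_target, latency, model_transience(upper, latency, polarity, tau_r)),
      call. = FALSE)
  }
  stats::uniroot(f, c(1e-3, upper), tol = 1e-6)$root
}

# ---- population sampling ---------------------------------------------------

#' Sample a synthetic ganglion-cell population
#'
#' Draws `n_per_archetype` cells per archetype row: receptive-field centres
#' uniform over the field (optionally inset by `margin`), latency and RF
#' diameter from truncated Gaussians, and, for DS archetypes without a fixed
#' `preferred_direction`, a uniform random preferred direction. The kernel
#' decay constant is calibrated once per archetype at its mean latency.
#'
#' @param archetypes Archetype table as from [rgc_archetypes()].
#' @param n_per_archetype Cells per archetype (>= 1).
#' @param field A [field_geometry()].
#' @param seed Integer seed; the population is bit-reproducible given
#'   `(seed, inputs)`.
#' @param margin Inset (um) applied to the placement rectangle on every side.
#' @param tau_r Kernel rise time constant (s).
#' @return A tibble with one row per cell: identifiers, archetype fields as
#'   sampled, `rf_x`, `rf_y`, `rf_sigma`, and the calibrated `tau_d`.
#' @examples
#' pop <- sample_population(n_per_archetype = 2, seed = 1)
#' nrow(pop)
#' @export
sample_population <- function(archetypes = rgc_archetypes(),
                              n_per_archetype = 40,
                              field = field_geometry(), seed = 0,
                              margin = 0, tau_r = 0.02) {
  if (nrow(archetypes) == 0) stop("`archetypes` must be non-empty", call. = FALSE)
  check_number(n_per_archetype, "n_per_archetype", lower = 1)
  tau_d <- vapply(seq_len(nrow(archetypes)), function(i) {
    calibrate_tau_d(archetypes$latency_mean[i], archetypes$transience_target[i],
                    archetypes$polarity[i], tau_r)
  }, numeric(1))
  with_seed(seed, {
    cells <- purrr::map_dfr(seq_len(nrow(archetypes)), function(i) {
      a <- archetypes[i, ]
      n <- n_per_archetype
      pd <- if (a$is_ds) {
        if (is.na(a$preferred_direction)) stats::runif(n, 0, 360)
        else rep(a$preferred_direction, n)
      } else rep(NA_real_, n)
      tibble::tibble(
        archetype = a$name, polarity = a$polarity,
        rf_x = stats::runif(n, field$origin[1] + margin,
                            field$origin[1] + field$width - margin),
        rf_y = stats::runif(n, field$origin[2] + margin,
                            field$origin[2] + field$height - margin),
        latency = pmax(0.02, stats::rnorm(n, a$latency_mean, a$latency_sd)),
        transience_target = a$transience_target,
        rf_diameter = pmax(120, stats::rnorm(n, a$rf_diameter_mean,
                                             a$rf_diameter_sd)),
        is_ds = a$is_ds, ds_concentration = a$ds_concentration,
        preferred_direction = pd,
        speed_pref = a$speed_pref, speed_bw = a$speed_bw,
        width_pref = a$width_pref, width_bw = a$width_bw,
        peak_rate = a$peak_rate, baseline_rate = a$baseline_rate,
        tau_r = tau_r, tau_d = tau_d[i]
      )
    })
    cells$rf_sigma <- rf_sigma_from_diameter(cells$rf_diameter)
    cells$cell_id <- seq_len(nrow(cells))
    dplyr::relocate(cells, "cell_id")
  })
}

# ---- stimulus drive --------------------------------------------------------

# overlap of a square footprint with a unit-peak Gaussian RF (product of
# per-axis cumulative overlaps, normalized so a point stimulus at the RF
# centre would give 1; a centred 100 um square on a 270 um RF gives ~0.3)
square_gain <- function(cx, cy, side, rf_x, rf_y, sigma) {
  gx <- stats::pnorm((cx + side / 2 - rf_x) / sigma) -
    stats::pnorm((cx - side / 2 - rf_x) / sigma)
  gy <- stats::pnorm((cy + side / 2 - rf_y) / sigma) -
    stats::pnorm((cy - side / 2 - rf_y) / sigma)
  gx * gy
}

# von Mises-shaped direction gain, 1 at the preferred direction
direction_gain <- function(direction_deg, preferred_deg, kappa) {
  exp(kappa * (cos(deg2rad(direction_deg - preferred_deg)) - 1))
}

# log-Gaussian tuning, 1 at the preferred value
log_tuning <- function(value, pref, bw) {
  exp(-(log(value / pref))^2 / (2 * bw^2))
}

#' Closed-form DS index implied by a von Mises direction gain
#'
#' Evaluates the vector-average DS index of the direction-gain profile itself
#' over `n_dir` equally spaced directions, with the preferred direction offset
#' `phase` degrees from the nearest sampled direction. Used as the generator's
#' ground-truth DSI in recovery tests.
#'
#' @param kappa von Mises concentration (>= 0).
#' @param n_dir Number of equally spaced sampled directions.
#' @param phase Offset of the preferred direction from the direction grid
#'   (deg).
#' @return DS index in [0, 1].
#' @export
ds_index_von_mises <- function(kappa, n_dir = 8, phase = 0) {
  dirs <- seq(0, 360 - 360 / n_dir, length.out = n_dir)
  g <- direction_gain(dirs, phase, kappa)
  ds_index(g, dirs)
}

#' Stimulus-driven firing-rate function of one synthetic cell
#'
#' Builds the piecewise rate function lambda(t) = baseline + sum of
#' kernel-shaped response components, one component per driving stimulus
#' transition. ON cells are driven at positive-contrast onsets (square
#' appearance, bright-bar leading edge, dark-bar trailing edge), OFF cells at
#' negative-contrast onsets (square disappearance, dark-bar leading edge,
#' bright-bar trailing edge), ON_OFF cells at both with a slightly dominant ON
#' lobe. Component peak rate is
#' `peak_rate * G_spatial * S(speed) * W(width) * D(direction)`.
#'
#' @param cell One-row tibble (a [sample_population()] row).
#' @param events A `stimulus_set`.
#' @param geometry Field geometry (defaults to the one stored on `events`).
#' @param min_gain Components with peak rate below `min_gain` Hz are dropped.
#' @return A `rate_fn` object: a tibble of components (`event_index`, `t0` =
#'   kernel start time, `gain` in Hz, `lobe`) with attributes `baseline`,
#'   `tau_r`, `tau_d`, `cell_id`.
#' @export
drive_cell <- function(cell, events, geometry = NULL, min_gain = 1e-4) {
  geometry <- geometry %||% attr(events, "geometry") %||% field_geometry()
  ev <- tibble::as_tibble(events)
  ts <- kernel_peak_time(cell$tau_r, cell$tau_d)
  rel_x <- cell$rf_x - field_center(geometry)[1]
  rel_y <- cell$rf_y - field_center(geometry)[2]
  comp <- vector("list", 2L)

  sq <- ev[ev$kind == "square", , drop = FALSE]
  if (nrow(sq) > 0) {
    g <- cell$peak_rate *
      square_gain(sq$center_x, sq$center_y, sq$bar_width,
                  cell$rf_x, cell$rf_y, cell$rf_sigma)
    phase <- (sq$offset_s - sq$onset_s) / 2
    on_t <- ifelse(sq$contrast > 0, sq$onset_s, sq$onset_s + phase)
    off_t <- ifelse(sq$contrast > 0, sq$onset_s + phase, sq$onset_s)
    comp[[1]] <- tibble::tibble(
      event_index = rep(sq$event_index, 2L),
      stim_time = c(on_t, off_t),
      gain = c(g, g),
      lobe = rep(c("ON", "OFF"), each = nrow(sq))
    )
  }

  br <- ev[ev$kind == "bar", , drop = FALSE]
  if (nrow(br) > 0) {
    u <- dir_unit(br$direction_deg)
    along <- u[, 1] * rel_x + u[, 2] * rel_y
    lateral <- -u[, 2] * rel_x + u[, 1] * rel_y - br$offset
    extent <- travel_extent(geometry)
    g_lat <- stats::pnorm((br$bar_length / 2 - lateral) / cell$rf_sigma) -
      stats::pnorm((-br$bar_length / 2 - lateral) / cell$rf_sigma)
    g_dir <- if (isTRUE(cell$is_ds)) {
      direction_gain(br$direction_deg, cell$preferred_direction,
                     cell$ds_concentration)
    } else 1
    g <- cell$peak_rate * g_lat * g_dir *
      log_tuning(br$speed, cell$speed_pref, cell$speed_bw) *
      log_tuning(br$bar_width, cell$width_pref, cell$width_bw)
    t_lead <- br$onset_s + (extent / 2 + along) / br$speed
    t_trail <- t_lead + br$bar_width / br$speed
    on_t <- ifelse(br$contrast > 0, t_lead, t_trail)
    off_t <- ifelse(br$contrast > 0, t_trail, t_lead)
    comp[[2]] <- tibble::tibble(
      event_index = rep(br$event_index, 2L),
      stim_time = c(on_t, off_t),
      gain = c(g, g),
      lobe = rep(c("ON", "OFF"), each = nrow(br))
    )
  }

  comp <- dplyr::bind_rows(comp)
  keep <- switch(cell$polarity,
                 ON = comp$lobe == "ON",
                 OFF = comp$lobe == "OFF",
                 ON_OFF = rep(TRUE, nrow(comp)),
                 stop("unknown polarity: ", cell$polarity, call. = FALSE))
  comp <- comp[keep, , drop = FALSE]
  if (cell$polarity == "ON_OFF") {
    comp$gain[comp$lobe == "OFF"] <- comp$gain[comp$lobe == "OFF"] * ONOFF_OFF_GAIN
  }
  comp$t0 <- comp$stim_time + cell$latency - ts
  comp$stim_time <- NULL
  comp <- comp[comp$gain >= min_gain, , drop = FALSE]
  comp <- comp[order(comp$t0), , drop = FALSE]
  structure(comp,
            class = c("rate_fn", class(comp)),
            baseline = cell$baseline_rate,
            tau_r = cell$tau_r, tau_d = cell$tau_d,
            cell_id = cell$cell_id %||% NA_integer_)
}

# effective support of one component after its kernel start
rate_fn_horizon <- function(tau_r, tau_d) {
  kernel_peak_time(tau_r, tau_d) + 12 * tau_d + 6 * tau_r
}

#' Evaluate a rate function
#'
#' @param rate A `rate_fn` from [drive_cell()].
#' @param times Numeric vector of times (s).
#' @return Firing rate lambda(t) in Hz at each time.
#' @export
rate_at <- function(rate, times) {
  tau_r <- attr(rate, "tau_r")
  tau_d <- attr(rate, "tau_d")
  out <- rep(attr(rate, "baseline"), length(times))
  if (nrow(rate) == 0 || length(times) == 0) return(out)
  horizon <- rate_fn_horizon(tau_r, tau_d)
  active <- which(rate$t0 < max(times) & rate$t0 + horizon > min(times))
  for (i in active) {
    t0 <- rate$t0[i]
    sel <- which(times > t0 & times < t0 + horizon)
    if (length(sel)) {
      out[sel] <- out[sel] +
        rate$gain[i] * kernel_eval(times[sel] - t0, tau_r, tau_d)
    }
  }
  out
}

# vectorized expected counts over many windows; components are pre-filtered
# per window via findInterval on their (sorted) start times
expected_counts_vec <- function(rate, a, b) {
  tau_r <- attr(rate, "tau_r")
  tau_d <- attr(rate, "tau_d")
  out <- attr(rate, "baseline") * (b - a)
  if (nrow(rate) == 0) return(out)
  t0 <- rate$t0; gain <- rate$gain
  horizon <- rate_fn_horizon(tau_r, tau_d)
  lo <- findInterval(a - horizon, t0) + 1L
  hi <- findInterval(b, t0)
  for (w in seq_along(a)) {
    if (hi[w] >= lo[w]) {
      idx <- lo[w]:hi[w]
      out[w] <- out[w] + sum(gain[idx] *
        kernel_integral(tau_r, tau_d, a[w] - t0[idx], b[w] - t0[idx]))
    }
  }
  out
}

# exact expected spike count of a rate_fn over [a, b]
expected_count <- function(rate, a, b) {
  tau_r <- attr(rate, "tau_r")
  tau_d <- attr(rate, "tau_d")
  base <- attr(rate, "baseline") * (b - a)
  if (nrow(rate) == 0) return(base)
  base + sum(rate$gain *
               kernel_integral(tau_r, tau_d, a - rate$t0, b - rate$t0))
}

# ---- spike generation ------------------------------------------------------

apply_refractory <- function(times, refractory) {
  if (refractory <= 0 || length(times) < 2) return(times)
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Inhomogeneous-Poisson spike times from a rate function
#'
#' For a `rate_fn`, each response component is sampled by thinning a uniform
#' candidate stream against that component's peak rate and the baseline is
#' sampled homogeneously; the superposition of the resulting independent
#' Poisson processes realizes lambda(t) exactly. For a plain R function,
#' classical thinning against `lambda_max` is used. An absolute refractory
#' period (default 2 ms) is applied afterwards by deletion.
#'
#' @param rate A `rate_fn` or a vectorized function of time returning Hz.
#' @param t_end Simulate over `[0, t_end]` seconds.
#' @param seed Integer seed.
#' @param refractory Absolute refractory period (s); 0 disables.
#' @param lambda_max Upper bound on the rate, required when `rate` is a
#'   function.
#' @return Sorted numeric vector of spike times (s).
#' @export
spikes_from_rate <- function(rate, t_end, seed = 0, refractory = 0.002,
                             lambda_max = NULL) {
  check_number(t_end, "t_end", lower = 0)
  times <- with_seed(seed, {
    if (is.function(rate)) {
      if (is.null(lambda_max)) {
        stop("`lambda_max` is required when `rate` is a function", call. = FALSE)
      }
      n_cand <- stats::rpois(1, lambda_max * t_end)
      cand <- sort(stats::runif(n_cand, 0, t_end))
      lam <- rate(cand)
      if (any(lam > lambda_max + 1e-9)) {
        stop("`rate` exceeds `lambda_max`", call. = FALSE)
      }
      cand[stats::runif(n_cand) * lambda_max < lam]
    } else {
      tau_r <- attr(rate, "tau_r")
      tau_d <- attr(rate, "tau_d")
      horizon <- rate_fn_horizon(tau_r, tau_d)
      base <- attr(rate, "baseline")
      out <- if (base > 0) {
        n <- stats::rpois(1, base * t_end)
        stats::runif(n, 0, t_end)
      } else numeric(0)
      comp <- tibble::as_tibble(rate)
      for (i in seq_len(nrow(comp))) {
        t0 <- comp$t0[i]
        if (t0 >= t_end) next
        span <- min(horizon, t_end - t0)
        g <- comp$gain[i]
        n <- stats::rpois(1, g * span)
        if (n == 0) next
        cand <- stats::runif(n, 0, span)
        acc <- stats::runif(n) < kernel_eval(cand, tau_r, tau_d)
        out <- c(out, t0 + cand[acc])
      }
      sort(out)
    }
  })
  apply_refractory(sort(times), refractory)
}

#' Simulate spike trains of a population for a set of protocols
#'
#' Runs [drive_cell()] and [spikes_from_rate()] for every cell x protocol
#' combination, with per-combination sub-seeds spawned deterministically from
#' `seed`.
#'
#' @param population Tibble from [sample_population()].
#' @param protocols Named list of `stimulus_set`s (see
#'   [stimulus_protocols()]).
#' @param seed Integer root seed.
#' @param refractory Absolute refractory period (s).
#' @return A tibble of spikes: `cell_id`, `protocol`, `time_s`.
#' @export
simulate_retina <- function(population, protocols, seed = 0,
                            refractory = 0.002) {
  stopifnot(is.list(protocols), length(protocols) > 0)
  n_comb <- nrow(population) * length(protocols)
  sub_seeds <- with_seed(seed,
                         sample.int(.Machine$integer.max - 1L, n_comb))
  k <- 0L
  out <- vector("list", n_comb)
  for (ci in seq_len(nrow(population))) {
    cell <- population[ci, ]
    for (pn in names(protocols)) {
      k <- k + 1L
      ev <- protocols[[pn]]
      rf <- drive_cell(cell, ev)
      t_end <- max(ev$offset_s) + 1
      st <- spikes_from_rate(rf, t_end, seed = sub_seeds[k],
                             refractory = refractory)
      out[[k]] <- tibble::tibble(cell_id = cell$cell_id, protocol = pn,
                                 time_s = st)
    }
  }
  dplyr::bind_rows(out)
}
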