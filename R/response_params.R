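# The seven response parameters: ON-OFF bias index, latency, transience,
# receptive-field diameter, direction-selectivity index, preferred-speed and
# preferred-width indices, plus responsiveness flags.
#
# All response measures are baseline-corrected: the cell's spontaneous rate,
# estimated from the inter-stimulus background intervals (or known exactly in
# noiseless mode), is subtracted from counts and rates before any index is
# formed, so the indices reflect stimulus-driven firing only.

PSTH_WINDOW <- 1.5   # s; the post-stimulus window used for transience
PSTH_BIN <- 0.005    # s
SMOOTH_WINDOW <- 0.025  # s; latency integration window

# ---- PSTH ------------------------------------------------------------------

#' Post-stimulus time histogram
#'
#' Bins spikes relative to a set of aligned onsets and averages over
#' repetitions; the result is a firing rate in Hz per bin.
#'
#' @param times Sorted spike times (s).
#' @param onsets Alignment times, one per repetition (s).
#' @param window Post-onset window `c(from, to)` (s).
#' @param bin Bin width (s).
#' @return A `psth` object: list with `time` (bin centres relative to onset),
#'   `rate` (Hz), `bin_width`, `window`, `n_rep`.
#' @export
psth_from_spikes <- function(times, onsets, window = c(0, PSTH_WINDOW),
                             bin = PSTH_BIN) {
  nb <- max(1L, floor((window[2] - window[1]) / bin + 1e-9))
  span <- nb * bin
  counts <- numeric(nb)
  for (on in onsets) {
    rel <- times[times >= on + window[1] & times < on + window[1] + span] - on
    if (length(rel)) {
      counts <- counts +
        tabulate(floor((rel - window[1]) / bin) + 1L, nbins = nb)
    }
  }
  new_psth(counts / (length(onsets) * bin),
           window[1] + bin * (seq_len(nb) - 0.5), bin, window,
           length(onsets))
}

new_psth <- function(rate, time, bin, window, n_rep) {
  structure(list(time = time, rate = rate, bin_width = bin, window = window,
                 n_rep = n_rep), class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %d bins of %g ms over [%g, %g] s, %d repetition(s), peak %.2f Hz\n",
              length(x$rate), x$bin_width * 1000, x$window[1], x$window[2],
              x$n_rep, max(x$rate)))
  invisible(x)
}

# centred boxcar mean with partial windows at the edges
smooth_boxcar <- function(x, k) {
  if (k <= 1) return(x)
  h <- floor(k / 2)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

smooth_psth_rate <- function(psth, window = SMOOTH_WINDOW) {
  smooth_boxcar(psth$rate, round(window / psth$bin_width))
}

# ---- scalar indices --------------------------------------------------------

#' ON-OFF bias index
#'
#' `BI = (ON - OFF) / (ON + OFF)`: +1 for a pure ON response, -1 for a pure
#' OFF response, 0 for a balanced ON-OFF response.
#'
#' @param on_count,off_count Non-negative (baseline-corrected) spike counts.
#' @return Bias index in `[-1, 1]`, or `NA` when both counts are zero (the
#'   cell is flagged non-responsive upstream).
#' @examples
#' bias_index(10, 0)  # +1
#' bias_index(7, 7)   # 0
#' @export
bias_index <- function(on_count, off_count) {
  stopifnot(on_count >= 0, off_count >= 0)
  tot <- on_count + off_count
  ifelse(tot == 0, NA_real_, (on_count - off_count) / tot)
}

#' Response latency
#'
#' Time from stimulus onset to the maximum firing rate, after smoothing the
#' PSTH with a sliding 25 ms integration window; ties at the maximum resolve
#' to the earliest bin.
#'
#' @param psth A [psth_from_spikes()] object (baseline-corrected).
#' @param smooth Integration window (s).
#' @return Latency in seconds (bin centre), or `NA` for an all-zero PSTH.
#' @export
response_latency <- function(psth, smooth = SMOOTH_WINDOW) {
  sm <- smooth_psth_rate(psth, smooth)
  if (max(sm) <= 0) return(NA_real_)
  psth$time[which.max(sm)] - psth$window[1]
}

#' Transience index
#'
#' The PSTH over the 1.5 s post-stimulus window is normalized to unit peak,
#' integrated, and divided by 1.5: 1 for a response sustained over the whole
#' window, approaching 0 for an infinitely brief response.
#'
#' @param psth A `psth` whose window is 1.5 s long (baseline-corrected).
#' @return Transience in `[0, 1]`, or `NA` for an all-zero PSTH.
#' @export
transience_index <- function(psth) {
  if (abs(diff(psth$window) - PSTH_WINDOW) > 1e-9) {
    stop(sprintf("transience requires a %.1f s PSTH window", PSTH_WINDOW),
         call. = FALSE)
  }
  peak <- max(psth$rate)
  if (peak <= 0) return(NA_real_)
  sum(psth$rate / peak) * psth$bin_width / PSTH_WINDOW
}

#' Direction-selectivity index
#'
#' Vector average of the direction-wise firing rates:
#' `D = |sum_i r_i u(theta_i)| / sum_i r_i`, 0 for no directional
#' preference, 1 for a unidirectional response.
#'
#' @param rates Non-negative mean firing rates, one per direction.
#' @param directions Directions in degrees (same length).
#' @return DS index in `[0, 1]`, or `NA` when all rates are zero.
#' @examples
#' ds_index(rep(5, 8), seq(0, 315, by = 45))  # 0
#' @export
ds_index <- function(rates, directions) {
  stopifnot(length(rates) == length(directions), all(rates >= 0))
  tot <- sum(rates)
  if (tot == 0) return(NA_real_)
  u <- dir_unit(directions)
  sqrt(sum(rates * u[, 1])^2 + sum(rates * u[, 2])^2) / tot
}

# rate-weighted mean direction (deg in [0, 360)), NA if no net vector
preferred_direction_of <- function(rates, directions) {
  u <- dir_unit(directions)
  vx <- sum(rates * u[, 1]); vy <- sum(rates * u[, 2])
  if (vx == 0 && vy == 0) return(NA_real_)
  (rad2deg(atan2(vy, vx)) + 360) %% 360
}

#' Preferred speed / width index
#'
#' The response-weighted mean of the tested condition values (the preferred
#' speed or width), normalized by the maximum tested value: 1 for a cell
#' responding only at the largest condition.
#'
#' @param responses Non-negative mean peak responses, one per condition.
#' @param values Condition values (um/s for speed, um for width).
#' @return Index in `(0, 1]`, or `NA` when all responses are zero.
#' @examples
#' preferred_index(c(0, 0, 0, 0, 0, 3), c(150, 300, 600, 900, 1200, 1800))
#' @export
preferred_index <- function(responses, values) {
  stopifnot(length(responses) == length(values), length(values) >= 2,
            all(responses >= 0))
  if (sum(responses) == 0) return(NA_real_)
  sum(values * responses) / sum(responses) / max(values)
}

# ---- receptive field -------------------------------------------------------

# vectorized bilinear interpolation of a matrix at row coords ci, col
# coords cj (in index units, clamped to [1, n])
bilinear_upsample <- function(map, ci, cj) {
  nr <- nrow(map); nc <- ncol(map)
  i0 <- pmin(floor(ci), max(nr - 1, 1)); fi <- if (nr > 1) ci - i0 else rep(0, length(ci))
  j0 <- pmin(floor(cj), max(nc - 1, 1)); fj <- if (nc > 1) cj - j0 else rep(0, length(cj))
  if (nr == 1) map <- rbind(map, map)
  if (nc == 1) map <- cbind(map, map)
  fi_m <- matrix(fi, length(ci), length(cj))
  fj_m <- matrix(fj, length(ci), length(cj), byrow = TRUE)
  m00 <- map[i0, j0, drop = FALSE]
  m10 <- map[i0 + 1, j0, drop = FALSE]
  m01 <- map[i0, j0 + 1, drop = FALSE]
  m11 <- map[i0 + 1, j0 + 1, drop = FALSE]
  m00 * (1 - fi_m) * (1 - fj_m) + m10 * fi_m * (1 - fj_m) +
    m01 * (1 - fi_m) * fj_m + m11 * fi_m * fj_m
}

#' Receptive-field area, diameter and centre from a response map
#'
#' The map of mean spike counts per square location is upsampled nine times
#' per axis, thresholded at 33% of its maximum, and the supra-threshold pixel
#' fraction is scaled to the mapped area `A`; the equivalent-circle diameter
#' is `d = sqrt(4 A / pi)`. The centre is the response-weighted centroid of
#' the supra-threshold pixels.
#'
#' @param map Numeric matrix of mean (baseline-corrected) spike counts;
#'   `map[i, j]` is the location at `x_centers[j]`, `y_centers[i]`.
#' @param x_centers,y_centers Location centres (um).
#' @param upsample Per-axis upsampling factor.
#' @param threshold Fraction of the maximum defining the field.
#' @param interp `"bilinear"` (default) or `"nearest"` upsampling.
#' @return A list of class `receptive_field`: `area` (um^2), `diameter`
#'   (um), `center` (um 2-vector), `n_pixels`, `total_pixels`.
#' @export
receptive_field <- function(map, x_centers = seq(50, 850, by = 100),
                            y_centers = seq(50, 850, by = 100),
                            upsample = 9, threshold = 0.33,
                            interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(is.matrix(map), nrow(map) == length(y_centers),
            ncol(map) == length(x_centers))
  if (max(map) <= 0) {
    stop("response map has no positive maximum; receptive field undefined",
         call. = FALSE)
  }
  spacing_x <- if (length(x_centers) > 1) diff(x_centers)[1] else 100
  spacing_y <- if (length(y_centers) > 1) diff(y_centers)[1] else 100
  nr <- nrow(map); nc <- ncol(map)
  # upsampled pixel centres in original index units
  ui <- 0.5 + (seq_len(nr * upsample) - 0.5) / upsample
  uj <- 0.5 + (seq_len(nc * upsample) - 0.5) / upsample
  if (interp == "nearest") {
    up <- map[pmin(pmax(round(ui), 1), nr), pmin(pmax(round(uj), 1), nc)]
  } else {
    up <- bilinear_upsample(map, pmin(pmax(ui, 1), nr), pmin(pmax(uj, 1), nc))
  }
  mask <- up >= threshold * max(up)
  total_area <- nr * nc * spacing_x * spacing_y
  area <- sum(mask) / length(mask) * total_area
  diameter <- sqrt(4 * area / pi)
  # pixel centres in um
  px <- x_centers[1] + (uj - 1) * spacing_x
  py <- y_centers[1] + (ui - 1) * spacing_y
  w <- up * mask
  center <- c(sum(t(w) * px) / sum(w), sum(w * py) / sum(w))
  structure(list(area = area, diameter = diameter, center = center,
                 n_pixels = sum(mask), total_pixels = length(mask)),
            class = "receptive_field")
}

#' @export
print.receptive_field <- function(x, ...) {
  cat(sprintf("<receptive_field> diameter %.1f um, area %.0f um^2, centre (%.0f, %.0f) um\n",
              x$diameter, x$area, x$center[1], x$center[2]))
  invisible(x)
}

# ---- bar-response selection ------------------------------------------------

#' Direction-wise bar responses nearest the receptive-field centre
#'
#' For each of the eight directions of the narrow-bar protocol, the lateral
#' offset whose motion axis passes closest to the cell's receptive-field
#' centre is selected post hoc; the response is the baseline-corrected mean
#' firing rate over that bar's traversal window, averaged over the tested
#' speeds.
#'
#' @param rf_center Receptive-field centre (um 2-vector).
#' @param events Narrow-bar `stimulus_set`.
#' @param rate_of Function of an event row returning its baseline-corrected
#'   mean rate (Hz).
#' @param geometry Field geometry.
#' @return Tibble: `direction_deg`, `offset` (chosen), `rate`.
#' @export
select_bar_responses <- function(rf_center, events, rate_of,
                                 geometry = NULL) {
  geometry <- geometry %||% attr(events, "geometry") %||% field_geometry()
  ev <- tibble::as_tibble(events)
  ctr <- field_center(geometry)
  rel <- rf_center - ctr
  u <- dir_unit(ev$direction_deg)
  ev$lateral_dist <- abs(-u[, 2] * rel[1] + u[, 1] * rel[2] - ev$offset)
  purrr::map_dfr(sort(unique(ev$direction_deg)), function(d) {
    sub <- ev[ev$direction_deg == d, ]
    best_off <- sub$offset[which.min(sub$lateral_dist)]
    sel <- sub[sub$offset == best_off, ]
    rates <- vapply(seq_len(nrow(sel)), function(i) rate_of(sel[i, ]),
                    numeric(1))
    tibble::tibble(direction_deg = d, offset = best_off,
                   rate = mean(pmax(rates, 0)))
  })
}

# ---- measurement interfaces -----------------------------------------------

# Spike-train measurement backend: empirical counts, PSTHs, peak rates and
# background-interval baseline statistics for one cell's protocol recordings.
spike_measure <- function(times_by_protocol, protocols, bin = PSTH_BIN) {
  times_by_protocol <- lapply(times_by_protocol, sort)
  gaps_of <- function(pn) {
    ev <- protocols[[pn]]
    ord <- order(ev$onset_s)
    on <- ev$onset_s[ord]; off <- ev$offset_s[ord]
    tibble::tibble(from = off[-length(off)], to = on[-1])
  }
  base_cache <- new.env()
  baseline_stats <- function(pn) {
    if (!is.null(base_cache[[pn]])) return(base_cache[[pn]])
    tt <- times_by_protocol[[pn]]
    g <- gaps_of(pn)
    g <- g[g$to - g$from > 0.05, , drop = FALSE]
    samples <- unlist(purrr::map2(g$from, g$to, function(a, b) {
      br <- seq(a, b, by = SMOOTH_WINDOW)
      if (length(br) < 2) return(numeric(0))
      (findInterval(br[-1], tt) - findInterval(br[-length(br)], tt)) /
        SMOOTH_WINDOW
    }))
    st <- if (length(samples) == 0) list(rate = 0, sd = 0) else {
      list(rate = mean(samples), sd = stats::sd(samples))
    }
    base_cache[[pn]] <- st
    st
  }
  list(
    count = function(pn, a, b) {
      tt <- times_by_protocol[[pn]]
      findInterval(b, tt) - findInterval(a, tt)
    },
    psth = function(pn, onsets, window) {
      psth_from_spikes(times_by_protocol[[pn]], onsets, window, bin)
    },
    peak_rates = function(pn, ev) {
      vapply(seq_len(nrow(ev)), function(i) {
        p <- psth_from_spikes(times_by_protocol[[pn]], ev$onset_s[i],
                              c(0, ev$offset_s[i] - ev$onset_s[i]), bin)
        max(smooth_psth_rate(p))
      }, numeric(1))
    },
    baseline = function(pn) baseline_stats(pn)$rate,
    baseline_sd = function(pn) baseline_stats(pn)$sd
  )
}

# Noiseless measurement backend: exact expectations under the cell's rate
# function (drives = list of rate_fn per protocol).
noiseless_measure <- function(cell, drives, bin = PSTH_BIN) {
  tau_r <- cell$tau_r; tau_d <- cell$tau_d
  peak_cache <- new.env()
  # peak of the 25 ms-smoothed one-or-two-lobe response shape, per unit gain
  lobe_peak <- function(sep, ratio) {
    key <- sprintf("%.6f_%.4f", sep, ratio)
    if (!is.null(peak_cache[[key]])) return(peak_cache[[key]])
    span <- sep + kernel_peak_time(tau_r, tau_d) + 10 * tau_d + 6 * tau_r
    t <- seq(0, span, by = 0.001)
    y <- kernel_eval(t, tau_r, tau_d) + ratio * kernel_eval(t - sep, tau_r, tau_d)
    v <- max(smooth_boxcar(y, round(SMOOTH_WINDOW / 0.001)))
    peak_cache[[key]] <- v
    v
  }
  # per-protocol index of component rows by event
  ev_index <- lapply(drives, function(rf) {
    split(seq_len(nrow(rf)), rf$event_index)
  })
  list(
    count = function(pn, a, b) expected_counts_vec(drives[[pn]], a, b),
    psth = function(pn, onsets, window) {
      tt <- seq(window[1] + bin / 2, window[2] - bin / 2, by = bin)
      rate <- rowMeans(vapply(onsets, function(on) {
        rate_at(drives[[pn]], on + tt)
      }, numeric(length(tt))))
      new_psth(rate, tt, bin, window, length(onsets))
    },
    peak_rates = function(pn, ev) {
      rf <- drives[[pn]]
      base <- attr(rf, "baseline")
      idx <- ev_index[[pn]]
      t0 <- rf$t0; gain <- rf$gain
      vapply(ev$event_index, function(eid) {
        rows <- idx[[as.character(eid)]]
        if (is.null(rows)) return(base)
        rows <- rows[order(t0[rows])]
        pk <- if (length(rows) == 1) {
          gain[rows] * lobe_peak(0, 0)
        } else {
          gain[rows[1]] * lobe_peak(t0[rows[2]] - t0[rows[1]],
                                    gain[rows[2]] / gain[rows[1]])
        }
        base + pk
      }, numeric(1))
    },
    baseline = function(pn) cell$baseline_rate,
    baseline_sd = function(pn) 0
  )
}

# ---- per-cell analysis -----------------------------------------------------

# Responsiveness decision for one protocol: observed window counts against
# the Poisson background expectation, Bonferroni-corrected across windows.
# With an exact (noiseless) baseline the rule degenerates to "any positive
# stimulus-driven expectation".
pois_responsive <- function(obs, mu, exact_baseline, alpha = 0.001) {
  if (exact_baseline) return(any(obs > mu + 1e-9))
  # single-window evidence, Bonferroni-corrected across windows
  p <- ifelse(obs <= 0, 1,
              stats::ppois(ceiling(obs) - 1, mu, lower.tail = FALSE))
  if (min(p) < alpha / length(obs)) return(TRUE)
  # pooled evidence: weak responses spread over many presentations
  tot <- sum(obs)
  tot > 0 && stats::ppois(ceiling(tot) - 1, sum(mu), lower.tail = FALSE) < alpha
}

# Runs the whole parameter extraction for one cell against a measurement
# backend; returns a one-row tibble.
analyze_cell <- function(m, protocols, bin = PSTH_BIN) {
  ms <- tibble::as_tibble(protocols$marching_square)
  geometry <- attr(protocols$marching_square, "geometry") %||% field_geometry()
  phase <- (ms$offset_s[1] - ms$onset_s[1]) / 2
  b_ms <- m$baseline("marching_square")

  xs <- sort(unique(ms$center_x)); ys <- sort(unique(ms$center_y))
  on_map <- matrix(0, length(ys), length(xs))
  off_map <- matrix(0, length(ys), length(xs))
  on_all <- m$count("marching_square", ms$onset_s, ms$onset_s + phase)
  off_all <- m$count("marching_square", ms$onset_s + phase, ms$onset_s + 2 * phase)
  ii <- match(ms$center_y, ys); jj <- match(ms$center_x, xs)
  n_rep <- max(ms$repetition)
  for (k in seq_len(nrow(ms))) {
    on_map[ii[k], jj[k]] <- on_map[ii[k], jj[k]] + on_all[k] / n_rep
    off_map[ii[k], jj[k]] <- off_map[ii[k], jj[k]] + off_all[k] / n_rep
  }
  on_map <- pmax(on_map - b_ms * phase, 0)
  off_map <- pmax(off_map - b_ms * phase, 0)
  combined <- on_map + off_map

  rf <- NULL
  rf_diam <- NA_real_; rf_area <- NA_real_
  rf_center <- field_center(geometry)
  if (max(combined) > 0) {
    rf <- receptive_field(combined, xs, ys)
    rf_diam <- rf$diameter; rf_area <- rf$area; rf_center <- rf$center
  }
  best <- which(combined == max(combined), arr.ind = TRUE)[1, ]
  bi <- bias_index(on_map[best[1], best[2]], off_map[best[1], best[2]])

  best_events <- ms[ms$center_x == xs[best[2]] & ms$center_y == ys[best[1]], ]
  sub_base <- function(p) {
    p$rate <- pmax(p$rate - b_ms, 0)
    p
  }
  on_psth <- sub_base(m$psth("marching_square", best_events$onset_s,
                             c(0, PSTH_WINDOW)))
  off_psth <- sub_base(m$psth("marching_square", best_events$onset_s + phase,
                              c(0, PSTH_WINDOW)))
  polarity <- if (is.na(bi)) NA_character_
  else if (bi > 1 / 3) "ON" else if (bi < -1 / 3) "OFF" else "ON_OFF"
  chosen <- if (is.na(polarity)) NULL
  else if (polarity == "ON") on_psth
  else if (polarity == "OFF") off_psth
  else if (max(smooth_psth_rate(on_psth)) >= max(smooth_psth_rate(off_psth))) {
    on_psth
  } else off_psth
  latency <- if (is.null(chosen)) NA_real_ else response_latency(chosen)
  transience <- if (is.null(chosen)) NA_real_ else transience_index(chosen)
  exact_base <- m$baseline_sd("marching_square") == 0 && b_ms > 0
  loc_tot_on <- as.vector(rowsum(on_all, paste(ii, jj)))
  loc_tot_off <- as.vector(rowsum(off_all, paste(ii, jj)))
  resp_ms <- pois_responsive(c(loc_tot_on, loc_tot_off),
                             rep(b_ms * phase * n_rep,
                                 length(loc_tot_on) + length(loc_tot_off)),
                             exact_base)

  # narrow bars: DS index. The rate window runs from bar entry to the end of
  # the post-traversal settle interval, so trailing-edge (OFF) responses are
  # captured equally in every direction.
  nb <- protocols$narrow_bars
  b_nb <- m$baseline("narrow_bars")
  settle <- attr(protocols$narrow_bars, "gap") %||% 0.5
  rate_of <- function(ev) {
    m$count("narrow_bars", ev$onset_s, ev$offset_s + settle) /
      (ev$offset_s + settle - ev$onset_s) - b_nb
  }
  bar_resp <- select_bar_responses(rf_center, nb, rate_of)
  dsi <- ds_index(bar_resp$rate, bar_resp$direction_deg)
  pref_dir <- preferred_direction_of(bar_resp$rate, bar_resp$direction_deg)
  bar_responsive <- function(pn) {
    ev <- tibble::as_tibble(protocols[[pn]])
    b <- m$baseline(pn)
    w <- ev$offset_s + settle - ev$onset_s
    obs <- m$count(pn, ev$onset_s, ev$onset_s + w)
    pois_responsive(obs, b * w, m$baseline_sd(pn) == 0 && b > 0)
  }
  resp_nb <- bar_responsive("narrow_bars")

  # width and speed tests: preferred indices from per-condition peak rates,
  # maximized across contrast, direction (and the other geometry factor)
  condition_responses <- function(pn, cond_col) {
    ev <- tibble::as_tibble(protocols[[pn]])
    b <- m$baseline(pn)
    # include the post-traversal settle interval so trailing-edge response
    # peaks are inside the window
    ev$offset_s <- ev$offset_s + (attr(protocols[[pn]], "gap") %||% 0.5)
    peaks <- m$peak_rates(pn, ev)
    vals <- sort(unique(ev[[cond_col]]))
    resp <- vapply(vals, function(v) {
      max(pmax(peaks[ev[[cond_col]] == v] - b, 0))
    }, numeric(1))
    list(values = vals, responses = resp, responsive = bar_responsive(pn))
  }
  wt <- condition_responses("width_test", "bar_width")
  width_index <- preferred_index(wt$responses, wt$values)
  st <- condition_responses("speed_test", "speed")
  speed_index <- preferred_index(st$responses, st$values)

  tibble::tibble(
    bias_index = bi, latency_s = latency, transience = transience,
    rf_diameter_um = rf_diam, rf_area_um2 = rf_area,
    rf_x = rf_center[1], rf_y = rf_center[2],
    ds_index = dsi, preferred_direction_deg = pref_dir,
    speed_index = speed_index, width_index = width_index,
    polarity_call = polarity,
    responded_marching_square = resp_ms, responded_narrow_bars = resp_nb,
    responded_width_test = wt$responsive, responded_speed_test = st$responsive,
    responded_all = resp_ms && resp_nb && wt$responsive && st$responsive &&
      !is.na(bi) && !is.na(dsi) && !is.na(speed_index) && !is.na(width_index)
  )
}

#' Extract response parameters from spike trains
#'
#' Computes the seven response parameters and responsiveness flags for every
#' cell in a spike table, given the four stimulus protocols. See the package
#' vignette for the measurement conventions (baseline correction, polarity
#' windows, smoothing).
#'
#' @param spikes Tibble with `cell_id`, `protocol`, `time_s`; `protocol`
#'   values must name entries of `protocols`.
#' @param protocols Named list of `stimulus_set`s, with elements
#'   `marching_square`, `narrow_bars`, `width_test`, `speed_test`.
#' @param bin PSTH bin width (s).
#' @return A tibble with one row per cell: `cell_id`, `bias_index`,
#'   `latency_s`, `transience`, `rf_diameter_um`, `ds_index`, `speed_index`,
#'   `width_index`, auxiliary columns and responsiveness flags.
#' @export
extract_parameters <- function(spikes, protocols, bin = PSTH_BIN) {
  needed <- c("marching_square", "narrow_bars", "width_test", "speed_test")
  if (!all(needed %in% names(protocols))) {
    stop("`protocols` must contain: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  ids <- sort(unique(spikes$cell_id))
  purrr::map_dfr(ids, function(id) {
    sub <- spikes[spikes$cell_id == id, ]
    tbp <- lapply(stats::setNames(needed, needed), function(pn) {
      sub$time_s[sub$protocol == pn]
    })
    m <- spike_measure(tbp, protocols, bin)
    dplyr::bind_cols(tibble::tibble(cell_id = id),
                     analyze_cell(m, protocols, bin))
  })
}

#' Expected (noiseless) response parameters of a synthetic population
#'
#' Runs the identical extraction pipeline against the exact expectation of
#' each cell's rate function instead of sampled spikes: counts become
#' integrals of lambda(t), PSTHs become lambda(t) itself, and the baseline is
#' known exactly. This is the parameter-recovery reference path.
#'
#' @param population Tibble from [sample_population()].
#' @param protocols Named list of the four `stimulus_set`s.
#' @param bin PSTH bin width (s).
#' @return As [extract_parameters()], plus the generating `archetype`.
#' @export
expected_parameters <- function(population, protocols, bin = PSTH_BIN) {
  purrr::map_dfr(seq_len(nrow(population)), function(i) {
    cell <- population[i, ]
    drives <- lapply(protocols, function(ev) drive_cell(cell, ev))
    m <- noiseless_measure(cell, drives, bin)
    dplyr::bind_cols(tibble::tibble(cell_id = cell$cell_id,
                                    archetype = cell$archetype),
                     analyze_cell(m, protocols, bin))
  })
}

#' Filter cells that responded to all four protocols
#'
#' @param params Parameter tibble from [extract_parameters()] or
#'   [expected_parameters()].
#' @return The responsive subset; the discarded rows, with their failing
#'   protocols, are attached as attribute `"discarded"`.
#' @export
responsiveness_filter <- function(params) {
  flags <- c("responded_marching_square", "responded_narrow_bars",
             "responded_width_test", "responded_speed_test")
  bad <- params[!params$responded_all, , drop = FALSE]
  if (nrow(bad) > 0) {
    bad$failed_protocols <- vapply(seq_len(nrow(bad)), function(i) {
      f <- flags[!unlist(bad[i, flags])]
      paste(sub("responded_", "", f), collapse = ";")
    }, character(1))
  }
  kept <- params[params$responded_all, , drop = FALSE]
  attr(kept, "discarded") <- bad
  kept
}
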