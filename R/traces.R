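# Extracellular trace synthesis on a high-density electrode block.

#' Rectangular electrode configuration
#'
#' A contiguous block of recording electrodes on a 17.5 um pitch grid. The
#' default 6 x 21 block has 126 electrodes, the number recorded
#' simultaneously.
#'
#' @param rows,cols Grid dimensions.
#' @param pitch Electrode pitch (um).
#' @param origin Lower-left electrode position (um).
#' @param sample_rate Sampling rate (Hz).
#' @return An `electrode_config`: a tibble with `electrode`, `x`, `y`, `row`,
#'   `col` and attributes `pitch`, `sample_rate`, `rows`, `cols`.
#' @export
electrode_config <- function(rows = 6, cols = 21, pitch = 17.5,
                             origin = c(0, 0), sample_rate = 20000) {
  grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  cfg <- tibble::tibble(
    electrode = seq_len(nrow(grid)),
    x = origin[1] + (grid$col - 1) * pitch,
    y = origin[2] + (grid$row - 1) * pitch,
    row = grid$row, col = grid$col
  )
  structure(cfg, class = c("electrode_config", class(cfg)),
            pitch = pitch, sample_rate = sample_rate,
            rows = rows, cols = cols)
}

# biphasic extracellular waveform, ~1.5 ms, unit peak-to-peak, dominant
# negative lobe first; trough width, rebound amplitude and rebound latency
# vary per cell (real units differ in waveform shape, which is what makes
# nearby cells separable by template correlation)
spike_waveform <- function(sample_rate, duration = 0.0015,
                           trough_sd = 0.00012, rebound = 0.45,
                           rebound_t = 0.0008) {
  t <- seq(0, duration, by = 1 / sample_rate)
  w <- -exp(-((t - 0.00035) / trough_sd)^2) +
    rebound * exp(-((t - rebound_t) / 0.00025)^2)
  w / (max(w) - min(w))
}

#' Render multi-electrode voltage traces from spike trains
#'
#' Each cell contributes a biphasic template with exponential spatial decay
#' around its footprint centre; white Gaussian noise is added at `noise_rms`.
#' Ground truth (cells, spike times, per-electrode peak-to-peak footprints) is
#' embedded in the returned object.
#'
#' @param cells Tibble with `cell_id`, `x`, `y` (um, inside the
#'   configuration) and optionally `amplitude` (peak-to-peak uV; drawn
#'   uniformly from `amplitude_range` when absent).
#' @param trains Tibble of spikes: `cell_id`, `time_s`.
#' @param duration Trace length (s).
#' @param config An [electrode_config()].
#' @param noise_rms Additive white-noise RMS (uV); 2.4 matches the recording
#'   noise floor of the device emulated.
#' @param decay_const Spatial exponential decay length (um).
#' @param amplitude_range Range for drawn peak-to-peak amplitudes (uV).
#' @param seed Integer seed (noise and amplitude draws).
#' @return A `trace_block`: list with `samples` (electrodes x samples matrix,
#'   uV), `sample_rate`, `electrodes`, `duration`, `noise_rms` and a
#'   `ground_truth` list (`cells` incl. drawn amplitudes, `trains`).
#' @export
render_traces <- function(cells, trains, duration, config = electrode_config(),
                          noise_rms = 2.4, decay_const = 25,
                          amplitude_range = c(50, 300), seed = 0) {
  sample_rate <- attr(config, "sample_rate")
  n_samp <- round(duration * sample_rate)
  n_elec <- nrow(config)
  if (nrow(cells) > 0 &&
      (any(cells$x < min(config$x) - decay_const * 4) ||
       any(cells$x > max(config$x) + decay_const * 4) ||
       any(cells$y < min(config$y) - decay_const * 4) ||
       any(cells$y > max(config$y) + decay_const * 4))) {
    stop("cell positions lie outside the electrode configuration", call. = FALSE)
  }
  nw <- length(spike_waveform(sample_rate))
  with_seed(seed, {
    if (nrow(cells) > 0 && !("amplitude" %in% names(cells))) {
      cells$amplitude <- stats::runif(nrow(cells), amplitude_range[1],
                                      amplitude_range[2])
    }
    shapes <- tibble::tibble(
      trough_sd = stats::runif(nrow(cells), 0.0001, 0.00016),
      rebound = stats::runif(nrow(cells), 0.3, 0.6),
      rebound_t = stats::runif(nrow(cells), 0.0007, 0.00095)
    )
    samples <- matrix(stats::rnorm(n_elec * n_samp, sd = noise_rms),
                      nrow = n_elec)
    for (i in seq_len(nrow(cells))) {
      cell <- cells[i, ]
      wave <- spike_waveform(sample_rate, trough_sd = shapes$trough_sd[i],
                             rebound = shapes$rebound[i],
                             rebound_t = shapes$rebound_t[i])
      peak_shift <- which.min(wave) - 1L  # spike time = negative-peak time
      spk <- trains$time_s[trains$cell_id == cell$cell_id]
      spk <- spk[spk >= (peak_shift + 1) / sample_rate &
                   spk < duration - nw / sample_rate]
      if (length(spk) == 0) next
      idx0 <- round(spk * sample_rate) + 1L - peak_shift
      d <- sqrt((config$x - cell$x)^2 + (config$y - cell$y)^2)
      amp <- cell$amplitude * exp(-d / decay_const)
      elecs <- which(amp > 0.5)          # footprint: electrodes above 0.5 uV
      pos <- rep(idx0, each = nw) + rep(0:(nw - 1L), times = length(idx0))
      wrep <- rep(wave, times = length(idx0))
      for (e in elecs) {
        samples[e, pos] <- samples[e, pos] + amp[e] * wrep
      }
    }
    structure(list(
      samples = samples, sample_rate = sample_rate, electrodes = config,
      duration = duration, noise_rms = noise_rms,
      ground_truth = list(cells = cells, trains = trains)
    ), class = "trace_block")
  })
}

#' @export
print.trace_block <- function(x, ...) {
  cat(sprintf("<trace_block> %d electrodes x %d samples (%.1f s at %g kHz), %d ground-truth cells\n",
              nrow(x$samples), ncol(x$samples), x$duration,
              x$sample_rate / 1000, nrow(x$ground_truth$cells)))
  invisible(x)
}
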