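# Activity scan: choosing the most active electrode configuration out of a
# sequence of candidate blocks using peak-to-peak amplitude maps.

#' Per-electrode maximum peak-to-peak amplitude map
#'
#' Detects spikes on a (band-passed) trace block and records, per electrode,
#' the maximum peak-to-peak amplitude over its detections; electrodes without
#' detections get 0.
#'
#' @param block A `trace_block`.
#' @param k_sd Detection threshold multiplier (see [detect_spikes()]).
#' @param filter Band-pass the block first.
#' @return An `amplitude_map` tibble: `electrode`, `x`, `y`, `row`, `col`,
#'   `amplitude` (uV).
#' @export
amplitude_map <- function(block, k_sd = 3.5, filter = TRUE) {
  if (filter) block <- bandpass_traces(block)
  det <- detect_spikes(block, k_sd)
  cfg <- tibble::as_tibble(block$electrodes)
  amp <- rep(0, nrow(cfg))
  if (nrow(det) > 0) {
    mx <- tapply(det$peak_to_peak, det$electrode, max)
    amp[as.integer(names(mx))] <- as.numeric(mx)
  }
  out <- dplyr::mutate(cfg, amplitude = amp)
  class(out) <- c("amplitude_map", class(out))
  out
}

# grid matrix view of an amplitude map (rows x cols)
amplitude_grid <- function(map) {
  m <- matrix(0, nrow = max(map$row), ncol = max(map$col))
  m[cbind(map$row, map$col)] <- map$amplitude
  m
}

#' Count local maxima in an amplitude map
#'
#' An electrode counts as a local maximum (a putative ganglion cell) when its
#' amplitude exceeds `min_amplitude` and strictly exceeds all of its
#' 8-neighbours on the electrode grid.
#'
#' @param map An [amplitude_map()].
#' @param min_amplitude Amplitude floor (uV, default 30).
#' @return Integer count.
#' @export
count_local_maxima <- function(map, min_amplitude = 30) {
  check_number(min_amplitude, "min_amplitude", lower = 0)
  g <- amplitude_grid(map)
  nr <- nrow(g); nc <- ncol(g)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- g
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[2:(nr + 1) + dr, 2:(nc + 1) + dc, drop = FALSE]
    is_max <- is_max & (g > nb)
  }
  sum(is_max & g > min_amplitude)
}

#' Select the most active electrode configuration
#'
#' Given candidate trace blocks recorded at different retinal regions,
#' returns the index of the block whose amplitude map has the most local
#' maxima; ties are broken by larger summed amplitude, then by lower index.
#'
#' @param blocks List of `trace_block`s (typically 12).
#' @param min_amplitude Floor passed to [count_local_maxima()].
#' @param k_sd Detection threshold multiplier.
#' @return A `configuration_scan` tibble (`configuration`, `n_local_maxima`,
#'   `sum_amplitude`, `selected`) with the chosen index in attribute
#'   `selected`.
#' @export
select_configuration <- function(blocks, min_amplitude = 30, k_sd = 3.5) {
  stopifnot(length(blocks) >= 1)
  report <- purrr::map_dfr(seq_along(blocks), function(i) {
    m <- amplitude_map(blocks[[i]], k_sd)
    tibble::tibble(configuration = i,
                   n_local_maxima = count_local_maxima(m, min_amplitude),
                   sum_amplitude = sum(m$amplitude))
  })
  ord <- order(-report$n_local_maxima, -report$sum_amplitude,
               report$configuration)
  sel <- report$configuration[ord[1]]
  if (all(report$n_local_maxima == 0)) {
    warning("no configuration shows any local maxima; defaulting by tie-break",
            call. = FALSE)
  }
  report$selected <- report$configuration == sel
  structure(report, selected = sel,
            class = c("configuration_scan", class(report)))
}
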