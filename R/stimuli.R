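# Stimulus protocol generation.
#
# All four protocols are produced as ordered event tables sharing one column
# layout, so the simulator and the parameter extractors consume a single
# authoritative stimulus description. Times are seconds, lengths micrometres.
# Direction convention: 0 deg = motion toward +x, counterclockwise positive.

#' Projected stimulation field geometry
#'
#' Describes the rectangle of retina covered by the projected image. The
#' default is a 1 x 1 mm field with the origin at its lower-left corner; the
#' flashing-square grid occupies the central 900 x 900 um sub-area.
#'
#' @param width,height Field extent in micrometres; both must be positive.
#' @param origin Numeric 2-vector, lower-left corner in micrometres.
#' @return An object of class `field_geometry`: a named list with elements
#'   `width`, `height`, `origin`.
#' @examples
#' field_geometry()
#' @export
field_geometry <- function(width = 1000, height = 1000, origin = c(0, 0)) {
  check_number(width, "width", lower = 1e-9)
  check_number(height, "height", lower = 1e-9)
  stopifnot(is.numeric(origin), length(origin) == 2L)
  structure(list(width = width, height = height, origin = as.numeric(origin)),
            class = "field_geometry")
}

#' @export
print.field_geometry <- function(x, ...) {
  cat(sprintf("<field_geometry> %g x %g um, origin (%g, %g)\n",
              x$width, x$height, x$origin[1], x$origin[2]))
  invisible(x)
}

field_center <- function(geometry) {
  geometry$origin + c(geometry$width, geometry$height) / 2
}

# Inter-event background intervals (s), configurable per protocol call. Bar
# protocols use a longer interval so that trailing-edge responses of sluggish
# cells (latency + response duration) are fully contained in the counting
# window even when the bar exits the field just before the response starts.
DEFAULT_GAP <- 0.5
BAR_GAP <- 1.0

# Common event-table skeleton. Square events keep their side length in both
# bar_width and bar_length so one schema serves both kinds.
new_stimulus_set <- function(events, protocol, geometry, seed, gap) {
  events <- tibble::as_tibble(events)
  # seeded pseudo-random presentation order
  ord <- with_seed(seed, sample.int(nrow(events)))
  events <- events[ord, , drop = FALSE]
  dur <- events$duration
  onset <- cumsum(c(0, (dur + gap)[-length(dur)]))
  events$onset_s <- onset
  events$offset_s <- onset + dur
  events$duration <- NULL
  events$event_index <- seq_len(nrow(events))
  events$protocol <- protocol
  cols <- c("protocol", "event_index", "kind", "center_x", "center_y",
            "direction_deg", "speed", "bar_width", "bar_length", "offset",
            "contrast", "repetition", "onset_s", "offset_s")
  events <- events[, cols]
  structure(events,
            class = c("stimulus_set", class(events)),
            protocol_name = protocol, geometry = geometry,
            rng_seed = seed, gap = gap)
}

bar_skeleton <- function(n) {
  tibble::tibble(
    kind = rep("bar", n), center_x = NA_real_, center_y = NA_real_,
    direction_deg = NA_real_, speed = NA_real_, bar_width = NA_real_,
    bar_length = NA_real_, offset = 0, contrast = 1, repetition = 1L,
    duration = NA_real_
  )
}

# Every bar travels a path of fixed length equal to the larger field extent,
# centred on the field centre, so offset/onset arithmetic is uniform across
# directions (see the methods vignette for the corner-coverage caveat).
travel_extent <- function(geometry) max(geometry$width, geometry$height)

#' Marching-square receptive-field mapping protocol
#'
#' A 100 x 100 um square is flashed at 81 pseudo-randomly ordered locations
#' tiling a 900 x 900 um area (9 x 9 lattice, centres 100 um apart), five
#' repetitions per location, 2 s per presentation. Each presentation is a 1 s
#' bright phase followed by a 1 s return to the mean-luminance background, so
#' ON responses are anchored to square onset and OFF responses to square
#' offset.
#'
#' @param geometry A [field_geometry()]; must admit the 900 x 900 um grid.
#' @param seed Integer seed controlling the presentation order.
#' @param side Square side length (um).
#' @param n_rep Repetitions per location.
#' @param duration Presentation duration (s); the bright phase is the first
#'   half.
#' @param gap Inter-event background interval (s).
#' @return A `stimulus_set` tibble with one row per presentation (405 by
#'   default).
#' @examples
#' ms <- stim_marching_square(seed = 1)
#' nrow(ms) # 405
#' @export
stim_marching_square <- function(geometry = field_geometry(), seed = 0,
                                 side = 100, n_rep = 5, duration = 2,
                                 gap = DEFAULT_GAP) {
  grid_extent <- 9 * side
  if (geometry$width < grid_extent || geometry$height < grid_extent) {
    stop(sprintf(
      "geometry (%g x %g um) too small for the %g x %g um square grid",
      geometry$width, geometry$height, grid_extent, grid_extent),
      call. = FALSE)
  }
  # 9x9 half-open cells from the field origin; centres at origin + 50 + 100 i
  x0 <- geometry$origin[1]
  y0 <- geometry$origin[2]
  centers <- expand.grid(ix = 0:8, iy = 0:8)
  ev <- tidyr::expand_grid(loc = seq_len(81), repetition = seq_len(n_rep))
  events <- tibble::tibble(
    kind = "square",
    center_x = x0 + side / 2 + side * centers$ix[ev$loc],
    center_y = y0 + side / 2 + side * centers$iy[ev$loc],
    direction_deg = NA_real_, speed = NA_real_,
    bar_width = side, bar_length = side, offset = 0,
    contrast = 1, repetition = as.integer(ev$repetition),
    duration = duration
  )
  new_stimulus_set(events, "marching_square", geometry, seed, gap)
}

#' Narrow moving bars (direction-selectivity protocol)
#'
#' Bright bars with a 1000 um extent along the motion axis and 500 um
#' orthogonal extent travel in eight equally spaced directions, at lateral
#' offsets of -250, 0 and 250 um orthogonal to the travel vector, at each of
#' the given speeds.
#'
#' @inheritParams stim_marching_square
#' @param speeds Bar speeds in um/s, each in (0, 5000].
#' @return A `stimulus_set` with `8 * 3 * length(speeds)` rows (48 by
#'   default).
#' @export
stim_narrow_bars <- function(geometry = field_geometry(), seed = 0,
                             speeds = c(600, 1200), gap = BAR_GAP) {
  if (length(speeds) == 0) stop("`speeds` must be non-empty", call. = FALSE)
  if (any(speeds <= 0 | speeds > 5000)) {
    stop("all `speeds` must lie in (0, 5000] um/s", call. = FALSE)
  }
  ctr <- field_center(geometry)
  grid <- tidyr::expand_grid(direction_deg = seq(0, 315, by = 45),
                             offset = c(-250, 0, 250),
                             speed = as.numeric(speeds))
  events <- bar_skeleton(nrow(grid))
  events$center_x <- ctr[1]
  events$center_y <- ctr[2]
  events$direction_deg <- grid$direction_deg
  events$offset <- grid$offset
  events$speed <- grid$speed
  events$bar_width <- 1000
  events$bar_length <- 500
  events$duration <- (travel_extent(geometry) + events$bar_width) / events$speed
  new_stimulus_set(events, "narrow_bars", geometry, seed, gap)
}

#' Width test (spatial tuning protocol)
#'
#' Bright and dark full-length bars of five widths (extent along the motion
#' axis) moving in four directions at two speeds: 5 x 2 x 4 x 2 = 80 events.
#'
#' @inheritParams stim_marching_square
#' @param widths Bar widths (um).
#' @param speeds Bar speeds (um/s).
#' @return A `stimulus_set` with 80 rows at the defaults.
#' @export
stim_width_test <- function(geometry = field_geometry(), seed = 0,
                            widths = c(75, 150, 300, 600, 900),
                            speeds = c(150, 900), gap = BAR_GAP) {
  ctr <- field_center(geometry)
  full_len <- sqrt(geometry$width^2 + geometry$height^2)
  grid <- tidyr::expand_grid(bar_width = as.numeric(widths),
                             contrast = c(1, -1),
                             direction_deg = seq(0, 270, by = 90),
                             speed = as.numeric(speeds))
  events <- bar_skeleton(nrow(grid))
  events$center_x <- ctr[1]
  events$center_y <- ctr[2]
  events$direction_deg <- grid$direction_deg
  events$speed <- grid$speed
  events$bar_width <- grid$bar_width
  events$contrast <- grid$contrast
  events$bar_length <- full_len
  events$duration <- (travel_extent(geometry) + events$bar_width) / events$speed
  new_stimulus_set(events, "width_test", geometry, seed, gap)
}

#' Speed test (temporal tuning protocol)
#'
#' Bright and dark bars of two widths moving in four directions at six speeds:
#' 2 x 2 x 4 x 6 = 96 events.
#'
#' @inheritParams stim_marching_square
#' @param widths Bar widths (um).
#' @param speeds Bar speeds (um/s).
#' @return A `stimulus_set` with 96 rows at the defaults.
#' @export
stim_speed_test <- function(geometry = field_geometry(), seed = 0,
                            widths = c(150, 600),
                            speeds = c(150, 300, 600, 900, 1200, 1800),
                            gap = BAR_GAP) {
  ctr <- field_center(geometry)
  full_len <- sqrt(geometry$width^2 + geometry$height^2)
  grid <- tidyr::expand_grid(bar_width = as.numeric(widths),
                             contrast = c(1, -1),
                             direction_deg = seq(0, 270, by = 90),
                             speed = as.numeric(speeds))
  events <- bar_skeleton(nrow(grid))
  events$center_x <- ctr[1]
  events$center_y <- ctr[2]
  events$direction_deg <- grid$direction_deg
  events$speed <- grid$speed
  events$bar_width <- grid$bar_width
  events$contrast <- grid$contrast
  events$bar_length <- full_len
  events$duration <- (travel_extent(geometry) + events$bar_width) / events$speed
  new_stimulus_set(events, "speed_test", geometry, seed, gap)
}

#' Generate all four stimulus protocols
#'
#' @inheritParams stim_marching_square
#' @return Named list with elements `marching_square`, `narrow_bars`,
#'   `width_test`, `speed_test`.
#' @export
stimulus_protocols <- function(geometry = field_geometry(), seed = 0) {
  list(
    marching_square = stim_marching_square(geometry, seed),
    narrow_bars = stim_narrow_bars(geometry, seed + 1L),
    width_test = stim_width_test(geometry, seed + 2L),
    speed_test = stim_speed_test(geometry, seed + 3L)
  )
}

#' Time at which a moving bar's leading edge reaches a point
#'
#' The bar travels a straight path of length `travel_extent` (the larger field
#' dimension) centred on the field centre, displaced laterally by the event's
#' `offset`. The crossing time is the event onset plus the along-axis distance
#' from the leading edge's start position to the point, divided by the speed.
#'
#' @param event One-row bar event (a `stimulus_set` row or equivalent list).
#' @param point Numeric 2-vector (um).
#' @param geometry The [field_geometry()] the event was generated for.
#' @return Crossing time in seconds, or `NA` if the bar path never covers the
#'   point (laterally farther than `bar_length / 2` from the path axis, or
#'   beyond the travelled extent).
#' @export
bar_crossing_time <- function(event, point, geometry = field_geometry()) {
  stopifnot(is.numeric(point), length(point) == 2L)
  u <- dir_unit(event$direction_deg)[1, ]
  v <- c(-u[2], u[1])                      # leftward normal
  ctr <- field_center(geometry)
  rel <- point - ctr
  lateral <- sum(v * rel) - event$offset
  if (abs(lateral) > event$bar_length / 2) return(NA_real_)
  extent <- travel_extent(geometry)
  s <- extent / 2 + sum(u * rel)           # distance from leading-edge start
  if (s < 0 || s > extent) return(NA_real_)
  event$onset_s + s / event$speed
}

#' Write / read a stimulus event log
#'
#' Event logs are tab-separated with one row per presentation and the column
#' layout shared by all protocols. `read_event_log()` restores the table (and
#' `stimulus_set` class) exactly; numeric columns round-trip at full
#' precision.
#'
#' @param events A `stimulus_set` (or plain event tibble).
#' @param path File path.
#' @return `write_event_log()` returns `events` invisibly; `read_event_log()`
#'   returns a tibble of events.
#' @export
write_event_log <- function(events, path) {
  readr::write_tsv(tibble::as_tibble(events), path)
  invisible(events)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  spec <- readr::cols(
    protocol = readr::col_character(),
    event_index = readr::col_integer(),
    kind = readr::col_character(),
    repetition = readr::col_integer(),
    .default = readr::col_double()
  )
  out <- suppressWarnings(readr::read_tsv(path, col_types = spec, progress = FALSE))
  problems <- readr::problems(out)
  if (nrow(problems) > 0) {
    stop(sprintf("malformed event log '%s': %s at line %d, column %s",
                 path, problems$expected[1], problems$row[1],
                 as.character(problems$col[1])), call. = FALSE)
  }
  out
}
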