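make_psth <- function(rate, bin = 0.005, window = c(0, 1.5)) {
  tt <- seq(window[1] + bin / 2, window[2] - bin / 2, by = bin)
  rgctyper:::new_psth(rate, tt, bin, window, 1)
}

test_that("bias index hits its boundary values and is antisymmetric", {
  expect_equal(bias_index(10, 0), 1)
  expect_equal(bias_index(0, 10), -1)
  expect_equal(bias_index(7, 7), 0)
  expect_equal(bias_index(3, 9), -0.5)
  expect_true(is.na(bias_index(0, 0)))
  set.seed(4)
  for (i in 1:50) {
    a <- runif(1, 0, 20); b <- runif(1, 0, 20)
    expect_equal(bias_index(a, b), -bias_index(b, a))
    expect_lte(abs(bias_index(a, b)), 1)
  }
})

test_that("latency finds the smoothed-rate peak, earliest on ties", {
  # one spike at 0.140 s in every repetition, 5 ms bins
  counts <- numeric(300)
  counts[ceiling(0.140 / 0.005) + 1] <- 10
  lat <- response_latency(make_psth(counts))
  expect_gte(lat, 0.1275)
  expect_lte(lat, 0.1525)
  # uniform PSTH: earliest maximising bin
  expect_equal(response_latency(make_psth(rep(2, 300))), 0.0025)
  expect_true(is.na(response_latency(make_psth(rep(0, 300)))))
})

test_that("transience matches closed forms", {
  expect_equal(transience_index(make_psth(rep(7, 300))), 1)
  one_bin <- numeric(300); one_bin[40] <- 3
  expect_equal(transience_index(make_psth(one_bin)), 0.005 / 1.5)
  # exponential decay, tau = 0.2 s: integral oracle tau (1 - e^{-1.5/tau}) / 1.5
  bin <- 0.0005
  tt <- seq(bin / 2, 1.5 - bin / 2, by = bin)
  p <- rgctyper:::new_psth(exp(-tt / 0.2), tt, bin, c(0, 1.5), 1)
  expect_equal(transience_index(p), 0.2 * (1 - exp(-1.5 / 0.2)) / 1.5,
               tolerance = 2e-3)
  expect_error(transience_index(make_psth(rep(1, 100), window = c(0, 0.5))),
               "1.5 s")
})

test_that("DS index boundary values and invariances", {
  dirs <- seq(0, 315, by = 45)
  expect_equal(ds_index(rep(5, 8), dirs), 0, tolerance = 1e-12)
  expect_equal(ds_index(c(5, rep(0, 7)), dirs), 1)
  expect_equal(ds_index(c(3, 0, 0, 0, 3, 0, 0, 0), dirs), 0, tolerance = 1e-12)
  expect_true(is.na(ds_index(rep(0, 8), dirs)))
  # scale invariance
  set.seed(7)
  r <- runif(8)
  expect_equal(ds_index(r, dirs), ds_index(17.3 * r, dirs))
})

test_that("DS index equals the brute-force complex-sum oracle", {
  set.seed(11)
  dirs <- seq(0, 315, by = 45)
  worst <- max(vapply(seq_len(10000), function(i) {
    r <- stats::rexp(8)
    abs(ds_index(r, dirs) - dsi_brute(r, dirs))
  }, numeric(1)))
  expect_lt(worst, 1e-12)
})

test_that("receptive field closed-form examples", {
  # single supra-threshold location, nearest-neighbour variant
  m <- matrix(0, 9, 9); m[5, 5] <- 1
  rf <- receptive_field(m, interp = "nearest")
  expect_equal(rf$area, 10000)
  expect_equal(rf$diameter, sqrt(4 * 1e4 / pi), tolerance = 1e-9)
  expect_equal(rf$center, c(450, 450))
  # all locations equal: the whole mapped area
  rf2 <- receptive_field(matrix(2, 9, 9))
  expect_equal(rf2$area, 810000)
  expect_equal(rf2$diameter, sqrt(4 * 810000 / pi), tolerance = 1e-9)
  expect_error(receptive_field(matrix(0, 9, 9)), "positive")
})

test_that("receptive-field diameter is recovered within 15% at archetype scale", {
  protocols <- stimulus_protocols(seed = 0)
  for (xy in list(c(430, 470), c(505, 455), c(380, 605))) {
    cell <- one_cell(one_archetype("ON"), x = xy[1], y = xy[2])
    par <- expected_parameters(cell, protocols)
    expect_lt(abs(par$rf_diameter_um - cell$rf_diameter) / cell$rf_diameter,
              0.15)
  }
})

test_that("bar offset selection picks the axis nearest the RF centre", {
  nb <- stim_narrow_bars(seed = 1)
  rate_zero <- function(ev) 0
  # centre on the 0-offset axis: offset 0 chosen in every direction
  sel <- select_bar_responses(c(500, 500), nb, rate_zero)
  expect_true(all(sel$offset == 0))
  # displaced +200 um orthogonally to direction 0: +250 offset chosen there
  sel2 <- select_bar_responses(c(500, 700), nb, rate_zero)
  expect_equal(sel2$offset[sel2$direction_deg == 0], 250)
  expect_equal(sel2$offset[sel2$direction_deg == 180], -250)
})

test_that("preferred indices follow the weighted-mean definition", {
  speeds <- c(150, 300, 600, 900, 1200, 1800)
  expect_equal(preferred_index(c(0, 0, 0, 0, 0, 4), speeds), 1)
  widths <- c(75, 150, 300, 600, 900)
  expect_equal(preferred_index(c(0, 0, 0, 0, 2), widths), 1)
  expect_equal(preferred_index(rep(3, 5), widths), 405 / 900)
  expect_true(is.na(preferred_index(rep(0, 5), widths)))
})

test_that("responsiveness filter keeps responders and tags failures", {
  protocols <- stimulus_protocols(seed = 0)
  pop <- sample_population(degenerate_archetypes()[c(3, 6), ],
                           n_per_archetype = 1, seed = 2, margin = 250)
  par <- expected_parameters(pop, protocols)
  kept <- responsiveness_filter(par)
  expect_equal(nrow(kept), 2)
  # forge a cell silent during the speed test only
  par2 <- par
  par2$responded_speed_test[1] <- FALSE
  par2$responded_all[1] <- FALSE
  kept2 <- responsiveness_filter(par2)
  expect_equal(nrow(kept2), 1)
  disc <- attr(kept2, "discarded")
  expect_equal(disc$failed_protocols, "speed_test")
})

test_that("a baseline-only Poisson cell is discarded as non-responsive", {
  protocols <- list(
    marching_square = stim_marching_square(seed = 1),
    narrow_bars = stim_narrow_bars(seed = 2),
    width_test = stim_width_test(seed = 3),
    speed_test = stim_speed_test(seed = 4)
  )
  spikes <- purrr::map_dfr(names(protocols), function(pn) {
    t_end <- max(protocols[[pn]]$offset_s)
    tibble::tibble(cell_id = 1L, protocol = pn,
                   time_s = spikes_from_rate(function(t) rep(3, length(t)),
                                             t_end, seed = match(pn, names(protocols)),
                                             lambda_max = 3))
  })
  par <- extract_parameters(spikes, protocols)
  expect_false(par$responded_all)
})

test_that("spike-based extraction agrees with the noiseless path at high rates", {
  protocols <- stimulus_protocols(seed = 0)
  arch <- one_archetype("ON")
  arch$peak_rate <- 150
  cell <- one_cell(arch, x = 450, y = 450)
  spikes <- simulate_retina(cell, protocols, seed = 31)
  par_sp <- extract_parameters(spikes, protocols)
  par_nl <- expected_parameters(cell, protocols)
  expect_lt(abs(par_sp$bias_index - par_nl$bias_index), 0.1)
  expect_lt(abs(par_sp$latency_s - par_nl$latency_s), 0.03)
  expect_lt(abs(par_sp$transience - par_nl$transience), 0.15)
  expect_lt(abs(par_sp$rf_diameter_um - par_nl$rf_diameter_um) /
              par_nl$rf_diameter_um, 0.25)
  expect_lt(abs(par_sp$ds_index - par_nl$ds_index), 0.15)
  expect_true(par_sp$responded_all)
})
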