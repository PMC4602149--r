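test_that("population sampling counts, determinism and degenerate draws", {
  pop <- sample_population(n_per_archetype = 5, seed = 3)
  expect_equal(nrow(pop), 7 * 5)
  expect_true(all(table(pop$archetype) == 5))
  expect_identical(pop, sample_population(n_per_archetype = 5, seed = 3))
  expect_false(identical(pop, sample_population(n_per_archetype = 5, seed = 4)))

  # all sd parameters zero: cells of an archetype identical except position
  a <- degenerate_archetypes()[1, ]
  pop0 <- sample_population(a, n_per_archetype = 4, seed = 1)
  fixed <- setdiff(names(pop0), c("cell_id", "rf_x", "rf_y"))
  expect_true(all(vapply(pop0[fixed], function(x) length(unique(x)) == 1,
                         logical(1))))
  expect_gt(length(unique(pop0$rf_x)), 1)

  expect_error(sample_population(rgc_archetypes()[0, ], 3), "non-empty")
})

test_that("drive gives equal bar gains in all directions for non-DS cells", {
  cell <- one_cell(one_archetype("ON"), x = 500, y = 500)
  nb <- stim_narrow_bars(seed = 1)
  rf <- drive_cell(cell, nb)
  ev <- tibble::as_tibble(nb)
  gains <- vapply(ev$event_index[ev$offset == 0 & ev$speed == 600], function(e) {
    sum(rf$gain[rf$event_index == e])
  }, numeric(1))
  expect_equal(max(gains) / min(gains), 1, tolerance = 1e-9)
})

test_that("OFF cells are not driven at bright-square onset", {
  cell <- one_cell(one_archetype("OFF"), x = 450, y = 450)
  ms <- stim_marching_square(seed = 1)
  rf <- drive_cell(cell, ms)
  ev <- tibble::as_tibble(ms)
  best <- ev[which.min((ev$center_x - 450)^2 + (ev$center_y - 450)^2), ][1, ]
  # rate within the bright phase preceding the square's disappearance stays
  # at baseline (the OFF kernel starts only after offset)
  tt <- seq(best$onset_s + 0.01, best$onset_s + 0.9, by = 0.01)
  expect_equal(rate_at(rf, tt), rep(cell$baseline_rate, length(tt)))
  # and there is a response after square offset
  t2 <- seq(best$onset_s + 1, best$onset_s + 2, by = 0.01)
  expect_gt(max(rate_at(rf, t2)), cell$baseline_rate + 1)
})

test_that("DS gain ratio between preferred and null matches the von Mises form", {
  kappa <- 1.5
  cell <- one_cell(one_archetype("ON", is_ds = TRUE, kappa = kappa,
                                 preferred_direction = 0), x = 500, y = 500)
  nb <- stim_narrow_bars(seed = 1)
  rf <- drive_cell(cell, nb)
  ev <- tibble::as_tibble(nb)
  g_of <- function(dir) {
    sum(rf$gain[rf$event_index %in%
                  ev$event_index[ev$direction_deg == dir & ev$offset == 0 &
                                   ev$speed == 600]])
  }
  expect_equal(g_of(0) / g_of(180), exp(2 * kappa), tolerance = 1e-9)
  expect_equal(g_of(0) / g_of(90), exp(kappa), tolerance = 1e-9)
})

test_that("constant-rate spiking has Poisson-scale counts; zero rate is silent", {
  st <- spikes_from_rate(function(t) rep(10, length(t)), 100, seed = 11,
                         refractory = 0, lambda_max = 10)
  expect_lt(abs(length(st) - 1000), 3 * sqrt(1000))
  expect_true(all(diff(st) > 0))
  expect_length(spikes_from_rate(function(t) rep(0, length(t)), 50, seed = 1,
                                 lambda_max = 1), 0)
})

test_that("refractory deletion leaves no sub-refractory intervals", {
  st <- spikes_from_rate(function(t) rep(200, length(t)), 20, seed = 2,
                         refractory = 0.002, lambda_max = 200)
  expect_true(all(diff(st) >= 0.002))
})

test_that("thinning agrees with a time-rescaling oracle on a ramp rate", {
  # lambda(t) = 2 t on [0, 100]: Lambda(t) = t^2, so rescaled unit-rate
  # arrivals map back through sqrt()
  t_end <- 100
  thin <- spikes_from_rate(function(t) 2 * t, t_end, seed = 5,
                           refractory = 0, lambda_max = 2 * t_end)
  rescale <- local({
    set.seed(99)
    arr <- cumsum(stats::rexp(12000))
    sqrt(arr[arr < t_end^2])
  })
  expect_gt(length(thin), 9000)
  ks <- suppressWarnings(stats::ks.test(thin, rescale))
  expect_gt(ks$p.value, 0.001)
})

test_that("closing the loop: noiseless extraction recovers the generating values", {
  protocols <- stimulus_protocols(seed = 0)
  pop <- sample_population(degenerate_archetypes(), n_per_archetype = 2,
                           seed = 21, margin = 250)
  par <- expected_parameters(pop, protocols)
  bi_target <- c(ON = 1, OFF = -1, ON_OFF = 0)[pop$polarity]
  expect_true(all(abs(par$bias_index - bi_target) <= 0.1))
  expect_true(all(abs(par$latency_s - pop$latency) <= 0.015))
  expect_true(all(abs(par$transience - pop$transience_target) <= 0.05))
  expect_true(all(abs(par$rf_diameter_um - pop$rf_diameter) /
                    pop$rf_diameter <= 0.15))
  dsi_target <- ifelse(pop$is_ds,
                       vapply(seq_len(nrow(pop)), function(i) {
                         if (!pop$is_ds[i]) return(0)
                         ds_index_von_mises(pop$ds_concentration[i],
                                            phase = pop$preferred_direction[i] %% 45)
                       }, numeric(1)), 0)
  expect_true(all(abs(par$ds_index - dsi_target) <= 0.1))
  expect_true(all(par$responded_all))
})

test_that("extracted DS index increases with the concentration parameter", {
  protocols <- stimulus_protocols(seed = 0)
  dsi <- vapply(c(0.5, 1.5, 3), function(k) {
    cell <- one_cell(one_archetype("ON", is_ds = TRUE, kappa = k,
                                   preferred_direction = 20),
                     x = 480, y = 520)
    expected_parameters(cell, protocols)$ds_index
  }, numeric(1))
  expect_true(all(diff(dsi) > 0))
})

test_that("transience calibration honours its target and rejects impossible ones", {
  for (tgt in c(0.1, 0.25, 0.5)) {
    td <- calibrate_tau_d(0.12, tgt, "ON")
    expect_equal(rgctyper:::model_transience(td, 0.12, "ON"), tgt,
                 tolerance = 1e-4)
  }
  expect_error(calibrate_tau_d(0.5, 0.95, "ON"), "not attainable")
})

test_that("rendered traces embed cells at the right scale", {
  # zero cells: pure noise at the requested RMS
  blk0 <- render_traces(tibble::tibble(cell_id = integer(0), x = numeric(0),
                                       y = numeric(0)),
                        tibble::tibble(cell_id = integer(0),
                                       time_s = numeric(0)),
                        duration = 2, config = electrode_config(4, 6),
                        noise_rms = 2.4, seed = 1)
  expect_lt(abs(sqrt(mean(blk0$samples^2)) - 2.4) / 2.4, 0.05)

  # one noiseless cell: thresholding recovers the exact ground-truth count
  cells <- tibble::tibble(cell_id = 1L, x = 40, y = 30, amplitude = 120)
  trains <- tibble::tibble(cell_id = 1L, time_s = seq(0.1, 1.9, by = 0.05))
  blk1 <- render_traces(cells, trains, duration = 2,
                        config = electrode_config(4, 6), noise_rms = 0,
                        seed = 1)
  det <- detect_spikes(blk1)
  pe <- det$electrode[which.max(det$peak_to_peak)]
  expect_equal(sum(det$electrode == pe), length(trains$time_s))

  # two cells 100 um apart: distinct peak electrodes
  cells2 <- tibble::tibble(cell_id = 1:2, x = c(30, 130), y = c(30, 30),
                           amplitude = c(150, 150))
  trains2 <- tibble::tibble(cell_id = rep(1:2, each = 10),
                            time_s = rep(seq(0.1, 1, by = 0.1), 2))
  blk2 <- render_traces(cells2, trains2, duration = 1.5,
                        config = electrode_config(4, 10), noise_rms = 0,
                        seed = 1)
  p2p <- apply(blk2$samples, 1, function(x) max(x) - min(x))
  cfg <- blk2$electrodes
  top2 <- order(-p2p)
  e1 <- which.min((cfg$x - 30)^2 + (cfg$y - 30)^2)
  e2 <- which.min((cfg$x - 130)^2 + (cfg$y - 30)^2)
  expect_equal(cfg$x[e1] != cfg$x[e2], TRUE)
  expect_gt(p2p[e1], 100)
  expect_gt(p2p[e2], 100)
})

test_that("simulated spike trains are reproducible from the seed", {
  protocols <- list(narrow_bars = stim_narrow_bars(seed = 1))
  pop <- sample_population(n_per_archetype = 1, seed = 5)[1:2, ]
  s1 <- simulate_retina(pop, protocols, seed = 8)
  s2 <- simulate_retina(pop, protocols, seed = 8)
  expect_identical(s1, s2)
})
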