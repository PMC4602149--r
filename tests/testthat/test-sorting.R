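test_that("band-pass filter has the designed stop/pass behaviour", {
  sr <- 20000
  t <- seq(0, 1 - 1 / sr, by = 1 / sr)
  blk <- list(samples = rbind(sin(2 * pi * 50 * t),
                              sin(2 * pi * 1000 * t),
                              rep(3, length(t))),
              sample_rate = sr)
  out <- bandpass_traces(blk)
  mid <- 5000:15000  # avoid filter edge transients
  # 50 Hz attenuated by >= 40 dB
  expect_lt(max(abs(out$samples[1, mid])), 10^(-40 / 20))
  # 1 kHz within 1 dB of unity
  expect_gt(max(abs(out$samples[2, mid])), 10^(-1 / 20))
  expect_lt(max(abs(out$samples[2, mid])), 10^(1 / 20))
  # DC removed
  expect_lt(mean(abs(out$samples[3, mid])), 1e-3)
  expect_error(bandpass_traces(blk, 300, 11000), "Nyquist")
})

test_that("detection recovers noiseless spikes exactly and respects k_sd", {
  cells <- tibble::tibble(cell_id = 1L, x = 40, y = 30, amplitude = 100)
  trains <- tibble::tibble(cell_id = 1L, time_s = seq(0.05, 4.95, by = 0.035))
  blk <- render_traces(cells, trains, duration = 5,
                       config = electrode_config(4, 6), noise_rms = 0, seed = 1)
  det <- detect_spikes(blk)
  pe <- det$electrode[which.max(det$peak_to_peak)]
  expect_equal(sum(det$electrode == pe), nrow(trains))
  # enormous threshold: nothing detected on a noisy block
  blk2 <- render_traces(cells, trains, duration = 5,
                        config = electrode_config(4, 6), noise_rms = 2.4,
                        seed = 1)
  blk2 <- bandpass_traces(blk2)
  expect_equal(nrow(detect_spikes(blk2, k_sd = 50)), 0)
  # monotonicity: raising k_sd never increases the count
  counts <- vapply(c(3, 3.5, 4.5, 6), function(k) {
    nrow(detect_spikes(blk2, k_sd = k))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("noise-only detection rate is consistent with the Gaussian-process level-crossing prediction", {
  sr <- 20000
  dur <- 10
  cfg <- electrode_config(2, 2, sample_rate = sr)
  blk <- render_traces(tibble::tibble(cell_id = integer(0), x = numeric(0),
                                      y = numeric(0)),
                       tibble::tibble(cell_id = integer(0), time_s = numeric(0)),
                       duration = dur, config = cfg, noise_rms = 2.4, seed = 3)
  blk <- bandpass_traces(blk)
  det <- detect_spikes(blk, k_sd = 3.5)
  fp_rate <- nrow(det) / (nrow(cfg) * dur)
  # Rice formula for the 300 Hz - 8 kHz band: downcrossings of -3.5 sd at
  # nu0 * exp(-3.5^2 / 2), nu0 = sqrt((f2^3 - f1^3) / (3 (f2 - f1)))
  nu0 <- sqrt((8000^3 - 300^3) / (3 * (8000 - 300)))
  pred <- nu0 * exp(-3.5^2 / 2)
  expect_gt(fp_rate, pred / 3)
  expect_lt(fp_rate, pred * 3)
})

test_that("PCA demixing separates two distinct waveforms with full purity", {
  cfg <- electrode_config(4, 8)
  # two cells near the same centre electrode but with distinct footprints
  cells <- tibble::tibble(cell_id = 1:2, x = c(52.5, 87.5), y = c(35, 35),
                          amplitude = c(200, 120))
  t1 <- seq(0.1, 9.9, by = 0.040)
  t2 <- seq(0.113, 9.9, by = 0.047)
  trains <- dplyr::bind_rows(tibble::tibble(cell_id = 1L, time_s = t1),
                             tibble::tibble(cell_id = 2L, time_s = t2))
  blk <- bandpass_traces(render_traces(cells, trains, 10, cfg,
                                       noise_rms = 2.4, seed = 5))
  det <- detect_spikes(blk)
  center <- which.min((cfg$x - 70)^2 + (cfg$y - 35)^2)
  clusters <- demix_group(blk, det, center)
  expect_gte(length(clusters), 2)
  # screen out noise-built clusters the same way the sorter does, then every
  # surviving cluster maps cleanly onto one ground-truth train
  sigma <- apply(blk$samples, 1, rgctyper:::robust_sd)
  clusters <- Filter(function(ss) {
    tm <- build_template(blk, ss)
    attr(tm, "peak_to_peak") >= 7 * sigma[attr(tm, "peak_electrode")]
  }, clusters)
  expect_gte(length(clusters), 2)
  purity <- vapply(clusters, function(ss) {
    tt <- (ss - 1) / blk$sample_rate
    hits1 <- mean(vapply(tt, function(x) min(abs(x - t1)) < 0.0015, logical(1)))
    hits2 <- mean(vapply(tt, function(x) min(abs(x - t2)) < 0.0015, logical(1)))
    max(hits1, hits2)
  }, numeric(1))
  expect_true(all(purity > 0.99))
})

test_that("identical snippets collapse to one zero-variance cluster", {
  cfg <- electrode_config(4, 6)
  cells <- tibble::tibble(cell_id = 1L, x = 40, y = 30, amplitude = 150)
  trains <- tibble::tibble(cell_id = 1L, time_s = seq(0.1, 9.9, by = 0.04))
  blk <- render_traces(cells, trains, 10, cfg, noise_rms = 0, seed = 1)
  det <- detect_spikes(blk)
  center <- det$electrode[which.max(det$peak_to_peak)]
  clusters <- demix_group(blk, det, center)
  expect_equal(length(clusters), 1)
  sn <- rgctyper:::cut_snippets(blk, clusters[[1]],
                                rgctyper:::electrode_group(cfg, center))
  expect_lt(max(apply(sn$mat, 2, stats::var)), 1e-12)
})

test_that("template matching recovers known times exactly in the noiseless limit", {
  cfg <- electrode_config(4, 6)
  cells <- tibble::tibble(cell_id = 1L, x = 40, y = 30, amplitude = 150)
  true_t <- seq(0.1, 9.9, by = 0.037)
  trains <- tibble::tibble(cell_id = 1L, time_s = true_t)
  blk <- render_traces(cells, trains, 10, cfg, noise_rms = 0, seed = 1)
  det <- detect_spikes(blk)
  tmpl <- build_template(blk, det$sample[det$electrode ==
                                           det$electrode[which.max(det$peak_to_peak)]])
  m <- match_template(blk, tmpl, det)
  expect_equal(nrow(m), length(true_t))
  err <- vapply(m$time_s, function(x) min(abs(x - true_t)), numeric(1))
  expect_lt(max(err), 1.5 / blk$sample_rate)
  # absent template: zero matches on a pure-noise block
  blk0 <- bandpass_traces(render_traces(
    tibble::tibble(cell_id = integer(0), x = numeric(0), y = numeric(0)),
    tibble::tibble(cell_id = integer(0), time_s = numeric(0)),
    duration = 5, config = cfg, noise_rms = 2.4, seed = 2))
  m0 <- match_template(blk0, tmpl, detect_spikes(blk0))
  expect_equal(nrow(m0), 0)
})

test_that("qc_merge merges duplicates, spares distinct units, honours violations", {
  # two fabricated templates: identical vs orthogonal
  sr <- 20000
  win <- (-10):20
  base <- matrix(0, 8, length(win))
  tA <- base; tA[3, ] <- -80 * exp(-((win - 0) / 4)^2)
  tB <- base; tB[7, ] <- 60 * sin(win / 3)
  mk_tmpl <- function(m) {
    structure(m, class = "template", source_count = 50,
              peak_electrode = which.max(apply(m, 1, function(x) max(abs(x)))),
              peak_sample = 11, peak_to_peak = max(m) - min(m),
              footprint = which(apply(m, 1, function(x) any(x != 0))),
              window = win)
  }
  mk_units <- function(tmpls, times) {
    structure(tibble::tibble(
      unit_id = seq_along(tmpls), n_spikes = lengths(times),
      violation_fraction = vapply(times, violation_fraction, numeric(1)),
      peak_electrode = 1L, peak_to_peak = 100,
      merged_from = as.list(seq_along(tmpls)),
      template = tmpls, times = times
    ), class = c("sorted_units", "tbl_df", "tbl", "data.frame"))
  }
  # identical templates, disjoint non-violating trains -> merged
  u1 <- mk_units(list(mk_tmpl(tA), mk_tmpl(tA)),
                 list(seq(0, 5, by = 0.01), seq(5.105, 10, by = 0.01)))
  merged <- qc_merge(u1)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$merged_from[[1]], c(1, 2))
  # orthogonal templates -> no merge
  u2 <- mk_units(list(mk_tmpl(tA), mk_tmpl(tB)),
                 list(seq(0, 5, by = 0.01), seq(5.105, 10, by = 0.01)))
  expect_equal(nrow(qc_merge(u2)), 2)
  # identical templates but interleaved trains violating the refractory rule
  ta <- seq(0, 5, by = 0.01)
  u3 <- mk_units(list(mk_tmpl(tA), mk_tmpl(tA)), list(ta, ta + 0.0005))
  expect_equal(nrow(qc_merge(u3)), 2)
  # idempotence
  expect_equal(qc_merge(merged)$times, merged$times)
})

test_that("end-to-end sorting on a small block recovers every cell", {
  cfg <- electrode_config(6, 12)
  cells <- tibble::tibble(cell_id = 1:3,
                          x = c(30, 100, 170), y = c(30, 60, 30),
                          amplitude = c(180, 120, 240))
  trains <- purrr::map_dfr(1:3, function(i) {
    tibble::tibble(cell_id = i,
                   time_s = spikes_from_rate(function(t) rep(8, length(t)),
                                             20, seed = 40 + i,
                                             lambda_max = 8))
  })
  blk <- render_traces(cells, trains, 20, cfg, noise_rms = 2.4, seed = 9)
  units <- sort_spikes(blk)
  expect_equal(nrow(units), 3)
  expect_true(all(units$violation_fraction <= 0.01))
  for (i in 1:3) {
    tt <- trains$time_s[trains$cell_id == i]
    best <- which.max(vapply(units$times, function(ut) {
      mean(vapply(tt, function(x) min(abs(x - ut)) < 5e-4, logical(1)))
    }, numeric(1)))
    recall <- mean(vapply(tt, function(x) {
      min(abs(x - units$times[[best]])) < 5e-4
    }, logical(1)))
    precision <- mean(vapply(units$times[[best]], function(x) {
      min(abs(x - tt)) < 5e-4
    }, logical(1)))
    expect_gte(recall, 0.95)
    expect_gte(precision, 0.98)
  }
})
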