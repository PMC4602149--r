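# Spike sorting: band-pass filtering, robust threshold detection,
# electrode-group PCA demixing, STA template construction, template-matching
# scan and duplicate-merge quality control.

SNIPPET_PRE <- 0.0005   # s before the negative peak
SNIPPET_POST <- 0.001   # s after

#' Zero-phase band-pass filter a trace block
#'
#' Second-order Butterworth band-pass applied forward and backward
#' (zero-phase) per electrode. Defaults: 300 Hz - 8 kHz.
#'
#' @param block A `trace_block`.
#' @param low,high Corner frequencies (Hz); `0 < low < high < Nyquist`.
#' @return The filtered `trace_block`.
#' @export
bandpass_traces <- function(block, low = 300, high = 8000) {
  nyq <- block$sample_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop(sprintf("need 0 < low < high < Nyquist (%g Hz)", nyq), call. = FALSE)
  }
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  for (e in seq_len(nrow(block$samples))) {
    block$samples[e, ] <- signal::filtfilt(bf, block$samples[e, ])
  }
  block
}

# robust per-electrode baseline SD: median absolute value / 0.6745, which is
# insensitive to the spikes riding on the baseline
robust_sd <- function(x) stats::median(abs(x)) / 0.6745

#' Threshold spike detection
#'
#' Negative threshold crossings at `k_sd` times the robust baseline SD per
#' electrode, deduplicated within a dead time, with the event anchored at the
#' negative peak.
#'
#' @param block A (band-passed) `trace_block`.
#' @param k_sd Threshold multiplier (> 0; default 3.5).
#' @param dead_time Per-electrode dead time between events (s).
#' @return Tibble of detections: `electrode`, `sample`, `time_s`, `value`
#'   (peak voltage, uV), `peak_to_peak` (uV), `threshold` (uV).
#' @export
detect_spikes <- function(block, k_sd = 3.5, dead_time = 0.001) {
  check_number(k_sd, "k_sd", lower = 1e-9)
  sr <- block$sample_rate
  dead <- max(1L, round(dead_time * sr))
  post <- round(SNIPPET_POST * sr)
  out <- vector("list", nrow(block$samples))
  for (e in seq_len(nrow(block$samples))) {
    x <- block$samples[e, ]
    thr <- k_sd * robust_sd(x)
    if (!is.finite(thr)) next
    cand <- which(x < -thr)
    if (length(cand) == 0) next
    # greedy peak picking: most negative first, enforce the dead time
    ord <- cand[order(x[cand])]
    taken <- integer(0)
    blocked <- logical(length(x))
    for (s in ord) {
      if (!blocked[s]) {
        taken <- c(taken, s)
        lo <- max(1L, s - dead); hi <- min(length(x), s + dead)
        blocked[lo:hi] <- TRUE
      }
    }
    taken <- sort(taken)
    # afterpotential suppression: a much shallower trough up to 2 ms after a
    # deep one on the same electrode is the filter undershoot of that spike,
    # not a new event
    if (length(taken) > 1) {
      span <- round(0.002 * sr)
      drop <- logical(length(taken))
      for (k in 2:length(taken)) {
        prev <- which(taken >= taken[k] - span & taken < taken[k] & !drop)
        if (length(prev) &&
            abs(x[taken[k]]) <= 0.35 * max(abs(x[taken[prev]]))) {
          drop[k] <- TRUE
        }
      }
      taken <- taken[!drop]
    }
    p2p <- vapply(taken, function(s) {
      hi <- min(length(x), s + post)
      max(x[s:hi]) - x[s]
    }, numeric(1))
    out[[e]] <- tibble::tibble(electrode = e, sample = taken,
                               time_s = (taken - 1) / sr,
                               value = x[taken], peak_to_peak = p2p,
                               threshold = thr)
  }
  dplyr::bind_rows(out)
}

# snippet matrix (events x electrodes*samples) cut around detection samples;
# row layout: electrode-major, samples within electrode
cut_snippets <- function(block, samples, electrodes) {
  sr <- block$sample_rate
  pre <- round(SNIPPET_PRE * sr)
  post <- round(SNIPPET_POST * sr)
  win <- (-pre):post
  ok <- samples + min(win) >= 1 & samples + max(win) <= ncol(block$samples)
  samples <- samples[ok]
  ne <- length(electrodes); nw <- length(win); n <- length(samples)
  if (n == 0) {
    return(list(mat = matrix(0, 0, ne * nw), samples = samples,
                window = win, kept = ok))
  }
  raw <- block$samples[electrodes, as.vector(outer(win, samples, "+")),
                       drop = FALSE]                    # ne x (nw*n)
  arr <- array(raw, c(ne, nw, n))
  mat <- t(matrix(aperm(arr, c(2, 1, 3)), nrow = nw * ne))
  list(mat = mat, samples = samples, window = win, kept = ok)
}

# the seven-electrode neighborhood (centre + six nearest) of one electrode
electrode_group <- function(config, center, size = 7) {
  d <- sqrt((config$x - config$x[center])^2 + (config$y - config$y[center])^2)
  order(d, config$electrode)[seq_len(min(size, nrow(config)))]
}

#' Demix detections on one electrode group by PCA + Gaussian mixture
#'
#' Snippets of detections anchored at the group's centre electrode are cut
#' across the seven-electrode neighborhood, projected onto the leading
#' principal components and clustered with a Gaussian mixture whose component
#' count is chosen by BIC.
#'
#' @param block Band-passed `trace_block`.
#' @param detections Output of [detect_spikes()].
#' @param center Centre electrode index.
#' @param n_pc Number of principal components (default 3).
#' @param min_events Minimum events per retained cluster (default 20).
#' @param max_components Maximum mixture components tried (default 5).
#' @param min_p2p Minimum peak-to-peak (uV) of a cluster's mean snippet over
#'   the group; clusters of threshold-crossing noise average out far below
#'   any real template and are dropped here cheaply (0 keeps everything).
#' @return List of integer sample vectors, one per retained cluster, or an
#'   empty list when the group has too few events.
#' @export
demix_group <- function(block, detections, center, n_pc = 3,
                        min_events = 20, max_components = 5, min_p2p = 0) {
  det <- detections[detections$electrode == center, ]
  if (nrow(det) < max(min_events, n_pc + 1)) return(list())
  grp <- electrode_group(block$electrodes, center)
  sn <- cut_snippets(block, det$sample, grp)
  if (nrow(sn$mat) < max(min_events, n_pc + 1)) return(list())
  pc <- stats::prcomp(sn$mat, center = TRUE, scale. = FALSE)
  k_use <- min(n_pc, ncol(pc$x))
  scores <- pc$x[, seq_len(k_use), drop = FALSE]
  if (max(pc$sdev) < 1e-12) {
    cls <- rep(1L, nrow(scores))      # identical snippets: one cluster
  } else {
    # fit the mixture on a subsample for speed, classify everything
    n_ev <- nrow(scores)
    fit_idx <- if (n_ev > 500) {
      unique(round(seq(1, n_ev, length.out = 500)))   # deterministic thinning
    } else seq_len(n_ev)
    fit <- mclust::Mclust(scores[fit_idx, , drop = FALSE],
                          G = seq_len(max_components), verbose = FALSE,
                          control = mclust::emControl(itmax = c(200, 200)))
    cls <- if (is.null(fit)) {
      rep(1L, n_ev)
    } else if (length(fit_idx) == n_ev) {
      fit$classification
    } else {
      stats::predict(fit, scores)$classification
    }
  }
  groups <- split(seq_along(sn$samples), cls)
  groups <- groups[vapply(groups, length, integer(1)) >= min_events]
  if (min_p2p > 0) {
    groups <- Filter(function(idx) {
      mean_snip <- colMeans(sn$mat[idx, , drop = FALSE])
      max(mean_snip) - min(mean_snip) >= min_p2p
    }, groups)
  }
  lapply(groups, function(idx) sn$samples[idx])
}

#' Spike-triggered average template
#'
#' Averages the band-passed traces around the given event samples over all
#' electrodes of the configuration, aligned at the negative peak.
#'
#' @param block Band-passed `trace_block`.
#' @param samples Integer event samples (negative-peak anchors).
#' @param min_source Minimum number of averaged events.
#' @param max_source Events averaged beyond this are thinned
#'   deterministically (the STA has converged long before).
#' @return A `template` object: electrodes x samples matrix with attributes
#'   `source_count`, `peak_electrode`, `peak_sample`, `peak_to_peak`,
#'   `footprint` (electrode indices), `window`.
#' @export
build_template <- function(block, samples, min_source = 20,
                           max_source = 200) {
  samples <- as.integer(samples)
  n_all <- length(samples)
  if (n_all > max_source) {
    samples <- samples[unique(round(seq(1, n_all, length.out = max_source)))]
  }
  sr <- block$sample_rate
  pre <- round(SNIPPET_PRE * sr)
  post <- round(SNIPPET_POST * sr)
  win <- (-pre):post
  samples <- samples[samples + min(win) >= 1 &
                       samples + max(win) <= ncol(block$samples)]
  if (length(samples) < min_source) {
    stop(sprintf("template needs >= %d source events, got %d",
                 min_source, length(samples)), call. = FALSE)
  }
  sta_of <- function(ss) {
    raw <- block$samples[, as.vector(outer(win, ss, "+")), drop = FALSE]
    rowMeans(array(raw, c(nrow(raw), length(win), length(ss))), dims = 2)
  }
  tmpl <- sta_of(samples)
  # realign each event on the negative peak of the strongest electrode:
  # detection-sample jitter on weak electrodes otherwise smears the STA
  pe0 <- which.max(apply(tmpl, 1, function(w) max(w) - min(w)))
  jit <- -3:3
  samples <- vapply(samples, function(s) {
    lo <- max(1L, s + min(jit)); hi <- min(ncol(block$samples), s + max(jit))
    seg <- block$samples[pe0, lo:hi]
    lo + which.min(seg) - 1L
  }, integer(1))
  samples <- samples[samples + min(win) >= 1 &
                       samples + max(win) <= ncol(block$samples)]
  tmpl <- sta_of(samples)
  p2p <- apply(tmpl, 1, function(w) max(w) - min(w))
  pe <- which.max(p2p)
  # electrodes that carry signal; a permissive floor would dilute the
  # matching score with noise-only channels on small cells
  footprint <- which(p2p > max(p2p) * 0.25)
  structure(tmpl, class = "template",
            source_count = length(samples), peak_electrode = pe,
            peak_sample = which.min(tmpl[pe, ]), peak_to_peak = p2p[pe],
            footprint = footprint, window = win, p2p_by_electrode = p2p)
}

#' Template-matching scan
#'
#' Scores candidate event times (threshold detections on the template's
#' footprint electrodes) by normalized least squares over the multi-electrode
#' template window: `score = 1 - RSS/TSS`, maximized over small lags.
#' Acceptances above `threshold` are resolved best-score-first with a 1 ms
#' exclusion per unit.
#'
#' @param block Band-passed `trace_block`.
#' @param template A [build_template()] result.
#' @param detections Detections from [detect_spikes()]; recomputed when
#'   `NULL`.
#' @param threshold Acceptance score (default 0.6).
#' @param max_lag Lag search half-width (s).
#' @param exclusion Minimum separation between accepted matches (s).
#' @return Tibble of matches: `time_s`, `sample`, `score`.
#' @export
match_template <- function(block, template, detections = NULL,
                           threshold = 0.6, max_lag = 0.00025,
                           exclusion = 0.001) {
  if (max(abs(template)) == 0) stop("degenerate all-zero template", call. = FALSE)
  if (is.null(detections)) detections <- detect_spikes(block)
  sr <- block$sample_rate
  fp <- attr(template, "footprint")
  win <- attr(template, "window")
  pe <- attr(template, "peak_electrode")
  lag <- round(max_lag * sr)
  # candidates: detections on the peak electrode (or its immediate footprint)
  # whose negative peak reaches at least half the template's -- noise
  # crossings at the detection threshold are far below any real template
  pk_val <- template[pe, attr(template, "peak_sample")]
  sel <- detections$electrode == pe & detections$value <= 0.5 * pk_val
  if (sum(sel) == 0) sel <- detections$electrode %in% fp
  cand <- detections$sample[sel]
  cand <- sort(unique(cand))
  if (length(cand) > 1) {
    keep <- c(TRUE, diff(cand) > round(0.0005 * sr))
    # keep the first of each close run; lags absorb the residual shift
    cand <- cand[keep]
  }
  lo <- 1L - (min(win) - lag)
  hi <- ncol(block$samples) - (max(win) + lag)
  cand <- cand[cand >= lo & cand <= hi]
  if (length(cand) == 0) {
    return(tibble::tibble(time_s = numeric(0), sample = integer(0),
                          score = numeric(0), energy = numeric(0)))
  }
  tvec <- as.vector(template[fp, , drop = FALSE])
  best_score <- rep(-Inf, length(cand))
  best_energy <- rep(0, length(cand))
  best_lag <- integer(length(cand))
  nfp <- length(fp)
  ns <- length(win)
  n_elec <- nrow(block$samples)
  for (l in (-lag):lag) {
    cols <- as.vector(outer(win + l, cand, "+"))   # sample index per (s, cand)
    # linear indices into the trace matrix: electrode fastest, then sample,
    # then candidate -- matches the column-major template vector
    idx <- rep((cols - 1) * n_elec, each = nfp) + fp
    snip <- matrix(block$samples[idx], nrow = nfp * ns)
    rss <- colSums((snip - tvec)^2)
    tss <- colSums(snip^2)
    sc <- 1 - rss / pmax(tss, 1e-12)
    better <- sc > best_score
    best_score[better] <- sc[better]
    best_lag[better] <- l
    best_energy[better] <- (tss - rss)[better]
  }
  acc <- which(best_score >= threshold)
  if (length(acc) == 0) {
    return(tibble::tibble(time_s = numeric(0), sample = integer(0),
                          score = numeric(0), energy = numeric(0)))
  }
  samp <- cand[acc] + best_lag[acc]
  sc <- best_score[acc]
  en <- best_energy[acc]
  # best-score-first exclusion
  ord <- order(-sc)
  taken <- integer(0)
  excl <- round(exclusion * sr)
  for (i in ord) {
    if (length(taken) == 0 || all(abs(samp[i] - samp[taken]) >= excl)) {
      taken <- c(taken, i)
    }
  }
  taken <- taken[order(samp[taken])]
  tibble::tibble(time_s = (samp[taken] - 1) / sr, sample = samp[taken],
                 score = sc[taken], energy = en[taken])
}

#' Refractory-period violation fraction of a spike train
#'
#' @param times Sorted spike times (s).
#' @param refractory Refractory period (s).
#' @return Fraction of inter-spike intervals shorter than `refractory`.
#' @export
violation_fraction <- function(times, refractory = 0.002) {
  if (length(times) < 2) return(0)
  mean(diff(sort(times)) < refractory)
}

# Pearson correlation of two multi-electrode templates over the union of
# their footprints, aligned at their negative peaks (small per-group peak
# jitter otherwise deflates the correlation of true duplicates).
template_correlation <- function(t1, t2) {
  fp <- union(attr(t1, "footprint"), attr(t2, "footprint"))
  shift <- (attr(t2, "peak_sample") %||% 0) - (attr(t1, "peak_sample") %||% 0)
  n <- ncol(t1)
  i1 <- seq(max(1, 1 + shift), min(n, n + shift))
  i2 <- i1 - shift
  a <- as.vector(t1[fp, i1, drop = FALSE])
  b <- as.vector(t2[fp, i2, drop = FALSE])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Merge duplicate sorted units
#'
#' Units whose multi-electrode templates correlate above `r_threshold` are
#' duplicate candidates; a candidate pair is accepted when the merged spike
#' train keeps its refractory-violation fraction at or below
#' `max_violation`. Merging is the transitive closure over accepted pairs;
#' the merged template is the source-count-weighted mean. Idempotent.
#'
#' @param units A `sorted_units` tibble (see [sort_spikes()]).
#' @param r_threshold Template Pearson correlation for duplicates (default
#'   0.90).
#' @param refractory Refractory period (s, default 2 ms).
#' @param max_violation Maximum tolerated violation fraction (default 0.01).
#' @return A `sorted_units` tibble with duplicates merged; `merged_from`
#'   lists the constituent unit ids.
#' @export
qc_merge <- function(units, r_threshold = 0.90, refractory = 0.002,
                     max_violation = 0.01) {
  n <- nrow(units)
  if (n == 0) stop("need at least one unit", call. = FALSE)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        r <- template_correlation(units$template[[i]], units$template[[j]])
        if (r > r_threshold) {
          merged <- sort(c(units$times[[i]], units$times[[j]]))
          if (violation_fraction(merged, refractory) <= max_violation) {
            parent[find(j)] <- find(i)
          }
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- purrr::map_dfr(unique(comp), function(cc) {
    idx <- which(comp == cc)
    times <- sort(unique(unlist(units$times[idx])))
    srcs <- vapply(units$template[idx], attr, numeric(1), "source_count")
    tmpl <- Reduce(`+`, purrr::map2(units$template[idx], srcs, `*`)) / sum(srcs)
    tmpl <- structure(tmpl, class = "template",
                      source_count = sum(srcs),
                      peak_electrode = attr(units$template[[idx[1]]], "peak_electrode"),
                      peak_sample = attr(units$template[[idx[1]]], "peak_sample"),
                      peak_to_peak = max(apply(tmpl, 1, function(w) max(w) - min(w))),
                      footprint = Reduce(union, purrr::map(units$template[idx], attr, "footprint")),
                      window = attr(units$template[[idx[1]]], "window"))
    tibble::tibble(
      unit_id = units$unit_id[idx[1]],
      n_spikes = length(times),
      violation_fraction = violation_fraction(times, refractory),
      peak_electrode = attr(tmpl, "peak_electrode"),
      peak_to_peak = attr(tmpl, "peak_to_peak"),
      merged_from = list(sort(unique(unlist(units$merged_from[idx])))),
      template = list(tmpl), times = list(times)
    )
  })
  class(out) <- c("sorted_units", class(out))
  out
}

#' Sort spikes from a trace block
#'
#' Runs the full chain: band-pass filter, robust threshold detection,
#' per-electrode-group PCA/mixture demixing, STA template construction,
#' template screening (peak-to-peak at least `min_template_snr` robust SDs),
#' duplicate collapsing, template-matching re-extraction of spike times, and
#' refractory-violation quality control with duplicate merging.
#'
#' @param block A raw `trace_block`.
#' @param k_sd Detection threshold multiplier.
#' @param min_events Minimum detections per electrode group / cluster.
#' @param match_threshold Template-matching acceptance score.
#' @param min_template_snr Minimum template peak-to-peak in units of the peak
#'   electrode's robust SD (screens noise-built templates).
#' @param refractory,max_violation Refractory QC settings.
#' @param filter Band-pass first (set `FALSE` if `block` is already
#'   filtered).
#' @return A `sorted_units` tibble: `unit_id`, `n_spikes`,
#'   `violation_fraction`, `peak_electrode`, `peak_to_peak`, `merged_from`,
#'   and list-columns `template`, `times`.
#' @export
sort_spikes <- function(block, k_sd = 3.5, min_events = 20,
                        match_threshold = 0.6, min_template_snr = 7,
                        refractory = 0.002, max_violation = 0.01,
                        filter = TRUE) {
  if (filter) block <- bandpass_traces(block)
  det <- detect_spikes(block, k_sd)
  if (nrow(det) == 0) {
    return(structure(tibble::tibble(
      unit_id = integer(0), n_spikes = integer(0),
      violation_fraction = numeric(0), peak_electrode = integer(0),
      peak_to_peak = numeric(0), merged_from = list(),
      template = list(), times = list()
    ), class = c("sorted_units", "tbl_df", "tbl", "data.frame")))
  }
  sigma <- apply(block$samples, 1, robust_sd)
  active <- as.integer(names(which(table(det$electrode) >= min_events)))
  templates <- list()
  for (e in active) {
    clusters <- demix_group(block, det, e, min_events = min_events,
                            min_p2p = min_template_snr * sigma[e])
    for (cl in clusters) {
      tmpl <- build_template(block, cl, min_source = min_events)
      pe <- attr(tmpl, "peak_electrode")
      if (attr(tmpl, "peak_to_peak") >= min_template_snr * sigma[pe]) {
        templates[[length(templates) + 1L]] <- tmpl
      }
    }
  }
  if (length(templates) == 0) {
    stop("no templates passed screening; nothing to sort", call. = FALSE)
  }
  # collapse duplicate candidate templates before the matching scan; keep
  # the sharpest (largest peak-to-peak) representative -- partially
  # misaligned clusters yield amplitude-diluted variants of the same unit
  # that still correlate above the duplicate threshold
  keep <- rep(TRUE, length(templates))
  amp <- vapply(templates, attr, numeric(1), "peak_to_peak")
  ord <- order(-amp)
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq_along(ord)) {
      j <- ord[b]
      if (i == j || !keep[j]) next
      if (amp[j] <= amp[i] &&
          template_correlation(templates[[i]], templates[[j]]) > 0.9) {
        keep[j] <- FALSE
      }
    }
  }
  templates <- templates[keep]
  matches <- purrr::map_dfr(seq_along(templates), function(i) {
    m <- match_template(block, templates[[i]], detections = det,
                        threshold = match_threshold)
    m$unit <- i
    m
  })
  # resolve the same spike being claimed by several templates (imperfectly
  # demixed blends correlate below the duplicate threshold but still match
  # their dominant cell): best score wins within 1 ms among units whose
  # footprints overlap
  n_t <- length(templates)
  fps <- lapply(templates, attr, "footprint")
  fp_overlap <- matrix(TRUE, n_t, n_t)
  for (i in seq_len(n_t)) for (j in seq_len(n_t)) {
    fp_overlap[i, j] <- length(intersect(fps[[i]], fps[[j]])) >
      0.3 * min(length(fps[[i]]), length(fps[[j]]))
  }
  excl <- round(0.001 * block$sample_rate)
  # resolve by explained energy (TSS - RSS): the score is scale-free, so a
  # small artifact template can score as well as the true large one
  matches <- matches[order(-matches$energy), , drop = FALSE]
  bins <- new.env(parent = emptyenv())
  accepted <- logical(nrow(matches))
  for (r in seq_len(nrow(matches))) {
    b <- matches$sample[r] %/% excl
    clash <- FALSE
    for (bb in (b - 1):(b + 1)) {
      prior <- bins[[as.character(bb)]]
      if (is.null(prior)) next
      near <- abs(prior$sample - matches$sample[r]) < excl
      if (any(near & fp_overlap[prior$unit, matches$unit[r]])) {
        clash <- TRUE
        break
      }
    }
    if (!clash) {
      accepted[r] <- TRUE
      key <- as.character(b)
      bins[[key]] <- rbind(bins[[key]],
                           data.frame(sample = matches$sample[r],
                                      unit = matches$unit[r]))
    }
  }
  matches <- matches[accepted, , drop = FALSE]
  units <- purrr::map_dfr(seq_len(n_t), function(i) {
    tm <- matches$time_s[matches$unit == i]
    tibble::tibble(
      unit_id = i, n_spikes = length(tm),
      violation_fraction = violation_fraction(tm, refractory),
      peak_electrode = attr(templates[[i]], "peak_electrode"),
      peak_to_peak = attr(templates[[i]], "peak_to_peak"),
      merged_from = list(i),
      template = list(templates[[i]]), times = list(sort(tm))
    )
  })
  units <- units[units$n_spikes >= min_events, , drop = FALSE]
  units <- units[units$violation_fraction <= max_violation, , drop = FALSE]
  if (nrow(units) == 0) stop("all units failed quality control", call. = FALSE)
  class(units) <- c("sorted_units", class(units))
  qc_merge(units, refractory = refractory, max_violation = max_violation)
}

#' Write a quality-control report for sorted units
#'
#' @param units A `sorted_units` tibble.
#' @param path CSV path.
#' @return The report tibble, invisibly.
#' @export
write_qc_report <- function(units, path) {
  rep <- tibble::tibble(
    unit_id = units$unit_id, n_spikes = units$n_spikes,
    violation_fraction = units$violation_fraction,
    peak_electrode = units$peak_electrode,
    peak_to_peak = units$peak_to_peak,
    merged_from = vapply(units$merged_from, paste, character(1), collapse = ";")
  )
  readr::write_csv(rep, path)
  invisible(rep)
}
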