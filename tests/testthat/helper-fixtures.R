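# Shared fixtures, built in code at test time.

# archetype table with all per-cell variability removed (recovery tests
# isolate the estimators from draw scatter; positions stay random)
degenerate_archetypes <- function() {
  a <- rgc_archetypes()
  a$latency_sd <- 0
  a$rf_diameter_sd <- 0
  a
}

# a single archetype row for targeted drive tests
one_archetype <- function(polarity = "ON", is_ds = FALSE, kappa = 0,
                          latency = 0.12, transience = 0.15,
                          preferred_direction = NA_real_) {
  a <- rgc_archetypes()[1, ]
  a$name <- "test"
  a$polarity <- polarity
  a$latency_mean <- latency
  a$latency_sd <- 0
  a$transience_target <- transience
  a$is_ds <- is_ds
  a$ds_concentration <- kappa
  a$preferred_direction <- preferred_direction
  a$rf_diameter_sd <- 0
  a
}

# one cell of a given archetype at a fixed position
one_cell <- function(arch = one_archetype(), x = 450, y = 450, seed = 1) {
  pop <- sample_population(arch, n_per_archetype = 1, seed = seed)
  pop$rf_x <- x
  pop$rf_y <- y
  pop
}

# small trace block with cells at given positions, homogeneous-Poisson trains
make_block <- function(n_cells = 3, duration = 5, rate = 10,
                       config = electrode_config(rows = 6, cols = 10),
                       amplitudes = NULL, noise_rms = 2.4, seed = 1,
                       spacing = 60) {
  xs <- seq(min(config$x) + 20, max(config$x) - 20,
            length.out = max(n_cells, 2))[seq_len(n_cells)]
  ys <- rep(c(30, 60), length.out = n_cells)
  cells <- tibble::tibble(cell_id = seq_len(n_cells), x = xs, y = ys)
  if (!is.null(amplitudes)) cells$amplitude <- amplitudes
  trains <- purrr::map_dfr(seq_len(n_cells), function(i) {
    tibble::tibble(cell_id = i,
                   time_s = spikes_from_rate(function(t) rep(rate, length(t)),
                                             duration, seed = seed + i,
                                             lambda_max = rate))
  })
  render_traces(cells, trains, duration, config, noise_rms = noise_rms,
                seed = seed)
}

# brute-force silhouette oracle: direct O(n^2) double loop over Eq.-style
# definitions, independent of the package implementation
silhouette_brute <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(vapply(setdiff(own, i), function(j) d(i, j), numeric(1)))
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(vapply(which(labels == cl), function(j) d(i, j), numeric(1)))
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# brute-force DS index oracle via complex arithmetic
dsi_brute <- function(rates, directions) {
  Mod(sum(rates * exp(1i * directions * pi / 180))) / sum(rates)
}
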