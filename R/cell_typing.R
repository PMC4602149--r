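# Functional cell typing: k-means sweep with silhouette-selected k, pairwise
# Fisher-discriminant separation, per-cluster characteristics, and the two
# confirmation diagnostics (receptive-field tiling, DS polar lobes).

CLUSTER_COLUMNS <- c("bias_index", "latency_s", "transience", "ds_index",
                     "speed_index")
# columns whose definition already confines them to [-1, 1] or [0, 1]
INTRINSIC_RANGE <- c("bias_index", "transience", "ds_index", "speed_index",
                     "width_index")

#' Normalize a parameter table for clustering
#'
#' Columns with an intrinsic `[-1, 1]` / `[0, 1]` range (bias, transience,
#' DS, speed, width indices) pass through unchanged; all others (latency,
#' receptive-field diameter) are min-max scaled to `[0, 1]`. The scaling
#' record is attached for inversion. Idempotent.
#'
#' @param params Parameter tibble (>= 2 rows).
#' @param columns Columns to keep, in order; defaults to the five clustered
#'   parameters.
#' @return A tibble of normalized columns with attributes `normalization`
#'   (tibble: `column`, `method`, `lo`, `hi`) and `cell_id`.
#' @export
normalize_parameters <- function(params, columns = CLUSTER_COLUMNS) {
  if (nrow(params) < 2) stop("need at least 2 cells", call. = FALSE)
  missing_cols <- setdiff(columns, names(params))
  if (length(missing_cols)) {
    stop("missing parameter columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(params[, columns]))) {
    stop("parameter table contains missing values; run responsiveness_filter() first",
         call. = FALSE)
  }
  rec <- purrr::map_dfr(columns, function(cn) {
    x <- params[[cn]]
    if (cn %in% INTRINSIC_RANGE) {
      tibble::tibble(column = cn, method = "identity", lo = NA_real_,
                     hi = NA_real_)
    } else {
      tibble::tibble(column = cn, method = "minmax", lo = min(x), hi = max(x))
    }
  })
  out <- purrr::map(columns, function(cn) {
    x <- params[[cn]]
    r <- rec[rec$column == cn, ]
    if (r$method == "identity") return(x)
    if (r$hi == r$lo) {
      warning(sprintf("column '%s' is constant; scaled to 0", cn),
              call. = FALSE)
      return(rep(0, length(x)))
    }
    (x - r$lo) / (r$hi - r$lo)
  })
  names(out) <- columns
  out <- tibble::as_tibble(out)
  attr(out, "normalization") <- rec
  attr(out, "cell_id") <- params$cell_id %||% seq_len(nrow(params))
  out
}

#' Mean silhouette value of a labelling
#'
#' Per-point silhouette `S_i = (b_i - a_i) / max(a_i, b_i)` with Euclidean
#' distance: `a_i` is the mean distance to the other members of the point's
#' own cluster, `b_i` the smallest mean distance to the members of any other
#' cluster. Points in singleton clusters score 0.
#'
#' @param x Numeric matrix or normalized parameter tibble (rows = cells).
#' @param labels Integer cluster labels (k >= 2).
#' @param dist_matrix Optional precomputed full distance matrix.
#' @return Mean silhouette over all points, in `[-1, 1]`.
#' @export
silhouette_mean <- function(x, labels, dist_matrix = NULL) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("silhouette undefined for a single cluster", call. = FALSE)
  if (is.null(dist_matrix)) {
    dist_matrix <- as.matrix(stats::dist(as.matrix(x)))
  }
  n <- nrow(dist_matrix)
  sizes <- tabulate(labels, k)
  ind <- matrix(0, n, k)
  ind[cbind(seq_len(n), labels)] <- 1
  sums <- dist_matrix %*% ind                  # n x k: summed distance to each cluster
  own <- sums[cbind(seq_len(n), labels)]
  a <- own / pmax(sizes[labels] - 1, 1)
  means_other <- sums / matrix(sizes, n, k, byrow = TRUE)
  means_other[cbind(seq_len(n), labels)] <- Inf
  b <- apply(means_other, 1, min)
  s <- (b - a) / pmax(pmax(a, b), .Machine$double.eps)
  s[sizes[labels] == 1] <- 0
  mean(s)
}

# best-of-restarts k-means; sequential single-start calls so that a longer
# restart budget strictly extends a shorter one under the same RNG state
kmeans_best <- function(x, k, restarts) {
  best <- NULL
  for (r in seq_len(restarts)) {
    km <- tryCatch(
      stats::kmeans(x, centers = k, iter.max = 100, nstart = 1),
      error = function(e) NULL
    )
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

#' k-means sweep with silhouette-based selection of k
#'
#' For each k in `k_range`, runs best-of-`restarts` k-means (squared
#' Euclidean objective) and scores the resulting labelling by mean
#' silhouette; returns the model with the highest mean silhouette, ties going
#' to the smallest k. Fully reproducible from `seed`.
#'
#' @param x Normalized parameter tibble (from [normalize_parameters()]) or a
#'   numeric matrix.
#' @param k_range Candidate cluster counts (default 4 to 25).
#' @param restarts Random restarts per k (default 5000).
#' @param seed Integer seed.
#' @return An `rgc_clusters` object: list with `k`, `labels`, `centroids`,
#'   `mean_silhouette`, `per_k` (tibble of k, mean silhouette, objective),
#'   `restarts`, `seed`, `data`, `cell_id`.
#' @export
sweep_k <- function(x, k_range = 4:25, restarts = 5000, seed = 0) {
  xm <- if (is.matrix(x)) x else as.matrix(tibble::as_tibble(x))
  storage.mode(xm) <- "double"
  if (any(!is.finite(xm))) stop("non-finite values in parameter matrix", call. = FALSE)
  n <- nrow(xm)
  if (any(k_range < 2)) stop("k_range must be >= 2", call. = FALSE)
  usable <- k_range[k_range < n]
  if (length(usable) < length(k_range)) {
    warning(sprintf("skipping k >= n (= %d)", n), call. = FALSE)
  }
  if (length(usable) == 0) stop("no usable k in k_range", call. = FALSE)
  D <- as.matrix(stats::dist(xm))
  fits <- with_seed(seed, {
    lapply(usable, function(k) kmeans_best(xm, k, restarts))
  })
  sil <- vapply(seq_along(usable), function(i) {
    if (is.null(fits[[i]])) return(-Inf)
    silhouette_mean(xm, fits[[i]]$cluster, D)
  }, numeric(1))
  per_k <- tibble::tibble(
    k = usable, mean_silhouette = sil,
    objective = vapply(fits, function(f) {
      if (is.null(f)) NA_real_ else f$tot.withinss
    }, numeric(1))
  )
  best_i <- which.max(sil)          # first max = smallest k on ties
  best <- fits[[best_i]]
  structure(list(
    k = usable[best_i], labels = best$cluster, centroids = best$centers,
    mean_silhouette = sil[best_i], per_k = per_k,
    restarts = restarts, seed = seed, data = xm,
    cell_id = attr(x, "cell_id") %||% seq_len(n)
  ), class = "rgc_clusters")
}

#' @export
print.rgc_clusters <- function(x, ...) {
  cat(sprintf("<rgc_clusters> k = %d (mean silhouette %.3f) over %d cells, %d restarts\n",
              x$k, x$mean_silhouette, nrow(x$data), x$restarts))
  invisible(x)
}

#' Pairwise Fisher-discriminant separation of two clusters
#'
#' Projects both clusters' points onto the axis joining their means in
#' parameter space and reports the distance between the means divided by the
#' average of the two groups' projection SDs — effectively the number of
#' standard deviations separating the clusters.
#'
#' @param x Numeric matrix / normalized tibble.
#' @param labels Cluster labels.
#' @param pair Length-2 vector of cluster ids to compare.
#' @param cap Value reported when both projection SDs are zero.
#' @return Separation coefficient (>= 0), with attribute `projection`: a
#'   tibble of per-group projection mean and SD.
#' @export
fisher_separation <- function(x, labels, pair, cap = 1e6) {
  xm <- if (is.matrix(x)) x else as.matrix(tibble::as_tibble(x))
  g1 <- xm[labels == pair[1], , drop = FALSE]
  g2 <- xm[labels == pair[2], , drop = FALSE]
  if (nrow(g1) < 2 || nrow(g2) < 2) {
    stop("both clusters need at least 2 members", call. = FALSE)
  }
  mu1 <- colMeans(g1); mu2 <- colMeans(g2)
  d <- sqrt(sum((mu2 - mu1)^2))
  if (d == 0) return(structure(0, projection = NULL))
  axis <- (mu2 - mu1) / d
  p1 <- as.vector(g1 %*% axis); p2 <- as.vector(g2 %*% axis)
  s1 <- stats::sd(p1); s2 <- stats::sd(p2)
  denom <- (s1 + s2) / 2
  sep <- if (denom == 0) cap else d / denom
  structure(sep, projection = tibble::tibble(
    cluster = pair, mean = c(mean(p1), mean(p2)), sd = c(s1, s2), d = d
  ))
}

#' Full pairwise separation matrix
#'
#' @inheritParams fisher_separation
#' @return Symmetric k x k matrix of separation coefficients (0 diagonal).
#' @export
separation_matrix <- function(x, labels, cap = 1e6) {
  ks <- sort(unique(labels))
  k <- length(ks)
  m <- matrix(0, k, k, dimnames = list(ks, ks))
  if (k < 2) return(m)
  sizes <- table(factor(labels, levels = ks))
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    m[i, j] <- m[j, i] <- if (sizes[i] < 2 || sizes[j] < 2) {
      NA_real_   # projection SD undefined for singleton clusters
    } else {
      as.numeric(fisher_separation(x, labels, c(ks[i], ks[j]), cap))
    }
  }
  m
}

#' Per-cluster parameter means and suggested type labels
#'
#' Computes the mean of every parameter per cluster and suggests a functional
#' type label: polarity from the mean bias index (thresholds +/- 0.33), DS
#' when the mean DS index exceeds 0.2, brisk/sluggish and
#' transient/sustained from median splits of the cluster-mean latency and
#' transience. Labels are descriptive only; membership never depends on them.
#'
#' @param params Full parameter tibble.
#' @param labels Cluster labels (same order as `params`).
#' @return Tibble: `cluster`, `n`, one mean column per parameter, and
#'   `suggested_label`.
#' @export
group_characteristics <- function(params, labels) {
  cols <- intersect(c("bias_index", "latency_s", "transience",
                      "rf_diameter_um", "ds_index", "speed_index",
                      "width_index"), names(params))
  out <- params[, cols]
  out$cluster <- labels
  means <- out |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(cols), mean),
                     .groups = "drop")
  lat_med <- stats::median(means$latency_s)
  tra_med <- stats::median(means$transience)
  means$suggested_label <- vapply(seq_len(nrow(means)), function(i) {
    pol <- if (means$bias_index[i] > 0.33) "ON"
    else if (means$bias_index[i] < -0.33) "OFF" else "ON-OFF"
    ds <- if (means$ds_index[i] > 0.2) "DS" else NULL
    speedy <- if (means$latency_s[i] <= lat_med) "brisk" else "sluggish"
    dur <- if (means$transience[i] <= tra_med) "transient" else "sustained"
    paste(c(pol, ds, speedy, dur), collapse = " ")
  }, character(1))
  means
}

# area of the lens-shaped intersection of two circles
circle_intersection_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - a3
}

#' Receptive-field tiling diagnostics per cluster
#'
#' For each cluster, the fraction of a reference rectangle covered by the
#' union of the members' 33%-contour receptive-field circles, and the mean
#' pairwise intersection-over-union of those circles. A functional type that
#' tiles the retina shows high coverage and low overlap.
#'
#' @param params Parameter tibble with `rf_x`, `rf_y`, `rf_diameter_um`.
#' @param labels Cluster labels.
#' @param rect Reference rectangle `c(xmin, xmax, ymin, ymax)` (um);
#'   typically the recording-configuration footprint.
#' @param raster Grid resolution per axis for the coverage estimate.
#' @return Tibble: `cluster`, `n`, `coverage`, `mean_overlap`,
#'   `overlap_defined`.
#' @export
tiling_report <- function(params, labels, rect, raster = 80) {
  gx <- seq(rect[1], rect[2], length.out = raster)
  gy <- seq(rect[3], rect[4], length.out = raster)
  grid <- expand.grid(x = gx, y = gy)
  purrr::map_dfr(sort(unique(labels)), function(cl) {
    sub <- params[labels == cl, , drop = FALSE]
    r <- sub$rf_diameter_um / 2
    inside <- rep(FALSE, nrow(grid))
    for (i in seq_len(nrow(sub))) {
      inside <- inside |
        ((grid$x - sub$rf_x[i])^2 + (grid$y - sub$rf_y[i])^2 <= r[i]^2)
    }
    n <- nrow(sub)
    if (n >= 2) {
      pairs <- utils::combn(n, 2)
      iou <- vapply(seq_len(ncol(pairs)), function(p) {
        i <- pairs[1, p]; j <- pairs[2, p]
        d <- sqrt((sub$rf_x[i] - sub$rf_x[j])^2 + (sub$rf_y[i] - sub$rf_y[j])^2)
        inter <- circle_intersection_area(r[i], r[j], d)
        inter / (pi * r[i]^2 + pi * r[j]^2 - inter)
      }, numeric(1))
      overlap <- mean(iou); defined <- TRUE
    } else {
      overlap <- 0; defined <- FALSE
    }
    tibble::tibble(cluster = cl, n = n, coverage = mean(inside),
                   mean_overlap = overlap, overlap_defined = defined)
  })
}

#' Polar summary of preferred directions in DS clusters
#'
#' Kernel density of the members' preferred directions on the circle (von
#' Mises kernel, 20 degree bandwidth by default); modes are local maxima
#' above half the density peak. A flat density (minimum above the mode
#' threshold) is flagged inconclusive.
#'
#' @param directions_deg Preferred directions (deg) of one cluster's cells.
#' @param bandwidth_deg Kernel bandwidth (deg).
#' @param mode_threshold Fraction of the peak a mode must exceed.
#' @return List of class `ds_polar_summary`: `n_modes`, `mode_directions`
#'   (deg), `inconclusive`, `density` (tibble `direction_deg`, `density`).
#' @export
ds_polar_summary <- function(directions_deg, bandwidth_deg = 20,
                             mode_threshold = 0.5) {
  directions_deg <- directions_deg[!is.na(directions_deg)]
  stopifnot(length(directions_deg) >= 1)
  kappa <- 1 / deg2rad(bandwidth_deg)^2
  grid <- 0:359
  dens <- vapply(grid, function(g) {
    mean(exp(kappa * (cos(deg2rad(g - directions_deg)) - 1)))
  }, numeric(1))
  dens <- dens / sum(dens)
  inconclusive <- min(dens) > mode_threshold * max(dens)
  nxt <- c(2:360, 1); prv <- c(360, 1:359)
  is_mode <- dens > dens[nxt] & dens >= dens[prv] &
    dens > mode_threshold * max(dens)
  structure(list(
    n_modes = sum(is_mode), mode_directions = grid[is_mode],
    inconclusive = inconclusive,
    density = tibble::tibble(direction_deg = grid, density = dens)
  ), class = "ds_polar_summary")
}

#' Cluster a parameter table into functional types
#'
#' Convenience wrapper: [normalize_parameters()] then [sweep_k()], keeping
#' the source parameter table attached for [tidy()], [augment()] and the
#' diagnostics. Clustering uses the five canonical parameters (bias index,
#' latency, transience, DS index, speed index); set `use_seven = TRUE` to add
#' the receptive-field diameter and width index.
#'
#' @param params Responsive-cell parameter tibble.
#' @param k_range,restarts,seed Passed to [sweep_k()].
#' @param use_seven Cluster on all seven parameters instead of five.
#' @return An `rgc_clusters` object with the parameter table in `$params`.
#' @export
cluster_cells <- function(params, k_range = 4:25, restarts = 5000, seed = 0,
                          use_seven = FALSE) {
  columns <- if (use_seven) {
    c(CLUSTER_COLUMNS, "rf_diameter_um", "width_index")
  } else CLUSTER_COLUMNS
  nm <- normalize_parameters(params, columns)
  model <- sweep_k(nm, k_range = k_range, restarts = restarts, seed = seed)
  model$params <- params
  model
}

# ---- broom-style methods ---------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted cluster model
#'
#' @param x An `rgc_clusters` object.
#' @param ... Unused.
#' @return One row per cluster: size, within-cluster silhouette and centroid
#'   coordinates.
#' @export
tidy.rgc_clusters <- function(x, ...) {
  cent <- tibble::as_tibble(x$centroids)
  D <- as.matrix(stats::dist(x$data))
  sil_by <- vapply(seq_len(x$k), function(cl) {
    # mean silhouette of the members of one cluster
    labels <- x$labels
    n <- nrow(D)
    sizes <- tabulate(labels, x$k)
    ind <- matrix(0, n, x$k); ind[cbind(seq_len(n), labels)] <- 1
    sums <- D %*% ind
    a <- sums[cbind(seq_len(n), labels)] / pmax(sizes[labels] - 1, 1)
    mo <- sums / matrix(sizes, n, x$k, byrow = TRUE)
    mo[cbind(seq_len(n), labels)] <- Inf
    b <- apply(mo, 1, min)
    s <- (b - a) / pmax(pmax(a, b), .Machine$double.eps)
    mean(s[labels == cl])
  }, numeric(1))
  dplyr::bind_cols(
    tibble::tibble(cluster = seq_len(x$k),
                   size = tabulate(x$labels, x$k),
                   silhouette = sil_by),
    cent
  )
}

#' Glance at a fitted cluster model
#'
#' @param x An `rgc_clusters` object.
#' @param ... Unused.
#' @return One row: `k`, `n`, `mean_silhouette`, `restarts`, `seed`.
#' @export
glance.rgc_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n = nrow(x$data),
                 mean_silhouette = x$mean_silhouette,
                 restarts = x$restarts, seed = x$seed)
}

#' Augment the source parameter table with cluster assignments
#'
#' @param x An `rgc_clusters` object (from [cluster_cells()]).
#' @param data Parameter table to annotate; defaults to the one clustered.
#' @param ... Unused.
#' @return `data` with a `.cluster` column.
#' @export
augment.rgc_clusters <- function(x, data = x$params, ...) {
  if (is.null(data)) stop("no parameter table attached; supply `data`", call. = FALSE)
  data$.cluster <- factor(x$labels)
  data
}
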