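## Intensity-zone model: ceiling denoising + min-max normalisation + PCA +
## K-means with elbow-selected k, and labelling of the clusters as
## low / middle / high intensity.

#' Partition minutes into training and excluded rows
#'
#' Rows flagged \code{excluded} (no prior coverage) or whose preceding
#' 5-min distance falls below the threshold (halftime recovery, game and
#' half openings) are kept out of model fitting; they are later assigned
#' the label "unclassified".
#'
#' @param table minute-feature table.
#' @param threshold_m minimum preceding-5-min distance in metres
#'   (default 200; the boundary value is retained).
#' @return list with \code{train} and \code{excluded} tables.
#' @export
exclude_low_distance <- function(table, threshold_m = 200) {
  drop <- table$excluded | table$distance_m < threshold_m
  if (all(drop)) abort("exclude_low_distance: no training rows left")
  list(train = table[!drop], excluded = table[drop])
}

#' Min-max normalisation bounds
#'
#' @param train_rows training partition of the feature table.
#' @return named list of \code{(min, max)} per feature.
#' @export
fit_minmax <- function(train_rows) {
  bounds <- lapply(minute_feature_names(), function(cn) {
    x <- train_rows[[cn]]
    c(min = min(x), max = max(x))
  })
  names(bounds) <- minute_feature_names()
  bounds
}

#' @rdname fit_minmax
#' @param rows rows to scale (training rows land in [0,1]; unseen values
#'   outside the bounds are not clipped — the ceiling is applied upstream).
#' @param bounds output of \code{fit_minmax}.
#' @return numeric matrix (rows x 25).
#' @export
minmax_transform <- function(rows, bounds) {
  fn <- minute_feature_names()
  out <- matrix(0, nrow(rows), length(fn), dimnames = list(NULL, fn))
  for (cn in fn) {
    b <- bounds[[cn]]
    rng <- b["max"] - b["min"]
    if (rng <= 0) {
      warning(sprintf("constant feature %s mapped to 0", cn))
      out[, cn] <- 0
    } else out[, cn] <- (rows[[cn]] - b["min"]) / rng
  }
  out
}

#' Principal component reduction of the unit-scaled features
#'
#' Components are ordered by decreasing explained variance; the number
#' kept is the smallest reaching \code{variance_target}, unless a fixed
#' \code{n_components} is given.
#'
#' @param unit_rows matrix from [minmax_transform()].
#' @param variance_target fraction of variance to preserve (0, 1].
#' @param n_components optional fixed component count (overrides target).
#' @return list with \code{rotation}, \code{center}, \code{explained}
#'   (variance fractions) and \code{n_components}.
#' @export
fit_pca <- function(unit_rows, variance_target = 0.92, n_components = NULL) {
  if (nrow(unit_rows) < 2) abort("fit_pca: need at least 2 rows")
  if (is.null(n_components) &&
      !(variance_target > 0 && variance_target <= 1))
    abort("variance_target must be in (0,1]", class = "mpezones_config_error")
  pc <- stats::prcomp(unit_rows, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  n <- if (!is.null(n_components)) min(as.integer(n_components), ncol(pc$rotation))
  else which(cumsum(expl) >= variance_target - 1e-12)[1]
  list(rotation = pc$rotation, center = pc$center, explained = expl,
       n_components = n)
}

pca_project <- function(unit_rows, pca) {
  sweep(unit_rows, 2, pca$center) %*% pca$rotation[, seq_len(pca$n_components), drop = FALSE]
}

## k-means++ initial centers
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1, prob = p)
    centers[j + 1, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ])^2))
  }
  centers
}

nearest_center <- function(x, centers) {
  d <- matrix(0, nrow(x), nrow(centers))
  for (j in seq_len(nrow(centers)))
    d[, j] <- rowSums(sweep(x, 2, centers[j, ])^2)
  list(cluster = max.col(-d, ties.method = "first"),
       wcss_row = d[cbind(seq_len(nrow(x)), max.col(-d, ties.method = "first"))])
}

lloyd <- function(x, centers, max_iter, tol) {
  k <- nrow(centers)
  wcss_prev <- Inf
  for (it in seq_len(max_iter)) {
    nc <- nearest_center(x, centers)
    cl <- nc$cluster
    for (j in seq_len(k)) {
      sel <- cl == j
      if (!any(sel)) {
        ## re-seed an empty cluster at the point farthest from its center
        centers[j, ] <- x[which.max(nc$wcss_row), ]
      } else centers[j, ] <- colMeans(x[sel, , drop = FALSE])
    }
    nc <- nearest_center(x, centers)
    wcss <- sum(nc$wcss_row)
    if (wcss_prev - wcss <= tol * max(1, wcss_prev)) break
    wcss_prev <- wcss
  }
  list(centers = centers, cluster = nc$cluster, wcss = sum(nc$wcss_row))
}

#' K-means with k-means++ seeding and restarts
#'
#' Standard Lloyd iterations; the best of \code{n_init} restarts by
#' within-cluster sum of squares (WCSS) is returned. Deterministic under
#' \code{seed}.
#'
#' @param x numeric matrix of projected rows.
#' @param k number of clusters (<= nrow(x)).
#' @param seed integer seed.
#' @param n_init restarts.
#' @param max_iter,tol Lloyd iteration controls.
#' @return list with \code{centers}, \code{cluster}, \code{wcss}.
#' @export
fit_kmeans <- function(x, k, seed = 17L, n_init = 10L, max_iter = 300L,
                       tol = 1e-6) {
  x <- as.matrix(x)
  if (k > nrow(x)) abort("fit_kmeans: k (%d) exceeds number of rows (%d)",
                         k, nrow(x))
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- with_seed(derive_seed(seed, r), {
      lloyd(x, kmeanspp_init(x, k), max_iter, tol)
    })
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  best
}

#' Elbow selection of the cluster count
#'
#' Given WCSS values over a k-grid, picks the k whose point lies farthest
#' (perpendicular distance) from the chord joining the first and last grid
#' points — an automated version of the visual elbow; ties break to the
#' smallest k.
#'
#' @param wcss named numeric vector, names are k values.
#' @return integer k.
#' @export
choose_k <- function(wcss) {
  k <- as.integer(names(wcss))
  if (length(k) < 3) abort("choose_k: need at least 3 grid points")
  o <- order(k)
  k <- k[o]; w <- as.numeric(wcss)[o]
  x1 <- k[1]; y1 <- w[1]; x2 <- k[length(k)]; y2 <- w[length(w)]
  ## |cross product| of (point - start) with the chord direction
  dist <- abs((k - x1) * (y2 - y1) - (w - y1) * (x2 - x1)) /
    sqrt((x2 - x1)^2 + (y2 - y1)^2)
  k[which.max(dist)] # which.max takes the first (smallest k) on ties
}

#' Label k = 3 clusters as low / middle / high intensity
#'
#' The cluster with the lowest mean observed-minute event count is "low"
#' (no MPE activity); of the remaining two, the one with the greater mean
#' preceding-5-min general energy is "high", the other "middle". With
#' k != 3 the labels fall back to ordinal ranks by mean event count, with
#' a warning.
#'
#' @param cluster integer cluster assignment of the training rows.
#' @param train_rows the training feature table (same row order).
#' @return character vector label per cluster index.
#' @export
label_clusters <- function(cluster, train_rows) {
  ks <- sort(unique(cluster))
  mean_count <- vapply(ks, function(j) mean(train_rows$cur_event_count[cluster == j]),
                       numeric(1))
  if (length(ks) != 3) {
    warning("label_clusters: k != 3; using ordinal rank labels by event count")
    return(stats::setNames(paste0("zone", rank(mean_count, ties.method = "first")),
                           ks))
  }
  mean_energy <- vapply(ks, function(j) mean(train_rows$general_energy_jkg[cluster == j]),
                        numeric(1))
  labels <- character(3)
  low_i <- which(mean_count == min(mean_count))
  if (length(low_i) > 1) {
    warning("label_clusters: tie on event count; breaking by cluster index")
    low_i <- low_i[1]
  }
  labels[low_i] <- "low"
  rest <- setdiff(seq_len(3), low_i)
  hi_rel <- which(mean_energy[rest] == max(mean_energy[rest]))
  if (length(hi_rel) > 1) {
    warning("label_clusters: tie on prior energy; breaking by cluster index")
    hi_rel <- hi_rel[1]
  }
  labels[rest[hi_rel]] <- "high"
  labels[rest[-hi_rel]] <- "middle"
  stats::setNames(labels, ks)
}

#' Fit the full intensity model
#'
#' Ceiling denoising, low-distance exclusion, min-max normalisation, PCA
#' and K-means over a k-grid with elbow selection, then semantic labelling.
#' All thresholds/bounds are fit on the training rows and frozen into the
#' model for later assignment of new data.
#'
#' @param table minute-feature table from [build_minute_table()].
#' @param k_grid candidate cluster counts (default 2:15).
#' @param k optional fixed k (skips the elbow).
#' @param ceiling_quantile winsorisation quantile (default 0.995).
#' @param distance_threshold_m training-row minimum prior distance (200 m).
#' @param variance_target PCA variance fraction to keep (default 0.92).
#' @param n_components optional fixed PCA component count.
#' @param seed seed for K-means restarts.
#' @param n_init K-means restarts per k.
#' @return object of class \code{intensity_model}.
#' @export
fit_intensity_model <- function(table, k_grid = 2:15, k = NULL,
                                ceiling_quantile = 0.995,
                                distance_threshold_m = 200,
                                variance_target = 0.92, n_components = NULL,
                                seed = 17L, n_init = 10L) {
  parts <- exclude_low_distance(table, distance_threshold_m)
  ceil <- apply_ceiling(parts$train, ceiling_quantile)
  bounds <- fit_minmax(ceil$table)
  unit <- minmax_transform(ceil$table, bounds)
  pca <- fit_pca(unit, variance_target, n_components)
  proj <- pca_project(unit, pca)
  wcss <- stats::setNames(numeric(length(k_grid)), k_grid)
  fits <- list()
  for (kk in k_grid) {
    fits[[as.character(kk)]] <- fit_kmeans(proj, kk, seed = seed, n_init = n_init)
    wcss[as.character(kk)] <- fits[[as.character(kk)]]$wcss
  }
  k_star <- if (!is.null(k)) as.integer(k) else choose_k(wcss)
  fit <- fits[[as.character(k_star)]] %||% fit_kmeans(proj, k_star, seed = seed,
                                                      n_init = n_init)
  label_map <- label_clusters(fit$cluster, ceil$table)
  structure(list(feature_order = minute_feature_names(),
                 ceiling_thresholds = ceil$thresholds,
                 ceiling_quantile = ceiling_quantile,
                 minmax_bounds = bounds,
                 pca = pca,
                 kmeans_centroids = fit$centers,
                 label_map = label_map,
                 training_meta = list(k_grid = as.integer(k_grid),
                                      wcss = wcss, chosen_k = k_star,
                                      seed = as.integer(seed),
                                      n_init = as.integer(n_init),
                                      distance_threshold_m = distance_threshold_m,
                                      variance_target = variance_target,
                                      n_train = nrow(ceil$table))),
            class = "intensity_model")
}

#' @export
print.intensity_model <- function(x, ...) {
  cat(sprintf("<intensity_model> k = %d, %d PCA components (%.1f%% variance), %d training minutes\n",
              x$training_meta$chosen_k, x$pca$n_components,
              100 * sum(x$pca$explained[seq_len(x$pca$n_components)]),
              x$training_meta$n_train))
  cat("labels:", paste(sprintf("%s=%s", names(x$label_map), x$label_map),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Assign intensity labels to minutes
#'
#' Excluded rows (no prior coverage or below the distance threshold)
#' become "unclassified"; others get the label of the nearest K-means
#' centroid in component space.
#'
#' @param model an \code{intensity_model}.
#' @param rows minute-feature table.
#' @return \code{data.table} with \code{game_id, player_id, minute, label}.
#' @export
assign_intensity <- function(model, rows) {
  missing <- setdiff(minute_feature_names(), names(rows))
  if (length(missing))
    abort("assign_intensity: missing feature(s): %s",
          paste(missing, collapse = ", "), class = "mpezones_schema_error")
  out <- data.table(game_id = rows$game_id, player_id = rows$player_id,
                    minute = rows$minute, label = "unclassified")
  ok <- !(rows$excluded | rows$distance_m < model$training_meta$distance_threshold_m)
  if (any(ok)) {
    sub <- rows[ok]
    clipped <- apply_ceiling(sub, thresholds = model$ceiling_thresholds)$table
    unit <- minmax_transform(clipped, model$minmax_bounds)
    proj <- pca_project(unit, model$pca)
    cl <- nearest_center(proj, model$kmeans_centroids)$cluster
    out[ok, "label" := unname(model$label_map[as.character(cl)])]
  }
  out[]
}

#' Serialise / load an intensity model (JSON)
#'
#' @param model an \code{intensity_model}.
#' @param path JSON file path.
#' @return \code{path} (write) or the model (read).
#' @export
write_intensity_model <- function(model, path) {
  payload <- unclass(model)
  payload$kmeans_centroids <- as.data.frame(payload$kmeans_centroids)
  payload$pca$rotation <- as.data.frame(payload$pca$rotation)
  ## jsonlite drops names of atomic vectors; keep them via named lists
  payload$ceiling_thresholds <- as.list(payload$ceiling_thresholds)
  payload$label_map <- as.list(payload$label_map)
  payload$minmax_bounds <- lapply(payload$minmax_bounds, as.list)
  payload$training_meta$wcss <- as.list(payload$training_meta$wcss)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_intensity_model
#' @export
read_intensity_model <- function(path) {
  p <- jsonlite::fromJSON(path)
  p$kmeans_centroids <- as.matrix(p$kmeans_centroids)
  p$pca$rotation <- as.matrix(p$pca$rotation)
  p$pca$center <- unlist(p$pca$center)
  p$minmax_bounds <- lapply(p$minmax_bounds, function(b) unlist(b))
  p$ceiling_thresholds <- unlist(p$ceiling_thresholds)
  p$label_map <- unlist(p$label_map)
  p$training_meta$wcss <- unlist(p$training_meta$wcss)
  structure(p, class = "intensity_model")
}
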