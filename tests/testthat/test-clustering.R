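test_that("low-distance exclusion keeps the boundary and drops halftime lull", {
  feats <- data.table::copy(tiny_features())
  feats$distance_m[1] <- 150; feats$excluded[1] <- FALSE
  feats$distance_m[2] <- 200; feats$excluded[2] <- FALSE
  parts <- exclude_low_distance(feats, 200)
  key1 <- paste(feats$player_id[1], feats$minute[1])
  expect_true(key1 %in% paste(parts$excluded$player_id, parts$excluded$minute))
  key2 <- paste(feats$player_id[2], feats$minute[2])
  expect_true(key2 %in% paste(parts$train$player_id, parts$train$minute))

  # minutes right after the break inherit the halftime lull and drop out
  resume <- parts$excluded[parts$excluded$minute >= 60 & parts$excluded$minute < 65, ]
  full_players <- tiny_corpus()$meta[[1]]$lineup
  full_players <- full_players$player_id[full_players$on_s == 0]
  expect_true(all(full_players %in% resume$player_id))

  all_low <- data.table::copy(feats)[, "distance_m" := 0]
  expect_error(exclude_low_distance(all_low, 200), "no training rows")
})

test_that("min-max normalisation follows the fitted bounds", {
  tr <- data.table::as.data.table(
    stats::setNames(as.list(rep(1, 25)), minute_feature_names()))
  tr <- tr[rep(1, 3)]
  tr[, "distance_m" := c(2, 4, 6)]
  b <- fit_minmax(tr)
  expect_equal(unname(b$distance_m), c(2, 6))
  w <- testthat::capture_warnings(u <- minmax_transform(tr, b))
  expect_true(any(grepl("constant feature", w)))
  expect_equal(unname(u[, "distance_m"]), c(0, 0.5, 1))
  unseen <- data.table::copy(tr)[1, "distance_m" := 8]
  u2 <- suppressWarnings(minmax_transform(unseen, b))
  expect_equal(unname(u2[1, "distance_m"]), 1.5) # not clipped
  expect_true(all(u2[, "mpe_count"] == 0))       # constant feature maps to 0
})

test_that("PCA keeps the smallest component count reaching the variance target", {
  set.seed(4)
  n <- 400
  # 3 informative directions + 22 near-constant ones
  x <- cbind(matrix(rnorm(n * 3, sd = c(3, 2, 1)), n, 3, byrow = TRUE),
             matrix(rnorm(n * 22, sd = 0.01), n, 22))
  colnames(x) <- minute_feature_names()
  pca <- fit_pca(x, variance_target = 0.92)
  expect_lte(pca$n_components, 4)
  # oracle: eigendecomposition of the covariance matrix
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(pca$explained, ev / sum(ev), tolerance = 1e-8)
  expect_equal(pca$n_components,
               which(cumsum(ev / sum(ev)) >= 0.92)[1])

  proj <- mpezones:::pca_project(x, pca)
  expect_true(all(abs(colMeans(proj)) < 1e-9))

  full <- fit_pca(x, variance_target = 1.0)
  expect_equal(full$n_components, 25L)
  expect_error(fit_pca(x, variance_target = 1.5), class = "mpezones_config_error")

  # reconstruction error shrinks as components are added
  errs <- vapply(c(2, 5, 10, 20), function(k) {
    p <- fit_pca(x, n_components = k)
    pr <- mpezones:::pca_project(x, p)
    rec <- pr %*% t(p$rotation[, seq_len(k), drop = FALSE])
    sum((sweep(x, 2, p$center) - rec)^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("choose_k implements the chord rule with smallest-k ties", {
  expect_equal(choose_k(c(`2` = 100, `3` = 30, `4` = 25, `5` = 22, `6` = 20)), 3L)
  lin <- stats::setNames(seq(100, 20, length.out = 5), 2:6)
  expect_equal(choose_k(lin), 2L)
  expect_error(choose_k(c(`2` = 5, `3` = 4)), "at least 3")
})

test_that("fit_kmeans is a deterministic restarted Lloyd with k-means++", {
  set.seed(11)
  a <- matrix(rnorm(200, mean = 0, sd = 0.1), 100, 2)
  b <- matrix(rnorm(200, mean = 5, sd = 0.1), 100, 2)
  x <- rbind(a, b)
  f1 <- fit_kmeans(x, 2, seed = 3)
  f2 <- fit_kmeans(x, 2, seed = 3)
  expect_identical(f1$centers, f2$centers)
  cents <- f1$centers[order(f1$centers[, 1]), ]
  expect_true(all(abs(cents[1, ] - colMeans(a)) < 0.05))
  expect_true(all(abs(cents[2, ] - colMeans(b)) < 0.05))

  f0 <- fit_kmeans(x, 1, seed = 3)
  expect_equal(f0$wcss, sum(scale(x, scale = FALSE)^2), tolerance = 1e-9)
  expect_error(fit_kmeans(x[1:3, ], 5), "exceeds")

  # WCSS is nonincreasing in k on a fixed dataset (n_init >= 10)
  wcss <- vapply(2:6, function(k) fit_kmeans(x, k, seed = 3)$wcss, numeric(1))
  expect_true(all(diff(wcss) <= 1e-9))
})

test_that("cluster labelling matches the zone semantics and is permutation-invariant", {
  mk <- function(counts, energies, n = 30) {
    rows <- lapply(seq_along(counts), function(j) {
      dt <- data.table::as.data.table(
        stats::setNames(as.list(rep(0, 25)), minute_feature_names()))
      dt <- dt[rep(1, n)]
      dt[, "cur_event_count" := counts[j]]
      dt[, "general_energy_jkg" := energies[j]]
      dt
    })
    data.table::rbindlist(rows)
  }
  # Table-3-like profile: low has no events; high has the larger prior energy
  tr <- mk(c(0, 1.8, 2.0), c(2900, 1300, 2800))
  cl <- rep(1:3, each = 30)
  lm <- label_clusters(cl, tr)
  expect_equal(unname(lm[c("1", "2", "3")]), c("low", "middle", "high"))

  perm <- c(3L, 1L, 2L)[cl] # relabel cluster indices
  lm2 <- label_clusters(perm, tr)
  expect_equal(unname(lm2[c("3", "1", "2")]), c("low", "middle", "high"))

  expect_warning(label_clusters(rep(1:2, each = 30), mk(c(0, 2), c(1, 2))),
                 "k != 3")
  tie <- mk(c(0, 2, 2), c(1000, 1500, 1500))
  expect_warning(label_clusters(cl, tie), "tie")
})

test_that("assignment is centroid-consistent and unclassifies excluded minutes", {
  fit <- accept_fit()
  feats <- fit$features; model <- fit$model; a <- fit$assignments
  expect_setequal(unique(a$label), c("low", "middle", "high", "unclassified"))
  # training rows keep their training cluster's label
  parts <- exclude_low_distance(feats, model$training_meta$distance_threshold_m)
  atr <- assign_intensity(model, parts$train)
  expect_false(any(atr$label == "unclassified"))
  # excluded rows are never classified
  aex <- merge(a, feats[, c("game_id", "player_id", "minute", "excluded")],
               by = c("game_id", "player_id", "minute"))
  expect_true(all(aex$label[aex$excluded] == "unclassified"))
  expect_error(assign_intensity(model, feats[, 1:5]),
               class = "mpezones_schema_error")
})

test_that("intensity model serialises to JSON and back without loss", {
  fit <- accept_fit()
  p <- withr::local_tempfile(fileext = ".json")
  write_intensity_model(fit$model, p)
  m2 <- read_intensity_model(p)
  expect_equal(m2$kmeans_centroids, unname(fit$model$kmeans_centroids),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(m2$label_map), unname(fit$model$label_map))
  expect_equal(m2$training_meta$chosen_k, fit$model$training_meta$chosen_k)
  a1 <- assign_intensity(fit$model, fit$features)
  a2 <- assign_intensity(m2, fit$features)
  expect_identical(a1$label, a2$label)
})
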