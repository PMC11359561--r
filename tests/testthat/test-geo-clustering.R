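test_that("haversine distance: zero, equator arc, symmetry, validation", {
  expect_equal(haversine_km(c(10, 20), c(10, 20)), 0)
  # one degree of arc on the equator, radius 6378.137 km
  expect_equal(haversine_km(c(0, 0), c(1, 0)), 6378.137 * pi / 180,
               tolerance = 1e-10)
  set.seed(1)
  for (i in 1:10) {
    a <- c(runif(1, -180, 180), runif(1, -90, 90))
    b <- c(runif(1, -180, 180), runif(1, -90, 90))
    expect_equal(haversine_km(a, b), haversine_km(b, a))
    expect_gte(haversine_km(a, b), 0)
  }
  expect_error(haversine_km(c(0, 91), c(0, 0)), "out of range")
  expect_error(haversine_km(c(181, 0), c(0, 0)), "out of range")
})

test_that("POI profiles: empty, exact-location, brute-force equivalence", {
  st <- data.frame(station_id = c("A", "B"), lon = c(110.0, 110.3),
                   lat = c(20.0, 20.0))
  empty <- data.frame(category = integer(0), lon = numeric(0),
                      lat = numeric(0))
  expect_true(all(build_poi_profiles(st, empty, n_categories = 3) == 0))

  at_station <- data.frame(category = 2L, lon = 110.0, lat = 20.0)
  prof <- build_poi_profiles(st, at_station, n_categories = 3)
  expect_equal(prof["A", 2], 1L, ignore_attr = TRUE)
  expect_equal(sum(prof["B", ]), 0L)

  set.seed(2)
  stn <- data.frame(station_id = sprintf("S%d", 1:5),
                    lon = runif(5, 110, 110.05), lat = runif(5, 20, 20.04))
  pois <- data.frame(category = sample(1:4, 60, replace = TRUE),
                     lon = runif(60, 110, 110.05),
                     lat = runif(60, 20, 20.04))
  prof <- build_poi_profiles(stn, pois, radius_km = 1, n_categories = 4)
  brute <- matrix(0L, 5, 4)
  for (i in 1:5) for (j in 1:60) {
    d <- haversine_km(c(pois$lon[j], pois$lat[j]),
                      c(stn$lon[i], stn$lat[i]))
    if (d < 1) brute[i, pois$category[j]] <- brute[i, pois$category[j]] + 1L
  }
  expect_equal(unname(prof), brute)
  expect_error(build_poi_profiles(stn, transform(pois, category = 9),
                                  n_categories = 4), "categories")
})

test_that("normalized Euclidean distance: identity, 1-D case, scale invariance", {
  expect_equal(normalized_euclidean(c(1, 2), c(1, 2), c(1, 1)), 0)
  expect_equal(normalized_euclidean(3, 1, 2), 1)
  set.seed(3)
  X <- matrix(rpois(40, 5), 8, 5)
  s <- profile_sds(X)
  d0 <- normalized_euclidean(X[1, ], X[2, ], s)
  Xs <- X; Xs[, 3] <- X[, 3] * 7   # rescale one dimension
  expect_equal(normalized_euclidean(Xs[1, ], Xs[2, ], profile_sds(Xs)), d0)
})

test_that("trivial cuts: k = N singletons, k = 1 everything together", {
  set.seed(4)
  X <- matrix(rpois(24, 4), 6, 4)
  res_n <- hierarchical_cluster(X, k = 6)
  expect_equal(unname(res_n$assignment), 1:6)
  expect_length(res_n$merge_history, 0L)
  res_1 <- hierarchical_cluster(X, k = 1)
  expect_equal(unique(unname(res_1$assignment)), 1L)
  expect_length(res_1$full_history, 5L)
  expect_true(all(vapply(res_1$full_history, `[[`, 0, "distance") >= 0))
  expect_error(hierarchical_cluster(X, k = 7), "exceeds")
})

test_that("merge sequence matches the exhaustive re-scan oracle", {
  set.seed(5)
  for (rep in 1:30) {
    N <- sample(3:8, 1)
    K <- sample(2:5, 1)
    X <- matrix(rpois(N * K, 4), N, K)
    X[, 1] <- X[1, 1]  # exercise a zero-sd dimension
    got <- hierarchical_cluster(X, k = 1)$full_history
    want <- oracle_hclust(X)
    expect_length(got, length(want))
    for (s in seq_along(want)) {
      expect_equal(sort(got[[s]]$a), sort(want[[s]]$a))
      expect_equal(sort(got[[s]]$b), sort(want[[s]]$b))
      expect_equal(got[[s]]$distance, want[[s]]$distance)
    }
  }
})

test_that("cuts at k and k+1 are nested; clustering is permutation-equivariant", {
  set.seed(6)
  X <- matrix(rpois(60, 6), 10, 6)
  rownames(X) <- sprintf("S%d", 1:10)
  res <- hierarchical_cluster(X, k = 3)
  for (k in 2:9) {
    fine <- cut_clusters(res, k + 1)
    coarse <- cut_clusters(res, k)
    # every fine cluster maps into exactly one coarse cluster
    expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1))
  }
  perm <- sample(10)
  res_p <- hierarchical_cluster(X[perm, ], k = 3)
  a <- res$assignment[rownames(X)[perm]]
  b <- res_p$assignment[rownames(X)[perm]]
  # same partition up to label names
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(a[i] == a[j], b[i] == b[j], ignore_attr = TRUE)
  }
})

test_that("correlated-station screening: zero noise, noise station, empty cluster", {
  cfg <- tiny_synth(seed = 9L, n_hours = 600L, n_stations = 6L,
                    station_noise_sd = 0, gap_spec = c(short = 0L))
  pn <- generate_panel(cfg, generate_stations(cfg))
  assign_all <- stats::setNames(rep(1L, 6), pn$station_ids)
  res <- select_correlated_stations("S1", assign_all, pn, r_min = 0.5)
  expect_setequal(res$station_id, paste0("S", 2:6))
  expect_true(all(abs(res$r - 1) < 1e-12))
  expect_equal(res$r, sort(res$r, decreasing = TRUE))

  # replace one station's PM2.5 with pure noise: excluded at r_min = 0.5
  set.seed(10)
  pn$values[, "S3", "PM2.5"] <- runif(600, 0, 50)
  res2 <- select_correlated_stations("S1", assign_all, pn, r_min = 0.5)
  expect_false("S3" %in% res2$station_id)

  lone <- stats::setNames(c(1L, rep(2L, 5)), pn$station_ids)
  expect_equal(nrow(select_correlated_stations("S1", lone, pn)), 0L)
  expect_error(select_correlated_stations("nope", lone, pn), "not present")
})

test_that("planted two-cluster POI layout is recovered at k = 2", {
  cfg <- synth_config(n_stations = 10L, n_poi = 800L, n_hours = 50L,
                      seed = 11L, n_clusters = 2L)
  st <- generate_stations(cfg)
  st <- build_poi_profiles(st)
  res <- hierarchical_cluster(st$profiles, k = 2)
  truth <- st$stations$cluster_true
  got <- unname(res$assignment)
  agreement <- max(mean(got == truth), mean(got == 3L - truth))
  expect_equal(agreement, 1)
})
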