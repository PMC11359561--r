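# Station grouping from POI composition: great-circle POI assignment within
# a 1 km radius, normalized Euclidean distances between POI count profiles,
# and average-linkage agglomeration with a deterministic tie-break.

EARTH_RADIUS_KM <- 6378.137  # equatorial radius

#' Great-circle (haversine) distance in kilometres
#'
#' Uses the equatorial radius 6378.137 km. Inputs are WGS84 degrees
#' (lon, lat) and are converted to radians internally. Vectorized with
#' recycling over the longer argument.
#'
#' @param p,s numeric vectors `c(lon, lat)`, or two-column matrices /
#'   data frames with columns lon, lat (in that order).
#' @return distance(s) in km.
#' @export
haversine_km <- function(p, s) {
  as_ll <- function(x) {
    if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
    if (is.null(dim(x))) x <- matrix(x, ncol = 2, byrow = length(x) > 2)
    storage.mode(x) <- "double"
    x
  }
  p <- as_ll(p); s <- as_ll(s)
  if (any(abs(p[, 2]) > 90) || any(abs(s[, 2]) > 90) ||
      any(abs(p[, 1]) > 180) || any(abs(s[, 1]) > 180)) {
    stop_config("coordinates out of range: need lon in [-180,180], lat in [-90,90]")
  }
  rad <- pi / 180
  plon <- p[, 1] * rad; plat <- p[, 2] * rad
  slon <- s[, 1] * rad; slat <- s[, 2] * rad
  a <- sin((plat - slat) / 2)^2 +
    cos(plat) * cos(slat) * sin((plon - slon) / 2)^2
  2 * asin(sqrt(pmin(1, a))) * EARTH_RADIUS_KM
}

#' Count POIs per category around each station
#'
#' `profiles[i, k]` is the number of category-`k` POIs strictly closer than
#' `radius_km` (great-circle) to station `i`.
#'
#' @param stations a `station_set`, or a data frame with columns
#'   station_id, lon, lat.
#' @param pois data frame with columns category (integer in `1..K`), lon,
#'   lat; taken from `stations$pois` when omitted and available.
#' @param radius_km assignment radius, default 1 km, strict inequality.
#' @param n_categories number of categories K; inferred from the
#'   `station_set` or the data when omitted.
#' @return if `stations` is a `station_set`, the same object with
#'   `$profiles` filled; otherwise the integer profile matrix (stations x
#'   categories, rownames = station ids).
#' @export
build_poi_profiles <- function(stations, pois = NULL, radius_km = 1.0,
                               n_categories = NULL) {
  ss <- NULL
  if (inherits(stations, "station_set")) {
    ss <- stations
    if (is.null(pois)) pois <- ss$pois
    if (is.null(n_categories)) n_categories <- ss$n_categories
    stations <- ss$stations
  }
  stopifnot(is.data.frame(stations),
            all(c("station_id", "lon", "lat") %in% names(stations)))
  if (is.null(pois)) pois <- data.frame(category = integer(0),
                                        lon = numeric(0), lat = numeric(0))
  if (is.null(n_categories)) {
    n_categories <- if (nrow(pois)) max(pois$category) else 1L
  }
  if (nrow(pois) && (any(pois$category < 1) ||
                     any(pois$category > n_categories) ||
                     any(pois$category != floor(pois$category)))) {
    stop_config("POI categories must be integers in 1..%d", n_categories)
  }
  n <- nrow(stations)
  prof <- matrix(0L, n, n_categories,
                 dimnames = list(stations$station_id, NULL))
  if (nrow(pois)) {
    for (i in seq_len(n)) {
      d <- haversine_km(cbind(pois$lon, pois$lat),
                        c(stations$lon[i], stations$lat[i]))
      near <- pois$category[d < radius_km]
      if (length(near)) {
        tab <- tabulate(near, nbins = n_categories)
        prof[i, ] <- as.integer(tab)
      }
    }
  }
  if (!is.null(ss)) { ss$profiles <- prof; return(ss) }
  prof
}

#' Normalized Euclidean distance between two profile rows
#'
#' Each squared coordinate difference is divided by that dimension's
#' standard deviation before summing:
#' `sqrt(sum(((pa - qb) / sd)^2))`. Dimensions with zero sd carry no
#' discriminative information and are dropped (see [profile_sds()]).
#'
#' @param pa,qb numeric vectors of equal length.
#' @param sd per-dimension standard deviations, same length.
#' @return a non-negative scalar.
#' @export
normalized_euclidean <- function(pa, qb, sd) {
  stopifnot(length(pa) == length(qb), length(sd) == length(pa))
  keep <- sd > 0
  if (!any(keep)) return(0)
  sqrt(sum(((pa[keep] - qb[keep]) / sd[keep])^2))
}

#' Per-category standard deviations of a profile matrix
#'
#' Sample standard deviation over all stations, one per POI category; the
#' denominators of the normalized Euclidean distance.
#'
#' @param profiles stations x categories matrix.
#' @return numeric vector of length `ncol(profiles)`.
#' @export
profile_sds <- function(profiles) {
  apply(profiles, 2, stats::sd)
}

#' Average-linkage agglomerative clustering of POI profiles
#'
#' Starts from singleton clusters and repeatedly merges the pair with the
#' smallest average pairwise normalized-Euclidean distance, running to a
#' single cluster; the partition returned is the cut after `N - k` merges.
#' When several pairs tie at the minimal distance the pair with the
#' lexicographically smallest current position `(i, j)` is merged; the
#' merged cluster takes position `i` and later clusters shift down, so the
#' sequence is fully deterministic. Cluster-to-cluster distances are
#' maintained by the average-linkage Lance-Williams update
#' `D(Ci+Cj, Ck) = (|Ci| D(Ci,Ck) + |Cj| D(Cj,Ck)) / (|Ci|+|Cj|)`,
#' which is algebraically the mean over point pairs.
#'
#' @param profiles stations x categories matrix (rownames = station ids),
#'   or a `station_set` with `$profiles`.
#' @param k number of clusters to cut at (default 4).
#' @return an object of class `cluster_result`: `$assignment` (named
#'   integer vector, labels `1..k` in order of first appearance),
#'   `$merge_history` (the `N - k` merges used by the cut; each a list with
#'   members `a`, `b` — station index vectors — and `distance`),
#'   `$full_history` (all `N - 1` merges), `$k`, `$ids`.
#' @export
hierarchical_cluster <- function(profiles, k = 4L) {
  if (inherits(profiles, "station_set")) {
    if (is.null(profiles$profiles)) {
      stop_config("station_set has no profiles; run build_poi_profiles() first")
    }
    profiles <- profiles$profiles
  }
  profiles <- as.matrix(profiles)
  N <- nrow(profiles)
  assert_count(k, "k")
  if (k > N) stop_config("k = %d exceeds the number of stations (%d)", k, N)
  ids <- rownames(profiles) %||% sprintf("S%d", seq_len(N))

  sds <- profile_sds(profiles)
  pd <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (j > i) pd[i, j] <- pd[j, i] <-
        normalized_euclidean(profiles[i, ], profiles[j, ], sds)
  }

  clusters <- as.list(seq_len(N))      # member indices, in current position order
  M <- pd                              # cluster-to-cluster distances
  sizes <- rep(1L, N)
  history <- vector("list", N - 1L)
  for (step in seq_len(N - 1L)) {
    n <- length(clusters)
    # minimal distance, then the lexicographically first pair within a
    # float-noise tolerance of it (exact ties are common with integer
    # profiles, and the incremental distance update may differ from a
    # fresh re-average in the last ulp)
    m0 <- Inf
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (M[i, j] < m0) m0 <- M[i, j]
    }
    thresh <- m0 + 1e-9 * (1 + abs(m0))
    best <- c(NA_integer_, NA_integer_)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (M[i, j] <= thresh) { best <- c(i, j); break }
      }
      if (!is.na(best[1])) break
    }
    i <- best[1]; j <- best[2]; bestd <- M[i, j]
    history[[step]] <- list(a = clusters[[i]], b = clusters[[j]],
                            distance = bestd)
    keep <- setdiff(seq_len(n), j)
    newrow <- (sizes[i] * M[i, ] + sizes[j] * M[j, ]) / (sizes[i] + sizes[j])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    clusters <- clusters[keep]
    sizes <- sizes[keep]
    M[i, ] <- newrow; M[, i] <- newrow  # symmetric by construction
    M <- M[keep, keep, drop = FALSE]
    M[cbind(seq_along(keep), seq_along(keep))] <- 0
  }

  structure(list(
    assignment = cut_assignment(history, N, k, ids),
    merge_history = history[seq_len(N - k)],
    full_history = history, k = as.integer(k), ids = ids
  ), class = "cluster_result")
}

# replay the first N - k merges into a labelled partition
cut_assignment <- function(history, N, k, ids) {
  label <- seq_len(N)
  for (step in seq_len(N - k)) {
    m <- history[[step]]
    label[label %in% label[m$b]] <- label[m$a][1]
  }
  stats::setNames(match(label, unique(label)), ids)
}

#' Cut an existing merge history at a different cluster count
#'
#' @param result a `cluster_result`.
#' @param k new cluster count.
#' @return named integer assignment vector.
#' @export
cut_clusters <- function(result, k) {
  stopifnot(inherits(result, "cluster_result"))
  N <- length(result$ids)
  assert_count(k, "k")
  if (k > N) stop_config("k = %d exceeds the number of stations (%d)", k, N)
  cut_assignment(result$full_history, N, k, result$ids)
}

#' Screen stations of the target's cluster by PM2.5 correlation
#'
#' Computes the pairwise-complete Pearson correlation of each cluster
#' member's PM2.5 with the target station's, keeps members with
#' `r >= r_min`, and returns them sorted by descending correlation.
#' Candidates with fewer than two overlapping observed hours are skipped
#' with a warning.
#'
#' @param target target station id.
#' @param cluster a `cluster_result` or a named assignment vector.
#' @param panel a `synth_panel` (or any object with
#'   `$values[time, station, "PM2.5"]`).
#' @param r_min correlation threshold, default 0.5.
#' @return data frame with columns station_id, r (possibly 0 rows).
#' @export
select_correlated_stations <- function(target, cluster, panel, r_min = 0.5) {
  assignment <- if (inherits(cluster, "cluster_result")) cluster$assignment else cluster
  if (!target %in% names(assignment)) {
    stop_config("target '%s' not present in the cluster assignment", target)
  }
  members <- setdiff(names(assignment)[assignment == assignment[[target]]],
                     target)
  y <- panel$values[, target, "PM2.5"]
  out <- data.frame(station_id = character(0), r = numeric(0))
  for (sid in members) {
    x <- panel$values[, sid, "PM2.5"]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 2L) {
      warning(sprintf("station %s skipped: < 2 overlapping observations with %s",
                      sid, target), call. = FALSE)
      next
    }
    r <- stats::cor(x[ok], y[ok])
    if (is.finite(r) && r >= r_min) {
      out <- rbind(out, data.frame(station_id = sid, r = r))
    }
  }
  out[order(-out$r), , drop = FALSE]
}

#' Write cluster assignment and merge history as CSV
#'
#' @param result a `cluster_result`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_cluster_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "cluster_assignment.csv")
  utils::write.csv(data.frame(station_id = names(result$assignment),
                              cluster = unname(result$assignment)),
                   p1, row.names = FALSE)
  hist_df <- do.call(rbind, lapply(seq_along(result$full_history), function(s) {
    m <- result$full_history[[s]]
    data.frame(step = s,
               members_a = paste(result$ids[m$a], collapse = "|"),
               members_b = paste(result$ids[m$b], collapse = "|"),
               distance = m$distance)
  }))
  p2 <- file.path(dir, "merge_history.csv")
  utils::write.csv(hist_df, p2, row.names = FALSE)
  invisible(c(assignment = p1, history = p2))
}

#' Read stations or POIs from CSV or GeoJSON
#'
#' CSV needs columns `station_id, lon, lat` (stations) or
#' `category, lon, lat` (POIs). GeoJSON must be a FeatureCollection of
#' Points with matching properties; coordinates are `[lon, lat]`.
#'
#' @param path file path (`.csv` or `.geojson`/`.json`).
#' @param kind `"stations"` or `"pois"`.
#' @return a data frame.
#' @export
read_points <- function(path, kind = c("stations", "pois")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_config("file not found: %s", path)
  need <- if (kind == "stations") c("station_id", "lon", "lat") else
    c("category", "lon", "lat")
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    rows <- lapply(gj$features, function(f) {
      cc <- unlist(f$geometry$coordinates)
      props <- f$properties
      c(props[setdiff(need, c("lon", "lat"))], list(lon = cc[1], lat = cc[2]))
    })
    df <- do.call(rbind.data.frame, rows)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_config("%s file %s lacks column(s): %s", kind, path,
                paste(missing_cols, collapse = ", "))
  }
  df[need]
}
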