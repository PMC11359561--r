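# Synthetic multi-station air-quality world: a shared latent regional PM2.5
# process (AR(1) + 24 h diurnal cycle), station-level observation noise,
# covariates with graded correlation to PM2.5, POIs planted in >= 2 cluster
# archetypes, and injected missing-data gaps. Stands in for non-public
# monitoring-network data in all tests.

#' Configuration for the synthetic data generator
#'
#' Defaults describe a small coastal-city monitoring network: hourly PM2.5
#' around a mean of 16 ug/m3 with marginal spread of ~8 ug/m3 (latent) plus
#' 3 ug/m3 independent station noise, a 6 ug/m3 diurnal cycle, strong
#' persistence (lag-1 autocorrelation 0.95), 14 POI categories, and a
#' handful of short/medium/long data outages.
#'
#' @param n_stations number of monitoring stations.
#' @param n_poi total number of POI points placed around stations.
#' @param n_categories number of POI categories (default 14).
#' @param n_hours length of the hourly series.
#' @param seed integer root seed; identical seeds give bit-identical output.
#' @param ar_coefficient lag-1 coefficient of the latent AR(1), in (0, 1).
#' @param diurnal_amplitude amplitude of the 24 h sinusoid, ug/m3.
#' @param station_noise_sd sd of independent per-station noise, ug/m3.
#' @param latent_sd marginal sd of the AR(1) component, ug/m3.
#' @param baseline_level mean latent PM2.5 level, ug/m3.
#' @param covariate_spec named character vector mapping covariate names to
#'   `"strong"` or `"weak"`; strong covariates share latent signal, weak
#'   ones are pure noise.
#' @param gap_spec named integer vector of gap counts per duration class
#'   (`short` 1-4 h, `medium` 5-72 h, `long` 73-120 h).
#' @param n_clusters number of planted POI-profile clusters (>= 2 for the
#'   clustering recovery tests to be meaningful).
#' @param bbox numeric vector `c(lon_min, lat_min, lon_max, lat_max)`.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_stations = 20L,
                         n_poi = 2000L,
                         n_categories = 14L,
                         n_hours = 20000L,
                         seed = 1L,
                         ar_coefficient = 0.95,
                         diurnal_amplitude = 6,
                         station_noise_sd = 3,
                         latent_sd = 8,
                         baseline_level = 16,
                         covariate_spec = NULL,
                         gap_spec = c(short = 6L, medium = 3L, long = 1L),
                         n_clusters = 2L,
                         bbox = c(110.10, 19.85, 110.60, 20.10)) {
  assert_count(n_stations, "n_stations")
  assert_count(n_poi, "n_poi", min = 0L)
  assert_count(n_categories, "n_categories")
  assert_count(n_hours, "n_hours")
  assert_count(n_clusters, "n_clusters")
  assert_prob(ar_coefficient, "ar_coefficient")
  if (any(c(diurnal_amplitude, station_noise_sd, latent_sd) < 0)) {
    stop_config("amplitudes and standard deviations must be non-negative")
  }
  if (length(bbox) != 4L || bbox[1] >= bbox[3] || bbox[2] >= bbox[4] ||
      abs(bbox[2]) > 90 || abs(bbox[4]) > 90 ||
      abs(bbox[1]) > 180 || abs(bbox[3]) > 180) {
    stop_config("invalid bounding box: need c(lon_min, lat_min, lon_max, lat_max) with min < max")
  }
  if (is.null(covariate_spec)) covariate_spec <- default_covariate_spec()
  if (is.null(names(covariate_spec)) ||
      !all(covariate_spec %in% c("strong", "weak"))) {
    stop_config("covariate_spec must be a named vector of 'strong'/'weak'")
  }
  gap_spec <- gap_spec[gap_spec > 0]
  if (length(gap_spec) && !all(names(gap_spec) %in% c("short", "medium", "long"))) {
    stop_config("gap_spec names must be among short/medium/long")
  }
  structure(list(
    n_stations = as.integer(n_stations), n_poi = as.integer(n_poi),
    n_categories = as.integer(n_categories), n_hours = as.integer(n_hours),
    seed = as.integer(seed), ar_coefficient = ar_coefficient,
    diurnal_amplitude = diurnal_amplitude,
    station_noise_sd = station_noise_sd, latent_sd = latent_sd,
    baseline_level = baseline_level, covariate_spec = covariate_spec,
    gap_spec = gap_spec, n_clusters = as.integer(n_clusters), bbox = bbox
  ), class = "synth_config")
}

default_covariate_spec <- function() {
  c(PM10 = "strong", CO = "strong", O3 = "strong",
    wind_speed = "strong", wind_direction = "strong",
    temperature = "strong", pressure = "strong",
    NO2 = "weak", SO2 = "weak", humidity = "weak")
}

# latent-mixing weight and affine placement (mean, sd) per covariate; weights
# of unlisted strong covariates default to 0.5. Signs mimic typical
# relationships (wind and temperature disperse PM, ozone anticorrelates).
covariate_world <- function(spec) {
  weights <- c(PM10 = 0.90, CO = 0.60, O3 = -0.50, wind_speed = -0.45,
               wind_direction = 0.30, temperature = -0.35, pressure = 0.40)
  scales <- list(PM10 = c(30, 18), CO = c(0.7, 0.25), O3 = c(55, 25),
                 wind_speed = c(2.5, 1.2), wind_direction = c(180, 80),
                 temperature = c(25, 5), pressure = c(1010, 6),
                 NO2 = c(12, 6), SO2 = c(6, 3), humidity = c(78, 12))
  out <- lapply(names(spec), function(v) {
    w <- if (spec[[v]] == "weak") 0 else unname(weights[v])
    if (is.na(w)) w <- 0.5
    sc <- scales[[v]] %||% c(10, 4)
    list(name = v, weight = w, mean = sc[1], sd = sc[2])
  })
  names(out) <- names(spec)
  out
}

#' Generate a synthetic station network with planted POI clusters
#'
#' Stations are placed inside the bounding box and assigned round-robin to
#' `n_clusters` planted groups. Each group has a distinct POI category
#' archetype (a contiguous block of categories is 6x over-represented), and
#' every POI is dropped within 0.9 km of its station, so POI count profiles
#' within the 1 km assignment radius separate the planted groups. Ground
#' truth labels are stored in `$stations$cluster_true`.
#'
#' @param cfg a [synth_config()].
#' @return an object of class `station_set` with `$stations`
#'   (station_id, lon, lat, cluster_true), `$pois` (category, lon, lat),
#'   `$n_categories`, and `$profiles` (filled by [build_poi_profiles()]).
#' @export
generate_stations <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(derive_seed(cfg$seed, 11L))
  n <- cfg$n_stations
  G <- min(cfg$n_clusters, n)
  bb <- cfg$bbox
  # cluster geographic centres spread along the box diagonal, jittered
  cx <- seq(bb[1] + 0.1 * (bb[3] - bb[1]), bb[3] - 0.1 * (bb[3] - bb[1]),
            length.out = G)
  cy <- seq(bb[2] + 0.1 * (bb[4] - bb[2]), bb[4] - 0.1 * (bb[4] - bb[2]),
            length.out = G)
  grp <- rep_len(seq_len(G), n)
  lon <- cx[grp] + stats::rnorm(n, 0, 0.02)
  lat <- cy[grp] + stats::rnorm(n, 0, 0.012)
  lon <- pmin(pmax(lon, bb[1]), bb[3])
  lat <- pmin(pmax(lat, bb[2]), bb[4])
  ids <- sprintf("S%d", seq_len(n))
  stations <- data.frame(station_id = ids, lon = lon, lat = lat,
                         cluster_true = grp, stringsAsFactors = FALSE)

  pois <- data.frame(category = integer(0), lon = numeric(0), lat = numeric(0))
  if (cfg$n_poi > 0) {
    K <- cfg$n_categories
    block <- split(seq_len(K), cut(seq_len(K), breaks = G, labels = FALSE))
    arch <- lapply(seq_len(G), function(g) {
      w <- rep(1, K); w[block[[min(g, length(block))]]] <- 6; w / sum(w)
    })
    host <- sample.int(n, cfg$n_poi, replace = TRUE)
    dist_km <- stats::runif(cfg$n_poi, 0, 0.9)
    bearing <- stats::runif(cfg$n_poi, 0, 2 * pi)
    km_per_deg <- 6378.137 * pi / 180
    plat <- stations$lat[host] + dist_km * cos(bearing) / km_per_deg
    plon <- stations$lon[host] + dist_km * sin(bearing) /
      (km_per_deg * cos(stations$lat[host] * pi / 180))
    cat_g <- grp[host]
    category <- vapply(seq_len(cfg$n_poi), function(i) {
      sample.int(K, 1L, prob = arch[[cat_g[i]]])
    }, integer(1))
    pois <- data.frame(category = category, lon = plon, lat = plat)
  }

  structure(list(stations = stations, pois = pois,
                 n_categories = cfg$n_categories, profiles = NULL,
                 bbox = bb), class = "station_set")
}

gap_length_range <- c(short = 1L, medium = 5L, long = 73L)
gap_length_max <- c(short = 4L, medium = 72L, long = 120L)

#' Generate the synthetic hourly multi-station panel
#'
#' Every station observes PM2.5 as `latent + N(0, station_noise_sd)` where
#' the shared latent process is `baseline + AR(1) + diurnal sinusoid`,
#' clipped at zero. Covariates mix the standardized latent process with
#' independent noise using per-covariate weights (`"weak"` covariates use
#' weight 0, so their correlation with PM2.5 vanishes as `n_hours` grows).
#' Gaps are injected per `gap_spec` into randomly chosen (station,
#' variable) series; the mask records exactly the injected positions
#' (`TRUE` = missing) and masked values are `NA`.
#'
#' @param cfg a [synth_config()].
#' @param stations a `station_set` from [generate_stations()].
#' @return an object of class `synth_panel`: `$timestamps` (POSIXct,
#'   hourly), `$values` and `$mask` arrays of dim `T x stations x
#'   variables`, and `$metadata` (latent components, mixing weights, gap
#'   table, planted cluster labels, config).
#' @export
generate_panel <- function(cfg, stations) {
  stopifnot(inherits(cfg, "synth_config"), inherits(stations, "station_set"))
  set.seed(derive_seed(cfg$seed, 12L))
  T_ <- cfg$n_hours
  n <- nrow(stations$stations)
  phi <- cfg$ar_coefficient
  innov_sd <- cfg$latent_sd * sqrt(1 - phi^2)
  ar <- as.numeric(stats::filter(stats::rnorm(T_, 0, innov_sd), phi,
                                 method = "recursive"))
  diurnal <- cfg$diurnal_amplitude * sin(2 * pi * (seq_len(T_) - 1) / 24)
  latent <- cfg$baseline_level + ar + diurnal
  z <- (latent - mean(latent)) / stats::sd(latent)

  world <- covariate_world(cfg$covariate_spec)
  vars <- c("PM2.5", names(world))
  ids <- stations$stations$station_id
  values <- array(NA_real_, dim = c(T_, n, length(vars)),
                  dimnames = list(NULL, ids, vars))
  for (s in seq_len(n)) {
    values[, s, "PM2.5"] <- pmax(0, latent + stats::rnorm(T_, 0, cfg$station_noise_sd))
    for (v in names(world)) {
      w <- world[[v]]$weight
      x <- w * z + sqrt(max(0, 1 - w^2)) * stats::rnorm(T_)
      values[, s, v] <- pmax(0, world[[v]]$mean + world[[v]]$sd * x)
    }
  }

  mask <- array(FALSE, dim = dim(values), dimnames = dimnames(values))
  gaps <- list()
  for (cls in names(cfg$gap_spec)) {
    for (i in seq_len(cfg$gap_spec[[cls]])) {
      for (try in 1:200) {
        len <- sample(seq.int(gap_length_range[[cls]], gap_length_max[[cls]]), 1L)
        if (len >= T_) next
        s <- sample.int(n, 1L); v <- sample.int(length(vars), 1L)
        start <- sample.int(T_ - len + 1L, 1L)
        idx <- start:(start + len - 1L)
        # keep runs maximal: forbid touching an existing gap
        lo <- max(1L, start - 1L); hi <- min(T_, start + len)
        if (!any(mask[lo:hi, s, v])) {
          mask[idx, s, v] <- TRUE
          gaps[[length(gaps) + 1L]] <- data.frame(
            station_id = ids[s], variable = vars[v], start = start,
            length = len, class = cls, stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  values[mask] <- NA_real_
  gap_table <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(station_id = character(0), variable = character(0),
               start = integer(0), length = integer(0), class = character(0))

  timestamps <- as.POSIXct("2020-10-30 00:00:00", tz = "UTC") +
    3600 * (seq_len(T_) - 1)
  structure(list(
    timestamps = timestamps, values = values, mask = mask,
    station_ids = ids, variables = vars,
    metadata = list(
      latent = latent, ar_component = ar, diurnal = diurnal,
      mixing_weights = vapply(world, `[[`, numeric(1), "weight"),
      gaps = gap_table,
      cluster_true = stats::setNames(stations$stations$cluster_true, ids),
      config = unclass(cfg))
  ), class = "synth_panel")
}

#' Extract one station's modelling series from a synthetic panel
#'
#' Builds the `T x M` multivariate series for the target station: its own
#' variables (PM2.5 first) plus, optionally, the PM2.5 series of correlated
#' neighbour stations appended as extra features named `PM2.5_<id>`.
#'
#' @param panel a `synth_panel`.
#' @param station_id the target station id.
#' @param correlated character vector of neighbour station ids.
#' @return a [series_panel()].
#' @export
station_series <- function(panel, station_id, correlated = character()) {
  stopifnot(inherits(panel, "synth_panel"))
  if (!station_id %in% panel$station_ids) {
    stop_config("unknown station '%s'", station_id)
  }
  bad <- setdiff(correlated, panel$station_ids)
  if (length(bad)) stop_config("unknown correlated station(s): %s",
                               paste(bad, collapse = ", "))
  vals <- panel$values[, station_id, , drop = TRUE]
  msk <- panel$mask[, station_id, , drop = TRUE]
  nm <- panel$variables
  for (sid in correlated) {
    vals <- cbind(vals, panel$values[, sid, "PM2.5"])
    msk <- cbind(msk, panel$mask[, sid, "PM2.5"])
    nm <- c(nm, paste0("PM2.5_", sid))
  }
  colnames(vals) <- colnames(msk) <- nm
  series_panel(timestamps = panel$timestamps, values = vals, mask = msk)
}

#' Write the synthetic artefacts as plain-text files
#'
#' Stations and POIs go to CSV (and stations optionally to GeoJSON), the
#' panel to long-format CSV (`timestamp, station_id, variable, value`) with
#' missing entries absent, and generator metadata (mixing weights, gap
#' table, planted labels) to JSON.
#'
#' @param stations a `station_set`.
#' @param panel a `synth_panel`.
#' @param dir output directory (created if absent).
#' @param geojson also write `stations.geojson`.
#' @return invisibly, the paths written.
#' @export
write_synth <- function(stations, panel, dir, geojson = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(stations = file.path(dir, "stations.csv"),
             pois = file.path(dir, "pois.csv"),
             panel = file.path(dir, "panel.csv"),
             metadata = file.path(dir, "metadata.json"))
  utils::write.csv(stations$stations[c("station_id", "lon", "lat")],
                   paths["stations"], row.names = FALSE)
  utils::write.csv(stations$pois, paths["pois"], row.names = FALSE)
  long <- panel_to_long(panel)
  utils::write.csv(long, paths["panel"], row.names = FALSE)
  meta <- panel$metadata
  meta$latent <- NULL; meta$ar_component <- NULL; meta$diurnal <- NULL
  jsonlite::write_json(meta, paths["metadata"], auto_unbox = TRUE,
                       digits = NA)
  if (geojson) {
    gj <- list(type = "FeatureCollection", features = lapply(
      seq_len(nrow(stations$stations)), function(i) {
        s <- stations$stations[i, ]
        list(type = "Feature",
             geometry = list(type = "Point",
                             coordinates = c(s$lon, s$lat)),
             properties = list(station_id = s$station_id))
      }))
    jsonlite::write_json(gj, file.path(dir, "stations.geojson"),
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, geojson = file.path(dir, "stations.geojson"))
  }
  invisible(paths)
}

panel_to_long <- function(panel) {
  dn <- dimnames(panel$values)
  long <- expand.grid(timestamp = seq_along(panel$timestamps),
                      station_id = dn[[2]], variable = dn[[3]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$value <- as.vector(panel$values)
  long <- long[!is.na(long$value), ]
  long$timestamp <- format(panel$timestamps[long$timestamp],
                           "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  rownames(long) <- NULL
  long
}

#' Read a long-format panel CSV back into a `synth_panel`
#'
#' Inverse of the panel part of [write_synth()]: absent
#' (timestamp, station, variable) entries become missing values in the
#' mask. The hourly grid is reconstructed from the full timestamp range.
#'
#' @param path CSV with columns timestamp, station_id, variable, value.
#' @return a `synth_panel` (without generator metadata).
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) stop_config("panel file not found: %s", path)
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  ts <- as.POSIXct(long$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  grid <- seq(min(ts), max(ts), by = 3600)
  ids <- unique(long$station_id)
  vars <- unique(long$variable)
  if ("PM2.5" %in% vars) vars <- c("PM2.5", setdiff(vars, "PM2.5"))
  values <- array(NA_real_, dim = c(length(grid), length(ids), length(vars)),
                  dimnames = list(NULL, ids, vars))
  ti <- match(ts, grid)
  si <- match(long$station_id, ids)
  vi <- match(long$variable, vars)
  values[cbind(ti, si, vi)] <- long$value
  mask <- is.na(values)
  structure(list(timestamps = grid, values = values, mask = mask,
                 station_ids = ids, variables = vars, metadata = list()),
            class = "synth_panel")
}
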