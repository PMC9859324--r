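# Region-level inputs: derived covariates, station aggregation, file readers.

#' Convert barometric pressure to ambient oxygen partial pressure
#'
#' Ambient oxygen concentration is expressed as the partial pressure of
#' oxygen in mmHg: barometric pressure (kPa) times oxygen's atmospheric
#' volume fraction (20.93%) times 7.5 mmHg/kPa. No intermediate rounding is
#' applied.
#'
#' @param pressure_kpa Numeric vector of barometric pressures in kPa; must be
#'   non-negative.
#' @return Numeric vector of oxygen partial pressures in mmHg.
#' @examples
#' oxygen_from_pressure(101.325) # sea level, about 159 mmHg
#' @export
oxygen_from_pressure <- function(pressure_kpa) {
  if (!is.numeric(pressure_kpa)) abort_input("pressure must be numeric")
  if (any(!is.na(pressure_kpa) & pressure_kpa < 0)) {
    abort_input("pressure must be non-negative (got %g)",
                min(pressure_kpa, na.rm = TRUE))
  }
  pressure_kpa * 0.2093 * 7.5
}

#' Average years of education from attainment counts
#'
#' Population-weighted mean years of schooling: university counts as 16
#' years, high school 12, middle school 9, primary school 6, and no
#' schooling 0, divided by the total population aged six and over. The
#' convention slightly overestimates attainment for dropouts, which is
#' accepted (dropout rates are low in the populations this targets).
#'
#' @param n_university,n_highschool,n_middleschool,n_primary,n_noschool
#'   Non-negative counts (vectors recycle in parallel).
#' @return Average years of education.
#' @export
avg_years_education <- function(n_university, n_highschool, n_middleschool,
                                n_primary, n_noschool) {
  counts <- cbind(n_university, n_highschool, n_middleschool, n_primary, n_noschool)
  if (any(counts < 0, na.rm = TRUE)) abort_input("education counts must be non-negative")
  total <- rowSums(counts)
  if (any(total <= 0, na.rm = TRUE)) abort_input("total population must be positive")
  as.numeric(counts %*% c(16, 12, 9, 6, 0)) / total
}

#' Health technicians per 1000 permanent residents
#'
#' @param personnel Count of health technical personnel (non-negative).
#' @param residents Count of permanent residents at year end (positive).
#' @return Rate per 1000 residents.
#' @export
health_tech_per_1000 <- function(personnel, residents) {
  if (any(residents <= 0, na.rm = TRUE)) abort_input("residents must be positive")
  if (any(personnel < 0, na.rm = TRUE)) abort_input("personnel must be non-negative")
  personnel / residents * 1000
}

#' Aggregate daily station records to per-region annual means
#'
#' Uninhabited stations are dropped, then each meteorological variable is
#' averaged arithmetically over all retained daily records assigned to a
#' region. Regions listed in `region_ids` that have no retained records get
#' a row of `NA` (missing is flagged, never fabricated).
#'
#' @param records Data frame of daily station records with columns
#'   `station_id`, `region_id`, `inhabited` (logical) and one column per
#'   meteorological variable.
#' @param variables Character vector of variable columns to average.
#' @param region_ids Optional character vector of all regions that should
#'   appear in the output (those without stations get `NA` means).
#' @return Data frame with one row per region and the per-variable means.
#' @export
aggregate_stations <- function(records,
                               variables = c("pressure", "sunshine", "wind",
                                             "rel_humidity", "temperature"),
                               region_ids = NULL) {
  if (nrow(records) == 0) {
    warning("no station records supplied; returning empty aggregation")
    out <- data.frame(region_id = character(0))
    for (v in variables) out[[v]] <- numeric(0)
    return(out)
  }
  required <- c("region_id", "inhabited", variables)
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort_input("station table is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  kept <- records[records$inhabited, , drop = FALSE]
  if (any(is.na(kept$region_id)) || any(kept$region_id == "")) {
    abort_input("every retained station record needs a region assignment")
  }
  ids <- region_ids %||% sort(unique(kept$region_id))
  out <- data.frame(region_id = ids, stringsAsFactors = FALSE)
  for (v in variables) {
    means <- tapply(kept[[v]], kept$region_id, mean)
    out[[v]] <- as.numeric(means[ids])
  }
  out
}

# Columns a region table must carry (covariates may be any subset beyond these).
.region_required <- c("region_id", "lon", "lat", "life_expectancy")

#' Validate a region table
#'
#' Checks identifier uniqueness, coordinate ranges, positive oxygen and a
#' plausible life expectancy. Returns the table invisibly so it can be used
#' in pipelines; raises a named validation error otherwise.
#'
#' @param regions Data frame with at least `region_id`, `lon`, `lat`,
#'   `life_expectancy`; optionally `pressure` (kPa), `oxygen` (mmHg) and
#'   covariate columns.
#' @return The validated data frame, invisibly.
#' @export
validate_region_table <- function(regions) {
  missing_cols <- setdiff(.region_required, names(regions))
  if (length(missing_cols) > 0) {
    abort_input("region table is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(names(regions), c("region_id", "name", "level"))) {
    if (!is.numeric(regions[[col]])) {
      abort_input("column '%s' must be numeric", col)
    }
  }
  if (anyDuplicated(regions$region_id)) {
    dup <- regions$region_id[duplicated(regions$region_id)][1]
    abort_input("duplicate region_id: '%s'", dup)
  }
  if (any(abs(regions$lat) > 90, na.rm = TRUE)) abort_input("lat outside [-90, 90]")
  if (any(abs(regions$lon) > 180, na.rm = TRUE)) abort_input("lon outside [-180, 180]")
  le <- regions$life_expectancy
  if (any(!is.na(le) & (le <= 0 | le >= 120))) {
    abort_input("life_expectancy outside (0, 120)")
  }
  if ("oxygen" %in% names(regions) &&
      any(!is.na(regions$oxygen) & regions$oxygen <= 0)) {
    abort_input("oxygen must be positive where present")
  }
  invisible(regions)
}

#' Read and validate a region table from CSV
#'
#' Reads a UTF-8 CSV with a header row, derives `oxygen` from `pressure`
#' when only the latter is present, and validates the result (see
#' [validate_region_table()]).
#'
#' @param path Path to the CSV file.
#' @return Validated region data frame.
#' @export
read_region_table <- function(path) {
  regions <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!"oxygen" %in% names(regions) && "pressure" %in% names(regions)) {
    regions$oxygen <- oxygen_from_pressure(regions$pressure)
  }
  validate_region_table(regions)
  regions
}

# Shoelace centroid of one polygon ring given as a two-column matrix of
# lon/lat vertices (closed or open ring both accepted).
.ring_centroid <- function(xy) {
  if (!all(xy[1, ] == xy[nrow(xy), ])) xy <- rbind(xy, xy[1, ])
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  cross <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(xy[-n, , drop = FALSE]))
  cx <- sum((x[-n] + x[-1]) * cross) / (6 * a)
  cy <- sum((y[-n] + y[-1]) * cross) / (6 * a)
  c(cx, cy)
}

#' Read region centroids from a GeoJSON file
#'
#' Accepts a FeatureCollection of Points, Polygons or MultiPolygons
#' (RFC 7946). Polygon centroids are area-weighted centroids of the exterior
#' ring; MultiPolygon centroids weight each part by its area. The feature
#' property `region_id` (or `id`) names each unit.
#'
#' @param path Path to a GeoJSON file.
#' @return Data frame with columns `region_id`, `lon`, `lat`.
#' @export
read_geometry <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) abort_input("GeoJSON must be a FeatureCollection")
  rows <- lapply(gj$features, function(f) {
    id <- f$properties$region_id %||% f$properties$id %||% f$id
    if (is.null(id)) abort_input("feature lacks a region_id property")
    geom <- f$geometry
    cen <- switch(geom$type,
      Point = unlist(geom$coordinates)[1:2],
      Polygon = .ring_centroid(do.call(rbind, lapply(geom$coordinates[[1]], unlist))),
      MultiPolygon = {
        parts <- lapply(geom$coordinates, function(poly) {
          xy <- do.call(rbind, lapply(poly[[1]], unlist))
          ring <- if (all(xy[1, ] == xy[nrow(xy), ])) xy else rbind(xy, xy[1, ])
          x <- ring[, 1]; y <- ring[, 2]; n <- nrow(ring)
          a <- sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
          list(area = abs(a), centroid = .ring_centroid(xy))
        })
        areas <- vapply(parts, `[[`, numeric(1), "area")
        cens <- do.call(rbind, lapply(parts, `[[`, "centroid"))
        colSums(cens * areas) / sum(areas)
      },
      abort_input("unsupported geometry type '%s'", geom$type)
    )
    data.frame(region_id = as.character(id), lon = cen[1], lat = cen[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign points to polygon regions (optional helper)
#'
#' Even-odd ray-casting point-in-polygon test against the exterior rings in
#' a GeoJSON file. Intended for linking stations to regions when the input
#' station table lacks a `region_id` column; boundary points are resolved by
#' the ray-casting convention.
#'
#' @param lon,lat Point coordinates.
#' @param geojson_path GeoJSON FeatureCollection of Polygon/MultiPolygon
#'   features with `region_id` properties.
#' @return Character vector of region ids (`NA` where no polygon contains
#'   the point).
#' @export
assign_points_to_regions <- function(lon, lat, geojson_path) {
  gj <- jsonlite::read_json(geojson_path)
  polys <- lapply(gj$features, function(f) {
    id <- f$properties$region_id %||% f$properties$id %||% f$id
    rings <- switch(f$geometry$type,
      Polygon = list(do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))),
      MultiPolygon = lapply(f$geometry$coordinates,
                            function(p) do.call(rbind, lapply(p[[1]], unlist))),
      abort_input("unsupported geometry type '%s'", f$geometry$type))
    list(id = as.character(id), rings = rings)
  })
  in_ring <- function(px, py, xy) {
    x <- xy[, 1]; y <- xy[, 2]; n <- nrow(xy); inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((y[i] > py) != (y[j] > py) &&
          px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]) {
        inside <- !inside
      }
      j <- i
    }
    inside
  }
  vapply(seq_along(lon), function(k) {
    for (p in polys) {
      if (any(vapply(p$rings, function(r) in_ring(lon[k], lat[k], r), logical(1)))) {
        return(p$id)
      }
    }
    NA_character_
  }, character(1))
}
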