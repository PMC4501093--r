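# mean Earth radius; great-circle distances are insensitive to the
# spherical-vs-ellipsoidal choice at continental regression scales
EARTH_RADIUS_KM <- 6371.0

#' Create a geographic point
#'
#' A latitude/longitude pair in decimal degrees with an optional label.
#' Coordinates are validated on construction.
#'
#' @param latitude Decimal degrees in \[-90, 90\].
#' @param longitude Decimal degrees in \[-180, 180\].
#' @param label Optional character label (e.g. a city or population name).
#' @return An object of class `geo_point`.
#' @examples
#' addis <- geo_point(9.03, 38.74, "Addis Ababa")
#' @export
geo_point <- function(latitude, longitude, label = NA_character_) {
  if (!is.numeric(latitude) || !is.numeric(longitude) ||
      length(latitude) != 1L || length(longitude) != 1L ||
      is.na(latitude) || is.na(longitude)) {
    stop("latitude and longitude must be single finite numbers", call. = FALSE)
  }
  if (latitude < -90 || latitude > 90) {
    stop("latitude out of range [-90, 90]: ", latitude, call. = FALSE)
  }
  if (longitude < -180 || longitude > 180) {
    stop("longitude out of range [-180, 180]: ", longitude, call. = FALSE)
  }
  structure(list(latitude = latitude, longitude = longitude,
                 label = as.character(label)),
            class = "geo_point")
}

#' @export
print.geo_point <- function(x, ...) {
  cat(sprintf("<geo_point> %s (%.4f, %.4f)\n",
              ifelse(is.na(x$label), "?", x$label), x$latitude, x$longitude))
  invisible(x)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of mean Earth radius 6371.0 km.
#'
#' @param a,b `geo_point` objects.
#' @return Distance in km (non-negative, symmetric).
#' @examples
#' great_circle_km(geo_point(9.03, 38.74), geo_point(30.05, 31.25))
#' @export
great_circle_km <- function(a, b) {
  stopifnot(inherits(a, "geo_point"), inherits(b, "geo_point"))
  haversine_km(a$latitude, a$longitude, b$latitude, b$longitude)
}

# vectorised haversine on decimal degrees
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  phi1 <- lat1 * rad; phi2 <- lat2 * rad
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  h <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  h <- pmin(pmax(h, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(h))
}

#' Define a migration route
#'
#' An origin plus an ordered (possibly empty) list of waypoints. The distance
#' from the origin to a target along the route is the sum of the consecutive
#' leg distances origin -> w1 -> ... -> wk -> target.
#'
#' @param origin A `geo_point`.
#' @param waypoints A list of `geo_point`s, in travel order (may be empty).
#' @return An object of class `route`.
#' @export
route <- function(origin, waypoints = list()) {
  stopifnot(inherits(origin, "geo_point"))
  if (inherits(waypoints, "geo_point")) waypoints <- list(waypoints)
  ok <- vapply(waypoints, inherits, logical(1), what = "geo_point")
  if (!all(ok)) stop("all waypoints must be geo_point objects", call. = FALSE)
  structure(list(origin = origin, waypoints = waypoints), class = "route")
}

#' Waypoint-routed distance to a target
#'
#' Sum of great-circle legs along a [route()]: origin to the first waypoint,
#' waypoint to waypoint, and the final waypoint to the target. With no
#' waypoints this is the direct origin-to-target great-circle distance.
#'
#' @param target A `geo_point`.
#' @param rte A [route()].
#' @return Distance in km.
#' @export
route_distance_km <- function(target, rte) {
  stopifnot(inherits(target, "geo_point"), inherits(rte, "route"))
  pts <- c(list(rte$origin), rte$waypoints, list(target))
  total <- 0
  for (i in seq_len(length(pts) - 1L)) {
    total <- total + great_circle_km(pts[[i]], pts[[i + 1L]])
  }
  total
}

#' Default waypoint cities
#'
#' Origin and waypoints used for out-of-Africa migration distances:
#' origin Addis Ababa; waypoints Cairo, Istanbul, Anadyr, Phnom Penh and
#' Prince Rupert.
#'
#' @return Named list of `geo_point`s.
#' @export
waypoint_cities <- function() {
  list(
    addis_ababa   = geo_point(9.03, 38.74, "Addis Ababa"),
    cairo         = geo_point(30.05, 31.25, "Cairo"),
    istanbul      = geo_point(41.01, 28.96, "Istanbul"),
    anadyr        = geo_point(64.73, 177.51, "Anadyr"),
    phnom_penh    = geo_point(11.55, 104.92, "Phnom Penh"),
    prince_rupert = geo_point(54.32, -130.32, "Prince Rupert")
  )
}

#' Default region-to-route table
#'
#' Maps broad sampling regions to waypoint routes from Addis Ababa. African
#' populations are reached directly; Middle Eastern ones via Cairo; European
#' and Central/South Asian ones via Cairo and Istanbul; East Asian and
#' Oceanian ones via Cairo and Phnom Penh; American ones via Cairo, Anadyr
#' and Prince Rupert. Fully overrideable: pass your own named list of
#' [route()]s to [assign_distances()].
#'
#' @return Named list of [route()]s keyed by region.
#' @export
default_route_table <- function() {
  w <- waypoint_cities()
  org <- w$addis_ababa
  list(
    africa             = route(org),
    middle_east        = route(org, list(w$cairo)),
    europe             = route(org, list(w$cairo, w$istanbul)),
    central_south_asia = route(org, list(w$cairo, w$istanbul)),
    east_asia          = route(org, list(w$cairo, w$phnom_penh)),
    oceania            = route(org, list(w$cairo, w$phnom_penh)),
    america            = route(org, list(w$cairo, w$anadyr, w$prince_rupert))
  )
}

#' Assign waypoint-routed distances to populations
#'
#' @param panel Data frame with columns `population`, `region`, `latitude`,
#'   `longitude`.
#' @param route_table Named list of [route()]s keyed by region; defaults to
#'   [default_route_table()].
#' @return Named numeric vector of distances in km, one per population.
#' @export
assign_distances <- function(panel, route_table = default_route_table()) {
  need <- c("population", "region", "latitude", "longitude")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop("panel is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- numeric(nrow(panel))
  for (i in seq_len(nrow(panel))) {
    reg <- as.character(panel$region[i])
    rte <- route_table[[reg]]
    if (is.null(rte)) {
      stop("no route defined for region '", reg, "' (population '",
           panel$population[i], "')", call. = FALSE)
    }
    tgt <- geo_point(panel$latitude[i], panel$longitude[i],
                     as.character(panel$population[i]))
    d[i] <- route_distance_km(tgt, rte)
  }
  names(d) <- as.character(panel$population)
  d
}
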