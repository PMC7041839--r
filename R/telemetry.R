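#' Triangulate a set of simultaneous bearings
#'
#' Estimates a transmitter position as the least-squares intersection of the
#' bearing lines: the point minimising the sum of squared perpendicular
#' distances to every line. Azimuths are degrees clockwise from north. By
#' default bearings are treated as full lines (the common convention when
#' signal direction may be ambiguous); `rays = TRUE` additionally requires
#' the solution to lie forward of every station.
#'
#' @param bearings A data frame with columns `x`, `y` (station coordinates,
#'   metres), `azimuth` (degrees in \[0, 360)) and optionally `station_id`
#'   and `timestamp`.
#' @param window_s Maximum allowed timestamp spread in seconds (default 60);
#'   only checked when a `timestamp` column is present.
#' @param min_angle_deg Minimum pairwise angle between bearing lines; below
#'   this the geometry is declared degenerate (default 5).
#' @param rays If `TRUE`, require the solution to lie in the forward
#'   direction of every bearing.
#' @return A one-row tibble with `x`, `y` and `source = "triangulated"`.
#' @examples
#' b <- tibble::tibble(station_id = c("A", "B"), x = c(0, 10), y = c(0, 10),
#'                     azimuth = c(90, 180))
#' triangulate(b)  # (10, 0)
#' @export
triangulate <- function(bearings, window_s = 60, min_angle_deg = 5,
                        rays = FALSE) {
  b <- tibble::as_tibble(bearings)
  if (!all(c("x", "y", "azimuth") %in% names(b))) {
    stop("bearings need columns `x`, `y`, `azimuth`", call. = FALSE)
  }
  if (!"station_id" %in% names(b)) b$station_id <- seq_len(nrow(b))
  if (dplyr::n_distinct(b$station_id) < 2L) {
    stop("insufficient bearings", call. = FALSE)
  }
  if (any(!is.finite(b$x)) || any(!is.finite(b$y))) {
    stop("station coordinates must be finite", call. = FALSE)
  }
  if (any(b$azimuth < 0 | b$azimuth >= 360)) {
    stop("azimuth must lie in [0, 360)", call. = FALSE)
  }
  if ("timestamp" %in% names(b)) {
    ts <- as.POSIXct(b$timestamp, tz = "UTC")
    if (diff(range(as.numeric(ts))) > window_s) {
      stop("bearings span more than one simultaneity window", call. = FALSE)
    }
  }
  theta <- b$azimuth * pi / 180
  # line through station with direction (sin t, cos t); normal (cos t, -sin t)
  # degenerate when all lines are near-parallel (angles compared mod 180)
  ang <- (b$azimuth %% 180)
  dmat <- abs(outer(ang, ang, "-"))
  dmat <- pmin(dmat, 180 - dmat)
  if (all(dmat[upper.tri(dmat)] < min_angle_deg)) {
    stop("degenerate geometry", call. = FALSE)
  }
  nx <- cos(theta); ny <- -sin(theta)
  A <- cbind(nx, ny)
  rhs <- nx * b$x + ny * b$y
  sol <- solve(crossprod(A), crossprod(A, rhs))
  if (rays) {
    fwd <- (sol[1] - b$x) * sin(theta) + (sol[2] - b$y) * cos(theta)
    if (any(fwd < -1e-9)) {
      stop("no forward intersection under `rays = TRUE`", call. = FALSE)
    }
  }
  tibble::tibble(x = sol[1], y = sol[2], source = "triangulated")
}

#' Assign timestamps to tracking nights
#'
#' Bats are active from sunset to sunrise, so a "night" spans midnight:
#' every timestamp from local noon of day *d* to local noon of day *d + 1*
#' belongs to the night of day *d*.
#'
#' @param timestamps POSIXct vector or character parseable as ISO 8601
#'   (assumed to share one local timezone).
#' @return A `Date` vector giving the night each timestamp belongs to.
#' @examples
#' assign_night(c("2010-11-03 22:10:00", "2010-11-04 03:00:00"))
#' @export
assign_night <- function(timestamps) {
  ts <- timestamps
  if (!inherits(ts, "POSIXct")) {
    ts <- tryCatch(
      as.POSIXct(as.character(timestamps), tz = "UTC",
                 tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                                "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                "%Y-%m-%d")),
      error = function(e) NA)
  }
  if (any(is.na(ts))) stop("unparseable timestamp", call. = FALSE)
  as.Date(ts - 12 * 3600, tz = "UTC")
}

#' Assign location fixes to foraging-site visits
#'
#' A bat is credited with visiting a site on a night when at least
#' `min_fixes_per_visit` of its fixes that night fall inside the site's
#' circle; the threshold (default 2) suppresses visits conjured by a single
#' spurious triangulation. If the fixes carry no `night` column, nights are
#' derived from `timestamp` via [assign_night()] and indexed consecutively
#' from the earliest night in the data.
#'
#' @param fixes Tibble with `bat_id`, `x`, `y` and either `night` (integer)
#'   or `timestamp`; coordinates must share the landscape's planar frame.
#' @param landscape A `landscape` (circular sites: `site_id`, `x`, `y`,
#'   `radius`).
#' @param min_fixes_per_visit Minimum fixes inside a site to count a visit.
#' @return A visit tibble: `bat_id`, `night`, `site_id`, `n_fixes`, sorted;
#'   one row per (bat, night, site).
#' @export
assign_visits <- function(fixes, landscape, min_fixes_per_visit = 2) {
  if (nrow(landscape$sites) == 0L) stop("empty landscape", call. = FALSE)
  fx <- tibble::as_tibble(fixes)
  if (!"night" %in% names(fx)) {
    nd <- assign_night(fx$timestamp)
    fx$night <- as.integer(nd - min(nd)) + 1L
  }
  sites <- landscape$sites
  hits <- purrr::map(seq_len(nrow(sites)), function(i) {
    inside <- (fx$x - sites$x[i])^2 + (fx$y - sites$y[i])^2 <= sites$radius[i]^2
    if (!any(inside)) return(NULL)
    dplyr::mutate(fx[inside, c("bat_id", "night")], site_id = sites$site_id[i])
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(bat_id = character(), night = integer(),
                          site_id = character(), n_fixes = integer()))
  }
  hits |>
    dplyr::count(.data$bat_id, .data$night, .data$site_id, name = "n_fixes") |>
    dplyr::filter(.data$n_fixes >= min_fixes_per_visit) |>
    dplyr::arrange(.data$bat_id, .data$night, .data$site_id)
}

#' Tracking effort: the rate of discovering new foraging sites
#'
#' For each consecutive tracking night *t* (per bat), a site counts as new
#' for a bat the first night that bat is recorded there. The per-night mean
#' number of newly visited sites is averaged over the bats observed on that
#' night; the probability of visiting a new site is that mean divided by
#' the night number *t* (`method = "literal"`). The alternative
#' `"cumulative"` divides the mean cumulative count of distinct sites seen
#' up to night *t* by *t* instead.
#'
#' @param visits A visit tibble (`bat_id`, `night`, `site_id`).
#' @param method `"literal"` (default) or `"cumulative"`; see Details.
#' @return Tibble with one row per consecutive night: `night`, `n_bats`,
#'   `mean_new_sites`, `p_new_site`.
#' @export
tracking_effort <- function(visits, method = c("literal", "cumulative")) {
  method <- match.arg(method)
  if (nrow(visits) == 0L) stop("`visits` is empty", call. = FALSE)
  v <- visits |>
    dplyr::distinct(.data$bat_id, .data$night, .data$site_id) |>
    dplyr::group_by(.data$bat_id) |>
    dplyr::mutate(night_rank = dplyr::dense_rank(.data$night)) |>
    dplyr::group_by(.data$bat_id, .data$site_id) |>
    dplyr::mutate(new_site = .data$night_rank == min(.data$night_rank)) |>
    dplyr::ungroup()
  per_bat_night <- v |>
    dplyr::group_by(.data$bat_id, .data$night_rank) |>
    dplyr::summarise(n_new = sum(.data$new_site), .groups = "drop") |>
    dplyr::group_by(.data$bat_id) |>
    dplyr::arrange(.data$night_rank, .by_group = TRUE) |>
    dplyr::mutate(cum_new = cumsum(.data$n_new)) |>
    dplyr::ungroup()
  per_bat_night |>
    dplyr::group_by(night = .data$night_rank) |>
    dplyr::summarise(
      n_bats = dplyr::n(),
      mean_new_sites = mean(.data$n_new),
      mean_cum_sites = mean(.data$cum_new),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p_new_site = if (method == "literal") .data$mean_new_sites / .data$night
                   else .data$mean_cum_sites / .data$night
    ) |>
    dplyr::select("night", "n_bats", "mean_new_sites", "p_new_site")
}
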