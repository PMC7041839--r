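#' Minimum convex polygon for one set of fixes
#'
#' The classical MCP home-range estimator: retain the `floor(level/100 * n)`
#' fixes closest to the arithmetic mean centre (a single peeling pass; ties
#' in distance keep the earlier record, so supply fixes in time order), then
#' take their convex hull. The area comes from the shoelace formula and is
#' reported in hectares.
#'
#' @param x,y Numeric coordinate vectors in metres.
#' @param level Percentage of fixes to retain, in (0, 100\]; 95 is the
#'   conventional home range, 50 the core area.
#' @return A list of class `mcp` with `level`, `n_fixes` (retained),
#'   `area_ha`, `collinear` (TRUE when the retained fixes span no area; the
#'   degenerate polygon is returned with a warning) and `polygon`
#'   (two-column matrix of hull vertices in counter-clockwise order).
#' @export
mcp <- function(x, y, level = 95) {
  stopifnot(length(x) == length(y), level > 0, level <= 100)
  keep_n <- floor(level / 100 * length(x))
  ctr <- c(mean(x), mean(y))
  d2 <- (x - ctr[1])^2 + (y - ctr[2])^2
  ord <- order(d2)                       # stable: ties keep earlier records
  keep <- sort(ord[seq_len(keep_n)])     # restore time order
  if (keep_n < 5L) stop("too few fixes", call. = FALSE)
  px <- x[keep]; py <- y[keep]
  h <- grDevices::chull(px, py)
  poly <- cbind(x = px[h], y = py[h])
  area_m2 <- shoelace_area(poly)
  collinear <- nrow(poly) < 3L || area_m2 == 0
  if (collinear) warning("fixes are collinear; zero-area polygon returned",
                         call. = FALSE)
  structure(
    list(level = level, n_fixes = keep_n, area_ha = area_m2 / 1e4,
         collinear = collinear, polygon = poly),
    class = "mcp"
  )
}

shoelace_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  i2 <- c(2:n, 1L)
  abs(sum(poly[, 1] * poly[i2, 2] - poly[i2, 1] * poly[, 2])) / 2
}

#' Home ranges and core areas for many bats
#'
#' Applies [mcp()] per bat (and per season when a `season` column is
#' present) at each requested level. Bats with too few fixes at a level are
#' dropped with a warning.
#'
#' @param fixes Tibble with `bat_id`, `x`, `y` and optionally `season`;
#'   rows should be in time order (ties in peeling keep earlier fixes).
#' @param levels Percentages to estimate (default home range 95 and core
#'   area 50).
#' @return A tibble with one row per bat x level: `bat_id` (`season`),
#'   `level`, `n_fixes`, `area_ha`, `collinear`, and the hull in the
#'   list-column `polygon`.
#' @export
home_ranges <- function(fixes, levels = c(50, 95)) {
  keys <- intersect(c("bat_id", "season"), names(fixes))
  grp <- dplyr::group_split(dplyr::group_by(fixes, dplyr::across(dplyr::all_of(keys))))
  out <- purrr::map(grp, function(g) {
    purrr::map(levels, function(lv) {
      hr <- tryCatch(suppressWarnings(mcp(g$x, g$y, lv)), error = function(e) NULL)
      if (is.null(hr)) return(NULL)
      res <- g[1L, keys]
      res$level <- lv
      res$n_fixes <- hr$n_fixes
      res$area_ha <- hr$area_ha
      res$collinear <- hr$collinear
      res$polygon <- list(hr$polygon)
      res
    }) |> dplyr::bind_rows()
  })
  dropped <- sum(vapply(out, nrow, 1L) < length(levels))
  if (dropped > 0L) {
    warning(sprintf("%d bat(s) dropped at some level (too few fixes)", dropped),
            call. = FALSE)
  }
  dplyr::bind_rows(out)
}

#' Seasonal summary of home-range areas
#'
#' Per-season distributions of MCP/CA areas — medians and quartiles, plus
#' the raw area vectors for downstream rank tests (e.g.
#' [node_perm_kruskal()]). Seasons with fewer than two bats are excluded
#' with a warning.
#'
#' @param homeranges Output of [home_ranges()] including a `season` column.
#' @param level Which level to summarise (default 95).
#' @return A list of class `season_area_summary` with `summary` (tibble:
#'   `season`, `n`, `median_ha`, `q25_ha`, `q75_ha`) and `areas` (named
#'   list of per-season area vectors).
#' @export
seasonal_area_summary <- function(homeranges, level = 95) {
  hr <- dplyr::filter(homeranges, .data$level == !!level)
  if (!"season" %in% names(hr)) stop("`homeranges` needs a `season` column",
                                     call. = FALSE)
  counts <- dplyr::count(hr, .data$season)
  small <- counts$season[counts$n < 2L]
  if (length(small) > 0L) {
    warning(sprintf("season(s) excluded with < 2 bats: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    hr <- dplyr::filter(hr, !.data$season %in% small)
  }
  summ <- hr |>
    dplyr::group_by(.data$season) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_ha = median(.data$area_ha),
      q25_ha = quantile(.data$area_ha, 0.25, names = FALSE),
      q75_ha = quantile(.data$area_ha, 0.75, names = FALSE),
      .groups = "drop"
    )
  structure(
    list(summary = summ,
         areas = split(hr$area_ha, hr$season)),
    class = "season_area_summary"
  )
}

#' @export
print.season_area_summary <- function(x, ...) {
  cat("Seasonal home-range area summary (ha)\n")
  print(x$summary)
  invisible(x)
}
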