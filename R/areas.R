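#' Read arrival areas from a GeoJSON-style polygon file
#'
#' Loads named simple polygons used by [first_arrival_ages()]. With no
#' `path`, the bundled observation regions are returned: the published
#' Mauritania bycatch box (20-30 degW, 11-22 degN) plus documented
#' approximations (~150 km offshore bands) for Portugal, the Gulf of Cadiz,
#' Tunisia, the Bay of Biscay and Galicia.
#'
#' @param path Path to a GeoJSON FeatureCollection of Polygon features with a
#'   `name` property; default: the bundled area file.
#' @return A long tibble with columns `area`, `lon`, `lat` (ordered
#'   vertices, unclosed) and `provenance`.
#' @examples
#' dplyr::count(read_arrival_areas(), area)
#' @export
read_arrival_areas <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "arrival_areas.geojson", package = "stamm",
                        mustWork = TRUE)
  }
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  rows <- purrr::map(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, purrr::map(ring, ~ c(.x[[1]], .x[[2]])))
    # drop the closing vertex; membership code closes rings itself
    if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) {
      xy <- xy[-nrow(xy), , drop = FALSE]
    }
    check_simple_polygon(xy, f$properties$name)
    tibble::tibble(
      area = f$properties$name,
      lon = xy[, 1], lat = xy[, 2],
      provenance = f$properties$provenance %||% NA_character_
    )
  })
  out <- dplyr::bind_rows(rows)
  nms <- purrr::map_chr(gj$features, ~ .x$properties$name)
  if (anyDuplicated(nms)) stop("area names must be unique")
  out
}

# reject self-intersecting rings (adjacent segments sharing a vertex are fine)
check_simple_polygon <- function(xy, name) {
  n <- nrow(xy)
  if (n < 3) stop(sprintf("polygon '%s' has fewer than 3 vertices", name))
  seg <- cbind(xy, rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE]))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      if (segments_cross(seg[i, ], seg[j, ])) {
        stop(sprintf("polygon '%s' is self-intersecting", name))
      }
    }
  }
  invisible(TRUE)
}

segments_cross <- function(s1, s2) {
  d <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d1 <- d(s1[1], s1[2], s1[3], s1[4], s2[1], s2[2])
  d2 <- d(s1[1], s1[2], s1[3], s1[4], s2[3], s2[4])
  d3 <- d(s2[1], s2[2], s2[3], s2[4], s1[1], s1[2])
  d4 <- d(s2[1], s2[2], s2[3], s2[4], s1[3], s1[4])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}
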