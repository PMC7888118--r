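#' Study domains
#'
#' A domain is the region from which presences arise and inside which every
#' pseudo-absence must fall: either a longitude/latitude bounding box or a
#' gridded logical mask. Both support a vectorized containment predicate and
#' uniform-by-area sampling.
#'
#' @param lon_min,lon_max,lat_min,lat_max Box bounds in decimal degrees.
#' @return An object of class `pa_domain`.
#' @examples
#' d <- domain_bbox(-140, -115, 32, 45)
#' domain_contains(d, -120, 40)
#' @export
domain_bbox <- function(lon_min, lon_max, lat_min, lat_max) {
  if (!is.finite(lon_min) || !is.finite(lon_max) || lon_min >= lon_max)
    stop("domain_bbox: lon bounds must be finite and ordered (lon_min < lon_max)")
  if (!is.finite(lat_min) || !is.finite(lat_max) || lat_min >= lat_max)
    stop("domain_bbox: lat bounds must be finite and ordered (lat_min < lat_max)")
  if (lat_min < -90 || lat_max > 90)
    stop("domain_bbox: lat bounds must lie in [-90, 90]")
  structure(list(lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max),
            class = c("pa_bbox", "pa_domain"))
}

#' @rdname domain_bbox
#' @param grid A grid geometry as returned by [env_grid()].
#' @param mask Logical matrix (`n_rows x n_cols`), `TRUE` where the domain is.
#' @export
domain_mask <- function(grid, mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (nrow(mask) != grid$n_rows || ncol(mask) != grid$n_cols)
    stop("domain_mask: mask dimensions must match the grid")
  if (!any(mask)) stop("domain_mask: mask has no TRUE cells (empty domain)")
  structure(list(grid = grid, mask = mask),
            class = c("pa_mask", "pa_domain"))
}

#' Test whether points fall inside a domain
#'
#' @param domain A `pa_domain`.
#' @param lon,lat Numeric vectors of coordinates (degrees).
#' @return Logical vector.
#' @export
domain_contains <- function(domain, lon, lat) UseMethod("domain_contains")

#' @export
domain_contains.pa_bbox <- function(domain, lon, lat) {
  lon >= domain$lon_min & lon <= domain$lon_max &
    lat >= domain$lat_min & lat <= domain$lat_max
}

#' @export
domain_contains.pa_mask <- function(domain, lon, lat) {
  idx <- grid_cell_index(domain$grid, lon, lat)
  ok <- !is.na(idx)
  ok[ok] <- domain$mask[idx[ok]]
  ok
}

#' Sample points uniformly by area within a domain
#'
#' For a bounding box the latitude is drawn with density proportional to
#' cos(latitude), so samples are uniform with respect to spherical area
#' rather than uniform in degrees. Masked domains are sampled by rejection
#' from the grid's bounding box.
#'
#' Uses the current RNG state; call `set.seed()` for reproducibility.
#'
#' @param domain A `pa_domain`.
#' @param n Number of points.
#' @param max_tries Rejection-sampling cap per point (mask domains).
#' @return A data.frame with columns `lon`, `lat`.
#' @export
domain_sample <- function(domain, n, max_tries = 1000L) UseMethod("domain_sample")

#' @export
domain_sample.pa_bbox <- function(domain, n, max_tries = 1000L) {
  lon <- stats::runif(n, domain$lon_min, domain$lon_max)
  s1 <- sin(domain$lat_min * pi / 180)
  s2 <- sin(domain$lat_max * pi / 180)
  lat <- asin(stats::runif(n, s1, s2)) * 180 / pi
  data.frame(lon = lon, lat = lat)
}

#' @export
domain_sample.pa_mask <- function(domain, n, max_tries = 1000L) {
  g <- domain$grid
  box <- domain_bbox(g$lon0, g$lon0 + g$n_cols * g$cell,
                     g$lat0 - g$n_rows * g$cell, g$lat0)
  out <- matrix(NA_real_, n, 2)
  filled <- 0L
  tries <- 0L
  while (filled < n) {
    if (tries >= max_tries)
      stop("domain_sample: rejection sampling failed after ", max_tries,
           " rounds (degenerate mask?)")
    cand <- domain_sample.pa_bbox(box, max(2L * (n - filled), 32L))
    keep <- domain_contains(domain, cand$lon, cand$lat)
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) > 0) {
      take <- min(nrow(cand), n - filled)
      out[(filled + 1):(filled + take), ] <- as.matrix(cand[seq_len(take), ])
      filled <- filled + take
    }
    tries <- tries + 1L
  }
  data.frame(lon = out[, 1], lat = out[, 2])
}

#' @export
print.pa_domain <- function(x, ...) {
  if (inherits(x, "pa_bbox")) {
    cat(sprintf("<domain: bounding box lon [%g, %g], lat [%g, %g]>\n",
                x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  } else {
    cat(sprintf("<domain: raster mask %d x %d, %d cells inside>\n",
                x$grid$n_rows, x$grid$n_cols, sum(x$mask)))
  }
  invisible(x)
}
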