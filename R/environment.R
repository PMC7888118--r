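#' Grid geometry
#'
#' Grids are cell-center registered and indexed row-major from the
#' north-west corner: `lon0`, `lat0` are the coordinates of the NW *edge*
#' of the grid, `cell` is the cell size in decimal degrees, and cell
#' `(i, j)` (0-based internally) has its center at
#' `lon0 + (j + 0.5) cell`, `lat0 - (i + 0.5) cell`.
#'
#' @param lon0,lat0 North-west corner of the grid (degrees).
#' @param cell Cell size in degrees (> 0).
#' @param n_cols,n_rows Grid dimensions (>= 2).
#' @return A list of class `env_grid`.
#' @export
env_grid <- function(lon0, lat0, cell, n_cols, n_rows) {
  if (!is.finite(cell) || cell <= 0)
    stop("env_grid: 'cell' must be a positive number")
  if (n_cols < 2 || n_rows < 2)
    stop("env_grid: 'n_cols' and 'n_rows' must both be >= 2")
  if (lat0 - n_rows * cell < -90 || lat0 > 90)
    stop("env_grid: 'lat0' places the grid outside [-90, 90] latitude")
  structure(list(lon0 = lon0, lat0 = lat0, cell = cell,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
            class = "env_grid")
}

# linear (column-major, R matrix) index of the cell containing each point,
# NA outside the grid extent
grid_cell_index <- function(grid, lon, lat) {
  j <- floor((lon - grid$lon0) / grid$cell)        # 0-based col
  i <- floor((grid$lat0 - lat) / grid$cell)        # 0-based row from north
  ok <- !is.na(j) & !is.na(i) & j >= 0 & j < grid$n_cols & i >= 0 & i < grid$n_rows
  idx <- rep(NA_integer_, length(lon))
  idx[ok] <- as.integer(i[ok] + 1 + j[ok] * grid$n_rows)
  idx
}

# centers of all cells, row-major from the NW corner
grid_cell_centers <- function(grid) {
  lons <- grid$lon0 + (seq_len(grid$n_cols) - 0.5) * grid$cell
  lats <- grid$lat0 - (seq_len(grid$n_rows) - 0.5) * grid$cell
  list(lon = lons, lat = lats)
}

#' Layer specifications for synthetic environments
#'
#' Three layer kinds cover the qualitative variety of real predictor stacks:
#' smooth monotone gradients (e.g. an onshore-offshore temperature gradient),
#' spatially autocorrelated noise (e.g. chlorophyll patchiness), and distance
#' to a set of point features (e.g. distance to water holes or roads).
#' Layers are `static` (one slice) or `monthly` (12 slices indexed 1-12).
#'
#' @param name Layer name (must be unique within a spec).
#' @param direction_deg Compass direction of increase for gradient layers
#'   (90 = values increase eastward).
#' @param range Length-2 numeric, value range of the gradient.
#' @param temporal `"static"` or `"monthly"`. Monthly gradient layers get a
#'   deterministic sinusoidal seasonal offset (amplitude
#'   `seasonal_amplitude`); monthly noise layers get independent fields per
#'   month.
#' @param seasonal_amplitude Additive seasonal amplitude for monthly
#'   gradients, in layer units.
#' @return A `layer_spec` list.
#' @export
layer_gradient <- function(name, direction_deg = 90, range = c(0, 1),
                           temporal = c("static", "monthly"),
                           seasonal_amplitude = 0.1 * diff(range)) {
  temporal <- match.arg(temporal)
  stopifnot(length(range) == 2, diff(range) > 0)
  structure(list(name = name, kind = "gradient", temporal = temporal,
                 direction_deg = direction_deg, range = range,
                 seasonal_amplitude = seasonal_amplitude),
            class = "layer_spec")
}

#' @rdname layer_gradient
#' @param correlation_length Gaussian smoothing length in cells (> 0);
#'   controls the spatial autocorrelation range of the noise field.
#' @export
layer_noise <- function(name, correlation_length = 5,
                        temporal = c("static", "monthly")) {
  temporal <- match.arg(temporal)
  stopifnot(correlation_length > 0)
  structure(list(name = name, kind = "smoothed-noise", temporal = temporal,
                 correlation_length = correlation_length),
            class = "layer_spec")
}

#' @rdname layer_gradient
#' @param features Two-column matrix or data.frame of feature lon/lat.
#' @export
layer_distance <- function(name, features, temporal = c("static", "monthly")) {
  temporal <- match.arg(temporal)
  features <- as.matrix(features)
  stopifnot(ncol(features) == 2, nrow(features) >= 1)
  structure(list(name = name, kind = "distance-to-feature", temporal = temporal,
                 features = features),
            class = "layer_spec")
}

#' Specification of a synthetic environment
#'
#' @param grid An [env_grid()].
#' @param layers List of layer specs ([layer_gradient()], [layer_noise()],
#'   [layer_distance()]); at least one, names unique.
#' @param missing_frac Fraction of cells (per layer, shared across that
#'   layer's time slices) marked missing, in `[0, 1)`.
#' @param seed Integer seed controlling all stochastic layers.
#' @return An `env_spec` list.
#' @export
env_spec <- function(grid, layers, missing_frac = 0, seed = 1L) {
  if (!inherits(grid, "env_grid")) stop("env_spec: 'grid' must be an env_grid")
  if (length(layers) < 1) stop("env_spec: 'layers' must contain at least one layer")
  if (!all(vapply(layers, inherits, TRUE, "layer_spec")))
    stop("env_spec: every element of 'layers' must be a layer_spec")
  nm <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("env_spec: layer names must be unique")
  if (missing_frac < 0 || missing_frac >= 1)
    stop("env_spec: 'missing_frac' must be in [0, 1)")
  names(layers) <- nm
  structure(list(grid = grid, layers = layers,
                 missing_frac = missing_frac, seed = as.integer(seed)),
            class = "env_spec")
}

# Gaussian smoothing of a matrix, separable kernel, reflect padding
smooth_matrix <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(min(half, n))]), v, rev(v[n + 1 - seq_len(min(half, n))]))
    if (length(vp) < n + 2 * half)   # short vectors: pad by recycling edges
      vp <- c(rep(vp[1], n + 2 * half - length(vp)), vp)
    out <- stats::filter(vp, k, sides = 2)
    out[(half + 1):(half + n)]
  }
  m2 <- apply(m, 2, pad_conv)
  t(apply(m2, 1, pad_conv))
}

#' Generate a synthetic environment stack
#'
#' Deterministic given the spec (including its seed): gradient layers vary
#' monotonically along their stated direction; smoothed-noise layers are
#' Gaussian-smoothed white noise standardized to zero mean and unit variance;
#' distance layers hold the geodesic distance (km) to the nearest feature
#' point. A `missing_frac` fraction of each layer's cells is set to `NA`
#' (the same cells across that layer's time slices).
#'
#' @param spec An [env_spec()].
#' @return An object of class `env_stack`: named layers, each with 1 (static)
#'   or 12 (monthly) matrices of `n_rows x n_cols`, plus the grid geometry.
#' @export
generate_environment <- function(spec) {
  if (!inherits(spec, "env_spec")) stop("generate_environment: 'spec' must be an env_spec")
  g <- spec$grid
  cc <- grid_cell_centers(g)
  lon_m <- matrix(cc$lon, g$n_rows, g$n_cols, byrow = TRUE)
  lat_m <- matrix(cc$lat, g$n_rows, g$n_cols)

  set.seed(spec$seed)
  layers <- vector("list", length(spec$layers))
  names(layers) <- names(spec$layers)

  for (li in seq_along(spec$layers)) {
    ls <- spec$layers[[li]]
    n_slices <- if (ls$temporal == "monthly") 12L else 1L
    base <- switch(ls$kind,
      "gradient" = {
        th <- ls$direction_deg * pi / 180
        # projection of cell center onto the direction of increase; latitude
        # and longitude in degrees on a common scale is fine for ranking
        proj <- sin(th) * lon_m + cos(th) * lat_m
        p01 <- (proj - min(proj)) / (max(proj) - min(proj))
        ls$range[1] + p01 * diff(ls$range)
      },
      "smoothed-noise" = NULL,           # per-slice
      "distance-to-feature" = {
        d <- matrix(Inf, g$n_rows, g$n_cols)
        for (fi in seq_len(nrow(ls$features))) {
          d <- pmin(d, matrix(
            gc_distance_km(as.vector(lon_m), as.vector(lat_m),
                           ls$features[fi, 1], ls$features[fi, 2]),
            g$n_rows, g$n_cols))
        }
        d
      },
      stop("generate_environment: unknown layer kind '", ls$kind, "'"))

    slices <- vector("list", n_slices)
    for (s in seq_len(n_slices)) {
      slices[[s]] <- switch(ls$kind,
        "gradient" = {
          if (n_slices == 1L) base
          else base + ls$seasonal_amplitude * sin(2 * pi * (s - 1) / 12)
        },
        "smoothed-noise" = {
          z <- smooth_matrix(matrix(stats::rnorm(g$n_rows * g$n_cols),
                                    g$n_rows, g$n_cols),
                             ls$correlation_length)
          (z - mean(z)) / stats::sd(z)
        },
        base)
    }

    if (spec$missing_frac > 0) {
      n_cells <- g$n_rows * g$n_cols
      miss <- sample.int(n_cells, size = round(spec$missing_frac * n_cells))
      for (s in seq_len(n_slices)) slices[[s]][miss] <- NA_real_
    }
    layers[[li]] <- list(kind = ls$kind, temporal = ls$temporal, slices = slices)
  }

  env <- structure(list(grid = g, layers = layers, spec = spec),
                   class = "env_stack")
  env$stats <- env_layer_stats(env)
  env
}

# per-layer mean/sd over all finite values across slices (used to
# standardize covariates for habitat-biased track simulation)
env_layer_stats <- function(env) {
  lapply(env$layers, function(L) {
    v <- unlist(lapply(L$slices, as.vector), use.names = FALSE)
    v <- v[is.finite(v)]
    list(mean = mean(v), sd = max(stats::sd(v), 1e-12))
  })
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack: %d x %d grid, cell %g deg, %d layer(s)>\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$cell, length(x$layers)))
  for (nm in names(x$layers)) {
    L <- x$layers[[nm]]
    cat(sprintf("  %-14s %-20s %s\n", nm, L$kind,
                if (L$temporal == "monthly") "monthly (12 slices)" else "static"))
  }
  invisible(x)
}

#' Layer names of an environment stack
#' @param env An `env_stack`.
#' @export
env_layer_names <- function(env) names(env$layers)

#' Bounding-box domain covering a stack's grid extent
#' @param env An `env_stack`.
#' @export
env_domain <- function(env) {
  g <- env$grid
  domain_bbox(g$lon0, g$lon0 + g$n_cols * g$cell,
              g$lat0 - g$n_rows * g$cell, g$lat0)
}

#' Serialize / read an environment stack as plain text
#'
#' Writes a JSON header (grid geometry, layer kinds) and one long-format CSV
#' of cell values (`layer, month, row, col, value`; `row`/`col` 0-based from
#' the north-west corner, `month` 0 for static layers).
#'
#' @param env An `env_stack`.
#' @param dir Directory to write `env_header.json` and `env_values.csv` into.
#' @return `dir`, invisibly (for `write_env_csv`); an `env_stack` (for
#'   `read_env_csv`).
#' @export
write_env_csv <- function(env, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- env$grid
  hdr <- list(grid = g[c("lon0", "lat0", "cell", "n_cols", "n_rows")],
              layers = lapply(env$layers, function(L) L[c("kind", "temporal")]))
  jsonlite::write_json(hdr, file.path(dir, "env_header.json"),
                       auto_unbox = TRUE, digits = NA)
  rows <- list()
  for (nm in names(env$layers)) {
    L <- env$layers[[nm]]
    for (s in seq_along(L$slices)) {
      m <- L$slices[[s]]
      rows[[length(rows) + 1]] <- data.frame(
        layer = nm,
        month = if (L$temporal == "monthly") s else 0L,
        row = rep(seq_len(nrow(m)) - 1L, ncol(m)),
        col = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
        value = as.vector(m))
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "env_values.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_env_csv
#' @export
read_env_csv <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "env_header.json"))
  g <- do.call(env_grid, hdr$grid)
  vals <- utils::read.csv(file.path(dir, "env_values.csv"))
  layers <- list()
  for (nm in names(hdr$layers)) {
    info <- hdr$layers[[nm]]
    lv <- vals[vals$layer == nm, ]
    months <- sort(unique(lv$month))
    slices <- lapply(months, function(mo) {
      sl <- lv[lv$month == mo, ]
      m <- matrix(NA_real_, g$n_rows, g$n_cols)
      m[cbind(sl$row + 1L, sl$col + 1L)] <- sl$value
      m
    })
    layers[[nm]] <- list(kind = info$kind, temporal = info$temporal,
                         slices = slices)
  }
  env <- structure(list(grid = g, layers = layers, spec = NULL),
                   class = "env_stack")
  env$stats <- env_layer_stats(env)
  env
}
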