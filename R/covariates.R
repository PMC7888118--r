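# value of one layer at points; month required for monthly layers
extract_layer <- function(env, name, lon, lat, month = NULL) {
  L <- env$layers[[name]]
  if (is.null(L)) stop("extract_layer: no layer named '", name, "'")
  idx <- grid_cell_index(env$grid, lon, lat)
  if (L$temporal == "monthly") {
    if (is.null(month)) stop("extract_layer: layer '", name,
                             "' is monthly but no month was given")
    month <- as.integer(month)
    if (any(month < 1 | month > 12, na.rm = TRUE))
      stop("extract_layer: month out of 1-12")
    if (length(month) == 1L) month <- rep(month, length(lon))
    out <- rep(NA_real_, length(lon))
    ok <- !is.na(idx)
    for (mo in unique(month[ok])) {
      sel <- ok & month == mo
      out[sel] <- L$slices[[mo]][idx[sel]]
    }
    out
  } else {
    out <- rep(NA_real_, length(lon))
    ok <- !is.na(idx)
    out[ok] <- L$slices[[1]][idx[ok]]
    out
  }
}

#' Extract covariate values at points
#'
#' Containing-cell (nearest-cell) lookup per layer, no interpolation.
#' Monthly layers are indexed by each point's calendar month, so points must
#' carry timestamps when any layer is monthly. Points outside the grid
#' extent or on missing cells yield `NA` (not an error).
#'
#' @param env An `env_stack`.
#' @param points A data.frame with `lon`, `lat` and (if needed) `timestamp`.
#' @return A data.frame with one column per layer, `nrow(points)` rows.
#' @export
extract_covariates <- function(env, points) {
  any_monthly <- any(vapply(env$layers, function(L) L$temporal == "monthly", TRUE))
  month <- NULL
  if (any_monthly) {
    if (is.null(points$timestamp))
      stop("extract_covariates: points need a 'timestamp' column for monthly layers")
    month <- as.integer(format(points$timestamp, "%m"))
  }
  out <- lapply(env_layer_names(env), function(nm) {
    if (env$layers[[nm]]$temporal == "monthly")
      extract_layer(env, nm, points$lon, points$lat, month)
    else extract_layer(env, nm, points$lon, points$lat)
  })
  names(out) <- env_layer_names(env)
  as.data.frame(out, optional = TRUE)
}

#' Assemble the presence/pseudo-absence model table
#'
#' Binds presences (label 1) and a pseudo-absence set (label 0), extracts
#' all covariates, and drops rows with any missing covariate, logging the
#' dropped count per label. After dropping, both labels must survive; exact
#' 1:1 balance may be lost (and is reported by the drop log).
#'
#' @param presences Data.frame with `animal_id`, `timestamp`, `lon`, `lat`.
#' @param absences A [pa_generate()] pseudo-absence set (label 0 records).
#' @param env An `env_stack`.
#' @param quiet Suppress the drop-count message.
#' @return A `pa_table`: label, animal_id, timestamp, lon, lat, method, one
#'   column per covariate.
#' @export
build_pa_table <- function(presences, absences, env, quiet = FALSE) {
  method <- if (!is.null(absences$method)) as.character(absences$method[1]) else "unknown"
  pres <- data.frame(label = 1L,
                     animal_id = as.character(presences$animal_id),
                     timestamp = presences$timestamp,
                     lon = presences$lon, lat = presences$lat,
                     method = method)
  abs_ <- data.frame(label = 0L,
                     animal_id = as.character(absences$animal_id),
                     timestamp = absences$timestamp,
                     lon = absences$lon, lat = absences$lat,
                     method = method)
  tab <- rbind(pres, abs_)
  covs <- extract_covariates(env, tab)
  keep <- stats::complete.cases(covs)
  n_drop_pres <- sum(!keep & tab$label == 1L)
  n_drop_abs <- sum(!keep & tab$label == 0L)
  if (!quiet && (n_drop_pres || n_drop_abs))
    message("build_pa_table: dropped ", n_drop_pres, " presence and ",
            n_drop_abs, " pseudo-absence row(s) with missing covariates")
  out <- cbind(tab[keep, , drop = FALSE], covs[keep, , drop = FALSE])
  if (!nrow(out)) stop("build_pa_table: all rows dropped (no usable covariates)")
  if (length(unique(out$label)) < 2)
    stop("build_pa_table: one label lost entirely after dropping missing rows")
  rownames(out) <- NULL
  attr(out, "covariates") <- env_layer_names(env)
  attr(out, "dropped") <- c(presence = n_drop_pres, absence = n_drop_abs)
  class(out) <- unique(c("pa_table", class(out)))
  out
}

#' Covariate column names of a model table
#' @param table A `pa_table`.
#' @export
pa_covariates <- function(table) {
  cv <- attr(table, "covariates")
  if (!is.null(cv)) return(cv)
  setdiff(names(table), c("label", "animal_id", "timestamp", "lon", "lat",
                          "method", "segment"))
}

#' Write a model table to CSV
#' @param table A `pa_table`.
#' @param path Output path.
#' @export
write_pa_table_csv <- function(table, path) {
  df <- as.data.frame(table)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
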