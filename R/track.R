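#' Telemetry tracks
#'
#' A track is one animal's time-ordered fixes: a data.frame with columns
#' `animal_id` (character), `timestamp` (POSIXct, UTC), `lon`, `lat`
#' (decimal degrees). Timestamps must be strictly increasing and there must
#' be at least 2 fixes.
#'
#' @param df A data.frame with the four track columns.
#' @return The validated track, classed `pa_track`.
#' @export
as_track <- function(df) {
  req <- c("animal_id", "timestamp", "lon", "lat")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("as_track: missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) < 2) stop("as_track: a track needs at least 2 fixes")
  if (!inherits(df$timestamp, "POSIXct"))
    df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  attr(df$timestamp, "tzone") <- "UTC"
  if (is.unsorted(df$timestamp, strictly = TRUE))
    stop("as_track: timestamps must be strictly increasing (animal ",
         df$animal_id[1], ")")
  if (any(df$lon < -180 | df$lon > 180, na.rm = TRUE))
    stop("as_track: lon outside [-180, 180]")
  if (any(df$lat < -90 | df$lat > 90, na.rm = TRUE))
    stop("as_track: lat outside [-90, 90]")
  df$animal_id <- as.character(df$animal_id)
  rownames(df) <- NULL
  class(df) <- unique(c("pa_track", class(df)))
  df
}

#' Read / write track CSV
#'
#' Tracks serialize as CSV with columns `animal_id`, `timestamp`
#' (ISO-8601 UTC), `lon`, `lat`. `read_track_csv` returns a list of tracks,
#' one per animal.
#'
#' @param path CSV file path.
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%SZ")
  lapply(split(df, df$animal_id), as_track)
}

#' @rdname read_track_csv
#' @param tracks A track or list of tracks.
#' @export
write_track_csv <- function(tracks, path) {
  if (inherits(tracks, "pa_track")) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, as.data.frame))
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df[, c("animal_id", "timestamp", "lon", "lat")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Regularize a track in time
#'
#' Resamples a track to fixes at exact multiples of `interval_hours` from its
#' first fix, linearly interpolating lon/lat in time between bracketing
#' observed fixes. No interpolation happens across observation gaps longer
#' than `max_gap_hours`: the output is split into segments instead (column
#' `segment`), and no fix is placed inside such a gap. Never extrapolates
#' beyond the first or last observed fix.
#'
#' @param track A [as_track()] track.
#' @param interval_hours Target sampling interval, hours (> 0).
#' @param max_gap_hours Longest observation gap to interpolate across, hours.
#' @return A regular track with a `segment` column.
#' @export
regularize_track <- function(track, interval_hours, max_gap_hours = Inf) {
  track <- as_track(track)
  if (interval_hours <= 0) stop("regularize_track: 'interval_hours' must be > 0")
  t_h <- as.numeric(difftime(track$timestamp, track$timestamp[1], units = "hours"))
  if (t_h[length(t_h)] < interval_hours)
    stop("regularize_track: track ", track$animal_id[1],
         " is shorter than one interval")
  targets <- seq(0, t_h[length(t_h)], by = interval_hours)

  # bracketing observed fix for each target time
  lo <- findInterval(targets, t_h)             # t_h[lo] <= target < t_h[lo+1]
  hi <- pmin(lo + 1L, length(t_h))
  exact <- abs(targets - t_h[lo]) < 1e-9
  hi[exact] <- lo[exact]
  gap_ok <- exact | (t_h[hi] - t_h[lo]) <= max_gap_hours
  keep <- which(gap_ok)
  if (!length(keep))
    stop("regularize_track: no target time is interpolable for track ",
         track$animal_id[1])

  w <- ifelse(exact, 0, (targets - t_h[lo]) / pmax(t_h[hi] - t_h[lo], 1e-12))
  lon <- track$lon[lo] + w * (track$lon[hi] - track$lon[lo])
  lat <- track$lat[lo] + w * (track$lat[hi] - track$lat[lo])

  # segment id increments at every dropped target
  seg <- cumsum(c(1L, diff(keep) > 1L))
  out <- data.frame(
    animal_id = track$animal_id[1],
    timestamp = track$timestamp[1] + targets[keep] * 3600,
    lon = lon[keep], lat = lat[keep],
    segment = seg)
  # drop segments that cannot contribute even one displacement
  tab <- table(out$segment)
  out <- out[out$segment %in% as.integer(names(tab)[tab >= 2]), , drop = FALSE]
  if (nrow(out) < 2)
    stop("regularize_track: all segments shorter than 2 fixes for track ",
         track$animal_id[1])
  rownames(out) <- NULL
  class(out) <- unique(c("pa_track", class(out)))
  out
}

#' Empirical movement distribution
#'
#' Extracts the paired (step length, turn angle) samples from regularized
#' tracks. Each interior fix of a segment contributes one pair: the step
#' length is the geodesic length (km) of its outgoing displacement and the
#' turn angle is the signed change in bearing from the incoming to the
#' outgoing displacement, wrapped to `(-pi, pi]` with counterclockwise turns
#' positive. Pairs are kept paired; the first fix of a segment contributes
#' none (it has no incoming bearing).
#'
#' @param tracks A track or list of tracks (regular; a `segment` column is
#'   honored if present).
#' @param pooling `"pooled"` (default) or `"per-animal"`; retained as an
#'   attribute and used by [pa_generate()] when simulating CRWs.
#' @return A data.frame of class `move_dist` with columns `step_km`,
#'   `turn_rad`, `animal_id`.
#' @export
empirical_moves <- function(tracks, pooling = c("pooled", "per-animal")) {
  pooling <- match.arg(pooling)
  if (inherits(tracks, "pa_track")) tracks <- list(tracks)
  out <- list()
  for (tr in tracks) {
    seg <- if ("segment" %in% names(tr)) tr$segment else rep(1L, nrow(tr))
    for (s in unique(seg)) {
      sub <- tr[seg == s, , drop = FALSE]
      n <- nrow(sub)
      if (n < 3) next
      b_init <- gc_bearing(sub$lon[-n], sub$lat[-n], sub$lon[-1], sub$lat[-1])
      b_final <- gc_final_bearing(sub$lon[-n], sub$lat[-n], sub$lon[-1], sub$lat[-1])
      d <- gc_distance_km(sub$lon[-n], sub$lat[-n], sub$lon[-1], sub$lat[-1])
      # pair i: incoming displacement i, outgoing displacement i+1
      turns <- turn_angle_rad(b_final[-(n - 1)], b_init[-1])
      out[[length(out) + 1]] <- data.frame(
        step_km = d[-1], turn_rad = turns, animal_id = sub$animal_id[1])
    }
  }
  if (!length(out))
    stop("empirical_moves: no segment has the >= 3 fixes needed for a pair")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "pooling") <- pooling
  class(res) <- unique(c("move_dist", class(res)))
  res
}

#' Mode step length
#'
#' The center of the most populated histogram bin of the step-length sample,
#' over equal-width bins covering `[0, max step]`; ties break toward the
#' smaller bin. Used to set the buffer-sampling radius.
#'
#' @param moves A [empirical_moves()] distribution (or any data.frame with a
#'   `step_km` column).
#' @param bin_width Bin width in km; default 5% of the 95th percentile step.
#' @return Mode step length in km.
#' @export
mode_step_length <- function(moves, bin_width = NULL) {
  steps <- moves$step_km
  if (!length(steps)) stop("mode_step_length: empty step-length distribution")
  if (is.null(bin_width)) {
    bin_width <- 0.05 * stats::quantile(steps, 0.95, names = FALSE)
    if (bin_width <= 0) bin_width <- max(max(steps), 1e-6) * 0.05
  }
  if (bin_width <= 0) stop("mode_step_length: 'bin_width' must be > 0")
  breaks <- seq(0, max(steps) + bin_width, by = bin_width)
  counts <- tabulate(findInterval(steps, breaks), nbins = length(breaks) - 1)
  i <- which.max(counts)                     # first max: smaller bin wins ties
  breaks[i] + bin_width / 2
}

#' Serialize a movement distribution to CSV
#' @param moves A `move_dist`.
#' @param path CSV path (columns `step_km`, `turn_rad`, `animal_id`).
#' @export
write_moves_csv <- function(moves, path) {
  utils::write.csv(as.data.frame(moves)[, c("step_km", "turn_rad", "animal_id")],
                   path, row.names = FALSE)
  invisible(path)
}
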