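#' Pseudo-absence generation
#'
#' Four methods of generating putative absence locations for presence-only
#' telemetry, each at an exact 1:1 ratio with the presences and confined to
#' the study domain:
#'
#' * `background` — points uniform by area over the whole domain;
#' * `buffer` — one point uniform by area on the geodesic disc of a fixed
#'   radius around each presence (radius conventionally the mode step
#'   length);
#' * `crw` — a correlated random walk resampling paired (step length, turn
#'   angle) draws from the empirical movement distribution, started at the
#'   tagging location;
#' * `reverse_crw` — the same walk started at the last fix and assigned
#'   timestamps backwards to the tagging date.
#'
#' Every record inherits the timestamp of its matched presence so dynamic
#' (monthly) covariates can be extracted without temporal bias.
#'
#' @name pseudo-absences
NULL

pa_set <- function(animal_id, timestamp, lon, lat, method, matched_idx) {
  df <- data.frame(animal_id = as.character(animal_id), timestamp = timestamp,
                   lon = lon, lat = lat, label = 0L, method = method,
                   matched_presence_index = matched_idx)
  rownames(df) <- NULL
  class(df) <- unique(c("pa_set", class(df)))
  df
}

#' Background sampling
#'
#' Draws one pseudo-absence per presence, uniform by area within the domain
#' (latitude density proportional to cos(lat) for bounding boxes; rejection
#' sampling against raster masks). Pseudo-absence `i` inherits the timestamp
#' and animal id of presence `i`.
#'
#' @param presences Data.frame with `animal_id`, `timestamp`, `lon`, `lat`.
#' @param domain A `pa_domain`.
#' @param seed Integer seed.
#' @return A `pa_set` with `nrow(presences)` records, label 0.
#' @export
background_sample <- function(presences, domain, seed = 1L) {
  n <- nrow(presences)
  if (!n) stop("background_sample: no presences")
  set.seed(seed)
  pts <- domain_sample(domain, n)
  pa_set(presences$animal_id, presences$timestamp, pts$lon, pts$lat,
         "background", seq_len(n))
}

# one point uniform by area on a geodesic disc, constrained to the domain;
# returns NULL when the retry cap is exhausted
disc_point <- function(lon, lat, radius_km, domain, tries = 20L) {
  for (i in seq_len(tries)) {
    b <- stats::runif(1, 0, 360)
    d <- radius_km * sqrt(stats::runif(1))
    p <- gc_destination(lon, lat, b, d)
    if (domain_contains(domain, p[1], p[2])) return(p)
  }
  NULL
}

#' Buffer sampling
#'
#' For each presence, draws one point uniform by area on the geodesic disc
#' of radius `radius_km` centered at that presence (bearing uniform,
#' distance `radius * sqrt(u)`), redrawing points that fall outside the
#' domain. If a presence's disc has no usable area after 20 tries, that
#' presence is skipped with a warning and a replacement is drawn around a
#' randomly chosen other presence, preserving the exact 1:1 count.
#'
#' @inheritParams background_sample
#' @param radius_km Disc radius in km (> 0); conventionally the mode step
#'   length of the empirical movement distribution.
#' @return A `pa_set` with `nrow(presences)` records.
#' @export
buffer_sample <- function(presences, radius_km, domain, seed = 1L) {
  if (!is.finite(radius_km) || radius_km <= 0)
    stop("buffer_sample: 'radius_km' must be > 0")
  n <- nrow(presences)
  if (!n) stop("buffer_sample: no presences")
  set.seed(seed)
  lon <- numeric(n); lat <- numeric(n); matched <- seq_len(n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    p <- disc_point(presences$lon[i], presences$lat[i], radius_km, domain)
    if (is.null(p)) { failed <- c(failed, i); next }
    lon[i] <- p[1]; lat[i] <- p[2]
  }
  if (length(failed)) {
    warning("buffer_sample: ", length(failed),
            " presence(s) had no in-domain buffer area; replacement(s) drawn ",
            "around other presences", call. = FALSE)
    donors <- setdiff(seq_len(n), failed)
    if (!length(donors))
      stop("buffer_sample: no presence has in-domain buffer area")
    for (i in failed) {
      repeat {
        j <- donors[sample.int(length(donors), 1)]
        p <- disc_point(presences$lon[j], presences$lat[j], radius_km, domain)
        if (!is.null(p)) break
      }
      lon[i] <- p[1]; lat[i] <- p[2]; matched[i] <- j
    }
  }
  out <- pa_set(presences$animal_id, presences$timestamp, lon, lat,
                "buffer", matched)
  attr(out, "radius_km") <- radius_km
  out
}

#' Correlated random walk pseudo-absences
#'
#' Simulates one walk per track by resampling paired (step length, turn
#' angle) rows from the empirical movement distribution with replacement.
#' `forward` walks start at the track's first fix with the heading of its
#' first observed displacement; `reverse` walks start at the last fix (with
#' the reversed track's initial heading) and assign timestamps backwards to
#' the tagging date. The start point is the first output record, so the
#' walk's length equals the track's fix count (1:1 per animal). Steps
#' landing outside the domain are redrawn up to 20 times, then the heading
#' is reflected (turned 180 degrees, turn angle redrawn) up to 20 more
#' times before the step errors out.
#'
#' @param track A [as_track()] track (>= 2 fixes).
#' @param moves An [empirical_moves()] distribution (non-empty).
#' @param domain A `pa_domain`.
#' @param seed Integer seed.
#' @param direction `"forward"` or `"reverse"`.
#' @return A `pa_set` with `nrow(track)` records.
#' @export
crw_simulate <- function(track, moves, domain, seed = 1L,
                         direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  track <- as_track(track)
  if (!nrow(moves)) stop("crw_simulate: empty move distribution")
  n <- nrow(track)
  set.seed(seed)

  if (direction == "forward") {
    lon0 <- track$lon[1]; lat0 <- track$lat[1]
    heading <- gc_bearing(track$lon[1], track$lat[1],
                          track$lon[2], track$lat[2])
    ts <- track$timestamp
    matched <- seq_len(n)
  } else {
    lon0 <- track$lon[n]; lat0 <- track$lat[n]
    heading <- gc_bearing(track$lon[n], track$lat[n],
                          track$lon[n - 1], track$lat[n - 1])
    ts <- rev(track$timestamp)          # strictly decreasing in generation order
    matched <- rev(seq_len(n))
  }

  lon <- numeric(n); lat <- numeric(n)
  lon[1] <- lon0; lat[1] <- lat0
  for (step in seq_len(n - 1)) {
    placed <- FALSE
    for (try in seq_len(20L)) {
      mv <- draw_moves(moves, 1L)
      b <- apply_turn(heading, mv$turn_rad)
      p <- gc_destination(lon[step], lat[step], b, mv$step_km)
      if (domain_contains(domain, p[1], p[2])) { placed <- TRUE; break }
    }
    if (!placed) {                       # reflect heading, redraw turn only
      heading <- (heading + 180) %% 360
      for (try in seq_len(20L)) {
        mv <- draw_moves(moves, 1L)
        b <- apply_turn(heading, mv$turn_rad)
        p <- gc_destination(lon[step], lat[step], b, mv$step_km)
        if (domain_contains(domain, p[1], p[2])) { placed <- TRUE; break }
      }
    }
    if (!placed)
      stop("crw_simulate: retries exhausted at step ", step,
           " for animal ", track$animal_id[1])
    lon[step + 1] <- p[1]; lat[step + 1] <- p[2]
    heading <- gc_final_bearing(lon[step], lat[step], p[1], p[2])
  }

  pa_set(track$animal_id[1], ts, lon, lat,
         if (direction == "forward") "crw" else "reverse_crw", matched)
}

#' Methods available to [pa_generate()]
#' @export
pa_methods <- function() c("background", "buffer", "crw", "reverse_crw")

#' Generate pseudo-absences for a study
#'
#' Dispatches over the four generation methods and concatenates per-animal
#' sets, preserving the global 1:1 invariant with the study's presences.
#' CRW methods consume the empirical movement distribution (per-animal
#' subsets when `moves` was built with `pooling = "per-animal"`); buffer
#' sampling needs a radius, defaulting to [mode_step_length()] of `moves`.
#'
#' @param method One of [pa_methods()].
#' @param study A [generate_study()] study (or any list with `tracks` and
#'   `domain`).
#' @param moves An [empirical_moves()] distribution (required for `crw`,
#'   `reverse_crw`, and for the default buffer radius).
#' @param radius_km Buffer radius override in km.
#' @param seed Integer master seed; per-animal sub-seeds are derived from it.
#' @return A `pa_set` with exactly as many records as the study has fixes.
#' @export
pa_generate <- function(method, study, moves = NULL, radius_km = NULL,
                        seed = 1L) {
  if (!method %in% pa_methods())
    stop("pa_generate: unknown method '", method, "'; valid: ",
         paste(pa_methods(), collapse = ", "))
  presences <- study_presences(study)
  domain <- study$domain

  if (method == "background")
    return(background_sample(presences, domain, seed = seed))

  if (method == "buffer") {
    if (is.null(radius_km)) {
      if (is.null(moves))
        stop("pa_generate: buffer needs 'radius_km' or 'moves' to derive it")
      radius_km <- mode_step_length(moves)
    }
    return(buffer_sample(presences, radius_km, domain, seed = seed))
  }

  # CRW variants: one walk per animal, deterministic sub-seeds
  if (is.null(moves)) stop("pa_generate: '", method, "' needs 'moves'")
  per_animal <- identical(attr(moves, "pooling"), "per-animal")
  tracks <- study$tracks
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(tracks))
  sets <- vector("list", length(tracks))
  offset <- 0L
  for (i in seq_along(tracks)) {
    mv <- moves
    if (per_animal) {
      mv_i <- moves[moves$animal_id == tracks[[i]]$animal_id[1], , drop = FALSE]
      if (nrow(mv_i)) mv <- mv_i       # fall back to pooled if animal absent
    }
    s <- crw_simulate(tracks[[i]], mv, domain, seed = sub_seeds[i],
                      direction = if (method == "crw") "forward" else "reverse")
    s$matched_presence_index <- s$matched_presence_index + offset
    offset <- offset + nrow(tracks[[i]])
    sets[[i]] <- s
  }
  out <- do.call(rbind, sets)
  rownames(out) <- NULL
  class(out) <- unique(c("pa_set", class(out)))
  out
}

#' Write a pseudo-absence set to CSV
#' @param pa A `pa_set`.
#' @param path Output path.
#' @export
write_pa_csv <- function(pa, path) {
  df <- as.data.frame(pa)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
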