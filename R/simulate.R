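#' Parametric move model
#'
#' A simple movement kernel for synthetic tracks: right-skewed Weibull step
#' lengths and wrapped-normal turn angles concentrated around 0 (persistent
#' heading). An [empirical_moves()] distribution can be used anywhere a move
#' model is expected, in which case paired (step, turn) rows are resampled
#' with replacement.
#'
#' @param step_scale_km Weibull scale of the step length (km).
#' @param step_shape Weibull shape (> 1 gives the right-skewed, unimodal
#'   shape typical of regularized telemetry steps).
#' @param turn_sd Standard deviation (radians) of the wrapped-normal turn
#'   angle; small values give strongly directional movement.
#' @return A `move_param` object.
#' @export
move_param <- function(step_scale_km = 15, step_shape = 1.5, turn_sd = 0.6) {
  stopifnot(step_scale_km > 0, step_shape > 0, turn_sd >= 0)
  structure(list(step_scale_km = step_scale_km, step_shape = step_shape,
                 turn_sd = turn_sd),
            class = "move_param")
}

# draw n paired (step_km, turn_rad) from a move model
draw_moves <- function(move, n) {
  if (inherits(move, "move_param")) {
    data.frame(step_km = stats::rweibull(n, move$step_shape, move$step_scale_km),
               turn_rad = wrap_pi(stats::rnorm(n, 0, move$turn_sd)))
  } else if (is.data.frame(move)) {
    if (!nrow(move)) stop("draw_moves: empty move distribution")
    i <- sample.int(nrow(move), n, replace = TRUE)
    data.frame(step_km = move$step_km[i], turn_rad = move$turn_rad[i])
  } else stop("draw_moves: unsupported move model")
}

#' Habitat-selection parameters for track simulation
#'
#' Ground truth for the synthetic world: at each step, `k_candidates`
#' destinations are proposed from the move model and one is chosen with
#' probability proportional to `exp(sum(beta * z))`, where `z` are the
#' candidate's covariates standardized by the domain-wide layer mean and SD
#' (so `beta` is in log-odds per SD). The step-selection form makes the
#' selection coefficients recoverable by downstream models.
#'
#' @param beta Named numeric vector of selection coefficients; every name
#'   must be a layer of the environment used for simulation.
#' @param k_candidates Candidates per step (>= 1); 1 gives an unbiased
#'   correlated random walk regardless of `beta`.
#' @param move A [move_param()] or [empirical_moves()] object.
#' @return A `selection_params` object.
#' @export
selection_params <- function(beta, k_candidates = 10L, move = move_param()) {
  if (is.null(names(beta)) || any(names(beta) == ""))
    stop("selection_params: 'beta' must be a named vector of layer coefficients")
  if (k_candidates < 1) stop("selection_params: 'k_candidates' must be >= 1")
  structure(list(beta = beta, k_candidates = as.integer(k_candidates),
                 move = move),
            class = "selection_params")
}

#' Simulate a habitat-biased track
#'
#' Step-selection simulation on a gridded environment: from the current
#' position and heading, `k_candidates` destinations are drawn as paired
#' (step length, turn angle) geodesic displacements; one is chosen with
#' probability proportional to the exponentiated linear predictor of the
#' standardized covariates at the candidate. Candidates outside the domain
#' are redrawn (up to 20 rounds); if only missing-covariate in-domain
#' candidates remain, the best of those is taken (missing contributions
#' score 0); if nothing is in domain, the heading is resampled uniformly
#' (logged warning, up to 5 times) before the animal holds position for that
#' step. Timestamps advance by a fixed interval.
#'
#' @param env An [generate_environment()] stack.
#' @param domain A [domain_bbox()]/[domain_mask()] domain.
#' @param sel A [selection_params()] object; every `beta` name must be a
#'   layer of `env`.
#' @param start Length-2 numeric `c(lon, lat)`, inside the domain.
#' @param start_time POSIXct start timestamp (UTC).
#' @param n_steps Number of steps (>= 1); the track has `n_steps + 1` fixes.
#' @param interval_hours Fix interval in hours.
#' @param animal_id Identifier for the output track.
#' @param init_heading_deg Initial compass heading; default uniform random.
#' @return A [as_track()] track of `n_steps + 1` fixes.
#' @export
simulate_track <- function(env, domain, sel, start,
                           start_time = as.POSIXct("2020-01-01", tz = "UTC"),
                           n_steps = 100L, interval_hours = 24,
                           animal_id = "animal_01", init_heading_deg = NULL) {
  stopifnot(inherits(env, "env_stack"), inherits(domain, "pa_domain"),
            inherits(sel, "selection_params"), n_steps >= 1)
  bad <- setdiff(names(sel$beta), env_layer_names(env))
  if (length(bad))
    stop("simulate_track: beta names not in environment: ",
         paste(bad, collapse = ", "))
  if (!domain_contains(domain, start[1], start[2]))
    stop("simulate_track: start point is outside the domain")

  stats_tab <- env$stats
  beta <- sel$beta
  K <- sel$k_candidates
  lon <- numeric(n_steps + 1); lat <- numeric(n_steps + 1)
  lon[1] <- start[1]; lat[1] <- start[2]
  ts <- start_time + (0:n_steps) * interval_hours * 3600
  months <- as.integer(format(ts, "%m"))
  heading <- if (is.null(init_heading_deg)) stats::runif(1, 0, 360)
             else init_heading_deg %% 360

  # standardized linear predictor at candidate points (NA contributions -> 0)
  lp_at <- function(plon, plat, month) {
    lp <- numeric(length(plon))
    n_miss <- integer(length(plon))
    for (nm in names(beta)) {
      v <- extract_layer(env, nm, plon, plat, month)
      z <- (v - stats_tab[[nm]]$mean) / stats_tab[[nm]]$sd
      miss <- !is.finite(z)
      n_miss <- n_miss + miss
      z[miss] <- 0
      lp <- lp + beta[[nm]] * z
    }
    list(lp = lp, n_miss = n_miss)
  }

  for (step in seq_len(n_steps)) {
    placed <- FALSE
    for (attempt in seq_len(5L)) {
      cand_lon <- numeric(0); cand_lat <- numeric(0); cand_b <- numeric(0)
      for (round in seq_len(20L)) {
        mv <- draw_moves(sel$move, K)
        b <- apply_turn(heading, mv$turn_rad)
        p <- gc_destination(lon[step], lat[step], b, mv$step_km)
        ok <- domain_contains(domain, p[, 1], p[, 2])
        cand_lon <- c(cand_lon, p[ok, 1]); cand_lat <- c(cand_lat, p[ok, 2])
        cand_b <- c(cand_b, b[ok])
        if (length(cand_lon) >= K) break
      }
      if (length(cand_lon)) {
        sc <- lp_at(cand_lon, cand_lat, months[step + 1])
        # prefer fully observed candidates; fall back to least-missing
        pool <- which(sc$n_miss == min(sc$n_miss))
        lp <- sc$lp[pool]
        pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
        pick <- pool[sample.int(length(pool), 1, prob = pr)]
        lon[step + 1] <- cand_lon[pick]
        lat[step + 1] <- cand_lat[pick]
        heading <- gc_final_bearing(lon[step], lat[step],
                                    lon[step + 1], lat[step + 1])
        placed <- TRUE
        break
      }
      warning("simulate_track: no in-domain candidate at step ", step,
              "; resampling heading", call. = FALSE)
      heading <- stats::runif(1, 0, 360)
    }
    if (!placed) {   # hold position; keeps the fix count contract
      lon[step + 1] <- lon[step]
      lat[step + 1] <- lat[step]
    }
  }

  as_track(data.frame(animal_id = animal_id, timestamp = ts,
                      lon = lon, lat = lat))
}

#' Generate a full synthetic study
#'
#' A study bundles a synthetic environment, its domain, and a set of
#' habitat-biased tracks simulated with known selection coefficients — the
#' ground truth for every downstream pipeline test. Per-animal sub-seeds are
#' derived deterministically from the master seed, so identical calls give
#' byte-identical serialized tracks.
#'
#' @param env_spec An [env_spec()] (or an already generated `env_stack`).
#' @param sel A [selection_params()] object.
#' @param n_animals Number of animals (>= 1).
#' @param n_steps Steps per track (each track has `n_steps + 1` fixes).
#' @param interval_hours Fix cadence in hours (24 emulates daily ARGOS-style
#'   sampling; 6 emulates GPS collars).
#' @param seed Master seed.
#' @param clustered_starts If `TRUE`, start points cluster around a single
#'   random deployment site (tag-deployment bias) instead of being uniform.
#' @param cluster_radius_km Radius of the deployment cluster.
#' @param start_time First fix timestamp, UTC.
#' @return A `pa_study` list: `env`, `domain`, `tracks` (list of tracks),
#'   `sel`, `seed`.
#' @export
generate_study <- function(env_spec, sel, n_animals = 10L, n_steps = 200L,
                           interval_hours = 24, seed = 1L,
                           clustered_starts = FALSE, cluster_radius_km = 50,
                           start_time = as.POSIXct("2020-01-01", tz = "UTC")) {
  if (n_animals < 1) stop("generate_study: 'n_animals' must be >= 1")
  env <- if (inherits(env_spec, "env_stack")) env_spec
         else generate_environment(env_spec)
  domain <- env_domain(env)

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_animals + 1L)

  set.seed(sub_seeds[1])
  if (clustered_starts) {
    center <- domain_sample(domain, 1)
    starts <- data.frame(lon = numeric(n_animals), lat = numeric(n_animals))
    for (i in seq_len(n_animals)) {
      repeat {
        p <- gc_destination(center$lon, center$lat, stats::runif(1, 0, 360),
                            cluster_radius_km * sqrt(stats::runif(1)))
        if (domain_contains(domain, p[1], p[2])) break
      }
      starts$lon[i] <- p[1]; starts$lat[i] <- p[2]
    }
  } else {
    starts <- domain_sample(domain, n_animals)
  }

  ids <- sprintf("animal_%02d", seq_len(n_animals))
  tracks <- vector("list", n_animals)
  for (i in seq_len(n_animals)) {
    set.seed(sub_seeds[i + 1])
    tracks[[i]] <- simulate_track(
      env, domain, sel, c(starts$lon[i], starts$lat[i]),
      start_time = start_time, n_steps = n_steps,
      interval_hours = interval_hours, animal_id = ids[i])
  }
  names(tracks) <- ids
  structure(list(env = env, domain = domain, tracks = tracks,
                 sel = sel, seed = as.integer(seed),
                 interval_hours = interval_hours),
            class = "pa_study")
}

#' @export
print.pa_study <- function(x, ...) {
  n_fix <- sum(vapply(x$tracks, nrow, 0L))
  cat(sprintf("<pa_study: %d animal(s), %d fixes, %d layer(s), seed %d>\n",
              length(x$tracks), n_fix, length(x$env$layers), x$seed))
  invisible(x)
}

#' All presence records of a study
#'
#' @param study A `pa_study`.
#' @return One data.frame of all fixes (the presences, label 1 implied).
#' @export
study_presences <- function(study) {
  df <- do.call(rbind, lapply(study$tracks, as.data.frame))
  rownames(df) <- NULL
  df[, c("animal_id", "timestamp", "lon", "lat")]
}
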