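# Shared fixtures and independent oracles for the test suite.
# Fixtures are generated in code; nothing is read from disk.

# --- independent metric oracles --------------------------------------

# AUC by exhaustive presence-absence pair enumeration, ties counted 1/2
auc_brute <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# TSS by brute-force sweep over all midpoint thresholds
tss_brute <- function(labels, scores) {
  u <- sort(unique(scores))
  thr <- if (length(u) == 1) u else (u[-length(u)] + u[-1]) / 2
  best <- -Inf
  for (t in thr) {
    pred <- scores >= t
    sens <- mean(pred[labels == 1])
    spec <- mean(!pred[labels == 0])
    best <- max(best, sens + spec - 1)
  }
  best
}

# Bhattacharyya coefficient by a direct two-pass histogram computation
bc_brute <- function(p, q, n_bins) {
  rng <- range(c(p, q))
  if (rng[1] == rng[2]) return(1)
  width <- diff(rng) / n_bins
  count_bins <- function(x) {
    cnt <- numeric(n_bins)
    for (v in x) {
      i <- min(n_bins, max(1, ceiling((v - rng[1]) / width)))
      if (v == rng[1]) i <- 1
      cnt[i] <- cnt[i] + 1
    }
    cnt / length(x)
  }
  sum(sqrt(count_bins(p) * count_bins(q)))
}

# --- shared synthetic fixtures ---------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# small gradient + noise world on a 60 x 60, 0.1-degree grid
tiny_env_spec <- function(seed = 101, missing_frac = 0, monthly = FALSE) {
  env_spec(env_grid(-125, 45, 0.1, 60, 60),
           list(layer_gradient("sst", direction_deg = 90, range = c(10, 25),
                               temporal = if (monthly) "monthly" else "static"),
                layer_noise("chl", correlation_length = 5)),
           missing_frac = missing_frac, seed = seed)
}

tiny_env <- function(seed = 101, ...) {
  cached(sprintf("env_%d_%s", seed, paste(c(...), collapse = "_")),
         generate_environment(tiny_env_spec(seed, ...)))
}

# strong-gradient study: clustered deployments, presences dragged east by
# selection on sst (edge-bounce warnings are part of the boundary contract)
tiny_study <- function(seed = 202, beta = 3, n_animals = 3, n_steps = 60) {
  cached(sprintf("study_%d_%g_%d_%d", seed, beta, n_animals, n_steps),
         suppressWarnings(
           generate_study(tiny_env_spec(seed),
                          selection_params(c(sst = beta),
                                           move = move_param(25, 1.5, 0.6)),
                          n_animals = n_animals, n_steps = n_steps,
                          interval_hours = 24, seed = seed,
                          clustered_starts = TRUE)))
}

# a simple manual track: regular daily fixes along given coordinates
manual_track <- function(lon, lat, id = "a1", interval_hours = 24) {
  as_track(data.frame(
    animal_id = id,
    timestamp = as.POSIXct("2020-03-01", tz = "UTC") +
      (seq_along(lon) - 1) * interval_hours * 3600,
    lon = lon, lat = lat))
}

# presence/absence table with a known response, for model-family tests:
# shape = "step" (sharp threshold) or "quadratic" (band preference)
synthetic_table <- function(n = 1000, seed = 1, shape = c("step", "quadratic"),
                            n_animals = 4) {
  shape <- match.arg(shape)
  set.seed(seed)
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  lp <- switch(shape,
               step = ifelse(x1 > 0, 3, -3),
               quadratic = 2 - 3 * x1^2 + 0.5 * x2)
  df <- data.frame(
    label = stats::rbinom(n, 1, stats::plogis(lp)),
    animal_id = sample(sprintf("a%d", seq_len(n_animals)), n, replace = TRUE),
    timestamp = as.POSIXct("2020-06-01", tz = "UTC") + seq_len(n) * 3600,
    lon = stats::runif(n, -125, -119), lat = stats::runif(n, 39, 45),
    method = "synthetic", x1 = x1, x2 = x2)
  attr(df, "covariates") <- c("x1", "x2")
  class(df) <- unique(c("pa_table", class(df)))
  df
}
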