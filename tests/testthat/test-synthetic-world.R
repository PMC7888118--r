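test_that("environment generation honors layer contracts", {
  env <- tiny_env()
  g <- env$grid

  # east gradient: values increase strictly west -> east in every row
  sst <- env$layers$sst$slices[[1]]
  expect_true(all(sst[, g$n_cols] > sst[, 1]))
  expect_true(all(apply(sst, 1, function(r) all(diff(r) >= 0))))

  # no missing cells when missing_frac = 0
  expect_false(anyNA(sst))
  expect_false(anyNA(env$layers$chl$slices[[1]]))

  # identical spec + seed => identical grids
  env2 <- generate_environment(tiny_env_spec(101))
  expect_identical(env$layers$chl$slices[[1]], env2$layers$chl$slices[[1]])

  # noise layer has spatial autocorrelation: neighbor correlation high
  chl <- env$layers$chl$slices[[1]]
  r_lag1 <- stats::cor(as.vector(chl[, -1]), as.vector(chl[, -ncol(chl)]))
  expect_gt(r_lag1, 0.8)
})

test_that("monthly layers carry 12 slices and preserve in-slice monotonicity", {
  env <- tiny_env(seed = 303, monthly = TRUE)
  expect_length(env$layers$sst$slices, 12)
  for (s in c(1, 4, 7, 10))
    expect_true(all(env$layers$sst$slices[[s]][, 60] >
                      env$layers$sst$slices[[s]][, 1]))
})

test_that("requested fraction of cells is marked missing", {
  env <- generate_environment(tiny_env_spec(55, missing_frac = 0.1))
  for (nm in env_layer_names(env)) {
    frac <- mean(is.na(env$layers[[nm]]$slices[[1]]))
    expect_equal(frac, 0.1, tolerance = 0.01)
  }
})

test_that("invalid geometry is rejected with a message naming the field", {
  expect_error(env_grid(-125, 45, 0, 60, 60), "cell")
  expect_error(env_grid(-125, 45, 0.1, 1, 60), "n_cols")
  expect_error(env_spec(env_grid(-125, 45, 0.1, 10, 10), list()), "layers")
  expect_error(env_spec(env_grid(-125, 45, 0.1, 10, 10),
                        list(layer_gradient("a")), missing_frac = 1),
               "missing_frac")
})

test_that("environment stacks round-trip through CSV serialization", {
  env <- generate_environment(
    env_spec(env_grid(-122, 41, 0.2, 12, 10),
             list(layer_gradient("sst", 45, c(0, 1), temporal = "monthly"),
                  layer_noise("chl", 2)),
             missing_frac = 0.05, seed = 9))
  dir <- withr::local_tempdir()
  write_env_csv(env, dir)
  env2 <- read_env_csv(dir)
  expect_equal(env2$grid$n_cols, env$grid$n_cols)
  for (nm in env_layer_names(env))
    for (s in seq_along(env$layers[[nm]]$slices))
      expect_equal(env2$layers[[nm]]$slices[[s]], env$layers[[nm]]$slices[[s]])
})

test_that("degenerate move model with zero selection walks a straight geodesic", {
  env <- tiny_env()
  domain <- env_domain(env)
  moves <- data.frame(step_km = 1, turn_rad = 0)
  set.seed(5)
  tr <- simulate_track(env, domain, selection_params(c(sst = 0), move = moves),
                       start = c(-122, 42), n_steps = 30,
                       init_heading_deg = 80)
  d <- gc_distance_km(tr$lon[-31], tr$lat[-31], tr$lon[-1], tr$lat[-1])
  expect_equal(d, rep(1, 30), tolerance = 1e-6)
  # straight line: empirical turn angles all zero
  mv <- empirical_moves(tr)
  expect_equal(mv$turn_rad, rep(0, nrow(mv)), tolerance = 1e-8)
  expect_equal(mv$step_km, rep(1, nrow(mv)), tolerance = 1e-6)
})

test_that("unbiased walk (beta = 0, K = 1) reproduces the move model marginal", {
  # large domain so boundary rejections cannot truncate the step marginal
  env <- generate_environment(
    env_spec(env_grid(-135, 50, 0.25, 80, 80),
             list(layer_gradient("sst", 90, c(10, 25))), seed = 1))
  domain <- env_domain(env)
  mm <- move_param(step_scale_km = 4, step_shape = 1.5, turn_sd = 0.6)
  set.seed(42)
  tr <- simulate_track(env, domain,
                       selection_params(c(sst = 0), k_candidates = 1, move = mm),
                       start = c(-125, 40), n_steps = 1000)
  steps <- gc_distance_km(tr$lon[-1001], tr$lat[-1001], tr$lon[-1], tr$lat[-1])
  set.seed(43)
  ref <- stats::rweibull(1000, mm$step_shape, mm$step_scale_km)
  ks <- suppressWarnings(stats::ks.test(steps, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("positive selection drags fixes toward high covariate values", {
  env <- tiny_env()
  domain <- env_domain(env)
  sst_domain_mean <- mean(env$layers$sst$slices[[1]])
  # single tracks wander; the monotonicity property is over seeds
  mean_sst_at <- function(beta) {
    mean(vapply(1:10, function(seed) {
      set.seed(seed)
      # edge bounces log warnings by contract; they are expected here
      tr <- suppressWarnings(
        simulate_track(env, domain,
                       selection_params(c(sst = beta),
                                        move = move_param(10, 1.5, 0.6)),
                       start = c(-122, 42), n_steps = 150))
      mean(extract_covariates(env, tr)$sst)
    }, 0))
  }
  m0 <- mean_sst_at(0); m1 <- mean_sst_at(1); m3 <- mean_sst_at(3)
  expect_gt(m3, sst_domain_mean)      # strong selection beats domain average
  expect_gte(m3, m1)                  # non-decreasing in beta over seeds
  expect_gte(m1, m0)
})

test_that("study generation meets count, containment and determinism contracts", {
  st <- generate_study(tiny_env_spec(77), selection_params(c(sst = 1)),
                       n_animals = 4, n_steps = 25, seed = 77)
  expect_length(st$tracks, 4)
  for (tr in st$tracks) {
    expect_equal(nrow(tr), 26)
    expect_true(all(domain_contains(st$domain, tr$lon, tr$lat)))
    expect_false(is.unsorted(tr$timestamp, strictly = TRUE))
  }
  st2 <- generate_study(tiny_env_spec(77), selection_params(c(sst = 1)),
                        n_animals = 4, n_steps = 25, seed = 77)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(st$tracks, f1); write_track_csv(st2$tracks, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical serialization
})

test_that("clustered starts sit closer together than uniform starts", {
  mean_pairwise <- function(clustered) {
    st <- generate_study(tiny_env_spec(88), selection_params(c(sst = 0)),
                         n_animals = 6, n_steps = 2, seed = 88,
                         clustered_starts = clustered, cluster_radius_km = 30)
    s <- t(vapply(st$tracks, function(tr) c(tr$lon[1], tr$lat[1]), numeric(2)))
    dd <- outer(seq_len(6), seq_len(6), function(i, j)
      gc_distance_km(s[i, 1], s[i, 2], s[j, 1], s[j, 2]))
    mean(dd[upper.tri(dd)])
  }
  expect_lt(mean_pairwise(TRUE), mean_pairwise(FALSE))
})

test_that("start outside the domain and unknown beta names are rejected", {
  env <- tiny_env()
  expect_error(simulate_track(env, env_domain(env),
                              selection_params(c(sst = 1)),
                              start = c(0, 0)), "outside")
  expect_error(simulate_track(env, env_domain(env),
                              selection_params(c(nope = 1)),
                              start = c(-122, 42)), "nope")
})
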