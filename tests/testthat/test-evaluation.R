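test_that("auc matches its worked examples and edge conventions", {
  expect_equal(auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2)), 0.75)
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.4, 0.2)), 1.0)
  expect_equal(auc(c(1, 0, 1, 0), rep(0.3, 4)), 0.5)       # ties count 1/2
  expect_error(auc(c(1, 1), c(0.5, 0.6)), "both labels")
})

test_that("auc equals exhaustive pair enumeration on all small instances", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(2:12, 1)
    labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))        # both classes
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)    # force ties often
    expect_equal(auc(labels, scores), auc_brute(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("auc is invariant under strictly monotone score transforms", {
  set.seed(12)
  labels <- stats::rbinom(50, 1, 0.5); labels[1:2] <- c(0, 1)
  scores <- stats::rnorm(50)
  a <- auc(labels, scores)
  expect_equal(auc(labels, exp(scores)), a, tolerance = 1e-12)
  expect_equal(auc(labels, stats::plogis(3 * scores + 2)), a, tolerance = 1e-12)
})

test_that("tss matches its worked examples and the brute-force sweep", {
  expect_equal(tss(c(1, 1, 0, 0), c(0.9, 0.8, 0.4, 0.2)), 1.0)
  expect_equal(tss(c(1, 1, 0, 0), c(0.9, 0.6, 0.7, 0.1)), 0.5)
  set.seed(13)
  for (rep in 1:200) {
    n <- sample(3:12, 1)
    labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, 0.2), n, replace = TRUE)
    expect_equal(tss(labels, scores), tss_brute(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("tss is 1 exactly when some threshold separates the classes", {
  set.seed(14)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
    scores <- stats::runif(n)
    separable <- min(scores[labels == 1]) > max(scores[labels == 0])
    expect_equal(tss(labels, scores) == 1, separable)
  }
})

test_that("tss of label-independent scores is near zero at large n", {
  set.seed(15)
  labels <- stats::rbinom(2000, 1, 0.5)
  scores <- stats::runif(2000)
  expect_lt(abs(tss(labels, scores)), 0.1)
})

test_that("bhattacharyya matches its examples, symmetry, and the oracle", {
  x <- stats::rnorm(40)
  expect_equal(bhattacharyya(x, x), 1)
  expect_equal(bhattacharyya(1:50, 101:150), 0)             # disjoint support
  expect_equal(bhattacharyya(c(1, 1, 2, 2), c(1, 1, 1, 1), n_bins = 2),
               sqrt(0.5))
  set.seed(16)
  for (rep in 1:30) {
    p <- stats::rnorm(sample(5:60, 1))
    q <- stats::rnorm(sample(5:60, 1), mean = stats::runif(1, 0, 2))
    nb <- sample(2:20, 1)
    expect_equal(bhattacharyya(p, q, nb), bc_brute(p, q, nb),
                 tolerance = 1e-12)
    expect_equal(bhattacharyya(p, q, nb), bhattacharyya(q, p, nb),
                 tolerance = 1e-12)
  }
  expect_error(bhattacharyya(numeric(0), 1:3), "non-empty")
})

test_that("explained deviance behaves at its extremes", {
  tab <- synthetic_table(600, seed = 17, shape = "step")
  tab$label <- as.integer(tab$x1 > 0)            # perfectly separable truth
  fit <- habitat_model(tab, "trees")             # full 2000-tree fit saturates
  expect_gte(explained_deviance(fit), 0.95)                 # near-saturated
  fit$null_deviance <- 0
  expect_error(explained_deviance(fit), "null deviance")
  fit$null_deviance <- 100; fit$residual_deviance <- 120
  expect_warning(v <- explained_deviance(fit), "clipped")
  expect_equal(v, 0)
})

test_that("cv splits meet their count and partition contracts", {
  tab <- synthetic_table(1000, seed = 18)
  full <- cv_split(tab, "full")
  expect_length(full, 1)
  expect_identical(full[[1]]$train, full[[1]]$test)

  r75 <- cv_split(tab, "random75", seed = 5)
  expect_length(r75[[1]]$train, 750)
  expect_length(r75[[1]]$test, 250)
  expect_length(intersect(r75[[1]]$train, r75[[1]]$test), 0)
  expect_setequal(c(r75[[1]]$train, r75[[1]]$test), seq_len(1000))
  expect_identical(cv_split(tab, "random75", seed = 5)[[1]]$train,
                   r75[[1]]$train)

  # monthly: spread timestamps over 12 months
  tab$timestamp <- as.POSIXct("2020-01-15", tz = "UTC") +
    (seq_len(1000) %% 12) * 31 * 86400
  lomo <- cv_split(tab, "month")
  expect_length(lomo, 12)
  for (f in lomo) {
    mo <- unique(format(tab$timestamp[f$test], "%m"))
    expect_length(mo, 1)
    expect_setequal(c(f$train, f$test), seq_len(1000))
  }
  # single-month data cannot be held out temporally
  tab$timestamp <- rep(as.POSIXct("2020-06-01", tz = "UTC"), 1000)
  expect_error(cv_split(tab, "month"), "2 calendar months")
})

test_that("the separation-skill regression recovers exact and noisy lines", {
  # exact negative line ("essentially perfect fit" warning is the point)
  bc <- c(0.2, 0.5, 0.8)
  r <- suppressWarnings(separation_skill_regression(bc, 1 - 0.5 * bc))
  expect_equal(r$slope, -0.5, tolerance = 1e-10)
  expect_lt(r$p_value, 1e-8)
  expect_equal(sum(stats::residuals(r$fit)^2), 0, tolerance = 1e-20)

  set.seed(19)
  bc <- stats::runif(24, 0.2, 0.95)
  auc_v <- 0.95 - 0.3 * bc + stats::rnorm(24, 0, 0.02)
  r2 <- separation_skill_regression(bc, auc_v)
  expect_gt(r2$slope, -0.4); expect_lt(r2$slope, -0.2)
  expect_lt(r2$p_value, 0.05)

  expect_error(separation_skill_regression(rep(0.5, 5), stats::runif(5)),
               "identical")
  expect_error(separation_skill_regression(c(0.1, 0.2), c(0.8, 0.9)), ">= 3")
})

test_that("evaluate_experiment produces the full metric grid and round-trips", {
  study <- tiny_study()
  rep_ <- evaluate_experiment(study, families = c("linear", "trees"),
                              schemes = "full", seed = 31, quiet = TRUE)
  expect_equal(nrow(rep_$metrics), 4 * 2 * 1)    # methods x families x schemes
  expect_setequal(unique(rep_$metrics$method), pa_methods())
  expect_true(all(rep_$metrics$auc >= 0 & rep_$metrics$auc <= 1))
  expect_true(all(rep_$metrics$tss >= -1 & rep_$metrics$tss <= 1))
  expect_true(all(rep_$metrics$r2 >= 0 & rep_$metrics$r2 <= 1))
  expect_true(all(rep_$bc$bc >= 0 & rep_$bc$bc <= 1))
  expect_equal(nrow(rep_$bc), 4 * 2)             # methods x covariates
  expect_length(rep_$top_covariates, 2)          # only two covariates exist

  dir <- withr::local_tempdir()
  write_skill_report(rep_, dir)
  back <- read_skill_report(dir)
  expect_equal(back$metrics, rep_$metrics, tolerance = 1e-12)
  expect_equal(back$bc, rep_$bc, tolerance = 1e-12)
  expect_equal(back$regression, rep_$regression, tolerance = 1e-12)
  expect_identical(back$top_covariates, rep_$top_covariates)
})

test_that("mean predictions at presences exceed those at pseudo-absences", {
  study <- tiny_study()
  rep_ <- evaluate_experiment(study, methods = "background",
                              families = "linear", schemes = "full",
                              seed = 32, quiet = TRUE)
  expect_gt(rep_$metrics$mean_pred_presence, rep_$metrics$mean_pred_absence)
})
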