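#' Fit a habitat suitability model
#'
#' One fitting function for the three model families used with
#' presence/pseudo-absence telemetry tables, all with a binomial response on
#' `label`:
#'
#' * `linear` — logistic regression with one linear term per covariate and a
#'   penalized (ridge-shrunken) per-animal random intercept, via
#'   [mgcv::gam()] with `s(animal_id, bs = "re")`;
#' * `smooth` — the same mixed structure with a thin-plate spline smooth per
#'   covariate (basis dimension `k`, default 5);
#' * `trees` — stochastic gradient-boosted regression trees via xgboost
#'   (learning rate 0.005, bag fraction 0.75, interaction depth 5, 2000
#'   trees by default; no random effect), seeded and single-threaded for
#'   reproducibility.
#'
#' With fewer than two animals the mixed families drop the random effect
#' with a warning. Training null and residual binomial deviances are stored
#' so explanatory power ([explained_deviance()]) needs no refit.
#'
#' @param table A [build_pa_table()] table (both labels present).
#' @param family `"linear"`, `"smooth"` or `"trees"`.
#' @param covariates Covariate columns to use; default all layer columns.
#' @param k Spline basis dimension per covariate (smooth family; >= 3).
#' @param learning_rate,bag_fraction,interaction_depth,n_trees Boosting
#'   hyperparameters (trees family).
#' @param seed Integer seed (trees family bagging).
#' @return An object of class `habitat_model` with `print`, `summary`,
#'   `coef`, `predict`, `plot` and `residuals` methods.
#' @examples
#' \donttest{
#' spec <- env_spec(env_grid(-125, 45, 0.1, 60, 60),
#'                  list(layer_gradient("sst", 90, c(10, 25))), seed = 7)
#' study <- generate_study(spec, selection_params(c(sst = 2)),
#'                         n_animals = 3, n_steps = 60, seed = 7)
#' moves <- empirical_moves(study$tracks)
#' pa <- pa_generate("background", study, moves, seed = 7)
#' tab <- build_pa_table(study_presences(study), pa, study$env)
#' m <- habitat_model(tab, "linear")
#' summary(m)
#' }
#' @export
habitat_model <- function(table, family = c("linear", "smooth", "trees"),
                          covariates = NULL, k = 5,
                          learning_rate = 0.005, bag_fraction = 0.75,
                          interaction_depth = 5, n_trees = 2000,
                          seed = 1L) {
  family <- match.arg(family)
  if (is.null(covariates)) covariates <- pa_covariates(table)
  missing_cols <- setdiff(covariates, names(table))
  if (length(missing_cols))
    stop("habitat_model: missing covariate column(s): ",
         paste(missing_cols, collapse = ", "))
  if (length(unique(table$label)) < 2)
    stop("habitat_model: both labels (0 and 1) must be present")
  if (k < 3) stop("habitat_model: spline basis dimension 'k' must be >= 3")
  stopifnot(learning_rate > 0, bag_fraction > 0, bag_fraction <= 1,
            interaction_depth >= 1, n_trees >= 1)

  df <- as.data.frame(table)
  df$label <- as.integer(df$label)
  df$animal_id <- factor(df$animal_id)
  animals <- levels(df$animal_id)
  use_re <- length(animals) >= 2
  if (!use_re && family != "trees")
    warning("habitat_model: single animal; fitting without a random effect",
            call. = FALSE)

  if (family == "trees") {
    x <- as.matrix(df[, covariates, drop = FALSE])
    y <- df$label
    dm <- xgboost::xgb.DMatrix(x, label = y)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = learning_rate,
                    max_depth = interaction_depth, subsample = bag_fraction,
                    nthread = 1, seed = as.integer(seed)),
      data = dm, nrounds = n_trees, verbose = 0)
    p <- predict(fit, dm)
    null_dev <- binomial_deviance(y, mean(y))
    resid_dev <- binomial_deviance(y, p)
    fitted_vals <- p
  } else {
    terms <- if (family == "linear") covariates
             else sprintf("s(%s, k = %d, bs = \"tp\")", covariates, k)
    if (use_re) terms <- c(terms, "s(animal_id, bs = \"re\")")
    fml <- stats::as.formula(paste("label ~", paste(terms, collapse = " + ")))
    fit <- mgcv::gam(fml, family = stats::binomial(), data = df,
                     method = "REML")
    null_dev <- fit$null.deviance
    resid_dev <- stats::deviance(fit)
    fitted_vals <- as.numeric(fit$fitted.values)
  }

  ranges <- lapply(df[covariates], range)
  medians <- vapply(df[covariates], stats::median, 0)

  structure(list(
    family = family, fit = fit, covariates = covariates,
    animals = animals, use_re = use_re, k = k,
    trees_params = list(learning_rate = learning_rate,
                        bag_fraction = bag_fraction,
                        interaction_depth = interaction_depth,
                        n_trees = n_trees, seed = as.integer(seed)),
    null_deviance = null_dev, residual_deviance = resid_dev,
    fitted = fitted_vals, y = df$label,
    ranges = ranges, medians = medians, n = nrow(df),
    call = match.call()), class = "habitat_model")
}

# -2 log-likelihood of a Bernoulli fit, probabilities clamped away from 0/1
binomial_deviance <- function(y, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Predict suitability at points
#'
#' Population-level predictions on the response scale, always in `[0, 1]`:
#' the per-animal random intercept is excluded, so predictions do not depend
#' on which (or whether a known) animal is supplied.
#'
#' @param object A `habitat_model`.
#' @param newdata Data.frame carrying the model's covariate columns.
#' @param ... Unused.
#' @return Numeric vector of suitabilities in `[0, 1]`.
#' @export
predict.habitat_model <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$covariates, names(newdata))
  if (length(missing_cols))
    stop("predict.habitat_model: newdata is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (object$family == "trees") {
    x <- as.matrix(newdata[, object$covariates, drop = FALSE])
    p <- predict(object$fit, xgboost::xgb.DMatrix(x))
  } else {
    nd <- newdata[, object$covariates, drop = FALSE]
    nd$animal_id <- factor(object$animals[1], levels = object$animals)
    p <- as.numeric(predict(object$fit, nd, type = "response",
                            exclude = "s(animal_id)",
                            newdata.guaranteed = TRUE))
  }
  pmin(pmax(p, 0), 1)
}

#' Predict suitability over the environment grid
#'
#' One suitability value per grid cell with complete covariates; cells with
#' any missing predictor are emitted as `NA` (white pixels in a map).
#'
#' @param model A `habitat_model`.
#' @param env An `env_stack` sharing the model's covariates.
#' @param month Calendar month 1-12; required when any layer is monthly.
#' @return Matrix `n_rows x n_cols` of suitabilities (NA where missing).
#' @export
predict_grid <- function(model, env, month = NULL) {
  any_monthly <- any(vapply(env$layers, function(L) L$temporal == "monthly", TRUE))
  if (any_monthly) {
    if (is.null(month)) stop("predict_grid: 'month' is required for monthly layers")
    if (month < 1 || month > 12) stop("predict_grid: 'month' must be in 1-12")
  }
  g <- env$grid
  cc <- grid_cell_centers(g)
  pts <- data.frame(lon = rep(cc$lon, each = g$n_rows),
                    lat = rep(cc$lat, g$n_cols))
  covs <- lapply(env_layer_names(env), function(nm) {
    if (env$layers[[nm]]$temporal == "monthly")
      extract_layer(env, nm, pts$lon, pts$lat, month)
    else extract_layer(env, nm, pts$lon, pts$lat)
  })
  names(covs) <- env_layer_names(env)
  covs <- as.data.frame(covs, optional = TRUE)
  ok <- stats::complete.cases(covs[, model$covariates, drop = FALSE])
  out <- rep(NA_real_, nrow(pts))
  if (any(ok)) out[ok] <- predict(model, covs[ok, , drop = FALSE])
  matrix(out, g$n_rows, g$n_cols)
}

#' Marginal response curve of one covariate
#'
#' Varies one covariate over its training range with all others held at
#' their training medians — the standard partial-response diagnostic.
#'
#' @param model A `habitat_model`.
#' @param covariate Covariate name.
#' @param n Number of evaluation points.
#' @return Data.frame with columns `value` and `suitability`.
#' @export
response_curve <- function(model, covariate, n = 100) {
  if (!covariate %in% model$covariates)
    stop("response_curve: '", covariate, "' is not a model covariate")
  grid_x <- seq(model$ranges[[covariate]][1], model$ranges[[covariate]][2],
                length.out = n)
  nd <- as.data.frame(as.list(model$medians))[rep(1, n), , drop = FALSE]
  nd[[covariate]] <- grid_x
  data.frame(value = grid_x, suitability = predict(model, nd))
}

#' Relative influence of covariates (trees family)
#'
#' Gain-based relative influence of each covariate, normalized to sum to 1.
#' Only defined for the boosted-trees family; used to pick the "most
#' important" covariates for the separation-skill regression.
#'
#' @param model A `habitat_model` with `family = "trees"`.
#' @return Named numeric vector over all model covariates (zeros for
#'   covariates never used in a split), decreasing.
#' @export
relative_influence <- function(model) {
  if (model$family != "trees")
    stop("relative_influence: only defined for the trees family")
  imp <- xgboost::xgb.importance(model = model$fit)
  out <- stats::setNames(rep(0, length(model$covariates)), model$covariates)
  out[imp$Feature] <- imp$Gain
  sort(out / sum(out), decreasing = TRUE)
}

#' @export
print.habitat_model <- function(x, ...) {
  lab <- c(linear = "linear logistic (mixed)",
           smooth = "smooth logistic (mixed)",
           trees = "boosted regression trees")[x$family]
  cat(sprintf("<habitat_model: %s, %d rows, %d covariate(s)%s>\n",
              lab, x$n, length(x$covariates),
              if (x$use_re && x$family != "trees")
                sprintf(", %d-animal random intercept", length(x$animals))
              else ""))
  cat(sprintf("  explained deviance: %.3f\n", explained_deviance(x)))
  invisible(x)
}

#' @export
summary.habitat_model <- function(object, ...) {
  print(object)
  cat(sprintf("  null deviance: %.2f on %d rows\n",
              object$null_deviance, object$n))
  cat(sprintf("  residual deviance: %.2f\n", object$residual_deviance))
  if (object$family == "trees") {
    cat("  relative influence:\n")
    ri <- relative_influence(object)
    for (nm in names(ri)) cat(sprintf("    %-16s %.3f\n", nm, ri[[nm]]))
  } else if (object$family == "linear") {
    cat("  fixed-effect coefficients:\n")
    cf <- coef(object)
    for (nm in names(cf)) cat(sprintf("    %-16s % .4f\n", nm, cf[[nm]]))
  }
  invisible(object)
}

#' @export
coef.habitat_model <- function(object, ...) {
  if (object$family == "trees") return(NULL)
  cf <- stats::coef(object$fit)
  cf[!grepl("^s\\(", names(cf))]
}

#' @export
residuals.habitat_model <- function(object, type = "deviance", ...) {
  p <- pmin(pmax(object$fitted, 1e-12), 1 - 1e-12)
  y <- object$y
  d <- -2 * (y * log(p) + (1 - y) * log(1 - p))
  switch(type,
         deviance = sign(y - p) * sqrt(pmax(d, 0)),
         response = y - p,
         stop("residuals.habitat_model: unknown type '", type, "'"))
}

#' @export
plot.habitat_model <- function(x, covariates = NULL, ...) {
  covariates <- covariates %||% x$covariates
  old <- graphics::par(mfrow = c(1, length(covariates)))
  on.exit(graphics::par(old))
  for (nm in covariates) {
    rc <- response_curve(x, nm)
    graphics::plot(rc$value, rc$suitability, type = "l", xlab = nm,
                   ylab = "suitability", ylim = c(0, 1), ...)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
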