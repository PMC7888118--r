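#' Run the full pseudo-absence comparison experiment
#'
#' For every pseudo-absence method x model family x cross-validation scheme:
#' generate the pseudo-absences, build the model table, fit on the training
#' folds, score the test folds, and record explained deviance (training),
#' AUC, TSS, and the mean predicted suitability at presences and at
#' pseudo-absences (fold metrics averaged unweighted). Alongside the skill
#' table the report carries the per-covariate Bhattacharyya coefficients
#' between presence and pseudo-absence covariate samples for each method,
#' and, per model family, the OLS regression of AUC on the Bhattacharyya
#' coefficient pooled over methods and the top `n_top` covariates (ranked
#' by mean boosted-trees relative influence across methods).
#'
#' @param study A [generate_study()] study.
#' @param methods Pseudo-absence methods to compare (subset of
#'   [pa_methods()]).
#' @param families Model families (subset of linear / smooth / trees).
#' @param schemes CV schemes (subset of full / random75 / month).
#' @param seed Master seed; stage sub-seeds derive from it.
#' @param n_bins Shared histogram bins for the Bhattacharyya coefficient.
#' @param n_top Number of top covariates entering the regression.
#' @param moves_pooling Pooling for the empirical movement distribution.
#' @param radius_km Buffer radius override; default mode step length.
#' @param regression_scheme Which scheme's AUC feeds the regression
#'   (default the first of `schemes`).
#' @param quiet Suppress per-stage progress messages.
#' @return A `skill_report`: `metrics` (one row per method x family x
#'   scheme), `bc` (covariate x method), `regression` (per family),
#'   `top_covariates`, `influence`, and `provenance`.
#' @export
evaluate_experiment <- function(study,
                                methods = pa_methods(),
                                families = c("linear", "smooth", "trees"),
                                schemes = "full",
                                seed = 1L, n_bins = 50L, n_top = 3L,
                                moves_pooling = "pooled",
                                radius_km = NULL,
                                regression_scheme = schemes[1],
                                quiet = FALSE) {
  stopifnot(inherits(study, "pa_study"))
  methods <- match.arg(methods, pa_methods(), several.ok = TRUE)
  families <- match.arg(families, c("linear", "smooth", "trees"),
                        several.ok = TRUE)
  schemes <- match.arg(schemes, c("full", "random75", "month"),
                       several.ok = TRUE)
  say <- function(...) if (!quiet) message(...)

  presences <- study_presences(study)
  moves <- empirical_moves(study$tracks, pooling = moves_pooling)
  if (is.null(radius_km)) radius_km <- mode_step_length(moves)
  covs <- env_layer_names(study$env)

  set.seed(seed)
  method_seeds <- stats::setNames(
    sample.int(.Machine$integer.max - 1L, length(methods)), methods)
  cv_seed <- sample.int(.Machine$integer.max - 1L, 1L)

  # --- generation + tables + environmental separation -----------------
  tables <- list()
  bc_rows <- list()
  for (m in methods) {
    pa <- pa_generate(m, study, moves = moves, radius_km = radius_km,
                      seed = method_seeds[[m]])
    tab <- build_pa_table(presences, pa, study$env, quiet = quiet)
    tables[[m]] <- tab
    say(sprintf("evaluate_experiment: %-12s %d rows (%d presences, %d absences)",
                m, nrow(tab), sum(tab$label == 1), sum(tab$label == 0)))
    for (cv in covs) {
      bc_rows[[length(bc_rows) + 1]] <- data.frame(
        covariate = cv, method = m,
        bc = bhattacharyya(tab[[cv]][tab$label == 1],
                           tab[[cv]][tab$label == 0], n_bins))
    }
  }
  bc <- do.call(rbind, bc_rows)

  # --- fits + skill ----------------------------------------------------
  metric_rows <- list()
  influence <- stats::setNames(rep(0, length(covs)), covs)
  n_trees_fits <- 0L
  for (m in methods) {
    tab <- tables[[m]]
    for (fam in families) {
      for (sch in schemes) {
        folds <- cv_split(tab, sch, seed = cv_seed)
        fm <- matrix(NA_real_, length(folds), 5)
        for (fi in seq_along(folds)) {
          fold <- folds[[fi]]
          fit <- habitat_model(tab[fold$train, , drop = FALSE], fam,
                               covariates = covs,
                               seed = method_seeds[[m]])
          test <- tab[fold$test, , drop = FALSE]
          p <- predict(fit, test)
          fm[fi, ] <- c(explained_deviance(fit),
                        auc(test$label, p),
                        tss(test$label, p),
                        mean(p[test$label == 1]),
                        mean(p[test$label == 0]))
          if (fam == "trees" && sch == schemes[1] && fi == 1L) {
            ri <- relative_influence(fit)
            influence[names(ri)] <- influence[names(ri)] + ri
            n_trees_fits <- n_trees_fits + 1L
          }
        }
        metric_rows[[length(metric_rows) + 1]] <- data.frame(
          method = m, family = fam, scheme = sch,
          r2 = mean(fm[, 1]), auc = mean(fm[, 2]), tss = mean(fm[, 3]),
          mean_pred_presence = mean(fm[, 4]),
          mean_pred_absence = mean(fm[, 5]),
          n_folds = length(folds))
        say(sprintf("evaluate_experiment: %-12s %-7s %-9s AUC %.3f",
                    m, fam, sch, mean(fm[, 2])))
      }
    }
  }
  metrics <- do.call(rbind, metric_rows)

  # --- covariate importance ranking -----------------------------------
  if (n_trees_fits > 0L) {
    influence <- influence / n_trees_fits
  } else {
    # no trees family requested: fit one ranking model on the first table
    rank_fit <- habitat_model(tables[[methods[1]]], "trees",
                              covariates = covs, seed = seed)
    influence <- relative_influence(rank_fit)
  }
  influence <- sort(influence, decreasing = TRUE)
  top_covariates <- names(influence)[seq_len(min(n_top, length(influence)))]

  # --- separation vs skill regression, per family ---------------------
  reg_rows <- list()
  for (fam in families) {
    pts_bc <- numeric(0); pts_auc <- numeric(0)
    for (m in methods) {
      a <- metrics$auc[metrics$method == m & metrics$family == fam &
                         metrics$scheme == regression_scheme]
      for (cv in top_covariates) {
        pts_bc <- c(pts_bc, bc$bc[bc$method == m & bc$covariate == cv])
        pts_auc <- c(pts_auc, a)
      }
    }
    reg <- tryCatch(separation_skill_regression(pts_bc, pts_auc),
                    error = function(e) NULL)
    reg_rows[[fam]] <- data.frame(
      family = fam,
      slope = if (is.null(reg)) NA_real_ else reg$slope,
      intercept = if (is.null(reg)) NA_real_ else reg$intercept,
      p_value = if (is.null(reg)) NA_real_ else reg$p_value,
      r_squared = if (is.null(reg)) NA_real_ else reg$r_squared,
      n_points = length(pts_bc))
  }
  regression <- do.call(rbind, reg_rows)
  rownames(regression) <- NULL

  structure(list(
    metrics = metrics, bc = bc, regression = regression,
    top_covariates = top_covariates, influence = influence,
    provenance = list(seed = seed, method_seeds = as.list(method_seeds),
                      cv_seed = cv_seed, methods = methods,
                      families = families, schemes = schemes,
                      regression_scheme = regression_scheme,
                      n_bins = n_bins, n_top = n_top,
                      radius_km = radius_km,
                      moves_pooling = moves_pooling,
                      n_presences = nrow(presences),
                      study_seed = study$seed)),
    class = "skill_report")
}

#' @export
print.skill_report <- function(x, ...) {
  cat(sprintf("<skill_report: %d method(s) x %d family(ies) x %d scheme(s)>\n",
              length(x$provenance$methods), length(x$provenance$families),
              length(x$provenance$schemes)))
  print(x$metrics, row.names = FALSE, digits = 3)
  cat("\nSeparation (BC) vs skill (AUC) regression per family:\n")
  print(x$regression, row.names = FALSE, digits = 3)
  cat("\nTop covariates:", paste(x$top_covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / read a skill report
#'
#' Writes `metrics.csv`, `bc.csv`, `regression.csv` and a JSON manifest of
#' seeds and configuration; `read_skill_report` reconstructs the report
#' (minus transient fit objects) losslessly from those files.
#'
#' @param report A `skill_report`.
#' @param dir Output directory.
#' @export
write_skill_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$bc, file.path(dir, "bc.csv"), row.names = FALSE)
  utils::write.csv(report$regression, file.path(dir, "regression.csv"),
                   row.names = FALSE)
  manifest <- report$provenance
  manifest$top_covariates <- report$top_covariates
  manifest$influence <- as.list(report$influence)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_skill_report
#' @export
read_skill_report <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(list(
    metrics = utils::read.csv(file.path(dir, "metrics.csv")),
    bc = utils::read.csv(file.path(dir, "bc.csv")),
    regression = utils::read.csv(file.path(dir, "regression.csv")),
    top_covariates = manifest$top_covariates,
    influence = unlist(manifest$influence),
    provenance = manifest[setdiff(names(manifest),
                                  c("top_covariates", "influence"))]),
    class = "skill_report")
}
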