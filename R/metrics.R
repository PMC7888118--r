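#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' presence receives a higher score than a randomly chosen absence, ties
#' counted one half.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores Numeric scores, higher = more presence-like.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2))  # 0.75
#' @export
auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("auc: both labels must be present")
  if (length(labels) != length(scores))
    stop("auc: 'labels' and 'scores' differ in length")
  r <- rank(scores)                     # midranks give the ties-1/2 convention
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True Skill Statistic
#'
#' Maximum over candidate thresholds (all midpoints between consecutive
#' sorted unique scores) of sensitivity + specificity - 1, predicting
#' presence when `score >= threshold`. With a single unique score the one
#' usable threshold predicts everything presence, giving 0.
#'
#' @inheritParams auc
#' @param details If `TRUE`, also return the maximizing threshold.
#' @return TSS in `[-1, 1]`, or a list with `tss` and `threshold`.
#' @examples
#' tss(c(1, 1, 0, 0), c(0.9, 0.6, 0.7, 0.1))  # 0.5
#' @export
tss <- function(labels, scores, details = FALSE) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("tss: both labels must be present")
  u <- sort(unique(scores))
  thr <- if (length(u) == 1L) u else (u[-length(u)] + u[-1]) / 2
  best <- -Inf; best_thr <- thr[1]
  for (t in thr) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1L) / n1
    spec <- sum(!pred & labels == 0L) / n0
    v <- sens + spec - 1
    if (v > best) { best <- v; best_thr <- t }
  }
  if (details) list(tss = best, threshold = best_thr) else best
}

#' Explained deviance of a fitted habitat model
#'
#' `(null deviance - residual deviance) / null deviance` on the training
#' data (binomial deviances; for the trees family these are computed from
#' training predictions against the intercept-only fit). Negative values
#' are clipped to 0 with a warning.
#'
#' @param model A [habitat_model()] fit.
#' @return Fraction in `[0, 1]`.
#' @export
explained_deviance <- function(model) {
  nd <- model$null_deviance; rd <- model$residual_deviance
  if (!is.finite(nd) || nd <= 0)
    stop("explained_deviance: null deviance is zero (degenerate labels)")
  v <- (nd - rd) / nd
  if (v < 0) {
    warning("explained_deviance: negative value clipped to 0", call. = FALSE)
    v <- 0
  }
  min(v, 1)
}

#' Bhattacharyya coefficient of two samples
#'
#' Overlap of the two samples' distributions over shared equal-width bins
#' spanning the pooled range: `sum(sqrt(p_i * q_i))` with `p`, `q` the bin
#' proportions. 1 means identical binned distributions, 0 disjoint support.
#' Used to quantify the environmental separation between presences and
#' pseudo-absences, covariate by covariate.
#'
#' @param sample_p,sample_q Non-empty numeric samples.
#' @param n_bins Number of shared bins (>= 2; default 50).
#' @return Coefficient in `[0, 1]`.
#' @examples
#' bhattacharyya(c(1, 1, 2, 2), c(1, 1, 1, 1), n_bins = 2)  # sqrt(0.5)
#' @export
bhattacharyya <- function(sample_p, sample_q, n_bins = 50L) {
  sample_p <- sample_p[is.finite(sample_p)]
  sample_q <- sample_q[is.finite(sample_q)]
  if (!length(sample_p) || !length(sample_q))
    stop("bhattacharyya: both samples must be non-empty")
  if (n_bins < 2) stop("bhattacharyya: 'n_bins' must be >= 2")
  rng <- range(c(sample_p, sample_q))
  if (rng[1] == rng[2]) return(1)       # all mass in one degenerate bin
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- function(x) {
    i <- findInterval(x, breaks, rightmost.closed = TRUE)
    tabulate(i, nbins = n_bins) / length(x)
  }
  sum(sqrt(bin(sample_p) * bin(sample_q)))
}

#' Cross-validation folds
#'
#' Three schemes: `full` (train = test = all rows), `random75` (one seeded
#' 75/25 row split) and `month` (leave-one-month-out: one fold per calendar
#' month present, testing on that month and training on the rest; requires
#' timestamps spanning at least two months).
#'
#' @param table A `pa_table` (or any data.frame; `month` needs `timestamp`).
#' @param scheme `"full"`, `"random75"` or `"month"`.
#' @param seed Integer seed (random75).
#' @return List of folds, each `list(train, test, tag)` of row indices.
#' @export
cv_split <- function(table, scheme = c("full", "random75", "month"),
                     seed = 1L) {
  scheme <- match.arg(scheme)
  n <- nrow(table)
  if (scheme == "full")
    return(list(list(train = seq_len(n), test = seq_len(n), tag = "full")))
  if (scheme == "random75") {
    set.seed(seed)
    train <- sort(sample.int(n, size = floor(0.75 * n)))
    return(list(list(train = train, test = setdiff(seq_len(n), train),
                     tag = "random75")))
  }
  if (is.null(table$timestamp))
    stop("cv_split: 'month' scheme needs a timestamp column")
  months <- as.integer(format(table$timestamp, "%m"))
  um <- sort(unique(months))
  if (length(um) < 2)
    stop("cv_split: 'month' scheme needs data spanning >= 2 calendar months",
         " (static single-month data cannot be held out temporally)")
  lapply(um, function(mo) {
    test <- which(months == mo)
    list(train = which(months != mo), test = test,
         tag = sprintf("month_%02d", mo))
  })
}

#' Regression of predictive skill on environmental separation
#'
#' Ordinary least squares of AUC on the Bhattacharyya coefficient, with the
#' two-sided p-value for the slope. A significantly negative slope is the
#' signature that skill is driven by environmental separation between
#' presences and pseudo-absences rather than by the model itself.
#'
#' @param bc Bhattacharyya coefficients (>= 3 points, non-constant).
#' @param auc_values Matching AUC values.
#' @return List with `slope`, `intercept`, `p_value`, `r_squared`, `n` and
#'   the underlying `lm` fit.
#' @export
separation_skill_regression <- function(bc, auc_values) {
  if (length(bc) != length(auc_values))
    stop("separation_skill_regression: input lengths differ")
  ok <- is.finite(bc) & is.finite(auc_values)
  bc <- bc[ok]; auc_values <- auc_values[ok]
  if (length(bc) < 3)
    stop("separation_skill_regression: need >= 3 points")
  if (stats::var(bc) == 0)
    stop("separation_skill_regression: all Bhattacharyya values identical")
  fit <- stats::lm(auc_values ~ bc)
  sm <- summary(fit)
  co <- sm$coefficients
  p <- if (nrow(co) >= 2 && !is.nan(co[2, 4])) co[2, 4] else 0
  list(slope = unname(co[2, 1]), intercept = unname(co[1, 1]),
       p_value = unname(p), r_squared = sm$r.squared,
       n = length(bc), fit = fit)
}
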