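#' Exact one-tailed binomial test of turning direction
#'
#' Tests whether wall-contact turns are pro-wall-hook more often than
#' chance (null proportion 0.5, alternative greater). The p-value is the
#' exact upper binomial tail and the confidence bound is the one-sided
#' Clopper-Pearson lower limit, i.e. the `p` solving
#' `P(X >= n_pro | p) = 1 - conf` (0 when `n_pro = 0`); the upper limit
#' is fixed at 1.
#'
#' @param n_pro Number of pro-wall-hook turns.
#' @param n_total Total number of classified turns (>= 1).
#' @param conf One-sided confidence level (default 0.95).
#' @return An object of class `direction_test`: a list with `n_pro`,
#'   `n_total`, `proportion`, `p_value`, `ci_low`, `ci_high`, `conf`.
#' @export
#' @examples
#' binomial_direction_test(52, 63)
binomial_direction_test <- function(n_pro, n_total, conf = 0.95) {
  stopifnot(n_total >= 1, n_pro >= 0, n_pro <= n_total,
            conf > 0, conf < 1)
  p_value <- stats::pbinom(n_pro - 1, n_total, 0.5, lower.tail = FALSE)
  # Clopper-Pearson one-sided lower bound via the beta quantile identity
  ci_low <- if (n_pro == 0) 0 else
    stats::qbeta(1 - conf, n_pro, n_total - n_pro + 1)
  structure(list(
    n_pro = as.integer(n_pro), n_total = as.integer(n_total),
    proportion = n_pro / n_total,
    p_value = p_value, ci_low = ci_low, ci_high = 1, conf = conf
  ), class = "direction_test")
}

#' @export
print.direction_test <- function(x, digits = 4, ...) {
  cat("Exact binomial test of turning direction (one-tailed, null 0.5)\n")
  cat(sprintf("  pro-wall-hook: %d of %d (%.2f%%)\n",
              x$n_pro, x$n_total, 100 * x$proportion))
  cat(sprintf("  p-value: %s\n", format(x$p_value, digits = digits)))
  cat(sprintf("  one-sided %d%% CI: (%.*f, %.2f)\n",
              round(100 * x$conf), digits, x$ci_low, x$ci_high))
  invisible(x)
}

#' Fit a kinetics regression model
#'
#' Least-squares fit of a (by default log-transformed) kinetic parameter
#' on wall covariates, the fixed-effects counterpart of mixed models with
#' per-animal random intercepts: at simulation scale there is no grouping
#' structure to pool over, and group identifiers can enter as indicator
#' covariates. Rows with missing (undefined-marker) responses or
#' covariates are dropped with a logged count; zero or negative responses
#' become missing before a log transform.
#'
#' @param data Data frame holding the response and covariate columns.
#' @param response Name of the response column (e.g. `"vcl"`).
#' @param covariates Character vector of covariate column names (e.g.
#'   `c("distance_um", "angle_rad")`). Factor/character columns enter as
#'   indicators.
#' @param transform `"log"` (natural log, default) or `"identity"`.
#' @return An object of class `kinetics_fit` wrapping the underlying
#'   [stats::lm()] fit, with `coefficients` (matrix of estimate, SE,
#'   t, p), `n_obs`, `n_dropped`, `response`, `transform` and
#'   `degenerate` (TRUE when the response is constant).
#' @export
#' @examples
#' d <- data.frame(vcl = exp(4 - 0.02 * (1:50) + rnorm(50, 0, 0.1)),
#'                 distance_um = 1:50)
#' fit <- fit_kinetics_model(d, "vcl", "distance_um")
#' coef(fit)
fit_kinetics_model <- function(data, response, covariates,
                               transform = c("log", "identity")) {
  transform <- match.arg(transform)
  stopifnot(response %in% names(data), all(covariates %in% names(data)))
  y <- data[[response]]
  if (transform == "log") {
    y[!is.na(y) & y <= 0] <- NA_real_
    y <- log(y)
  }
  d <- data[, covariates, drop = FALSE]
  d$.y <- y
  ok <- stats::complete.cases(d)
  d <- d[ok, , drop = FALSE]
  n_dropped <- sum(!ok)
  if (nrow(d) < 10) {
    stop("fewer than 10 usable rows after dropping undefined values",
         call. = FALSE)
  }
  fm <- stats::as.formula(paste(
    ".y ~", paste(sprintf("`%s`", covariates), collapse = " + ")))
  mm <- stats::model.matrix(fm, d)
  if (qr(mm)$rank < ncol(mm)) {
    stop("design matrix is rank-deficient; drop collinear covariates",
         call. = FALSE)
  }
  degenerate <- stats::sd(d$.y) == 0
  fit <- stats::lm(fm, data = d)
  cf <- if (degenerate) {
    suppressWarnings(summary(fit)$coefficients)  # zero-residual fit
  } else {
    summary(fit)$coefficients
  }
  if (degenerate) {
    cf[-1, "Estimate"] <- 0
  }
  structure(list(
    lm = fit,
    coefficients = cf,
    response = response, transform = transform,
    covariates = covariates,
    n_obs = nrow(d), n_dropped = n_dropped,
    degenerate = degenerate
  ), class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("kinetics_fit: %s(%s) ~ %s  [n = %d, dropped %d%s]\n",
              if (x$transform == "log") "log" else "",
              x$response, paste(x$covariates, collapse = " + "),
              x$n_obs, x$n_dropped,
              if (x$degenerate) ", DEGENERATE response" else ""))
  stats::printCoefmat(x$coefficients, ...)
  invisible(x)
}

#' @export
summary.kinetics_fit <- function(object, ...) summary(object$lm, ...)

#' @export
coef.kinetics_fit <- function(object, ...) {
  cf <- object$coefficients[, "Estimate"]
  names(cf) <- rownames(object$coefficients)
  cf
}

#' @export
predict.kinetics_fit <- function(object, newdata = NULL, ...) {
  stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
residuals.kinetics_fit <- function(object, ...) stats::residuals(object$lm)

#' Group-wise summaries of kinetic parameters
#'
#' Per-group median, interquartile range and n for each kinetic parameter
#' — the numbers a grouped boxplot displays. Descriptive only; no test is
#' attached.
#'
#' @param params Kinematics table (see [compute_kinematics()]) plus a
#'   grouping column.
#' @param group_label Name of the grouping column.
#' @param parameters Parameter columns to summarise.
#' @return Data frame with `group`, `parameter`, `n`, `median`, `q1`,
#'   `q3`, `iqr` (missing values excluded per parameter).
#' @export
compare_groups <- function(params, group_label,
                           parameters = c("vcl", "vsl", "lin", "swr")) {
  if (!group_label %in% names(params)) {
    stop("unknown group label: ", group_label, call. = FALSE)
  }
  stopifnot(all(parameters %in% names(params)))
  g <- params[[group_label]]
  out <- list()
  for (lev in unique(g)) {
    for (p in parameters) {
      v <- params[[p]][g == lev]
      v <- v[!is.na(v)]
      qs <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75),
                                           names = FALSE)
            else rep(NA_real_, 3)
      out[[length(out) + 1]] <- data.frame(
        group = lev, parameter = p, n = length(v),
        median = qs[2], q1 = qs[1], q3 = qs[3], iqr = qs[3] - qs[1]
      )
    }
  }
  do.call(rbind, out)
}
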