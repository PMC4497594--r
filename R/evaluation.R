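# Error, goodness-of-fit, exclusion and model-choice diagnostics.

#' Per-route log errors of a prediction
#'
#' `error = log(observed) - log(predicted)`, defined only on routes where
#' both are positive. Zero-flow routes (observed or predicted) are counted
#' and reported, not silently dropped.
#'
#' @param od OD table with `trips`.
#' @param predictions numeric vector of predicted means aligned to `od`.
#' @param model label attached to the output.
#' @return data.frame `origin_id`, `dest_id`, `observed`, `predicted`,
#'   `error`, `model`; attribute `zero_counts` holds the counts of routes
#'   with zero observed / zero predicted flow.
#' @export
route_errors <- function(od, predictions, model = "model") {
  assert_cols(od, c("origin_id", "dest_id", "trips"), "od")
  stopifnot(length(predictions) == nrow(od))
  ok <- od$trips > 0 & predictions > 0
  out <- data.frame(origin_id = od$origin_id[ok], dest_id = od$dest_id[ok],
                    observed = od$trips[ok], predicted = predictions[ok],
                    error = log(od$trips[ok]) - log(predictions[ok]),
                    model = model, stringsAsFactors = FALSE)
  attr(out, "zero_counts") <- c(zero_observed = sum(od$trips == 0),
                                zero_predicted = sum(predictions == 0))
  out
}

#' Flag routes poorly described by the models
#'
#' Under the working assumption that log errors are N(0, 1), a route is
#' flagged for a model when its |error| exceeds 2 (`rule = "fixed"`). The
#' `"empirical"` variant flags errors outside mean +- 2 SD of that model's
#' own error distribution. A route is *unmodelable* when it is flagged for
#' every model supplied; the rule is applied identically to all models.
#'
#' @param errors named list of [route_errors()] outputs (one per model),
#'   all over the same route set.
#' @param rule `"fixed"` (N(0,1) band \[-2, 2\]) or `"empirical"`
#'   (mean +- 2 SD per model).
#' @return data.frame with the route, per-model `flag_<model>` columns and
#'   `unmodelable`.
#' @export
flag_unmodelable <- function(errors, rule = c("fixed", "empirical")) {
  rule <- match.arg(rule)
  stopifnot(is.list(errors), length(errors) >= 1L)
  base <- errors[[1]][, c("origin_id", "dest_id")]
  key <- paste(base$origin_id, base$dest_id)
  out <- base
  flags <- matrix(FALSE, nrow(base), length(errors))
  for (m in seq_along(errors)) {
    e <- errors[[m]]
    stopifnot(identical(paste(e$origin_id, e$dest_id), key))
    if (rule == "fixed") {
      flags[, m] <- abs(e$error) > 2
    } else {
      flags[, m] <- abs(e$error - mean(e$error)) > 2 * sd(e$error)
    }
    out[[paste0("flag_", names(errors)[m] %||% paste0("model", m))]] <- flags[, m]
  }
  out$unmodelable <- apply(flags, 1L, all)
  out
}

#' Kolmogorov-Smirnov test of errors against the standard normal
#'
#' One-sample KS statistic of the error sample versus N(0, 1) (fixed
#' moments, matching the working assumption, not estimated ones).
#'
#' @param errors numeric vector of log errors.
#' @return list with `statistic` and `p_value`.
#' @export
ks_normality <- function(errors) {
  errors <- errors[is.finite(errors)]
  if (length(errors) < 3L) stopf("need at least 3 errors for the KS test")
  kt <- suppressWarnings(ks.test(errors, "pnorm", 0, 1))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

# Poisson deviance of observations around arbitrary positive means.
poisson_deviance <- function(y, mu) {
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}

#' Goodness-of-fit report for a prediction
#'
#' Computes, over the routes of an OD table:
#' * reduction in deviance, `100 * (null - residual) / null`, where the
#'   null model is the intercept-only Poisson model (mean = grand mean) —
#'   defined for fitted and parameter-free models alike;
#' * adjusted R-squared of the OLS regression of log observed on log
#'   predicted over positive-positive routes, adjusted for the interaction
#'   model's parameter count `n_params`;
#' * sum of squared errors (linear scale);
#' * mean and 2.5/97.5% quantiles of predicted/observed and
#'   observed/predicted ratios over positive-positive routes;
#' * Sorensen-Dice agreement `2 * min(obs, pred) / (obs + pred)` per route
#'   and its mean.
#'
#' @param od OD table with `trips`.
#' @param predictions predicted means aligned to `od`.
#' @param model label.
#' @param n_params parameter count used in the R-squared adjustment
#'   (gravity 4; radiation 1 for the fitted traveler fraction).
#' @return object of class `fit_report`.
#' @export
fit_statistics <- function(od, predictions, model = "model", n_params = 0) {
  assert_cols(od, c("trips"), "od")
  stopifnot(length(predictions) == nrow(od))
  y <- od$trips
  mu <- predictions
  null_dev <- poisson_deviance(y, mean(y))
  red_dev <- if (null_dev == 0) NA_real_ else {
    100 * (null_dev - poisson_deviance(y, pmax(mu, 1e-12))) / null_dev
  }
  ok <- y > 0 & mu > 0
  n_ok <- sum(ok)
  adj_r2 <- NA_real_
  if (n_ok >= 3L) {
    fit <- lm(log(y[ok]) ~ log(mu[ok]))
    r2 <- suppressWarnings(summary(fit)$r.squared)
    adj_r2 <- 1 - (1 - r2) * (n_ok - 1) / (n_ok - n_params - 1)
  }
  ratio_po <- mu[ok] / y[ok]
  ratio_op <- y[ok] / mu[ok]
  qs <- function(v) quantile(v, c(0.025, 0.975), names = FALSE)
  dice <- 2 * pmin(y, mu) / (y + mu)
  dice[y + mu == 0] <- 1  # both zero: perfect agreement
  structure(list(
    model = model,
    n_routes = nrow(od), n_positive = n_ok,
    reduction_deviance = red_dev,
    adjusted_r2 = adj_r2,
    sse = sum((y - mu)^2),
    ratio_pred_obs = list(mean = mean(ratio_po), q = qs(ratio_po)),
    ratio_obs_pred = list(mean = mean(ratio_op), q = qs(ratio_op)),
    dice = dice, dice_mean = mean(dice),
    zero_observed = sum(y == 0), zero_predicted = sum(mu == 0)
  ), class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("Fit report: %s (%d routes, %d with positive obs & pred)\n",
              x$model, x$n_routes, x$n_positive))
  cat(sprintf("  reduction in deviance: %s\n",
              if (is.na(x$reduction_deviance)) "undefined (constant observations)"
              else sprintf("%.1f%%", x$reduction_deviance)))
  cat(sprintf("  adjusted R2 (log-log): %.3f\n", x$adjusted_r2))
  cat(sprintf("  mean pred/obs: %.3g  [%.3g, %.3g]\n", x$ratio_pred_obs$mean,
              x$ratio_pred_obs$q[1], x$ratio_pred_obs$q[2]))
  cat(sprintf("  mean obs/pred: %.3g  [%.3g, %.3g]\n", x$ratio_obs_pred$mean,
              x$ratio_obs_pred$q[1], x$ratio_obs_pred$q[2]))
  cat(sprintf("  mean Sorensen-Dice: %.3f\n", x$dice_mean))
  invisible(x)
}

#' Label the better model per route
#'
#' The winner on a route is the model with the smaller |log error|; exact
#' ties go to `"gravity"` (deterministic, documented). Unmodelable routes
#' are excluded.
#'
#' @param err_gravity,err_radiation [route_errors()] outputs over the same
#'   routes.
#' @param exclude logical vector (e.g. `flags$unmodelable`) marking routes
#'   to drop; NULL keeps all.
#' @return data.frame with the route, both absolute errors and `winner`.
#' @export
label_better_model <- function(err_gravity, err_radiation, exclude = NULL) {
  key_g <- paste(err_gravity$origin_id, err_gravity$dest_id)
  key_r <- paste(err_radiation$origin_id, err_radiation$dest_id)
  stopifnot(identical(key_g, key_r))
  keep <- if (is.null(exclude)) rep(TRUE, nrow(err_gravity)) else !exclude
  out <- data.frame(
    origin_id = err_gravity$origin_id[keep],
    dest_id = err_gravity$dest_id[keep],
    abs_err_gravity = abs(err_gravity$error[keep]),
    abs_err_radiation = abs(err_radiation$error[keep]),
    stringsAsFactors = FALSE
  )
  out$winner <- ifelse(out$abs_err_gravity <= out$abs_err_radiation,
                       "gravity", "radiation")
  out
}

#' Logistic regression for choosing between models
#'
#' Fits `logit(p) = b0 + b1 * X` by maximum likelihood, where `p` is the
#' probability that the gravity model beats the radiation model on a route
#' and `X` is the gravity factor, log10-transformed by default (it spans
#' many orders of magnitude; the raw scale is switchable). Complete
#' separation raises an error.
#'
#' @param winners `"gravity"`/`"radiation"` labels per route (or the
#'   [label_better_model()] output).
#' @param gm gravity factors aligned to the routes.
#' @param transform `"log10"` or `"identity"`.
#' @param n_bins number of equal-count bins for the empirical win-rate
#'   curve.
#' @return object of class `choice_model` with `b0`, `b1`, Wald CIs,
#'   deviance pseudo-R2 and binned win rates.
#' @export
fit_choice_logistic <- function(winners, gm, transform = c("log10", "identity"),
                                n_bins = 10L) {
  transform <- match.arg(transform)
  if (is.data.frame(winners)) winners <- winners$winner
  stopifnot(length(winners) == length(gm))
  y <- as.integer(winners == "gravity")
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stopf("complete separation: need at least 2 routes won by each model")
  }
  x <- if (transform == "log10") log10(gm) else gm
  g <- suppressWarnings(glm(y ~ x, family = binomial()))
  sep <- any(abs(coef(g)) > 50) ||
    all(fitted(g) > 1 - 1e-8 | fitted(g) < 1e-8)
  if (sep) stopf("logistic fit shows complete separation in the covariate")
  ci <- confint.default(g)
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- cut(x, breaks = br, include.lowest = TRUE)
  rates <- tapply(y, bin, mean)
  mids <- tapply(x, bin, mean)
  structure(list(
    b0 = unname(coef(g)[1]), b1 = unname(coef(g)[2]),
    ci = matrix(ci, ncol = 2, dimnames = list(c("b0", "b1"),
                                              c("lower", "upper"))),
    transform = transform,
    pseudo_r2 = 1 - g$deviance / g$null.deviance,
    glm = g,
    win_rates = data.frame(x = as.vector(mids), rate = as.vector(rates))
  ), class = "choice_model")
}

#' @export
coef.choice_model <- function(object, ...) c(b0 = object$b0, b1 = object$b1)

#' @param newdata gravity factors to predict choice probabilities for.
#' @rdname fit_choice_logistic
#' @export
predict.choice_model <- function(object, newdata, ...) {
  x <- if (object$transform == "log10") log10(newdata) else newdata
  plogis(object$b0 + object$b1 * x)
}

#' @export
print.choice_model <- function(x, ...) {
  cat("Model-choice logistic regression (gravity vs radiation)\n")
  cat(sprintf("  covariate: %s(gravity factor)\n",
              if (x$transform == "log10") "log10" else "identity"))
  cat(sprintf("  b0 = %.3f (%.3f, %.3f)\n", x$b0, x$ci[1, 1], x$ci[1, 2]))
  cat(sprintf("  b1 = %.3f (%.3f, %.3f)\n", x$b1, x$ci[2, 1], x$ci[2, 2]))
  cat(sprintf("  deviance pseudo-R2: %.3f\n", x$pseudo_r2))
  invisible(x)
}

#' Classify districts as urban / intermediate / rural
#'
#' Population-density terciles (population over district area when areas
#' are supplied, raw population otherwise).
#'
#' @param districts district set.
#' @param areas optional district areas (km^2) in district order.
#' @return factor with levels `rural`, `intermediate`, `urban`.
#' @export
district_classes <- function(districts, areas = NULL) {
  dens <- if (is.null(areas)) districts$population else districts$population / areas
  qs <- quantile(dens, c(1, 2) / 3)
  cut(dens, breaks = c(-Inf, qs, Inf),
      labels = c("rural", "intermediate", "urban"))
}

#' Refit the gravity model on route subsets and distance measures
#'
#' For each route subset and each distance column, refits the gravity model
#' and tabulates the reduction in deviance, so distance measures can be
#' compared across kinds of travel (e.g. urban vs rural routes).
#' Subsets with fewer than `min_routes` routes are skipped with a warning.
#'
#' @param od OD table carrying one column per distance measure.
#' @param subsets named list of logical vectors over the rows of `od` (or
#'   predicate functions of `od`).
#' @param distance_cols distance columns to compare.
#' @param min_routes minimum subset size.
#' @return data.frame `subset`, `distance`, `n_routes`,
#'   `reduction_deviance`, `adjusted_r2`.
#' @export
subset_analysis <- function(od, subsets, distance_cols = "dist_euclid_km",
                            min_routes = 5L) {
  rows <- list()
  for (sn in names(subsets)) {
    sel <- subsets[[sn]]
    if (is.function(sel)) sel <- sel(od)
    stopifnot(is.logical(sel), length(sel) == nrow(od))
    sub <- od[sel, , drop = FALSE]
    if (nrow(sub) < min_routes) {
      warning(sprintf("subset '%s' has %d route(s) (< %d); skipped", sn,
                      nrow(sub), min_routes), call. = FALSE)
      next
    }
    for (dc in distance_cols) {
      f <- fit_gravity(sub, distance_col = dc)
      rep_ <- fit_statistics(sub, predict(f), model = dc, n_params = 4)
      rows[[length(rows) + 1L]] <- data.frame(
        subset = sn, distance = dc, n_routes = nrow(sub),
        reduction_deviance = f$reduction_deviance,
        adjusted_r2 = rep_$adjusted_r2,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
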