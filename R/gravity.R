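# The gravity model: N_ij = k * pop_i^alpha * pop_j^beta / d(i,j)^gamma,
# fitted by Poisson regression with a log link (log pop_i, log pop_j and
# log d as covariates; log k is the intercept).

#' Predicted gravity-model flows
#'
#' Mean flow per route: `exp(log_k) * pop_i^alpha * pop_j^beta / d^gamma`.
#'
#' @param params list or named vector with `alpha`, `beta`, `gamma`, `log_k`.
#' @param od OD table with `pop_orig`, `pop_dest` and the distance column.
#' @param distance_col name of the distance column (default
#'   `"dist_euclid_km"`).
#' @return numeric vector of predicted means, one per OD row.
#' @export
gravity_predict <- function(params, od, distance_col = "dist_euclid_km") {
  params <- as.list(params)
  assert_cols(od, c("pop_orig", "pop_dest", distance_col), "od")
  d <- od[[distance_col]]
  if (any(d <= 0)) stopf("distances must be strictly positive")
  exp(params$log_k + params$alpha * log(od$pop_orig) +
        params$beta * log(od$pop_dest) - params$gamma * log(d))
}

#' Fit the gravity model by Poisson regression
#'
#' Maximum-likelihood Poisson fit with log link on `log(pop_orig)`,
#' `log(pop_dest)` and `log(distance)`; the intercept is `log_k`. Routes
#' with zero observed flow are retained (they carry likelihood
#' information). Wald 95% confidence intervals are reported per parameter,
#' along with the percentage reduction in deviance relative to the
#' intercept-only model.
#'
#' @param od OD table with `trips`, `pop_orig`, `pop_dest` and a distance
#'   column.
#' @param distance_col distance column to use.
#' @return an object of class `gravity_fit`.
#' @export
fit_gravity <- function(od, distance_col = "dist_euclid_km") {
  assert_cols(od, c("trips", "pop_orig", "pop_dest", distance_col), "od")
  if (nrow(od) < 5L) stopf("need at least 5 routes to fit the gravity model")
  d <- od[[distance_col]]
  if (any(d <= 0)) stopf("distances must be strictly positive")
  df <- data.frame(trips = od$trips,
                   lpo = log(od$pop_orig), lpd = log(od$pop_dest),
                   ld = log(d))
  if (sd(df$lpo) == 0 || sd(df$lpd) == 0 || sd(df$ld) == 0 ||
      qr(cbind(1, df$lpo, df$lpd, df$ld))$rank < 4L) {
    stopf("covariates are collinear (e.g. all populations equal); gravity parameters are not identifiable")
  }
  g <- glm(trips ~ lpo + lpd + ld, family = poisson(), data = df)
  est <- coef(g)
  ci <- confint.default(g)  # Wald
  params <- c(alpha = unname(est["lpo"]), beta = unname(est["lpd"]),
              gamma = -unname(est["ld"]), log_k = unname(est["(Intercept)"]))
  cis <- rbind(alpha = ci["lpo", ],
               beta = ci["lpd", ],
               gamma = rev(-ci["ld", ]),
               log_k = ci["(Intercept)", ])
  colnames(cis) <- c("lower", "upper")
  structure(list(
    params = params,
    ci = cis,
    glm = g,
    distance_col = distance_col,
    od = od,
    reduction_deviance = 100 * (g$null.deviance - g$deviance) / g$null.deviance,
    n_routes = nrow(od)
  ), class = "gravity_fit")
}

#' @export
coef.gravity_fit <- function(object, ...) object$params

#' @export
confint.gravity_fit <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95) {
    ci <- confint.default(object$glm, level = level)
    out <- rbind(alpha = ci["lpo", ], beta = ci["lpd", ],
                 gamma = rev(-ci["ld", ]), log_k = ci["(Intercept)", ])
    colnames(out) <- c("lower", "upper")
  } else {
    out <- object$ci
  }
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @param newdata optional OD table to predict for (defaults to the fitted
#'   table).
#' @rdname fit_gravity
#' @export
predict.gravity_fit <- function(object, newdata = NULL, ...) {
  od <- newdata %||% object$od
  gravity_predict(object$params, od, object$distance_col)
}

#' @export
residuals.gravity_fit <- function(object, type = c("log", "deviance"), ...) {
  type <- match.arg(type)
  if (type == "deviance") return(residuals(object$glm, type = "deviance"))
  mu <- predict(object)
  ifelse(object$od$trips > 0, log(object$od$trips) - log(mu), NA_real_)
}

#' @export
simulate.gravity_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- predict(object)
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(nsim, rpois(length(mu), mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.gravity_fit <- function(x, ...) {
  cat("Gravity model (Poisson regression,", x$distance_col, ")\n")
  cat(sprintf("  routes: %d\n", x$n_routes))
  p <- x$params; ci <- x$ci
  for (nm in rownames(ci)) {
    cat(sprintf("  %-6s %8.3f  (%.3f, %.3f)\n", nm, p[[nm]],
                ci[nm, 1], ci[nm, 2]))
  }
  cat(sprintf("  reduction in deviance: %.1f%%\n", x$reduction_deviance))
  invisible(x)
}

#' @export
summary.gravity_fit <- function(object, ...) {
  structure(list(fit = object, glm_summary = summary(object$glm)),
            class = "summary.gravity_fit")
}

#' @export
print.summary.gravity_fit <- function(x, ...) {
  print(x$fit)
  cat("\nUnderlying Poisson regression:\n")
  print(x$glm_summary$coefficients)
  invisible(x)
}

#' @export
plot.gravity_fit <- function(x, ...) {
  obs <- x$od$trips
  mu <- predict(x)
  ok <- obs > 0 & mu > 0
  plot(log10(mu[ok]), log10(obs[ok]),
       xlab = "log10 predicted trips", ylab = "log10 observed trips",
       main = "Gravity model fit", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Gravity factor (parameter-free travel-volume proxy)
#'
#' `gm = pop_i * pop_j / d(i,j)` per route; symmetric in origin and
#' destination, increasing in either population, decreasing in distance.
#'
#' @param od OD table.
#' @param distance_col distance column.
#' @return numeric vector, one value per route.
#' @export
gravity_factor <- function(od, distance_col = "dist_euclid_km") {
  assert_cols(od, c("pop_orig", "pop_dest", distance_col), "od")
  d <- od[[distance_col]]
  if (any(d <= 0)) stopf("distances must be strictly positive")
  as.numeric(od$pop_orig) * as.numeric(od$pop_dest) / d
}
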