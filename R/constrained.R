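# Constrained gravity variants. The kernel exponents of the unconstrained
# side(s) are estimated by Poisson regression with origin and/or
# destination fixed effects (the maximum-likelihood analogue of the
# constrained model); balancing factors are then computed by iterative
# proportional fitting (IPF) so the constrained margins match the observed
# margins.

#' Fit a constrained gravity model
#'
#' Variants: `"production"` constrains predicted origin (row) totals to the
#' observed ones, `"attraction"` constrains destination (column) totals,
#' `"doubly"` constrains both. For the singly constrained variants the
#' kernel is `f_ij = pop^beta * d^-gamma` in the unconstrained dimension;
#' for the doubly constrained model it is the pure distance kernel
#' `f_ij = d^-gamma` (population effects are absorbed into the balancing
#' factors). Balancing runs until the maximum relative margin error falls
#' below `tol` (default 1e-8) or `max_iter` iterations, then errors.
#'
#' @param od OD table with `trips` (should cover all ordered pairs of the
#'   districts involved; use [aggregate_od()] with `zero_fill = TRUE`).
#' @param variant `"production"`, `"attraction"` or `"doubly"`.
#' @param distance_col distance column.
#' @param tol convergence tolerance on the relative margin error.
#' @param max_iter iteration cap for the doubly constrained balancing.
#' @return object of class `gravity_constrained` with balancing factors
#'   `A` (origins) and/or `B` (destinations), kernel exponents, predictions
#'   and convergence metadata.
#' @export
fit_constrained_gravity <- function(od, variant = c("production", "attraction",
                                                    "doubly"),
                                    distance_col = "dist_euclid_km",
                                    tol = 1e-8, max_iter = 10000L) {
  variant <- match.arg(variant)
  assert_cols(od, c("origin_id", "dest_id", "trips", "pop_orig", "pop_dest",
                    distance_col), "od")
  d <- od[[distance_col]]
  if (any(d <= 0)) stopf("distances must be strictly positive")
  o <- factor(od$origin_id)
  dd <- factor(od$dest_id)
  O <- tapply(od$trips, o, sum)           # observed origin totals
  Dst <- tapply(od$trips, dd, sum)        # observed destination totals
  if (variant %in% c("production", "doubly") && any(O <= 0)) {
    stopf("observed origin totals must be positive for variant '%s'", variant)
  }
  if (variant %in% c("attraction", "doubly") && any(Dst <= 0)) {
    stopf("observed destination totals must be positive for variant '%s'",
          variant)
  }
  df <- data.frame(trips = od$trips, o = o, d = dd,
                   lpo = log(od$pop_orig), lpd = log(od$pop_dest),
                   ld = log(d))
  fml <- switch(variant,
                production = trips ~ o + lpd + ld,
                attraction = trips ~ d + lpo + ld,
                doubly     = trips ~ o + d + ld)
  g <- glm(fml, family = poisson(), data = df)
  cf <- coef(g)
  # a covariate exactly collinear with the fixed effects (e.g. log d on a
  # 3-district doubly constrained fit) is dropped by the GLM; its kernel
  # contribution is then absorbed by the balancing factors, and any value
  # yields the same IPF fixed point — use 0
  dropped <- names(cf)[is.na(cf)]
  cf[is.na(cf)] <- 0
  gamma <- -unname(cf["ld"])
  beta <- switch(variant,
                 production = unname(cf["lpd"]),
                 attraction = unname(cf["lpo"]),
                 doubly = NA_real_)
  f <- switch(variant,
              production = od$pop_dest^beta * d^-gamma,
              attraction = od$pop_orig^beta * d^-gamma,
              doubly = d^-gamma)
  oi <- as.integer(o); di <- as.integer(dd)
  nO <- nlevels(o); nD <- nlevels(dd)
  A <- rep(1, nO); B <- rep(1, nD)
  iter <- 0L; err <- Inf
  repeat {
    iter <- iter + 1L
    if (variant %in% c("production", "doubly")) {
      denom <- tapply(B[di] * f, oi, sum)
      A <- as.vector(O / denom)
    }
    if (variant %in% c("attraction", "doubly")) {
      denom <- tapply(A[oi] * f, di, sum)
      B <- as.vector(Dst / denom)
    }
    mu <- A[oi] * B[di] * f
    err <- 0
    if (variant %in% c("production", "doubly")) {
      err <- max(err, max(abs(tapply(mu, oi, sum) - O) / O))
    }
    if (variant %in% c("attraction", "doubly")) {
      err <- max(err, max(abs(tapply(mu, di, sum) - Dst) / Dst))
    }
    if (err < tol || iter >= max_iter) break
  }
  if (err >= tol) {
    stopf("balancing did not converge in %d iterations (last margin error %.3g)",
          iter, err)
  }
  structure(list(
    variant = variant,
    A = setNames(A, levels(o)), B = setNames(B, levels(dd)),
    beta = beta, gamma = gamma,
    distance_col = distance_col,
    od = od, fitted = mu, glm = g,
    iterations = iter, margin_error = err, dropped_terms = dropped,
    reduction_deviance = 100 * (g$null.deviance - g$deviance) / g$null.deviance
  ), class = "gravity_constrained")
}

#' @export
predict.gravity_constrained <- function(object, ...) object$fitted

#' @export
coef.gravity_constrained <- function(object, ...) {
  c(beta = object$beta, gamma = object$gamma)
}

#' @export
print.gravity_constrained <- function(x, ...) {
  cat(sprintf("Constrained gravity model (%s, %s)\n", x$variant,
              x$distance_col))
  cat(sprintf("  gamma: %.3f", x$gamma))
  if (!is.na(x$beta)) cat(sprintf("   beta: %.3f", x$beta))
  cat(sprintf("\n  balancing: %d iteration(s), margin error %.2g\n",
              x$iterations, x$margin_error))
  cat(sprintf("  reduction in deviance: %.1f%%\n", x$reduction_deviance))
  invisible(x)
}

# Plain-matrix IPF used as the independent oracle in tests and exported for
# reuse: scales `kernel` so row sums match `row_targets` and column sums
# match `col_targets`.

#' Iterative proportional fitting of a flow matrix
#'
#' @param kernel positive matrix to scale.
#' @param row_targets,col_targets target margins (either may be NULL to
#'   leave that margin free).
#' @param tol,max_iter convergence control.
#' @return the scaled matrix.
#' @export
ipf_scale <- function(kernel, row_targets = NULL, col_targets = NULL,
                      tol = 1e-10, max_iter = 10000L) {
  M <- kernel
  for (it in seq_len(max_iter)) {
    if (!is.null(row_targets)) M <- M * (row_targets / rowSums(M))
    if (!is.null(col_targets)) M <- sweep(M, 2, col_targets / colSums(M), `*`)
    err <- 0
    if (!is.null(row_targets)) {
      err <- max(err, max(abs(rowSums(M) - row_targets) / row_targets))
    }
    if (!is.null(col_targets)) {
      err <- max(err, max(abs(colSums(M) - col_targets) / col_targets))
    }
    if (err < tol) return(M)
  }
  stopf("IPF did not converge (last error %.3g)", err)
}
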