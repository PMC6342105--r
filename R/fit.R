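#' Fit a thermal response curve
#'
#' Fits the probability of occurrence of one species along one temperature
#' variable as a binomial (logit-link) model on a quadratic B-spline basis
#' with 3 degrees of freedom for the smooth (piecewise polynomials of
#' maximal order two; interior knots at quantiles of the observed
#' temperatures).  The fitted object carries an evaluable curve over the
#' observed temperature range with pointwise 95% confidence intervals
#' (inverse-link of linear predictor +/- 1.96 standard errors), the
#' presence/absence probability threshold that minimises
#' |sensitivity - specificity|, and the training sensitivity/specificity.
#'
#' Perfect or quasi-perfect separation (possible for range-restricted
#' species) is handled by refitting with a light ridge penalty on the
#' spline coefficients; such fits are flagged via `$penalized`.
#'
#' @param x A formula `presence ~ temperature`, or a binary presence vector.
#' @param ... Passed on to methods.
#' @return An object of class `trc`.
#' @export
fit_trc <- function(x, ...) UseMethod("fit_trc")

#' @rdname fit_trc
#' @param data A data.frame for the formula interface.
#' @export
fit_trc.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  if (ncol(mf) != 2)
    stopf("fit_trc formula must be of the form presence ~ temperature")
  out <- fit_trc.default(mf[[1]], mf[[2]],
                         variable = names(mf)[2], ...)
  out$call <- match.call()
  out
}

#' @rdname fit_trc
#' @param temperature Temperature at each catchment, degC.
#' @param df Degrees of freedom of the spline smooth (default 3).
#' @param species_id,variable Optional labels carried into results.
#' @param grid_points Evaluation grid size over the observed range.
#' @param lambda Ridge penalty used on separation fallback.
#' @param conf_level Confidence level of the pointwise interval.
#' @export
fit_trc.default <- function(x, temperature, df = 3, species_id = NULL,
                            variable = NULL, grid_points = 200,
                            lambda = 0.01, conf_level = 0.95, ...) {
  y <- as.integer(as.logical(x))
  t_var <- as.numeric(temperature)
  if (length(y) != length(t_var)) stopf("presence/temperature length mismatch")
  keep <- is.finite(t_var) & !is.na(y)
  if (!all(keep)) stopf("fit_trc: non-finite temperatures or missing presences")
  if (length(unique(y)) < 2)
    stopf("fit_trc: need both presences and absences (single-class input)")
  if (length(unique(t_var)) < df + 2)
    stopf("fit_trc: degenerate temperature gradient (fewer than %d unique values)",
          df + 2)

  basis <- splines::bs(t_var, df = df, degree = 2)
  X <- cbind(`(Intercept)` = 1, unclass(basis))

  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(maxit = 200)),
    warning = function(w) invokeRestart("muffleWarning"))
  penalized <- FALSE
  # separation shows as non-convergence or runaway link-scale coefficients
  # (|eta| far beyond any estimable probability); extreme fitted
  # probabilities or steep flanks alone are normal for range-restricted
  # species and must not trigger the penalised fallback
  if (!fit$converged || any(!is.finite(fit$coefficients)) ||
      max(abs(fit$coefficients)) > 100) {
    pf <- ridge_logit(X, y, lambda = lambda)
    beta <- pf$beta
    vc <- pf$vcov
    penalized <- TRUE
  } else {
    beta <- fit$coefficients
    w <- fit$weights
    vc <- solve(crossprod(X * sqrt(w)))
  }

  rng <- range(t_var)
  grid_T <- seq(rng[1], rng[2], length.out = grid_points)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  obj <- structure(list(
    call = match.call(), species_id = species_id, variable = variable,
    df = df, coefficients = beta, vcov = vc, basis = basis,
    range = rng, penalized = penalized, lambda = if (penalized) lambda else 0,
    conf_z = z, y = y, temperature = t_var,
    n_presence = sum(y == 1), n_absence = sum(y == 0)
  ), class = "trc")

  pr <- predict(obj, temperature = grid_T, se.fit = TRUE)
  obj$grid_T <- grid_T
  obj$p_hat <- pr$fit
  obj$ci_low <- pr$ci_low
  obj$ci_high <- pr$ci_high

  scores <- predict(obj, temperature = t_var)
  obj$fitted.values <- scores
  thr <- select_threshold(scores, y)
  obj$threshold <- thr$threshold
  obj$sensitivity <- thr$sensitivity
  obj$specificity <- thr$specificity
  obj$threshold_degenerate <- thr$degenerate
  obj
}

# Newton iteration for ridge-penalised logistic regression; penalty
# lambda * sum(beta[-1]^2) leaves the intercept free.
ridge_logit <- function(X, y, lambda = 0.1, maxit = 100, tol = 1e-9) {
  p <- ncol(X)
  pen <- diag(c(0, rep(2 * lambda, p - 1)), p)
  beta <- rep(0, p)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - drop(pen %*% beta)
    H <- crossprod(X * sqrt(w)) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  w <- pmax(stats::plogis(eta) * (1 - stats::plogis(eta)), 1e-10)
  list(beta = stats::setNames(beta, colnames(X)),
       vcov = solve(crossprod(X * sqrt(w)) + pen))
}

#' Evaluate a fitted thermal response curve
#'
#' @param object A `trc` object.
#' @param temperature Temperatures at which to evaluate, degC.  Values
#'   outside the observed range return `NA` (the curve is only defined on
#'   the range the species was modelled over).
#' @param type `"response"` (probability) or `"link"` (logit).
#' @param se.fit If `TRUE`, also return link-scale SE and the pointwise
#'   confidence band on the probability scale.
#' @param ... Unused.
#' @return Probabilities, or a list with `fit`, `se_link`, `ci_low`,
#'   `ci_high` when `se.fit = TRUE`.
#' @export
predict.trc <- function(object, temperature = NULL, type = "response",
                        se.fit = FALSE, ...) {
  if (is.null(temperature)) temperature <- object$temperature
  tt <- as.numeric(temperature)
  inside <- tt >= object$range[1] & tt <= object$range[2]
  tt_in <- tt
  tt_in[!inside] <- object$range[1]  # placeholder, masked to NA below
  B <- stats::predict(object$basis, tt_in)
  X <- cbind(1, B)
  eta <- drop(X %*% object$coefficients)
  eta[!inside] <- NA_real_
  if (type == "link" && !se.fit) return(eta)
  p <- stats::plogis(eta)
  if (!se.fit) return(p)
  se <- sqrt(pmax(rowSums((X %*% object$vcov) * X), 0))
  se[!inside] <- NA_real_
  list(fit = p, se_link = se,
       ci_low = stats::plogis(eta - object$conf_z * se),
       ci_high = stats::plogis(eta + object$conf_z * se))
}

#' @export
print.trc <- function(x, ...) {
  cat("Thermal response curve fit (binomial quadratic-spline, df =",
      x$df, ")\n")
  if (!is.null(x$species_id)) cat("  species :", x$species_id, "\n")
  if (!is.null(x$variable)) cat("  variable:", x$variable, "\n")
  cat(sprintf("  data    : %d presences, %d absences over %.2f..%.2f degC\n",
              x$n_presence, x$n_absence, x$range[1], x$range[2]))
  cat(sprintf("  max fitted probability: %.4f at %.2f degC\n",
              max(x$p_hat), x$grid_T[which.max(x$p_hat)]))
  cat(sprintf("  threshold: %.4f (Se %.3f / Sp %.3f)\n",
              x$threshold, x$sensitivity, x$specificity))
  if (x$penalized)
    cat("  note: separation detected; ridge-penalised fit (lambda =",
        x$lambda, ")\n")
  invisible(x)
}

#' @export
summary.trc <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  coefs <- cbind(Estimate = object$coefficients, `Std. Error` = se,
                 `z value` = object$coefficients / se)
  out <- list(trc = object, coefficients = coefs,
              auc_train = compute_auc(object$fitted.values, object$y),
              tss_train = compute_tss(object$sensitivity,
                                      object$specificity))
  class(out) <- "summary.trc"
  out
}

#' @export
print.summary.trc <- function(x, ...) {
  print(x$trc)
  cat("\nCoefficients (logit scale):\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nTraining AUC %.3f, training TSS %.3f\n",
              x$auc_train, x$tss_train))
  invisible(x)
}

#' @export
coef.trc <- function(object, ...) object$coefficients

#' @export
vcov.trc <- function(object, ...) object$vcov

#' @export
fitted.trc <- function(object, ...) object$fitted.values

#' @export
residuals.trc <- function(object, type = c("deviance", "pearson", "response"),
                          ...) {
  type <- match.arg(type)
  y <- object$y
  mu <- object$fitted.values
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu * (1 - mu)),
    deviance = sign(y - mu) *
      sqrt(-2 * (y * log(pmax(mu, 1e-300)) +
                   (1 - y) * log(pmax(1 - mu, 1e-300)))))
}

#' Simulate presence/absence data from a fitted curve
#'
#' Draws Bernoulli presences at the original catchment temperatures from
#' the fitted occurrence probabilities.
#'
#' @param object A `trc` object.
#' @param nsim Number of replicate presence vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return data.frame with `nsim` columns of 0/1 presences.
#' @export
simulate.trc <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    p <- object$fitted.values
    out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' Plot a fitted thermal response curve
#'
#' Fitted probability with the pointwise confidence band and a rug of
#' presence (top) and absence (bottom) temperatures.
#'
#' @param x A `trc` object.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.trc <- function(x, main = NULL, ...) {
  if (is.null(main))
    main <- paste0("TRC", if (!is.null(x$species_id))
      paste0(": ", x$species_id), if (!is.null(x$variable))
        paste0(" ~ ", x$variable))
  graphics::plot(x$grid_T, x$p_hat, type = "n", ylim = c(0, 1),
                 xlab = "Temperature (degC)",
                 ylab = "Probability of occurrence", main = main, ...)
  graphics::polygon(c(x$grid_T, rev(x$grid_T)),
                    c(x$ci_low, rev(x$ci_high)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(x$grid_T, x$p_hat, lwd = 2, col = "steelblue4")
  graphics::abline(h = x$threshold, lty = 3, col = "grey40")
  graphics::rug(x$temperature[x$y == 1], side = 3, col = "firebrick")
  graphics::rug(x$temperature[x$y == 0], side = 1, col = "grey60")
  invisible(x)
}
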