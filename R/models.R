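#' Orientation-dependence model curves
#'
#' Closed forms of the five orientation-dependence models fitted to binned
#' white-matter curves (angle in degrees):
#' \describe{
#'   \item{susceptibility}{`y = a + b sin^2(t) + c sin^4(t)`}
#'   \item{classical_dipole}{`y = a + b |3 cos^2(t) - 1|`}
#'   \item{extended_dipole}{`y = a + b (3 cos^2(t) - 1)^2`}
#'   \item{gen_mae}{`y = p_i + p_a f(alpha, t - eps0)` with the residual
#'     dipolar-coupling kernel `f` of [gen_mae_f()]}
#'   \item{gen_mae_eps0corr}{as `gen_mae` with the offset angle removed from
#'     the parameter set (the data are epsilon-binned instead)}
#' }
#'
#' @param model_id One of `"susceptibility"`, `"classical_dipole"`,
#'   `"extended_dipole"`, `"gen_mae"`, `"gen_mae_eps0corr"`.
#' @param params Named numeric vector/list: `a`, `b`, `c` or `p_i`, `p_a`,
#'   `alpha`, `eps0` (degrees).
#' @param angle Angle(s) in degrees.
#' @return Model value(s).
#' @export
#' @examples
#' model_eval("classical_dipole", c(a = 0, b = 1), 54.7356)  # ~0
#' gen_mae_f(0, 0)                                           # 4
model_eval <- function(model_id, params, angle) {
  p <- as.list(params)
  t <- angle * pi / 180
  switch(model_id,
    susceptibility = p$a + p$b * sin(t)^2 + p$c * sin(t)^4,
    classical_dipole = p$a + p$b * abs(3 * cos(t)^2 - 1),
    extended_dipole = p$a + p$b * (3 * cos(t)^2 - 1)^2,
    gen_mae = p$p_i + p$p_a * gen_mae_f(p$alpha, angle - p$eps0),
    gen_mae_eps0corr = p$p_i + p$p_a * gen_mae_f(p$alpha, angle),
    abort(sprintf("unknown model '%s'.", model_id))
  )
}

#' @rdname model_eval
#' @param alpha Coupling angle between the residual dipolar couplings and the
#'   fiber axis, degrees.
#' @param eps Fiber-to-field angle of the actual fiber direction, degrees.
#' @export
gen_mae_f <- function(alpha, eps) {
  a <- alpha * pi / 180
  e <- eps * pi / 180
  0.25 * (3 * cos(a)^2 - 1)^2 * (3 * cos(e)^2 - 1)^2 +
    (9 / 8) * (sin(a)^4 * sin(e)^4 + sin(2 * a)^2 * sin(2 * e)^2)
}

model_params <- function(model_id) {
  switch(model_id,
    susceptibility = c("a", "b", "c"),
    classical_dipole = c("a", "b"),
    extended_dipole = c("a", "b"),
    gen_mae = c("p_i", "p_a", "alpha", "eps0"),
    gen_mae_eps0corr = c("p_i", "p_a", "alpha"),
    abort(sprintf("unknown model '%s'.", model_id))
  )
}

#' Fit an orientation-dependence model to a binned curve
#'
#' Least squares of the bin means against the bin-centre angles, with uniform
#' weights. The three polynomial-in-trig models are linear in their
#' coefficients and fitted unconstrained by linear least squares. The generalized
#' magic-angle-effect model uses biologically informed bounds
#' (`p_i` in \[0, 100\] 1/s, `p_a` in \[0, 50\] 1/s, `alpha` in \[0, 90\]
#' degrees, `eps0` in \[0, 45\] degrees for relaxation-rate targets; for the
#' already-normalized asymmetry index `p_i`, `p_a` are unconstrained) and
#' bounded Levenberg-Marquardt with a multi-start over 8 initializations of
#' `alpha` (ties resolved towards the smaller `alpha`). Goodness of fit is
#' the coefficient of determination `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param curve A `binned_curve` (see [bin_parameter()]) or any data frame
#'   with `angle_mid`, `mean` and `n` columns; only non-empty bins are used.
#' @param model_id Model name; see [model_eval()].
#' @param target `"R1"`, `"R2"` (rate bounds) or `"AI"` (unconstrained
#'   amplitude).
#' @param fix Named list of parameters to hold fixed (e.g.,
#'   `fix = list(eps0 = 0)` for simulated substrates where the principal and
#'   actual fiber directions coincide).
#' @return An `orientation_fit` object with elements `model`, `params`,
#'   `r_squared`, `fitted`, `data`, `bounds`; methods: [tidy()], [glance()],
#'   `predict()`, [autoplot()].
#' @export
#' @examples
#' th <- seq(1.25, 88.75, by = 2.5)
#' y <- model_eval("susceptibility", c(a = 20.04, b = 0.03, c = 3.07), th)
#' fit <- fit_model(tibble::tibble(angle_mid = th, mean = y, n = 1),
#'                  "susceptibility")
#' glance(fit)
fit_model <- function(curve, model_id, target = c("R2", "R1", "AI"),
                      fix = list()) {
  target <- match.arg(target)
  ok <- curve$n > 0 & is.finite(curve$mean)
  x <- curve$angle_mid[ok]
  y <- curve$mean[ok]
  pn <- model_params(model_id)
  free <- setdiff(pn, names(fix))
  if (length(y) < length(free))
    abort("fewer non-empty bins than free parameters.")
  sst <- sum((y - mean(y))^2)

  if (model_id %in% c("susceptibility", "classical_dipole", "extended_dipole")) {
    t <- x * pi / 180
    X <- switch(model_id,
      susceptibility = cbind(1, sin(t)^2, sin(t)^4),
      classical_dipole = cbind(1, abs(3 * cos(t)^2 - 1)),
      extended_dipole = cbind(1, (3 * cos(t)^2 - 1)^2))
    fit <- lm.fit(X, y)
    params <- setNames(fit$coefficients, pn)
    yhat <- drop(X %*% fit$coefficients)
    bounds <- NULL
  } else {
    eps_free <- model_id == "gen_mae" && !("eps0" %in% names(fix))
    lower <- c(p_i = if (target == "AI") -Inf else 0,
               p_a = if (target == "AI") -Inf else 0,
               alpha = 0, eps0 = 0)
    upper <- c(p_i = if (target == "AI") Inf else 100,
               p_a = if (target == "AI") Inf else 50,
               alpha = 90, eps0 = 45)
    nm <- free
    resid_fn <- function(p) {
      pl <- c(as.list(setNames(p, nm)), fix)
      if (model_id == "gen_mae_eps0corr") pl$eps0 <- NULL
      model_eval(model_id, pl, x) - y
    }
    best <- NULL
    for (a0 in seq(5, 85, length.out = 8)) {
      start <- c(p_i = max(min(y), lower[["p_i"]]),
                 p_a = max(diff(range(y)) / 4, 1e-3),
                 alpha = a0, eps0 = 15)[nm]
      ft <- tryCatch(
        minpack.lm::nls.lm(par = start, lower = lower[nm], upper = upper[nm],
                           fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-14, ptol = 1e-14, maxiter = 300)),
        error = function(e) NULL)
      if (is.null(ft)) next
      ss <- sum(resid_fn(ft$par)^2)
      if (is.null(best) || ss < best$ss - 1e-12 * max(best$ss, 1) ||
          (abs(ss - best$ss) <= 1e-12 * max(best$ss, 1) &&
           ("alpha" %in% nm) && ft$par[["alpha"]] < best$par[["alpha"]])) {
        best <- list(par = ft$par, ss = ss)
      }
    }
    if (is.null(best)) abort("generalized MAE fit failed from all starts.")
    params <- unlist(c(as.list(best$par), fix))[pn[pn %in% c(nm, names(fix))]]
    pl <- as.list(params)
    if (model_id == "gen_mae_eps0corr") pl$eps0 <- NULL
    yhat <- model_eval(model_id, pl, x)
    bounds <- list(lower = lower[nm], upper = upper[nm])
  }

  ssr <- sum((y - yhat)^2)
  structure(
    list(model = model_id, params = params,
         r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
         rss = ssr, fitted = yhat, target = target,
         data = tibble(angle = x, value = y), bounds = bounds, fix = fix),
    class = "orientation_fit"
  )
}

#' @export
print.orientation_fit <- function(x, ...) {
  cat(sprintf("orientation fit (%s, target %s): R^2 = %.4g\n  %s\n",
              x$model, x$target, x$r_squared,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname fit_model
#' @param x,object An `orientation_fit`.
#' @param newdata Optional data frame with an `angle_mid` (or `angle`) column.
#' @param ... Unused.
#' @export
predict.orientation_fit <- function(object, newdata = NULL, ...) {
  ang <- if (is.null(newdata)) object$data$angle
         else newdata$angle_mid %||% newdata$angle
  pl <- as.list(object$params)
  if (object$model == "gen_mae_eps0corr") pl$eps0 <- NULL
  model_eval(object$model, pl, ang)
}

#' @rdname fit_model
#' @export
tidy.orientation_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params),
         fixed = names(x$params) %in% names(x$fix))
}

#' @rdname fit_model
#' @export
glance.orientation_fit <- function(x, ...) {
  tibble(model = x$model, target = x$target, r.squared = x$r_squared,
         rss = x$rss, n_bins = nrow(x$data))
}
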