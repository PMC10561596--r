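#' Fit the compound removal probability to clearance times
#'
#' Maximum-likelihood estimate of `p_d` from observed direct-interference
#' clearance times under the first-passage model, by bounded
#' one-dimensional optimisation of the log likelihood in log(p_d).
#'
#' @param times Clearance times (min); at least 20 samples, all past the
#'   induction delay `tau_c` (the density is zero before it).
#' @param profile An [induction_profile()].
#' @param m0 Initial target count.
#' @param interval Search interval for `p_d` (1/(molecule min)).
#' @return An object of class `fpt_fit` with components `estimate`,
#'   `logLik`, `which`, `model` (the fitted [fpt_model()]) and `n`.
#' @seealso [fit_pp()], [sample_fpt()]
#' @export
#' @examples
#' mod <- fpt_model()
#' x <- sample_fpt(mod, 100, "direct", seed = 1)
#' fit_pd(x, mod$profile, mod$m0)
fit_pd <- function(times, profile = induction_profile(), m0 = 5,
                   interval = c(1e-8, 1e-1)) {
  .check_fit_samples(times, profile)
  mu <- cascade_mean(times, profile)
  x <- cascade_exposure(times, profile)
  nll <- function(lpd) {
    pd <- exp(lpd)
    g <- -expm1(-pd * x)
    -sum(log(m0 * pd * mu) - pd * x + (m0 - 1) * log(g))
  }
  opt <- stats::optimize(nll, interval = log(interval), tol = 1e-10)
  est <- exp(opt$minimum)
  .warn_if_at_bounds(est, interval, "p_d")
  model <- fpt_model(profile, p_d = est, m0 = m0)
  structure(list(estimate = est, logLik = -opt$objective, which = "direct",
                 parameter = "p_d", model = model, n = length(times)),
            class = "fpt_fit")
}

#' Fit the compound acquisition probability to priming clearance times
#'
#' Maximum-likelihood estimate of `p_p` from observed priming clearance
#' times, with `p_d` held fixed. The marginal priming density is
#' evaluated by quadrature of the closed-form conditional clearance
#' density against the acquisition density on an adaptive acquisition
#' grid, so that each likelihood evaluation is a vectorised sum.
#'
#' @inheritParams fit_pd
#' @param p_d Fixed compound removal probability (1/(molecule min)).
#' @param interval Search interval for `p_p`.
#' @param n_grid Size of the acquisition-time quadrature grid.
#' @return An object of class `fpt_fit` (see [fit_pd()]).
#' @export
fit_pp <- function(times, profile = induction_profile(), m0 = 5,
                   p_d = 4.4e-4, interval = c(1e-9, 1e-3),
                   n_grid = 2000L) {
  .check_fit_samples(times, profile)
  if (m0 < 2L) stop("'m0' must be at least 2 for the priming pathway")
  nll <- function(lpp) {
    pp <- exp(lpp)
    model <- fpt_model(profile, p_d = p_d, p_p = pp, m0 = m0)
    dens <- .fptau_grid(times, model, n_grid = n_grid)
    -sum(log(pmax(dens, 1e-300)))
  }
  opt <- stats::optimize(nll, interval = log(interval), tol = 1e-8)
  est <- exp(opt$minimum)
  .warn_if_at_bounds(est, interval, "p_p")
  model <- fpt_model(profile, p_d = p_d, p_p = est, m0 = m0)
  structure(list(estimate = est, logLik = -opt$objective, which = "priming",
                 parameter = "p_p", model = model, n = length(times)),
            class = "fpt_fit")
}

# vectorised trapezoid evaluation of the marginal priming density at many
# time points; acquisition times beyond the largest observation cannot
# contribute (the conditional clearance density is zero for t < tau_p),
# so the grid spans [tau_c, max(times)]
.fptau_grid <- function(times, model, n_grid = 2000L) {
  prof <- model$profile
  tp <- seq(prof$tau_c, max(times), length.out = n_grid)
  w <- fpt_acquisition(tp, model)
  dtp <- tp[2L] - tp[1L]
  x_tp <- cascade_exposure(tp, prof)
  mu_t <- cascade_mean(times, prof)
  x_t <- cascade_exposure(times, prof)
  m1 <- model$m0 - 1L
  # cond[i, j] = clearance density at times[i] given acquisition at tp[j]
  xp <- outer(x_t, x_tp, "-")
  live <- outer(times, tp, ">=") & xp > 0
  g <- -expm1(-model$p_d * xp)
  cond <- m1 * model$p_d * mu_t * exp(-model$p_d * xp) * g^(m1 - 1L)
  cond[!live] <- 0
  # trapezoid weights
  wt <- w * dtp
  wt[c(1L, n_grid)] <- wt[c(1L, n_grid)] / 2
  as.numeric(cond %*% wt)
}

.check_fit_samples <- function(times, profile) {
  stopifnot(is.numeric(times))
  if (length(times) < 20L)
    stop("at least 20 clearance-time samples are required")
  if (any(times <= profile$tau_c))
    stop("all samples must exceed the induction delay tau_c = ",
         profile$tau_c, " min (the clearance density is zero before it)")
  invisible(TRUE)
}

.warn_if_at_bounds <- function(est, interval, name) {
  if (est / interval[1] < 1.001 || interval[2] / est < 1.001)
    warning("estimate of ", name, " is at the search bound; ",
            "the likelihood may be flat in this direction")
  invisible(NULL)
}

#' @export
print.fpt_fit <- function(x, ...) {
  cat(sprintf("Maximum-likelihood fit of %s (%s pathway)\n",
              x$parameter, x$which))
  cat(sprintf("  estimate = %g /(molecule min)  (n = %d, logLik = %.2f)\n",
              x$estimate, x$n, x$logLik))
  invisible(x)
}

#' @export
coef.fpt_fit <- function(object, ...) {
  stats::setNames(object$estimate, object$parameter)
}

#' @export
logLik.fpt_fit <- function(object, ...) {
  structure(object$logLik, df = 1L, nobs = object$n, class = "logLik")
}
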