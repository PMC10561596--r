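#' Induced Cascade expression profile
#'
#' Describes the mean Cascade copy number after induction as a delayed
#' production--degradation process: production at rate `sigma` starts
#' `tau_c` minutes after induction and molecules turn over at rate `lam`,
#' so the bulk mean is \eqn{\mu(t) = (\sigma/\lambda)(1 - e^{-\lambda (t -
#' \tau_c)})} for \eqn{t > \tau_c} and 0 before. The defaults are the
#' values estimated from bulk Cascade induction data (steady state
#' \eqn{\sigma/\lambda \approx 492} molecules per cell).
#'
#' @param tau_c Delay between induction and the start of Cascade
#'   production (min), \eqn{\ge 0}.
#' @param sigma Cascade production rate (molecules/min), \eqn{> 0}.
#' @param lam Cascade turnover rate (1/min), \eqn{> 0}.
#' @return An object of class `induction_profile`.
#' @seealso [cascade_mean()], [cascade_exposure()], [fpt_model()]
#' @export
#' @examples
#' prof <- induction_profile()
#' cascade_mean(c(0, 100, 1000), prof)
induction_profile <- function(tau_c = 34, sigma = 3, lam = 0.0061) {
  stopifnot(is.numeric(tau_c), length(tau_c) == 1L, tau_c >= 0,
            is.numeric(sigma), length(sigma) == 1L, sigma > 0,
            is.numeric(lam), length(lam) == 1L, lam > 0)
  structure(list(tau_c = tau_c, sigma = sigma, lam = lam),
            class = "induction_profile")
}

#' @export
print.induction_profile <- function(x, ...) {
  cat("Induced Cascade expression profile\n")
  cat(sprintf("  delay tau_c   = %g min\n", x$tau_c))
  cat(sprintf("  production    = %g molecules/min\n", x$sigma))
  cat(sprintf("  turnover      = %g /min\n", x$lam))
  cat(sprintf("  steady state  = %.1f molecules/cell\n", x$sigma / x$lam))
  invisible(x)
}

#' Mean Cascade copy number at time t
#'
#' Evaluates \eqn{\mu(t) = (\sigma/\lambda)\,\theta(t-\tau_c)\,(1 -
#' e^{-\lambda(t-\tau_c)})}, the expected copy number of the delayed
#' production--degradation process.
#'
#' @param t Time since induction (min), vectorised; must be \eqn{\ge 0}.
#' @param profile An [induction_profile()].
#' @return Expected Cascade copy number at each `t`.
#' @export
cascade_mean <- function(t, profile = induction_profile()) {
  stopifnot(inherits(profile, "induction_profile"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be nonnegative")
  d <- pmax(t - profile$tau_c, 0)
  (profile$sigma / profile$lam) * (-expm1(-profile$lam * d))
}

#' Integrated Cascade exposure up to time t
#'
#' Closed form of \eqn{X(t) = \int_0^t \mu(t')\,dt'} (molecule minutes),
#' the quantity that the survival probability of a target depends on.
#'
#' @inheritParams cascade_mean
#' @return Integrated exposure at each `t` (molecule min).
#' @export
cascade_exposure <- function(t, profile = induction_profile()) {
  stopifnot(inherits(profile, "induction_profile"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be nonnegative")
  d <- pmax(t - profile$tau_c, 0)
  # (sigma/lam) * (d - (1 - exp(-lam d))/lam), written with expm1 so the
  # lam -> 0 limit sigma*d^2/2 is reached without cancellation
  (profile$sigma / profile$lam) *
    (d + expm1(-profile$lam * d) / profile$lam)
}

#' First-passage-time model of target clearance
#'
#' Bundles an induction profile with the compound per-Cascade, per-target
#' event probabilities into the analytic clearance-time model. `p_d` is
#' the compound probability per unit time that a Cascade binds a target
#' and the target is removed; `p_p` is the compound probability per unit
#' time that a binding event yields an integrated spacer (only used by
#' the two-step priming pathway); `m0` is the initial target count.
#'
#' @param profile An [induction_profile()].
#' @param p_d Compound removal probability (1/(molecule min)), \eqn{> 0}.
#' @param p_p Compound acquisition probability (1/(molecule min)),
#'   \eqn{\ge 0}. The default is the value fitted to priming loss times.
#' @param m0 Initial number of targets per cell (integer \eqn{\ge 1}).
#' @return An object of class `fpt_model`.
#' @seealso [fpt_direct()], [fpt_priming_total()], [sample_fpt()],
#'   [fit_pd()], [fit_pp()]
#' @export
#' @examples
#' mod <- fpt_model()
#' mean_fpt_direct(mod)  # about 94 min
fpt_model <- function(profile = induction_profile(), p_d = 4.4e-4,
                      p_p = 1e-6, m0 = 5) {
  stopifnot(inherits(profile, "induction_profile"),
            is.numeric(p_d), length(p_d) == 1L, p_d > 0,
            is.numeric(p_p), length(p_p) == 1L, p_p >= 0,
            is.numeric(m0), length(m0) == 1L, m0 >= 1, m0 == round(m0))
  structure(list(profile = profile, p_d = p_d, p_p = p_p, m0 = as.integer(m0)),
            class = "fpt_model")
}

#' @export
print.fpt_model <- function(x, ...) {
  cat("First-passage-time model of CRISPR target clearance\n")
  print(x$profile)
  cat(sprintf("  p_d = %g /(molecule min), p_p = %g /(molecule min), m0 = %d\n",
              x$p_d, x$p_p, x$m0))
  cat(sprintf("  mean direct-interference clearance time: %.1f min\n",
              mean_fpt_direct(x)))
  invisible(x)
}

#' Probability that all targets are cleared by time t (direct interference)
#'
#' The survival-complement \eqn{P_0(t\mid M_0) = (1 - e^{-p_d
#' X(t)})^{M_0}} of the clearance master equation: 0 before the induction
#' delay and 1 in the long-time limit (target zero is absorbing).
#'
#' @param t Time since induction (min), vectorised.
#' @param model An [fpt_model()].
#' @return Clearance probability at each `t`.
#' @export
p0_direct <- function(t, model = fpt_model()) {
  stopifnot(inherits(model, "fpt_model"))
  x <- cascade_exposure(t, model$profile)
  (-expm1(-model$p_d * x))^model$m0
}

#' Clearance-time density for direct interference
#'
#' The first-passage-time density \eqn{FP_r(t \mid M_0) = M_0 p_d \mu(t)
#' e^{-p_d X(t)} (1 - e^{-p_d X(t)})^{M_0 - 1}}, i.e. the exact time
#' derivative of [p0_direct()]. Nonnegative and normalised to 1.
#'
#' @inheritParams p0_direct
#' @return Density values (1/min).
#' @export
fpt_direct <- function(t, model = fpt_model()) {
  stopifnot(inherits(model, "fpt_model"))
  mu <- cascade_mean(t, model$profile)
  x <- cascade_exposure(t, model$profile)
  g <- -expm1(-model$p_d * x)       # 1 - exp(-p_d X)
  model$m0 * model$p_d * mu * exp(-model$p_d * x) * g^(model$m0 - 1L)
}

# time beyond which the direct clearance CDF exceeds 1 - eps
.fpt_upper <- function(model, eps = 1e-12) {
  prof <- model$profile
  hi <- prof$tau_c + 10
  while (p0_direct(hi, model) < 1 - eps) hi <- hi * 2
  hi
}

# invert the exposure integral X(t) = xval (X is strictly increasing past
# tau_c); vectorised: monotone-interpolation start, Newton polish with
# X'(t) = mu(t)
.exposure_inverse <- function(xval, profile, tol = 1e-10) {
  if (!length(xval)) return(numeric(0))
  out <- rep(profile$tau_c, length(xval))
  pos <- which(xval > 0)
  if (!length(pos)) return(out)
  xmax <- max(xval[pos])
  hi <- profile$tau_c + 10
  while (cascade_exposure(hi, profile) < xmax) hi <- hi * 2
  tg <- seq(profile$tau_c, hi, length.out = 4096L)
  t0 <- stats::approx(cascade_exposure(tg, profile), tg,
                      xout = xval[pos], rule = 2)$y
  for (i in 1:4) {
    mu <- pmax(cascade_mean(t0, profile), 1e-300)
    t0 <- pmax(t0 - (cascade_exposure(t0, profile) - xval[pos]) / mu,
               profile$tau_c * (1 + 1e-12) + 1e-12)
  }
  out[pos] <- t0
  out
}

#' Mean clearance time under direct interference
#'
#' Computes \eqn{\tau = \int_0^\infty t'\,FP_r(t' \mid M_0)\,dt'} by
#' adaptive quadrature on a finite window chosen so the truncated tail
#' mass is below `eps`. With the default model parameters this evaluates
#' to about 94 min.
#'
#' @param model An [fpt_model()].
#' @param rel.tol Relative quadrature tolerance.
#' @param eps Tail mass allowed beyond the quadrature window.
#' @return The mean clearance time (min), with the quadrature's absolute
#'   error estimate attached as attribute `"abs.error"`.
#' @export
mean_fpt_direct <- function(model = fpt_model(), rel.tol = 1e-9,
                            eps = 1e-12) {
  stopifnot(inherits(model, "fpt_model"))
  upper <- .fpt_upper(model, eps)
  q <- stats::integrate(function(t) t * fpt_direct(t, model),
                        lower = model$profile$tau_c, upper = upper,
                        rel.tol = rel.tol, subdivisions = 500L)
  if (q$message != "OK")
    stop("quadrature did not converge (achieved abs.error = ",
         format(q$abs.error), "): ", q$message)
  structure(q$value, abs.error = q$abs.error)
}

#' Spacer-acquisition-time density (first target hit during priming)
#'
#' Density of the waiting time \eqn{\tau_p} for the first acquisition
#' event, \eqn{FP_p(\tau_p \mid M_0) = M_0 p_p \mu(\tau_p) e^{-M_0 p_p
#' X(\tau_p)}}; normalised to 1.
#'
#' @param tau_p Acquisition times (min), vectorised.
#' @inheritParams p0_direct
#' @return Density values (1/min).
#' @export
fpt_acquisition <- function(tau_p, model = fpt_model()) {
  stopifnot(inherits(model, "fpt_model"))
  mu <- cascade_mean(tau_p, model$profile)
  x <- cascade_exposure(tau_p, model$profile)
  model$m0 * model$p_p * mu * exp(-model$m0 * model$p_p * x)
}

# conditional clearance density for m targets given exposure starts at
# tau_p: the FP_r form with X(t) replaced by X(t) - X(tau_p)
.fpt_conditional <- function(t, tau_p, model, m) {
  mu <- cascade_mean(t, model$profile)
  xp <- cascade_exposure(t, model$profile) -
    cascade_exposure(tau_p, model$profile)
  g <- -expm1(-model$p_d * xp)
  out <- m * model$p_d * mu * exp(-model$p_d * xp) * g^(m - 1L)
  out[t < tau_p] <- 0
  out
}

#' Clearance-time density conditional on acquisition at tau_p
#'
#' The direct-interference first-passage form with the Cascade exposure
#' integral started at the acquisition time \eqn{\tau_p} (the new spacer
#' can only act once acquired): zero for \eqn{t < \tau_p}, and for
#' \eqn{\tau_p = 0} it reduces exactly to [fpt_direct()].
#'
#' @param t Clearance times (min), vectorised.
#' @param tau_p Acquisition time (min), scalar.
#' @param model An [fpt_model()]; the conditional uses the model's `m0`
#'   targets.
#' @return Density values (1/min).
#' @export
fpt_priming_conditional <- function(t, tau_p, model = fpt_model()) {
  stopifnot(inherits(model, "fpt_model"), is.numeric(tau_p),
            length(tau_p) == 1L, tau_p >= 0, all(t >= 0))
  .fpt_conditional(t, tau_p, model, model$m0)
}

#' Marginal clearance-time density for the two-step priming pathway
#'
#' Composes acquisition and subsequent clearance of the remaining
#' \eqn{M_0 - 1} targets, \eqn{FP_\tau(t \mid M_0) = \int_0^\infty
#' FP_r(t \mid M_0 - 1, \tau_p)\,FP_p(\tau_p \mid M_0)\,d\tau_p}, by
#' adaptive quadrature over the acquisition time (the integral has no
#' closed form). The resulting distribution is much broader than the
#' direct-interference one at equal parameters.
#'
#' @param t Clearance times (min), vectorised.
#' @param model An [fpt_model()] with `m0 >= 2` and `p_p > 0`.
#' @param rel.tol Relative tolerance of the inner quadrature.
#' @return Density values (1/min).
#' @export
fpt_priming_total <- function(t, model = fpt_model(), rel.tol = 1e-8) {
  stopifnot(inherits(model, "fpt_model"))
  if (model$m0 < 2L)
    stop("'m0' must be at least 2: the conditional clearance step uses m0 - 1 targets")
  if (model$p_p <= 0) stop("'p_p' must be positive for the priming pathway")
  tau_c <- model$profile$tau_c
  vapply(t, function(ti) {
    if (ti <= tau_c) return(0)
    stats::integrate(function(tp)
      .fpt_conditional(ti, tp, model, model$m0 - 1L) *
        fpt_acquisition(tp, model),
      lower = tau_c, upper = ti, rel.tol = rel.tol,
      subdivisions = 500L, stop.on.error = FALSE)$value
  }, numeric(1))
}

# cumulative distribution of the priming clearance time, by quadrature of
# the closed-form conditional CDF against the acquisition density
.fpt_priming_cdf <- function(t, model, rel.tol = 1e-8) {
  tau_c <- model$profile$tau_c
  m1 <- model$m0 - 1L
  vapply(t, function(ti) {
    if (ti <= tau_c) return(0)
    stats::integrate(function(tp) {
      xp <- cascade_exposure(ti, model$profile) -
        cascade_exposure(tp, model$profile)
      (-expm1(-model$p_d * xp))^m1 * fpt_acquisition(tp, model)
    }, lower = tau_c, upper = ti, rel.tol = rel.tol,
    subdivisions = 500L, stop.on.error = FALSE)$value
  }, numeric(1))
}

#' Evaluate a clearance-time density and CDF on a time grid
#'
#' Convenience evaluation of the direct or priming clearance model on a
#' grid, returning density and cumulative values together.
#'
#' @param model An [fpt_model()].
#' @param which `"direct"` or `"priming"`.
#' @param grid Time grid (min); by default an even grid covering
#'   essentially all probability mass.
#' @param n Grid size used when `grid` is `NULL`.
#' @return A data frame with columns `time`, `pdf`, `cdf`.
#' @export
fpt_density <- function(model = fpt_model(), which = c("direct", "priming"),
                        grid = NULL, n = 512L) {
  which <- match.arg(which)
  if (is.null(grid)) {
    upper <- if (which == "direct") .fpt_upper(model, 1e-9) else {
      hi <- .fpt_upper(model, 1e-9)
      while (.fpt_priming_cdf(hi, model) < 1 - 1e-6) hi <- hi * 2
      hi
    }
    grid <- seq(0, upper, length.out = n)
  }
  if (which == "direct") {
    data.frame(time = grid, pdf = fpt_direct(grid, model),
               cdf = p0_direct(grid, model))
  } else {
    data.frame(time = grid, pdf = fpt_priming_total(grid, model),
               cdf = .fpt_priming_cdf(grid, model))
  }
}

#' Cumulative probability of spacer acquisition under an arbitrary
#' Cascade profile
#'
#' \eqn{F_{SA}(t \mid M_0) = 1 - e^{-M_0 p_p \int_0^t m(t')\,dt'}}: the
#' acquisition probability depends on the Cascade history only through
#' its time integral, so any rearrangement of the profile that preserves
#' the integral gives the same value. A short high burst therefore
#' reaches saturation faster than a constant profile of equal average.
#'
#' @param t Times (min), vectorised.
#' @param m Cascade copy-number profile: a function of time or a single
#'   constant.
#' @param p_p Compound acquisition probability (1/(molecule min)).
#' @param m0 Target count.
#' @param breaks Optional numeric vector of discontinuity points of `m`,
#'   used to split the quadrature (needed for step profiles).
#' @return Acquisition probabilities at each `t`.
#' @export
#' @examples
#' # constant 500 copies over 0--1000 min vs a 2500-copy burst on
#' # 200--400 min: equal integral, hence equal value at t = 1000
#' const <- function(t) ifelse(t <= 1000, 500, 0)
#' burst <- function(t) ifelse(t >= 200 & t <= 400, 2500, 0)
#' cumulative_acquisition(1000, const, 1e-6, 5, breaks = 1000)
#' cumulative_acquisition(1000, burst, 1e-6, 5, breaks = c(200, 400))
cumulative_acquisition <- function(t, m, p_p, m0, breaks = NULL) {
  stopifnot(is.numeric(t), all(t >= 0), is.numeric(p_p), p_p >= 0,
            is.numeric(m0), m0 >= 1)
  mfun <- if (is.function(m)) m else {
    stopifnot(is.numeric(m), length(m) == 1L, m >= 0)
    function(tt) rep(m, length(tt))
  }
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    cuts <- sort(unique(c(0, breaks[breaks > 0 & breaks < ti], ti)))
    integral <- 0
    for (k in seq_len(length(cuts) - 1L)) {
      integral <- integral +
        stats::integrate(function(x) vapply(x, mfun, numeric(1)) + 0 * x,
                         lower = cuts[k], upper = cuts[k + 1L],
                         rel.tol = 1e-10, subdivisions = 200L)$value
    }
    -expm1(-m0 * p_p * integral)
  }, numeric(1))
}

#' Draw clearance times from the analytic model
#'
#' Exact inverse-CDF sampling. Direct interference inverts the
#' closed-form survival function through the exposure integral; priming
#' composes an acquisition time drawn from its density with a
#' conditional clearance of the remaining `m0 - 1` targets (exactly the
#' marginal [fpt_priming_total()] distribution).
#'
#' @param model An [fpt_model()].
#' @param n Number of samples.
#' @param which `"direct"` or `"priming"`.
#' @param seed Optional integer seed for reproducibility.
#' @return A numeric vector of `n` clearance times (min).
#' @export
sample_fpt <- function(model = fpt_model(), n,
                       which = c("direct", "priming"), seed = NULL) {
  which <- match.arg(which)
  stopifnot(inherits(model, "fpt_model"), is.numeric(n), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  prof <- model$profile
  if (which == "direct") {
    u <- stats::runif(n)
    xv <- -log1p(-u^(1 / model$m0)) / model$p_d
    .exposure_inverse(xv, prof)
  } else {
    if (model$m0 < 2L) stop("priming sampling needs 'm0' >= 2")
    if (model$p_p <= 0) stop("priming sampling needs 'p_p' > 0")
    u1 <- stats::runif(n)
    x_tp <- -log1p(-u1) / (model$m0 * model$p_p)
    tp <- .exposure_inverse(x_tp, prof)
    u2 <- stats::runif(n)
    x_t <- cascade_exposure(tp, prof) -
      log1p(-u2^(1 / (model$m0 - 1L))) / model$p_d
    .exposure_inverse(x_t, prof)
  }
}

#' @export
simulate.fpt_model <- function(object, nsim = 1, seed = NULL,
                               which = c("direct", "priming"), ...) {
  sample_fpt(object, n = nsim, which = match.arg(which), seed = seed)
}

#' @export
plot.fpt_model <- function(x, which = c("direct", "priming"), n = 200L,
                           ...) {
  which <- match.arg(which)
  d <- fpt_density(x, which, n = n)
  graphics::plot(d$time, d$pdf, type = "l", xlab = "time (min)",
                 ylab = "clearance-time density (1/min)",
                 main = sprintf("%s clearance-time distribution", which),
                 ...)
  graphics::abline(v = x$profile$tau_c, lty = 3)
  invisible(x)
}
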