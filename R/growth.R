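#' Single-cell growth and division parameters
#'
#' Growth-rate, division-size and division-ratio distributions for the
#' agent-based population. Growth rates are lognormal with mean `mu_p`
#' and log-sd `sigma_p`; division sizes are lognormal with mean `mu_vd`
#' and standard deviation `sigma_vd` (micrometres); the division ratio of
#' daughter 1 is Normal(`mu_vr`, `sigma_vr`^2), redrawn if outside
#' (0.1, 0.9). Defaults correspond to E. coli growing with a 70-min
#' doubling time and an 11% division-size CV.
#'
#' @param mu_p Mean growth rate (1/min).
#' @param sigma_p Log-scale standard deviation of the growth rate.
#' @param mu_vr Mean division ratio (fraction of mother size to
#'   daughter 1).
#' @param sigma_vr Standard deviation of the division ratio.
#' @param mu_vd Mean division size (um).
#' @param sigma_vd Standard deviation of the division size (um).
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(mu_p = log(2) / 70, sigma_p = 0.2,
                          mu_vr = 0.5, sigma_vr = 0.07 * 0.5,
                          mu_vd = 3.9, sigma_vd = 0.11 * 3.9) {
  stopifnot(mu_p > 0, sigma_p >= 0, mu_vr > 0, mu_vr < 1, sigma_vr >= 0,
            mu_vd > 0, sigma_vd >= 0)
  # lognormal with distribution mean equal to the printed physical value:
  # meanlog = log(mean) - sdlog^2/2. Division size uses the printed sd,
  # converted to a log-sd through the CV.
  vd_sdlog <- sqrt(log(1 + (sigma_vd / mu_vd)^2))
  structure(list(
    mu_p = mu_p, sigma_p = sigma_p, mu_vr = mu_vr, sigma_vr = sigma_vr,
    mu_vd = mu_vd, sigma_vd = sigma_vd,
    mu_meanlog = log(mu_p) - sigma_p^2 / 2, mu_sdlog = sigma_p,
    vd_meanlog = log(mu_vd) - vd_sdlog^2 / 2, vd_sdlog = vd_sdlog),
    class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Single-cell growth parameters\n")
  cat(sprintf("  growth rate : lognormal, mean %.5f /min (doubling %.0f min), log-sd %.2f\n",
              x$mu_p, log(2) / x$mu_p, x$sigma_p))
  cat(sprintf("  division size: lognormal, mean %.2f um, sd %.2f um\n",
              x$mu_vd, x$sigma_vd))
  cat(sprintf("  division ratio: Normal(%.2f, %.3f^2)\n", x$mu_vr, x$sigma_vr))
  invisible(x)
}
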