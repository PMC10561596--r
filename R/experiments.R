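#' Run an ensemble of independent simulated experiments
#'
#' Repeats the agent-based simulation with independent seeds and pools
#' the per-lineage outcome records into one summary: loss-time mean and
#' squared coefficient of variation, censored fraction, the fraction of
#' losses through the low-level-interference/partitioning pathway, and
#' the adaptation/interference time breakdown for primed losses.
#'
#' @param condition `"direct"` or `"priming"`.
#' @param overrides Named list of [rate_params()] overrides.
#' @param n_experiments Number of independent populations (the
#'   experimental default is 100).
#' @param config An [engine_config()] object (per-experiment settings;
#'   its seed field is ignored in favour of `seed`).
#' @param growth A [growth_params()] object.
#' @param seed Base seed; experiment i uses `seed + i - 1`.
#' @return An object of class `ensemble_summary`.
#' @export
run_ensemble <- function(condition = c("priming", "direct"),
                         overrides = list(), n_experiments = 100,
                         config = engine_config(),
                         growth = growth_params(), seed = 1) {
  condition <- match.arg(condition)
  stopifnot(n_experiments >= 1)
  rates <- do.call(rate_params, overrides)
  system <- build_system(rates, condition, growth)
  seeds <- seed + seq_len(n_experiments) - 1L
  loss <- vector("list", n_experiments)
  censored <- 0L
  for (i in seq_len(n_experiments)) {
    cfg <- config
    cfg$seed <- seeds[i]
    oc <- record_outcomes(run_population(system, growth, cfg))
    li <- oc$losses
    li$experiment <- i
    loss[[i]] <- li
    censored <- censored + oc$censored
  }
  losses <- do.call(rbind, loss)
  if (nrow(losses) == 0L)
    warning("ensemble is fully censored: no lineage lost its targets ",
            "within t_final")
  lt <- losses$t_loss
  primed <- !is.na(losses$t_adapt)
  structure(list(
    condition = condition, overrides = overrides, losses = losses,
    n_experiments = n_experiments, seeds = seeds,
    mean_plt = mean(lt), cv2 = stats::var(lt) / mean(lt)^2,
    n_losses = length(lt), censored = censored,
    frac_censored = censored / (censored + length(lt)),
    frac_lowlevel = mean(!primed),
    adaptation_times = losses$t_adapt[primed],
    interference_times = (losses$t_loss - losses$t_adapt)[primed]),
    class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Ensemble of %d experiments (%s condition)\n",
              x$n_experiments, x$condition))
  if (length(x$overrides))
    cat("  overrides: ",
        paste(names(x$overrides), unlist(x$overrides), sep = "=",
              collapse = ", "), "\n", sep = "")
  cat(sprintf("  %d loss events, %.1f%% censored, %.1f%% without acquisition\n",
              x$n_losses, 100 * x$frac_censored, 100 * x$frac_lowlevel))
  cat(sprintf("  mean PLT %.0f min, CV^2 = %.3f\n", x$mean_plt, x$cv2))
  if (length(x$adaptation_times))
    cat(sprintf("  primed losses: median adaptation %.0f min, mean interference %.0f min\n",
                stats::median(x$adaptation_times),
                mean(x$interference_times)))
  invisible(x)
}

# jackknife-over-experiments standard error of a pooled statistic
.ensemble_se <- function(losses, stat) {
  ex <- unique(losses$experiment)
  if (length(ex) < 2) return(NA_real_)
  jk <- vapply(ex, function(e) stat(losses[losses$experiment != e, ]),
               numeric(1))
  sqrt((length(ex) - 1) * mean((jk - mean(jk))^2))
}

#' Standard error of the ensemble mean loss time
#'
#' Jackknife over experiments, which respects the within-experiment
#' correlation of loss times (shared lineages and population dynamics).
#'
#' @param summary An [run_ensemble()] result.
#' @return Standard error of `mean_plt` (min).
#' @export
mean_plt_se <- function(summary) {
  stopifnot(inherits(summary, "ensemble_summary"))
  .ensemble_se(summary$losses, function(d) mean(d$t_loss))
}

#' Mean plasmid loss time versus target copy number
#'
#' Runs ensembles across target set points. Under direct interference
#' the mean loss time increases monotonically with copy number; under
#' priming the dependence is non-monotonic: a single target is lost
#' quickly through low-level interference and partitioning, mid copy
#' numbers wait longest for spacer acquisition, and higher copy numbers
#' speed acquisition up again (more destruction events producing
#' pre-spacers) while slowing the interference phase.
#'
#' @param condition `"direct"` or `"priming"`.
#' @param p_s_values Target set points to sweep.
#' @param n_experiments Experiments per set point.
#' @param overrides Additional rate overrides applied at every point.
#' @inheritParams run_ensemble
#' @return An object of class `copy_number_sweep`: a data frame of
#'   per-point summaries with the full summaries attached.
#' @export
copy_number_sweep <- function(condition = c("priming", "direct"),
                              p_s_values = c(1, 2, 3, 5, 8, 12, 20, 30, 50),
                              n_experiments = 25, overrides = list(),
                              config = engine_config(),
                              growth = growth_params(), seed = 1) {
  condition <- match.arg(condition)
  summaries <- lapply(p_s_values, function(ps) {
    ov <- overrides
    ov$p_s <- ps
    run_ensemble(condition, ov, n_experiments, config, growth, seed)
  })
  tab <- data.frame(
    p_s = p_s_values,
    mean_plt = vapply(summaries, function(s) s$mean_plt, numeric(1)),
    se_plt = vapply(summaries, mean_plt_se, numeric(1)),
    cv2 = vapply(summaries, function(s) s$cv2, numeric(1)),
    frac_lowlevel = vapply(summaries, function(s) s$frac_lowlevel,
                           numeric(1)),
    frac_censored = vapply(summaries, function(s) s$frac_censored,
                           numeric(1)),
    median_adaptation = vapply(summaries, function(s)
      if (length(s$adaptation_times)) stats::median(s$adaptation_times)
      else NA_real_, numeric(1)),
    mean_interference = vapply(summaries, function(s)
      if (length(s$interference_times)) mean(s$interference_times)
      else NA_real_, numeric(1)))
  structure(list(condition = condition, table = tab,
                 summaries = summaries),
            class = "copy_number_sweep")
}

#' @export
print.copy_number_sweep <- function(x, ...) {
  cat(sprintf("Copy-number sweep (%s condition)\n", x$condition))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.copy_number_sweep <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$p_s, tab$mean_plt, type = "b", log = "x",
                 xlab = "target copy-number set point",
                 ylab = "mean loss time (min)",
                 main = sprintf("Mean PLT vs copy number (%s)",
                                x$condition), ...)
  graphics::arrows(tab$p_s, tab$mean_plt - tab$se_plt, tab$p_s,
                   tab$mean_plt + tab$se_plt, angle = 90, code = 3,
                   length = 0.03)
  invisible(x)
}

#' The affinity / integration-rate grid
#'
#' Four priming ensembles crossing Cascade-target binding affinity
#' (low = shipped default for a mutated PAM; high = 100-fold increase)
#' with the spacer-integration rate (fast = default; slow = 100-fold
#' reduction), holding Cas3-mediated destruction constant. A broad
#' loss-time distribution arises only in the low-affinity column: slow
#' integration alone does not generate it, and with high affinity the
#' original spacer clears the target directly regardless of the
#' integration rate.
#'
#' @inheritParams run_ensemble
#' @param affinity_factor Binding multiplier for the high-affinity column.
#' @param integration_factor Integration divisor for the slow column.
#' @param overrides Additional rate overrides applied at every cell.
#' @return An object of class `affinity_grid`: a data frame of the four
#'   cells with the full summaries attached.
#' @export
affinity_integration_grid <- function(n_experiments = 25,
                                      affinity_factor = 100,
                                      integration_factor = 100,
                                      overrides = list(),
                                      config = engine_config(),
                                      growth = growth_params(), seed = 1) {
  base <- do.call(rate_params, overrides)
  cells <- expand.grid(affinity = c("low", "high"),
                       integration = c("fast", "slow"),
                       stringsAsFactors = FALSE)
  summaries <- lapply(seq_len(nrow(cells)), function(i) {
    ov <- overrides
    ov$k_on_low <- base$k_on_low *
      if (cells$affinity[i] == "high") affinity_factor else 1
    ov$k_int <- base$k_int /
      if (cells$integration[i] == "slow") integration_factor else 1
    run_ensemble("priming", ov, n_experiments, config, growth, seed)
  })
  tab <- cbind(cells, data.frame(
    mean_plt = vapply(summaries, function(s) s$mean_plt, numeric(1)),
    se_plt = vapply(summaries, mean_plt_se, numeric(1)),
    cv2 = vapply(summaries, function(s) s$cv2, numeric(1)),
    n_losses = vapply(summaries, function(s) s$n_losses, numeric(1)),
    frac_censored = vapply(summaries, function(s) s$frac_censored,
                           numeric(1))))
  structure(list(table = tab, summaries = summaries),
            class = "affinity_grid")
}

#' @export
print.affinity_grid <- function(x, ...) {
  cat("Affinity x integration grid (priming condition)\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Cascade expression-variability sweep
#'
#' Varies the burst-variability factor `a` (burst size multiplied by
#' `a`, burst rate divided by `a`, conserving mean production flux) and
#' summarises the priming outcome per value: loss times, the
#' adaptation/interference breakdown, and the steady-state Cascade
#' concentration statistics measured on separate target-free populations
#' of the same kinetics.
#'
#' @param a_values Burst-variability factors (>= 1).
#' @inheritParams run_ensemble
#' @param overrides Additional rate overrides.
#' @param cascade_t Time (min) at which the steady-state Cascade
#'   concentration is measured.
#' @param cascade_cells Population size of the Cascade measurement runs.
#' @return An object of class `burst_sweep`: per-`a` table plus the
#'   full summaries.
#' @export
burst_variability_sweep <- function(a_values = c(1, 100),
                                    n_experiments = 25,
                                    overrides = list(),
                                    config = engine_config(),
                                    growth = growth_params(), seed = 1,
                                    cascade_t = 1500,
                                    cascade_cells = 400) {
  summaries <- lapply(a_values, function(a) {
    ov <- overrides
    ov$a <- a
    run_ensemble("priming", ov, n_experiments, config, growth, seed)
  })
  casc <- lapply(a_values, function(a) {
    ov <- overrides
    ov$a <- a
    cascade_steady_stats(do.call(rate_params, ov), growth,
                         t_measure = cascade_t, n_cells = cascade_cells,
                         seed = seed)
  })
  tab <- data.frame(
    a = a_values,
    mean_plt = vapply(summaries, function(s) s$mean_plt, numeric(1)),
    se_plt = vapply(summaries, mean_plt_se, numeric(1)),
    cv2 = vapply(summaries, function(s) s$cv2, numeric(1)),
    median_adaptation = vapply(summaries, function(s)
      stats::median(s$adaptation_times), numeric(1)),
    var_interference = vapply(summaries, function(s)
      stats::var(s$interference_times), numeric(1)),
    cascade_mean = vapply(casc, function(c) c[["mean_count"]], numeric(1)),
    cascade_cv = vapply(casc, function(c) c[["cv_conc"]], numeric(1)))
  structure(list(table = tab, summaries = summaries, cascade = casc),
            class = "burst_sweep")
}

#' @export
print.burst_sweep <- function(x, ...) {
  cat("Cascade burst-variability sweep (priming condition)\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Steady-state Cascade statistics of a target-free population
#'
#' Simulates a population with the given kinetics but no targets (so
#' expression and growth are unperturbed by interference) and returns
#' the population mean total Cascade copy number (free plus
#' crRNA-loaded, bound and unbound) and the cell-to-cell coefficient of
#' variation of its concentration at the measurement time.
#'
#' @param rates A [rate_params()] object.
#' @param growth A [growth_params()] object.
#' @param t_measure Measurement time (min); should exceed a few turnover
#'   times so the population is at steady state.
#' @param n_cells Population size.
#' @param seed Seed.
#' @return Named vector with `mean_count` and `cv_conc`.
#' @export
cascade_steady_stats <- function(rates = rate_params(),
                                 growth = growth_params(),
                                 t_measure = 1500, n_cells = 200,
                                 seed = 1) {
  sys <- build_system(rates, "priming", growth)
  sys$init_state["P"] <- 0
  sys$init_state["Y"] <- 0
  cfg <- engine_config(n_cells = n_cells, t_final = t_measure, seed = seed,
                       stop_when_cleared = FALSE,
                       record_interval = t_measure)
  run <- run_population(sys, growth, cfg)
  fs <- run$final_state
  total <- fs[, "C"] + fs[, "E"] + fs[, "Es"] + fs[, "EP"] + fs[, "EsP"]
  idx <- run$final_cell
  size <- run$cells$v_birth[idx] *
    exp(run$cells$mu[idx] * (run$t_end - run$cells$t_birth[idx]))
  conc <- total / size
  c(mean_count = mean(total), cv_conc = stats::sd(conc) / mean(conc))
}
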