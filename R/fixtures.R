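#' Specification of a synthetic lineage-tree fixture
#'
#' Describes mother-machine-style lineage chains with known ground
#' truth: exponential growth with lognormal rate variability, divisions
#' at a fixed size, a plasmid reporter channel (`yfp`) whose production
#' sits at a plateau, ramps down linearly over the true clearance time
#' `ct` and stops at the injected loss time, and a constitutive
#' concentration channel (`rfp`) constant per lineage. Optional
#' ingredients: photobleaching, multiplicative measurement noise,
#' growth arrest (death) injection, a growth-rate offset for loss
#' lineages (feature-loss coupling), and loss times drawn with a hazard
#' proportional to cumulative `rfp` exposure.
#'
#' @param n_lineages Number of independent lineage chains.
#' @param frame_interval Imaging interval (min).
#' @param t_total Observation span (min).
#' @param growth_rate Mean elongation rate (1/min).
#' @param growth_cv Lognormal log-sd of the per-lineage growth rate.
#' @param div_size Division length (um); birth length is half.
#' @param plateau Reporter production rate at the plateau (a.u./min).
#' @param ct True clearance time: duration of the linear production
#'   ramp-down before the loss (min).
#' @param bleach_rate Photobleaching rate (1/min).
#' @param noise Multiplicative measurement noise sd on the reporter
#'   total fluorescence.
#' @param loss Injected plasmid loss times: `NULL` (none), a numeric
#'   vector recycled over lineages (NA = no loss for that lineage), or
#'   `"rfp"` to draw losses with hazard proportional to cumulative rfp
#'   exposure.
#' @param rfp_mean,rfp_cv Mean and lognormal log-sd of the per-lineage
#'   rfp concentration (a.u./um).
#' @param rfp_hazard Hazard scale for `loss = "rfp"` (per (a.u. min)).
#' @param growth_arrest Optional vector of arrest (death) times per
#'   lineage (NA = none).
#' @param feature_effect Fractional growth-rate offset applied to loss
#'   lineages (0 = null cohort).
#' @param seed Seed for the generator.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_lineages = 50, frame_interval = 3,
                         t_total = 600, growth_rate = log(2) / 70,
                         growth_cv = 0.2, div_size = 3.9, plateau = 100,
                         ct = 60, bleach_rate = 0, noise = 0,
                         loss = NULL, rfp_mean = 100, rfp_cv = 0.3,
                         rfp_hazard = 1e-6, growth_arrest = NULL,
                         feature_effect = 0, seed = 1) {
  stopifnot(n_lineages >= 1, frame_interval > 0, t_total > frame_interval,
            growth_rate > 0, growth_cv >= 0, plateau >= 0, ct >= 0,
            bleach_rate >= 0, noise >= 0)
  if (is.numeric(loss) && length(loss) > n_lineages)
    stop("loss schedule refers to more lineages than exist")
  if (!is.null(growth_arrest) && length(growth_arrest) > n_lineages)
    stop("growth-arrest schedule refers to more lineages than exist")
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic lineage tree with ground truth
#'
#' Builds the lineage chains described by a [fixture_spec()] in the
#' standard cells/series schema, together with a ground-truth table
#' (per lineage: true loss time, true clearance time, true growth rate,
#' rfp concentration, arrest time, feature-effect flag) sufficient to
#' predict every analysis output in closed form at zero noise. Output
#' is bit-reproducible under the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @return A [lineage_tree()] with the ground truth in `$truth`.
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_lineages
  # injected loss times
  rfp_conc <- spec$rfp_mean * exp(stats::rnorm(n, 0, spec$rfp_cv) -
                                    spec$rfp_cv^2 / 2)
  plt <- rep(NA_real_, n)
  if (is.numeric(spec$loss)) {
    plt <- rep_len(as.numeric(spec$loss), n)
  } else if (identical(spec$loss, "rfp")) {
    # hazard h(t) = rfp_hazard * rfp * t  (cumulative exposure grows
    # linearly), so T = sqrt(2 E / (rfp_hazard * rfp)), E ~ Exp(1)
    plt <- sqrt(2 * stats::rexp(n) / (spec$rfp_hazard * rfp_conc))
    plt[plt > spec$t_total] <- NA_real_
  } else if (!is.null(spec$loss)) {
    stop("'loss' must be NULL, a numeric schedule, or \"rfp\"")
  }
  arrest <- rep(NA_real_, n)
  if (!is.null(spec$growth_arrest))
    arrest <- rep_len(as.numeric(spec$growth_arrest), n)
  is_loss <- !is.na(plt)
  gamma <- spec$growth_rate * (1 + ifelse(is_loss, spec$feature_effect, 0)) *
    exp(stats::rnorm(n, 0, spec$growth_cv) - spec$growth_cv^2 / 2)

  frames <- seq(0, spec$t_total, by = spec$frame_interval)
  cells_l <- list(); series_l <- list()
  next_id <- 1L
  for (j in seq_len(n)) {
    lin <- .fixture_lineage(spec, j, gamma[j], plt[j], arrest[j],
                            rfp_conc[j], frames, next_id)
    cells_l[[j]] <- lin$cells
    series_l[[j]] <- lin$series
    next_id <- lin$next_id
  }
  truth <- data.frame(
    lineage = seq_len(n),
    root_cell = vapply(cells_l, function(d) d$cell[1L], numeric(1)),
    leaf_cell = vapply(cells_l, function(d) d$cell[nrow(d)], numeric(1)),
    true_plt = plt, true_ct = ifelse(is_loss, spec$ct, NA_real_),
    growth_rate = gamma, rfp_conc = rfp_conc, arrest = arrest,
    has_effect = is_loss & spec$feature_effect != 0)
  lineage_tree(do.call(rbind, cells_l), do.call(rbind, series_l),
               truth = truth)
}

# one mother-machine chain: divisions at div_size, one daughter followed
.fixture_lineage <- function(spec, j, gamma, plt, arrest, rfp_conc,
                             frames, next_id) {
  t_gen <- log(2) / gamma
  phase <- stats::runif(1)
  # division times; growth (and divisions) stop at arrest
  first_div <- (1 - phase) * t_gen
  divs <- if (first_div > spec$t_total) numeric(0) else
    seq(first_div, spec$t_total, by = t_gen)
  if (!is.na(arrest)) divs <- divs[divs < arrest]
  bounds <- c(0, divs, spec$t_total)
  ids <- next_id + seq_len(length(bounds) - 1L) - 1L
  cells <- data.frame(
    cell = ids,
    parent = c(NA_integer_, ids[-length(ids)]),
    t_birth = bounds[-length(bounds)],
    t_div = c(divs, NA_real_))
  # the first observed cell is mid-cycle at t = 0 (age phase * t_gen)
  l_birth0 <- spec$div_size * exp(-gamma * (1 - phase) * t_gen)

  prod_rate <- function(t) {
    if (is.na(plt)) return(rep(spec$plateau, length(t)))
    p <- rep(spec$plateau, length(t))
    if (spec$ct > 0) {
      ramp <- t > plt - spec$ct & t < plt
      p[ramp] <- spec$plateau * (plt - t[ramp]) / spec$ct
    }
    p[t >= plt] <- 0
    p
  }
  # integrate dF/dt = prod - bleach*F on a fine grid, halving at divisions
  dt_f <- spec$frame_interval / 5
  tg <- sort(unique(c(seq(0, spec$t_total, by = dt_f), frames, divs)))
  f <- numeric(length(tg))
  # cyclo-stationary start (bleach-free): birth total p*t_gen, plus age
  f[1] <- spec$plateau * t_gen * (1 + phase)
  for (k in 2:length(tg)) {
    h <- tg[k] - tg[k - 1]
    p_mid <- prod_rate((tg[k] + tg[k - 1]) / 2)
    f[k] <- f[k - 1] * exp(-spec$bleach_rate * h) +
      p_mid * (if (spec$bleach_rate > 0)
        (1 - exp(-spec$bleach_rate * h)) / spec$bleach_rate else h)
    if (any(abs(divs - tg[k]) < 1e-9)) f[k] <- f[k] / 2
  }
  fi <- stats::approxfun(tg, f, method = "linear")

  cidx <- pmin(pmax(findInterval(frames, bounds,
                                 rightmost.closed = TRUE), 1L),
               length(ids))
  tb <- cells$t_birth[cidx]
  len <- numeric(length(frames))
  for (k in seq_along(frames)) {
    t <- frames[k]
    tbk <- tb[k]
    lb <- if (cidx[k] == 1L) l_birth0 else spec$div_size / 2
    tcap <- if (!is.na(arrest)) min(t, arrest) else t
    len[k] <- lb * exp(gamma * max(tcap - tbk, 0))
  }
  yfp <- fi(frames)
  if (spec$noise > 0)
    yfp <- yfp * (1 + stats::rnorm(length(yfp), 0, spec$noise))
  series <- data.frame(cell = ids[cidx], time = frames, length = len,
                       yfp = yfp, rfp = rfp_conc * len)
  list(cells = cells, series = series, next_id = next_id + length(ids))
}

#' Matched null and effect cohorts for calibration
#'
#' Two fixtures identical in structure: in the null cohort, loss
#' lineages are a random subset with no feature-loss coupling; in the
#' effect cohort, loss lineages additionally carry the requested
#' fractional growth-rate offset. Used to calibrate the false-positive
#' rate and power of the ranking/binomial procedure.
#'
#' @param spec A [fixture_spec()] whose `loss` field gives the loss
#'   schedule.
#' @param effect Fractional growth-rate offset of the effect cohort.
#' @return List with `null` and `effect` lineage trees.
#' @export
generate_null_and_effect_cohorts <- function(spec, effect = 0.2) {
  stopifnot(inherits(spec, "fixture_spec"))
  sp0 <- spec
  sp0$feature_effect <- 0
  sp1 <- spec
  sp1$feature_effect <- effect
  list(null = generate_tree(sp0), effect = generate_tree(sp1))
}
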