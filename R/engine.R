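#' Engine configuration for the agent-based population simulator
#'
#' @param n_cells Constant population size (the experimental default is
#'   100 cells).
#' @param t_final Simulated duration (min; default 1e4).
#' @param lookahead Extrande look-ahead horizon (min). `NULL` uses the
#'   time to the next division, the natural horizon of the
#'   first-division scheduling loop.
#' @param seed Optional integer seed applied before a run.
#' @param record_interval Interval (min) at which per-cell time series
#'   are recorded; 0 disables series recording (outcome-only runs, in
#'   which cleared lineages are frozen for speed).
#' @param stop_when_cleared Stop a run early once every lineage has lost
#'   its targets (exact for loss statistics, since zero targets is
#'   absorbing).
#' @param headroom Multiplicative safety factor of the thinning bound
#'   over the current total propensity.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(n_cells = 100, t_final = 1e4, lookahead = NULL,
                          seed = NULL, record_interval = 0,
                          stop_when_cleared = TRUE, headroom = 1.5) {
  stopifnot(n_cells >= 1, t_final > 0, record_interval >= 0, headroom >= 1)
  structure(list(n_cells = as.integer(n_cells), t_final = t_final,
                 lookahead = lookahead, seed = seed,
                 record_interval = record_interval,
                 stop_when_cleared = stop_when_cleared,
                 headroom = headroom),
            class = "engine_config")
}

#' Initialise a desynchronised population
#'
#' Draws `n_cells` cells with lognormal growth rates and division sizes
#' and a uniformly distributed cell-cycle phase: the age of each cell is
#' a uniform fraction of its own generation time, which desynchronises
#' the population without admitting negative ages. Birth size is the
#' mean division ratio times the division size. All cells start with
#' identical molecule counts.
#'
#' @param growth A [growth_params()] object.
#' @param config An [engine_config()] object.
#' @param system A [build_system()] reaction system providing the
#'   initial molecule counts and array state.
#' @return An object of class `abm_population`: a list with a `cells`
#'   data frame (id, growth rate, birth/division size, generation time,
#'   age), a `state` count matrix and an `astar` array-state vector.
#' @export
initialize_population <- function(growth = growth_params(),
                                  config = engine_config(),
                                  system = build_system()) {
  n <- config$n_cells
  mu <- stats::rlnorm(n, growth$mu_meanlog, growth$mu_sdlog)
  vd <- stats::rlnorm(n, growth$vd_meanlog, growth$vd_sdlog)
  vb <- growth$mu_vr * vd
  t_gen <- log(vd / vb) / mu
  age <- stats::runif(n) * t_gen
  state <- matrix(rep(as.numeric(system$init_state), each = n), nrow = n,
                  dimnames = list(NULL, names(system$init_state)))
  structure(list(
    cells = data.frame(id = seq_len(n), parent = NA_integer_, mu = mu,
                       v_birth = vb, v_div = vd, t_gen = t_gen, age = age),
    state = state,
    astar = rep(system$init_astar, n)),
    class = "abm_population")
}

#' Next dividing cell and scheduling step
#'
#' Returns the index of the cell with the least remaining time to
#' division (lowest index wins ties) and the scheduling step, capped by
#' the look-ahead horizon.
#'
#' @param population An [initialize_population()] object.
#' @param lookahead Horizon cap (min); `Inf` for none.
#' @return List with `index`, `dt`, and `divides` (whether the step ends
#'   in the division of that cell or at the horizon).
#' @export
next_division <- function(population, lookahead = Inf) {
  stopifnot(inherits(population, "abm_population"))
  rem <- population$cells$t_gen - population$cells$age
  j <- which.min(rem)  # first minimum: deterministic lowest-id tie-break
  dt <- min(rem[j], lookahead)
  list(index = j, dt = dt, divides = rem[j] <= lookahead)
}

#' Divide a cell into two daughters
#'
#' Daughter 1 receives a Normal division-ratio fraction of the mother's
#' division size (redrawn outside (0.1, 0.9)); daughter 2 the remainder.
#' Free proteins are split binomially with probability equal to the
#' daughter size fraction; targets and target-containing complexes are
#' split by a stochastically rounded multivariate hypergeometric scheme
#' so each daughter receives on average half. Both daughters inherit the
#' mother's CRISPR array state and draw fresh growth rate, division size
#' and generation time. All counts are conserved.
#'
#' @param mother A list with `state` (named counts), `astar`, `v_div`.
#' @param growth A [growth_params()] object.
#' @return List of two daughters, each with `state`, `astar`,
#'   `v_birth`, `v_div`, `mu`, `t_gen`.
#' @export
divide_cell <- function(mother, growth = growth_params()) {
  r1 <- .draw_ratio(growth)
  vb1 <- r1 * mother$v_div
  vb2 <- mother$v_div - vb1
  st <- mother$state
  d1 <- stats::setNames(numeric(length(st)), names(st))
  protein <- c("C", "R", "Rs", "E", "Es", "F", "Y")
  d1[protein] <- stats::rbinom(length(protein), st[protein], r1)
  tg <- c("P", "EP", "EsP")
  d1[tg] <- .partition_targets(st[tg], r1)
  d2 <- st - d1
  mk <- function(vb, state) {
    mu <- stats::rlnorm(1, growth$mu_meanlog, growth$mu_sdlog)
    vd <- stats::rlnorm(1, growth$vd_meanlog, growth$vd_sdlog)
    guard <- 0
    while (vd <= vb * 1.05 && (guard <- guard + 1) < 100)
      vd <- stats::rlnorm(1, growth$vd_meanlog, growth$vd_sdlog)
    if (vd <= vb * 1.05) vd <- vb * 2
    list(state = state, astar = mother$astar, v_birth = vb, v_div = vd,
         mu = mu, t_gen = log(vd / vb) / mu)
  }
  list(mk(vb1, d1), mk(vb2, d2))
}

.draw_ratio <- function(growth) {
  for (i in 1:1000) {
    r <- stats::rnorm(1, growth$mu_vr, growth$sigma_vr)
    if (r > 0.1 && r < 0.9) return(r)
  }
  growth$mu_vr
}

# daughter-1 share of the target-containing entities: total K is the
# stochastically rounded fraction r1 of the pool, species identities by
# sequential hypergeometric draws (= multivariate hypergeometric)
.partition_targets <- function(pools, r1) {
  ntot <- sum(pools)
  if (ntot == 0) return(pools * 0)
  kf <- ntot * r1
  K <- floor(kf) + (stats::runif(1) < kf - floor(kf))
  K <- min(K, ntot)
  out <- pools * 0
  left <- K
  remaining <- ntot
  for (i in seq_along(pools)) {
    if (left == 0) break
    if (i == length(pools)) { out[i] <- left; break }
    out[i] <- stats::rhyper(1, pools[i], remaining - pools[i], left)
    left <- left - out[i]
    remaining <- remaining - pools[i]
  }
  out
}

#' Remove a uniformly random cell after a division
#'
#' The removal pool contains all cells, including both newborn
#' daughters; the removed cell's pending division disappears with it.
#'
#' @param population An `abm_population` of size N + 1.
#' @return The population reduced to size N, with attribute `"removed"`
#'   holding the removed row.
#' @export
cull_random <- function(population) {
  stopifnot(inherits(population, "abm_population"))
  n <- nrow(population$cells)
  i <- sample.int(n, 1)
  removed <- population$cells[i, ]
  population$cells <- population$cells[-i, , drop = FALSE]
  population$state <- population$state[-i, , drop = FALSE]
  population$astar <- population$astar[-i]
  attr(population, "removed") <- removed
  population
}

#' Generic reaction system with time-varying propensities
#'
#' A minimal container for testing and for processes outside the CRISPR
#' network: a propensity function `a(state, t)` returning one rate per
#' channel, a stoichiometry matrix (species x channels), and a bound
#' function `B(state, t, dt)` that must dominate the total propensity
#' over `[t, t + dt]`.
#'
#' @param propensity Function `(state, t) -> numeric vector`.
#' @param stoich Integer matrix, species in rows, channels in columns.
#' @param bound Function `(state, t, dt) -> scalar upper bound` on the
#'   total propensity over the window.
#' @return An object of class `generic_reaction_system`.
#' @export
generic_reaction_system <- function(propensity, stoich, bound) {
  stopifnot(is.function(propensity), is.matrix(stoich), is.function(bound))
  structure(list(propensity = propensity, stoich = stoich, bound = bound),
            class = "generic_reaction_system")
}

#' Advance a cell's chemistry by exact thinning (Extrande step)
#'
#' Samples the inhomogeneous jump process exactly over a window of
#' length `dt`: candidate events are generated at the bound rate B and
#' accepted with probability a0(t)/B; a violated bound (total propensity
#' above B) aborts with an error, since it indicates a mis-specified
#' bound. For a [generic_reaction_system()] the propensities may depend
#' on time; for the CRISPR [build_system()] network the propensities are
#' state-only and the bound is the current total times the configured
#' headroom.
#'
#' @param state Named (CRISPR) or plain numeric state vector.
#' @param dt Window length (min).
#' @param system A [build_system()] or [generic_reaction_system()]
#'   object.
#' @param t0 Absolute window start time.
#' @param astar Array state (CRISPR system only).
#' @param headroom Bound headroom for the CRISPR system.
#' @param max_events Guard on candidate events per call.
#' @return List with the updated `state`, the number of accepted events
#'   `n_events`, per-channel counts `counts`, and for the CRISPR system
#'   the updated `astar` and any `t_adapt`/`t_loss` event times.
#' @export
extrande_advance <- function(state, dt, system, t0 = 0, astar = 0L,
                             headroom = 1.5, max_events = 1e7) {
  stopifnot(dt >= 0)
  if (inherits(system, "reaction_system")) {
    res <- cpp_advance_cell(as.numeric(state), as.integer(astar), t0, dt,
                            unclass(system$rates), headroom, max_events)
    res$state <- stats::setNames(res$state, crispr_species())
    names(res$counts) <- crispr_reactions()
    return(res)
  }
  if (!inherits(system, "generic_reaction_system"))
    stop("'system' must be a reaction_system or generic_reaction_system")
  t <- t0; t_end <- t0 + dt
  counts <- integer(ncol(system$stoich))
  times <- numeric(0)
  n_acc <- 0L; n_iter <- 0L
  done <- FALSE
  repeat {
    B <- system$bound(state, t, t_end - t)
    if (B <= 0) break
    repeat {
      n_iter <- n_iter + 1L
      if (n_iter > max_events)
        stop("runaway event rate: more than ", max_events,
             " candidate events in one advance step")
      t <- t + stats::rexp(1, B)
      if (t >= t_end) { done <- TRUE; break }
      a <- system$propensity(state, t)
      a0 <- sum(a)
      if (a0 > B * (1 + 1e-9))
        stop("propensity bound violated: a0 = ", a0, " > B = ", B,
             " at t = ", t)
      u <- stats::runif(1, 0, B)
      if (u <= a0) {
        ch <- findInterval(u, cumsum(a), left.open = TRUE) + 1L
        state <- state + system$stoich[, ch]
        counts[ch] <- counts[ch] + 1L
        n_acc <- n_acc + 1L
        times <- c(times, t)
        break  # propensities changed with the state
      }
    }
    if (done) break
  }
  list(state = state, n_events = n_acc, counts = counts, times = times)
}

#' Run the agent-based population simulation
#'
#' The full first-division loop: advance every cell's chemistry to the
#' next division (or recording point), divide the mother into two
#' daughters with stochastic partitioning, remove a uniformly random
#' cell to keep the population size constant, and repeat until
#' `t_final`. Runs are bit-reproducible under a fixed seed.
#'
#' @param system A [build_system()] reaction system.
#' @param growth A [growth_params()] object.
#' @param config An [engine_config()] object.
#' @param init Optional pre-built [initialize_population()]; drawn
#'   internally when `NULL`.
#' @return An object of class `abm_run`: cells table (lineage tree with
#'   parent links and fates), loss events, key-event log, per-cell
#'   reaction firing counts, optional recorded series, and the final
#'   population state.
#' @seealso [record_outcomes()], [run_ensemble()]
#' @export
run_population <- function(system = build_system(),
                           growth = growth_params(),
                           config = engine_config(), init = NULL) {
  stopifnot(inherits(system, "reaction_system"),
            inherits(growth, "growth_params"),
            inherits(config, "engine_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(init)) init <- initialize_population(growth, config, system)
  cl <- init$cells
  res <- cpp_simulate(init$state, as.integer(init$astar), cl$mu,
                      cl$v_birth, cl$v_div, cl$age,
                      unclass(system$rates), unclass(growth),
                      config$t_final, config$record_interval,
                      config$stop_when_cleared,
                      config$record_interval <= 0, config$headroom,
                      1e8)
  cells <- res$cells
  cells$fate <- c("alive", "divided", "culled")[cells$fate + 1L]
  counts <- res$counts
  colnames(counts) <- crispr_reactions()
  series <- NULL
  if (!is.null(res$series) && length(res$series)) {
    series <- as.data.frame(res$series$data, stringsAsFactors = FALSE)
  }
  final <- res$final_state
  colnames(final) <- crispr_species()
  structure(list(cells = cells, losses = res$losses, events = res$events,
                 counts = counts, series = series,
                 final_state = final, final_cell = res$final_cell,
                 final_astar = res$final_astar, final_age = res$final_age,
                 t_end = res$t_end, system = system, growth = growth,
                 config = config),
            class = "abm_run")
}

#' @export
print.abm_run <- function(x, ...) {
  cat(sprintf("Agent-based run: %d cells, simulated to t = %.0f min (%s)\n",
              x$config$n_cells, x$t_end, x$system$condition))
  cat(sprintf("  %d cells created, %d divisions, %d loss events\n",
              nrow(x$cells), sum(x$cells$fate == "divided"),
              nrow(x$losses)))
  invisible(x)
}

#' Per-lineage outcome records of a run
#'
#' For every lineage that reached zero targets: the loss time (first
#' time the lineage's total target count, free plus effector-bound, hit
#' zero), the ancestry-inclusive adaptation time (first spacer
#' integration anywhere in the lineage), and the loss pathway --
#' `"primed"` when an integration preceded the loss, otherwise
#' `"low-level"` (clearance through low-level interference and/or
#' unequal partitioning, without acquisition). Lineages still carrying
#' targets at the end of the run are reported censored.
#'
#' @param run An [run_population()] result.
#' @return A list with `losses` (data frame: cell, t_loss, t_adapt,
#'   pathway), the number of `censored` lineages, and the run end time.
#' @export
record_outcomes <- function(run) {
  stopifnot(inherits(run, "abm_run"))
  ls <- run$losses
  ls$pathway <- ifelse(is.na(ls$t_adapt), "low-level", "primed")
  censored <- sum(rowSums(run$final_state[, c("P", "EP", "EsP"),
                                          drop = FALSE]) > 0)
  list(losses = ls, censored = censored, t_end = run$t_end)
}
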