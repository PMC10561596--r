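#' Null probability of a loss event in an unrelated cell
#'
#' Recursive probability that at least one of `length(c_i)` loss
#' events, the i-th of which occurred while `c_i` unrelated cells still
#' carried the plasmid, would fall in one given unrelated cell:
#' p_0 = 0, p_i = (1 - p_{i-1}) / c_i + p_{i-1}.
#'
#' @param c_i Integer vector: number of plasmid-bearing cells at each
#'   loss event (all >= 1); may be empty (probability 0).
#' @return The null probability p_n in [0, 1].
#' @export
related_loss_probability <- function(c_i) {
  if (length(c_i) == 0) return(0)
  stopifnot(is.numeric(c_i))
  if (any(c_i < 1)) stop("all c_i must be at least 1")
  p <- 0
  for (ci in c_i) p <- (1 - p) / ci + p
  p
}

#' Exact Poisson-binomial tail test
#'
#' Exact distribution of the number of successes among independent
#' Bernoulli trials with individual probabilities, by dynamic-
#' programming convolution; returns the upper tail probability
#' P(X >= observed).
#'
#' @param probs Per-trial success probabilities in [0, 1] (e.g. the
#'   per-pair null probabilities from [related_loss_probability()]).
#' @param observed Observed number of successes, in 0..length(probs).
#' @return The tail probability.
#' @export
poisson_binomial_test <- function(probs, observed) {
  stopifnot(all(probs >= 0 & probs <= 1))
  n <- length(probs)
  if (observed < 0 || observed > n)
    stop("'observed' must lie in 0..", n)
  pmf <- c(1, numeric(n))
  for (p in probs)
    pmf <- c(pmf, 0)[1:(n + 1)] * (1 - p) + c(0, pmf[1:n]) * p
  sum(pmf[(observed + 1):(n + 1)])
}

#' Cell-cycle fraction of loss events
#'
#' Places each loss event at its relative position in the cell cycle,
#' (PLT - birth) / (division - birth), binned into `n_bins` equal
#' intervals.
#'
#' @param events Loss events (cell, plt).
#' @param tree A [lineage_tree()]; the loss cells must have known birth
#'   and division times.
#' @param n_bins Number of equal cell-cycle bins.
#' @return Data frame (cell, plt, fraction, bin).
#' @export
cell_cycle_fraction <- function(events, tree, n_bins = 5) {
  cells <- tree$cells
  i <- match(events$cell, cells$cell)
  tb <- cells$t_birth[i]
  td <- cells$t_div[i]
  if (any(is.na(td)))
    stop("loss cells without a recorded division time: ",
         paste(events$cell[is.na(td)], collapse = ", "))
  frac <- (events$plt - tb) / (td - tb)
  if (any(frac < 0 | frac > 1))
    stop("loss events outside the cell cycle of their cell")
  bin <- pmin(floor(frac * n_bins) + 1L, n_bins)
  data.frame(cell = events$cell, plt = events$plt, fraction = frac,
             bin = bin)
}

#' Percentile ranks of loss lineages in a lookback window
#'
#' For each loss event, a cell feature is averaged over a lookback
#' window before the loss ([plt - t2, plt - t1]) along the loss
#' lineage, and ranked as a percentile among the window averages of all
#' concurrent non-loss lineages (paths without a loss up to that time
#' with data in the same absolute window). Percentiles use the
#' strictly-below fraction with midranks for ties, so identical values
#' everywhere rank at exactly 50.
#'
#' @param tree A [lineage_tree()].
#' @param events Loss events (cell, plt).
#' @param feature Per-frame feature values: data frame (cell, time,
#'   value) -- e.g. the `frames` component of [growth_features()]
#'   renamed, or sizes or concentrations on the frame grid.
#' @param lookback Numeric `c(t1, t2)`, t2 > t1 >= 0: window from t2 to
#'   t1 minutes before the loss.
#' @return List with `ranks` (one percentile per usable loss event),
#'   `median_rank`, and the per-event detail table.
#' @export
rank_loss_lineages <- function(tree, events, feature,
                               lookback = c(0, 30)) {
  stopifnot(length(lookback) == 2, lookback[2] > lookback[1])
  if (!all(c("cell", "time", "value") %in% names(feature)))
    stop("'feature' needs columns cell, time, value")
  paths <- lineage_paths(tree)
  key <- paste(feature$cell, feature$time)
  path_avg <- function(path, lo, hi) {
    ps <- path_series(tree, path)
    sel <- ps$time >= lo & ps$time <= hi
    if (!any(sel)) return(NA_real_)
    v <- feature$value[match(paste(ps$cell[sel], ps$time[sel]), key)]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  # leaves of paths containing a loss event at or before a given time
  loss_cells <- events$cell
  ranks <- numeric(0)
  detail <- list()
  for (e in seq_len(nrow(events))) {
    t_loss <- events$plt[e]
    lo <- t_loss - lookback[2]
    hi <- t_loss - lookback[1]
    own <- path_avg(.path_through(tree, events$cell[e]), lo, hi)
    if (is.na(own)) next
    comp <- numeric(0)
    for (p in paths) {
      ev_on <- events$plt[events$cell %in% p]
      if (any(ev_on <= t_loss)) next  # a loss lineage, not a comparator
      av <- path_avg(p, lo, hi)
      if (!is.na(av)) comp <- c(comp, av)
    }
    if (!length(comp)) {
      warning("loss event in cell ", events$cell[e],
              " has no concurrent non-loss lineage; skipped")
      next
    }
    r <- 100 * (sum(comp < own) + 0.5 * sum(comp == own)) / length(comp)
    ranks <- c(ranks, r)
    detail[[length(detail) + 1L]] <-
      data.frame(cell = events$cell[e], plt = t_loss, average = own,
                 n_comparators = length(comp), rank = r)
  }
  list(ranks = ranks,
       median_rank = stats::median(ranks),
       detail = do.call(rbind, detail))
}

#' Two-sided exact binomial test of the median rank
#'
#' Tests whether percentile ranks deviate from the 50th percentile:
#' counts ranks above versus below 50 (ties at exactly 50 are dropped)
#' and applies the exact two-sided binomial test with success
#' probability 1/2.
#'
#' @param ranks Percentile ranks (at least 5).
#' @return The two-sided p-value.
#' @export
binomial_median_test <- function(ranks) {
  stopifnot(length(ranks) >= 5)
  above <- sum(ranks > 50)
  below <- sum(ranks < 50)
  if (above + below == 0)
    stop("all ranks tie at exactly 50; the test is undefined")
  stats::binom.test(above, above + below, p = 0.5,
                    alternative = "two.sided")$p.value
}

#' Cumulative Cascade search effort of a lineage
#'
#' The trapezoid integral of a channel's fluorescence concentration
#' (total fluorescence / length) along a lineage path from induction up
#' to a time point, ancestry included -- the total search hours spent
#' by the surveillance complexes of that lineage.
#'
#' @param tree A [lineage_tree()].
#' @param channel Channel column name.
#' @param up_to Upper integration limit (min).
#' @param paths Optional list of paths (defaults to all root-to-leaf
#'   paths).
#' @return Named numeric vector of integrals (a.u. min), one per path.
#' @export
cascade_search_hours <- function(tree, channel, up_to = Inf,
                                 paths = lineage_paths(tree)) {
  stopifnot(channel %in% tree_channels(tree))
  vapply(paths, function(p) {
    ps <- path_series(tree, p)
    sel <- ps$time <= up_to
    if (sum(sel) < 2) return(0)
    t <- ps$time[sel]
    conc <- ps[[channel]][sel] / ps$length[sel]
    sum(diff(t) * (conc[-1] + conc[-length(conc)]) / 2)
  }, numeric(1))
}

#' Correlation of loss time with cumulative Cascade exposure over time
#'
#' At regular time points from induction, the Pearson correlation
#' between the plasmid loss time of each loss lineage and its
#' cumulative Cascade concentration integral up to that time point,
#' with a 95% Fisher-transform confidence interval and the t-test
#' p-value for r != 0. Lineages that have already lost by a time point
#' stop contributing there; time points with fewer than `min_n`
#' lineages give no estimate.
#'
#' @param tree A [lineage_tree()].
#' @param events Loss events (cell, plt) (at least 10).
#' @param channel Channel column name (Cascade reporter).
#' @param interval Spacing of time points (min).
#' @param min_n Minimum lineages per estimate.
#' @return Data frame (time, n, r, lower, upper, p).
#' @export
plt_correlation_timecourse <- function(tree, events, channel,
                                       interval = 10, min_n = 4) {
  if (nrow(events) < 10)
    stop("at least 10 loss lineages are required")
  paths <- lapply(events$cell, function(id) .path_through(tree, id))
  times <- seq(0, max(events$plt), by = interval)
  out <- lapply(times, function(tt) {
    live <- events$plt >= tt
    if (sum(live) < min_n)
      return(data.frame(time = tt, n = sum(live), r = NA_real_,
                        lower = NA_real_, upper = NA_real_,
                        p = NA_real_))
    x <- cascade_search_hours(tree, channel, up_to = tt,
                              paths = paths[live])
    y <- events$plt[live]
    n <- length(y)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(time = tt, n = n, r = NA_real_,
                        lower = NA_real_, upper = NA_real_,
                        p = NA_real_))
    r <- stats::cor(x, y)
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    data.frame(time = tt, n = n, r = r,
               lower = tanh(z - 1.96 * se), upper = tanh(z + 1.96 * se),
               p = 2 * stats::pt(-abs(tstat), df = n - 2))
  })
  do.call(rbind, out)
}

#' Lineage autocorrelation function and decorrelation time
#'
#' Lagged autocorrelation of a per-frame feature along root-to-leaf
#' paths. Pairs of observations are weighted by 1 / (number of leaves
#' below the cell holding the later observation), so segments shared by
#' several paths are not double-counted. The decorrelation time is the
#' first lag at which the 95% band of the coefficient (based on the
#' effective number of pairs) includes zero.
#'
#' @param tree A [lineage_tree()].
#' @param feature Per-frame data frame (cell, time, value).
#' @param max_lag Largest lag, in frames.
#' @return List with `acf` (data frame: lag, lag_time, r, n_eff) and
#'   `decorrelation_time` (min; NA if never decorrelated within
#'   max_lag).
#' @export
autocorrelation_time <- function(tree, feature, max_lag = 20) {
  stopifnot(all(c("cell", "time", "value") %in% names(feature)))
  dt <- .frame_interval(tree)
  leafn <- .leaf_counts(tree)
  key <- paste(feature$cell, feature$time)
  mu <- mean(feature$value, na.rm = TRUE)
  s2 <- stats::var(feature$value, na.rm = TRUE)
  acc <- matrix(0, max_lag, 2)  # weighted sum of products, sum of weights
  for (p in lineage_paths(tree)) {
    ps <- path_series(tree, p)
    if (nrow(ps) < 2) next
    v <- feature$value[match(paste(ps$cell, ps$time), key)] - mu
    w <- 1 / leafn[as.character(ps$cell)]
    n <- length(v)
    for (L in seq_len(min(max_lag, n - 1))) {
      a <- v[1:(n - L)]; b <- v[(1 + L):n]
      wt <- w[(1 + L):n]
      ok <- !is.na(a) & !is.na(b)
      acc[L, 1] <- acc[L, 1] + sum(wt[ok] * a[ok] * b[ok])
      acc[L, 2] <- acc[L, 2] + sum(wt[ok])
    }
  }
  if (all(acc[, 2] == 0))
    stop("feature series too short for any lag")
  r <- ifelse(acc[, 2] > 0, acc[, 1] / (acc[, 2] * s2), NA_real_)
  n_eff <- acc[, 2]
  band <- 1.96 / sqrt(pmax(n_eff, 1))
  dec <- which(!is.na(r) & abs(r) <= band)
  list(acf = data.frame(lag = seq_len(max_lag),
                        lag_time = seq_len(max_lag) * dt, r = r,
                        n_eff = n_eff),
       decorrelation_time = if (length(dec)) dec[1] * dt else NA_real_)
}
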