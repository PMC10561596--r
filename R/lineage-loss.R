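#' Detect plasmid loss times from production-rate series
#'
#' Walks every root-to-leaf path and reports the first frame at which
#' the (already smoothed) production rate falls below the threshold;
#' the event is assigned to the cell in which the crossing happens, so
#' a loss inherited by both daughters is counted once. Paths that never
#' cross are censored.
#'
#' The threshold should be calibrated from plasmid-free cells, e.g. via
#' [loss_threshold()].
#'
#' @param tree A [lineage_tree()].
#' @param production Data frame from [production_rate()].
#' @param threshold Production-rate threshold (a.u./min).
#' @return Data frame of loss events (cell, plt) with one row per
#'   unique crossing, plus attribute `"censored"` holding the leaf ids
#'   of paths with no crossing.
#' @export
detect_plt <- function(tree, production, threshold) {
  stopifnot(inherits(tree, "lineage_tree"), is.numeric(threshold))
  key <- paste(production$cell, production$time)
  events <- list()
  censored <- integer(0)
  for (path in lineage_paths(tree)) {
    ps <- path_series(tree, path)
    pr <- production$production[match(paste(ps$cell, ps$time), key)]
    below <- which(!is.na(pr) & pr < threshold)
    if (!length(below)) {
      censored <- c(censored, path[length(path)])
    } else {
      i <- below[1L]
      events[[length(events) + 1L]] <-
        data.frame(cell = ps$cell[i], plt = ps$time[i])
    }
  }
  out <- unique(do.call(rbind, c(events,
                                 list(data.frame(cell = integer(0),
                                                 plt = numeric(0))))))
  rownames(out) <- NULL
  structure(out, censored = unique(censored))
}

#' Production-rate threshold from plasmid-free calibration cells
#'
#' An upper quantile of the production-rate distribution of cells known
#' to carry no plasmid (residual background production).
#'
#' @param production Data frame from [production_rate()] computed on
#'   plasmid-free lineages.
#' @param quantile Upper quantile used (default 99th percentile).
#' @return Threshold (a.u./min).
#' @export
loss_threshold <- function(production, quantile = 0.99) {
  stats::quantile(production$production, quantile, na.rm = TRUE,
                  names = FALSE)
}

#' Clearance-time estimate from PLT-aligned production trends
#'
#' Aligns the production-rate traces of all loss lineages at their
#' plasmid loss time, averages them on the common frame grid,
#' normalises the average trend by its pre-loss plateau, and returns
#' the duration from the onset of the decrease (last time the trend
#' exceeds `plateau_frac` of the plateau) to the PLT.
#'
#' @param tree A [lineage_tree()].
#' @param production Data frame from [production_rate()].
#' @param events Loss events from [detect_plt()] (or a ground-truth
#'   table with columns cell, plt).
#' @param plateau_frac Onset criterion: fraction of the plateau below
#'   which the trend is considered decreasing.
#' @param window_before Alignment window before the PLT (min).
#' @return List with `ct` (min), the aligned `trend` data frame
#'   (rel_time, mean_production, n), and the plateau value.
#' @export
estimate_ct <- function(tree, production, events, plateau_frac = 0.9,
                        window_before = 140) {
  if (nrow(events) < 10)
    stop("at least 10 loss lineages are required to estimate the ",
         "clearance time (got ", nrow(events), ")")
  dt <- .frame_interval(tree)
  grid <- seq(-ceiling(window_before / dt) * dt, 0, by = dt)
  key <- paste(production$cell, production$time)
  traces <- matrix(NA_real_, nrow(events), length(grid))
  for (e in seq_len(nrow(events))) {
    path <- .path_through(tree, events$cell[e])
    ps <- path_series(tree, path)
    pr <- production$production[match(paste(ps$cell, ps$time), key)]
    rel <- ps$time - events$plt[e]
    sel <- rel >= grid[1] - dt / 2 & rel <= dt / 2
    idx <- round((rel[sel] - grid[1]) / dt) + 1
    ok <- idx >= 1 & idx <= length(grid)
    traces[e, idx[ok]] <- pr[sel][ok]
  }
  trend <- colMeans(traces, na.rm = TRUE)
  n_at <- colSums(!is.na(traces))
  plateau <- stats::median(trend[seq_len(max(3, length(grid) %/% 3))],
                           na.rm = TRUE)
  above <- which(!is.na(trend) & trend >= plateau_frac * plateau)
  onset <- if (length(above)) grid[max(above)] else grid[1]
  list(ct = -onset,
       trend = data.frame(rel_time = grid, mean_production = trend,
                          n = n_at),
       plateau = plateau)
}

# root-to-leaf-wards path passing through a given cell: ancestry up to
# the root plus the cell itself (frames after the event are not needed
# upstream of the alignment window handling)
.path_through <- function(tree, id) {
  cells <- tree$cells
  path <- id
  repeat {
    p <- cells$parent[match(path[1L], cells$cell)]
    if (is.na(p)) break
    path <- c(p, path)
  }
  path
}

.frame_interval <- function(tree) {
  dt <- diff(sort(unique(tree$series$time)))
  stats::median(dt)
}

#' Exponential-decay fit of post-loss fluorescence concentration
#'
#' Least-squares fit of `conc ~ C0 * exp(-k * t)`. With strictly
#' positive data the fit is initialised from the log-linear regression
#' and refined by nonlinear least squares in linear space; with
#' non-positive values only the linear-space fit is used. A constant
#' series yields k = 0.
#'
#' @param time Frame times (min), typically measured from the PLT.
#' @param conc Fluorescence concentration values.
#' @return List with `rate` (1/min), `c0`, and `residual_norm`.
#' @export
fit_exponential_decay <- function(time, conc) {
  stopifnot(length(time) == length(conc), length(time) >= 5)
  t0 <- time - time[1L]
  if (all(conc > 0)) {
    lf <- stats::lm.fit(cbind(1, t0), log(conc))
    start <- c(exp(lf$coefficients[1L]), -lf$coefficients[2L])
  } else {
    start <- c(max(conc, 1e-12), 0.01)
  }
  obj <- function(p) sum((conc - p[1] * exp(-p[2] * t0))^2)
  opt <- stats::optim(unname(start), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  list(rate = unname(opt$par[2L]), c0 = unname(opt$par[1L]),
       residual_norm = sqrt(opt$value))
}
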