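#' Per-cell and per-frame growth features
#'
#' Per cell: the elongation rate from an exponential fit to the
#' recorded lengths (linear least squares on log length), the
#' interdivision time, and the mean size. Per frame: a sliding-window
#' elongation rate (local log-linear slope over `window` frames), used
#' by death filtering and by the ranking analyses.
#'
#' @param tree A [lineage_tree()].
#' @param window Sliding-window width in frames (odd; at least 3).
#' @return List with `cells` (cell, growth_rate, interdiv_time,
#'   mean_size) and `frames` (cell, time, growth_rate).
#' @export
growth_features <- function(tree, window = 5) {
  stopifnot(inherits(tree, "lineage_tree"), window >= 3)
  s <- tree$series
  if (any(s$length <= 0)) stop("non-positive lengths in fitted window")
  bycell <- split(seq_len(nrow(s)), s$cell)
  fit_rate <- function(t, l) {
    if (length(t) < 3) return(NA_real_)
    stats::coef(stats::lm.fit(cbind(1, t), log(l)))[2L]
  }
  cells <- tree$cells
  per_cell <- data.frame(
    cell = as.integer(names(bycell)),
    growth_rate = vapply(bycell, function(i)
      fit_rate(s$time[i], s$length[i]), numeric(1)),
    mean_size = vapply(bycell, function(i) mean(s$length[i]), numeric(1)))
  per_cell$interdiv_time <-
    (cells$t_div - cells$t_birth)[match(per_cell$cell, cells$cell)]
  half <- floor(window / 2)
  frames <- do.call(rbind, lapply(bycell, function(i) {
    t <- s$time[i]; l <- s$length[i]
    n <- length(i)
    gr <- rep(NA_real_, n)
    for (k in seq_len(n)) {
      lo <- max(1, k - half); hi <- min(n, k + half)
      if (hi - lo + 1 >= 3) gr[k] <- fit_rate(t[lo:hi], l[lo:hi])
    }
    data.frame(cell = s$cell[i], time = t, growth_rate = gr)
  }))
  rownames(frames) <- NULL
  list(cells = per_cell, frames = frames)
}

#' Mask post-death frames of arrested lineages
#'
#' Applies a moving-average filter to the per-frame elongation rate
#' along every root-to-leaf path; if the smoothed rate reaches zero (or
#' below) at some point and never recovers for the remainder of the
#' path, all later frames on that path are removed. Transient dips that
#' recover are kept.
#'
#' @param tree A [lineage_tree()].
#' @param window Moving-average window (frames) applied on top of the
#'   sliding-window rate.
#' @param threshold Growth-rate death threshold (1/min).
#' @return The tree with post-death frames (and fully masked cells)
#'   dropped.
#' @export
filter_dead <- function(tree, window = 5, threshold = 0) {
  stopifnot(inherits(tree, "lineage_tree"))
  gf <- growth_features(tree, window)$frames
  drop_keys <- character(0)
  for (path in lineage_paths(tree)) {
    ps <- path_series(tree, path)
    gr <- gf$growth_rate[match(paste(ps$cell, ps$time),
                               paste(gf$cell, gf$time))]
    sm <- .moving_average(gr, window)
    eps <- 1e-10  # slope of a numerically constant log-length series
    dead <- which(!is.na(sm) & sm <= threshold + eps)
    if (!length(dead)) next
    ok <- which(!is.na(sm) & sm > threshold + eps)
    last_ok <- if (length(ok)) max(ok) else 0L
    # terminal arrest: at or below threshold with no later recovery
    terminal <- dead[dead > last_ok]
    if (!length(terminal)) next
    i0 <- min(terminal)
    if (i0 < nrow(ps))
      drop_keys <- c(drop_keys,
                     paste(ps$cell[(i0 + 1):nrow(ps)],
                           ps$time[(i0 + 1):nrow(ps)]))
  }
  if (length(drop_keys)) {
    key <- paste(tree$series$cell, tree$series$time)
    tree$series <- tree$series[!(key %in% drop_keys), , drop = FALSE]
    kept <- unique(tree$series$cell)
    gone <- setdiff(tree$cells$cell, kept)
    # drop cells that lost all frames, and their (frameless) descendants
    tree$cells <- tree$cells[tree$cells$cell %in% kept, , drop = FALSE]
    tree$cells$parent[!(tree$cells$parent %in% tree$cells$cell)] <-
      NA_integer_
  }
  tree
}

.moving_average <- function(x, window) {
  n <- length(x)
  half <- floor(window / 2)
  out <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    lo <- max(1, k - half); hi <- min(n, k + half)
    v <- x[lo:hi]
    if (any(!is.na(v))) out[k] <- mean(v, na.rm = TRUE)
  }
  out
}

#' Fluorescence production rate per frame
#'
#' Estimates the reporter production rate from the total cellular
#' fluorescence of a channel as dF/dt + k_bleach * F, computed within
#' each cell by central differences and smoothed by a moving average.
#' Working on the total (rather than the concentration) removes the
#' growth-dilution term, so only photobleaching needs correcting.
#'
#' @param tree A [lineage_tree()].
#' @param channel Channel column name in the series table.
#' @param bleach_rate Photobleaching rate of the fluorophore (1/min).
#' @param window Moving-average window (frames); 1 disables smoothing.
#' @return Data frame (cell, time, production); cells with a single
#'   frame contribute no rows.
#' @export
production_rate <- function(tree, channel, bleach_rate = 0, window = 5) {
  stopifnot(inherits(tree, "lineage_tree"),
            channel %in% tree_channels(tree))
  s <- tree$series
  out <- lapply(split(seq_len(nrow(s)), s$cell), function(i) {
    if (length(i) < 2) return(NULL)
    t <- s$time[i]; f <- s[[channel]][i]
    n <- length(i)
    df <- numeric(n)
    df[1] <- (f[2] - f[1]) / (t[2] - t[1])
    df[n] <- (f[n] - f[n - 1]) / (t[n] - t[n - 1])
    if (n > 2)
      df[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    prod <- df + bleach_rate * f
    data.frame(cell = s$cell[i], time = t,
               production = .moving_average(prod, window))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
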