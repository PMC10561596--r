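#' Lineage tree of single-cell time-lapse records
#'
#' The common container for segmentation-style single-cell data: a
#' `cells` table with one row per cell (id, parent id, birth and
#' division times) and a `series` table of per-frame records (time, cell
#' length, and one column of total fluorescence per channel). Both the
#' agent-based simulator and the synthetic fixture generator emit this
#' schema.
#'
#' @param cells Data frame with columns `cell`, `parent` (NA for
#'   roots), `t_birth`, `t_div` (NA while undivided).
#' @param series Data frame with columns `cell`, `time`, `length`, plus
#'   any number of numeric channel columns (total fluorescence, a.u.).
#' @param truth Optional ground-truth table carried along by fixtures.
#' @param tol Tolerance for the birth-time/division-time consistency
#'   check (min).
#' @return An object of class `lineage_tree`.
#' @export
lineage_tree <- function(cells, series, truth = NULL, tol = 1e-6) {
  need_c <- c("cell", "parent", "t_birth", "t_div")
  need_s <- c("cell", "time", "length")
  if (!all(need_c %in% names(cells)))
    stop("'cells' must have columns ", paste(need_c, collapse = ", "))
  if (!all(need_s %in% names(series)))
    stop("'series' must have columns ", paste(need_s, collapse = ", "))
  if (anyDuplicated(cells$cell)) stop("duplicated cell ids")
  known <- cells$cell
  par <- cells$parent
  orphan <- !is.na(par) & !(par %in% known)
  if (any(orphan))
    stop("orphan cells (parent not in table): ",
         paste(cells$cell[orphan], collapse = ", "))
  idx <- match(par, known)
  bad <- !is.na(par) & abs(cells$t_birth - cells$t_div[idx]) > tol
  if (any(bad, na.rm = TRUE))
    stop("cells born away from their mother's division time: ",
         paste(cells$cell[which(bad)], collapse = ", "))
  if (any(series$length <= 0, na.rm = TRUE))
    stop("non-positive cell lengths in series")
  ord <- order(series$cell, series$time)
  series <- series[ord, , drop = FALSE]
  dup <- stats::ave(series$time, series$cell,
                    FUN = function(t) c(1, diff(t)))
  if (any(dup <= 0))
    stop("frame times must be strictly increasing within each cell")
  rownames(cells) <- rownames(series) <- NULL
  structure(list(cells = cells, series = series, truth = truth),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  ch <- tree_channels(x)
  cat(sprintf("Lineage tree: %d cells (%d roots), %d frames%s\n",
              nrow(x$cells), sum(is.na(x$cells$parent)), nrow(x$series),
              if (length(ch)) paste0(", channels: ",
                                     paste(ch, collapse = ", ")) else ""))
  if (!is.null(x$truth)) cat("  ground-truth table attached\n")
  invisible(x)
}

#' Fluorescence channels of a lineage tree
#' @param tree A [lineage_tree()].
#' @return Character vector of channel column names.
#' @export
tree_channels <- function(tree) {
  setdiff(names(tree$series), c("cell", "time", "length", "area"))
}

#' Root-to-leaf paths of a lineage tree
#'
#' @param tree A [lineage_tree()].
#' @return Named list, one integer vector of cell ids per leaf, ordered
#'   root first.
#' @export
lineage_paths <- function(tree) {
  cells <- tree$cells
  leaves <- cells$cell[!(cells$cell %in% cells$parent)]
  up <- function(id) {
    path <- id
    repeat {
      p <- cells$parent[match(path[1L], cells$cell)]
      if (is.na(p)) break
      path <- c(p, path)
    }
    path
  }
  out <- lapply(leaves, up)
  names(out) <- as.character(leaves)
  out
}

#' Per-frame series along a lineage path
#'
#' Concatenates the frames of the cells on one root-to-leaf path in
#' time order.
#'
#' @param tree A [lineage_tree()].
#' @param path Integer vector of cell ids (root first), e.g. one
#'   element of [lineage_paths()].
#' @return The `series` rows of those cells, ordered by time.
#' @export
path_series <- function(tree, path) {
  s <- tree$series[tree$series$cell %in% path, , drop = FALSE]
  s[order(s$time), , drop = FALSE]
}

# number of leaves below each cell (own leaf counts as 1)
.leaf_counts <- function(tree) {
  cells <- tree$cells
  n <- stats::setNames(rep(0L, nrow(cells)), cells$cell)
  leaves <- cells$cell[!(cells$cell %in% cells$parent)]
  for (lf in leaves) {
    id <- lf
    repeat {
      n[as.character(id)] <- n[as.character(id)] + 1L
      id <- cells$parent[match(id, cells$cell)]
      if (is.na(id)) break
    }
  }
  n
}

#' Convert an agent-based run into a lineage tree
#'
#' Maps the simulator's recorded per-cell series (requires a positive
#' `record_interval`) to the analysis container, with the reporter
#' count as a fluorescence channel (`yfp`, arbitrary units per
#' molecule) and the total Cascade protein as a second channel (`rfp`).
#'
#' @param run An [run_population()] result with recorded series.
#' @return A [lineage_tree()].
#' @export
as_lineage_tree <- function(run) {
  stopifnot(inherits(run, "abm_run"))
  if (is.null(run$series))
    stop("run has no recorded series; rerun with record_interval > 0")
  s <- run$series
  cells <- data.frame(cell = run$cells$cell, parent = run$cells$parent,
                      t_birth = run$cells$t_birth,
                      t_div = ifelse(run$cells$fate == "divided",
                                     run$cells$t_end, NA_real_))
  series <- data.frame(cell = s$cell, time = s$time, length = s$size,
                       yfp = s$Y,
                       rfp = s$C + s$E + s$Es + s$EP + s$EsP)
  keep <- series$cell %in% cells$cell
  lineage_tree(cells, series[keep, , drop = FALSE])
}
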