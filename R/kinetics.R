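#' Kinetic rate parameters of the CRISPR-Cas reaction network
#'
#' Rates of the per-cell reaction network: bursty Cascade expression,
#' crRNA synthesis and decay, effector assembly, PAM-dependent target
#' binding, Cas3-mediated target destruction producing pre-spacer
#' fragments, fragment decay and spacer integration, logistic target
#' maintenance, and a fluorescent reporter expressed from the target.
#'
#' Cascade proteins are produced in geometrically distributed bursts at
#' rate `k1 / a` with mean burst size `a * b_c`, so the variability
#' factor `a` changes expression noise while conserving the mean
#' production flux `k1 * b_c`. Effectors carrying the original spacer
#' bind a mutated-PAM target at `k_on_low`; effectors carrying a newly
#' acquired (consensus-PAM) spacer bind `fold_consensus` times faster.
#' Targets are maintained by logistic replication toward the set point
#' `p_s`. Defaults were calibrated so that the steady-state Cascade
#' level is about 500 molecules per cell, direct-interference clearance
#' takes on the order of 1.5-3 h, and the priming loss-time distribution
#' is at least fivefold broader (squared coefficient of variation) than
#' the direct-interference one.
#'
#' @param k1 Cascade burst initiation rate (1/min).
#' @param b_c Mean geometric burst size (molecules).
#' @param a Variability factor: burst size is multiplied by `a`, burst
#'   rate divided by `a`.
#' @param k_r crRNA production rate per array spacer (1/min).
#' @param d_r Free-crRNA decay rate (1/min).
#' @param k_a Effector assembly rate (1/(molecule min)).
#' @param k_on_low Mutated-PAM target binding rate (1/(molecule min)).
#' @param fold_consensus Consensus-PAM affinity multiplier; binding to a
#'   consensus PAM is reported to be 100-150-fold stronger than to a
#'   mutated one.
#' @param k_deg Cas3 destruction rate of a bound target (1/min).
#' @param n_f Pre-spacer fragments produced per destroyed target.
#' @param d_f Fragment decay rate (1/min).
#' @param k_int Spacer integration rate per fragment (1/min).
#' @param k_rep Target replication rate (1/min).
#' @param p_s Target copy-number set point.
#' @param k_y Reporter production rate per free target (1/min).
#' @return An object of class `rate_params`.
#' @export
rate_params <- function(k1 = 2.5, b_c = 2, a = 1,
                        k_r = 3, d_r = 0.2,
                        k_a = 0.01,
                        k_on_low = 1e-5, fold_consensus = 150,
                        k_deg = 1, n_f = 3, d_f = 0.5, k_int = 0.008,
                        k_rep = 0.3, p_s = 5, k_y = 0.5) {
  vals <- list(k1 = k1, b_c = b_c, a = a, k_r = k_r, d_r = d_r, k_a = k_a,
               k_on_low = k_on_low, fold_consensus = fold_consensus,
               k_deg = k_deg, n_f = as.integer(n_f), d_f = d_f,
               k_int = k_int, k_rep = k_rep, p_s = p_s, k_y = k_y)
  num <- unlist(vals)
  if (any(num < 0)) stop("all rate parameters must be nonnegative")
  if (a < 1) stop("'a' must be at least 1")
  if (fold_consensus < 100 || fold_consensus > 150)
    stop("'fold_consensus' must lie in [100, 150], the reported range ",
         "of the consensus-vs-mutated PAM affinity ratio")
  structure(vals, class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("CRISPR-Cas kinetic rate parameters\n")
  cat(sprintf("  Cascade bursts: rate %g/min x mean size %g (a = %g)\n",
              x$k1 / x$a, x$a * x$b_c, x$a))
  cat(sprintf("  binding: mutated PAM %g, consensus %g /(molecule min)\n",
              x$k_on_low, x$fold_consensus * x$k_on_low))
  cat(sprintf("  destruction %g/min -> %d fragments (decay %g/min), integration %g/min\n",
              x$k_deg, x$n_f, x$d_f, x$k_int))
  cat(sprintf("  target maintenance: logistic, k_rep = %g/min, set point %g\n",
              x$k_rep, x$p_s))
  invisible(x)
}

#' Build the per-cell CRISPR-Cas reaction system
#'
#' Assembles the reaction network for one of the two experimental
#' conditions. Both conditions use the identical network; only the
#' initial CRISPR array differs. Under `"priming"` the array carries the
#' original spacer whose target PAM is mutated (low binding affinity),
#' so clearance requires primed acquisition of a consensus spacer. Under
#' `"direct"` the array starts in the expanded state, expressing the
#' consensus-PAM spacer from induction onward.
#'
#' The initial state has `p_s` targets (rounded), no Cascade or crRNA
#' (production is induced at t = 0), and the reporter at its
#' steady-state level `k_y * p_s / mu_p` so pre-clearance fluorescence
#' plateaus exist.
#'
#' @param rates A [rate_params()] object.
#' @param condition `"direct"` or `"priming"`.
#' @param growth A [growth_params()] object (used for the reporter
#'   steady state).
#' @return An object of class `reaction_system` with the rates, the
#'   condition, the initial species counts and the initial array state.
#' @export
build_system <- function(rates = rate_params(),
                         condition = c("priming", "direct"),
                         growth = growth_params()) {
  stopifnot(inherits(rates, "rate_params"))
  condition <- match.arg(condition)
  init <- stats::setNames(numeric(10), crispr_species())
  init["P"] <- round(rates$p_s)
  init["Y"] <- round(rates$k_y * init[["P"]] / growth$mu_p)
  structure(list(rates = rates, condition = condition,
                 init_state = init,
                 init_astar = if (condition == "direct") 1L else 0L),
            class = "reaction_system")
}

#' Species names of the CRISPR-Cas network
#'
#' `P` targets, `C` free Cascade, `R`/`Rs` free crRNAs (original / new
#' spacer), `E`/`Es` effector complexes, `EP`/`EsP` effector-target
#' complexes, `F` pre-spacer fragments, `Y` reporter molecules. The
#' CRISPR array state (original vs expanded) is carried per cell as a
#' 0/1 flag rather than as a species, which keeps the A + A* = 1
#' constraint structural.
#'
#' @return Character vector of species names in engine order.
#' @export
crispr_species <- function() {
  c("P", "C", "R", "Rs", "E", "Es", "EP", "EsP", "F", "Y")
}

#' @export
print.reaction_system <- function(x, ...) {
  cat(sprintf("CRISPR-Cas reaction system (%s condition)\n", x$condition))
  cat(sprintf("  initial array: %s\n",
              if (x$init_astar == 1L) "expanded (consensus spacer)"
              else "original (mutated-PAM spacer)"))
  cat("  initial counts: ",
      paste(names(x$init_state), x$init_state, sep = "=", collapse = " "),
      "\n", sep = "")
  print(x$rates)
  invisible(x)
}

#' Reaction channel labels of the engine
#'
#' Labels, in engine order, for the per-cell reaction firing counts
#' returned by [run_population()].
#'
#' @return Character vector of reaction labels.
#' @export
crispr_reactions <- function() {
  c("cascade_burst", "crRNA", "crRNA_new", "assembly_E", "assembly_Es",
    "bind_E", "bind_Es", "destroy_EP", "destroy_EsP", "decay_R",
    "decay_Rs", "decay_F", "integration", "replication", "reporter")
}
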