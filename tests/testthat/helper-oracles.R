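# Independent oracles used across the test files.

# trapezoid quadrature of f on [lo, hi] with a fixed step
trap_quad <- function(f, lo, hi, step = 0.01) {
  x <- seq(lo, hi, by = step)
  y <- f(x)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# plain direct-method (Gillespie) SSA for time-homogeneous propensities:
# reference implementation for comparing against the Extrande advance
ssa_direct <- function(state, t0, dt, propensity, stoich) {
  t <- t0; t_end <- t0 + dt
  times <- numeric(0)
  repeat {
    a <- propensity(state, t)
    a0 <- sum(a)
    if (a0 <= 0) break
    t <- t + stats::rexp(1, a0)
    if (t >= t_end) break
    ch <- sample.int(length(a), 1, prob = a)
    state <- state + stoich[, ch]
    times <- c(times, t)
  }
  list(state = state, times = times)
}

# exhaustive distribution of daughter-1 counts under the partitioning
# scheme used at division: K = floor(n r) + Bernoulli(frac), then a
# multivariate hypergeometric split of K among the pools
partition_pmf_zero <- function(pools, r) {
  # probability that daughter 1 receives zero entities overall is the
  # probability that K = 0
  ntot <- sum(pools)
  kf <- ntot * r
  if (floor(kf) > 0) 0 else 1 - (kf - floor(kf))
}

# exact hypergeometric probability that daughter 1 receives k of pool 1
partition_pmf_pool1 <- function(pools, r, k1) {
  ntot <- sum(pools)
  kf <- ntot * r
  Ks <- c(floor(kf), floor(kf) + 1)
  pK <- c(1 - (kf - floor(kf)), kf - floor(kf))
  keep <- Ks <= ntot & pK > 0
  sum(vapply(which(keep), function(i)
    pK[i] * stats::dhyper(k1, pools[1], ntot - pools[1], Ks[i]),
    numeric(1)))
}

# exhaustive Poisson-binomial tail probability by enumerating all 2^n
# outcomes (n <= 16)
pb_tail_enum <- function(probs, observed) {
  n <- length(probs)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) >= observed)
      total <- total + prod(ifelse(bits == 1, probs, 1 - probs))
  }
  total
}

# exhaustive two-sided binomial p-value for the sign test on ranks
sign_test_enum <- function(n_above, n) {
  pmf <- stats::dbinom(0:n, n, 0.5)
  sum(pmf[pmf <= pmf[n_above + 1] + 1e-12])
}

# build a single-chain lineage tree directly from vectors (one cell)
chain_tree <- function(time, length, channels = list()) {
  cells <- data.frame(cell = 1L, parent = NA_integer_, t_birth = time[1],
                      t_div = NA_real_)
  series <- data.frame(cell = 1L, time = time, length = length)
  for (nm in names(channels)) series[[nm]] <- channels[[nm]]
  lineage_tree(cells, series)
}
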