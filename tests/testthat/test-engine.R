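growth <- growth_params()

test_that("population initialisation draws the prescribed distributions", {
  set.seed(10)
  pop <- initialize_population(growth, engine_config(n_cells = 100),
                               build_system())
  expect_equal(nrow(pop$cells), 100L)
  expect_true(all(pop$cells$age >= 0 & pop$cells$age <= pop$cells$t_gen))
  expect_true(all(pop$state[, "P"] == 5))
  expect_equal(length(unique(pop$state[, "Y"])), 1L)
  # sigma_p = 0 collapses the growth-rate distribution
  set.seed(11)
  g0 <- growth_params(sigma_p = 0)
  pop0 <- initialize_population(g0, engine_config(n_cells = 20),
                                build_system())
  expect_equal(pop0$cells$mu, rep(g0$mu_p, 20))
  # Monte-Carlo moment check on 1e4 draws
  set.seed(12)
  big <- initialize_population(growth, engine_config(n_cells = 1e4),
                               build_system())
  expect_lt(abs(mean(big$cells$mu) / growth$mu_p - 1), 0.02)
  expect_lt(abs(mean(big$cells$v_div) / growth$mu_vd - 1), 0.02)
})

test_that("next dividing cell is the argmin with horizon capping and ties", {
  pop <- structure(list(cells = data.frame(
    id = 1:2, parent = NA, mu = 0.01, v_birth = 2, v_div = 4,
    t_gen = c(10, 12), age = c(5, 3))), class = "abm_population")
  nd <- next_division(pop)
  expect_equal(nd$index, 1L)
  expect_equal(nd$dt, 5)
  expect_true(nd$divides)
  capped <- next_division(pop, lookahead = 3)
  expect_equal(capped$dt, 3)
  # tie: deterministic lowest-index winner
  pop$cells$age <- c(5, 7)
  expect_equal(next_division(pop)$index, 1L)
})

test_that("division conserves every species and handles empty mothers", {
  set.seed(21)
  species <- crispr_species()
  for (i in 1:200) {
    st <- stats::setNames(stats::rpois(10, c(5, 300, 3, 1, 80, 40, 2, 1,
                                             4, 200)), species)
    mother <- list(state = st, astar = 1L, v_div = 3.9)
    ds <- divide_cell(mother, growth)
    expect_equal(ds[[1]]$state + ds[[2]]$state, st)
    expect_true(all(ds[[1]]$state >= 0) && all(ds[[2]]$state >= 0))
    expect_equal(ds[[1]]$astar, 1L)
    expect_equal(ds[[1]]$v_birth + ds[[2]]$v_birth, 3.9)
  }
  empty <- list(state = stats::setNames(numeric(10), species),
                astar = 0L, v_div = 3.9)
  ds <- divide_cell(empty, growth)
  expect_true(all(ds[[1]]$state == 0) && all(ds[[2]]$state == 0))
})

test_that("target partitioning matches the exact enumeration of the scheme", {
  set.seed(22)
  pools <- c(P = 5, EP = 0, EsP = 0)
  r <- 0.45
  n_rep <- 4e4
  d1 <- replicate(n_rep, crisprtime:::.partition_targets(pools, r)[1])
  # probability daughter 1 receives zero targets, exact from the
  # stochastic-rounding + hypergeometric construction
  p0_exact <- partition_pmf_zero(pools, r)
  expect_equal(p0_exact, 0)            # floor(5 * 0.45) = 2 > 0
  expect_equal(mean(d1 == 0), 0, tolerance = 1e-12)
  # full pmf of the daughter-1 count at a ratio where K is random
  r2 <- 0.1
  d2 <- replicate(n_rep, sum(crisprtime:::.partition_targets(pools, r2)))
  p0_2 <- partition_pmf_zero(pools, r2)   # K = 0 w.p. 0.5
  expect_lt(abs(mean(d2 == 0) - p0_2), 0.01)
  # mixed pools: pool-1 marginal matches the hypergeometric mixture
  pools3 <- c(P = 3, EP = 2, EsP = 1)
  d3 <- replicate(n_rep, crisprtime:::.partition_targets(pools3, 0.5)[1])
  for (k in 0:3)
    expect_lt(abs(mean(d3 == k) - partition_pmf_pool1(pools3, 0.5, k)),
              0.012)
  # on average half
  expect_equal(mean(d3), 1.5, tolerance = 0.02)
})

test_that("culling removes a uniformly random cell and its pending division", {
  set.seed(23)
  mk <- function() structure(list(
    cells = data.frame(id = 1:6, parent = NA, mu = 0.01, v_birth = 2,
                       v_div = 4, t_gen = 70, age = 1:6),
    state = matrix(0, 6, 10), astar = rep(0L, 6)),
    class = "abm_population")
  removed <- replicate(6000, attr(cull_random(mk()), "removed")$id)
  tab <- table(factor(removed, levels = 1:6))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  out <- cull_random(mk())
  expect_equal(nrow(out$cells), 5L)
  expect_false(attr(out, "removed")$id %in% out$cells$id)
})

test_that("thinning advance is exact for constant-rate production", {
  # single production channel at rate k: event count over dt must be
  # Poisson(k dt)
  set.seed(31)
  k <- 0.8; dt <- 6
  sys <- generic_reaction_system(
    propensity = function(state, t) k,
    stoich = matrix(1, 1, 1),
    bound = function(state, t, dt) 1.5 * k)
  counts <- replicate(4000, extrande_advance(0, dt, sys)$n_events)
  lam <- k * dt
  breaks <- c(-0.5, 0:11 + 0.5, Inf)
  obs <- table(cut(counts, breaks))
  pr <- diff(stats::ppois(c(-1, 0:11, Inf), lam))
  keep <- pr * length(counts) >= 5
  chi <- sum((obs[keep] - length(counts) * pr[keep])^2 /
               (length(counts) * pr[keep]))
  expect_gt(stats::pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.001)
  # zero propensity leaves the state untouched
  null_sys <- generic_reaction_system(
    propensity = function(state, t) 0,
    stoich = matrix(1, 1, 1),
    bound = function(state, t, dt) 0)
  expect_equal(extrande_advance(7, 100, null_sys)$state, 7)
})

test_that("thinning advance is exact for a linearly increasing hazard", {
  # inhomogeneous Poisson with a(t) = c t: the first-event time has
  # CDF 1 - exp(-c t^2 / 2)
  set.seed(32)
  cc <- 0.05
  sys <- generic_reaction_system(
    propensity = function(state, t) cc * t,
    stoich = matrix(1, 1, 1),
    bound = function(state, t, dt) cc * (t + dt))
  first_time <- replicate(3000, {
    r <- extrande_advance(0, 40, sys, t0 = 0)
    if (length(r$times)) r$times[1] else NA_real_
  })
  first_time <- first_time[!is.na(first_time)]
  ks <- suppressWarnings(
    stats::ks.test(first_time, function(q) -expm1(-cc * q^2 / 2)))
  expect_gt(ks$p.value, 0.001)
})

test_that("a violated propensity bound aborts", {
  sys <- generic_reaction_system(
    propensity = function(state, t) 10,
    stoich = matrix(1, 1, 1),
    bound = function(state, t, dt) 1)
  set.seed(33)
  expect_error(extrande_advance(0, 10, sys), "bound violated")
})

test_that("Extrande matches a direct-method SSA for homogeneous kinetics", {
  # immigration-death process: compare inter-event time distributions
  set.seed(34)
  k <- 3; g <- 0.05
  prop <- function(state, t) c(k, g * state)
  stoich <- matrix(c(1, -1), 1, 2)
  sys <- generic_reaction_system(
    propensity = prop, stoich = stoich,
    bound = function(state, t, dt) 1.5 * (k + g * (state + 200)))
  ext_times <- unlist(lapply(1:60, function(i)
    diff(extrande_advance(10, 60, sys)$times)))
  ssa_times <- unlist(lapply(1:60, function(i)
    diff(ssa_direct(10, 0, 60, prop, stoich)$times)))
  ks <- suppressWarnings(stats::ks.test(ext_times, ssa_times))
  expect_gt(ks$p.value, 0.001)
})

test_that("CRISPR-system advance conserves structure and handles silence", {
  rates <- rate_params(k1 = 0, k_r = 0, k_a = 0, k_on_low = 0, k_deg = 0,
                       d_r = 0, d_f = 0, k_int = 0, k_rep = 0, k_y = 0)
  sys <- build_system(rates, "priming")
  st <- sys$init_state
  out <- extrande_advance(st, 100, sys)
  expect_equal(out$state, st)
  expect_equal(out$n_events, 0)
  # production-only system: Poisson bursts of size 1
  set.seed(35)
  rates2 <- rate_params(k1 = 1, b_c = 1, k_r = 0, k_a = 0, k_on_low = 0,
                        k_deg = 0, d_r = 0, d_f = 0, k_int = 0,
                        k_rep = 0, k_y = 0)
  sys2 <- build_system(rates2, "priming")
  counts <- replicate(2000, {
    extrande_advance(sys2$init_state, 5, sys2)$state[["C"]]
  })
  expect_lt(abs(mean(counts) - 5), 0.2)
  expect_lt(abs(stats::var(counts) - 5), 0.5)
})

test_that("a reaction-free population keeps constant size and counts", {
  rates <- rate_params(k1 = 0, k_r = 0, k_a = 0, k_on_low = 0, k_deg = 0,
                       d_r = 0, d_f = 0, k_int = 0, k_rep = 0, k_y = 0)
  sys <- build_system(rates, "priming")
  sys$init_state["C"] <- 1000
  sys$init_state["P"] <- 7
  run <- run_population(sys, growth,
                        engine_config(n_cells = 50, t_final = 500,
                                      seed = 41, record_interval = 50,
                                      stop_when_cleared = FALSE))
  s <- run$series
  expect_true(all(table(s$time) == 50))
  # counts constant within each cell (no reactions)
  for (sp in c("C", "P"))
    expect_true(all(tapply(s[[sp]], s$cell,
                           function(x) length(unique(x))) == 1))
  # molecule conservation at division: sibling first-frame counts sum to
  # the mother's (constant) count
  cells <- run$cells
  sib <- split(cells$cell[!is.na(cells$parent)],
               cells$parent[!is.na(cells$parent)])
  checked <- 0
  for (p in names(sib)) {
    ids <- sib[[p]]
    if (length(ids) != 2) next
    if (!all(ids %in% s$cell) || !(as.integer(p) %in% s$cell)) next
    tot <- sapply(c(ids, as.integer(p)), function(id)
      s$C[s$cell == id][1])
    expect_equal(tot[1] + tot[2], tot[3])
    checked <- checked + 1
  }
  expect_gt(checked, 20)
})

test_that("interdivision times follow the growth model exactly when noiseless", {
  g0 <- growth_params(sigma_p = 0, sigma_vr = 0, sigma_vd = 0)
  rates <- rate_params(k1 = 0, k_r = 0, k_a = 0, k_on_low = 0, k_deg = 0,
                       d_r = 0, d_f = 0, k_int = 0, k_rep = 0, k_y = 0)
  run <- run_population(build_system(rates, "priming", g0), g0,
                        engine_config(n_cells = 20, t_final = 400,
                                      seed = 42,
                                      stop_when_cleared = FALSE))
  cells <- run$cells
  done <- cells$fate == "divided" & !is.na(cells$parent)
  tdiv <- cells$t_end[done] - cells$t_birth[done]
  expect_equal(tdiv, rep(log(2) / g0$mu_p, sum(done)), tolerance = 1e-9)
})

test_that("runs are bit-identical under a fixed seed", {
  cfg <- engine_config(n_cells = 30, t_final = 300, seed = 77)
  r1 <- run_population(build_system(condition = "priming"), growth, cfg)
  r2 <- run_population(build_system(condition = "priming"), growth, cfg)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$losses, r2$losses)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$final_state, r2$final_state)
})

test_that("the lineage forest of a run is structurally valid", {
  run <- run_population(build_system(condition = "direct"), growth,
                        engine_config(n_cells = 40, t_final = 400,
                                      seed = 55))
  cells <- run$cells
  kids <- !is.na(cells$parent)
  pi <- match(cells$parent[kids], cells$cell)
  expect_false(anyNA(pi))
  expect_true(all(cells$fate[pi] == "divided"))
  expect_equal(cells$t_birth[kids], cells$t_end[pi])
  expect_true(all(run$final_state >= 0))
})
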