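test_that("lineage trees validate their structural invariants", {
  cells <- data.frame(cell = 1:2, parent = c(NA, 1L),
                      t_birth = c(0, 50), t_div = c(50, NA))
  series <- data.frame(cell = c(1, 1, 2, 2), time = c(0, 25, 50, 75),
                       length = c(2, 3, 1.5, 2), yfp = 1)
  expect_s3_class(lineage_tree(cells, series), "lineage_tree")
  bad <- cells; bad$t_birth[2] <- 40  # born before mother's division
  expect_error(lineage_tree(bad, series), "division time")
  orf <- cells; orf$parent[2] <- 99L
  expect_error(lineage_tree(orf, series), "orphan")
  neg <- series; neg$length[1] <- -1
  expect_error(lineage_tree(cells, neg), "length")
  dup <- series; dup$time[2] <- 0
  expect_error(lineage_tree(cells, dup), "strictly increasing")
})

test_that("exponential growth rates are recovered exactly and noisily", {
  tt <- seq(0, 60, by = 3)
  gamma <- 0.0123
  tr <- chain_tree(tt, 2 * exp(gamma * tt), list(yfp = 1))
  gf <- growth_features(tr)
  expect_equal(gf$cells$growth_rate, gamma, tolerance = 1e-10)
  expect_equal(gf$frames$growth_rate[5], gamma, tolerance = 1e-10)
  # constant length has rate zero
  tc <- chain_tree(tt, rep(2, length(tt)), list(yfp = 1))
  expect_equal(growth_features(tc)$cells$growth_rate, 0,
               tolerance = 1e-12)
  # lognormal-noise fixture: recovery within the fixture tolerance
  fx <- generate_tree(fixture_spec(n_lineages = 20, seed = 2))
  g <- growth_features(fx)
  est <- g$cells$growth_rate[match(fx$truth$root_cell, g$cells$cell)]
  expect_lt(max(abs(est / fx$truth$growth_rate - 1), na.rm = TRUE), 1e-8)
})

test_that("death filtering truncates arrested lineages and only those", {
  sp <- fixture_spec(n_lineages = 8, t_total = 600,
                     growth_arrest = c(rep(NA, 4), rep(350, 4)), seed = 5)
  fx <- generate_tree(sp)
  fd <- filter_dead(fx)
  for (j in seq_len(8)) {
    ids <- fx$truth$root_cell[j]:fx$truth$leaf_cell[j]
    last <- max(fd$series$time[fd$series$cell %in% ids])
    if (is.na(fx$truth$arrest[j])) {
      expect_equal(last, 600)
    } else {
      expect_lt(abs(last - 350), 15 + 1e-9)  # within one window
    }
  }
  # a transient dip that recovers is kept in full
  tt <- seq(0, 300, by = 3)
  len <- exp(0.01 * tt)
  len[tt >= 99 & tt <= 129] <- len[tt == 99]
  len[tt > 129] <- len[tt == 129] * exp(0.01 * (tt[tt > 129] - 129))
  dip <- chain_tree(tt, len, list(yfp = 1))
  expect_equal(nrow(filter_dead(dip)$series), length(tt))
})

test_that("production rate has the right closed forms", {
  tt <- seq(0, 90, by = 3)
  flat <- chain_tree(tt, exp(0.01 * tt), list(yfp = rep(500, length(tt))))
  pr <- production_rate(flat, "yfp", bleach_rate = 0, window = 1)
  expect_equal(pr$production, rep(0, length(tt)), tolerance = 1e-12)
  # total F = F0 e^{g t} with zero bleaching: production = g F
  g <- 0.02
  gro <- chain_tree(tt, exp(0.01 * tt), list(yfp = 100 * exp(g * tt)))
  pg <- production_rate(gro, "yfp", window = 1)
  mid <- 5:25
  expect_equal(pg$production[mid], g * 100 * exp(g * tt[mid]),
               tolerance = 2e-3)
  # bleaching correction: constant F under bleaching k_b means
  # production k_b F
  pb <- production_rate(flat, "yfp", bleach_rate = 0.01, window = 1)
  expect_equal(pb$production, 0.01 * 500 + 0 * tt, tolerance = 1e-12)
  one <- chain_tree(c(0), c(2), list(yfp = 1))
  expect_null(production_rate(one, "yfp"))
})

test_that("loss detection recovers injected losses within one frame", {
  sp <- fixture_spec(n_lineages = 40, loss = c(rep(300, 20), rep(NA, 20)),
                     noise = 0, seed = 3)
  fx <- generate_tree(sp)
  pr <- production_rate(fx, "yfp")
  thr <- 0.05 * sp$plateau
  ev <- detect_plt(fx, pr, thr)
  expect_equal(nrow(ev), 20L)
  expect_equal(length(attr(ev, "censored")), 20L)
  # detection happens where the ramp crosses the threshold:
  # plt - ct * threshold/plateau, within one frame interval
  expected_cross <- 300 - sp$ct * thr / sp$plateau
  expect_true(all(abs(ev$plt - expected_cross) <= sp$frame_interval))
  # always-above production is censored
  ev0 <- detect_plt(fx, pr, -1)
  expect_equal(nrow(ev0), 0L)
  expect_equal(length(attr(ev0, "censored")), 40L)
})

test_that("clearance time is recovered from PLT-aligned average trends", {
  sp <- fixture_spec(n_lineages = 50, loss = 300, noise = 0, seed = 7)
  fx <- generate_tree(sp)
  pr <- production_rate(fx, "yfp")
  ev <- detect_plt(fx, pr, 0.05 * sp$plateau)
  est <- estimate_ct(fx, pr, ev)
  expect_lt(abs(est$ct - 60), 10)
  # invariant to the order of lineages
  ev_shuf <- ev[rev(seq_len(nrow(ev))), ]
  expect_equal(estimate_ct(fx, pr, ev_shuf)$ct, est$ct)
  # an instantaneous production drop yields an estimate within two
  # frame intervals
  spi <- fixture_spec(n_lineages = 30, loss = 300, ct = 0, noise = 0,
                      seed = 8)
  fxi <- generate_tree(spi)
  pri <- production_rate(fxi, "yfp", window = 1)
  evi <- detect_plt(fxi, pri, 0.05 * spi$plateau)
  esti <- estimate_ct(fxi, pri, evi)
  expect_lte(esti$ct, 2 * spi$frame_interval)
  expect_error(estimate_ct(fx, pr, ev[1:5, ]), "at least 10")
})

test_that("exponential decay fits recover rates to machine precision", {
  tt <- seq(0, 100, by = 5)
  f <- fit_exponential_decay(tt, 80 * exp(-0.035 * tt))
  expect_equal(f$rate, 0.035, tolerance = 1e-10)
  expect_lt(f$residual_norm, 1e-8)
  fc <- fit_exponential_decay(tt, rep(4, length(tt)))
  expect_equal(fc$rate, 0, tolerance = 1e-12)
  # fixture: concentration after loss decays at growth + bleaching
  sp <- fixture_spec(n_lineages = 6, loss = 200, t_total = 500,
                     bleach_rate = 0.004, noise = 0, growth_cv = 0,
                     seed = 9)
  fx <- generate_tree(sp)
  j <- 1
  ids <- fx$truth$root_cell[j]:fx$truth$leaf_cell[j]
  s <- fx$series[fx$series$cell %in% ids & fx$series$time > 210, ]
  conc <- s$yfp / s$length
  fit <- fit_exponential_decay(s$time - min(s$time), conc)
  expect_equal(fit$rate, sp$growth_rate + sp$bleach_rate,
               tolerance = 0.05)
})

test_that("the related-loss recursion matches hand computation and MC", {
  expect_equal(related_loss_probability(numeric(0)), 0)
  expect_equal(related_loss_probability(2), 0.5)
  expect_equal(related_loss_probability(c(4, 3)), 0.5)  # (1-1/4)/3 + 1/4
  expect_error(related_loss_probability(c(2, 0)), "at least 1")
  # nondecreasing in the number of events, bounded by 1
  set.seed(12)
  for (i in 1:20) {
    cs <- sample(1:8, 6, replace = TRUE)
    ps <- vapply(1:6, function(k) related_loss_probability(cs[1:k]),
                 numeric(1))
    expect_true(all(diff(ps) >= -1e-12))
    expect_true(all(ps <= 1))
  }
  # Monte-Carlo randomisation oracle: place each event uniformly among
  # the cells carrying the plasmid; P(a fixed cell hit at least once)
  set.seed(13)
  cs <- c(5, 3, 2)
  hit <- replicate(2e5, any(vapply(cs, function(ci)
    sample.int(ci, 1) == 1, logical(1))))
  expect_lt(abs(mean(hit) - related_loss_probability(cs)), 0.005)
})

test_that("the Poisson-binomial test is exact", {
  expect_equal(poisson_binomial_test(c(0.5, 0.5), 2), 0.25)
  expect_equal(poisson_binomial_test(rep(0, 4), 1), 0)
  expect_equal(poisson_binomial_test(rep(0.3, 3), 0), 1)
  set.seed(14)
  for (i in 1:5) {
    probs <- stats::runif(12)
    obs <- sample(0:12, 1)
    expect_equal(poisson_binomial_test(probs, obs),
                 pb_tail_enum(probs, obs), tolerance = 1e-12)
  }
  expect_error(poisson_binomial_test(c(0.2, 0.4), 3), "0..2")
})

test_that("cell-cycle fractions bin correctly and uniformly", {
  cells <- data.frame(cell = 1:3, parent = NA, t_birth = c(0, 0, 0),
                      t_div = c(100, 100, 100))
  series <- data.frame(cell = 1:3, time = 0, length = 2, yfp = 1)
  tr <- lineage_tree(cells, series)
  ev <- data.frame(cell = c(1, 2, 3), plt = c(0, 55, 100))
  cc <- cell_cycle_fraction(ev, tr, n_bins = 5)
  expect_equal(cc$bin, c(1L, 3L, 5L))
  expect_error(cell_cycle_fraction(data.frame(cell = 1, plt = 120), tr),
               "outside")
  # uniform losses spread uniformly over bins
  set.seed(15)
  cellsu <- data.frame(cell = 1:1000, parent = NA, t_birth = 0,
                       t_div = 100)
  seriesu <- data.frame(cell = 1:1000, time = 0, length = 2, yfp = 1)
  tru <- lineage_tree(cellsu, seriesu)
  evu <- data.frame(cell = 1:1000, plt = stats::runif(1000, 0, 100))
  tab <- table(cell_cycle_fraction(evu, tru)$bin)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("percentile ranking behaves at the boundaries", {
  # ten chains, constant feature values; loss lineage above all others
  cells <- data.frame(cell = 1:10, parent = NA, t_birth = 0,
                      t_div = NA_real_)
  tt <- seq(0, 100, by = 10)
  series <- do.call(rbind, lapply(1:10, function(i)
    data.frame(cell = i, time = tt, length = 2, yfp = 1)))
  tr <- lineage_tree(cells, series)
  feat <- do.call(rbind, lapply(1:10, function(i)
    data.frame(cell = i, time = tt, value = i)))
  ev <- data.frame(cell = 10L, plt = 80)
  rk <- rank_loss_lineages(tr, ev, feat, lookback = c(0, 30))
  expect_equal(rk$ranks, 100)
  # identical values everywhere rank at exactly 50 by midrank
  feat50 <- transform(feat, value = 1)
  expect_equal(rank_loss_lineages(tr, ev, feat50, c(0, 30))$ranks, 50)
})

test_that("feature-coupled cohorts are detected by rank + binomial test", {
  sp <- fixture_spec(n_lineages = 40, t_total = 400,
                     loss = c(seq(200, 320, length.out = 12), rep(NA, 28)),
                     seed = 7)
  co <- generate_null_and_effect_cohorts(sp, effect = 0.25)
  tr <- co$effect
  gf <- growth_features(tr)
  feat <- data.frame(cell = gf$frames$cell, time = gf$frames$time,
                     value = gf$frames$growth_rate)
  t_truth <- tr$truth[!is.na(tr$truth$true_plt), ]
  ev <- data.frame(cell = t_truth$leaf_cell, plt = t_truth$true_plt)
  rk <- rank_loss_lineages(tr, ev, feat, lookback = c(0, 30))
  expect_gt(rk$median_rank, 50)
  expect_lt(binomial_median_test(rk$ranks), 0.05)
})

test_that("the binomial median test matches closed forms and enumeration", {
  expect_equal(binomial_median_test(c(60, 70, 80, 90, 55, 65, 75, 85,
                                      95, 99)),
               2 * 0.5^10, tolerance = 1e-12)
  expect_equal(binomial_median_test(c(60, 70, 80, 90, 99, 40, 30, 20,
                                      10, 1)), 1)
  set.seed(16)
  for (i in 1:5) {
    n <- sample(5:12, 1)
    ranks <- stats::runif(n, 0, 100)
    expect_equal(binomial_median_test(ranks),
                 sign_test_enum(sum(ranks > 50), n), tolerance = 1e-12)
  }
  expect_error(binomial_median_test(rep(50, 6)), "tie")
  expect_error(binomial_median_test(c(60, 70)), "length")
})

test_that("search hours integrate concentration along ancestry", {
  tt <- seq(0, 100, by = 5)
  tr <- chain_tree(tt, rep(2, length(tt)),
                   list(rfp = rep(2 * 7, length(tt))))  # conc = 7
  sh <- cascade_search_hours(tr, "rfp", up_to = 100)
  expect_equal(unname(sh), 7 * 100, tolerance = 1e-10)
  # piecewise profile: hand-computed trapezoid
  conc <- ifelse(tt < 50, 3, 9)
  tr2 <- chain_tree(tt, rep(2, length(tt)), list(rfp = 2 * conc))
  sh2 <- cascade_search_hours(tr2, "rfp", up_to = 100)
  hand <- sum(diff(tt) * (conc[-1] + conc[-length(conc)]) / 2)
  expect_equal(unname(sh2), hand, tolerance = 1e-10)
  # burst vs constant with equal integral are equal
  burst <- ifelse(tt >= 20 & tt <= 40, 5 * 100 / 20, 0)
  flat <- rep(5, length(tt))
  tr3 <- chain_tree(tt, rep(2, length(tt)), list(rfp = 2 * burst))
  tr4 <- chain_tree(tt, rep(2, length(tt)), list(rfp = 2 * flat))
  s3 <- cascade_search_hours(tr3, "rfp", 100)
  s4 <- cascade_search_hours(tr4, "rfp", 100)
  expect_equal(unname(s3), unname(s4), tolerance = 0.3)
})

test_that("loss-time/search-hour correlations behave under null and effect", {
  # perfectly anticorrelated synthetic data
  n <- 20
  cells <- data.frame(cell = 1:n, parent = NA, t_birth = 0,
                      t_div = NA_real_)
  tt <- seq(0, 200, by = 10)
  conc <- seq(1, 4, length.out = n)
  series <- do.call(rbind, lapply(1:n, function(i)
    data.frame(cell = i, time = tt, length = 2, rfp = 2 * conc[i])))
  tr <- lineage_tree(cells, series)
  ev <- data.frame(cell = 1:n, plt = 200 - 40 * conc)
  pc <- plt_correlation_timecourse(tr, ev, "rfp", interval = 10)
  expect_equal(pc$r[pc$time == 20], -1, tolerance = 1e-10)
  expect_lt(pc$p[pc$time == 20], 1e-10)
  # independent data: |r| small for most seeds
  set.seed(17)
  hits <- replicate(40, {
    evr <- data.frame(cell = 1:n, plt = stats::runif(n, 50, 200))
    pcr <- plt_correlation_timecourse(tr, evr, "rfp", interval = 50)
    abs(pcr$r[pcr$time == 50])
  })
  expect_gt(mean(hits < 0.45, na.rm = TRUE), 0.9)
  # fixture with loss hazard increasing in cumulative concentration
  spc <- fixture_spec(n_lineages = 80, loss = "rfp", rfp_cv = 1,
                      rfp_hazard = 2e-6, t_total = 900, seed = 18)
  fxc <- generate_tree(spc)
  tc <- fxc$truth[!is.na(fxc$truth$true_plt), ]
  evc <- data.frame(cell = tc$leaf_cell, plt = tc$true_plt)
  pcc <- plt_correlation_timecourse(fxc, evc, "rfp", interval = 20)
  early <- pcc[pcc$time == 20, ]
  expect_lt(early$r, 0)
  expect_lt(early$p, 0.05)
})

test_that("autocorrelation times separate white noise from AR(1)", {
  set.seed(19)
  n_fr <- 100
  cells <- data.frame(cell = 1:4, parent = c(NA, 1, 2, 3),
                      t_birth = c(0, 100, 200, 300),
                      t_div = c(100, 200, 300, NA))
  tt <- seq(0, 399, by = 1)
  mk_tree <- function() lineage_tree(
    cells, data.frame(cell = rep(1:4, each = n_fr), time = tt,
                      length = 1, yfp = 0))
  tr <- mk_tree()
  white <- data.frame(cell = rep(1:4, each = n_fr), time = tt,
                      value = stats::rnorm(400))
  aw <- autocorrelation_time(tr, white, max_lag = 10)
  expect_lte(aw$decorrelation_time, 1)
  phi <- 0.8
  x <- as.numeric(stats::arima.sim(list(ar = phi), 400))
  ar1 <- data.frame(cell = rep(1:4, each = n_fr), time = tt, value = x)
  aa <- autocorrelation_time(tr, ar1, max_lag = 10)
  expect_lt(abs(aa$acf$r[1] - phi), 0.15)
  expect_gt(aa$decorrelation_time, 3)
  short <- lineage_tree(
    data.frame(cell = 1L, parent = NA_integer_, t_birth = 0,
               t_div = NA_real_),
    data.frame(cell = 1L, time = 0, length = 1, yfp = 0))
  expect_error(autocorrelation_time(
    short, data.frame(cell = 1L, time = 0, value = 1)), "lag")
})

test_that("simulated Cascade decorrelates more slowly than growth rate", {
  run <- run_population(build_system(condition = "priming"),
                        growth_params(),
                        engine_config(n_cells = 25, t_final = 1200,
                                      seed = 20, record_interval = 10,
                                      stop_when_cleared = FALSE))
  tr <- as_lineage_tree(run)
  sel <- tr$series$time >= 400  # past the induction transient
  conc <- data.frame(cell = tr$series$cell[sel],
                     time = tr$series$time[sel],
                     value = tr$series$rfp[sel] / tr$series$length[sel])
  ac_c <- autocorrelation_time(tr, conc, max_lag = 60)
  gf <- growth_features(tr)
  gsel <- gf$frames$time >= 400
  gr <- data.frame(cell = gf$frames$cell[gsel],
                   time = gf$frames$time[gsel],
                   value = gf$frames$growth_rate[gsel])
  ac_g <- autocorrelation_time(tr, gr, max_lag = 60)
  expect_gt(ac_c$decorrelation_time, ac_g$decorrelation_time)
})
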