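test_that("spike detection counts upward threshold crossings", {
  dt <- 0.05
  flat <- rep(-76, 2000)
  expect_length(detect_spikes(flat, dt = dt), 0)
  one <- c(rep(-76, 500), seq(-76, 30, length.out = 20),
           seq(30, -76, length.out = 20), rep(-76, 500))
  expect_length(detect_spikes(one, dt = dt), 1)
  ## threshold insensitivity on a spiking model trace
  r <- simulate(default_model(),
                sample_excitatory(default_morph(), 50, 30, sigma = 0,
                                  dt = 0, seed = 2),
                simulation_config(duration = 300))
  ## late intra-burst spikes of the reduced model peak only a few mV above
  ## zero, so the detection count is threshold-insensitive over -20..0 mV
  n0 <- length(detect_spikes(r$v[, "soma"], r$time, threshold = 0))
  expect_equal(length(detect_spikes(r$v[, "soma"], r$time, threshold = -20)), n0)
  expect_equal(length(detect_spikes(r$v[, "soma"], r$time, threshold = -10)), n0)
  expect_gte(n0, 1)
  ## model ISIs respect the 3 ms refractory floor
  if (n0 > 1) expect_gt(min(diff(r$spikes)), 3)
})

test_that("ISI grouping matches the stated rule and a brute-force oracle", {
  expect_equal(group_bursts(c(100, 104, 108, 300)),
               list(c(100, 104, 108), 300))
  expect_equal(spikes_per_burst(c(0, 30, 60, 90)), 1) # all ISIs > 20
  expect_equal(spikes_per_burst(numeric(0)), 0)
  ## oracle: transitive closure of the |dt| <= 20 relation on sorted times
  brute <- function(s, max_isi = 20) {
    if (!length(s)) return(list())
    grp <- cumsum(c(1, as.integer(diff(s) > max_isi)))
    unname(split(s, grp))
  }
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(0:12, 1)
    s <- sort(runif(n, 0, 400))
    s <- s[c(TRUE, diff(s) > 1e-6)]
    expect_identical(group_bursts(s), brute(s))
  }
})

test_that("intra-burst rate follows (n-1)/duration with 0 Hz singletons", {
  expect_equal(intra_burst_rate(c(100, 104, 108)), 250)
  expect_equal(intra_burst_rate(42), 0)
  expect_equal(intra_burst_rate(c(0, 20)), 50)
})

test_that("aggregate rate is the spike-count-weighted mean over all bursts", {
  trials <- list(c(100, 104, 108),   # 250 Hz, weight 3
                 c(50, 300),         # two singletons, 0 Hz, weight 1 each
                 c(10, 20))          # 100 Hz, weight 2
  expect_equal(aggregate_rate(trials),
               (250 * 3 + 0 + 0 + 100 * 2) / 7)
  expect_equal(aggregate_rate(trials, weighted = FALSE), (250 + 0 + 0 + 100) / 4)
  expect_equal(aggregate_rate(trials, bursts_only = TRUE),
               (250 * 3 + 100 * 2) / 5)
  expect_true(is.na(aggregate_rate(list(numeric(0)))))
})

test_that("burst statistics are invariant to time-shifting the train", {
  set.seed(5)
  for (i in 1:25) {
    s <- sort(runif(sample(2:9, 1), 0, 500))
    s <- s[c(TRUE, diff(s) > 1e-6)]
    sh <- s + runif(1, -40, 40)
    expect_equal(spikes_per_burst(s), spikes_per_burst(sh))
    expect_equal(burst_summary(s)$rates, burst_summary(sh)$rates,
                 tolerance = 1e-9)
  }
})

test_that("batch-mean SD reproduces the direct formula", {
  set.seed(8)
  x <- rnorm(200, 2, 0.7)
  direct <- sd(vapply(split(x, rep(1:10, each = 20)), mean, numeric(1)))
  expect_equal(batch_mean_sd(x, 10), direct)
  expect_true(is.na(batch_mean_sd(numeric(1))))
})

test_that("window metrics interpolate the 2-spikes/burst crossings", {
  dts <- c(-20, -15, -10, 0, 10, 20, 25, 30)
  vals <- c(1, 2, 2.5, 3, 2.5, 2.2, 2, 1)
  wm <- window_metrics(dts, vals)
  expect_equal(wm$width, 40)
  expect_equal(wm$center, 5)
  ## flat curve below the level
  expect_equal(window_metrics(dts, rep(1.5, 8))$width, 0)
  ## symmetric triangle is centered at its apex
  tri <- window_metrics(-5:5, 3 - abs(-5:5) * 0.4)
  expect_equal(tri$center, 0)
  ## disjoint super-level sets: the one holding the maximum wins
  two <- window_metrics(seq(-30, 30, by = 5),
                        c(1, 2.2, 2.2, 1, 1, 1, 1, 1, 1, 2.8, 2.8, 1, 1))
  expect_gt(two$center, 0)
})

test_that("burst-class rule reproduces the count boxes", {
  expect_equal(classify_regime(100, 100), "tuft-NMDA")
  expect_equal(classify_regime(200, 50), "coincidence")
  expect_equal(classify_regime(130, 110), "unassigned")
  expect_equal(classify_regime(c(0, 300, 130), c(60, 0, 110)),
               c("tuft-NMDA", "coincidence", "unassigned"))
})

test_that("CV and Fano follow their definitions", {
  expect_equal(cv_fano(rep(7, 10))$cv, 0)
  expect_equal(cv_fano(rep(7, 10))$fano, 0)
  expect_equal(cv_fano(c(10, 30))$cv, 0.5)
  set.seed(31)
  isi <- rexp(1e5, rate = 5 / 1000) # 5 Hz Poisson train
  expect_equal(cv_fano(isi)$cv, 1, tolerance = 0.01)
  expect_error(cv_fano(3), "at least 2")
})

test_that("irregular bursts (1.5-fold internal ISI spread) are flagged", {
  expect_true(burst_summary(c(100, 104, 110))$irregular)  # 4 vs 6 ms
  expect_false(burst_summary(c(100, 104, 108.5))$irregular)
  expect_false(burst_summary(c(100, 104))$irregular)      # single ISI
})
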