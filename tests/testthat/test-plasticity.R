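test_that("omega evaluates the two-sigmoid rule and its limits", {
  p <- plasticity_params()
  expect_equal(omega(0.10, p), 0.2500, tolerance = 5e-5)
  expect_equal(omega(1.0, p), 1.000, tolerance = 5e-4)
  expect_equal(omega(0.30, p), 0.25 + plogis(80 * (0.30 - 0.4)) -
                 0.25 * plogis(80 * (0.30 - 0.25)), tolerance = 1e-12)
  expect_lt(omega(0.30, p), 0.01) # LTD trough
  ## limits, asserted to 3 decimals at the stated concentrations
  expect_equal(omega(0.01, p), 0.25, tolerance = 5e-4)
  expect_equal(omega(2, p), 1, tolerance = 5e-4)
  ## bounded and numerically stable far out
  expect_true(all(is.finite(omega(c(0, 1e3), p))))
  expect_true(all(omega(seq(0, 5, by = 0.01), p) > 0 &
                    omega(seq(0, 5, by = 0.01), p) < 1.25))
})

test_that("the learning rate is silent at rest and saturating", {
  p <- plasticity_params()
  expect_lt(eta(0.05, p), 0.01 * p$eta_max)
  e <- eta(c(0.2, 0.4, 1.0), p)
  expect_true(all(diff(e) >= 0))
  expect_equal(eta(100, p), p$eta_max, tolerance = 1e-6)
  ## doubling eta_max doubles small weight changes (linearization)
  tr <- rep(0.3, 2000)
  d1 <- update_weight(tr, 1, plasticity_params(eta_max = 0.05),
                      dt = 0.025, repetitions = 1) - 1
  d2 <- update_weight(tr, 1, plasticity_params(eta_max = 0.1),
                      dt = 0.025, repetitions = 1) - 1
  expect_equal(d2 / d1, 2, tolerance = 0.02)
})

test_that("weight dynamics relax toward omega and protect at rest", {
  p <- plasticity_params()
  ## long constant-calcium exposure drives w to omega(ca)
  tr <- rep(0.8, 4e5)
  expect_equal(update_weight(tr, 1, p, dt = 0.025, repetitions = 10),
               omega(0.8, p), tolerance = 1e-3)
  ## resting calcium leaves the weight untouched
  expect_equal(update_weight(rep(0.05, 24000), 1, p, dt = 0.025,
                             repetitions = 1), 1, tolerance = 1e-3)
  expect_equal(update_weight(rep(0.05, 24000), 1, p, dt = 0.025), 1,
               tolerance = 5e-3)
  ## contraction: w stays inside the envelope spanned by w0 and omega
  set.seed(12)
  tr <- abs(0.4 + cumsum(rnorm(5000, 0, 0.01)))
  om <- omega(tr, p)
  w <- update_weight(tr, 1, p, dt = 0.025)
  expect_true(w >= min(1, min(om)) - 1e-9 && w <= max(1, max(om)) + 1e-9)
})

test_that("long supra-LTD time beats a brief supra-LTP excursion", {
  p <- plasticity_params()
  ## calcium sits in the depression band for 80 ms but peaks over theta_p
  ## for only 2 ms: net depression despite the suprathreshold maximum
  ca <- c(rep(0.32, 3200), rep(0.55, 80), rep(0.32, 3200), rep(0.05, 2000))
  w <- update_weight(ca, 1, p, dt = 0.025)
  expect_lt(w, 1)
  expect_gt(max(ca), p$theta_p)
})

test_that("repetition count converges (10 vs 20 within 5 %)", {
  set.seed(3)
  ca <- c(rep(0.05, 500), rep(0.7, 1500), seq(0.7, 0.05, length.out = 2000),
          rep(0.05, 1000))
  p <- plasticity_params()
  w10 <- update_weight(ca, 1, p, dt = 0.025, repetitions = 10)
  w20 <- update_weight(ca, 1, p, dt = 0.025, repetitions = 20)
  expect_lt(abs(w20 - w10) / w10, 0.05)
})

test_that("plasticity_map classifies outcomes and checks inputs", {
  p <- plasticity_params()
  traces <- cbind(rep(0.05, 4000),                  # protected
                  rep(0.31, 4000),                  # LTD band
                  c(rep(0.9, 2500), rep(0.05, 1500))) # LTP
  map <- plasticity_map(traces, path_dist = c(700, 900, 1100), p = p,
                        dt = 0.025)
  expect_equal(map$class, c("protected", "LTD", "LTP"))
  expect_equal(map$max_ca, c(0.05, 0.31, 0.9))
  expect_equal(map$t_above_theta_p, c(0, 0, 2500 * 0.025))
  ## all-zero calcium: flat protected profile at weight 1
  flat <- plasticity_map(matrix(0.05, 2000, 5), path_dist = 1:5 * 100, p = p)
  expect_true(all(flat$class == "protected"))
  expect_equal(flat$weight, rep(1, 5), tolerance = 1e-3)
  expect_error(plasticity_map(traces, path_dist = c(1, 2)), "per synapse")
})

test_that("raising theta_p monotonically shrinks the potentiated set", {
  set.seed(21)
  ## synapses with graded calcium exposure
  peaks <- seq(0.2, 1.2, length.out = 12)
  traces <- vapply(peaks, function(pk)
    c(rep(0.05, 500), rep(pk, 2500), rep(0.05, 1000)), numeric(4000))
  grid <- seq(0.25, 0.85, by = 0.1)
  sc <- theta_scan(traces, theta_p_grid = grid)
  n_ltp <- colSums(sc > log2(1.02))
  expect_true(all(diff(n_ltp) <= 0))
})
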