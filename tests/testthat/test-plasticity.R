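test_that("eligibility trace decays by the closed form without spikes", {
  e <- matrix(1, 3, 3)
  zero <- numeric(3)
  for (t in 1:50) {
    e <- update_eligibility(e, zero, zero, zero, zero, tau_e = 10, f = 1)
    expect_equal(e, matrix(0.9^t, 3, 3), tolerance = 1e-12)
  }
})

test_that("eligibility bracket matches exhaustive enumeration of spike combos", {
  for (f in c(1, 0.01)) {
    for (post_now in 0:1) for (post_prev in 0:1)
      for (pre_now in 0:1) for (pre_prev in 0:1) {
        e <- update_eligibility(matrix(0, 1, 1), post_now, post_prev,
                                pre_now, pre_prev, tau_e = 15, f = f)
        expect_equal(e[1, 1], post_now * pre_prev - f * post_prev * pre_now,
                     tolerance = 1e-12)
      }
  }
})

test_that("vectorized eligibility equals the double-loop oracle with a mask", {
  set.seed(31)
  for (rep in 1:20) {
    e <- matrix(stats::rnorm(20), 4, 5)
    mask <- matrix(stats::rbinom(20, 1, 0.5), 4, 5)
    e <- e * mask
    post_now <- as.numeric(stats::runif(4) < 0.5)
    post_prev <- as.numeric(stats::runif(4) < 0.5)
    pre_now <- as.numeric(stats::runif(5) < 0.5)
    pre_prev <- as.numeric(stats::runif(5) < 0.5)
    got <- update_eligibility(e, post_now, post_prev, pre_now, pre_prev,
                              tau_e = 7, f = 0.3, mask = mask)
    want <- naive_eligibility(e, post_now, post_prev, pre_now, pre_prev,
                              7, 0.3, mask = mask)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("reward update is the identity when the modulation factor is zero", {
  set.seed(8)
  w <- matrix(stats::runif(25), 5, 5)
  e <- matrix(stats::rnorm(25), 5, 5)
  expect_identical(apply_reward(w, e, m = 0, eta = 0.1), w)
})

test_that("reward update arithmetic and the weight floor", {
  w <- matrix(0.2, 1, 1); e <- matrix(0.5, 1, 1)
  expect_equal(apply_reward(w, e, m = 1, eta = 0.1)[1, 1], 0.25)
  e2 <- matrix(5, 1, 1)
  unclipped <- 0.2 + 0.1 * (-1) * 5
  expect_lt(unclipped, 0)
  expect_equal(apply_reward(w, e2, m = -1, eta = 0.1)[1, 1], max(unclipped, 0))
  # off-mask entries stay exactly zero
  w3 <- matrix(c(0.5, 0), 1, 2); e3 <- matrix(1, 1, 2)
  mask <- matrix(c(1, 0), 1, 2)
  expect_identical(apply_reward(w3, e3, m = 1, eta = 0.1, mask = mask)[1, 2], 0)
})

test_that("row normalization sums rows to one, keeps zero rows, is idempotent", {
  expect_equal(normalize_rows(matrix(c(1, 1, 2), 1, 3)),
               matrix(c(0.25, 0.25, 0.5), 1, 3))
  expect_equal(normalize_rows(matrix(c(0.2, 0.3, 0.5), 1, 3)),
               matrix(c(0.2, 0.3, 0.5), 1, 3), tolerance = 1e-15)
  set.seed(12)
  w <- matrix(stats::runif(2500), 50, 50)
  w[sample(50, 5), ] <- 0
  w1 <- normalize_rows(w)
  nz <- rowSums(w) > 0
  expect_equal(rowSums(w1)[nz], rep(1, sum(nz)), tolerance = 1e-12)
  expect_true(all(w1[!nz, ] == 0))
  expect_equal(normalize_rows(w1), w1, tolerance = 1e-12)
  expect_equal(w1, naive_normalize(w), tolerance = 1e-12)
  expect_error(normalize_rows(matrix(-1, 1, 1)), "negative")
})

test_that("intrinsic plasticity moves thresholds toward the target rate", {
  expect_equal(intrinsic_update(0, 1, 0.1, 0.001), 0.0009)
  expect_equal(intrinsic_update(0, 0, 0.1, 0.001), -0.0001)
  # silent neuron: threshold decreases; active neuron: threshold increases
  expect_lt(intrinsic_update(0.5, 0, 0.1, 0.001), 0.5)
  expect_gt(intrinsic_update(0.5, 1, 0.1, 0.001), 0.5)
})

test_that("long-run firing rate converges to mu_ip under noisy drive", {
  set.seed(21)
  mu <- 0.1; eta_ip <- 0.001
  theta <- 0.5
  steps <- 1e5
  fired <- logical(steps)
  psi <- stats::runif(steps)       # i.i.d. drive
  for (t in seq_len(steps)) {
    s <- as.numeric(psi[t] >= theta)
    fired[t] <- s == 1
    theta <- intrinsic_update(theta, s, mu, eta_ip)
  }
  rate <- mean(fired[(steps / 2 + 1):steps])
  expect_lt(abs(rate - mu), 0.02)
})

test_that("structural step prunes weak connections and respects degenerate p_sp", {
  mask <- matrix(0, 4, 4); mask[1, 2] <- 1; mask[3, 4] <- 1
  w <- matrix(0, 4, 4); w[1, 2] <- 1e-6; w[3, 4] <- 0.5
  out <- structural_step(mask, w, p_sp = 1e-12, w_th = 1e-4, w_new = 0.001)
  expect_identical(out$mask[1, 2], 0)
  expect_identical(out$w[1, 2], 0)
  expect_identical(out$mask[3, 4], 1)
  expect_identical(out$w[3, 4], 0.5)
  deaths <- out$events[out$events$kind == "death", ]
  expect_identical(nrow(deaths), 1L)
  expect_equal(deaths$w, 1e-6)
  expect_error(structural_step(mask, w, 0.1, w_th = 0.01, w_new = 0.001),
               "w_th")
})

test_that("birth counts follow the binomial law (99% CI over 200 seeds)", {
  n <- 100; p_sp <- 0.01
  mask <- matrix(0, n, n); w <- matrix(0, n, n)
  n_pairs <- n * (n - 1)
  births <- vapply(1:200, function(s) {
    set.seed(s)
    out <- structural_step(mask, w, p_sp, w_th = 1e-4, w_new = 0.001)
    sum(out$events$kind == "birth")
  }, numeric(1))
  expected <- p_sp * n_pairs
  se <- sqrt(p_sp * (1 - p_sp) * n_pairs / 200)
  expect_lt(abs(mean(births) - expected), 2.58 * se)
  # births land only on off-diagonal empty pairs
  set.seed(1)
  out <- structural_step(mask, w, p_sp, w_th = 1e-4, w_new = 0.001)
  b <- out$events[out$events$kind == "birth", ]
  expect_true(all(b$i != b$j))
  expect_true(all(out$w[cbind(b$i, b$j)] == 0.001))
})

test_that("after a structural step no existing connection is below threshold", {
  set.seed(77)
  mask <- matrix(stats::rbinom(400, 1, 0.3), 20, 20); diag(mask) <- 0
  w <- matrix(stats::runif(400, 0, 1e-3), 20, 20) * mask
  out <- structural_step(mask, w, p_sp = 0.05, w_th = 1e-4, w_new = 0.001)
  expect_true(all(out$w[out$mask == 1] >= 1e-4))
  expect_true(all(out$w[out$mask == 0] == 0))
})

test_that("baseline follows the exponential moving average closed form", {
  b <- 0.3
  for (t in 1:40) {
    b <- update_baseline(b, 1, alpha = 0.2)
    expect_equal(abs(b - 1), 0.8^t * 0.7, tolerance = 1e-9)
  }
  # alternating rewards, alpha = 1/2: 0.5, -0.25, 0.375, ...
  b <- 0
  b <- update_baseline(b, 1, 0.5);  expect_equal(b, 0.5)
  b <- update_baseline(b, -1, 0.5); expect_equal(b, -0.25)
  b <- update_baseline(b, 1, 0.5);  expect_equal(b, 0.375)
})

test_that("baseline long-run mean matches Bernoulli reward statistics", {
  set.seed(99)
  q <- 0.3; alpha <- 0.05
  b <- 0
  vals <- numeric(2e4)
  for (t in seq_along(vals)) {
    b <- update_baseline(b, stats::rbinom(1, 1, q), alpha)
    vals[t] <- b
  }
  sd_stat <- sqrt(alpha * q * (1 - q) / (2 - alpha))
  est <- mean(vals[10001:20000])
  expect_lt(abs(est - q), 3 * sd_stat)
})
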