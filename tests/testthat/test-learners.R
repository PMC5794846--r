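test_that("the first HGF trial from a neutral prior is maximally uncertain", {
  traj <- hgf3_filter(c(1L, 0L), hgf_params())
  expect_equal(traj$muhat1[1], 0.5)
  expect_equal(traj$unc1[1], 0.25)
  expect_equal(traj$surprise[1], log(2))
  traj0 <- hgf3_filter(c(0L, 1L), hgf_params())
  expect_equal(traj0$surprise[1], log(2))
})

test_that("one level-2 update step matches the worked example", {
  # mu2 = 0, sigma2 = 1, kappa*mu3 + omega2 = 0, u = 1:
  # v2 = 1, pihat2 = 1/2, pi2 = 3/4, update gain = 4/3
  core <- contextlearn:::.hgf3_core(1L, 0, 0, 1, 0, 1, 0, 1)
  expect_equal(core$mu2, 2 / 3, tolerance = 1e-12)
  expect_equal(core$sigma2, 4 / 3, tolerance = 1e-12)
  expect_equal(core$alpha2, 0.25 * 4 / 3, tolerance = 1e-12)
})

test_that("all four filters match independent single-step oracles", {
  set.seed(42)
  for (r in 1:20) {
    mu2 <- rnorm(1); s2 <- runif(1, 0.2, 2)
    mu3 <- rnorm(1); s3 <- runif(1, 0.2, 2)
    om2 <- runif(1, -5, -1); om3 <- runif(1, -8, -3)
    u <- rbinom(1, 1, 0.5)
    ora <- hgf3_step_oracle(u, mu2, s2, mu3, s3, om2, om3)
    got <- contextlearn:::.hgf3_core(u, om2, om3, 1, mu2, s2, mu3, s3)
    for (f in c("muhat1", "delta1", "surprise", "unc1", "unc2",
                "volatility", "mu2", "sigma2", "alpha2", "mu3", "sigma3",
                "alpha3"))
      expect_equal(got[[f]], ora[[f]], tolerance = 1e-12, label = f)

    ora2 <- hgf2_step_oracle(u, mu2, s2, om2)
    got2 <- contextlearn:::.hgf2_core(u, om2, mu2, s2)
    for (f in c("muhat1", "mu2", "sigma2", "unc2", "alpha2"))
      expect_equal(got2[[f]], ora2[[f]], tolerance = 1e-12, label = f)

    v <- runif(1, 0.05, 0.95); a <- runif(1, 0.05, 0.95)
    expect_equal(contextlearn:::.rw_core(c(u, 1L), a, v)$muhat1[2],
                 rw_step_oracle(u, v, a)$v, tolerance = 1e-12)

    b <- rnorm(1, -2); h <- rnorm(1, 0, 0.5); mm <- runif(1, 0.05, 1)
    oraK <- sk1_step_oracle(u, v, b, h, mm)
    gotK <- contextlearn:::.sk1_core(c(u, 1L), mm, v, b, h, 1e-6)
    expect_equal(gotK$lr[1], oraK$lr, tolerance = 1e-12)
    expect_equal(gotK$muhat1[2], oraK$v, tolerance = 1e-12)
  }
})

test_that("constant input drives beliefs monotonically towards certainty", {
  traj <- hgf3_filter(rep(1L, 200), hgf_params())
  expect_true(all(diff(traj$mu2) >= 0))
  expect_true(all(diff(traj$muhat1) >= 0))
  expect_gt(traj$muhat1[200], 0.95)
  expect_true(all(traj$sigma2 > 0) && all(traj$sigma3 > 0))
  expect_true(all(traj$muhat1 > 0 & traj$muhat1 < 1))
  expect_true(all(traj$alpha2 > 0 & traj$alpha2 <= 1))
})

test_that("the two-level filter is the frozen-volatility limit of the three-level one", {
  set.seed(9)
  u <- rbinom(200, 1, 0.7)
  h2 <- hgf2_filter(u, hgf_params(omega2 = -2.5))
  expect_false("alpha3" %in% names(h2))
  expect_false("volatility" %in% names(h2))
  # freeze level 3 at mu3 = 0 with a pinned prior: identical level-2 path
  h3 <- hgf3_filter(u, hgf_params(omega2 = -2.5, omega3 = -20,
                                  mu3_0 = 0, sigma3_0 = 1e-8))
  expect_lt(max(abs(h3$mu2 - h2$mu2)), 1e-6)
  expect_lt(max(abs(h3$alpha2 - h2$alpha2)), 1e-6)
})

test_that("learning rates rise with the volatility estimate, all else equal", {
  step_lo <- contextlearn:::.hgf3_core(1L, -3, -6, 1, 0.3, 0.5, 0.5, 1)
  step_hi <- contextlearn:::.hgf3_core(1L, -3, -6, 1, 0.3, 0.5, 2.0, 1)
  expect_gt(step_hi$alpha2, step_lo$alpha2)
})

test_that("volatile task phases raise the probability learning rate", {
  wins <- vapply(1:10, function(s) {
    sched <- generate_schedule(schedule_config(seed = 500 + s))
    tr <- hgf3_filter(sched$u, hgf_params(omega2 = -3, omega3 = -6))
    mean(tr$alpha2[sched$phase == "volatile"]) >
      mean(tr$alpha2[sched$phase == "stable"])
  }, logical(1))
  expect_true(all(wins))
})

test_that("Rescorla-Wagner follows the delta rule exactly", {
  r <- rw_filter(c(1L, 1L), rw_params(alpha_rw = 0.1, v0 = 0.5))
  expect_equal(r$muhat1, c(0.5, 0.55))
  # alpha = 1 tracks the input with a one-trial lag
  u <- c(1L, 0L, 0L, 1L, 1L)
  r1 <- rw_filter(u, rw_params(alpha_rw = 1, v0 = 0.5))
  expect_equal(r1$muhat1[-1], as.numeric(u[-length(u)]))
  # long-run mean prediction converges to the outcome rate
  set.seed(13)
  u_long <- rbinom(4000, 1, 0.84)
  rl <- rw_filter(u_long, rw_params(alpha_rw = 0.1))
  expect_lt(abs(mean(rl$muhat1[-(1:100)]) - 0.84), 0.02)
})

test_that("Sutton K1 adapts its gain after a contingency reversal", {
  s <- sk1_filter(c(1L, 0L), sk1_params(mu_meta = 0.5, h0 = 0, b0 = -2))
  expect_equal(s$lr[1], exp(-2))  # h0 = 0: first trial leaves the gain alone
  # the exponentiated gain is capped at 1
  s2 <- sk1_filter(c(1L,  1L), sk1_params(mu_meta = 0.5, b0 = 5, h0 = 1))
  expect_equal(s2$lr[1], 1)
  u_rev <- c(rep(1L, 50), rep(0L, 50))
  s3 <- sk1_filter(u_rev, sk1_params(mu_meta = 0.5))
  expect_gt(mean(s3$lr[51:100]), mean(s3$lr[1:50]))
})

test_that("trajectories are length-preserving, deterministic, and validated", {
  u <- rbinom(100, 1, 0.5)
  for (tr in list(hgf3_filter(u), hgf2_filter(u), rw_filter(u),
                  sk1_filter(u)))
    expect_equal(nrow(tr), 100L)
  expect_identical(as.data.frame(hgf3_filter(u)),
                   as.data.frame(hgf3_filter(u)))
  expect_error(hgf3_filter(c(1L, 2L)), "binary")
  expect_error(hgf3_filter(integer(0)), "non-empty")
  # numerically degenerate parameters raise a classed error with the trial
  err <- tryCatch(hgf3_filter(rbinom(300, 1, 0.5), hgf_params(omega2 = 2)),
                  trajectory_invalid = function(e) e)
  expect_s3_class(err, "trajectory_invalid")
  expect_true(is.numeric(err$trial) && err$trial >= 1)
})
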