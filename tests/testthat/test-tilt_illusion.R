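test_that("orientation sets follow the 1.5-threshold spacing rule", {
  expect_equal(make_orientation_set(0, 1)$o,
               c(-4.5, -3, -1.5, 0, 1.5, 3, 4.5))
  expect_equal(make_orientation_set(2, 0.5)$o,
               c(-0.25, 0.5, 1.25, 2, 2.75, 3.5, 4.25))
  for (i in 1:10) {
    a <- rnorm(1); s <- runif(1, 0.2, 3)
    o <- make_orientation_set(a, s)$o
    expect_equal(o[4], a)                       # centre is the PSE
    expect_equal(diff(o), rep(1.5 * s, 6))      # uniform spacing
  }
  expect_error(make_orientation_set(0, -1), "positive")
})

test_that("the psychometric function crosses one half at its midpoint", {
  expect_equal(psy_fun(-1.3, a = -1.3, b = 2), 0.5)
  expect_equal(psy_fun(1e6, a = 0, b = 1), 0.98)
  expect_equal(psy_fun(-1e6, a = 0, b = 1), 0.02)
})

test_that("staircases terminate at 19 reversals with 0.1-degree steps", {
  for (s in c(1, 2, 3)) {
    res <- run_staircase(staircase_config(), disc_observer(scale = 1),
                         seed = s)
    expect_equal(length(res$reversal_values), 19L)
    steps <- diff(res$trials$difference)
    expect_true(all(abs(steps[steps != 0]) - 0.1 < 1e-12))
    expect_gt(res$threshold, 0)
    # identical seed reproduces the run exactly
    res2 <- run_staircase(staircase_config(), disc_observer(scale = 1),
                          seed = s)
    expect_identical(res$trials, res2$trials)
  }
})

test_that("an always-correct observer descends to the floor and terminates", {
  perfect <- structure(list(p_correct = function(d) rep(1, length(d))),
                       class = "disc_observer")
  res <- run_staircase(staircase_config(), perfect, seed = 1)
  expect_true(res$clamped)
  expect_true(all(diff(res$trials$difference) <= 0))
  expect_equal(res$threshold, 0.1)
})

test_that("the staircase targets the 70.71%-correct level", {
  obs <- disc_observer(scale = 1)
  th <- vapply(1:150, function(s)
    run_staircase(staircase_config(), obs, seed = s)$threshold, numeric(1))
  pc <- mean(obs$p_correct(th))
  expect_lt(abs(pc - 0.7071), 0.03)
})

test_that("tilt sessions present each orientation the same number of times", {
  oset <- make_orientation_set(-1.3, 1)
  obs <- tilt_observer(a_true = -1.3, b_true = 1.5)
  sess <- simulate_tilt_session(oset, obs, seed = 5)
  expect_equal(nrow(sess), 126L)
  expect_true(all(table(sess$orientation) == 18L))
  expect_identical(sess, simulate_tilt_session(oset, obs, seed = 5))
  # at the observer's true magnitude, responses are at chance
  big <- simulate_tilt_session(oset, tilt_observer(a_true = oset$o[4],
                                                   b_true = 1.5),
                               reps = 600, seed = 6)
  at_centre <- big$response_cw[big$orientation == oset$o[4]]
  expect_lt(abs(mean(at_centre) - 0.5), 0.05)
})

test_that("PSE adjustment averages seeded draws around the true magnitude", {
  obs0 <- tilt_observer(a_true = -1.1, pse_noise = 0)
  expect_equal(measure_pse(obs0, seed = 2), -1.1)
  obs <- tilt_observer(a_true = -1.1, pse_noise = 0.4)
  expect_identical(measure_pse(obs, seed = 2), measure_pse(obs, seed = 2))
  pses <- vapply(1:1000, function(s) measure_pse(obs, seed = s), numeric(1))
  expect_equal(sd(pses), 0.4 / 2, tolerance = 0.02)  # SE of a 4-trial mean
})

test_that("psychometric fitting recovers a simulated observer", {
  oset <- make_orientation_set(-1.3, 1)
  sess <- simulate_tilt_session(oset, tilt_observer(-1.3, 1.5), reps = 200,
                                seed = 8)
  f <- fit_psychometric(sess, n_boot = 200, n_gof = 0, seed = 9)
  expect_lt(abs(f$a - (-1.3)), 0.2)
  expect_lt(abs(f$b - 1.5) / 1.5, 0.25)
  expect_false(f$excluded)
  # invariant to trial order
  f2 <- fit_psychometric(sess[sample(nrow(sess)), ], n_boot = 0, n_gof = 0)
  expect_equal(f2$a, f$a, tolerance = 1e-8)
})

test_that("degenerate and ill-behaved sessions are flagged, good ones kept", {
  oset <- make_orientation_set(0, 1)
  allsame <- data.frame(trial = 1:14, orientation = rep(oset$o, 2),
                        response_cw = 1L)
  f <- fit_psychometric(allsame, n_boot = 0, n_gof = 0)
  expect_true(f$excluded)
  expect_match(f$reason, "degenerate")

  # near-zero slope: the 68% CI exceeds the orientation range
  flagged <- vapply(1:5, function(r) {
    oset2 <- make_orientation_set(0, 0.3)
    sess <- simulate_tilt_session(oset2, tilt_observer(0, 0.02), seed = r)
    fit_psychometric(sess, n_boot = 300, n_gof = 0, seed = r + 50)$excluded
  }, logical(1))
  expect_gte(sum(flagged), 3L)

  # a clean 126-trial logistic session with b >= 1 is never excluded
  kept <- vapply(1:5, function(r) {
    sess <- simulate_tilt_session(make_orientation_set(-1.3, 1),
                                  tilt_observer(-1.3, 1.5), seed = r)
    fit_psychometric(sess, n_boot = 300, n_gof = 300,
                     seed = r + 70)$excluded
  }, logical(1))
  expect_false(any(kept))
})

test_that("goodness of fit detects a non-logistic response curve", {
  o <- seq(-4.5, 4.5, by = 1.5)
  p_true <- pmin(pmax(0.5 + 0.8 * (o / 4.5)^3, 0.02), 0.98)
  hits <- vapply(1:6, function(r) {
    set.seed(r)
    x <- rep(o, each = 40)
    sess <- data.frame(trial = seq_along(x), orientation = x,
                       response_cw = rbinom(length(x), 1,
                                            rep(p_true, each = 40)))
    fit_psychometric(sess, n_boot = 0, n_gof = 400,
                     seed = r + 300)$gof_p < 0.05
  }, logical(1))
  expect_gte(sum(hits), 4L)
})
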