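test_that("condition means cover the nine expectedness-by-noise cells", {
  sub <- make_sim_subject(seed = 41)
  sched <- sub$schedule
  sched$rt_ms <- rep(650, nrow(sched))
  cm <- condition_means(sched)
  expect_equal(nrow(cm), 9L)
  expect_true(all(cm$mean_rt_ms == 650))
  expect_false(attr(cm, "flagged"))
  expect_equal(sum(cm$n_trials), sum(sched$accuracy == 1L))

  # trial order is irrelevant
  ord <- sample(nrow(sched))
  cm2 <- condition_means(sched[ord, ])
  expect_equal(cm2$mean_rt_ms, cm$mean_rt_ms)

  # an empty cell flags the subject
  sched3 <- sub$schedule
  drop <- sched3$expectedness == "neutral" & sched3$noise == "high"
  sched3$accuracy[drop] <- 0L
  cm3 <- condition_means(sched3)
  expect_true(attr(cm3, "flagged"))
  expect_true(is.na(cm3$mean_rt_ms[cm3$expectedness == "neutral" &
                                     cm3$noise == "high"]))
})

test_that("surprise effects appear as slower unexpected RTs across a cohort", {
  coh <- simulate_cohort(cohort_spec(n_per_group = 10, seed = 7))
  sgn <- vapply(coh$subjects, function(s) {
    cm <- condition_means(s$schedule)
    w <- tapply(cm$mean_rt_ms * cm$n_trials, cm$expectedness, sum) /
      tapply(cm$n_trials, cm$expectedness, sum)
    w[["unexpected"]] > w[["expected"]]
  }, logical(1))
  expect_gte(sum(sgn), 15L)
})

test_that("phase learning-rate summaries respect the learner's fields", {
  sub <- make_sim_subject(seed = 42)
  pr <- phase_learning_rates(sub$trajectory, sub$schedule)
  expect_setequal(pr$rate, c("alpha2", "alpha3"))
  expect_true(all(is.finite(pr$stable)) && all(is.finite(pr$volatile)))

  h2 <- hgf2_filter(sub$schedule$u)
  pr2 <- phase_learning_rates(h2, sub$schedule)
  expect_equal(pr2$rate, "alpha2")
  expect_error(phase_learning_rates(h2, sub$schedule, rates = "alpha3"),
               "does not define")

  # an all-stable schedule leaves the volatile column empty, flagged
  plan <- list(list(list(length = 72L, p = 0.84, phase = "stable")))
  sched_s <- generate_schedule(
    schedule_config(block_lengths = 72L, phase_plan = plan, seed = 3))
  pr3 <- phase_learning_rates(hgf3_filter(sched_s$u), sched_s)
  expect_true(all(is.na(pr3$volatile)))
  expect_equal(attr(pr3, "missing_phases"), "volatile")
})

test_that("the split-plot ANOVA matches an independent sums-of-squares oracle", {
  # hand-checkable 4-subject example
  hand <- data.frame(
    subject = rep(c("s1", "s2", "s3", "s4"), each = 2),
    group = rep(c("g1", "g1", "g2", "g2"), each = 2),
    phase = rep(c("stable", "volatile"), 4),
    value = c(0.20, 0.30, 0.25, 0.40, 0.30, 0.55, 0.35, 0.65))
  got <- mixed_anova_2x2(hand)
  ora <- split_plot_oracle(hand)
  expect_equal(got$F, ora$F, tolerance = 1e-10)
  expect_equal(got$peta2, ora$peta2, tolerance = 1e-10)
  expect_equal(got$df1, ora$df1)
  expect_equal(got$df2, ora$df2)

  # random datasets against the oracle
  set.seed(5)
  for (r in 1:10) {
    n <- sample(3:6, 1)
    d <- data.frame(
      subject = rep(sprintf("s%02d", 1:(2 * n)), each = 2),
      group = rep(c("a", "b"), each = 2 * n),
      phase = rep(c("stable", "volatile"), 2 * n),
      value = rnorm(4 * n))
    expect_equal(mixed_anova_2x2(d)$F, split_plot_oracle(d)$F,
                 tolerance = 1e-8)
  }
})

test_that("a pure group shift loads on the group effect, not the phase effect", {
  n <- 6
  subj <- sprintf("s%02d", 1:(2 * n))
  grp <- rep(c("a", "b"), each = n)
  base <- ifelse(grp == "a", 0, 5) + rnorm(2 * n, sd = 0.1)
  # within-subject deviations that cancel exactly across subjects
  dev <- rep(c(0.05, -0.05), n)
  d <- data.frame(subject = rep(subj, each = 2),
                  group = rep(grp, each = 2),
                  phase = rep(c("stable", "volatile"), 2 * n),
                  value = rep(base, each = 2) + as.vector(rbind(dev, -dev)))
  res <- mixed_anova_2x2(d)
  expect_lt(abs(res$F[res$effect == "phase"]), 1e-10)
  expect_gt(res$F[res$effect == "group"], 100)
})

test_that("parametric and permutation p-values agree under the null", {
  set.seed(11)
  n <- 10
  d <- data.frame(subject = rep(sprintf("s%02d", 1:(2 * n)), each = 2),
                  group = rep(c("a", "b"), each = 2 * n),
                  phase = rep(c("stable", "volatile"), 2 * n),
                  value = rnorm(4 * n))
  res <- mixed_anova_2x2(d)
  f_obs <- res$F[res$effect == "group"]
  f_perm <- vapply(1:1000, function(i) {
    dd <- d
    new_grp <- sample(rep(c("a", "b"), each = n))
    dd$group <- rep(new_grp, each = 2)
    split_plot_oracle(dd)$F[1]
  }, numeric(1))
  p_perm <- mean(f_perm >= f_obs)
  expect_lt(abs(p_perm - res$p[res$effect == "group"]), 0.03)
})

test_that("ANOVA input validation rejects unbalanced or tiny designs", {
  d <- data.frame(subject = c("s1", "s1", "s2"), group = "a",
                  phase = c("stable", "volatile", "stable"), value = 1:3)
  expect_error(mixed_anova_2x2(d), "two levels")
  d2 <- data.frame(subject = rep(c("s1", "s2"), each = 2),
                   group = rep(c("a", "b"), each = 2),
                   phase = rep(c("stable", "volatile"), 2),
                   value = rnorm(4))
  expect_error(mixed_anova_2x2(d2), "at least 2 subjects")
})

test_that("cross-task correlations behave like Pearson's r", {
  x <- rnorm(30)
  r1 <- cross_task_correlation(x, x)
  expect_equal(r1$r, 1)
  set.seed(3)
  r2 <- cross_task_correlation(x, -x + rnorm(30, sd = 0.3))
  expect_lt(r2$r, 0)
  expect_error(cross_task_correlation(1:2, 2:3), "at least 3")
  # null calibration at the study's sample size
  set.seed(17)
  rs <- vapply(1:1000, function(i) cor(rnorm(65), rnorm(65)), numeric(1))
  expect_gte(mean(abs(rs) < 0.25), 0.95)
})
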