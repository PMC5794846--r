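# Independent single-step oracles, written directly from the update
# equations in plain R. They deliberately share no code with the package
# internals (which run in C++).

hgf3_step_oracle <- function(u, mu2, sigma2, mu3, sigma3, omega2, omega3,
                             kappa = 1) {
  muhat1 <- 1 / (1 + exp(-mu2))
  delta1 <- u - muhat1
  v2 <- exp(kappa * mu3 + omega2)
  pihat2 <- 1 / (sigma2 + v2)
  pi2 <- pihat2 + muhat1 * (1 - muhat1)
  mu2_new <- mu2 + (1 / pi2) * delta1
  sigma2_new <- 1 / pi2
  w2 <- v2 * pihat2
  delta2 <- (sigma2_new + (mu2_new - mu2)^2) * pihat2 - 1
  pihat3 <- 1 / (sigma3 + exp(omega3))
  pi3 <- pihat3 + 0.5 * kappa^2 * w2 * (w2 + (2 * w2 - 1) * delta2)
  alpha3 <- 0.5 * kappa * w2 / pi3
  list(muhat1 = muhat1, delta1 = delta1,
       surprise = -log(ifelse(u == 1, muhat1, 1 - muhat1)),
       unc1 = muhat1 * (1 - muhat1), unc2 = sigma2 + v2,
       volatility = exp(mu3),
       alpha2 = muhat1 * (1 - muhat1) / pi2,
       mu2 = mu2_new, sigma2 = sigma2_new,
       mu3 = mu3 + alpha3 * delta2, sigma3 = 1 / pi3, alpha3 = alpha3)
}

hgf2_step_oracle <- function(u, mu2, sigma2, omega2) {
  muhat1 <- 1 / (1 + exp(-mu2))
  v2 <- exp(omega2)
  pihat2 <- 1 / (sigma2 + v2)
  pi2 <- pihat2 + muhat1 * (1 - muhat1)
  list(muhat1 = muhat1, mu2 = mu2 + (1 / pi2) * (u - muhat1),
       sigma2 = 1 / pi2, unc2 = sigma2 + v2,
       alpha2 = muhat1 * (1 - muhat1) / pi2)
}

rw_step_oracle <- function(u, v, alpha) {
  list(muhat1 = v, v = v + alpha * (u - v))
}

sk1_step_oracle <- function(u, v, b, h, mu_meta, eps = 1e-6) {
  d <- u - v
  b_new <- b + mu_meta * d * h
  k <- min(1, exp(b_new))
  v_new <- min(max(v + k * d, eps), 1 - eps)
  list(muhat1 = v, lr = k, v = v_new, b = b_new,
       h = h * max(0, 1 - k) + k * d)
}

# Balanced 2 (phase, within) x 2 (group, between) split-plot ANOVA by
# explicit sums of squares; independent of stats::aov.
split_plot_oracle <- function(data) {
  y <- data$value
  s <- as.character(data$subject)
  p <- as.character(data$phase)
  g <- as.character(data$group)
  grand <- mean(y)
  subs <- unique(s)
  grp_of <- vapply(subs, function(si) g[s == si][1], character(1))
  n_g <- table(grp_of)
  P <- length(unique(p))
  m_sub <- vapply(subs, function(si) mean(y[s == si]), numeric(1))
  m_grp <- vapply(names(n_g), function(gi) mean(y[g == gi]), numeric(1))
  m_pha <- vapply(unique(p), function(pi) mean(y[p == pi]), numeric(1))
  m_cell <- outer(names(n_g), unique(p),
                  Vectorize(function(gi, pi) mean(y[g == gi & p == pi])))
  ss_group <- P * sum(n_g * (m_grp - grand)^2)
  ss_serr <- P * sum((m_sub - m_grp[grp_of])^2)
  ss_phase <- length(subs) * sum((m_pha - grand)^2)
  ss_pg <- sum(rep(n_g, times = P) *
                 (t(t(m_cell) - m_pha) - (m_grp - grand))^2)
  fit_cell <- numeric(length(y))
  for (i in seq_along(y)) {
    gi <- match(g[i], names(n_g)); pi <- match(p[i], unique(p))
    fit_cell[i] <- m_sub[match(s[i], subs)] + m_cell[gi, pi] - m_grp[gi]
  }
  ss_werr <- sum((y - fit_cell)^2)
  G <- length(n_g); N <- length(subs)
  data.frame(
    effect = c("group", "phase", "phase:group"),
    df1 = c(G - 1, P - 1, (P - 1) * (G - 1)),
    df2 = c(N - G, (N - G) * (P - 1), (N - G) * (P - 1)),
    F = c((ss_group / (G - 1)) / (ss_serr / (N - G)),
          (ss_phase / (P - 1)) / (ss_werr / ((N - G) * (P - 1))),
          (ss_pg / ((P - 1) * (G - 1))) / (ss_werr / ((N - G) * (P - 1)))),
    peta2 = c(ss_group / (ss_group + ss_serr),
              ss_phase / (ss_phase + ss_werr),
              ss_pg / (ss_pg + ss_werr)))
}

# A quick simulated PAL subject: HGF3 beliefs -> response model RTs.
make_sim_subject <- function(seed, omega2 = -3, omega3 = -6,
                             params = response_params(),
                             error_rate = 0) {
  sched <- generate_schedule(schedule_config(seed = seed))
  traj <- hgf3_filter(sched$u, hgf_params(omega2 = omega2, omega3 = omega3))
  sched$rt_ms <- simulate_rts(params, traj, sched, seed = seed + 1L)
  set.seed(seed + 2L)
  sched$accuracy <- 1L - rbinom(nrow(sched), 1L, error_rate)
  list(schedule = sched, trajectory = traj)
}
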