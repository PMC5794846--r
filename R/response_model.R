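#' Response-model parameters
#'
#' The response model maps trial-wise beliefs to log reaction times:
#' `log RT(t) ~ Normal(beta0 + beta1 surprise(t) + beta2 unc1(t)
#'  + beta3 unc2(t) + beta4 volatility(t), zeta)`,
#' where `beta0` is baseline log RT (log seconds), `beta1` weights outcome
#' surprise, `beta2`/`beta3` weight belief uncertainty at levels 1 and 2,
#' `beta4` weights the phasic volatility estimate, and `zeta` is the
#' decision-noise variance of log RT residuals (parameterised on the log
#' scale for unconstrained optimisation). Learners without a regressor
#' drop the corresponding term: RW and SK1 use only surprise and `unc1`;
#' the two-level HGF has no volatility term.
#'
#' @param beta0,beta1,beta2,beta3,beta4 Regression weights.
#' @param log_zeta Log of the residual variance `zeta`.
#' @return A list of class `response_params`.
#' @export
response_params <- function(beta0 = -0.3, beta1 = 0.1, beta2 = 0.5,
                            beta3 = 0.5, beta4 = 0.2, log_zeta = log(0.04)) {
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 beta4 = beta4, log_zeta = log_zeta),
            class = "response_params")
}

regressor_names <- function(trajectory) {
  intersect(c("surprise", "unc1", "unc2", "volatility"), names(trajectory))
}

#' Build the response-model design matrix
#'
#' Selects the trials that enter the likelihood — correct trials with a
#' recorded reaction time — and assembles the learner's regressors
#' together with the natural log of RT in seconds. Columns the learner
#' does not define (e.g. `volatility` for the two-level HGF, `unc2` for
#' RW/SK1) are absent, not zero.
#'
#' @param trajectory A `belief_trajectory`, aligned 1:1 with the schedule.
#' @param schedule A `pal_schedule`.
#' @param rts Per-trial RTs in milliseconds; defaults to
#'   `schedule$rt_ms`.
#' @param accuracy Per-trial 0/1 accuracy; defaults to
#'   `schedule$accuracy`.
#' @return A data.frame of class `regressor_matrix` with one row per
#'   included trial, the regressor columns, `log_rt`, and the learner
#'   name as attribute `model`.
#' @export
build_regressors <- function(trajectory, schedule, rts = NULL,
                             accuracy = NULL) {
  rts <- rts %||% schedule$rt_ms
  accuracy <- accuracy %||% schedule$accuracy
  n <- nrow(schedule)
  if (nrow(trajectory) != n || length(rts) != n || length(accuracy) != n)
    stop("trajectory, schedule, rts and accuracy must be aligned 1:1")
  include <- !is.na(accuracy) & accuracy == 1L & !is.na(rts)
  if (any(include & rts <= 0))
    stop("non-positive RT on an included (correct) trial")
  regs <- regressor_names(trajectory)
  X <- as.data.frame(trajectory)[include, regs, drop = FALSE]
  X$log_rt <- log(rts[include] / 1000)
  if (nrow(X) && !all(is.finite(as.matrix(X))))
    stop("non-finite regressor or log RT on an included trial")
  rownames(X) <- NULL
  structure(X, class = c("regressor_matrix", "data.frame"),
            model = attr(trajectory, "model"))
}

#' Log-likelihood of log reaction times under the linear response model
#'
#' Sums, over the rows of the regressor matrix, the Gaussian log density
#' of `log_rt` with mean `beta0 + sum_i beta_i x_i` and variance `zeta`.
#' Only the betas matching the matrix's columns enter the mean.
#'
#' @param params A [response_params()].
#' @param X A `regressor_matrix` from [build_regressors()].
#' @return The scalar log-likelihood; `-Inf` for invalid parameter points.
#' @export
rt_loglik <- function(params, X) {
  if (nrow(X) == 0L) stop("no valid trials: regressor matrix is empty")
  mu <- response_mean(params, X)
  zeta <- exp(params$log_zeta)
  ll <- sum(dnorm(X$log_rt, mean = mu, sd = sqrt(zeta), log = TRUE))
  if (!is.finite(ll)) -Inf else ll
}

beta_for <- c(surprise = "beta1", unc1 = "beta2", unc2 = "beta3",
              volatility = "beta4")

response_mean <- function(params, X) {
  regs <- intersect(names(beta_for), names(X))
  mu <- rep(params$beta0, nrow(X))
  for (r in regs) mu <- mu + params[[beta_for[[r]]]] * X[[r]]
  mu
}

#' Simulate reaction times from beliefs
#'
#' The generative inverse of the response model: draws per-trial log RTs
#' from the Normal with the model mean (plus an optional additive offset
#' per image-noise level, in log units) and variance `zeta`, for all
#' trials of the schedule.
#'
#' @param params A [response_params()].
#' @param trajectory A `belief_trajectory` aligned with `schedule`.
#' @param schedule A `pal_schedule`.
#' @param seed Integer seed.
#' @param noise_offsets Named additive log-RT offsets, one per noise
#'   level.
#' @return Numeric vector of RTs in milliseconds.
#' @export
simulate_rts <- function(params, trajectory, schedule, seed = 1L,
                         noise_offsets = c(low = 0, medium = 0, high = 0)) {
  if (nrow(trajectory) != nrow(schedule))
    stop("trajectory and schedule must be aligned 1:1")
  set.seed(seed)
  X <- as.data.frame(trajectory)[, regressor_names(trajectory), drop = FALSE]
  mu <- response_mean(params, X) + unname(noise_offsets[schedule$noise])
  log_rt <- rnorm(nrow(schedule), mean = mu, sd = sqrt(exp(params$log_zeta)))
  1000 * exp(log_rt)
}
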