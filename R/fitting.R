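#' Default priors for MAP estimation
#'
#' Independent Gaussian priors in the estimation space of each parameter:
#' identity for the omegas and betas, log for the residual variance
#' `zeta` and the SK1 meta-learning rate, logit for the RW learning rate.
#' Values are weakly informative toolbox-style defaults and are
#' overridable per parameter.
#'
#' @param ... Named overrides, each a `c(mean, var)` pair.
#' @return Named list of `c(mean, var)` pairs, class `prior_spec`.
#' @export
default_priors <- function(...) {
  pr <- list(
    omega2        = c(mean = -3, var = 16),
    omega3        = c(mean = -6, var = 16),
    beta0         = c(mean = 0, var = 4),
    beta1         = c(mean = 0, var = 4),
    beta2         = c(mean = 0, var = 4),
    beta3         = c(mean = 0, var = 4),
    beta4         = c(mean = 0, var = 4),
    log_zeta      = c(mean = -3, var = 4),
    logit_alpha_rw = c(mean = 0, var = 4),
    log_mu_meta   = c(mean = -2, var = 16))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(pr)) stop("unknown prior parameter: ", nm)
    pr[[nm]] <- setNames(as.numeric(over[[nm]]), c("mean", "var"))
  }
  if (any(vapply(pr, function(p) p[["var"]], numeric(1)) <= 0))
    stop("prior variances must be positive")
  structure(pr, class = "prior_spec")
}

# Per-model description: free parameters (estimation space), the
# regressors its trajectory defines, and the core filter call.
model_info <- function(model_id) {
  switch(model_id,
    hgf3 = list(
      theta_names = c("omega2", "omega3", "beta0", "beta1", "beta2",
                      "beta3", "beta4", "log_zeta"),
      regs = c("surprise", "unc1", "unc2", "volatility"),
      run = function(u, th)
        .hgf3_core(u, th[["omega2"]], th[["omega3"]], 1, 0, 1, 1, 1)),
    hgf2 = list(
      theta_names = c("omega2", "beta0", "beta1", "beta2", "beta3",
                      "log_zeta"),
      regs = c("surprise", "unc1", "unc2"),
      run = function(u, th) .hgf2_core(u, th[["omega2"]], 0, 1)),
    rw = list(
      theta_names = c("logit_alpha_rw", "beta0", "beta1", "beta2",
                      "log_zeta"),
      regs = c("surprise", "unc1"),
      run = function(u, th) .rw_core(u, plogis(th[["logit_alpha_rw"]]), 0.5)),
    sk1 = list(
      theta_names = c("log_mu_meta", "beta0", "beta1", "beta2", "log_zeta"),
      regs = c("surprise", "unc1"),
      run = function(u, th)
        .sk1_core(u, exp(th[["log_mu_meta"]]), 0.5, -2, 0, 1e-6)),
    stop("unknown model_id: ", model_id))
}

# The betas pairing with each regressor, in model_info()$regs order.
reg_betas <- function(regs) {
  unname(beta_for[regs])
}

# Log joint density (log-likelihood + log prior) as a closure over the
# data; -Inf at numerically invalid parameter points.
make_log_joint <- function(schedule, rts, accuracy, model_id, priors) {
  info <- model_info(model_id)
  u <- check_u(schedule$u)
  include <- !is.na(accuracy) & accuracy == 1L & !is.na(rts) & rts > 0
  log_rt <- log(rts[include] / 1000)
  pm <- vapply(priors[info$theta_names], `[[`, numeric(1), "mean")
  pv <- vapply(priors[info$theta_names], `[[`, numeric(1), "var")
  lp_const <- -0.5 * sum(log(2 * pi * pv))
  bnames <- reg_betas(info$regs)

  function(theta) {
    names(theta) <- info$theta_names
    core <- info$run(u, theta)
    if (core$invalid > 0L) return(-Inf)
    mu <- rep(theta[["beta0"]], length(log_rt))
    for (i in seq_along(info$regs))
      mu <- mu + theta[[bnames[i]]] * core[[info$regs[i]]][include]
    zeta <- exp(theta[["log_zeta"]])
    ll <- -0.5 * length(log_rt) * log(2 * pi * zeta) -
      0.5 * sum((log_rt - mu)^2) / zeta
    lp <- lp_const - 0.5 * sum((theta - pm)^2 / pv)
    val <- ll + lp
    if (!is.finite(val)) -Inf else val
  }
}

#' Fit one subject's reaction times with a learning model
#'
#' Maximum a posteriori estimation of the joint perceptual + response
#' parameter vector by quasi-Newton (BFGS) ascent of the log joint
#' density, with seeded multi-start: the first start is the prior mean,
#' the remaining `n_restarts - 1` are drawn from the priors scaled by
#' `start_scale`. Parameter points yielding numerically invalid belief
#' trajectories score `-Inf`. The log model evidence is a Laplace
#' approximation at the MAP (see [laplace_evidence()]).
#'
#' @param schedule A `pal_schedule` with `u` (and, by default, `accuracy`
#'   and `rt_ms`).
#' @param rts RTs in milliseconds; defaults to `schedule$rt_ms`.
#' @param model_id One of `"hgf3"`, `"hgf2"`, `"rw"`, `"sk1"`.
#' @param priors A [default_priors()] list.
#' @param options List: `n_restarts` (default 8), `seed` (default 1),
#'   `start_scale` (default 0.25, multiplies the prior SD for restart
#'   draws), `maxit` (default 500), `min_trials` (default 50),
#'   `accuracy` (override for `schedule$accuracy`).
#' @return A `subject_fit`: list with `model_id`, `estimates` (natural
#'   space), `theta` (estimation space), `log_joint`, `log_evidence`,
#'   `hessian_ok`, `n_restarts_used`, `n_trials`, `seed`, and the log
#'   joint closure `objective`.
#' @examples
#' \donttest{
#' sched <- generate_schedule(schedule_config(seed = 8))
#' traj <- hgf3_filter(sched$u)
#' sched$rt_ms <- simulate_rts(response_params(), traj, sched, seed = 8)
#' sched$accuracy <- 1L
#' fit <- fit_subject(sched, model_id = "hgf3",
#'                    options = list(n_restarts = 2))
#' fit$estimates["omega2"]
#' }
#' @export
fit_subject <- function(schedule, rts = NULL,
                        model_id = c("hgf3", "hgf2", "rw", "sk1"),
                        priors = default_priors(), options = list()) {
  model_id <- match.arg(model_id)
  opts <- modifyList(list(n_restarts = 8L, seed = 1L, start_scale = 0.25,
                          maxit = 500L, min_trials = 50L, accuracy = NULL),
                     options)
  rts <- rts %||% schedule$rt_ms
  accuracy <- opts$accuracy %||% schedule$accuracy
  if (length(rts) != nrow(schedule) || length(accuracy) != nrow(schedule))
    stop("rts and accuracy must be aligned with the schedule")
  n_valid <- sum(!is.na(accuracy) & accuracy == 1L & !is.na(rts) & rts > 0)
  if (n_valid < opts$min_trials)
    stop("too few valid trials to fit (", n_valid, " < ", opts$min_trials, ")")

  info <- model_info(model_id)
  obj <- make_log_joint(schedule, rts, accuracy, model_id, priors)
  pm <- vapply(priors[info$theta_names], `[[`, numeric(1), "mean")
  psd <- sqrt(vapply(priors[info$theta_names], `[[`, numeric(1), "var"))
  d <- length(pm)

  set.seed(opts$seed)
  starts <- rbind(pm, matrix(rnorm((opts$n_restarts - 1L) * d,
                                   mean = rep(pm, each = opts$n_restarts - 1L),
                                   sd = rep(opts$start_scale * psd,
                                            each = opts$n_restarts - 1L)),
                             ncol = d, byrow = FALSE))
  neg <- function(th) { v <- obj(th); if (is.finite(v)) -v else 1e10 }

  best <- NULL
  n_ok <- 0L
  for (r in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[r, ], neg, method = "BFGS",
            control = list(maxit = opts$maxit)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value) || res$value >= 1e10) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all ", opts$n_restarts, " restarts failed for model ", model_id)

  theta <- setNames(best$par, info$theta_names)
  fit <- structure(
    list(model_id = model_id, theta = theta,
         estimates = natural_estimates(theta),
         log_joint = -best$value, log_evidence = NA_real_,
         hessian_ok = NA, n_restarts_used = n_ok,
         n_trials = n_valid, seed = opts$seed, objective = obj),
    class = "subject_fit")
  ev <- laplace_evidence(fit)
  fit$log_evidence <- as.numeric(ev)
  fit$hessian_ok <- attr(ev, "hessian_ok")
  fit
}

natural_estimates <- function(theta) {
  est <- theta
  if ("log_zeta" %in% names(est)) {
    est[["zeta"]] <- exp(est[["log_zeta"]])
    est <- est[names(est) != "log_zeta"]
  }
  if ("logit_alpha_rw" %in% names(est)) {
    est[["alpha_rw"]] <- plogis(est[["logit_alpha_rw"]])
    est <- est[names(est) != "logit_alpha_rw"]
  }
  if ("log_mu_meta" %in% names(est)) {
    est[["mu_meta"]] <- exp(est[["log_mu_meta"]])
    est <- est[names(est) != "log_mu_meta"]
  }
  est
}

# Central-difference Hessian with per-coordinate step 1e-4 * max(1, |x|).
num_hessian <- function(f, x, rel_step = 1e-4) {
  d <- length(x)
  h <- rel_step * pmax(1, abs(x))
  H <- matrix(NA_real_, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(d), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Laplace approximation of the log model evidence
#'
#' At the MAP `theta*`, approximates the log marginal likelihood by
#' `log p(y, theta*) + (d/2) log(2 pi) - (1/2) log det H`, where `H` is
#' the negative Hessian of the log joint at the MAP, obtained by central
#' differences (step `1e-4 * max(1, |theta_i|)` per coordinate). A
#' non-positive-definite `H` is repaired by clamping its eigenvalues from
#' below, and flagged via the `hessian_ok` attribute.
#'
#' @param fit A `subject_fit` (anything with elements `objective` — the
#'   log joint function — `theta` and `log_joint`).
#' @return The log evidence (numeric scalar) with attributes
#'   `hessian_ok` and `log_det`.
#' @export
laplace_evidence <- function(fit) {
  negf <- function(th) {
    v <- fit$objective(th)
    if (is.finite(v)) -v else 1e10
  }
  H <- num_hessian(negf, fit$theta)
  if (!all(is.finite(H))) stop("evidence undefined: non-finite Hessian")
  eg <- eigen(0.5 * (H + t(H)), symmetric = TRUE, only.values = TRUE)$values
  ok <- all(eg > 0)
  lam <- pmax(eg, 1e-8 * max(abs(eg), 1))
  if (any(lam <= 0)) stop("evidence undefined: singular Hessian after repair")
  d <- length(fit$theta)
  ev <- fit$log_joint + 0.5 * d * log(2 * pi) - 0.5 * sum(log(lam))
  structure(ev, hessian_ok = ok, log_det = sum(log(lam)))
}

#' @export
print.subject_fit <- function(x, ...) {
  cat("Subject fit [", x$model_id, "]: log evidence ",
      format(x$log_evidence, digits = 6), " on ", x$n_trials,
      " trials\n", sep = "")
  print(round(x$estimates, 4))
  invisible(x)
}
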