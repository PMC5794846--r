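#' Parameters for the hierarchical Gaussian filter
#'
#' `omega2` is the tonic log-volatility at level 2 and acts as the rate at
#' which cue-outcome probabilities are estimated to change (probability
#' learning rate); `omega3` is the tonic log-volatility at level 3 and
#' governs how fast the volatility estimate itself drifts. The coupling
#' `kappa` between levels 2 and 3 is fixed at 1 by default. Initial
#' posterior means/variances follow common toolbox conventions
#' (`mu2_0 = 0`, `sigma2_0 = 1`, `mu3_0 = 1`, `sigma3_0 = 1`) and are
#' overridable.
#'
#' @param omega2,omega3 Tonic log-volatilities at levels 2 and 3.
#' @param kappa Positive level-2/3 coupling.
#' @param mu2_0,sigma2_0,mu3_0,sigma3_0 Initial posterior state.
#' @return A list of class `hgf_params`.
#' @export
hgf_params <- function(omega2 = -3, omega3 = -6, kappa = 1,
                       mu2_0 = 0, sigma2_0 = 1, mu3_0 = 1, sigma3_0 = 1) {
  if (sigma2_0 <= 0 || sigma3_0 <= 0) stop("initial variances must be positive")
  if (kappa <= 0) stop("kappa must be positive")
  structure(list(omega2 = omega2, omega3 = omega3, kappa = kappa,
                 mu2_0 = mu2_0, sigma2_0 = sigma2_0,
                 mu3_0 = mu3_0, sigma3_0 = sigma3_0),
            class = "hgf_params")
}

check_u <- function(u) {
  u <- as.integer(u)
  if (length(u) < 1L || anyNA(u) || !all(u %in% c(0L, 1L)))
    stop("u must be a non-empty binary (0/1) sequence")
  u
}

trajectory_invalid <- function(trial, model) {
  stop(structure(
    class = c("trajectory_invalid", "error", "condition"),
    list(message = sprintf("%s trajectory numerically invalid at trial %d",
                           model, trial),
         call = NULL, trial = trial)))
}

finish_trajectory <- function(core, model, params, n) {
  if (core$invalid > 0L) trajectory_invalid(core$invalid, model)
  core$invalid <- NULL
  out <- as.data.frame(core)
  stopifnot(nrow(out) == n)
  structure(out, class = c("belief_trajectory", "data.frame"),
            model = model, params = params)
}

#' Belief filters: trial-wise learning trajectories
#'
#' Forward filters mapping a binary cue-outcome congruency sequence `u`
#' to trial-wise beliefs. All four filters are deterministic and
#' length-preserving, and expose the prediction-time outcome probability
#' `muhat1`, the level-1 prediction error `delta1 = u - muhat1`, the
#' information surprise of the observed outcome (nats), and the level-1
#' uncertainty `unc1 = muhat1 (1 - muhat1)`.
#'
#' `hgf3_filter()` runs the binary three-level HGF. Per trial, with
#' previous posterior (mu2, sigma2, mu3, sigma3):
#' prediction `muhat1 = logistic(mu2)`; level-2 prediction variance
#' inflation `v2 = exp(kappa mu3 + omega2)`; precisions
#' `pihat2 = 1/(sigma2 + v2)`, `pi2 = pihat2 + muhat1 (1 - muhat1)`;
#' update `mu2' = mu2 + (1/pi2) delta1`, `sigma2' = 1/pi2` (the update
#' gain equals the new posterior variance). The dynamic probability
#' learning rate exposed as `alpha2` is this precision weight expressed
#' on the outcome-probability scale — the trial-wise gain of `muhat1`:
#' `alpha2 = muhat1 (1 - muhat1) / pi2`, bounded in (0, 1) and rising
#' when the volatility estimate rises. Volatility prediction
#' error: `delta2 = (sigma2' + (mu2' - mu2)^2) pihat2 - 1` with weight
#' `w2 = v2 pihat2`; level-3 precisions `pihat3 = 1/(sigma3 + exp(omega3))`,
#' `pi3 = pihat3 + (kappa^2/2) w2 (w2 + (2 w2 - 1) delta2)`; learning rate
#' `alpha3 = (kappa/2) w2 / pi3`; update `mu3' = mu3 + alpha3 delta2`,
#' `sigma3' = 1/pi3`. Additional response-model regressors are
#' prediction-time quantities: `unc2 = sigma2 + v2` and
#' `volatility = exp(mu3)`.
#'
#' `hgf2_filter()` eliminates volatility updates: `v2 = exp(omega2)` is
#' constant and no level-3 fields (`mu3`, `sigma3`, `alpha3`,
#' `volatility`) are emitted.
#'
#' `rw_filter()` is the Rescorla-Wagner delta rule
#' `v' = v + alpha_rw (u - v)` with fixed learning rate.
#'
#' `sk1_filter()` is a scalar Sutton K1 learner with meta-learned gain:
#' `delta = u - v`; `b' = b + mu_meta delta h`; `k = min(1, exp(b'))`;
#' `v' = clip(v + k delta, eps, 1 - eps)`;
#' `h' = h max(0, 1 - k) + k delta`. The gain `k` is exposed as the
#' trial-wise dynamic learning rate column `lr`.
#'
#' A numerically invalid state (non-positive `pi3`, non-finite posterior)
#' raises a condition of class `trajectory_invalid` carrying the trial
#' index; the fitting layer treats such parameter points as `-Inf`.
#'
#' @param u Binary (0/1) input sequence.
#' @param params Model parameters ([hgf_params()], [rw_params()],
#'   [sk1_params()]).
#' @return A `belief_trajectory`: a data.frame with one row per trial,
#'   with the model name and parameters as attributes.
#' @examples
#' traj <- hgf3_filter(rbinom(100, 1, 0.84), hgf_params())
#' head(traj[, c("muhat1", "alpha2", "alpha3")])
#' @export
hgf3_filter <- function(u, params = hgf_params()) {
  u <- check_u(u)
  core <- .hgf3_core(u, params$omega2, params$omega3, params$kappa,
                     params$mu2_0, params$sigma2_0,
                     params$mu3_0, params$sigma3_0)
  finish_trajectory(core, "hgf3", params, length(u))
}

#' @rdname hgf3_filter
#' @export
hgf2_filter <- function(u, params = hgf_params()) {
  u <- check_u(u)
  core <- .hgf2_core(u, params$omega2, params$mu2_0, params$sigma2_0)
  finish_trajectory(core, "hgf2", params, length(u))
}

#' Parameters for the Rescorla-Wagner learner
#' @param alpha_rw Fixed learning rate in (0, 1]; at 1 the prediction
#'   tracks the input with a one-trial lag.
#' @param v0 Initial prediction.
#' @return A list of class `rw_params`.
#' @export
rw_params <- function(alpha_rw = 0.1, v0 = 0.5) {
  if (alpha_rw <= 0 || alpha_rw > 1) stop("alpha_rw must lie in (0, 1]")
  structure(list(alpha_rw = alpha_rw, v0 = v0), class = "rw_params")
}

#' Parameters for the Sutton K1 learner
#' @param mu_meta Positive meta-learning rate.
#' @param v0,b0,h0 Initial prediction, log-gain and trace.
#' @param eps Clipping bound keeping predictions inside (0, 1).
#' @return A list of class `sk1_params`.
#' @export
sk1_params <- function(mu_meta = 0.1, v0 = 0.5, b0 = -2, h0 = 0,
                       eps = 1e-6) {
  if (mu_meta <= 0) stop("mu_meta must be positive")
  structure(list(mu_meta = mu_meta, v0 = v0, b0 = b0, h0 = h0, eps = eps),
            class = "sk1_params")
}

#' @rdname hgf3_filter
#' @export
rw_filter <- function(u, params = rw_params()) {
  u <- check_u(u)
  core <- .rw_core(u, params$alpha_rw, params$v0)
  finish_trajectory(core, "rw", params, length(u))
}

#' @rdname hgf3_filter
#' @export
sk1_filter <- function(u, params = sk1_params()) {
  u <- check_u(u)
  core <- .sk1_core(u, params$mu_meta, params$v0, params$b0, params$h0,
                    params$eps)
  finish_trajectory(core, "sk1", params, length(u))
}

#' @export
print.belief_trajectory <- function(x, ...) {
  cat("Belief trajectory (", attr(x, "model"), "): ", nrow(x),
      " trials, fields: ", paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}
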