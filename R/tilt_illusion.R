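#' Tilt-illusion psychophysics pipeline
#'
#' The tilt illusion is the perceptual repulsion of a central grating's
#' apparent orientation away from the orientation of a surrounding
#' annular grating; its magnitude indexes sensitivity to spatial context.
#' The pipeline measures, per (simulated) participant: an orientation
#' discrimination threshold by 1-up-2-down adaptive staircase; a point of
#' perceptual equality (PSE) by a short adjustment procedure; a
#' seven-orientation two-interval forced-choice session built from both;
#' and a logistic psychometric fit of the illusion magnitude with
#' parametric-bootstrap standard errors and Monte-Carlo goodness of fit.
#'
#' @name tilt_illusion
NULL

#' Staircase configuration
#'
#' 1-up-2-down rule: an incorrect response increases the orientation
#' difference by `step` degrees; two consecutive correct responses
#' decrease it by `step`. The run stops after `stop_reversals` direction
#' reversals and the threshold is the mean difference over the last
#' `average_last` reversals — the level at which the observer is correct
#' 70.71% of the time (the rule's fixed point satisfies p^2 = 1/2).
#'
#' @param step Step size in degrees.
#' @param stop_reversals Reversals at which the run terminates.
#' @param average_last Number of final reversals averaged into the
#'   threshold.
#' @param start_difference Initial orientation difference in degrees.
#'   Default 1, on the order of the expected threshold: with the fixed
#'   0.1-degree step, starting far above threshold leaves the run in its
#'   descent transient for most of the 19 reversals and biases the
#'   last-13-reversal average upward.
#' @return A list of class `staircase_config`.
#' @export
staircase_config <- function(step = 0.1, stop_reversals = 19L,
                             average_last = 13L, start_difference = 1) {
  if (step <= 0) stop("step must be positive")
  if (average_last > stop_reversals)
    stop("average_last cannot exceed stop_reversals")
  structure(list(step = step, stop_reversals = as.integer(stop_reversals),
                 average_last = as.integer(average_last),
                 start_difference = start_difference),
            class = "staircase_config")
}

#' Simulated psychophysical observers
#'
#' `disc_observer()` builds a two-alternative forced-choice
#' discrimination observer for the staircase: its probability of a
#' correct response rises logistically with the absolute orientation
#' difference `d`, from chance at `d = 0` towards `1 - 2 lapse`:
#' `p(d) = 0.5 + (0.5 - lapse) (2 logistic(d / scale) - 1)`.
#'
#' `tilt_observer()` builds an illusion observer for the 2IFC session:
#' the probability of judging the variable grating clockwise of the
#' surrounded reference follows the psychometric function
#' `psi(x; a, b, c, d)` of [psy_fun()] with `a = a_true` (the true
#' illusion magnitude in degrees), slope `b_true`, and guess/lapse rates
#' `c`/`d`. `pse_noise` is the SD of a single PSE adjustment trial.
#'
#' @param scale Discrimination scale in degrees (threshold is
#'   approximately `0.92 * scale`).
#' @param lapse Lapse rate.
#' @param a_true,b_true True illusion magnitude (degrees) and slope.
#' @param guess Guess rate `c`.
#' @param pse_noise SD (degrees) of one PSE adjustment.
#' @return Lists of class `disc_observer` / `tilt_observer`; a
#'   `disc_observer` has a function `p_correct(d)`.
#' @export
disc_observer <- function(scale = 1, lapse = 0.02) {
  if (scale <= 0) stop("scale must be positive")
  structure(list(scale = scale, lapse = lapse,
                 p_correct = function(d)
                   0.5 + (0.5 - lapse) * (2 * plogis(abs(d) / scale) - 1)),
            class = "disc_observer")
}

#' @rdname disc_observer
#' @export
tilt_observer <- function(a_true = -1.3, b_true = 1.5, guess = 0.02,
                          lapse = 0.02, pse_noise = 0.3) {
  if (b_true <= 0) stop("b_true must be positive")
  if (guess < 0 || guess >= 0.5 || lapse < 0 || lapse >= 0.5)
    stop("guess and lapse rates must lie in [0, 0.5)")
  structure(list(a_true = a_true, b_true = b_true, guess = guess,
                 lapse = lapse, pse_noise = pse_noise),
            class = "tilt_observer")
}

#' Run a 1-up-2-down adaptive staircase
#'
#' @param config A [staircase_config()].
#' @param observer A [disc_observer()].
#' @param seed Integer seed (responses are Bernoulli draws from the
#'   observer).
#' @return A `staircase_result`: list with the trial table
#'   (`difference`, `correct`), `reversal_values`, `threshold`, and a
#'   `clamped` flag (TRUE when the difference was held at `step` to stay
#'   positive).
#' @examples
#' res <- run_staircase(staircase_config(), disc_observer(scale = 1),
#'                      seed = 3)
#' res$threshold
#' @export
run_staircase <- function(config = staircase_config(),
                          observer = disc_observer(), seed = 1L) {
  set.seed(seed)
  d <- config$start_difference
  n_correct <- 0L
  last_dir <- 0L
  reversals <- numeric(0)
  difference <- numeric(0)
  correct <- logical(0)
  clamped <- FALSE
  while (length(reversals) < config$stop_reversals) {
    resp_ok <- runif(1) < observer$p_correct(d)
    difference <- c(difference, d)
    correct <- c(correct, resp_ok)
    if (resp_ok) {
      n_correct <- n_correct + 1L
      dir <- if (n_correct == 2L) -1L else 0L
      if (n_correct == 2L) n_correct <- 0L
    } else {
      n_correct <- 0L
      dir <- 1L
    }
    if (dir != 0L) {
      if (last_dir != 0L && dir != last_dir)
        reversals <- c(reversals, d)   # level at which direction flipped
      last_dir <- dir
      d <- d + dir * config$step
      if (d < config$step) {
        # floor bounce: the difference cannot shrink further; count it as
        # a reversal so a (near-)perfect observer still terminates
        d <- config$step
        clamped <- TRUE
        reversals <- c(reversals, d)
      }
    }
    if (length(difference) > 1e5)
      stop("staircase failed to terminate within 1e5 trials")
  }
  tail_rev <- reversals[(length(reversals) - config$average_last + 1):
                          length(reversals)]
  structure(
    list(trials = data.frame(difference = difference, correct = correct),
         reversal_values = reversals,
         threshold = mean(tail_rev),
         clamped = clamped, seed = as.integer(seed)),
    class = "staircase_result")
}

#' Construct the seven-orientation stimulus set
#'
#' `o_i = a_pse + 1.5 s (i - 4)` for `i = 1..7`: seven orientations
#' centred on the participant's point of perceptual equality and spaced
#' by 1.5 discrimination thresholds.
#'
#' @param a_pse Point of perceptual equality (degrees).
#' @param s Orientation discrimination threshold (degrees), positive.
#' @return List of class `orientation_set` with `o` (length 7), `a_pse`,
#'   `s`.
#' @examples
#' make_orientation_set(0, 1)$o   # -4.5 -3 -1.5 0 1.5 3 4.5
#' @export
make_orientation_set <- function(a_pse, s) {
  if (s <= 0) stop("discrimination threshold s must be positive")
  structure(list(o = a_pse + 1.5 * s * (-3:3), a_pse = a_pse, s = s),
            class = "orientation_set")
}

#' Psychometric function
#'
#' `psi(x; a, b, c, d) = c + (1 - c - d) F(x; a, b)` with the logistic
#' `F(x; a, b) = 1 / (1 + exp(-b (x - a)))`. `a` is the tilt-illusion
#' magnitude, `b` the slope, `c` the guess rate and `d` the lapse rate.
#'
#' @param x Orientation (degrees).
#' @param a,b,c,d Parameters.
#' @return Probability of a clockwise response.
#' @export
psy_fun <- function(x, a, b, c = 0.02, d = 0.02) {
  c + (1 - c - d) * plogis(b * (x - a))
}

#' Simulate a tilt-illusion 2IFC session
#'
#' Presents each of the seven orientations `reps` times in seeded random
#' order; responses are Bernoulli draws from the observer's psychometric
#' function. The interval carrying the surround is randomised.
#'
#' @param set An [make_orientation_set()] result.
#' @param observer A [tilt_observer()].
#' @param reps Presentations per orientation (default 18, i.e. 126
#'   trials).
#' @param seed Integer seed.
#' @return Data.frame of class `tilt_session`: `trial`, `orientation`,
#'   `with_surround_interval`, `response_cw`.
#' @export
simulate_tilt_session <- function(set, observer, reps = 18L, seed = 1L) {
  if (reps < 1L) stop("reps must be at least 1")
  set.seed(seed)
  x <- sample(rep(set$o, each = reps))
  p <- psy_fun(x, observer$a_true, observer$b_true, observer$guess,
               observer$lapse)
  structure(
    data.frame(trial = seq_along(x), orientation = x,
               with_surround_interval = sample(1:2, length(x), replace = TRUE),
               response_cw = rbinom(length(x), 1L, p)),
    class = c("tilt_session", "data.frame"))
}

#' Measure the point of perceptual equality
#'
#' Mean of `n_adjust` adjustment trials, each a Gaussian draw around the
#' observer's true illusion magnitude with SD `pse_noise`.
#'
#' @param observer A [tilt_observer()].
#' @param n_adjust Number of adjustment trials.
#' @param seed Integer seed.
#' @return The measured PSE in degrees.
#' @export
measure_pse <- function(observer, n_adjust = 4L, seed = 1L) {
  if (n_adjust < 1L) stop("n_adjust must be at least 1")
  set.seed(seed)
  mean(rnorm(n_adjust, observer$a_true, observer$pse_noise))
}

# Aggregate a session to per-orientation binomial cells.
tilt_cells <- function(trials) {
  agg <- aggregate(cbind(k = trials$response_cw,
                         n = rep(1L, nrow(trials))),
                   by = list(x = trials$orientation), FUN = sum)
  agg[order(agg$x), ]
}

psy_nll <- function(par, cells, guess, lapse) {
  p <- psy_fun(cells$x, par[1], exp(par[2]), guess, lapse)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(cells$k * log(p) + (cells$n - cells$k) * log(1 - p))
}

fit_psy_mle <- function(cells, guess, lapse, starts, reltol = 1e-10) {
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[s, ], psy_nll, cells = cells, guess = guess,
            lapse = lapse, method = "Nelder-Mead",
            control = list(maxit = 500, reltol = reltol)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  best
}

#' Fit the psychometric function to a tilt session
#'
#' Bernoulli maximum likelihood over `(a, b)` with the guess and lapse
#' rates fixed (0.02 by default), the slope constrained positive via a
#' log transform, and 5 deterministic starts. Standard errors and the
#' 68% confidence interval for the illusion magnitude come from a
#' parametric bootstrap (`n_boot` simulations from the fitted curve,
#' refit each); goodness of fit compares the observed deviance (twice
#' the log-likelihood ratio against the saturated binomial model) with
#' `n_gof` Monte-Carlo deviances simulated from the fitted curve.
#'
#' The fit is flagged `excluded` when the goodness-of-fit test fails
#' (`gof_p < 0.05`) or the 68% bootstrap percentile interval for `a` is
#' wider than the orientation range `o7 - o1`.
#'
#' @param trials A `tilt_session` data.frame (`orientation`,
#'   `response_cw`).
#' @param n_boot Bootstrap simulations (default 1000).
#' @param n_gof Goodness-of-fit simulations (default 1000; 0 skips the
#'   test).
#' @param seed Integer seed for bootstrap and Monte-Carlo draws.
#' @param guess,lapse Fixed guess and lapse rates.
#' @return A `psychometric_fit`: list with `a`, `b`, `se_a`, `se_b`,
#'   `ci68_a`, `gof_p`, `excluded`, `reason`, `n_trials`, `loglik`.
#' @export
fit_psychometric <- function(trials, n_boot = 1000L, n_gof = 1000L,
                             seed = 1L, guess = 0.02, lapse = 0.02) {
  cells <- tilt_cells(trials)
  if (nrow(cells) < 2L)
    stop("need responses at >= 2 distinct orientations")
  o_range <- max(cells$x) - min(cells$x)
  out <- list(a = NA_real_, b = NA_real_, se_a = NA_real_, se_b = NA_real_,
              ci68_a = c(NA_real_, NA_real_), gof_p = NA_real_,
              excluded = FALSE, reason = NA_character_,
              n_trials = sum(cells$n), loglik = NA_real_)
  class(out) <- "psychometric_fit"
  if (sum(cells$k) == 0L || sum(cells$k) == sum(cells$n)) {
    out$excluded <- TRUE
    out$reason <- "degenerate data: all responses identical"
    return(out)
  }

  span <- max(o_range, 1e-6)
  a0 <- sum(cells$x * cells$n) / sum(cells$n)
  starts <- rbind(c(a0, 0),
                  c(a0, log(4 / span)),
                  c(a0 - span / 4, log(1)),
                  c(a0 + span / 4, log(1)),
                  c(a0, log(0.25)))
  best <- fit_psy_mle(cells, guess, lapse, starts)
  if (is.null(best)) {
    out$excluded <- TRUE
    out$reason <- "maximum-likelihood fit failed"
    return(out)
  }
  out$a <- best$par[1]
  out$b <- exp(best$par[2])
  out$loglik <- -best$value

  set.seed(seed)
  p_hat <- psy_fun(cells$x, out$a, out$b, guess, lapse)
  refit <- function(k_sim) {
    cs <- cells
    cs$k <- k_sim
    fit_psy_mle(cs, guess, lapse, matrix(best$par, nrow = 1),
                reltol = 1e-8)
  }
  if (n_boot > 0L) {
    ab <- matrix(NA_real_, n_boot, 2)
    for (i in seq_len(n_boot)) {
      r <- refit(rbinom(nrow(cells), cells$n, p_hat))
      if (!is.null(r)) ab[i, ] <- c(r$par[1], exp(r$par[2]))
    }
    ab <- ab[is.finite(ab[, 1]), , drop = FALSE]
    out$se_a <- sd(ab[, 1])
    out$se_b <- sd(ab[, 2])
    out$ci68_a <- unname(quantile(ab[, 1], c(0.16, 0.84)))
  }
  if (n_gof > 0L) {
    dev_obs <- psy_deviance(cells, p_hat)
    dev_sim <- numeric(n_gof)
    for (i in seq_len(n_gof)) {
      k_sim <- rbinom(nrow(cells), cells$n, p_hat)
      cs <- cells
      cs$k <- k_sim
      r <- refit(k_sim)
      dev_sim[i] <- if (is.null(r)) NA_real_ else
        psy_deviance(cs, psy_fun(cs$x, r$par[1], exp(r$par[2]), guess, lapse))
    }
    dev_sim <- dev_sim[is.finite(dev_sim)]
    out$gof_p <- mean(dev_sim >= dev_obs)
  }

  fails_gof <- n_gof > 0L && is.finite(out$gof_p) && out$gof_p < 0.05
  too_wide <- is.finite(out$ci68_a[2]) &&
    (out$ci68_a[2] - out$ci68_a[1]) > o_range
  if (fails_gof || too_wide) {
    out$excluded <- TRUE
    out$reason <- paste(c(if (fails_gof) "goodness-of-fit failure",
                          if (too_wide) "68% CI wider than orientation range"),
                        collapse = "; ")
  }
  out
}

# Deviance against the saturated binomial model.
psy_deviance <- function(cells, p_fit) {
  p_sat <- cells$k / cells$n
  term <- function(k, n, p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    k * log(p) + (n - k) * log(1 - p)
  }
  2 * sum(term(cells$k, cells$n, p_sat) - term(cells$k, cells$n, p_fit))
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Psychometric fit: a = ", format(x$a, digits = 4),
      " deg (SE ", format(x$se_a, digits = 3), "), b = ",
      format(x$b, digits = 4), "\n", sep = "")
  if (is.finite(x$gof_p)) cat("  goodness-of-fit p = ", x$gof_p, "\n", sep = "")
  if (isTRUE(x$excluded)) cat("  EXCLUDED: ", x$reason, "\n", sep = "")
  invisible(x)
}
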