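#' Specification of a synthetic cohort
#'
#' Defines the generative population the validation suite simulates in
#' place of human participants: two groups of subjects whose perceptual
#' (`omega2`, `omega3`) and response (`beta0`-`beta4`, `zeta`) parameters
#' are drawn from Gaussian group distributions, whose PAL reaction times
#' are generated by the three-level HGF driving the linear response
#' model, and whose tilt-illusion sessions come from a logistic observer.
#'
#' Defaults encode the study scenario the analysis is designed to
#' detect: a `+0.7` shift of the second group's mean `omega2` (faster
#' probability learning), additive log-RT offsets of 0/0.03/0.06 across
#' image-noise levels, an error model logistic in noise level and
#' outcome improbability calibrated to ~90-95% overall accuracy, and
#' tilt observers with illusion magnitude around -1.34 degrees
#' (SD 0.83).
#'
#' @param n_per_group Subjects per group.
#' @param groups Two group labels.
#' @param omega2_shift Additive shift of group 2's mean `omega2` (0 for
#'   a null scenario).
#' @param params Named list of `c(mean, sd)` pairs for `omega2`,
#'   `omega3`, `beta0`-`beta4`, `log_zeta`.
#' @param error_model Coefficients of the trial error model
#'   `p(error) = logistic(intercept + noise * noise_index
#'   + improb * (1 - p(outcome|cue)))` with noise index 0/1/2.
#' @param noise_offsets Additive log-RT offset per noise level.
#' @param tilt List: `a_mean`, `a_sd` (illusion magnitude distribution,
#'   degrees), `b_mean`, `b_sd` (slope), `pse_noise`,
#'   `disc_scale_meanlog`, `disc_scale_sdlog` (log-normal
#'   discrimination scale).
#' @param seed Master seed; every subject-level seed derives from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 36L, groups = c("A", "B"),
                        omega2_shift = 0.7,
                        params = list(
                          omega2 = c(-3, 1), omega3 = c(-6, 1),
                          beta0 = c(-0.3, 0.2), beta1 = c(0.1, 0.03),
                          beta2 = c(0.5, 0.1), beta3 = c(0.5, 0.1),
                          beta4 = c(0.8, 0.2),
                          log_zeta = c(log(0.04), 0.3)),
                        error_model = c(intercept = -3.5, noise = 0.25,
                                        improb = 1.0),
                        noise_offsets = c(low = 0, medium = 0.03,
                                          high = 0.06),
                        tilt = list(a_mean = -1.342, a_sd = 0.828,
                                    b_mean = 1.5, b_sd = 0.3,
                                    pse_noise = 0.3,
                                    disc_scale_meanlog = 0,
                                    disc_scale_sdlog = 0.3),
                        seed = 1L) {
  if (n_per_group < 1L) stop("n_per_group must be at least 1")
  if (length(groups) != 2L) stop("exactly two groups are supported")
  sds <- vapply(params, `[`, numeric(1), 2)
  if (any(sds < 0)) stop("parameter SDs must be non-negative")
  if (exp(params$log_zeta[1]) <= 0) stop("zeta mean must be positive")
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 omega2_shift = omega2_shift, params = params,
                 error_model = error_model, noise_offsets = noise_offsets,
                 tilt = tilt, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of synthetic participants
#'
#' Per subject: draws ground-truth parameters from the group
#' distributions; generates a fresh PAL schedule (seeded per subject);
#' runs the three-level HGF on the schedule's binary input; simulates
#' log RTs from the response model plus the noise-level offsets; draws
#' error trials from the error model; and generates a tilt-illusion
#' session (PSE adjustment, 1-up-2-down staircase, seven-orientation
#' 2IFC block). Fully deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort`: list with `subjects` (list; each has
#'   `subject_id`, `group`, `seed`, `true_params`, `schedule` with
#'   simulated `rt_ms`/`accuracy`, and `tilt` with observer truth,
#'   measured PSE, staircase threshold and the session table) and
#'   `manifest` (one row per subject of ground truth — the test oracle).
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_per_group = 2, seed = 11))
#' coh$manifest[, c("subject_id", "group", "omega2")]
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  n_total <- 2L * spec$n_per_group
  set.seed(spec$seed)
  subj_seeds <- sample.int(1e8L, n_total) * 20L  # derived seeds are +1..+17
  groups <- rep(spec$groups, each = spec$n_per_group)

  subjects <- vector("list", n_total)
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sched <- generate_schedule(schedule_config(seed = subj_seeds[i] + 1L))
    # The generative population is the numerically valid support of the
    # three-level HGF: parameter draws whose trajectory degenerates on
    # this schedule (large omega2 pushing the level-3 precision
    # non-positive) are rejected and redrawn, deterministically.
    attempt <- 0L
    repeat {
      set.seed(subj_seeds[i] + 17L * attempt)
      draw <- function(nm) rnorm(1, spec$params[[nm]][1], spec$params[[nm]][2])
      tp <- c(omega2 = draw("omega2") +
                if (groups[i] == spec$groups[2]) spec$omega2_shift else 0,
              omega3 = draw("omega3"), beta0 = draw("beta0"),
              beta1 = draw("beta1"), beta2 = draw("beta2"),
              beta3 = draw("beta3"), beta4 = draw("beta4"),
              log_zeta = draw("log_zeta"))
      tl <- spec$tilt
      a_true <- rnorm(1, tl$a_mean, tl$a_sd)
      b_true <- abs(rnorm(1, tl$b_mean, tl$b_sd)) + 1e-3
      disc_scale <- exp(rnorm(1, tl$disc_scale_meanlog, tl$disc_scale_sdlog))

      traj <- tryCatch(
        hgf3_filter(sched$u, hgf_params(omega2 = tp[["omega2"]],
                                        omega3 = tp[["omega3"]])),
        trajectory_invalid = function(e) NULL)
      if (!is.null(traj)) break
      attempt <- attempt + 1L
      if (attempt > 50L)
        stop("could not draw valid parameters for subject ", i)
    }
    rpar <- response_params(beta0 = tp[["beta0"]], beta1 = tp[["beta1"]],
                            beta2 = tp[["beta2"]], beta3 = tp[["beta3"]],
                            beta4 = tp[["beta4"]],
                            log_zeta = tp[["log_zeta"]])
    sched$rt_ms <- simulate_rts(rpar, traj, sched, seed = subj_seeds[i] + 3L,
                                noise_offsets = spec$noise_offsets)
    set.seed(subj_seeds[i] + 5L)
    noise_idx <- match(sched$noise, names(spec$noise_offsets)) - 1L
    p_outcome <- ifelse(sched$u == 1L, sched$p_face_given_high,
                        1 - sched$p_face_given_high)
    p_err <- plogis(spec$error_model[["intercept"]] +
                      spec$error_model[["noise"]] * noise_idx +
                      spec$error_model[["improb"]] * (1 - p_outcome))
    sched$accuracy <- 1L - rbinom(nrow(sched), 1L, p_err)

    obs <- tilt_observer(a_true = a_true, b_true = b_true,
                         pse_noise = tl$pse_noise)
    a_pse <- measure_pse(obs, seed = subj_seeds[i] + 7L)
    stair <- run_staircase(staircase_config(),
                           disc_observer(scale = disc_scale),
                           seed = subj_seeds[i] + 9L)
    oset <- make_orientation_set(a_pse, stair$threshold)
    session <- simulate_tilt_session(oset, obs, seed = subj_seeds[i] + 11L)

    sid <- sprintf("S%03d", i)
    subjects[[i]] <- list(subject_id = sid, group = groups[i],
                          seed = subj_seeds[i], true_params = tp,
                          schedule = sched,
                          tilt = list(a_true = a_true, b_true = b_true,
                                      disc_scale = disc_scale,
                                      a_pse = a_pse,
                                      threshold = stair$threshold,
                                      staircase = stair, set = oset,
                                      session = session))
    rows[[i]] <- data.frame(subject_id = sid, group = groups[i],
                            seed = subj_seeds[i], t(tp),
                            tilt_a_true = a_true, tilt_b_true = b_true,
                            mean_accuracy = mean(sched$accuracy))
  }
  structure(list(subjects = subjects, manifest = do.call(rbind, rows),
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$subjects), "subjects (",
      paste(x$spec$groups, collapse = " / "), "), seed",
      x$spec$seed, "\n")
  cat("  mean accuracy:",
      round(mean(x$manifest$mean_accuracy), 3), "\n")
  invisible(x)
}

#' Write a cohort to a directory of plain-text files
#'
#' One trials CSV per subject plus a JSON manifest of ground-truth
#' parameters and seeds.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects)
    write_trials(s$schedule, file.path(dir, paste0(s$subject_id,
                                                   "_trials.csv")))
  jsonlite::write_json(
    list(spec_seed = cohort$spec$seed,
         subjects = cohort$manifest),
    file.path(dir, "manifest.json"),
    dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
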