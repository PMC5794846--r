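#' Condition-mean reaction times
#'
#' Mean RT over correct trials for each expectedness x noise cell of the
#' PAL task (9 cells). Subjects with one or more empty cells are flagged
#' so they can be excluded from condition-level analyses.
#'
#' @param schedule A `pal_schedule` with `expectedness` and `noise`.
#' @param rts RTs in milliseconds (default `schedule$rt_ms`).
#' @param accuracy 0/1 accuracy flags (default `schedule$accuracy`).
#' @return A `condition_table`: data.frame with `expectedness`, `noise`,
#'   `mean_rt_ms`, `n_trials`, and attribute `flagged` (TRUE when any
#'   cell is empty).
#' @export
condition_means <- function(schedule, rts = NULL, accuracy = NULL) {
  rts <- rts %||% schedule$rt_ms
  accuracy <- accuracy %||% schedule$accuracy
  if (length(rts) != nrow(schedule) || length(accuracy) != nrow(schedule))
    stop("rts and accuracy must be aligned with the schedule")
  cells <- expand.grid(expectedness = c("expected", "neutral", "unexpected"),
                       noise = c("low", "medium", "high"),
                       stringsAsFactors = FALSE)
  ok <- !is.na(accuracy) & accuracy == 1L & !is.na(rts)
  cells$mean_rt_ms <- NA_real_
  cells$n_trials <- 0L
  for (i in seq_len(nrow(cells))) {
    sel <- ok & schedule$expectedness == cells$expectedness[i] &
      schedule$noise == cells$noise[i]
    cells$n_trials[i] <- sum(sel)
    if (any(sel)) cells$mean_rt_ms[i] <- mean(rts[sel])
  }
  structure(cells, class = c("condition_table", "data.frame"),
            flagged = any(cells$n_trials == 0L))
}

#' Phase means of the dynamic learning rates
#'
#' Mean trial-wise learning rate in the stable and the volatile task
#' phases, for `alpha2` (probability learning) and, when the trajectory
#' defines it, `alpha3` (volatility learning). Requesting `alpha3` from
#' a learner that does not track volatility (e.g. the two-level HGF) is
#' an error.
#'
#' @param trajectory A `belief_trajectory` aligned with `schedule`.
#' @param schedule A `pal_schedule` with phase labels.
#' @param rates Which rates to summarise; default all the trajectory
#'   defines.
#' @return Data.frame with `rate`, `stable`, `volatile` columns; a phase
#'   absent from the schedule yields `NA` with attribute
#'   `missing_phases`.
#' @export
phase_learning_rates <- function(trajectory, schedule, rates = NULL) {
  if (nrow(trajectory) != nrow(schedule))
    stop("trajectory and schedule must be aligned 1:1")
  available <- intersect(c("alpha2", "alpha3"), names(trajectory))
  if (!length(available))
    stop("trajectory defines no dynamic learning rates")
  rates <- rates %||% available
  missing_rates <- setdiff(rates, available)
  if (length(missing_rates))
    stop("trajectory (", attr(trajectory, "model"), ") does not define: ",
         paste(missing_rates, collapse = ", "))
  phases <- c("stable", "volatile")
  out <- data.frame(rate = rates)
  for (ph in phases)
    out[[ph]] <- vapply(rates, function(r) {
      sel <- schedule$phase == ph
      if (!any(sel)) NA_real_ else mean(trajectory[[r]][sel])
    }, numeric(1))
  structure(out, missing_phases = phases[!phases %in% schedule$phase])
}

#' Two-by-two mixed-design ANOVA
#'
#' Repeated-measures ANOVA with one two-level within-subject factor
#' (task phase: stable vs volatile) and one two-level between-subject
#' factor (group), the design used to compare learning-rate trajectories
#' across phases and groups. Sums of squares are decomposed by the
#' classical split-plot model (between-subject stratum: group vs
#' subjects-within-groups; within-subject stratum: phase and phase x
#' group vs phase x subjects-within-groups), fitted via
#' `stats::aov` with an `Error(subject/phase)` stratum. Partial eta
#' squared is `SS_effect / (SS_effect + SS_error)` with each effect's
#' own error stratum.
#'
#' @param data Long data.frame with columns `subject`, `phase` (two
#'   levels), `group` (two levels), `value`; one value per subject x
#'   phase.
#' @return Data.frame with `effect` (`group`, `phase`, `phase:group`),
#'   `df1`, `df2`, `F`, `p`, `peta2`.
#' @export
mixed_anova_2x2 <- function(data) {
  need <- c("subject", "phase", "group", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns subject, phase, group, value")
  data$subject <- factor(data$subject)
  data$phase <- factor(data$phase)
  data$group <- factor(data$group)
  if (nlevels(data$phase) != 2L || nlevels(data$group) != 2L)
    stop("phase and group must each have exactly two levels")
  counts <- table(data$subject, data$phase)
  if (any(counts != 1L))
    stop("need exactly one value per subject and phase (balanced design)")
  if (any(table(unique(data[, c("subject", "group")])$group) < 2L))
    stop("need at least 2 subjects per group")

  fit <- aov(value ~ group * phase + Error(subject / phase), data = data)
  sm <- summary(fit)
  btw <- as.data.frame(sm[["Error: subject"]][[1]])
  wth <- as.data.frame(sm[["Error: subject:phase"]][[1]])
  row_of <- function(tab, nm) {
    i <- which(trimws(rownames(tab)) == nm)
    if (!length(i)) stop("ANOVA term not found: ", nm)
    tab[i, ]
  }
  ss <- function(r) r[["Sum Sq"]]
  mkrow <- function(effect, eff_row, err_row) {
    data.frame(effect = effect,
               df1 = eff_row[["Df"]], df2 = err_row[["Df"]],
               F = eff_row[["F value"]], p = eff_row[["Pr(>F)"]],
               peta2 = ss(eff_row) / (ss(eff_row) + ss(err_row)))
  }
  rbind(
    mkrow("group", row_of(btw, "group"), row_of(btw, "Residuals")),
    mkrow("phase", row_of(wth, "phase"), row_of(wth, "Residuals")),
    mkrow("phase:group", row_of(wth, "group:phase"), row_of(wth, "Residuals")))
}

#' Cross-task Pearson correlation
#'
#' Pearson product-moment correlation with a two-sided t-based p value,
#' used to relate context-sensitivity measures across the temporal
#' (learning) and spatial (tilt illusion) tasks.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `r`, `p`, `n`, `conf_int` (95%).
#' @export
cross_task_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       conf_int = as.numeric(ct$conf.int))
}
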