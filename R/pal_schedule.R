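#' Configuration for the probabilistic associative learning task
#'
#' The PAL task pairs an auditory cue (high or low tone) with a visual
#' outcome (face or house). The cue-outcome contingency
#' `p(face | high tone)` changes across contiguous *periods* of 12, 36 or
#' 72 trials, taking one of three levels: highly predictive (0.84),
#' neutral (0.5) or weakly predictive (0.16). Three blocks of 168, 120 and
#' 168 trials give 456 trials in total. Long single-contingency periods
#' form *stable* phases; runs of short 12-trial periods with switching
#' contingencies form *volatile* phases. Each period crosses both cues with
#' three image-noise levels in equal numbers.
#'
#' @param block_lengths Integer vector of trials per block.
#' @param contingency_levels Allowed contingency probabilities.
#' @param period_lengths Allowed period lengths (trials); each must be
#'   divisible by 6 (2 cues x 3 noise levels).
#' @param noise_levels Ordered labels for the three image-noise levels.
#' @param phase_plan List with one element per block; each element is a
#'   list of periods, each period a list with `length`, `p`
#'   (the period's `p(face | high)`) and `phase` (`"stable"` or
#'   `"volatile"`). Defaults to [default_phase_plan()].
#' @param seed Integer seed controlling cue/noise shuffling and outcome
#'   draws in [generate_schedule()].
#' @return An object of class `schedule_config`.
#' @seealso [generate_schedule()]
#' @export
schedule_config <- function(block_lengths = c(168L, 120L, 168L),
                            contingency_levels = c(0.84, 0.5, 0.16),
                            period_lengths = c(12L, 36L, 72L),
                            noise_levels = c("low", "medium", "high"),
                            phase_plan = default_phase_plan(),
                            seed = 1L) {
  block_lengths <- as.integer(block_lengths)
  if (any(block_lengths <= 0L)) stop("block_lengths must be positive")
  if (any(contingency_levels < 0 | contingency_levels > 1))
    stop("contingency levels must lie in [0, 1]")
  if (any(period_lengths %% 6L != 0L))
    stop("every period length must be divisible by 6 (2 cues x 3 noise levels)")
  if (length(noise_levels) != 3L) stop("exactly 3 noise levels are required")
  if (length(phase_plan) != length(block_lengths))
    stop("phase_plan must have one element per block")
  for (b in seq_along(phase_plan)) {
    lens <- vapply(phase_plan[[b]], function(p) as.integer(p$length), integer(1))
    if (any(lens %% 6L != 0L))
      stop("period length not divisible by 6 in block ", b)
    if (!all(lens %in% period_lengths))
      stop("period length outside period_lengths in block ", b)
    if (sum(lens) != block_lengths[b])
      stop("phase_plan periods in block ", b, " sum to ", sum(lens),
           ", expected ", block_lengths[b])
    ps <- vapply(phase_plan[[b]], function(p) p$p, numeric(1))
    if (any(ps < 0 | ps > 1)) stop("contingency outside [0, 1] in block ", b)
    phs <- vapply(phase_plan[[b]], function(p) p$phase, character(1))
    if (!all(phs %in% c("stable", "volatile")))
      stop("phase labels must be 'stable' or 'volatile'")
  }
  structure(
    list(block_lengths = block_lengths,
         contingency_levels = contingency_levels,
         period_lengths = as.integer(period_lengths),
         noise_levels = noise_levels,
         phase_plan = phase_plan,
         seed = as.integer(seed)),
    class = "schedule_config")
}

period_spec <- function(length, p, phase) list(length = length, p = p, phase = phase)

#' Default phase plan for the 456-trial PAL schedule
#'
#' Stable phases are sustained periods of 36 or 72 trials under one
#' contingency; volatile phases are runs of consecutive 12-trial periods
#' alternating between the strongly predictive levels. The exact sequence
#' is configuration, not a constant: any plan whose periods tile the
#' blocks is accepted by [schedule_config()].
#'
#' @return A list of three blocks of period specifications.
#' @export
default_phase_plan <- function() {
  list(
    # block 1 (168): long stable run, then a volatile tail
    list(period_spec(72L, 0.84, "stable"),
         period_spec(36L, 0.50, "stable"),
         period_spec(12L, 0.16, "volatile"),
         period_spec(12L, 0.84, "volatile"),
         period_spec(12L, 0.16, "volatile"),
         period_spec(12L, 0.84, "volatile"),
         period_spec(12L, 0.16, "volatile")),
    # block 2 (120): stable reversal, then volatile switching
    list(period_spec(72L, 0.16, "stable"),
         period_spec(12L, 0.84, "volatile"),
         period_spec(12L, 0.16, "volatile"),
         period_spec(12L, 0.84, "volatile"),
         period_spec(12L, 0.16, "volatile")),
    # block 3 (168): volatile opening, then long stable runs
    list(period_spec(12L, 0.84, "volatile"),
         period_spec(12L, 0.16, "volatile"),
         period_spec(12L, 0.84, "volatile"),
         period_spec(12L, 0.16, "volatile"),
         period_spec(12L, 0.84, "volatile"),
         period_spec(36L, 0.50, "stable"),
         period_spec(72L, 0.16, "stable")))
}

#' Generate a PAL task schedule
#'
#' Lays periods out according to the configuration's phase plan, assigns
#' cues and noise levels in equal numbers within every period (shuffled,
#' seeded), draws the visual outcome independently per trial from the
#' period's contingency, recodes the outcome as the binary cue-outcome
#' congruency `u`, and labels expectedness.
#'
#' `u = 1` iff (high tone and face) or (low tone and house). Because
#' `p(face | high) = 1 - p(house | high)` within a period, `P(u = 1)`
#' equals the period contingency for both cues, so a single binary
#' sequence tracks the contingency for every learner.
#'
#' @param config A [schedule_config()].
#' @return A `pal_schedule`: a data.frame with one row per trial and
#'   columns `index` (0-based), `block`, `period_id`, `phase`, `cue`,
#'   `noise`, `p_face_given_high`, `outcome`, `u`, `expectedness`,
#'   `accuracy`, `rt_ms` (the last two `NA` until simulated or supplied),
#'   with the config attached as an attribute.
#' @examples
#' sched <- generate_schedule(schedule_config(seed = 42))
#' nrow(sched)            # 456
#' table(sched$phase)
#' @export
generate_schedule <- function(config = schedule_config()) {
  if (!inherits(config, "schedule_config"))
    stop("config must be a schedule_config")
  set.seed(config$seed)
  rows <- list()
  period_id <- 0L
  for (b in seq_along(config$phase_plan)) {
    for (per in config$phase_plan[[b]]) {
      period_id <- period_id + 1L
      n <- as.integer(per$length)
      cells <- expand.grid(cue = c("high_tone", "low_tone"),
                           noise = config$noise_levels,
                           stringsAsFactors = FALSE)
      cells <- cells[rep(seq_len(nrow(cells)), each = n / 6L), ]
      cells <- cells[sample.int(n), ]
      face_if_high <- runif(n) < per$p
      face <- ifelse(cells$cue == "high_tone", face_if_high, !face_if_high)
      rows[[period_id]] <- data.frame(
        block = b,
        period_id = period_id,
        phase = per$phase,
        cue = cells$cue,
        noise = cells$noise,
        p_face_given_high = per$p,
        outcome = ifelse(face, "face", "house"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$index <- seq_len(nrow(out)) - 1L
  out$u <- recode_u(out$cue, out$outcome)
  out$accuracy <- NA_integer_
  out$rt_ms <- NA_real_
  out <- out[, c("index", "block", "period_id", "phase", "cue", "noise",
                 "p_face_given_high", "outcome", "u", "accuracy", "rt_ms")]
  rownames(out) <- NULL
  out <- structure(out, class = c("pal_schedule", "data.frame"),
                   config = config)
  label_expectedness(out)
}

recode_u <- function(cue, outcome) {
  as.integer((cue == "high_tone" & outcome == "face") |
             (cue == "low_tone" & outcome == "house"))
}

#' Label trial expectedness from the period contingency
#'
#' A trial is `expected` when the probability of its outcome given its cue
#' is 0.84, `neutral` at 0.5 and `unexpected` at 0.16. By complementarity
#' the probability of the observed outcome given the cue is the period
#' contingency when `u = 1` and its complement when `u = 0`. Idempotent.
#'
#' @param schedule A `pal_schedule` (or data.frame with `u` and
#'   `p_face_given_high`).
#' @return The schedule with an `expectedness` column.
#' @export
label_expectedness <- function(schedule) {
  p_outcome <- ifelse(schedule$u == 1L, schedule$p_face_given_high,
                      1 - schedule$p_face_given_high)
  lab <- rep(NA_character_, length(p_outcome))
  tol <- 1e-9
  lab[abs(p_outcome - 0.84) < tol] <- "expected"
  lab[abs(p_outcome - 0.50) < tol] <- "neutral"
  lab[abs(p_outcome - 0.16) < tol] <- "unexpected"
  if (anyNA(lab)) {
    bad <- unique(schedule$period_id[is.na(lab)])
    stop("cannot label expectedness: contingency not in {0.84, 0.5, 0.16} ",
         "in period(s) ", paste(bad, collapse = ", "))
  }
  schedule$expectedness <- lab
  schedule
}

#' @export
print.pal_schedule <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("PAL task schedule: ", nrow(x), " trials in ",
      length(unique(x$block)), " blocks, ",
      length(unique(x$period_id)), " contingency periods\n", sep = "")
  cat("  phases: ", paste(sprintf("%s=%d", names(table(x$phase)),
                                  as.integer(table(x$phase))),
                          collapse = ", "), "\n", sep = "")
  if (!is.null(cfg)) cat("  seed: ", cfg$seed, "\n", sep = "")
  invisible(x)
}

schedule_required_cols <- c("index", "cue", "outcome", "p_face_given_high",
                            "noise", "period_id", "phase")

#' Read / write PAL trial tables
#'
#' Trial tables round-trip through plain CSV. `read_trials()` validates
#' the required columns, recodes `u` from cue and outcome, and relabels
#' expectedness; unknown columns are preserved.
#'
#' @param path CSV file path.
#' @param schedule A `pal_schedule` or compatible data.frame.
#' @return `read_trials()` returns a `pal_schedule`; `write_trials()`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(schedule_required_cols, names(df))
  if (length(missing))
    stop("trial table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!all(df$outcome %in% c("face", "house")))
    stop("outcome codes must be 'face' or 'house'")
  if (!all(df$cue %in% c("high_tone", "low_tone")))
    stop("cue codes must be 'high_tone' or 'low_tone'")
  df$u <- recode_u(df$cue, df$outcome)
  if (is.null(df$accuracy)) df$accuracy <- NA_integer_
  if (is.null(df$rt_ms)) df$rt_ms <- NA_real_
  df <- structure(df, class = c("pal_schedule", "data.frame"))
  label_expectedness(df)
}

#' @rdname read_trials
#' @export
write_trials <- function(schedule, path) {
  write.csv(as.data.frame(schedule), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
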