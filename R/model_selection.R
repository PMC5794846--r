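#' Random-effects Bayesian model selection
#'
#' Treats the model generating each subject's data as a random effect
#' with population frequencies following a Dirichlet distribution, and
#' estimates the Dirichlet posterior from per-subject log model
#' evidences by the standard variational scheme: iterate, per subject
#' `n` and model `k`,
#' `u_nk ∝ exp(L_nk + psi(alpha_k) - psi(sum alpha))` (normalised over
#' `k`), then `alpha_k = alpha0 + sum_n u_nk`, until the largest change
#' in `alpha` falls below `tol`. Exceedance probabilities — the posterior
#' probability that each model is the most frequent in the population —
#' are estimated by seeded Dirichlet Monte Carlo.
#'
#' @param table Numeric matrix of log evidences, subjects x models, with
#'   model names as column names.
#' @param alpha0 Dirichlet prior count per model (default 1, uniform).
#' @param tol Convergence tolerance on `max |delta alpha|`.
#' @param max_iter Iteration cap.
#' @param mc_samples Dirichlet Monte-Carlo draws for exceedance
#'   probabilities.
#' @param seed Seed for the Monte-Carlo draws.
#' @return A `bms_result`: list with `dirichlet_alpha`,
#'   `expected_frequencies`, `exceedance_prob`, `n_iterations`,
#'   `mc_samples`, `seed`.
#' @examples
#' L <- cbind(m1 = c(0, 0, 0), m2 = c(3, 2, 4))
#' rfx_bms(L)$exceedance_prob
#' @export
rfx_bms <- function(table, alpha0 = 1, tol = 1e-6, max_iter = 1e4,
                    mc_samples = 1e6, seed = 1L) {
  table <- as.matrix(table)
  if (!all(is.finite(table))) stop("log evidences must all be finite")
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("need at least 2 subjects and 2 models")
  K <- ncol(table)
  N <- nrow(table)
  if (is.null(colnames(table))) colnames(table) <- paste0("model", seq_len(K))
  L <- table - apply(table, 1, max)   # per-subject normalisation

  alpha <- rep(alpha0, K)
  it <- 0L
  repeat {
    it <- it + 1L
    logu <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    logu <- logu - apply(logu, 1, max)
    u <- exp(logu)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
    if (it >= max_iter)
      stop("random-effects BMS failed to converge in ", max_iter,
           " iterations")
  }

  set.seed(seed)
  g <- matrix(rgamma(mc_samples * K, shape = rep(alpha, each = mc_samples)),
              nrow = mc_samples, ncol = K)
  xp <- tabulate(max.col(g), nbins = K) / mc_samples

  structure(
    list(dirichlet_alpha = setNames(alpha, colnames(table)),
         expected_frequencies = setNames(alpha / sum(alpha), colnames(table)),
         exceedance_prob = setNames(xp, colnames(table)),
         n_subjects = N, n_iterations = it,
         mc_samples = mc_samples, seed = as.integer(seed)),
    class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects BMS over", length(x$dirichlet_alpha), "models,",
      x$n_subjects, "subjects\n")
  print(data.frame(model = names(x$dirichlet_alpha),
                   alpha = round(unname(x$dirichlet_alpha), 3),
                   expected_freq = round(unname(x$expected_frequencies), 4),
                   exceedance = round(unname(x$exceedance_prob), 4)))
  invisible(x)
}

#' Assemble an evidence table from subject fits
#'
#' @param fits A list (subjects) of lists (models) of `subject_fit`
#'   objects. Subjects with an undefined evidence for any model are
#'   dropped listwise with a message.
#' @return Numeric matrix subjects x models of log evidences.
#' @export
evidence_table <- function(fits) {
  models <- names(fits[[1]])
  tab <- t(vapply(fits, function(sf)
    vapply(models, function(m) sf[[m]]$log_evidence, numeric(1)),
    numeric(length(models))))
  colnames(tab) <- models
  bad <- !apply(is.finite(tab), 1, all)
  if (any(bad)) {
    message(sum(bad), " subject(s) dropped from BMS (undefined evidence)")
    tab <- tab[!bad, , drop = FALSE]
  }
  tab
}
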