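#' MCMC chain configuration
#'
#' Settings for the Metropolis-within-Gibbs sampler. The reference run uses
#' 110,000 iterations with a 10,000-iteration burn-in and thinning by 100
#' (1,000 retained draws). [chain_config_reduced()] gives the desk-scale
#' chain used by the scenario study (6,000 / 1,000 / 5, also 1,000 retained
#' draws).
#'
#' @param n_iterations Total iterations.
#' @param burn_in Iterations discarded before retention; must be smaller than
#'   `n_iterations`.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param proposal_scale Initial random-walk proposal SD; per-parameter scales
#'   are adapted during burn-in toward 30-45% acceptance, then frozen.
#' @param theta_c_prior_mean,theta_c_prior_variance Normal prior on the
#'   cheating ability, default N(1, 2) (mean 1, variance 2).
#' @param seed Integer seed for the chain.
#' @return A list of class `chain_config`.
#' @export
chain_config <- function(n_iterations = 110000, burn_in = 10000, thin = 100,
                         proposal_scale = 0.5, theta_c_prior_mean = 1,
                         theta_c_prior_variance = 2, seed = 1L) {
  if (burn_in >= n_iterations) rlang::abort("`burn_in` must be < `n_iterations`.")
  if (thin < 1) rlang::abort("`thin` must be >= 1.")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 proposal_scale = proposal_scale,
                 theta_c_prior_mean = theta_c_prior_mean,
                 theta_c_prior_variance = theta_c_prior_variance,
                 seed = as.integer(seed)),
            class = "chain_config")
}

#' @rdname chain_config
#' @export
chain_config_reduced <- function(seed = 1L, ...) {
  chain_config(n_iterations = 6000, burn_in = 1000, thin = 5, seed = seed, ...)
}

#' Fit the gated item response model by MCMC
#'
#' Fits the deterministic gated mixture of two 1-PL models to a binary
#' response matrix with known item exposure flags. Priors: true ability and
#' difficulty standard normal, cheating ability N(1, 2) by default; the
#' cheater indicator of a draw is deterministic, `theta_t < theta_c`. The
#' per-student posterior cheater probability is the fraction of retained
#' draws in which that inequality holds.
#'
#' @param responses Binary response matrix (students x items) or a tibble
#'   with a `student_id` column and one 0/1 column per item.
#' @param exposed 0/1 vector of item exposure flags, one per item column.
#' @param chain A [chain_config()]; the run is deterministic given
#'   `(responses, exposed, chain$seed)`.
#' @param keep_draws Keep the retained ability/difficulty draws (needed for
#'   convergence diagnostics; default `TRUE`).
#' @param fixed_difficulty Optional numeric vector of known item
#'   difficulties; when supplied they are held fixed (anchored calibration)
#'   instead of being sampled.
#' @return An object of class `dgm_fit` with elements `students` (tibble:
#'   `student_id`, `p_cheater`, `theta_true_mean`, `theta_cheat_mean`),
#'   `items` (tibble: `item_id`, `exposed`, `difficulty_mean`),
#'   `retained_draws`, `acceptance_rate`, `diagnostics` (per-parameter
#'   effective sample size and split-chain scale reduction) and, optionally,
#'   the raw `draws`.
#' @export
fit_dgm <- function(responses, exposed, chain = chain_config(),
                    keep_draws = TRUE, fixed_difficulty = NULL) {
  y <- as_response_matrix(responses)
  exposed <- as.integer(exposed)
  if (length(exposed) != ncol(y) || !all(exposed %in% c(0L, 1L))) {
    rlang::abort("`exposed` must be a 0/1 flag per item column.")
  }
  if (sum(exposed) < 1) {
    rlang::abort("no exposed items: the gated model is unidentified.")
  }
  if (sum(exposed) == ncol(y)) {
    rlang::abort("no secure items: true ability is unanchored.")
  }
  if (!is.null(fixed_difficulty) && length(fixed_difficulty) != ncol(y)) {
    rlang::abort("`fixed_difficulty` must give one value per item.")
  }
  set.seed(chain$seed)
  raw <- dgm_sampler(y, exposed, chain$n_iterations, chain$burn_in,
                     chain$thin, chain$proposal_scale,
                     chain$theta_c_prior_mean, chain$theta_c_prior_variance,
                     fixed_difficulty)

  students <- tibble::tibble(
    student_id = rownames(y),
    p_cheater = as.numeric(raw$p_cheater),
    theta_true_mean = colMeans(raw$draws_theta_t),
    theta_cheat_mean = colMeans(raw$draws_theta_c))
  items <- tibble::tibble(
    item_id = colnames(y),
    exposed = exposed,
    difficulty_mean = colMeans(raw$draws_b))

  diagnostics <- mcmc_diagnostics(raw)
  out <- list(students = students, items = items,
              retained_draws = raw$retained_draws,
              acceptance_rate = raw$acceptance_rate,
              diagnostics = diagnostics, chain = chain)
  if (keep_draws) {
    out$draws <- list(theta_t = raw$draws_theta_t,
                      theta_c = raw$draws_theta_c, b = raw$draws_b)
  }
  structure(out, class = "dgm_fit")
}

# ESS from initial-positive-sequence autocorrelations; split-chain Rhat
ess_one <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 2L, 200L), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0.05) break
    s <- s + ac[k]
  }
  n / (1 + 2 * s)
}

split_rhat_one <- function(x) {
  n <- floor(length(x) / 2)
  halves <- list(x[seq_len(n)], x[n + seq_len(n)])
  m <- lengths(halves)[1]
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- m * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((m - 1) / m * W + B / m) / W)
}

mcmc_diagnostics <- function(raw) {
  per_mat <- function(mat, prefix) {
    tibble::tibble(
      parameter = paste0(prefix, "[", seq_len(ncol(mat)), "]"),
      ess = apply(mat, 2, ess_one),
      split_rhat = apply(mat, 2, split_rhat_one))
  }
  dplyr::bind_rows(per_mat(raw$draws_theta_t, "theta_t"),
                   per_mat(raw$draws_theta_c, "theta_c"),
                   per_mat(raw$draws_b, "b"))
}

#' @export
print.dgm_fit <- function(x, ...) {
  cat(sprintf(
    "<dgm_fit> %d students, %d items (%d exposed); %d retained draws, %.0f%% acceptance\n",
    nrow(x$students), nrow(x$items), sum(x$items$exposed),
    x$retained_draws, 100 * x$acceptance_rate))
  cat(sprintf("  students with p_cheater > 0.9: %d\n",
              sum(x$students$p_cheater > 0.9)))
  invisible(x)
}

#' Tidy a gated model fit
#'
#' @param x A `dgm_fit`.
#' @param ... Unused.
#' @return The per-student posterior summary tibble.
#' @method tidy dgm_fit
#' @export
tidy.dgm_fit <- function(x, ...) x$students

#' One-row summary of a gated model fit
#'
#' @param x A `dgm_fit`.
#' @param ... Unused.
#' @method glance dgm_fit
#' @export
glance.dgm_fit <- function(x, ...) {
  tibble::tibble(n_students = nrow(x$students), n_items = nrow(x$items),
                 n_exposed = sum(x$items$exposed),
                 retained_draws = x$retained_draws,
                 acceptance_rate = x$acceptance_rate,
                 mean_p_cheater = mean(x$students$p_cheater),
                 max_split_rhat = max(x$diagnostics$split_rhat, na.rm = TRUE),
                 min_ess = min(x$diagnostics$ess, na.rm = TRUE))
}

#' Posterior cheater-probability plot
#'
#' Histogram of per-student posterior cheater probabilities with the
#' classification cut-off marked.
#'
#' @param object A `dgm_fit`.
#' @param cutoff Cut-off to mark (default 0.9).
#' @param ... Unused.
#' @method autoplot dgm_fit
#' @export
autoplot.dgm_fit <- function(object, cutoff = 0.9, ...) {
  ggplot2::ggplot(object$students, ggplot2::aes(x = .data$p_cheater)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = 2, colour = "red") +
    ggplot2::labs(x = "posterior P(cheater)", y = "students") +
    ggplot2::theme_minimal()
}

#' Proportion correct by student class and item class
#'
#' The score-gain table behind the model's face validity: mean proportion of
#' correct answers in a 2x2 layout of {flagged, not flagged} students by
#' {exposed, secure} items. Flagged students with pre-knowledge should show
#' an excess only in the exposed-item column. Empty classes yield `NA` cells.
#'
#' @param responses Binary response matrix or tibble.
#' @param exposed 0/1 exposure flag per item.
#' @param labels 0/1 per student: a classification (or the truth).
#' @return A tibble with columns `student_class`, `item_class`,
#'   `prop_correct`, `n_students`, `n_items`.
#' @export
score_gain_summary <- function(responses, exposed, labels) {
  y <- as_response_matrix(responses)
  exposed <- as.integer(exposed)
  labels <- as.integer(labels)
  if (length(labels) != nrow(y)) rlang::abort("one label per student required.")
  if (length(exposed) != ncol(y)) rlang::abort("one flag per item required.")
  grid <- tidyr::expand_grid(student_class = c("flagged", "not_flagged"),
                             item_class = c("exposed", "secure"))
  purrr::pmap_dfr(grid, function(student_class, item_class) {
    rows <- labels == (student_class == "flagged")
    cols <- exposed == (item_class == "exposed")
    tibble::tibble(
      student_class = student_class, item_class = item_class,
      prop_correct = if (any(rows) && any(cols)) {
        mean(y[rows, cols, drop = FALSE])
      } else NA_real_,
      n_students = sum(rows), n_items = sum(cols))
  })
}
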