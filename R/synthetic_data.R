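#' Simulate an item bank
#'
#' Item difficulties are drawn i.i.d. standard normal; exactly `n_exposed`
#' items are flagged as exposed, chosen uniformly at random without
#' replacement.
#'
#' @param n_items Number of items.
#' @param n_exposed Number of exposed (compromised) items; must be strictly
#'   between 0 and `n_items`.
#' @param seed Optional integer seed; if `NULL`, the current RNG state is used.
#' @return An [item_bank()] tibble.
#' @export
simulate_items <- function(n_items, n_exposed, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_exposed <= 0 || n_exposed >= n_items) {
    rlang::abort("`n_exposed` must satisfy 0 < n_exposed < n_items.")
  }
  difficulty <- stats::rnorm(n_items)
  exposed <- integer(n_items)
  exposed[sample.int(n_items, n_exposed)] <- 1L
  item_bank(difficulty, exposed)
}

#' Simulate a student cohort
#'
#' True abilities are i.i.d. standard normal. Exactly
#' `round(prop_cheaters * n_students)` students are designated cheaters,
#' chosen uniformly at random, so each replicate's true prevalence is exact.
#' Cheater gains are drawn from a scaled Beta distribution:
#' `3 * Beta(9, 4)` for `efficacy = "high"` (mean gain about 2.08 logits) or
#' `3 * Beta(5, 5)` for `efficacy = "low"` (mean gain 1.5 logits). Honest
#' students have zero gain; `efficacy = "none"` forces an all-honest cohort.
#'
#' @param n_students Number of students.
#' @param prop_cheaters Fraction in \[0, 1\] of students with pre-knowledge.
#' @param efficacy One of `"high"`, `"low"`, `"none"`.
#' @param seed Optional integer seed.
#' @return A [student_cohort()] tibble.
#' @export
simulate_cohort <- function(n_students, prop_cheaters,
                            efficacy = c("high", "low", "none"),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  efficacy <- rlang::arg_match(efficacy)
  if (prop_cheaters < 0 || prop_cheaters > 1) {
    rlang::abort("`prop_cheaters` must lie in [0, 1].")
  }
  theta_true <- stats::rnorm(n_students)
  gain <- numeric(n_students)
  if (efficacy != "none" && prop_cheaters > 0) {
    n_cheaters <- round(prop_cheaters * n_students)
    idx <- sample.int(n_students, n_cheaters)
    shape <- switch(efficacy, high = c(9, 4), low = c(5, 5))
    gain[idx] <- 3 * stats::rbeta(n_cheaters, shape[1], shape[2])
  }
  student_cohort(theta_true, gain)
}

#' Simulate a binary response matrix
#'
#' Each entry is an independent Bernoulli draw with success probability given
#' by [gated_prob()]: cheaters use their cheating ability on exposed items,
#' all other responses follow true ability.
#'
#' @param items An [item_bank()] tibble.
#' @param cohort A [student_cohort()] tibble.
#' @param seed Optional integer seed.
#' @return Integer 0/1 matrix, students (rows) by items (columns), with
#'   `student_id` / `item_id` dimnames.
#' @export
simulate_responses <- function(items, cohort, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(c("difficulty", "exposed") %in% names(items)) ||
      !all(c("theta_true", "theta_cheat", "is_cheater") %in% names(cohort))) {
    rlang::abort("`items` must be an item bank and `cohort` a student cohort.")
  }
  M <- nrow(cohort); I <- nrow(items)
  # effective ability per (student, item): theta_c only for cheater x exposed
  theta_eff <- outer(cohort$theta_true, rep(1, I))
  cheat_cells <- outer(cohort$is_cheater == 1L, items$exposed == 1L, `&`)
  theta_eff[cheat_cells] <- rep(cohort$theta_cheat, times = I)[cheat_cells]
  p <- stats::plogis(sweep(theta_eff, 2, items$difficulty))
  y <- matrix(as.integer(stats::runif(M * I) < p), nrow = M,
              dimnames = list(cohort$student_id, items$item_id))
  y
}

#' Scenario configuration
#'
#' Bundles the simulation design of one examination scenario: cohort size,
#' item counts, cheater prevalence and gain efficacy, number of replicates.
#' Defaults mirror the examination conditions the simulation study emulates:
#' 200 students, 100 items of which 20 are reused, and 100 replicates.
#'
#' @param prop_cheaters Fraction of students with pre-knowledge.
#' @param efficacy `"high"`, `"low"` or `"none"`.
#' @param n_students,n_items,n_exposed Exam dimensions.
#' @param n_replicates Replicates to simulate when running a study.
#' @return A one-row tibble of class `scenario_config`.
#' @export
scenario_config <- function(prop_cheaters, efficacy = c("high", "low", "none"),
                            n_students = 200, n_items = 100, n_exposed = 20,
                            n_replicates = 100) {
  efficacy <- rlang::arg_match(efficacy)
  if (n_exposed >= n_items) rlang::abort("`n_exposed` must be < `n_items`.")
  out <- tibble::tibble(prop_cheaters = prop_cheaters, efficacy = efficacy,
                        n_students = n_students, n_items = n_items,
                        n_exposed = n_exposed, n_replicates = n_replicates)
  class(out) <- c("scenario_config", class(out))
  out
}

#' The standard eight-scenario grid
#'
#' Four prevalence levels (5, 10, 35, 70%) crossed with two gain-efficacy
#' levels (high, low), each at the default exam dimensions.
#'
#' @param n_replicates Replicates per scenario.
#' @param ... Passed to [scenario_config()] (e.g. smaller dimensions).
#' @return A tibble with one row per scenario.
#' @export
scenario_grid <- function(n_replicates = 100, ...) {
  grid <- tidyr::expand_grid(prop_cheaters = c(0.05, 0.10, 0.35, 0.70),
                             efficacy = c("high", "low"))
  purrr::pmap_dfr(grid, function(prop_cheaters, efficacy) {
    scenario_config(prop_cheaters, efficacy, n_replicates = n_replicates, ...)
  })
}

#' Simulate one full examination
#'
#' Draws items, cohort and responses for one scenario replicate.
#'
#' @param scenario A [scenario_config()] row (or compatible list).
#' @param seed Optional integer seed governing all three draws.
#' @return A list of class `exam_sim` with elements `items`, `cohort`,
#'   `responses` and the scenario row.
#' @export
simulate_exam <- function(scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  items <- simulate_items(scenario$n_items, scenario$n_exposed)
  cohort <- simulate_cohort(scenario$n_students, scenario$prop_cheaters,
                            scenario$efficacy)
  responses <- simulate_responses(items, cohort)
  structure(list(items = items, cohort = cohort, responses = responses,
                 scenario = tibble::as_tibble(scenario)),
            class = "exam_sim")
}

#' @export
print.exam_sim <- function(x, ...) {
  cat(sprintf("<exam_sim> %d students x %d items (%d exposed), %d cheaters\n",
              nrow(x$responses), ncol(x$responses), sum(x$items$exposed),
              sum(x$cohort$is_cheater)))
  invisible(x)
}

# deterministic per-replicate sub-seeds from one master seed
replicate_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}
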