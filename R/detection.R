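#' Classify students from posterior cheater probabilities
#'
#' A student is flagged when their posterior cheater probability strictly
#' exceeds the cut-off; a student exactly at the cut-off is not flagged
#' (conservative toward honest students).
#'
#' @param p_cheater Numeric vector of posterior probabilities in \[0, 1\].
#' @param cutoff Cut-off in (0, 1); default 0.90.
#' @return Integer 0/1 vector.
#' @export
classify <- function(p_cheater, cutoff = 0.9) {
  if (cutoff <= 0 || cutoff >= 1) rlang::abort("`cutoff` must lie in (0, 1).")
  if (any(p_cheater < 0 | p_cheater > 1)) {
    rlang::abort("`p_cheater` must lie in [0, 1].")
  }
  as.integer(p_cheater > cutoff)
}

# child-weighted binary entropy of a split of `truth` at `cut` (on p)
split_entropy <- function(p, truth, cut) {
  h <- function(y) {
    if (length(y) == 0) return(0)
    q <- mean(y)
    if (q == 0 || q == 1) return(0)
    -q * log2(q) - (1 - q) * log2(1 - q)
  }
  left <- truth[p <= cut]
  right <- truth[p > cut]
  (length(left) * h(left) + length(right) * h(right)) / length(truth)
}

#' Entropy-optimal classification cut-off
#'
#' Single-split (stump) classification-tree search: candidate cut-offs are
#' the midpoints between consecutive distinct sorted probabilities, and the
#' returned cut-off minimizes the child-weighted sum of binary entropies of
#' the true labels. Ties are broken in favour of the largest candidate
#' (favours specificity). With perfectly separated classes the gap midpoint
#' achieves entropy zero.
#'
#' @param p_cheater Posterior probabilities.
#' @param truth 0/1 true cheater status; both classes must be present.
#' @return The selected cut-off, with the achieved weighted entropy attached
#'   as attribute `"entropy"`.
#' @export
best_cutoff_entropy <- function(p_cheater, truth) {
  truth <- as.integer(truth)
  if (length(truth) != length(p_cheater)) {
    rlang::abort("`p_cheater` and `truth` must have equal length.")
  }
  if (length(unique(truth)) < 2) {
    rlang::abort("`truth` must contain both classes.")
  }
  u <- sort(unique(p_cheater))
  if (length(u) < 2) {
    rlang::abort("all probabilities identical: no split exists.")
  }
  candidates <- (u[-length(u)] + u[-1]) / 2
  ent <- vapply(candidates, function(ct) split_entropy(p_cheater, truth, ct), 0)
  best <- max(candidates[ent <= min(ent) + 1e-12])  # tie -> largest cut-off
  structure(best, entropy = min(ent))
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity, specificity, predictive values, absolute agreement, apparent
#' prevalence and Cohen's kappa of a classification against the truth, as
#' proportions. Ratios with zero denominators (e.g. sensitivity with no true
#' positives in `truth`) are returned as `NA`, not errors.
#'
#' @param predicted,truth 0/1 vectors of equal length.
#' @return A one-row tibble with columns `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `agreement`, `apparent_prevalence`, `kappa`, plus the raw counts
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(predicted, truth) {
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (length(predicted) != length(truth)) {
    rlang::abort("`predicted` and `truth` must have equal length.")
  }
  M <- length(truth)
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  tn <- sum(predicted == 0 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  p_o <- (tp + tn) / M
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / M^2
  tibble::tibble(
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    agreement = p_o,
    apparent_prevalence = (tp + fp) / M,
    kappa = if (p_e == 1) NA_real_ else (p_o - p_e) / (1 - p_e),
    tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Run the full detection simulation study
#'
#' For each scenario and replicate: simulate an examination, fit the gated
#' model, classify at the fixed cut-off, and compute confusion metrics
#' against the known cheater labels. Per scenario the entropy-optimal
#' cut-off is also computed, both from the replicates pooled together and
#' per replicate. Failed replicates are dropped with a count reported.
#'
#' @param scenarios Tibble of scenarios (rows as from [scenario_config()] /
#'   [scenario_grid()]).
#' @param chain A [chain_config()]; the scenario runner defaults to the
#'   reduced desk-scale chain.
#' @param cutoff Fixed classification cut-off (default 0.90).
#' @param seed Master seed; replicate r of scenario s gets a deterministic
#'   sub-seed so replicates are independent yet reproducible.
#' @param progress Print a line per scenario.
#' @return An object of class `dgm_study` with `replicates` (per-replicate
#'   metrics), `summary` (mean and SD per metric per scenario),
#'   `best_cutoffs` (pooled and per-replicate entropy cut-offs) and
#'   `n_failed`.
#' @export
run_simulation_study <- function(scenarios, chain = chain_config_reduced(),
                                 cutoff = 0.9, seed = 1L, progress = FALSE) {
  scenarios <- tibble::as_tibble(scenarios)
  scen_seeds <- replicate_seeds(seed, nrow(scenarios))
  n_failed <- 0L
  all_reps <- purrr::map_dfr(seq_len(nrow(scenarios)), function(s) {
    scen <- scenarios[s, ]
    rep_seeds <- replicate_seeds(scen_seeds[s], scen$n_replicates)
    if (progress) {
      message(sprintf("scenario %d/%d: prevalence %.0f%%, %s efficacy (%d replicates)",
                      s, nrow(scenarios), 100 * scen$prop_cheaters,
                      scen$efficacy, scen$n_replicates))
    }
    purrr::map_dfr(seq_len(scen$n_replicates), function(r) {
      res <- tryCatch({
        exam <- simulate_exam(scen, seed = rep_seeds[r])
        ch <- chain; ch$seed <- rep_seeds[r]
        fit <- fit_dgm(exam$responses, exam$items$exposed, ch,
                       keep_draws = FALSE)
        pred <- classify(fit$students$p_cheater, cutoff)
        met <- confusion_metrics(pred, exam$cohort$is_cheater)
        dplyr::bind_cols(
          tibble::tibble(scenario = s,
                         prop_cheaters = scen$prop_cheaters,
                         efficacy = scen$efficacy, replicate = r),
          met,
          tibble::tibble(p_cheater = list(fit$students$p_cheater),
                         truth = list(exam$cohort$is_cheater)))
      }, error = function(e) {
        warning(sprintf("replicate %d of scenario %d failed: %s",
                        r, s, conditionMessage(e)))
        NULL
      })
      if (is.null(res)) n_failed <<- n_failed + 1L
      res
    })
  })

  metric_cols <- c("sensitivity", "specificity", "ppv", "npv", "agreement",
                   "apparent_prevalence", "kappa")
  summary <- all_reps |>
    dplyr::group_by(.data$scenario, .data$prop_cheaters, .data$efficacy) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols),
                                   list(mean = ~mean(.x, na.rm = TRUE),
                                        sd = ~stats::sd(.x, na.rm = TRUE))),
                     n_replicates = dplyr::n(), .groups = "drop")

  best_cutoffs <- all_reps |>
    dplyr::group_by(.data$scenario, .data$prop_cheaters, .data$efficacy) |>
    dplyr::summarise(
      pooled_cutoff = {
        p <- unlist(.data$p_cheater); tr <- unlist(.data$truth)
        if (length(unique(tr)) < 2) NA_real_ else
          as.numeric(best_cutoff_entropy(p, tr))
      },
      replicate_cutoffs = list(purrr::map2_dbl(
        .data$p_cheater, .data$truth,
        ~ if (length(unique(.y)) < 2) NA_real_ else
            as.numeric(best_cutoff_entropy(.x, .y)))),
      .groups = "drop")

  structure(list(replicates = dplyr::select(all_reps, -"p_cheater", -"truth"),
                 summary = summary, best_cutoffs = best_cutoffs,
                 n_failed = n_failed, cutoff = cutoff),
            class = "dgm_study")
}

#' @export
print.dgm_study <- function(x, ...) {
  cat(sprintf("<dgm_study> %d scenario(s), cut-off %.2f, %d failed replicate(s)\n",
              nrow(x$summary), x$cutoff, x$n_failed))
  print(x$summary)
  invisible(x)
}

#' Tidy a simulation study
#'
#' Long-format scenario summary: one row per scenario x metric with the
#' across-replicate mean and SD (metrics as proportions).
#'
#' @param x A `dgm_study`.
#' @param ... Unused.
#' @method tidy dgm_study
#' @export
tidy.dgm_study <- function(x, ...) {
  x$summary |>
    tidyr::pivot_longer(dplyr::matches("_(mean|sd)$"),
                        names_to = c("metric", ".value"),
                        names_pattern = "(.*)_(mean|sd)$")
}

#' @method glance dgm_study
#' @export
glance.dgm_study <- function(x, ...) {
  tibble::tibble(n_scenarios = nrow(x$summary),
                 n_replicates_total = nrow(x$replicates),
                 n_failed = x$n_failed, cutoff = x$cutoff)
}

#' Scenario-summary plot
#'
#' Metric means with +/- 1 SD bars across scenarios, faceted by metric.
#'
#' @param object A `dgm_study`.
#' @param ... Unused.
#' @method autoplot dgm_study
#' @export
autoplot.dgm_study <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(scenario_label = paste0(100 * .data$prop_cheaters, "% ",
                                          .data$efficacy))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scenario_label, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "scenario", y = "metric (proportion)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Render a study summary as a percentage table
#'
#' Metrics-by-scenario layout with "mean (SD)" cells in percent, matching the
#' conventional reporting format for detector performance tables.
#'
#' @param study A `dgm_study`.
#' @return A tibble, one row per metric, one column per scenario.
#' @export
study_table <- function(study) {
  tidy(study) |>
    dplyr::mutate(cell = sprintf("%.2f (%.2f)", 100 * .data$mean,
                                 100 * .data$sd),
                  scenario_label = paste0(100 * .data$prop_cheaters, "% ",
                                          .data$efficacy)) |>
    dplyr::select("metric", "scenario_label", "cell") |>
    tidyr::pivot_wider(names_from = "scenario_label", values_from = "cell")
}
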