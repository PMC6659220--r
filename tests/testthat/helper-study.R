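# The reduced-scale detection study shared by the acceptance tests: three
# scenarios at the exam dimensions (200 students, 100 items, 20 exposed),
# 15 replicates each, desk-scale chain, fixed 0.90 cut-off. Computed once
# per test session.
.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (!is.null(.study_cache$study)) return(.study_cache$study)
  scenarios <- dplyr::bind_rows(
    scenario_config(0.70, "high", n_replicates = 15),
    scenario_config(0.05, "high", n_replicates = 15),
    scenario_config(0.70, "low", n_replicates = 15))
  .study_cache$study <- run_simulation_study(
    scenarios, chain_config_reduced(), cutoff = 0.9, seed = 20260901)
  .study_cache$study
}

scenario_row <- function(study, prop, eff) {
  dplyr::filter(study$summary, .data$prop_cheaters == prop,
                .data$efficacy == eff)
}
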