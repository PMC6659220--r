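test_that("classification uses a strict threshold", {
  expect_equal(classify(c(0.95, 0.5, 0.91), 0.9), c(1L, 0L, 1L))
  expect_equal(classify(c(0.9), 0.9), 0L)           # exactly at cut-off
  expect_equal(classify(c(0.2, 0.8, 0.99), 0.999), c(0L, 0L, 0L))
  expect_error(classify(0.5, 1), "cutoff")
  expect_error(classify(1.2, 0.9), "0, 1")
})

test_that("entropy cut-off finds the perfect split and reports zero entropy", {
  ct <- best_cutoff_entropy(c(0.1, 0.2, 0.95, 0.99), c(0, 0, 1, 1))
  expect_equal(as.numeric(ct), 0.575)
  expect_equal(attr(ct, "entropy"), 0)
  # inverted labels: the split still isolates each class, entropy 0
  ct2 <- best_cutoff_entropy(c(0.4, 0.6), c(1, 0))
  expect_equal(as.numeric(ct2), 0.5)
  expect_equal(attr(ct2, "entropy"), 0)
  expect_error(best_cutoff_entropy(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("entropy cut-off equals a brute-force midpoint scan on random instances", {
  set.seed(42)
  for (case in 1:100) {
    n <- sample(5:40, 1)
    p <- round(runif(n), 3)
    truth <- rbinom(n, 1, 0.4)
    if (length(unique(truth)) < 2 || length(unique(p)) < 2) next
    got <- best_cutoff_entropy(p, truth)
    oracle <- brute_force_cutoff(p, truth)
    expect_equal(as.numeric(got), oracle$cutoff)
    expect_equal(attr(got, "entropy"), oracle$entropy, tolerance = 1e-12)
  }
})

test_that("confusion metrics match the hand-computed 2x2 table", {
  m <- confusion_metrics(c(1, 0, 0, 0), c(1, 1, 0, 0))
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1)
  expect_equal(m$agreement, 0.75)
  expect_equal(m$kappa, 0.5)
  expect_equal(m$apparent_prevalence, 0.25)

  perfect <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_true(all(unlist(perfect[c("sensitivity", "specificity", "ppv",
                                   "npv", "agreement")]) == 1))
  expect_equal(perfect$kappa, 1)

  allneg <- confusion_metrics(rep(0, 20), c(rep(1, 1), rep(0, 19)))
  expect_equal(allneg$specificity, 1)
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$apparent_prevalence, 0)
  expect_true(is.na(allneg$ppv))   # nothing flagged: PPV undefined
})

test_that("kappa agrees with an independent contingency-table implementation", {
  skip_if_not_installed("e1071")
  set.seed(7)
  for (case in 1:200) {
    n <- sample(10:80, 1)
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
    ours <- confusion_metrics(pred, truth)$kappa
    tab <- table(factor(pred, 0:1), factor(truth, 0:1))
    ref <- e1071::classAgreement(tab)$kappa
    if (is.na(ours) || is.nan(ref)) next
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("apparent prevalence obeys the prevalence identity per confusion table", {
  set.seed(13)
  for (case in 1:50) {
    n <- sample(20:100, 1)
    truth <- rbinom(n, 1, 0.5)
    pred <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) next
    m <- confusion_metrics(pred, truth)
    prev <- mean(truth)
    expect_equal(m$apparent_prevalence,
                 prev * m$sensitivity + (1 - prev) * (1 - m$specificity),
                 tolerance = 1e-12)
  }
})

test_that("the study runner aggregates replicates reproducibly", {
  scen <- scenario_config(0.3, "high", n_students = 40, n_items = 24,
                          n_exposed = 6, n_replicates = 3)
  ch <- chain_config(1500, 500, 5, seed = 1)
  st1 <- run_simulation_study(scen, ch, cutoff = 0.9, seed = 5)
  st2 <- run_simulation_study(scen, ch, cutoff = 0.9, seed = 5)
  expect_equal(st1$summary, st2$summary)
  expect_equal(nrow(st1$replicates), 3)
  expect_equal(st1$n_failed, 0)
  expect_true(all(st1$summary$specificity_mean >= 0 &
                  st1$summary$specificity_mean <= 1))
  # tidy gives one row per metric, best cut-off within [0, 1]
  td <- tidy(st1)
  expect_setequal(unique(td$metric),
                  c("sensitivity", "specificity", "ppv", "npv", "agreement",
                    "apparent_prevalence", "kappa"))
  expect_true(all(st1$best_cutoffs$pooled_cutoff >= 0 &
                  st1$best_cutoffs$pooled_cutoff <= 1))
  tab <- study_table(st1)
  expect_equal(nrow(tab), 7)
})

test_that("score-gain table shows the exposed-item excess for flagged cheaters", {
  exam <- tiny_exam(seed = 3, prop = 0.5, n_students = 300)
  tab <- score_gain_summary(exam$responses, exam$items$exposed,
                            exam$cohort$is_cheater)
  expect_equal(nrow(tab), 4)
  get <- function(s, i) tab$prop_correct[tab$student_class == s &
                                         tab$item_class == i]
  expect_gt(get("flagged", "exposed"), get("flagged", "secure"))
  expect_lt(abs(get("not_flagged", "exposed") - get("not_flagged", "secure")),
            0.08)
  # degenerate all-correct single student
  one <- matrix(1L, 1, 4, dimnames = list("s1", paste0("i", 1:4)))
  tab1 <- score_gain_summary(one, c(1, 1, 0, 0), 1)
  expect_true(all(tab1$prop_correct[tab1$student_class == "flagged"] == 1))
  expect_true(all(is.na(tab1$prop_correct[tab1$student_class == "not_flagged"])))
})
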