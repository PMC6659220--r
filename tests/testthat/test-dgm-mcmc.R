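test_that("chain configuration enforces its invariants", {
  expect_error(chain_config(1000, 1000, 5), "burn_in")
  expect_error(chain_config(1000, 100, 0), "thin")
  ch <- chain_config_reduced(seed = 3)
  expect_equal((ch$n_iterations - ch$burn_in) / ch$thin, 1000)
})

test_that("fitting requires both item classes and valid flags", {
  exam <- tiny_exam(seed = 1, n_students = 20, n_items = 10, n_exposed = 3)
  expect_error(fit_dgm(exam$responses, rep(0, 10), chain_config(200, 100, 1)),
               "unidentified")
  expect_error(fit_dgm(exam$responses, rep(1, 10), chain_config(200, 100, 1)),
               "unanchored")
  expect_error(fit_dgm(exam$responses, rep(1, 3), chain_config(200, 100, 1)),
               "per item")
})

test_that("the fit is deterministic given data and seed", {
  exam <- tiny_exam(seed = 2, n_students = 30, n_items = 16, n_exposed = 4)
  ch <- chain_config(1200, 400, 4, seed = 17)
  f1 <- fit_dgm(exam$responses, exam$items$exposed, ch, keep_draws = FALSE)
  f2 <- fit_dgm(exam$responses, exam$items$exposed, ch, keep_draws = FALSE)
  expect_identical(f1$students, f2$students)
  expect_identical(f1$items, f2$items)
  expect_equal(f1$retained_draws, 200)
  expect_true(all(f1$students$p_cheater >= 0 & f1$students$p_cheater <= 1))
  expect_true(all(c("ess", "split_rhat") %in% names(f1$diagnostics)))
})

test_that("sampler posterior matches a brute-force 2-D quadrature on 1-student toys", {
  # anchored difficulties so the oracle integrates over (theta_t, theta_c)
  b <- c(-1.2, -0.5, 0, 0.4, 0.9, -0.8, -0.2, 0.1, 0.6, 1.1,
         -1.5, -0.9, -0.3, 0.2, 0.8, 1.3, -0.6, 0, 0.5, 1)
  exposed <- c(rep(0, 15), rep(1, 5))
  cases <- list(
    # looks like pre-knowledge: weak on secure, perfect on exposed
    strong = c(1, 1, 0, 0, 0, 1, 0, 0, 0, 0, 1, 1, 0, 0, 0, 1, 1, 1, 1, 1),
    # average throughout: no signal
    honest = c(1, 1, 1, 0, 0, 1, 1, 0, 0, 0, 1, 1, 1, 1, 0, 0, 1, 0, 1, 0),
    # strong everywhere: ceiling, weakly identified
    ceiling = c(rep(1, 14), 0, rep(1, 5)))
  for (nm in names(cases)) {
    y <- matrix(cases[[nm]], nrow = 1,
                dimnames = list("s1", paste0("i", 1:20)))
    fit <- fit_dgm(y, exposed, chain_config(110000, 10000, 20, seed = 5),
                   fixed_difficulty = b, keep_draws = FALSE)
    oracle <- quadrature_p_cheater(cases[[nm]], b, exposed)
    expect_equal(fit$students$p_cheater, oracle, tolerance = 0.02,
                 label = paste0("sampler p_cheater (", nm, ")"))
  }
})

test_that("longer chains shrink the Monte-Carlo error of p_cheater", {
  exam <- tiny_exam(seed = 4, n_students = 30, n_items = 16, n_exposed = 4)
  mc_sd <- function(n_iter, burn) {
    reps <- vapply(1:8, function(s) {
      f <- fit_dgm(exam$responses, exam$items$exposed,
                   chain_config(n_iter, burn, 5, seed = s),
                   keep_draws = FALSE)
      f$students$p_cheater[1]
    }, 0)
    sd(reps)
  }
  expect_lt(mc_sd(41000, 1000), mc_sd(2000, 1000))
})

test_that("item relabelling leaves the posterior unchanged up to Monte-Carlo error", {
  exam <- tiny_exam(seed = 6, n_students = 40, n_items = 20, n_exposed = 5)
  ch <- chain_config(20000, 2000, 10, seed = 9)
  f <- fit_dgm(exam$responses, exam$items$exposed, ch, keep_draws = FALSE)
  perm <- sample(seq_len(20))
  fp <- fit_dgm(exam$responses[, perm], exam$items$exposed[perm], ch,
                keep_draws = FALSE)
  expect_gt(cor(f$students$p_cheater, fp$students$p_cheater), 0.95)
  expect_lt(mean(abs(f$students$p_cheater - fp$students$p_cheater)), 0.05)
})

test_that("constant response columns are tolerated by the sampler", {
  exam <- tiny_exam(seed = 8, n_students = 25, n_items = 12, n_exposed = 3)
  y <- exam$responses
  y[, 1] <- 1L; y[, 2] <- 0L
  f <- fit_dgm(y, exam$items$exposed, chain_config(1000, 200, 4, seed = 2),
               keep_draws = FALSE)
  expect_true(all(is.finite(f$items$difficulty_mean)))
})
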