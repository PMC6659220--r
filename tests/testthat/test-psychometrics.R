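test_that("parallel items give alpha 1 and all-correct items are easy", {
  base <- rep(c(1, 0), each = 5)
  y <- cbind(a = base, b = base)
  s <- ctt_summary(y)
  expect_equal(s$cronbach_alpha, 1)

  y2 <- cbind(always = rep(1, 10), mixed = base)
  s2 <- ctt_summary(y2)
  expect_equal(s2$items$difficulty[1], 1)
  expect_equal(as.character(s2$items$difficulty_category[1]), "easy")
  expect_true(is.na(s2$items$discrimination[1]))  # zero variance
})

test_that("independent coin-flip responses have near-zero alpha and discrimination", {
  set.seed(31)
  y <- matrix(rbinom(3000 * 20, 1, 0.5), 3000, 20)
  s <- ctt_summary(y)
  expect_lt(abs(s$cronbach_alpha), 0.06)
  expect_lt(max(abs(s$items$discrimination)), 0.08)
})

test_that("category labels flip exactly at the printed cut points", {
  dc <- gatekeepr:::difficulty_category
  expect_equal(as.character(dc(c(0, 0.30, 0.31, 0.80, 0.81, 1))),
               c("difficult", "difficult", "medium", "medium", "easy", "easy"))
  rc <- gatekeepr:::discrimination_category
  expect_equal(as.character(rc(c(-1, -0.19, -0.18, 0.19, 0.20, 0.29,
                                 0.30, 0.39, 0.40, 1))),
               c("negative", "negative", "weak", "weak", "sufficient",
                 "sufficient", "good", "good", "very_good", "very_good"))
})

test_that("difficulty is exact at crafted proportions; anti-keyed items discriminate negatively", {
  set.seed(5)
  ability <- rnorm(300)
  p_good <- stats::plogis(ability)
  y <- sapply(1:6, function(i) rbinom(300, 1, p_good))
  y <- cbind(y, anti = rbinom(300, 1, 1 - p_good))  # keyed against ability
  colnames(y) <- c(paste0("item", 1:6), "anti")
  s <- ctt_summary(y)
  expect_lt(s$items$discrimination[7], -0.19)
  expect_equal(as.character(s$items$discrimination_category[7]), "negative")
  expect_true(all(s$items$discrimination[1:6] > 0.19))
  # exact difficulty: 3 of 10 correct
  y10 <- cbind(a = c(rep(1, 3), rep(0, 7)), b = rep(c(1, 0), 5),
               c = c(rep(1, 8), 0, 0))
  s10 <- ctt_summary(y10)
  expect_equal(s10$items$difficulty, c(0.3, 0.5, 0.8))
  expect_equal(as.character(s10$items$difficulty_category),
               c("difficult", "medium", "medium"))
})

test_that("EM marginal likelihood matches direct numerical maximization on a toy set", {
  set.seed(11)
  theta <- rnorm(50)
  b_true <- c(-1, -0.3, 0, 0.5, 1.2)
  y <- sapply(b_true, function(b) rbinom(50, 1, stats::plogis(theta - b)))
  colnames(y) <- paste0("i", 1:5)
  fit <- fit_irt(y, "one_pl")
  quad <- gatekeepr:::ability_quadrature(61)
  negll <- function(par) {
    a <- exp(par[6])
    P <- stats::plogis(a * outer(quad$nodes, par[1:5], `-`))
    P <- pmin(pmax(P, 1e-10), 1 - 1e-10)
    -gatekeepr:::marginal_loglik(y, P, quad$weights)
  }
  opt <- stats::optim(c(rep(0, 5), 0), negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  expect_equal(fit$log_likelihood, -opt$value, tolerance = 1e-3)
})

test_that("the 2-PL never fits worse than the 1-PL and criteria use their formulas", {
  exam <- tiny_exam(seed = 13, prop = 0, efficacy = "none",
                    n_students = 150, n_items = 12, n_exposed = 2)
  f1 <- fit_irt(exam$responses, "one_pl")
  f2 <- fit_irt(exam$responses, "two_pl")
  expect_gte(f2$log_likelihood, f1$log_likelihood - 1e-6)
  expect_equal(f1$n_parameters, 13)
  expect_equal(f2$n_parameters, 24)
  expect_equal(f1$aic, -2 * f1$log_likelihood + 2 * 13)
  expect_equal(f1$bic, -2 * f1$log_likelihood + 13 * log(150))
})

test_that("CHull picks the elbow model on the hand-computed scree example", {
  res <- chull_select(tibble::tibble(model = c("m1", "m2", "m3"),
                                     complexity = c(10, 20, 40),
                                     fit = c(-100, -50, -49)))
  expect_true(all(res$on_hull))
  expect_equal(res$scree_ratio[res$model == "m2"], (50 / 10) / (1 / 20))
  expect_equal(res$model[res$selected], "m2")
  expect_true(all(is.na(res$scree_ratio[res$model != "m2"])))
})

test_that("CHull handles two-model and collinear degeneracies", {
  # dominated complex model: simple one wins outright
  r1 <- chull_select(tibble::tibble(model = c("s", "c"),
                                    complexity = c(5, 10), fit = c(-40, -45)))
  expect_equal(r1$model[r1$selected], "s")
  expect_false(r1$on_hull[r1$model == "c"])
  # genuinely better complex model: selected via pseudo-endpoints
  r2 <- chull_select(tibble::tibble(model = c("s", "c"),
                                    complexity = c(5, 10), fit = c(-40, -20)))
  expect_equal(r2$model[r2$selected], "c")
  # collinear fits: interior ratio 1, no sharp elbow
  r3 <- chull_select(tibble::tibble(complexity = c(1, 2, 3),
                                    fit = c(-30, -20, -10)))
  expect_equal(r3$scree_ratio[2], 1)
  expect_error(chull_select(tibble::tibble(complexity = 1, fit = 0)), ">= 2")
  expect_error(chull_select(tibble::tibble(complexity = c(1, 1),
                                           fit = c(0, 1))), "distinct")
})

test_that("model comparison prefers the generating model", {
  set.seed(23)
  # 1-PL data, common discrimination 1: BIC should pick the 1-PL
  theta <- rnorm(600)
  b <- rnorm(15)
  y1 <- sapply(b, function(bi) rbinom(600, 1, stats::plogis(theta - bi)))
  colnames(y1) <- paste0("i", 1:15)
  cmp1 <- compare_models(y1)
  expect_equal(cmp1$winners$winner[cmp1$winners$criterion == "bic"], "one_pl")
  # strongly varying discriminations: the 2-PL should win AIC and BIC
  a2 <- rep(c(0.3, 2), length.out = 15)
  y2 <- sapply(1:15, function(i) rbinom(600, 1, stats::plogis(a2[i] * (theta - b[i]))))
  colnames(y2) <- paste0("i", 1:15)
  cmp2 <- compare_models(y2)
  expect_equal(cmp2$winners$winner[cmp2$winners$criterion == "aic"], "two_pl")
  expect_equal(cmp2$winners$winner[cmp2$winners$criterion == "bic"], "two_pl")
})

test_that("alpha is invariant to item order and difficulty to student order", {
  exam <- tiny_exam(seed = 17, n_students = 80, n_items = 10, n_exposed = 2)
  y <- exam$responses
  s <- ctt_summary(y)
  s_perm <- ctt_summary(y[, sample(ncol(y))])
  expect_equal(s$cronbach_alpha, s_perm$cronbach_alpha)
  s_rows <- ctt_summary(y[sample(nrow(y)), ])
  expect_equal(s$items$difficulty, s_rows$items$difficulty)
})
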