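#' Classical test theory summary
#'
#' Per-item difficulty (proportion of correct answers), biserial
#' discrimination against the rest-score (total score excluding the item),
#' Cronbach's alpha, and the conventional category labels. The biserial is
#' the point-biserial corrected to the latent-continuity scale,
#' \eqn{r_b = r_{pb}\sqrt{p(1-p)}/\phi(\Phi^{-1}(p))}. Items with zero
#' variance (or zero rest-score variance) get `NA` discrimination.
#'
#' Category conventions (boundaries inclusive on the left interval):
#' difficulty 0-30% difficult, 31-80% medium, 81-100% easy, implemented on
#' the proportion scale as \[0, .30\], (.30, .80\], (.80, 1\]; discrimination
#' \[-1, -.19\] negative, (-.19, .19\] weak, (.19, .29\] sufficient,
#' (.29, .39\] good, (.39, 1\] very good.
#'
#' @param responses Binary response matrix or tibble (>= 3 students,
#'   >= 2 items).
#' @return An object of class `ctt_summary`: `items` tibble and
#'   `cronbach_alpha`.
#' @export
ctt_summary <- function(responses) {
  y <- as_response_matrix(responses)
  if (nrow(y) < 3 || ncol(y) < 2) {
    rlang::abort("need at least 3 students and 2 items.")
  }
  p <- colMeans(y)
  total <- rowSums(y)
  disc <- vapply(seq_len(ncol(y)), function(i) {
    rest <- total - y[, i]
    if (stats::sd(y[, i]) == 0 || stats::sd(rest) == 0) return(NA_real_)
    r_pb <- stats::cor(y[, i], rest)
    r_pb * sqrt(p[i] * (1 - p[i])) / stats::dnorm(stats::qnorm(p[i]))
  }, 0)
  k <- ncol(y)
  var_total <- stats::var(total)
  alpha <- if (var_total == 0) NA_real_ else {
    k / (k - 1) * (1 - sum(apply(y, 2, stats::var)) / var_total)
  }
  items <- tibble::tibble(
    item_id = colnames(y),
    difficulty = unname(p),
    discrimination = unname(disc),
    difficulty_category = difficulty_category(p),
    discrimination_category = discrimination_category(disc))
  structure(list(items = items, cronbach_alpha = alpha,
                 n_students = nrow(y), n_items = k),
            class = "ctt_summary")
}

#' @export
print.ctt_summary <- function(x, ...) {
  cat(sprintf("<ctt_summary> %d students x %d items, Cronbach's alpha %.3f\n",
              x$n_students, x$n_items, x$cronbach_alpha))
  print(x$items)
  invisible(x)
}

# proportion-scale renderings of the printed integer-percent ranges:
# 0-30% difficult, 31-80% medium, 81-100% easy
difficulty_category <- function(p) {
  cut(p, c(-Inf, 0.30, 0.80, Inf),
      labels = c("difficult", "medium", "easy"))
}

# -1.00..-0.19 negative, -0.20..0.19 weak (boundary resolved at -0.19),
# 0.20-0.29 sufficient, 0.30-0.39 good, 0.40-1.00 very good
discrimination_category <- function(d) {
  cut(d, c(-Inf, -0.19, 0.19, 0.29, 0.39, Inf),
      labels = c("negative", "weak", "sufficient", "good", "very_good"))
}

#' @method tidy ctt_summary
#' @export
tidy.ctt_summary <- function(x, ...) x$items

#' @method glance ctt_summary
#' @export
glance.ctt_summary <- function(x, ...) {
  tibble::tibble(cronbach_alpha = x$cronbach_alpha,
                 mean_difficulty = mean(x$items$difficulty),
                 mean_discrimination = mean(x$items$discrimination,
                                            na.rm = TRUE),
                 n_students = x$n_students, n_items = x$n_items)
}

# quadrature over standard-normal ability: 61 Gauss-Hermite nodes when
# pracma is available, otherwise a normalized fixed grid on [-6, 6]
ability_quadrature <- function(n_nodes = 61) {
  if (requireNamespace("pracma", quietly = TRUE)) {
    gh <- pracma::gaussHermite(n_nodes)
    list(nodes = sqrt(2) * gh$x, weights = gh$w / sqrt(pi))
  } else {
    x <- seq(-6, 6, length.out = n_nodes)
    w <- stats::dnorm(x)
    list(nodes = x, weights = w / sum(w))
  }
}

# marginal log-likelihood given K x I probability matrix P and data Y (M x I)
marginal_loglik <- function(y, P, weights) {
  lp <- log(P); lq <- log1p(-P)
  # M x K matrix of per-node log-likelihoods
  ll <- y %*% t(lp) + (1 - y) %*% t(lq)
  mx <- apply(ll, 1, max)
  sum(mx + log(exp(ll - mx) %*% weights))
}

#' Fit a 1-PL or 2-PL model by marginal maximum likelihood
#'
#' EM estimation integrating a standard-normal ability distribution by fixed
#' quadrature (61 nodes). The 1-PL estimates one difficulty per item plus a
#' single common discrimination (`n_parameters = I + 1`); the 2-PL estimates
#' a difficulty and a discrimination per item (`n_parameters = 2I`). The
#' response model is \eqn{P(y=1) = \mathrm{logit}^{-1}(a_i(\theta - b_i))}.
#'
#' @param responses Binary response matrix or tibble.
#' @param model `"one_pl"` or `"two_pl"`.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the log-likelihood change
#'   (default 1e-5).
#' @param n_nodes Quadrature nodes (default 61).
#' @return An object of class `irt_fit`: `model`, `log_likelihood`,
#'   `n_parameters`, `aic`, `bic`, `items` tibble (difficulty,
#'   discrimination), `converged`, `n_iterations`.
#' @export
fit_irt <- function(responses, model = c("one_pl", "two_pl"),
                    max_iter = 500, tol = 1e-5, n_nodes = 61) {
  model <- rlang::arg_match(model)
  y <- as_response_matrix(responses)
  M <- nrow(y); I <- ncol(y)
  const_cols <- apply(y, 2, function(v) length(unique(v)) == 1)
  if (model == "two_pl" && any(const_cols)) {
    warning(sprintf("%d all-constant item column(s); 2-PL slopes for these are unstable.",
                    sum(const_cols)))
  }
  quad <- ability_quadrature(n_nodes)
  th <- quad$nodes; A <- quad$weights; K <- length(th)

  p_emp <- pmin(pmax(colMeans(y), 0.5 / M), 1 - 0.5 / M)
  b <- -stats::qlogis(p_emp)
  a <- rep(1, I)
  common_a <- 1

  prob_mat <- function(a, b) {   # K x I
    P <- stats::plogis(outer(th, b, `-`) * rep(a, each = K))
    pmin(pmax(P, 1e-10), 1 - 1e-10)
  }

  ll_old <- -Inf; converged <- FALSE; it <- 0
  while (it < max_iter) {
    it <- it + 1
    P <- prob_mat(if (model == "one_pl") rep(common_a, I) else a, b)
    # E-step: posterior node weights per student
    lp <- log(P); lq <- log1p(-P)
    ll_mk <- y %*% t(lp) + (1 - y) %*% t(lq)          # M x K
    mx <- apply(ll_mk, 1, max)
    W <- exp(ll_mk - mx) * rep(A, each = M)
    ll_new <- sum(mx + log(rowSums(W)))
    W <- W / rowSums(W)
    n_k <- colSums(W)                                  # K
    r_ki <- t(W) %*% y                                 # K x I

    if (model == "two_pl") {
      for (i in seq_len(I)) {
        frac <- pmin(pmax(r_ki[, i] / pmax(n_k, 1e-12), 0), 1)
        fit <- suppressWarnings(
          stats::glm.fit(cbind(1, th), frac,
                         weights = n_k, family = stats::binomial()))
        co <- fit$coefficients
        if (all(is.finite(co)) && abs(co[2]) > 1e-8) {
          a[i] <- co[2]; b[i] <- -co[1] / co[2]
        }
      }
    } else {
      # ECM: Newton update of each b_i given a, then of the common a
      for (rep_cycle in 1:2) {
        Pk <- stats::plogis(common_a * outer(th, b, `-`))
        for (i in seq_len(I)) {
          resid <- r_ki[, i] - n_k * Pk[, i]
          g <- -common_a * sum(resid)
          h <- -common_a^2 * sum(n_k * Pk[, i] * (1 - Pk[, i]))
          if (h < 0) b[i] <- b[i] - g / h
        }
        Pk <- stats::plogis(common_a * outer(th, b, `-`))
        dev <- outer(th, b, `-`)
        g <- sum((r_ki - n_k * Pk) * dev)
        h <- -sum((n_k * Pk * (1 - Pk)) * dev^2)
        if (h < 0) {
          step <- g / h
          common_a <- max(common_a - sign(step) * min(abs(step), 0.5), 0.01)
        }
      }
    }
    if (abs(ll_new - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll_new
  }
  P <- prob_mat(if (model == "one_pl") rep(common_a, I) else a, b)
  ll <- marginal_loglik(y, P, A)
  n_par <- if (model == "one_pl") I + 1 else 2L * I
  items <- tibble::tibble(
    item_id = colnames(y), difficulty = b,
    discrimination = if (model == "one_pl") rep(common_a, I) else a)
  structure(list(model = model, log_likelihood = ll,
                 n_parameters = n_par,
                 aic = -2 * ll + 2 * n_par,
                 bic = -2 * ll + n_par * log(M),
                 items = items,
                 common_discrimination = if (model == "one_pl") common_a else NA_real_,
                 converged = converged, n_iterations = it,
                 n_students = M),
            class = "irt_fit")
}

#' @export
print.irt_fit <- function(x, ...) {
  cat(sprintf("<irt_fit> %s: logLik %.2f, %d parameters, AIC %.1f, BIC %.1f%s\n",
              x$model, x$log_likelihood, x$n_parameters, x$aic, x$bic,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @method tidy irt_fit
#' @export
tidy.irt_fit <- function(x, ...) x$items

#' @method glance irt_fit
#' @export
glance.irt_fit <- function(x, ...) {
  tibble::tibble(model = x$model, log_likelihood = x$log_likelihood,
                 n_parameters = x$n_parameters, aic = x$aic, bic = x$bic,
                 converged = x$converged, n_iterations = x$n_iterations)
}

#' CHull model selection
#'
#' Retains the models on the upper convex hull of (complexity,
#' goodness-of-fit) and computes, for interior hull models, the scree ratio
#' \deqn{st_i = \frac{(f_i - f_{i-1})/(c_i - c_{i-1})}{(f_{i+1} - f_i)/(c_{i+1} - c_i)}.}
#' The model with the highest ratio is selected. Hull boundary models have no
#' two adjacent segments; with three or more hull models they receive `NA`
#' ratios, and with exactly two hull models pseudo-endpoints with zero
#' fit-gain are appended so a ratio is defined (the better-fitting model then
#' wins whenever its fit gain is positive).
#'
#' @param fits A data frame with columns `complexity` (parameter count) and
#'   `fit` (goodness of fit, larger is better, e.g. log-likelihood), plus an
#'   optional `model` label column.
#' @return A tibble with `model`, `complexity`, `fit`, `on_hull`,
#'   `scree_ratio`, `selected`.
#' @export
chull_select <- function(fits) {
  fits <- tibble::as_tibble(fits)
  if (!all(c("complexity", "fit") %in% names(fits)) || nrow(fits) < 2) {
    rlang::abort("`fits` needs >= 2 rows with columns `complexity` and `fit`.")
  }
  if (anyDuplicated(fits$complexity)) {
    rlang::abort("model complexities must be distinct.")
  }
  if (!"model" %in% names(fits)) {
    fits$model <- paste0("model_", seq_len(nrow(fits)))
  }
  fits <- dplyr::arrange(fits, .data$complexity)
  # upper convex hull, left to right: keep points with decreasing slopes,
  # dropping any model not improving on a simpler one
  hull <- 1L
  for (j in 2:nrow(fits)) {
    while (length(hull) >= 1 && fits$fit[j] >= fits$fit[hull[length(hull)]]) {
      if (length(hull) >= 2) {
        k <- hull[length(hull)]; km1 <- hull[length(hull) - 1]
        s_prev <- (fits$fit[k] - fits$fit[km1]) /
                  (fits$complexity[k] - fits$complexity[km1])
        s_new <- (fits$fit[j] - fits$fit[k]) /
                 (fits$complexity[j] - fits$complexity[k])
        if (s_new > s_prev) hull <- hull[-length(hull)] else break
      } else break
    }
    if (fits$fit[j] > fits$fit[hull[length(hull)]]) hull <- c(hull, j)
  }
  on_hull <- seq_len(nrow(fits)) %in% hull
  cx <- fits$complexity[hull]; fx <- fits$fit[hull]
  if (length(hull) == 2) {            # pseudo-endpoints with zero fit-gain
    d <- diff(cx)
    cx <- c(cx[1] - d, cx, cx[2] + d)
    fx <- c(fx[1], fx, fx[2])
    interior <- 2:3
  } else {
    interior <- if (length(hull) > 2) seq(2, length(hull) - 1) else integer(0)
    cx <- cx; fx <- fx
  }
  ratio <- rep(NA_real_, length(hull))
  offs <- if (length(hull) == 2) 1L else 0L
  for (k in seq_along(hull)) {
    pos <- k + offs
    if (!(pos %in% if (length(hull) == 2) interior else (interior))) next
    if (length(hull) > 2 && (k == 1 || k == length(hull))) next
    s1 <- (fx[pos] - fx[pos - 1]) / (cx[pos] - cx[pos - 1])
    s2 <- (fx[pos + 1] - fx[pos]) / (cx[pos + 1] - cx[pos])
    ratio[k] <- if (s2 == 0) Inf else s1 / s2
  }
  out <- fits |>
    dplyr::mutate(on_hull = on_hull, scree_ratio = NA_real_)
  out$scree_ratio[hull] <- ratio
  sel <- if (all(is.na(out$scree_ratio))) {
    hull[which.max(fits$fit[hull])]    # single informative hull model
  } else {
    cand <- which(out$scree_ratio == max(out$scree_ratio, na.rm = TRUE))
    cand[which.min(out$complexity[cand])]
  }
  out$selected <- seq_len(nrow(out)) == sel
  out
}

#' Compare 1-PL and 2-PL fits on one response matrix
#'
#' Fits both models by marginal maximum likelihood and reports
#' log-likelihood, AIC, BIC and the CHull scree ratio per model, along with
#' the winner under each criterion (lowest AIC/BIC, highest CHull ratio).
#'
#' @param responses Binary response matrix or tibble.
#' @param ... Passed to [fit_irt()].
#' @return A list of class `irt_comparison`: `table` (one row per model),
#'   `winners` (criterion -> model), and both `irt_fit` objects.
#' @export
compare_models <- function(responses, ...) {
  f1 <- fit_irt(responses, "one_pl", ...)
  f2 <- fit_irt(responses, "two_pl", ...)
  ch <- chull_select(tibble::tibble(
    model = c("one_pl", "two_pl"),
    complexity = c(f1$n_parameters, f2$n_parameters),
    fit = c(f1$log_likelihood, f2$log_likelihood)))
  tab <- tibble::tibble(
    model = c("one_pl", "two_pl"),
    log_likelihood = c(f1$log_likelihood, f2$log_likelihood),
    n_parameters = c(f1$n_parameters, f2$n_parameters),
    aic = c(f1$aic, f2$aic), bic = c(f1$bic, f2$bic),
    chull_ratio = ch$scree_ratio[match(c("one_pl", "two_pl"), ch$model)])
  winners <- tibble::tibble(
    criterion = c("aic", "bic", "chull"),
    winner = c(tab$model[which.min(tab$aic)],
               tab$model[which.min(tab$bic)],
               ch$model[ch$selected]))
  structure(list(table = tab, winners = winners, fits = list(f1, f2)),
            class = "irt_comparison")
}

#' @export
print.irt_comparison <- function(x, ...) {
  print(x$table)
  cat("winners:\n"); print(x$winners)
  invisible(x)
}

#' @method tidy irt_comparison
#' @export
tidy.irt_comparison <- function(x, ...) x$table
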