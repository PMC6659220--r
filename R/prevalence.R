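#' Closed-form true-prevalence correction
#'
#' Inverts the apparent-prevalence relation
#' \deqn{AP = TP \cdot SEN + (1 - TP)(1 - SPE)}
#' to give the Rogan-Gladen-type estimate
#' \eqn{TP = (AP + SPE - 1)/(SEN + SPE - 1)}, truncated to \[0, 1\]. Requires
#' an informative detector (`sen + spe > 1`).
#'
#' @param ap Apparent prevalence (proportion flagged), in \[0, 1\].
#' @param sen,spe Detector sensitivity and specificity (proportions).
#' @return Estimated true prevalence (proportion).
#' @export
rogan_gladen_tp <- function(ap, sen, spe) {
  if (any(ap < 0 | ap > 1)) rlang::abort("`ap` must lie in [0, 1].")
  if (any(sen + spe <= 1)) {
    rlang::abort("`sen + spe` must exceed 1 for the inversion to be defined.")
  }
  pmin(pmax((ap + spe - 1) / (sen + spe - 1), 0), 1)
}

#' Forward apparent-prevalence map
#'
#' @param tp True prevalence.
#' @param sen,spe Detector sensitivity and specificity.
#' @return Apparent prevalence `tp*sen + (1-tp)*(1-spe)`.
#' @export
apparent_prevalence <- function(tp, sen, spe) {
  tp * sen + (1 - tp) * (1 - spe)
}

#' Uniform prior bounds on detector accuracy
#'
#' Box prior SEN ~ U(sen_bounds), SPE ~ U(spe_bounds). The defaults are the
#' minimum and maximum scenario means of the simulation study's sensitivity
#' (60.30-90.75%) and specificity (77.82-98.00%) at the 0.90 cut-off.
#'
#' @param sen_bounds,spe_bounds Length-2 numeric `(low, high)`, each in
#'   \[0, 1\] with `low <= high`. Degenerate bounds (`low == high`) give a
#'   point prior.
#' @return A list of class `accuracy_prior`.
#' @export
accuracy_prior <- function(sen_bounds = c(0.603, 0.9075),
                           spe_bounds = c(0.7782, 0.98)) {
  chk <- function(b, nm) {
    if (length(b) != 2 || b[1] > b[2] || b[1] < 0 || b[2] > 1) {
      rlang::abort(sprintf("`%s` must be (low, high) within [0, 1].", nm))
    }
  }
  chk(sen_bounds, "sen_bounds"); chk(spe_bounds, "spe_bounds")
  structure(list(sen_bounds = sen_bounds, spe_bounds = spe_bounds),
            class = "accuracy_prior")
}

#' Bayesian true-prevalence estimate
#'
#' Posterior of the true prevalence TP given `n_flagged` positives out of
#' `n_students`, under TP ~ Uniform(0, 1), SEN ~ Uniform(`sen_bounds`),
#' SPE ~ Uniform(`spe_bounds`) and
#' `n_flagged ~ Binomial(n_students, TP*SEN + (1-TP)*(1-SPE))`.
#' The posterior is computed on a deterministic tensor grid
#' (TP x SEN x SPE) and marginalized over the accuracy parameters, avoiding
#' Monte Carlo noise in this three-parameter problem; no randomness is
#' involved.
#'
#' @param n_flagged Number of students flagged by the detector.
#' @param n_students Cohort size.
#' @param prior An [accuracy_prior()].
#' @param grid_size Grid points per axis (default 400).
#' @param level Credible-interval level (default 0.95).
#' @return A list of class `tp_estimate` with `tp_mean`, `tp_sd`,
#'   `credible_interval`, `method`, and the marginal posterior grid
#'   (`tp_grid`, `posterior`).
#' @export
bayesian_tp <- function(n_flagged, n_students, prior = accuracy_prior(),
                        grid_size = 400, level = 0.95) {
  if (n_flagged < 0 || n_flagged > n_students) {
    rlang::abort("`n_flagged` must lie in [0, n_students].")
  }
  axis <- function(b) {
    if (b[1] == b[2]) b[1] else seq(b[1], b[2], length.out = grid_size)
  }
  tp <- seq(0, 1, length.out = grid_size)
  sen <- axis(prior$sen_bounds)
  spe <- axis(prior$spe_bounds)
  # accuracy grid as an outer product; loop over TP to bound memory
  sen_g <- rep(sen, times = length(spe))
  spe_g <- rep(spe, each = length(sen))
  post <- vapply(tp, function(t) {
    q <- t * sen_g + (1 - t) * (1 - spe_g)
    mean(stats::dbinom(n_flagged, n_students, q))
  }, 0)
  w <- post / sum(post)
  tp_mean <- sum(w * tp)
  tp_sd <- sqrt(sum(w * (tp - tp_mean)^2))
  cdf <- cumsum(w)
  a <- (1 - level) / 2
  ci <- c(tp[which(cdf >= a)[1]], tp[which(cdf >= 1 - a)[1]])
  structure(list(tp_mean = tp_mean, tp_sd = tp_sd, credible_interval = ci,
                 level = level, method = "bayesian", n_flagged = n_flagged,
                 n_students = n_students, prior = prior,
                 tp_grid = tp, posterior = w),
            class = "tp_estimate")
}

#' @export
print.tp_estimate <- function(x, ...) {
  cat(sprintf(
    "<tp_estimate> true prevalence %.2f%% (SD %.2f%%), %d%% CI [%.2f%%, %.2f%%]\n",
    100 * x$tp_mean, 100 * x$tp_sd, round(100 * x$level),
    100 * x$credible_interval[1], 100 * x$credible_interval[2]))
  invisible(x)
}

#' @method tidy tp_estimate
#' @export
tidy.tp_estimate <- function(x, ...) {
  tibble::tibble(tp_mean = x$tp_mean, tp_sd = x$tp_sd,
                 ci_lower = x$credible_interval[1],
                 ci_upper = x$credible_interval[2],
                 level = x$level, method = x$method)
}

#' @method glance tp_estimate
#' @export
glance.tp_estimate <- function(x, ...) {
  dplyr::bind_cols(tidy(x),
                   tibble::tibble(n_flagged = x$n_flagged,
                                  n_students = x$n_students))
}

#' Posterior-density plot of the true prevalence
#'
#' @param object A `tp_estimate`.
#' @param ... Unused.
#' @method autoplot tp_estimate
#' @export
autoplot.tp_estimate <- function(object, ...) {
  d <- tibble::tibble(tp = object$tp_grid, posterior = object$posterior)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tp, y = .data$posterior)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$tp_mean, linetype = 2) +
    ggplot2::labs(x = "true prevalence", y = "posterior mass") +
    ggplot2::theme_minimal()
}
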