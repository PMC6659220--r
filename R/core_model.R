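#' One-parameter logistic response probability
#'
#' Probability that an examinee of ability `theta` answers an item of
#' difficulty `b` correctly under the Rasch-type 1-PL model with common
#' discrimination fixed at 1:
#' \deqn{P(y = 1 \mid \theta, b) = \frac{1}{1 + e^{-(\theta - b)}}.}
#' The probability is strictly increasing in ability and strictly decreasing
#' in difficulty. Both arguments are vectorised and recycled.
#'
#' @param theta Numeric vector of abilities on the logit scale.
#' @param b Numeric vector of item difficulties on the logit scale.
#' @return Numeric vector of probabilities strictly inside (0, 1).
#' @examples
#' one_pl_prob(0, 0)            # 0.5
#' one_pl_prob(1, 0)            # ~0.731
#' one_pl_prob(c(-2, 0, 2), 0)  # increasing in theta
#' @export
one_pl_prob <- function(theta, b) {
  if (!is.numeric(theta) || !is.numeric(b) || !all(is.finite(theta)) ||
      !all(is.finite(b))) {
    rlang::abort("`theta` and `b` must be finite numeric values.")
  }
  stats::plogis(theta - b)
}

#' Gated response probability
#'
#' The gated mixture used by the pre-knowledge model: an examinee's response
#' to an item follows the 1-PL with their true ability `theta_t`, except when
#' the examinee is a cheater (`is_cheater = 1`) *and* the item is exposed
#' (`exposed = 1`), in which case the elevated cheating ability `theta_c`
#' drives the response. Equivalently, with \eqn{T} the cheater flag and
#' \eqn{G} the exposure flag,
#' \deqn{P = P_t^{1-T}\,[(1-G) P_t + G P_c]^{T},}
#' where \eqn{P_t, P_c} are the 1-PL probabilities at the two abilities.
#'
#' All arguments are vectorised and recycled, so a full students-by-items
#' probability matrix can be built with `outer()`-style expansion.
#'
#' @param theta_t Numeric, true ability.
#' @param theta_c Numeric, cheating ability.
#' @param is_cheater Binary (0/1), cheater indicator.
#' @param exposed Binary (0/1), item exposure indicator.
#' @param b Numeric, item difficulty.
#' @return Numeric vector of probabilities in (0, 1).
#' @examples
#' gated_prob(0, 2, is_cheater = 1, exposed = 1, b = 0)  # uses theta_c
#' gated_prob(0, 2, is_cheater = 0, exposed = 1, b = 0)  # uses theta_t
#' @export
gated_prob <- function(theta_t, theta_c, is_cheater, exposed, b) {
  if (!all(is.finite(theta_t)) || !all(is.finite(theta_c)) ||
      !all(is.finite(b))) {
    rlang::abort("abilities and difficulties must be finite.")
  }
  if (!all(is_cheater %in% c(0, 1)) || !all(exposed %in% c(0, 1))) {
    rlang::abort("`is_cheater` and `exposed` must be 0/1 flags.")
  }
  use_cheat <- (is_cheater == 1) & (exposed == 1)
  theta_eff <- ifelse(use_cheat, theta_c, theta_t)
  one_pl_prob(theta_eff, b)
}

#' Construct an item bank
#'
#' A tibble of items with their 1-PL difficulties and exposure status.
#' Exposed (compromised) items are those reused from earlier examinations and
#' therefore potentially known in advance; secure items appear for the first
#' time.
#'
#' @param difficulty Numeric vector of item difficulties (logit scale).
#' @param exposed Binary (0/1) vector, same length, exposure flags.
#' @param item_id Optional character labels; defaults to `item_1, item_2, ...`.
#' @return A tibble with columns `item_id`, `difficulty`, `exposed`.
#' @export
item_bank <- function(difficulty, exposed, item_id = NULL) {
  if (!all(is.finite(difficulty))) {
    rlang::abort("item difficulties must be finite.")
  }
  if (length(exposed) != length(difficulty) || !all(exposed %in% c(0, 1))) {
    rlang::abort("`exposed` must be 0/1 flags, one per item.")
  }
  if (is.null(item_id)) {
    item_id <- paste0("item_", seq_along(difficulty))
  }
  if (anyDuplicated(item_id)) rlang::abort("duplicated `item_id`.")
  tibble::tibble(item_id = as.character(item_id),
                 difficulty = as.numeric(difficulty),
                 exposed = as.integer(exposed))
}

#' Construct a student cohort
#'
#' A tibble of examinees with true ability, cheating ability, effective gain
#' and cheater status. By definition a cheater is an examinee whose cheating
#' ability exceeds their true ability (`theta_cheat = theta_true + gain`,
#' `gain > 0`); honest examinees have zero gain.
#'
#' @param theta_true Numeric vector of true abilities.
#' @param gain Non-negative numeric vector of effective score gains.
#' @param student_id Optional character labels.
#' @return A tibble with columns `student_id`, `theta_true`, `theta_cheat`,
#'   `gain`, `is_cheater`.
#' @export
student_cohort <- function(theta_true, gain, student_id = NULL) {
  if (!all(is.finite(theta_true)) || !all(is.finite(gain))) {
    rlang::abort("abilities and gains must be finite.")
  }
  if (length(gain) != length(theta_true) || any(gain < 0)) {
    rlang::abort("`gain` must be non-negative, one value per student.")
  }
  if (is.null(student_id)) {
    student_id <- paste0("student_", seq_along(theta_true))
  }
  if (anyDuplicated(student_id)) rlang::abort("duplicated `student_id`.")
  tibble::tibble(student_id = as.character(student_id),
                 theta_true = as.numeric(theta_true),
                 theta_cheat = as.numeric(theta_true + gain),
                 gain = as.numeric(gain),
                 is_cheater = as.integer(gain > 0))
}

# Coerce user input (tibble with student_id + item columns, data.frame, or
# plain matrix) to a validated binary integer matrix with dimnames.
as_response_matrix <- function(responses) {
  if (is.data.frame(responses)) {
    df <- responses
    id_col <- if ("student_id" %in% names(df)) "student_id" else NULL
    if (!is.null(id_col)) {
      ids <- as.character(df[[id_col]])
      df <- df[setdiff(names(df), id_col)]
    } else {
      ids <- paste0("student_", seq_len(nrow(df)))
    }
    mat <- as.matrix(df)
    storage.mode(mat) <- "integer"
    rownames(mat) <- ids
  } else if (is.matrix(responses)) {
    mat <- responses
    storage.mode(mat) <- "integer"
    if (is.null(rownames(mat))) {
      rownames(mat) <- paste0("student_", seq_len(nrow(mat)))
    }
    if (is.null(colnames(mat))) {
      colnames(mat) <- paste0("item_", seq_len(ncol(mat)))
    }
  } else {
    rlang::abort("`responses` must be a matrix or data frame of 0/1 values.")
  }
  if (anyNA(mat)) rlang::abort("missing responses are not supported.")
  if (!all(mat %in% c(0L, 1L))) {
    rlang::abort("responses must be binary (0/1).")
  }
  mat
}
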