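#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted maxent model
#'
#' One row per feature with its weight and penalty scale; `term` follows the
#' feature naming (`cov1`, `cov1^2`, `cov1:cov2`).
#'
#' @param x a `maxent_model`
#' @param ... unused
#' @return tibble with `term`, `kind`, `estimate`, `penalty`
#' @export
tidy.maxent_model <- function(x, ...) {
  tibble::tibble(
    term = names(x$lambda),
    kind = vapply(x$spec$features, `[[`, "", "kind"),
    estimate = unname(x$lambda),
    penalty = unname(x$beta)
  )
}

#' @rdname tidy.maxent_model
#' @return for `glance()`: a one-row tibble with fit summaries
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    n_presence = x$n_presence, n_background = x$n_background,
    n_features = length(x$lambda), n_nonzero = sum(x$lambda != 0),
    rm = x$rm, gain = x$gain, gain_reg = x$gain_reg,
    entropy = x$entropy, iterations = x$iterations, converged = x$converged
  )
}

#' Tidy a maxent evaluation
#'
#' @param x a `maxent_evaluation`
#' @param ... unused
#' @return per-replicate tibble (`tidy`) or one-row means (`glance`)
#' @export
tidy.maxent_evaluation <- function(x, ...) x$replicates

#' @rdname tidy.maxent_evaluation
#' @export
glance.maxent_evaluation <- function(x, ...) {
  tibble::tibble(replicates = nrow(x$replicates), split = x$split,
                 kfold = x$kfold,
                 auc_train_mean = x$auc_train_mean,
                 auc_test_mean = x$auc_test_mean)
}
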