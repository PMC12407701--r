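# broom-style accessors for fitted objects.

#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' Tidy the parameter estimates of a fit
#'
#' @param x a `grn_fit`.
#' @param ... unused.
#' @return A tibble with one row per parameter: `name`, `gene`, `role`,
#'   `free`, `estimate`.
#' @exportS3Method generics::tidy
tidy.grn_fit <- function(x, ...) {
  dplyr::rename(x$theta, estimate = "value")
}

#' One-row summary of a fit
#'
#' @param x a `grn_fit`.
#' @param ... unused.
#' @return A tibble with `model_index`, `nll`, `sigma_hat`, `n_parameters`,
#'   `n_obs`, `n_failed_starts`, `failed`.
#' @exportS3Method generics::glance
glance.grn_fit <- function(x, ...) {
  tibble::tibble(
    model_index = x$model$model_index,
    nll = x$nll,
    sigma_hat = x$sigma_hat,
    n_parameters = sum(x$theta$free),
    n_obs = nrow(x$data),
    n_failed_starts = x$n_failed_starts,
    failed = x$failed
  )
}

#' Observations augmented with fitted values and residuals
#'
#' @param x a `grn_fit`.
#' @param ... unused.
#' @return The fit's data with `.fitted` and the relative residual
#'   `.resid_rel = (y - x) / x` that the multiplicative error model
#'   penalizes.
#' @exportS3Method generics::augment
augment.grn_fit <- function(x, ...) {
  if (x$failed) abort("cannot augment a failed fit.")
  out <- x$data
  out$.fitted <- x$predictions$value[match(
    paste(out$gene, out$time_h),
    paste(x$predictions$gene, x$predictions$time_h)
  )]
  out$.resid_rel <- (out$value - out$.fitted) / out$.fitted
  out
}

#' Tidy a trained acceptability classifier
#'
#' @param x a `grn_classifier`.
#' @param ... unused.
#' @return A tibble of the tree's variable importances (empty for a
#'   majority-rule classifier).
#' @exportS3Method generics::tidy
tidy.grn_classifier <- function(x, ...) {
  if (is.null(x$tree) || is.null(x$tree$variable.importance)) {
    return(tibble::tibble(feature = character(), importance = numeric()))
  }
  imp <- x$tree$variable.importance
  tibble::tibble(feature = names(imp), importance = as.numeric(imp))
}

#' @exportS3Method generics::glance
glance.grn_classifier <- function(x, ...) {
  tibble::tibble(
    cv_accuracy = x$cv_accuracy,
    null_accuracy = x$null_accuracy,
    n_folds = length(x$fold_accuracies)
  )
}
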