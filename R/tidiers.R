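#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a promoter classifier into a coefficient table
#'
#' @param x a `promoter_classifier`.
#' @param ... unused.
#' @return tibble (term, estimate, cutoff) including the `(Intercept)` row.
#' @export
tidy.promoter_classifier <- function(x, ...) {
  cut <- x$rules$cutoff[match(x$features, x$rules$feature)]
  bind_rows(
    tibble(term = "(Intercept)", estimate = x$intercept, cutoff = NA_real_),
    tibble(term = x$features, estimate = unname(x$coefficients),
           cutoff = cut))
}

#' @export
glance.promoter_classifier <- function(x, ...) {
  tibble(name = x$name, n_features = length(x$features),
         intercept = x$intercept,
         probability_threshold = x$probability_threshold)
}

#' Tidy / glance methods for ROC results
#'
#' `tidy()` returns the per-sample probabilities; `glance()` the one-row
#' performance summary (AUC with DeLong CI, accuracy, sensitivity,
#' specificity, threshold).
#'
#' @param x a `roc_result`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.roc_result <- function(x, ...) {
  x$probabilities
}

#' @rdname tidy.roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, auc_ci_low = x$auc_ci_low,
         auc_ci_high = x$auc_ci_high, accuracy = x$accuracy,
         sensitivity = x$sensitivity, specificity = x$specificity,
         threshold = x$threshold)
}

#' Tidy a logistic fit
#' @param x a `logistic_fit`.
#' @param ... unused.
#' @return tibble (term, estimate).
#' @export
tidy.logistic_fit <- function(x, ...) {
  bind_rows(tibble(term = "(Intercept)", estimate = x$intercept),
            tibble(term = names(x$coefficients),
                   estimate = unname(x$coefficients)))
}
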