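#' Tidy a Cox fit
#'
#' @param x a `cox_fit`.
#' @param ... unused.
#' @return Tibble `term`, `estimate`, `se`, `hr`, `conf.low`,
#'   `conf.high`, `p`.
#' @export
tidy.cox_fit <- function(x, ...) x$coefficients

#' @rdname tidy.cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event, loglik = x$loglik,
                 aic = x$aic, converged = x$converged)
}

#' Tidy a risk model
#'
#' @param x a `risk_model`.
#' @param ... unused.
#' @return Tibble `pair_id`, `lncA`, `lncB`, `beta`, `hr`.
#' @export
tidy.risk_model <- function(x, ...) {
  dplyr::mutate(x$pairs,
                pair_id = paste(.data$lncA, .data$lncB, sep = "|"),
                hr = exp(.data$beta), .before = 1)
}

#' @rdname tidy.risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs), cutoff = x$cutoff,
                 horizon = x$horizon)
}

#' Tidy a time-dependent ROC curve
#'
#' @param x a `td_roc`.
#' @param ... unused.
#' @return The `cutoff`, `fp`, `tp` tibble.
#' @export
tidy.td_roc <- function(x, ...) x$curve

#' @rdname tidy.td_roc
#' @export
glance.td_roc <- function(x, ...) {
  tibble::tibble(t_star = x$t_star, auc = x$auc, n = x$n,
                 n_event_by_t = x$n_event_by_t)
}

#' Tidy a fitted signature
#'
#' @param x a `pairsig_fit`.
#' @param ... unused.
#' @return As [tidy.risk_model()] on the fitted model.
#' @export
tidy.pairsig_fit <- function(x, ...) tidy(x$model)

#' @rdname tidy.pairsig_fit
#' @export
glance.pairsig_fit <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$model$pairs), training_auc = x$auc,
                 cutoff = x$model$cutoff, horizon = x$model$horizon,
                 n_high = x$cutoff$n_high, n_low = x$cutoff$n_low)
}
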