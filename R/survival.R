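#' Fit a Cox proportional-hazards model (Breslow ties)
#'
#' Front end over [survival::coxph()] with Breslow tie handling, a tight
#' convergence tolerance and Wald inference: per covariate the hazard
#' ratio `exp(beta)`, its 95% CI from `beta +/- 1.96 * SE` and the Wald
#' p-value. Model-level AIC is `-2 * logPL + 2 * k`.
#'
#' @param x data frame or matrix of covariates (samples in rows).
#' @param time,status follow-up in days and event indicator (1 event,
#'   0 censored); at least one event required.
#' @return Object of class `cox_fit` with `coefficients` (tibble `term`,
#'   `estimate`, `se`, `hr`, `conf.low`, `conf.high`, `p`), `loglik`,
#'   `aic`, `n`, `n_event`, `converged` and the underlying `coxph` fit.
#' @export
cox_fit <- function(x, time, status) {
  check_surv(time, status)
  x <- as.data.frame(x)
  abort_if(nrow(x) != length(time), "`x` rows must match the survival records")
  abort_if(ncol(x) < 1, "need at least one covariate")
  abort_if(any(!is.finite(as.matrix(x))), "covariates must be finite")
  terms <- colnames(x)
  dat <- x
  names(dat) <- paste0("V", seq_along(dat))   # shield non-syntactic pair ids
  dat$.time <- time; dat$.status <- status
  fit <- survival::coxph(
    survival::Surv(.time, .status) ~ ., data = dat, ties = "breslow",
    control = survival::coxph.control(eps = 1e-9, iter.max = 100))
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  coefficients <- tibble::tibble(
    term = terms,
    estimate = unname(beta),
    se = unname(se),
    hr = exp(unname(beta)),
    conf.low = exp(unname(beta) - 1.96 * unname(se)),
    conf.high = exp(unname(beta) + 1.96 * unname(se)),
    p = unname(2 * stats::pnorm(-abs(beta / se)))
  )
  ll <- fit$loglik[length(fit$loglik)]
  k <- sum(!is.na(beta))
  structure(list(
    coefficients = coefficients,
    loglik = ll, aic = -2 * ll + 2 * k,
    n = fit$n, n_event = fit$nevent,
    converged = is.null(fit$info) && fit$iter < 100 && all(is.finite(se)),
    fit = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (Breslow): n = %d, events = %d, logPL = %.4f, AIC = %.4f\n",
              x$n, x$n_event, x$loglik, x$aic))
  if (!x$converged) cat("  [warning] fit did not converge cleanly\n")
  print(x$coefficients, ...)
  invisible(x)
}

#' Univariate Cox screen of pair indicators
#'
#' One single-covariate Cox fit per pair; pairs with a Wald p-value below
#' `alpha` are retained, sorted by p. Pairs constant on this cohort are
#' degenerate for a proportional-hazards fit and are skipped with a
#' message.
#'
#' @param pairs pair tibble from [build_pairs()] / [filter_pairs()].
#' @param clinical tibble with `sample_id`, `os_time`, `os_status`
#'   covering the cohort to screen (samples are taken from it).
#' @param alpha retention threshold on the Wald p-value (strict).
#' @return Tibble `pair_id`, `lncA`, `lncB`, `estimate`, `hr`,
#'   `conf.low`, `conf.high`, `p` for retained pairs, ordered by `p`.
#' @export
univariate_screen <- function(pairs, clinical, alpha = 0.05) {
  x <- pair_design(pairs, clinical$sample_id)
  check_surv(clinical$os_time, clinical$os_status)
  prev <- colMeans(x)
  degen <- prev == 0 | prev == 1
  if (any(degen)) {
    message(sum(degen), " pair(s) constant on this cohort skipped")
  }
  keep <- which(!degen)
  res <- purrr::map_dfr(keep, function(j) {
    f <- cox_fit(x[, j, drop = FALSE], clinical$os_time, clinical$os_status)
    f$coefficients
  })
  if (nrow(res) == 0) return(res)
  res |>
    dplyr::rename(pair_id = "term") |>
    dplyr::left_join(pairs[c("pair_id", "lncA", "lncB")], by = "pair_id") |>
    dplyr::filter(.data$p < alpha) |>
    dplyr::arrange(.data$p) |>
    dplyr::select("pair_id", "lncA", "lncB", "estimate", "hr",
                  "conf.low", "conf.high", "p")
}

#' LASSO-penalized Cox regression with cross-validated lambda
#'
#' Front end over [glmnet::cv.glmnet()] (`family = "cox"`): an L1 path is
#' fitted over a decreasing lambda grid with warm starts and the penalty
#' `lambda_min` minimizing the k-fold cross-validated partial-likelihood
#' deviance is chosen; fold assignment is drawn from `fold_seed`.
#'
#' @param x numeric covariate matrix (samples x covariates, >= 2 columns).
#' @param time,status survival outcome.
#' @param lambda optional user lambda sequence (decreasing; may end in 0).
#' @param n_folds number of CV folds.
#' @param fold_seed integer seed for the fold assignment.
#' @param nlambda grid length when `lambda` is NULL.
#' @return List with `lambda_min`, `beta` (named coefficients at
#'   `lambda_min`), `support` (names of nonzero coefficients), `cv_path`
#'   (tibble `lambda`, `deviance`, `se`) and the `cv.glmnet` object.
#' @export
lasso_cox <- function(x, time, status, lambda = NULL, n_folds = 10,
                      fold_seed = 1L, nlambda = 100) {
  check_surv(time, status)
  x <- as.matrix(x)
  abort_if(ncol(x) < 2, "glmnet needs at least 2 covariates")
  abort_if(sum(status) < n_folds,
           "need at least as many events as CV folds")
  y <- survival::Surv(time, status)
  foldid <- withr::with_seed(as.integer(fold_seed),
                             sample(rep_len(seq_len(n_folds), nrow(x))))
  cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                          lambda = lambda, nlambda = nlambda,
                          standardize = FALSE)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(beta) <- rownames(stats::coef(cv, s = "lambda.min"))
  support <- names(beta)[beta != 0]
  if (length(support) == 0) {
    warning("LASSO path is all-zero at lambda_min; empty support returned")
  }
  list(lambda_min = cv$lambda.min, beta = beta, support = support,
       cv_path = tibble::tibble(lambda = cv$lambda, deviance = cv$cvm,
                                se = cv$cvsd),
       cv = cv)
}

#' Iterated LASSO-Cox selection by occurrence frequency
#'
#' Runs `n_iter` independent cross-validated LASSO-Cox fits, each with a
#' fresh fold assignment drawn from a seed derived from `base_seed`
#' (optionally also resampling patients with replacement). A covariate's
#' frequency is the number of runs in which its coefficient at
#' `lambda_min` is nonzero; covariates seen strictly more than `freq_min`
#' times are selected. With the defaults (1000 iterations, threshold 100)
#' the threshold is 10% of the runs; when fewer iterations are requested
#' keep `freq_min = n_iter / 10` to preserve that proportion.
#'
#' @inheritParams lasso_cox
#' @param n_iter number of repeated CV LASSO runs.
#' @param freq_min strict selection threshold on the frequency.
#' @param base_seed integer seed; the whole procedure is reproducible.
#' @param bootstrap also resample patients with replacement per run.
#' @return List with `frequency` (tibble `term`, `freq`, sorted
#'   decreasing) and `selected` (terms with `freq > freq_min`).
#' @export
iterated_lasso_selection <- function(x, time, status, n_iter = 1000,
                                     freq_min = n_iter / 10,
                                     n_folds = 10, base_seed = 1L,
                                     bootstrap = FALSE) {
  abort_if(n_iter < 1, "`n_iter` must be >= 1")
  x <- as.matrix(x)
  check_surv(time, status)
  # one shared lambda grid from the full data keeps runs comparable
  y <- survival::Surv(time, status)
  grid <- glmnet::glmnet(x, y, family = "cox", nlambda = 60,
                         standardize = FALSE)$lambda
  seeds <- withr::with_seed(as.integer(base_seed),
                            sample.int(.Machine$integer.max, n_iter))
  counts <- setNames(integer(ncol(x)), colnames(x))
  for (i in seq_len(n_iter)) {
    rows <- seq_len(nrow(x))
    if (bootstrap) {
      rows <- withr::with_seed(seeds[i] %% 1000003L + 1L,
                               sample(rows, replace = TRUE))
    }
    fit <- tryCatch(
      suppressWarnings(
        lasso_cox(x[rows, , drop = FALSE], time[rows], status[rows],
                  lambda = grid, n_folds = n_folds, fold_seed = seeds[i])),
      error = function(e) NULL)
    if (is.null(fit)) next
    counts[fit$support] <- counts[fit$support] + 1L
  }
  frequency <- tibble::tibble(term = names(counts), freq = unname(counts)) |>
    dplyr::arrange(dplyr::desc(.data$freq), .data$term)
  list(frequency = frequency,
       selected = frequency$term[frequency$freq > freq_min])
}

#' Bidirectional stepwise Cox model search by AIC
#'
#' Starts from the full model over all candidates and repeatedly applies
#' the single add-or-drop move that lowers AIC most (`AIC = -2 logPL +
#' 2k`, with `k` the number of covariates in the model, so an exactly
#' collinear duplicate is always penalized), stopping when no move
#' improves. Ties are broken by candidate order, making the search
#' deterministic; moves whose fit fails are skipped.
#'
#' @param x data frame or matrix with one column per candidate covariate.
#' @param time,status survival outcome.
#' @return List with `terms` (final covariates, possibly empty), `fit`
#'   (`cox_fit` of the final model, or NULL when empty) and `path`, a list
#'   of the successive model states (`terms`, `aic`, `fit`) from the full
#'   start to the final model — the nested candidates later scored by
#'   [select_model_by_auc()].
#' @export
stepwise_cox <- function(x, time, status) {
  x <- as.data.frame(x)
  abort_if(ncol(x) < 1, "need at least one candidate covariate")
  check_surv(time, status)
  all_terms <- colnames(x)

  null_ll <- survival::coxph(survival::Surv(time, status) ~ 1)$loglik[1]
  aic_of <- function(terms) {
    if (length(terms) == 0) return(list(aic = -2 * null_ll, fit = NULL))
    f <- tryCatch(suppressWarnings(cox_fit(x[terms], time, status)),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) return(NULL)
    list(aic = -2 * f$loglik + 2 * length(terms), fit = f)
  }

  current <- all_terms
  state <- aic_of(current)
  if (is.null(state)) {
    # full model unfit (e.g. separation): fall back to the empty model
    # and let forward steps rebuild
    current <- character()
    state <- aic_of(current)
  }
  path <- list(list(terms = current, aic = state$aic, fit = state$fit))
  repeat {
    moves <- c(lapply(current, function(t) setdiff(current, t)),
               lapply(setdiff(all_terms, current), function(t) c(current, t)))
    best <- NULL; best_aic <- state$aic - 1e-8
    for (mv in moves) {
      cand <- aic_of(mv)
      if (!is.null(cand) && cand$aic < best_aic) {
        best <- list(terms = mv, aic = cand$aic, fit = cand$fit)
        best_aic <- cand$aic
      }
    }
    if (is.null(best)) break
    current <- best$terms
    state <- best
    path <- c(path, list(best))
  }
  list(terms = current, fit = state$fit, path = path)
}

#' Per-patient risk score of a pair signature
#'
#' `RiskScore(s) = sum_i beta_i * G_i(s)` over the model's pairs, with
#' `G_i(s)` the patient's 0/1 pair indicators.
#'
#' @param model a [risk_model()].
#' @param pairs pair tibble from [build_pairs()] containing every model
#'   pair (missing pairs are an error naming them).
#' @param samples optional subset of samples to score.
#' @return Tibble `sample_id`, `risk_score`.
#' @export
risk_score <- function(model, pairs, samples = NULL) {
  abort_if(!inherits(model, "risk_model"), "`model` must be a risk_model")
  ids <- paste(model$pairs$lncA, model$pairs$lncB, sep = "|")
  missing <- setdiff(ids, pairs$pair_id)
  abort_if(length(missing) > 0,
           paste0("pairs absent from the indicator table: ",
                  paste(missing, collapse = ", ")))
  x <- pair_design(pairs[match(ids, pairs$pair_id), ], samples)
  tibble::tibble(sample_id = rownames(x),
                 risk_score = as.numeric(x %*% model$pairs$beta))
}

#' Kaplan-Meier product-limit survival estimate
#'
#' @param time,status survival outcome (all-censored input is allowed:
#'   the curve is then 1 everywhere).
#' @return Tibble `time`, `n_risk`, `n_event`, `n_censor`, `surv`,
#'   anchored at `time = 0`, `surv = 1`; the estimate is non-increasing
#'   and drops only at event times.
#' @export
km_estimate <- function(time, status) {
  abort_if(length(time) == 0, "empty survival input")
  abort_if(any(time <= 0) || !all(status %in% c(0, 1)),
           "need time > 0 and status in {0, 1}")
  sf <- survival::survfit(survival::Surv(time, status) ~ 1)
  tibble::tibble(
    time = c(0, sf$time),
    n_risk = c(length(time), sf$n.risk),
    n_event = c(0, sf$n.event),
    n_censor = c(0, sf$n.censor),
    surv = c(1, sf$surv)
  )
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic (1 df for two groups) with hypergeometric
#' variance, via [survival::survdiff()].
#'
#' @param time,status survival outcome.
#' @param group group label per record; every level must be non-empty.
#' @return List with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, status, group) {
  group <- as.factor(droplevels(as.factor(group)))
  abort_if(nlevels(group) < 2, "log-rank needs at least 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, status) ~ group)
  df <- nlevels(group) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}
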