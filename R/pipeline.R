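#' Train a rank-pair risk signature end to end
#'
#' Runs the model-construction chain on a training cohort:
#' univariate Cox screening of the pair indicators (Wald `p < alpha`),
#' iterated cross-validated LASSO-Cox with selection of pairs recorded
#' strictly more than `freq_min` times, a bidirectional stepwise-AIC Cox
#' search over the selected pairs, scoring of every model on the stepwise
#' path with the time-dependent AUC at `t_star` and retention of the
#' maximizer, and finally the AIC-minimizing risk-score cut-off on the
#' winning model's training scores.
#'
#' @param pairs pair tibble from [build_pairs()]/[filter_pairs()].
#' @param clinical training-cohort tibble with `sample_id`, `os_time`,
#'   `os_status`.
#' @param alpha univariate screen threshold.
#' @param n_iter,freq_min,n_folds iterated-LASSO settings (see
#'   [iterated_lasso_selection()]).
#' @param t_star ROC horizon in days (default 5 years).
#' @param seed integer seed driving the CV fold randomness.
#' @return List of class `pairsig_fit`: `model` (a [risk_model()] with the
#'   learned cut-off), `auc` (training AUC at `t_star`), `screen`
#'   (univariate results), `frequency` (LASSO frequency table), `stepwise`
#'   (the stepwise path), `auc_table`, `cutoff` (the `risk_cutoff`),
#'   `scores` (training scores with risk groups).
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_config(
#'   n_tumor = 120, n_normal = 30, n_lnc = 20, n_immune = 10,
#'   n_de = 8, planted_pairs = data.frame(lncA = 1, lncB = 2, beta = 1.2),
#'   seed = 42))
#' pr <- build_pairs(sim$expression[1:20, ], sim$clinical$sample_id) |>
#'   filter_pairs()
#' fit <- train_risk_signature(pr, sim$clinical, n_iter = 20, freq_min = 2,
#'                             seed = 1)
#' fit$model
#' }
#' @export
train_risk_signature <- function(pairs, clinical, alpha = 0.05,
                                 n_iter = 1000, freq_min = n_iter / 10,
                                 n_folds = 10,
                                 t_star = years_to_days(5), seed = 1L) {
  screen <- univariate_screen(pairs, clinical, alpha = alpha)
  abort_if(nrow(screen) == 0, "no pair passed the univariate Cox screen")

  x <- pair_design(pairs[match(screen$pair_id, pairs$pair_id), ],
                   clinical$sample_id)
  if (ncol(x) >= 2) {
    il <- iterated_lasso_selection(x, clinical$os_time, clinical$os_status,
                                   n_iter = n_iter, freq_min = freq_min,
                                   n_folds = n_folds, base_seed = seed)
    selected <- il$selected
    frequency <- il$frequency
  } else {
    selected <- colnames(x)
    frequency <- tibble::tibble(term = selected, freq = n_iter)
  }
  abort_if(length(selected) == 0,
           "no pair exceeded the LASSO frequency threshold")

  sw <- stepwise_cox(x[, selected, drop = FALSE],
                     clinical$os_time, clinical$os_status)
  path_terms <- Filter(function(t) length(t) > 0,
                       lapply(sw$path, `[[`, "terms"))
  abort_if(length(path_terms) == 0, "stepwise search retained no pair")
  candidates <- lapply(path_terms, function(terms) {
    f <- cox_fit(x[, terms, drop = FALSE],
                 clinical$os_time, clinical$os_status)
    pair_model_from_fit(f)
  })

  sel <- select_model_by_auc(candidates, pairs, clinical, t_star)
  scores <- risk_score(sel$model, pairs, clinical$sample_id)
  cut <- aic_cutoff(scores, clinical)
  model <- risk_model(sel$model$pairs, cutoff = cut$cutoff, horizon = t_star)

  structure(list(model = model, auc = sel$auc, screen = screen,
                 frequency = frequency, stepwise = sw,
                 auc_table = sel$auc_table, cutoff = cut,
                 scores = apply_cutoff(scores, cut)),
            class = "pairsig_fit")
}

# cox_fit over pair-id columns -> risk_model (cutoff learned later)
pair_model_from_fit <- function(fit) {
  co <- fit$coefficients
  parts <- strsplit(co$term, "|", fixed = TRUE)
  risk_model(tibble::tibble(lncA = vapply(parts, `[`, "", 1),
                            lncB = vapply(parts, `[`, "", 2),
                            beta = co$estimate))
}

#' @export
print.pairsig_fit <- function(x, ...) {
  cat("pairsig fit:", nrow(x$model$pairs), "pair(s), training AUC",
      sprintf("%.3f", x$auc), "at t* =", x$model$horizon, "days\n")
  print(x$model$pairs)
  invisible(x)
}

#' Evaluate a fitted signature on a cohort
#'
#' Scores the cohort, applies the (training-learned) cut-off unchanged,
#' and reports the time-dependent AUC at the requested horizons together
#' with the high/low log-rank test.
#'
#' @param fit a `pairsig_fit` or a bare [risk_model()].
#' @param pairs pair tibble covering the cohort's samples.
#' @param clinical cohort tibble with `sample_id`, `os_time`, `os_status`.
#' @param horizons numeric vector of horizons in days.
#' @return List with `scores` (tibble with `risk_group`), `auc` (tibble
#'   `horizon`, `auc`), `logrank` (list `chisq`, `df`, `p`).
#' @export
evaluate_risk_signature <- function(fit, pairs, clinical,
                                    horizons = years_to_days(c(1, 3, 5))) {
  model <- if (inherits(fit, "pairsig_fit")) fit$model else fit
  abort_if(!inherits(model, "risk_model"), "`fit` must carry a risk_model")
  scores <- risk_score(model, pairs, clinical$sample_id)
  grouped <- apply_cutoff(scores, model$cutoff)
  auc <- purrr::map_dfr(horizons, function(h) {
    a <- tryCatch(
      td_roc(scores$risk_score, clinical$os_time, clinical$os_status, h)$auc,
      error = function(e) NA_real_)
    tibble::tibble(horizon = h, auc = a)
  })
  lr <- if (length(unique(grouped$risk_group)) == 2) {
    logrank_test(clinical$os_time, clinical$os_status, grouped$risk_group)
  } else {
    list(chisq = NA_real_, df = NA_real_, p = NA_real_)
  }
  list(scores = grouped, auc = auc, logrank = lr)
}
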