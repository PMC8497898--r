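# internal product-limit survival probability at a single horizon
km_surv_at <- function(time, status, t_star) {
  ev <- which(status == 1 & time <= t_star)
  if (length(ev) == 0) return(1)
  # ties: group events by time against the risk set at that time
  ut <- sort(unique(time[ev]))
  d <- vapply(ut, function(u) sum(time[ev] == u), numeric(1))
  r <- vapply(ut, function(u) sum(time >= u), numeric(1))
  prod(1 - d / r)
}

#' Time-dependent (cumulative/dynamic) ROC curve for censored survival
#'
#' At horizon `t_star`, cases are subjects with an event by `t_star` and
#' controls those event-free at `t_star`; censoring is handled with
#' Kaplan-Meier estimates. With `S` the overall KM survival and `S_c` the
#' KM survival within the marker-above-cutoff subgroup `{X > c}`,
#' `TP(c) = (1 - S_c(t*)) P(X > c) / (1 - S(t*))` and
#' `FP(c) = S_c(t*) P(X > c) / S(t*)`. The cutoff sweep runs over the
#' distinct marker values (plus the all-in endpoint), anchoring the curve
#' at (0,0) and (1,1); AUC is the trapezoid over (FP, TP). With no
#' censoring the curve reduces exactly to the empirical ROC of the binary
#' event-by-`t_star` outcome and the AUC to the Mann-Whitney AUC.
#'
#' @param marker numeric risk marker, higher = higher risk.
#' @param time,status survival outcome aligned with `marker`.
#' @param t_star evaluation horizon (same units as `time`); must not
#'   exceed the last observed time, and at least one event must precede it.
#' @return Object of class `td_roc`: list with `curve` (tibble `cutoff`,
#'   `fp`, `tp`), `auc`, `t_star`, `n`, `n_event_by_t`.
#' @export
td_roc <- function(marker, time, status, t_star) {
  check_surv(time, status)
  abort_if(length(marker) != length(time),
           "`marker` must align with the survival records")
  abort_if(any(!is.finite(marker)), "marker values must be finite")
  abort_if(t_star > max(time), "`t_star` lies beyond the observed follow-up")
  abort_if(sum(status == 1 & time <= t_star) < 1,
           "no events observed by `t_star`")
  s_all <- km_surv_at(time, status, t_star)
  abort_if(s_all >= 1, "no events observed by `t_star`")
  abort_if(s_all <= 0, "KM survival at `t_star` is zero; lower `t_star`")

  cuts <- sort(unique(marker), decreasing = TRUE)
  tp <- fp <- numeric(length(cuts) + 1)
  for (i in seq_along(cuts)) {
    above <- marker > cuts[i]
    p_above <- mean(above)
    if (!any(above)) { tp[i] <- 0; fp[i] <- 0; next }
    s_sub <- km_surv_at(time[above], status[above], t_star)
    tp[i] <- (1 - s_sub) * p_above / (1 - s_all)
    fp[i] <- s_sub * p_above / s_all
  }
  tp[length(cuts) + 1] <- 1; fp[length(cuts) + 1] <- 1  # c below min(marker)
  curve <- tibble::tibble(cutoff = c(cuts, -Inf), fp = fp, tp = tp)
  auc <- sum(diff(fp) * (head(tp, -1) + tp[-1]) / 2)
  structure(list(curve = curve, auc = auc, t_star = t_star,
                 n = length(marker),
                 n_event_by_t = sum(status == 1 & time <= t_star)),
            class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("time-dependent ROC at t* = %g: AUC = %.4f (n = %d, %d events by t*)\n",
              x$t_star, x$auc, x$n, x$n_event_by_t))
  invisible(x)
}

#' Choose the risk model maximizing the time-dependent AUC
#'
#' Scores every candidate model on the cohort, evaluates its
#' cumulative/dynamic AUC at `t_star`, and returns the maximizer; exact
#' AUC ties are broken toward the model with fewer pairs. This mirrors
#' stopping a stepwise search at the point of maximum AUC.
#'
#' @param candidates list of [risk_model()] objects (e.g. the states of a
#'   stepwise path converted to models).
#' @param pairs pair tibble for scoring.
#' @param clinical tibble with `sample_id`, `os_time`, `os_status`.
#' @param t_star ROC horizon (days).
#' @return List with `model` (the winner), `auc` (its AUC) and
#'   `auc_table` (tibble `candidate`, `n_pairs`, `auc`).
#' @export
select_model_by_auc <- function(candidates, pairs, clinical, t_star) {
  abort_if(length(candidates) < 1, "need at least one candidate model")
  scores <- lapply(candidates, function(m) {
    risk_score(m, pairs, clinical$sample_id)$risk_score
  })
  auc <- vapply(scores, function(s) {
    td_roc(s, clinical$os_time, clinical$os_status, t_star)$auc
  }, numeric(1))
  n_pairs <- vapply(candidates, function(m) nrow(m$pairs), numeric(1))
  best <- order(-auc, n_pairs)[1]
  list(model = candidates[[best]], auc = auc[best],
       auc_table = tibble::tibble(candidate = seq_along(candidates),
                                  n_pairs = n_pairs, auc = auc))
}

#' AIC-minimizing dichotomization cut-off for a risk score
#'
#' Every candidate cut-off (midpoints between consecutive distinct sorted
#' scores, restricted so each side keeps at least `min_frac` of the
#' patients) dichotomizes the cohort; a single-covariate Cox model on the
#' high/low indicator is fitted and its AIC recorded. The cut-off
#' minimizing AIC is returned together with the full profile. Because
#' only the ranks of the scores enter, any strictly increasing transform
#' of the scores yields the same grouping. `method = "youden"` instead
#' maximizes TP - FP on the time-dependent ROC at `t_star`.
#'
#' @param scores tibble `sample_id`, `risk_score` (or a bare numeric
#'   vector aligned with `clinical`).
#' @param clinical tibble with `sample_id`, `os_time`, `os_status`.
#' @param min_frac minimum fraction of patients on each side of a
#'   candidate cut-off.
#' @param method `"aic"` (default) or `"youden"`.
#' @param t_star horizon, required for `method = "youden"`.
#' @return List of class `risk_cutoff`: `cutoff`, `n_high`, `n_low`,
#'   `method` and `profile` (tibble `cutoff`, `aic` or `youden`,
#'   `n_high`, `n_low`).
#' @export
aic_cutoff <- function(scores, clinical, min_frac = 0.1,
                       method = c("aic", "youden"), t_star = NULL) {
  method <- match.arg(method)
  if (is.data.frame(scores)) {
    s <- scores$risk_score[match(clinical$sample_id, scores$sample_id)]
  } else {
    s <- as.numeric(scores)
  }
  abort_if(any(is.na(s)), "scores missing for some clinical samples")
  check_surv(clinical$os_time, clinical$os_status)
  u <- sort(unique(s))
  abort_if(length(u) < 2, "all risk scores identical; no cut-off exists")
  cand <- (u[-1] + u[-length(u)]) / 2
  n <- length(s)
  n_high <- vapply(cand, function(c) sum(s > c), numeric(1))
  ok <- n_high >= min_frac * n & (n - n_high) >= min_frac * n
  if (!any(ok)) ok <- rep(TRUE, length(cand))  # tiny cohorts: keep all splits
  cand <- cand[ok]; n_high <- n_high[ok]

  if (method == "aic") {
    crit <- vapply(cand, function(c) {
      f <- tryCatch(cox_fit(data.frame(high = as.numeric(s > c)),
                            clinical$os_time, clinical$os_status),
                    error = function(e) NULL)
      if (is.null(f)) return(Inf)
      f$aic
    }, numeric(1))
    best <- which.min(crit)
    profile <- tibble::tibble(cutoff = cand, aic = crit,
                              n_high = n_high, n_low = n - n_high)
  } else {
    abort_if(is.null(t_star), "`t_star` is required for method = 'youden'")
    roc <- td_roc(s, clinical$os_time, clinical$os_status, t_star)
    j <- setNames(roc$curve$tp - roc$curve$fp, NULL)
    crit <- vapply(cand, function(c) {
      i <- which.min(abs(roc$curve$cutoff - c))
      -j[i]
    }, numeric(1))
    best <- which.min(crit)
    profile <- tibble::tibble(cutoff = cand, youden = -crit,
                              n_high = n_high, n_low = n - n_high)
  }
  structure(list(cutoff = cand[best], n_high = n_high[best],
                 n_low = n - n_high[best], method = method,
                 profile = profile),
            class = "risk_cutoff")
}

#' @export
print.risk_cutoff <- function(x, ...) {
  cat(sprintf("risk-score cut-off (%s): c* = %g (high %d / low %d)\n",
              x$method, x$cutoff, x$n_high, x$n_low))
  invisible(x)
}

#' Assign high/low risk groups at a fixed cut-off
#'
#' Label is `"high"` iff `score > cutoff` (strict). The cut-off learned on
#' the training cohort is applied unchanged to validation cohorts; a
#' one-sided result there only raises a warning.
#'
#' @param scores tibble `sample_id`, `risk_score`.
#' @param cutoff numeric cut-off (or a [risk_model()] / `risk_cutoff`
#'   carrying one).
#' @return The `scores` tibble with an added factor column `risk_group`
#'   (levels low, high).
#' @export
apply_cutoff <- function(scores, cutoff) {
  if (inherits(cutoff, "risk_model")) cutoff <- cutoff$cutoff
  if (inherits(cutoff, "risk_cutoff")) cutoff <- cutoff$cutoff
  abort_if(!is.numeric(cutoff) || is.na(cutoff), "invalid cut-off")
  out <- dplyr::mutate(
    scores,
    risk_group = factor(ifelse(.data$risk_score > cutoff, "high", "low"),
                        levels = c("low", "high")))
  if (length(unique(out$risk_group)) == 1) {
    warning("all samples fall on one side of the cut-off")
  }
  out
}

#' Convert year horizons to days
#'
#' @param years numeric horizon in years.
#' @return Days, using 365.25 days per year.
#' @export
years_to_days <- function(years) 365.25 * years
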