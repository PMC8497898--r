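#' Chi-square association between risk group and clinical categoricals
#'
#' Per clinical variable, `"Unknown"` levels are excluded, zero-margin
#' rows/columns are dropped (with a message), and a Pearson chi-square
#' test without continuity correction is run on the contingency table
#' against the risk group. Significance stars follow the `*` < 0.05,
#' `**` < 0.01, `***` < 0.001 convention.
#'
#' @param data data frame with one row per patient.
#' @param group column name (string) of the risk-group factor.
#' @param variables character vector of clinical column names to test.
#' @return Tibble `variable`, `statistic`, `df`, `p`, `stars`.
#' @export
chisq_association <- function(data, group = "risk_group",
                              variables = setdiff(names(data),
                                                  c(group, "sample_id"))) {
  abort_if(!group %in% names(data), paste0("no column `", group, "`"))
  purrr::map_dfr(variables, function(v) {
    keep <- !is.na(data[[v]]) & data[[v]] != "Unknown" & !is.na(data[[group]])
    tab <- table(data[[group]][keep], data[[v]][keep])
    zero <- c(which(rowSums(tab) == 0), which(colSums(tab) == 0))
    if (length(zero) > 0) {
      message("zero-margin level(s) dropped for ", v)
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    }
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      return(tibble::tibble(variable = v, statistic = NA_real_,
                            df = NA_real_, p = NA_real_, stars = ""))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tibble::tibble(variable = v, statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p = unname(ct$p.value),
                   stars = signif_stars(unname(ct$p.value)))
  })
}

#' Two-group rank-sum (Mann-Whitney) comparison
#'
#' Two-sided Wilcoxon rank-sum test via [stats::wilcox.test()]: exact when
#' samples are small and untied, otherwise the normal approximation with
#' tie correction. (Group comparisons between independent high/low risk
#' patients are unpaired, so the rank-sum — not signed-rank — test
#' applies.)
#'
#' @param values numeric vector.
#' @param group two-level grouping aligned with `values`.
#' @return List with `statistic` (rank-sum W), `p`.
#' @export
ranksum_by_group <- function(values, group) {
  group <- droplevels(as.factor(group))
  abort_if(nlevels(group) != 2, "need exactly 2 groups")
  abort_if(any(table(group) < 1), "both groups must be non-empty")
  abort_if(any(table(group) < 2),
           "a single-sample group cannot be compared")
  wt <- stats::wilcox.test(values ~ group)
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Spearman correlation of the risk score with immune features
#'
#' For every (cell type, method) column of a long immune-fraction table,
#' Spearman's rho on midranks with p from the t transform
#' (`cor.test(..., method = "spearman", exact = FALSE)`), computed over
#' the samples shared with the score table. Constant columns have
#' undefined rho and are reported as `NA`.
#'
#' @param scores tibble `sample_id`, `risk_score`.
#' @param fractions long tibble `sample_id`, `cell_type`, `method`,
#'   `abundance`.
#' @return Tibble `cell_type`, `method`, `n`, `rho`, `p`, `stars`,
#'   sorted by `rho` (the lollipop-plot order).
#' @export
spearman_immune <- function(scores, fractions) {
  abort_if(!all(c("sample_id", "cell_type", "method", "abundance") %in%
                  names(fractions)),
           "`fractions` needs sample_id, cell_type, method, abundance")
  joined <- dplyr::inner_join(fractions, scores, by = "sample_id")
  abort_if(length(unique(joined$sample_id)) < 3,
           "need >= 3 overlapping samples")
  one <- function(ab, sc) {
    if (sd(ab) == 0 || sd(sc) == 0) {
      return(tibble::tibble(n = length(ab), rho = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(ab, sc, method = "spearman", exact = FALSE)
    tibble::tibble(n = length(ab), rho = unname(ct$estimate), p = ct$p.value)
  }
  joined |>
    dplyr::group_by(.data$cell_type, .data$method) |>
    dplyr::reframe(one(.data$abundance, .data$risk_score)) |>
    dplyr::mutate(stars = signif_stars(.data$p)) |>
    dplyr::arrange(.data$rho)
}

#' Column-wise rank-sum comparison of a feature table between risk groups
#'
#' Applies [ranksum_by_group()] to every feature column (e.g. per-drug
#' IC50 or per-cell-type abundance), reporting the direction as the sign
#' of the median difference.
#'
#' @param groups tibble `sample_id`, `risk_group` (two levels, low/high).
#' @param features wide tibble `sample_id` plus one numeric column per
#'   feature.
#' @return Tibble `feature`, `statistic`, `p`, `direction`
#'   (`"high > low"` / `"low > high"` / `"equal"`), `stars`.
#' @export
compare_groups_table <- function(groups, features) {
  joined <- dplyr::inner_join(groups, features, by = "sample_id")
  cols <- setdiff(names(features), "sample_id")
  purrr::map_dfr(cols, function(f) {
    rs <- ranksum_by_group(joined[[f]], joined$risk_group)
    med <- tapply(joined[[f]], joined$risk_group, median)
    dir <- if (med[["high"]] > med[["low"]]) "high > low"
           else if (med[["high"]] < med[["low"]]) "low > high" else "equal"
    tibble::tibble(feature = f, statistic = rs$statistic, p = rs$p,
                   direction = dir, stars = signif_stars(rs$p))
  })
}
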