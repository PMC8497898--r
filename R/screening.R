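#' Identify immune-related lncRNAs by Pearson correlation screening
#'
#' A lncRNA is called immune-related when at least one immune gene shows
#' `|R| > r_min` with `p < p_max`, where the two-sided p-value comes from
#' the t transform `t = R * sqrt((n - 2) / (1 - R^2))` on `n - 2` degrees
#' of freedom. lncRNAs or immune genes constant across samples have
#' undefined correlation and can never match (they are skipped silently).
#'
#' @param lnc_expr,immune_expr expression tibbles sharing the same ordered
#'   sample columns (at least 3 samples).
#' @param r_min,p_max strict thresholds on `|R|` and the p-value.
#' @param log2_transform correlate `log2(x + 1)` instead of raw FPKM
#'   (default): FPKM is heavy-tailed and a handful of extreme values can
#'   dominate the raw-scale product-moment correlation.
#' @return List with
#'   * `ir_ids`: character vector of retained lncRNA IDs;
#'   * `correlations`: tibble `lnc_id`, `immune_gene_id`, `r`, `p` of every
#'     (lncRNA, immune gene) combination passing both thresholds.
#' @export
pearson_screen <- function(lnc_expr, immune_expr, r_min = 0.5, p_max = 0.001,
                           log2_transform = TRUE) {
  check_expr(lnc_expr, "lnc_expr"); check_expr(immune_expr, "immune_expr")
  s1 <- sample_ids(lnc_expr); s2 <- sample_ids(immune_expr)
  abort_if(!identical(sort(s1), sort(s2)),
           "lncRNA and immune matrices must cover the same samples")
  n <- length(s1)
  abort_if(n < 3, "correlation screening needs at least 3 samples")

  x <- t(expr_matrix(lnc_expr))                 # samples x lnc
  y <- t(expr_matrix(immune_expr))[s1, , drop = FALSE]
  if (log2_transform) { x <- log2(x + 1); y <- log2(y + 1) }
  r <- suppressWarnings(stats::cor(x, y))       # NA rows for constant genes
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tval), df = n - 2)
  hit <- which(!is.na(r) & abs(r) > r_min & p < p_max, arr.ind = TRUE)
  correlations <- tibble::tibble(
    lnc_id = rownames(r)[hit[, 1]],
    immune_gene_id = colnames(r)[hit[, 2]],
    r = r[hit], p = p[hit]
  ) |> dplyr::arrange(.data$lnc_id, .data$p)
  list(ir_ids = sort(unique(correlations$lnc_id)), correlations = correlations)
}

#' Tumor-vs-normal differential expression on log2(FPKM + 1)
#'
#' Per gene, `log2FC` is the tumor minus normal difference of mean
#' `log2(x + 1)`; the p-value is a Welch (unequal-variance) two-sample t
#' test on the same transform, and FDR is Benjamini-Hochberg. A gene is
#' flagged significant when `|log2FC| > lfc_min` and `FDR < fdr_max`
#' (both strict).
#'
#' @param expr expression tibble covering both cohorts.
#' @param groups tibble `sample_id`, `group` with levels `"tumor"` and
#'   `"normal"`; each group needs at least 2 samples.
#' @param lfc_min,fdr_max strict thresholds.
#' @return Tibble `gene_id`, `log2fc`, `p`, `fdr`, `direction`
#'   (`"up"`/`"down"`), `significant`, ordered as the input genes.
#' @export
differential_expression <- function(expr, groups, lfc_min = 2, fdr_max = 0.05) {
  check_expr(expr)
  abort_if(!all(c("sample_id", "group") %in% names(groups)),
           "`groups` needs sample_id and group columns")
  m <- log2(expr_matrix(expr) + 1)
  tum <- intersect(colnames(m), groups$sample_id[groups$group == "tumor"])
  nrm <- intersect(colnames(m), groups$sample_id[groups$group == "normal"])
  abort_if(length(tum) < 2 || length(nrm) < 2,
           "each of the tumor and normal groups needs >= 2 samples")
  xt <- m[, tum, drop = FALSE]; xn <- m[, nrm, drop = FALSE]
  n1 <- length(tum); n2 <- length(nrm)
  m1 <- rowMeans(xt); m2 <- rowMeans(xn)
  v1 <- apply(xt, 1, var); v2 <- apply(xn, 1, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  # degenerate zero-variance genes: identical means -> no evidence
  p[se2 == 0] <- ifelse(m1[se2 == 0] == m2[se2 == 0], 1, 0)
  lfc <- unname(m1 - m2)
  p <- unname(p)
  fdr <- bh_fdr(p)
  tibble::tibble(
    gene_id = rownames(m),
    log2fc = lfc, p = p, fdr = fdr,
    direction = ifelse(lfc >= 0, "up", "down"),
    significant = abs(lfc) > lfc_min & fdr < fdr_max
  )
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Thin validated front end over [stats::p.adjust()] with `method = "BH"`:
#' sorted ascending, `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1,
#' returned in input order.
#'
#' @param p p-values in `[0, 1]` (NA allowed, propagated).
#' @return Adjusted values of the same length.
#' @export
bh_fdr <- function(p) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  abort_if(!all(ok), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
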