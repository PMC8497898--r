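#' Build the 0-or-1 pair-indicator table from an expression matrix
#'
#' For every unordered pair of genes one canonical row is created, with
#' `lncA` preceding `lncB` in lexicographic gene-ID order. Per sample the
#' indicator is 1 when expression of A strictly exceeds that of B and 0
#' otherwise (ties score 0). The encoding depends only on within-sample
#' ranks, so it is invariant to any strictly monotone transform of the
#' expression values and immune to cross-sample normalization.
#'
#' @param expr expression tibble (typically restricted to the
#'   differentially expressed immune-related lncRNAs).
#' @param samples optional character vector of sample columns to encode
#'   (e.g. the tumor cohort); defaults to all samples in `expr`.
#' @return Tibble with columns `pair_id` (`"lncA|lncB"`), `lncA`, `lncB`,
#'   `prevalence` (row mean of the indicator) and one 0/1 column per
#'   sample; `k * (k - 1) / 2` rows for `k` genes.
#' @export
build_pairs <- function(expr, samples = NULL) {
  check_expr(expr)
  m <- expr_matrix(expr)
  if (!is.null(samples)) {
    abort_if(!all(samples %in% colnames(m)),
             "some requested samples are absent from `expr`")
    m <- m[, samples, drop = FALSE]
  }
  abort_if(nrow(m) < 2, "pair construction needs at least 2 genes")
  m <- m[order(rownames(m)), , drop = FALSE]
  k <- nrow(m)
  ia <- rep(seq_len(k - 1), times = (k - 1):1)
  ib <- unlist(lapply(seq_len(k - 1), function(i) (i + 1):k))
  ind <- (m[ia, , drop = FALSE] > m[ib, , drop = FALSE]) * 1L
  meta <- tibble::tibble(
    pair_id = paste(rownames(m)[ia], rownames(m)[ib], sep = "|"),
    lncA = rownames(m)[ia], lncB = rownames(m)[ib],
    prevalence = unname(rowMeans(ind))
  )
  dplyr::bind_cols(meta, tibble::as_tibble(ind, .name_repair = "minimal"))
}

#' Prevalence filter for pair indicators
#'
#' Retains a pair only when its indicator is 1 in strictly more than
#' `low` and strictly less than `high` of the encoded samples. Constant
#' pairs (prevalence 0 or 1) carry no rank information and are always
#' removed; the default 20--80% band additionally drops near-constant
#' pairs.
#'
#' @param pairs tibble from [build_pairs()].
#' @param low,high open prevalence band, `0 <= low < high <= 1`.
#' @return The filtered tibble, row order preserved.
#' @export
filter_pairs <- function(pairs, low = 0.2, high = 0.8) {
  abort_if(!(low >= 0 && low < high && high <= 1),
           "need 0 <= low < high <= 1")
  dplyr::filter(pairs, .data$prevalence > low, .data$prevalence < high)
}

# pairs-tibble -> samples x pairs numeric matrix for model fitting
pair_design <- function(pairs, samples = NULL) {
  meta <- c("pair_id", "lncA", "lncB", "prevalence")
  smp <- setdiff(names(pairs), meta)
  if (!is.null(samples)) {
    abort_if(!all(samples %in% smp),
             paste0("samples missing from pair table: ",
                    paste(setdiff(samples, smp), collapse = ", ")))
    smp <- samples
  }
  x <- t(as.matrix(pairs[smp]))
  colnames(x) <- pairs$pair_id
  x
}
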