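# shared validators and small helpers (internal)

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

# expression tables are tibbles: first column `gene_id`, remaining columns
# one numeric column per sample
check_expr <- function(expr, arg = "expr") {
  abort_if(!is.data.frame(expr), paste0("`", arg, "` must be a data frame"))
  abort_if(!"gene_id" %in% names(expr),
           paste0("`", arg, "` must have a `gene_id` column"))
  abort_if(anyDuplicated(expr$gene_id) > 0,
           paste0("duplicate gene IDs in `", arg, "`"))
  smp <- setdiff(names(expr), "gene_id")
  abort_if(length(smp) == 0, paste0("`", arg, "` has no sample columns"))
  abort_if(anyDuplicated(smp) > 0, paste0("duplicate sample IDs in `", arg, "`"))
  invisible(expr)
}

expr_matrix <- function(expr) {
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  rownames(m) <- expr$gene_id
  storage.mode(m) <- "double"
  m
}

sample_ids <- function(expr) setdiff(names(expr), "gene_id")

check_surv <- function(time, status) {
  abort_if(length(time) != length(status),
           "`time` and `status` must have equal length")
  abort_if(any(!is.finite(time)) || any(time <= 0),
           "survival times must be finite and > 0")
  abort_if(!all(status %in% c(0, 1)), "`status` must be 0 (censored) or 1 (event)")
  abort_if(sum(status) < 1, "no events in the survival data")
  invisible(NULL)
}

# significance stars at the conventional thresholds
signif_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}
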