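#' Read a genes-by-samples expression table
#'
#' Expects tab-separated text with gene identifiers in the first column and
#' sample identifiers in the header row (the Xena FPKM layout). Duplicate
#' gene rows are collapsed by their mean; all-zero rows are retained (they
#' are removed by later screening, not at load).
#'
#' @param path file path.
#' @return Tibble with a `gene_id` column followed by one numeric column
#'   per sample.
#' @export
read_expression <- function(path) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  abort_if(ncol(raw) < 2, "expression file needs a gene column and >= 1 sample")
  smp <- names(raw)[-1]
  abort_if(anyDuplicated(smp) > 0,
           paste0("duplicate sample ID in header: ",
                  paste(unique(smp[duplicated(smp)]), collapse = ", ")))
  vals <- matrix(NA_real_, nrow(raw), length(smp),
                 dimnames = list(NULL, smp))
  for (j in seq_along(smp)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad <- which(is.na(v) & !is.na(raw[[j + 1]]) & raw[[j + 1]] != "NA")
    abort_if(length(bad) > 0,
             sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                     raw[[j + 1]][bad[1]], raw[[1]][bad[1]], smp[j]))
    vals[, j] <- v
  }
  gene <- raw[[1]]
  if (anyDuplicated(gene) > 0) {
    n_dup <- sum(duplicated(gene))
    vals <- rowsum(vals, gene, reorder = FALSE) /
      as.vector(table(factor(gene, levels = unique(gene))))
    gene <- unique(raw[[1]])
    message(n_dup, " duplicate gene row(s) collapsed by mean")
  }
  out <- tibble::as_tibble(as.data.frame(vals))
  out <- dplyr::bind_cols(tibble::tibble(gene_id = gene), out)
  check_expr(out, "expression file")
}

#' Write an expression table as tab-separated text
#'
#' @param expr expression tibble (`gene_id` + sample columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  check_expr(expr)
  write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Tab-separated text with at least `sample_id`, `os_time` (days) and
#' `os_status` (0 censored / 1 event). Records with missing or
#' non-positive follow-up, or a status outside \{0, 1\}, are excluded with
#' a message stating the count; categorical covariates may carry an
#' `"Unknown"` level.
#'
#' @param path file path.
#' @return Tibble of retained records.
#' @export
read_clinical <- function(path) {
  cl <- tibble::as_tibble(read.delim(path, check.names = FALSE))
  abort_if(!all(c("sample_id", "os_time", "os_status") %in% names(cl)),
           "clinical file needs sample_id, os_time, os_status columns")
  abort_if(anyDuplicated(cl$sample_id) > 0, "duplicate sample IDs in clinical file")
  keep <- !is.na(cl$os_time) & cl$os_time > 0 &
    !is.na(cl$os_status) & cl$os_status %in% c(0, 1)
  if (any(!keep)) {
    message(sum(!keep), " clinical record(s) excluded ",
            "(missing/non-positive follow-up or invalid status)")
  }
  cl[keep, ]
}

#' @rdname read_clinical
#' @param clinical clinical tibble.
#' @export
write_clinical <- function(clinical, path) {
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text gene list (one symbol or ID per line)
#'
#' @param path file path.
#' @return Character vector of unique, non-empty entries.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Read gene annotation (biotype, name) from a GENCODE-style GTF
#'
#' Only `gene` feature lines are consulted. Both `gene_type` (GENCODE) and
#' `gene_biotype` (Ensembl) attribute spellings are recognized, and version
#' suffixes (".N") are stripped from `gene_id` so that GENCODE and Xena ID
#' dialects match.
#'
#' @param path GTF file path.
#' @return Tibble `gene_id`, `biotype`, `gene_name` (one row per gene; the
#'   first record wins on duplicates).
#' @export
read_gene_annotation <- function(path) {
  abort_if(!requireNamespace("rtracklayer", quietly = TRUE),
           "reading GTF requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gtf", feature.type = "gene")
  mc <- as.data.frame(gr)
  bio <- mc$gene_type %||% mc$gene_biotype
  abort_if(is.null(bio), "GTF has neither gene_type nor gene_biotype attribute")
  ann <- tibble::tibble(
    gene_id = sub("\\.\\d+$", "", mc$gene_id),
    biotype = as.character(bio),
    gene_name = as.character(mc$gene_name %||% mc$gene_id)
  )
  dplyr::distinct(ann, .data$gene_id, .keep_all = TRUE)
}

#' Restrict an expression matrix to lncRNA biotypes
#'
#' Genes absent from the annotation are dropped (their count is reported);
#' version suffixes on expression gene IDs are stripped before matching.
#'
#' @param expr expression tibble.
#' @param annotation tibble from [read_gene_annotation()] (or with the same
#'   columns).
#' @param biotypes biotype labels to keep. GENCODE collapsed `antisense`
#'   and `lincRNA` into `lncRNA` in later releases, so all three are kept
#'   by default.
#' @return Filtered expression tibble.
#' @export
filter_lncrnas <- function(expr, annotation,
                           biotypes = c("lncRNA", "antisense", "lincRNA")) {
  check_expr(expr)
  ids <- sub("\\.\\d+$", "", expr$gene_id)
  hit <- match(ids, annotation$gene_id)
  n_missing <- sum(is.na(hit))
  if (n_missing > 0) message(n_missing, " gene(s) absent from annotation dropped")
  keep <- !is.na(hit) & annotation$biotype[hit] %in% biotypes
  abort_if(sum(keep) == 0,
           "no genes left after lncRNA filtering; check the `biotypes` set")
  expr[keep, ]
}

#' Randomly split samples into training and validation cohorts
#'
#' For a 1:1 split of an odd number of samples the training cohort receives
#' the extra sample (`ceiling(n * ratio)`), e.g. 259 samples split 130/129.
#'
#' @param ids sample identifiers.
#' @param ratio training fraction, in (0, 1).
#' @param seed integer seed making the partition reproducible.
#' @return List with `training` and `validation` character vectors forming
#'   a disjoint, exhaustive partition of `ids`.
#' @export
split_cohort <- function(ids, ratio = 0.5, seed = 1L) {
  abort_if(ratio <= 0 || ratio >= 1, "`ratio` must lie strictly in (0, 1)")
  abort_if(length(ids) < 2, "need at least 2 samples to split")
  n_train <- ceiling(length(ids) * ratio)
  tr <- withr::with_seed(as.integer(seed), sample(ids, n_train))
  list(training = tr, validation = setdiff(ids, tr))
}

#' Construct a risk model
#'
#' A fitted pair signature: the selected pairs with their Cox
#' coefficients, the risk-score cut-off learned on the training cohort and
#' the ROC horizon (days) the model was tuned at.
#'
#' @param pairs tibble with columns `lncA`, `lncB`, `beta` (>= 1 row).
#' @param cutoff risk-score cut-off `c*` (`NA` until learned).
#' @param horizon ROC horizon in days.
#' @return Object of class `risk_model`.
#' @export
risk_model <- function(pairs, cutoff = NA_real_, horizon = NA_real_) {
  pairs <- tibble::as_tibble(pairs)
  abort_if(!all(c("lncA", "lncB", "beta") %in% names(pairs)),
           "`pairs` needs columns lncA, lncB, beta")
  abort_if(nrow(pairs) < 1, "a risk model must contain at least one pair")
  abort_if(any(!is.finite(pairs$beta)), "pair coefficients must be finite")
  structure(list(pairs = pairs[c("lncA", "lncB", "beta")],
                 cutoff = as.numeric(cutoff),
                 horizon = as.numeric(horizon)),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Rank-pair risk model:", nrow(x$pairs), "pair(s)\n")
  cat("  cutoff c* =", format(x$cutoff), " horizon =", format(x$horizon), "days\n")
  print(x$pairs, ...)
  invisible(x)
}

pairsig_model_format <- 1L

#' Save / load a risk model (exact round trip)
#'
#' Models are stored as JSON with coefficients at full double precision,
#' so `load_risk_model(save_risk_model(m, f))` reproduces `m` bit-exactly.
#'
#' @param model a [risk_model()].
#' @param path file path.
#' @return `save_risk_model()` returns `path` invisibly; `load_risk_model()`
#'   returns the model. A file written by an unknown format version is
#'   rejected.
#' @export
save_risk_model <- function(model, path) {
  abort_if(!inherits(model, "risk_model"), "`model` must be a risk_model")
  payload <- list(format = pairsig_model_format,
                  pairs = as.data.frame(model$pairs),
                  cutoff = model$cutoff, horizon = model$horizon)
  # I(17) = 17 *significant* digits, enough for exact double round trips
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_risk_model
#' @export
load_risk_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  abort_if(is.null(payload$format) || payload$format != pairsig_model_format,
           sprintf("unsupported model file format '%s' (expected %d)",
                   payload$format %||% "missing", pairsig_model_format))
  risk_model(tibble::as_tibble(payload$pairs),
             cutoff = payload$cutoff %||% NA_real_,
             horizon = payload$horizon %||% NA_real_)
}
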