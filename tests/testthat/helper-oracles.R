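# Independent brute-force oracles used across the suite. These never call
# into the package code paths they check.

# explicit Breslow-tie Cox log partial likelihood for a single covariate
breslow_loglik <- function(beta, x, time, status) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

# Mann-Whitney AUC of a marker against a binary outcome (ties count 1/2)
mw_auc <- function(marker, y) {
  pos <- marker[y == 1]; neg <- marker[y == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# hand product-limit estimator: survival after each distinct event time
manual_km <- function(time, status) {
  ut <- sort(unique(time[status == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    d <- sum(time == ut[i] & status == 1)
    r <- sum(time >= ut[i])
    s <- s * (1 - d / r)
    out[i] <- s
  }
  tibble::tibble(time = ut, surv = out)
}

# hand two-group log-rank chi-square (observed - expected, hypergeometric
# variance), groups coded 0/1
manual_logrank <- function(time, status, group) {
  ut <- sort(unique(time[status == 1]))
  o_minus_e <- 0; v <- 0
  for (u in ut) {
    at <- time >= u
    n <- sum(at); n1 <- sum(at & group == 1)
    d <- sum(time == u & status == 1)
    d1 <- sum(time == u & status == 1 & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Kolmogorov-Smirnov distance of a sample to Uniform(0, 1)
ks_distance_uniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(abs(c(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)))
}

# small random survival data set
rand_surv <- function(n, seed, event_rate = 0.7) {
  withr::with_seed(seed, tibble::tibble(
    sample_id = sprintf("P%03d", seq_len(n)),
    os_time = rexp(n, 1 / 500),
    os_status = rbinom(n, 1, event_rate)
  ))
}

# expression tibble -> plain matrix (test-side, independent of package
# internals)
expr_matrix_for_test <- function(expr) {
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  rownames(m) <- expr$gene_id
  m
}

# expression tibble from a bare matrix
expr_tbl <- function(m, gene_ids = sprintf("g%03d", seq_len(nrow(m))),
                     samples = sprintf("s%03d", seq_len(ncol(m)))) {
  dimnames(m) <- list(gene_ids, samples)
  tibble::as_tibble(m, rownames = "gene_id")
}

# the study conditions for the planted-pair recovery experiment: a cohort
# whose tumor arm is split 300 training / 150 validation, two planted
# pairs with log-hazards +1 / -1 among 50 noise lncRNAs, 30% censoring
recovery_config <- function(seed) {
  sim_config(n_tumor = 450, n_normal = 78, n_lnc = 54, n_immune = 20,
             n_de = 12,
             planted_pairs = data.frame(lncA = c(1, 3), lncB = c(2, 4),
                                        beta = c(1, -1)),
             censor_rate = 0.3, seed = seed)
}

# one full train/validate replicate under the recovery conditions;
# returns whether both planted pairs were recovered (sign-correct, within
# +/- tol) and the validation-cohort high/low log-rank p-value
recovery_replicate <- function(seed, n_iter = 100, tol = 0.35) {
  sim <- simulate_dataset(recovery_config(seed))
  ids <- sim$clinical$sample_id
  sp <- split_cohort(ids, ratio = 2 / 3, seed = seed)
  lnc <- sim$expression[grepl("^lnc", sim$expression$gene_id), ]
  pr <- filter_pairs(build_pairs(lnc, sp$training))
  clin_tr <- sim$clinical[sim$clinical$sample_id %in% sp$training, ]
  clin_va <- sim$clinical[sim$clinical$sample_id %in% sp$validation, ]
  fit <- suppressWarnings(suppressMessages(
    train_risk_signature(pr, clin_tr, n_iter = n_iter,
                         freq_min = n_iter / 10, seed = seed + 1000)))
  truth <- sim$truth$planted_pairs
  got <- dplyr::inner_join(truth, fit$model$pairs, by = c("lncA", "lncB"),
                           suffix = c(".true", ".est"))
  recovered <- nrow(got) == nrow(truth) &&
    all(sign(got$beta.est) == sign(got$beta.true)) &&
    all(abs(got$beta.est - got$beta.true) <= tol)
  ev <- suppressWarnings(
    evaluate_risk_signature(fit, build_pairs(lnc, ids), clin_va))
  list(recovered = recovered, val_logrank_p = ev$logrank$p, fit = fit)
}
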