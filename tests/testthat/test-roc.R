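test_that("perfect separation gives AUC 1 and anchored endpoints", {
  time <- c(1, 2, 3, 10, 11, 12)
  status <- rep(1, 6)
  marker <- c(9, 8, 7, 1, 2, 3)   # events by t* = 5 all score higher
  roc <- td_roc(marker, time, status, 5)
  expect_equal(roc$auc, 1)
  expect_equal(roc$curve$fp[1], 0)
  expect_equal(roc$curve$tp[1], 0)
  expect_equal(tail(roc$curve$fp, 1), 1)
  expect_equal(tail(roc$curve$tp, 1), 1)
})

test_that("without censoring td_roc reduces to the Mann-Whitney AUC", {
  for (s in 1:20) {
    withr::with_seed(100 + s, {
      n <- 50
      time <- rexp(n, 1 / 400)
      marker <- rnorm(n) + 0.8 * (time < 300)
      if (s %% 4 == 0) marker <- round(marker)  # tied markers too
    })
    roc <- td_roc(marker, time, rep(1, n), 300)
    expect_equal(roc$auc, mw_auc(marker, as.numeric(time <= 300)),
                 tolerance = 1e-10)
  }
})

test_that("td_roc AUC is invariant under strictly increasing marker transforms", {
  surv <- rand_surv(80, seed = 31)
  marker <- withr::with_seed(32, rnorm(80))
  a <- td_roc(marker, surv$os_time, surv$os_status, 400)
  b <- td_roc(exp(2 * marker) + 5, surv$os_time, surv$os_status, 400)
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
})

test_that("td_roc enforces its horizon contract", {
  surv <- rand_surv(30, seed = 33)
  marker <- withr::with_seed(34, rnorm(30))
  expect_error(td_roc(marker, surv$os_time, surv$os_status,
                      max(surv$os_time) + 1), "beyond")
  expect_error(td_roc(marker, surv$os_time, surv$os_status,
                      min(surv$os_time) / 2), "no events")
})

test_that("AUC-max model selection prefers the true-signal model", {
  wins <- vapply(1:10, function(s) {
    sim <- simulate_dataset(sim_config(
      n_tumor = 200, n_normal = 2, n_lnc = 8, n_immune = 2, n_de = 4,
      planted_pairs = data.frame(lncA = 1, lncB = 2, beta = 1.5),
      censor_rate = 0.2, seed = 600 + s))
    lnc <- sim$expression[grepl("^lnc", sim$expression$gene_id), ]
    pr <- build_pairs(lnc, sim$clinical$sample_id)
    truth <- sim$truth$planted_pairs
    true_model <- risk_model(truth)
    noise <- pr[!pr$pair_id %in% paste(truth$lncA, truth$lncB, sep = "|") &
                  pr$prevalence > 0.2 & pr$prevalence < 0.8, ][1, ]
    noise_model <- risk_model(tibble::tibble(lncA = noise$lncA,
                                             lncB = noise$lncB, beta = 1.5))
    sel <- select_model_by_auc(list(noise_model, true_model), pr,
                               sim$clinical, t_star = 1000)
    identical(sel$model$pairs, true_model$pairs)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("AUC ties break toward the model with fewer pairs", {
  withr::with_seed(41, m <- matrix(runif(3 * 40), 3, 40))
  expr <- expr_tbl(m, gene_ids = c("a", "b", "c"))
  pr <- build_pairs(expr)
  surv <- rand_surv(40, seed = 42)
  one <- risk_model(tibble::tibble(lncA = "a", lncB = "b", beta = 1))
  # duplicating the pair halves the weights: identical scores per patient
  two <- risk_model(tibble::tibble(lncA = c("a", "a"), lncB = c("b", "b"),
                                   beta = c(0.5, 0.5)))
  clin <- tibble::tibble(sample_id = sprintf("s%03d", 1:40),
                         os_time = surv$os_time, os_status = surv$os_status)
  sel <- select_model_by_auc(list(two, one), pr, clin, t_star = 500)
  expect_equal(nrow(sel$model$pairs), 1)
})

test_that("the AIC cut-off splits well-separated risk clusters", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(700 + s, {
      n <- 300
      grp <- rbinom(n, 1, 0.4)
      scores <- rnorm(n, mean = ifelse(grp == 1, 3, 0), sd = 0.5)
      t_ev <- rexp(n, rate = 3^grp / 1000)
      cens <- runif(n, 0, 3000)
    })
    clin <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                           os_time = pmin(t_ev, cens),
                           os_status = as.integer(t_ev <= cens))
    cut <- aic_cutoff(tibble::tibble(sample_id = clin$sample_id,
                                     risk_score = scores), clin)
    # the chosen split should recover the hazard-carrying cluster labels
    mean((scores > cut$cutoff) == (grp == 1)) >= 0.95
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the cut-off depends only on score ranks", {
  surv <- rand_surv(60, seed = 51)
  scores <- withr::with_seed(52, rnorm(60))
  clin <- tibble::tibble(sample_id = surv$sample_id,
                         os_time = surv$os_time, os_status = surv$os_status)
  sc <- tibble::tibble(sample_id = surv$sample_id, risk_score = scores)
  sc_tr <- tibble::tibble(sample_id = surv$sample_id,
                          risk_score = exp(scores) + 3)
  g1 <- apply_cutoff(sc, aic_cutoff(sc, clin))$risk_group
  g2 <- apply_cutoff(sc_tr, aic_cutoff(sc_tr, clin))$risk_group
  expect_identical(g1, g2)
})

test_that("a binary score admits only its unique split", {
  surv <- rand_surv(50, seed = 61)
  s <- withr::with_seed(62, rbinom(50, 1, 0.5))
  sc <- tibble::tibble(sample_id = surv$sample_id, risk_score = s)
  clin <- tibble::tibble(sample_id = surv$sample_id,
                         os_time = surv$os_time, os_status = surv$os_status)
  cut <- aic_cutoff(sc, clin)
  expect_equal(cut$cutoff, 0.5)
  expect_equal(nrow(cut$profile), 1)
  expect_error(aic_cutoff(tibble::tibble(sample_id = surv$sample_id,
                                         risk_score = rep(1, 50)), clin),
               "identical")
})

test_that("apply_cutoff labels strictly above the cut-off as high", {
  sc <- tibble::tibble(sample_id = c("a", "b", "c"), risk_score = c(1, 2, 3))
  out <- apply_cutoff(sc, 2)
  expect_equal(as.character(out$risk_group), c("low", "low", "high"))
  expect_warning(apply_cutoff(sc, 10), "one side")
  # validation protocol: labels depend only on (scores, cutoff)
  again <- suppressWarnings(apply_cutoff(sc, 10))
  expect_true(all(again$risk_group == "low"))
})

test_that("year horizons convert at 365.25 days", {
  expect_equal(years_to_days(c(1, 3, 5)), c(365.25, 1095.75, 1826.25))
})
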