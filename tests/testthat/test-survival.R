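test_that("cox_fit matches brute-force maximization of the partial likelihood", {
  # 6 observations, binary covariate, tie-free: Breslow = exact
  time <- c(3, 5, 7, 11, 13, 17)
  status <- c(1, 1, 0, 1, 1, 1)
  x <- c(1, 0, 1, 1, 0, 0)
  fit <- cox_fit(data.frame(g = x), time, status)
  brute <- optimize(function(b) -breslow_loglik(b, x, time, status),
                    c(-10, 10), tol = 1e-10)
  expect_equal(fit$coefficients$estimate, brute$minimum, tolerance = 1e-6)
  expect_equal(fit$loglik, -brute$objective, tolerance = 1e-9)
  expect_equal(fit$aic, -2 * fit$loglik + 2)
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$estimate))
})

test_that("cox_fit is invariant to time shifts and errors without events", {
  surv <- rand_surv(40, seed = 12)
  x <- data.frame(z = withr::with_seed(13, rnorm(40)))
  a <- cox_fit(x, surv$os_time, surv$os_status)
  b <- cox_fit(x, surv$os_time + 1000, surv$os_status)
  expect_equal(a$loglik, b$loglik, tolerance = 1e-9)
  expect_equal(a$coefficients$estimate, b$coefficients$estimate,
               tolerance = 1e-8)
  expect_error(cox_fit(x, surv$os_time, rep(0, 40)), "no events")
})

test_that("cox_fit is consistent for a true hazard ratio of 2", {
  withr::with_seed(77, {
    g <- rep(0:1, each = 1000)
    t_ev <- rexp(2000, rate = 0.002 * 2^g)
    cens <- runif(2000, 0, 1500)
  })
  time <- pmin(t_ev, cens); status <- as.integer(t_ev <= cens)
  fit <- cox_fit(data.frame(g = g), time, status)
  expect_gt(fit$coefficients$hr, 1.8)
  expect_lt(fit$coefficients$hr, 2.2)
})

test_that("univariate screen keeps strong pairs, respects alpha", {
  sim <- simulate_dataset(sim_config(
    n_tumor = 300, n_normal = 2, n_lnc = 12, n_immune = 2, n_de = 4,
    planted_pairs = data.frame(lncA = 1, lncB = 2, beta = 1),
    censor_rate = 0.3, seed = 8))
  lnc <- sim$expression[grepl("^lnc", sim$expression$gene_id), ]
  pr <- filter_pairs(build_pairs(lnc, sim$clinical$sample_id))
  sc <- univariate_screen(pr, sim$clinical)
  truth_id <- paste(sim$truth$planted_pairs$lncA,
                    sim$truth$planted_pairs$lncB, sep = "|")
  expect_true(truth_id %in% sc$pair_id)
  expect_true(all(sc$p < 0.05))
  expect_equal(sc$p, sort(sc$p))
  expect_equal(nrow(univariate_screen(pr, sim$clinical, alpha = 0)), 0)
})

test_that("lasso_cox shrinks fully at lambda_max and matches coxph at 0", {
  withr::with_seed(5, {
    x <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
    t_ev <- rexp(200, rate = exp(0.7 * x[, 1]) / 500)
    cens <- runif(200, 0, 1800)
  })
  time <- pmin(t_ev, cens); status <- as.integer(t_ev <= cens)

  big <- suppressWarnings(
    lasso_cox(x, time, status, lambda = c(50, 10), fold_seed = 1))
  expect_true(all(big$beta == 0))

  lam <- c(exp(seq(log(1), log(1e-4), length.out = 40)), 0)
  lc <- lasso_cox(x, time, status, lambda = lam, fold_seed = 1)
  b0 <- as.numeric(glmnet::coef.glmnet(lc$cv$glmnet.fit, s = 0))
  ref <- cox_fit(x, time, status)$coefficients$estimate
  expect_equal(b0, ref, tolerance = 1e-4)
})

test_that("iterated selection is reproducible and finds a dominant predictor", {
  withr::with_seed(9, {
    x <- matrix(rbinom(150 * 10, 1, 0.5), 150, 10,
                dimnames = list(NULL, sprintf("p%02d", 1:10)))
    t_ev <- rexp(150, rate = exp(2 * x[, 1]) / 800)
  })
  status <- rep(1L, 150)
  a <- iterated_lasso_selection(x, t_ev, status, n_iter = 20, freq_min = 2,
                                base_seed = 4)
  b <- iterated_lasso_selection(x, t_ev, status, n_iter = 20, freq_min = 2,
                                base_seed = 4)
  expect_identical(a$frequency, b$frequency)
  expect_true("p01" %in% a$selected)
  expect_equal(a$frequency$freq[a$frequency$term == "p01"], 20)
  expect_error(iterated_lasso_selection(x, t_ev, status, n_iter = 0), "n_iter")
})

test_that("stepwise AIC drops an exact duplicate and keeps a strong single", {
  withr::with_seed(14, {
    z <- rnorm(120)
    t_ev <- rexp(120, rate = exp(z) / 400)
  })
  status <- rep(1L, 120)
  sw <- stepwise_cox(data.frame(s = z, dup = z), t_ev, status)
  expect_length(sw$terms, 1)

  single <- stepwise_cox(data.frame(s = z), t_ev, status)
  expect_identical(single$terms, "s")
})

test_that("stepwise agrees with exhaustive subset search on small problems", {
  withr::with_seed(15, {
    x <- as.data.frame(matrix(rnorm(200 * 4), 200, 4))
    names(x) <- c("n1", "n2", "n3", "n4")
    t_ev <- rexp(200, 1 / 300)   # pure noise candidates
  })
  status <- rep(1L, 200)
  sw <- stepwise_cox(x, t_ev, status)

  # oracle: AIC of every subset (k counted as number of covariates)
  subsets <- unlist(lapply(0:4, function(k) combn(names(x), k, simplify = FALSE)),
                    recursive = FALSE)
  aics <- vapply(subsets, function(s) {
    if (length(s) == 0) {
      -2 * survival::coxph(survival::Surv(t_ev, status) ~ 1)$loglik[1]
    } else {
      f <- survival::coxph(survival::Surv(t_ev, status) ~ .,
                           data = x[s], ties = "breslow")
      -2 * f$loglik[2] + 2 * length(s)
    }
  }, numeric(1))
  best <- subsets[[which.min(aics)]]
  sw_aic <- sw$path[[length(sw$path)]]$aic
  # greedy stepwise must land on a model no worse than any single move
  # from it; on null data it should match the exhaustive optimum
  expect_setequal(sw$terms, best)
  expect_equal(sw_aic, min(aics), tolerance = 1e-8)
})

test_that("risk scores are the exact linear combination of indicators", {
  withr::with_seed(20, m <- matrix(runif(4 * 6), 4, 6))
  expr <- expr_tbl(m, gene_ids = c("a", "b", "c", "d"))
  pr <- build_pairs(expr)
  model <- risk_model(tibble::tibble(lncA = c("a", "b"), lncB = c("b", "c"),
                                     beta = c(0.5, -1.0)))
  sc <- risk_score(model, pr)
  g1 <- as.numeric(m[1, ] > m[2, ]); g2 <- as.numeric(m[2, ] > m[3, ])
  expect_equal(sc$risk_score, 0.5 * g1 - 1.0 * g2)

  # all-zero indicators score 0; beta = (0.5, -1), G = (1, 1) scores -0.5
  expect_equal(0.5 * 1 - 1.0 * 1, -0.5)

  # linearity in the coefficients over shared pairs
  m1 <- risk_model(dplyr::mutate(model$pairs, beta = c(0.2, 0.3)))
  m2 <- risk_model(dplyr::mutate(model$pairs, beta = c(1.1, -0.4)))
  msum <- risk_model(dplyr::mutate(model$pairs, beta = c(1.3, -0.1)))
  expect_equal(risk_score(msum, pr)$risk_score,
               risk_score(m1, pr)$risk_score + risk_score(m2, pr)$risk_score,
               tolerance = 1e-12)

  bad <- risk_model(tibble::tibble(lncA = "a", lncB = "z", beta = 1))
  expect_error(risk_score(bad, pr), "a\\|z")
})

test_that("Kaplan-Meier matches closed forms and a hand computation", {
  all_cens <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(all_cens$surv == 1))

  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(1, 2 / 3, 1 / 3, 0))

  time <- c(1, 2, 2, 3, 5, 8, 9, 12)
  status <- c(1, 1, 0, 1, 0, 1, 1, 0)
  km8 <- km_estimate(time, status)
  oracle <- manual_km(time, status)
  got <- km8[km8$n_event > 0, c("time", "surv")]
  expect_equal(got$time, oracle$time)
  expect_equal(got$surv, oracle$surv, tolerance = 1e-12)
  expect_true(all(diff(km8$surv) <= 0))
  expect_error(km_estimate(numeric(), integer()), "empty")
})

test_that("log-rank matches the hand statistic and is 0 for identical groups", {
  time <- c(1, 3, 4, 6, 8, 9, 11, 13, 15, 16)
  status <- c(1, 1, 0, 1, 1, 0, 1, 1, 1, 0)
  group <- c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0)
  lr <- logrank_test(time, status, group)
  expect_equal(lr$chisq, manual_logrank(time, status, group), tolerance = 1e-9)
  expect_equal(lr$df, 1)

  dup <- logrank_test(rep(time, 2), rep(status, 2),
                      rep(c("A", "B"), each = 10))
  expect_equal(dup$chisq, 0, tolerance = 1e-12)
  expect_equal(dup$p, 1, tolerance = 1e-9)
  expect_error(logrank_test(time, status, rep("A", 10)), "2 non-empty")
})
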