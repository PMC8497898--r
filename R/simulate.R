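#' Simulation settings for a synthetic tumor/normal expression cohort
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate a TCGA-style sarcoma cohort paired with normal soft
#' tissue: 259 tumor and 78 normal samples, log-normal FPKM-like expression
#' built over latent immune factors, a subset of lncRNAs co-expressed with
#' immune genes, tumor-restricted differential-expression shifts, and
#' exponential survival driven by planted within-sample rank pairs.
#'
#' @param n_tumor,n_normal number of tumor / normal samples.
#' @param n_lnc,n_immune number of lncRNAs and immune genes.
#' @param n_latent number of latent immune factors shared between immune
#'   genes and the immune-linked lncRNAs.
#' @param frac_immune_linked_lnc proportion of lncRNAs (the first ones in
#'   index order) loaded on a latent immune factor.
#' @param target_r population Pearson correlation between an immune-linked
#'   lncRNA and an immune gene sharing its factor (both carry equal
#'   loadings, so r = a^2 / (a^2 + noise_sd^2) and the loading is solved
#'   from `target_r`).
#' @param n_de number of lncRNAs given a tumor-only log2 expression shift
#'   (planted-pair genes are always among them, both genes of a pair
#'   shifted in the same direction so the pair indicator is unaffected).
#' @param de_log2_shift magnitude of the tumor/normal shift, in log2 units.
#' @param planted_pairs data frame with columns `lncA`, `lncB` (1-based
#'   lncRNA indices) and `beta` (true log-hazard coefficient of the pair
#'   indicator G = 1 when expression of A exceeds B within a sample).
#' @param baseline_hazard baseline hazard, events per day.
#' @param censor_rate target proportion of censored tumor samples, in
#'   `[0, 1)`; censoring times are uniform on `[0, T_max]` with `T_max`
#'   solved by bisection.
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param seed integer seed; the whole dataset is reproducible from it.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_dataset()]
#' @export
sim_config <- function(n_tumor = 259, n_normal = 78,
                       n_lnc = 300, n_immune = 100, n_latent = 5,
                       frac_immune_linked_lnc = 0.3, target_r = 0.8,
                       n_de = 40, de_log2_shift = 4,
                       planted_pairs = NULL,
                       baseline_hazard = 1 / 1500, censor_rate = 0.3,
                       noise_sd = 1, seed = 1L) {
  counts <- c(n_tumor = n_tumor, n_normal = n_normal, n_lnc = n_lnc,
              n_immune = n_immune, n_latent = n_latent)
  abort_if(any(counts < 1), "all counts must be >= 1")
  abort_if(frac_immune_linked_lnc < 0 || frac_immune_linked_lnc > 1,
           "`frac_immune_linked_lnc` must lie in [0, 1]")
  abort_if(target_r <= 0 || target_r >= 1, "`target_r` must lie in (0, 1)")
  abort_if(censor_rate < 0 || censor_rate > 1, "`censor_rate` must lie in [0, 1]")
  abort_if(censor_rate >= 1, "`censor_rate` = 1 leaves no events")
  abort_if(baseline_hazard <= 0, "`baseline_hazard` must be > 0")
  abort_if(n_de < 0 || n_de > n_lnc, "`n_de` must lie in [0, n_lnc]")
  abort_if(noise_sd <= 0, "`noise_sd` must be > 0")

  if (is.null(planted_pairs)) {
    planted_pairs <- tibble::tibble(lncA = integer(), lncB = integer(),
                                    beta = double())
  }
  planted_pairs <- tibble::as_tibble(planted_pairs)
  abort_if(!all(c("lncA", "lncB", "beta") %in% names(planted_pairs)),
           "`planted_pairs` needs columns lncA, lncB, beta")
  idx <- c(planted_pairs$lncA, planted_pairs$lncB)
  abort_if(length(idx) > 0 && (any(idx < 1) || any(idx > n_lnc)),
           "planted pair references a lncRNA index outside 1..n_lnc")
  abort_if(any(planted_pairs$lncA == planted_pairs$lncB),
           "planted pair lncRNA indices must be distinct")
  abort_if(anyDuplicated(idx) > 0,
           "planted pairs must reference distinct lncRNAs")
  abort_if(2 * nrow(planted_pairs) > n_de && nrow(planted_pairs) > 0,
           "`n_de` must cover both genes of every planted pair")

  structure(list(
    n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
    n_lnc = as.integer(n_lnc), n_immune = as.integer(n_immune),
    n_latent = as.integer(n_latent),
    frac_immune_linked_lnc = frac_immune_linked_lnc, target_r = target_r,
    n_de = as.integer(n_de), de_log2_shift = de_log2_shift,
    planted_pairs = planted_pairs,
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic expression + survival cohort with known ground truth
#'
#' Log2 expression is `baseline + loading * latent_factor + DE shift
#' (tumor only) + N(0, noise_sd)` and FPKM-like values are `2^log2expr`,
#' so values are strictly positive and heavy-tailed. Immune genes and the
#' designated fraction of lncRNAs share latent-factor loadings sized for
#' `target_r`. The two genes of a planted pair share one baseline, one
#' factor loading and one DE shift, so their within-sample order is a fair
#' coin per sample and their pair indicator carries only the planted
#' hazard signal. Tumor survival times are exponential with hazard
#' `baseline_hazard * exp(sum(beta_k * G_k))`; independent uniform
#' censoring on `[0, T_max]` is calibrated by bisection to the target
#' censoring proportion.
#'
#' @param config a [sim_config()].
#' @return A list with elements
#'   * `expression`: tibble, `gene_id` plus one numeric column per sample
#'     (lncRNAs prefixed `lnc`, immune genes `imm`);
#'   * `samples`: tibble `sample_id`, `group` (`"tumor"`/`"normal"`);
#'   * `clinical`: tibble of tumor samples with `os_time` (days),
#'     `os_status` (1 event / 0 censored) and categorical covariates;
#'   * `truth`: list with `immune_linked_lnc_ids`, `de_lnc` (tibble
#'     `gene_id`, `direction`), `planted_pairs` (tibble `lncA`, `lncB`,
#'     `beta` as gene IDs in canonical lexicographic orientation) and
#'     `linear_predictor` (named per-tumor-sample true log-hazard).
#' @examples
#' sim <- simulate_dataset(sim_config(n_tumor = 40, n_normal = 10,
#'                                    n_lnc = 20, n_immune = 10, seed = 7))
#' dim(sim$expression)
#' @export
simulate_dataset <- function(config) {
  abort_if(!inherits(config, "sim_config"), "`config` must be a sim_config")
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  n_s <- cfg$n_tumor + cfg$n_normal
  smp <- sprintf("S%04d", seq_len(n_s))
  grp <- rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal))
  lnc_ids <- sprintf("lnc%04d", seq_len(cfg$n_lnc))
  imm_ids <- sprintf("imm%04d", seq_len(cfg$n_immune))

  # loading giving population r = a^2/(a^2 + sd^2) between two genes that
  # both carry loading a on the same factor
  a <- cfg$noise_sd * sqrt(cfg$target_r / (1 - cfg$target_r))
  fac <- matrix(rnorm(cfg$n_latent * n_s), cfg$n_latent, n_s)

  n_linked <- floor(cfg$frac_immune_linked_lnc * cfg$n_lnc)
  lnc_factor <- rep(NA_integer_, cfg$n_lnc)
  if (n_linked > 0) {
    lnc_factor[seq_len(n_linked)] <- rep_len(seq_len(cfg$n_latent), n_linked)
  }
  imm_factor <- rep_len(seq_len(cfg$n_latent), cfg$n_immune)

  lnc_mu <- rnorm(cfg$n_lnc, mean = 3, sd = 1)
  imm_mu <- rnorm(cfg$n_immune, mean = 4, sd = 1)

  # DE assignment: planted-pair genes first (shared direction per pair),
  # then random lncRNAs with random directions
  pp <- cfg$planted_pairs
  de_dir <- rep(0L, cfg$n_lnc)
  planted_idx <- integer()
  if (nrow(pp) > 0) {
    pair_dir <- sample(c(1L, -1L), nrow(pp), replace = TRUE)
    for (i in seq_len(nrow(pp))) {
      de_dir[c(pp$lncA[i], pp$lncB[i])] <- pair_dir[i]
      # shared baseline and factor so that P(A > B) = 1/2 within sample
      mu_i <- rnorm(1, mean = 3, sd = 1)
      lnc_mu[c(pp$lncA[i], pp$lncB[i])] <- mu_i
      lnc_factor[pp$lncB[i]] <- lnc_factor[pp$lncA[i]]
    }
    planted_idx <- c(rbind(pp$lncA, pp$lncB))
  }
  n_more <- cfg$n_de - length(planted_idx)
  if (n_more > 0) {
    pool <- setdiff(seq_len(cfg$n_lnc), planted_idx)
    extra <- sample(pool, n_more)
    de_dir[extra] <- sample(c(1L, -1L), n_more, replace = TRUE)
  }

  load_row <- function(factors, mu) {
    k <- length(mu)
    z <- matrix(rnorm(k * n_s, sd = cfg$noise_sd), k, n_s) + mu
    has_f <- !is.na(factors)
    if (any(has_f)) z[has_f, ] <- z[has_f, ] + a * fac[factors[has_f], , drop = FALSE]
    z
  }
  z_lnc <- load_row(lnc_factor, lnc_mu)
  z_imm <- load_row(imm_factor, imm_mu)
  is_tum <- grp == "tumor"
  z_lnc[, is_tum] <- z_lnc[, is_tum] + cfg$de_log2_shift * de_dir

  expr <- rbind(2^z_lnc, 2^z_imm)
  dimnames(expr) <- list(c(lnc_ids, imm_ids), smp)
  expression <- tibble::as_tibble(expr, rownames = "gene_id")

  # planted pairs in canonical (lexicographic) orientation, beta flipped
  # when the canonical A is the generator's B: G_canon = 1 - G (tie-free)
  truth_pairs <- tibble::tibble(lncA = character(), lncB = character(),
                                beta = double())
  tum_smp <- smp[is_tum]
  lp <- setNames(rep(0, cfg$n_tumor), tum_smp)
  if (nrow(pp) > 0) {
    idA <- lnc_ids[pp$lncA]; idB <- lnc_ids[pp$lncB]
    flip <- idA > idB
    canonA <- ifelse(flip, idB, idA)
    canonB <- ifelse(flip, idA, idB)
    beta <- ifelse(flip, -pp$beta, pp$beta)
    truth_pairs <- tibble::tibble(lncA = canonA, lncB = canonB, beta = beta)
    for (i in seq_len(nrow(truth_pairs))) {
      g <- as.numeric(expr[truth_pairs$lncA[i], is_tum] >
                        expr[truth_pairs$lncB[i], is_tum])
      lp <- lp + truth_pairs$beta[i] * g
    }
  }

  t_event <- rexp(cfg$n_tumor, rate = cfg$baseline_hazard * exp(lp))
  if (cfg$censor_rate > 0) {
    t_max <- calibrate_censoring(t_event, cfg$censor_rate)
    c_time <- runif(cfg$n_tumor, 0, t_max)
    os_time <- pmin(t_event, c_time)
    os_status <- as.integer(t_event <= c_time)
  } else {
    os_time <- t_event
    os_status <- rep(1L, cfg$n_tumor)
  }
  os_time <- pmax(os_time, 1e-8)

  clinical <- tibble::tibble(
    sample_id = tum_smp,
    os_time = os_time,
    os_status = os_status,
    age_group = sample(c("<=60", ">60"), cfg$n_tumor, TRUE),
    gender = sample(c("FEMALE", "MALE"), cfg$n_tumor, TRUE),
    histological_type = sample(
      c("DDLPS", "LMS", "MFS", "SS", "UPS", "Other"), cfg$n_tumor, TRUE,
      prob = c(58, 104, 25, 10, 51, 11) / 259),
    metastasis = sample(c("M0", "M1", "Unknown"), cfg$n_tumor, TRUE,
                        prob = c(0.75, 0.15, 0.10)),
    margin_status = sample(c("R0", "R1", "Unknown"), cfg$n_tumor, TRUE,
                           prob = c(0.70, 0.20, 0.10)),
    recurrence = sample(c("NO", "YES", "Unknown"), cfg$n_tumor, TRUE,
                        prob = c(0.6, 0.3, 0.1)),
    radiotherapy = sample(c("NO", "YES"), cfg$n_tumor, TRUE)
  )

  list(
    expression = expression,
    samples = tibble::tibble(sample_id = smp, group = grp),
    clinical = clinical,
    truth = list(
      immune_linked_lnc_ids = lnc_ids[seq_len(n_linked)],
      de_lnc = tibble::tibble(
        gene_id = lnc_ids[de_dir != 0],
        direction = ifelse(de_dir[de_dir != 0] > 0, "up", "down")),
      planted_pairs = truth_pairs,
      linear_predictor = lp
    )
  )
}

# find T_max so that uniform-[0, T_max] censoring hits the target
# censored proportion: P(censored_i) = min(T_i / T_max, 1)
calibrate_censoring <- function(t_event, rate) {
  f <- function(tm) mean(pmin(t_event / tm, 1)) - rate
  lo <- min(t_event) / 2
  hi <- max(t_event) * 2
  while (f(hi) > 0) hi <- hi * 2   # raise until censoring drops below target
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}
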