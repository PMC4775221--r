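pair_cohort <- function(df) {
  # df: patient, mT, mN, plus optional plate_T/plate_N/center columns
  n <- nrow(df)
  center <- if ("center" %in% names(df)) df$center else rep("C", n)
  plate_T <- if ("plate_T" %in% names(df)) df$plate_T else rep("pl", n)
  plate_N <- if ("plate_N" %in% names(df)) df$plate_N else rep("pl", n)
  est <- tibble::tibble(
    sample_id = c(paste0(df$patient, "-T"), paste0(df$patient, "-N")),
    rm = 100L, rn = 100000L, R = 1,
    m_raw = c(df$mT, df$mN), m = c(df$mT, df$mN),
    log10_m = log10(c(df$mT, df$mN)), flagged = FALSE
  )
  meta <- tibble::tibble(
    sample_id = est$sample_id,
    patient_id = rep(df$patient, 2),
    sample_type = rep(c("tumor", "normal_tissue"), each = n),
    platform = "WXS", center = rep(center, 2),
    plate_id = c(plate_T, plate_N)
  )
  list(est = est, meta = meta)
}

test_that("pairs require same plate and center, and never use blood", {
  pc <- pair_cohort(tibble::tibble(
    patient = c("p1", "p2"), mT = c(50, 60), mN = c(100, 90),
    plate_T = c("pl1", "pl1"), plate_N = c("pl1", "pl2")
  ))
  pairs <- build_pairs(pc$est, pc$meta)
  expect_equal(pairs$patient_id, "p1")
  expect_equal(pairs$r, log2(50 / 100))

  # tumor + blood only: no pair
  meta_blood <- pc$meta
  meta_blood$sample_type[meta_blood$sample_type == "normal_tissue"] <- "blood"
  expect_equal(nrow(build_pairs(pc$est, meta_blood)), 0L)
})

test_that("multiple candidate pairs resolve to the lexicographically smallest", {
  est <- tibble::tibble(
    sample_id = c("p1-T2", "p1-T1", "p1-N2", "p1-N1"),
    rm = 100L, rn = 100000L, R = 1,
    m_raw = c(50, 40, 100, 80), m = c(50, 40, 100, 80),
    log10_m = log10(c(50, 40, 100, 80)), flagged = FALSE
  )
  meta <- tibble::tibble(
    sample_id = est$sample_id, patient_id = "p1",
    sample_type = c("tumor", "tumor", "normal_tissue", "normal_tissue"),
    platform = "WXS", center = "C", plate_id = "pl"
  )
  expect_message(pairs <- build_pairs(est, meta), "multiple candidate")
  expect_equal(pairs$tumor_id, "p1-T1")
  expect_equal(pairs$normal_id, "p1-N1")
})

test_that("the paired ratio is antisymmetric under tumor/normal swap", {
  set.seed(5)
  m <- tibble::tibble(patient = sprintf("p%d", 1:8),
                      mT = runif(8, 10, 100), mN = runif(8, 10, 100))
  pc <- pair_cohort(m)
  pairs <- build_pairs(pc$est, pc$meta)
  swapped_meta <- pc$meta
  swapped_meta$sample_type <- rep(c("normal_tissue", "tumor"), each = 8)
  pairs_sw <- build_pairs(pc$est, swapped_meta)
  expect_equal(sort(pairs_sw$r), sort(-pairs$r))
})

test_that("signed-rank p matches exact enumeration for small samples", {
  set.seed(17)
  for (n in c(6, 9, 12)) {
    r <- round(rnorm(n, -0.3, 0.6), 6)
    got <- wilcoxon_signed_rank_p(r)
    expect_equal(got, oracle_signed_rank_p(r), tolerance = 1e-12)
  }
})

test_that("depletion calls follow the sign pattern and the pair-count floor", {
  pairs <- tibble::tibble(
    patient_id = sprintf("p%d", 1:29),
    cancer_type = c(rep("DEPL", 20), rep("FEW", 9)),
    tumor_id = "t", normal_id = "n", platform = "WXS", center = "C",
    plate_id = "pl", mT = 1, mN = 2,
    r = c(-seq(0.2, 2.1, by = 0.1), seq(0.1, 0.9, by = 0.1))
  )
  res <- depletion_test(pairs, min_pairs = 10)
  expect_equal(res$cancer_type, "DEPL")   # 9-pair group omitted
  expect_equal(res$direction, "depleted")
  expect_equal(res$frac_depleted, 1)
  # all 20 ratios negative: smallest attainable two-sided exact p
  expect_equal(res$p, 2 / 2^20, tolerance = 1e-9)
  expect_true(all(res$q >= res$p))
})

test_that("depletion direction flips when ratios are negated", {
  set.seed(23)
  pairs <- tibble::tibble(
    patient_id = sprintf("p%d", 1:30), cancer_type = "CT",
    tumor_id = "t", normal_id = "n", platform = "WXS", center = "C",
    plate_id = "pl", mT = 1, mN = 2, r = rnorm(30, -0.8, 0.4)
  )
  res <- depletion_test(pairs)
  neg <- depletion_test(dplyr::mutate(pairs, r = -r))
  expect_equal(res$p, neg$p)
  expect_equal(res$direction, "depleted")
  expect_equal(neg$direction, "accumulated")
})

test_that("type-I error of the depletion test is calibrated under the null", {
  set.seed(77)
  n_rep <- 400
  rej <- replicate(n_rep, {
    r <- rnorm(20, 0, 0.5)
    wilcoxon_signed_rank_p(r) < 0.05
  })
  ci <- qbinom(c(0.025, 0.975), n_rep, 0.05) / n_rep
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})

test_that("platform concordance is 1 under a monotone transform and skips tiny groups", {
  est <- tibble::tibble(
    sample_id = c(paste0("p", 1:10, "-WXS"), paste0("p", 1:10, "-WGS")),
    rm = 100L, rn = 100000L, R = 1, m_raw = 1, m = 1,
    log10_m = c(1:10 / 10, log(1:10 / 10 + 1)),  # strictly monotone map
    flagged = FALSE
  )
  meta <- tibble::tibble(
    sample_id = est$sample_id, patient_id = rep(paste0("p", 1:10), 2),
    sample_type = "tumor",
    platform = rep(c("WXS", "WGS"), each = 10), center = "C",
    plate_id = "pl"
  )
  res <- platform_concordance(est, meta)
  expect_equal(res$rho, 1)
  expect_true(res$applicable)

  small <- platform_concordance(est[c(1, 2, 11, 12), ], meta)
  expect_false(small$applicable)
})

test_that("covariate correlation handles perfect anticorrelation and degenerate input", {
  d <- tibble::tibble(log10_m = 1:10 / 5, score = -(1:10 / 5))
  res <- correlate_covariate(d, log10_m, score)
  expect_equal(res$rho, -1)
  expect_error(
    correlate_covariate(tibble::tibble(x = 1:5, y = rep(1, 5)), x, y),
    class = "mtcn_config_error"
  )
  expect_error(
    correlate_covariate(tibble::tibble(x = 1:2, y = 2:1), x, y),
    class = "mtcn_config_error"
  )
})

test_that("permuted covariates give uniform p-values", {
  set.seed(55)
  n_rep <- 300
  p <- replicate(n_rep, {
    d <- tibble::tibble(x = rnorm(30), y = rnorm(30))
    correlate_covariate(d, x, y)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})

test_that("Cox association recovers a planted log-hazard and flags degenerate input", {
  co <- simulate_cohort(n_patients = 300, seed = 41, survival_gamma = 1,
                        plate_sd = 0, n_genes = 10, n_decoy_sets = 1)
  est <- estimate_copy_number(co$counts, co$meta, co$purity)
  fit <- fit_batch_model(est, co$meta)
  estc <- correct_copy_number(fit, est, co$meta)
  res <- cox_survival(estc, co$survival, co$meta)
  expect_true(res$estimable)
  expect_equal(res$hazard_ratio, exp(res$coefficient))
  expect_lt(res$wald_p, 0.01)
  # measurement noise only attenuates; truth gamma = 1
  expect_equal(res$coefficient, 1, tolerance = 0.35)
  expect_equal(res$n_high + res$n_low, res$n)

  # constant copy number: unestimable
  est_const <- est
  est_const$log10_m <- 2
  res2 <- cox_survival(est_const, co$survival, co$meta)
  expect_false(res2$estimable)
})
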