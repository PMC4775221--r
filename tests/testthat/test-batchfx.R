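make_est <- function(sample_id, log10_m) {
  tibble::tibble(sample_id = sample_id, rm = 100L, rn = 100000L, R = 1,
                 m_raw = 10^log10_m, m = 10^log10_m, log10_m = log10_m,
                 flagged = FALSE)
}

make_meta <- function(sample_id, plate_id, sample_type = "tumor",
                      platform = "WXS", cancer_type = NULL) {
  out <- tibble::tibble(
    sample_id = sample_id, patient_id = paste0("p", seq_along(sample_id)),
    sample_type = sample_type, platform = platform, center = "C",
    plate_id = plate_id
  )
  if (!is.null(cancer_type)) out$cancer_type <- cancer_type
  out
}

test_that("single plate, single tissue collapses to the grand mean", {
  est <- make_est(paste0("s", 1:6), c(2.1, 2.3, 2.0, 2.2, 2.4, 2.0))
  meta <- make_meta(est$sample_id, "plateA")
  fit <- fit_batch_model(est, meta)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "mu"], mean(est$log10_m))
  expect_equal(td$estimate[td$term == "plate"], 0)
})

test_that("two equal plates with a +0.3 offset recover the closed-form contrast", {
  y1 <- c(2.0, 2.1, 2.2, 1.9, 2.05)
  y2 <- y1 + 0.3
  est <- make_est(paste0("s", 1:10), c(y1, y2))
  meta <- make_meta(est$sample_id, rep(c("p1", "p2"), each = 5))
  fit <- fit_batch_model(est, meta)
  alpha <- fit$fits[[1]]$alpha
  expect_equal(unname(alpha["p2"] - alpha["p1"]),
               oracle_two_plate_alpha_diff(y1, y2))
  # weighted sum-to-zero constraint holds
  expect_equal(sum(alpha * c(5, 5)) / 10, 0, tolerance = 1e-12)
  expect_equal(sum(fit$fits[[1]]$residuals$residual), 0, tolerance = 1e-10)
})

test_that("plate effects drawn N(0, 0.15^2) are recovered within Monte-Carlo error", {
  set.seed(202)
  errs <- replicate(25, {
    n_plate <- 6; n_per <- 40
    alpha <- rnorm(n_plate, 0, 0.15)
    alpha <- alpha - mean(alpha)
    plate <- rep(sprintf("pl%d", 1:n_plate), each = n_per)
    y <- 2 + alpha[as.integer(factor(plate))] + rnorm(n_plate * n_per, 0, 0.2)
    est <- make_est(sprintf("s%03d", seq_along(y)), y)
    meta <- make_meta(est$sample_id, plate)
    fit <- fit_batch_model(est, meta)
    mean(abs(fit$fits[[1]]$alpha[sprintf("pl%d", 1:n_plate)] - alpha))
  })
  se <- 0.2 / sqrt(40)
  expect_lt(mean(errs), 3 * se)
})

test_that("correction subtracts the plate effect from WXS only and preserves contrasts", {
  y <- c(2.0, 2.1, 2.2, 2.45, 2.55, 2.6, 2.35)
  est <- make_est(paste0("s", 1:7), y)
  meta <- make_meta(est$sample_id,
                    c("a", "a", "a", "b", "b", "b", "b"),
                    platform = c(rep("WXS", 6), "WGS"))
  fit <- fit_batch_model(est, meta)
  corr <- correct_copy_number(fit, est, meta)
  alpha <- fit$fits[[1]]$alpha
  expect_equal(corr$log10_m_corrected[1:3], y[1:3] - alpha[["a"]])
  # WGS passes through untouched even though its plate has an estimate
  expect_equal(corr$log10_m_corrected[7], y[7])
  # between-sample contrasts within a plate are invariant to the coding
  expect_equal(diff(corr$log10_m_corrected[1:2]), diff(y[1:2]))
})

test_that("correction is idempotent: refitting corrected values gives near-zero plate effects", {
  set.seed(7)
  plate <- rep(c("a", "b", "c"), each = 20)
  y <- 2 + c(a = -0.2, b = 0.1, c = 0.1)[plate] + rnorm(60, 0, 0.15)
  est <- make_est(sprintf("s%02d", 1:60), y)
  meta <- make_meta(est$sample_id, plate)
  fit <- fit_batch_model(est, meta)
  corr <- correct_copy_number(fit, est, meta)
  est2 <- make_est(corr$sample_id, corr$log10_m_corrected)
  fit2 <- fit_batch_model(est2, meta)
  expect_true(all(abs(fit2$fits[[1]]$alpha) < 1e-10))
})

test_that("adding a constant shifts mu only (translation equivariance)", {
  set.seed(8)
  plate <- rep(c("a", "b"), each = 10)
  stype <- rep(c("tumor", "blood"), 10)
  y <- rnorm(20, 2, 0.3)
  est <- make_est(sprintf("s%02d", 1:20), y)
  meta <- make_meta(est$sample_id, plate, sample_type = stype)
  f1 <- fit_batch_model(est, meta)
  f2 <- fit_batch_model(make_est(est$sample_id, y + 5), meta)
  expect_equal(f2$fits[[1]]$mu, f1$fits[[1]]$mu + 5)
  expect_equal(f2$fits[[1]]$alpha, f1$fits[[1]]$alpha)
  expect_equal(f2$fits[[1]]$beta, f1$fits[[1]]$beta)
})

test_that("tissue effect is estimated, and dropped under perfect confounding", {
  set.seed(9)
  plate <- rep(c("a", "b"), each = 12)
  stype <- rep(rep(c("tumor", "blood"), each = 6), 2)
  beta_true <- ifelse(stype == "blood", -0.4, 0)
  y <- 2 + beta_true + rnorm(24, 0, 0.02)
  est <- make_est(sprintf("s%02d", 1:24), y)
  meta <- make_meta(est$sample_id, plate, sample_type = stype)
  fit <- fit_batch_model(est, meta)
  beta <- fit$fits[[1]]$beta
  expect_equal(unname(beta["blood"] - beta["tissue"]), -0.4, tolerance = 0.05)

  # plate a = all tumor, plate b = all blood: confounded
  stype2 <- rep(c("tumor", "blood"), each = 12)
  meta2 <- make_meta(est$sample_id, plate, sample_type = stype2)
  expect_warning(fit2 <- fit_batch_model(est, meta2), "confounded")
  expect_true(fit2$fits[[1]]$tissue_dropped)
})

test_that("fits are stratified by cancer type and unknown plates are errors", {
  est <- make_est(paste0("s", 1:8), c(1:4 / 10 + 2, 1:4 / 10 + 3))
  meta <- make_meta(est$sample_id, rep(c("a", "b"), 4),
                    cancer_type = rep(c("CT1", "CT2"), each = 4))
  fit <- fit_batch_model(est, meta)
  expect_setequal(glance(fit)$cancer_type, c("CT1", "CT2"))

  meta_bad <- meta
  meta_bad$plate_id[1] <- "zz"
  expect_error(correct_copy_number(fit, est, meta_bad),
               class = "mtcn_config_error")
})

test_that("tidy flags single-sample plates as low confidence", {
  est <- make_est(paste0("s", 1:5), c(2, 2.1, 2.2, 2.3, 2.9))
  meta <- make_meta(est$sample_id, c("a", "a", "a", "a", "b"))
  td <- tidy(fit_batch_model(est, meta))
  expect_true(td$low_confidence[td$term == "plate" & td$level == "b"])
  expect_false(td$low_confidence[td$term == "plate" & td$level == "a"])
})

test_that("diagnostics mark single-plate cohorts not applicable and detect shared plate effects", {
  est <- make_est(paste0("s", 1:6), rnorm(6, 2, 0.1))
  meta <- make_meta(est$sample_id, "only_plate")
  diag1 <- batch_diagnostics(est, meta)
  expect_true(all(!diag1$applicable))

  set.seed(31)
  n_plate <- 5
  alpha <- seq(-0.3, 0.3, length.out = n_plate)
  rows <- purrr::map_dfr(seq_len(n_plate), function(i) {
    tibble::tibble(
      plate = sprintf("pl%d", i),
      stype = rep(c("blood", "tumor"), each = 4),
      y = 2 + alpha[i] + ifelse(rep(c(TRUE, FALSE), each = 4), -0.3, 0) +
        rnorm(8, 0, 0.05)
    )
  })
  est2 <- make_est(sprintf("s%02d", seq_len(nrow(rows))), rows$y)
  meta2 <- make_meta(est2$sample_id, rows$plate, sample_type = rows$stype)
  diag2 <- batch_diagnostics(est2, meta2)
  pear <- diag2[diag2$diagnostic == "plate_mean_pearson", ]
  expect_true(pear$applicable)
  expect_gt(pear$estimate, 0.8)
  kw <- diag2[grepl("kruskal", diag2$diagnostic), ]
  expect_true(all(kw$applicable))
  expect_true(all(kw$p < 0.05))
})
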