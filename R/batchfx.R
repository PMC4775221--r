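tissue_class_of <- function(sample_type) {
  ifelse(sample_type == "blood", "blood", "tissue")
}

join_meta_for_fit <- function(estimates, meta) {
  required <- c("sample_id", "sample_type", "platform", "plate_id")
  stopifnot(all(required %in% names(meta)))
  d <- inner_join(estimates, meta, by = "sample_id",
                  suffix = c("", ".meta"))
  if (!"cancer_type" %in% names(d)) d$cancer_type <- "all"
  d$tissue_class <- tissue_class_of(d$sample_type)
  d
}

fit_one_batch_model <- function(d, cancer_type) {
  d <- d[!is.na(d$log10_m), , drop = FALSE]
  plate <- factor(d$plate_id)
  tissue <- factor(d$tissue_class)
  n_plate <- table(plate)
  n_tissue <- table(tissue)
  y <- d$log10_m

  drop_tissue <- FALSE
  rhs <- c(if (nlevels(plate) > 1L) "plate",
           if (nlevels(tissue) > 1L) "tissue")
  alpha_raw <- setNames(numeric(nlevels(plate)), levels(plate))
  beta_raw <- setNames(numeric(nlevels(tissue)), levels(tissue))
  if (length(rhs) == 0L) {
    mu_raw <- mean(y)
    resid <- y - mu_raw
  } else {
    # plate enters first so perfect plate/tissue confounding aliases tissue
    fit <- lm(stats::reformulate(rhs, response = "y"))
    cf <- coef(fit)
    tissue_cf <- cf[grepl("^tissue", names(cf))]
    if (length(tissue_cf) > 0 && anyNA(tissue_cf)) {
      warn(paste0("Plate and tissue are perfectly confounded in '",
                  cancer_type, "'; tissue effect dropped"))
      drop_tissue <- TRUE
      fit <- lm(y ~ plate)
      cf <- coef(fit)
    }
    plate_cf <- cf[grepl("^plate", names(cf))]
    if (anyNA(plate_cf)) {
      abort(paste0("Plate effects not estimable in '", cancer_type, "'"),
            class = "mtcn_config_error")
    }
    alpha_raw[sub("^plate", "", names(plate_cf))] <- plate_cf
    if (!drop_tissue) {
      tissue_cf <- cf[grepl("^tissue", names(cf))]
      beta_raw[sub("^tissue", "", names(tissue_cf))] <- tissue_cf
    }
    mu_raw <- cf[["(Intercept)"]]
    resid <- stats::residuals(fit)
  }

  # re-parameterize to sample-size-weighted sum-to-zero effects so the
  # correction preserves the cohort mean; fitted values are unchanged
  w_alpha <- as.numeric(n_plate[names(alpha_raw)])
  w_beta <- as.numeric(n_tissue[names(beta_raw)])
  alpha <- alpha_raw - stats::weighted.mean(alpha_raw, w_alpha)
  beta <- beta_raw - stats::weighted.mean(beta_raw, w_beta)
  mu <- mu_raw + stats::weighted.mean(alpha_raw, w_alpha) +
    stats::weighted.mean(beta_raw, w_beta)

  list(
    cancer_type = cancer_type,
    mu = mu,
    alpha = alpha,
    beta = beta,
    n_plate = setNames(as.integer(n_plate), names(n_plate)),
    n_tissue = setNames(as.integer(n_tissue), names(n_tissue)),
    tissue_dropped = drop_tissue,
    residuals = tibble(sample_id = d$sample_id, residual = unname(resid)),
    sigma = stats::sd(resid),
    n = length(y)
  )
}

#' Fit the plate/tissue batch-effect model to log10 copy number
#'
#' Fits, separately for each cancer type, the linear model
#'
#'   log10(m) = mu + alpha\[plate\] + beta\[tissue\] + epsilon
#'
#' by least squares, where tissue is the two-class factor
#' tissue-derived (tumor or adjacent normal) vs blood. The model is
#' over-parameterized, so effects are reported under a sample-size-weighted
#' sum-to-zero constraint on both `alpha` and `beta`: the weighted mean of
#' the plate effects (and of the tissue effects) is zero, so subtracting
#' `alpha` preserves the cohort mean. Any full-rank coding yields identical
#' corrected differences between samples.
#'
#' @param estimates Copy-number estimates from [estimate_copy_number()]
#'   (rows with `log10_m = NA` are dropped from the fit).
#' @param meta Sample metadata with `plate_id`, `sample_type`, `platform`,
#'   and optionally `cancer_type`.
#'
#' @return An object of class `mtcn_batch_fit`. Use [tidy()] for the effect
#'   estimates, [glance()] for per-cancer-type fit summaries, and
#'   [correct_copy_number()] to subtract the plate effects.
#'
#' @details A plate observed in a single sample has its effect estimated but
#'   flagged low-confidence in `tidy()` output. If plate and tissue are
#'   perfectly confounded the tissue term is dropped with a warning.
#' @export
fit_batch_model <- function(estimates, meta) {
  d <- join_meta_for_fit(estimates, meta)
  d <- d[!is.na(d$log10_m), , drop = FALSE]
  if (nrow(d) == 0L) {
    abort("No usable samples (all log10_m missing)", class = "mtcn_config_error")
  }
  fits <- lapply(split(d, d$cancer_type), function(dd) {
    fit_one_batch_model(dd, dd$cancer_type[[1]])
  })
  structure(
    list(fits = fits, constraint = "weighted_sum_to_zero"),
    class = "mtcn_batch_fit"
  )
}

#' @export
print.mtcn_batch_fit <- function(x, ...) {
  cat("<mtcn_batch_fit> ", length(x$fits), " cancer type(s), constraint: ",
      x$constraint, "\n", sep = "")
  for (f in x$fits) {
    cat(sprintf("  %s: n = %d, %d plate(s), mu = %.3f, sigma = %.3f%s\n",
                f$cancer_type, f$n, length(f$alpha), f$mu, f$sigma,
                if (f$tissue_dropped) " (tissue dropped)" else ""))
  }
  invisible(x)
}

#' @describeIn fit_batch_model Effect estimates as a tibble: one row per
#'   (cancer_type, term, level) with `estimate`, `n`, and `low_confidence`
#'   for single-sample plates.
#' @param x,object An `mtcn_batch_fit`.
#' @param ... Unused.
#' @method tidy mtcn_batch_fit
#' @export
tidy.mtcn_batch_fit <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    bind_rows(
      tibble(cancer_type = f$cancer_type, term = "mu", level = NA_character_,
             estimate = f$mu, n = f$n, low_confidence = FALSE),
      tibble(cancer_type = f$cancer_type, term = "plate",
             level = names(f$alpha), estimate = unname(f$alpha),
             n = as.integer(f$n_plate[names(f$alpha)]),
             low_confidence = f$n_plate[names(f$alpha)] < 2),
      tibble(cancer_type = f$cancer_type, term = "tissue",
             level = names(f$beta), estimate = unname(f$beta),
             n = as.integer(f$n_tissue[names(f$beta)]),
             low_confidence = f$tissue_dropped)
    )
  })
}

#' @describeIn fit_batch_model One-row-per-cancer-type fit summary.
#' @method glance mtcn_batch_fit
#' @export
glance.mtcn_batch_fit <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    tibble(cancer_type = f$cancer_type, n = f$n, n_plates = length(f$alpha),
           mu = f$mu, sigma = f$sigma, tissue_dropped = f$tissue_dropped)
  })
}

#' Subtract estimated plate effects from WXS copy numbers
#'
#' Applies the fitted plate effects: for every WXS sample,
#' `log10_m_corrected = log10_m - alpha[plate]`. The tissue effect is a real
#' biological contrast and is never subtracted. WGS samples pass through
#' uncorrected (`log10_m_corrected = log10_m`), reflecting the much smaller
#' and inconsistent batch signal in whole-genome data. Both raw and
#' corrected values are retained in the output.
#'
#' @param fit An `mtcn_batch_fit` from [fit_batch_model()].
#' @param estimates Copy-number estimates from [estimate_copy_number()].
#' @param meta Sample metadata (must cover every sample and its plate).
#'
#' @return `estimates` with added columns `log10_m_corrected` and
#'   `m_corrected` (= 10^log10_m_corrected; `NA` for flagged samples).
#' @export
correct_copy_number <- function(fit, estimates, meta) {
  stopifnot(inherits(fit, "mtcn_batch_fit"))
  d <- join_meta_for_fit(estimates, meta)
  corrected <- d$log10_m
  wxs <- which(d$platform == "WXS" & !is.na(d$log10_m))
  for (i in wxs) {
    f <- fit$fits[[d$cancer_type[[i]]]]
    if (is.null(f)) {
      abort(paste0("No batch fit for cancer type '", d$cancer_type[[i]], "'"),
            class = "mtcn_config_error")
    }
    if (!d$plate_id[[i]] %in% names(f$alpha)) {
      abort(paste0("Plate '", d$plate_id[[i]], "' absent from batch fit for '",
                   d$cancer_type[[i]], "'"), class = "mtcn_config_error")
    }
    corrected[[i]] <- d$log10_m[[i]] - f$alpha[[d$plate_id[[i]]]]
  }
  estimates %>%
    left_join(tibble(sample_id = d$sample_id, log10_m_corrected = corrected),
              by = "sample_id") %>%
    mutate(m_corrected = 10^.data$log10_m_corrected)
}

#' Batch-effect diagnostics
#'
#' Reproduces the two screens used to justify the plate correction:
#' per-cancer-type Kruskal-Wallis tests of log10 copy number across plates,
#' run separately for blood and tissue-derived samples, and the Pearson
#' correlation between per-plate mean blood and mean tissue copy number.
#' A shared plate-level contribution shows up as a positive plate-mean
#' correlation even though blood and tissue from a patient are often
#' processed on different plates.
#'
#' @param estimates Copy-number estimates from [estimate_copy_number()].
#' @param meta Sample metadata.
#' @param min_plates Minimum plates for the plate-mean correlation (each
#'   needing `min_per_plate` blood and tissue samples). Defaults 3 and 3.
#' @param min_per_plate See `min_plates`.
#'
#' @return A tibble with one row per (cancer_type, diagnostic): columns
#'   `cancer_type`, `diagnostic` (`kruskal_blood`, `kruskal_tissue`,
#'   `plate_mean_pearson`), `n_plates`, `n`, `statistic`, `estimate`
#'   (Pearson r where applicable), `p`, `applicable`, `note`.
#' @export
batch_diagnostics <- function(estimates, meta, min_plates = 3,
                              min_per_plate = 3) {
  d <- join_meta_for_fit(estimates, meta)
  d <- d[!is.na(d$log10_m), , drop = FALSE]
  purrr::map_dfr(split(d, d$cancer_type), function(dd) {
    ct <- dd$cancer_type[[1]]
    kw_row <- function(sub, label) {
      n_pl <- length(unique(sub$plate_id))
      if (nrow(sub) < 2L || n_pl < 2L) {
        return(tibble(cancer_type = ct, diagnostic = label, n_plates = n_pl,
                      n = nrow(sub), statistic = NA_real_,
                      estimate = NA_real_, p = NA_real_, applicable = FALSE,
                      note = "needs >= 2 plates"))
      }
      kt <- kruskal.test(sub$log10_m, factor(sub$plate_id))
      tibble(cancer_type = ct, diagnostic = label, n_plates = n_pl,
             n = nrow(sub), statistic = unname(kt$statistic),
             estimate = NA_real_, p = kt$p.value, applicable = TRUE,
             note = NA_character_)
    }
    blood <- dd[dd$tissue_class == "blood", ]
    tissue <- dd[dd$tissue_class == "tissue", ]
    means <- dd %>%
      group_by(.data$plate_id, .data$tissue_class) %>%
      summarise(mean_l10 = mean(.data$log10_m), k = n(), .groups = "drop") %>%
      filter(.data$k >= min_per_plate) %>%
      tidyr::pivot_wider(id_cols = "plate_id",
                         names_from = "tissue_class",
                         values_from = "mean_l10") %>%
      tidyr::drop_na()
    pearson <- if (!all(c("blood", "tissue") %in% names(means)) ||
                   nrow(means) < min_plates) {
      tibble(cancer_type = ct, diagnostic = "plate_mean_pearson",
             n_plates = nrow(means), n = NA_integer_, statistic = NA_real_,
             estimate = NA_real_, p = NA_real_, applicable = FALSE,
             note = paste0("needs >= ", min_plates, " plates with >= ",
                           min_per_plate, " blood and tissue samples"))
    } else {
      ct_test <- cor.test(means$blood, means$tissue, method = "pearson")
      tibble(cancer_type = ct, diagnostic = "plate_mean_pearson",
             n_plates = nrow(means), n = nrow(means),
             statistic = unname(ct_test$statistic),
             estimate = unname(ct_test$estimate), p = ct_test$p.value,
             applicable = TRUE, note = NA_character_)
    }
    bind_rows(kw_row(blood, "kruskal_blood"), kw_row(tissue, "kruskal_tissue"),
              pearson)
  })
}
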