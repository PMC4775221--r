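#' Build matched tumor/adjacent-normal pairs
#'
#' Pairs each tumor sample with the adjacent-normal tissue sample from the
#' same patient, sequenced at the same center, on the same platform and
#' within the same plate — so any shared plate contribution cancels in the
#' ratio. Blood normals are never used. For each pair the log2 ratio
#' `r = log2(mT / mN)` is computed; negative `r` means the tumor holds less
#' mtDNA than its matched normal.
#'
#' @param estimates Copy-number estimates ([estimate_copy_number()]).
#' @param meta Sample metadata.
#'
#' @return A tibble with one row per patient pair: `patient_id`,
#'   `cancer_type`, `tumor_id`, `normal_id`, `platform`, `center`,
#'   `plate_id`, `mT`, `mN`, `r`.
#'
#' @details A patient with several admissible tumor/normal combinations
#'   contributes one pair, chosen deterministically as the lexicographically
#'   smallest (tumor_id, normal_id); a note is emitted. Pairs in which
#'   either member is flagged (zero mitochondrial reads) are dropped.
#' @export
build_pairs <- function(estimates, meta) {
  d <- join_meta_for_fit(estimates, meta)
  d <- d[!d$flagged & !is.na(d$m) & d$m > 0, , drop = FALSE]
  tum <- d[d$sample_type == "tumor", ]
  nor <- d[d$sample_type == "normal_tissue", ]
  cand <- inner_join(
    tum %>% select(patient_id = "patient_id", cancer_type = "cancer_type",
                   tumor_id = "sample_id", platform = "platform",
                   center = "center", plate_id = "plate_id", mT = "m"),
    nor %>% select(patient_id = "patient_id", normal_id = "sample_id",
                   platform = "platform", center = "center",
                   plate_id = "plate_id", mN = "m"),
    by = c("patient_id", "platform", "center", "plate_id"),
    relationship = "many-to-many"
  )
  if (nrow(cand) == 0L) {
    return(tibble(patient_id = character(), cancer_type = character(),
                  tumor_id = character(), normal_id = character(),
                  platform = character(), center = character(),
                  plate_id = character(), mT = numeric(), mN = numeric(),
                  r = numeric()))
  }
  multi <- cand %>% count(.data$patient_id, .data$platform) %>%
    filter(.data$n > 1)
  if (nrow(multi) > 0L) {
    inform(paste0(nrow(multi), " patient(s) with multiple candidate pairs; ",
                  "keeping the lexicographically smallest sample-id pair"))
  }
  cand %>%
    arrange(.data$patient_id, .data$platform, .data$tumor_id,
            .data$normal_id) %>%
    group_by(.data$patient_id, .data$platform) %>%
    dplyr::slice(1L) %>%
    ungroup() %>%
    mutate(r = log2(.data$mT / .data$mN)) %>%
    select("patient_id", "cancer_type", "tumor_id", "normal_id", "platform",
           "center", "plate_id", "mT", "mN", "r")
}

# Wilcoxon signed-rank on x against 0: zero-discard convention, exact
# distribution for small untied samples, normal approximation with
# continuity correction otherwise.
wilcoxon_signed_rank <- function(x, exact_max_n = 25) {
  x <- x[!is.na(x) & x != 0]
  n <- length(x)
  if (n == 0L) {
    return(list(n = 0L, statistic = NA_real_, p = NA_real_, testable = FALSE))
  }
  exact <- n <= exact_max_n && !any(duplicated(abs(x)))
  wt <- suppressWarnings(
    wilcox.test(x, mu = 0, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  list(n = n, statistic = unname(wt$statistic), p = wt$p.value,
       testable = TRUE)
}

#' Test each cancer type for mtDNA depletion or accumulation in tumors
#'
#' Runs a two-sided Wilcoxon signed-rank test of the paired log2 ratios `r`
#' against zero within each cancer type, then applies Benjamini-Hochberg
#' correction across the tested cancer types. A cancer type is called
#' `depleted` (median r < 0) or `accumulated` (median r > 0) when its
#' adjusted p-value falls below `q_threshold`, otherwise `none`.
#'
#' @param pairs Pair table from [build_pairs()].
#' @param min_pairs Minimum matched pairs per cancer type; groups below this
#'   are omitted from the results (default 10).
#' @param q_threshold FDR threshold for calling a direction (default 0.05).
#'
#' @return A tibble with columns `cancer_type`, `n_pairs`, `frac_depleted`
#'   (share of pairs with r < 0), `statistic`, `p`, `q`, `direction`.
#'   Groups in which every ratio is exactly zero are marked untestable
#'   (`p = NA`, direction `none`) and excluded from the BH family.
#' @export
depletion_test <- function(pairs, min_pairs = 10, q_threshold = 0.05) {
  res <- pairs %>%
    group_by(.data$cancer_type) %>%
    filter(n() >= min_pairs) %>%
    summarise(
      n_pairs = n(),
      frac_depleted = mean(.data$r < 0),
      median_r = median(.data$r),
      test = list(wilcoxon_signed_rank(.data$r)),
      .groups = "drop"
    ) %>%
    mutate(
      statistic = purrr::map_dbl(.data$test, "statistic"),
      p = purrr::map_dbl(.data$test, "p"),
      testable = purrr::map_lgl(.data$test, "testable")
    ) %>%
    select(-"test")
  res$q <- NA_real_
  res$q[res$testable] <- p.adjust(res$p[res$testable], method = "BH")
  res %>%
    mutate(
      direction = dplyr::case_when(
        !.data$testable | is.na(.data$q) | .data$q >= q_threshold ~ "none",
        .data$median_r < 0 ~ "depleted",
        .data$median_r > 0 ~ "accumulated",
        TRUE ~ "none"
      )
    ) %>%
    select("cancer_type", "n_pairs", "frac_depleted", "median_r",
           "statistic", "p", "q", "direction")
}

# Spearman correlation with asymptotic t-approximation p-value, matching
# cor.test(..., method = "spearman", exact = FALSE).
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  rho <- suppressWarnings(cor(x, y, method = "spearman"))
  if (is.na(rho) || n < 3) return(list(rho = rho, p = NA_real_, n = n))
  if (abs(rho) == 1) return(list(rho = rho, p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Cross-platform concordance of copy-number estimates
#'
#' For samples profiled by both whole-exome and whole-genome sequencing,
#' computes the Spearman rank correlation between the two platforms'
#' (corrected) log10 copy-number estimates, per cancer type. Concordance of
#' the two capture chemistries is the primary validation that the depth
#' ratio tracks underlying mtDNA content.
#'
#' @param estimates Copy-number estimates, ideally after
#'   [correct_copy_number()].
#' @param meta Sample metadata; WXS/WGS measurements of the same specimen
#'   are matched on (`patient_id`, `sample_type`).
#' @param min_overlap Minimum matched samples per cancer type (default 3);
#'   smaller groups are reported with `applicable = FALSE`.
#'
#' @return A tibble: `cancer_type`, `n`, `rho`, `p`, `applicable`.
#' @export
platform_concordance <- function(estimates, meta, min_overlap = 3) {
  d <- join_meta_for_fit(estimates, meta)
  val <- if ("log10_m_corrected" %in% names(d)) d$log10_m_corrected else d$log10_m
  d$value <- val
  d <- d[!is.na(d$value), , drop = FALSE]
  wide <- d %>%
    arrange(.data$sample_id) %>%
    group_by(.data$cancer_type, .data$patient_id, .data$sample_type,
             .data$platform) %>%
    summarise(value = .data$value[[1]], .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "platform", values_from = "value") %>%
    tidyr::drop_na(dplyr::any_of(c("WXS", "WGS")))
  if (!all(c("WXS", "WGS") %in% names(wide))) {
    wide$WXS <- wide$WXS %||% NA_real_
    wide$WGS <- wide$WGS %||% NA_real_
  }
  purrr::map_dfr(split(wide, wide$cancer_type), function(w) {
    ct <- w$cancer_type[[1]]
    if (nrow(w) < min_overlap) {
      return(tibble(cancer_type = ct, n = nrow(w), rho = NA_real_,
                    p = NA_real_, applicable = FALSE))
    }
    sc <- spearman_cor(w$WXS, w$WGS)
    tibble(cancer_type = ct, n = sc$n, rho = sc$rho, p = sc$p,
           applicable = TRUE)
  })
}

#' Correlate copy number (or paired ratio) with a sample-level covariate
#'
#' Spearman rank correlation between a per-sample copy-number quantity and
#' an external covariate such as an immune or stromal infiltration score.
#' The p-value is reported uncorrected; this is a screening statistic.
#'
#' @param data A data frame holding both columns (join beforehand).
#' @param value Column with the copy-number quantity (e.g. `log10_m` or a
#'   paired log ratio `r`); tidy-eval.
#' @param covariate Covariate column; tidy-eval.
#'
#' @return A one-row tibble: `n`, `rho`, `p`.
#' @export
correlate_covariate <- function(data, value, covariate) {
  x <- dplyr::pull(data, {{ value }})
  y <- dplyr::pull(data, {{ covariate }})
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) {
    abort("Need at least 3 complete sample pairs", class = "mtcn_config_error")
  }
  if (length(unique(y[ok])) == 1L) {
    abort("Covariate is constant; correlation undefined",
          class = "mtcn_config_error")
  }
  sc <- spearman_cor(x, y)
  tibble(n = sc$n, rho = sc$rho, p = sc$p)
}

#' Univariate Cox survival association with tumor mtDNA copy number
#'
#' Fits, per cancer type, a univariate Cox proportional-hazards model of
#' overall survival on the log10-transformed (corrected) tumor mtDNA copy
#' number, and reports the Wald test of the coefficient. A median-split
#' two-group summary is included for visualization only; inference always
#' uses the continuous covariate.
#'
#' @param estimates Copy-number estimates, ideally after
#'   [correct_copy_number()]; only tumor samples are used.
#' @param survival_tbl Survival table: `patient_id`, `time_days`, `event`.
#' @param meta Sample metadata.
#' @param min_events Minimum events per cancer type (default 2); below this
#'   the group is marked unestimable.
#'
#' @return A tibble per cancer type: `n`, `n_events`, `coefficient`
#'   (log-hazard per unit log10 copy number), `hazard_ratio`, `wald_p`,
#'   `median_cut`, `n_high`, `n_low`, `estimable`.
#' @export
cox_survival <- function(estimates, survival_tbl, meta, min_events = 2) {
  d <- join_meta_for_fit(estimates, meta)
  d$value <- if ("log10_m_corrected" %in% names(d)) d$log10_m_corrected else d$log10_m
  d <- d %>%
    filter(.data$sample_type == "tumor", !is.na(.data$value)) %>%
    arrange(.data$sample_id) %>%
    distinct(.data$patient_id, .keep_all = TRUE) %>%
    inner_join(survival_tbl, by = "patient_id")
  purrr::map_dfr(split(d, d$cancer_type), function(dd) {
    ct <- dd$cancer_type[[1]]
    base <- tibble(cancer_type = ct, n = nrow(dd),
                   n_events = sum(dd$event),
                   coefficient = NA_real_, hazard_ratio = NA_real_,
                   wald_p = NA_real_, median_cut = NA_real_,
                   n_high = NA_integer_, n_low = NA_integer_,
                   estimable = FALSE)
    if (sum(dd$event) < min_events || length(unique(dd$value)) < 2L) {
      return(base)
    }
    fit <- survival::coxph(survival::Surv(time_days, event) ~ value,
                           data = dd)
    sm <- summary(fit)
    cut <- median(dd$value)
    base %>% mutate(
      coefficient = unname(coef(fit)[["value"]]),
      hazard_ratio = exp(.data$coefficient),
      wald_p = sm$coefficients["value", "Pr(>|z|)"],
      median_cut = cut,
      n_high = sum(dd$value > cut),
      n_low = sum(dd$value <= cut),
      estimable = TRUE
    )
  })
}
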