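#' Purity/ploidy correction factor ("effective ploidy")
#'
#' The depth-ratio estimator compares mitochondrial reads against a nuclear
#' genome of known copy number. Normal tissue and blood are diploid, so no
#' correction is needed (R = 1). A bulk tumor sample is a mixture of tumor
#' cells at average ploidy `ploidy` and diploid stromal/immune cells at
#' fraction `1 - purity`, so its nuclear denominator is rescaled by
#'
#'   R = (purity * ploidy + (1 - purity) * 2) / 2
#'
#' which reduces to 1 for a sample composed of pure normal tissue
#' (purity 0).
#'
#' @param sample_type Character vector: `tumor`, `normal_tissue`, or `blood`.
#' @param purity Tumor cell fraction in \[0, 1\]; may be `NA` for non-tumor
#'   samples.
#' @param ploidy Average tumor genome copy number, positive; may be `NA` for
#'   non-tumor samples.
#' @param missing_policy What to do for a tumor sample without purity/ploidy:
#'   `"error"` (default) or `"unit"` (fall back to R = 1 with a warning).
#'
#' @return Numeric vector of correction factors, one per sample.
#' @export
#'
#' @examples
#' correction_factor("tumor", purity = 0, ploidy = 2)    # 1
#' correction_factor("tumor", purity = 1, ploidy = 4)    # 2
#' correction_factor("tumor", purity = 0.5, ploidy = 4)  # 1.5
#' correction_factor("normal_tissue", NA, NA)            # 1
correction_factor <- function(sample_type, purity = NA_real_,
                              ploidy = NA_real_,
                              missing_policy = c("error", "unit")) {
  missing_policy <- match.arg(missing_policy)
  n <- max(length(sample_type), length(purity), length(ploidy))
  sample_type <- rep_len(sample_type, n)
  purity <- rep_len(purity, n)
  ploidy <- rep_len(ploidy, n)
  bad_type <- !sample_type %in% sample_type_levels()
  if (any(bad_type)) {
    abort(paste0("Unknown sample_type: ",
                 paste(unique(sample_type[bad_type]), collapse = ", ")),
          class = "mtcn_config_error")
  }
  if (any(purity < 0 | purity > 1, na.rm = TRUE)) {
    abort("purity must lie in [0, 1]", class = "mtcn_config_error")
  }
  if (any(ploidy <= 0, na.rm = TRUE)) {
    abort("ploidy must be positive", class = "mtcn_config_error")
  }
  is_tumor <- sample_type == "tumor"
  missing_pp <- is_tumor & (is.na(purity) | is.na(ploidy))
  if (any(missing_pp)) {
    if (missing_policy == "error") {
      abort(paste0(sum(missing_pp), " tumor sample(s) lack purity/ploidy; ",
                   "supply them or set missing_policy = \"unit\""),
            class = "mtcn_config_error")
    }
    warn(paste0(sum(missing_pp), " tumor sample(s) lack purity/ploidy; ",
                "falling back to R = 1"))
  }
  R <- rep(1, n)
  use <- is_tumor & !missing_pp
  R[use] <- (purity[use] * ploidy[use] + (1 - purity[use]) * 2) / 2
  R
}

#' Estimate relative mtDNA copy number from read counts
#'
#' Computes, per sample, the relative mtDNA copy number
#' `m = rm / rn * R`, where `rm` and `rn` are the filtered mitochondrial and
#' nuclear read counts and `R` the purity/ploidy correction factor
#' ([correction_factor()]). `m` is a relative, platform-dependent quantity:
#' exome capture recovers mtDNA incidentally while WGS sequences it
#' uniformly, so raw values are comparable only within a platform (and,
#' before batch correction, within a plate).
#'
#' @param counts A tibble with columns `sample_id`, `rm`, `rn`
#'   ([summarise_mt_counts()]), or `sample_id`, `contig`, `read_count`
#'   (reduced internally with default settings).
#' @param meta Sample metadata ([read_metadata()]); required to identify
#'   tumor samples. If `NULL`, all samples are treated as normal (R = 1).
#' @param purity Purity/ploidy table ([read_purity_ploidy()]) for tumor
#'   samples, or `NULL`.
#' @param missing_policy Passed to [correction_factor()].
#'
#' @return A tibble with one row per sample: `sample_id`, `rm`, `rn`, `R`,
#'   `m_raw` (= rm/rn), `m` (= m_raw * R), `log10_m`, and `flagged`
#'   (`TRUE` when rm = 0; such samples have m = 0, `log10_m = NA`, and are
#'   excluded from all log-scale analyses — a zero indicates capture
#'   failure, not biology). Samples with rn = 0 are an error.
#' @export
estimate_copy_number <- function(counts, meta = NULL, purity = NULL,
                                 missing_policy = c("error", "unit")) {
  if (all(c("contig", "read_count") %in% names(counts))) {
    counts <- summarise_mt_counts(counts)
  }
  stopifnot(all(c("sample_id", "rm", "rn") %in% names(counts)))
  if (any(counts$rn == 0)) {
    abort(paste0("rn = 0 for sample(s) ",
                 paste(counts$sample_id[counts$rn == 0], collapse = ", "),
                 "; no nuclear reads survive filtering"),
          class = "mtcn_config_error")
  }
  est <- as_tibble(counts[c("sample_id", "rm", "rn")])
  if (is.null(meta)) {
    est$sample_type <- "normal_tissue"
  } else {
    est <- left_join(est, meta[c("sample_id", "sample_type")],
                     by = "sample_id")
    if (anyNA(est$sample_type)) {
      abort(paste0("Samples missing from metadata: ",
                   paste(est$sample_id[is.na(est$sample_type)], collapse = ", ")),
            class = "mtcn_config_error")
    }
  }
  if (is.null(purity)) {
    est$purity <- NA_real_
    est$ploidy <- NA_real_
  } else {
    est <- left_join(est, purity[c("sample_id", "purity", "ploidy")],
                     by = "sample_id")
  }
  est %>%
    mutate(
      R = correction_factor(.data$sample_type, .data$purity, .data$ploidy,
                            missing_policy = missing_policy),
      m_raw = .data$rm / .data$rn,
      m = .data$m_raw * .data$R,
      log10_m = ifelse(.data$rm > 0, log10(.data$m), NA_real_),
      flagged = .data$rm == 0
    ) %>%
    select("sample_id", "rm", "rn", "R", "m_raw", "m", "log10_m", "flagged")
}
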