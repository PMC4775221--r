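#' Plot paired tumor/normal log2 ratios by cancer type
#'
#' Histograms of the paired log2 ratio r per cancer type with the no-change
#' line at zero; mass to the left of the line indicates mtDNA depletion in
#' tumors.
#'
#' @param pairs Pair table from [build_pairs()].
#' @param results Optional [depletion_test()] output used to color panels
#'   by call (depleted / accumulated / none).
#' @param bins Histogram bins (default 25).
#' @return A ggplot object.
#' @export
plot_paired_ratios <- function(pairs, results = NULL, bins = 25) {
  d <- pairs
  if (!is.null(results)) {
    d <- left_join(d, results[c("cancer_type", "direction")],
                   by = "cancer_type") %>%
      mutate(direction = ifelse(is.na(.data$direction), "none",
                                .data$direction))
  } else {
    d$direction <- "none"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, fill = .data$direction)) +
    ggplot2::geom_histogram(bins = bins, color = "grey30", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~cancer_type, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(depleted = "#4575b4",
                                          accumulated = "#d73027",
                                          none = "grey70")) +
    ggplot2::labs(x = expression(log[2](m[T] / m[N])), y = "pairs",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot signed gene-set enrichment scores
#'
#' Diverging bar chart of the signed enrichment score `-log10(q)` for the
#' strongest gene sets; positive (red) bars are enriched for positive
#' correlation with copy number, negative (blue) for negative correlation.
#'
#' @param scan Output of [gene_set_scan()].
#' @param top_n Sets to show, by absolute score (default 15).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(scan, top_n = 15) {
  d <- scan %>%
    group_by(.data$gene_set) %>%
    dplyr::slice_max(abs(.data$enrichment_score), n = 1,
                     with_ties = FALSE) %>%
    ungroup() %>%
    dplyr::slice_max(abs(.data$enrichment_score), n = top_n,
                     with_ties = FALSE) %>%
    mutate(gene_set = stats::reorder(.data$gene_set,
                                     .data$enrichment_score))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$enrichment_score,
                                  y = .data$gene_set,
                                  fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::scale_fill_manual(values = c(up = "#d73027", down = "#4575b4")) +
    ggplot2::labs(x = expression(signed ~ -log[10](q)), y = NULL,
                  fill = "direction") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for the median split on tumor mtDNA copy number
#'
#' For visualization only: patients are split at the median (corrected)
#' log10 tumor copy number and Kaplan-Meier curves drawn per group;
#' inference should come from [cox_survival()], which uses the continuous
#' covariate.
#'
#' @param estimates Copy-number estimates.
#' @param survival_tbl Survival table.
#' @param meta Sample metadata.
#' @param cancer_type Optional single cancer type to plot (default: all,
#'   faceted).
#' @return A ggplot object.
#' @export
plot_survival_split <- function(estimates, survival_tbl, meta,
                                cancer_type = NULL) {
  d <- join_meta_for_fit(estimates, meta)
  d$value <- if ("log10_m_corrected" %in% names(d)) d$log10_m_corrected else d$log10_m
  d <- d %>%
    filter(.data$sample_type == "tumor", !is.na(.data$value)) %>%
    distinct(.data$patient_id, .keep_all = TRUE) %>%
    inner_join(survival_tbl, by = "patient_id")
  if (!is.null(cancer_type)) d <- d[d$cancer_type %in% cancer_type, ]
  d <- d %>%
    group_by(.data$cancer_type) %>%
    mutate(group = ifelse(.data$value > median(.data$value),
                          "high mtDNA", "low mtDNA")) %>%
    ungroup()
  km <- purrr::map_dfr(split(d, list(d$cancer_type, d$group), drop = TRUE),
                       function(dd) {
    sf <- survival::survfit(survival::Surv(time_days, event) ~ 1, data = dd)
    tibble(cancer_type = dd$cancer_type[[1]], group = dd$group[[1]],
           time = c(0, sf$time), surv = c(1, sf$surv))
  })
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$surv,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~cancer_type) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "days", y = "survival", color = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_batch_model Dot plot of estimated plate effects with the
#'   weighted-zero reference line.
#' @method autoplot mtcn_batch_fit
#' @export
autoplot.mtcn_batch_fit <- function(object, ...) {
  d <- tidy(object) %>% filter(.data$term == "plate")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$estimate,
                                  size = .data$n)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~cancer_type, scales = "free_x") +
    ggplot2::labs(x = "plate", y = expression(hat(alpha) ~ (log[10])),
                  size = "samples") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
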