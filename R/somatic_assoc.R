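coding_variant_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
    "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Splice_Site")
}

noncoding_variant_classes <- function() {
  c("Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "IGR",
    "RNA", "lincRNA", "Nonstop_Mutation", "Translation_Start_Site",
    "De_novo_Start_InFrame", "De_novo_Start_OutOfFrame", "Targeted_Region")
}

#' Build per-gene mutation carrier sets from a MAF-like table
#'
#' Restricts to nonsynonymous coding mutation classes (missense, nonsense,
#' frameshift, in-frame indels, splice site), removes hypermutator samples
#' carrying more than `hypermutator_cutoff` such mutations, and keeps genes
#' mutated in strictly more than `min_freq` of the remaining patients. The
#' frequency denominator is the number of patients with any mutation data
#' after hypermutator removal; it is recorded in the output attributes.
#'
#' @param maf Data frame with columns `Hugo_Symbol`,
#'   `Tumor_Sample_Barcode`, `Variant_Classification` (standard MAF
#'   vocabulary). Unknown classification values are treated as non-coding
#'   with a warning.
#' @param hypermutator_cutoff Samples with more nonsynonymous coding
#'   mutations than this are excluded before counting (default 600).
#' @param min_freq Minimum carrier fraction, exclusive (default 0.04).
#'
#' @return A tibble of alteration calls: `alteration_id` (gene), `kind`
#'   (`"mutation"`), `n_carriers`, `carriers` (list-column of sample ids).
#'   Attributes `n_patients` (denominator) and `n_hypermutators`.
#' @export
build_mutation_calls <- function(maf, hypermutator_cutoff = 600,
                                 min_freq = 0.04) {
  stopifnot(all(c("Hugo_Symbol", "Tumor_Sample_Barcode",
                  "Variant_Classification") %in% names(maf)))
  unknown <- setdiff(unique(maf$Variant_Classification),
                     c(coding_variant_classes(), noncoding_variant_classes()))
  if (length(unknown) > 0L) {
    warn(paste0("Unknown Variant_Classification value(s) treated as ",
                "non-coding: ", paste(unknown, collapse = ", ")))
  }
  all_samples <- unique(maf$Tumor_Sample_Barcode)
  coding <- maf %>%
    filter(.data$Variant_Classification %in% coding_variant_classes())
  per_sample <- coding %>% count(.data$Tumor_Sample_Barcode)
  hyper <- per_sample$Tumor_Sample_Barcode[per_sample$n > hypermutator_cutoff]
  kept_samples <- setdiff(all_samples, hyper)
  coding <- coding %>% filter(.data$Tumor_Sample_Barcode %in% kept_samples)
  n_patients <- length(kept_samples)
  calls <- coding %>%
    distinct(.data$Hugo_Symbol, .data$Tumor_Sample_Barcode) %>%
    group_by(alteration_id = .data$Hugo_Symbol) %>%
    summarise(carriers = list(sort(.data$Tumor_Sample_Barcode)),
              n_carriers = n(), .groups = "drop") %>%
    filter(.data$n_carriers / n_patients > min_freq) %>%
    mutate(kind = "mutation") %>%
    select("alteration_id", "kind", "n_carriers", "carriers") %>%
    arrange(.data$alteration_id)
  attr(calls, "n_patients") <- n_patients
  attr(calls, "n_hypermutators") <- length(hyper)
  calls
}

#' Read a binary copy-number-alteration carrier matrix
#'
#' Upstream significance selection (e.g. keeping arm-level and focal events
#' at q < 0.1) is assumed done; this consumes the resulting 0/1 matrix.
#'
#' @param x Path to a tab-delimited file (first column `alteration_id`,
#'   remaining columns one per sample, entries 0/1) or an equivalent data
#'   frame.
#'
#' @return A tibble of alteration calls: `alteration_id`, `kind` (`"cna"`),
#'   `n_carriers`, `carriers` (list-column). Rows with no carriers are
#'   retained but flagged `untestable`.
#' @export
read_cna_calls <- function(x) {
  df <- if (is.character(x)) {
    read_tsv_quiet(x, readr::cols(.default = readr::col_character()))
  } else {
    as_tibble(x)
  }
  id_col <- if ("alteration_id" %in% names(df)) "alteration_id" else names(df)[[1]]
  sample_cols <- setdiff(names(df), id_col)
  vals <- as.matrix(df[sample_cols])
  mode(vals) <- "character"
  if (!all(vals %in% c("0", "1"))) {
    bad <- which(matrix(!vals %in% c("0", "1"), nrow = nrow(vals)),
                 arr.ind = TRUE)[1, ]
    abort(paste0("CNA matrix must be binary 0/1; offending entry at row ",
                 bad[["row"]], ", column '", sample_cols[bad[["col"]]], "'"),
          class = "mtcn_parse_error")
  }
  if (anyDuplicated(df[[id_col]])) {
    abort("Duplicate alteration_id in CNA matrix", class = "mtcn_parse_error")
  }
  binary <- vals == "1"
  tibble(
    alteration_id = df[[id_col]],
    kind = "cna",
    n_carriers = as.integer(rowSums(binary)),
    carriers = purrr::map(seq_len(nrow(binary)),
                          ~ sort(sample_cols[binary[.x, ]])),
    untestable = rowSums(binary) == 0L
  )
}

mann_whitney <- function(x, y) {
  exact <- length(x) + length(y) <= 50 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' Scan somatic alterations for association with tumor mtDNA copy number
#'
#' For each alteration, compares (corrected) tumor copy number between
#' carriers and non-carriers with a two-sided Mann-Whitney U test, then
#' adjusts p-values by Benjamini-Hochberg. Mutations and CNAs are corrected
#' as separate families by default (`bh_family = "kind"`); pass
#' `bh_family = "all"` to pool. Supplying `strata` (e.g. a molecular
#' subtype label) restricts each comparison within strata by testing on
#' stratum-mean-centered values, guarding against subtype confounding.
#'
#' @param calls Alteration calls ([build_mutation_calls()],
#'   [read_cna_calls()], or a row-bound combination).
#' @param estimates Copy-number estimates for the tumor cohort, ideally
#'   after [correct_copy_number()].
#' @param meta Optional metadata; when given, only tumor samples are used.
#' @param value_col Optional explicit value column.
#' @param strata Optional named vector sample_id -> stratum label.
#' @param bh_family `"kind"` (default) or `"all"`.
#' @param q_threshold FDR threshold for reporting direction (default 0.05).
#'
#' @return A tibble per alteration: `alteration_id`, `kind`, `n_carriers`,
#'   `n_noncarriers`, `u_statistic`, `p`, `q`, `direction` (`increases`,
#'   `decreases`, or `none`), `testable`.
#' @export
association_scan <- function(calls, estimates, meta = NULL, value_col = NULL,
                             strata = NULL, bh_family = c("kind", "all"),
                             q_threshold = 0.05) {
  bh_family <- match.arg(bh_family)
  if (!is.null(meta)) {
    tumor_ids <- meta$sample_id[meta$sample_type == "tumor"]
    estimates <- estimates %>% filter(.data$sample_id %in% tumor_ids)
  }
  vals <- extract_cn_values(estimates, value_col)
  vals <- vals[!is.na(vals)]
  if (!is.null(strata)) {
    st <- strata[names(vals)]
    centers <- tapply(vals, st, median)
    vals <- vals - as.numeric(centers[match(st, names(centers))])
  }
  cohort <- names(vals)
  res <- purrr::pmap_dfr(
    calls[c("alteration_id", "kind", "carriers")],
    function(alteration_id, kind, carriers) {
      car <- intersect(carriers, cohort)
      non <- setdiff(cohort, car)
      base <- tibble(alteration_id = alteration_id, kind = kind,
                     n_carriers = length(car), n_noncarriers = length(non),
                     u_statistic = NA_real_, p = NA_real_,
                     direction = "none", testable = FALSE)
      if (length(car) == 0L || length(non) == 0L) return(base)
      mw <- mann_whitney(vals[car], vals[non])
      base %>% mutate(
        u_statistic = mw$u, p = mw$p, testable = TRUE,
        direction = ifelse(median(vals[car]) >= median(vals[non]),
                           "increases", "decreases")
      )
    }
  )
  res$q <- NA_real_
  fam <- if (bh_family == "kind") res$kind else "all"
  for (f in unique(fam)) {
    idx <- res$testable & fam == f
    res$q[idx] <- p.adjust(res$p[idx], method = "BH")
  }
  res %>%
    mutate(direction = ifelse(.data$testable & !is.na(.data$q) &
                                .data$q < q_threshold,
                              .data$direction, "none")) %>%
    select("alteration_id", "kind", "n_carriers", "n_noncarriers",
           "u_statistic", "p", "q", "direction", "testable")
}

#' Compare copy number between two labelled groups
#'
#' Two-sided Mann-Whitney U comparison of a copy-number quantity between
#' two groups (e.g. a molecular subtype vs the rest, or mtDNA-indel-mutated
#' vs unmutated samples).
#'
#' @param data Data frame holding both columns.
#' @param value Copy-number column; tidy-eval.
#' @param group Two-level grouping column; tidy-eval.
#'
#' @return A one-row tibble: `group_high` (the group with the larger
#'   median), `n1`, `n2`, `u_statistic`, `p`, `direction` (relative to the
#'   first group level, `increases`/`decreases`/`none` at p >= 1).
#' @export
group_compare <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- as.character(g[ok])
  lev <- sort(unique(g))
  if (length(lev) != 2L) {
    abort("group must have exactly two non-empty levels",
          class = "mtcn_config_error")
  }
  x <- v[g == lev[[1]]]; y <- v[g == lev[[2]]]
  mw <- mann_whitney(x, y)
  med_diff <- median(x) - median(y)
  tibble(
    group_high = if (med_diff >= 0) lev[[1]] else lev[[2]],
    n1 = length(x), n2 = length(y),
    u_statistic = mw$u, p = mw$p,
    direction = dplyr::case_when(
      med_diff > 0 ~ "increases",
      med_diff < 0 ~ "decreases",
      TRUE ~ "none"
    )
  )
}
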