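#' Read gene sets from a GMT file
#'
#' Standard tab-delimited GMT: set name, description, then member genes.
#' Duplicate set names are disambiguated by suffixing `.2`, `.3`, ... with a
#' message, so later entries are never silently dropped.
#'
#' @param path GMT file path.
#' @return A tibble with columns `gene_set`, `description`, `genes`
#'   (list-column of character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    abort(paste0(path, ": GMT line(s) ", paste(which(bad), collapse = ", "),
                 " have fewer than 3 fields"), class = "mtcn_parse_error")
  }
  name <- purrr::map_chr(parts, 1)
  if (anyDuplicated(name)) {
    inform("Duplicate gene-set names in GMT; suffixing later entries")
    name <- make.unique(name, sep = ".")
  }
  tibble(
    gene_set = name,
    description = purrr::map_chr(parts, 2),
    genes = purrr::map(parts, ~ unique(.x[-(1:2)][nzchar(.x[-(1:2)])]))
  )
}

as_expr_matrix <- function(expr) {
  if (is.matrix(expr)) return(expr)
  stopifnot(is.data.frame(expr))
  gene_col <- if ("gene_id" %in% names(expr)) "gene_id" else names(expr)[[1]]
  m <- as.matrix(expr[setdiff(names(expr), gene_col)])
  rownames(m) <- expr[[gene_col]]
  m
}

#' Filter lowly expressed genes
#'
#' Removes genes whose mean read count across samples is below
#' `min_mean_count` (strictly: a gene with mean exactly at the threshold is
#' retained). Low-count genes carry little rank information and inflate the
#' correlation screen.
#'
#' @param expr Expression matrix (genes x samples, rownames = gene ids) or a
#'   data frame whose first column (`gene_id`) holds gene ids.
#' @param min_mean_count Threshold on the per-gene mean (default 16).
#'
#' @return A filtered matrix (always a matrix, whatever the input form).
#' @export
filter_genes <- function(expr, min_mean_count = 16) {
  m <- as_expr_matrix(expr)
  if (any(m < 0, na.rm = TRUE)) {
    abort("Expression values must be non-negative", class = "mtcn_parse_error")
  }
  keep <- rowMeans(m, na.rm = TRUE) >= min_mean_count
  if (!any(keep)) {
    abort("No genes pass the mean-count filter", class = "mtcn_config_error")
  }
  m[keep, , drop = FALSE]
}

extract_cn_values <- function(copy_number, value_col = NULL) {
  if (is.numeric(copy_number) && !is.null(names(copy_number))) {
    return(copy_number)
  }
  stopifnot(is.data.frame(copy_number), "sample_id" %in% names(copy_number))
  if (is.null(value_col)) {
    value_col <- intersect(c("log10_m_corrected", "log10_m", "m"),
                           names(copy_number))[1]
    if (is.na(value_col)) {
      abort("No copy-number value column found", class = "mtcn_config_error")
    }
  }
  setNames(copy_number[[value_col]], copy_number$sample_id)
}

#' Per-gene Spearman correlation with mtDNA copy number
#'
#' Correlates each gene's expression with the per-sample copy number using
#' Spearman rank correlation, then applies the spurious-correlation guard:
#' genes with p > `zero_p` have their coefficient set to zero
#' (`rho_thresholded`), so downstream ranking is driven only by correlations
#' distinguishable from noise.
#'
#' @param expr Filtered expression matrix ([filter_genes()]).
#' @param copy_number Copy-number estimates (a tibble with `sample_id` and a
#'   value column — corrected log10 values preferred — or a named numeric
#'   vector). Being rank-based, the result is identical for `m` and
#'   `log10_m`.
#' @param value_col Optional explicit value column name.
#' @param min_samples Minimum overlapping samples (default 20); fewer is an
#'   error — the screen is underpowered below this.
#' @param zero_p Zeroing threshold on the uncorrected p-value (default 0.05).
#'
#' @return A tibble: `gene_id`, `rho`, `p`, `rho_thresholded`, `constant`
#'   (gene had zero variance; rho recorded as 0).
#' @export
gene_correlations <- function(expr, copy_number, value_col = NULL,
                              min_samples = 20, zero_p = 0.05) {
  m <- as_expr_matrix(expr)
  cn <- extract_cn_values(copy_number, value_col)
  cn <- cn[!is.na(cn)]
  shared <- intersect(colnames(m), names(cn))
  if (length(shared) < min_samples) {
    abort(paste0("Only ", length(shared), " overlapping samples; need at ",
                 "least ", min_samples), class = "mtcn_config_error")
  }
  m <- m[, shared, drop = FALSE]
  cn_rank <- rank(cn[shared])
  n <- length(shared)
  gene_ranks <- t(apply(m, 1L, rank))
  rho <- suppressWarnings(
    as.numeric(cor(t(gene_ranks), cn_rank, method = "pearson"))
  )
  constant <- is.na(rho)
  rho[constant] <- 0
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[constant] <- NA_real_
  tibble(
    gene_id = rownames(m),
    rho = rho,
    p = p,
    rho_thresholded = ifelse(!constant & p <= zero_p, rho, 0),
    constant = constant
  )
}

#' Mean-rank gene-set test
#'
#' Tests whether the genes of a set sit unusually high (`alternative =
#' "up"`) or low (`"down"`) in the ranking of a per-gene statistic, against
#' the competitive null that set membership is random. The p-value comes
#' from the Wilcoxon two-sample rank-sum normal approximation of set versus
#' complement, with midranks and the tie correction — ties are expected en
#' masse when the statistic is a thresholded correlation with many exact
#' zeros.
#'
#' @param statistics Named numeric vector, gene -> statistic (the gene
#'   universe).
#' @param gene_set Character vector of member genes; intersected with the
#'   universe, which must leave a non-empty proper subset.
#' @param alternative `"up"` or `"down"`.
#'
#' @return One-sided p-value in (0, 1).
#' @export
mean_rank_gene_set_test <- function(statistics, gene_set,
                                    alternative = c("up", "down")) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(statistics), !is.null(names(statistics)))
  in_set <- names(statistics) %in% gene_set
  n1 <- sum(in_set)
  N <- length(statistics)
  if (n1 == 0L) {
    abort("Gene set has no overlap with the statistic universe",
          class = "mtcn_config_error")
  }
  if (n1 == N) {
    abort("Gene set covers the entire universe; no complement to compare",
          class = "mtcn_config_error")
  }
  r <- rank(statistics)
  n2 <- N - n1
  T_set <- sum(r[in_set])
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (T_set - mu) / sqrt(sigma2)
  if (alternative == "up") pnorm(z, lower.tail = FALSE) else pnorm(z)
}

#' Scan a gene-set collection for enrichment in copy-number correlation
#'
#' Applies [mean_rank_gene_set_test()] to every gene set in both directions
#' over the thresholded per-gene correlations, adjusts all (set, direction)
#' p-values by Benjamini-Hochberg within the run, and reports the signed
#' enrichment score `-log10(q)` (positive for `up`, negative for `down`).
#' Tumor and normal tissue runs are kept separate via `tissue_label`.
#'
#' @param correlations Output of [gene_correlations()].
#' @param gene_sets A [read_gmt()] tibble.
#' @param tissue_label Optional label (`"tumor"`/`"normal"`) stamped on the
#'   output.
#'
#' @return A tibble with one row per (gene_set, direction): `gene_set`,
#'   `tissue`, `direction`, `n_genes_in_universe`, `p`, `q`,
#'   `enrichment_score`. Sets with no overlapping genes are skipped with a
#'   message.
#' @export
gene_set_scan <- function(correlations, gene_sets, tissue_label = NA_character_) {
  stats <- setNames(correlations$rho_thresholded, correlations$gene_id)
  universe <- names(stats)
  rows <- purrr::pmap_dfr(
    gene_sets[c("gene_set", "genes")],
    function(gene_set, genes) {
      overlap <- intersect(genes, universe)
      if (length(overlap) == 0L || length(overlap) == length(universe)) {
        inform(paste0("Skipping gene set '", gene_set,
                      "': no usable overlap with the expression universe"))
        return(tibble())
      }
      purrr::map_dfr(c("up", "down"), function(dir) {
        tibble(
          gene_set = gene_set,
          direction = dir,
          n_genes_in_universe = length(overlap),
          p = mean_rank_gene_set_test(stats, overlap, alternative = dir)
        )
      })
    }
  )
  if (nrow(rows) == 0L) {
    abort("No gene set overlaps the expression universe",
          class = "mtcn_config_error")
  }
  rows %>%
    mutate(
      tissue = tissue_label,
      q = p.adjust(.data$p, method = "BH"),
      enrichment_score = ifelse(.data$direction == "up", 1, -1) *
        -log10(.data$q)
    ) %>%
    select("gene_set", "tissue", "direction", "n_genes_in_universe", "p",
           "q", "enrichment_score") %>%
    arrange(.data$q, .data$gene_set)
}

#' Report the correlation of a single gene with copy number
#'
#' Returns the unthresholded Spearman rho and p for one gene (e.g. the
#' mitochondrial transcription factor TFAM), or a not-available row if the
#' gene did not survive the expression filter.
#'
#' @param correlations Output of [gene_correlations()].
#' @param gene_id Gene identifier.
#'
#' @return A one-row tibble: `gene_id`, `rho`, `p`, `available`.
#' @export
single_gene_report <- function(correlations, gene_id) {
  row <- correlations[correlations$gene_id == gene_id, , drop = FALSE]
  if (nrow(row) == 0L) {
    return(tibble(gene_id = gene_id, rho = NA_real_, p = NA_real_,
                  available = FALSE))
  }
  tibble(gene_id = gene_id, rho = row$rho[[1]], p = row$p[[1]],
         available = TRUE)
}
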