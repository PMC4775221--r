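#' Default mitochondrial contig aliases
#'
#' Contig names commonly used for the mitochondrial genome across GRCh37/38
#' style references. The first alias found in a BAM header (or counts table)
#' is taken as the mitochondrial contig.
#'
#' @return Character vector of contig names.
#' @export
mt_contig_names <- function() c("MT", "chrM", "chrMT", "M")

#' Default regex for non-primary contigs
#'
#' Matches decoys, unplaced/unlocalized scaffolds, alternate haplotypes and
#' viral decoys that should not contribute to the nuclear read count. The
#' nuclear denominator contrasts the mitochondrial genome against primary
#' autosomes and sex chromosomes only.
#'
#' @return A single regular expression string.
#' @export
nonprimary_contig_regex <- function() {
  "^(GL|KI|KN|JH|NC_|hs37d5|NT_)|_(alt|random|decoy|fix)$|hap[0-9]+|^chrUn|^chrEBV$|^EBV$"
}

#' Count quality-filtered reads per contig in a BAM file
#'
#' Counts primary alignments per contig after applying the read filters used
#' for depth-ratio mtDNA copy number estimation: reads must pass platform
#' quality control, not be marked duplicate, be properly paired, and have
#' Phred-scaled mapping quality strictly greater than `mapq_min`. Secondary
#' and supplementary alignments are always excluded. The pairing and mapping
#' quality requirements suppress reads attracted by nuclear integrations of
#' mitochondrial sequence (NUMTs).
#'
#' @param bam_file Path to a coordinate-sorted BAM file.
#' @param sample_id Sample identifier attached to the output rows.
#' @param mt_names Candidate mitochondrial contig names; at least one must be
#'   present in the BAM header.
#' @param mapq_min Reads with MAPQ strictly greater than this are kept.
#'   Default 30 (a 99.9% correct-alignment probability); 20 has been shown
#'   adequate in prior work and can be set here.
#'
#' @return A tibble with columns `sample_id`, `contig`, `read_count`, one row
#'   per contig in the BAM header (zero counts included).
#'
#' @details Single-end data are refused: the properly-paired filter would
#'   silently remove every read, so an unpaired file is a configuration
#'   error, not an empty result.
#' @seealso [summarise_mt_counts()] to reduce per-contig counts to the
#'   mitochondrial (`rm`) and nuclear (`rn`) totals.
#' @export
count_filtered_reads <- function(bam_file, sample_id,
                                 mt_names = mt_contig_names(),
                                 mapq_min = 30) {
  if (!file.exists(bam_file)) {
    abort(paste0("BAM file not found: ", bam_file), class = "mtcn_io_error")
  }
  hdr <- tryCatch(
    Rsamtools::scanBamHeader(bam_file)[[1]]$targets,
    error = function(e) {
      abort(paste0("Cannot read BAM header from ", bam_file, ": ",
                   conditionMessage(e)), class = "mtcn_io_error")
    }
  )
  contigs <- names(hdr)
  if (!any(mt_names %in% contigs)) {
    abort(paste0("No mitochondrial contig (", paste(mt_names, collapse = ", "),
                 ") in BAM header of ", bam_file),
          class = "mtcn_config_error")
  }

  mapped <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  n_unpaired <- Rsamtools::countBam(
    bam_file,
    param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isPaired = FALSE)
    )
  )$records
  n_paired <- Rsamtools::countBam(
    bam_file,
    param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isPaired = TRUE)
    )
  )$records
  if (n_paired == 0L && n_unpaired > 0L) {
    abort(paste0("BAM ", bam_file, " contains only unpaired reads; the ",
                 "properly-paired filter would remove everything. ",
                 "Single-end data are not supported."),
          class = "mtcn_config_error")
  }

  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isProperPair = TRUE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = FALSE,
    isNotPassingQualityControls = FALSE
  )
  param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = mapq_min + 1L,
                                   what = "rname")
  rname <- Rsamtools::scanBam(bam_file, param = param)[[1]]$rname
  tab <- table(factor(rname, levels = contigs))
  tibble(
    sample_id = sample_id,
    contig = contigs,
    read_count = as.integer(tab[contigs])
  )
}

#' Reduce per-contig counts to mitochondrial and nuclear totals
#'
#' Splits filtered per-contig read counts into the mitochondrial read count
#' `rm` and the nuclear read count `rn` (sum over all primary non-MT
#' contigs). Decoy/alternate contigs matching `exclude_regex` contribute to
#' neither.
#'
#' @param counts A tibble as returned by [count_filtered_reads()] or
#'   [read_counts_table()]: columns `sample_id`, `contig`, `read_count`.
#' @param mt_names Candidate mitochondrial contig names.
#' @param exclude_regex Regex of non-primary contigs dropped from `rn`.
#'
#' @return A tibble with one row per sample: `sample_id`, `rm`, `rn`.
#' @export
summarise_mt_counts <- function(counts,
                                mt_names = mt_contig_names(),
                                exclude_regex = nonprimary_contig_regex()) {
  stopifnot(all(c("sample_id", "contig", "read_count") %in% names(counts)))
  if (any(counts$read_count < 0)) {
    abort("read_count must be non-negative", class = "mtcn_parse_error")
  }
  present_mt <- intersect(mt_names, unique(counts$contig))
  if (length(present_mt) == 0L) {
    abort(paste0("No mitochondrial contig (", paste(mt_names, collapse = ", "),
                 ") in counts table"), class = "mtcn_config_error")
  }
  counts %>%
    mutate(
      is_mt = .data$contig %in% present_mt,
      is_excluded = !.data$is_mt & grepl(exclude_regex, .data$contig)
    ) %>%
    group_by(.data$sample_id) %>%
    summarise(
      rm = sum(.data$read_count[.data$is_mt]),
      rn = sum(.data$read_count[!.data$is_mt & !.data$is_excluded]),
      .groups = "drop"
    )
}

read_tsv_quiet <- function(path, col_types) {
  # column presence and value validity are checked explicitly afterwards
  suppressWarnings(
    readr::read_tsv(path, col_types = col_types, progress = FALSE,
                    na = c("", "NA"))
  )
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(paste0(path, ": missing column(s) ", paste(missing, collapse = ", ")),
          class = "mtcn_parse_error")
  }
}

fail_rows <- function(bad, path, column, why) {
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    rows <- which(bad | is.na(bad))
    abort(paste0(path, ": column '", column, "' ", why, " at row(s) ",
                 paste(head(rows, 5), collapse = ", "),
                 if (length(rows) > 5) " ..."),
          class = "mtcn_parse_error")
  }
}

#' Read a per-contig read-count table
#'
#' @param path Tab-delimited file with header `sample_id`, `contig`,
#'   `read_count`.
#' @return A validated tibble with those columns.
#' @export
read_counts_table <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    sample_id = readr::col_character(),
    contig = readr::col_character(),
    read_count = readr::col_double(),
    .default = readr::col_character()
  ))
  check_columns(df, c("sample_id", "contig", "read_count"), path)
  fail_rows(df$read_count < 0 | df$read_count != floor(df$read_count),
            path, "read_count", "must be a non-negative integer")
  dup <- duplicated(df[c("sample_id", "contig")])
  fail_rows(dup, path, "sample_id/contig", "is duplicated")
  df %>% mutate(read_count = as.integer(.data$read_count)) %>% as_tibble()
}

sample_type_levels <- function() c("tumor", "normal_tissue", "blood")

#' Read a sample metadata table
#'
#' @param path Tab-delimited file with header `sample_id`, `patient_id`,
#'   `sample_type` (one of `tumor`, `normal_tissue`, `blood`), `platform`
#'   (`WXS` or `WGS`), `center`, `plate_id`. An optional `cancer_type`
#'   column is carried through and used to stratify downstream fits.
#' @return A validated tibble.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(.default = readr::col_character()))
  check_columns(df, c("sample_id", "patient_id", "sample_type", "platform",
                      "center", "plate_id"), path)
  fail_rows(!df$sample_type %in% sample_type_levels(), path, "sample_type",
            paste0("must be one of ", paste(sample_type_levels(), collapse = ", ")))
  fail_rows(!df$platform %in% c("WXS", "WGS"), path, "platform",
            "must be WXS or WGS")
  fail_rows(duplicated(df$sample_id), path, "sample_id", "is duplicated")
  as_tibble(df)
}

#' Read a tumor purity/ploidy table
#'
#' @param path Tab-delimited file with header `sample_id`, `purity`
#'   (fraction in \[0, 1\]), `ploidy` (positive; average tumor genome copy
#'   number).
#' @return A validated tibble.
#' @export
read_purity_ploidy <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    sample_id = readr::col_character(),
    purity = readr::col_double(),
    ploidy = readr::col_double()
  ))
  check_columns(df, c("sample_id", "purity", "ploidy"), path)
  fail_rows(df$purity < 0 | df$purity > 1, path, "purity",
            "must lie in [0, 1]")
  fail_rows(df$ploidy <= 0, path, "ploidy", "must be positive")
  fail_rows(duplicated(df$sample_id), path, "sample_id", "is duplicated")
  as_tibble(df)
}

#' Read a survival table
#'
#' @param path Tab-delimited file with header `patient_id`, `time_days`
#'   (non-negative), `event` (0 censored / 1 event).
#' @return A validated tibble.
#' @export
read_survival <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    patient_id = readr::col_character(),
    time_days = readr::col_double(),
    event = readr::col_double()
  ))
  check_columns(df, c("patient_id", "time_days", "event"), path)
  fail_rows(df$time_days < 0, path, "time_days", "must be non-negative")
  fail_rows(!df$event %in% c(0, 1), path, "event", "must be 0 or 1")
  as_tibble(df)
}
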