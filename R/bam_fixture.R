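#' Specify reads for a synthetic BAM fixture
#'
#' Convenience constructor for one row of a fixture specification: `n`
#' reads on `contig` with the given MAPQ and flag properties.
#'
#' @param contig Contig name.
#' @param n Number of alignment records.
#' @param mapq Mapping quality (default 60).
#' @param proper Properly paired (default TRUE).
#' @param duplicate Marked duplicate (default FALSE).
#' @param qcfail Failed platform QC (default FALSE).
#' @param secondary Secondary alignment (default FALSE).
#' @param supplementary Supplementary alignment (default FALSE).
#' @param paired Read is paired at all (default TRUE; unpaired reads model
#'   single-end data).
#' @return A one-row tibble; row-bind several to build a full spec.
#' @export
bam_read_spec <- function(contig, n, mapq = 60, proper = TRUE,
                          duplicate = FALSE, qcfail = FALSE,
                          secondary = FALSE, supplementary = FALSE,
                          paired = TRUE) {
  tibble(contig = contig, n = as.integer(n), mapq = as.integer(mapq),
         proper = proper, duplicate = duplicate, qcfail = qcfail,
         secondary = secondary, supplementary = supplementary,
         paired = paired)
}

sam_flag_of <- function(paired, proper, duplicate, qcfail, secondary,
                        supplementary) {
  flag <- 0L
  if (paired) flag <- flag + 1L + 32L + 64L   # paired, mate reverse, first
  if (paired && proper) flag <- flag + 2L
  if (secondary) flag <- flag + 256L
  if (qcfail) flag <- flag + 512L
  if (duplicate) flag <- flag + 1024L
  if (supplementary) flag <- flag + 2048L
  flag
}

#' Generate a miniature indexed BAM fixture
#'
#' Writes a valid, sorted, indexed BAM containing exactly the alignment
#' records described by `spec` on a miniature reference: one nuclear-like
#' contig and one 16,569 bp mitochondrial contig (plus any extra contigs
#' named in the spec). Used to exercise the read-counting filters against a
#' file whose correct answer is known by construction.
#'
#' @param spec A tibble of [bam_read_spec()] rows. May have zero rows (an
#'   empty, valid BAM results).
#' @param dir Output directory (default a fresh tempdir subdirectory).
#' @param seed Seed for read placement (default 1).
#' @param contig_lengths Named lengths of header contigs; defaults provide
#'   `chr1` (100 kb) and `MT` (16,569 bp), extended automatically for other
#'   contig names in the spec.
#'
#' @return A list: `bam` (path), `sam` (path of the SAM text it was built
#'   from, kept for independent re-parsing), `records` (tibble of the
#'   emitted records with their flags).
#' @export
generate_bam_fixture <- function(spec, dir = tempfile("bamfix"), seed = 1,
                                 contig_lengths = c(chr1 = 100000L,
                                                    MT = 16569L)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  extra <- setdiff(unique(spec$contig), names(contig_lengths))
  if (length(extra) > 0L) {
    contig_lengths <- c(contig_lengths, setNames(rep(50000L, length(extra)),
                                                 extra))
  }
  if (nrow(spec) > 0 && !all(spec$contig %in% names(contig_lengths))) {
    abort("Spec names a contig absent from contig_lengths",
          class = "mtcn_config_error")
  }
  read_len <- 50L
  records <- if (nrow(spec) == 0L) {
    tibble(qname = character(), flag = integer(), contig = character(),
           pos = integer(), mapq = integer())
  } else {
    purrr::pmap_dfr(spec, function(contig, n, mapq, proper, duplicate,
                                   qcfail, secondary, supplementary,
                                   paired) {
      if (n == 0L) return(tibble())
      maxpos <- contig_lengths[[contig]] - read_len - 200L
      tibble(
        qname = paste0("r", contig, "_", mapq, "_",
                       sam_flag_of(paired, proper, duplicate, qcfail,
                                   secondary, supplementary),
                       "_", seq_len(n)),
        flag = sam_flag_of(paired, proper, duplicate, qcfail, secondary,
                           supplementary),
        contig = contig,
        pos = sort(sample.int(max(maxpos, 1L), n, replace = TRUE)),
        mapq = mapq
      )
    })
  }
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths), contig_lengths)
  )
  body <- if (nrow(records) == 0L) character() else {
    paired <- bitwAnd(records$flag, 1L) > 0L
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t%d\t%s\t%s",
            records$qname, records$flag, records$contig, records$pos,
            records$mapq, read_len,
            ifelse(paired, "=", "*"),
            ifelse(paired, records$pos + 100L, 0L),
            ifelse(paired, 150L, 0L),
            strrep("A", read_len), strrep("I", read_len))
  }
  sam <- file.path(dir, "fixture.sam")
  writeLines(c(header, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "fixture"), overwrite = TRUE,
                          indexDestination = TRUE)
  list(bam = bam, sam = sam, records = records)
}
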