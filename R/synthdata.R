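MT_LENGTH <- 16569L
HAPLOID_NUCLEAR_LENGTH <- 3.1e9

# relative copy number implied by C mtDNA copies per diploid cell
m_of_copies <- function(copies) copies * MT_LENGTH / (2 * HAPLOID_NUCLEAR_LENGTH)

#' Simulate a synthetic sequencing cohort with known ground truth
#'
#' Generates every input the pipeline consumes — per-contig read counts,
#' sample metadata, purity/ploidy, gene expression with planted gene sets,
#' mutation calls, a binary CNA matrix, and survival times — from an
#' explicit generative model, and records all latent parameters so each
#' stage's estimates can be scored against truth.
#'
#' The model: each patient carries a baseline log10 mtDNA copies-per-cell
#' drawn around `mean_copies` (tissue cells typically hold hundreds to a
#' couple of thousand copies); blood is shifted by `blood_shift` and tumors
#' by `tumor_log2_shift` (in log2, the scale of the paired ratio). Plate
#' effects act multiplicatively in log10 space on the *observed* read
#' ratio; platform capture efficiency scales the mitochondrial read yield
#' (WGS sequences mtDNA uniformly, exome capture recovers it only
#' off-target). Tumor reads are generated under the true purity/ploidy mix
#' so the effective-ploidy correction is genuinely needed. Nuclear read
#' totals are Poisson; mitochondrial counts are Poisson (optionally
#' gamma-overdispersed). Planted gene sets have expression monotone in true
#' copy number; a planted alteration shifts carriers' tumor copy number;
#' survival times are exponential with log-hazard linear in log10 copy
#' number.
#'
#' @param n_patients Patients per cancer type (default 100).
#' @param cancer_types Character vector of cohort labels (default "SYNTH").
#' @param seed Master seed; every random stream derives from it, so a fixed
#'   (config, seed) pair reproduces the cohort exactly.
#' @param platform `"WXS"` or `"WGS"` for the cohort, or `"both"` to
#'   profile every sample on both platforms (for concordance checks).
#' @param n_plates Number of sequencing plates (default 6).
#' @param plate_sd SD of plate effects in log10 space (default 0.15).
#' @param mean_copies Mean tissue mtDNA copies per cell (default 1000).
#' @param sd_patient SD of patient baselines, log10 (default 0.2).
#' @param sd_sample Within-patient sample SD, log10 (default 0.11; gives a
#'   paired log2-ratio SD near 0.5).
#' @param blood_shift Blood tissue effect, log10 (default -0.3).
#' @param tumor_log2_shift Tumor vs matched-normal shift, log2 (default 0 =
#'   no depletion; the depletion studies use -0.5).
#' @param p_normal,p_blood Probability a patient contributes an
#'   adjacent-normal / blood sample (defaults 0.7, 0.7).
#' @param nuclear_depth Expected filtered nuclear read count per sample
#'   (default 1e6).
#' @param capture_wxs,capture_wgs Platform mtDNA capture efficiency
#'   (defaults 0.05, 1).
#' @param overdispersion Gamma overdispersion of mitochondrial counts; 0 =
#'   pure Poisson (default 0).
#' @param n_genes Genes in the expression matrix (default 400).
#' @param n_decoy_sets Unassociated gene sets (default 50).
#' @param set_size Genes per set (default 20).
#' @param planted_set_effect Slope of planted-set log2 expression per unit
#'   log10 copy number; 0 disables the planted set (default 0).
#' @param mutation_shift Planted mutated gene's carrier shift, log10
#'   copy number (default 0 = none).
#' @param cna_shift Planted CNA carrier shift, log10 (default 0 = none).
#' @param carrier_fraction Fraction of tumors carrying each planted
#'   alteration (default 0.3).
#' @param survival_gamma Log-hazard per unit log10 copy number (default 0).
#' @param base_hazard Baseline hazard per day (default log(2)/500).
#' @param censor_time Administrative censoring time in days (default 1500).
#'
#' @return A list of class `mtcn_cohort` with elements `counts` (long
#'   per-contig tibble), `meta`, `purity`, `expression` (matrix),
#'   `gene_sets`, `maf`, `cna`, `survival`, and `truth` (all latent
#'   parameters, including per-sample true `m`).
#' @seealso [write_cohort()] to materialize the cohort as the tab-delimited
#'   files the readers consume.
#' @export
simulate_cohort <- function(n_patients = 100,
                            cancer_types = "SYNTH",
                            seed = 1,
                            platform = c("WXS", "WGS", "both"),
                            n_plates = 6,
                            plate_sd = 0.15,
                            mean_copies = 1000,
                            sd_patient = 0.2,
                            sd_sample = 0.11,
                            blood_shift = -0.3,
                            tumor_log2_shift = 0,
                            p_normal = 0.7,
                            p_blood = 0.7,
                            nuclear_depth = 1e6,
                            capture_wxs = 0.05,
                            capture_wgs = 1,
                            overdispersion = 0,
                            n_genes = 400,
                            n_decoy_sets = 50,
                            set_size = 20,
                            planted_set_effect = 0,
                            mutation_shift = 0,
                            cna_shift = 0,
                            carrier_fraction = 0.3,
                            survival_gamma = 0,
                            base_hazard = log(2) / 500,
                            censor_time = 1500) {
  platform <- match.arg(platform)
  if (n_patients < 1 || n_plates < 1) {
    abort("n_patients and n_plates must be positive",
          class = "mtcn_config_error")
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  stream_seeds <- sample.int(.Machine$integer.max - 1L, 8L)

  # --- design: patients, samples, plates -------------------------------
  set.seed(stream_seeds[[1]])
  alpha_true <- setNames(rnorm(n_plates, 0, plate_sd),
                         sprintf("plate%02d", seq_len(n_plates)))
  alpha_true <- alpha_true - mean(alpha_true)
  design <- purrr::map_dfr(cancer_types, function(ct) {
    purrr::map_dfr(seq_len(n_patients), function(i) {
      pid <- sprintf("%s-P%04d", ct, i)
      types <- c("tumor",
                 if (runif(1) < p_normal) "normal_tissue",
                 if (runif(1) < p_blood) "blood")
      tissue_plate <- sample(names(alpha_true), 1)
      tibble(
        patient_id = pid, cancer_type = ct, sample_type = types,
        plate_id = ifelse(types == "blood",
                          sample(names(alpha_true), length(types),
                                 replace = TRUE),
                          tissue_plate)
      )
    })
  }) %>%
    mutate(sample_id = paste0(.data$patient_id, "-",
                              dplyr::recode(.data$sample_type,
                                            tumor = "T", normal_tissue = "N",
                                            blood = "B")))

  # --- latent copy number ----------------------------------------------
  set.seed(stream_seeds[[2]])
  baseline <- setNames(rnorm(length(unique(design$patient_id)),
                             log10(mean_copies), sd_patient),
                       unique(design$patient_id))
  tumor_shift_l10 <- tumor_log2_shift * log10(2)
  design <- design %>%
    mutate(
      log10_copies = baseline[.data$patient_id] +
        rnorm(n(), 0, sd_sample) +
        ifelse(.data$sample_type == "blood", blood_shift, 0) +
        ifelse(.data$sample_type == "tumor", tumor_shift_l10, 0)
    )

  # --- purity/ploidy ----------------------------------------------------
  set.seed(stream_seeds[[3]])
  tumors <- design$sample_id[design$sample_type == "tumor"]
  purity <- tibble(
    sample_id = tumors,
    purity = rbeta(length(tumors), 6, 3),
    ploidy = sample(c(2, 3, 4), length(tumors), replace = TRUE,
                    prob = c(0.6, 0.25, 0.15))
  )

  # --- planted alterations (shift tumor copy number) --------------------
  set.seed(stream_seeds[[4]])
  mut_carriers <- sort(sample(tumors, round(carrier_fraction * length(tumors))))
  cna_carriers <- sort(sample(tumors, round(carrier_fraction * length(tumors))))
  shift <- setNames(numeric(nrow(design)), design$sample_id)
  shift[mut_carriers] <- shift[mut_carriers] + mutation_shift
  shift[cna_carriers] <- shift[cna_carriers] + cna_shift
  design$log10_copies <- design$log10_copies + shift[design$sample_id]
  design$m_true <- m_of_copies(10^design$log10_copies)

  # --- reads ------------------------------------------------------------
  set.seed(stream_seeds[[5]])
  platforms <- if (platform == "both") c("WXS", "WGS") else platform
  capture <- c(WXS = capture_wxs, WGS = capture_wgs)
  obs <- purrr::map_dfr(platforms, function(pf) {
    d <- design
    d$platform <- pf
    if (platform == "both") d$sample_id <- paste0(d$sample_id, "-", pf)
    R_true <- rep(1, nrow(d))
    it <- d$sample_type == "tumor"
    pp_key <- sub("-(WXS|WGS)$", "", d$sample_id[it])
    pp <- purity[match(pp_key, purity$sample_id), ]
    R_true[it] <- (pp$purity * pp$ploidy + (1 - pp$purity) * 2) / 2
    rn <- rpois(nrow(d), nuclear_depth)
    lambda_m <- rn * d$m_true * capture[[pf]] *
      10^alpha_true[d$plate_id] / R_true
    if (overdispersion > 0) {
      lambda_m <- lambda_m * stats::rgamma(nrow(d), shape = 1 / overdispersion,
                                           scale = overdispersion)
    }
    d$rn <- rn
    d$rm <- rpois(nrow(d), lambda_m)
    d$R_true <- R_true
    d
  })
  # spread nuclear reads over a few contigs plus a decoy, mt reads on MT
  counts <- purrr::map_dfr(seq_len(nrow(obs)), function(i) {
    nuc <- stats::rmultinom(1, obs$rn[[i]], prob = rep(1, 4))[, 1]
    tibble(
      sample_id = obs$sample_id[[i]],
      contig = c("MT", paste0("chr", 1:4), "GL000207.1"),
      read_count = c(obs$rm[[i]], nuc, rpois(1, 50))
    )
  })
  meta <- obs %>%
    mutate(center = "CENTER1") %>%
    select("sample_id", "patient_id", "sample_type", "platform", "center",
           "plate_id", "cancer_type")
  if (platform == "both") {
    purity <- bind_rows(
      purity %>% mutate(sample_id = paste0(.data$sample_id, "-WXS")),
      purity %>% mutate(sample_id = paste0(.data$sample_id, "-WGS"))
    )
  }

  # --- expression with planted gene sets --------------------------------
  set.seed(stream_seeds[[6]])
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  set_size <- min(set_size, max(2L, floor(n_genes / 2)))
  n_sets <- n_decoy_sets + 1
  membership <- purrr::map(seq_len(n_sets),
                           ~ sort(sample(genes, set_size)))
  names(membership) <- c("PLANTED_SET",
                         sprintf("DECOY_SET_%02d", seq_len(n_decoy_sets)))
  gene_sets <- tibble(
    gene_set = names(membership),
    description = ifelse(names(membership) == "PLANTED_SET",
                         "expression monotone in mtDNA copy number",
                         "no association"),
    genes = membership
  )
  expr_samples <- obs$sample_id[obs$sample_type == "tumor" &
                                  obs$platform == platforms[[1]]]
  expr_truth <- obs$log10_copies[match(expr_samples, obs$sample_id)]
  base_mean <- rlnorm(n_genes, log(150), 0.8)
  base_mean[sample.int(n_genes, round(0.1 * n_genes))] <-
    runif(round(0.1 * n_genes), 1, 10)   # genes meant to fail the filter
  slope <- setNames(numeric(n_genes), genes)
  slope[membership$PLANTED_SET] <- planted_set_effect
  centered <- expr_truth - mean(expr_truth)
  lambda <- outer(base_mean, rep(1, length(expr_samples))) *
    2^(outer(slope[genes], centered)) *
    exp(matrix(rnorm(n_genes * length(expr_samples), 0, 0.3),
               n_genes, length(expr_samples)))
  expression <- matrix(rpois(length(lambda), lambda),
                       nrow = n_genes, dimnames = list(genes, expr_samples))

  # --- mutation calls (MAF) and CNA matrix ------------------------------
  set.seed(stream_seeds[[7]])
  planted_gene <- "MUTGENE1"
  decoy_genes <- sprintf("BG_GENE%02d", 1:10)
  maf_rows <- list(
    tibble(Hugo_Symbol = planted_gene, Tumor_Sample_Barcode = mut_carriers,
           Variant_Classification = "Missense_Mutation")
  )
  for (g in decoy_genes) {
    car <- sample(tumors, max(1, round(0.08 * length(tumors))))
    maf_rows[[length(maf_rows) + 1]] <- tibble(
      Hugo_Symbol = g, Tumor_Sample_Barcode = car,
      Variant_Classification = sample(c("Missense_Mutation", "Silent"),
                                      length(car), replace = TRUE,
                                      prob = c(0.8, 0.2))
    )
  }
  maf <- bind_rows(maf_rows)
  if (platform == "both") {
    maf$Tumor_Sample_Barcode <- paste0(maf$Tumor_Sample_Barcode, "-",
                                       platforms[[1]])
  }
  cna_ids <- c("PLANTED_CNA", sprintf("DECOY_CNA_%02d", 1:5))
  cna_carrier_sets <- c(
    list(cna_carriers),
    purrr::map(1:5, ~ sort(sample(tumors,
                                  round(carrier_fraction * length(tumors)))))
  )
  eff_tumors <- if (platform == "both") paste0(tumors, "-", platforms[[1]]) else tumors
  cna <- tibble(
    alteration_id = cna_ids,
    kind = "cna",
    n_carriers = lengths(cna_carrier_sets),
    carriers = purrr::map(cna_carrier_sets, function(s) {
      if (platform == "both") paste0(s, "-", platforms[[1]]) else s
    }),
    untestable = lengths(cna_carrier_sets) == 0L
  )

  # --- survival ---------------------------------------------------------
  set.seed(stream_seeds[[8]])
  surv_d <- obs %>%
    filter(.data$sample_type == "tumor",
           .data$platform == platforms[[1]]) %>%
    distinct(.data$patient_id, .keep_all = TRUE)
  lin <- survival_gamma * (surv_d$log10_copies - mean(surv_d$log10_copies))
  t_event <- rexp(nrow(surv_d), rate = base_hazard * exp(lin))
  survival_tbl <- tibble(
    patient_id = surv_d$patient_id,
    time_days = pmin(t_event, censor_time),
    event = as.integer(t_event <= censor_time)
  )

  truth <- list(
    seed = seed,
    alpha = alpha_true,
    blood_shift = blood_shift,
    tumor_log2_shift = tumor_log2_shift,
    plate_sd = plate_sd,
    capture = capture,
    samples = obs %>% select("sample_id", "patient_id", "cancer_type",
                             "sample_type", "platform", "plate_id",
                             "log10_copies", "m_true", "R_true"),
    planted_set = "PLANTED_SET",
    planted_set_effect = planted_set_effect,
    planted_mutation = planted_gene,
    mutation_shift = mutation_shift,
    mutation_carriers = mut_carriers,
    planted_cna = "PLANTED_CNA",
    cna_shift = cna_shift,
    cna_carriers = cna_carriers,
    survival_gamma = survival_gamma
  )
  structure(
    list(counts = counts, meta = meta, purity = purity,
         expression = expression, gene_sets = gene_sets, maf = maf,
         cna = cna, survival = survival_tbl, truth = truth),
    class = "mtcn_cohort"
  )
}

#' @export
print.mtcn_cohort <- function(x, ...) {
  cat("<mtcn_cohort> ", nrow(x$meta), " samples, ",
      length(unique(x$meta$patient_id)), " patients, ",
      length(unique(x$meta$plate_id)), " plates, seed ", x$truth$seed,
      "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Materializes a [simulate_cohort()] result as the tab-delimited files the
#' package readers consume: `counts.tsv`, `meta.tsv`, `purity.tsv`,
#' `expr.tsv`, `muts.maf`, `cna.tsv`, `survival.tsv`, `sets.gmt`, and
#' `truth.json` (requires jsonlite).
#'
#' @param cohort An `mtcn_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mtcn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_tsv(df, file.path(dir, name), progress = FALSE)
  }
  w(cohort$counts, "counts.tsv")
  w(cohort$meta, "meta.tsv")
  w(cohort$purity, "purity.tsv")
  w(cohort$survival, "survival.tsv")
  w(cohort$maf, "muts.maf")
  expr <- as_tibble(cohort$expression, rownames = "gene_id")
  w(expr, "expr.tsv")
  cna_wide <- cohort$cna
  samples <- sort(unique(unlist(cna_wide$carriers)))
  mat <- purrr::map_dfr(seq_len(nrow(cna_wide)), function(i) {
    row <- as.list(setNames(as.integer(samples %in% cna_wide$carriers[[i]]),
                            samples))
    tibble(alteration_id = cna_wide$alteration_id[[i]], !!!row)
  })
  w(mat, "cna.tsv")
  gmt_lines <- purrr::pmap_chr(
    cohort$gene_sets[c("gene_set", "description", "genes")],
    function(gene_set, description, genes) {
      paste(c(gene_set, description, genes), collapse = "\t")
    }
  )
  writeLines(gmt_lines, file.path(dir, "sets.gmt"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- cohort$truth
    truth$alpha <- as.list(truth$alpha)
    truth$capture <- as.list(truth$capture)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(dir)
}
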