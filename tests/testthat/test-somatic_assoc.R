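test_that("mutation calls apply class, hypermutator and frequency filters", {
  maf <- dplyr::bind_rows(
    tibble::tibble(Hugo_Symbol = "FREQ", Tumor_Sample_Barcode = paste0("s", 1:6),
                   Variant_Classification = "Missense_Mutation"),
    tibble::tibble(Hugo_Symbol = "RARE", Tumor_Sample_Barcode = paste0("s", 1:3),
                   Variant_Classification = "Nonsense_Mutation"),
    tibble::tibble(Hugo_Symbol = "SILENT_ONLY",
                   Tumor_Sample_Barcode = paste0("s", 1:50),
                   Variant_Classification = "Silent"),
    # make sure every patient appears in the MAF
    tibble::tibble(Hugo_Symbol = "BGGENE",
                   Tumor_Sample_Barcode = paste0("s", 1:100),
                   Variant_Classification = "Silent")
  )
  calls <- build_mutation_calls(maf)
  # denominator 100 patients: FREQ at 6% kept, RARE at 3% dropped,
  # silent-only gene has no coding carriers
  expect_equal(calls$alteration_id, "FREQ")
  expect_equal(calls$n_carriers, 6L)
  expect_equal(attr(calls, "n_patients"), 100L)

  # a hypermutator is excluded before counting
  hyper <- tibble::tibble(
    Hugo_Symbol = sprintf("H%04d", 1:700), Tumor_Sample_Barcode = "s1",
    Variant_Classification = "Missense_Mutation"
  )
  calls2 <- build_mutation_calls(dplyr::bind_rows(maf, hyper))
  expect_equal(attr(calls2, "n_hypermutators"), 1L)
  expect_equal(attr(calls2, "n_patients"), 99L)
  expect_false("s1" %in% calls2$carriers[[1]])

  expect_warning(
    build_mutation_calls(tibble::tibble(
      Hugo_Symbol = "X", Tumor_Sample_Barcode = paste0("s", 1:10),
      Variant_Classification = c(rep("Missense_Mutation", 9), "Weird_Class")
    )),
    "Unknown"
  )
})

test_that("a gene mutated in exactly 4% of patients is dropped (strict >4%)", {
  maf <- dplyr::bind_rows(
    tibble::tibble(Hugo_Symbol = "AT4PCT", Tumor_Sample_Barcode = paste0("s", 1:4),
                   Variant_Classification = "Missense_Mutation"),
    tibble::tibble(Hugo_Symbol = "BG", Tumor_Sample_Barcode = paste0("s", 1:100),
                   Variant_Classification = "Silent")
  )
  expect_equal(nrow(build_mutation_calls(maf)), 0L)
})

test_that("CNA matrices must be binary and empty rows are flagged untestable", {
  wide <- tibble::tibble(
    alteration_id = c("a1", "a2", "a3"),
    s1 = c("1", "0", "0"), s2 = c("0", "1", "0"), s3 = c("1", "0", "0")
  )
  calls <- read_cna_calls(wide)
  expect_equal(nrow(calls), 3L)
  expect_equal(calls$carriers[[1]], c("s1", "s3"))
  expect_true(calls$untestable[[3]])

  bad <- wide
  bad$s1[1] <- "2"
  expect_error(read_cna_calls(bad), class = "mtcn_parse_error")
})

test_that("completely separated groups reach the minimal attainable exact p", {
  est <- tibble::tibble(sample_id = paste0("s", 1:20),
                        log10_m = c(1:10 / 100 + 2, 1:10 / 100 + 3))
  calls <- tibble::tibble(alteration_id = "ALT", kind = "cna",
                          n_carriers = 10L,
                          carriers = list(paste0("s", 11:20)))
  res <- association_scan(calls, est)
  # 10 vs 10, disjoint supports: p = 2 / choose(20, 10)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$p, oracle_mann_whitney_p(est$log10_m[11:20],
                                            est$log10_m[1:10]),
               tolerance = 1e-12)
  expect_equal(res$direction, "increases")
})

test_that("Mann-Whitney p matches exact enumeration across group sizes up to 12", {
  set.seed(29)
  for (sizes in list(c(4, 5), c(6, 6), c(8, 3), c(10, 10), c(12, 12))) {
    x <- rnorm(sizes[1], 0.3)
    y <- rnorm(sizes[2])
    expect_equal(mann_whitney_p(x, y), oracle_mann_whitney_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("association is invariant to monotone transforms and label swap flips direction", {
  set.seed(37)
  est <- tibble::tibble(sample_id = paste0("s", 1:30),
                        log10_m = rnorm(30, 2, 0.4))
  carriers <- paste0("s", sample(30, 12))
  calls <- tibble::tibble(alteration_id = "ALT", kind = "mutation",
                          n_carriers = 12L, carriers = list(carriers))
  res <- association_scan(calls, est, q_threshold = 1)
  est_t <- dplyr::mutate(est, log10_m = exp(2 * log10_m))
  res_t <- association_scan(calls, est_t, q_threshold = 1)
  expect_equal(res$p, res_t$p)
  expect_equal(res$direction, res_t$direction)

  d <- tibble::tibble(v = est$log10_m,
                      g = ifelse(est$sample_id %in% carriers, "carrier", "wt"))
  gc1 <- group_compare(d, v, g)
  # relabel so the alphabetically first level is now the wild-type group
  gc2 <- group_compare(dplyr::mutate(d, g = ifelse(g == "wt", "awt", "zcarrier")), v, g)
  expect_equal(gc1$p, gc2$p)
  # the group with the larger median is the same underlying set of samples
  expect_equal(gc1$group_high == "carrier", gc2$group_high == "zcarrier")
  expect_true(gc1$direction != gc2$direction || gc1$direction == "none")
})

test_that("a planted carrier shift is detected and BH families stay separate", {
  set.seed(43)
  n <- 30
  est <- tibble::tibble(
    sample_id = paste0("s", 1:(2 * n)),
    log10_m = c(rnorm(n, 2, 0.2), rnorm(n, 2.3, 0.2))
  )
  calls <- dplyr::bind_rows(
    tibble::tibble(alteration_id = "SHIFTED", kind = "mutation",
                   n_carriers = n, carriers = list(paste0("s", (n + 1):(2 * n)))),
    tibble::tibble(alteration_id = "NULL_CNA", kind = "cna", n_carriers = 20L,
                   carriers = list(paste0("s", sample(2 * n, 20))))
  )
  res <- association_scan(calls, est)
  shifted <- res[res$alteration_id == "SHIFTED", ]
  expect_lt(shifted$q, 0.05)
  expect_equal(shifted$direction, "increases")
  # separate families: each kind's single test has q == p
  expect_equal(res$q, res$p)
  pooled <- association_scan(calls, est, bh_family = "all")
  expect_true(any(pooled$q != pooled$p))
})

test_that("degenerate carrier sets are untestable rather than wrong", {
  est <- tibble::tibble(sample_id = paste0("s", 1:5), log10_m = 1:5 / 10)
  calls <- tibble::tibble(
    alteration_id = c("NOBODY", "EVERYBODY"), kind = "cna",
    n_carriers = c(0L, 5L),
    carriers = list(character(), paste0("s", 1:5))
  )
  res <- association_scan(calls, est)
  expect_false(any(res$testable))
  expect_true(all(res$direction == "none"))
})

test_that("group comparison requires two groups and reports identical groups as null", {
  d <- tibble::tibble(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  res <- group_compare(d, v, g)
  expect_gt(res$p, 0.99)
  expect_equal(res$direction, "none")
  expect_error(group_compare(tibble::tibble(v = 1:3, g = "a"), v, g),
               class = "mtcn_config_error")
})

test_that("stratified testing removes a subtype confound", {
  set.seed(51)
  n <- 40
  subtype <- rep(c("serous", "endometrioid"), each = n)
  # copy number driven entirely by subtype; alteration enriched in serous
  vals <- ifelse(subtype == "serous", rnorm(2 * n, 2.5, 0.1),
                 rnorm(2 * n, 2.0, 0.1))
  est <- tibble::tibble(sample_id = paste0("s", 1:(2 * n)), log10_m = vals)
  carriers <- paste0("s", c(1:30, 41:45))
  calls <- tibble::tibble(alteration_id = "CONFOUNDED", kind = "cna",
                          n_carriers = length(carriers),
                          carriers = list(carriers))
  naive <- association_scan(calls, est)
  strat <- association_scan(calls, est,
                            strata = stats::setNames(subtype, est$sample_id))
  expect_lt(naive$p, 0.01)     # spurious without stratification
  expect_gt(strat$p, 0.05)     # gone once compared within subtype
})
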