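# Independent oracles used to check the package's statistics and counting
# against first-principles implementations.

# Record-by-record SAM filter: parses the SAM text itself and applies the
# flag/MAPQ rules by bit arithmetic, independently of Rsamtools.
oracle_sam_counts <- function(sam_path, mapq_min = 30) {
  lines <- readLines(sam_path)
  contigs <- sub("\tLN:.*$", "", sub("^@SQ\tSN:", "", grep("^@SQ", lines, value = TRUE)))
  body <- lines[!grepl("^@", lines)]
  counts <- setNames(integer(length(contigs)), contigs)
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2]); contig <- f[3]; mapq <- as.integer(f[5])
    if (bitwAnd(flag, 4L) > 0L) next                    # unmapped
    if (bitwAnd(flag, 256L) > 0L) next                  # secondary
    if (bitwAnd(flag, 2048L) > 0L) next                 # supplementary
    if (bitwAnd(flag, 1024L) > 0L) next                 # duplicate
    if (bitwAnd(flag, 512L) > 0L) next                  # QC fail
    if (bitwAnd(flag, 2L) == 0L) next                   # not properly paired
    if (mapq <= mapq_min) next
    counts[contig] <- counts[contig] + 1L
  }
  counts
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of all 2^n sign
# assignments (requires no zeros and no tied absolute values).
oracle_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  stopifnot(n <= 15, !any(duplicated(abs(x))))
  rk <- rank(abs(x))
  v_obs <- sum(rk[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  pl <- mean(v_all <= v_obs)
  pu <- mean(v_all >= v_obs)
  min(1, 2 * min(pl, pu))
}

# Exact two-sided Mann-Whitney p from the exact null distribution of the
# rank sum, built by dynamic programming over ranks 1..N (no ties).
oracle_mann_whitney_p <- function(x, y) {
  stopifnot(!any(duplicated(c(x, y))))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  rk <- rank(c(x, y))
  w_obs <- sum(rk[seq_len(n1)])
  # counts[k+1, s+1] = number of k-subsets of {1..r} with sum s
  max_s <- N * (N + 1) / 2
  counts <- matrix(0, nrow = n1 + 1, ncol = max_s + 1)
  counts[1, 1] <- 1
  for (r in seq_len(N)) {
    for (k in rev(seq_len(min(r, n1)))) {
      s_idx <- seq_len(max_s + 1 - r)
      counts[k + 1, s_idx + r] <- counts[k + 1, s_idx + r] + counts[k, s_idx]
    }
  }
  dist <- counts[n1 + 1, ]
  total <- sum(dist)
  sums <- 0:max_s
  pl <- sum(dist[sums <= w_obs]) / total
  pu <- sum(dist[sums >= w_obs]) / total
  min(1, 2 * min(pl, pu))
}

# Permutation estimate of the one-sided mean-rank gene-set p-value.
oracle_mean_rank_perm_p <- function(statistics, gene_set, alternative,
                                    n_perm = 10000, seed = 1) {
  set.seed(seed)
  r <- rank(statistics)
  in_set <- names(statistics) %in% gene_set
  n1 <- sum(in_set)
  obs <- mean(r[in_set])
  draws <- replicate(n_perm, mean(sample(r, n1)))
  if (alternative == "up") {
    (1 + sum(draws >= obs)) / (1 + n_perm)
  } else {
    (1 + sum(draws <= obs)) / (1 + n_perm)
  }
}

# Closed-form two-group least squares: with two plates, one tissue class,
# the difference in plate effects equals the difference in group means.
oracle_two_plate_alpha_diff <- function(y1, y2) mean(y2) - mean(y1)

`%||%` <- function(a, b) if (is.null(a)) b else a

wilcoxon_signed_rank_p <- function(x) mtcn:::wilcoxon_signed_rank(x)$p

mann_whitney_p <- function(x, y) mtcn:::mann_whitney(x, y)$p
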