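# Independent brute-force oracles used to check the package's statistics and
# interval arithmetic. These deliberately avoid the code paths they verify:
# the Fisher oracle enumerates the hypergeometric support directly, the
# Wilcoxon oracle enumerates group assignments, and the interval oracle works
# on per-base boolean masks.

oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  k <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(k, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

oracle_wilcox_exact_two_sided <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  pooled <- c(x, y)
  r <- rank(pooled)
  m <- length(x); n <- length(y)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, function(idx) sum(r[idx])) - m * (m + 1) / 2
  total <- ncol(combos)
  p <- 2 * min(sum(u_all <= u_obs), sum(u_all >= u_obs)) / total
  min(1, p)
}

# Per-base boolean mask of an interval tibble over chromosomes of length L
# (named vector). Positions are 0-based; mask index i+1 covers base i.
interval_mask <- function(x, chrom_lens) {
  masks <- lapply(chrom_lens, function(L) logical(L))
  for (i in seq_len(nrow(x))) {
    ch <- x$chrom[i]
    masks[[ch]][(x$start[i] + 1):x$end[i]] <- TRUE
  }
  masks
}

mask_to_intervals <- function(masks) {
  out <- list()
  for (ch in names(masks)) {
    m <- masks[[ch]]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- tibble::tibble(chrom = ch, start = starts[keep], end = ends[keep])
    }
  }
  if (length(out) == 0) interval_tbl() else
    dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

random_interval_set <- function(n, chroms = c("chr1", "chr2"), L = 10000) {
  ch <- sample(chroms, n, replace = TRUE)
  start <- sample.int(L - 100, n, replace = TRUE) - 1L
  len <- sample.int(300, n, replace = TRUE)
  interval_tbl(ch, start, pmin(start + len, L))
}

# Small deterministic fixture shared by several pipeline tests.
small_fixture <- function(seed = 7, n_total = 300, chrom_length = 2e5,
                          multipliers = c(no_change = 1, hmc_loss_or_mc_gain = 1,
                                          hmc_gain = 3, background = 1)) {
  cfg <- sim_config(
    seed = seed,
    genome = list(chrom_length_bp = chrom_length),
    peaks = list(n_peaks_per_category = c(no_change = 8, hmc_loss_or_mc_gain = 8,
                                          hmc_gain = 8),
                 peak_length_mean_bp = 800, min_gap_bp = 400),
    mutations = list(n_total = n_total, rate_multipliers = multipliers)
  )
  genome <- simulate_genome(cfg)
  pk <- simulate_peaks(cfg, genome)
  list(cfg = cfg, genome = genome, peaks = pk,
       mutations = simulate_mutations(cfg, genome, pk$truth))
}
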