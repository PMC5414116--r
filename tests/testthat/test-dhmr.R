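test_that("diff_peaks handles identical, disjoint and overlapping peak sets", {
  wt <- interval_tbl("chr1", 100, 200)
  d <- diff_peaks(wt, wt)
  expect_equal(nrow(d$gained), 0)
  expect_equal(nrow(d$lost), 0)
  expect_equal(d$shared, wt)

  d2 <- diff_peaks(interval_tbl(), interval_tbl("chr1", 500, 600))
  expect_equal(d2$gained, interval_tbl("chr1", 500, 600))

  # any overlap disqualifies gain at the default fraction of 0
  d3 <- diff_peaks(interval_tbl("chr1", 100, 200), interval_tbl("chr1", 199, 300))
  expect_equal(nrow(d3$gained), 0)
  expect_error(diff_peaks(wt, wt, min_overlap_fraction = 1.5), "0, 1")
})

test_that("diff_peaks agrees with a per-base oracle at fraction 0", {
  lens <- c(chr1 = 10000)
  set.seed(13)
  for (i in 1:10) {
    ref <- interval_merge(random_interval_set(10, "chr1"))
    qry <- interval_merge(random_interval_set(10, "chr1"))
    d <- diff_peaks(ref, qry)
    mref <- interval_mask(ref, lens)
    # gained = query peaks with zero overlap against the reference mask
    gained_oracle <- qry[vapply(seq_len(nrow(qry)), function(j) {
      !any(mref$chr1[(qry$start[j] + 1):qry$end[j]])
    }, logical(1)), ]
    expect_equal(as.data.frame(d$gained), as.data.frame(gained_oracle),
                 ignore_attr = TRUE)
    expect_equal(d$shared,
                 mask_to_intervals(purrr::map2(mref, interval_mask(qry, lens), `&`)))
  }
})

test_that("classify_loci reproduces the three-way category definitions", {
  # KO-only 5hmC peak, no 5mC change -> hmc_gain
  loci <- classify_loci(interval_tbl(), interval_tbl("chr1", 500, 600),
                        interval_tbl(), interval_tbl())
  expect_equal(as.character(loci$category), "hmc_gain")
  expect_equal(loci$start, 500L)

  # identical peaks for both marks -> everything shared 5hmC is no_change
  hmc <- interval_tbl("chr1", c(100, 300), c(200, 400))
  mc <- interval_tbl("chr1", 700, 800)
  loci2 <- classify_loci(hmc, hmc, mc, mc)
  expect_true(all(loci2$category == "no_change"))
  expect_equal(interval_total_bp(loci2[, 1:3]), 200)

  # KO-only 5mC peak overlapping a shared 5hmC peak takes precedence
  loci3 <- classify_loci(hmc, hmc, interval_tbl(), interval_tbl("chr1", 150, 180))
  fp <- category_footprints(loci3)
  expect_equal(fp$footprint_bp[fp$category == "hmc_loss_or_mc_gain"], 30)
  expect_equal(fp$footprint_bp[fp$category == "no_change"], 170)
  expect_equal(fp$footprint_bp[fp$category == "hmc_gain"], 0)
})

test_that("classification matches a per-base precedence oracle", {
  lens <- c(chr1 = 10000)
  set.seed(101)
  for (i in 1:10) {
    hmc_wt <- interval_merge(random_interval_set(8, "chr1"))
    hmc_ko <- interval_merge(random_interval_set(8, "chr1"))
    mc_wt <- interval_merge(random_interval_set(5, "chr1"))
    mc_ko <- interval_merge(random_interval_set(5, "chr1"))
    loci <- classify_loci(hmc_wt, hmc_ko, mc_wt, mc_ko)

    m <- lapply(list(hmc_wt = hmc_wt, hmc_ko = hmc_ko,
                     mc_wt = mc_wt, mc_ko = mc_ko),
                function(x) interval_mask(x, lens)$chr1)
    # whole-peak gain/loss at fraction 0, reduced to bases
    peak_mask <- function(peaks, other_mask, invert = FALSE) {
      out <- logical(lens)
      for (j in seq_len(nrow(peaks))) {
        idx <- (peaks$start[j] + 1):peaks$end[j]
        if (!any(other_mask[idx])) out[idx] <- TRUE
      }
      out
    }
    gain <- peak_mask(hmc_ko, m$hmc_wt)
    hmc_lost <- peak_mask(hmc_wt, m$hmc_ko)
    mc_gain <- peak_mask(mc_ko, m$mc_wt)
    loss <- (hmc_lost | mc_gain) & !gain
    no_change <- m$hmc_wt & m$hmc_ko & !gain & !loss

    expect_equal(loci[loci$category == "hmc_gain", 1:3], mask_to_intervals(list(chr1 = gain)))
    expect_equal(loci[loci$category == "hmc_loss_or_mc_gain", 1:3],
                 mask_to_intervals(list(chr1 = loss)))
    expect_equal(loci[loci$category == "no_change", 1:3],
                 mask_to_intervals(list(chr1 = no_change)))
  }
})

test_that("categories are pairwise disjoint at base level", {
  set.seed(55)
  for (i in 1:5) {
    loci <- classify_loci(
      interval_merge(random_interval_set(10, "chr1")),
      interval_merge(random_interval_set(10, "chr1")),
      interval_merge(random_interval_set(6, "chr1")),
      interval_merge(random_interval_set(6, "chr1"))
    )
    total <- sum(category_footprints(loci)$footprint_bp)
    expect_equal(interval_total_bp(loci[, 1:3]), total)
  }
})

test_that("swapping WT and KO swaps gain with the 5hmC-loss component", {
  set.seed(77)
  hmc_wt <- interval_merge(random_interval_set(10, "chr1"))
  hmc_ko <- interval_merge(random_interval_set(10, "chr1"))
  fwd <- classify_loci(hmc_wt, hmc_ko, interval_tbl(), interval_tbl())
  rev <- classify_loci(hmc_ko, hmc_wt, interval_tbl(), interval_tbl())
  expect_equal(fwd[fwd$category == "hmc_gain", 1:3],
               rev[rev$category == "hmc_loss_or_mc_gain", 1:3])
  expect_equal(fwd[fwd$category == "hmc_loss_or_mc_gain", 1:3],
               rev[rev$category == "hmc_gain", 1:3])
})

test_that("mislabelled mark_peaks inputs are rejected", {
  p <- interval_tbl("chr1", 0, 100)
  mp <- mark_peaks(p, condition = "KO", mark = "5hmC")
  expect_error(classify_loci(mp, p, p, p), "labelled KO/5hmC")
})

test_that("classification recovers simulator truth on non-adjacent peaks", {
  fx <- small_fixture(seed = 303)
  pk <- fx$peaks
  loci <- classify_loci(pk$hmc_wt, pk$hmc_ko, pk$mc_wt, pk$mc_ko)
  # every truth region must be fully classified as its intended category
  truth_bp <- sum(pk$truth$end - pk$truth$start)
  recovered <- sum(vapply(seq_len(nrow(pk$truth)), function(i) {
    sub <- loci[loci$category == as.character(pk$truth$category[i]), 1:3]
    interval_total_bp(interval_intersect(
      interval_tbl(pk$truth$chrom[i], pk$truth$start[i], pk$truth$end[i]), sub))
  }, numeric(1)))
  expect_gte(recovered / truth_bp, 0.99)
})
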