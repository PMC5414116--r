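make_loci <- function() {
  loci <- dplyr::bind_rows(
    dplyr::mutate(interval_tbl("chr1", 0, 1000), category = "no_change"),
    dplyr::mutate(interval_tbl("chr1", 2000, 3000), category = "hmc_loss_or_mc_gain"),
    dplyr::mutate(interval_tbl("chr1", 4000, 5000), category = "hmc_gain")
  )
  loci$category <- factor(loci$category, levels = dhmr_categories())
  loci
}

test_that("variants are assigned by their single changed base", {
  loci <- make_loci()
  v <- variant_tbl("chr1", c(4500, 1500, 1000, 2000), # 1-based
                   c("C", "C", "C", "CA"), c("T", "T", "T", "C"))
  av <- variant_categories(v, loci)
  expect_equal(as.character(av$category),
               c("hmc_gain", NA, "no_change", "hmc_loss_or_mc_gain"))
  # the deletion's first changed base (0-based 2000) is inside [2000, 3000)
  counts <- assign_variants(v, loci)
  expect_equal(counts$n_variants, c(1L, 1L, 1L, 1L))
  expect_equal(sum(counts$n_variants), nrow(v))
  expect_equal(counts$rate_per_mb[1], 1 / (1000 / 1e6))
})

test_that("per-category counts match simulator truth exactly", {
  fx <- small_fixture(seed = 11)
  loci <- classify_loci(fx$peaks$hmc_wt, fx$peaks$hmc_ko,
                        fx$peaks$mc_wt, fx$peaks$mc_ko)
  av <- variant_categories(fx$mutations, loci)
  got <- as.character(av$category)
  got[is.na(got)] <- "background"
  expect_identical(got, as.character(fx$mutations$true_category))
})

test_that("enrichment test is footprint-normalized chi-squared", {
  counts <- tibble::tibble(
    category = factor(c(dhmr_categories(), "unassigned"),
                      levels = c(dhmr_categories(), "unassigned")),
    n_variants = c(10L, 10L, 40L, 7L),
    footprint_bp = c(1e6, 1e6, 1e6, NA),
    rate_per_mb = c(10, 10, 40, NA)
  )
  er <- enrichment_test(counts)
  expect_equal(er$test$statistic, 30)
  expect_equal(er$test$df, 2)

  # equal rates across equal footprints: no signal
  counts$n_variants <- c(20L, 20L, 20L, 0L)
  er2 <- enrichment_test(counts)
  expect_equal(er2$test$statistic, 0)
  expect_equal(er2$test$p_value, 1)

  # p is invariant to category ordering
  expect_equal(enrichment_test(counts[c(3, 1, 2, 4), ])$test$p_value,
               er2$test$p_value)

  counts$footprint_bp <- c(0, 0, 0, NA)
  expect_error(enrichment_test(counts), "at least 2 categories")
})

test_that("C-to-T filtering keeps exactly the collapsed C>T class", {
  v <- variant_tbl("chr1", 1:5, c("C", "G", "A", "C", "CA"),
                   c("T", "A", "G", "G", "C"))
  kept <- filter_c_to_t(v)
  expect_equal(kept$pos, 1:2)
  n_snv <- sum(v$kind == "SNV")
  expect_equal(nrow(kept) + (n_snv - nrow(kept)), n_snv)
})

test_that("binding enrichment counts coverage per category", {
  loci <- make_loci()
  # TET2 peaks exactly the hmc_gain footprint: extreme association
  be <- binding_enrichment(interval_tbl("chr1", 4000, 5000), loci)
  expect_equal(be$coverage$fraction, c(0, 0, 1))
  expect_lt(be$test$p_value, 1e-10)

  # uniform coverage: no association
  be2 <- binding_enrichment(
    interval_tbl("chr1", c(0, 2000, 4000), c(500, 2500, 4500)), loci)
  expect_equal(be2$coverage$fraction, c(0.5, 0.5, 0.5))
  expect_equal(be2$test$p_value, 1, tolerance = 1e-12)
})

test_that("binding coverage agrees with a per-base oracle", {
  lens <- c(chr1 = 10000)
  set.seed(12)
  for (i in 1:5) {
    tet2 <- interval_merge(random_interval_set(8, "chr1"))
    loci <- classify_loci(
      interval_merge(random_interval_set(8, "chr1")),
      interval_merge(random_interval_set(8, "chr1")),
      interval_tbl(), interval_tbl()
    )
    if (sum(category_footprints(loci)$footprint_bp) == 0) next
    be <- binding_enrichment(tet2, loci)
    mt <- interval_mask(tet2, lens)$chr1
    for (k in seq_along(dhmr_categories())) {
      cat_mask <- interval_mask(
        loci[loci$category == dhmr_categories()[k], 1:3], lens)$chr1
      expect_equal(be$coverage$covered_bp[k], sum(mt & cat_mask))
    }
  }
})

test_that("mutation overlap with binding peaks is counted and calibrated", {
  v <- variant_tbl("chr1", c(10, 20, 30), c("C", "C", "C"), c("T", "T", "T"))
  expect_equal(binding_mutation_overlap(v, interval_tbl("chr1", 0, 100))$n_overlapping, 3L)
  expect_equal(binding_mutation_overlap(v, interval_tbl())$n_overlapping, 0L)

  # synthetic placement with known coverage: recovered fraction within
  # the binomial 95% CI
  fx <- small_fixture(seed = 21, n_total = 600)
  loci <- classify_loci(fx$peaks$hmc_wt, fx$peaks$hmc_ko,
                        fx$peaks$mc_wt, fx$peaks$mc_ko)
  in_loci <- dplyr::filter(variant_categories(fx$mutations, loci),
                           !is.na(category))
  ov <- binding_mutation_overlap(in_loci, fx$peaks$tet2)
  # expected fraction: per-category TET2 coverage weighted by where the
  # in-locus variants are
  truth_cov <- fx$peaks$truth
  covered <- interval_total_bp(interval_intersect(
    fx$peaks$tet2, loci[, 1:3]))
  p_exp <- covered / interval_total_bp(loci[, 1:3])
  # variants are uniform within categories only approximately; allow CI slack
  ci <- qbinom(c(0.0025, 0.9975), ov$n_total, p_exp) / ov$n_total
  expect_gte(ov$fraction, ci[1] - 0.1)
  expect_lte(ov$fraction, ci[2] + 0.1)
})

test_that("feature fold enrichment matches its definition and null", {
  peaks <- interval_tbl("chr1", c(100, 300, 500), c(200, 400, 600))
  whole <- interval_tbl("chr1", 0, 10000)
  expect_equal(feature_fold_enrichment(peaks, whole, 10000), 1)

  feat <- interval_tbl("chr1", 0, 1000)   # 10% of the genome
  inside <- interval_tbl("chr1", c(100, 300), c(200, 400))
  expect_equal(feature_fold_enrichment(inside, feat, 10000), 10)
  expect_error(feature_fold_enrichment(inside, interval_tbl(), 10000), "zero footprint")

  # random peaks vs random feature: fold ~ 1 on average
  # 1-bp peaks so the any-overlap rule reduces to base coverage
  set.seed(33)
  folds <- replicate(200, {
    s <- sample.int(10000, 40) - 1
    peaks <- interval_merge(interval_tbl("chr1", s, s + 1))
    fs <- sample.int(8000, 10) - 1
    feat <- interval_merge(interval_tbl("chr1", fs, fs + sample(300:900, 10)))
    feature_fold_enrichment(peaks, feat, 10000)
  })
  expect_equal(mean(folds), 1, tolerance = 0.05)
})

test_that("rates are invariant under joint rescaling of counts and footprints", {
  counts <- assign_variants(
    variant_tbl("chr1", c(500, 2500), c("C", "C"), c("T", "T")), make_loci())
  scaled <- counts
  scaled$n_variants <- scaled$n_variants * 10L
  scaled$footprint_bp <- scaled$footprint_bp * 10
  r1 <- counts$n_variants / (counts$footprint_bp / 1e6)
  r2 <- scaled$n_variants / (scaled$footprint_bp / 1e6)
  expect_equal(r1, r2)  # both count and footprint scale, so the rate is unchanged
})
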