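test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 77, genome = list(chrom_length_bp = 5e4),
                    peaks = list(n_peaks_per_category = c(
                      no_change = 4, hmc_loss_or_mc_gain = 4, hmc_gain = 4),
                      peak_length_mean_bp = 500, min_gap_bp = 200),
                    mutations = list(n_total = 100))
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  p1 <- simulate_peaks(cfg, g1); p2 <- simulate_peaks(cfg, g2)
  expect_identical(p1$truth, p2$truth)
  m1 <- simulate_mutations(cfg, g1, p1$truth)
  m2 <- simulate_mutations(cfg, g2, p2$truth)
  expect_identical(m1, m2)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  expect_identical(simulate_fluctuation(cfg), simulate_fluctuation(cfg))
  # different seeds give different draws
  cfg2 <- sim_config(seed = 78, genome = list(chrom_length_bp = 5e4),
                     mutations = list(n_total = 100))
  expect_false(identical(as.character(g1),
                         as.character(simulate_genome(cfg2))))
})

test_that("simulated CpG spacing matches the configured mean", {
  cfg <- sim_config(seed = 2, genome = list(chrom_length_bp = 1e6))
  g <- simulate_genome(cfg)
  cpg <- find_cpg_sites(g)
  gaps <- diff(cpg$pos)
  expect_lt(abs(mean(gaps) - 100) / 100, 0.05)
})

test_that("degenerate spacing two with no variance yields tandem CGs", {
  cfg <- sim_config(seed = 3, genome = list(chrom_length_bp = 40,
                                            cpg_mean_spacing_bp = 2,
                                            spacing_model = "fixed"))
  g <- simulate_genome(cfg)
  s <- as.character(g[[1]])
  # after the first planted site the sequence is tandem CGCGCG...
  expect_true(grepl("^(CG)+", substr(s, 3, 38)))
  expect_error(simulate_genome(sim_config(
    genome = list(cpg_mean_spacing_bp = 1))), ">= 2")
})

test_that("simulated peaks realize every intended category", {
  cfg <- sim_config(seed = 9, genome = list(chrom_length_bp = 2e5),
                    peaks = list(n_peaks_per_category = c(
                      no_change = 5, hmc_loss_or_mc_gain = 5, hmc_gain = 5)))
  g <- simulate_genome(cfg)
  pk <- simulate_peaks(cfg, g)
  loci <- classify_loci(pk$hmc_wt, pk$hmc_ko, pk$mc_wt, pk$mc_ko)
  # each of the 15 truth regions is recovered under its intended category
  for (i in seq_len(nrow(pk$truth))) {
    sub <- loci[loci$category == as.character(pk$truth$category[i]), 1:3]
    reg <- interval_tbl(pk$truth$chrom[i], pk$truth$start[i], pk$truth$end[i])
    expect_equal(interval_total_bp(interval_intersect(reg, sub)),
                 pk$truth$end[i] - pk$truth$start[i])
  }
})

test_that("a category with zero peaks stays empty downstream", {
  cfg <- sim_config(seed = 10, genome = list(chrom_length_bp = 1e5),
                    peaks = list(n_peaks_per_category = c(
                      no_change = 5, hmc_loss_or_mc_gain = 5, hmc_gain = 0)))
  g <- simulate_genome(cfg)
  pk <- simulate_peaks(cfg, g)
  loci <- classify_loci(pk$hmc_wt, pk$hmc_ko, pk$mc_wt, pk$mc_ko)
  fp <- category_footprints(loci)
  expect_equal(fp$footprint_bp[fp$category == "hmc_gain"], 0)
})

test_that("infeasible peak packing raises a configuration error", {
  cfg <- sim_config(seed = 12, genome = list(chrom_length_bp = 1e4),
                    peaks = list(n_peaks_per_category = c(
                      no_change = 50, hmc_loss_or_mc_gain = 50, hmc_gain = 50)))
  g <- simulate_genome(cfg)
  expect_error(simulate_peaks(cfg, g), "infeasible packing")
})

test_that("a 3x rate multiplier produces a ~3x empirical rate ratio", {
  # footprints of ~1 Mb per category so the ratio estimate is stable at n=600
  cfg <- sim_config(seed = 41, genome = list(chrom_length_bp = 4e6),
                    peaks = list(n_peaks_per_category = c(
                      no_change = 200, hmc_loss_or_mc_gain = 200, hmc_gain = 200),
                      peak_length_mean_bp = 5000, min_gap_bp = 400))
  g <- simulate_genome(cfg)
  pk <- simulate_peaks(cfg, g)
  mu <- simulate_mutations(cfg, g, pk$truth)
  loci <- classify_loci(pk$hmc_wt, pk$hmc_ko, pk$mc_wt, pk$mc_ko)
  counts <- assign_variants(mu, loci)
  r <- counts$rate_per_mb
  ratio <- r[3] / mean(r[1:2])
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 3.5)
})

test_that("requesting more variants than positions fails loudly", {
  cfg <- sim_config(seed = 13, genome = list(chrom_length_bp = 1e3),
                    peaks = list(n_peaks_per_category = c(
                      no_change = 1, hmc_loss_or_mc_gain = 1, hmc_gain = 1),
                      peak_length_mean_bp = 100, min_gap_bp = 50),
                    mutations = list(n_total = 5000))
  g <- simulate_genome(cfg)
  pk <- simulate_peaks(cfg, g)
  expect_error(simulate_mutations(cfg, g, pk$truth), "exceeds available")
})

test_that("cohort and assay generators respect their parameters", {
  cfg <- sim_config(seed = 15)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co), 41 + 154)
  expect_equal(sum(co$tet2_status == "mutated"), 41)
  expect_error(simulate_cohort(sim_config(cohort = list(mu_wild_type = -1))), "> 0")

  a0 <- simulate_fluctuation(sim_config(seed = 16, assay = list(
    true_frequency = c(null = 0))))
  expect_true(all(a0$colonies_6tg == 0))
  expect_error(simulate_fluctuation(sim_config(assay = list(
    true_frequency = c(bad = 2)))), "\\[0, 1\\]")
})

test_that("fixture directories are parseable and byte-stable", {
  cfg <- sim_config(seed = 19, genome = list(chrom_length_bp = 5e4),
                    peaks = list(n_peaks_per_category = c(
                      no_change = 4, hmc_loss_or_mc_gain = 4, hmc_gain = 4)),
                    mutations = list(n_total = 80))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- simulate_all(cfg, d1)
  fx2 <- simulate_all(cfg, d2)
  for (nm in setdiff(names(fx1$paths), "config")) {
    expect_identical(readLines(fx1$paths[[nm]]), readLines(fx2$paths[[nm]]),
                     info = nm)
  }
  # round-trip through the standard readers
  g <- read_fasta(fx1$paths$genome)
  expect_identical(as.character(g), as.character(fx1$genome))
  expect_equal(read_bed(fx1$paths$hmc_ko), fx1$peaks$hmc_ko)
  v <- read_vcf(fx1$paths$vcf, genome = g)
  expect_equal(nrow(v), 80)
})
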