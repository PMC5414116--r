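#' Simulation configuration
#'
#' Builds the single configuration object driving every generator. Defaults
#' reproduce the study conditions of the analyses the package implements:
#' CpG sites at mean spacing 100 bp; three locus categories; mutations with a
#' 3-fold elevated per-bp rate in the `hmc_gain` category; a substitution
#' spectrum of 35% collapsed C>T transitions, 23% T>C transitions, 38%
#' transversions (split evenly over the four classes) and 4% single-base
#' indels with -1 deletions more common than +1 insertions; a CpG-proximity
#' placement bias; two-condition cohorts of 41 mutated vs 154 wild-type
#' samples with negative-binomial burdens; and a triplicate 5e5-cells/dish
#' fluctuation assay with 500 cells plated for plating efficiency.
#'
#' @param seed Integer root seed; each generator derives its own substream
#'   deterministically so stages can be regenerated independently.
#' @param genome,peaks,mutations,cohort,assay Named lists overriding any
#'   subset of the defaults (see the function body for every field).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome = list(), peaks = list(),
                       mutations = list(), cohort = list(), assay = list()) {
  defaults <- list(
    seed = as.integer(seed),
    genome = list(
      n_chroms = 1L,
      chrom_length_bp = 1e6,
      gc_fraction = 0.4,
      cpg_mean_spacing_bp = 100,
      spacing_model = "exponential"   # or "fixed" (zero gap variance)
    ),
    peaks = list(
      n_peaks_per_category = c(no_change = 30L, hmc_loss_or_mc_gain = 30L,
                               hmc_gain = 30L),
      peak_length_mean_bp = 1000,
      min_gap_bp = 500,
      tet2_coverage = c(no_change = 0.2, hmc_loss_or_mc_gain = 0.2,
                        hmc_gain = 0.7)
    ),
    mutations = list(
      n_total = 600L,
      rate_multipliers = c(no_change = 1, hmc_loss_or_mc_gain = 1,
                           hmc_gain = 3, background = 1),
      spectrum_weights = c(c_to_t = 0.35, t_to_c = 0.23,
                           c_to_a = 0.095, c_to_g = 0.095,
                           t_to_a = 0.095, t_to_g = 0.095,
                           ins1 = 0.015, del1 = 0.025),
      cpg_proximity_bias = 0.5,
      cpg_window_bp = 30L
    ),
    cohort = list(
      n_mutated = 41L,
      n_wild_type = 154L,
      mu_wild_type = 10,
      mu_ratio = 1.5,
      nb_size = 8
    ),
    assay = list(
      true_frequency = c(control = 1e-6, tet2_kd = 2.4e-5),
      plating_efficiency = 0.5,
      cells_per_dish = 5e5,
      n_dishes = 3L,
      cells_plated_pe = 500
    )
  )
  cfg <- defaults
  for (blk in c("genome", "peaks", "mutations", "cohort", "assay")) {
    cfg[[blk]] <- utils::modifyList(defaults[[blk]], get(blk))
  }
  w <- cfg$mutations$spectrum_weights
  if (abs(sum(w) - 1) > 1e-8) rlang::abort("spectrum_weights must sum to 1")
  if (any(w < 0) || any(cfg$mutations$rate_multipliers < 0)) {
    rlang::abort("spectrum weights and rate multipliers must be >= 0")
  }
  structure(cfg, class = "sim_config")
}

# Deterministic per-stage substream of the root seed (kept below 2^31).
stage_seed <- function(seed, stage) {
  offsets <- c(genome = 101L, peaks = 211L, mutations = 307L,
               cohort = 401L, assay = 503L)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% 2147483629)
}

#' Simulate a genome with CpG sites at a configured mean spacing
#'
#' Generates random background sequence at the configured GC fraction,
#' removes any incidentally formed CpG dinucleotides, then plants CG
#' dinucleotides whose inter-site gaps are exponential with the configured
#' mean (or exactly regular with `spacing_model = "fixed"`), so observed CpG
#' spacing matches the null model used by [expected_cpg_fraction()]. No N
#' bases are emitted. Deterministic under a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A `DNAStringSet`.
#' @export
simulate_genome <- function(config) {
  g <- config$genome
  if (g$cpg_mean_spacing_bp < 2) rlang::abort("cpg_mean_spacing_bp must be >= 2 (a CpG occupies 2 bp)")
  set.seed(stage_seed(config$seed, "genome"))
  chroms <- lapply(seq_len(g$n_chroms), function(i) {
    L <- as.integer(g$chrom_length_bp)
    gc <- g$gc_fraction
    b <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    cg <- which(b[-L] == "C" & b[-1] == "G")
    if (length(cg) > 0) b[cg + 1L] <- "A"   # A cannot seed a new CpG
    spacing <- g$cpg_mean_spacing_bp
    n_est <- ceiling(L / spacing * 1.5) + 50
    gaps <- if (g$spacing_model == "fixed" || spacing == 2) {
      rep(spacing, n_est)
    } else {
      2 + round(stats::rexp(n_est, rate = 1 / (spacing - 2)))
    }
    p <- cumsum(gaps)                      # 0-based C offsets
    p <- p[p <= L - 2]
    b[p + 1L] <- "C"
    b[p + 2L] <- "G"
    paste(b, collapse = "")
  })
  names(chroms) <- paste0("chr", seq_len(g$n_chroms))
  Biostrings::DNAStringSet(unlist(chroms))
}

#' Simulate condition-specific peak sets realizing the three locus categories
#'
#' Lays out non-adjacent regions (separated by at least `min_gap_bp`) and
#' realizes each category through WT/KO peak presence patterns: `no_change`
#' regions carry a 5hmC peak in both conditions; `hmc_loss_or_mc_gain`
#' regions alternate between a WT-only 5hmC peak and a KO-only 5mC peak;
#' `hmc_gain` regions carry a KO-only 5hmC peak. TET2-binding peaks cover
#' each region with the per-category probability `tet2_coverage`.
#'
#' @param config A [sim_config()].
#' @param genome Genome from [simulate_genome()].
#' @return List with interval tibbles `hmc_wt`, `hmc_ko`, `mc_wt`, `mc_ko`,
#'   `tet2`, and `truth` (tibble `chrom`, `start`, `end`, `category`,
#'   `mechanism`).
#' @export
simulate_peaks <- function(config, genome) {
  p <- config$peaks
  set.seed(stage_seed(config$seed, "peaks"))
  n_cat <- p$n_peaks_per_category
  if (!all(dhmr_categories() %in% names(n_cat))) {
    rlang::abort("n_peaks_per_category must name all three categories")
  }
  labels <- rep(dhmr_categories(), times = n_cat[dhmr_categories()])
  mech <- labels
  i_loss <- which(labels == "hmc_loss_or_mc_gain")
  mech[i_loss] <- rep(c("hmc_loss", "mc_gain"), length.out = length(i_loss))
  n <- length(labels)
  ord <- sample.int(n)
  labels <- labels[ord]; mech <- mech[ord]
  lens <- pmax(20L, as.integer(round(stats::rnorm(n, p$peak_length_mean_bp,
                                                  0.2 * p$peak_length_mean_bp))))
  gaps <- p$min_gap_bp + as.integer(round(stats::rexp(n, 1 / p$min_gap_bp)))

  chrom_len <- genome_lengths(genome)
  chrom <- character(n); start <- integer(n)
  ci <- 1L; cursor <- gaps[1]
  for (i in seq_len(n)) {
    while (ci <= length(chrom_len) && cursor + lens[i] > chrom_len[ci]) {
      ci <- ci + 1L
      cursor <- gaps[i]
    }
    if (ci > length(chrom_len)) {
      rlang::abort("infeasible packing: peaks + gaps exceed genome size")
    }
    chrom[i] <- names(chrom_len)[ci]
    start[i] <- as.integer(cursor)
    cursor <- cursor + lens[i] + gaps[min(i + 1L, n)]
  }
  truth <- tibble::tibble(chrom = chrom, start = start, end = start + lens,
                          category = factor(labels, levels = dhmr_categories()),
                          mechanism = mech)
  truth <- dplyr::arrange(truth, .data$chrom, .data$start)

  iv <- function(rows) {
    if (sum(rows) == 0) interval_tbl() else
      interval_tbl(truth$chrom[rows], truth$start[rows], truth$end[rows])
  }
  tet2_rows <- stats::runif(n) < p$tet2_coverage[as.character(truth$category)]
  list(
    hmc_wt = iv(truth$category == "no_change" | truth$mechanism == "hmc_loss"),
    hmc_ko = iv(truth$category %in% c("no_change", "hmc_gain")),
    mc_wt = interval_tbl(),
    mc_ko = iv(truth$mechanism == "mc_gain"),
    tet2 = iv(tet2_rows),
    truth = truth
  )
}

# pyrimidine-class allele table: for a reference base, the alt realizing a
# given collapsed class.
.class_alt <- list(
  c_to_t = c(C = "T", G = "A"), c_to_a = c(C = "A", G = "T"),
  c_to_g = c(C = "G", G = "C"), t_to_c = c(T = "C", A = "G"),
  t_to_a = c(T = "A", A = "T"), t_to_g = c(T = "G", A = "C")
)

#' Simulate somatic mutations over categorized loci
#'
#' Places `n_total` variants with per-base-pair rate proportional to the
#' category rate multipliers (background = everything outside the truth
#' regions), draws each variant's class from the spectrum weights placing it
#' on a compatible reference base, and, with probability
#' `cpg_proximity_bias`, restricts an SNV's position to within
#' `cpg_window_bp` of a CpG site. Every truth label is recorded.
#'
#' @param config A [sim_config()].
#' @param genome Genome from [simulate_genome()].
#' @param truth Truth region tibble from [simulate_peaks()].
#' @return A variant tibble with extra truth columns `true_category`,
#'   `true_class` and `near_cpg` (drop them with [dplyr::select()] or write
#'   with [write_vcf()], which keeps only the VCF fields).
#' @export
simulate_mutations <- function(config, genome, truth) {
  m <- config$mutations
  set.seed(stage_seed(config$seed, "mutations"))
  genome <- as_genome(genome)
  lens <- genome_lengths(genome)

  bg <- complement_intervals(truth, lens)
  regions <- dplyr::bind_rows(
    dplyr::mutate(truth[, c("chrom", "start", "end")],
                  category = as.character(truth$category)),
    dplyr::mutate(bg, category = "background")
  )
  regions$len <- regions$end - regions$start
  mult <- m$rate_multipliers[regions$category]
  wt <- regions$len * mult
  if (sum(wt) <= 0) rlang::abort("all region weights are zero")

  n <- as.integer(m$n_total)
  if (n > sum(regions$len)) rlang::abort("requested n exceeds available positions")
  region_i <- sample.int(nrow(regions), n, replace = TRUE, prob = wt)
  class_i <- sample(names(m$spectrum_weights), n, replace = TRUE,
                    prob = m$spectrum_weights)
  near_i <- stats::runif(n) < m$cpg_proximity_bias &
    !class_i %in% c("ins1", "del1")

  cpg <- find_cpg_sites(genome)
  cpg_by_chrom <- split(cpg$pos, cpg$chrom)
  # raw byte vectors per chromosome: fast vectorized base comparisons
  braw <- lapply(stats::setNames(names(genome), names(genome)),
                 function(ch) charToRaw(as.character(genome[[ch]])))
  .r <- function(b) as.raw(utf8ToInt(b))
  need_raw <- list(CG = c(.r("C"), .r("G")), TA = c(.r("T"), .r("A")), ANY = NULL)
  class_need <- c(c_to_t = "CG", c_to_a = "CG", c_to_g = "CG",
                  t_to_c = "TA", t_to_a = "TA", t_to_g = "TA",
                  ins1 = "ANY", del1 = "ANY")
  base_at <- function(ch, p0) {  # base character at 0-based positions
    rawToChar(braw[[ch]][p0 + 1L], multiple = TRUE)
  }

  cand_cache <- new.env(parent = emptyenv())
  get_cand <- function(ri, ns, near) {
    key <- paste0(ri, "|", ns, "|", near)
    hit <- cand_cache[[key]]
    if (!is.null(hit)) return(hit)
    ch <- regions$chrom[ri]
    cand <- seq.int(max(regions$start[ri], 1L), regions$end[ri] - 1L) # 0-based, >= 1
    if (ns != "ANY") {
      bb <- braw[[ch]][cand + 1L]
      cand <- cand[bb == need_raw[[ns]][1] | bb == need_raw[[ns]][2]]
    }
    if (near && length(cand) > 0) {
      ok <- positions_near_cpg(cand, cpg_by_chrom[[ch]], m$cpg_window_bp)
      if (any(ok)) cand <- cand[ok]
    }
    if (length(cand) == 0) {  # degenerate composition: place anywhere in region
      cand <- seq.int(max(regions$start[ri], 1L), regions$end[ri] - 1L)
    }
    cand_cache[[key]] <- cand
    cand
  }

  pos0 <- integer(n)
  key <- paste0(region_i, "|", class_need[class_i], "|", near_i)
  for (k in unique(key)) {
    idx <- which(key == k)
    cand <- get_cand(region_i[idx[1]], class_need[[class_i[idx[1]]]], near_i[idx[1]])
    pos0[idx] <- cand[sample.int(length(cand), length(idx), replace = TRUE)]
  }

  # build alleles
  chrom <- regions$chrom[region_i]
  ref <- character(n); alt <- character(n); pos1 <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    cl <- class_i[i]
    is_snv <- !cl %in% c("ins1", "del1")
    # SNVs
    sj <- i[is_snv]
    if (length(sj) > 0) {
      bj <- base_at(ch, pos0[sj])
      aj <- vapply(seq_along(sj), function(t) {
        tbl <- .class_alt[[class_i[sj[t]]]]
        if (bj[t] %in% names(tbl)) tbl[[bj[t]]] else
          sample(setdiff(c("A", "C", "G", "T"), bj[t]), 1)  # fallback placement
      }, character(1))
      ref[sj] <- bj; alt[sj] <- aj; pos1[sj] <- pos0[sj] + 1L
    }
    # insertions: anchor is the base before the assigned position
    ij <- i[class_i[i] == "ins1"]
    if (length(ij) > 0) {
      anchor <- base_at(ch, pos0[ij] - 1L)
      ins <- sample(c("A", "C", "G", "T"), length(ij), replace = TRUE)
      ref[ij] <- anchor
      alt[ij] <- paste0(anchor, ins)
      pos1[ij] <- pos0[ij]             # 1-based anchor position
    }
    # -1 deletions: assigned base is the deleted one
    dj <- i[class_i[i] == "del1"]
    if (length(dj) > 0) {
      anchor <- base_at(ch, pos0[dj] - 1L)
      ref[dj] <- paste0(anchor, base_at(ch, pos0[dj]))
      alt[dj] <- anchor
      pos1[dj] <- pos0[dj]
    }
  }
  # rare fallback placements can produce ref == alt patterns only via the
  # class table, which never maps a base to itself, so construction is safe
  v <- variant_tbl(chrom, pos1, ref, alt)
  realized <- rep(NA_character_, n)
  snv <- v$kind == "SNV"
  if (any(snv)) {
    cc <- classify_substitution(v$ref[snv], v$alt[snv])$class
    realized[snv] <- as.character(cc)
  }
  realized[!snv] <- class_i[!snv]
  near_true <- logical(n)
  for (ch in unique(v$chrom)) {
    i <- which(v$chrom == ch)
    near_true[i] <- positions_near_cpg(variant_pos0(v)[i], cpg_by_chrom[[ch]],
                                       m$cpg_window_bp)
  }
  dplyr::mutate(v,
                true_category = factor(regions$category[region_i],
                                       levels = c(dhmr_categories(), "background")),
                true_class = realized,
                near_cpg = near_true)
}

#' Simulate a two-group mutational-burden cohort
#'
#' Per-sample nonsynonymous mutation counts drawn from negative-binomial
#' distributions; the mutated group's mean is `mu_ratio` times the
#' wild-type mean.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `sample_id`, `tet2_status`, `n_mutations`.
#' @export
simulate_cohort <- function(config) {
  cc <- config$cohort
  if (cc$mu_wild_type <= 0 || cc$mu_ratio <= 0 || cc$nb_size <= 0) {
    rlang::abort("cohort distribution parameters must be > 0")
  }
  set.seed(stage_seed(config$seed, "cohort"))
  n1 <- cc$n_mutated; n2 <- cc$n_wild_type
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n1 + n2)),
    tet2_status = rep(c("mutated", "wild_type"), c(n1, n2)),
    n_mutations = c(
      stats::rnbinom(n1, size = cc$nb_size, mu = cc$mu_wild_type * cc$mu_ratio),
      stats::rnbinom(n2, size = cc$nb_size, mu = cc$mu_wild_type)
    )
  )
}

#' Simulate a single-cell targeted locus panel
#'
#' Generates mutant/total cell counts at a panel of loci in two groups
#' (knockout vs wild type), with a subset of loci carrying a truly elevated
#' mutant-cell fraction in the knockout group. Input for
#' [per_locus_fisher()].
#'
#' @param seed Integer seed.
#' @param n_loci Number of loci in the panel.
#' @param n_elevated Number of loci with an elevated knockout fraction.
#' @param n_cells Cells genotyped per group per locus.
#' @param p_baseline Mutant-cell fraction at unelevated loci (both groups).
#' @param p_elevated Knockout mutant-cell fraction at elevated loci.
#' @return A tibble in [per_locus_fisher()] long format with an extra
#'   `elevated` truth column.
#' @export
simulate_locus_panel <- function(seed = 1L, n_loci = 13, n_elevated = 7,
                                 n_cells = 50, p_baseline = 0.01,
                                 p_elevated = 0.5) {
  if (n_elevated > n_loci) rlang::abort("n_elevated cannot exceed n_loci")
  set.seed(as.integer(seed))
  elevated <- seq_len(n_loci) <= n_elevated
  p_ko <- ifelse(elevated, p_elevated, p_baseline)
  tibble::tibble(
    locus_id = rep(sprintf("L%02d", seq_len(n_loci)), each = 2),
    group = rep(c("ko", "wt"), n_loci),
    n_mutant_cells = as.integer(rbind(
      stats::rbinom(n_loci, n_cells, p_ko),
      stats::rbinom(n_loci, n_cells, p_baseline)
    )),
    n_total_cells = as.integer(n_cells),
    elevated = rep(elevated, each = 2)
  )
}

#' Simulate fluctuation-assay colony counts
#'
#' For each condition, 6-TG-resistant colony counts are Poisson with mean
#' `cells_plated * true_frequency * plating_efficiency` per dish, and the
#' plating-efficiency colony count is binomial over the cells plated without
#' selection.
#'
#' @param config A [sim_config()].
#' @return Tibble with one row per condition and dish: `condition`, `dish`,
#'   `cells_plated_selection`, `colonies_6tg`, `cells_plated_pe`,
#'   `colonies_pe` (the PE dish is shared across a condition's rows).
#' @export
simulate_fluctuation <- function(config) {
  a <- config$assay
  if (any(a$true_frequency < 0) || any(a$true_frequency > 1)) {
    rlang::abort("true_frequency must be in [0, 1]")
  }
  set.seed(stage_seed(config$seed, "assay"))
  purrr::map_dfr(names(a$true_frequency), function(cond) {
    f <- a$true_frequency[[cond]]
    col_pe <- stats::rbinom(1, a$cells_plated_pe, a$plating_efficiency)
    tibble::tibble(
      condition = cond,
      dish = seq_len(a$n_dishes),
      cells_plated_selection = a$cells_per_dish,
      colonies_6tg = stats::rpois(a$n_dishes,
                                  a$cells_per_dish * f * a$plating_efficiency),
      cells_plated_pe = a$cells_plated_pe,
      colonies_pe = col_pe
    )
  })
}

#' Generate a complete synthetic fixture directory
#'
#' Runs every generator and writes the standard-format files consumed by the
#' analysis entry points: `genome.fa`, four mark BEDs, `tet2.bed`,
#' `variants.vcf`, truth TSVs, `cohort.tsv`, `assay.tsv` and the resolved
#' configuration as JSON. Byte-identical under a fixed seed.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the generated objects and `paths`.
#' @export
simulate_all <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(config)
  pk <- simulate_peaks(config, genome)
  muts <- simulate_mutations(config, genome, pk$truth)
  cohort <- simulate_cohort(config)
  assay <- simulate_fluctuation(config)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    hmc_wt = file.path(dir, "hmc_wt.bed"), hmc_ko = file.path(dir, "hmc_ko.bed"),
    mc_wt = file.path(dir, "mc_wt.bed"), mc_ko = file.path(dir, "mc_ko.bed"),
    tet2 = file.path(dir, "tet2.bed"),
    vcf = file.path(dir, "variants.vcf"),
    truth_regions = file.path(dir, "truth_regions.tsv"),
    truth_variants = file.path(dir, "truth_variants.tsv"),
    cohort = file.path(dir, "cohort.tsv"),
    assay = file.path(dir, "assay.tsv"),
    config = file.path(dir, "config.json")
  )
  write_fasta(genome, paths$genome)
  for (nm in c("hmc_wt", "hmc_ko", "mc_wt", "mc_ko", "tet2")) {
    write_bed(pk[[nm]], paths[[nm]])
  }
  write_vcf(muts, paths$vcf)
  readr::write_tsv(pk$truth, paths$truth_regions)
  readr::write_tsv(muts, paths$truth_variants)
  readr::write_tsv(cohort, paths$cohort)
  readr::write_tsv(assay, paths$assay)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(genome = genome, peaks = pk, mutations = muts,
                 cohort = cohort, assay = assay, paths = paths))
}
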