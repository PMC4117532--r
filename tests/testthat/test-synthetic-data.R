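test_that("generators are pure functions of spec and seed", {
  spec <- synthetic_genome_spec(
    length = 6000L, seed = 11L,
    repeats = data.frame(name = "r", unit = "GAAA", copies = 14,
                         purity = 100, start = 2000L),
    cgis = data.frame(name = "c", start = 2300L, length = 300L),
    sites = data.frame(enzyme = "HpaII", repeat_name = "r", offset = 30L))
  g1 <- build_synthetic_genome(spec)
  g2 <- build_synthetic_genome(spec)
  expect_identical(g1$seq, g2$seq)
  expect_identical(g1$truth, g2$truth)

  cs <- cohort_spec(n_females = 8, n_males = 3, area_cv = 0.1, seed = 21L)
  s1 <- simulate_cohort(cs)
  s2 <- simulate_cohort(cs)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$genotypes, s2$genotypes)
})

test_that("planted genome features are recovered by the detection operations", {
  spec <- synthetic_genome_spec(
    length = 9000L, seed = 31L,
    repeats = data.frame(name = c("r1", "r2"), unit = c("GAAA", "CAGT"),
                         copies = c(16, 13), purity = 100,
                         start = c(2000L, 6000L)),
    cgis = data.frame(name = "c1", start = 2500L, length = 500L),
    sites = data.frame(enzyme = c("HpaII", "BstUI"),
                       repeat_name = c("r1", "r1"), offset = c(40L, 60L)))
  g <- build_synthetic_genome(spec)
  reps <- find_tandem_repeats(g$seq, repeat_scan_params(min_copy_number = 12,
                                                        min_match_pct = 90))
  for (i in seq_len(nrow(g$truth))) {
    hit <- reps[reps$start == g$truth$start[i] & reps$end == g$truth$end[i], ]
    expect_equal(nrow(hit), 1L, info = g$truth$name[i])
    expect_equal(hit$copy_number, g$truth$copies[i])
    expect_equal(hit$match_pct, 100)
  }
  isl <- detect_cpg_islands(g$seq)
  expect_true(any(abs(isl$start - 2500) <= 200 & abs(isl$end - 3000) <= 200))
  sites <- scan_restriction_sites(g$seq)
  for (i in seq_len(nrow(g$sites))) {
    expect_true(any(sites$start == g$sites$start[i] &
                      sites$enzyme == g$sites$enzyme[i]),
                info = g$sites$enzyme[i])
  }
})

test_that("impure planted arrays carry their designed imperfection", {
  spec <- synthetic_genome_spec(
    length = 5000L, seed = 41L,
    repeats = data.frame(name = "r", unit = "GAAA", copies = 16,
                         purity = 95, start = 2000L))
  g <- build_synthetic_genome(spec)
  reps <- find_tandem_repeats(g$seq, repeat_scan_params(min_copy_number = 12,
                                                        min_match_pct = 80))
  hit <- reps[abs(reps$start - 2000) < 5, ]
  expect_equal(nrow(hit), 1L)
  expect_lt(hit$match_pct, 100)
  expect_gt(hit$match_pct, 90)
  expect_lt(hit$longest_perfect_run, 16L)
})

test_that("overlapping planted features are rejected at spec construction", {
  expect_error(synthetic_genome_spec(
    length = 5000L,
    repeats = data.frame(name = "r", unit = "GAAA", copies = 16,
                         purity = 100, start = 2000L),
    cgis = data.frame(name = "c", start = 2010L, length = 300L)),
    "overlap")
  expect_error(synthetic_genome_spec(
    length = 100L,
    repeats = data.frame(name = "r", unit = "GAAA", copies = 30,
                         purity = 100, start = 50L)),
    "outside")
})

test_that("the noise-free full-digestion pipeline returns planted Xi fractions exactly", {
  for (s in c(0.5, 0.65, 0.8, 0.9, 0.99)) {
    sim <- simulate_cohort(cohort_spec(n_females = 6, n_males = 2, skew = s,
                                       area_cv = 0, seed = 7L))
    res <- quantify_xci(sim$peaks)
    merged <- merge(res, sim$truth, by = c("sample", "locus"))
    inf <- merged[!is.na(merged$xi_fraction_allele1.x) & merged$heterozygous, ]
    expect_gt(nrow(inf), 0)
    expect_equal(inf$xi_fraction_allele1.x, inf$xi_fraction_allele1.y,
                 tolerance = 1e-9, info = sprintf("s = %.2f", s))
    expect_equal(inf$main_inactive_pct.x,
                 rep(100 * max(s, 1 - s), nrow(inf)), tolerance = 1e-9)
  }
})

test_that("full-efficiency digestion abolishes the male allele (QC passes)", {
  sim <- simulate_cohort(cohort_spec(n_females = 2, n_males = 5, skew = 0.6,
                                     area_cv = 0, seed = 9L))
  males <- sprintf("S%03d", 3:7)
  qc <- batch_digestion_qc(sim$peaks, males)
  expect_gt(nrow(qc), 0)
  expect_true(all(qc$pass))
  expect_true(all(qc$residual_ratio == 0))
  # incomplete digestion is detected
  sim2 <- simulate_cohort(cohort_spec(n_females = 2, n_males = 5, skew = 0.6,
                                      digestion_efficiency = 0.8,
                                      area_cv = 0, seed = 9L))
  qc2 <- batch_digestion_qc(sim2$peaks, males)
  expect_false(any(qc2$pass))
})

test_that("mean recovered skew is within 3 points of truth at n = 50", {
  for (s in c(0.5, 0.65, 0.8, 0.9, 0.99)) {
    sim <- simulate_cohort(cohort_spec(
      n_females = 50, n_males = 0, skew = s, area_cv = 0.05,
      seed = 1000L + round(100 * s),
      loci = default_cohort_loci()[1]))
    res <- quantify_xci(sim$peaks)
    got <- res$main_inactive_pct[!is.na(res$main_inactive_pct)]
    expect_gt(length(got), 20)
    expect_lt(abs(mean(got) - 100 * max(s, 1 - s)), 3,
              label = sprintf("skew recovery at s = %.2f", s))
  }
})

test_that("two loci driven by shared Xi fractions are highly concordant", {
  sim <- simulate_cohort(cohort_spec(n_females = 50, n_males = 0,
                                     area_cv = 0.05, seed = 77L))
  res <- quantify_xci(sim$peaks)
  a <- res[res$locus == "GAAA", c("sample", "main_inactive_pct")]
  b <- res[res$locus == "CAG", c("sample", "main_inactive_pct")]
  m <- merge(a, b, by = "sample")
  m <- m[!is.na(m$main_inactive_pct.x) & !is.na(m$main_inactive_pct.y), ]
  expect_gte(nrow(m), 20)
  cc <- concordance(m$main_inactive_pct.x, m$main_inactive_pct.y)
  expect_gte(cc$spearman_r, 0.9)
  expect_lt(cc$p_value, 1e-4)
})

test_that("stutter parameter is recovered from hemizygous cohorts", {
  sim <- simulate_cohort(cohort_spec(n_females = 0, n_males = 60,
                                     area_cv = 0.1, seed = 42L))
  und <- sim$peaks[sim$peaks$treatment == "undigested", ]
  est_gaaa <- estimate_stutter_fraction(und[und$locus == "GAAA", ], 4)
  est_cag <- estimate_stutter_fraction(und[und$locus == "CAG", ], 3)
  expect_lt(abs(est_gaaa - 0.026), 0.003)   # within 0.3 percentage points
  expect_lt(abs(est_cag - 0.176), 0.01)     # within 1 percentage point
})

test_that("biallelic populations obey Hardy-Weinberg heterozygosity", {
  expect_error(simulate_biallelic_population(1, 10), "strictly inside")
  expect_error(simulate_biallelic_population(0, 10), "strictly inside")
  g <- simulate_biallelic_population(0.22, 10000, seed = 5L)
  h <- population_stats(g)$observed_heterozygosity
  expect_lt(abs(h - 2 * 0.22 * 0.78), 0.02)
  g2 <- simulate_biallelic_population(0.5, 10000, seed = 6L)
  h2 <- population_stats(g2)$observed_heterozygosity
  expect_lt(abs(h2 - 0.5), 0.02)
})

test_that("a monomorphic frequency table yields no heterozygotes, not an error", {
  loci <- list(list(id = "MONO", unit_bp = 4L, stutter_fraction = 0.02,
                    allele_sizes = 360, allele_freqs = 1))
  sim <- simulate_cohort(cohort_spec(loci = loci, n_females = 10, n_males = 0,
                                     skew = 0.7, area_cv = 0, seed = 3L))
  expect_true(all(!sim$truth$heterozygous))
  res <- quantify_xci(sim$peaks, models = list(MONO = stutter_model("MONO", 4, 0.02)))
  expect_true(all(is.na(res$main_inactive_pct)))
})
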