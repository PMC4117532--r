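test_that("stutter fraction estimation averages per-sample ratios", {
  peaks <- data.frame(
    sample = rep(c("m1", "m2", "m3"), each = 2),
    locus = "GAAA", treatment = "undigested",
    allele_size = c(368, 364, 360, 356, 372, 368),
    area = c(10000, 260, 8000, 208, 4000, 104),
    height = c(1000, 26, 800, 21, 400, 10))
  expect_equal(estimate_stutter_fraction(peaks, 4), 0.026)

  no_stutter <- peaks[c(1, 3, 5), ]
  expect_equal(estimate_stutter_fraction(no_stutter, 4), 0)
  expect_error(estimate_stutter_fraction(peaks[0, ], 4), "stutter_model")
})

test_that("stutter correction applies only at the n-1 position and conserves area", {
  m <- stutter_model("GAAA", 4, 0.026)
  adj <- correct_stutter(c(368, 364), c(10000, 5260), m)
  expect_equal(adj$areas, c(10000, 5000))
  expect_equal(adj$subtracted[2], 260)
  # conservation: corrected + subtracted = observed
  expect_equal(adj$areas[2] + adj$subtracted[2], 5260, tolerance = 1e-9)

  far <- correct_stutter(c(368, 352), c(10000, 5260), m)
  expect_equal(far$areas, c(10000, 5260))

  none <- correct_stutter(c(368, 364), c(10000, 5260), stutter_model("x", 4, 0))
  expect_equal(none$areas, c(10000, 5260))

  over <- correct_stutter(c(368, 364), c(10000, 150), stutter_model("x", 4, 0.2))
  expect_equal(over$areas[2], 0)
  expect_identical(over$qc, "stutter_overcorrection")
})

test_that("Xi fractions follow the normalized digested-ratio formula", {
  bal <- compute_xci_ratio(c(10000, 10000), c(5000, 5000))
  expect_equal(bal$xi_fraction_allele1, 0.5)
  expect_equal(bal$main_inactive_pct, 50)
  expect_equal(bal$skew_class, "random")

  sk <- compute_xci_ratio(c(5000, 10000), c(5000, 2000))
  expect_equal(sk$xi_fraction_allele1, 1 / 1.2)   # (1.0)/(1.0 + 0.2)
  expect_equal(sk$skew_class, "non_random")

  full <- compute_xci_ratio(c(8000, 9000), c(7900, 0))
  expect_equal(full$xi_fraction_allele1, 1)
  expect_equal(full$main_inactive_pct, 100)
  expect_true("extremely_skewed" %in% full$qc)

  expect_error(compute_xci_ratio(c(0, 10000), c(1, 1)),
               "uninformative_or_allele_dropout")
  expect_error(compute_xci_ratio(c(10000, 10000), c(0, 0)),
               "total_digestion_no_signal")
})

test_that("swapping allele labels maps r to 1-r and preserves the call", {
  set.seed(5)
  for (i in 1:25) {
    u <- runif(2, 1000, 20000)
    d <- runif(2, 0, 1) * u
    a <- compute_xci_ratio(u, d)
    b <- compute_xci_ratio(rev(u), rev(d))
    expect_equal(a$xi_fraction_allele1, 1 - b$xi_fraction_allele1,
                 tolerance = 1e-12)
    expect_equal(a$main_inactive_pct, b$main_inactive_pct, tolerance = 1e-12)
    expect_identical(a$skew_class, b$skew_class)
  }
  # normalization identity: digested == undigested gives exactly 0.5
  u <- c(8123.4, 15321.9)
  expect_equal(compute_xci_ratio(u, u)$xi_fraction_allele1, 0.5)
})

test_that("skewing classification uses the strict 80% boundary", {
  expect_identical(classify_skewing(65), "random")
  expect_identical(classify_skewing(80), "random")
  expect_identical(classify_skewing(80.5), "non_random")
  expect_identical(classify_skewing(95), "non_random")
  expect_error(classify_skewing(38), "fold")
})

test_that("digestion QC compares residual signal to tolerance", {
  expect_true(digestion_qc(10000, 0)$pass)
  expect_true(digestion_qc(10000, 400)$pass)     # ratio 0.04
  expect_false(digestion_qc(10000, 1000)$pass)   # ratio 0.10
  expect_error(digestion_qc(NA, 100), "undigested companion")
  # all-female batch: no applicable control
  peaks <- data.frame(sample = "f1", locus = "L", treatment = "undigested",
                      allele_size = 100, area = 1, height = 1)
  expect_warning(qc <- batch_digestion_qc(peaks, character()),
                 "no applicable")
  expect_identical(nrow(qc), 0L)
})

test_that("population statistics count heterozygous females", {
  g <- data.frame(sample = sprintf("s%02d", 1:19),
                  sex = c(rep("F", 14), rep("M", 5)),
                  allele1 = c(rep(318, 9), rep(318, 5), rep(327, 5)),
                  allele2 = c(rep(318, 9), rep(327, 5), rep(NA, 5)))
  st <- population_stats(g)
  expect_equal(st$n_typed, 14L)
  expect_equal(st$n_heterozygous, 5L)
  expect_equal(st$observed_heterozygosity, 5 / 14)
  expect_equal(sum(st$allele_frequencies), 1, tolerance = 1e-9)
  expect_equal(st$allelic_span, 9)

  hom <- data.frame(sample = "a", sex = "F", allele1 = 318, allele2 = 318)
  expect_equal(population_stats(hom)$observed_heterozygosity, 0)
  males <- data.frame(sample = "m", sex = "M", allele1 = 318, allele2 = NA)
  expect_error(population_stats(males), "zero typed females")
})

test_that("combined informativeness covers independence and empirical modes", {
  # two equally weighted subsets with printed per-locus heterozygosities
  expect_equal(round(combined_informativeness(
    list(c(0.85, 0.85), c(0.73, 0.87))), 2), 0.97)
  expect_equal(combined_informativeness(0.85), 0.85)
  emp <- data.frame(sample = c("a", "b", "c"),
                    locusA = c(TRUE, TRUE, TRUE),
                    locusB = c(FALSE, TRUE, FALSE))
  expect_equal(combined_informativeness(emp, mode = "empirical"), 1)
  emp$locusA <- c(TRUE, FALSE, FALSE)
  expect_equal(combined_informativeness(emp, mode = "empirical"), 2 / 3)
  expect_error(combined_informativeness(
    data.frame(sample = "a", locusA = 1), mode = "empirical"), "logical")
})

test_that("the allelic span reproduces the printed amplimer range", {
  expect_equal(allelic_span(c(350, 362, 374, 391)), 41)
  expect_equal(allelic_span(368), 0)
})

test_that("concordance matches a first-principles rank computation", {
  x <- c(52, 55, 61, 64, 70, 75, 81, 88, 93, 99)
  expect_equal(concordance(x, x)$spearman_r, 1)
  expect_equal(concordance(x, rev(x))$spearman_r, -1)

  set.seed(8)
  y <- x + rnorm(10, 0, 6)
  got <- concordance(x, y)
  expect_equal(got$spearman_r, oracle_spearman(x, y), tolerance = 1e-12)
  expect_equal(got$n, 10L)
  expect_true(got$ci95[1] <= got$spearman_r && got$spearman_r <= got$ci95[2])
  # ties are mid-ranked in both routes
  yt <- c(1, 2, 2, 3, 4, 5, 5, 6, 7, 8)
  expect_equal(concordance(x, yt)$spearman_r, oracle_spearman(x, yt),
               tolerance = 1e-12)
  expect_error(concordance(c(1, 2), c(1, 2)), "insufficient")
})

test_that("trio phasing assigns the parental origin of Xi", {
  expect_identical(phase_trio(c(368, 350), 340, c(368, 340), 368), "maternal")
  expect_identical(phase_trio(c(350, 354), 368, c(350, 368), 368), "paternal")
  expect_identical(phase_trio(c(368, 350), 368, c(368, 368), 368), "ambiguous")
  expect_error(phase_trio(c(350, 354), 340, c(350, 368), 368), "Mendelian")
})
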