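#' Specification of a simulated QF-PCR cohort
#'
#' Recipe for electropherogram peak tables of a genotyped cohort: allele
#' frequencies per locus, the distribution of inactivation skewing across
#' females, per-locus stutter fractions, digestion behaviour and
#' multiplicative area noise. Defaults emulate the two-locus
#' tetranucleotide (GAAA, low stutter) / trinucleotide (CAG, high stutter)
#' biplex: stutter fractions 0.026 and 0.176, full digestion, and a skew
#' mixture in which most females are random (folded Beta around 0.5,
#' main inactive allele within 50-80%) and the remainder skewed at fixed
#' strong values.
#'
#' @param loci List of locus descriptors, each a list with `id`,
#'   `unit_bp`, `stutter_fraction`, `allele_sizes` (bp) and
#'   `allele_freqs` (summing to 1).
#' @param n_females,n_males Cohort sizes.
#' @param skew Either a single numeric in `[0.5, 1)` applied to every
#'   female, or a list with `random_frac`, `beta_shape` (symmetric Beta
#'   concentration for the random component) and `skewed_values` (vector
#'   of Xi fractions for the skewed component).
#' @param digestion_efficiency Probability that an unmethylated site is
#'   cut, in `[0, 1]` (1 = complete digestion).
#' @param area_cv Coefficient of variation of the multiplicative
#'   log-normal area noise (0 = noise-free).
#' @param enzymes Digestion treatments to simulate.
#' @param base_area Mean undigested per-allele peak area.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(loci = default_cohort_loci(),
                        n_females = 50L, n_males = 10L,
                        skew = list(random_frac = 0.7, beta_shape = 12,
                                    skewed_values = c(0.85, 0.92, 0.99)),
                        digestion_efficiency = 1, area_cv = 0,
                        enzymes = "HpaII", base_area = 10000, seed = 1L) {
  stopifnot(area_cv >= 0, digestion_efficiency >= 0, digestion_efficiency <= 1)
  for (lc in loci) {
    stopifnot(all(c("id", "unit_bp", "stutter_fraction", "allele_sizes",
                    "allele_freqs") %in% names(lc)))
    if (abs(sum(lc$allele_freqs) - 1) > 1e-9) {
      stop("allele frequencies of locus ", lc$id, " do not sum to 1",
           call. = FALSE)
    }
    stopifnot(lc$stutter_fraction >= 0, lc$stutter_fraction < 1)
  }
  structure(list(loci = loci, n_females = as.integer(n_females),
                 n_males = as.integer(n_males), skew = skew,
                 digestion_efficiency = digestion_efficiency,
                 area_cv = area_cv, enzymes = enzymes,
                 base_area = base_area, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_cohort_loci <- function() {
  list(
    list(id = "GAAA", unit_bp = 4L, stutter_fraction = 0.026,
         allele_sizes = seq(352, 388, by = 4),
         allele_freqs = c(0.04, 0.06, 0.10, 0.15, 0.22, 0.18, 0.12,
                          0.07, 0.04, 0.02)),
    list(id = "CAG", unit_bp = 3L, stutter_fraction = 0.176,
         allele_sizes = seq(259, 286, by = 3),
         allele_freqs = c(0.05, 0.08, 0.14, 0.20, 0.20, 0.14, 0.08,
                          0.06, 0.03, 0.02))
  )
}

#' Simulate a QF-PCR cohort
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium from the locus
#' frequency tables (males hemizygous). Each female receives one skew
#' parameter `s` (the Xi fraction of a randomly oriented allele) shared by
#' all her loci, so inter-locus concordance reflects a common cellular
#' state. Undigested allele areas are `base_area` per allele dose;
#' digestion retains the methylated (Xi) dose plus the uncut remainder
#' `(1 - efficiency)` of the unmethylated dose; a male's single X is fully
#' active, hence fully cut at full efficiency. Stutter adds
#' `stutter_fraction` of each allele's area one repeat unit below it
#' (co-migrating peaks sum). All areas then receive independent
#' multiplicative log-normal noise of the stated CV. Same spec, same seed:
#' identical tables.
#'
#' @param spec A [cohort_spec()].
#' @return List with `genotypes` (sample, sex, locus, allele1, allele2),
#'   `peaks` (a peak table covering `undigested` plus each enzyme) and
#'   `truth` (per sample/locus: skew `s`, `xi_fraction_allele1`,
#'   `main_inactive_pct`, heterozygosity).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_females + spec$n_males
  samples <- sprintf("S%03d", seq_len(n))
  sex <- c(rep("F", spec$n_females), rep("M", spec$n_males))
  s_female <- draw_skew(spec$skew, spec$n_females)
  skew_of <- setNames(c(s_female, rep(NA_real_, spec$n_males)), samples)

  geno <- truth <- list()
  peak_rows <- list()
  noisy <- function(x) {
    if (spec$area_cv == 0 || length(x) == 0L) return(x)
    sdlog <- sqrt(log(1 + spec$area_cv^2))
    x * rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  for (lc in spec$loci) {
    for (i in seq_len(n)) {
      smp <- samples[i]
      a <- lc$allele_sizes[sample.int(length(lc$allele_sizes),
                                      if (sex[i] == "F") 2L else 1L,
                                      replace = TRUE, prob = lc$allele_freqs)]
      a <- sort(a)
      a1 <- a[1]; a2 <- if (length(a) == 2L) a[2] else NA_real_
      het <- !is.na(a2) && a1 != a2
      s <- skew_of[[smp]]
      # Xi fraction attributed to allele1 (the shorter): random orientation
      xi1 <- if (sex[i] == "F") { if (runif(1) < 0.5) s else 1 - s } else NA_real_
      geno[[length(geno) + 1L]] <- data.frame(
        sample = smp, sex = sex[i], locus = lc$id,
        allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        sample = smp, sex = sex[i], locus = lc$id, skew = s,
        xi_fraction_allele1 = if (het) xi1 else NA_real_,
        main_inactive_pct = if (!is.na(s)) 100 * max(s, 1 - s) else NA_real_,
        heterozygous = het, stringsAsFactors = FALSE)

      # per-allele-copy doses: female het (1,1) on two sizes, hom (2) on one
      sizes <- unique(a)
      dose <- vapply(sizes, function(sz) sum(a == sz), numeric(1))
      und <- spec$base_area * dose
      meth <- if (sex[i] == "M") 0 else if (het) {
        c(xi1, 1 - xi1)
      } else if (!is.na(s)) {
        # homozygote: both copies co-migrate; methylated dose is s+(1-s)=1 copy
        0.5
      } else 0
      eff <- spec$digestion_efficiency
      dig <- und * (meth + (1 - meth) * (1 - eff))
      add_peaks <- function(areas, treatment) {
        pk <- setNames(areas, sizes)
        for (j in seq_along(sizes)) {
          st_size <- sizes[j] - lc$unit_bp
          st_area <- lc$stutter_fraction * areas[j]
          if (st_area > 0) {
            key <- as.character(st_size)
            pk[key] <- if (key %in% names(pk)) pk[[key]] + st_area else st_area
          }
        }
        pk <- noisy(pk)
        pk <- pk[pk > 0]
        if (length(pk) == 0L) return()
        peak_rows[[length(peak_rows) + 1L]] <<- data.frame(
          sample = smp, locus = lc$id, treatment = treatment,
          allele_size = as.numeric(names(pk)), area = as.numeric(pk),
          height = as.numeric(pk) / 10, stringsAsFactors = FALSE)
      }
      add_peaks(und, "undigested")
      for (enz in spec$enzymes) add_peaks(dig, enz)
    }
  }
  genotypes <- do.call(rbind, geno)
  truth_df <- do.call(rbind, truth)
  peaks <- do.call(rbind, peak_rows)
  rownames(genotypes) <- rownames(truth_df) <- rownames(peaks) <- NULL
  list(genotypes = genotypes, peaks = validate_peak_table(peaks),
       truth = truth_df)
}

draw_skew <- function(skew, n_females) {
  if (n_females == 0L) return(numeric())
  if (is.numeric(skew) && length(skew) == 1L) {
    stopifnot(skew >= 0.5, skew < 1)
    return(rep(skew, n_females))
  }
  stopifnot(is.list(skew),
            all(c("random_frac", "beta_shape", "skewed_values") %in% names(skew)))
  is_random <- runif(n_females) < skew$random_frac
  s <- numeric(n_females)
  nr <- sum(is_random)
  if (nr > 0L) {
    b <- rbeta(nr, skew$beta_shape, skew$beta_shape)
    # fold to [0.5, 0.8]: random XCI spans main-allele 50-80%
    s[is_random] <- pmin(0.5 + abs(b - 0.5), 0.8)
  }
  ns <- n_females - nr
  if (ns > 0L) {
    s[!is_random] <- sample(skew$skewed_values, ns, replace = TRUE)
  }
  s
}

#' Simulate a biallelic Hardy-Weinberg population
#'
#' Female genotypes at a two-allele locus with allele-1 frequency `p`.
#' Observed heterozygosity converges to `2p(1-p)`, maximised at 0.5 when
#' `p = 0.5` -- the ceiling for any biallelic system.
#'
#' @param p Frequency of the first allele, strictly inside (0, 1).
#' @param n Number of females.
#' @param seed Integer seed.
#' @param allele_sizes Length-2 allele sizes in bp.
#' @return Genotype data.frame (`sample`, `sex`, `allele1`, `allele2`).
#' @export
simulate_biallelic_population <- function(p, n, seed = 1L,
                                          allele_sizes = c(318, 327)) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("allele frequency p must lie strictly inside (0, 1)", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- matrix(sample(allele_sizes, 2L * n, replace = TRUE,
                         prob = c(p, 1 - p)), ncol = 2L)
  data.frame(sample = sprintf("S%04d", seq_len(n)), sex = "F",
             allele1 = pmin(draws[, 1], draws[, 2]),
             allele2 = pmax(draws[, 1], draws[, 2]),
             stringsAsFactors = FALSE)
}
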