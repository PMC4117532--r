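#' Stutter model for a locus
#'
#' PCR slippage produces a stutter peak one repeat unit below each true
#' allele with area proportional to the true-allele area. The proportionality
#' constant is locus-specific: tetranucleotide arrays stutter far less than
#' trinucleotide arrays.
#'
#' @param locus Locus id.
#' @param repeat_unit_bp Repeat unit length in bp.
#' @param stutter_fraction Expected stutter area as a fraction of the true
#'   allele area at the n-1 position; must be < 1.
#' @return A list of class `stutter_model`.
#' @export
stutter_model <- function(locus, repeat_unit_bp, stutter_fraction) {
  stopifnot(stutter_fraction >= 0, stutter_fraction < 1, repeat_unit_bp >= 1)
  structure(list(locus = locus, repeat_unit_bp = as.integer(repeat_unit_bp),
                 stutter_fraction = stutter_fraction),
            class = "stutter_model")
}

#' Default stutter models for the two assay loci
#'
#' Mean stutter-to-true-allele area fractions: 0.026 for the RP2-promoter
#' GAAA tetranucleotide and 0.176 for the AR exon-1 CAG trinucleotide.
#'
#' @return Named list of [stutter_model()] objects (`GAAA`, `CAG`).
#' @export
default_stutter_models <- function() {
  list(GAAA = stutter_model("GAAA", 4L, 0.026),
       CAG = stutter_model("CAG", 3L, 0.176))
}

#' Estimate the stutter fraction from single-allele samples
#'
#' Hemizygous (male) or homozygous samples carry one true allele, so any
#' peak one repeat unit below it is pure stutter. The estimate is the mean
#' over samples of stutter area / true-allele area; a sample with no
#' detectable stutter peak contributes 0.
#'
#' @param peaks Peak table (see [read_peak_table()]) restricted to one locus
#'   and one treatment; each sample must show exactly one true allele.
#' @param repeat_unit_bp Repeat unit length in bp.
#' @param size_tol Matching tolerance in bp for the stutter position
#'   (default 1).
#' @return Estimated stutter fraction (mean of per-sample ratios).
#' @export
estimate_stutter_fraction <- function(peaks, repeat_unit_bp, size_tol = 1) {
  samples <- unique(peaks$sample)
  if (length(samples) == 0L) {
    stop("no single-allele samples available; supply a stutter_model instead",
         call. = FALSE)
  }
  ratios <- vapply(samples, function(s) {
    pk <- peaks[peaks$sample == s, , drop = FALSE]
    true_i <- which.max(pk$area)
    true_size <- pk$allele_size[true_i]
    st <- which(abs(pk$allele_size - (true_size - repeat_unit_bp)) <= size_tol)
    if (length(st) == 0L) 0 else sum(pk$area[st]) / pk$area[true_i]
  }, numeric(1))
  mean(ratios)
}

#' Correct allele peak areas for stutter
#'
#' When the two alleles of a heterozygote are exactly one repeat unit apart,
#' the stutter of the longer allele co-migrates with the shorter allele's
#' true peak. The shorter allele's area is corrected by subtracting
#' `stutter_fraction` times the longer allele's observed area (floored at
#' zero); alleles further apart are left unchanged.
#'
#' @param sizes Numeric vector of the two allele sizes (bp); a single size
#'   is returned unchanged.
#' @param areas Observed peak areas, same order as `sizes`.
#' @param model A [stutter_model()].
#' @param size_tol Tolerance in bp for "one unit apart" (default 1).
#' @return List with `areas` (corrected), `subtracted` (stutter removed from
#'   each peak) and `qc` (character vector of flags;
#'   `"stutter_overcorrection"` when the correction exceeded the observed
#'   area by more than 5%).
#' @export
correct_stutter <- function(sizes, areas, model, size_tol = 1) {
  stopifnot(inherits(model, "stutter_model"), length(sizes) == length(areas))
  subtracted <- rep(0, length(areas))
  qc <- character()
  if (length(sizes) == 2L) {
    gap <- abs(sizes[1] - sizes[2])
    if (abs(gap - model$repeat_unit_bp) <= size_tol) {
      short_i <- which.min(sizes)
      long_i <- which.max(sizes)
      stut <- model$stutter_fraction * areas[long_i]
      corrected <- areas[short_i] - stut
      if (corrected < -0.05 * areas[short_i]) qc <- "stutter_overcorrection"
      subtracted[short_i] <- min(stut, areas[short_i])
      areas[short_i] <- max(corrected, 0)
    }
  }
  list(areas = areas, subtracted = subtracted, qc = qc)
}

#' Compute the Xa/Xi ratio from paired undigested and digested areas
#'
#' After digestion with a methylation-sensitive enzyme, only methylated
#' (inactive-X) alleles survive to amplify. Normalising each digested area
#' by its undigested companion removes allele-specific amplification bias:
#' `xi_fraction_allele1 = (d1/u1) / (d1/u1 + d2/u2)` is the proportion of
#' cells carrying allele 1 on the inactive X.
#'
#' @param undigested Numeric length-2, areas (u1, u2); both must be > 0.
#' @param digested Numeric length-2, areas (d1, d2); non-negative.
#' @return List with `xi_fraction_allele1`, `main_inactive_pct`
#'   (`100 * max(r, 1 - r)`), `skew_class` and `qc` flags.
#' @export
compute_xci_ratio <- function(undigested, digested) {
  stopifnot(length(undigested) == 2L, length(digested) == 2L)
  if (any(undigested <= 0)) {
    stop("uninformative_or_allele_dropout: undigested area of zero",
         call. = FALSE)
  }
  if (any(digested < 0)) stop("digested areas must be non-negative", call. = FALSE)
  if (sum(digested) == 0) {
    stop("total_digestion_no_signal: no digested signal on either allele",
         call. = FALSE)
  }
  n1 <- digested[1] / undigested[1]
  n2 <- digested[2] / undigested[2]
  r <- n1 / (n1 + n2)
  main <- 100 * max(r, 1 - r)
  list(xi_fraction_allele1 = r,
       main_inactive_pct = main,
       skew_class = classify_skewing(main),
       qc = if (main >= 90) "extremely_skewed" else character())
}

#' Classify inactivation skewing
#'
#' Random inactivation spans main-inactive-allele percentages of 50-80;
#' above 80 (strictly) the pattern is called non-random. 80 itself is
#' random.
#'
#' @param main_inactive_pct Percentage in `[50, 100]` of cells inactivating
#'   the majority allele.
#' @return `"random"` or `"non_random"`.
#' @export
classify_skewing <- function(main_inactive_pct) {
  if (any(main_inactive_pct < 50 | main_inactive_pct > 100)) {
    stop("main_inactive_pct must lie in [50,100]; fold to the main allele first",
         call. = FALSE)
  }
  ifelse(main_inactive_pct > 80, "non_random", "random")
}

#' Digestion quality control on single-X samples
#'
#' A male (or otherwise hemizygous) sample carries its only X active and
#' therefore unmethylated: complete digestion must abolish its allele peak.
#' Residual digested signal above tolerance indicates incomplete digestion
#' and invalidates the batch.
#'
#' @param undigested_area,digested_area Areas of the single allele in the
#'   undigested and digested runs.
#' @param tolerance Maximum acceptable residual ratio (default 0.05).
#' @return List with `pass` (logical) and `residual_ratio`.
#' @export
digestion_qc <- function(undigested_area, digested_area, tolerance = 0.05) {
  if (missing(undigested_area) || is.na(undigested_area) || undigested_area <= 0) {
    stop("missing undigested companion for digestion QC", call. = FALSE)
  }
  ratio <- digested_area / undigested_area
  list(pass = ratio <= tolerance, residual_ratio = ratio)
}

#' Population allele statistics for an STR locus
#'
#' Observed heterozygosity is the fraction of typed females with two
#' distinct alleles; hemizygous males contribute alleles to the frequency
#' table but are excluded from the heterozygosity denominator. Expected
#' heterozygosity `1 - sum(p_i^2)` is reported alongside.
#'
#' @param genotypes Data.frame with columns `sample`, `sex` (`"F"`/`"M"`),
#'   `allele1`, `allele2` (`allele2` `NA` for hemizygous males).
#' @return List with `n_typed`, `n_heterozygous`, `observed_heterozygosity`,
#'   `expected_heterozygosity`, `allele_frequencies` (named numeric summing
#'   to 1) and `allelic_span` (bp between longest and shortest allele).
#' @export
population_stats <- function(genotypes) {
  females <- genotypes[genotypes$sex == "F", , drop = FALSE]
  if (nrow(females) == 0L) {
    stop("zero typed females: heterozygosity undefined", call. = FALSE)
  }
  het <- females$allele1 != females$allele2
  alleles <- c(genotypes$allele1, genotypes$allele2)
  alleles <- alleles[!is.na(alleles)]
  freq <- table(alleles) / length(alleles)
  freqs <- as.numeric(freq)
  names(freqs) <- names(freq)
  list(n_typed = nrow(females),
       n_heterozygous = sum(het),
       observed_heterozygosity = mean(het),
       expected_heterozygosity = 1 - sum(freqs^2),
       allele_frequencies = freqs,
       allelic_span = allelic_span(as.numeric(names(freqs))))
}

#' Allelic span of a locus
#'
#' Difference in bp between the longest and shortest observed allele.
#'
#' @param sizes Numeric allele sizes in bp.
#' @return Span in bp (0 for a single allele).
#' @export
allelic_span <- function(sizes) {
  sizes <- sizes[!is.na(sizes)]
  if (length(sizes) == 0L) return(NA_real_)
  max(sizes) - min(sizes)
}

#' Combined informativeness of a multi-locus assay
#'
#' Probability that at least one marker is heterozygous. In `independence`
#' mode this is `1 - prod(1 - H_locus)` from per-locus heterozygosities;
#' when several population subsets are given (a list of heterozygosity
#' vectors), subset values are averaged with equal weight. In `empirical`
#' mode it is the fraction of samples heterozygous at one or more loci.
#'
#' @param x For `independence` mode, a numeric vector of per-locus
#'   heterozygosities or a list of such vectors (one per subset). For
#'   `empirical` mode, a data.frame with column `sample` and one logical
#'   heterozygosity column per locus.
#' @param mode `"independence"` or `"empirical"`.
#' @return Combined informativeness in `[0, 1]`.
#' @export
combined_informativeness <- function(x, mode = c("independence", "empirical")) {
  mode <- match.arg(mode)
  if (mode == "independence") {
    if (!is.list(x) || is.data.frame(x)) x <- list(x)
    vals <- vapply(x, function(h) 1 - prod(1 - h), numeric(1))
    mean(vals)
  } else {
    stopifnot(is.data.frame(x), "sample" %in% names(x))
    het_cols <- x[setdiff(names(x), "sample")]
    if (any(!vapply(het_cols, is.logical, logical(1)))) {
      stop("empirical mode needs logical per-locus heterozygosity columns",
           call. = FALSE)
    }
    mean(apply(as.matrix(het_cols), 1, any))
  }
}

#' Inter-locus concordance of XCI calls
#'
#' Spearman rank correlation between the main-inactive-allele percentages
#' of two loci measured in the same samples, with a Fisher-z 95% confidence
#' interval (`tanh(atanh(r) +/- 1.96/sqrt(n-3))`). Ties are mid-ranked.
#'
#' @param a,b Numeric vectors of `main_inactive_pct`, paired by sample.
#' @return List with `n`, `spearman_r`, `ci95` (lo, hi), `p_value`.
#' @export
concordance <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L) stop("insufficient data: need >= 3 informative pairs", call. = FALSE)
  ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  r <- unname(ct$estimate)
  if (n > 3L && abs(r) < 1) {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    ci <- tanh(c(z - 1.96 * se, z + 1.96 * se))
  } else {
    ci <- c(r, r)
  }
  list(n = n, spearman_r = r, ci95 = ci, p_value = ct$p.value)
}

#' Phase the inactive X in a parent-child trio
#'
#' Determines the parental origin of the child's preferentially inactivated
#' allele from STR genotypes at one locus: maternal if the Xi-bearing allele
#' size occurs in the mother but not the hemizygous father, paternal in the
#' reverse case, ambiguous when both parents carry it.
#'
#' @param mother Numeric length-2 genotype (allele sizes).
#' @param father Numeric length-1 hemizygous genotype.
#' @param child Numeric length-2 genotype.
#' @param child_xi_allele Size of the child's Xi-bearing allele.
#' @return `"maternal"`, `"paternal"` or `"ambiguous"`.
#' @export
phase_trio <- function(mother, father, child, child_xi_allele) {
  stopifnot(length(father) == 1L)
  if (!(child_xi_allele %in% child)) {
    stop("child Xi allele not in the child genotype", call. = FALSE)
  }
  if (any(!(child %in% c(mother, father)))) {
    stop("Mendelian inconsistency: child allele absent from both parents",
         call. = FALSE)
  }
  in_m <- child_xi_allele %in% mother
  in_f <- child_xi_allele %in% father
  if (in_m && !in_f) "maternal"
  else if (in_f && !in_m) "paternal"
  else if (in_m && in_f) "ambiguous"
  else stop("Mendelian inconsistency: child Xi allele absent from both parents",
            call. = FALSE)
}
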