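#' Read a fragment-analysis peak table
#'
#' CSV with header `sample,locus,treatment,allele_size,area,height`:
#' one row per fluorescence peak, `treatment` either `undigested` or the
#' digesting enzyme name, `area` in arbitrary units, `height` in RFU.
#'
#' @param path CSV path.
#' @return Validated peak data.frame.
#' @export
read_peak_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_peak_table(df)
}

#' @rdname read_peak_table
#' @param peaks Peak data.frame to validate in place.
#' @export
validate_peak_table <- function(peaks) {
  need <- c("sample", "locus", "treatment", "allele_size", "area", "height")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) {
    stop("peak table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(peaks$area)) || any(peaks$area < 0)) {
    stop("peak areas must be finite and non-negative", call. = FALSE)
  }
  key <- paste(peaks$sample, peaks$locus, peaks$treatment, peaks$allele_size)
  if (anyDuplicated(key)) {
    stop("duplicate (sample, locus, treatment, allele_size) rows", call. = FALSE)
  }
  peaks
}

#' @rdname read_peak_table
#' @export
write_peak_table <- function(peaks, path) {
  write.csv(peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Call true alleles from one sample's undigested peaks
#'
#' Takes the tallest peaks after excluding stutter positions (any peak lying
#' one repeat unit, within `size_tol`, below a taller peak). At most two
#' alleles are called; a secondary peak below 10% of the major peak's area
#' is not called as an allele.
#'
#' @param peaks Peak rows for one sample/locus/treatment.
#' @param repeat_unit_bp Repeat unit length in bp.
#' @param size_tol Size-matching tolerance in bp (default 1).
#' @return Data.frame of called alleles (columns `allele_size`, `area`,
#'   `height`), ordered by size.
#' @export
call_alleles <- function(peaks, repeat_unit_bp, size_tol = 1) {
  if (nrow(peaks) == 0L) return(peaks)
  is_stutter <- vapply(seq_len(nrow(peaks)), function(i) {
    any(peaks$height > peaks$height[i] &
          abs((peaks$allele_size - repeat_unit_bp) - peaks$allele_size[i]) <= size_tol)
  }, logical(1))
  cand <- peaks[!is_stutter, , drop = FALSE]
  cand <- cand[order(-cand$area), , drop = FALSE]
  cand <- cand[cand$area >= 0.1 * cand$area[1], , drop = FALSE]
  cand <- cand[seq_len(min(2L, nrow(cand))), , drop = FALSE]
  cand <- cand[order(cand$allele_size), c("allele_size", "area", "height")]
  rownames(cand) <- NULL
  cand
}

#' Quantify X-inactivation from a peak table
#'
#' Per sample and locus: calls alleles from the undigested run, matches
#' digested peaks to the undigested allele sizes (digestion can abolish
#' peaks, so sizes always come from the undigested reference), corrects
#' both runs for stutter, and converts the area pairs into an Xi fraction
#' and skewing class via [compute_xci_ratio()]. Samples with a single
#' called allele are reported uninformative. Results are reported per
#' enzyme and never averaged across enzymes; when several enzymes are
#' quantified, pairs differing by more than 15 percentage points in
#' `main_inactive_pct` gain a `cross_enzyme_discordance` flag.
#'
#' @param peaks Peak table ([read_peak_table()] format).
#' @param models Named list of [stutter_model()] objects keyed by locus id
#'   (default [default_stutter_models()]); `"auto"` estimates each locus's
#'   fraction from the single-allele samples in the table.
#' @param enzymes Character vector of digestion treatments to quantify
#'   (default: every non-`undigested` treatment present).
#' @param size_tol Peak-to-allele size matching tolerance in bp.
#' @return Data.frame with one row per sample/locus/enzyme: allele sizes,
#'   corrected areas, `xi_fraction_allele1`, `main_inactive_pct`,
#'   `skew_class`, `qc`.
#' @export
quantify_xci <- function(peaks, models = default_stutter_models(),
                         enzymes = NULL, size_tol = 1) {
  validate_peak_table(peaks)
  if (is.null(enzymes)) {
    enzymes <- setdiff(unique(peaks$treatment), "undigested")
  }
  if (identical(models, "auto")) {
    models <- auto_stutter_models(peaks, size_tol)
  }
  rows <- list()
  for (locus in unique(peaks$locus)) {
    model <- models[[locus]]
    if (is.null(model)) stop("no stutter model for locus ", locus, call. = FALSE)
    lp <- peaks[peaks$locus == locus, , drop = FALSE]
    for (smp in unique(lp$sample)) {
      und <- lp[lp$sample == smp & lp$treatment == "undigested", , drop = FALSE]
      if (nrow(und) == 0L) next
      alleles <- call_alleles(und, model$repeat_unit_bp, size_tol)
      for (enz in enzymes) {
        dig <- lp[lp$sample == smp & lp$treatment == enz, , drop = FALSE]
        if (nrow(dig) == 0L && nrow(alleles) < 2L) next
        row <- quantify_one(smp, locus, enz, alleles, und, dig, model, size_tol)
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_xci_results())
  rownames(out) <- NULL
  flag_cross_enzyme_discordance(out)
}

empty_xci_results <- function() {
  data.frame(sample = character(), locus = character(), enzyme = character(),
             allele1 = numeric(), allele2 = numeric(),
             u1 = numeric(), u2 = numeric(), d1 = numeric(), d2 = numeric(),
             xi_fraction_allele1 = numeric(), main_inactive_pct = numeric(),
             skew_class = character(), qc = character(),
             stringsAsFactors = FALSE)
}

quantify_one <- function(smp, locus, enz, alleles, und, dig, model, size_tol) {
  base <- data.frame(sample = smp, locus = locus, enzyme = enz,
                     allele1 = NA_real_, allele2 = NA_real_,
                     u1 = NA_real_, u2 = NA_real_, d1 = NA_real_, d2 = NA_real_,
                     xi_fraction_allele1 = NA_real_,
                     main_inactive_pct = NA_real_,
                     skew_class = NA_character_, qc = "",
                     stringsAsFactors = FALSE)
  if (nrow(alleles) < 2L) {
    base$allele1 <- if (nrow(alleles)) alleles$allele_size[1] else NA_real_
    base$u1 <- if (nrow(alleles)) alleles$area[1] else NA_real_
    if (nrow(alleles) == 1L && nrow(dig)) {
      di <- match_peak_area(dig, alleles$allele_size[1], size_tol)
      base$d1 <- di
    }
    base$qc <- "uninformative_or_allele_dropout"
    return(base)
  }
  sizes <- alleles$allele_size
  u <- correct_stutter(sizes, alleles$area, model, size_tol)
  d_raw <- vapply(sizes, function(sz) match_peak_area(dig, sz, size_tol),
                  numeric(1))
  d <- correct_stutter(sizes, d_raw, model, size_tol)
  base$allele1 <- sizes[1]; base$allele2 <- sizes[2]
  base$u1 <- u$areas[1]; base$u2 <- u$areas[2]
  base$d1 <- d$areas[1]; base$d2 <- d$areas[2]
  qc <- c(u$qc, d$qc)
  res <- tryCatch(compute_xci_ratio(u$areas, d$areas), error = function(e) e)
  if (inherits(res, "error")) {
    qc <- c(qc, sub(":.*$", "", conditionMessage(res)))
  } else {
    base$xi_fraction_allele1 <- res$xi_fraction_allele1
    base$main_inactive_pct <- res$main_inactive_pct
    base$skew_class <- res$skew_class
    qc <- c(qc, res$qc)
  }
  base$qc <- paste(qc, collapse = ";")
  base
}

match_peak_area <- function(peaks, size, size_tol) {
  if (nrow(peaks) == 0L) return(0)
  hit <- which(abs(peaks$allele_size - size) <= size_tol)
  if (length(hit) == 0L) 0 else sum(peaks$area[hit])
}

auto_stutter_models <- function(peaks, size_tol) {
  und <- peaks[peaks$treatment == "undigested", , drop = FALSE]
  models <- list()
  for (locus in unique(und$locus)) {
    lp <- und[und$locus == locus, , drop = FALSE]
    unit <- infer_unit_bp(lp)
    single <- Filter(function(s) {
      nrow(call_alleles(lp[lp$sample == s, , drop = FALSE], unit, size_tol)) == 1L
    }, unique(lp$sample))
    if (length(single) == 0L) {
      stop("locus ", locus, ": no single-allele samples for stutter ",
           "estimation; supply a stutter_model", call. = FALSE)
    }
    f <- estimate_stutter_fraction(lp[lp$sample %in% single, , drop = FALSE],
                                   unit, size_tol)
    models[[locus]] <- stutter_model(locus, unit, f)
  }
  models
}

# Repeat unit from the spacing of observed peak sizes (GCD of pairwise
# size differences, capped at 6 bp).
infer_unit_bp <- function(peaks) {
  sizes <- sort(unique(round(peaks$allele_size)))
  if (length(sizes) < 2L) return(4L)
  d <- diff(sizes)
  g <- Reduce(function(a, b) { while (b) { t <- b; b <- a %% b; a <- t }; a }, d)
  as.integer(max(1L, min(6L, g)))
}

flag_cross_enzyme_discordance <- function(out) {
  if (nrow(out) == 0L) return(out)
  key <- paste(out$sample, out$locus)
  for (k in unique(key)) {
    idx <- which(key == k & !is.na(out$main_inactive_pct))
    if (length(idx) >= 2L &&
        diff(range(out$main_inactive_pct[idx])) > 15) {
      out$qc[idx] <- vapply(out$qc[idx], function(q) {
        paste(c(Filter(nzchar, strsplit(q, ";")[[1]]),
                "cross_enzyme_discordance"), collapse = ";")
      }, character(1))
    }
  }
  out
}
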