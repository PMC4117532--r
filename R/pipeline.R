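#' Run the candidate screen end to end on files
#'
#' Thin file-level wrapper over [screen_candidates()]: reads the genome and
#' tracks, writes the full provenance table (TSV, 1-based inclusive
#' coordinates), a BED of accepted loci and a JSON report from
#' [explain_candidate()]. Every output starts with a provenance header
#' recording the thresholds used.
#'
#' @param genome FASTA path.
#' @param gff,cgi,par,escape Optional annotation paths (GFF3, BED, BED,
#'   one gene id per line).
#' @param out,bed,json Optional output paths.
#' @param config A [screen_config()]; the escape file, when given,
#'   overrides `config$escape_genes`.
#' @return The screen result data.frame, invisibly when writing files.
#' @export
run_screen <- function(genome, gff = NULL, cgi = NULL, par = NULL,
                       escape = NULL, out = NULL, bed = NULL, json = NULL,
                       config = screen_config()) {
  for (f in Filter(Negate(is.null), list(genome, gff, cgi, par, escape))) {
    if (!file.exists(f)) stop("missing input: ", f, call. = FALSE)
  }
  if (!is.null(escape)) {
    ids <- readLines(escape, warn = FALSE)
    config$escape_genes <- ids[nzchar(ids)]
  }
  res <- screen_candidates(genome, annotation = gff, cgi_track = cgi,
                           par_track = par, config = config)
  if (!is.null(out)) {
    hdr <- provenance_header(config)
    con <- file(out, "w")
    writeLines(hdr, con)
    x <- res
    x$start <- x$start + 1L
    suppressWarnings(write.table(x, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    close(con)
  }
  if (!is.null(bed)) {
    acc <- res[res$accepted, , drop = FALSE]
    acc$name <- acc$unit
    acc$score <- round(acc$match_pct, 2)
    write_bed_track(acc, bed)
  }
  if (!is.null(json)) {
    reports <- lapply(seq_len(nrow(res)), function(i) {
      explain_candidate(res[i, , drop = FALSE])
    })
    jsonlite::write_json(reports, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (is.null(out) && is.null(bed) && is.null(json)) res else invisible(res)
}

provenance_header <- function(config) {
  sp <- config$scan_params
  c(sprintf("# xcistr %s", as.character(utils::packageVersion("xcistr"))),
    sprintf("# thresholds: period %d-%d, copies >= %s, match_pct > %s, cgi < %d bp, enzyme < %d bp",
            sp$min_period, sp$max_period, sp$min_copy_number,
            sp$min_match_pct, config$cgi_max_distance,
            config$enzyme_max_distance))
}

#' Quantify XCI from a peak-table file
#'
#' File-level wrapper over [quantify_xci()]; writes a results TSV and,
#' optionally, a JSON mirror. In strict mode any digestion-control failure
#' among hemizygous samples (supplied via `male_samples`) raises an error.
#'
#' @param peaks_csv Peak table CSV path.
#' @param out,json Optional output paths.
#' @param stutter `"auto"`, a stutter TSV (columns `locus`,
#'   `repeat_unit_bp`, `stutter_fraction`) or a named list of
#'   [stutter_model()].
#' @param enzymes Enzymes to quantify (default: all present).
#' @param male_samples Optional character vector of known single-X samples
#'   used for digestion QC.
#' @param qc_tolerance Residual-ratio tolerance for digestion QC.
#' @param strict Error out on digestion QC failure.
#' @return The results data.frame (invisibly when writing files), with a
#'   `digestion_qc` attribute when controls were supplied.
#' @export
run_quantify <- function(peaks_csv, out = NULL, json = NULL,
                         stutter = default_stutter_models(), enzymes = NULL,
                         male_samples = character(), qc_tolerance = 0.05,
                         strict = FALSE) {
  if (!file.exists(peaks_csv)) stop("missing input: ", peaks_csv, call. = FALSE)
  peaks <- read_peak_table(peaks_csv)
  models <- if (is.character(stutter) && identical(stutter, "auto")) {
    "auto"
  } else if (is.character(stutter)) {
    df <- read.delim(stutter, stringsAsFactors = FALSE)
    ms <- lapply(seq_len(nrow(df)), function(i) {
      stutter_model(df$locus[i], df$repeat_unit_bp[i], df$stutter_fraction[i])
    })
    setNames(ms, df$locus)
  } else stutter
  res <- quantify_xci(peaks, models = models, enzymes = enzymes)
  if (length(male_samples)) {
    qc <- batch_digestion_qc(peaks, male_samples, enzymes, qc_tolerance)
    attr(res, "digestion_qc") <- qc
    if (strict && any(!qc$pass)) {
      stop("digestion QC failed for: ",
           paste(qc$sample[!qc$pass], collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(out)) {
    write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(res, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (is.null(out) && is.null(json)) res else invisible(res)
}

#' Digestion QC across a batch of known single-X samples
#'
#' @param peaks Peak table.
#' @param male_samples Known hemizygous sample ids.
#' @param enzymes Enzymes to check (default: all present).
#' @param tolerance Residual-ratio tolerance.
#' @return Data.frame (`sample`, `locus`, `enzyme`, `residual_ratio`,
#'   `pass`); zero rows with a warning when no control is applicable.
#' @export
batch_digestion_qc <- function(peaks, male_samples, enzymes = NULL,
                               tolerance = 0.05) {
  if (is.null(enzymes)) enzymes <- setdiff(unique(peaks$treatment), "undigested")
  rows <- list()
  for (smp in intersect(male_samples, unique(peaks$sample))) {
    for (locus in unique(peaks$locus[peaks$sample == smp])) {
      und <- peaks[peaks$sample == smp & peaks$locus == locus &
                     peaks$treatment == "undigested", , drop = FALSE]
      if (nrow(und) == 0L) next
      true_size <- und$allele_size[which.max(und$area)]
      u <- und$area[which.max(und$area)]
      for (enz in enzymes) {
        dig <- peaks[peaks$sample == smp & peaks$locus == locus &
                       peaks$treatment == enz, , drop = FALSE]
        d <- match_peak_area(dig, true_size, 1)
        qc <- digestion_qc(u, d, tolerance)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = smp, locus = locus, enzyme = enz,
          residual_ratio = qc$residual_ratio, pass = qc$pass,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    warning("no applicable single-X digestion control in this batch")
    return(data.frame(sample = character(), locus = character(),
                      enzyme = character(), residual_ratio = numeric(),
                      pass = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concordance between two quantification result files
#'
#' @param a,b Result TSVs from [run_quantify()], paired by sample on
#'   `main_inactive_pct`.
#' @return A [concordance()] result list.
#' @export
run_concordance <- function(a, b) {
  ra <- read.delim(a, stringsAsFactors = FALSE)
  rb <- read.delim(b, stringsAsFactors = FALSE)
  common <- intersect(ra$sample[!is.na(ra$main_inactive_pct)],
                      rb$sample[!is.na(rb$main_inactive_pct)])
  concordance(ra$main_inactive_pct[match(common, ra$sample)],
              rb$main_inactive_pct[match(common, rb$sample)])
}
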