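#' Screen configuration
#'
#' Thresholds of the multi-criterion X-linked STR screen. Defaults encode
#' the published criteria: tetra-/pentanucleotide arrays of at least 12
#' units with match percentage above 90 (criterion i); outside exons and
#' pseudoautosomal regions (ii); strictly less than 300 bp from, or inside,
#' a CpG island of a non-escape gene (iii); at least one methylation-
#' sensitive restriction site strictly within 300 bp of the repeat (iv).
#' Detection runs at a relaxed floor (`detect_params`) so near-miss repeats
#' are still emitted with a criterion-i failure recorded, keeping the
#' screen's provenance auditable.
#'
#' @param scan_params Criterion-i thresholds, a [repeat_scan_params()].
#' @param detect_params Relaxed parameters used for detection itself.
#' @param cgi_max_distance Edge-gap cutoff in bp for criterion iii
#'   (strict `<`).
#' @param enzyme_max_distance Edge-gap cutoff in bp for criterion iv
#'   (strict `<`).
#' @param escape_genes Character vector of escape-gene ids excluded by
#'   criterion iii; may be empty, in which case escape filtering is off.
#' @param tss_link_window CpG-island-to-gene linkage window in bp (nearest
#'   annotated TSS within this distance of the island).
#' @param enzymes Enzyme table for criterion iv.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(scan_params = repeat_scan_params(),
                          detect_params = repeat_scan_params(
                            min_copy_number = 5, min_match_pct = 80),
                          cgi_max_distance = 300L,
                          enzyme_max_distance = 300L,
                          escape_genes = character(),
                          tss_link_window = 2000L,
                          enzymes = restriction_enzymes()) {
  stopifnot(cgi_max_distance > 0L, enzyme_max_distance > 0L,
            tss_link_window >= 0L)
  structure(list(scan_params = scan_params, detect_params = detect_params,
                 cgi_max_distance = as.integer(cgi_max_distance),
                 enzyme_max_distance = as.integer(enzyme_max_distance),
                 escape_genes = as.character(escape_genes),
                 tss_link_window = as.integer(tss_link_window),
                 enzymes = enzymes),
            class = "screen_config")
}

#' Screen a genome for XCI-marker candidate repeats
#'
#' Runs repeat detection on every record of the genome and evaluates six
#' sub-criteria per repeat: `i_repeat` (unit count and match percentage),
#' `ii_extragenic` (no exon overlap), `ii_non_par` (no pseudoautosomal
#' overlap), `iii_cgi_proximity` (edge gap to the nearest CpG island
#' strictly below the cutoff, overlap counting as 0), `iii_non_escape`
#' (linked gene not on the escape list), and `iv_enzyme_site` (nearest
#' methylation-sensitive restriction site strictly within the cutoff).
#' A locus is accepted iff all six pass. Islands are linked to genes by
#' nearest annotated TSS within `tss_link_window`; an unlinked island
#' passes `iii_non_escape` only when the escape list is empty.
#'
#' @param genome Path to a FASTA file or a named character vector of
#'   sequences.
#' @param annotation Path to a GFF3 file, or a list with `genes`/`exons`
#'   interval data.frames (see [read_gff3_annotation()]), or `NULL` for no
#'   annotation.
#' @param cgi_track Path to a BED file or an interval data.frame of CpG
#'   islands; `NULL` computes islands from sequence via
#'   [detect_cpg_islands()].
#' @param par_track Path to a BED file or an interval data.frame of
#'   pseudoautosomal regions; `NULL` for none.
#' @param config A [screen_config()].
#' @return A data.frame, one row per detected repeat, with repeat fields,
#'   the six criterion columns (logical), evidence columns (`cgi_edge_gap`,
#'   `cgi_start_to_start`, `cgi_id`, `gene_id`, `exon_id`, `site_enzyme`,
#'   `site_gap`) and `accepted`.
#' @export
screen_candidates <- function(genome, annotation = NULL, cgi_track = NULL,
                              par_track = NULL, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  seqs <- load_genome(genome)
  ann <- load_annotation(annotation)
  cgis <- load_track(cgi_track)
  pars <- load_track(par_track)
  check_chrom_names(names(seqs), ann, cgis, pars)

  res <- lapply(names(seqs), function(chr) {
    seq <- seqs[[chr]]
    reps <- find_tandem_repeats(seq, config$detect_params, chrom = chr)
    if (nrow(reps) == 0L) return(NULL)
    chr_cgis <- if (is.null(cgis)) {
      ci <- detect_cpg_islands(seq, chrom = chr)
      ci$name <- if (nrow(ci)) sprintf("CGI_%s_%d", chr, seq_len(nrow(ci))) else character()
      ci
    } else cgis[cgis$chrom == chr, , drop = FALSE]
    if (!is.null(chr_cgis) && nrow(chr_cgis) && is.null(chr_cgis$name)) {
      chr_cgis$name <- sprintf("CGI_%s_%d", chr, seq_len(nrow(chr_cgis)))
    }
    sites <- scan_restriction_sites(seq, config$enzymes, chrom = chr)
    sites <- sites[vapply(sites$enzyme, function(e) {
      isTRUE(config$enzymes$methylation_sensitive[config$enzymes$name == e][1])
    }, logical(1)), , drop = FALSE]
    evaluate_criteria(reps, seq, ann, chr_cgis, pars, sites, config)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    return(cbind(find_tandem_repeats("", config$detect_params),
                 empty_criteria_cols()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

empty_criteria_cols <- function() {
  data.frame(i_repeat = logical(), ii_extragenic = logical(),
             ii_non_par = logical(), iii_cgi_proximity = logical(),
             iii_non_escape = logical(), iv_enzyme_site = logical(),
             cgi_edge_gap = integer(), cgi_start_to_start = integer(),
             cgi_id = character(), gene_id = character(),
             exon_id = character(), site_enzyme = character(),
             site_gap = integer(), accepted = logical(),
             stringsAsFactors = FALSE)
}

evaluate_criteria <- function(reps, seq, ann, cgis, pars, sites, config) {
  sp <- config$scan_params
  n <- nrow(reps)
  out <- reps
  out$i_repeat <- reps$period >= sp$min_period & reps$period <= sp$max_period &
    reps$copy_number >= sp$min_copy_number & reps$match_pct > sp$min_match_pct
  out$ii_extragenic <- TRUE
  out$ii_non_par <- TRUE
  out$iii_cgi_proximity <- FALSE
  out$iii_non_escape <- TRUE
  out$iv_enzyme_site <- FALSE
  out$cgi_edge_gap <- NA_integer_
  out$cgi_start_to_start <- NA_integer_
  out$cgi_id <- NA_character_
  out$gene_id <- NA_character_
  out$exon_id <- NA_character_
  out$site_enzyme <- NA_character_
  out$site_gap <- NA_integer_

  for (k in seq_len(n)) {
    rep_iv <- reps[k, c("chrom", "start", "end")]
    rep_iv$strand <- "."
    if (!is.null(ann)) {
      hit <- which_overlaps(rep_iv, ann$exons)
      if (length(hit)) {
        out$ii_extragenic[k] <- FALSE
        out$exon_id[k] <- ann$exons$id[hit[1]]
      }
    }
    if (!is.null(pars) && overlaps_any(rep_iv, pars)) out$ii_non_par[k] <- FALSE
    if (!is.null(cgis) && nrow(cgis)) {
      same <- cgis[cgis$chrom == rep_iv$chrom, , drop = FALSE]
      if (nrow(same)) {
        gaps <- pmax(same$start - rep_iv$end, rep_iv$start - same$end, 0L)
        best <- which.min(gaps)
        out$cgi_edge_gap[k] <- gaps[best]
        out$cgi_start_to_start[k] <-
          distance_to_feature(rep_iv, same[best, ], "start_to_start")$distance
        out$cgi_id[k] <- same$name[best]
        out$iii_cgi_proximity[k] <- gaps[best] < config$cgi_max_distance
        gene <- link_cgi_to_gene(same[best, ], ann, config$tss_link_window)
        out$gene_id[k] <- gene
        if (length(config$escape_genes)) {
          out$iii_non_escape[k] <- !is.na(gene) && !(gene %in% config$escape_genes)
        }
      }
    }
    if (nrow(sites)) {
      same <- sites[sites$chrom == rep_iv$chrom, , drop = FALSE]
      if (nrow(same)) {
        gaps <- pmax(same$start - rep_iv$end, rep_iv$start - same$end, 0L)
        best <- which.min(gaps)
        out$site_gap[k] <- gaps[best]
        out$site_enzyme[k] <- same$enzyme[best]
        out$iv_enzyme_site[k] <- gaps[best] < config$enzyme_max_distance
      }
    }
  }
  out$accepted <- out$i_repeat & out$ii_extragenic & out$ii_non_par &
    out$iii_cgi_proximity & out$iii_non_escape & out$iv_enzyme_site
  out
}

# Nearest annotated TSS within `window` bp of the island, else NA.
link_cgi_to_gene <- function(cgi, ann, window) {
  if (is.null(ann) || nrow(ann$genes) == 0L) return(NA_character_)
  genes <- ann$genes[ann$genes$chrom == cgi$chrom, , drop = FALSE]
  if (nrow(genes) == 0L) return(NA_character_)
  tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  d <- pmax(cgi$start - tss - 1L, tss - cgi$end, 0L)
  d[tss >= cgi$start & tss < cgi$end] <- 0L
  best <- which.min(d)
  if (d[best] <= window) genes$gene_id[best] else NA_character_
}

load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    seqs <- as.list(as.character(ss))
    names(seqs) <- sub("\\s.*$", "", names(ss))
    seqs
  } else if (is.character(genome) && !is.null(names(genome))) {
    as.list(genome)
  } else {
    stop("genome must be a FASTA path or a named character vector",
         call. = FALSE)
  }
}

load_annotation <- function(annotation) {
  if (is.null(annotation)) return(NULL)
  if (is.character(annotation)) return(read_gff3_annotation(annotation))
  stopifnot(is.list(annotation), all(c("genes", "exons") %in% names(annotation)))
  annotation
}

load_track <- function(track) {
  if (is.null(track)) return(NULL)
  if (is.character(track)) return(read_bed_track(track))
  track
}

check_chrom_names <- function(chroms, ann, cgis, pars) {
  offenders <- character()
  chk <- function(x, label) {
    if (is.null(x) || nrow(x) == 0L) return()
    bad <- setdiff(unique(x$chrom), chroms)
    if (length(bad)) {
      offenders <<- c(offenders,
                      sprintf("%s: %s", label, paste(bad, collapse = ",")))
    }
  }
  if (!is.null(ann)) { chk(ann$genes, "genes"); chk(ann$exons, "exons") }
  chk(cgis, "cgi"); chk(pars, "par")
  if (length(offenders)) {
    stop("chromosome names absent from genome -- ",
         paste(offenders, collapse = "; "), call. = FALSE)
  }
}

#' Explain a screened locus
#'
#' Expands one row of [screen_candidates()] output into a structured
#' justification of each pass/fail with its supporting evidence, suitable
#' for JSON serialisation.
#'
#' @param locus Single row of the screen output.
#' @return A list with `locus` (coordinates, 1-based inclusive, and repeat
#'   statistics), `criteria` (named list of pass/fail + evidence) and
#'   `accepted`.
#' @export
explain_candidate <- function(locus) {
  stopifnot(nrow(locus) == 1L)
  crit <- list(
    i_repeat = list(pass = locus$i_repeat,
                    copy_number = locus$copy_number,
                    match_pct = locus$match_pct),
    ii_extragenic = list(pass = locus$ii_extragenic,
                         exon_id = locus$exon_id),
    ii_non_par = list(pass = locus$ii_non_par),
    iii_cgi_proximity = list(pass = locus$iii_cgi_proximity,
                             cgi_id = locus$cgi_id,
                             edge_gap_bp = locus$cgi_edge_gap,
                             start_to_start_bp = locus$cgi_start_to_start),
    iii_non_escape = list(pass = locus$iii_non_escape,
                          gene_id = locus$gene_id),
    iv_enzyme_site = list(pass = locus$iv_enzyme_site,
                          enzyme = locus$site_enzyme,
                          edge_gap_bp = locus$site_gap)
  )
  failed <- names(crit)[!vapply(crit, function(x) isTRUE(x$pass), logical(1))]
  list(locus = list(chrom = locus$chrom,
                    start = locus$start + 1L, end = locus$end,
                    unit = locus$unit, period = locus$period,
                    copy_number = locus$copy_number,
                    match_pct = locus$match_pct),
       criteria = crit,
       failed = failed,
       accepted = isTRUE(locus$accepted))
}
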