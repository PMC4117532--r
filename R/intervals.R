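#' Genomic interval records
#'
#' Intervals are held internally as plain data.frames in 0-based half-open
#' coordinates (the BED convention): a feature occupying the first ten bases
#' of a chromosome is `start = 0, end = 10`. Conversions to and from 1-based
#' inclusive coordinates (GFF3, and the coordinates printed in user-facing
#' tables) happen only at I/O boundaries.
#'
#' @param chrom Chromosome name(s).
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0L) || any(start >= end)) {
    stop("invalid interval: require 0 <= start < end", call. = FALSE)
  }
  if (!all(strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  }
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Distance between a repeat and an annotated feature
#'
#' Two conventions are exposed because published distances rarely state
#' theirs. `start_to_start` is the absolute difference between the 1-based
#' start coordinates (this reproduces printed repeat-to-island distances
#' computed from printed coordinates). `edge_gap` is the number of bases
#' strictly between the two intervals: 0 for touching or overlapping
#' intervals, which is the measure the proximity filter uses ("residing
#' within" counts as distance 0).
#'
#' @param x,feature Single-row interval data.frames ([genomic_interval()])
#'   on the same chromosome.
#' @param convention `"start_to_start"` or `"edge_gap"`.
#' @return A list with `distance` (integer bp) and `overlap` (logical; `TRUE`
#'   when the intervals share at least one base).
#' @export
distance_to_feature <- function(x, feature,
                                convention = c("start_to_start", "edge_gap")) {
  convention <- match.arg(convention)
  if (x$chrom != feature$chrom) {
    stop("intervals on different chromosomes: ", x$chrom, " vs ", feature$chrom,
         call. = FALSE)
  }
  overlap <- x$start < feature$end && feature$start < x$end
  if (convention == "start_to_start") {
    # identical in 0- and 1-based terms: the +1 shift cancels
    d <- abs(feature$start - x$start)
  } else {
    d <- if (overlap) 0L else max(feature$start - x$end, x$start - feature$end, 0L)
  }
  list(distance = as.integer(d), overlap = overlap)
}

#' Test whether an interval overlaps any interval of a track
#'
#' Half-open semantics: `[0,10)` does not overlap `[10,20)`.
#'
#' @param q Single-row interval data.frame.
#' @param track Interval data.frame (any number of rows).
#' @return `TRUE` iff `q` shares at least one base with some track interval
#'   on the same chromosome.
#' @export
overlaps_any <- function(q, track) {
  if (is.null(track) || nrow(track) == 0L) return(FALSE)
  same <- track$chrom == q$chrom
  any(same & track$start < q$end & q$start < track$end)
}

# Index of track rows overlapping q, in track order.
which_overlaps <- function(q, track) {
  if (is.null(track) || nrow(track) == 0L) return(integer())
  which(track$chrom == q$chrom & track$start < q$end & q$start < track$end)
}

#' Read a BED track into the internal interval representation
#'
#' @param path BED file path.
#' @return Interval data.frame (0-based half-open) with a `name` column when
#'   the BED file carries one.
#' @export
read_bed_track <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  nm <- gr$name
  if (!is.null(nm)) df$name <- nm
  df
}

#' Write intervals as BED
#'
#' @param x Interval data.frame; optional `name` and `score` columns are
#'   carried into BED columns 4-5, any further columns are appended (BED6+).
#' @param path Output path.
#' @param extra Character vector of extra column names to append after
#'   strand.
#' @export
write_bed_track <- function(x, path, extra = character()) {
  name <- if ("name" %in% names(x)) x$name else rep(".", nrow(x))
  score <- if ("score" %in% names(x)) x$score else rep(0, nrow(x))
  strand <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
  out <- data.frame(x$chrom, x$start, x$end, name, score, strand,
                    stringsAsFactors = FALSE)
  for (col in extra) out[[col]] <- x[[col]]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene and exon features from a GFF3 annotation
#'
#' @param path GFF3 file path.
#' @return A list with interval data.frames `genes` and `exons`, each with
#'   `gene_id` (and `id` for exons) columns; coordinates converted to
#'   0-based half-open.
#' @export
read_gff3_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  df$id <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(df))
  genes <- df[df$type == "gene", , drop = FALSE]
  genes$gene_id <- genes$id
  exons <- df[df$type == "exon", , drop = FALSE]
  exons$gene_id <- parent[df$type == "exon"]
  rownames(genes) <- rownames(exons) <- NULL
  list(genes = genes[, c("chrom", "start", "end", "strand", "gene_id")],
       exons = exons[, c("chrom", "start", "end", "strand", "id", "gene_id")])
}

#' Write a minimal gene/exon GFF3 file
#'
#' @param genes Interval data.frame with `gene_id`.
#' @param exons Interval data.frame with `id` and `gene_id`.
#' @param path Output path.
#' @export
write_gff3_annotation <- function(genes, exons, path) {
  lines <- "##gff-version 3"
  fmt <- function(df, type, attr) {
    if (nrow(df) == 0L) return(character())
    sprintf("%s\txcistr\t%s\t%d\t%d\t.\t%s\t.\t%s",
            df$chrom, type, df$start + 1L, df$end, df$strand, attr)
  }
  lines <- c(lines,
             fmt(genes, "gene", sprintf("ID=%s", genes$gene_id)),
             fmt(exons, "exon", sprintf("ID=%s;Parent=%s", exons$id, exons$gene_id)))
  writeLines(lines, path)
  invisible(path)
}
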