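#' Canonical representation of a repeat unit
#'
#' Tandem-array units are equivalence classes under cyclic rotation: an array
#' entered mid-phase reads as a rotated unit. The representative is the
#' lexicographically smallest rotation, except where the field has settled on
#' a different rotation for a well-known family: the default override table
#' reports `GAAA` (not `AAAG`) for the RP2-type tetranucleotide family and
#' `CAG` (not `AGC`) for the androgen-receptor trinucleotide family.
#'
#' @param unit Non-empty DNA string.
#' @param overrides Named character vector mapping lexicographic
#'   representatives to preferred display rotations.
#' @return The canonical unit string.
#' @export
canonical_unit <- function(unit, overrides = default_unit_overrides()) {
  if (!is.character(unit) || length(unit) != 1L || !nzchar(unit)) {
    stop("unit must be a non-empty DNA string", call. = FALSE)
  }
  unit <- toupper(unit)
  rot <- cyclic_rotations(unit)
  rep <- min(rot)
  if (!is.null(overrides) && rep %in% names(overrides)) overrides[[rep]] else rep
}

#' @rdname canonical_unit
#' @export
default_unit_overrides <- function() {
  c(AAAG = "GAAA", AGC = "CAG")
}

cyclic_rotations <- function(unit) {
  p <- nchar(unit)
  doubled <- paste0(unit, unit)
  vapply(seq_len(p), function(i) substr(doubled, i, i + p - 1L), character(1))
}

#' Longest uninterrupted run of a repeat unit
#'
#' Counts the maximum number of consecutive exact copies of `unit` anywhere
#' in `seq`, at any phase, on the given strand. Perfect-run length is the
#' conserved quantity for cross-species repeat comparisons and predicts
#' polymorphism better than total array length.
#'
#' @param seq DNA string.
#' @param unit Non-empty unit string (exact matching, forward strand).
#' @return Integer count of consecutive copies; 0 if the unit is absent.
#' @export
count_uninterrupted_units <- function(seq, unit) {
  if (!is.character(unit) || length(unit) != 1L || !nzchar(unit)) {
    stop("unit must be a non-empty string", call. = FALSE)
  }
  if (!nzchar(seq)) return(0L)
  pat <- sprintf("(?:%s)+", unit)
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(0L)
  max(attr(m, "match.length")) %/% nchar(unit)
}

#' Repeat-scan parameters
#'
#' Alignment weights follow the screen's stated scoring: +2 per matching
#' column, 7-point penalties for mismatches and indels. Thresholds follow
#' the printed criteria semantics: copy number is inclusive
#' (`copy_number >= min_copy_number`), match percentage strict
#' (`match_pct > min_match_pct`).
#'
#' @param match_weight Score per matching column (default +2).
#' @param mismatch_penalty,indel_penalty Non-negative penalties (default 7).
#' @param min_period,max_period Unit-length scan range in bp (1-6 supported).
#' @param min_copy_number Minimum copies, inclusive.
#' @param min_match_pct Match-percentage floor, exclusive.
#' @return A list of class `repeat_scan_params`.
#' @export
repeat_scan_params <- function(match_weight = 2L, mismatch_penalty = 7L,
                               indel_penalty = 7L, min_period = 4L,
                               max_period = 5L, min_copy_number = 12,
                               min_match_pct = 90) {
  stopifnot(mismatch_penalty >= 0, indel_penalty >= 0,
            min_period >= 1L, max_period <= 6L, min_period <= max_period,
            min_copy_number >= 1, min_match_pct >= 0, min_match_pct <= 100)
  structure(list(match_weight = as.integer(match_weight),
                 mismatch_penalty = as.integer(mismatch_penalty),
                 indel_penalty = as.integer(indel_penalty),
                 min_period = as.integer(min_period),
                 max_period = as.integer(max_period),
                 min_copy_number = min_copy_number,
                 min_match_pct = min_match_pct),
            class = "repeat_scan_params")
}

#' Wraparound alignment of a sequence against a tandemly repeated unit
#'
#' Globally aligns `seq` to an unbounded tandem concatenation of `unit`
#' using wraparound dynamic programming: the unit index wraps modulo the
#' period, partial units at either boundary are free (any entry and exit
#' phase). Scoring is `+match_weight` per match, `-mismatch_penalty` per
#' mismatch, `-indel_penalty` per inserted or deleted base.
#'
#' @param seq DNA string (the candidate array region).
#' @param unit Unit string, length 1-6.
#' @param match_weight,mismatch_penalty,indel_penalty Scoring weights
#'   (penalties given as non-negative numbers).
#' @return List with `score`, `matches`, `mismatches`, `indels`, `columns`
#'   (aligned columns = matches + mismatches + indels), `match_pct` and
#'   `indel_pct` (percentages of aligned columns).
#' @export
wraparound_align <- function(seq, unit, match_weight = 2L,
                             mismatch_penalty = 7L, indel_penalty = 7L) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  u <- strsplit(toupper(unit), "", fixed = TRUE)[[1]]
  n <- length(s)
  p <- length(u)
  stopifnot(p >= 1L)
  mw <- as.numeric(match_weight)
  xp <- -as.numeric(mismatch_penalty)
  gp <- -as.numeric(indel_penalty)

  # state j in 1..p: j-1 unit characters of the current copy consumed
  # (column j's diagonal consumes unit char u[j-1 -> wraps]); row i = i
  # characters of seq consumed. Row 0 is all-zero: free entry phase.
  sc <- rep(0, p)        # scores, previous row
  nm <- nx <- ni <- rep(0L, p)
  for (i in seq_len(n)) {
    prev_j <- c(p, seq_len(p - 1L))          # (j-1) with wraparound
    uchr <- u[prev_j]                        # unit char consumed entering state j
    hit <- s[i] == uchr
    diag_sc <- sc[prev_j] + ifelse(hit, mw, xp)
    ins_sc <- sc + gp                        # consume s[i] against a gap
    take_diag <- diag_sc > ins_sc | (diag_sc == ins_sc & (nm[prev_j] + hit) >= nm)
    cur_sc <- ifelse(take_diag, diag_sc, ins_sc)
    cur_nm <- ifelse(take_diag, nm[prev_j] + as.integer(hit), nm)
    cur_nx <- ifelse(take_diag, nx[prev_j] + as.integer(!hit), nx)
    cur_ni <- ifelse(take_diag, ni[prev_j], ni + 1L)
    # in-row deletions (consume a unit char against a gap) wrap around the
    # unit circle; with negative gap cost two sweeps reach a fixed point
    for (sweep in 1:2) {
      for (j in seq_len(p)) {
        jp <- if (j == 1L) p else j - 1L
        cand <- cur_sc[jp] + gp
        if (cand > cur_sc[j] || (cand == cur_sc[j] && cur_nm[jp] > cur_nm[j])) {
          cur_sc[j] <- cand
          cur_nm[j] <- cur_nm[jp]
          cur_nx[j] <- cur_nx[jp]
          cur_ni[j] <- cur_ni[jp] + 1L
        }
      }
    }
    sc <- cur_sc; nm <- cur_nm; nx <- cur_nx; ni <- cur_ni
  }
  best <- which.max(sc)                      # free exit phase
  cols <- nm[best] + nx[best] + ni[best]
  list(score = sc[best], matches = nm[best], mismatches = nx[best],
       indels = ni[best], columns = cols,
       match_pct = if (cols > 0) 100 * nm[best] / cols else 0,
       indel_pct = if (cols > 0) 100 * ni[best] / cols else 0)
}

#' Detect tandem repeats in a DNA sequence
#'
#' Candidate arrays are seeded from perfect tandem stretches (autocorrelation
#' at lag = period), same-unit seeds separated by short interruptions are
#' merged, each candidate is extended greedily while flanking bases continue
#' the unit in phase (a mismatching base lowers the +2/-7 score, so extension
#' is score-maximal), and the merged region is scored by wraparound dynamic
#' programming against its unit. Overlapping calls with the same canonical
#' unit are merged; overlapping calls with different units are resolved by
#' higher alignment score, then smaller period, then leftmost start. Runs of
#' `N` split the sequence; no repeat spans an `N`.
#'
#' @param seq DNA string over `A,C,G,T,N` (case-insensitive).
#' @param params A [repeat_scan_params()] object.
#' @param chrom Chromosome name recorded on the output intervals.
#' @return A data.frame with one row per repeat: `chrom`, `start`, `end`
#'   (0-based half-open), `unit` (canonical rotation), `period`,
#'   `copy_number` (interval length / period), `match_pct`, `indel_pct`,
#'   `longest_perfect_run`, `score`; ordered by (start, period). Empty input
#'   gives an empty data.frame.
#' @export
find_tandem_repeats <- function(seq, params = repeat_scan_params(),
                                chrom = "seq") {
  stopifnot(inherits(params, "repeat_scan_params"))
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      unit = character(), period = integer(),
                      copy_number = numeric(), match_pct = numeric(),
                      indel_pct = numeric(), longest_perfect_run = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (!nzchar(seq)) return(empty)
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop("invalid character '", substr(seq, bad, bad), "' at offset ", bad - 1L,
         call. = FALSE)
  }
  segs <- n_free_segments(seq)
  calls <- list()
  for (k in seq_along(segs$seq)) {
    sub <- segs$seq[k]
    off <- segs$offset[k]
    for (p in params$min_period:params$max_period) {
      for (cand in candidate_regions(sub, p)) {
        # interval length is final here, so the copy-number floor can be
        # applied before the costly alignment
        if ((cand$end - cand$start + 1L) / p < params$min_copy_number) next
        aln <- wraparound_align(substr(sub, cand$start, cand$end), cand$unit,
                                params$match_weight, params$mismatch_penalty,
                                params$indel_penalty)
        len <- cand$end - cand$start + 1L
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = chrom,
          start = off + cand$start - 1L,   # 0-based
          end = off + cand$end,
          unit = canonical_unit(cand$unit),
          period = p,
          copy_number = len / p,
          match_pct = aln$match_pct,
          indel_pct = aln$indel_pct,
          longest_perfect_run = count_uninterrupted_units(
            substr(sub, cand$start, cand$end), cand$unit),
          score = aln$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(calls) == 0L) return(empty)
  out <- do.call(rbind, calls)
  out <- resolve_overlapping_calls(out, seq, params)
  out <- out[out$copy_number >= params$min_copy_number &
               out$match_pct > params$min_match_pct, , drop = FALSE]
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

n_free_segments <- function(seq) {
  m <- gregexpr("[ACGT]+", seq)[[1]]
  if (m[1] == -1L) return(list(seq = character(), offset = integer()))
  list(seq = vapply(seq_along(m), function(i) {
    substr(seq, m[i], m[i] + attr(m, "match.length")[i] - 1L)
  }, character(1)), offset = as.integer(m) - 1L)
}

# Perfect tandem stretches at lag p, merged across short interruptions and
# extended in phase. Returns list of lists (start, end 1-based inclusive
# within `sub`, unit = the in-phase unit at the region start).
candidate_regions <- function(sub, p, min_seed_copies = 2L, merge_gap = NULL) {
  v <- strsplit(sub, "", fixed = TRUE)[[1]]
  L <- length(v)
  if (L < 2L * p) return(list())
  if (is.null(merge_gap)) merge_gap <- max(3L, p)
  eq <- v[seq_len(L - p)] == v[(p + 1L):L]
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths + p) >= min_seed_copies * p
  if (!any(keep)) return(list())
  seeds <- data.frame(start = starts[keep], end = ends[keep] + p)
  seeds$unit <- vapply(seeds$start, function(s) {
    canonical_unit(paste(v[s:(s + p - 1L)], collapse = ""), overrides = NULL)
  }, character(1))
  # merge same-unit seeds separated by at most merge_gap bases
  regions <- list()
  cur <- seeds[1, ]
  for (i in seq_len(nrow(seeds))[-1]) {
    if (seeds$unit[i] == cur$unit && seeds$start[i] - cur$end - 1L <= merge_gap) {
      cur$end <- max(cur$end, seeds$end[i])
    } else {
      regions[[length(regions) + 1L]] <- cur
      cur <- seeds[i, ]
    }
  }
  regions[[length(regions) + 1L]] <- cur
  lapply(regions, function(rg) {
    s <- rg$start; e <- rg$end
    # greedy in-phase extension: stop at the first base off the unit pattern
    while (s > 1L && v[s - 1L] == v[s + p - 1L]) s <- s - 1L
    while (e < L && v[e + 1L] == v[e + 1L - p]) e <- e + 1L
    list(start = s, end = e,
         unit = paste(v[s:(s + p - 1L)], collapse = ""))
  })
}

resolve_overlapping_calls <- function(out, seq, params) {
  if (nrow(out) <= 1L) return(out)
  # partition calls into overlap clusters; resolution is quadratic only
  # within a cluster
  o <- order(out$start, out$end)
  out <- out[o, , drop = FALSE]
  cluster <- integer(nrow(out))
  cid <- 1L
  cluster[1] <- cid
  hi <- out$end[1]
  for (i in 2:nrow(out)) {
    if (out$start[i] >= hi) cid <- cid + 1L
    cluster[i] <- cid
    hi <- max(hi, out$end[i])
  }
  parts <- lapply(split(seq_len(nrow(out)), cluster), function(idx) {
    if (length(idx) == 1L) out[idx, , drop = FALSE]
    else resolve_cluster(out[idx, , drop = FALSE], seq, params)
  })
  do.call(rbind, parts)
}

resolve_cluster <- function(out, seq, params) {
  repeat {
    out <- out[order(-out$score, out$period, out$start), , drop = FALSE]
    drop <- rep(FALSE, nrow(out))
    merged <- FALSE
    for (i in seq_len(nrow(out) - 1L)) {
      if (drop[i]) next
      for (j in (i + 1L):nrow(out)) {
        if (drop[j]) next
        if (out$start[i] < out$end[j] && out$start[j] < out$end[i]) {
          if (out$unit[i] == out$unit[j] && out$period[i] == out$period[j]) {
            # same canonical unit: merge to the union and re-score
            s <- min(out$start[i], out$start[j])
            e <- max(out$end[i], out$end[j])
            aln <- wraparound_align(substr(seq, s + 1L, e), out$unit[i],
                                    params$match_weight,
                                    params$mismatch_penalty,
                                    params$indel_penalty)
            out$start[i] <- s; out$end[i] <- e
            out$copy_number[i] <- (e - s) / out$period[i]
            out$match_pct[i] <- aln$match_pct
            out$indel_pct[i] <- aln$indel_pct
            out$score[i] <- aln$score
            out$longest_perfect_run[i] <- count_uninterrupted_units(
              substr(seq, s + 1L, e), out$unit[i])
            merged <- TRUE
          }
          drop[j] <- TRUE
        }
      }
    }
    out <- out[!drop, , drop = FALSE]
    if (!merged) break
  }
  out
}

#' Scan a FASTA file for tandem repeats
#'
#' Each record is scanned independently with [find_tandem_repeats()].
#'
#' @param fasta Path to a FASTA file (multi-record allowed).
#' @param params A [repeat_scan_params()] object.
#' @return Combined repeat data.frame across records.
#' @export
find_tandem_repeats_fasta <- function(fasta, params = repeat_scan_params()) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  res <- lapply(seq_along(seqs), function(i) {
    find_tandem_repeats(as.character(seqs[[i]]), params, chrom = names(seqs)[i])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write detected repeats as BED6+ and TSV
#'
#' BED name column carries the canonical unit and score the match
#' percentage; extra columns hold period, copy number and longest perfect
#' run. The TSV mirror reports 1-based inclusive coordinates.
#'
#' @param repeats Output of [find_tandem_repeats()].
#' @param bed,tsv Output paths (either may be `NULL` to skip).
#' @export
write_repeats <- function(repeats, bed = NULL, tsv = NULL) {
  if (!is.null(bed)) {
    x <- repeats
    x$name <- x$unit
    x$score <- round(x$match_pct, 2)
    write_bed_track(x, bed, extra = c("period", "copy_number",
                                      "longest_perfect_run"))
  }
  if (!is.null(tsv)) {
    x <- repeats
    x$start <- x$start + 1L   # 1-based inclusive for human-facing tables
    write.table(x, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(repeats)
}
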