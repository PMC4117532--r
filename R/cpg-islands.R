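#' Detect CpG islands by composition
#'
#' Gardiner-Garden-and-Frommer-style windowed detection, provided so the
#' screen can run on synthetic genomes without an external island track.
#' Real-genome screens should prefer a curated island annotation supplied as
#' a BED track; islands found here carry `source = "computed"`.
#'
#' Every window of `min_length` bp that satisfies all three thresholds
#' (GC fraction, observed/expected CpG, implicitly the length) is flagged;
#' overlapping and adjacent qualifying windows are merged into maximal
#' regions. A merged region that no longer meets the thresholds as a whole
#' is trimmed from its weaker end until it does, so every reported island
#' re-tests positive under its own thresholds. Observed/expected CpG is
#' `nCpG * L / (nC * nG)`.
#'
#' @param seq DNA string over `A,C,G,T,N`.
#' @param min_length Minimum island length in bp (default 200).
#' @param min_gc Minimum GC fraction (default 0.5).
#' @param min_oe Minimum observed/expected CpG ratio (default 0.6).
#' @param chrom Chromosome name recorded on output intervals.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `gc_fraction`, `obs_exp_cpg`, `source`.
#' @export
detect_cpg_islands <- function(seq, min_length = 200L, min_gc = 0.5,
                               min_oe = 0.6, chrom = "seq") {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      gc_fraction = numeric(), obs_exp_cpg = numeric(),
                      source = character(), stringsAsFactors = FALSE)
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < min_length) return(empty)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  isC <- v == "C"
  isG <- v == "G"
  isN <- v == "N"
  cpg <- c(isC[-L] & isG[-1], FALSE)    # CpG starting at each position
  cumC <- cumsum(isC); cumG <- cumsum(isG)
  cumCpG <- cumsum(cpg); cumN <- cumsum(isN)
  w <- as.integer(min_length)
  starts <- seq_len(L - w + 1L)         # window start, 1-based
  ends <- starts + w - 1L
  rsum <- function(cum, s, e) cum[e] - c(0, cum)[s]
  nC <- rsum(cumC, starts, ends)
  nG <- rsum(cumG, starts, ends)
  nN <- rsum(cumN, starts, ends)
  # CpGs fully inside the window: starting positions s .. e-1
  nCpG <- rsum(cumCpG, starts, ends - 1L)
  gc <- (nC + nG) / w
  oe <- ifelse(nC > 0 & nG > 0, nCpG * w / (nC * nG), 0)
  ok <- nN == 0L & gc >= min_gc & oe >= min_oe
  if (!any(ok)) return(empty)
  r <- rle(ok)
  re <- cumsum(r$lengths)
  rs <- re - r$lengths + 1L
  hit <- which(r$values)
  stats_for <- function(s, e) {     # 1-based inclusive region
    n <- e - s + 1L
    c_ <- rsum(cumC, s, e); g_ <- rsum(cumG, s, e)
    cg <- if (e > s) rsum(cumCpG, s, e - 1L) else 0L
    list(gc = (c_ + g_) / n,
         oe = if (c_ > 0 && g_ > 0) cg * n / (c_ * g_) else 0)
  }
  rows <- lapply(hit, function(k) {
    s <- rs[k]
    e <- re[k] + w - 1L               # last qualifying window's end
    st <- stats_for(s, e)
    # trim toward thresholds from the compositionally weaker end
    while ((st$gc < min_gc || st$oe < min_oe) && (e - s + 1L) > w) {
      left <- stats_for(s + 1L, e)
      right <- stats_for(s, e - 1L)
      lscore <- min(left$gc - min_gc, left$oe - min_oe)
      rscore <- min(right$gc - min_gc, right$oe - min_oe)
      if (lscore >= rscore) { s <- s + 1L; st <- left } else { e <- e - 1L; st <- right }
    }
    if (st$gc < min_gc || st$oe < min_oe) return(NULL)
    data.frame(chrom = chrom, start = s - 1L, end = e,
               gc_fraction = st$gc, obs_exp_cpg = st$oe,
               source = "computed", stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
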