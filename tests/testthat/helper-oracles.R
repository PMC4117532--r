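# Independent brute-force oracles used to pin expected values. These stay
# deliberately naive and share no code with the package implementation.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# All maximal perfect tandem arrays (period range, min copies) by direct
# enumeration of every (start, period).
oracle_perfect_runs <- function(seq, min_period, max_period, min_copies) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(v)
  out <- list()
  for (p in min_period:max_period) {
    i <- 1L
    while (i + 2L * p - 1L <= L) {
      # extend the perfect period-p run starting at i
      j <- i
      while (j + p <= L && v[j + p] == v[j]) j <- j + 1L
      run_len <- j - i + p
      if (run_len >= min_copies * p) {
        # maximal: cannot extend left
        if (i == 1L || v[i - 1L] != v[i + p - 1L]) {
          out[[length(out) + 1L]] <- data.frame(
            start = i - 1L, end = i - 1L + run_len, period = p,
            copies = run_len / p,
            unit = paste(v[i:(i + p - 1L)], collapse = ""),
            stringsAsFactors = FALSE)
        }
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      copies = numeric(), unit = character()))
  }
  do.call(rbind, out)
}

# Best alignment of seq against an effectively unbounded tandem
# concatenation of unit, scored +2 match / -7 mismatch / -7 per gapped
# base; global in seq, local in the concatenation, so partial units at the
# array boundaries are free (fractional copies). Returns score and the
# match percentage of aligned columns.
oracle_tandem_alignment <- function(seq, unit, match = 2, mismatch = -7,
                                    gap = -7) {
  p <- nchar(unit)
  k <- ceiling(nchar(seq) / p) + 3L
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = seq, subject = strrep(unit, k), type = "global-local",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = -gap)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  nmatch <- sum(pat == sub & pat != "-")
  list(score = Biostrings::score(aln), matches = nmatch,
       columns = length(pat), match_pct = 100 * nmatch / length(pat))
}

# Naive IUPAC pattern matching on both strands.
oracle_sites <- function(seq, enzymes) {
  iupac_regex <- function(x) {
    map <- Biostrings::IUPAC_CODE_MAP
    paste(vapply(strsplit(x, "")[[1]], function(ch) {
      e <- map[[ch]]
      if (nchar(e) == 1L) e else paste0("[", e, "]")
    }, character(1)), collapse = "")
  }
  revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }
  find_all <- function(pat, subject) {
    hits <- integer()
    from <- 1L
    repeat {
      m <- regexpr(pat, substr(subject, from, nchar(subject)), perl = TRUE)
      if (m == -1L) break
      hits <- c(hits, from + m - 1L)
      from <- from + m
    }
    hits
  }
  rows <- list()
  for (i in seq_len(nrow(enzymes))) {
    rec <- enzymes$recognition[i]
    rc <- revcomp(rec)
    for (s in find_all(iupac_regex(rec), seq)) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = s - 1L, enzyme = enzymes$name[i], strand = "+",
        stringsAsFactors = FALSE)
    }
    if (rc != rec) {
      for (s in find_all(iupac_regex(rc), seq)) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = s - 1L, enzyme = enzymes$name[i], strand = "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), enzyme = character(),
                      strand = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$enzyme, out$strand), , drop = FALSE]
}

# Quadratic all-pairs interval overlap (0-based half-open).
oracle_overlaps <- function(qs, qe, ts, te) {
  any(mapply(function(s, e) qs < e && s < qe, ts, te))
}

# Merged qualifying fixed-width windows (the island definition, written
# longhand with substrings).
oracle_cgi_regions <- function(seq, w, min_gc, min_oe) {
  L <- nchar(seq)
  ok <- logical(max(0L, L - w + 1L))
  for (s in seq_along(ok)) {
    win <- substr(seq, s, s + w - 1L)
    v <- strsplit(win, "")[[1]]
    nc <- sum(v == "C"); ng <- sum(v == "G")
    ncpg <- sum(v[-w] == "C" & v[-1] == "G")
    gc <- (nc + ng) / w
    oe <- if (nc > 0 && ng > 0) ncpg * w / (nc * ng) else 0
    ok[s] <- !any(v == "N") && gc >= min_gc && oe >= min_oe
  }
  if (!any(ok)) return(data.frame(start = integer(), end = integer()))
  r <- rle(ok)
  e <- cumsum(r$lengths); s <- e - r$lengths + 1L
  hit <- which(r$values)
  data.frame(start = s[hit] - 1L, end = e[hit] + w - 1L)
}

# CpG-enriched test block (not the generator's process).
cpg_block_for_test <- function(n) {
  pieces <- sample(c("CG", "A", "C", "G", "T"), n, replace = TRUE,
                   prob = c(0.3, 0.175, 0.175, 0.175, 0.175))
  substr(paste(pieces, collapse = ""), 1, n)
}

# Spearman correlation from first principles: mid-ranks, then the Pearson
# product-moment formula written out.
oracle_spearman <- function(a, b) {
  midrank <- function(x) {
    sapply(x, function(xi) sum(x < xi) + (1 + sum(x == xi)) / 2)
  }
  ra <- midrank(a); rb <- midrank(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}
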