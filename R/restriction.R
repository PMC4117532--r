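#' Built-in methylation-sensitive restriction enzymes
#'
#' The five 5meCpG-sensitive endonucleases used by the XCI assay family.
#' Cleavage of each is blocked by methylation of the CpG(s) inside its
#' recognition sequence, so an uncut allele after digestion reports a
#' methylated (inactive-X) allele. `cpg_offsets` gives the 1-based offsets
#' of the C of each CpG dinucleotide within the recognition sequence.
#'
#' @return A data.frame with columns `name`, `recognition`, `cpg_offsets`
#'   (comma-separated), `methylation_sensitive`.
#' @export
restriction_enzymes <- function() {
  data.frame(
    name = c("HpaII", "HhaI", "BstUI", "AciI", "FauI"),
    recognition = c("CCGG", "GCGC", "CGCG", "CCGC", "CCCGC"),
    cpg_offsets = c("2", "2", "1,3", "2", "3"),
    methylation_sensitive = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Read an enzyme table override
#'
#' TSV with columns `name`, `recognition`, `methylation_sensitive`;
#' CpG offsets are derived from the recognition sequence.
#'
#' @param path TSV path.
#' @return Enzyme data.frame as from [restriction_enzymes()].
#' @export
read_enzyme_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "recognition", "methylation_sensitive")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("enzyme table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$recognition <- toupper(df$recognition)
  validate_enzymes(df)
  df$cpg_offsets <- vapply(df$recognition, function(r) {
    paste(cpg_offsets_of(r), collapse = ",")
  }, character(1))
  df[, c("name", "recognition", "cpg_offsets", "methylation_sensitive")]
}

cpg_offsets_of <- function(recognition) {
  v <- strsplit(recognition, "", fixed = TRUE)[[1]]
  which(v[-length(v)] == "C" & v[-1] == "G")
}

validate_enzymes <- function(enzymes) {
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  for (i in seq_len(nrow(enzymes))) {
    rec <- enzymes$recognition[i]
    if (nchar(rec) < 4L) {
      stop("enzyme ", enzymes$name[i], ": recognition shorter than 4 bp",
           call. = FALSE)
    }
    chars <- strsplit(rec, "", fixed = TRUE)[[1]]
    bad <- setdiff(chars, iupac)
    if (length(bad)) {
      stop("enzyme ", enzymes$name[i], ": invalid IUPAC code '",
           paste(bad, collapse = ""), "'", call. = FALSE)
    }
  }
  invisible(enzymes)
}

#' Scan a sequence for restriction sites
#'
#' Matches each enzyme's recognition sequence on both strands under IUPAC
#' ambiguity semantics. Palindromic recognition sequences are reported once
#' (strand `+`). Sites of different enzymes whose CpG dinucleotides fall on
#' the same genomic position are cross-flagged in `overlapping_sites`,
#' because methylation at a shared CpG couples their digestion behaviour.
#'
#' @param seq DNA string.
#' @param enzymes Enzyme table ([restriction_enzymes()] format).
#' @param chrom Chromosome name recorded on output intervals.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `enzyme`, `cpg_positions` (comma-separated 0-based
#'   genomic positions of CpG Cs), `overlapping_sites`; ordered by
#'   (start, enzyme).
#' @export
scan_restriction_sites <- function(seq, enzymes = restriction_enzymes(),
                                   chrom = "seq") {
  validate_enzymes(enzymes)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), enzyme = character(),
                      cpg_positions = character(),
                      overlapping_sites = character(), stringsAsFactors = FALSE)
  if (!nzchar(seq)) return(empty)
  subject <- Biostrings::DNAString(toupper(seq))
  rows <- list()
  for (i in seq_len(nrow(enzymes))) {
    rec <- enzymes$recognition[i]
    w <- nchar(rec)
    pat <- Biostrings::DNAString(rec)
    rcp <- Biostrings::reverseComplement(pat)
    palindromic <- as.character(rcp) == rec
    fwd <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
    add <- function(starts, strand) {
      if (length(starts) == 0L) return()
      # CpG genomic positions: a CpG inside the site is a CpG on both
      # strands; for a minus-strand match at [s, s+w) the recognition offset
      # o (1-based C position) maps to genomic 0-based (s + w - o - 1)
      offs <- cpg_offsets_of(rec)
      for (s in starts) {     # s 1-based match start
        gpos <- if (strand == "+") s - 1L + offs - 1L else s - 1L + w - offs - 1L
        rows[[length(rows) + 1L]] <<- data.frame(
          chrom = chrom, start = s - 1L, end = s - 1L + w, strand = strand,
          enzyme = enzymes$name[i],
          cpg_positions = paste(sort(gpos), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    add(Biostrings::start(fwd), "+")
    if (!palindromic) {
      rev <- Biostrings::matchPattern(rcp, subject, fixed = FALSE)
      add(Biostrings::start(rev), "-")
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$enzyme, out$strand), , drop = FALSE]
  # cross-flag sites of different enzymes sharing a CpG genomic position
  cpgs <- strsplit(out$cpg_positions, ",", fixed = TRUE)
  pos_enz <- split(rep(out$enzyme, lengths(cpgs)), unlist(cpgs))
  out$overlapping_sites <- vapply(seq_len(nrow(out)), function(k) {
    others <- unique(unlist(pos_enz[cpgs[[k]]], use.names = FALSE))
    paste(sort(setdiff(others, out$enzyme[k])), collapse = ",")
  }, character(1))
  rownames(out) <- NULL
  out
}
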