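#' Specification of a synthetic chromosome
#'
#' A ground-truth recipe for an X-chromosome-like test sequence: random
#' background of realistic GC content with planted genes (modelled as
#' single-exon intervals), pseudoautosomal regions, CpG-island blocks,
#' tandem-repeat arrays of controlled unit, copy number and purity, and
#' restriction sites placed at a stated edge gap from a named repeat.
#' Given the seed the spec fully determines the sequence and all tracks.
#'
#' @param chrom Chromosome name.
#' @param length Chromosome length in bp.
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, seed).
#' @param background_gc Background GC fraction (default 0.40, away from the
#'   island thresholds).
#' @param repeats Data.frame with columns `name`, `unit`, `copies`,
#'   `purity` (percent, 100 = perfect), `start` (0-based); an optional
#'   `scrub_flank` column (bp) removes every CpG dinucleotide from the
#'   background within that window of the repeat, so no accidental
#'   methylation-sensitive site survives near it.
#' @param cgis Data.frame with columns `name`, `start`, `length`
#'   (0-based start; composition is CpG-rich, GC ~0.7, obs/exp > 1); an
#'   optional logical `write_seq` column (default `TRUE`) controls whether
#'   the CpG-rich block is written into the sequence or the island exists
#'   only in the annotation track (mimicking a curated island annotation).
#' @param genes Data.frame with columns `gene_id`, `start`, `end`, `strand`
#'   (each gene is emitted with one exon spanning it).
#' @param pars Data.frame with columns `start`, `end`.
#' @param sites Data.frame with columns `enzyme`, `repeat_name`, `offset`
#'   (edge gap in bp between the repeat end and the site start).
#' @param escape_genes Character vector of escape-gene ids.
#' @return A list of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(chrom = "chrXsim", length = 10000L,
                                  seed = 1L, background_gc = 0.40,
                                  repeats = NULL, cgis = NULL, genes = NULL,
                                  pars = NULL, sites = NULL,
                                  escape_genes = character()) {
  spec <- structure(list(chrom = chrom, length = as.integer(length),
                         seed = as.integer(seed),
                         background_gc = background_gc,
                         repeats = repeats, cgis = cgis, genes = genes,
                         pars = pars, sites = sites,
                         escape_genes = escape_genes),
                    class = "synthetic_genome_spec")
  validate_genome_spec(spec)
  spec
}

validate_genome_spec <- function(spec) {
  L <- spec$length
  ivs <- list()
  if (!is.null(spec$repeats)) {
    stopifnot(all(c("name", "unit", "copies", "purity", "start") %in%
                    names(spec$repeats)))
    if (any(spec$repeats$purity < 0 | spec$repeats$purity > 100)) {
      stop("repeat purity must lie in [0,100]", call. = FALSE)
    }
    len <- nchar(spec$repeats$unit) * spec$repeats$copies
    ivs <- c(ivs, Map(c, spec$repeats$start, spec$repeats$start + len))
  }
  if (!is.null(spec$cgis)) {
    stopifnot(all(c("name", "start", "length") %in% names(spec$cgis)))
    ivs <- c(ivs, Map(c, spec$cgis$start, spec$cgis$start + spec$cgis$length))
  }
  for (iv in ivs) {
    if (iv[1] < 0 || iv[2] > L) stop("planted feature outside chromosome",
                                     call. = FALSE)
  }
  if (length(ivs) > 1L) {
    o <- order(vapply(ivs, `[`, numeric(1), 1))
    ivs <- ivs[o]
    for (i in seq_len(length(ivs) - 1L)) {
      if (ivs[[i + 1L]][1] < ivs[[i]][2]) {
        stop("planted repeat/CGI features overlap", call. = FALSE)
      }
    }
  }
  invisible(spec)
}

#' Build a synthetic chromosome from a spec
#'
#' Background bases are drawn i.i.d. at the spec's GC fraction; planted
#' features then overwrite the background. Repeat arrays are written with
#' 1-bp phase-breaking flanks so the planted boundaries are also the
#' detected boundaries; impurity substitutes evenly spaced bases inside the
#' array. CpG-island blocks are generated by a CpG-enriched process
#' (GC ~0.7, obs/exp CpG well above 1). Restriction sites are written at
#' their stated edge gap from the named repeat. Regeneration with the same
#' spec is bit-identical.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param outdir Optional directory; when given, writes `genome.fa`,
#'   `genes.gff3`, `cgi.bed`, `par.bed`, `escape.txt` and
#'   `truth_repeats.tsv` there.
#' @return List with `seq` (character), `chrom`, interval data.frames
#'   `genes`, `exons`, `cgis`, `pars`, `sites`, the repeat `truth` table
#'   (0-based half-open coordinates of every planted array) and
#'   `escape_genes`; plus `paths` when `outdir` was given.
#' @export
build_synthetic_genome <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  L <- spec$length
  pgc <- spec$background_gc
  v <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
              prob = c((1 - pgc) / 2, pgc / 2, pgc / 2, (1 - pgc) / 2))

  cgis <- empty_intervals()
  if (!is.null(spec$cgis)) {
    write_seq <- if ("write_seq" %in% names(spec$cgis)) {
      spec$cgis$write_seq
    } else rep(TRUE, nrow(spec$cgis))
    for (i in seq_len(nrow(spec$cgis))) {
      s <- spec$cgis$start[i]
      n <- spec$cgis$length[i]
      if (write_seq[i]) v[(s + 1L):(s + n)] <- cpg_rich_block(n)
      cgis <- rbind(cgis, data.frame(chrom = spec$chrom, start = s,
                                     end = s + n, strand = ".",
                                     stringsAsFactors = FALSE))
    }
    cgis$name <- spec$cgis$name
  }

  truth <- data.frame(name = character(), unit = character(),
                      start = integer(), end = integer(),
                      copies = numeric(), purity = numeric(),
                      stringsAsFactors = FALSE)
  if (!is.null(spec$repeats)) {
    for (i in seq_len(nrow(spec$repeats))) {
      unit <- toupper(spec$repeats$unit[i])
      p <- nchar(unit)
      copies <- spec$repeats$copies[i]
      s <- spec$repeats$start[i]                    # 0-based
      arr <- strsplit(strrep(unit, copies), "", fixed = TRUE)[[1]]
      n_sub <- round((1 - spec$repeats$purity[i] / 100) * length(arr))
      if (n_sub > 0L) {
        # substitute the second base of evenly spaced interior units,
        # leaving two clean units at each edge: a substitution is then a
        # plain mismatch that neither shifts the array phase nor moves
        # the planted boundaries
        if (copies < 5L) stop("purity < 100 needs at least 5 copies",
                              call. = FALSE)
        interior <- (3:(copies - 2L) - 1L) * p + 2L
        pos <- interior[round(seq(1L, length(interior),
                                  length.out = min(n_sub, length(interior))))]
        arr[pos] <- vapply(arr[pos], function(b) {
          setdiff(c("C", "G", "T", "A"), b)[1]
        }, character(1))
      }
      v[(s + 1L):(s + length(arr))] <- arr
      # phase-breaking flanks: planted edges become detected edges; left
      # alone when the adjacent base belongs to another planted feature
      # (a touching island makes the edge gap 0 either way)
      in_cgi <- function(pos0) {
        !is.null(spec$cgis) &&
          any(pos0 >= spec$cgis$start & pos0 < spec$cgis$start + spec$cgis$length)
      }
      uchars <- strsplit(unit, "", fixed = TRUE)[[1]]
      flank_base <- function(avoid) {
        # prefer a base absent from the unit so lag-p autocorrelation runs
        # cannot bridge the flank
        cand <- setdiff(c("C", "T", "A", "G"), unique(uchars))
        if (length(cand) == 0L) cand <- setdiff(c("C", "T", "A", "G"), avoid)
        cand[1]
      }
      if (s >= 1L && !in_cgi(s - 1L)) {
        v[s] <- flank_base(uchars[length(uchars)])
      }
      if (s + length(arr) < L && !in_cgi(s + length(arr))) {
        v[s + length(arr) + 1L] <- flank_base(uchars[1])
      }
      # break any accidental 2-copy tandem of this period hugging the
      # array, so detection can neither merge with nor extend into the
      # background and the planted edges stay the detected edges
      v <- disrupt_adjacent_seeds(v, s, s + length(arr), p, spec, L)
      truth <- rbind(truth, data.frame(
        name = spec$repeats$name[i], unit = canonical_unit(unit),
        start = s, end = s + length(arr), copies = copies,
        purity = spec$repeats$purity[i], stringsAsFactors = FALSE))
    }
  }

  if (!is.null(spec$repeats) && "scrub_flank" %in% names(spec$repeats)) {
    for (i in seq_len(nrow(spec$repeats))) {
      fl <- spec$repeats$scrub_flank[i]
      if (is.na(fl) || fl <= 0) next
      rp <- truth[i, ]
      win <- c(max(1L, rp$start + 1L - fl), min(L, rp$end + fl))
      idx <- win[1]:(win[2] - 1L)
      idx <- idx[idx <= rp$start | idx > rp$end]    # keep the array itself
      is_cpg <- idx[v[idx] == "C" & v[idx + 1L] == "G"]
      v[is_cpg] <- "T"    # CG -> TG: kills the CpG, creates none, breaks no phase
    }
  }

  sites <- empty_intervals()
  if (!is.null(spec$sites)) {
    enz <- restriction_enzymes()
    sites$enzyme <- character()
    for (i in seq_len(nrow(spec$sites))) {
      rec <- enz$recognition[enz$name == spec$sites$enzyme[i]]
      if (length(rec) == 0L) stop("unknown enzyme ", spec$sites$enzyme[i],
                                  call. = FALSE)
      rp <- truth[truth$name == spec$sites$repeat_name[i], , drop = FALSE]
      if (nrow(rp) == 0L) stop("site anchored to unknown repeat ",
                               spec$sites$repeat_name[i], call. = FALSE)
      s <- rp$end + spec$sites$offset[i]            # 0-based site start
      w <- nchar(rec)
      v[(s + 1L):(s + w)] <- strsplit(rec, "", fixed = TRUE)[[1]]
      sites <- rbind(sites, data.frame(chrom = spec$chrom, start = s,
                                       end = s + w, strand = "+",
                                       enzyme = spec$sites$enzyme[i],
                                       stringsAsFactors = FALSE))
    }
  }

  genes <- exons <- empty_intervals()
  if (!is.null(spec$genes)) {
    genes <- data.frame(chrom = spec$chrom, start = spec$genes$start,
                        end = spec$genes$end, strand = spec$genes$strand,
                        gene_id = spec$genes$gene_id, stringsAsFactors = FALSE)
    exons <- genes
    exons$id <- paste0(exons$gene_id, ".e1")
    exons <- exons[, c("chrom", "start", "end", "strand", "id", "gene_id")]
    genes <- genes[, c("chrom", "start", "end", "strand", "gene_id")]
  }
  pars <- empty_intervals()
  if (!is.null(spec$pars)) {
    pars <- data.frame(chrom = spec$chrom, start = spec$pars$start,
                       end = spec$pars$end, strand = ".",
                       stringsAsFactors = FALSE)
  }

  out <- list(seq = paste(v, collapse = ""), chrom = spec$chrom,
              genes = genes, exons = exons, cgis = cgis, pars = pars,
              sites = sites, truth = truth,
              escape_genes = spec$escape_genes)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(outdir, "genome.fa"),
                  gff3 = file.path(outdir, "genes.gff3"),
                  cgi = file.path(outdir, "cgi.bed"),
                  par = file.path(outdir, "par.bed"),
                  escape = file.path(outdir, "escape.txt"),
                  truth = file.path(outdir, "truth_repeats.tsv"))
    writeLines(c(paste0(">", spec$chrom), out$seq), paths$fasta)
    write_gff3_annotation(genes, exons, paths$gff3)
    write_bed_track(out$cgis, paths$cgi)
    write_bed_track(out$pars, paths$par)
    writeLines(spec$escape_genes, paths$escape)
    write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- paths
  }
  out
}

# Enforce v[i] != v[i+p] in a zone around the planted array (1-based
# a1..a2), so no lag-p autocorrelation run can bridge an edge or seed a
# mergeable background tandem next to it. Only background bases outside
# the array, the flanks and any planted island are mutated; replacements
# avoid re-creating equality with either lag-p neighbour and avoid
# creating a CpG.
disrupt_adjacent_seeds <- function(v, s0, e0, p, spec, L) {
  a1 <- s0 + 1L
  a2 <- e0
  reach <- 3L * p + max(3L, p) + 2L
  zone <- c(seq(max(1L, a1 - reach), a1 - 1L),
            seq(a2 - p + 1L, min(L - p, a2 + reach)))
  zone <- zone[zone >= 1L & zone + p <= L]
  protected <- function(j) {
    j >= a1 - 1L && j <= a2 + 1L ||                 # array + flanks
      (!is.null(spec$cgis) &&
         any(j - 1L >= spec$cgis$start &
               j - 1L < spec$cgis$start + spec$cgis$length))
  }
  for (iter in 1:25) {
    changed <- FALSE
    for (i in zone) {
      if (v[i] != v[i + p]) next
      j <- if (!protected(i + p)) i + p else if (!protected(i)) i else next
      avoid <- c(v[j - p][j - p >= 1L], if (j + p <= L) v[j + p])
      cand <- setdiff(c("A", "C", "G", "T"), avoid)
      no_cpg <- cand[!(cand == "G" & j > 1L & v[j - 1L] == "C") &
                       !(cand == "C" & j < L & v[j + 1L] == "G")]
      v[j] <- if (length(no_cpg)) no_cpg[1] else cand[1]
      changed <- TRUE
    }
    if (!changed) break
  }
  v
}

# CpG-enriched block: emit the dinucleotide CG with probability 0.25, else
# a single near-equifrequent base. Gives GC ~0.7 and obs/exp CpG ~1.6,
# comfortably above the 0.5/0.6 island thresholds.
cpg_rich_block <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    k <- max(16L, ceiling((n - length(out)) / 1.25))
    steps <- runif(k) < 0.25
    pieces <- ifelse(steps, "CG",
                     sample(c("A", "C", "G", "T"), k, replace = TRUE,
                            prob = c(0.25, 0.25, 0.25, 0.25)))
    out <- c(out, strsplit(paste(pieces, collapse = ""), "", fixed = TRUE)[[1]])
  }
  out[seq_len(n)]
}
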