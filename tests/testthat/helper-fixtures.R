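# A synthetic chromosome planting one fully compliant locus plus decoys
# each designed to fail exactly one screening criterion. Loci are spaced
# 3 kb apart; each gets its own island and HpaII site unless the decoy
# design says otherwise. The island of the enzyme-less decoy exists only
# in the annotation track and the decoy's flanks are CpG-scrubbed, so no
# accidental site can rescue it.
decoy_genome <- function(seed = 101L) {
  at <- function(k) as.integer(3000 * k)         # locus anchor
  repeats <- data.frame(
    name = c("good", "few_units", "in_exon", "in_par", "cgi_far",
             "escape_linked", "no_enzyme"),
    unit = "GAAA",
    copies = c(16, 11, 16, 16, 16, 16, 16),
    purity = 100,
    start = at(1:7),
    scrub_flank = c(0, 0, 0, 0, 0, 0, 320),
    stringsAsFactors = FALSE)
  rep_end <- repeats$start + 4L * repeats$copies
  cgis <- data.frame(
    name = paste0("CGI_", repeats$name),
    start = rep_end + c(150, 150, 150, 150, 350, 150, 150),
    length = 400L,
    write_seq = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  # each island is linked (nearest TSS within 2 kb) to its own gene so the
  # escape filter has a defined verdict everywhere; only GENE_escape is on
  # the escape list, and only GENE_exon overlaps its repeat
  cgi_end <- cgis$start + cgis$length
  genes <- data.frame(
    gene_id = c("G_good", "G_few", "GENE_exon", "G_par", "G_far",
                "GENE_escape", "G_noenz"),
    start = c(cgi_end[1] + 100L, cgi_end[2] + 100L, repeats$start[3] - 50L,
              cgi_end[4] + 100L, cgi_end[5] + 100L, cgi_end[6] + 100L,
              cgi_end[7] + 100L),
    end = c(cgi_end[1] + 500L, cgi_end[2] + 500L, rep_end[3] + 50L,
            cgi_end[4] + 500L, cgi_end[5] + 500L, cgi_end[6] + 500L,
            cgi_end[7] + 500L),
    strand = "+",
    stringsAsFactors = FALSE)
  pars <- data.frame(start = repeats$start[4] - 100L, end = rep_end[4] + 100L)
  sites <- data.frame(
    enzyme = "HpaII",
    repeat_name = c("good", "few_units", "in_exon", "in_par", "cgi_far",
                    "escape_linked"),
    offset = 50L,
    stringsAsFactors = FALSE)
  spec <- synthetic_genome_spec(
    chrom = "chrXsim", length = 26000L, seed = seed,
    repeats = repeats, cgis = cgis, genes = genes, pars = pars,
    sites = sites, escape_genes = "GENE_escape")
  build_synthetic_genome(spec)
}

screen_decoy_genome <- function(g, config = NULL) {
  if (is.null(config)) {
    config <- screen_config(escape_genes = g$escape_genes)
  }
  screen_candidates(stats::setNames(g$seq, g$chrom),
                    annotation = list(genes = g$genes, exons = g$exons),
                    cgi_track = g$cgis, par_track = g$pars, config = config)
}
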