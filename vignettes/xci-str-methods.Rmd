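---
title: "Screening X-linked STR markers of X-inactivation and quantifying skewing"
author: "xcistr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening X-linked STR markers of X-inactivation and quantifying skewing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcistr)
```

## The problem

In female eutherian mammals one X-chromosome per cell is epigenetically
silenced (X-chromosome inactivation, XCI). Which parental X is silenced is
decided early and clonally inherited, so a tissue carries a mixture of
cells inactivating either X. The fraction of cells inactivating the
majority allele — the *lyonization ratio* — is diagnostic for clonality,
carrier status of X-linked disease, and hematopoietic aging. The standard
readout digests genomic DNA with a 5meCpG-sensitive restriction enzyme
(the inactive X is methylated at promoter-associated CpG islands and
resists digestion), then amplifies a polymorphic short tandem repeat (STR)
so the two X chromosomes can be told apart by allele length on a capillary
analyzer.

`xcistr` implements both halves of that workflow as testable components:

1. **Marker discovery** — a multi-criterion screen of an X-chromosome
   sequence for core-promoter STRs suitable as XCI reporters.
2. **Skewing quantification** — conversion of paired undigested/digested
   fragment-analysis peak tables into stutter-corrected Xa/Xi ratios,
   skewing classes, QC verdicts, population informativeness, inter-locus
   concordance, and trio phasing of the inactive X.

Because no public dataset accompanies the assay, the package also ships
first-class synthetic-data generators that plant ground truth into
chromosome sequences and electropherogram tables, closing the loop for
every stage.

## The genome screen

A candidate locus must satisfy four criteria, evaluated as six auditable
sub-checks per detected repeat:

* **(i)** a tetra- or pentanucleotide tandem array with at least 12 repeat
  units and a match percentage above 90, under alignment weights +2 for a
  match and 7-point penalties for mismatches and indels;
* **(ii)** outside annotated exons and pseudoautosomal regions (PARs are
  shared with the Y and escape inactivation);
* **(iii)** strictly within 300 bp of — or inside — a CpG island linked to
  a gene subject to XCI (escape genes are excluded by an input list, since
  their promoter methylation does not track inactivation);
* **(iv)** at least one 5meCpG-sensitive restriction site strictly within
  300 bp of the repeat, so the methylation state is assayable.

### Repeat detection

Repeat detection is seeded from perfect tandem stretches (lag-*p*
autocorrelation), merges same-unit seeds across short interruptions,
extends each candidate while flanking bases continue the unit in phase,
and scores the result by **wraparound dynamic programming** against the
candidate unit: the unit index wraps modulo the period and partial units
at either boundary are free, which yields fractional copy numbers
(a 49-bp array of 4-bp units is 12.25 copies). The match percentage is the
fraction of aligned columns that match. We do not reimplement the full
probabilistic model of the published repeat finders; the aim is
reproducing accept/reject behaviour at the stated thresholds with
semantics simple enough to verify against brute-force oracles, which the
test suite does on every run.

Two interpretation choices were genuinely open:

* *Match percentage.* Published repeat tables report both a percent-match
  and a percent-indel figure; we take "match percentage" as matches over
  aligned columns (matches + mismatches + indels) and report the indel
  percentage alongside.
* *Maximality.* We extend candidate intervals greedily while the next base
  continues the unit in phase. Under +2/−7 scoring any mismatching base
  lowers the alignment score, so the reported interval is score-maximal.
  The alternative — extend while the match percentage stays above the
  threshold — would let a perfect 64-bp array absorb several mismatching
  flank bases and still sit above 90%, which contradicts how repeat
  boundaries are conventionally reported; we therefore use score
  maximality.

Thresholds are strict as printed: `copy_number >= 12` (inclusive),
`match_pct > 90` (exclusive). Units are reported as canonical rotations
with a small override table so the field's names (`GAAA`, `CAG`) are used
rather than the lexicographic minima (`AAAG`, `AGC`).

### Annotation and distances

Coordinates are 0-based half-open internally; BED and GFF3 conventions are
honoured exactly at I/O (via `rtracklayer`), and human-facing TSVs print
1-based inclusive coordinates. Two distance conventions are exposed,
because published distances rarely state theirs: `start_to_start`
(absolute difference of 1-based starts; this is the convention that
reproduces printed repeat-to-island distances from printed coordinates)
and `edge_gap` (bases strictly between the intervals, 0 when touching or
overlapping). The proximity filters use `edge_gap` with strict `<`, so an
overlap ("residing within") passes at distance 0 and a gap of exactly
300 bp fails.

CpG islands are preferably supplied as a curated BED track. A
composition-based detector (windows of ≥ 200 bp with GC ≥ 0.5 and
observed/expected CpG ≥ 0.6, where obs/exp = nCpG·L/(nC·nG); qualifying
windows merged, merged regions trimmed until they re-test positive) is
provided so synthetic genomes need no external track.

Restriction sites are matched under IUPAC semantics on both strands
(`Biostrings`); palindromic recognitions are reported once. The built-in
table carries the five assay enzymes (HpaII CCGG, HhaI GCGC, BstUI CGCG,
AciI CCGC, FauI CCCGC), all methylation-sensitive; sites of different
enzymes sharing a CpG position are cross-flagged, since methylation at the
shared cytosine couples their digestion behaviour. Island-to-gene linkage
uses the nearest annotated TSS within a 2-kb window (the linkage rule is
not standardised anywhere; 2 kb covers the island "shores"). When escape
filtering is active, an island with no linkable gene fails the escape
check — the conservative reading, since its XCI status is unknown.

## Quantifying skewing

For each heterozygous sample the two allele peak areas are measured in an
undigested and a digested run. Normalising each digested area by its
undigested companion cancels allele-specific amplification bias
(shorter alleles amplify better), giving

$$r = \frac{d_1/u_1}{d_1/u_1 + d_2/u_2},$$

the fraction of cells carrying allele 1 on the inactive X. The
main-inactive-allele percentage is $100\max(r, 1-r)$; 50–80% is classified
*random*, strictly above 80% *non-random* (the convention used when the
assay was validated), with an advisory flag at ≥ 90% ("extremely skewed" —
the literature uses the phrase without a fixed threshold, so it is a flag,
not a third class).

**Stutter correction.** Polymerase slippage puts a stutter peak one repeat
unit below each true allele, proportional to the true-allele area. When a
heterozygote's alleles are exactly one unit apart, the longer allele's
stutter co-migrates with the shorter allele's true peak; the corrected
shorter-allele area is the observed area minus `stutter_fraction` times
the longer allele's observed area, floored at zero (with a QC flag when
the correction overshoots by more than 5%). Alleles further apart are
untouched. The stutter fraction is locus-specific — tetranucleotides
stutter far less than trinucleotides; defaults are 0.026 (GAAA locus) and
0.176 (CAG locus) — and can be re-estimated from any samples showing a
single true allele (`estimate_stutter_fraction`), since for them the n−1
peak is pure stutter. The exact arithmetic of the historically cited
normalisation procedure is not published in reproducible form; the model
here (single n−1 position, proportional to the true allele, applied only
at one-unit spacing) is the minimal model consistent with reporting a mean
stutter *percentage of the true allele*, and it is stated explicitly so it
can be audited.

**Quality control.** A male (single-X) sample carries its only X active
and unmethylated, so complete digestion must abolish its peak: residual
digested/undigested signal above 5% fails the batch. Results are reported
per enzyme and never averaged across enzymes — overlapping-site chemistry
makes different enzymes legitimately disagree — with a discordance flag
when two enzymes differ by more than 15 percentage points.

**Population statistics.** Observed heterozygosity is the fraction of
typed females with two distinguishable alleles (males are excluded from
the denominator but contribute alleles to the frequency table); expected
heterozygosity $1-\sum p_i^2$ is reported alongside because published
tables label their rates either way. Combined informativeness of a
multi-locus panel is $1-\prod(1-H_\ell)$ in independence mode (averaged
with equal weight over population subsets when several are supplied) or
the empirical fraction of samples heterozygous at ≥ 1 locus. Inter-locus
concordance is Spearman rank correlation with a Fisher-z 95% CI
($\tanh(\operatorname{atanh} r \pm 1.96/\sqrt{n-3})$) — the validation
literature names the statistic but not the CI method, and Fisher-z is the
standard choice. Trio phasing assigns the parental origin of a daughter's
preferentially inactivated allele from genotypes alone (father
hemizygous).

## The synthetic-data generators

`build_synthetic_genome` writes an X-chromosome-like sequence: i.i.d.
background at GC 0.40 (clear of the island thresholds), planted
single-exon genes, PARs, CpG-island blocks from a CpG-enriched process
(GC ≈ 0.7, obs/exp ≈ 1.6), tandem arrays of controlled unit, copy number
and purity, and restriction sites at stated edge gaps from named repeats.
So that planted coordinates are also detected coordinates, each array gets
1-bp phase-breaking flanks drawn from bases absent from the unit, and the
background immediately around each edge is edited so no lag-*p*
autocorrelation run can bridge the edge or seed a mergeable background
tandem there; impurity substitutions touch only interior units. Everything
is a pure function of the spec and seed.

`simulate_cohort` draws genotypes under Hardy-Weinberg equilibrium from
per-locus allele-frequency tables (males hemizygous), gives each female
one skew parameter shared across loci (so inter-locus concordance reflects
a common cellular state), and renders peak tables: undigested areas
proportional to allele dose, digested areas retaining the methylated (Xi)
dose plus the uncut fraction `1 - digestion_efficiency` of the active
dose, stutter added at the n−1 position, and independent multiplicative
log-normal noise of the stated CV on every peak. The methylation model is
deliberately binary — Xi fully methylated, Xa fully unmethylated at the
assayed site, which is the assay's interpretive model for non-escape
loci; partial methylation and overlapping-site digestion kinetics are
represented only through the efficiency scalar, and this is a known
limitation. The default skew mixture makes ~70% of females random
(a folded Beta(12,12) around 0.5, capped at main-allele 80%) and the rest
skewed at 0.85/0.92/0.99; the default allele-frequency tables give
single-locus heterozygosities around 0.85, matching what highly
polymorphic X-linked STRs show in outbred populations.

What passing on synthetic data does *not* show: real electropherograms
have baseline noise, minus-A artefacts, size-calling error beyond ±1 bp,
and tissue-specific escape variation, none of which are modelled; real
cohort concordance and heterozygosities depend on the study population.

## Numerical and design notes

* Degenerate inputs: an empty sequence screens to an empty result (not an
  error); an all-N sequence likewise; invalid alphabet characters raise an
  error naming the offset; a zero undigested area is reported as allele
  dropout, zero total digested signal as complete digestion without
  signal, and a cohort with a monomorphic locus simply yields no
  informative samples.
* Tie-breaks: overlapping repeat calls with different units are resolved
  by higher alignment score, then smaller period, then leftmost start;
  same-unit overlaps are merged and re-scored. Output ordering is
  deterministic by (start, period).
* Tolerances: stutter conservation holds to 1e−9 relative; the noise-free
  closed loop (simulate → quantify) reproduces planted Xi fractions to
  1e−9.
* Problem sizes used by the validation suite: oracle equivalence on
  sequences ≤ 2 kb; threshold grids of 5–501 planted loci; cohorts of
  50–60 samples per condition. These sizes are where the brute-force
  oracles stay exact and the Monte-Carlo properties (skew recovery within
  3 points, two-locus Spearman r ≥ 0.9 at 5% noise) are stable.

## A worked screen

```{r screen-example}
spec <- synthetic_genome_spec(
  chrom = "chrXsim", length = 12000L, seed = 55L,
  repeats = data.frame(name = "good", unit = "GAAA", copies = 16,
                       purity = 100, start = 5000L),
  cgis = data.frame(name = "CGI1", start = 5214L, length = 500L),
  genes = data.frame(gene_id = "RP2like", start = 5814L, end = 6400L,
                     strand = "+"),
  sites = data.frame(enzyme = "HpaII", repeat_name = "good", offset = 50L))
g <- build_synthetic_genome(spec)
res <- screen_candidates(setNames(g$seq, g$chrom),
                         annotation = list(genes = g$genes, exons = g$exons),
                         cgi_track = g$cgis)
res[res$accepted, c("start", "end", "unit", "copy_number", "match_pct",
                    "cgi_edge_gap", "site_enzyme", "site_gap", "gene_id")]
```

## A worked quantification

```{r quant-example}
sim <- simulate_cohort(cohort_spec(n_females = 10, n_males = 2, skew = 0.75,
                                   area_cv = 0, seed = 12L))
res <- quantify_xci(sim$peaks)
head(res[!is.na(res$main_inactive_pct),
         c("sample", "locus", "allele1", "allele2",
           "xi_fraction_allele1", "main_inactive_pct", "skew_class")])
```

With zero noise and full digestion every informative female returns the
planted 75% exactly; the test suite asserts this closed loop across the
skew range, and the stochastic counterparts (5–10% noise) within their
stated tolerances.
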