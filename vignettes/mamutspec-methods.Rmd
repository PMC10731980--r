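---
title: "Methods: heritable mutation detection and spectrum analysis in MA cohorts"
author: "mamutspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heritable mutation detection and spectrum analysis in MA cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

A mutation-accumulation (MA) experiment propagates many independent
lineages of a selfing diploid from a common founder, so that spontaneous
(or treatment-induced) mutations accumulate nearly free of selection.
After joint variant calling, each line carries two kinds of
non-reference variants: founder **germline** variation shared by several
lines, and **de novo** mutations private to one line. Because the
per-site mutation rate is on the order of 10^-8^-10^-9^ per generation,
the probability that two independent lines mutate the same base is
negligible; a variant observed in exactly one line (a *singleton* or
unique site) is therefore a reliable proxy for a heritable de novo
mutation. `mamutspec` implements the post-calling stages of this
analysis: quality filtering, singleton selection, rate estimation,
substitution and InDel spectra, flanking-sequence context, region and
deleteriousness annotation, and group statistics.

# Filtering and singleton selection

Two locus-level quality filters are applied over the full cohort before
any singleton logic, both with **strict** inequalities:

* missing-call fraction (`./.` cells over *all* lines) > `max_missing_fraction` (default 0.20);
* heterozygous-call fraction > `max_het_fraction` (default 0.20).

The heterozygosity filter divides by **non-missing** calls by default:
the two filters address different failure modes (dropout vs
paralog-collapse/mapping artifacts), and a locus with many missing calls
should not have its het excess diluted by them. Since the convention is
not universal, `filter_config(het_denominator = "all")` flips the
denominator.

A locus is then a singleton iff exactly one line carries a
non-reference, non-missing genotype. Uniqueness is **positional**
(`contig`, `pos`): if two lines carry different alt alleles at the same
position, both records are discarded, because a site that is variable in
two lines — whatever the alleles — is evidence of shared variation or a
systematic artifact, not two independent mutations.
`select_singletons(allele_aware = TRUE)` switches to
(`contig`, `pos`, `ref`, `alt`) uniqueness for callers that emit
decomposed multi-allelics. The owning line's genotype sets zygosity
(`hom_alt` → homozygous, `het` → heterozygous).

Both VCF dialects are supported, since joint callers differ: one
multi-sample VCF (missing cells are explicit `./.`), or one VCF per line,
in which an absent record defaults to `hom_ref`
(`absent_means = "missing"` for callers that omit no-coverage sites).

# The zygosity-weighted rate estimator

In a selfing line, a heterozygous mutation is transmitted to fixation
(homozygosity) in the next generation with probability 1/2. The
effective heritable count of a singleton set is therefore

$$E = N_{hom} + \tfrac{1}{2} N_{het}, \qquad
\hat\mu = \frac{E}{D \cdot S \cdot L \cdot g},$$

with `S` the per-haplotype target size (reference non-N length by
default), `L` the number of lines, `g` generations of accumulation, and
`D` the diploid site factor. `D = 2` by default — both homologous copies
are mutational targets — and every report header prints the
`(S, D, L, g)` actually used, since published rates are frequently not
comparable precisely because these denominators are implicit.

Statistics mirror common practice in this literature: per-line counts
(lines with zero singletons count as 0) compared across groups by
one-way ANOVA with Tukey HSD; per-line transition fractions compared by
two-sided t-tests against the reference group (Welch by default, since
group sizes differ after any pooling of treatment arms; lines with zero
SNVs have an undefined fraction and are excluded, and reported). The
compact letter display is computed from the maximal cliques of the
"not significantly different" graph, so two groups share a letter
*iff* their Tukey-adjusted p ≥ α; cliques are ordered by descending
best member mean (ties by name) before letters are assigned, making the
display deterministic.

# Substitution spectrum and flanking context

The spectrum uses all **12 directed classes** on the reference strand
with no reverse-complement collapsing, because C>T and G>A (and the
purine-purine vs pyrimidine-pyrimidine transition subtotals) are
reported separately in this field; `spectrum_table(collapse6 = TRUE)`
adds the strand-collapsed view.

Flanking context is the position (-k..+k, default k = 5) × base
(A, C, G, T) relative-frequency matrix of the reference sequence around
mutated sites, optionally restricted by mutated base and group. Sites
closer than `k` to a contig end are excluded (rather than N-padded) so
every column sums to exactly 1; the excluded count is reported. The
consensus is the per-position argmax with lexicographic tie-breaking and
an explicit tie flag — a deterministic rule in place of the visual
judgement of a sequence logo. Upstream/downstream are defined on the
forward strand for all sites, including mutated-G subsets: the
reverse-complement convention for G sites is left to the caller
(`extract_flanks` is strand-agnostic), and results are labelled with the
subset used.

# InDel classification

InDels are carried in VCF anchor-base form; size is the allele-length
difference after the anchor. The short/long split is at 3 bp. Slippage
context is classified at the boundaries of the affected interval:

* **homopolymer**: a single-base run of ≥ `min_run` (default 4) starts at
  either boundary, or the inserted/deleted sequence is itself a
  homopolymer that extends an adjacent run (possibly of length 0) to
  ≥ `min_run`;
* **polynucleotide repeat**: a tandem repeat of unit 2-3 bp with
  ≥ `min_copies` (default 3) exact copies abuts either boundary, or the
  InDel sequence is an integer number of copies of the abutting unit and
  flank + InDel together reach `min_copies`.

The extension clauses make the natural cases — deleting one base of
`AAAA`, inserting one `AT` unit next to `ATATAT` — count as adjacent
even when the remaining flank alone falls below threshold. When both
classes match, homopolymer takes precedence (a homopolymer is a unit-1
repeat; precedence avoids double counting). "Adjacent" is read
literally: the run/repeat must touch the interval boundary, with no gap.
The thresholds are deliberate package choices — published analyses of
this kind rarely state theirs — chosen so that "adjacent" is non-trivial
on random sequence (a boundary run of ≥ 4 occurs by chance at roughly
3% of sites at uniform base composition); both are arguments and appear
in every report header.

# Region and intolerance annotation

Region calls use an explicit precedence over GFF3 features:
CDS-overlap → exon (coding); UTR → UTR; exon without CDS/UTR → exon
(non-coding); inside a gene otherwise → intron; else intergenic. InDels
are classified by any overlap of their affected interval under the same
precedence, and variants touching conflicting features of multiple
transcripts take the most severe call. Intolerance is a pure function of
(variant, region, score): an SNV with a supplied SIFT score strictly
below 0.05, or an InDel overlapping a CDS. SIFT scores are inputs, never
computed — reimplementing a protein-impact predictor is out of scope —
and score coverage is visible in the output (`basis`, `sift_score`
columns).

# The synthetic cohort generator

`simulate_cohort()` produces the full statistical structure the analysis
assumes, with a planted truth:

* an i.i.d. reference at configurable GC (default 0.36, a plant-genome
  value), salted with homopolymer tracts (5-12 bp) and 2-3 bp tandem
  repeats (3-6 copies) at 1 per 5 kb, recorded for InDel placement;
* germline variants planted in ≥ 2 lines each
  (`2 + Binom(L - 2, 0.25)` carriers), so the singleton filter must
  remove every one — the sharing law is a knob, as founder stocks differ;
* line-private de novo mutations: classes from a 12-class weight vector
  (built from `transition_fraction`, default 0.6, when not given
  explicitly), zygosity Bernoulli(`hom_fraction`, default 0.17), InDel
  sizes over 1-28 bp with 77% of mass on 1-3 bp, direction from
  `ins_del_ratio` (default 0.45), and a `repeat_adjacent_fraction`
  (default 0.5) share of InDels planted as expansions/contractions of
  the salted tracts. The tract type is chosen compatible with the drawn
  size (homopolymers accept any size), so planting adjacency does not
  distort the size distribution; contractions are clamped to leave part
  of the tract in place.

**Rate scale.** The configured `snv_rate`/`indel_rate` are *heritable*
rates on the same zygosity-weighted scale the estimator reports: the
expected observed count per line is
`rate * D * S * g * 2 / (1 + hom_fraction)`, so that
`E[N_hom + N_het/2] = rate * D * S * g` and the estimator is unbiased
for the configured value. This is the scale on which rates in this
literature are printed (a per-line observed burden of ~3.8 SNVs with a
17% homozygous share corresponds to a weighted rate of ~9.5 × 10^-9^
over a 2 × 119 Mb diploid target), and it keeps the simulator and
estimator coherent. The defaults (1 Mb genome, 4 groups × 40 lines,
`snv_rate` 1.1 × 10^-6^, `indel_rate` 1.3 × 10^-7^, D = 2) reproduce
realistic per-line burdens (~3.8 SNVs, ~0.45 InDels) at desk scale.

Planted variant positions keep a minimum mutual separation (32 bp, above
the maximum InDel span) so alleles, flanks and motif rewrites never
overlap; an optional context motif (e.g. `TTA` at -3..-1 upstream of
mutated C sites, applied with probability `strength`) rewrites the
reference before alleles are finalized, letting consensus recovery be
tested against a known planted signal.

The generator emulates genotype-level structure only. It does **not**
simulate reads, sequencing error, mapping artifacts, genotyping
uncertainty, selection, or Mendelian segregation beyond the observed
zygosity mixture (the ½-weighting is what is under test, not meiosis).
Passing recovery tests therefore validates the analysis logic under
clean calls; they say nothing about upstream calling accuracy on real
data.

# Numerical and degenerate-input choices

* Filter comparisons are strict (`>`), matching the "greater than"
  convention; a locus at exactly 20% is retained.
* Percentages are reported to 2 decimals; empty groups report NA, never
  NaN, and undefined insertion:deletion ratios (zero deletions) carry an
  explicit `ratio_defined = FALSE` flag instead of infinity.
* ANOVA on groups with zero within-group variance everywhere is refused
  as degenerate rather than returning an unstable F.
* MNPs and symbolic alleles are rejected at typing time; ambiguity codes
  other than N are rejected at FASTA load (spectrum classes are defined
  only on A/C/G/T) unless mapped to N by request.
* Report writing uses fixed column order, stable (contig, pos, line)
  sorting and fixed float precision, so identical runs are
  byte-identical.

# Validation problem sizes

The shipped test suite validates each stage against independent oracles
at sizes chosen to give tight checks in seconds-to-minutes: exact
composition fixtures at the published cohort's printed counts; 100
random cohorts (100-400 loci × 5-50 lines) against a brute-force
filter/singleton recount; 20-seed rate recovery at 40 lines × 1 Mb with
`D = 1` and `snv_rate` 5 × 10^-6^; ~1,000-SNV spectrum recovery with a
χ² goodness-of-fit at α = 0.01; planted-motif consensus recovery at
strength 0.9; ~400-InDel direction/adjacency recovery with 10^4
random-fixture classifier-vs-oracle comparisons; and 100 random datasets
for ANOVA/Tukey/t-test against closed-form references at 10^-6^.

# Known limitations

* Positional singleton uniqueness can discard true de novo mutations
  that land on a germline-variable site; at realistic densities this is
  rare, and the allele-aware option exists.
* The estimator assumes complete detection; no false-negative correction
  is applied, so rates inherit the caller's sensitivity.
* Repeat adjacency uses exact unit copies; diverged or interrupted
  repeats are not matched (a full tandem-repeat finder is out of scope).
* Region calls collapse all transcripts through one precedence; isoform-
  specific effects are not represented.
* GO/functional enrichment is out of scope; the annotated gene list can
  be exported for external tools.
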