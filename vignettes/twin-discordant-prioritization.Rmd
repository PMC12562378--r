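---
title: "Prioritizing variants in phenotype-discordant monozygotic twin exomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing variants in phenotype-discordant monozygotic twin exomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinwes)
```

## The analytical problem

Monozygotic (MZ) twins discordant for a congenital disorder are a rare and
informative design: the twins are genetically identical at conception, so a
coding variant that truly distinguishes them must be postzygotic, and any
inherited candidate must be weighed against the fact that the healthy twin
carries it too. `twinwes` implements the complete desk side of such an
analysis for a nuclear family containing a discordant twin pair: staged
filtering of an annotated multi-sample exome VCF, genotype-model screens
across the family, twin genotype concordance, a curated disease-gene panel
comparison, and a read-evidence review stage that turns manual BAM/IGV
inspection into reproducible flags.

The package assumes variant calling and annotation have already happened
(a joint-genotyped VCFv4.2 with ANNOVAR-style INFO fields, hg19-style
chromosome names in either naming convention). It deliberately does not
align reads, call variants, or recompute pathogenicity scores.

## The filtering funnel

Variants pass five gates in a fixed order, each applied to the survivors
of the previous one:

1. **Caller quality** — `FILTER == "PASS"` only. A bare `.` FILTER is
   treated as *not* PASS by default: an unlabeled call is not evidence of
   a high-confidence call. This is configurable for callers that leave
   FILTER unset.
2. **Population rarity** — the *maximum* allele frequency across the
   present sources (gnomAD exome, gnomAD genome, ExAC) must be at most
   `maf_threshold` (default 0.01). Using the maximum is the conservative
   reading when several databases are consulted. A variant absent from
   every source is retained: novel variants are precisely what a de novo
   screen is looking for.
3. **Protein-altering consequence** — functional region must intersect
   {exonic, splicing} (the composite `exonic;splicing` annotation counts
   as both) and the exonic class must be one of nonsynonymous SNV,
   stopgain, stoploss, frameshift insertion, frameshift deletion.
   Synonymous variants are excluded. A splicing variant with no exonic
   class (the intronic side of a splice junction) is retained, since
   ANNOVAR leaves the class empty there.
4. **Liberal pathogenicity tier** — at least one of SIFT, PolyPhen-2
   HDIV, MutationTaster calls the variant damaging. The damaging category
   sets are per-tool: SIFT {D}, PolyPhen-2 {D, P}, MutationTaster {D, A}.
   Counting PolyPhen-2 "possibly damaging" (P) is required for borderline
   candidates to survive into manual review; MutationTaster "polymorphism"
   (P/N) classes never count. A tool with no prediction contributes
   nothing — absent scores never pass any threshold in this package.
5. **Strict pathogenicity tier** — the liberal condition plus CADD
   strictly greater than 20 and REVEL at least 0.5. The asymmetry of the
   bounds matters at the margins: a variant at CADD exactly 20 fails,
   one at REVEL exactly 0.5 passes. CADD > 20 approximates the top 1% of
   scaled deleteriousness; REVEL 0.5 is the usual missense-pathogenicity
   operating point.

The strict tier is cumulative (it includes the liberal condition) rather
than an independent test; this makes the funnel counts monotone by
construction and matches how the survivors nest in practice.

## Genotype-model screens

Each variant is classified per sample as `hom_ref` (0/0), `het` (0/1),
`hom_alt` (1/1) or `no_call`. Phasing is ignored. Half-calls such as
`0/.` classify as `no_call`: an uncertain genotype should trigger review,
not silently count as reference or carrier.

The four screens, run on autosomes only by default:

* **De novo** — the affected twin carries at least one alternate allele
  (het *or* hom-alt; an apparently homozygous de novo call is suspicious
  but it is the review stage's job to say so) and every other member is
  homozygous reference.
* **Autosomal recessive** — affected twin hom-alt, both parents het
  carriers, and neither the unaffected twin nor any sibling hom-alt. A
  parent no-call never satisfies the carrier requirement under either
  no-call policy, because the pattern positively requires the carrier
  genotype.
* **Autosomal dominant** — affected twin het; unaffected twin, siblings
  and both parents homozygous reference. With incomplete penetrance
  enabled, exactly one carrier parent is tolerated and the candidate is
  flagged `penetrance_exception`.
* **Homozygous-in-affected** — simply hom-alt in the affected twin. This
  deliberately places no constraint on the rest of the family; variants
  equally homozygous in the healthy twin are flagged `concordant_twin`
  so the report can discount them, mirroring how such screens are pruned
  by twin comparison in practice.

**No-call policy.** The default is *permissive*: a missing genotype in a
member whose genotype only needs to be compatible with reference counts
as compatible, but the candidate carries a mandatory `no_call_supported`
flag. The alternative *strict* policy excludes such variants outright.
Permissive is the default because joint-genotyped family VCFs routinely
contain no-calls at real candidate sites, and silently discarding them
hides exactly the calls most in need of read-level review; the flag keeps
the weakness visible downstream. Under the strict policy every screen's
candidate set is provably a subset of its permissive counterpart, a
property the test suite checks.

Note that an affected-only heterozygous pattern satisfies both the de
novo and the dominant predicate — they are genuinely the same genotype
configuration, distinguished only by interpretation (mutation event vs.
non-penetrant transmission is unobservable within one family). The
report stage therefore cross-references candidates admitted by more than
one model rather than forcing them into one table.

## Twin concordance and the panel screen

Concordance counts variant *presence* (at least one alternate allele) per
twin: shared, unique-to-affected, unique-to-unaffected, and the shared
percentage of their union. For a true MZ pair virtually all germline
variants are shared; the unique margins are dominated by artifacts and —
rarely — postzygotic events.

The panel screen collects all variants in a curated gene list (categories:
Klippel-Feil syndrome, congenital scoliosis, other congenital spinal
deformities) and asks, per gene, whether the twins' genotype classes are
identical at every site. It is applied to quality-passing variants by
default rather than fully filtered ones: a twin-discordant genotype in an
established disease gene is worth seeing even when the variant is common
or synonymous. Gene matching is case-insensitive and splits ANNOVAR's
semicolon-joined symbols at gene boundaries.

The bundled panel file is a *synthetic fixture*: it has the real category
sizes (19/24/83, 126 unique genes) and contains fifteen well-known CSD
genes, but the remaining symbols are placeholders. Replace it with a
curated list for real analyses.

## Read-evidence review

Manual IGV review is narrative ("low coverage", "strand bias"); this
package re-expresses it as flags on a pileup summary (per sample and
site: depth, alternate reads by strand, reference reads by strand):

| flag | default rule |
|---|---|
| `low_depth` | depth < 20 |
| `low_alt_support` | carrier with < 3 alt reads or allele fraction < 0.20 |
| `strand_bias` | ≥ 3 alt reads all on one strand, or two-sided Fisher exact p < 0.05 on the strand table |
| `aaf_genotype_conflict` | het outside [0.25, 0.75]; hom-alt < 0.90; hom-ref > 0.05 |

Per-sample verdict: a called carrier with weak support or strand bias is
`likely_artifact`; depth or allele-fraction conflicts alone give
`uncertain`; no-calls are always `uncertain`; otherwise `supported`. The
cohort verdict is the worst among carriers. None of the numeric
thresholds comes from a published rule — they are package defaults chosen
so that the three canonical failure modes (a ~9% allele-fraction
strand-skewed het, a homozygous call on a single supporting read, a
borderline candidate at low depth) resolve to artifact, artifact and
uncertain respectively — and all are configurable. Only that qualitative
behavior is contractual; the exact numbers are not.

## The simulator

`simulate_cohort()` generates the full input bundle (annotated VCF,
pileup summary, QC metrics, PED, truth table) so every stage is testable
without external data. What it emulates:

* background sites are unlinked and biallelic; allele frequencies follow
  a Beta(0.5, 5) truncated to [1e-4, 0.5] — a rare-skewed site frequency
  spectrum typical of exome cohorts; founders are binomial draws and
  offspring receive one allele per parent (Mendelian transmission);
* the twins are genotype-identical at every background site, as MZ twins
  are in truth;
* planted candidates get their model's admitting genotype pattern
  *deterministically* (not sampled), so the truth table is exact and
  recovery tests can demand 100%;
* annotation scores at planted sites are drawn to hit a per-variant tier
  target (`strict_pass`, `liberal_only`, `fail`), closing the loop
  against the filtering module;
* artifacts are realized in the pileup (and, for `no_call_others`, in
  the VCF genotypes): low depth, one-strand alternate support, a het
  call whose pileup shows a ~9% allele fraction, and a homozygous call
  with no-calls elsewhere and a single supporting read.

Clean pileup evidence is strand-balanced *by construction* (alternate and
reference reads split evenly), not binomially: with a 5% Fisher
threshold, binomial strand splits would flag ~5% of clean carriers by
chance, which would make truth-table verdicts probabilistic. In this
simulator "clean" means unambiguously clean, and injected artifacts are
the only source of imbalance. Real data do not behave this way — the
false-positive rate of any strand-bias rule on real pileups is a
property the simulator intentionally does not model.

Default planted counts (5 de novo, 4 recessive, 6 dominant, 9
twin-concordant homozygous) mirror the strict-tier candidate yield of
the motivating family study. A single seed drives everything, split into
per-component streams (site scaffold, background genotypes, planted
sites, artifacts, pileup, QC) so that enlarging one component does not
reshuffle the others; identical configurations give byte-identical
output files.

What the simulator does *not* emulate: linkage and recombination,
sequencing error models, mosaic (fractional) genotypes, indel alleles'
length distribution, and multi-sample depth correlation. Passing tests
on simulated cohorts therefore demonstrate the correctness of the
screening logic, not the performance of the pipeline on real exomes —
absolute funnel counts on real data are expressly not a contract.

## Numerical conventions and degenerate inputs

* Reported percentages round half-up (87.65 prints as 87.7); cohort mean
  coverage to 3 decimals, percentage metrics to 2. R's default banker's
  rounding would print some published-style tables off by a final digit.
* Multiallelic records decompose to one row per alternate allele; in a
  decomposed row, alleles of *other* alternates become missing rather
  than reference. A `1/2` genotype thus yields `1/.` on each branch —
  a half-call, classified `no_call` — preventing phantom homozygous-
  reference calls from masked alleles. This conservative mapping means a
  multiallelic carrier never silently supports a model as "reference".
* Zero-depth evidence yields an absent allele fraction (never 0/0 = NaN);
  an empty cohort produces a structurally valid all-zero report; an
  empty panel is a no-op screen; a zero-total class breakdown is an
  error rather than a vector of NaNs.
* Candidate tables are ordered by natural chromosome order, then
  position, then alternate allele, so diffs between runs are meaningful.

## Problem sizes used by the test suite

The property suites run at sizes chosen to exercise the statistics while
keeping the suite quick on one CPU: 10,000 randomized score vectors for
tier nesting and funnel monotonicity; ten simulated cohorts (seeds 1-10,
1,000 background sites each) for screen recovery and cross-admission;
Mendelian consistency at the same scale; and exhaustive Fisher-vs-
enumeration comparison over all 2x2 tables with total count ≤ 30
(46,376 tables). Background-frequency recovery uses 4,000 sites, where
the binomial error of the founder dosage mean is ~2%.

## Known limitations

* X-linked and compound-heterozygous models are out of scope; the model
  set matches the family designs this analysis serves.
* The pipeline trusts its annotations: it never recomputes CADD/REVEL or
  population frequencies, so annotation-dialect mismatches silently
  become absent values (by design, absent never passes a filter — the
  failure mode is a too-empty funnel, which is visible).
* Zygosity is taken as given; the package does not verify that the twin
  pair is monozygotic.
* The evidence review consumes a pileup summary, not BAM files; the
  summary must be produced upstream (e.g. with `samtools mpileup`-based
  tooling) at the candidate positions.
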