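---
title: "The bestvar pipeline: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bestvar pipeline: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bestvar)
```

## The scientific problem

Mutations in *BEST1* cause a family of retinal diseases — Best vitelliform
macular dystrophy (BVMD), autosomal-recessive bestrophinopathy, adult-onset
vitelliform macular dystrophy (AVMD), ADVIRC, and some retinitis pigmentosa —
collectively the bestrophinopathies. The gene encodes bestrophin-1, a
585-residue calcium-activated chloride channel of the retinal pigment
epithelium with four transmembrane segments, two short extracellular loops,
and large intracellular regions whose C-terminus carries the Ca²⁺ machinery
(an acidic stretch at residues 293–308 and an EF-hand at 312–323).

Three questions about this gene recur and are what `bestvar` operationalises:

1. **Where do pathogenic mutations sit on the protein, and how does location
   relate to inheritance and phenotype?** Missense mutations cluster in a few
   regions; in some of those, almost every missense change behaves
   dominantly, while null-type alleles (nonsense, splicing, frameshift) are
   recessive essentially everywhere.
2. **How does mutation density relate to evolutionary conservation?**
   Regional conservation across an ortholog panel — measured by per-site
   identity and 30-residue sliding-window identity — tracks the
   dominant-missense hotspots.
3. **How common is the disease?** A national case collection gives prevalence
   *bounds*: the clinically diagnosed count bounds prevalence from above, the
   genetically confirmed subset from below.

The package is a reusable, tested implementation of that whole analysis:
catalogue curation under explicit filtering rules, region statistics on a
topology model, conservation profiles, and prevalence arithmetic — plus a
synthetic-data generator so that every stage can be validated against known
ground truth without any external database access.

## Variant representation and parsing

Catalogue rows are keyed by their HGVS coding-DNA description
(`c.967G>A`-style, coordinates 1-based on the coding sequence with the A of
the initiator ATG as position 1, ranges inclusive), optionally paired with a
protein description (`p.Asp323Asn`). Only the syntax subset that actually
occurs in bestrophinopathy catalogues is supported — substitution, deletion,
duplication, insertion, deletion–insertion, frameshift, nonsense, intron
offsets — and anything else is a *hard parse error*. Silently skipping
unparseable rows would bias every downstream count, so the parser fails
loudly and names the offending token.

Mutation-type classification applies rules in a fixed order: an intron
offset (or, when an exon table is supplied, an exonic change within 2 nt of
a boundary) means splicing; otherwise the protein-level consequence wins;
indels without a frameshift annotation are in-frame exactly when their net
length is divisible by three. A substitution with no protein annotation and
no applicable rule is classified `unknown` with a warning — never guessed.
One deliberate exception: a catalogue row *labelled* missense that the
splice rule would reclassify keeps its catalogue label and gains a
`splice_predicted` flag. Several known missense-annotated alleles are
predicted to affect splicing; preserving the label preserves the standard
counting while still exposing the prediction.

Residue positions derive from codon arithmetic, `ceiling(position / 3)`;
intronic changes have no residue and are therefore excluded from per-region
densities (they stay in catalogue-level tallies). A configuration switch can
instead place them at the codon of the nearest coding position.

## Curation rules

`apply_filters()` implements three exclusion rules, tested in a fixed order
so that each excluded record is attributed to exactly one rule, which makes
curation reports auditable:

| rule | criterion | default |
|------|-----------|---------|
| (a) high allele frequency | any per-database AF strictly `> max_af_any_db` | 0.005 |
| (b) unsupported single patient | one patient, no segregation **and** no clinical characterisation | on |
| (c) silent | synonymous change | on |

All AF comparisons are strict inequalities: a record at exactly 0.005 is
retained. The novelty gate for newly observed variants is likewise strict
("less than"): below 0.5% for recessive variants, below 0.05% for dominant
ones; a variant absent from every database counts as frequency 0 and passes.
The single-patient rule is stated ambiguously ("without segregation analysis
and/or without well-established clinical characteristics") in common
practice; we default to the conservative conjunctive reading — both kinds of
support missing — and expose the disjunctive reading as
`single_patient_rule = "disjunction"`.

Variants reported in both dominant and recessive families are modelled as
*one* record with `inheritance = "both"`. In two-way dominant/recessive
fractions these records are excluded from the denominator and reported
separately, since folding them into either side would double-count evidence.

Tallies count *distinct mutations* (keyed on the normalised cDNA string) and
*alleles* (summed `allele_count`). Records sharing a key are merged only if
their annotations agree; a conflict is an error naming the variant.

## Topology model and region statistics

The default topology hard-codes the nine-region bestrophin-1 model — IC1
(1–30), TM1 (31–50), EC1 (51–70), TM2 (71–94), IC2 (95–234), TM3 (235–257),
EC2 (258–268), TM4 (269–287), IC3 (288–585) — with the C-terminal
subregions of interest (Ca-binding 293–308, EF-hand 312–323, proximal IC3
288–323). Topology is *input*, not computed: it is overridable via a small
JSON schema, because topology predictions come from external platforms that
this package deliberately does not re-run. A `topology_model` validates hard
invariants: regions sorted, non-overlapping, jointly covering
`1..protein_length` with no gaps.

Per region, `region_statistics()` reports distinct-mutation counts, the
missense prevalence (missense mutations divided by region length — this can
exceed 1 in dense regions), the two-way inheritance split among missense
mutations, and disease composition. Fractions are computed over distinct
mutations by default because region plots mark mutations, not alleles;
`weight = "alleles"` switches to allele weighting. An in-frame deletion
spanning a region boundary is assigned to the region of its start residue.
`hotspot_report()` flags regions exceeding a density threshold and an
inheritance-skew threshold in either direction (strict comparisons; the
skew threshold must be a fraction in `[0, 1]`, the density threshold is
unbounded).

## Conservation

Orthologs can be supplied as a precomputed MSA (aligned FASTA or Clustal) —
the preferred route when an external multiple aligner has been run — or as
unaligned FASTA, in which case each ortholog is globally aligned to the
human sequence by Needleman–Wunsch with BLOSUM62 and affine gaps (open 10,
extend 0.5). Pairwise alignment is delegated to `Biostrings`; the
conservation statistics themselves are implemented here and tested against
brute-force recounts.

Two statistics are computed over *human* positions (ortholog-only columns
never shift the human coordinate system):

* **Per-site conservation**: the fraction of orthologs whose aligned residue
  is identical to the human residue. The denominator is the number of
  orthologs, not per-site coverage, and an aligned gap is a non-match —
  a site deleted in half the panel *is* half as conserved.
* **Sliding-window identity**: for each window of 30 consecutive human
  residues (step 1), `100 × matches / 30`, assigned to the window's first
  position. Gap columns count as mismatches and do not shrink the
  denominator; this is the simplest rule consistent with the low (~35%)
  identities seen for the most remote orthologs.

Each ortholog's "average identity" is by default the mean of its window
track; a whole-sequence alternative sits behind
`mean_method = "overall"`, since the windowed figure is the one regional
plots are built from but the overall one is what a single summary number
usually means. Similarly, a regional average such as "mean conservation of
residues 288–323" has two candidate definitions — the mean of per-site
fractions (default, matching per-residue preservation plots) and the mean
of windowed values across orthologs — and both are computable via
`region_mean_conservation(method =)`; on gap-free panels they differ only
through window-edge effects.

## Prevalence bounds

`prevalence_bounds()` encodes the bounding logic: upper bound = population /
clinically diagnosed cases, lower bound = population / genetically confirmed
cases. Formatting conventions matter here because published figures mix
them; we therefore always carry raw values alongside formatted ones:

* 1-in-N denominators are rounded to the nearest 1,000 by default
  (9,656,000 / 134 = 72,059.7 → "1 in 72,000"; / 76 = 127,052.6 → "1 in
  127,000"); granularity is a parameter because finer-grained figures
  (e.g. "1 in 83,600") appear in stratified tables.
* Per-100,000 rates are *truncated*, not rounded, to two decimals
  (76 / 9,656,000 × 10⁵ = 0.787 → 0.78), matching the printed range
  0.78–1.38; also configurable.
* The percentage helpers `pct_round()` / `pct_trunc()` expose both printed
  conventions; full-precision values are always returned.

`stratified_prevalence()` adds a pooled row (summing strata unless an
explicit `all` row is given) and refuses duplicate stratum names. Exact
Poisson 95% intervals on the case counts are available behind
`poisson_ci = TRUE`; they are an extra — the bounding argument itself is
deterministic. `cohort_fractions()` implements the allele accounting used
for cohort composition: one pathogenic allele per dominant (heterozygous)
patient, two per recessive (biallelic) patient; with 58 dominant and 18
recessive patients that yields 94 alleles, of which 36 (38.3%) are
recessive, and 84 missense alleles are 89.4% (printed as 89.3% under
truncation).

## The synthetic-data generator

The generator exists so that every pipeline stage has a test oracle: it
records exactly what it planted. Its defaults are fixed to emulate the
published BEST1 landscape and are not tuned per analysis:

* **Catalogue** (`simulate_catalogue()`): per-region missense rates
  concentrated in IC1/TM2/IC2 and the proximal part of IC3 (around 0.7–1.2
  expected mutations per residue there, 0.25 in the tolerant extracellular
  loops, giving ≈350 missense mutations in expectation); dominant fractions
  above 0.9 in IC1/TM2/IC3 versus ≈0.2 in TM1/TM4; fixed counts of 17
  nonsense, 16 splicing, 27 frameshift and 16 in-frame mutations scattered
  uniformly; in-frame deletions starting in residues 295–304 labelled
  dominant; null-type classes labelled recessive; a 3% dual-inheritance
  rate; allele counts 1 + Poisson(3); plus decoy records built to trip each
  curation rule, flagged in the ground truth. cDNA/protein pairs are
  arithmetically consistent by construction, and generated catalogues are
  byte-reproducible for a fixed seed.
* **Orthologs** (`simulate_orthologs()`): a random 585-residue reference and
  12 orthologs on a divergence ladder from 0 (an identical, chimp-like
  ortholog) to a remote fly-like one (~35–40% mean identity), with
  extracellular loops substituting at several times the transmembrane /
  intracellular rate (class probabilities EC 0.45, IC 0.12, TM 0.08 at
  scale 1, capped at 1 after scaling). Substituted residues are uniform over
  the 19 alternatives — no substitution-matrix realism is attempted because
  every conservation statistic here counts identity only. Indels are
  single-column ortholog gaps, sufficient to exercise gap handling.
* **Cohorts** (`simulate_cohort()`): Poisson case counts at a specified true
  prevalence and binomial genetic confirmation, per stratum.

What the generator does **not** emulate: phylogenetic correlation between
orthologs (no tree), realistic codon usage or mutational spectra,
ascertainment bias in catalogue assembly, or allele-frequency correlation
between databases. Passing parameter-recovery tests therefore demonstrates
that the *statistics* are computed correctly at realistic sizes and noise
levels — not that real catalogues are free of those biases.

## Numerical and testing choices

Deterministic behaviour is a design goal throughout: fixed rule order in
curation attribution, stable record order in retained sets, seeds recorded
in generator ground truth, and a `--deterministic` flag in the command-line
runner that suppresses timestamps so reruns are byte-identical.

Statistical test design (all chosen a priori): parameter-recovery checks on
conservation use a panel of 12 orthologs at full protein length (L = 585),
where the binomial standard error of a regional mean is small enough for a
3-SE band; per-region dominant-fraction recovery uses a catalogue of ≈500
missense mutations and exact binomial confidence intervals at a
Bonferroni-corrected level (family-wise 5% across the nine regions).
Property tests (window recounts, filter monotonicity and idempotence,
round-trip parsing, topology partition) run on a few hundred generated
cases under fixed seeds; the full suite completes in well under a minute.

## Limitations

* The pipeline consumes catalogues; it does not scrape LOVD/HGMD/PubMed,
  query live population databases, or lift variants between transcript
  reference versions — inputs must already be on a single reference.
* Topology is configuration, not prediction.
* Conservation is identity-based and unweighted; no phylogeny-aware score.
* The built-in pairwise aligner is a convenience for unaligned input; for
  publication-grade conservation figures, supply an MSA from a dedicated
  multiple-alignment tool.
* Prevalence bounds are exactly that — bounds from counts — with no
  capture–recapture correction or age standardisation.
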