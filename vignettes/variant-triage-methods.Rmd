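---
title: "Methods: population-based triage of reported disease-variant associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-based triage of reported disease-variant associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvncTriage)
```

## The problem

Left ventricular non-compaction (LVNC) is a rare cardiomyopathy with a
spongy, hypertrabeculated inner myocardial layer. Over two decades the
literature has accumulated dozens of protein-level variants reported as
LVNC-associated, typically on the strength of a single family or proband.
Large background-population exome collections (an ESP-like cohort of 6503
exomes split into African-American and European-American subpopulations,
and an ExAC-like cohort of 60,706 exomes) make a simple sanity check
possible: a variant that is supposed to cause a rare, dominant
cardiomyopathy should not be common in ostensibly healthy populations.

`lvncTriage` implements that re-evaluation as a reusable pipeline:

1. **Catalog** — a validated, protein-level catalog of reported variants
   (HGVS p. shorthand, one-letter residues), with per-row diagnostics on
   load and a lossless TSV round-trip.
2. **Population** — presence and pooled allele-frequency lookup in
   allele-count stores, plus a carrier-count plausibility rule.
3. **Predictors** — four in-silico channels: cross-species conservation,
   Grantham physicochemical distance, and adapters normalizing externally
   produced SIFT and PolyPhen-2 labels.
4. **Consensus** — the ≥3-agreement voting rule producing
   pathogenic / VUS / benign / not-analyzed / unclassifiable calls.
5. **Segregation** — the operational co-segregation rule on pedigrees.
6. **Summary** — deterministic aggregate reporting.
7. **Synthetic data** — seed-deterministic generators for cohorts,
   alignment columns, pedigrees and a marginally matched study fixture.

## The unit of analysis

Variants are keyed on (gene symbol, HGVS p. string); the catalog carries no
genomic coordinates, transcripts or isoforms, because the curated source
operates purely at protein level. A cis compound allele (the one MYH7
double mutation, p.D545N;p.D955N) is stored as a single record with two
protein changes, and every per-variant tally counts each constituent change
once — hence 60 variants across 59 records. Record-level annotations
(inheritance, tool labels, presence flags) apply to each constituent
change.

## Population presence and the carrier rule

A variant is *present* in a cohort when the store holds its key with total
allele count AC ≥ 1; the dichotomy carries no frequency floor. The pooled
allele frequency is `sum(AC) / sum(AN)` at full double precision; reports
round to 4 significant figures for display only. Carrier counts are
genotype-aware when the store records them and otherwise fall back to the
allele count, which is an upper bound on carriers; each presence row
records which convention was used, because the plausibility rule speaks of
*persons*: presence in **more than five** carriers flags a variant as
unlikely to be pathogenic (strictly more than; the threshold is a
parameter, default 5). For X-linked genes (TAZ) hemizygous males contribute
one allele each, so AN < 2N; the frequency definition is unchanged.

## The Grantham engine

The physicochemical distance between residues $a$ and $b$ is

$$D(a,b) = \rho\left[\alpha\,(c_a-c_b)^2 + \beta\,(p_a-p_b)^2 +
\gamma\,(v_a-v_b)^2\right]^{1/2}$$

with side-chain composition $c$, polarity $p$ and molecular volume $v$ per
residue, weights $\alpha = 1.833$, $\beta = 0.1018$, $\gamma = 0.000399$,
and $\rho = 50.723$ scaling the mean of the 190 inter-residue distances to
100. The property table and constants ship as checksummed package assets,
and the test suite recomputes all 190 pairs against an independent
transcription of the formula. Two numerical points are worth stating:

* **Tie at the cutoff.** The calling rule is "above 100 radical
  (pathogenic), under 100 conservative (benign)", which leaves a score of
  exactly 100 undefined; the package resolves the tie conservatively
  (benign — a pathogenic call requires strict excess) and exposes the
  cutoff as a parameter.
* **Printed-matrix rounding.** A handful of entries in the widely
  reproduced integer matrix differ by one unit from direct evaluation of
  the formula (e.g. S–R evaluates to 109.47 but is usually printed 110).
  The package is defined by the formula; frozen test values use only
  entries where formula and printed matrix agree (L–I = 5, R–C = 180,
  D–E = 45, F–Y = 22).

Stop gains have no defined distance and bypass all four channels.

## Conservation, SIFT and PolyPhen-2 channels

A position is conserved (pathogenic vote) only with **zero** substitutions
among the usable (non-gap) residues of the species panel; a single
substitution votes benign; fewer than two usable residues give no call.
The species panel is a free parameter: the curated source took conservation
labels from a database without stating the panel, so the package accepts
either a precomputed conserved yes/no label (which wins, with a notice) or
an alignment column to compute the call from. SIFT and PolyPhen-2 are
*not* re-implemented; their categorical labels are normalized
case-insensitively ("damaging" → pathogenic; "tolerated"/"tolerant" →
benign; "probably damaging"/"possibly damaging" → pathogenic; "benign" →
benign; anything else → unavailable with a warning). Numeric SIFT scores
are out of scope because the curated catalog carries only categories.

## The consensus rule

Among available tools: ≥3 pathogenic votes → **pathogenic**; 1–2 →
**VUS**; 0 → **benign**. Two guard rails:

* Benign requires a complete four-tool panel; zero pathogenic votes on a
  partial panel yield VUS with an `incomplete_tool_panel` flag. The
  curated source never calls a variant benign on partial evidence, and the
  flag keeps the distinction auditable.
* **not_analyzed** is reserved for stop gains and **unclassifiable** for
  variants whose residue could not be mapped onto the protein's isoforms.
  The latter is an explicit catalog annotation, never auto-detected: the
  package has no transcript model, and pretending to detect isoform
  mismatches would overstate what it knows.

The threshold and the benign rule are configurable via `consensusPolicy()`.
The classifier is tested exhaustively against a brute-force oracle over all
$3^4 = 81$ vote patterns, plus monotonicity and permutation-invariance
properties.

## Integer percentages

All reported percentages use **truncation toward zero** of
`100 * count / denominator`, in exact integer arithmetic, with the
analyzed-variant count (56 = 60 − 4 stop gains) as the default denominator
for class fractions. This is the unique convention under which the source's
printed class percentages are mutually consistent: 51/41/5 at denominator
56 has exactly one integer solution, (29, 23, 3), under truncation and none
under half-up rounding, and 10/18 printing as 55% (= 55.6) requires
truncation too — the test suite encodes that solver. One printed fraction
(17/24 as a percent of MYH7 variants) was evidently rounded half-up (71)
in its source; under the package's uniform convention it reports as 70,
with the counts 17 of 24 identical. The discrepancy is one unit on one
stratum and is documented rather than special-cased.

## Co-segregation and heredity

Co-segregation follows the operational curation rule: **yes** iff at least
two genotype-positive family members share the same phenotype label;
**no** when genotype data exist but the criterion fails; **not_assessed**
with fewer than two known genotypes. Decisions made explicit and
configurable:

* *Same phenotype* defaults to strict label equality (LVNC = LVNC); an
  `equivalence = TRUE` option treats the supplied phenotype set as one
  disease spectrum, because several source families mix LVNC with DCM or
  HCM.
* The proband counts toward the two genotype-positive members
  (`count_proband = FALSE` to exclude).
* A family is *familial* when ≥2 members are affected regardless of
  genotype; inheritance patterns are catalog annotations from the source
  literature, never inferred from pedigrees. The only computed pedigree
  check beyond co-segregation is X-linked consistency (no male-to-male
  transmission of carrier status), which is informational. Because the
  pedigree dialect's `relation` column is free text, the package adds
  optional `father_id`/`mother_id` columns for that check; without them it
  is vacuously true.
* The source counts 42 familial forms in one place and a 39-of-41
  denominator in another; the package computes 42 and leaves the
  discrepancy in the source undisturbed.

## What the generators emulate — and what they do not

`simulateCohort()` draws per-individual genotypes binomially at given true
allele frequencies (two draws per autosomal individual, one per hemizygous
male), and records AC, AN and carrier counts exactly consistent with the
drawn genotypes, so every store invariant holds by construction. It makes
no attempt at linkage, realistic site-frequency spectra, sub-population
structure beyond fixed sizes, or call-rate variation: it is the right null
model for testing a presence/frequency pipeline, not a population-genetics
simulator. `simulateAlignmentColumn()` substitutes each non-reference
species independently (probability $p$, uniform over the 19 alternatives),
giving the closed-form conserved fraction $(1-p)^{n-1}$ used in the
property tests. `simulatePedigree()` builds nuclear families with
Mendelian transmission, an ascertained affected proband, penetrance applied
to every other carrier, and an optional phenocopy rate (default 0).

`makeStudyFixture()` assembles a complete input set — catalog with tool
labels, both population stores, one pedigree per familial record — whose
marginal structure matches the curated study: 60 variants in 12 genes (24
in MYH7), 4 stop gains, 9/18/8 presence counts, class counts (29, 23, 3, 1),
stratified pathogenic counts 4/9, 10/18 and 17/24, and 42 familial records
with 30 co-segregating. Twenty-six variants named in the source's main text
are placed with their stated attributes; everything else is a flagged
synthetic placeholder. Three reconstructions deserve emphasis because the
source does not fully determine them: the 12th gene (ACTC1, named in the
source's introduction but not its results), the fourth stop gain (only
three are named), and the variant-level identity of the ESP-positive set
beyond the five variants the text resolves — all are synthetic choices
flagged as such. The worked-example allele frequency (a singleton at
AN = 121412, i.e. 8.236 × 10⁻⁶) is an arithmetic reconstruction used as an
example, not ground truth about the real database.

**Circularity caveat.** The fixture's marginals are inputs to the
generator, so end-to-end tests that recover them do not validate the
numbers themselves; what they validate is that the pipeline's independent
re-derivation — parsing, store lookup, Grantham computation from residues,
label normalization, voting, truncated percentages, pedigree assessment —
reproduces the marginals from raw inputs. If a transcription of the
original supplementary table is available in the catalog TSV dialect,
`readCatalog()` ingests it directly and the same pipeline runs against real
data instead.

## Problem sizes and numerical choices

The test suite runs the full fixture pipeline (60 variants), the exhaustive
81-pattern consensus oracle, all 190 Grantham pairs, a 100-seed allele
frequency recovery at AN = 4000, a 10,000-column conservation-fraction
check at $p = 0.1$ with 10 species, and a 300-pedigree penetrance recovery
at 0.7 — sizes chosen so each Monte-Carlo check has standard errors well
below its tolerance (3 standard errors throughout) while the whole suite
stays in the tens of seconds. Generators save and restore the caller's RNG
state, so they are pure functions of their seed and leave the session's
stream untouched. Report JSON uses fixed key order and fixed numeric
formatting: identical inputs give byte-identical output.

## Known limitations

* Protein-level keying cannot distinguish transcript isoforms; a mismatch
  must be annotated, not detected.
* Presence lookup depends on exact (gene, HGVS p.) string agreement after
  normalization; no DNA-level left-alignment or liftover exists.
* The carrier rule's allele-count fallback over-counts carriers when
  homozygotes exist; the per-row convention field makes this visible.
* Co-segregation is the two-member curation rule, not a likelihood (LOD)
  analysis; it cannot weigh pedigree size or structure.
* The consensus rule weights four heterogeneous tools equally and is not a
  calibrated classifier; it reproduces an established triage convention,
  with its thresholds exposed as policy parameters.
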