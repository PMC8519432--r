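---
title: "Trio exome prioritization: models, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio exome prioritization: models, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TrioExome)
```

# The diagnostic problem

Trio whole-exome sequencing of an affected child and both unaffected
parents turns variant interpretation into an inheritance problem: a
severe sporadic neurodevelopmental phenotype is most often explained by a
de novo coding variant, occasionally by an X-linked variant inherited
from a carrier mother, or by biallelic (recessive) variants. TrioExome
implements that screening logic as a reproducible pipeline: genotype-level
quality gating, inheritance-model filtering, coding-consequence
annotation, a reduced ACMG/AMP classification, and cohort reporting.

# Inheritance models and their thresholds

All thresholds live in one object with documented defaults:

```{r}
filterThresholds()
```

* **Quality gate** (`trioQualityPass`): GQ ≥ 20 (Phred) in proband,
  mother and father; DP ≥ 5 in each parent and ≥ 10 in the proband;
  missing genotypes or fields fail, they never pass by default. The
  parent/proband depth asymmetry reflects the asymmetric cost of the two
  error directions: an undercovered parent mimics a de novo call, while
  an undercovered proband merely loses sensitivity.
* **De novo** (`callDeNovo`): proband 0/1, parents 0/0, and proband
  alternate allele fraction strictly greater than 0.10. The strict
  inequality is deliberate (a site at exactly 10% fails); `AD = (18, 2)`
  is the boundary case. A missing allele fraction (AD absent or 0,0)
  fails: absence of read evidence must not pass a read filter.
* **X-linked** (`callXLinked`): male proband hemizygous (`"1"` or the
  `"1/1"` dialect), mother heterozygous, father hom-ref; population AF
  strictly below 0.001; protein-impactful consequence. Female probands
  are not handled by this model — a dominant de novo X variant in a girl
  is caught by the de novo model. Pseudoautosomal regions are not
  modelled; all of chrX is treated as X-linked.
* **Autosomal recessive** (`callAutosomalRecessive`): population AF
  strictly below 0.02 and impactful consequence for every involved site;
  either proband 1/1 with both parents 0/1, or a compound heterozygote
  phased purely by transmission (one site exclusively paternal, one
  exclusively maternal, same gene). Two proband-het sites carried by the
  same parent are in cis and rejected. No read-backed phasing is
  attempted: trio transmission is sufficient and far more robust at
  exome coverage. Parental allele-fraction caps (parental mosaicism) are
  not applied.

`prioritizeTrio` runs the models in the fixed order de novo → X-linked →
autosomal recessive, assigns each site to the first matching model, and
orders candidates within a model by consequence severity
(nonsense/frameshift/splice > deleterious missense > in-frame) and then
ascending population AF.

"Protein-impactful" is operationalized as {nonsense, frameshift,
splice_site, in_frame} plus missense with a deleterious predictor
consensus. The consensus is a majority rule over available categorical
calls (damaging classes: Probably/Possibly Damaging, Deleterious, Medium,
High); an empty call set is *not applicable*, which blocks a missense
from the impactful set but never crashes the pipeline.

# Consequence annotation

Annotation works entirely against user-supplied transcript models (GFF3
CDS features plus CDS FASTA) — there is no genome download. CDS position
`n` falls in codon `ceiling(n/3)` (HGVS residue numbering). SNVs are
classified by translating the affected codon before and after the change
with the standard genetic code; indels by frame arithmetic, with protein
naming derived from a prefix/suffix alignment of the reference and mutant
proteins (this yields correct HGVS-style 3'-adjusted names such as
`p.Val43del` for a deletion spanning a codon boundary, and duplication
detection for `p.Leu2198_Gln2199dup`). Frameshift names report the first
changed residue and the downstream stop offset (`fs*15`) only when the
transcript provides enough downstream sequence; otherwise the offset is
omitted, because it depends on sequence the caller did not supply.

Splice-site evaluation is a binary canonical-site rule: intronic
positions within ±2 nt of an exon/intron boundary are `splice_site`,
other intronic positions `intronic`. No splice-strength score is
computed; scoring models are a different tool class, and the canonical
dinucleotide rule is what the inheritance filters need.

Minus-strand transcripts are handled by reverse-complementing genomic
alleles before CDS mapping; the packaged KCNQ3 model is minus-strand and
unit-tested. Population AF lookup is exact on the normalized
`(chrom, pos, ref, alt)` key — hence the normalization module: alleles
are parsimony-trimmed and (when local context is available) left-aligned
with the standard shift algorithm, which is idempotent and
enumeration-verified in the tests. A key absent from the table means AF
0 ("novel"), matching how absence from a population database is read in
practice.

## Packaged synthetic transcripts

Real transcript sequences are not bundled. `exampleTranscripts()` builds
eleven deterministic synthetic models whose *named* codons are pinned so
the packaged candidate table reproduces its printed protein changes
(e.g. codon 621 of the SYNGAP1 model is CGA, so c.1861C>T yields
p.Arg621*; the SATB2 model's downstream sequence is constructed by a
seeded rejection search so c.1826delA yields exactly p.Asp609Alafs*15).
Everything else is pseudo-random non-stop filler. The same models ship
as GFF3+FASTA under `inst/extdata/` with a `synthetic_` prefix; the
builder function is the source of truth and a round-trip test keeps the
files honest.

# Reduced ACMG/AMP classification

Only the codes derivable from this pipeline's inputs are implemented:
PVS1, PS1, PS2, PM2, PM4, PP3. The combining rules are the published
ones restricted to that subset; the combination is provably monotone
(adding evidence never downgrades), which the tests check exhaustively
over all 64 subsets.

Two interpretation choices are the package's own:

* **PS1 is not applied to splice-site variants.** The p. description of
  a canonical splice change is a prediction of transcript effect, not an
  observed amino-acid substitution, so "same amino acid change as an
  established pathogenic variant" does not apply. This also matters for
  classification fidelity: the packaged splice-site case is Likely
  pathogenic, and granting it PS1 (plus PVS1) would wrongly promote it.
* **The per-gene LoF-intolerance flag encodes whether the null-variant
  argument (PVS1) applies to that gene's variant class.** The packaged
  SMARCE1 entry is flagged FALSE because its splice variant is predicted
  to produce an in-frame exon skip — not a null allele.

One packaged case is a documented divergence: the inherited X-linked
LAS1L missense (AF 0, damaging predictors) yields {PM2, PP3} → uncertain
significance, while its confirmed classification is Likely pathogenic.
The reduced code set simply has no segregation, functional or phenotype
evidence to draw on; the tests assert the divergence rather than
papering over it.

# The synthetic trio-exome simulator

`simulateCohort` generates the statistical structure the pipeline
assumes, not reads: per-site genotypes with VCF QC fields.

```{r}
simConfig(nTrios = 2)
```

**Calibration.** The defaults encode the study conditions the simulator
emulates: 21,170 exonic variants per individual on average — 9,570
missense, 351 loss-of-function, 237 non-frameshift (in-frame), 10,606
synonymous, the ~406 remainder unclassifiable — at 67× mean depth. The
background panel is sized class by class: sites are drawn with AF ~
Beta(0.8, 0.8) until the cumulative expected per-individual carrier mass
`sum(1 − (1 − p)²)` reaches each class mean, so the expected yield per
individual equals the configured averages *by construction*, and the
observed means land within sampling noise of the targets (checked at 21
individuals against two standard errors in the acceptance tests).

**What it emulates.** Hardy–Weinberg founder genotypes from per-site
AFs; Mendelian transmission (sons draw their single X allele from the
mother); Poisson(67) depth; Binomial(DP, ½) heterozygous allele depths;
GQ as the Phred-scaled likelihood ratio between best and second-best
genotype, capped at 99; optional genotyping error (a per-genotype
uniform miscall plus matching read-level noise) whose default is 0 — the
simulator stands in for a caller's *output*, and the clean default makes
the Mendelian-consistency and 100%-spike-recovery properties exact.
Spiked causal variants are placed on real map transcripts so annotation
genuinely recomputes their consequences, with genotypes arranged per
model and AF 0, and are recorded in a ground-truth table.

**What it does not emulate, and what passing tests therefore do not
show.** No read-level artifacts (mapping error, strand bias, indel
realignment), no linkage disequilibrium or population structure, no
mosaicism, no sex-dependent X background (chrX carries only spiked
variants, because the sex-pooled per-individual calibration targets
cannot resolve a sex-dependent count component), and a Beta AF law
rather than a realistic site-frequency spectrum — Beta(0.8, 0.8) is a
computational compromise that keeps the panel ~32,000 sites; a real
rare-shifted spectrum would need millions of sites to yield the same
per-individual counts. Perfect spike recovery on clean simulations
bounds pipeline logic errors, not performance on real sequencing
artifacts. The simulator's map transcripts are all plus-strand;
minus-strand correctness is covered by the packaged example transcripts
instead.

# Reporting

Diagnostic yield counts probands with at least one pathogenic / likely
pathogenic candidate and **truncates** (not rounds) the percentage to one
decimal — 11/14 = 78.57…% reports as 78.5 — matching the convention of
the cohort this package's fixtures transcribe. Phenotype summaries count
qualified cells (`"+ (Relative)"`) as present and exclude not-available
cells from the denominator, reporting them separately.

# Numerical and degenerate-input choices

* Strict inequalities throughout (`> 0.10`, `< 0.02`, `< 0.001`), per the
  filter definitions.
* Allele fraction with zero informative reads is undefined (`NA`), a
  value that fails read filters rather than erroring.
* Multiallelic split: genotype alleles equal to the split alt become 1,
  other alternates 0; a 1/2 parent therefore still shows as a carrier in
  its own alt's record, which is the conservative direction for de novo
  exclusion. Unphased genotypes are emitted in canonical sorted order.
* Left alignment stops with an error if it would run off the supplied
  context, rather than silently mis-anchoring.
* Chromosome dialects `chrX`/`X` are canonicalized everywhere.
* The empty evidence set classifies as uncertain significance; the empty
  cohort is an error (a yield needs a denominator).

# Problem sizes used by the test suite

Full-scale simulation (21,170 sites per individual) is used where
calibration itself is the claim: 7 trios / 21 individuals in the
acceptance checks and the acceptance script. Logic-level tests (spike
recovery, Mendelian consistency, the 14-trio end-to-end yield run) use a
scaled background of ~1,200 exonic variants per individual with the same
class proportions, defaults and thresholds — background size only sets
how much inert material the filters must ignore, and the scaled runs
keep the whole suite at a few minutes on one CPU.

# Known limitations

Beyond the simulator's scope above: no mosaic de novo detection, no
imprinting/UPD or CNV analysis, no benign-side ACMG codes (the engine
never outputs benign/likely benign), no full HGVS grammar (UTR and
complex intronic coordinates), and no splice-strength scoring. The
X-linked model requires the hemizygous-son/carrier-mother configuration;
X-linked dominant inheritance in females is intentionally left to the de
novo model.
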