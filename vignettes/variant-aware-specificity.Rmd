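---
title: "Variant-aware auditing of Cas9 guide specificity"
author: "crisprAudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant-aware auditing of Cas9 guide specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprAudit)
library(Biostrings)
library(GenomicRanges)
```

# The problem

S. pyogenes Cas9 cuts where a ~20-nt guide RNA protospacer matches genomic
DNA immediately 5' of an NGG PAM. Off-target risk is conventionally assessed
against a *reference* genome: every PAM-adjacent locus within a small
mismatch budget (here, at most three mismatches) is enumerated and assayed.
That picture misses the genome the edit actually happens in. A single
germline SNV inside a three-mismatch off-target site can "correct" one of
the mismatches, leaving an allele with only two mismatches — a configuration
at which Cas9 activity rises sharply — while the reference allele of the
same locus remains effectively uncuttable. Because such sites are invisible
to reference-based prediction, the practical question is *how often* personal
variation converts predicted-cold sites into warm ones, and how much
activity to expect there.

crisprAudit implements that audit end to end: genome-wide PAM-constrained
off-target enumeration, overlay of a personal SNV set onto the hit list,
conversion-event detection, cohort statistics (binned conversion fractions
and a zero-intercept regression against off-target counts), amplicon
deep-sequencing quantification of per-allele cutting, and the clone-level
filters used to attribute whole-genome-sequencing variants to nuclease
activity. A set of seeded simulators generates every input with ground
truth, so each stage is testable without external downloads.

# Conventions and containers

* Genomes are named `DNAStringSet`s over A/C/G/T/N; intervals are `GRanges`,
  hence **1-based inclusive** throughout — the same convention as VCF and as
  printed loci in the literature. We deliberately did not introduce a
  separate 0-based internal convention: using the field's standard container
  end to end removes the most common class of off-by-one defects, and the
  0-based half-open convention appears exactly where the format demands it
  (BED import/export).
* Mismatch positions are **PAM-anchored**: position 1 is the protospacer
  base adjacent to the PAM, position L (typically 20) the PAM-distal 5'
  end. This matches how mismatch positions are reported experimentally
  ("positions 11, 15 and 19 upstream of the PAM") and makes the
  PAM-proximal "seed" region easy to reason about. On the minus strand the
  protospacer is always reported 5'→3' on the guide-matching strand.
* Candidate windows containing N are discarded by every scanner: a base
  that cannot be matched confidently cannot support a mismatch count.

# Off-target scanning

`scanOfftargets()` returns all PAM-valid sites within a mismatch budget,
with two interchangeable engines that must agree exactly:

* **brute**: every PAM match (IUPAC-aware, both strands) defines a
  candidate window; windows are compared position-by-position.
* **seed** (default): the protospacer is split into `maxMismatch + 1`
  contiguous exact seeds. By pigeonhole, any site within the budget
  matches at least one seed exactly; seed hits are expanded to candidate
  windows and verified (PAM, N-freedom, full mismatch profile).

The engines differ in candidate generation only and share the verification
code path's *comparison*, so the equivalence test (exact hit-set equality
including mismatch positions, over seeded random genomes and guides, plus
an independent oracle built on `Biostrings::matchPattern(max.mismatch=)`
with an explicit PAM filter) is a genuine cross-check of the candidate
generation logic. The PAM is fixed to NGG by default; alternative PAMs
(NAG relaxation, etc.) are expressible through the `pam` argument of
`GuideRna()` but are not counted in any default analysis.

Two hits on opposite strands at the same locus are distinct records, and
overlapping windows are all evaluated. Hit order is deterministic
(chromosome, start, strand).

# SNV personalisation and conversion events

`overlaySnvs()` substitutes the alternative alleles of all SNVs falling in
a site's protospacer into a single variant haplotype (cis phase assumed —
the conservative superset; multi-SNV sites are flagged) and recomputes the
mismatch profile of both alleles from scratch. Strand handling is explicit:
SNV alleles are written into the plus-strand window and the window is
reverse-complemented once for minus-strand sites, a property verified by
re-scanning reverse-complemented genomes with swapped alleles.

A **conversion event** is a site with exactly three reference mismatches
whose variant allele reaches at most two (`threshold = 2`; the threshold is
"at most", not "exactly", since any further correction only increases
cutting likelihood). SNVs that create or destroy PAMs are collected
separately (`pamSnvs`) and excluded from the headline rate, which is
defined purely on protospacer mismatch counts. SNVs whose stated reference
base disagrees with the genome flag the site and remove it from the
analysis rather than guessing.

`genomeConversionRate()` reports the fraction of *targets* (not events)
with at least one conversion, with numerator and denominator — the
quantity that answers "how likely is my chosen guide to have acquired a
personal off-target?".

# Cohort statistics

The probability that a target acquires a converted off-target should grow
linearly with its number of three-mismatch off-targets N3 (each off-target
contributes a small, approximately independent conversion chance).
`binFractions()` bins targets by N3 (default width 5 over [0, 100]) and
`fitThroughOrigin()` fits

$$ f(x) = \beta x $$

by weighted least squares with bin target counts as weights, so the binned
fit equals the per-target through-origin fit exactly (the bin width and
weighting are our choices; published figures bin without stating either).
The slope is reported in percent per off-target site. R² is the
**uncentered** form $1 - SS_{res} / \sum w f^2$, the only well-defined
coefficient of determination when the intercept is pinned at zero; this is
the scale on which published slope/R² pairs for unbiased
(0.145%, R² ≈ 0.997) versus algorithm-selected (0.08%, R² ≈ 0.48) target
cohorts are interpretable. `predictRate()` extrapolates
$\beta \times \bar{N3}$, and `twoSampleZTest()` compares N3 distributions
between cohorts from summary statistics (a normal approximation —
appropriate at the million-site scale where it is used, where p underflows
to exactly 0 in double precision). `extrapolateClinicalRate()` multiplies a
conversion percentage by a relative-activity fraction to give the expected
mutation rate at converted sites relative to the intended target.

# Amplicon indel quantification

Cas9 activity at an assayed locus is the fraction of amplicon reads with
an insertion or deletion overlapping a ±10 bp window around the blunt cut
(between protospacer positions 3 and 4 upstream of the PAM). The window
width is our choice: wide enough to capture the NHEJ indel spectrum and
aligner placement ambiguity in repeats, narrow enough to exclude
amplicon-end artefacts; it is configurable. Substitutions never count, so
substitution-dominated sequencing error cannot inflate the estimate — a
property the tests assert directly.

Reads are aligned globally (read) against the amplicon (locally) with
affine gaps (match +2, mismatch −3, gap open −6, gap extend −1); reads
under 60% identity over the aligned span, or shorter than 30 bp, are
excluded from all denominators. Indel calls come from the alignment's
insertion/deletion ranges converted to amplicon coordinates. When the
amplicon defines a discriminating SNV, each read is assigned `ref`/`var`
from the base aligned over that position; reads whose SNV base is deleted
or uncovered are `undetermined`, never guessed. `siteEfficiency()` reports
the indel fraction with a Wilson 95% interval, the per-allele split
(read counts conserved by construction), and the on-target-normalised
relative efficiency. Fewer than 100 passing reads flags the report
low-coverage rather than silently returning a noisy estimate.

# Clone-level screening

Whole-genome sequencing of edited clones yields variant tables in which
genuine nuclease footprints are rare. Three filters implement the
attribution logic:

* `sampleSpecificVariants()` keeps only variants private to a single
  sample: double-strand-break repair is idiosyncratic, so identical
  variants in two clones are pre-existing or artefactual. The filter is
  keyed on (chrom, pos, ref, alt), is idempotent and order-independent,
  and partitions its input (retained + discarded).
* `filterRearrangements()` keeps structural calls with ≥ 4 discordant
  read pairs (inclusive threshold).
* `flankingHomologySearch()` slides the protospacer across ±100 bp around
  each retained indel (midpoint of the call — the published description
  does not fix the anchor; the midpoint treats asymmetric calls evenly),
  both strands, scoring ungapped identity. Hits with ≥ 16 of 20 matched
  bases pass, encoding "more than 15 bases, >75% identity"; both the
  flank and the threshold are exposed as arguments.

# The simulators, and what passing tests mean

`simulateGenome()` plants an on-target plus off-target families at exact
mismatch counts/positions on a random background (41% GC, human-like) and
then *verifies itself*: a brute-force scan must recover exactly the
planted set, or the construction is resampled. This
construction-then-verification design makes downstream oracle tests exact
instead of probabilistic. `plantSnvs()` places converting SNVs at
mismatching positions (restoring the guide base) and background SNVs
(density 10⁻³/bp, a human-like scale) outside all planted footprints.
`simulateAmpliconReads()` programs per-allele indel fractions exactly —
`round(f·n)` reads of each allele carry an indel (deletions 1–10 bp and
insertions 1–3 bp at 80/20, the short-deletion footprint of NHEJ), with
uniform substitution errors (0.2%) on top — so truth-based recovery checks
measure the pipeline, not the generator's sampling noise.
`simulateCloneTables()` builds the multi-sample sharing structure with
known unique counts. Everything is deterministic under a mandatory seed.

What the simulators do **not** emulate: repeats and segmental
duplications (which dominate real off-target lists), indel/structural
variants in the personal genome, PCR and quality-dependent error
structure in reads, bulged (gapped) guide-DNA pairings, and chromatin
effects on cutting. Passing tests therefore demonstrate correctness of
the computation under the stated model, not calibration against any
particular cell line.

# Numerical and degenerate-input choices

* Problem sizes in the test suite (100–200 kb genomes for scanner
  equivalence, cohorts of 2×10⁴–2×10⁵ targets for regression recovery,
  10⁴ reads per amplicon) were chosen so the whole suite runs in a few
  minutes while leaving estimator standard errors well below the
  tolerances being asserted.
* Through-origin fits require ≥ 2 non-empty bins and error when all bin
  centers are zero; bins are included when their interval overlaps the
  fit range.
* The Z test returns z = 0, p = 1 when both variances vanish with equal
  means, and ±Inf, p = 0 with unequal means.
* Homology windows truncate (with a message) at chromosome ends; loci
  outside the chromosome are errors.
* Empty read sets, empty SNV sets, and zero-copy planting specs all
  return well-formed empty results rather than failing.

# Limitations

The scanner models ungapped protospacer matches with a fixed PAM; bulges
and alternative PAMs are out of scope, as are activity scores (CFD/MIT)
— mismatch count is the only activity proxy, which the amplicon module is
designed to replace with measured fractions. Variant calling itself
(alignment, genotyping, copy-number segmentation) is consumed as input,
not performed. Conversion analysis is defined on biallelic single-base
substitutions; indel variants that lengthen or shorten a site are not
modelled. Zygosity is carried through reporting but does not gate
conversion detection — a heterozygous conversion is still a conversion,
with half the allelic dose.
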