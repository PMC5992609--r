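---
title: "Classifying chemoresistance-linked mutations in serially treated PDXs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying chemoresistance-linked mutations in serially treated PDXs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxresist)
```

## The problem

When a patient-derived xenograft (PDX) is passaged through repeated cycles of
one chemotherapy until relapses accelerate, the resulting "adapted" tumor is
operationally chemoresistant. Comparing exome-level allele counts between the
parental PDX, one or more treatment-adapted PDXs and the patient's germline
sample lets us ask which somatic mutations track that adaptation: mutations
that appear, vanish, or shift in allele frequency under treatment pressure.
`pdxresist` implements that comparison as a reusable, testable pipeline,
together with the downstream analyses that give the calls functional meaning
(deleteriousness consensus, pathway over-representation, and correlation of
the mutated genes' expression with drug IC50 profiles across cancer cell
line panels) and the error model used to verify low-frequency calls by deep
amplicon sequencing.

## The classification model

All evidence is read counts. For a variant observed with `alt` mutant reads
out of `total` reads, the allele frequency (AF) is `alt / total`, defined
only at positive depth. Two thresholds govern everything:

* a point mutation is **called** when `total >= 20` and `alt >= 2`;
  frameshifts are exempt from the depth requirement (two mutant reads
  suffice), because indel-supporting reads are harder to map and a depth
  gate would systematically miss them;
* **absence is certified** only at `alt == 0` with `total >= 20`. A missing
  observation, or zero mutant reads at shallow depth, is evidence of
  nothing; such pairs are classified `undetermined`.

Before classification, the somatic filter removes common variants (dbSNP
minor allele frequency > 1%, carried as an `is_common` input flag),
consequences with no expected protein impact (synonymous, intronic, UTR,
in-frame indels), and anything with mutant reads in the germline sample. We
additionally require the germline locus itself to be covered at least
20-fold before accepting a variant as somatic — the source procedure is
silent on this point, but certifying somatic status from an uncovered
germline locus would be asymmetric with the absence rule used everywhere
else. Variants failing it are dropped and counted separately in the filter
log rather than silently discarded.

Per adapted arm, each somatic variant then receives exactly one status:

* `de_novo` — called in the adapted PDX, absence certified in the parental;
* `completely_depleted` — the mirror image;
* in-common branch — at least one mutant read at >= 20-fold depth in both
  samples. A two-sided Fisher exact test on the 2x2 table of mutant and
  reference counts (parental vs adapted), Benjamini–Hochberg adjusted
  within the arm, resolves the branch: `enriched` when `q < 0.05` and the
  AF rose by at least 10 percentage points, `partially_depleted` when
  `q < 0.05` and it fell by at least that much, `common_unchanged`
  otherwise;
* `undetermined` — everything else.

Several of these choices were genuinely open and are deliberate:

* **FDR scope.** Adjustment is within each arm across its in-common
  variants, not pooled across arms: each arm is an independent comparison
  against the same parental sample, and pooling would let a heavily mutated
  arm change calls in another.
* **Fisher sidedness.** Two-sided, with enrichment vs depletion resolved
  afterwards by the sign of the AF difference. A one-sided test per
  direction would double the test count for no gain.
* **The >= 10% rule** is an absolute AF difference (0.10 in fraction
  units), not a relative change — AF is already a percentage-scale
  quantity, and a relative reading would promote negligible shifts at low
  AF. It post-filters significant results; it does not gate which variants
  enter the FDR adjustment, so the multiplicity correction stays honest.
* **BH ties** are resolved by `stats::p.adjust`'s stable step-up; input
  order is preserved.

The cross-arm summary counts, per status, how many variants hold it in
exactly *k* arms and which hold it in all arms. Completely and partially
depleted calls are additionally pooled into one `depleted` category,
deduplicated per variant, because the same variant can be completely
depleted in one setting and partially depleted in another.

## Functional impact and its category contrast

A mutation is **deleterious** when it is a frameshift, nonsense or canonical
splice-site change, or a missense change predicted damaging by *both* SIFT
and PolyPhen-2 (PolyPhen's probably/possibly-damaging grades are collapsed
to "deleterious" upstream; missense variants with missing predictions
default to non-deleterious, keeping the deleterious set specific at the cost
of sensitivity). Fractions of deleterious mutations per category are
compared with the classical pooled two-proportion z-test without continuity
correction; with that convention a z of 2.08 corresponds to a two-sided p of
0.0375. `prop.test`'s Yates-corrected chi-square would not reproduce that
printed convention, which is why the small formula is implemented directly.

## Pathway over-representation

Query genes (for example, genes carrying deleterious de novo or enriched
mutations) are tested against a GMT collection by one-sided Fisher exact
tests on the 2x2 membership table over the annotation universe, BH-adjusted
across pathways, significant at `q < 0.05`. The universe defaults to all
annotated genes and is configurable to, say, all exome-covered genes; with a
small universe, over-representation p-values shrink, so the choice matters
and is surfaced as an argument rather than hidden.

## The random-gene-set null for drug sensitivity

For one drug, every gene's expression across cell lines is correlated with
the IC50 profile (Pearson, pairwise-complete, p from the t transform on
n − 2 degrees of freedom, BH across genes; genes with fewer than three
complete pairs are omitted). The question "are the mutated genes enriched in
negative correlations?" is answered against 1000 random gene sets of the
same size drawn uniformly from all genes with defined correlations. Random
sets may overlap each other and the query — no exclusion is imposed, since
the null should represent "a set like ours, chosen at random". The test is a
one-sided Mann–Whitney comparison of the query's correlations against the
pooled correlations of all random sets (the simplest reading that yields a
single p per drug); exact enumeration is used when both groups have at most
8 untied values, the tie-corrected normal approximation otherwise. "Set size"
means the query size after intersection with genes having defined
correlations.

## The amplicon error model

Deep amplicon sequencing verifies low-frequency calls. From base calls
already restricted to Phred > 30, the per-base error rate is the pooled
fraction of non-reference substitution calls at positions free of mutation
or germline variation — pooled across the amplicon rather than estimated per
position, because a per-position rate at a single locus is itself a noisy
binomial estimate; the pooling identity (coverage-weighted mean of
per-position rates) is tested. Indel calls are excluded from the rate by
default (`include_indels` reverses this): indel background error is treated
as negligible, so any non-zero indel AF is reported as detected. For
substitutions, an AF below the rate is below the detection limit; at the
boundary `af == rate` the call is "detected", since only strictly lower
frequencies are indistinguishable from noise.

## What the synthetic data emulate — and what they do not

The generators are first-class package code and define the study conditions
once:

* **Variant cohort** (`simulate_variant_cohort`): six sample roles (germline,
  parental, four adapted arms named cisplatin, fluorouracil, lurbinectedin,
  olaparib); depth negative-binomial with mean 80 and dispersion 0.1 per
  sample; mutant reads binomial at the category's true AF. Planted category
  counts default to 64 de novo, 43 completely depleted, 22 enriched (AF
  0.05 → 0.30), 19 partially depleted (0.30 → 0.05), 39 unchanged, plus 20
  germline contaminants (AF 0.5 or 1.0), 20 common SNPs and 20
  excluded-consequence variants; consequences are drawn in proportion
  6:7:1:173 (frameshift:nonsense:splice:missense). A `noise_free` mode fixes
  depth at the mean and sets `alt = round(AF x depth)`, making classifier
  recovery deterministic for golden tests. `arm_assignment = "single"`
  confines each planted shift to one arm (round-robin) to exercise the
  cross-arm overlap counting.
* **Expression/IC50 panel** (`simulate_expression_drug`): standard-normal
  IC50 over 638 cell lines by default; a planted set of 40 genes drawn
  bivariate-normal with correlation −0.4 to the IC50 vector, all other
  genes independent.
* **Amplicon** (`simulate_amplicon_pileup`): 500 positions at mean depth
  2000 (a desk-scale stand-in for the much deeper real amplicon regime),
  substitution errors binomial at ε = 0.002 split uniformly over the three
  non-reference bases, planted mutations at AFs 0.05/0.10/0.30 at flagged
  positions.

These generators deliberately omit features of real data: no mapping or
strand artefacts, no mouse-read contamination, no copy-number structure or
subclonal phylogenies, no correlated errors along the amplicon, and variant
sites are independent. Passing tests therefore demonstrate that the
*procedure* is implemented correctly and calibrated under its own model —
not that the thresholds are optimal for any particular sequencing chemistry.

## Numerical and testing choices

Every stochastic routine takes an explicit seed and is a pure function of
(configuration, seed). Degenerate inputs map to explicit states rather than
NaNs: zero depth is an error for AF but simply fails the calling thresholds;
a degenerate pooled proportion yields z = 0, p = 1 with a warning; an empty
somatic set returns an empty record table with a warning. The test suite
checks the Fisher, Mann–Whitney and BH routes against brute-force
enumeration oracles (all-margins hypergeometric sums, rank-arrangement
enumeration, the step-up definition), recovery of planted truth both
noise-free (exact) and stochastic (power monotone in coverage and effect
size; false shift calls near the FDR level under the null), and the error
model against binomial sampling bounds. Problem sizes in the tests (for
example 100–200 planted variants per condition, 150–1000 genes, 60–200 cell
lines, 200–1000 null sets) were chosen to keep the default suite fast while
leaving Monte-Carlo margins wide.

## Limitations

Allele counts are taken at face value: no clonality deconvolution, no
copy-number adjustment of expected AFs, and no recalibration of the
`is_common` flag. The per-arm FDR scope and the one-vs-pooled Mann–Whitney
structure are documented choices, configurable in part, and alternatives
(pooled FDR; per-set median empirical p) could be defended. The
two-proportion z-test is an approximation that is poor at very small counts;
with category sizes in the tens, as here, it is standard.
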