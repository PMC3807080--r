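---
title: "Curation and risk-prediction methods in ravarkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation and risk-prediction methods in ravarkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ravarkit)
```

`ravarkit` curates literature-derived genetic-association tables for
rheumatoid arthritis (RA) into reproducibility-graded variant sets and turns
the confirmed markers into an individual risk prediction. This vignette is
the package's own account of the procedure: the rules, the model, the
numerical choices, and what the tests do and do not establish.

## Evidence grading

Association studies come in two statistical situations. A genome-wide scan
tests on the order of a million markers, so only P < 5×10⁻⁸ counts as strong
evidence and P ≤ 10⁻⁵ as moderate; a follow-up study genotypes a handful of
pre-selected markers, so the nominal P < 0.01 (strong) and P ≤ 0.05
(moderate) are the appropriate cuts. `select_regime()` keys the choice on
the study design first — meta-analyses of GWAS and combined GWAS+replication
analyses are held to the genome-wide standard regardless of coverage — and
on the genotyping coverage otherwise. Published P-values are taken as-is: no
recomputation from counts, no multiple-testing correction beyond the fixed
thresholds (the thresholds *are* the policy), no one-sided/two-sided
distinction, and no underflow clamping (P = 1×10⁻²⁹⁹ parses as written).

Boundary handling is a genuine design choice because prose descriptions of
"between" thresholds leave endpoints open. We grade *strong* strictly below
its threshold and close the *moderate* interval at both endpoints, so
P = 0.01 and P = 0.05 are moderate under the follow-up regime and
P = 5×10⁻⁸ is moderate under the genome-wide regime. This matches the strict
reading of "not significant above the weak threshold" and keeps the grading
monotone in P (a property test covers this).

## Populations and representative associations

Associations are grouped into nine geographical populations (European, East
Asian — absorbing South-East Asian, West Asian, South Asian, South American,
Central American, North African, South African, African American). The
synonym table lives in `extdata/population_synonyms.tsv` as data, not code,
so users can extend it; unknown labels are hard errors because a silently
mis-grouped study would corrupt every downstream class. A study population
maps to exactly one group.

Because most variants accumulate several studies per population, the
*representative association* for a (variant, population) pair is taken from
the study with the largest number of case subjects — sample size being the
dominant determinant of reliability here. Case count does not totally order
studies, so ties break deterministically: smaller P, then more controls,
then lexicographically smallest study identifier. The selection is
permutation-invariant and idempotent (property-tested). A consequence worth
noting — reproduced by the `small_study_only` class of the synthetic
generator — is that a significant small study is *displaced* by a larger
non-significant study of the same population, and the variant drops out.

## Direction harmonization and reproducibility classes

Two reports of one variant may describe either allele of a biallelic pair,
on either strand. `direction_verdict()` harmonizes them: identical alleles
(or a reverse-strand complement, covering T-vs-A reporting of the same SNP)
must sit on the same side of OR = 1 to be consistent; different,
non-complementary alleles must sit on opposite sides; with a missing allele
the raw odds ratios are compared directly; a missing odds ratio, or an odds
ratio of exactly 1, is *indeterminate* — never a conflict, because absence
of evidence for direction is not evidence of conflict. For A/T and C/G
palindromic markers the complement of one allele *is* the other allele, so a
strand flip is indistinguishable from an opposite-allele report; we apply
the same-allele rule and document this as a known ambiguity of
literature-level (genotype-free) curation.

A variant is **inter-population reproduced** when its significant (strong or
moderate) representatives span ≥ 2 populations with no conflicting pair; any
conflicting pair excludes the variant outright. It is **intra-population
reproduced** when a significant representative is seconded by at least one
independent study (distinct publication identifier) of the same population
that is significant under its own regime and not direction-conflicting.
Direction consistency for intra-population replication is enforced by
choice: an opposite-direction "replication" is not a replication. Both
classes are reported independently; a variant may hold both. "Independent
study" means a distinct publication — cohort overlap between publications is
undetectable from these inputs and is a documented limitation. A
multi-population meta-analysis record counts only toward the population it
is labeled with, and any significant same-population record (not only
representative-eligible ones) can second a representative.

The packaged fixture (`load_table1_fixture()`) transcribes the 40 published
representative associations of the 19 variants confirmed between
populations, spanning 12 gene-group loci; it exercises every evidence path
(missing odds ratios, missing alleles, opposite-allele reporting, both
regimes, meta-analysis rows). Meta-analysis rows of follow-up data are
encoded `design = followup` so they are graded at the follow-up thresholds
under which they were reported as confirmed; the genome-wide exception
applies to meta-analyses *of GWAS*, which the genome-wide-coverage rows
represent. One locus (OLIG3/TNFAIP3) pairs different SNPs across
populations in the published table; the fixture encodes the rows as printed
and the per-variant classifier yields the printed totals.

## Risk model

To avoid double counting, confirmed markers in one
linkage-disequilibrium block are pruned to the variant with the smallest
association P-value (`prune_ld()`; ties break lexicographically).

For marker *i* with allelic odds ratio $r_i$, risk-allele frequency $p_i$ in
controls, and carried copy number $X_i \in \{0,1,2\}$:

* **GRS** $= \sum_i X_i \ln r_i$. Unweighted allele counting is
  inappropriate for RA because HLA-region odds ratios dwarf the non-HLA
  ones; the log-OR weighting makes each marker's contribution proportional
  to its evidence. The natural logarithm is a convention; any base only
  rescales the score.
* **Per-marker RGR** $= s_i / a_i$ with genotype-specific risk
  $s_i = r_i^{X_i}$ (multiplicative allelic risk, the risk factor being the
  allelic OR) and Hardy–Weinberg population-average risk
  $a_i = p_i^2 r_i^2 + 2 p_i (1-p_i) r_i + (1-p_i)^2$. The defining property
  is $\mathbb{E}_{X \sim \mathrm{HWE}(p)}[\mathrm{RGR}] = 1$: the average
  member of the population scores exactly 1, which the test suite verifies
  to 1×10⁻¹² on a grid of $(r, p)$. The construction is also invariant under
  relabeling the risk and non-risk allele
  ($r \to 1/r$, $p \to 1-p$, $X \to 2-X$), which the panel loader exploits
  to flip protective-orientation rows.
* **Overall RGR** $= \prod_i \mathrm{RGR}_i$, assuming independence across
  (pruned) loci; the empty panel gives 1.
* **Lifetime risk** $= \min(\mathrm{RGR} \times \text{prevalence}, 1)$.
  Plain multiplication is used; at a 2.6-fold RGR and the default European
  prevalence of 1 % (shipped in `extdata/prevalence.tsv`, user-overridable)
  this gives 2.6 %, far from the cap. The cap matters only for extreme
  panels and marks the point where the relative-risk approximation leaves
  its domain of validity.

Degenerate inputs: $p = 0$ with $X > 0$, or $p = 1$ with $X < 2$, is an
error (the genotype is impossible at the stated frequency and the baseline
degenerates); $p = 1, X = 2$ returns 1. Markers with missing genotypes are
skipped rather than imputed — no imputation model is part of the method —
and `n_markers_used` reports how many contributed. Genotypes are supplied as
two-letter strings counted against the declared risk allele; unknown letters
are errors naming the marker, because a silent zero would understate risk.

## Synthetic data: what it emulates and what it does not

`simulate_association_table()` plants variants of six classes —
inter-reproduced, intra-reproduced, lone-significant, never-significant,
direction-conflict, and small-study-only — by constructing study records
that force each class under the rules above. Planted P-values sit an order
of magnitude beyond the thresholds (e.g. 10⁻⁹ vs 5×10⁻⁸) so recovery tests
never ride a boundary; boundary behaviour is tested separately in the
grading module. Odds ratios are drawn log-uniform in [1.05, 2.5], the
magnitude range of the published confirmed associations (0.61–2.88 across
both orientations). The generator is fully determined by its seed.

What it does *not* emulate: P-values are planted, not sampled from simulated
cohorts; there is no linkage-disequilibrium structure, no genotype-level
case/control sampling, no cohort overlap between "independent" studies, and
no publication bias. Recovery tests therefore establish that the classifier
implements its rules exactly — including on tables where a brute-force
pairwise oracle is feasible — not that the rules are robust to the noise
structure of real literature. `simulate_genotype()` draws risk-allele copy
numbers as Binomial(2, p) per marker, which is exactly the Hardy–Weinberg,
linkage-equilibrium assumption of the risk model; the Monte-Carlo
calibration (mean overall RGR of 100 000 simulated individuals on a
5-marker panel equal to 1 within three standard errors) checks the model
against its own assumptions, not against real genotype data.

Problem sizes used by the test suite — 50 random generator specifications
for label recovery, tables of up to 6 records per variant for oracle
equivalence, 100 000 individuals for the Monte-Carlo calibration — were
chosen so the defining properties are measured with comfortable
statistical margins while the whole suite stays fast enough to run on every
change.

## Interfaces and determinism

Tabular inputs and outputs are UTF-8 TSV with header rows; `""` and `"."`
denote missing optional values. Every writer is byte-stable: fixed column
order, LF endings, 6-significant-digit formatting for derived reports and
full precision for data tables so reads invert writes. The command-line
interface (`inst/cli/ravarkit.R`) is a thin wrapper over the exported
functions — subcommands `grade`, `curate`, `prune`, `predict`, `simulate`
(class counts and populations as flags, seeded), and `fixture` — exiting 0
on success and 2 on validation errors. Identical inputs and seeds give
byte-identical outputs.

## Known limitations

* Variant identifiers are opaque keys; synonymous rsID merging and
  HLA-nomenclature parsing are out of scope.
* Palindromic (A/T, C/G) markers cannot be strand-disambiguated from
  literature reports, as discussed above.
* Publication-level independence is assumed for intra-population
  replication; overlapping cohorts across papers would inflate it.
* The risk model multiplies per-locus relative risks (independence across
  loci) and ignores interaction terms, confidence intervals, and
  liability-threshold modelling.
* Curation classifies reported results; it does not pool them — no
  meta-analysis is performed.
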