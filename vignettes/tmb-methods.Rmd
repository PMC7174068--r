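---
title: "Methods: comparing panel-based and exome-based tumor mutation burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing panel-based and exome-based tumor mutation burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Tumor mutation burden is defined as the number of qualifying somatic coding
variants divided by the megabases of coding sequence interrogated. Two
laboratories can report very different TMB values for the same tumor if one
sequences the whole exome while the other sequences a 400-gene panel, or if
one counts synonymous variants while the other does not. `panelTMB`
implements each piece of that methodological space explicitly — footprints,
inclusion policies, regression-based concordance, and quartile survival —
together with a synthetic-cohort generator that provides ground truth for
all of it. This vignette documents the models, the defaults, and the
numerical decisions.

## Coding footprints

A panel's footprint is built from the coding exons of the **longest
transcript** of each panel gene; the exome footprint is the **union of all
coding exons of all transcripts** of all genes. The asymmetry is
deliberate: a targeted assay acquires one representative transcript per
gene, whereas exome capture covers every annotated coding base. "Longest"
means longest *coding* length, consistent with a denominator meant to count
coding sequence; total transcript span (with UTRs) would be the other
defensible reading, but UTR bases never contribute qualifying variants
here.

Conventions that matter for reproducibility:

* GTF input is 1-based inclusive; internally every interval is 0-based
  half-open, which makes interval arithmetic unambiguous at boundaries.
* Length ties between transcripts are broken by the lexicographically
  smallest transcript id, so footprints are deterministic.
* Coding bases shared by two panel genes are merged and counted **once**:
  the denominator is sequence acquired, not sequence summed per gene. The
  merge is idempotent, and the tests verify order-invariance with respect
  to both panel files and annotation streams.
* Gene symbols are matched case-sensitively after whitespace trimming, with
  no alias resolution. Panel genes absent from the annotation are reported
  (`missing_genes`) and warn; only a fully missing panel is an error.

## Variant inclusion

A counting method is a footprint plus an `inclusion_policy`: which variant
classes count (SNV, insertion, deletion), whether synonymous variants
count, and the region a variant must fall in. The consequence vocabulary is
`synonymous`, `missense`, `nonsense`, `frameshift`, `inframe_indel`,
`splice` (coding), and `noncoding`/`unknown`, which are never counted — the
inclusion rule is "within a coding exon", so intronic or unannotated calls
do not enter TMB under any policy. Splice variants count as non-synonymous
coding events by default (configurable), a choice most laboratories make
implicitly.

The membership test anchors a variant at its reported position — the
leftmost reference base affected, which for insertions is the base before
the inserted sequence — matching VCF convention. Exact duplicates (same
sample, position, alleles) are collapsed to a single event and logged; each
alternate allele of a multi-allelic record is its own event. Records whose
FILTER is neither `PASS` nor `.` are dropped at parse time and counted. No
minimum variant-allele-fraction filter is applied: VAF thresholds belong to
the upstream caller, and the package treats the variant list as the
caller's final word.

The consequence classifier translates a reference codon and its mutated
copy with the standard genetic code: same amino acid → synonymous, new stop
→ nonsense, otherwise missense. Enumerating all 61 sense codons × 3
positions × 3 alternate bases gives 549 substitution cases of which 134 are
synonymous, so uniform random coding substitutions are silent with
probability 134/549 ≈ 0.244 — the mechanistic origin of the familiar
"~25% of coding variants are synonymous" and of the ≈1.32 slope between
all-coding and non-synonymous TMB. The test suite checks the classifier
against an independent hard-coded codon table over all 549 cases.

## TMB

`tmb = variant_count / footprint_mb`, kept at full floating precision;
rounding is for display only, because downstream quartile cut-offs are
sensitive to it. A zero or invalid footprint is an error, never a silent 0
or infinity. Samples known to the cohort but absent from the variant table
get a count of zero — an empty variant list is an observation, not missing
data. The whole-exome method always uses the exome footprint as
denominator even though its variant lists are already exome-restricted.

## Concordance

Two TMB methods are compared by Deming (errors-in-variables) regression,
which, unlike ordinary least squares, does not attenuate the slope when
both measurements are noisy. With (n−1)-denominator moments
$s_{xx}, s_{yy}, s_{xy}$ and error-variance ratio
$\lambda = \mathrm{var}(\epsilon_y)/\mathrm{var}(\epsilon_x)$:

$$\hat\beta = \frac{s_{yy} - \lambda s_{xx} +
  \sqrt{(s_{yy} - \lambda s_{xx})^2 + 4\lambda s_{xy}^2}}{2 s_{xy}},
  \qquad \hat\alpha = \bar y - \hat\beta \bar x.$$

`lambda = 1` (orthogonal regression) is the default and the conventional
choice when nothing is known about the two methods' error variances; it is
exposed as an argument because it is not always right. For Poisson counting
noise, the TMB error variance scales inversely with footprint size, so a
panel-vs-exome comparison has a true ratio near `footprint_WES /
footprint_panel`; at realistic proportions (panel under 10% of the exome)
the practical difference between that and λ = 1 is small, but users fitting
small panels against the exome on low-burden cohorts should set λ
accordingly. The slope confidence interval is a leave-one-out jackknife
with a normal approximation, recorded in the output (`ci_method`). The
closed form is verified against an independent numeric orthogonal-distance
minimizer to 1e-6 on randomized instances, and the λ = 1 reciprocity
`slope(x,y)·slope(y,x) = 1` is tested to 1e-9.

No weighting and no outlier exclusion are applied: truncated-axis views of
heavy-tailed TMB distributions are presentation, not analysis, so fits use
every point. Zero-inflated TMB vectors are retained; only exact degeneracy
(constant x, zero covariance) aborts a fit, and in the all-pairs comparison
grid such failures are flagged per cell rather than aborting the grid.
Bland–Altman agreement is the mean difference `y − x` with limits at
±1.96 sample standard deviations.

## Survival

Samples are split into TMB quartiles at the empirical 25/50/75 percentiles,
computed with linear interpolation between order statistics
(`stats::quantile` type 7) — the algorithm is recorded in the output
because group membership near a cut depends on it. A sample goes to the
lowest quartile whose cut it does not exceed (ties fall **down**), so Q4 is
the highest-burden quarter. Quartiles are computed pan-cohort or within
each tumor type; both modes are provided because pan-tumor and per-type
analyses answer different questions and tumor types differ in baseline
burden by orders of magnitude. Strata with fewer than 8 samples or a
single distinct TMB value are skipped with a warning.

Kaplan–Meier curves come from `survival::survfit`; hazard ratios from
`survival::coxph` with the quartile as a categorical covariate, Efron tie
handling by default (Breslow available), and 95% Wald intervals from the
observed information. A quartile with no events produces a monotone
partial likelihood; the contrast is reported with its (effectively
infinite) bounds and flagged `unstable` instead of aborting. TMB and
clinical tables are joined on sample id (inner join, mismatches logged,
empty join is an error); records with missing survival fields are dropped
with a logged count, zero-time records are retained. No multiple-testing
correction is applied across tumor types or methods — the output is
per-stratum HRs with CIs, mirroring how such analyses are reported.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
any particular genome:

* **Genes**: log-normal coding lengths (default mean ≈ 1.5 kb, `sdlog`
  0.6, clipped to 150 b–100 kb), 1–20 exons, 1–3 transcripts with the
  first carrying the full footprint, laid out over 22 synthetic
  chromosomes.
* **Panels** are drawn without replacement from a shared pool of genes
  (default 1,000), so panels overlap partially as real assays do. The pool
  draw is **length-weighted**: clinical panels target long, heavily
  studied genes, and published panel footprints (0.5–3 Mb for 170–600
  genes) imply per-gene coding lengths well above the exome average. With
  length weighting, simulated panels land in a realistic size range while
  staying under 10% of the exome.
* **Burden**: each tumor draws a type and then a mutation rate log-uniform
  within the type's bounds (defaults span 0.5–100 /Mb across three types),
  reproducing the orders-of-magnitude spread of somatic burden; variants
  are then Poisson per gene, proportional to the gene's coding footprint,
  placed uniformly over coding positions. `count_bounds` substitutes a
  log-uniform total count per tumor (spread multinomially over genes) when
  exact count control is wanted. A per-panel `panel_rate_multiplier`
  scales the rate inside panel genes, which is the generative mechanism
  behind panel-vs-exome slopes different from 1.
* **Consequences**: either mechanistic (`genetic_code`: uniform sense
  codon, position and alternate base, classified by the standard code — the
  synonymous fraction *emerges* as 134/549 rather than being hard-coded) or
  parametric (`fixed_fraction`) for sharp unit tests. Indels (default 10%)
  are frameshift with probability 2/3.
* **Survival**: event times are exponential with hazard
  $h_0\,e^{\beta \log(\mathrm{TMB}+1)}$; censoring is independent
  exponential with its rate solved numerically (`uniroot`) so the expected
  censored fraction matches the configuration. Times are rounded up to
  whole days, producing the ties that make the Efron/Breslow distinction
  real.

Everything is deterministic given the seed: the three simulation stages use
fixed offsets of it, so reruns are byte-identical file for file.

What the generator does **not** model: trinucleotide mutational signatures
(placement is uniform within a gene), sequencing depth and error, tumor
purity and subclonality, germline contamination, and the empirical
per-tumor-type TMB distributions of any real cohort — the type defaults are
order-of-magnitude placeholders. Consequently, passing tests demonstrate
that the *computational* pipeline preserves generative structure
(rates, multipliers, hazard directions); they do not certify concordance
magnitudes on real tumors, where regional mutation-rate variation is the
dominant source of panel-vs-exome bias.

## Problem sizes and test design

The unit tests run on small fixtures (hundreds of genes, tens of samples)
built in code. The study-level checks use the sizes at which the claims are
stated: 500-tumor cohorts for the synonymous-toggle regression (counts
log-uniform 10–10,000) and for panel concordance (20,000 genes, six panels
of 170–596 genes, rates log-uniform 0.5–100 /Mb); multiplier recovery uses
an 8,000-gene exome so the 300-gene panel stays under 10% of the exome —
at much smaller exomes the multiplier materially shifts whole-exome TMB
itself and the recovered slope reflects the ratio of depleted panel to
diluted exome rather than the multiplier alone. Cox interval calibration
uses 200 replicates of an 800-subject, four-group exponential design.

## Known limitations

* Multi-nucleotide substitutions are lumped with SNVs by allele-length
  comparison; complex alleles are not normalized or re-annotated.
* `read_variants` trusts the VCF's own gene/consequence annotation
  (configurable INFO keys); it does not re-annotate against transcript
  sequence.
* The jackknife-normal slope CI is one of several reasonable choices for
  Deming regression; bootstrap or analytic alternatives may differ in small
  samples.
* Footprints carry no UTR/splice-site padding and no liftover; annotation
  and variants must share a coordinate system.
* Survival models are unadjusted single-covariate quartile contrasts —
  no age/stage covariates, trend tests, or competing risks.
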