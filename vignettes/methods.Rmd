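---
title: "Methods: single-SNP case-control association and the FPRP/BFDP screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-SNP case-control association and the FPRP/BFDP screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpcc)
```

## Scope and data model

`snpcc` analyses one biallelic SNP at a time in a two-cohort
(case/control) design. The atomic datum is a `genotype_counts` triple —
reference homozygotes, heterozygotes, alternate homozygotes — for one
cohort; a `cohort_pair` joins the case and control triples under one
declared allele orientation. Per-subject long-format records are
supported purely as a layer beneath the counts: genotypes are unordered
and unphased (restriction-digest genotyping gives no phase), missing
genotypes are dropped per SNP with a logged count and never imputed,
and `aggregate_subjects()` reduces records to exactly the count tables
the rest of the pipeline consumes.

One deliberate convention runs through the whole package: **the
reference allele is whatever the study declares it to be**, and the
baseline of every contrast is the reference-carrying group. No
re-orientation to the rarer allele ever happens. This matters when the
"variant" allele is the more frequent one (the packaged CYP2E1
rs2070673 example: the T allele is the declared variant with control
frequency 0.63); silently flipping to the minor allele would invert
published odds ratios such as 0.39 and 0.45 into their reciprocals and
make results impossible to compare across studies.

## Hardy–Weinberg testing

With sample reference-allele frequency
$\hat p = (2 n_{RR} + n_{RA})/2n$, the expected genotype counts are
$(\hat p^2 n,\; 2\hat p \hat q n,\; \hat q^2 n)$ and

$$X^2 = \sum_{g} \frac{(O_g - E_g)^2}{E_g}$$

is referred to $\chi^2_1$: three classes, minus one for the total,
minus one for the estimated allele frequency. No Yates continuity
correction is applied — the uncorrected statistic is the standard
genetics convention for this goodness-of-fit use, and it is the variant
that reproduces published HWE tables computed with mainstream
statistical software. Degenerate input is tolerated by design: a
monomorphic cohort yields a flagged result ($X^2 = 0$, $p = 1$) with a
warning rather than an error, so that batch analyses of simulated
cohorts never abort on an edge draw.

## Genetic models and odds ratios

The six contrasts are built directly from the count triples. Two
choices deserve a note:

* The additive-1 and additive-2 tables *drop* the unused genotype class
  entirely (their totals are smaller than the cohort sizes). They are
  genuine pairwise contrasts, not collapsed codominant recodings — this
  is what makes their denominators, and hence their confidence
  intervals, match published candidate-gene tables.
* The allelic model counts chromosomes, so its margins are $2n$. It
  treats alleles within a subject as independent, which is exactly true
  under HWE and only approximate otherwise — one reason the HWE test
  precedes it in the pipeline.

For a 2×2 table $(a, b, c, d)$ (case-exposed, case-baseline,
control-exposed, control-baseline), `odds_ratio_test()` uses the Woolf
log-scale machinery: $\mathrm{OR} = ad/bc$,
$\mathrm{SE} = \sqrt{1/a + 1/b + 1/c + 1/d}$, confidence limits
$\exp(\log \mathrm{OR} \mp z_{1-\alpha/2}\,\mathrm{SE})$, and the
two-sided p-value from the Wald statistic
$z = \log\mathrm{OR}/\mathrm{SE}$. The Wald-on-log-OR p-value (rather
than a Pearson chi-squared or Fisher exact p) is a deliberate
convention: it is self-consistent with the Woolf interval (the CI
covers 1 exactly when $p > 0.05$, a property the test suite checks
exhaustively over all tables with cells 1–12) and it is the convention
under which the packaged study's twelve significant/non-significant
p-values reproduce to the fourth decimal. Zero cells route through the
Haldane–Anscombe correction (+0.5 to all four cells) with a warning and
a `corrected` flag; p-values are floored at 1e-300 so downstream logs
and ratios stay finite.

## The noteworthiness screen

A small candidate-gene study can print an impressive p-value and still
be more likely false than true. The screen quantifies this two ways.

**FPRP.** Given the observed significance level $\alpha$, the power
$1-\beta$ to detect a stated target odds ratio, and a prior probability
$\pi$ that the association is real,

$$\mathrm{FPRP} = \frac{\alpha (1-\pi)}{\alpha (1-\pi) + (1-\beta)\pi}.$$

Three conventions are fixed here, each with a reason:

* **$\alpha$ is the exact observed p-value, not the printed one.** The
  two choices diverge visibly: for the packaged rs204993 CC-vs-TT
  contrast the exact p of 8.4e-5 gives power 0.0043 (prints 0.004),
  while the rounded 0.0001 would give 0.0049 (prints 0.005). The exact
  convention is the one consistent with published FPRP tables.
* **Power is the two-sided rejection probability under the shifted
  normal**, $\Phi(|\theta_1|/\mathrm{SE} - z_\alpha) +
  \Phi(-|\theta_1|/\mathrm{SE} - z_\alpha)$ with
  $\theta_1 = \pm\ln(\mathrm{OR}_{target})$. The second (discordant)
  tail is below 1e-6 in every realistic configuration, but keeping it
  makes the formula exact and direction-symmetric, which in turn makes
  the whole screen invariant under relabelling exposure — a property
  the tests assert. Protective estimates ($\mathrm{OR} < 1$) use the
  reciprocal target, equivalently $\theta_1 = -\ln 1.5$; an estimate of
  exactly 1 is screened as risk.
* **The default target OR is 1.5 and the default priors are 0.25, 0.1,
  0.01, 0.001, 0.0001 with a noteworthiness cutoff of 0.2** — the
  standard screening grid for candidate-gene work: 0.25 reflects a
  well-motivated candidate, 0.0001 a random marker. The literature also
  uses a more permissive 0.5 cutoff; `noteworthiness_config(fprp_cutoff
  = 0.5)` selects it, and it is the preset under which the packaged
  study's published bold/noteworthy pattern reproduces exactly.

**BFDP.** Wakefield's approximate Bayes factor compares the point null
$\theta = 0$ with $\theta \sim N(0, W)$, where the prior spread is
anchored so that its 97.5th percentile sits at the target odds ratio:
$W = (\ln 1.5 / 1.96)^2 \approx 0.0428$. With $V = \mathrm{SE}^2$ and
$z = \log\mathrm{OR}/\mathrm{SE}$,

$$\mathrm{ABF} = \sqrt{\frac{V+W}{V}}\,
  \exp\!\left(-\frac{z^2 W}{2(V+W)}\right), \qquad
\mathrm{BFDP} = \frac{\mathrm{ABF}\cdot PO}{1 + \mathrm{ABF}\cdot PO},
\quad PO = \frac{1-\pi}{\pi},$$

reported over priors 0.01, 0.001, 0.00001 with a cutoff of 0.8. ABF is
always reported alongside BFDP for auditability, because published BFDP
tables in this literature frequently come from spreadsheet
implementations whose $W$ and prior-odds conventions are unstated and
unrecoverable — the packaged study's BFDP columns are one such case,
and `self_test()` therefore treats BFDP as informational rather than a
diffable cell. The implementation is validated instead against the
closed form (independently re-evaluated in the tests), its exact limits
($W = 0 \Rightarrow \mathrm{ABF} = 1,\ \mathrm{BFDP} = 1 - \pi$;
$z = 0 \Rightarrow \mathrm{ABF} > 1$), and its monotonicities.

## The synthetic-data generator

`simulate_cohort_pair()` draws controls from a multinomial at
Hardy–Weinberg proportions $(p^2, 2pq, q^2)$ for control alternate
allele frequency $q$, and cases from those proportions tilted by
genotype odds ratios, normalised:
$f_{case} \propto (p^2,\; 2pq\cdot\mathrm{OR}_{het},\;
q^2\cdot\mathrm{OR}_{hom})$. This exposure-odds construction is the
natural generative model for a retrospective design: the sample
additive-1 and additive-2 odds ratios converge to
$\mathrm{OR}_{het}$ and $\mathrm{OR}_{hom}$ as cohorts grow, without
ever specifying a disease prevalence (which a case-control study cannot
identify anyway). Defaults mirror the packaged study's conditions: 210
cases, 210 controls, $q = 0.34$ (the control minor-allele frequency of
the central SNP), and null effects — so the default generator is a
type-I-error test bench. Seeds are explicit, draws are
bit-reproducible, and the seed travels into `run_study()` provenance.

What the generator *does not* emulate: linkage disequilibrium between
SNPs (each SNP is independent, as in a marginal analysis), population
stratification, genotyping error, and departures of the case
distribution from the multiplicative tilt. That last point is visible
in the packaged data themselves: the tilt model at the fitted control
frequency and the fitted ORs predicts case het/hom fractions of
(0.450, 0.258) where the study observed (0.486, 0.229). Passing
calibration tests therefore demonstrate that the *statistics* behave
correctly under a clean generative model — not that any real cohort
follows that model.

## Numerical and reporting choices

* Counts parse as exact integers from tab-separated UTF-8 with a
  mandatory header; malformed cells report the SNP and column.
* Display rounding: ORs and CI bounds to 2 decimals, p-values to 4,
  HWE statistics to 2 and HWE p to 3, screen probabilities to 3. The
  JSON report keeps full double precision and round-trips losslessly;
  every displayed number is the rounded full-precision value.
* Significance is flagged at $p \le 0.05$ inclusive, and no
  multiple-testing adjustment is made across the 18 model tests —
  mirrored from standard practice in this study design and stated in
  the report footer. The six models per SNP are overlapping recodings
  of the same table, so their tests are strongly dependent; readers
  should treat the FPRP/BFDP screen, not a Bonferroni line, as the
  guard against over-interpretation.
* `run_study()` is a pure function of (input bytes, configuration);
  provenance records the input checksum, configuration echo, package
  version and any simulation seed.

## Test problem sizes

The property and calibration suite runs at sizes chosen to make
Monte-Carlo bounds sharp while keeping the full suite around ten
seconds: exhaustive checks of the OR/CI/p identities over all 20,736
2×2 tables with cells 1–12; 2,000 null replicates at 210/210 for the
type-I error of the additive-2 test and for the nominal HWE rejection
rate (binomial bound 5% ± 1.5%); and 1,000 replicates at 5,000/5,000
for parameter recovery of both generative log-ORs to within 3
Monte-Carlo standard errors.

## Limitations

No covariate adjustment or logistic regression, no Cochran–Armitage
trend test, no exact (conditional) CIs or exact HWE test, no
multi-allelic or sex-linked sites, no imputation, and no cross-SNP
haplotype structure. The package reproduces and screens marginal 2×2
associations; anything conditional belongs to a regression framework.
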