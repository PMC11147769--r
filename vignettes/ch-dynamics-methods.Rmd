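---
title: "Models and methods behind chdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chdyn)
set.seed(1)
```

`chdyn` analyses clonal hematopoiesis (CH) from serial, error-corrected
variant calls in whole blood (WB) and plasma cell-free DNA (cfDNA) collected
under sequential DNA-damaging therapies — a platinum chemotherapy phase
followed by PARP-inhibitor maintenance. This vignette explains the models
the package implements, the parameters that matter, the synthetic-data
generator used to validate every stage, and the design choices made where
the methodology was genuinely open.

## The sigmoid clone-growth model

Clone size is tracked through the variant allele frequency (VAF) of a
heterozygous autosomal somatic mutation: a clone occupying the whole
hematopoietic compartment has VAF 1/2, which is therefore the model's
carrying capacity. Growth follows a logistic (sigmoid) curve

$$v(t) = \frac{1}{2}\,\frac{1}{1 + A e^{-st}},$$

where $t$ is time in years, $s$ is the clonal fitness (per year) and $A$ is
fixed by the anchoring condition $v(0) = v_0$, giving $A = 1/(2v_0) - 1$
(`solve_A()`). The single rate parameter makes the model identifiable from
two serial observations in closed form:

$$s = \frac{1}{\Delta t}\,\ln\frac{1/(2v_0)-1}{1/(2v_1)-1}
\quad\text{(\texttt{fit\_fitness()}).}$$

For $v \ll 1/2$ this reduces to exponential growth,
$s \approx \ln(v_1/v_0)/\Delta t$, so small-clone fitness behaves like an
ordinary log growth rate. Clones are categorised *increasing* when
$s > 0.25$/year, *decreasing* when $s < -0.25$/year and *stable* otherwise;
both inequalities are strict, so $s = \pm 0.25$ exactly is stable.

```{r}
v1 <- simulate_trajectory(0.05, log(6), eval_times = 1)
v1
fit_fitness(0.05, v1, dt_years = 1)
```

Three-timepoint trajectories (treatment start, maintenance start, end of
treatment) are decomposed per phase by `phase_fitness()`: each phase is fit
independently and re-anchors $A$ at its own starting VAF, so the two
estimates are continuous at the boundary but otherwise uncoupled. Overall
(two-timepoint WB) and per-phase (three-timepoint cfDNA) fitness are kept
as separate outputs and never averaged, because they answer different
questions about the same clone.

### Numerical choices

Observed VAFs are clamped into $[0.001, 0.499]$ before inversion. The lower
bound is the 0.1% detection floor of the error-corrected calling pipeline
the inputs come from; the upper bound keeps the estimate away from the
singularity at $v = 1/2$, where the heterozygous model is anyway invalid
(VAF above 50% arises under loss of heterozygosity). Any clamped endpoint
flags the estimate `censored`, and censored estimates should be treated as
bounds rather than measurements. The closed form is exact: on noiseless
trajectories the inversion agrees with numeric root-finding on the growth
equation to better than $10^{-9}$ relative error (see the test suite).

## Variant classification cascade

Annotated calls pass through, in order: a retention filter
(protein-altering coding or splice-site effect, and at least 10 alternate
consensus reads); a germline rule (VAF strictly above 45%); a polymorphism
exclusion (VAF strictly above 40% and flagged in dbSNP or above 1%
population allele frequency in gnomAD), from which highly recurrent CH
hotspots (DNMT3A R882, GNB1 K57E, JAK2 V617F, SF3B1 K666/K700, SRSF2 P95,
U2AF1 S34/Q157) are exempt; everything surviving is somatic. Inclusive
versus strict boundaries follow the wording of each rule as stated
("minimum of 10" is inclusive; "above 45%" is strict), and every boundary
has a dedicated row in the packaged 30-row fixture
(`inst/extdata/classification_fixture.tsv`).

Two readings deserve mention. "Nonsynonymous coding" is read broadly as
*protein-altering* (missense, stopgain, startloss, frameshift/truncating
indel), so that truncating germline BRCA variants are not discarded before
the germline stage — a literal missense-only reading would silently remove
the input of the HRD caller. And the legacy symbol SFRS2 is canonicalised
to SRSF2 on input, so the P95 hotspot matches under either name.

A patient is CH-positive if at least one somatic call in a CH-panel gene
has VAF ≥ 1% (inclusive). The packaged CH and HR gene lists are editable
stand-ins for panel-specific lists and are arguments everywhere they are
used.

## cfDNA origin attribution

cfDNA is a mixture of hematopoietic and tumor-derived fragments. A variant
enters the paired analysis when detected at ≥ 0.8% VAF in either source,
or in both sources with VAF sum ≥ 0.8%. Origin is attributed by fold
change: a cfDNA VAF at least 5-fold the WB VAF is non-hematopoietic
(tumor-shed). When WB is undetected the 0.1% floor is substituted for zero
— this avoids a division by zero and deliberately errs toward the
hematopoietic call, since an undetected WB variant may simply be below
depth. The 5-fold boundary is implemented inclusively; the source wording
("5-fold higher") does not resolve strict versus inclusive, and the choice
is documented rather than guessed as intent.

Serial retention (detected at ≥ 2 timepoints, ≥ 0.8% somewhere) is applied
per DNA source and then unioned per variant. For retained variants,
undetected timepoints are manually-reviewed in spirit: timepoints with any
supporting reads below the calling threshold are set to the 0.1% floor
(`rescued`), and timepoints with zero supporting reads get the same floor
but are flagged `censored` so fitness estimates using them are marked.
Tumor-mutation dynamics between two timepoints are categorised by an
inclusive 10-fold rule (increase, decrease, or stable).

`attribute_cfdna()` attributes origin at the earliest timepoint with any
detection in either source. Baseline is the least treatment-perturbed
sample; attributing per-timepoint instead would let therapy-induced tumor
response flip a variant's origin label mid-series.

## Germline HRD calling

Calls at germline-range VAF (> 40%) in BRCA1/2 are pathogenic if any
curated source (ClinVar, ENIGMA, expert review — pre-annotated columns,
never live queries) classes them pathogenic or likely pathogenic, or if
they are deleterious (splice, truncating indel, stopgain, startloss) with
population allele frequency below 1%. Other HR-pathway genes use only the
deleterious-and-rare arm. A missing population frequency is treated as
rare and flagged: absence from gnomAD nearly always means very rare, and
the flag keeps the assumption auditable. A patient is germline-HRD
positive with at least one pathogenic call.

## Single-cell clonal architecture

Genotype matrices (cells × variants; 0/1/2/NA) are analysed with an
assumption-light pipeline. A sample passes QC with ≥ 400 cells genotyped
at one or more somatic targets. Clones are exact genotype-vector groups
over the somatic targets; cells missing any target genotype are left
unassigned rather than imputed, because imputation would manufacture
exactly the co-occurrence signal the analysis is after. Mutant groups need
≥ 5 cells to be reported; the all-wild-type group is C0; homozygous-mutant
genotypes flag loss of heterozygosity. Pooled samples are demultiplexed by
germline SNP profile, assigning each cell to the best-concordant profile
and dropping cells below 0.9 concordance or with a top-two margin under
0.1 (the signature of an inter-sample doublet); both thresholds are this
package's choices.

Mutual exclusivity of two mutations is formalised as a one-sided exact
binomial test of the observed double-mutant cell fraction against the
doublet-driven background $2\,d\,f_a f_b$, where $d$ is the doublet rate
and $f_a, f_b$ the mutant-cell fractions. Using the observed (slightly
doublet-inflated) fractions in the background makes the test mildly
conservative, which is the right direction for an exclusivity claim: at
$\alpha = 0.05$, simulated truly-exclusive pairs across doublet rates
0–10% are falsely called co-occurring in ≤ 2–3% of replicates, while
nested subclones are detected essentially always.

## The synthetic cohort generator

Because no patient-level data ship with the package, `simulate_cohort()`
generates cohorts with known ground truth that emulate the study design
the analysis targets: ~100 patients sampled at 0, 0.5 and 1.0 years
(treatment start, maintenance start, end of treatment — the two phases'
median durations are each roughly half a year); CH clones with
gene-weighted prevalence (PPM1D most frequent) and per-phase fitness
priors encoding strong carboplatin-phase selection of TP53/PPM1D clones
(means 1.90 and 1.93/year), attenuated PPM1D fitness under maintenance
(0.36/year) and near-neutral DNMT3A/TET2 clones; germline variants at true
VAF 0.5 (common SNPs and rare pathogenic HR variants in ~30% of patients);
tumor-shed cfDNA-only variants in TP53/HR genes in half of patients; and
synonymous artifact calls for the retention filter to remove. Sequencing
noise is binomial on consensus reads at Poisson-distributed depth (means
2000× WB, 1000× cfDNA) — the generator's assumption, since error-corrected
pipelines do not publish a noise model; binomial noise on consensus reads
is the natural minimal model. Single-cell matrices add per-allele dropout
(default 10%) and doublets (default 8%), typical of droplet single-cell
DNA platforms.

What the generator does **not** emulate: sequencing error hotspots and
context-dependent artifacts, index hopping, copy-number change under
treatment (so no LOH-driven VAF > 50% trajectories in bulk data),
clone-clone interference, and correlated WB/cfDNA sampling noise. Passing
recovery tests on this generator therefore demonstrates correctness of the
estimators under the stated noise model, not robustness to every artifact
of real data.

Validation problem sizes (chosen to give stable rates at interactive run
times): 1000-triple inversion grids, 500 replicates per fitness level for
stochastic recovery, 300-patient cohorts for origin-attribution rates, and
200 replicates per doublet-rate setting for exclusivity calibration.

## Known limitations

* Fitness is a two-point closed form; it uses no read-count uncertainty,
  so downstream comparisons should weight or filter censored estimates.
* The origin rule is a fold-change heuristic; it cannot separate a large
  CH clone shed into plasma from tumor shedding when both are plausible.
* Exact-vector clone grouping fragments clones under heavy allele dropout;
  the unassigned fraction is reported so users can see how much signal was
  set aside.
* The packaged gene lists are generic stand-ins; analyses of real panels
  should supply the panel's own CH and HR lists.
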