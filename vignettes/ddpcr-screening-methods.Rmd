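---
title: "Methods: simulating and analysing duplex ddPCR mutation screening"
author: "ddscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing duplex ddPCR mutation screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddscreen)
```

## The problem

Urothelial bladder cancer sheds tumour DNA into urine. Two recurrent
non-coding substitutions in the *GPR126* (*ADGRG6*) sixth-intron
enhancer — chr6:142,706,206 G>A and chr6:142,706,209 C>T (GRCh37) —
together with *TERT* promoter mutations cover a large fraction of
tumours, so a droplet digital PCR (ddPCR) panel on urinary
cell-free DNA can detect the disease non-invasively. `ddscreen`
models the complete analysis chain of such a panel: the multiplex
screening assay itself, droplet-level data, Poisson quantification to
a mutant allele fraction (MAF), false-positive cutoff calibration on
known-negative samples, and cohort-level diagnostic evaluation.

## The screening assay model

A *screening* assay multiplexes one HEX-labelled wild-type probe with
several FAM-labelled mutant probes (one per mutant genotype: G/A,
C/T, and both) behind a single primer pair. Any mutation lights the
FAM channel, so one well detects all covered genotypes but cannot
tell them apart. `gpr126_assay()` carries the printed oligo set;
`discrimination_matrix()` verifies in silico that every probe is a
perfect match to exactly one genotype template and carries 1–2
mismatches against every other, which is the basis of TaqMan
genotype discrimination:

```{r}
discrimination_matrix(gpr126_assay())
```

Probes are stored 5'→3' on the sense strand (they hybridise to the
antisense strand), so genotype templates are built by direct
substitution into the wild-type probe-region sequence and compared by
plain string matching — no double reverse-complementing. Printed
sequences are whitespace-stripped on load; coordinates are 1-based
GRCh37 throughout.

`to_single_target_assay()` implements the screening-to-standard
conversion: keep one mutant probe and triple its concentration
(0.083 µM → 0.249 µM), leaving primers and the wild-type probe
untouched. `validate_assay()` checks that the summed FAM
concentration balances the HEX concentration to within 0.005 µM
(3 × 0.083 = 0.249 vs 0.25: the design intends equality at pipetting
precision) and, given a sense-strand reference fragment, locates both
primers and measures the amplicon (121 bp).

The repository ships a *synthetic* scaffold
(`inst/extdata/gpr126_region_synthetic.fa`) spanning the
chr6:142,705,865–142,706,619 coordinates: the printed primer and
probe sequences are embedded at the assay's true geometry and the
remaining bases are seeded random filler. It exercises primer
placement and amplicon arithmetic; it is **not** the genomic
reference sequence, so it cannot detect a primer that mismatches the
real genome.

## The droplet simulator

A well partitions template molecules into ~20,000 ≈0.85 nL droplets.
`partition_templates()` assigns each molecule independently and
uniformly to a droplet (multinomial), so per-genotype totals are
conserved *exactly* — a deliberate choice over per-droplet Poisson
draws because conservation makes truth-based tests sharp, while
Poisson occupancy still emerges in the limit (the occupied fraction
at 2000 copies in 20,000 droplets is 1 − e^−0.1 to within binomial
noise).

**False positives.** Wild-type-only urine DNA occasionally yields
mutant-channel-positive droplets. We model this with a per-molecule
misread: each WT molecule is flagged with probability ε (default
0.003), and a flagged molecule renders its droplet FAM-positive.
Because misreads are per molecule, the false-positive *copy number*
grows proportionally with DNA input while the false-positive *MAF*
stays near ε regardless of input — exactly the empirical signature
that motivates setting the blank cutoff on MAF rather than on
absolute concentration. The default ε = 0.003 places the simulated
control-group false-positive MAF at a median of ~0.3 %, the observed
scale in real control urine.

**Amplitudes.** Endpoint fluorescence per channel is two Gaussian
clusters (negative mean 1000, SD 150; positive mean 8000, SD 400,
arbitrary units) plus a small "rain" fraction (0.002) of positive
droplets drawn uniformly between the cluster means. These values
only shape the scatter geometry; classification tests use the same
separation with rain disabled so truth recovery is exact.

**Cohorts.** `cohort_config()` defaults encode the study design: 50
healthy volunteers, 22 cystitis patients and 70 UBC patients, two
markers per sample, total cell-free DNA input log-uniform over
200–20,000 copies/well (two orders of magnitude). Controls and
cystitis samples carry zero true mutant copies. UBC samples receive a
joint positivity category with probabilities 18/70 (both markers),
7/70 (*GPR126* only) and 22/70 (*TERT* only) — marginals 25/70 and
40/70, union 47/70. A positive sample's MAF is drawn from a
log-normal truncated to (0, 100] %, fitted numerically so that the
*truncated* distribution reproduces the printed median and quartiles
(GPR126 21.61 [8.30–44.52] %; TERT 28.29 [19.03–38.08] %); fitting
the untruncated quantiles and then truncating would shift the median
down by ~15 %. The drawn MAF partitions the sample's *total* input
into mutant and wild-type copies, which keeps the template load
inside the droplet dynamic range at any MAF. *GPR126*-positive
samples draw their genotype at the reported population mix
(M1 : M2 : M1M2 ≈ 0.57 : 0.26 : 0.17); the commercial *TERT* assay
is modelled abstractly as a second two-channel assay.

## Quantification

`classify_droplets()` thresholds each channel independently
(quadrant gating — sufficient for this four-cluster geometry; no
general multi-cluster gating is attempted). The automatic threshold
estimates the negative mode in two stages: the lower half of the
amplitudes yields a provisional median/MAD that is guaranteed to sit
inside the negative cluster even when most droplets are positive;
droplets within ten provisional spreads then define the negative
cluster whose median + 6 MAD is the threshold. The single-stage
lower-half estimate underestimates both centre and spread of a
Gaussian negative cluster and admits its upper tail; the refinement
removes that bias. The rule degrades once a channel exceeds roughly
85 % positivity — wells loaded beyond the Poisson dynamic range
should be diluted, as in real practice. Degenerate (zero-spread)
channels and wells under 100 droplets are errors, not guesses.

`poisson_concentration()` inverts counts through
λ = −ln(1 − p), concentration = λ / 0.00085 µL; the 95 % interval is
the delta-method normal interval on λ, adequate at N ≈ 20,000 (exact
ratio intervals would change nothing at this scale). A fully
positive well is a saturation error. Double-positive droplets count
toward *both* channels' positive totals, the standard duplex
convention. The MAF is

MAF = 100 · C_mut / (C_wt + C_mut) %

and a well with no template on either channel is flagged rather than
given a MAF.

## Cutoff calibration

`determine_cutoff()` implements the limit-of-blank rule at the
maximal-sensitivity operating point constrained to 100 % specificity:
the cutoff is the ROC midpoint between the largest control MAF and
the smallest case MAF above it, falling back to control_max + δ
(δ = 0.05 percentage points) when cases are absent or do not bracket
the control maximum. The exact coordinate convention that produced
the published 1.79 % → 1.85 % pair is not recoverable from the
printed values, so δ is a declared convention, not a reproduction.
`apply_cutoff()` subtracts the cutoff from every sample's raw MAF
(clipped at zero); a positive remainder is a mutation call. By
construction the calibration controls are all called negative —
specificity on *those* controls is exactly 100 % — while samples
outside the calibration set carry no such guarantee, which is the
honest property of the procedure. The cutoff is set on MAF, never on
absolute copies, per the input-correlation argument above. By
default only the healthy volunteers calibrate the cutoff; cystitis
samples are held out as a disease control (configurable).

Replicate variability is summarised as the sample SD (n−1) in
percent of the mean (`replicate_cv()`). In simulation, false-positive
MAFs vary far more across replicates than true MAFs at matched input
— the randomness signature that identifies them as artefacts. The
real-data contrast (31.4 vs 8.2 median CV) includes extraction and
pipetting noise that the simulator does not model, so this check is
reproduced qualitatively (direction and significance), not
numerically.

## Diagnostic evaluation

`roc_auc()` computes the tie-aware AUC
(#{case > control} + ½·#{case = control}) / (n₁n₀) via average
ranks, identical to the Mann–Whitney U normalisation (a brute-force
pairwise oracle and pROC agree in the tests). Scores are
*corrected* MAFs, so every calibrated control ties at exactly zero
and AUC reduces to (1 + sensitivity)/2 — which is why the published
AUC triple (0.679, 0.786, 0.836) follows deterministically from the
detection counts 25/70, 40/70 and 47/70 against 72 controls, and why
the check is insensitive to whether 50 or 72 controls were used. The
panel call is the OR across markers (union sensitivity can only
grow; specificity cannot improve under OR). Dual-positive samples
get a paired Wilcoxon comparison of the two markers' MAFs. The
nonparametric battery (Mann–Whitney, Wilcoxon signed-rank with zero
dropping and tie-corrected normal fallback, Spearman with
t-approximation, Fisher's exact, OLS R² for spike-in linearity)
delegates to base R's implementations behind a uniform result type;
no multiple-testing correction is applied, matching the original
analysis. Exact p-values are used for small untied samples
(signed-rank n ≤ 25; U test min(n) ≤ 8).

## Problem sizes and reproducibility

Every stochastic function is a pure function of an explicit seed;
cohort wells get seeds derived from the cohort seed, so whole
cohorts are byte-reproducible. The shipped analyses use the study's
own sizes — 142 samples × 2 markers at 20,000 droplets/well —
which simulate in seconds; the test suite uses the same well size
with smaller cohorts where only structure is under test, 50 seeds
for MAF-recovery properties, and 20 seeds for the replicate-CV
contrast.

## Known limitations

* The simulator omits PCR efficiency/kinetics, droplet volume
  variation, extraction/pipetting noise and plate effects; passing
  tests demonstrate correctness of the analysis chain on data
  matching the stated generative model, not instrument realism.
* The amplicon-length check runs against a synthetic scaffold (see
  above), so it validates geometry, not genomic primer specificity.
* Quadrant thresholding assumes the four-cluster duplex geometry and
  a minority-positive (or at most ~85 % positive) channel.
* The cohort generator draws marker positivity per sample from the
  published joint rates; it does not model tumour stage, grade, size
  or macrohematuria covariates.
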