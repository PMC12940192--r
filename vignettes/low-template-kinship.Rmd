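---
title: "Binary consensus and continuous peak-height models for low-template kinship testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary consensus and continuous peak-height models for low-template kinship testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strkin)
```

## Scope

`strkin` compares two ways of computing a paternity likelihood ratio (LR)
from low-template, degraded STR electropherograms: a binary consensus
workflow (replicate agreement, calibrated drop-out probabilities, discrete
genotype likelihoods) and a continuous probabilistic-genotyping workflow
(gamma peak-height likelihoods maximised over amplification parameters).
Because real casework electropherograms of this kind are not
redistributable, the package ships a seeded simulator whose generative
model is exactly the continuous likelihood's data model; the study pipeline
then reproduces the comparison *directionally* on synthetic cohorts. This
vignette records the models, the tunable parameters, the numerical choices,
and what the synthetic results do and do not show.

## The continuous peak-height model

All stochastic structure is carried by a single parameter set per kit
(`continuous_params`):

| parameter | meaning | unit | default (MD / HD preset) |
|---|---|---|---|
| `mu` | expected height of one heterozygote allele at the 125 bp reference size | RFU | 1500 / 400 |
| `omega` | coefficient of variation of peak height | — | 0.30 / 0.45 |
| `beta` | degradation survival factor per +100 bp | — | 0.95 / 0.05 |
| `xi_b`, `xi_f` | backward / forward stutter proportion | — | 0.06 / 0.01 |
| `lambda` | drop-in height decay rate above the threshold | RFU⁻¹ | 0.038 (ESI-like kit), 0.061 (ESX-like kit) |
| `p_c` | per-locus per-replicate drop-in probability | — | 0.05 |
| `at` | analytical threshold | RFU | 50 |

The contribution weight at allele position $a$ for a genotype with copy
numbers $n_g$ is

$$w_a = \sum_g \left[(1-\xi_B-\xi_F)\,n_g\,1(a{=}g) + \xi_B\,n_g\,1(a{=}g{-}1)
 + \xi_F\,n_g\,1(a{=}g{+}1)\right]\beta^{(s_a-125)/100},$$

and an observed height at a contributing position is
$\mathrm{Gamma}(w_a/\omega^2,\; \mu\omega^2)$ (shape/scale), so a single
clean heterozygote allele at 125 bp has mean $\mu$ and CV $\omega$. Stutter
*moves* expected mass (it is not additive noise), one repeat in either
direction only. Drop-out is censoring: a contributing position with no peak
contributes the gamma CDF at the threshold. A peak at a position with
$w_a = 0$ is a drop-in with likelihood
$p_C\,p_a\,\lambda e^{-\lambda(h-AT)}$, and a locus-replicate with no
drop-in contributes $1 - p_C$. Replicates — and kits — are conditionally
independent given the genotype, which is shared across all of them.

The degradation anchor at 125 bp with a per-100 bp exponent makes `beta`
comparable across kits whose loci sit at different sizes; the simulator and
the likelihood share the same anchor, so the model pair is self-consistent
(this is tested by parameter-recovery and likelihood-ranking tests).

### Hypotheses and the LR

The genotype prior under *parent–child* copies one allele from the typed
reference person (probability ½ each) and draws the other from the
Balding–Nichols urn conditioned on the reference's two alleles; under
*unrelated* both alleles come from the urn. The urn probability for an
allele with population frequency $p_a$, after $n$ alleles with $m$ copies
of $a$ have been sampled, is $(m\theta + (1-\theta)p_a)/(1+(n-1)\theta)$,
with $\theta = 0.01$ by default. `fit_mle` maximises the marginal
likelihood over $(\mu, \omega, \beta, \xi_B, \xi_F)$ per kit — multi-start
Nelder–Mead on transformed parameters ($\log\mu$, $\log\omega$, logit-type
maps keeping $\beta \in (0,1)$ and each stutter proportion below 0.5) —
while $\lambda$, $p_C$ and the threshold stay fixed, as in standard
continuous-model practice where drop-in is calibrated from validation data
(`fit_dropin_lambda` provides the closed-form exponential MLE
$\hat\lambda = 1/\overline{h - AT}$).

`select_model_and_lr` fits all eight on/off combinations of {degradation,
backward stutter, forward stutter} under both propositions and picks the
combination maximising the summed *adjusted log-likelihoods*, defined here
as log-likelihood minus the number of free parameters. The adjustment rule
is isolated in one place so an AIC/2-style alternative is a one-line
change. The LR is evaluated at the respective MLEs; the multi-kit mode
estimates peak-height parameters per kit with a shared genotype and can
carry over the flag combination selected with the single-kit data, which is
how the study pipeline uses it.

### Numerical choices

* **Starts.** The first optimizer start uses moment-based values (mean
  observed height for $\mu$, $\omega = 0.4$, $\beta = 0.85$); further
  starts jitter deterministically from the supplied seed. The default is 3
  starts; the single-source marginal likelihood is smooth and unimodal in
  practice, and during the eight-combination search a single start is used
  per combination with a full multi-start polish of the winner. Multi-kit
  fits additionally start from the single-kit estimates when those are
  supplied (`init_hp`/`init_hd`); with one replicate per kit the
  five-parameter fit is weakly identified and a poor start can otherwise
  settle on absurd stutter proportions.
* **Convergence.** Nelder–Mead with relative tolerance 1e-6 during the
  search and 1e-7 for the final fits; parameter transforms remove the need
  for constrained optimisation.
* **Degenerate inputs.** Loci with an untyped reference and no peaks are
  skipped (they carry no information and leave the LR unchanged); an
  observed allele missing from the frequency table receives the rare-allele
  floor ($5/(2n)$ when the table's sample size is known, otherwise 0.001)
  and the locus is renormalised.
* **Ties.** If two flag combinations tie on the adjusted log-likelihood the
  first in the fixed enumeration order wins, which keeps reruns identical.

### Model validation

`validate_model` computes, for every observed peak, its cumulative
probability under the fitted genotype-marginalised model (truncated gamma
at contributing positions, exponential drop-in otherwise, weighted by the
per-locus genotype posterior). Under a correct model these are uniform and
the sorted values track the diagonal of a probability–probability plot.
Loci are flagged when a peak deviates from the diagonal by more than 0.2
*or* when its model probability is more extreme than 1e-4 — the latter
catches the characteristic signature of an unmodelled parent–child
mutation, where a tall peak can only be explained through the drop-in tail
and its probability pins to 1 within machine precision while remaining
close to the diagonal vertically. The continuous model deliberately has no
mutation channel; the validation plot, not a patch to the likelihood, is
the instrument for spotting such loci. Two blind spots are documented by
the tests: a mutant allele one repeat from a true allele can hide in the
stutter channel, and a mismatch at a homozygous locus surfaces as a
*drop-out* of an expected allele, which a peak-based plot cannot display.

## The binary consensus arm

The 2× consensus keeps, per locus, the intersection of the two replicates'
allele sets: empty → locus excluded (no LR factor); two alleles → full
genotype, no drop-out; one allele → drop-out probability from a logistic
regression on log10 peak height, evaluated at the highest shared peak when
both replicates are otherwise clean, at the clean replicate's peak when
exactly one replicate shows extra alleles, and at the lowest shared peak
when both do. The asymmetry between the "highest" and "lowest" rules is
implemented as specified by the consensus protocol it reproduces; no
rationale is offered there and none is invented here. More than two
reproducible alleles violates the single-source assumption and is an error
by default; the study pipeline converts it to a locus exclusion, and—
because reproducible stutter would otherwise trigger it constantly on
mildly degraded profiles — applies a GeneMapper-style 15% ratio stutter
filter (`filter_stutter`) to the binary arm's replicates only. The
continuous arm always sees unfiltered peaks, since it models stutter.

The observation model treats the two allele copies as dropping
independently: a single-allele consensus $A$ has probability $1-d^2$ under
$A/A$ and $(1-d)d$ under $A/X$; there is no drop-in channel. The pedigree
likelihood enumerates the unknown founder genotypes exactly, with founder
alleles drawn sequentially from the Balding–Nichols urn conditioned on all
alleles already sampled in the pedigree (the urn is exchangeable, so the
order is immaterial), the equal-probability mutation model on every
parent–child transmission with sex-specific rates (default 0.2% where no
per-locus rate is supplied), and the alternative father under the defence
proposition as an unrelated founder. Untyped mothers in duo cases are
marginalised analytically through the urn's exchangeability. Reference
genotypes are treated as error-free; only the low-template profile is
contested.

### Drop-out calibration and degradation classification

`generate_calibration_set` simulates heterozygous single-locus
amplifications and pairs each allele's detection outcome with its partner
peak's height; `fit_dropout_logistic` fits
$\mathrm{logit}\,P(\text{drop-out}) = b_0 + b_1\log_{10}h$. The study
pipeline calibrates on a five-level dilution series (¼× to 4× of the
highly-degraded template amount, moderate degradation), the standard
internal-validation design; calibrating at a single template amount gives a
much shallower curve whose 5% point sits unrealistically low.

The 5% stochastic threshold (5ST) is the largest fragment size among
observed peaks whose predicted drop-out is below 5%; profiles with
5ST < 200 bp are called highly degraded (HD), otherwise mildly degraded
(MD). Peaks are pooled across replicates by default (a per-replicate mode
that takes the weaker replicate is available). The rule is deliberately
interpolation-free: only observed peaks qualify.

## The simulator and the study pipeline

`generate_case` draws a pedigree (founders through the urn, child by
Mendelian transmission; mutation injection only as an explicit option),
picks the duplicate kit at random, and simulates two replicates with that
kit plus one with the complementary kit — the replicate scheme the whole
package assumes. Case-level RNG substreams are derived by counter, so
cohorts are order-independent and byte-reproducible. The two bundled demo
kits cover the same 16 autosomal loci with reversed size layouts, so loci
that amplify long in one kit amplify short in the other; that
anti-correlation is what makes the multi-kit mode recover loci that
degradation erases in a single kit.

The class presets are stand-ins — the casework this emulates published no
peak-height parameters — chosen so the 5ST classifier reproduces the class
labels: the MD preset (μ=1500, ω=0.30, β=0.95) yields essentially complete
profiles, while the HD preset (μ=400, ω=0.45, β=0.05) pushes amplicons
beyond roughly 200 bp below the threshold. The HD slope is the parameter
that matters: gentler slopes (β ≥ 0.3 per 100 bp) leave 300 bp amplicons at
appreciable heights, and a faithful 5ST implementation then (correctly)
refuses to call such profiles highly degraded. Cohort composition defaults
mirror the emulated study: 21/33 trios, 20/33 HD, with the low-template
person being the alleged father (identification of remains, with the child
as the low-template person, is available via `case_kind`).

`run_study` runs, per case: the binary duo LR (plus the trio view when a
mother exists), the single-kit continuous LR on the duplicate pair with
full model selection, and the multi-kit continuous LR on one replicate per
kit with the selected flags carried over. Informative loci are counted
under each method's own rule — consensus loci with at least one allele for
the binary arm, loci with at least one above-threshold peak in any
replicate for the continuous arms. Summaries report, per degradation ×
pedigree stratum and method: median log10 LR, the proportion of LRs at or
above the 10,000 court-acceptance threshold, informative-locus means ± SD,
the share of cases where each method attains the highest LR, and the
maximum cross-method spread rounded half-up to whole orders of magnitude
(ΔLR max). Paired Wilcoxon signed-rank tests use exact sign-pattern
enumeration for n ≤ 12 (valid under ties, which arise naturally in paired
log-LRs), the exact signed-rank distribution up to n = 25 without ties, and
the continuity-corrected normal approximation beyond; log10 LRs are clipped
at ±300 so degenerate likelihood ratios cannot poison the summaries (the
clip is recorded per case).

Default problem sizes — 60-case cohorts, 2,000 calibration amplifications
per kit, 200-locus recovery panels — are chosen so a full comparison runs
in minutes on a single core while keeping every directional contrast
well-resolved; all are arguments, not constants.

## What passing tests show — and what they do not

The synthetic cohort reproduces the *directions* reported for casework of
this type: multi-kit continuous LRs dominate in highly degraded duos, the
binary arm with maternal information leads in mildly degraded trios, the
consensus rule discards far more loci than the continuous methods on
degraded samples, and informative-locus counts correlate positively with
LR. None of the synthetic magnitudes are comparable to casework values:
the generator draws peak heights independently given the template
parameters, whereas real electropherograms show within-profile correlation
(shared template quantity and injection), real degradation curves are not
exactly exponential, stutter ratios vary by locus and allele length, and
real validation data drive the drop-out curve. Mixtures, more than two
replicates per kit in the consensus, mutation inside the continuous model,
and conservative (sensitivity-interval) LRs are all out of scope.

## Known limitations

* The binary arm's homozygote drop-out convention is $d^2$ (independent
  copies); software packages differ here, and the convention is isolated in
  `obs_prob` so an alternative is a one-line change.
* The equal-probability mutation model uses the number of frequency-table
  alleles at the locus as the target count; silent alleles and linked
  markers are not modelled.
* The PP-plot outlier rule is peak-based and cannot display missing-peak
  evidence (see above).
* Whether theta enters both the relatedness prior and the founder
  frequencies is configurable because published practice is ambiguous; the
  default applies it in both places.
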