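# strkin

Kinship likelihood ratios for low-template, degraded STR profiles.

## The problem

Paternity testing on challenging samples — old bones, formalin-fixed
tissue, traces left on personal items — has to cope with stochastic PCR
artefacts: allelic **drop-out** (a true allele falls below the analytical
threshold), **drop-in** (a spurious allele appears), **stutter** (a slippage
peak one repeat unit away from a true allele) and exponential **degradation**
(large amplicons amplify poorly). Two interpretation philosophies coexist in
forensic practice:

* the **binary consensus** workflow: replicate amplifications are reduced to
  a 2× consensus profile (an allele counts only when seen in both
  replicates), a logistic regression calibrated on validation data assigns a
  drop-out probability to single-allele loci, and the paternity likelihood
  ratio is computed from allele frequencies with a coancestry (theta)
  correction and an equal-probability mutation model — duo (child only) or
  trio (child + mother) pedigrees;
* the **continuous probabilistic-genotyping** workflow: peak heights
  themselves are modelled. Heights follow a gamma distribution whose
  expectation scales with the contribution weight
  `w_a = Σ_g [(1−ξ_B−ξ_F)·n_g·1(a=g) + ξ_B·n_g·1(a=g−1) + ξ_F·n_g·1(a=g+1)]
  · β^((s_a−125)/100)`,
  drop-out is censoring at the analytical threshold, drop-in peaks decay
  exponentially above it, and the likelihood is maximised over
  `(μ, ω, β, ξ_B, ξ_F)` jointly across replicates — and across two STR kits
  with complementary amplicon layouts — under the competing propositions
  *parent–child* vs *unrelated*. The reported LR is the ratio of the
  maximised likelihoods at the model (degradation/stutter on–off)
  combination with the best adjusted log-likelihood.

`strkin` implements both arms end to end, plus a seeded electropherogram
simulator with exactly the generative structure the continuous model
assumes, and a study pipeline that compares the methods on simulated
casework cohorts (duo/trio × mildly/highly degraded), with
stochastic-threshold (5ST) degradation classification, informative-locus
counting, threshold proportions, ΔLR-max summaries, Wilcoxon signed-rank
and Pearson tests, and probability–probability plot model validation.

## Worked example

```r
library(strkin)

kits  <- demo_kits()            # two synthetic 16-locus panels, AT = 50 RFU
freqs <- demo_frequencies()
pop   <- population_model(theta = 0.01)

# one simulated mildly-degraded trio case: the low-template person is the
# alleged father; 2 replicates with one kit + 1 with the other
sim  <- simulation_config(seed = 5)
case <- generate_case(sim, case_index = 2)

# binary arm: stutter filter, 2x consensus, drop-out calibration, LR
dms  <- calibrate_study_dropout(study_config(seed = 5))
reps <- lapply(case$replicates[1:2], filter_stutter)
cons <- build_consensus(reps[[1]], reps[[2]], dms[[case$dup_kit]])
paternity_lr(cons, case$references, binary_hypothesis("father", "trio"),
             freqs, pop)
#> Binary trio LR (LT-DNA father): log10 LR = 9.695 over 16 loci

# continuous arm, single kit ("EFM mode"): 8 model combinations, adjusted
# log-likelihood selection
efm <- select_model_and_lr(case$replicates[1:2], case$references$child,
                           kits, freqs, pop,
                           lambda_by_kit = c(ESI = 0.038, ESX = 0.061))
efm
#> Continuous LR: log10 LR = 7.545 (deg=FALSE, xiB=TRUE, xiF=TRUE)

# multi-kit mode ("EFMrep mode"): one replicate per kit, flags carried over
select_model_and_lr(list(case$replicates[[1]], case$replicates[[3]]),
                    case$references$child, kits, freqs, pop,
                    lambda_by_kit = c(ESI = 0.038, ESX = 0.061),
                    fixed_flags = efm$flags)
#> Continuous LR: log10 LR = 7.71 (deg=FALSE, xiB=TRUE, xiF=TRUE)
```

A log10 LR near 7.5 means the peak data are about 30 million times more
likely if the low-template sample comes from the child's father than from
an unrelated man — far above the 10,000 court-acceptance threshold the
study pipeline uses. On this mildly degraded trio the binary arm with the
maternal genotype leads (the continuous model ignores the mother); on
highly degraded cases the consensus arm discards most loci and the
multi-kit continuous LR is typically the largest — exactly the contrasts
`run_study()` quantifies:

```r
st <- run_study(study_config(n_cases = 60, seed = 1))
st$summary$table      # per stratum x method: median log10 LR,
                      # proportion >= 10,000, informative loci, best-method share
render_report(st, "report")   # TSV/JSON tables + box/density/lollipop figures
```

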