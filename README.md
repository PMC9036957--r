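# frocdwi

Fractional-order-calculus (FROC) diffusion MRI modelling and the
diagnostic statistics used to evaluate diffusion parameters as imaging
biomarkers.

## The problem

Routine diffusion-weighted MRI summarises water mobility in a lesion with
a single apparent diffusion coefficient from the Gaussian model
S(b) = S₀·exp(−b·ADC).  Over an extended b-value range (here 0–2000
s/mm²) tumour tissue decays non-mono-exponentially, and the FROC
generalisation

S(b) = S₀·exp[ −D·μ^(2(β−1))·(γG_dδ)^(2β)·(Δ − ((2β−1)/(2β+1))·δ) ]

adds an intravoxel heterogeneity exponent β ∈ (0, 1] (β = 1 recovers
Gaussian diffusion; lower β = more heterogeneous tissue) and a spatial
scale μ (µm) alongside the anomalous diffusion coefficient D.  The
gradient amplitude G_d is eliminated through the Stejskal–Tanner relation
b = (γG_dδ)²(Δ − δ/3), so only the b-values and pulse timing (δ, Δ) are
needed.

The package is aimed at researchers who want to (a) fit ADC and the FROC
parameters voxelwise on multi-b-value DWI (NIfTI + bval sidecar), (b)
summarise them over lesion VOIs, and (c) run the full biomarker
statistics on a cohort table: Mann–Whitney group comparisons with
Bonferroni correction, ROC analysis with Youden-index cutoffs and
Hanley–McNeil confidence intervals, logistic combinations of parameters
(D+β, D+μ, β+μ, D+β+μ), correlated-AUC (Hanley–McNeil) and McNemar
comparisons against ADC.  A synthetic cohort/phantom generator with
Rician noise — presets emulating a 60-patient cervical carcinoma cohort
(47 SCC / 13 ACA; 28 low-grade / 32 high-grade) — makes every stage
testable without patient data.

## Worked example

```r
library(frocdwi)

sc <- cervicalProtocol()               # b = 0...2000 s/mm^2, delta 20 ms, Delta 40 ms
round(frocSignal(frocParams(1000, 0.77, 0.67, 8.19), sc), 1)
#> [1] 1000.0  951.7  924.3  882.3  819.3  793.4  652.1  506.5  338.8
```

A signal with S₀ = 1000 and tissue-like parameters loses half its
intensity by b = 1000 and decays visibly slower than exponentially at
high b.  Fitting a noisy realisation (SNR 50) recovers the parameters:

```r
fitFroc(ricianNoise(frocSignal(frocParams(1000, 0.74, 0.68, 8.26), sc),
                    sigma = 20, seed = 3), sc)
#> FrocFit: S0 = 979.1, D = 0.6899 x1e-3 mm^2/s, beta = 0.7393, mu = 7.999 um
#>   rss = 1348, converged = TRUE, iterations = 8, stage D = 0.9634
```

β and the overall decay scale are well determined; with a single-timing
acquisition D and μ are only jointly identified (see the methods
vignette), so μ sits near its 8 µm anchor and `stageD` records the
(biased) low-b slope separately.

A full synthetic study at the published cohort sizes:

```r
res <- runSimulationStudy(pipelineConfig("grade", seed = 7))
res$comparisons[, c("parameter", "p_raw", "p_bonferroni")]
#>   parameter   p_raw p_bonferroni
#> 1  mean_adc 0.05788       0.2315
#> 2 mean_beta 0.00612       0.0245
#> 3    mean_d 0.12331       0.4933
#> 4   mean_mu 0.51442       1.0000

res$rocCombined[, c("predictor", "sensitivity", "specificity", "accuracy", "auc")]
#>   predictor sensitivity specificity accuracy   auc
#> 1       adc       0.844       0.429    0.650 0.643
#> 2    d+beta       0.656       0.786    0.717 0.751
#> 3      d+mu       0.719       0.571    0.650 0.616
#> 4   beta+mu       0.719       0.714    0.717 0.723
#> 5 d+beta+mu       0.500       0.929    0.700 0.760
```

With one sampled 60-subject cohort, β separates the grades after
Bonferroni correction (p = 0.025) while μ does not, and the combined
D+β+μ score outperforms ADC in AUC (0.760 vs 0.643);
`res$pairedVsAdc` holds the paired Hanley–McNeil and McNemar p-values of
each combination against ADC.  Single runs fluctuate with the sampling
seed, as a 60-subject study would.

Image-level work uses `makePhantom()` / `fitMap()` / `voiSummary()` /
`runImagePipeline()`, and everything is scriptable from a shell via
`inst/exec/frocdwi` (subcommands `simulate-cohort`, `make-phantom`,
`fit`, `summarize`, `analyze`, `run-all`).

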