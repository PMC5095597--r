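# cestr

Deciding which CEST-MRI quantification metric actually measures chemical
exchange — and which ones are contaminated by water relaxation.

Chemical exchange saturation transfer (CEST) MRI reports on labile protons
(amine/amide groups of proteins and metabolites) through the Z-spectrum, the
normalized water signal Z(ω) after off-resonance saturation. The effect of
interest — set by the labile-proton exchange rate (pH-dependent) and
concentration (protein-dependent) — is entangled with direct water
saturation, water T1/T2, and NOE transfer at negative offsets. `cestr`
implements a Bloch–McConnell multi-pool forward model (CW and pulsed
Gaussian-train saturation), the standard metrics

    MTRasym(ω) = (Z(−ω) − Z(ω))/Z0
    APT*(ω)    = (Zref(ω) − Z(ω))/Z0,  Zref = (Z(ω+δω) + Z(ω−δω))/2
    MTRRex(ω)  = 1/Z(ω) − 1/Zref(ω)
    AREX(ω)    = MTRRex(ω)/T1

plus CESTR*, a model-based effect obtained by fitting a three-pool
(water / amine +2.8 ppm / NOE −3.5 ppm) Bloch–McConnell model with Bayesian
priors and simulating the fitted CEST pool against a water-only reference —
in two variants, with generic ("default") or independently measured water
T1/T2 prior means. A synthetic 52-phantom study (two tissue-extract models;
serial variation of pH 6.0–7.6, BSA 4–16% w/v, T1 0.3–1.7 s, T2 29–140 ms)
provides ground truth, and the statistical layer — per-parameter
regressions, Holm–Šidák-corrected cross-model slope tests, the ideal-metric
model `effect = α·pH + β·[BSA] + ε` with its specificity R², and pairwise
ΔpH back-calculation — identifies the metric that is sensitive to pH and
protein only.

Inversion-recovery/spin-echo relaxometry fitting, Z-spectrum B0 correction,
CSV/YAML/NIfTI adapters and a deterministic end-to-end driver are included.

## Worked example

```r
library(cestr)

# one tumour-model phantom at pH 6.6, 8% BSA
sys  <- phantomSystem(ph = 6.6, bsa = 8, t1 = 1.7, t2 = 0.14, "tumour")
sch  <- saturationScheme()      # 300 Gaussian pulses, 26 ms, 180 deg, 50% duty
spec <- simulateZSpectrum(sys, sch)

mtrAsym(spec)                   # 9.83  (%M0 at 2.8 ppm)
aptStar(spec)                   # 9.62
mtrRex(spec)                    # 10.85
arex(mtrRex(spec), t1 = 1.7)    # 6.38  (%M0/s)

fit <- fitZSpectrum(spec, sch, measuredPriors(1.7, 0.14))
fit@kfProduct                   # 0.532 /s  (true rate x fraction: 0.523)
cestrStar(fit, sch)$value       # 11.99 (%M0, at standard relaxation)
```

`cestrStar` is larger than the direct metrics because it re-expresses the
fitted exchange effect against a clean water-only reference at standard
relaxation constants (1.8 s / 100 ms), free of the flanking-offset
spillover that depresses APT*. The fitted rate×fraction product agrees
with the generating truth to 2% on this noise-free spectrum.

The full study:

```r
report <- runFullStudy(seed = 1)     # ~2 min on one core
studySummary(report)$specificityR2
#> CESTRstar_measured   AREX   MTRRex  APTstar  CESTRstar_default  MTRasym
#>              0.868  0.796    0.763    0.758              0.750    0.695
```

CESTR* with measured T1/T2 priors ranks first: it is the only metric whose
T1- and T2-arm regressions are both non-significant while retaining strong
pH and protein sensitivity.

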