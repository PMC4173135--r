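# qepest

Quantitative estimates of pesticide-likeness for agrochemical library
triage. Instead of the hard pass/fail verdicts of classical descriptor
filters, `qepest` scores every molecule on a continuous 0–1 scale per
pesticide class — QEH (herbicide-), QEI (insecticide-), QEF
(fungicide-likeness) — and fuses them into the overall pesticide-likeness
scores QEPmax and QEPavg. It is aimed at cheminformaticians ranking large
compound libraries before more expensive virtual-screening steps.

## The model

For each class, the distribution of six descriptors — molecular weight
(MW), logP, hydrogen-bond acceptors (HBA) and donors (HBD), rotatable
bonds (RB) and aromatic rings (arR) — over a reference population is
fitted with a shared Gumbel-shaped peak

    f(x) = o + a · exp( −exp(−(x−b)/c) − (x−b)/c + 1 )

scaled by its analytic maximum `o + a` into a desirability `df(x) ∈ [0,1]`
with `df(b) = 1`. The class score is the unweighted geometric mean

    QEX = exp( (1/6) Σ ln df_i ),   QEX = 0 if any df_i ≤ 0

so a single unacceptable property zeroes the score. Continuous
descriptors are binned at the Shimazaki–Shinomoto optimal width before
fitting; integer descriptors use unit bins. The classical rule-based
comparators (Lipinski Ro5, Tice herbicide/insecticide, Hao pesticide)
are included, with inclusive bounds exactly as published.

## Worked example

```r
library(qepest)

profs <- default_profiles()   # packaged synthetic-reference calibration
desc  <- compute_descriptors(c(atrazine = "CCNc1nc(Cl)nc(NC(C)C)n1",
                               carbaryl = "CNC(=O)Oc1cccc2ccccc12",
                               caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C"))
desc
#>         id    MW   LogP HBA HBD RB arR arB
#> 1 atrazine 215.7  1.923   5   2  4   1   6
#> 2 carbaryl 201.2  2.949   3   1  2   2  11
#> 3 caffeine 194.2 -1.029   6   0  0   2  10

score_batch(desc, profs)
#>         id    QEH    QEI    QEF QEPmax QEPavg
#> 1 atrazine 0.3784 0.0479 0.2911 0.3784 0.2391
#> 2 carbaryl 0.2801 0.0597 0.5512 0.5512 0.2970
#> 3 caffeine 0.0114 0.0027 0.0006 0.0114 0.0049
```

The herbicide atrazine ranks highest on herbicide-likeness, the
carbamate carbaryl scores well as a pesticide, and caffeine — which
passes Lipinski and Hao with zero violations — is still ranked near
zero: the continuous scores retain information the binary filters
discard. Scores come from the packaged profiles, which are fitted on
the package's synthetic reference populations (see the vignette); fit
your own with `pesticide_profile()` and class-labelled descriptor data,
and exchange them as JSON via `write_profiles()` / `read_profiles()`.

A command-line interface wraps the same functions:

    qepest=$(Rscript -e 'cat(system.file("cli","qepest",package="qepest"))')
    Rscript $qepest score --input molecules.smi \
        --profiles profiles.json --out scores.csv
    Rscript $qepest filter --input scores.csv --out filters.csv --summary

Subcommands: `fit`, `score`, `filter`, `evaluate`, `synth`.

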