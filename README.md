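# CutpointScreen

Genome-wide discovery of prognostic expression biomarkers by **optimal
survival cutpoint selection**, for survival analysts and cancer
bioinformaticians working with cBioPortal-style z-scored expression
matrices and recurrence-free survival.

## The method

Declaring a gene "overexpressed" at a fixed threshold and then testing the
resulting groups hides a subjective choice inside every hazard ratio.
CutpointScreen instead selects, per gene, the cutoff that maximizes the
two-group log-rank separation, and corrects the p-value for that search.
For marker values \(x\) and survival data \((t_s,\delta_s)\):

- log-rank score of the above-cutoff group at candidate cutoff \(c\):
  \(S(c)=\sum_i \bigl(d_i^+ - d_i\,r_i^+/r_i\bigr)\) over distinct event
  times;
- selected cutoff \(c^*=\arg\max_c |S(c)|\) over midpoints between
  consecutive distinct values (with a per-side group floor);
- maximally selected rank statistic (Contal–O'Quigley standardization)
  \(Q=\max_c|S(c)|/(s\sqrt{D-1})\), with
  \(s^2=\frac{1}{D-1}\sum_{i=1}^{D}\bigl(1-\sum_{j=1}^{i}\frac{1}{D-j+1}\bigr)^2\)
  and \(D\) the event count;
- p-value from the supremum of the absolute Brownian bridge,
  \(p(Q)=2\sum_{j\ge 1}(-1)^{j+1}e^{-2j^2Q^2}\).

Genes are then filtered (cutpoint \(p<0.05\); cutoff z-score \(\ge 1\)
over-expression or \(\le -1\) under-expression) and partitioned into
shorter- vs longer-survival lists by the hazard direction of the banded
class. The package also ships a from-scratch survival core (Kaplan–Meier,
log-rank, Cox proportional hazards with Efron ties, Bonferroni
adjustment), H-score quantification of IHC intensity-category counts with
the highest-field rule, a hypergeometric overrepresentation + activation
z-score stand-in for pathway analysis, and a synthetic-cohort generator
with planted cutpoint effects for end-to-end validation.

## Worked example

```r
library(CutpointScreen)

cfg <- simulationConfig(nSamples = 300, nGenes = 100,
                        planted = list(plantedEffect(7, cutoffZ = 1, hr = 3)),
                        seed = 1)
cohort <- simulateCohort(cfg)      # a SurvCohort (SummarizedExperiment)
screen <- screenGenes(cohort)
screen
#> ScreenResult (optimal-cutpoint survival screen)
#>   analyzed 100 genes (0 skipped)
#>   associated with survival (p < 0.05): 4
#>   in cutoff z band (>= 1 or <= -1): 1
#>   shorter survival: 1, longer survival: 0
```

The planted gene is the one banded, shorter-survival hit. Its optimal
cutpoint sits at z ≈ 1.02 (truth: 1.0), with the search-corrected p-value
and the hazard ratio of the above- vs below-cutoff groups:

```r
bestCutpoint(SummarizedExperiment::assay(cohort)["G0007", ],
             survTime(cohort), survEvent(cohort), gene = "G0007")
#> CutpointResult [G0007]: cutoff = 1.0151 (Q = 1.881, p = 0.00168)
#>   HR (high vs low) = 3.833 [2.539, 5.785], high_worse; n = 47/253
```

`geneReport()` produces the single-gene figure/table material: KM curves
for both groups, the unadjusted Cox fit, the covariate-adjusted fit with
a Bonferroni column, and mean time to recurrence per group:

```r
rep <- geneReport(cohort, "G0007")
rep$coxMultivariate
#> CoxFit: n = 300, events = 139, converged (5 iterations)
#>    covariate      coef       se     HR CI_low CI_high         p p_bonferroni
#> 1      G0007  1.361063 0.211303 3.9003 2.5777  5.9015 1.185e-10    5.923e-10
#> 2        age -0.007932 0.012373 0.9921 0.9683  1.0165 5.215e-01    1.000e+00
#> 3         gs -0.100887 0.147643 0.9040 0.6769  1.2074 4.944e-01    1.000e+00
#> 4 t_category -0.436392 0.207901 0.6464 0.4300  0.9715 3.581e-02    1.791e-01
#> 5       ipsa -0.002410 0.003445 0.9976 0.9909  1.0044 4.843e-01    1.000e+00
round(rep$meanTime, 2)
#>   low  high
#> 29.89 13.30
```

So overexpression above the selected cutoff carries an adjusted HR ≈ 3.9
and roughly 13 vs 30 months mean time to recurrence — the planted effect,
recovered end-to-end.

File-based workflows (`readExpressionMatrix()` for the cBioPortal z-score
dialect, `readClinicalTable()`, `readGmt()`, `runSimulate()/runScreen()/
runReport()/runHscore()/runEnrich()` plus the thin CLI in
`inst/scripts/cutscreen.R`) cover the same ground from TSV/GMT inputs.

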