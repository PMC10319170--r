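# myeloFlow

Flow-cytometric determination of the **Ki-67 proliferation index** and the
**Bcl-2 anti-apoptotic index** of myeloid bone-marrow populations, for
hematology labs and hemato-oncology researchers who quantify proliferation
and apoptosis resistance in non-malignant marrow, myelodysplastic syndrome
(MDS) and acute myeloid leukemia (AML).

Per-sample analysis starts from multi-tube FCS event data and proceeds
through a deterministic surrogate of the manual hierarchical gating
strategy used in clinical immunophenotyping:

1. **Debris and doublet exclusion** — density-valley threshold on FSC;
   singlet band on the integral/peak scatter ratio (median ± 3·MAD).
   *Relevant events* are all events above the debris boundary (erythroid
   cells and doublets retained); they are the denominator of every
   population fraction and of the acquisition QC rule (≥ 100,000 relevant
   events required, 500,000 ideal).
2. **Population gating** — CD34+ blasts (CD45-dim ∧ CD34+), erythroid
   cells (CD45− minus CD13+, minus CD117−HLA-DR+ lymphoid, minus
   CD36+CD71− platelets, CD36−CD71+ proliferating non-erythroid and
   CD71+CD235a− non-nucleated red cells), myeloid/granulocytic cells
   (SSC-high, CD45-dim, minus CD14+ mature monocytes, autofluorescent
   eosinophils and CD117−HLA-DR+ immature monocytes), and monocytes by
   backgating from the mature CD14+ seed in SSC vs CD45.
3. **Positivity gating** — for each population *P* and marker
   *m* ∈ {Ki-67, Bcl-2}, the index is the exact positive fraction

   *I(P, m) = #\{events of P positive for m\} / #P*

   under four strategies: control-anchored **polygon** (per-SSC-bin
   adaptive boundary at the 99.5th percentile of the control) and
   **rectangle** (global control percentile), and fixed **40 FU** /
   **100 FU** thresholds that ignore controls. Controls are IgG1 isotype
   channels or the marker-negative population. Fewer than 100 positive
   cells raises a QC flag.
4. **Tube merging** — samples acquired over a 7-tube panel are combined
   on shared backbone markers (tubes 1/2/5: FSC, SSC, CD13, CD34, CD45,
   CD117, HLA-DR; tubes 3/4/6/7: FSC, SSC, CD33, CD45, CD117, HLA-DR) by
   nearest-neighbour imputation in robust-standardized backbone space,
   with a 1000-event eligibility rule and held-out noise metrics.
5. **Cohort statistics** — Student's t-test when both groups pass
   Shapiro-Wilk normality, otherwise Mann-Whitney U; stars \*, \*\*,
   \*\*\* at p < 0.05 / 0.01 / 0.001; median + IQR figures. No
   multiple-testing correction.

A calibrated synthetic-cohort generator (50 non-malignant / 25 MDS / 27
AML cases with the published per-case population fractions and
demographics, per-event ground truth, latent Ki-67/Bcl-2 positivity and
optional autofluorescence shifts) makes the whole pipeline testable
without any data download. The package also reads and writes FCS 3.0/3.1
files — including the Beckman Coulter LMD dialect — and applies spillover
compensation, so deposited instrument data can be substituted for the
simulator.

## Worked example

Simulate one non-malignant case from the packaged fraction tables, gate
it, and compute all 32 indices:

```r
library(myeloFlow)

pr <- profileFromFixture("non_malignant", 2, nEvents = 100000)
cs <- generateCase(pr, seed = 7, tubes = "full")
ev <- cs$tubes[["full"]]

g <- gateSample(ev)
g$fractions
#>   population count fraction
#> 1      blast   946    0.996
#> 2  erythroid 18282   19.244
#> 3    myeloid 50765   53.437
#> 4  monocytic  1342    1.413

qcSample(g$relevantCount)$status
#> [1] "below_minimum"     # 95,000 relevant events (5% simulated debris)

idx <- computeAllIndices(ev, g$masks)
subset(idx, population == "myeloid",
       c(marker, strategy, positive, total, fraction))
#>    marker  strategy positive total fraction
#> 17  Ki-67   polygon    12941 50765    0.255
#> 18  Ki-67 rectangle    12947 50765    0.255
#> 19  Ki-67   fixed40    14354 50765    0.283
#> 20  Ki-67  fixed100    12720 50765    0.251
#> ...
```

The case was configured from the printed fractions of non-malignant case
2 (blast 1.0%, erythroid 19.3%, myeloid 53.6%, monocytic 1.6% of relevant
events); the gates recover them within a fraction of a percentage point.
The simulated myeloid Ki-67 positive fraction is 0.25: both
control-anchored strategies land on it, while the fixed 40 FU threshold
overcalls (0.283) by absorbing the upper tail of the negative cloud —
the strategy contrast the package exists to quantify. A whole-cohort run
(`runPipeline(runConfig(...))`) writes index tables, QC verdicts,
pairwise cohort comparisons and median+IQR figures into an output
directory, byte-identically for a fixed seed.

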