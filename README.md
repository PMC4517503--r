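# lvconsensus

Multi-reader consensus contours and left-ventricular function from
short-axis cardiac MR.

## What this is for

Left-ventricular (LV) volumes (EDV, ESV), myocardial mass (LVM) and ejection
fraction (EF) are measured from manually drawn endocardial and epicardial
contours on short-axis cine CMR slices. Individual expert readers are very
consistent with themselves, but each core laboratory's contouring protocol
places contours systematically tighter or looser, so multi-center studies
collate volumes that can disagree by tens of millilitres. This package is
for imaging scientists and core-lab methodologists who need to:

- fuse several readers' contours into a statistically optimal **consensus
  contour** per slice, with each reader's sensitivity/specificity estimated
  along the way (STAPLE expectation-maximization);
- compute **slice-summation LV function** (EDV, ESV, LVM at 1.05 g/ml, EF)
  from any contour set;
- quantify **reader agreement**: inter-reader and consensus RMSE,
  Bland-Altman bias / precision / limits of agreement, per-case consensus
  standard errors, and per-slice reader-vs-consensus discrepancy reports;
- **simulate** realistic multi-reader cohorts (per-reader systematic bias,
  smooth contouring noise, occasional missing end slices) so the whole
  pipeline can be validated without patient data.

## The model in brief

Per slice/surface/frame, reader contours are rasterized to binary maps
$D_{ij}$ on a 4x supersampled grid. STAPLE treats the true label $T_i$ as
latent with prior $\pi$ and each reader as a classifier with sensitivity
$p_j$ and specificity $q_j$, and EM alternates

$$W_i = \frac{\pi \prod_j p_j^{D_{ij}}(1-p_j)^{1-D_{ij}}}
  {\pi \prod_j p_j^{D_{ij}}(1-p_j)^{1-D_{ij}} +
   (1-\pi) \prod_j (1-q_j)^{D_{ij}} q_j^{1-D_{ij}}},\qquad
p_j = \frac{\sum_i W_i D_{ij}}{\sum_i W_i},\quad
q_j = \frac{\sum_i (1-W_i)(1-D_{ij})}{\sum_i (1-W_i)}$$

initialized at the majority vote. The consensus contour is the 0.5 level set
of $W$; slices contoured by fewer than four readers get no consensus.
Volumes are slice sums, area x inter-slice distance. Agreement per
functional index $F$ uses

$$E_i(F)=\sqrt{\sum_{j\neq i}\sum_k \tfrac{(F_i(k)-F_j(k))^2}{N(R-1)}},\qquad
E_C(F)=\sqrt{\sum_{j}\sum_k \tfrac{(F_C(k)-F_j(k))^2}{NR}}$$

and the consensus is functionally acceptable when $E_C < \min_i E_i$ for
every index. See the vignette (`vignettes/consensus-contours.Rmd`) for every
numerical decision and the generator's design.

## Worked example

```r
library(lvconsensus)

cohort   <- simulate_cohort(cohort_config(n_cases = 5, seed = 42))
analysis <- analyze_cohort(cohort)
print(analysis)
#> <lv_analysis> 5 cases
#> <agreement_report> EDV_ml - E_C = 16.91 | reader E_i in [ 18.26 , 34.57 ] | consensus best: TRUE
#> <agreement_report> ESV_ml - E_C = 10.91 | reader E_i in [ 12.12 , 22.29 ] | consensus best: TRUE
#> <agreement_report> LVM_g - E_C = 34.39 | reader E_i in [ 37.1 , 69.38 ] | consensus best: TRUE
#> <agreement_report> EF_pct - E_C = 3.398 | reader E_i in [ 3.801 , 6.466 ] | consensus best: TRUE
```

For each index, `E_C` is the RMSE between the consensus and the reader
panel and `[min, max]` the range of single-reader RMSEs: the consensus
agrees with the panel better than any individual reader (`consensus best`).
Per-reader Bland-Altman statistics expose the simulated protocol biases —
readers drawing tight endocardial contours (R1: bias -25.4 ml in EDV) to
loose ones (R7: +27.3 ml), each with small per-case precision, exactly the
smaller-or-larger-than-consensus pattern seen between real core labs:

```r
analysis$reports$EDV_ml$per_reader
#>   reader  E_i     bias precision lower_limit upper_limit
#> 1     R1 33.4 -25.4249     3.245     -31.785     -19.065
#> 4     R4 18.3   0.0236     0.481      -0.919       0.966
#> 7     R7 34.6  27.3155     3.189      21.066      33.565
```

Per-case consensus values carry a between-reader standard error
(`consensus_table(analysis)`), e.g. case 1: EDV 181.9 +- 7.4 ml against a
simulated truth of 181.2 ml. File-based orchestration mirrors the same
steps: `pipeline_simulate()` writes a cohort in the package's contour
exchange format (one CSV record per contour point), `pipeline_consensus()`
fuses it and writes STAPLE diagnostics, `pipeline_analyze()` writes the LV
function, agreement and consensus tables plus per-reader discrepancy
reports (`inst/scripts/lvconsensus.R` wraps these for the shell).

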