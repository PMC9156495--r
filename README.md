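# lipidtraffic

Lipid traffic analysis of multi-tissue lipidomics data: given per-sample
lipid abundances from several tissue compartments in two phenotype groups,
the package maps where in a biological network each lipid occurs, how those
spatial distributions differ between the phenotypes, and how abundances
shift along the way. It is aimed at lipidomics and metabolomics researchers
who have processed intensity tables (not raw spectra) from a multi-organ
design — e.g. a control-vs-diabetic mouse cohort sampled in liver, brain,
heart atria, heart ventricles, spleen, renal medulla, renal cortex and
serum — and want system-level rather than tissue-by-tissue answers.

## The analysis

Lipids are traced over a *traffic network*: compartments (nodes) joined by
axes (edges); a lipid sits on an axis for a phenotype when it is present at
both endpoints. Presence in a (compartment, phenotype) group means signal
> 0 in ≥ 66% of that group's samples (integer arithmetic, so 2-of-3
passes). Three result surfaces:

* **Switch analysis** — per scope (every node and every axis) each lipid is
  **A-type** (present in both phenotypes), **B-type** (present in exactly
  one, attributed to it), or network-wide **U-type** (ubiquitous within a
  phenotype).
* **Jaccard–Tanimoto coefficients** — per scope, J = |u ∧ v| / |u ∨ v|
  between the two phenotypes' presence vectors, with a margin-preserving
  permutation p-value (B = 10000 by default, explicit seed required,
  p ≥ 1/(B+1)).
* **ENFC (error-normalised fold change)** — per compartment at class and
  species level: log2(μ_case/μ_ref) divided by its delta-method standard
  error; positive = higher in the non-reference group. Subclass panels
  select de novo lipogenesis marker TGs (short, saturated) and
  PUFA-containing species by configurable rules.

A synthetic-data generator (`simulation_design()` / `simulate_lta()`)
plants known A/B/U patterns, axis switches and fold changes, and emits a
machine-readable ground truth, so the entire pipeline is verifiable at
desk scale; `paper_fixture()` bundles a qualitative control-vs-diabetic
traffic pattern (DNL-TGs on the liver–serum axis in controls, PUFA-TGs in
the diabetic group, a PI swap on the serum–brain axis, and more).

## Worked example

```r
library(lipidtraffic)

out <- tempfile()
sim <- simulate_command("paper-fixture", file.path(out, "sim"), seed = 1)
cfg <- run_config(data = sim$paths[["abundance"]],
                  network = sim$paths[["network"]],
                  out = file.path(out, "results"),
                  reference = "control", seed = 1)
res <- run_pipeline(cfg)
```

```
[lta] simulated 108 lipids x 8 compartments x 2 phenotypes (n=5 per group) -> .../sim
[lta] network: 8 compartments, 7 axes
[lta] read 7840 records, 108 lipid variables, phenotypes: control vs diabetic
[lta] presence called at >=66%: 1568 of 1728 (lipid, compartment, phenotype) calls positive
[lta] switch analysis: 1355 A-type, 167 B-type calls over 15 scopes; 109 U-type attributions
[lta] class ENFC: 32 records (1 undefined)
[lta] panel DNL_MARKER: 64 records
[lta] panel PUFA: 272 records
[lta] wrote 8 files to .../results
```

The planted traffic pattern is recovered exactly:

```r
grep("^TG", b_type_lipids(res$switch, "serum-liver", "control"), value = TRUE)
#> [1] "TG(44:0)" "TG(46:0)"
```

— the two saturated DNL-marker triglycerides are the only control-attributed
B-type TGs on the liver–serum axis. The serum–brain scope, where the fixture
plants a PI isoform swap, is the most dissimilar scope between phenotypes:

```r
jt <- as.data.frame(res$switch$jaccard)
jt[jt$scope %in% c("brain", "serum-brain"),
   c("scope", "J", "p", "n_intersection", "n_union")]
#>        scope         J         p n_intersection n_union
#>        brain 0.8474576 9.999e-05             50      59
#>  serum-brain 0.8474576 9.999e-05             50      59
```

(50 of 59 lipids present on the axis in either group are shared; p is the
permutation minimum 1/(B+1) at B = 10000.) Class-level ENFC in liver shows
the planted directions — TG up in the diabetic liver, PC down (the fixture
removes four PC species from the diabetic network):

```r
ce <- as.data.frame(res$class_enfc)
ce[ce$compartment == "liver", c("unit", "enfc")]
#>  unit   enfc
#>    PC -4.061
#>    PE -1.098
#>    PI -0.851
#>    TG  3.238
```

ENFC is in standard-error units: TG ≈ +3.2 means the diabetic liver TG
class mean is about 3.2 SEs above the control mean on the log2 scale.

A command-line front end wraps the same pipeline:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "lta.R", package="lipidtraffic"))') \
    run --data abundance.tsv --network network.txt --out results \
    --reference control --threshold 66 --permutations 10000 --seed 1
```

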