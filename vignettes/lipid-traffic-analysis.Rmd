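---
title: "Lipid traffic analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lipid traffic analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidtraffic)
```

## The problem

Tissue–tissue comparisons of lipidomics data find local effects but miss
system-level ones: lipid metabolism is distributed, with synthesis,
lipoprotein transport and uptake linking organs through the circulation.
Lipid traffic analysis asks a different question — *where in a network of
connected compartments does each lipid occur, and does that spatial
distribution differ between two phenotypes?* The unit of evidence is not a
fold change at one site but a presence pattern across compartments and the
axes joining them.

The package implements three linked analyses over a user-defined
compartment network (default: eight compartments with serum as hub, one
axis from serum to each of liver, brain, heart atria, heart ventricles,
spleen, renal medulla, renal cortex):

1. **Switch analysis** — classify each lipid per *scope* (each node and
   each axis) as **A-type** (present in both phenotypes), **B-type**
   (present in exactly one, attributed to it), and network-wide **U-type**
   (ubiquitous: present at every compartment within a phenotype).
2. **Jaccard–Tanimoto comparison** — per scope, the similarity
   J = |intersection| / |union| of the two phenotypes' presence lists over
   the full lipid panel, with a permutation p-value.
3. **Abundance analysis** — error-normalised fold change (ENFC) between
   phenotypes per compartment, at head-group (class) level and for species
   panels (DNL-marker TGs, PUFA species).

## Presence calling

A lipid is *present* in a (compartment, phenotype) group when its signal is
strictly positive in at least 66% of that group's samples. Two numerical
choices matter:

* The comparison is the integer inequality `100 * detected >= 66 * n`,
  never a floating comparison against 0.66. This makes 2-of-3 samples
  (66.7%) present, and makes the threshold behave as an exact rational
  boundary: at threshold 67, 2-of-3 is absent.
* A signal of exactly 0 is "not detected" — no epsilon floor, because
  upstream processing already encodes non-detection as 0, and missing
  records are treated as signal 0 (non-detection), not missing-at-random.

Group sizes are per (phenotype, compartment) — tissue dropout between
compartments is tolerated and each group's own n is used.

## The Jaccard–Tanimoto permutation test

The test holds one presence vector fixed and permutes the entries of the
other uniformly at random B times (default B = 10000, explicit seed
mandatory), preserving both margins. Under such a permutation the overlap
is hypergeometric, and the implementation samples the null through that
identity rather than materialising permutations; the test suite verifies
the equivalence against a literal `sample()`-based oracle and, for vectors
of length ≤ 12, against exhaustive enumeration.

The two-sided p-value compares |J_b − mean(J_perm)| with
|J_obs − mean(J_perm)| and applies the standard +1 correction, so p ≥
1/(B+1) and p is never 0. One-sided alternatives (`less_similar`,
`more_similar`) use the corresponding tail. Degenerate scopes (either
vector all-zero or all-one — common for well-covered compartments where
everything is present in both groups) carry no permutation information and
are flagged `uninformative` with p = 1 instead of erroring, so
whole-network runs always complete. Two empty presence lists compare equal
(J = 1 by convention).

The original description of this test speaks of "the order of the binary
list"; Jaccard similarity is order-invariant, so the intended meaning is
unclear and we document rather than guess it: this package's p-value is the
margin-preserving permutation construction above, nothing more. p-values
are reported raw, with scope counts, and no multiplicity correction is
applied across scopes — users can correct downstream.

## ENFC: definition and caveat

The ENFC used here is the delta-method standardized log2 fold change:

$$\mathrm{ENFC} = \frac{\log_2(\mu_\text{case}/\mu_\text{ref})}{SE},
\qquad
SE = \frac{1}{\ln 2}\sqrt{\frac{s_\text{case}^2}{n_\text{case}\,\mu_\text{case}^2}
 + \frac{s_\text{ref}^2}{n_\text{ref}\,\mu_\text{ref}^2}}$$

Positive means more abundant in the non-reference (case) group. It is 0 at
equal means, shrinks with noise, negates under a group swap and is
invariant to common rescaling — all property-tested. **Caveat:** the
original traffic-analysis literature does not print its ENFC formula in a
form we could verify (log base and error propagation are both
unverifiable from the text available); this definition is the package's
own, stated prominently, and the qualitative contract (sign, zero point,
noise shrinkage) is what the tests guarantee. Records with a zero group
mean or fewer than 2 replicates are reported `undefined` with a reason,
never silently dropped; a zero standard error yields a ±Inf sentinel,
flagged. Class values are per-sample sums over the head group's species
(absent species contribute 0), summed *within* sample first.

## Subclass tagging

Two subclasses drive the panels, as pure functions of
(head group, carbons, double bonds) under a configurable policy:

* `DNL_MARKER` (de novo lipogenesis): TG with ≤ 1 double bond and ≤ 50
  carbons, plus an explicit list defaulting to TG(44:0), TG(46:0),
  TG(48:0), TG(48:1), TG(50:0), TG(50:1). The literature names TG(44:0)
  and TG(46:0) explicitly but not the full marker set; the default list is
  a documented stand-in and fully overridable.
* `PUFA`: ≥ 6 double bonds for TG, ≥ 4 for any other head group
  (phospholipids such as PE(40:7) and PI(38:6) motivate the lower cutoff).

Under the defaults the two rules are provably disjoint. Only plain
`HEAD(C:D)` shorthand is parsed; ether/oxidised notations like
`PC(O-34:1)` are rejected rather than coerced, and unknown head groups
parse with a warning (the vocabulary is open).

## The synthetic world

`simulation_design()` states a world; `simulate_lta()` draws from it.
Defaults are chosen once, as a realistic desk-scale version of a
two-phenotype (control vs diabetic), 8-compartment murine design:

* **Panel**: 108 species over TG/PC/PE/PI spanning C30–C60, 0–12 double
  bonds (the emulated study identified up to ~220 variables; ~100 keeps
  tests fast without changing the combinatorics).
* **Group size**: n = 5 per (phenotype, compartment) — typical of mouse
  cohorts.
* **Abundance**: log-normal per class (positivity, right skew), meanlog
  7/6.5/6/5.5 for TG/PC/PE/PI in arbitrary intensity units, sdlog 0.3
  (CV ≈ 0.3, typical of processed LC-MS intensities).
* **Dropout**: probability a truly-present lipid reads 0 in one sample;
  constrained to [0, 0.34) so planted presences survive the 66% rule in
  expectation. Default 0 (noise-free presence), because the fixture's job
  is sharp ground truth.
* **Plants are the only signal**: non-planted lipids are present in both
  phenotypes everywhere, so every B/U classification in the truth record
  traces to a plant.

One deliberate deviation from "background present everywhere": in the
bundled fixture (`paper_fixture()`) triglycerides are absent from brain in
both phenotypes, via the design's `absences` field. Without it every
background TG would be ubiquitous in both groups, whereas the emulated
finding is that *no* TG is U-type; CNS tissue is genuinely TG-poor, so the
class-level absence is also the biologically realistic choice.

What the generator does **not** emulate: mass-spectrometric artefacts
(isotopes, adducts, in-source fragmentation), between-sample normalisation
issues, correlated dropout, unequal cohort sizes (supported but not
defaulted), or real biological covariance between lipids. A green
switch-recovery test therefore establishes that the pipeline's logic is
correct on clean presence patterns — not that the statistics are robust to
every real-data pathology.

## Determinism and ordering

Every output table is deterministically ordered: scopes in network
declaration order (nodes before axes), lipids by head group, then carbons,
then double bonds. Per-scope permutation seeds derive from the run seed
(seed + 7919·scope-index, mod 2³¹−1). The run summary records input file
basenames and no timestamps. Consequence (tested): identical config +
inputs + seed ⇒ byte-identical output bundles.

## Worked example

```{r, eval = FALSE}
out <- tempfile()
sim <- simulate_command("paper-fixture", file.path(out, "sim"), seed = 1)
cfg <- run_config(data = sim$paths[["abundance"]],
                  network = sim$paths[["network"]],
                  out = file.path(out, "results"),
                  reference = "control", seed = 1)
res <- run_pipeline(cfg)
b_type_lipids(res$switch, "serum-liver", "control")
```

On the noise-free fixture the control-attributed B-type TGs on the
liver–serum axis are exactly TG(44:0) and TG(46:0), the diabetic-attributed
B-type PIs on the serum–brain axis are exactly PI(36:1) and PI(38:6), and
no TG is U-type — the planted qualitative pattern, recovered end to end.

## Known limitations

* The default serum-hub star topology is an assumption (the axes named in
  the emulated findings both pass through serum); any connected network can
  be supplied instead, and results are topology-dependent.
* ENFC is descriptive; no test statistic or multiplicity control is
  attached to it.
* Presence is a hard 0/1 call; no limit-of-detection modelling.
* Fatty-acyl-resolved nomenclature (sn-positions, individual chains) is out
  of scope; only class-level `HEAD(C:D)` shorthand is supported.
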