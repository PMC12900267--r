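# PNPWorkbench

Analytics for pseudo-natural-product (PNP) compound collections — small
molecules that recombine natural-product fragments into scaffolds nature
does not make — and for the phenotypic data used to discover what they do.
The package serves chemical biologists and cheminformaticians who need to
(i) place a new collection in chemical space relative to natural products
and drugs, (ii) turn plate-level cell painting feature tables into
interpretable bioactivity calls, and (iii) summarize mitochondrial stress
test (Seahorse) traces.

## What it computes

**Chemistry.** Canonicalized compound sets from SMILES/SDF/CSV; a
17-descriptor panel; QED as the weighted geometric mean of eight
desirability functions; NP-likeness from trained circular-fragment
log-odds contributions, `c_f = log[(p_NP(f)+eps)/(p_syn(f)+eps)]`, scores
clipped to [-5, 5]; the spatial complexity score
`SPS = sum_a h*s*r*n^2` over heavy atoms (nSPS = SPS / heavy atoms);
principal-moments-of-inertia shape ratios NPR1 = I1/I3, NPR2 = I2/I3 with
rod/disc/sphere classification; 2048-bit radius-2 circular-fingerprint
Tanimoto matrices; PCA/UMAP embeddings; substructure enrichment,
including a packaged 3a-aryloctahydroindole (AOHI) pattern — the
mesembrine scaffold.

**Cell painting profiles.** Robust z-score profiles against DMSO controls
(`z = (median_trt - median_ctrl) / (1.4826 * MAD_ctrl)` per feature,
replicate wells aggregated by median); induction = % of features with
|z| >= theta (default 3), active at >= 5%; biosimilarity = 100 × Pearson
correlation of z vectors, similar at >= 75%; cluster subprofiles (features
changed in the same direction across biosimilar references) and
assignment of test profiles to named bioactivity clusters; joint profile
UMAPs.

**Bioenergetics.** MitoStress decomposition of OCR traces (basal,
ATP-linked, proton leak, maximal, spare, non-mitochondrial) and acute
injection percent changes for OCR/ECAR.

**Synthetic data.** Seeded generators with ground truth: plates with
planted cluster structure and Hill dose response, curated toy compound
classes, and MitoStress traces that round-trip their targets exactly.

Molecular perception runs through a packaged RDKit helper script executed
via `python` (see `SystemRequirements`); all scoring models are
implemented in R.

## Worked example

```r
library(PNPWorkbench)

# complexity anchors: ethane, benzene, cyclohexane
nsps(c("CC", "c1ccccc1", "C1CCCCC1"))
#> [1]  3  8 24

# toy classes: which class is enriched in the AOHI scaffold?
cs <- genToyCompoundClasses(1)
enrichment(cs, aohiSmarts())
#>   class_label n_total n_matching   fraction
#> 1   drug_like      18          0 0.00000000
#> 2     np_like      18          1 0.05555556

# a synthetic plate with 4 planted mechanism clusters
gen  <- genPlate(syntheticPlateSpec(seed = 7))
prof <- zscoreProfiles(gen$plate, analysisConfig())
prof
#> profiles: 180 (125 active); usable features: 579 of 579

# MitoStress trace summarization
tr <- genOCRTrace(list(basal = 80, proton_leak = 20,
                       maximal = 130, non_mitochondrial = 20))
mitoParams(tr)
#> MitoStress respiration parameters (OCR units):
#>   basal                80.000
#>   atp_linked           60.000
#>   proton_leak          20.000
#>   maximal             130.000
#>   spare_capacity       50.000
#>   non_mitochondrial    20.000
```

The z-score profile set reports, per (compound, concentration), the
induction percentage (how much of the morphological feature space moved)
and the activity flag; `biosimMatrix()`, `extractSubprofile()` and
`assignClusters()` then map profiles into a named cluster space. A full
configuration-driven run (`runWorkbench()`) writes every table as CSV
plus a manifest with seeds, thresholds and md5 digests;
`writeDemoConfig()` builds a self-contained demo. A thin command-line
wrapper ships at `inst/cli/workbench.R`.

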