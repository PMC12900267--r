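---
title: "Models and methods of the PNP profiling workbench"
author: "PNPWorkbench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the PNP profiling workbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

PNPWorkbench supports two complementary views of a pseudo-natural-product
(PNP) compound collection: where the molecules sit in chemical space
relative to natural products and drugs, and what the molecules do to cells
as read out by morphological (cell painting) profiling, with a small
add-on for summarizing mitochondrial stress test traces. This vignette
documents the models, their assumptions, the defaults and the design
decisions, in that order of importance. Every empirical number quoted here
is computed by the package's own test suite or by
`scripts/acceptance.R`; the vignette itself makes no claims beyond them.

# Chemoinformatic layer

## Molecular perception

All structure handling (SMILES parsing, canonicalization, atom typing,
ring perception, stereocenter detection, SMARTS matching, conformer
embedding, circular environments) is delegated to a packaged RDKit helper
script (`inst/python/rdkit_backend.py`) executed in a python subprocess
and spoken to in JSON. This keeps a single, field-standard perception
model behind every descriptor while all scoring models live in R where
they are testable against independent oracles. The interpreter is `python`
on the PATH, overridable via the `PNPWORKBENCH_PYTHON` environment
variable. Calls are batched per compound set and cached per session, so
interpreter start-up (about a second) is paid once per distinct request,
not per molecule.

Canonicalization keeps the largest covalent fragment (stripping
counterions) and retains stereochemistry — the common preprocessing for
screening collections. Duplicate canonical structures are dropped within a
class label (with a warning) but permitted across labels, because one
substance can legitimately be both a natural product and a drug.

## The descriptor panel

`descriptorTable()` computes a 17-descriptor panel standard for
NP-versus-drug chemical space comparisons: molecular weight, cLogP, tPSA,
H-bond donors/acceptors, rotatable bonds, ring count, aromatic ring count,
heavy atoms, fraction sp3 carbons, stereocenter count (assigned plus
unassigned tetrahedral centers), heteroatoms, formal charge, ring-system
count, largest ring size, nitrogen and oxygen counts. The panel size is
conventional; the exact membership is a documented choice of this package
and any subset can be requested by name. LogP is the atomic-contribution
cLogP computed locally; no external property services are queried, and
pKa-dependent quantities (logD) are deliberately out of scope because they
require a trained ionization model.

## QED

`qed()` implements the quantitative estimate of drug-likeness as the
weighted geometric mean of eight desirability functions
\(d_i\) (molecular weight, ALOGP, HBA, HBD, PSA, rotatable bonds,
aromatic rings, structural alerts):

\[ \mathrm{QED} = \exp\!\left(\frac{\sum_i w_i \log d_i(x_i)}{\sum_i w_i}\right), \]

with the published asymmetric-double-sigmoid parameterization and
property weights. The raw properties come from the perception backend;
the desirability model and aggregation are implemented in R. The test
suite pins the result against reference values computed with an
independent published implementation (agreement to better than 1e-3; in
practice the values agree to full printed precision, e.g. paracetamol
0.5950262).

## Spatial score (SPS, nSPS)

The spatial score sums, over heavy atoms,

\[ \mathrm{SPS} = \sum_a h_a\, s_a\, r_a\, n_a^2 \]

with \(h\) = 1/2/3 for sp/sp2/sp3 (4 otherwise), \(s\) = 2 for
stereogenic atoms (assigned or potential) else 1, \(r\) = 2 for atoms in
a non-aromatic ring else 1, and \(n\) the heavy-neighbor count; nSPS
divides by the heavy atom count. The constants are isolated in one code
block. Worked anchors: ethane nSPS 3, benzene 8, cyclohexane 24. The
acceptance suite checks exact integer agreement between the vectorized
implementation and a brute-force per-atom oracle on more than 100
grammar-generated small molecules. Note that "stereogenic" counts
potential tetrahedral centers, so an undrawn wedge does not change the
score.

## NP-likeness

`trainNPLikeness()` contrasts circular-fragment incidence (radii 0–2, all
environments over heavy atoms) between a natural-product set and a
synthetic set:

\[ c_f = \log\frac{p_{\mathrm{NP}}(f) + \varepsilon_{\mathrm{NP}}}
                 {p_{\mathrm{syn}}(f) + \varepsilon_{\mathrm{syn}}}, \qquad
   \varepsilon = 1/|\text{set}| \text{ per side,} \]

where \(p(f)\) is the fraction of molecules containing fragment \(f\).
Tying the smoothing to its own set makes the table exactly antisymmetric
under swapping the two training sets, which the tests verify to machine
precision. A molecule's score is the multiplicity-weighted mean
contribution over its fragment occurrences, clipped to \([-5, 5]\) (the
conventional display range); fragments unseen in training contribute
\(\log(\varepsilon_{\mathrm{NP}}/\varepsilon_{\mathrm{syn}})\). Whether
the original analyses used a retrained or a published contribution table
is not knowable from the outside; this package always trains explicitly,
which keeps the model auditable.

## Shape (PMI) and fingerprints

`shapeDescriptors()` embeds each molecule (10 conformers from a seeded
distance-geometry method, force-field optimized, lowest energy kept,
hydrogens included), builds the inertia tensor from atomic masses and
coordinates, and reports NPR1 = I1/I3 and NPR2 = I2/I3 with the
rod/disc/sphere class given by the nearest triangle vertex at (0,1),
(0.5,0.5), (1,1). Ten conformers is a pragmatic budget: enough to escape
a single bad embedding, cheap enough to stay deterministic and fast. The
moment-space limit cases (linear rotor, flat symmetric ring) are exposed
directly through `shapeFromMoments()` so they can be tested without any
geometry.

Fingerprints are 2048-bit hashed circular fingerprints of radius 2
(identifier modulo width); `tanimotoMatrix()` computes bit-set Tanimoto
similarity. Folding can in principle collide two environments into one
bit; at 2048 bits and screening-collection molecule sizes this is rare
and is the standard trade-off.

## Substructure enrichment and the AOHI pattern

`enrichment()` counts substructure matches per class label. The packaged
3a-aryloctahydroindole pattern (`aohiSmarts()`) encodes a saturated 6-5
fused octahydroindole, nitrogen in the five-membered ring, with an aryl
substituent on the quaternary ring-fusion carbon — the scaffold of
mesembrine. The six-membered ring may carry sp2 carbons (mesembrine's
ketone) but no aromatic atoms. Published enrichment counts for alkaloid
classes depend on specific database extracts and on undocumented matching
conventions (stereochemistry, N-substitution), so the pattern here is
deliberately shipped as an editable, reviewable string and exercised on
packaged toy classes where the expected counts are exact.

# Morphological profile layer

## Z-score profiles

For a plate with \(\ge 4\) DMSO control wells, each feature \(f\) is
standardized by the control median and the control MAD:

\[ z_f = \frac{\tilde{x}_f^{\mathrm{trt}} - \mathrm{med}_f^{\mathrm{ctrl}}}
              {1.4826 \cdot \mathrm{MAD}_f^{\mathrm{ctrl}}}, \]

where \(\tilde{x}^{\mathrm{trt}}\) is the median over the replicate wells
of one (compound, concentration) treatment. Median aggregation before
scaling is deterministic and robust to a single bad well; the alternative
(z per well, then median) is a one-line change and was not taken to keep
one canonical profile per treatment. Degenerate features are handled
explicitly rather than silently: a feature whose control values are all
identical is excluded from the induction denominator (its z is NA), and a
feature with zero MAD but non-constant controls gets the smallest
positive control MAD on the plate substituted and is flagged.

## Induction and activity

Induction is the percentage of (non-excluded) features with
\(|z_f| \ge \theta\); a profile is active at induction \(\ge 5\%\). The
significance cutoff \(\theta\) is not standardized anywhere; this package
defaults to \(\theta = 3\), the usual robust-z convention in morphological
profiling, and exposes it in `analysisConfig()`. The boundary arithmetic
is pinned in tests: 29 of 579 altered features is 5.0086% (active), 28 is
4.8359% (inactive).

## Biosimilarity

BioSim between two profiles is \(100 \times\) the Pearson correlation of
their z vectors over shared non-missing features, with profiles similar at
\(\ge 75\%\). Correlation is the natural reading of profile
"cross-correlation" on a ±100% scale; it is scale-invariant
(biosim\((a\,p, p) = 100\) for \(a > 0\), \(-100\) for \(a < 0\)) and
undefined for constant profiles, which is reported as an error rather
than silently returned as 0.

## Subprofiles and cluster assignment

A cluster subprofile keeps the features changed in the same direction
across biosimilar reference profiles: feature \(f\) is selected when the
fraction of members sharing the sign of the per-feature median is at
least `consistency` (default 1.0 — the strictest reading of
"same direction") and \(|\mathrm{median}\, z_f| \ge\) `minAbsMedian`
(default 1.0, a minimal biologically meaningful shift); the stored values
are the medians. Cluster biosimilarity of a test profile is the Pearson
correlation (×100) between the profile restricted to the subprofile's
features and the subprofile values — correlating against the subprofile
vector rather than against each member individually, which is the more
stable of the two unstated alternatives and is validated by the recovery
experiments. Assignment takes the argmax cluster if it reaches the
similarity threshold, otherwise none; undefined cells are propagated as
NA (never 0); ties go to the first-declared cluster and are logged.
Reference cluster membership ships as a versioned JSON registry
(`writeClusterModel()`/`readClusterModel()`) because real reference
compound sets are facility-specific.

## Profile embeddings

Profile UMAPs use raw z vectors without column normalization (the
features are already on a common robust-z scale) and 10 neighbors;
descriptor-table UMAPs standardize columns first. Both are seeded and run
single-threaded, so identical inputs give identical layouts.

# Bioenergetics layer

`mitoParams()` applies the standard mitochondrial stress test
decomposition to an OCR trace segmented by the oligomycin / FCCP /
rotenone+antimycin injections: non-mitochondrial respiration is the
final-phase mean; basal is the last pre-oligomycin phase mean minus
non-mitochondrial; proton leak the post-oligomycin mean minus
non-mitochondrial; ATP-linked is basal minus leak; maximal uses the best
(maximum) post-FCCP measurement, following kit convention, because FCCP
responses peak and then decay; spare capacity is maximal minus basal. The
identities atp_linked + proton_leak = basal and spare = maximal − basal
hold by construction and are asserted for arbitrary traces. Replicate
wells are averaged per timepoint on reading. Measurements taken exactly
at an injection time are counted into the preceding phase.

# What the synthetic generators emulate — and what they do not

`genPlate()` emulates a plate of 579 features with a 32-well DMSO panel
and quadruplicate treatment wells: controls are feature-wise
Normal(\(\mu_f, \sigma_f\)) with \(\mu_f \sim U(50, 150)\) and per-feature
scales \(\sigma_f\) drawn log-uniformly over one decade so that robust
scaling is genuinely exercised; treatments add
\(a \cdot \mathrm{hill}(c) \cdot d_k(f) \cdot \sigma_f\) where \(d_k\) is
a ±1 sign pattern on that cluster's effect features, so the planted
z-magnitude is approximately \(a \cdot \mathrm{hill}(c)\). Defaults: k = 4
clusters with 58 effect features each (about 10% of 579, which puts
induction in the tens-of-percent range at saturation), amplitude 10,
concentrations {2, 10, 30, 50} µM with a Hill response (c50 = 10 µM,
slope 1) mirroring the tested concentration range and the qualitative
dose dependence of induction. Cluster templates occupy disjoint feature
subsets and are therefore exactly orthogonal — a stronger condition than
the near-orthogonality real mechanism classes exhibit.

The control-panel and replicate defaults were fixed by a design-time
calibration of the robust-z null: with a 32-well DMSO panel and
median-aggregated quadruplicates, the mean null induction at
\(\theta = 3\) is far below 1% and no null treatment reaches the 5%
activity flag; sparser layouts (e.g., 12 controls, single wells) inflate
the null tail of the studentized statistic itself, not of the biology.

For the dose-monotonicity experiment the acceptance suite deliberately
uses amplitude 4 instead of the default 10: at amplitude 10 every tested
concentration from 10 µM up drives the planted features far beyond
\(\theta\), so induction saturates and concentration differences drown in
noise; amplitude 4 places the dose range across the \(|z| = \theta\)
transition, where dose dependence is actually expressed. This was chosen
by a pre-test power analysis, not tuned afterwards.

Deliberate non-goals of the generator: features are independent given the
well (real CellProfiler features are strongly correlated in blocks), there
are no plate-position or batch effects, no image segmentation artifacts,
and effect templates are exactly orthogonal. Passing recovery tests on
this model therefore demonstrates correctness of the statistics, not
robustness to correlated-feature or batch-confounded data.

`genToyCompoundClasses()` packages 18 stereocenter-rich fused polycyclics
("np_like", including mesembrine — the single AOHI match) and 18 flat
aromatic drug-like molecules ("drug_like"). The seed only shuffles order;
content is fixed so that curated properties (100% parseability, exactly
one AOHI match, higher mean nSPS in the NP class) are stable.
`genOCRTrace()` builds four flat phases of three measurements whose means
reproduce the target respiration parameters exactly at zero noise.

# Numerical and interface choices

* CSV is the single on-disk dialect (comma, UTF-8, header; metadata
  columns `plate_id`, `well_id`, `compound_id`, `concentration_um`,
  `is_control`); numeric values are written with 17 significant digits so
  read(write(x)) is exact.
* PCA standardizes columns, drops constant columns with a warning, and
  fixes each component's sign by forcing the largest-magnitude loading
  positive, making embeddings reproducible to the bit.
* All stochastic steps (UMAP, conformers, generators) take explicit
  seeds; the pipeline runner (`runWorkbench()`) records seeds, thresholds
  and input/output md5 digests in a manifest, and rerunning a
  configuration yields byte-identical outputs.
* Problem sizes in the shipped test and acceptance runs were chosen to
  exercise the full default geometry where it matters (579 features, 1000
  null treatments, 40 active compounds over 4 clusters) while keeping toy
  fixtures small everywhere the property under test is scale-free.

# Known limitations

* Chemistry fidelity is bounded by the perception backend; exotic
  valences or organometallics outside its model are rejected rather than
  approximated.
* Potential-stereocenter counting makes SPS insensitive to drawn versus
  undrawn stereochemistry.
* The biosimilarity model is plain Pearson correlation on all features;
  no feature curation, covariance whitening or significance testing of
  cluster membership is attempted.
* Reference cluster models must be supplied (or generated synthetically);
  the package does not ship real reference profiles.
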