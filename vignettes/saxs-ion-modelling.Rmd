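---
title: "SAXS-guided ion placement and ensemble modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SAXS-guided ion placement and ensemble modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionsaxs)
```

## The problem

Predicted RNA structures usually lack the Mg²⁺ ions that stabilise folded
RNA in solution, and a single rigid conformation rarely captures the
molecule's plasticity. Both omissions show up when a model is scored
against a solution small-angle X-ray scattering (SAXS) profile. `ionsaxs`
addresses them in sequence: it scores conformations against the data,
predicts plausible Mg²⁺ binding sites from local atomic geometry, selects
the ion subset that best explains the scattering, and — when no single
decorated conformation fits within the noise — fits a small weighted
ensemble of conformations.

## Profile calculation and fitting

The theoretical intensity of a model is the Debye sum

$$I(q) = \sum_i \sum_j f_i(q)\, f_j(q)\, \frac{\sin(q d_{ij})}{q d_{ij}},$$

with the $q \to 0$ and $i = j$ limits of the sinc taken as 1. Per-atom
factors combine three tabulated ingredients:

$$f_i(q) = f_{v,i}(q) - c_1 G(q, c_1)\, f_{s,i}(q) + c_2\, s_i\, f_w(q).$$

* $f_v$ — vacuum factor, five-term Cromer–Mann coefficients, so
  $f_v(0)$ is the element's electron count;
* $f_s$ — displaced-solvent (dummy atom) factor,
  $\rho_0 V \exp(-q^2 V^{2/3}/4\pi)$ with $\rho_0 = 0.334\,e/\text{Å}^3$
  and Fraser-style atomic volumes;
* $f_w$ — a composite water factor (O + 2H) for the hydration layer,
  weighted by the atom's fractional solvent accessibility $s_i$.

$c_1 \in [0.95, 1.05]$ rescales the excluded volume through the standard
q-dependent adjustment $c_1 G(q,c_1) = c_1^3 \exp(-(4\pi/3)^{3/2} q^2
r_m^2 (c_1^2 - 1)/16\pi)$ ($r_m$: mean dummy radius), and
$c_2 \in [-2, 4]$ scales the hydration layer; negative values (observed
for nucleic acids at some ionic strengths) are deliberately allowed. At
$c_1 = c_2 = 1$ the model reduces to vacuum-minus-dummy plus a
unit-density hydration layer.

Agreement with an experimental profile is the error-weighted

$$\chi^2 = \frac{1}{S} \sum_{i=1}^{S}
\left(\frac{I_{exp}(q_i) - c\, I(q_i, c_1, c_2)}{\sigma(q_i)}\right)^2 ,$$

where the scale $c$ has a closed-form weighted-least-squares optimum and
is always optimised. $(c_1, c_2)$ are fixed at 1 by default — optimising
them while also placing ions invites overfitting — and, when requested,
are optimised by a deterministic grid search (steps 0.005 and 0.05) over
six precomputed partial intensities, so the whole grid costs $O(S)$ per
point rather than $O(N^2 S)$. A $\chi^2$ near 1 means the model fits
within the experimental noise; the pipeline uses 1.3 as its
"fits-within-noise" cutoff (configurable; the conventional closeness
criterion in solution scattering).

Solvent accessibility is computed by Shrake–Rupley dot sampling on a
fixed deterministic golden-spiral lattice (default 100 dots/atom, probe
1.4 Å). Two conventions matter downstream: RNA accessibility is a
property of the RNA solute (placed ions never occlude it), and each ion's
accessibility is computed against the RNA plus that ion alone. This makes
per-atom factors identical whether a profile is computed directly or
assembled from cached subprofiles — the decomposition below is then exact
rather than approximate. The fixed lattice makes results exactly
reproducible; the price is a small orientation dependence of order
$1/\sqrt{\text{dots}}$ (≈0.03 at 100 dots), which shrinks with `n_dots`.

### Analytics

`guinier_rg()` fits $\ln I$ vs $q^2$ over a low-$q$ window trimmed
iteratively until $q_{max} R_g \le 1.3$. `dimensionless_kratky()` returns
$(qR_g, (qR_g)^2 I/I(0))$; for a compact globular particle the peak sits
at $(\sqrt{3}, 3/e) \approx (1.73, 1.10)$, a model-free sanity check of
both data and $R_g$. `model_pr()` histograms pairwise distances weighted
by $f_i(0) f_j(0)$ — a model-based $P(r)$, not the regularised transform
of measured data.

## Predicting Mg²⁺ binding sites

Candidate positions are seeded on an occlusion-filtered dot surface:
every atom's sphere of radius vdW + probe is covered with the same
deterministic lattice and dots inside any other atom's sphere are
dropped, then near-duplicates are thinned on a 1 Å grid. This is a
simplification of a full reentrant molecular surface — for seeding
candidate points the coverage is equivalent and the construction is
deterministic. One practical consequence: with the default 1.5 Å probe,
dots sit at vdW + 1.5 Å ≈ 3 Å from atom centres, farther than a true
inner-sphere Mg–O contact (~2.1 Å). Where tight coordination pockets
matter, generate probes at the bare-ion scale (`probe_radius` ≈ 0.5 Å);
the pipeline exposes this knob.

Each probe's neighborhood — all RNA atoms within 8 Å — becomes a graph:
nodes carry an element one-hot, the distance to the probe and the atom's
accessibility; edges connect atom pairs within 5 Å and carry their
distance. Only distances enter the representation, so predictions are
invariant to rigid motion by construction (3D-grid representations are
not). Probes with empty neighborhoods are skipped.

The classifier is a small graph neural network: graph-attention layers
(single head; attention logits combine transformed endpoint features and
the edge distance, softmax over each node's in-edges), then
symmetric-normalised graph-convolution layers, mean pooling and a
logistic read-out. Defaults are 1 attention + 1 convolution layer of
width 16, trained 150 full-batch epochs with Adam (lr 0.02) on binary
cross-entropy; all of it is configurable (deeper 2+2/64 stacks train fine
but buy nothing on the synthetic task while costing CPU minutes). Class
imbalance is handled by subsampling the majority class to 1:1 each epoch.
The whole batch is packed into one block-diagonal edge list, so an epoch
is a handful of matrix products regardless of graph count; gradients are
derived by hand and verified against finite differences in the test
suite. Training reports stratified k-fold (default fourfold)
cross-validated AUROC before refitting on all data, and checkpoints embed
the feature schema so `predict()` refuses mismatched graphs.

Confident predictions are clustered greedily: repeatedly accept the
highest-probability probe above the threshold (0.5 by default, 0.9 for a
strict selection; ties broken by probe index) and discard probes within
`min_separation` (default 3.5 Å) of it. Raising the threshold can only
shrink the selection.

## Selecting the ion subset against the data

Which predicted sites are actually occupied is decided by the scattering
data. For candidates $k, l$ the Debye intensity of RNA ∪ A decomposes
exactly as

$$I_A = I_{RNA} + \sum_{k \in A} (I_{kk} + X_k) + \sum_{k<l \in A} C_{kl},$$

with $X_k$ the RNA–ion and $C_{kl}$ the ion–ion cross terms. All pieces
are precomputed once ($O(MN + M^2)$ profile work), after rejecting
candidates within 1 Å of an RNA atom; assembling any subset then costs
$O(|A|^2 S)$, independent of RNA size. The ion–ion terms are retained
deliberately: dropping them would make the assembly approximate and
silently bias $\chi^2$.

Subsets are enumerated level-wise: keep the $K$ best subsets of size $n$
(default $K = 50$; ties broken lexicographically; duplicates from
different parents merged), extend each by one unused candidate, and stop
when the best $\chi^2$ no longer improves or `max_ions` is reached. With
$K = \infty$ the search is exhaustive over the visited sizes. Note the
stopping rule is the search's definition of convergence, not a claim of
global optimality: a planted 3-ion target can score worse at size 2 than
at size 1, in which case the search (correctly, by its own rule) stops
early.

## Multistate models

If no decorated single conformation reaches $\chi^2 \le 1.3$, a weighted
mixture is fitted: $\chi^2$ of $c \sum_m w_m I_m(q)$ is minimised over
$c, w \ge 0$ by non-negative least squares on the $\sigma$-normalised
member profiles (Lawson–Hanson; convex and deterministic), with weights
normalised to sum 1 and the scale absorbing the norm. Conformer subsets
are enumerated with the same beam machinery, scored by the NNLS fit; the
best model per state count 1..`max_states` (default 4) is reported.
Because NNLS can zero a member, best $\chi^2$ is non-increasing in the
state count — the state count is chosen by parsimony (the smallest count
within noise), not by the raw minimum. Ions are selected per conformation
first and conformations combined afterwards; a joint search over
ions × conformers × weights would multiply the overfitting surface.

Two identifiability caveats: duplicated (or nearly collinear) member
profiles make the weight split arbitrary even though the fitted curve and
$\chi^2$ are unchanged; and a spurious ion on one conformer can
compensate a conformational difference, which is why the pipeline keeps
$c_1 = c_2 = 1$ during selection.

## The synthetic-data generator

All tests run on generated fixtures with known ground truth:

* `make_helix(n_bp)` — an idealized A-form-like double helix from a fixed
  6-pseudo-atom/nucleotide template (rise 2.81 Å, twist 32.7°). Coarse
  pseudo-atoms keep the $O(N^2)$ Debye cost low while preserving
  scattering-level realism (size, helical repeat, electron-density
  contrast).
* `perturb_ensemble()` — hinge rotations of the chain tail about pivots
  restricted to residue boundaries, so intra-segment geometry is exactly
  rigid; a stand-in for a kinematics-based conformational sampler, which
  is consumed as an external input in real use.
* `simulate_profile()` — Debye intensity plus seeded Gaussian noise with
  $\sigma(q) = 0.01\, I(q) + 0.002\, I(0)\, q/q_{max}$, mimicking the
  growing relative error at high $q$ of solution scattering; fitting the
  generating model back against its simulation yields $\chi^2 = 1$ on
  average, so $\chi^2$ values are on their conventional scale.
* `make_neighborhoods()` — labelled coordination shells: positives have
  4–6 oxygens at 2.0–2.2 Å on jittered octahedral directions (the
  geometry of an Mg²⁺ inner shell, which is predominantly oxygen
  coordinated), negatives are looser element-mixed shells with the
  nearest atom at 2.6–3.5 Å, both over random background atoms within
  8 Å.

What passing on these fixtures does and does not show: the synthetic
shells are separable by construction (a one-rule oracle — "≥4 O within
2.3 Å" — already reaches AUROC ≈ 1), so the classifier tests verify the
*mechanism* (training, invariance, calibration, clustering), not
real-PDB accuracy. A model trained on these shells is conservative on
realistic surfaces — ordinary helix surface probes score near 0 — and
real deployments should train on curated PDB neighborhoods through the
same interface. Likewise the helix/hinge generator produces no
sequence-dependent structure and no base-pairing constraints; it probes
the selection machinery, not RNA energetics.

## Numerical choices and degenerate inputs

* Debye kernels (and the six-partial decomposition) are compiled; the
  $q \to 0$, $i = j$ sinc limits are set to 1 explicitly.
* Computed profiles are evaluated directly on the experimental grid when
  a model is available; fixed computed profiles are linearly
  interpolated, and extrapolation is refused.
* Guinier fits require ≥5 window points and refuse non-negative slopes;
  Kratky peaks are refined by a local parabola through the grid maximum.
* Single-atom models get accessibility 1 by convention; empty
  neighborhoods are a signal (`NULL`), not an error, and callers skip
  those probes.
* Problem sizes in the tests (8–10 bp helices, ~200-point grids, ≤8
  candidates for exhaustive cross-checks, 1000 training graphs) were
  chosen so every oracle comparison runs at full precision in seconds —
  they are scientific choices of the smallest systems that exercise each
  mechanism, and every equivalence is at numerical precision
  (1e-8–1e-15), not a scaled-down approximation.

## Known limitations

* The surface dot construction is not a true reentrant Connolly surface;
  probes cannot sit in cavities unreachable from any atom sphere.
* Hydrogens are not modelled explicitly (standard at SAXS resolution).
* Only Mg²⁺ is supported; other ions would need labelled training data
  through the same interface.
* Weight uncertainties for multistate models are not estimated.
* mmCIF input is not supported; use PDB.
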