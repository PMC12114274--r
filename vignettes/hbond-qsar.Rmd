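---
title: "From hydrogen-bond geometry to channel inhibition: the hbq methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From hydrogen-bond geometry to channel inhibition: the hbq methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbq)
```

## The problem

Pannexin-1 (Panx1) is a heptameric plasma-membrane ATP-release channel and
a drug target in neuropathic pain, stroke, cancer, and polycystic kidney
disease. Candidate blockers are screened by whole-cell patch clamp, giving
a percent inhibition I% of the Panx1-dependent current at a fixed blocker
concentration. On the modeling side, each blocker is docked into the
extracellular domain of the channel, representative poses are energy
minimized in explicit solvent, and the resulting complexes are reduced to
a small set of geometric descriptors: the lengths of ligand-protein
hydrogen bonds.

`hbq` implements that computational chain as a reusable, tested pipeline:

1. **structure io** — parse minimized complexes from fixed-column atom
   records and partition atoms into protein / ligand / water roles;
2. **hydrogen-bond features** — detect direct and water-bridged polar
   contacts at a 3 Å cutoff and assemble a residue-keyed bond-length
   matrix with the I% response;
3. **pose clustering** — leader clustering of docking poses at a 10 Å RMSD
   homogeneity threshold with best-energy representatives covering at
   least 70% of poses;
4. **GA + MLR** — ordinary least squares of I% on a fixed-size subset of
   bond-length variables, with the subset chosen by a genetic algorithm
   whose fitness is the determination coefficient R²;
5. **pharmacology statistics** — the one-parameter dose-response model
   `Y = 100/(1 + X/IC50)`, mean ± SEM group summaries, and percent
   reduction of cyst cross-sectional areas;
6. **synthetic data** — generators with planted ground truth for every
   stage.

## The descriptor model and its assumptions

A hydrogen bond here is purely geometric: a ligand polar heavy atom
(N, O, S) and a protein polar heavy atom within 3 Å. Bond strength is
taken as inversely proportional to length in first approximation, which
is what makes plain bond lengths usable as regression variables. Three
modeling commitments follow from the source methodology and are worth
stating explicitly:

- **Distance-only detection.** No donor/acceptor typing and no angle
  criterion are applied, and distances are heavy-atom to heavy-atom (the
  protocol is silent on whether hydrogens were present; heavy-atom
  distances are the robust choice after minimization). The 3 Å ceiling on
  heavy-atom separation is itself a strict criterion, so little is lost.
- **Water bridges.** A water that is simultaneously within 3 Å of a
  ligand polar atom and of a protein polar atom contributes a *bridged*
  variable, rendered with a `W` prefix (`WSer73`). The recorded length is
  the ligand-water leg — the ligand-dependent quantity; the sum of both
  legs is available via `length_mode = "sum"`.
- **Chain-agnostic keys.** The channel is a homo-heptamer; a contact to
  Trp74 of any protomer is the same chemistry. Residue keys carry no
  chain id, and multiple bonds to one key collapse to the minimum length
  (the strongest contact).

Cells with no observed bond take the **fill value**, defaulting to the
cutoff (3 Å). The regression needs a complete matrix and the source never
states a missing-value convention; the cutoff encodes "weakest possible /
no interaction", which is consistent with how positive coefficients are
read (see below). The fill is configurable.

Rows of the matrix are *conformations*, not compounds: a compound with
several retained poses (`12e_2`) or a deprotonated variant (`12b-`)
contributes several rows sharing one measured I%.

## Pose clustering

Docking produces ~100 poses per ligand in one receptor frame, so RMSD is
computed without re-superposition and without symmetry correction.
Clustering is the energy-seeded leader algorithm: the lowest-energy
unassigned pose seeds a cluster and absorbs every unassigned pose within
the 10 Å threshold; the seed is therefore the best-energy member of its
cluster and serves as its representative. The exact clustering dialect
behind a "10 RMS homogeneity" criterion is not specified upstream;
leader clustering is the conventional docking-package behaviour and is the
documented choice here. Representatives are then accumulated by
descending cluster size (ties by better energy, then lower pose id) until
at least 70% of poses are covered. Because the sum of the m largest
cluster sizes dominates any other m-subset, this greedy rule provably
uses the minimum number of clusters for any coverage target — the
acceptance suite still cross-checks it against exhaustive minimal-cover
enumeration on small cases.

## Regression and subset selection

With ~30 candidate variables and ~40 conformations, a full-rank OLS would
overfit; about a quarter of the variables (k = 8 by default) is the
stated sweet spot. `fit_mlr()` is OLS with intercept via QR; R² is the
in-fit determination coefficient and RMSE the in-fit root-mean-square
residual in I% units. There is deliberately **no validation split**: the
upstream model is presented as descriptive, calculated in fitting, and
this package follows that contract (adding cross-validation is a
one-liner for the user but out of scope). A zero-variance response maps
to R² = 0 by convention so the GA fitness is always defined.

`ga_select()` searches fixed-cardinality subsets: tournament selection
(size 3), union-then-repair uniform crossover that preserves |subset| = k,
swap mutation with probability 0.1 per individual, elitism 1, population
100, 200 generations. The upstream operating conditions live in an
unavailable appendix, so these defaults are standard GA practice;
correctness is established not by matching hidden settings but by oracle
equivalence — on instances small enough to enumerate (`exhaustive_select()`),
the GA must find the same optimum, and on planted-model instances it must
recover the true subset. Every run is bit-reproducible from its seed.

The **sign report** encodes the interpretation logic: a negative
coefficient on a bond-length variable means shorter bond, higher I% — the
ligand should bind that residue strongly (deep-pocket residues such as
Trp74 and Cys434 behave this way); a positive coefficient means the bond
should be as long as possible — the ligand should *not* engage that
residue (outer-rim residues, e.g. the bridged water of Ser73).

## Dose-response and cyst statistics

IC50 comes from the one-parameter inhibitor-vs-normalized-response model
`Y = 100/(1 + X/IC50)`; there is no Hill slope and no floor/ceiling
parameter, matching the upstream fitting choice. The single parameter is
fit by least squares on log10(IC50) — positivity enforced by the
parameterization — with a deterministic 121-point grid multi-start over
three decades beyond the dosed range followed by golden-section
refinement, so the fit has no RNG dependence. Responses outside
[-10, 110]% draw a warning but are retained (clipping would bias the
fit). Group summaries use the n−1 sample standard deviation for SEM, and
`percent_reduction()` is `100·(control − treated)/control` on group
means.

## The synthetic world, and what a green test establishes

Generators are pure functions of (spec, seed). Their defaults are a
stated world, fixed once:

- bond lengths uniform in **2.4–3.0 Å** (plausible hydrogen-bond lengths
  under the 3 Å ceiling), missing rate 0.2;
- planted linear model with **n = 40 rows, p = 31 variables, k = 8 true
  variables, noise sd 2 I%**, coefficients alternating **±60** around an
  intercept of 55 — chosen so the response spread
  (`sqrt(8)·60·sd(U(2.4,3)) ≈ 29` I%) matches the observed inhibition
  range of roughly 10–100%;
- toy complexes place each planted contact in its own pocket 25 Å from
  the next, so detectors must return exactly the planted bond set;
  bridge partners are re-drawn (≤ 100 attempts) until no spurious direct
  contact is possible;
- pose sets are isotropic Gaussian blobs around centers separated by
  well over the clustering threshold; dose-response tables are the
  forward model plus Gaussian noise, unclipped.

What this does *not* emulate: correlated descriptors (real bond lengths
to neighbouring residues co-vary), heteroscedastic patch-clamp noise,
docking-pose energy/geometry correlation, and protonation-dependent
geometry changes. A green recovery test therefore establishes the
*machinery* — detectors equal brute-force enumeration, the GA finds
verifiable optima, the IC50 fitter inverts its own forward model — not
that an 8-variable distance model is the true generative story for any
real channel blocker. The upstream R² of 0.746 on the real matrix cannot
be re-derived here because the published hydrogen-bond tables live in a
supplement that is not distributed with this package; the acceptance
suite substitutes the property checks above, as specified.

## Numerical choices and edge cases

- Exact ties in exhaustive search resolve to the lexicographically first
  subset; leader-clustering ties resolve by ascending pose id; equal
  cluster sizes rank by better representative energy.
- Rank-deficient designs abort with the names of the collinear columns
  rather than silently dropping them.
- A single replicate yields SEM 0 with a warning; an all-equal response
  makes IC50 non-identifiable and is an error.
- Observed bond lengths longer than the fill value (possible only when
  `fill < cutoff`) are capped at the fill so the matrix stays bounded.
- Coordinates round-trip through the fixed-column format at 3-decimal
  printed precision; a second round trip is bit-exact.

## Known limitations

- Only the fixed-column ATOM/HETATM dialect is read (no mmCIF, no
  trajectories, no multi-model files); ligands are identified by
  caller-supplied residue names.
- No hydrophobic, π-stacking or electrostatic descriptors; the feature
  space is hydrogen-bond lengths only.
- The GA assumes a complete matrix; run it after filling, not on raw
  detector output.
- `exhaustive_select()` is capped (default 5·10⁵ subsets); beyond the cap
  it refuses rather than silently sampling.
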