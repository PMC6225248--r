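---
title: "Binding energetics of beta-sheet aggregation inhibitors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding energetics of beta-sheet aggregation inhibitors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmflie)
library(tibble)
```

# Scope and scientific setting

Amyloid-beta (Aβ) oligomerization proceeds through β-sheet stacking of its
central self-recognition region, Aβ~13–23~ (HHGKLVFFAED), here called R.
Designed eight-residue pseudo-peptides (PPs) of d- and unnatural amino acids
with backbone N-methylation bind one hydrogen-bonding edge of that strand and
cap sheet propagation. Evaluating such inhibitors computationally requires
three layers of analysis on top of molecular-dynamics output, and those
layers are what `pmflie` implements:

1. **Umbrella-sampling free energies** — reconstruct the potential of mean
   force (PMF) along the centre-of-mass (COM) separation of a dimer from
   harmonically biased windows via WHAM, read the binding free energy off
   the curve, and attach Bayesian-bootstrap error bars.
2. **Endpoint estimators** — for complexes too flexible for umbrella
   sampling, estimate binding free energies from ensemble-averaged
   force-field energy components: Gas-PBSA and the linear interaction
   energy family LIE-S / LIE-D / LIE-DR, with block-averaged uncertainties.
3. **Conformational and contact statistics** — RMSD-cutoff clustering,
   intermolecular hydrogen bonds, salt-bridge monitors, COM separation and
   β-sheet registry, which give the per-cluster context in which the energy
   estimates are interpreted.

A fourth, first-class layer generates synthetic inputs (biased
reaction-coordinate samples from a known potential, autocorrelated energy
series, idealized β-sheet conformer pairs) so every downstream stage is
exercisable and testable without an MD engine. Running MD itself, docking,
and solving the Poisson–Boltzmann equation are out of scope; PBSA solvation
energies enter as pluggable inputs.

# The PMF layer

## Model

Window $w$ restrains the reaction coordinate $x$ (COM separation, nm) with a
harmonic bias $U_w(x) = \tfrac{k}{2}(x - c_w)^2$. WHAM combines the window
histograms into the unbiased distribution by iterating

$$p(x_b) = \frac{\sum_w n_w(b)}{\sum_w N_w \exp[(f_w - U_w(x_b))/k_BT]},
\qquad
f_w = -k_BT \ln \sum_b p(x_b)\, e^{-U_w(x_b)/k_BT}$$

to self-consistency, after which $G(x) = -k_BT \ln p(x)$, shifted so its
minimum is zero. The binding free energy is minus the difference between the
highest and lowest points of the profile, so a deeper well means a more
negative $\Delta G_\mathrm{binding}$.

## Parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| bias force constant $k$ | 1000 | kJ/(mol nm²) | standard pull-code stiffness for peptide dimer dissociation; bias width $\sqrt{k_BT/k} \approx 0.05$ nm at 310 K |
| window spacing | 0.1 | nm | twice the bias width, giving adjacent-histogram overlap well above the 0.05 diagnostic threshold |
| temperature | 310 | K | physiological |
| bin width | 0.01 | nm | resolves PMF features a few bin-widths wide while keeping per-bin counts high; exposed in every call |
| convergence tolerance | 1e-7 | kJ/mol | offsets converge linearly; this leaves discretization, not iteration, as the dominant error |
| equilibration discard | first 10 of 50 | ns | common per-window protocol; `equilibration_split()` applies it by time stamp |

$k_B = 0.008314462618$ kJ/(mol K) throughout; lengths are nm and energies
kJ/mol everywhere inside the package, with Angstrom appearing only at the
PDB boundary and kcal/mol only for the published LIE offset constant.

## Error bars

`bayesian_bootstrap_errors()` reweights each window's samples with
Dirichlet(1, …, 1) weights at the level of statistically independent
blocks. The block length is the integrated autocorrelation time estimated by
the initial-positive-sequence rule (adjacent autocorrelation pairs summed
until a pair turns negative), rounded up; with `autocorrelation = FALSE`
every frame is its own block. Each of the (by default 100) replicates
re-solves WHAM warm-started from the full-data offsets, and the per-bin
standard deviation across replicates is reported as the 1σ error, the same
convention as PMF error-bar plots. The bootstrap standard deviation of
$\Delta G_\mathrm{binding}$ itself is reported as `dg_sigma`.

## Numerical choices and degenerate inputs

- Bins never sampled by any window are excluded; a largest-contiguous-run
  mask is applied before taking the max and min so that stray tail bins
  cannot fabricate a span. If two adjacent windows share no occupied bin the
  reconstruction aborts with a coverage-gap diagnostic rather than bridging
  the gap silently (`overlap_report()` gives the quantitative version).
- All windows must share one temperature; multi-temperature WHAM is not
  implemented.
- Ties in the clustering neighbour count (below) and all orderings in
  reports are broken deterministically, so repeated runs are
  byte-identical under a fixed seed.

# The endpoint layer

All terms are ensemble averages over the frames of one conformational
cluster (`ensemble_average()` takes the frame mask from the clustering
layer). The controlled vocabulary distinguishes the unbound moieties (`PP`,
`Abeta`), the starred moieties inside the complex (`PP_complex`,
`Abeta_complex`), and the pair itself (`complex`, which carries the
interaction terms).

**Gas-PBSA.** $\Delta G = G_\mathrm{gas}(\mathrm{complex}) +
G_\mathrm{sol}(\mathrm{complex}) - \sum_{m \in \{PP, A\beta\}}
[G_\mathrm{gas}(m) + G_\mathrm{sol}(m)]$ with $G_\mathrm{gas}$ the sum of
electrostatic and van der Waals force-field terms and $G_\mathrm{sol}$ a
PBSA solvation energy supplied as input. No entropy term is added. A
generalized-Born/surface-area surrogate (`born_sasa_gsol()`) exists solely
so end-to-end tests can run; it is labelled non-physical and is not a
substitute for a Poisson–Boltzmann solver in production use.

**LIE-S.** $\Delta G = \beta\,\Delta_{es} + \alpha\,\Delta_{vdW}$ with
$\Delta_{es} = V_{int,es} + V_{sol,es}(PP^*) - V_{sol,es}(PP)$ and the
analogous van der Waals bundle; $\beta = 0.5$, $\alpha = 0.161$,
$\gamma = 0$.

**LIE-D.** Adds the ligand's intramolecular gas-phase electrostatics to the
polar bundle and an offset fitted through the polar/nonpolar balance
parameter $D = \beta\,\Delta_{es} - \alpha\,\Delta_{vdW}$:
$\gamma = f D + g$ with $f = -0.95$, $g = -2.06$ kcal/mol and
$\alpha = 0.18$, $\beta = 0.43$. Two conventions required a decision:

- The published offset fit does not state the unit of $D$; the package
  keeps $f$ dimensionless, applies it to $D$ in kJ/mol, and stores $g$
  internally as $-8.61904$ kJ/mol ($-2.06 \times 4.184$). Users preferring
  the kcal/mol reading can pass their own `f`/`g` through `lie_params()`.
- The intramolecular electrostatic symbol appears under two spellings in
  the source literature (a "bonded" and a "gas" form); the package treats
  them as one quantity, stored once as `gas_es`.
- The prescription to adjust $\beta$ for the ligand's functional groups is
  not algorithmized; $\beta$ is a plain scalar with default 0.43.

**LIE-DR.** The exact role reversal of LIE-D: every pseudo-peptide symbol is
replaced by its Aβ counterpart, motivated when the "protein" (full-length
Aβ) is the more flexible partner. With a decomposition symmetric in the two
roles, LIE-D and LIE-DR coincide, which is tested.

**Uncertainties.** Per-term σ comes from block averaging
(`block_average_sigma()`): the variance of block means is evaluated on a
logarithmic grid of block lengths and the plateau extracted by a weighted
least-squares fit of $\mathrm{BSE}^2(b) = A - B/b$ over blocks longer than
three autocorrelation times (the leading finite-block correction for a
correlated series), $\sigma = \sqrt{A}$. Estimator σ then follows by linear
propagation; with $\gamma = fD + g$ the effective scalings are
$\beta(1+f)$ on the polar and $\alpha(1-f)$ on the nonpolar bundle.

# The conformational layer

- **RMSD** uses the closed-form least-squares (SVD/Kabsch) superposition,
  mass-unweighted by default with a flag for mass weighting.
- **Clustering** is the GROMOS neighbour-count algorithm: the frame with
  the most neighbours within the cutoff becomes a centre, it and its
  neighbours are removed, and the process repeats; clusters are relabelled
  by descending population. The conventional cutoffs are 0.25 nm (all
  atoms, small rigid R complexes) and 0.35 nm (backbone, flexible
  full-length complexes).
- **Hydrogen bonds** use the geometric criterion donor–acceptor ≤ 0.35 nm
  and hydrogen–donor–acceptor angle ≤ 30° (the GROMACS convention of the
  tooling era; both cutoffs are arguments), counted over both donor
  directions between the two selections.
- **Salt bridges** report the per-frame minimum distance between side-chain
  charged-group atoms (Lys NZ; Arg NH1/NH2/NE; Glu OE1/OE2; Asp OD1/OD2;
  plus ornithine NZ and diaminobutyric-acid NG for the pseudo-peptides,
  all overridable), with existence defined as separation below 1 nm.
- **Registry** of an antiparallel sheet between R (Aβ numbering $i$) and a
  PP (natural numbering $j$) is the constant $i + j$ over paired residues;
  an inconsistent pairing is an error listing the offending pairs, and for
  parallel sheets the registry is reported as not applicable. When no
  pairing is supplied it is derived from the backbone–backbone hydrogen
  bond graph (`pairing_from_hbonds()`).

# The synthetic-data layer

`gen_umbrella_windows()` draws from the exact biased Boltzmann density by
inverse-CDF lookup on a fine grid — independence sampling was chosen over
Markov-chain Monte Carlo deliberately, so tests face no equilibration or
mixing questions and distributional checks (Kolmogorov–Smirnov against the
Gaussian closed forms) apply exactly. `gen_energy_series()` produces
stationary Gaussian AR(1) series with specified marginal mean, sd and lag-1
autocorrelation, emulating per-frame force-field terms.
`gen_beta_sheet_pair()` builds two idealized extended strands (backbone
atoms N, H, Cα, C, O at a 0.35 nm rise) whose paired residues satisfy the
hydrogen-bond criterion exactly at zero noise; conformational noise is an
isotropic per-atom Gaussian with per-coordinate sd `rmsd_noise`/√3 so the
expected displacement matches the requested RMSD scale.

The default double-well reference potential has wells of 32 and 12 kJ/mol
below baseline separated by an 8 kJ/mol barrier (all width 0.08 nm), so
the span between the highest and lowest points of the true curve — the
quantity `binding_dg()` estimates — is 40 kJ/mol, in the middle of the
32–62 kJ/mol range typical of peptide-dimer umbrella-sampling studies.

What the generators deliberately do **not** emulate: force-field
energetics, 3-D dynamics and kinetics, side-chain rotamers, solvent
structure, or correlations between energy components and conformation.
Passing tests therefore demonstrate the correctness of the estimators and
their statistical machinery on inputs with known ground truth; they say
nothing about force-field accuracy or sampling adequacy of any real
simulation.

# Problem sizes

The test-suite and reproduction-script workloads use 19 umbrella windows
of 2×10⁴ samples (0.1 nm spacing, k = 1000 kJ/(mol nm²), 310 K) for the
double-well recovery with 100 bootstrap replicates, five windows of 2×10⁴
for the harmonic closed-form comparison, AR(1) series of 2×10⁴–10⁵ frames
for the error-estimator calibrations, and ensembles of ~10 conformers for
the clustering checks — sizes at which the statistical tolerances asserted
in the tests (e.g. RMS < 0.5 kJ/mol for the harmonic PMF, ±20–25% on error
scalings) are comfortably resolvable.

# Known limitations

- Absolute endpoint estimates for real complexes require the original
  trajectories and per-frame energy tables; the package validates the
  estimator arithmetic, linearity/symmetry properties and error
  propagation, not published absolute values.
- Within one source table of published binding energies, one row's
  effectiveness value is inconsistent with the defining formula applied to
  its own inputs ($2\Delta G_{R\text{-}PP} - \Delta G_{RR} -
  \Delta G_{PP\text{-}PP}$ on $(-56, -53, -46)$ gives $-13$, not the
  printed $-3$); `dgeff_table()` recomputes and flags such rows rather
  than matching them.
- No multi-temperature WHAM, no 2-D PMFs, no MBAR generalization, no
  concentration/stoichiometry modelling beyond the 1:1 effectiveness
  statistic, and no secondary-structure assignment beyond the hydrogen-bond
  pairing needed for the registry.
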