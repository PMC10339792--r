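---
title: "Modelling small-angle scattering from core-shell peptide nanofibers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling small-angle scattering from core-shell peptide nanofibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibersas)
```

## The structural model

β-sheet-forming multidomain peptides such as K₃W(QL)₆K₂ assemble into long
fibers: two stacked antiparallel β-sheets whose leucine (and likely
tryptophan) side chains pack into a hydrophobic interior, shielded from
water by the peptide backbone and the hydrophilic glutamine/lysine
residues. `fibersas` models the fiber as a rectangular parallelepiped of
length $c$ with a nested cross-section:

* a **core** of dimensions $a_\mathrm{core} \times b_\mathrm{core}$,
* a **peptide shell** of thicknesses $a_\mathrm{shell}, b_\mathrm{shell}$,
  giving the envelope $a_\mathrm{pep} = a_\mathrm{core} + 2a_\mathrm{shell}$,
  $b_\mathrm{pep} = b_\mathrm{core} + 2b_\mathrm{shell}$,
* optionally a **PEG corona** of thickness $d$
  ($a_\mathrm{tot} = a_\mathrm{pep} + 2d$, likewise $b_\mathrm{tot}$).

Each rectangle contributes the amplitude
$$A(Q, \alpha; a, b) = \operatorname{sinc}\!\big(\tfrac{Q a \sin\alpha}{2}\big)\,
\operatorname{sinc}\!\big(\tfrac{Q b \cos\alpha}{2}\big),$$
normalised to 1 at $Q = 0$, where $\alpha$ is the rotation angle of the
cross-section about the fiber axis. The three nested rectangles are
superposed so that each *physical region* carries its own excess scattering
length density (SLD):
$$A_\mathrm{cs} = \Delta\rho_\mathrm{core} V_\mathrm{core} A_\mathrm{core}
 + \Delta\rho_\mathrm{shell} (V_\mathrm{pep} A_\mathrm{pep} - V_\mathrm{core} A_\mathrm{core})
 + \Delta\rho_\mathrm{PEG} (V_\mathrm{tot} A_\mathrm{tot} - V_\mathrm{pep} A_\mathrm{pep}).$$
For a non-PEGylated fiber ($d = 0$) the last term vanishes identically.

Because $c \gg a_\mathrm{tot}, b_\mathrm{tot}$, the longitudinal scattering
decouples into the orientational average of an infinitely thin rod,
$P_\mathrm{rod}(Q) = 2\,\mathrm{Si}(Qc)/(Qc) - \operatorname{sinc}^2(Qc/2)$,
and the absolute intensity is
$$I(Q) = \frac{\phi}{V_\mathrm{pep}}\Big[
  \big\langle |A_\mathrm{cs}(Q,\alpha)|^2 \big\rangle_\alpha P_\mathrm{rod}(Q)
  + N_\mathrm{agg}\,(\Delta\rho_\mathrm{PEG} V_\mathrm{PEG})^2 B(Q, R_g)
\Big] + \mathrm{bkg},$$
where $B$ is a unit-amplitude Beaucage form (Guinier part plus a
$Q^{-2}$ Gaussian-chain power law) describing the "blob" scattering of the
solvent-swollen PEG chains, $N_\mathrm{agg}$ the number of molecules per
fiber, and $\phi$ the **peptide** volume fraction.

### Normalisation choices

Two conventions are worth stating explicitly because they interact:

* Amplitudes are unitless (1 at $Q=0$); all contrast × volume weights are
  applied when the regions are superposed. This keeps each region's weight
  explicit, and makes the forward limit
  $I(0) - \mathrm{bkg} = \phi\,(\sum_i \Delta\rho_i V_i)^2 / V_\mathrm{pep}$
  (plus the blob forward value) an exact closed-form test of the
  quadrature, which the test suite verifies to 0.1%.
* The fiber number density is $\phi / V_\mathrm{pep}$, with $V_\mathrm{pep}$
  the peptide-envelope volume. $\phi$ is what a mass concentration gives
  (10 mg/mL at 1.25 g/mL ≈ 0.8%) and does not count the swollen corona;
  with this choice the intensity at a solvent contrast that matches the
  PEG SLD is *identical* to that of the corresponding bare ($d=0$) fiber,
  as it must be.

### Validity of the decoupling approximation

The geometry constructor warns when $c < 10\,\max(a_\mathrm{tot},
b_\mathrm{tot})$. At that boundary ($c = 10\,b_\mathrm{tot}$) the decoupled
intensity agrees with a brute-force orientational average of the nested
parallelepipeds over the full sphere to better than 5% everywhere in the
rod regime ($Qc > 10$), with a median deviation of about 1%; the largest
deviations sit in the deep form-factor minima, where the decoupled curve
slightly underestimates the filled-in minimum. At smaller aspect ratios
(e.g. $c = 5\,b_\mathrm{tot}$) the error in the minima grows to ~10%, which
is why the warning threshold sits at 10.

### What the model deliberately omits

* **Twist.** Simulations of these fibers show a slow helical twist; the
  scattering model omits it, as the α-average washes out its high-*Q*
  signature at the resolution of typical data.
* **Polydispersity**, in both length and cross-section: the fiber length is
  at the edge of the experimental resolution, and length polydispersity is
  not resolvable; leaving it out minimises the number of fit parameters.
* **Resolution smearing** is available (`smear_intensity()`, used when a
  curve carries a fourth ΔQ column) but off by default.

## Compositions, SLDs, and contrast

`material()` couples an elemental formula (D distinct from H) with a mass
density and a count of labile hydrogens. X-ray SLDs are electron density
times the classical electron radius; neutron SLDs sum bound coherent
scattering lengths. Molecular volumes always come from formula mass over
density (1 g/cm³ = 0.60221 Da/Å³), so H↔D substitution changes scattering
length but not volume.

Conventions adopted for peptides, chosen once on physical grounds:

* **Ionisation.** At neutral pH, lysine side chains are protonated (3
  labile N–H each) and carboxylates deprotonated. This is also the
  convention under which the molecule mass bookkeeping of the reference
  fiber closes: the hydrophobic core defined as 6 leucine + 1 tryptophan
  side chains weighs 473 Da/molecule and the remainder 1866 Da, matching
  the fitted per-region masses, and the computed region SLDs reproduce the
  published X-ray and neutron values within 1.5% — see
  `k3_fiber_materials()`.
* **Exchange.** Labile hydrogens (backbone amides, side-chain N–H/O–H,
  terminal amide) exchange fully with the solvent at equilibrium
  (`exchange_fraction = 1`, exposed as a parameter); the buried core indole
  N–H of the assembled fiber is treated as non-exchanging.
* **Dissolved-molecule density.** For molecular (dissolved) species such as
  the PEG–peptide conjugates, the peptide density defaults to 1.370 g/mL —
  the standard protein partial specific volume of 0.73 mL/g — rather than
  any fiber-state fitted density, which reflects packing rather than
  molecular volume.
* **Termini.** N-terminal acetyl and C-terminal amide by default
  (solid-phase synthesis on a Rink-type resin); both configurable.
  `sequence_mass()` reports the neutral covalent molecule.
* **Buffers.** Salts at the tens-of-mM level shift solvent SLDs by well
  under 1% and are ignored.

The **zero-average-contrast** (ZAC) solvent for a pair of h/d-labelled
conjugates is the D₂O fraction at which the solvent neutron SLD equals the
mean of the two conjugate SLDs. Both sides of that equation depend on the
solvent (through labile hydrogens), so `zac_match_point()` solves it by 1-D
root finding; the bracketing function is strictly monotone, so the root is
unique whenever it exists. With the conventions above, the
hPEG(1.9k)/dPEG(2.1k) conjugates of the reference peptide give ≈54% D₂O.

## Global fitting

`fit_problem()` + `fit()` refine one shared parameter set against any
number of datasets, each carrying its own contrast set and optional
nuisance scale (SANS absolute-calibration drift) and flat background.
Numerical choices:

* **Optimiser.** Bounded Levenberg–Marquardt trust region
  (`minpack.lm::nls.lm`, `ftol = ptol = 1e-10`). The α-averaged
  cross-section oscillations create local minima, so `fit()` runs a seeded
  multi-start (default 8 starts, multiplicative perturbations of ±30%
  clipped to bounds) and keeps the best optimum. Refitting from the
  returned optimum does not improve χ² beyond 1e-6 (tested), and the
  result is invariant to dataset order.
* **Quadrature.** The α-average uses Gauss–Legendre nodes on [0, π/2];
  during fitting the order is fixed at 256 for speed, while standalone
  evaluations double the order (up to 2048) until the average changes by
  less than 1e-4 relative. At 256 nodes the quadrature is already converged
  to much better than the data noise over the *Q* ranges used here.
* **Uncertainties** are covariance-based: (J'J)⁻¹ scaled by the reduced
  χ². They are meaningful near a well-conditioned optimum and should be
  read as 1σ curvature estimates, not posterior widths.
* **Fiber length.** When the Guinier regime lies outside the measured
  window, the fitted $c$ is a lower bound; its recovery tolerance is
  accordingly wide (15%) in the validation suite.
* **Derived quantities** ($N_\mathrm{agg}$, per-molecule core/shell
  masses) are recomputed from the best-fit geometry, densities, and the
  molecule mass at every report — never cached from inputs. When densities
  are supplied, the blob term's $N_\mathrm{agg}$ is likewise recomputed
  from the current geometry at every objective evaluation.

## The synthetic-data generator

The generator exists so that every analysis stage is testable end-to-end
without beamline data. It emulates:

* single curves on log-spaced grids of 0.004–0.7 Å⁻¹ with Gaussian noise
  σ(Q) = 2%·I + 10⁻³ cm⁻¹ (the quality of good synchrotron/reactor data;
  both knobs exposed), the σ column storing the generating σ;
* H₂O/D₂O contrast series with per-contrast region SLDs recomputed from
  compositions, so PEG match-out behaves correctly;
* time-resolved ZAC blend decays. Exchange is tracked as the mean-field
  h-fraction $x_1(t)$ of each population's corona (populations mirror:
  $x_2 = 1 - x_1$, conserving molecules). The `end_only` mechanism relaxes
  only the accessible fraction $2 n_\mathrm{end}/N_\mathrm{agg}$ and
  therefore plateaus above the fully mixed baseline; `uniform_unimer` and
  `breakup_reform` relax fully (single exponential). The relaxation
  function $R(t) = \sqrt{(I(t) - I_\infty)/(I(0) - I_\infty)}$ is reported,
  following the kinetic-ZAC convention, and equals
  $(x_1 - \tfrac12)/\tfrac12$ exactly in this mean-field picture.

What it does **not** emulate: instrument resolution smearing (unless
requested), incoherent backgrounds that vary with composition,
inter-particle structure factors in the fiber phase, labelling
*correlations* within a corona (mean-field only — fine at shell-contrast
level, where the intensity depends on the population-average corona SLD),
and any foam/sonication physics. Passing recovery tests on these synthetic
data therefore demonstrates correctness of the estimator pipeline under
the stated noise model, not robustness to every real-beamline artefact.

Determinism: every stochastic entry point takes a `seed`; seeded calls
save and restore the session RNG state, and identical seeds reproduce
identical bytes.

## Validation problem sizes

The shipped test-suite and the `scripts/acceptance.R` summary use problem
sizes chosen to exercise the estimators well inside a desktop-R budget:
150-point two-instrument pairs and 120-point five-contrast series at 2%
noise, 10 noise seeds for cross-section recovery (median errors ~1–4%,
bound 5%; length bound 15%) and 5 seeds for the PEG-layer recovery (median
error ≪ 1%, bound 10%), 8 optimiser starts throughout. The
full-orientation oracle uses 600 × 300 Gauss–Legendre nodes over the
sphere octant.

## Known limitations

* The rectangular cross-section is a deliberate idealisation; real
  cross-sections are neither perfectly sharp-edged nor monodisperse, and
  fitted shell thicknesses absorb some interfacial smearing.
* The screened-Coulomb structure factor is an RPA correction on a
  Percus–Yevick reference — adequate for locating and shaping a repulsion
  peak, not for quantitative charge regression.
* Exchange-kinetics simulation is mean-field and is validated by internal
  invariants and limiting cases (plateau, full-mixing limit, mechanism
  continuity), not against quantitative decay measurements.
* The ZAC composition depends on exchange and protonation assumptions at
  the 2–3 percentage-point level; the defaults above are physically
  motivated but alternatives (partial exchange, neutral lysines) are one
  argument away.
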