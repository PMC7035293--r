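---
title: "Measuring conformational ensembles of trimeric elevator transporters in nanodiscs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring conformational ensembles of trimeric elevator transporters in nanodiscs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimerscope)
library(dplyr)
```

## The measurement problem

Glutamate transporter homologues are homotrimers in which each protomer
works as an independent elevator: a mobile transport domain carrying the
substrate site slides along a static scaffold domain across the membrane,
and a helical hairpin (HP2) gates the site on both membrane sides. A
cryo-EM ensemble of such trimers in lipid nanodiscs therefore poses a set
of purely geometric questions per model:

* Where is each transport domain along the membrane normal (inward,
  intermediate-outward, outward)?
* Is the HP2 gate open or occluded, and by how much?
* How far does the transport domain travel between states?
* Does the nanodisc belt protein (MSP) — a proxy for the local membrane —
  stay planar or buckle around particular protomers?

And one statistical question per dataset: given a per-protomer binding
probability, what mixture of trimer compositions should the particle
classes show?

trimerscope answers these with a small set of composable measurements.
This vignette records the model behind each one, the tunable parameters,
the numerical choices, and what the synthetic-fixture validation does and
does not demonstrate.

## Rigid-body machinery

All superpositions are least-squares rigid fits (Kabsch, via SVD of the
3×3 covariance of centred coordinates). Reflections are excluded by
flipping the smallest singular direction when the best orthogonal map is
improper, so the rotation always has determinant +1. Fewer than 3 pairs,
mismatched lengths, or a (near-)collinear reference are errors — the
rotation would be undefined or degenerate.

RMSDs pair atoms by shared author residue number within a named domain and
are **Cα-only by default**. Published per-domain RMSDs for these proteins
rarely state the atom selection; Cα-only is the conservative reading and
the `atoms` argument makes all-atom pairing available. Cross-protein
comparisons (e.g. a Glt_Tk protomer against a Glt_Ph reference) have no
shared numbering, so they require an explicit two-column residue map in
the config rather than a silent guess.

### The pseudo-three-fold axis

The trimer is only *pseudo*-symmetric: the scaffolds obey C3 closely while
the transport domains may not. The axis is therefore estimated from the
scaffolds alone: for each ordered protomer pair the scaffold-to-scaffold
rotation is fitted, its rotation axis extracted, the three axes
sign-aligned and averaged. On an exact C3 assembly each pairwise rotation
is 120° and the axes coincide; conformational heterogeneity perturbs both,
so fitted rotation angles outside **100–140°** trigger a warning rather
than silent acceptance. The frame origin is the centroid of all scaffold
Cα atoms; θ = 0 points at the first protomer's scaffold centroid
(projected ⊥ axis). Deposited coordinates carry no membrane frame, so the
extracellular sign of the axis comes from a config-designated marker
residue known to lie on the outside (the mean of its axial coordinate over
the three protomers decides the sign); with no marker the sign defaults to
+1 and only relative axial measurements are meaningful.

## Per-protomer metrics and classification

* **Gate opening**: Euclidean Cα–Cα distance between the HP1-tip and
  HP2-tip marker residues of one protomer. In the nanodisc ensembles this
  is ~4.4 Å when occluded, ~9.3 Å when open, and ~14 Å with a bulky
  inhibitor wedged in.
* **Gate displacement**: superpose two protomers on HP1 Cα, report the
  HP2-tip Cα distance — how far the gate itself moved between two states.
* **Elevator travel**: superpose on the scaffold, report the HP1-tip Cα
  distance — the across-the-membrane excursion of the transport domain
  (up to ~24 Å between inward and fully-outward).
* **Radial displacement**: signed change of a selection's Cα-centroid
  distance from the axis, positive outward — e.g. the ~4 Å outward shift
  of the TM7 C-half/HP2/TM8 N-half block on substrate binding.
* **Marker displacement**: the generic anchored-marker distance, used for
  side chains (the Met314 sulfur reports the TM7 unwound-region switch).
  The side chain's terminal SD atom is the default because published
  side-chain "distances" for this residue name no atom; a
  `side_chain_max` flag takes the maximum over shared side-chain atoms
  instead.

Classification is deliberately dumb and deterministic: the **elevator
coordinate** (axial position of the transport-domain Cα centroid minus the
scaffold Cα centroid) is cut at `t_in_A` and `t_out_A`, and the gate is
`open` iff the tip distance strictly exceeds `gate_open_A`. Values exactly
at a cut point go to the more-outward class — a fixed tie rule matters
more than its direction. Defaults:

| parameter | default | rationale |
|---|---|---|
| `t_in_A` | −5 Å | midway between inward (≈ −10 to −12 Å) and intermediate (≈ 0 to +2 Å) positions seen in reference structures |
| `t_out_A` | +5 Å | midway between intermediate and fully-outward (≈ +8 to +12 Å) positions |
| `gate_open_A` | 6.5 Å | midpoint of the occluded (~4.4 Å) and open (~9.3 Å) tip distances |

These live in the YAML config, not in code: published state labels are
qualitative, so the cut points are a calibration the user can re-pin
against reference structures for another protein. Likewise the domain
residue ranges are config, never hardcoded — the shipped `glttk.yaml`
carries ranges curated from the published Glt_Tk/Glt_Ph topology (scaffold
TM1/2/4/5; transport TM3/6/7/8 + HP1/HP2; HP2 tip Val358; HP1 apex pinned
at residue 279 by topology since no publication names it), flagged in the
file as defaults to verify against the specific deposition.

## Belt profiles

In the oriented frame every belt atom reduces to (θ, h, r): bearing,
height along the membrane normal, distance from the axis. The profile is
the per-bin arithmetic mean of h (and r) over **2° bins** of θ, using
**all belt atoms** by default — the published profiles plot all modeled
MSP atoms, and a Cα-only flag exists. No smoothing is applied: smoothing
is exactly what would hide buckling, the signal of interest. Empty bins
stay in the table with `NA` means rather than being interpolated away.

Buckling statistics use the circular mean height as baseline (the belt's
absolute height is arbitrary): peak-to-peak range and RMS deviation over
non-empty bins, plus per-sector ranges when a sector map is supplied.
Sector annotation walks 1° steps and assigns each to the protomer domain
whose Cα atoms subtend that bearing (ties to the innermost domain, since
the belt wraps the outermost protein surface but the question is which
protomer sits under it). The belt diameter is twice the mean Cα radius —
with the belt wrapped tightly around the trimer this lands at ~10–11 nm
rather than the nominal free-disc diameter of the scaffold protein.

One convention deserves a note: descriptions of these plots sometimes call
the vertical axis the "y-coordinate" while defining z as the symmetry
axis. trimerscope reads that as the figure's vertical plot axis and always
profiles the **axial (membrane-normal) coordinate** of the oriented frame.

## Occupancy and trimer compositions

Binding experiments for structure determination run at micromolar protein,
so ligand depletion can be material. `fraction_bound()` solves the
single-site mass balance exactly (stable quadratic root, clamped to
[0, min(S, L′)]), with `active_fraction` scaling the competent ligand —
0.5 for a racemic inhibitor of which only one enantiomer binds. S = 0
falls back to the familiar L′/(K_d + L′) and is flagged. Sodium binding is
lumped into a single per-protomer two-state event even though three ions
bind: the binomial argument over whole-protomer states is what the class
mixtures test.

Compositions per trimer follow Binomial(3, p) (multinomial for ≥3
per-protomer states, enumerated exactly). `fit_occupancy()` inverts this:
the MLE of p from composition-keyed particle counts (closed form when all
compositions were observable; a renormalised likelihood, flagged, when
only a subset was reconstructable), with a likelihood-ratio goodness-of-fit
against the saturated multinomial. Percentages round half away from zero
to match how such numbers are printed.

## The synthetic generator: what it does and does not show

`build_trimer()` constructs single-Cα-bead protomers: helical scaffold and
transport clusters (whole numbers of helix turns, so cluster centroids are
exactly their construction centres), HP1/HP2 clusters riding on the
transport domain, single-atom hairpin tips at an exact separation, and a
two-atom Met-like marker. Protomers are placed by exact 120° rotations
*before* per-protomer offsets, so the ground-truth axis is exact; Gaussian
noise is added *after* truths are recorded and a global pose last. The
default conditions mirror the nanodisc study design: scaffold ring radius
28 Å, belt radius 52.5 Å (10.5 nm diameter), gate distances 9.3/4.4 Å,
inward protomers at −12 Å and fully-outward at +12 Å so the inward ↔
fully-outward HP1-tip travel is the published 24 Å, and 0.2 Å coordinate
noise as a stand-in for model uncertainty at ~3.2–3.5 Å resolution.

Because every construction parameter maps linearly onto exactly one
measurement, recovery tests are sharp: at zero noise all metrics must hit
the truth to 0.01 Å (the PDB format itself quantises at 0.001 Å), and
under noise σ they must track within ~3σ/√N. What these fixtures do **not**
emulate: real secondary structure, domain rotation coupled to translation
(real elevator motion is a screw, so axial separation and tip travel are
not identical as they are here), partial occupancies, or correlated
coordinate error. Passing the fixture suite therefore validates the
*measurement machinery*, not the biological calibration of thresholds —
that calibration remains a config responsibility checked against reference
structures.

## Numerical choices and edge cases

* Altlocs: highest occupancy wins, ties by altloc letter — deposited
  transporter models are single-conformer, this only guards edge cases.
* Author residue numbering is preserved verbatim; all pairing is by author
  number (published residue names like Val358 only make sense that way).
* Distances are computed and stored at full precision; rounding to 0.1 Å
  happens only at CSV serialization, matching the field's printing
  convention.
* Degenerate inputs fail loudly: <3 superposition pairs, collinear
  references, empty mandatory markers, zero belt atoms, all-atoms-in-one-bin
  profiles, zero total particle counts.
* Determinism: identical inputs and config give byte-identical reports;
  all randomness in the generator is seed-controlled.

## Problem sizes

The shipped test suite and the acceptance script run on fixtures of 3 ×
~140 beads per trimer, belts of 360–1440 atoms, 10,000-draw binomial
samples, and a five-structure synthetic ensemble (15 protomers) — sizes
chosen so the full validation completes in well under a minute while the
statistical checks (axis recovery under noise, occupancy refits) still
have the power their tolerances assume.

## Known limitations

* The elevator coordinate is a 1-D projection; protomers caught mid-screw
  could classify differently from a rotation-aware metric.
* Axis estimation assumes the three scaffolds are genuinely similar; a
  partially unfolded or badly fitted scaffold drags the axis (the
  100–140° warning is the guard).
* Cross-protein RMSDs are only as good as the supplied residue map; no
  sequence alignment is performed by design.
* The occupancy model is equilibrium, single-site, non-cooperative; it is
  the model the class-mixture reasoning assumes, not a kinetic description.
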