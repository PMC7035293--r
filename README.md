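# trimerscope

Quantitative geometry and state-occupancy analysis of homotrimeric
**elevator-type transporters** (glutamate transporter homologues such as
Glt_Tk/Glt_Ph) reconstituted in **lipid nanodiscs**.

Single-particle cryo-EM of these transporters yields ensembles of trimers
whose three protomers move independently: each protomer's mobile *transport
domain* slides along the static *scaffold domain* across the membrane
(inward / intermediate-outward / outward), while the HP2 hairpin gates the
substrate site (open / occluded). trimerscope turns deposited or synthetic
coordinate models of such ensembles into numbers:

* **Rigid-body geometry** — Kabsch superposition and RMSD
  (`kabsch_superpose()`, `rmsd_between()`), estimation of the trimer's
  pseudo-three-fold axis from pairwise scaffold superpositions
  (`pseudo_threefold_axis()`), and reorientation into that frame
  (`orient_to_axis()`).
* **Per-protomer conformational metrics** — HP1/HP2 gate-tip distance
  (`gate_opening()`), HP1-anchored HP2 displacement (`gate_displacement()`),
  scaffold-anchored elevator travel of the HP1 tip (`elevator_travel()`),
  radial displacement of selections from the axis
  (`radial_displacement()`), side-chain marker movement
  (`marker_displacement()`), and threshold-based state classification
  (`classify_protomer()`, `protomer_report()`).
* **Nanodisc belt profiling** — height-versus-perimeter profiles of the
  membrane-scaffold (MSP) belt protein around the axis
  (`belt_height_profile()`), buckling statistics (`buckling_stats()`), belt
  diameter (`belt_diameter()`) and perimeter sector annotation
  (`annotate_sectors()`); belt buckling reports local membrane deformation.
* **State occupancy** — single-site equilibrium binding with ligand
  depletion, p = B/S with B the root of B² − (S+L′+K_d)B + SL′ = 0
  (`fraction_bound()`), exact binomial/multinomial distributions of
  protomer states per trimer, P(k) = C(n,k) p^k (1−p)^(n−k)
  (`trimer_state_distribution()`), observed class fractions
  (`observed_state_fractions()`) and a maximum-likelihood fit of p to
  composition counts with goodness-of-fit (`fit_occupancy()`, with broom
  `tidy()`/`glance()` methods).
* **Synthetic ground truth** — a deterministic generator of C3 trimer +
  belt fixtures in standard PDB with JSON sidecar truths
  (`build_trimer()`, `build_belt()`, `write_fixture()`), used throughout
  the test suite.

Everything is tibble-in / tibble-out and pipe-friendly; `autoplot()`
methods draw the belt profile and protomer-state figures. PDB/mmCIF I/O
goes through bio3d; domain definitions, chain roles and thresholds ship in
per-protein YAML configs (`inst/extdata/glttk.yaml`,
`inst/extdata/synthetic.yaml`).

## Worked example

```r
library(trimerscope)
library(dplyr)

# a nanodisc trimer: two inward-open protomers (gate 9.3 Å), one
# intermediate-outward occluded (4.4 Å), with 0.2 Å coordinate noise and a
# belt that buckles over protomer A
spec <- trimer_spec(elevator_offsets = c(-12, -12, 2),
                    gate_tip_distances = c(9.3, 9.3, 4.4),
                    noise_sigma = 0.2, seed = 42)
tr <- build_trimer(spec)
disc <- build_belt(belt_spec(radius = 52.5, n_atoms = 360,
                             height = list(type = "sector_bump", center_deg = 0,
                                           amplitude = 5, width_deg = 100)),
                   attach_to = tr$model)
analysis <- analyze_structure(disc$model, synthetic_config())
analysis
#> <transporter_analysis> synthetic_trimer
#> # A tibble: 3 × 6
#>   chain elevator_coordinate_A tip_distance_A position_label       gate_label
#>   <chr>                 <dbl>          <dbl> <chr>                <chr>
#> 1 A                    -12.1            9.26 inward               open
#> 2 B                    -12.0            9.49 inward               open
#> 3 C                      2.05           4.41 intermediate-outward occluded
#> # ℹ 1 more variable: ligand_label <chr>
#> belt: diameter 10.50 nm, buckling peak-to-peak 4.99 A
```

The elevator coordinate is the axial position (Å, extracellular positive)
of the transport-domain centroid relative to the scaffold centroid in the
trimer's axis frame: −12 Å puts the domain inward, +2 Å intermediate. The
tip distances recover the constructed gate openings to within the noise,
and the belt reports the 10.5 nm diameter and the 5 Å buckle built in.

```r
# does 50 µM aspartate saturate 16.8 µM binding sites at Kd = 120 nM?
fraction_bound(tibble(site_uM = 16.8, ligand_uM = 50, kd_uM = 0.12))
#>   site_uM ligand_uM kd_uM active_fraction p_bound bound_uM no_depletion
#> 1    16.8        50  0.12               1   0.996     16.7 FALSE

# trimer compositions at 70% per-protomer occupancy
trimer_state_distribution(0.7)
#>       k probability
#> 1     0       0.027
#> 2     1       0.189
#> 3     2       0.441
#> 4     3       0.343
```

So that condition saturates (p ≈ 0.996), and at p = 0.7 the most likely
trimer carries 2 occupied protomers — the binomial reasoning used to
interpret mixed particle classes at sub-saturating ligand.

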