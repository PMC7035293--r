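# Default analysis configuration for Glt_Tk trimers in MSP2N2 nanodiscs.
#
# Residue ranges are curated defaults from the published Glt_Tk/Glt_Ph
# topology (scaffold = TM1, TM2, TM4, TM5; transport = TM3, TM6, TM7, TM8
# plus hairpins HP1 and HP2; HP2 tip anchored at Val358, TM7 unwound region
# around Met314). Verify them against the specific deposition you analyse —
# domain boundaries shift by a few residues between models — and adjust the
# chain ids: protomer chains are A/B/C in the nanodisc depositions and the
# MSP2N2 belt chains vary between entries.
protein: GltTk
chain_roles:
  A: protomer
  B: protomer
  C: protomer
  M: belt
  N: belt
domains:
  scaffold:
    # TM1, TM2, TM4, TM5
    ranges: [[6, 38], [44, 78], [125, 180], [184, 215]]
    atoms: [CA]
  transport:
    # TM3, TM6, HP1, TM7, HP2, TM8
    ranges: [[84, 118], [222, 254], [261, 293], [294, 329], [343, 375], [380, 414]]
    atoms: [CA]
  HP1:
    ranges: [[261, 293]]
    atoms: [CA]
  HP2:
    ranges: [[343, 375]]
    atoms: [CA]
  hp1_tip:
    # hairpin apex between HP1a and HP1b (the HP2 tip is Val358; the HP1
    # apex is fixed here from topology)
    ranges: [[279, 279]]
    atoms: [CA]
  hp2_tip:
    # Val358
    ranges: [[358, 358]]
    atoms: [CA]
  met314:
    ranges: [[314, 314]]
    atoms: [CA, SD]
  tm7_c_half:
    ranges: [[315, 329]]
    atoms: [CA]
  hp2_helices:
    ranges: [[343, 375]]
    atoms: [CA]
  tm8_n_half:
    ranges: [[380, 395]]
    atoms: [CA]
thresholds:
  # elevator-coordinate cut points (A) calibrated on reference structures:
  # fully-outward ~ +8..+10 (aspartate-bound crystal / TBOA-open states),
  # inward ~ -8..-10 (inward-occluded reference); intermediate in between
  t_in_A: -5
  t_out_A: 5
  # midpoint of the occluded (~4.4 A) and open (~9.3 A) tip distances
  gate_open_A: 6.5
bin_width_deg: 2
out_marker:
  # HP2 tip: extracellular in the outward/intermediate-outward protomers
  # that dominate every deposition
  residue: 358
  atom: CA
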