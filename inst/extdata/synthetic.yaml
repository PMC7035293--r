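# Analysis configuration matching the synthetic fixture generator
# (single-CA bead protomers, chains A/B/C; belt chains M/N).
protein: synthetic
chain_roles:
  A: protomer
  B: protomer
  C: protomer
  M: belt
domains:
  scaffold:
    ranges: [[1, 40]]
    atoms: [CA]
  transport:
    ranges: [[101, 140]]
    atoms: [CA]
  HP1:
    ranges: [[151, 158]]
    atoms: [CA]
  HP2:
    ranges: [[161, 168]]
    atoms: [CA]
  hp1_tip:
    ranges: [[201, 201]]
    atoms: [CA]
  hp2_tip:
    ranges: [[205, 205]]
    atoms: [CA]
  met314:
    ranges: [[314, 314]]
    atoms: [CA]
  tm7_c_half:
    ranges: [[120, 126]]
    atoms: [CA]
  hp2_helices:
    ranges: [[161, 168]]
    atoms: [CA]
  tm8_n_half:
    ranges: [[131, 137]]
    atoms: [CA]
thresholds:
  t_in_A: -5
  t_out_A: 5
  gate_open_A: 6.5
bin_width_deg: 2
out_marker:
  residue: 40
  atom: CA
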