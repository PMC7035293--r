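# shared fixture builders for the test suite (all deterministic)

syn_cfg <- synthetic_config()

# a small trimer: two inward-open protomers, one intermediate-outward occluded
default_trimer <- function(...) {
  build_trimer(trimer_spec(elevator_offsets = c(-10, -10, 2),
                           gate_tip_distances = c(9.3, 9.3, 4.4), ...))
}

random_rotation <- function(seed) {
  set.seed(seed)
  ax <- unitize_t(rnorm(3))
  ang <- runif(1, 0.2, 3)
  rotation_about(ax, ang)
}

unitize_t <- function(v) v / sqrt(sum(v^2))

# Rodrigues rotation matrix: angle in radians about unit axis
rotation_about <- function(axis, angle) {
  k <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

random_pose <- function(seed) {
  set.seed(seed + 1000)
  list(rotation = random_rotation(seed), translation = runif(3, -30, 30))
}

angle_between_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, max(-1, ca))) * 180 / pi
}

# minimal single-atom PDB text
one_atom_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA  ALA A  17      11.104  -2.500   3.250  1.00 20.00           C",
    "END"), path)
  path
}
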