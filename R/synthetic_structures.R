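#' Specification of a synthetic trimer fixture
#'
#' Describes a C3(-ish) homotrimer of pseudo-protomers built from single-Cα
#' bead "residues": per protomer a rigid scaffold cluster on a ring about the
#' z axis, a transport cluster whose axial position is set by
#' `elevator_offsets`, HP1/HP2 clusters riding on the transport domain,
#' hairpin tip marker atoms at a controllable separation
#' (`gate_tip_distances`), a controllable radial offset of the transport
#' domain, and a two-atom Met-like marker residue whose side-chain position
#' is set by `marker_offsets`. Residue numbering matches
#' [synthetic_config()], so the same selection logic works on fixtures and
#' real depositions. Protomers are placed by exact 120° rotations before the
#' per-protomer offsets; Gaussian coordinate noise (applied after the ground
#' truth is recorded) and a global rigid pose (applied last) are optional.
#'
#' @param elevator_offsets Length-3 numeric, Å: axial position of each
#'   transport-domain centroid relative to its scaffold centroid.
#' @param gate_tip_distances Length-3 numeric, Å: HP1-tip to HP2-tip
#'   distance per protomer.
#' @param radial_offsets Length-3 numeric, Å: extra radial displacement of
#'   each transport domain (and everything riding on it).
#' @param marker_offsets Length-3 numeric, Å: axial displacement of the
#'   Met-marker side-chain atom relative to its reference position.
#' @param scaffold_radius Ring radius of the scaffold centres, Å.
#' @param atoms_per_domain Beads per scaffold/transport cluster.
#' @param noise_sigma Isotropic Gaussian coordinate noise, Å.
#' @param pose Optional global rigid pose: list with `rotation` (3 x 3) and
#'   `translation` (length 3).
#' @param seed Integer seed fixing all randomness.
#' @return A `trimer_spec` list.
#' @export
trimer_spec <- function(elevator_offsets = c(-10, -10, 2),
                        gate_tip_distances = c(9.3, 9.3, 4.4),
                        radial_offsets = c(0, 0, 0),
                        marker_offsets = c(0, 0, 0),
                        scaffold_radius = 28,
                        atoms_per_domain = 40,
                        noise_sigma = 0,
                        pose = NULL,
                        seed = 1) {
  for (nm in c("elevator_offsets", "gate_tip_distances", "radial_offsets", "marker_offsets")) {
    v <- get(nm)
    if (length(v) != 3 || !is.numeric(v)) abort(paste0(nm, " must be numeric length 3"))
  }
  if (any(gate_tip_distances < 0)) abort("gate_tip_distances must be >= 0")
  if (scaffold_radius <= 0) abort("scaffold_radius must be positive")
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")
  structure(list(elevator_offsets = elevator_offsets,
                 gate_tip_distances = gate_tip_distances,
                 radial_offsets = radial_offsets,
                 marker_offsets = marker_offsets,
                 scaffold_radius = scaffold_radius,
                 atoms_per_domain = atoms_per_domain,
                 noise_sigma = noise_sigma,
                 pose = pose, seed = seed),
            class = "trimer_spec")
}

# deterministic helical bead cluster whose centroid is exactly `center`:
# `turns` full turns over n beads, rise centred on zero
helix_beads <- function(center, u, v, w, n, radius = 5, turns = NULL, rise = 1) {
  if (is.null(turns)) turns <- max(1, round(n / 3.6))
  i <- seq_len(n)
  ang <- 2 * pi * turns * (i - 1) / n
  along <- (i - (n + 1) / 2) * rise
  # sum(cos) = sum(sin) = 0 over whole turns, so the centroid is `center`
  t(vapply(seq_len(n), function(j) {
    center + radius * cos(ang[j]) * u + radius * sin(ang[j]) * v + along[j] * w
  }, numeric(3)))
}

protomer_atoms <- function(p, spec) {
  phi <- deg2rad(120 * (p - 1))
  u <- c(cos(phi), sin(phi), 0)   # radial
  v <- c(-sin(phi), cos(phi), 0)  # tangential
  w <- c(0, 0, 1)
  rs <- spec$scaffold_radius
  elev <- spec$elevator_offsets[p]
  rad <- spec$radial_offsets[p]
  gate <- spec$gate_tip_distances[p]
  mark <- spec$marker_offsets[p]
  n <- spec$atoms_per_domain

  s_center <- rs * u
  t_center <- (rs + 12 + rad) * u + elev * w
  rows <- list()
  add <- function(resnos, coords, atom = "CA", resid = "ALA", element = "C") {
    rows[[length(rows) + 1]] <<- tibble(
      resno = resnos, resid = resid, atom = atom, element = element,
      x = coords[, 1], y = coords[, 2], z = coords[, 3])
  }
  add(1:n, helix_beads(s_center, u, v, w, n, radius = 5, turns = 11, rise = 1))
  add(100 + (1:n), helix_beads(t_center, u, v, w, n, radius = 5, turns = 11, rise = 1))
  add(151:158, helix_beads(t_center + 2 * u - 8 * w, u, v, w, 8, radius = 3, turns = 2, rise = 1))
  hp1_tip <- t_center + 4 * u - 12 * w
  hp2_tip <- hp1_tip + gate * v
  add(161:168, helix_beads(t_center + 4 * u - 10 * w + gate * v, u, v, w, 8,
                           radius = 3, turns = 2, rise = 1))
  add(201L, matrix(hp1_tip, 1, 3), resid = "GLY")
  add(205L, matrix(hp2_tip, 1, 3), resid = "VAL")
  met_ca <- t_center - 2 * u + 3 * w
  met_sd <- met_ca + 2 * v + mark * w
  rows[[length(rows) + 1]] <- tibble(
    resno = c(314L, 314L), resid = "MET", atom = c("CA", "SD"),
    element = c("C", "S"),
    x = c(met_ca[1], met_sd[1]), y = c(met_ca[2], met_sd[2]),
    z = c(met_ca[3], met_sd[3]))
  bind_rows(rows)
}

#' Build a synthetic trimer with ground truth
#'
#' Constructs the trimer described by a [trimer_spec()] as chains A/B/C and
#' returns both the [structure_model()] and a ground-truth list: the
#' (post-pose) axis and origin, and the per-protomer elevator coordinates,
#' tip distances, radial and marker offsets as built (pre-noise by
#' definition).
#'
#' @param spec A [trimer_spec()].
#' @return List with elements `model` and `truth`.
#' @export
build_trimer <- function(spec) {
  chains <- c("A", "B", "C")
  atoms <- purrr::map_dfr(1:3, function(p) {
    protomer_atoms(p, spec) %>% mutate(chain = chains[p], .before = 1)
  })
  truth <- list(
    kind = "trimer",
    chains = chains,
    axis = c(0, 0, 1),
    origin = c(0, 0, 0),
    elevator_offsets = spec$elevator_offsets,
    gate_tip_distances = spec$gate_tip_distances,
    radial_offsets = spec$radial_offsets,
    marker_offsets = spec$marker_offsets,
    scaffold_radius = spec$scaffold_radius,
    atoms_per_protomer = nrow(atoms) / 3,
    noise_sigma = spec$noise_sigma,
    seed = spec$seed
  )
  m <- coord_matrix(atoms)
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    m <- m + matrix(rnorm(length(m), sd = spec$noise_sigma), nrow(m), 3)
  }
  if (!is.null(spec$pose)) {
    m <- m %*% t(spec$pose$rotation) +
      matrix(spec$pose$translation, nrow(m), 3, byrow = TRUE)
    truth$axis <- as.vector(spec$pose$rotation %*% c(0, 0, 1))
    truth$origin <- as.vector(spec$pose$translation)
  }
  atoms <- set_coords(atoms, m)
  model <- structure_model(atoms, identifier = "synthetic_trimer",
                           chain_roles = setNames(rep("protomer", 3), chains))
  list(model = model, truth = truth)
}

#' Specification of a synthetic nanodisc belt
#'
#' A circular ring of pseudo-atoms emulating the membrane-scaffold belt
#' protein: `n_atoms` beads uniformly spaced in bearing at radius `radius`,
#' with height given by a named height function — `flat`, a `sinusoid`
#' `A * sin(freq * (theta - phase))`, or a `sector_bump` (raised-cosine bump
#' of a given amplitude and angular width centred on a sector).
#'
#' @param radius Belt radius, Å.
#' @param n_atoms Beads per chain (>= 3).
#' @param height Height function: `list(type = "flat")`,
#'   `list(type = "sinusoid", amplitude =, frequency =, phase_deg = 0)`, or
#'   `list(type = "sector_bump", center_deg =, amplitude =, width_deg =)`.
#' @param n_chains 1 or 2 belt chains (two stacked rings separated by
#'   `chain_separation`).
#' @param chain_separation Axial separation of the two rings, Å.
#' @param z0 Baseline height, Å.
#' @param seed Integer seed (reserved; the belt itself is deterministic).
#' @return A `belt_spec` list.
#' @export
belt_spec <- function(radius = 52.5, n_atoms = 720,
                      height = list(type = "flat"),
                      n_chains = 1, chain_separation = 10, z0 = 0, seed = 1) {
  if (radius <= 0) abort("belt radius must be positive")
  if (n_atoms < 3) abort("belt needs at least 3 atoms")
  if (!height$type %in% c("flat", "sinusoid", "sector_bump")) {
    abort("height$type must be flat, sinusoid or sector_bump")
  }
  if (!n_chains %in% 1:2) abort("n_chains must be 1 or 2")
  structure(list(radius = radius, n_atoms = n_atoms, height = height,
                 n_chains = n_chains, chain_separation = chain_separation,
                 z0 = z0, seed = seed),
            class = "belt_spec")
}

belt_height_fn <- function(height) {
  switch(height$type,
    flat = function(theta_deg) rep(0, length(theta_deg)),
    sinusoid = function(theta_deg) {
      height$amplitude * sin(height$frequency *
                               deg2rad(theta_deg - (height$phase_deg %||% 0)))
    },
    sector_bump = function(theta_deg) {
      d <- (theta_deg - height$center_deg + 180) %% 360 - 180
      ifelse(abs(d) < height$width_deg / 2,
             height$amplitude * 0.5 * (1 + cos(2 * pi * d / height$width_deg)),
             0)
    })
}

#' Build a synthetic belt, optionally attached to a trimer model
#'
#' Belt atoms are placed at `(r cos(theta), r sin(theta), z0 + h(theta))` for
#' uniformly spaced bearings; chains are named M (and N). The analytic
#' ground truth (diameter, buckling peak-to-peak of the height function) is
#' attached.
#'
#' @param spec A [belt_spec()].
#' @param attach_to Optional [structure_model()] (e.g. from [build_trimer()])
#'   the belt chains are appended to; chain-id collisions are an error.
#' @return List with elements `model` and `truth`.
#' @export
build_belt <- function(spec, attach_to = NULL) {
  hfun <- belt_height_fn(spec$height)
  chains <- c("M", "N")[seq_len(spec$n_chains)]
  z_off <- if (spec$n_chains == 2) c(-0.5, 0.5) * spec$chain_separation else 0
  atoms <- purrr::map_dfr(seq_len(spec$n_chains), function(ci) {
    # half-step phase: atoms sample angular bins symmetrically about centres
    theta <- 360 * (seq_len(spec$n_atoms) - 0.5) / spec$n_atoms
    tibble(chain = chains[ci],
           resno = seq_len(spec$n_atoms),
           resid = "ALA", atom = "CA", element = "C",
           x = spec$radius * cos(deg2rad(theta)),
           y = spec$radius * sin(deg2rad(theta)),
           z = spec$z0 + z_off[ci] + hfun(theta))
  })
  theta_fine <- seq(0, 360, by = 0.1)
  h_fine <- hfun(theta_fine)
  truth <- list(kind = "belt",
                chains = chains,
                radius = spec$radius,
                diameter_nm = 2 * spec$radius / 10,
                height = spec$height,
                buckling_peak_to_peak = max(h_fine) - min(h_fine),
                n_atoms = spec$n_atoms * spec$n_chains)
  if (!is.null(attach_to)) {
    clash <- intersect(chains, unique(attach_to$chain))
    if (length(clash) > 0) {
      abort(paste0("belt chain id(s) ", paste(clash, collapse = ","),
                   " already used by the model"))
    }
    roles <- attr(attach_to, "chain_roles") %||%
      setNames(rep("other", length(unique(attach_to$chain))), unique(attach_to$chain))
    roles <- c(roles, setNames(rep("belt", length(chains)), chains))
    combined <- bind_rows(as_tibble(attach_to), atoms)
    model <- structure_model(combined, identifier = model_identifier(attach_to),
                             chain_roles = roles)
  } else {
    model <- structure_model(atoms, identifier = "synthetic_belt",
                             chain_roles = setNames(rep("belt", length(chains)), chains))
  }
  list(model = model, truth = truth)
}

#' Write a fixture: PDB coordinates, JSON ground truth, YAML config
#'
#' Lays out a fixture directory (`fixture.pdb`, `truth.json`,
#' `config.yaml`) such that analysing the written PDB with the written
#' config reproduces the sidecar truths within the PDB coordinate precision
#' (0.001 Å) plus any construction noise.
#'
#' @param model A [structure_model()] (trimer, belt or both).
#' @param truth Ground-truth list (e.g. merged truths of [build_trimer()] and
#'   [build_belt()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(model, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_structure(model, file.path(dir, "fixture.pdb"))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- synthetic_config()
  roles <- attr(model, "chain_roles")
  cfg_list <- list(
    protein = "synthetic",
    chain_roles = as.list(roles),
    domains = lapply(cfg$domains, function(d) {
      list(ranges = lapply(d$ranges, as.integer), atoms = d$atoms)
    }),
    thresholds = cfg$thresholds,
    bin_width_deg = cfg$bin_width_deg,
    out_marker = cfg$out_marker
  )
  yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a fixture directory back
#'
#' @param dir Fixture directory written by [write_fixture()].
#' @return List with `model` ([structure_model()], chain roles from the
#'   config), `truth` (list) and `config` ([analysis_config()]).
#' @export
read_fixture <- function(dir) {
  config <- read_analysis_config(file.path(dir, "config.yaml"))
  model <- read_structure(file.path(dir, "fixture.pdb"),
                          chain_roles = config$chain_roles)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  list(model = model, truth = truth, config = config)
}
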