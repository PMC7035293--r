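#' HP1/HP2 gate opening of one protomer
#'
#' Euclidean distance between the Calpha atoms of the HP1-tip and HP2-tip
#' marker residues within one protomer. ~4.4 Å indicates an occluded gate,
#' ~9.3 Å an open one, and a bulky inhibitor wedged in the gate pushes it to
#' ~14 Å.
#'
#' @param model A [structure_model()].
#' @param chain Protomer chain id.
#' @param config An [analysis_config()] providing `hp1_tip` and `hp2_tip`
#'   domains (or a named list of domain definitions).
#' @return Tip distance in Å.
#' @export
gate_opening <- function(model, chain, config) {
  doms <- config_domains(config)
  a <- single_marker_atom(model, chain, doms$hp1_tip)
  b <- single_marker_atom(model, chain, doms$hp2_tip)
  vnorm(c(a$x - b$x, a$y - b$y, a$z - b$z))
}

config_domains <- function(config) {
  doms <- if (inherits(config, "analysis_config")) config$domains else config
  if (!is.list(doms)) abort("expected an analysis_config or a named list of domains")
  doms
}

#' Displacement of a marker atom after anchoring on a domain
#'
#' Superposes chain `chain_a` of `model_a` onto chain `chain_b` of `model_b`
#' using the Calpha atoms of the anchor domain (paired by residue number),
#' then reports the distance between the marker atoms of the two chains. This
#' is the generic measurement behind the gate-displacement (anchor HP1,
#' marker HP2-tip Calpha) and elevator-travel (anchor scaffold, marker
#' HP1-tip Calpha) numbers, and also serves side-chain markers such as the
#' Met314 sulfur.
#'
#' @param model_a,chain_a,model_b,chain_b Structures/chains to compare.
#' @param config [analysis_config()] or named domain list.
#' @param anchor Name of the anchor domain (e.g. `"HP1"`, `"scaffold"`,
#'   `"transport"`).
#' @param marker Name of the marker domain (e.g. `"hp2_tip"`, `"met314"`).
#' @param marker_atom Atom name measured on the marker residue (default
#'   `"CA"`).
#' @param side_chain_max If `TRUE`, ignore `marker_atom` and report the
#'   maximum displacement over the marker residue's side-chain atoms (those
#'   not named N/CA/C/O) shared by both chains.
#' @param residue_map Optional cross-protein residue map (see
#'   [rmsd_between()]).
#' @return Displacement in Å.
#' @export
marker_displacement <- function(model_a, chain_a, model_b, chain_b, config,
                                anchor, marker, marker_atom = "CA",
                                side_chain_max = FALSE, residue_map = NULL) {
  doms <- config_domains(config)
  anchor_dom <- doms[[anchor]] %||% abort(paste0("no domain named '", anchor, "'"))
  marker_dom <- doms[[marker]] %||% abort(paste0("no domain named '", marker, "'"))
  pr <- pair_by_residue(model_a, chain_a, model_b, chain_b, anchor_dom,
                        atoms = "CA", residue_map = residue_map)
  if (nrow(pr$a) < 3) {
    abort(paste0("anchor '", anchor, "' shares only ", nrow(pr$a),
                 " residues between the chains; need at least 3"))
  }
  fit <- kabsch_superpose(pr$a, pr$b)
  if (side_chain_max) {
    backbone <- c("N", "CA", "C", "O", "OXT")
    ma <- select_domain(model_a, chain_a, marker_dom, atoms = NULL) %>%
      filter(!.data$atom %in% backbone)
    mb <- select_domain(model_b, chain_b, marker_dom, atoms = NULL) %>%
      filter(!.data$atom %in% backbone)
    shared <- intersect(ma$atom, mb$atom)
    if (length(shared) == 0) abort("marker residue has no shared side-chain atoms")
    ma <- ma[match(shared, ma$atom), ]
    mb <- mb[match(shared, mb$atom), ]
    moved <- apply_transform(coord_matrix(ma), fit)
    return(max(sqrt(rowSums((moved - coord_matrix(mb))^2))))
  }
  ma <- single_marker_atom(model_a, chain_a, marker_dom, atom = marker_atom)
  mb <- single_marker_atom(model_b, chain_b, marker_dom, atom = marker_atom)
  moved <- apply_transform(coord_matrix(ma), fit)
  vnorm(moved[1, ] - coord_matrix(mb)[1, ])
}

#' Gate (HP2) displacement between two protomers after HP1 anchoring
#'
#' Distance moved by the HP2-tip Calpha between two protomer conformations
#' once their transport domains are aligned on HP1 — the measurement behind
#' the 4.4 Å (inward vs occluded) and 10.4 Å (inhibitor-wedged vs occluded)
#' gate openings.
#'
#' @inheritParams marker_displacement
#' @return Displacement in Å.
#' @export
gate_displacement <- function(model_a, chain_a, model_b, chain_b, config,
                              residue_map = NULL) {
  marker_displacement(model_a, chain_a, model_b, chain_b, config,
                      anchor = "HP1", marker = "hp2_tip",
                      residue_map = residue_map)
}

#' Elevator travel of the HP1 tip between two protomers
#'
#' Distance moved by the HP1-tip Calpha after superposing the two protomers
#' on their static scaffold domains — the across-the-membrane travel of the
#' transport domain (up to ~24 Å between inward and fully-outward states).
#'
#' @inheritParams marker_displacement
#' @return Travel in Å.
#' @export
elevator_travel <- function(model_a, chain_a, model_b, chain_b, config,
                            residue_map = NULL) {
  marker_displacement(model_a, chain_a, model_b, chain_b, config,
                      anchor = "scaffold", marker = "hp1_tip",
                      residue_map = residue_map)
}

#' Radial displacement of a selection between two frame-aligned protomers
#'
#' Signed change in the distance from the trimer axis of the selection's
#' Calpha centroid, positive when `model_a`'s selection sits further from the
#' axis than `model_b`'s. Both models must already be scaffold-superposed
#' into the same axis frame (or each oriented into its own frame).
#'
#' @param model_a,chain_a,model_b,chain_b Structures/chains to compare.
#' @param selection A [domain_definition()] (e.g. the TM7 C-half + HP2
#'   helices + TM8 N-half selection) or a list of them, pooled.
#' @param frame `axis_frame` both models live in; if `frame_b` is given,
#'   `frame` applies to `model_a` only.
#' @param frame_b Optional separate frame for `model_b`.
#' @return Signed radial displacement in Å.
#' @export
radial_displacement <- function(model_a, chain_a, model_b, chain_b,
                                selection, frame, frame_b = NULL) {
  if (is.null(frame_b)) frame_b <- frame
  sels <- if (inherits(selection, "domain_definition")) list(selection) else selection
  centroid_radius <- function(model, chain, fr) {
    atoms <- bind_rows(lapply(sels, function(d) select_domain(model, chain, d, atoms = "CA")))
    if (nrow(atoms) == 0) abort("radial_displacement: selection resolves to no atoms")
    radial_coordinate(matrix(colMeans(coord_matrix(atoms)), 1, 3), fr)
  }
  centroid_radius(model_a, chain_a, frame) - centroid_radius(model_b, chain_b, frame_b)
}

#' Elevator coordinate of one protomer
#'
#' Signed axial position (Å, extracellular positive) of the transport-domain
#' Calpha centroid minus the scaffold-domain Calpha centroid, measured in the
#' trimer's axis frame. Negative values put the transport domain toward the
#' cytoplasmic side (inward), positive toward the extracellular side
#' (outward).
#'
#' @param model A [structure_model()].
#' @param chain Protomer chain id.
#' @param frame `axis_frame` of the trimer.
#' @param config [analysis_config()] or named domain list.
#' @return Elevator coordinate in Å.
#' @export
elevator_coordinate <- function(model, chain, frame, config) {
  doms <- config_domains(config)
  sc <- select_domain(model, chain, doms$scaffold %||% abort("no 'scaffold' domain"))
  tr <- select_domain(model, chain, doms$transport %||% abort("no 'transport' domain"))
  if (nrow(sc) == 0 || nrow(tr) == 0) abort("scaffold/transport selection is empty")
  axial_coordinate(matrix(colMeans(coord_matrix(tr)), 1, 3), frame) -
    axial_coordinate(matrix(colMeans(coord_matrix(sc)), 1, 3), frame)
}

position_label_from_coordinate <- function(z, t_in, t_out) {
  # boundary values go to the more-outward class
  ifelse(z >= t_out, "outward",
         ifelse(z >= t_in, "intermediate-outward", "inward"))
}

#' Classify one protomer's conformational state
#'
#' Deterministic classification from the elevator coordinate (two cut points
#' `t_in_A < t_out_A`; a value exactly at a cut point is assigned to the
#' more-outward class) and the HP1/HP2 tip distance (gate `open` iff strictly
#' greater than `gate_open_A`).
#'
#' @param model A [structure_model()].
#' @param chain Protomer chain id.
#' @param frame `axis_frame` of the trimer.
#' @param config [analysis_config()] carrying domains and thresholds.
#' @param ligand_label Free-text ligand annotation (user metadata, e.g.
#'   `"apo"`, `"Na+-only"`, `"Asp"`, `"TBOA"`); never inferred from the
#'   coordinates.
#' @return One-row tibble: `chain`, `elevator_coordinate_A`,
#'   `tip_distance_A`, `position_label`, `gate_label`, `ligand_label`.
#' @export
classify_protomer <- function(model, chain, frame, config, ligand_label = NA_character_) {
  th <- config$thresholds
  z <- elevator_coordinate(model, chain, frame, config)
  tip <- gate_opening(model, chain, config)
  tibble(
    chain = chain,
    elevator_coordinate_A = z,
    tip_distance_A = tip,
    position_label = position_label_from_coordinate(z, th$t_in_A, th$t_out_A),
    gate_label = if (tip > th$gate_open_A) "open" else "occluded",
    ligand_label = ligand_label
  )
}

#' Per-protomer state report for a trimer
#'
#' Runs [classify_protomer()] over every protomer chain. Distances are
#' reported at full precision; round at serialization (the field convention
#' is 0.1 Å).
#'
#' @param model A [structure_model()].
#' @param config An [analysis_config()].
#' @param frame Optional precomputed `axis_frame` (estimated from the model
#'   otherwise).
#' @param protomer_chains Chain ids; default: chains with role "protomer".
#' @param ligand_labels Optional character vector (recycled) of ligand
#'   annotations per chain.
#' @return Tibble with one row per protomer.
#' @export
protomer_report <- function(model, config, frame = NULL, protomer_chains = NULL,
                            ligand_labels = NA_character_) {
  if (is.null(protomer_chains)) protomer_chains <- chains_with_role(model, "protomer")
  if (length(protomer_chains) == 0) abort("no protomer chains (set chain_roles)")
  if (is.null(frame)) {
    frame <- pseudo_threefold_axis(model, protomer_chains,
                                   config_domain(config, "scaffold"),
                                   out_marker = config$out_marker)
  }
  labels <- rep_len(ligand_labels, length(protomer_chains))
  purrr::map2_dfr(protomer_chains, labels,
                  function(ch, lab) classify_protomer(model, ch, frame, config, lab))
}
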