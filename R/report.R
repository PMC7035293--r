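#' Full per-structure analysis
#'
#' Runs the whole pipeline on one trimer structure: estimates the
#' pseudo-three-fold axis from the scaffold domains, reorients the model into
#' that frame, classifies every protomer (elevator coordinate, gate opening,
#' state labels), and — when belt chains are present — computes the belt
#' height profile, diameter, sector annotation and buckling statistics.
#'
#' @param x A [structure_model()] or a path to a PDB/mmCIF file.
#' @param config An [analysis_config()] (chain roles from the config are
#'   applied when `x` is a path).
#' @param ligand_labels Optional per-protomer ligand annotation (metadata).
#' @return A `transporter_analysis` list: `identifier`, `frame`,
#'   `oriented` (reoriented model), `protomers` (tibble), `belt` (list with
#'   `profile`, `diameter`, `sectors`, `buckling`, or `NULL` when the model
#'   has no belt chains).
#' @export
analyze_structure <- function(x, config, ligand_labels = NA_character_) {
  model <- if (is.character(x)) {
    read_structure(x, chain_roles = config$chain_roles)
  } else x
  protomer_chains <- chains_with_role(model, "protomer")
  if (length(protomer_chains) == 0 && !is.null(config$chain_roles)) {
    roles <- config$chain_roles[names(config$chain_roles) %in% unique(model$chain)]
    attr(model, "chain_roles") <- roles
    protomer_chains <- chains_with_role(model, "protomer")
  }
  frame <- pseudo_threefold_axis(model, protomer_chains,
                                 config_domain(config, "scaffold"),
                                 out_marker = config$out_marker)
  oriented <- orient_to_axis(model, frame)
  protomers <- protomer_report(oriented, config, frame = NULL,
                               protomer_chains = protomer_chains,
                               ligand_labels = ligand_labels)
  belt <- NULL
  belt_chains <- chains_with_role(model, "belt")
  if (length(belt_chains) > 0) {
    profile <- belt_height_profile(oriented, belt_chains,
                                   bin_width_deg = config$bin_width_deg)
    sectors <- annotate_sectors(oriented, config, protomer_chains)
    belt <- list(
      profile = profile,
      diameter = belt_diameter(oriented, belt_chains),
      sectors = sectors,
      buckling = buckling_stats(profile, protomer_sectors(sectors))
    )
  }
  structure(list(identifier = model_identifier(model), frame = frame,
                 oriented = oriented, protomers = protomers, belt = belt),
            class = "transporter_analysis")
}

#' @export
print.transporter_analysis <- function(x, ...) {
  cat("<transporter_analysis> ", x$identifier, "\n", sep = "")
  print(x$protomers)
  if (is.null(x$belt)) {
    cat("belt: absent\n")
  } else {
    cat("belt: diameter ", sprintf("%.2f", x$belt$diameter$diameter_nm),
        " nm, buckling peak-to-peak ",
        sprintf("%.2f", x$belt$buckling$peak_to_peak_A), " A\n", sep = "")
  }
  invisible(x)
}

round_numeric <- function(df, digits = 1) {
  dplyr::mutate(df, across(dplyr::where(is.numeric), ~ round_half_away(.x, digits)))
}

#' Write analysis reports to disk
#'
#' CSV reports carry units in column names and distances rounded to 0.1 Å
#' (the field's printing convention); the JSON report keeps full precision.
#'
#' @param analysis A `transporter_analysis` from [analyze_structure()].
#' @param dir Output directory.
#' @param format `"csv"`, `"json"` or both.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(analysis, dir, format = c("csv", "json")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  if ("csv" %in% format) {
    f <- file.path(dir, "protomers.csv")
    utils::write.csv(round_numeric(analysis$protomers, 1), f, row.names = FALSE)
    written <- c(written, f)
    if (!is.null(analysis$belt)) {
      f <- file.path(dir, "belt_profile.csv")
      utils::write.csv(round_numeric(as_tibble(analysis$belt$profile), 3), f,
                       row.names = FALSE)
      written <- c(written, f)
    }
  }
  if ("json" %in% format) {
    f <- file.path(dir, "report.json")
    payload <- list(
      identifier = analysis$identifier,
      axis = list(axis = analysis$frame$axis,
                  origin = analysis$frame$origin,
                  pair_angles_deg = analysis$frame$pair_angles_deg,
                  out_sign = analysis$frame$out_sign),
      protomers = analysis$protomers,
      belt = if (is.null(analysis$belt)) "absent" else list(
        diameter_nm = analysis$belt$diameter$diameter_nm,
        buckling_peak_to_peak_A = analysis$belt$buckling$peak_to_peak_A,
        buckling_rms_A = analysis$belt$buckling$rms_deviation_A,
        per_sector = analysis$belt$buckling$per_sector
      )
    )
    jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, f)
  }
  invisible(written)
}

#' Pairwise comparison of two protomer conformations
#'
#' Assembles the standard between-state measurements for one chain of one
#' structure against one chain of another: scaffold and transport RMSD,
#' gate displacement (HP1-anchored HP2-tip movement), elevator travel
#' (scaffold-anchored HP1-tip movement), Met-marker side-chain displacement
#' (transport-anchored) and — when both models are trimers — the radial
#' displacement of the TM7/HP2/TM8 selection in each trimer's own axis
#' frame. Cross-protein comparisons require `config$residue_map`.
#'
#' @param model_a,chain_a,model_b,chain_b Structures and chains to compare.
#' @param config An [analysis_config()].
#' @return One-row tibble of measurements (Å).
#' @export
compare_structures <- function(model_a, chain_a, model_b, chain_b, config) {
  doms <- config$domains
  rmap <- config$residue_map
  out <- tibble(
    chain_a = chain_a, chain_b = chain_b,
    rmsd_scaffold_A = as.numeric(rmsd_between(model_a, chain_a, model_b, chain_b,
                                              doms$scaffold, residue_map = rmap)),
    rmsd_transport_A = as.numeric(rmsd_between(model_a, chain_a, model_b, chain_b,
                                               doms$transport, residue_map = rmap)),
    gate_displacement_A = gate_displacement(model_a, chain_a, model_b, chain_b,
                                            config, residue_map = rmap),
    elevator_travel_A = elevator_travel(model_a, chain_a, model_b, chain_b,
                                        config, residue_map = rmap),
    marker_displacement_A = marker_displacement(model_a, chain_a, model_b, chain_b,
                                                config, anchor = "transport",
                                                marker = "met314", marker_atom = "SD",
                                                residue_map = rmap)
  )
  radial <- NA_real_
  sel_names <- intersect(c("tm7_c_half", "hp2_helices", "tm8_n_half"), names(doms))
  if (length(sel_names) > 0 &&
      length(chains_with_role(model_a, "protomer")) == 3 &&
      length(chains_with_role(model_b, "protomer")) == 3) {
    fa <- pseudo_threefold_axis(model_a, scaffold = doms$scaffold,
                                out_marker = config$out_marker)
    fb <- pseudo_threefold_axis(model_b, scaffold = doms$scaffold,
                                out_marker = config$out_marker)
    radial <- radial_displacement(model_a, chain_a, model_b, chain_b,
                                  doms[sel_names], frame = fa, frame_b = fb)
  }
  out$radial_displacement_A <- radial
  out
}

#' Occupancy report: equilibrium model next to observed class counts
#'
#' @param conditions Optional binding-condition table (see
#'   [fraction_bound()]); each row gains the predicted occupancy and the
#'   implied binomial distribution over trimer compositions.
#' @param class_counts Optional observed class counts — either labelled
#'   (`label`, `count`; percentages reported) or keyed by composition
#'   (`k`, `count`; the binomial occupancy is fitted).
#' @param n Protomers per complex.
#' @return List of class `occupancy_report` with elements `conditions`
#'   (tibble + nested `distribution`), `fractions` (tibble or NULL), `fit`
#'   (occupancy_fit or NULL).
#' @export
occupancy_report <- function(conditions = NULL, class_counts = NULL, n = 3) {
  cond_out <- NULL
  if (!is.null(conditions)) {
    cond_out <- fraction_bound(conditions)
    cond_out$distribution <- purrr::map(cond_out$p_bound,
                                        ~ as_tibble(trimer_state_distribution(.x, n)))
  }
  fractions <- NULL
  fit <- NULL
  if (!is.null(class_counts)) {
    cc <- if (is.data.frame(class_counts)) as_tibble(class_counts) else class_counts
    if (is.data.frame(cc) && "k" %in% names(cc)) {
      fit <- fit_occupancy(cc, n = n)
      fractions <- observed_state_fractions(
        tibble(label = as.character(cc$k), count = cc$count))
    } else {
      fractions <- observed_state_fractions(cc)
    }
  }
  structure(list(conditions = cond_out, fractions = fractions, fit = fit, n = n),
            class = "occupancy_report")
}

#' @export
print.occupancy_report <- function(x, ...) {
  cat("<occupancy_report>\n")
  if (!is.null(x$conditions)) print(x$conditions %>% select(-"distribution"))
  if (!is.null(x$fractions)) print(x$fractions)
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}
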