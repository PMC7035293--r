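#' Define a named residue-range selection (domain)
#'
#' Domains are named selections of author-numbered residue ranges used
#' throughout the geometry code: the rigid `scaffold` and mobile `transport`
#' domains, the two helical hairpins `HP1`/`HP2`, single-residue tip and
#' marker selections (`hp1_tip`, `hp2_tip`, `met314`) and the sub-selections
#' used for the radial-displacement measurement (`tm7_c_half`, `hp2_helices`,
#' `tm8_n_half`).
#'
#' @param name Domain name (free text; the shipped configs use the names
#'   above).
#' @param ranges List of inclusive `(start, end)` residue-number pairs, or a
#'   two-column matrix. Ranges must not overlap within one definition. An
#'   empty list defines an empty selection.
#' @param atoms Character vector of atom names kept by the selection
#'   (default `"CA"`). `NULL` keeps all atoms.
#' @return A `domain_definition` list.
#' @export
domain_definition <- function(name, ranges, atoms = "CA") {
  if (is.matrix(ranges)) ranges <- lapply(seq_len(nrow(ranges)), function(i) ranges[i, ])
  ranges <- lapply(ranges, function(r) {
    r <- as.integer(r)
    if (length(r) == 1) r <- c(r, r)
    if (length(r) != 2 || is.na(r[1]) || is.na(r[2]) || r[1] > r[2]) {
      abort(paste0("domain '", name, "': each range must be (start, end) with start <= end"))
    }
    r
  })
  if (length(ranges) > 1) {
    ord <- order(vapply(ranges, `[`, integer(1), 1))
    sorted <- ranges[ord]
    for (i in seq_len(length(sorted) - 1)) {
      if (sorted[[i + 1]][1] <= sorted[[i]][2]) {
        abort(paste0("domain '", name, "': residue ranges overlap"))
      }
    }
  }
  structure(list(name = name, ranges = ranges, atoms = atoms),
            class = "domain_definition")
}

#' @export
print.domain_definition <- function(x, ...) {
  rng <- paste(vapply(x$ranges, function(r) paste0(r[1], "-", r[2]), character(1)),
               collapse = ",")
  cat("<domain> ", x$name, " [", rng, "] atoms: ",
      if (is.null(x$atoms)) "all" else paste(x$atoms, collapse = ","), "\n", sep = "")
  invisible(x)
}

config_known_keys <- c("protein", "chain_roles", "domains", "thresholds",
                       "bin_width_deg", "out_marker", "residue_map")

#' Assemble an analysis configuration
#'
#' The configuration carries everything structure-specific: the chain-role
#' map, the domain definitions, the classification thresholds, the belt-profile
#' bin width and the marker residue that orients the extracellular ("out")
#' side of the pseudo-three-fold axis. Configurations are usually read from
#' YAML with [read_analysis_config()]; this constructor validates a list built
#' in code.
#'
#' @param protein Free-text protein label.
#' @param chain_roles Named character vector, chain id -> role.
#' @param domains Named list of [domain_definition()]s (names must match the
#'   definitions' own names).
#' @param thresholds Named list with `t_in_A`, `t_out_A` (elevator-coordinate
#'   cut points, Å, `t_in_A < t_out_A`) and `gate_open_A` (HP1/HP2 tip-distance
#'   threshold, Å).
#' @param bin_width_deg Belt-profile bin width in degrees (must divide 360).
#' @param out_marker List with `residue` (and optional `atom`, default CA)
#'   naming a residue known to lie on the extracellular side, used to sign the
#'   axis; `NULL` leaves the sign at `+1`.
#' @param residue_map Optional data frame with columns `residue_a`,
#'   `residue_b` giving the residue correspondence for cross-protein
#'   comparisons.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(protein = "unknown",
                            chain_roles = NULL,
                            domains = list(),
                            thresholds = list(t_in_A = -5, t_out_A = 5, gate_open_A = 6.5),
                            bin_width_deg = 2,
                            out_marker = NULL,
                            residue_map = NULL) {
  if (!is.list(domains) || (length(domains) > 0 && is.null(names(domains)))) {
    abort("domains must be a named list of domain_definition objects")
  }
  for (nm in names(domains)) {
    if (!inherits(domains[[nm]], "domain_definition")) {
      abort(paste0("domains[['", nm, "']] is not a domain_definition"))
    }
  }
  th <- modifyList(list(t_in_A = -5, t_out_A = 5, gate_open_A = 6.5), as.list(thresholds))
  unknown <- setdiff(names(th), c("t_in_A", "t_out_A", "gate_open_A"))
  if (length(unknown) > 0) {
    abort(paste0("unknown threshold key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!(th$t_in_A < th$t_out_A)) abort("thresholds must satisfy t_in_A < t_out_A")
  if (360 %% bin_width_deg != 0) abort("bin_width_deg must divide 360 exactly")
  if (!is.null(residue_map)) {
    residue_map <- as_tibble(residue_map)
    if (!all(c("residue_a", "residue_b") %in% names(residue_map))) {
      abort("residue_map needs columns residue_a, residue_b")
    }
  }
  structure(list(protein = protein,
                 chain_roles = chain_roles,
                 domains = domains,
                 thresholds = th,
                 bin_width_deg = bin_width_deg,
                 out_marker = out_marker,
                 residue_map = residue_map),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Unknown top-level keys are rejected with a message naming them, so a typo
#' in a config never silently falls back to a default.
#'
#' @param path Path to a YAML file. See the shipped examples
#'   `system.file("extdata", "glttk.yaml", package = "trimerscope")` and
#'   `system.file("extdata", "synthetic.yaml", package = "trimerscope")`.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_known_keys)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", "),
                 " (known: ", paste(config_known_keys, collapse = ", "), ")"))
  }
  domains <- list()
  for (nm in names(raw$domains)) {
    d <- raw$domains[[nm]]
    ranges <- d$ranges
    if (is.null(ranges)) abort(paste0("domain '", nm, "' has no ranges"))
    domains[[nm]] <- domain_definition(nm, ranges,
                                       atoms = if (is.null(d$atoms)) "CA" else d$atoms)
  }
  roles <- NULL
  if (!is.null(raw$chain_roles)) roles <- unlist(raw$chain_roles)
  analysis_config(protein = raw$protein %||% "unknown",
                  chain_roles = roles,
                  domains = domains,
                  thresholds = raw$thresholds %||% list(),
                  bin_width_deg = raw$bin_width_deg %||% 2,
                  out_marker = raw$out_marker,
                  residue_map = if (!is.null(raw$residue_map)) {
                    tibble(residue_a = vapply(raw$residue_map, function(p) as.integer(p[[1]]), integer(1)),
                           residue_b = vapply(raw$residue_map, function(p) as.integer(p[[2]]), integer(1)))
                  })
}

config_domain <- function(config, name) {
  d <- config$domains[[name]]
  if (is.null(d)) abort(paste0("config has no domain definition named '", name, "'"))
  d
}

#' Built-in configuration for the synthetic fixtures
#'
#' Matches the residue numbering used by [build_trimer()] and [build_belt()].
#'
#' @return An [analysis_config()].
#' @export
synthetic_config <- function() {
  dom <- function(name, ranges, atoms = "CA") domain_definition(name, ranges, atoms)
  analysis_config(
    protein = "synthetic",
    chain_roles = NULL, # supplied per model by the generator
    domains = list(
      scaffold = dom("scaffold", list(c(1, 40))),
      transport = dom("transport", list(c(101, 140))),
      HP1 = dom("HP1", list(c(151, 158))),
      HP2 = dom("HP2", list(c(161, 168))),
      hp1_tip = dom("hp1_tip", list(c(201, 201))),
      hp2_tip = dom("hp2_tip", list(c(205, 205))),
      met314 = dom("met314", list(c(314, 314))),
      tm7_c_half = dom("tm7_c_half", list(c(120, 126))),
      hp2_helices = dom("hp2_helices", list(c(161, 168))),
      tm8_n_half = dom("tm8_n_half", list(c(131, 137)))
    ),
    thresholds = list(t_in_A = -5, t_out_A = 5, gate_open_A = 6.5),
    bin_width_deg = 2,
    out_marker = list(residue = 40, atom = "CA")
  )
}
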