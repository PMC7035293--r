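#' Read a coordinate file into a structure model
#'
#' Parses PDB (fixed-column v3.3) or mmCIF (`atom_site` loop) files through
#' bio3d and returns the atoms as a [structure_model()] tibble. All ATOM and
#' HETATM records are kept, in file order, with author residue numbering
#' preserved verbatim. Alternate locations are resolved by keeping the
#' highest-occupancy conformer of each atom, ties broken by altloc letter
#' order (deposited transporter models are single-conformer, so this only
#' guards edge cases).
#'
#' @param path Path to the coordinate file.
#' @param format `"pdb"`, `"cif"` or `"auto"` (from the file extension).
#' @param identifier Model label; defaults to the file name without extension.
#' @param chain_roles Optional named character vector chain id -> role
#'   (`"protomer"`, `"belt"`, `"other"`), typically taken from an
#'   [analysis_config()].
#' @return A [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           identifier = NULL, chain_roles = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("coordinate file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     pdb = "pdb", ent = "pdb",
                     cif = "cif", mmcif = "cif",
                     abort(paste0("cannot infer coordinate format from extension '.", ext,
                                  "'; pass format = 'pdb' or 'cif'")))
  }
  parsed <- tryCatch(
    # rm.alt = FALSE: alternate locations are resolved here (highest
    # occupancy, ties by altloc letter), not by dropping everything but "A"
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) abort(paste0("failed to parse ", format, " file '", path,
                                     "': ", conditionMessage(e)))
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) abort(paste0("no atom records parsed from '", path, "'"))
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  atoms <- tibble(
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    atom = at$elety,
    element = if (!is.null(at$elesy)) ifelse(is.na(at$elesy), substr(at$elety, 1, 1), at$elesy)
              else substr(at$elety, 1, 1),
    x = at$x, y = at$y, z = at$z,
    occupancy = occ,
    b_factor = ifelse(is.na(at$b), 0, at$b),
    .alt = alt
  )
  # altloc resolution: highest occupancy wins, ties by altloc letter order
  atoms <- atoms %>% mutate(.row = seq_len(dplyr::n()))
  has_alt <- atoms$.alt != ""
  if (any(has_alt)) {
    resolved <- atoms[has_alt, ] %>%
      arrange(dplyr::desc(.data$occupancy), .data$.alt) %>%
      dplyr::distinct(.data$chain, .data$resno, .data$insert, .data$atom,
                      .keep_all = TRUE)
    atoms <- bind_rows(atoms[!has_alt, ], resolved)
  }
  atoms <- atoms %>% arrange(.data$.row) %>% select(-".alt", -".row")
  if (is.null(identifier)) identifier <- tools::file_path_sans_ext(basename(path))
  if (!is.null(chain_roles)) {
    chain_roles <- chain_roles[names(chain_roles) %in% unique(atoms$chain)]
    if (length(chain_roles) == 0) chain_roles <- NULL
  }
  structure_model(atoms, identifier = identifier, chain_roles = chain_roles)
}

#' Write a structure model as PDB
#'
#' Re-reading the written file reproduces atom count, names, chains and
#' residue numbers exactly, and coordinates to the PDB fixed-width precision
#' of 0.001 Å.
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  m <- coord_matrix(model)
  if (!all(is.finite(m))) abort("refusing to write non-finite coordinates")
  if (any(m <= -1000) || any(m >= 10000)) {
    abort("coordinates exceed the PDB fixed-width field (-999.999 .. 9999.999)")
  }
  xyz <- as.vector(t(m))
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   resno = model$resno, resid = model$resid,
                   chain = model$chain,
                   insert = ifelse(model$insert == "", NA, model$insert),
                   elety = model$atom, o = model$occupancy, b = model$b_factor,
                   elesy = model$element)
  invisible(path)
}

marker_domains <- c("hp1_tip", "hp2_tip", "met314")

#' Select the atoms of a domain within one chain
#'
#' Returns the atoms of `chain` whose residue number falls in the domain's
#' ranges and whose atom name passes the domain's atom filter, ordered by
#' residue number (file order within a residue). An empty selection is legal
#' except for the mandatory single-residue markers (`hp1_tip`, `hp2_tip`,
#' `met314`), for which an empty result is an error naming the residue.
#'
#' @param model A [structure_model()].
#' @param chain Chain id.
#' @param domain A [domain_definition()].
#' @param atoms Override of the domain's atom filter (`NULL` = all atoms).
#' @return Tibble of atom records.
#' @export
select_domain <- function(model, chain, domain, atoms = NULL) {
  if (!chain %in% unique(model$chain)) {
    abort(paste0("model '", model_identifier(model), "' has no chain '", chain, "'"))
  }
  filt <- if (missing(atoms)) domain$atoms else atoms
  rows <- model %>%
    filter(.data$chain == !!chain) %>%
    mutate(.row = seq_len(dplyr::n()))
  keep <- rep(FALSE, nrow(rows))
  for (r in domain$ranges) keep <- keep | (rows$resno >= r[1] & rows$resno <= r[2])
  rows <- rows[keep, , drop = FALSE]
  if (!is.null(filt)) rows <- rows %>% filter(.data$atom %in% filt)
  rows <- rows %>% arrange(.data$resno, .data$.row) %>% select(-".row")
  if (nrow(rows) == 0 && domain$name %in% marker_domains) {
    rng <- paste(vapply(domain$ranges, function(r) paste0(r[1], "-", r[2]), character(1)),
                 collapse = ",")
    abort(paste0("mandatory marker '", domain$name, "' (residue ", rng,
                 ") resolves to no atoms in chain ", chain))
  }
  as_tibble(rows)
}

single_marker_atom <- function(model, chain, domain, atom = "CA") {
  sel <- select_domain(model, chain, domain, atoms = atom)
  if (nrow(sel) == 0) {
    abort(paste0("marker '", domain$name, "' has no '", atom, "' atom in chain ", chain))
  }
  if (nrow(sel) > 1) {
    warn(paste0("marker '", domain$name, "' matches ", nrow(sel),
                " atoms in chain ", chain, "; using the first"))
    sel <- sel[1, , drop = FALSE]
  }
  sel
}
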