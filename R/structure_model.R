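#' Construct a structure model from an atom table
#'
#' A `structure_model` is a tibble of atom records — one row per atom, in file
#' order — carrying the coordinates every geometric measurement in the package
#' operates on. The tibble has columns `chain`, `resno` (author residue
#' numbering, preserved verbatim), `insert`, `resid` (3-letter residue name),
#' `atom` (atom name, e.g. `"CA"`), `element`, `x`, `y`, `z` (Å), `occupancy`
#' and `b_factor` (Å²). Two attributes ride along: `identifier` (a free-text
#' label such as a PDB id or fixture name) and `chain_roles`, a named character
#' vector mapping each chain id to a role in `{"protomer", "belt", "other"}`.
#'
#' @param atoms A data frame with the columns listed above (missing `insert`,
#'   `element`, `occupancy`, `b_factor` columns are filled with defaults).
#' @param identifier Free-text label for the model.
#' @param chain_roles Named character vector, `chain id -> role`. Chains absent
#'   from the map default to role `"other"`. Every mapped chain must occur in
#'   `atoms`.
#' @return A `structure_model` tibble.
#' @export
structure_model <- function(atoms, identifier = "model", chain_roles = NULL) {
  atoms <- as_tibble(atoms)
  required <- c("chain", "resno", "atom", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom coordinates must all be finite")
  }
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  if (!"resid" %in% names(atoms)) atoms$resid <- "ALA"
  if (!"element" %in% names(atoms)) atoms$element <- substr(atoms$atom, 1, 1)
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"b_factor" %in% names(atoms)) atoms$b_factor <- 0
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$resno <- as.integer(atoms$resno)
  atoms <- atoms[, c("chain", "resno", "insert", "resid", "atom", "element",
                     "x", "y", "z", "occupancy", "b_factor")]
  if (!is.null(chain_roles)) {
    bad <- setdiff(names(chain_roles), unique(atoms$chain))
    if (length(bad) > 0) {
      abort(paste0("chain_roles refers to chain(s) absent from the model: ",
                   paste(bad, collapse = ", ")))
    }
    ok <- chain_roles %in% c("protomer", "belt", "other")
    if (!all(ok)) abort("chain roles must be 'protomer', 'belt' or 'other'")
  }
  structure(atoms,
            identifier = identifier,
            chain_roles = chain_roles,
            class = c("structure_model", class(atoms)))
}

#' @export
print.structure_model <- function(x, ...) {
  roles <- attr(x, "chain_roles")
  cat("<structure_model> ", attr(x, "identifier"), ": ",
      nrow(x), " atoms, chains ",
      paste(unique(x$chain), collapse = ","), "\n", sep = "")
  if (!is.null(roles)) {
    cat("  roles: ", paste(names(roles), roles, sep = "=", collapse = " "), "\n", sep = "")
  }
  NextMethod()
}

model_identifier <- function(model) attr(model, "identifier") %||% "model"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chains of a structure model having a given role
#'
#' @param model A [structure_model()].
#' @param role One of `"protomer"`, `"belt"`, `"other"`.
#' @return Character vector of chain ids (possibly empty).
#' @export
chains_with_role <- function(model, role) {
  roles <- attr(model, "chain_roles")
  if (is.null(roles)) return(character(0))
  names(roles)[roles == role]
}

coord_matrix <- function(atoms) {
  m <- cbind(atoms$x, atoms$y, atoms$z)
  colnames(m) <- c("x", "y", "z")
  m
}

set_coords <- function(model, m) {
  model$x <- m[, 1]
  model$y <- m[, 2]
  model$z <- m[, 3]
  model
}
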