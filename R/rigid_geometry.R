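#' Rigid-body (Kabsch) superposition of two paired point sets
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' equal-length point sets paired by list position, by singular value
#' decomposition of the covariance of the centred coordinates. Reflections
#' are excluded: if the best orthogonal map has determinant -1, the smallest
#' singular direction is flipped so the returned rotation is always proper
#' (det = +1).
#'
#' @param mobile,reference n x 3 coordinate matrices or atom tibbles (with
#'   `x`, `y`, `z` columns), n >= 3, paired row by row.
#' @return A `rigid_transform` list with elements `rotation` (3 x 3,
#'   orthonormal, det +1), `translation` (length-3, Å) such that the fitted
#'   mobile coordinates are `x %*% t(rotation) + translation`, and `rmsd`
#'   (Å, after fitting).
#' @export
kabsch_superpose <- function(mobile, reference) {
  xm <- as_coords(mobile)
  xr <- as_coords(reference)
  if (nrow(xm) != nrow(xr)) {
    abort(paste0("point sets must pair one-to-one: mobile has ", nrow(xm),
                 " points, reference has ", nrow(xr)))
  }
  if (nrow(xm) < 3) abort("need at least 3 paired points for a rigid fit")
  cm <- colMeans(xm)
  cr <- colMeans(xr)
  xm_c <- sweep(xm, 2, cm)
  xr_c <- sweep(xr, 2, cr)
  sv_ref <- svd(xr_c)$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1)) {
    abort("reference points are (near-)collinear; the rotation is degenerate")
  }
  h <- crossprod(xm_c, xr_c)        # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.vector(cr - rot %*% cm)
  fitted <- xm %*% t(rot) + matrix(trans, nrow(xm), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - xr)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rmsd", format(x$rmsd, digits = 4), "A, angle",
      format(rotation_angle_deg(x$rotation), digits = 4), "deg\n")
  invisible(x)
}

as_coords <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3) abort("coordinate matrix must have 3 columns")
    return(unname(x))
  }
  if (is.data.frame(x)) return(unname(coord_matrix(x)))
  abort("coordinates must be an n x 3 matrix or a data frame with x/y/z")
}

#' Apply a rigid transform to coordinates or a structure model
#'
#' @param x Coordinate matrix, atom tibble, or [structure_model()].
#' @param transform A `rigid_transform` (see [kabsch_superpose()]), or a list
#'   with `rotation` and `translation`.
#' @return Object of the same kind with transformed coordinates.
#' @export
apply_transform <- function(x, transform) {
  rot <- transform$rotation
  tr <- transform$translation
  if (is.matrix(x)) {
    return(x %*% t(rot) + matrix(tr, nrow(x), 3, byrow = TRUE))
  }
  m <- coord_matrix(x)
  set_coords(x, m %*% t(rot) + matrix(tr, nrow(m), 3, byrow = TRUE))
}

rotation_angle_deg <- function(rot) {
  ct <- (sum(diag(rot)) - 1) / 2
  rad2deg(acos(pmin(1, pmax(-1, ct))))
}

rotation_axis <- function(rot) {
  ang <- deg2rad(rotation_angle_deg(rot))
  if (abs(sin(ang)) < 1e-8) {
    # near 0 or 180 deg: take the eigenvector with eigenvalue closest to +1
    e <- eigen(rot)
    i <- which.min(abs(e$values - 1))
    return(unitize(Re(e$vectors[, i])))
  }
  unitize(c(rot[3, 2] - rot[2, 3],
            rot[1, 3] - rot[3, 1],
            rot[2, 1] - rot[1, 2]) / (2 * sin(ang)))
}

pair_by_residue <- function(model_a, chain_a, model_b, chain_b, domain,
                            atoms = "CA", residue_map = NULL) {
  sel_a <- select_domain(model_a, chain_a, domain, atoms = atoms)
  sel_b <- select_domain(model_b, chain_b, domain, atoms = atoms)
  if (!is.null(residue_map)) {
    sel_a <- sel_a %>%
      dplyr::inner_join(residue_map, by = c(resno = "residue_a")) %>%
      mutate(resno = .data$residue_b) %>%
      select(-"residue_b")
  }
  shared <- intersect(sel_a$resno, sel_b$resno)
  sel_a <- sel_a %>% filter(.data$resno %in% shared) %>%
    dplyr::distinct(.data$resno, .data$atom, .keep_all = TRUE)
  sel_b <- sel_b %>% filter(.data$resno %in% shared) %>%
    dplyr::distinct(.data$resno, .data$atom, .keep_all = TRUE)
  key_a <- paste(sel_a$resno, sel_a$atom)
  key_b <- paste(sel_b$resno, sel_b$atom)
  common <- intersect(key_a, key_b)
  list(a = sel_a[match(common, key_a), , drop = FALSE],
       b = sel_b[match(common, key_b), , drop = FALSE])
}

#' RMSD between a domain of two chains, paired by residue number
#'
#' Residues are paired by shared author residue number (intersection of the
#' two selections); cross-protein comparisons need a `residue_map`
#' translating numbering. Calpha-only by default. The value is symmetric in
#' its arguments and invariant under rigid motion of either input.
#'
#' @param model_a,chain_a,model_b,chain_b Structures and chains to compare.
#' @param domain [domain_definition()] selecting the compared residues.
#' @param atoms Atom filter (default `"CA"`; `NULL` = all shared atoms).
#' @param residue_map Optional tibble (`residue_a`, `residue_b`) mapping
#'   `model_a` numbering onto `model_b` numbering.
#' @return RMSD in Å with attribute `n_pairs`, the number of paired atoms.
#' @export
rmsd_between <- function(model_a, chain_a, model_b, chain_b, domain,
                         atoms = "CA", residue_map = NULL) {
  pr <- pair_by_residue(model_a, chain_a, model_b, chain_b, domain,
                        atoms = atoms, residue_map = residue_map)
  if (nrow(pr$a) < 3) {
    abort(paste0("only ", nrow(pr$a), " shared residue atoms in domain '",
                 domain$name, "'; need at least 3"))
  }
  fit <- kabsch_superpose(pr$a, pr$b)
  structure(fit$rmsd, n_pairs = nrow(pr$a))
}

#' Estimate the pseudo-three-fold axis of a homotrimer
#'
#' Superposes the scaffold domain of each ordered protomer pair (A->B, B->C,
#' C->A), extracts the rotation axis of each fitted rotation, sign-aligns the
#' three axes and averages them. A genuinely C3 trimer gives three 120°
#' rotations with identical axes; conformational heterogeneity perturbs both,
#' so any pair whose fitted rotation angle falls outside 100–140° is flagged
#' with a warning (the axis is still returned). The frame origin is the
#' centroid of all scaffold Calpha atoms; the theta = 0 reference direction is
#' the in-plane projection of the first protomer's scaffold centroid; the
#' extracellular sign is taken from a config-designated marker residue when
#' provided (mean over protomers of the marker's axial coordinate).
#'
#' @param model A [structure_model()] containing the trimer.
#' @param protomer_chains Exactly 3 chain ids; default: chains with role
#'   `"protomer"`.
#' @param scaffold Scaffold [domain_definition()].
#' @param out_marker Optional list with `residue` (and optional `atom`) of an
#'   extracellular marker residue; `NULL` leaves `out_sign = +1`.
#' @return An `axis_frame` list: `axis` (unit 3-vector), `origin` (Å),
#'   `zero_direction` (unit 3-vector, perpendicular to `axis`), `out_sign`
#'   (+1/-1), `pair_angles_deg` (the three fitted rotation angles) and
#'   `chains`.
#' @export
pseudo_threefold_axis <- function(model, protomer_chains = NULL, scaffold,
                                  out_marker = NULL) {
  if (is.null(protomer_chains)) protomer_chains <- chains_with_role(model, "protomer")
  if (length(protomer_chains) != 3) {
    abort(paste0("axis estimation needs exactly 3 protomer chains, got ",
                 length(protomer_chains)))
  }
  sels <- lapply(protomer_chains, function(ch) select_domain(model, ch, scaffold, atoms = "CA"))
  pairs <- list(c(1, 2), c(2, 3), c(3, 1))
  axes <- matrix(0, 3, 3)
  angles <- numeric(3)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    pr <- pair_by_residue(model, protomer_chains[p[1]], model, protomer_chains[p[2]],
                          scaffold, atoms = "CA")
    if (nrow(pr$a) < 3) abort("protomer pair shares fewer than 3 scaffold residues")
    fit <- kabsch_superpose(pr$a, pr$b)
    angles[i] <- rotation_angle_deg(fit$rotation)
    axes[i, ] <- rotation_axis(fit$rotation)
  }
  if (any(angles < 100 | angles > 140)) {
    warn(paste0("pairwise scaffold rotation angle(s) outside 100-140 deg: ",
                paste(sprintf("%.1f", angles), collapse = ", "),
                " — trimer is strongly non-symmetric; axis may be unreliable"))
  }
  for (i in 2:3) if (sum(axes[i, ] * axes[1, ]) < 0) axes[i, ] <- -axes[i, ]
  axis <- unitize(colMeans(axes))
  all_scaffold <- bind_rows(sels)
  origin <- unname(colMeans(coord_matrix(all_scaffold)))
  ca <- unname(colMeans(coord_matrix(sels[[1]])))
  zero_raw <- (ca - origin) - sum((ca - origin) * axis) * axis
  zero_direction <- unitize(zero_raw)
  out_sign <- 1
  if (!is.null(out_marker)) {
    atom_name <- out_marker$atom %||% "CA"
    dom <- domain_definition("out_marker", list(c(out_marker$residue, out_marker$residue)))
    zs <- vapply(protomer_chains, function(ch) {
      sel <- select_domain(model, ch, dom, atoms = atom_name)
      if (nrow(sel) == 0) return(NA_real_)
      sum((colMeans(coord_matrix(sel)) - origin) * axis)
    }, numeric(1))
    if (all(is.na(zs))) abort("out_marker residue resolves to no atoms in any protomer chain")
    out_sign <- if (mean(zs, na.rm = TRUE) >= 0) 1 else -1
  }
  structure(list(axis = axis, origin = origin, zero_direction = zero_direction,
                 out_sign = out_sign, pair_angles_deg = angles,
                 chains = protomer_chains),
            class = "axis_frame")
}

#' @export
print.axis_frame <- function(x, ...) {
  cat("<axis_frame> axis (", paste(sprintf("%.4f", x$axis), collapse = ", "),
      "), out_sign ", x$out_sign, "\n  pair angles: ",
      paste(sprintf("%.2f", x$pair_angles_deg), collapse = ", "), " deg\n", sep = "")
  invisible(x)
}

frame_basis <- function(frame) {
  e3 <- unitize(frame$out_sign * frame$axis)
  z0 <- frame$zero_direction
  e1 <- unitize(z0 - sum(z0 * e3) * e3)
  e2 <- cross3(e3, e1)
  rbind(e1, e2, e3)
}

#' Reorient a model into an axis frame
#'
#' Pure rigid motion putting the frame origin at (0,0,0), the
#' pseudo-three-fold axis (extracellular side up) along +z and the
#' `zero_direction` along +x. All pairwise distances are preserved.
#'
#' @param model A [structure_model()].
#' @param frame An `axis_frame` from [pseudo_threefold_axis()].
#' @return The reoriented [structure_model()].
#' @export
orient_to_axis <- function(model, frame) {
  basis <- frame_basis(frame)
  tf <- list(rotation = basis, translation = as.vector(-basis %*% frame$origin))
  apply_transform(model, tf)
}

#' Axial coordinate of points in an axis frame
#'
#' Signed distance along the (out-signed) axis, in Å, without reorienting the
#' model.
#'
#' @param coords Coordinate matrix or atom tibble.
#' @param frame An `axis_frame`.
#' @return Numeric vector.
#' @export
axial_coordinate <- function(coords, frame) {
  m <- as_coords(coords)
  e3 <- frame$out_sign * frame$axis
  as.vector(sweep(m, 2, frame$origin) %*% e3)
}

radial_coordinate <- function(coords, frame) {
  m <- sweep(as_coords(coords), 2, frame$origin)
  ax <- frame$axis
  axial <- m %*% ax
  sqrt(pmax(0, rowSums(m^2) - axial^2))
}
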