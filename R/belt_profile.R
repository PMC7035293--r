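#' Height-versus-perimeter profile of the nanodisc belt protein
#'
#' In a model oriented with the trimer's pseudo-three-fold axis along +z
#' (see [orient_to_axis()]), every belt-protein atom is reduced to its
#' bearing theta = atan2(y, x) in [0, 360), its height h = z (membrane-normal
#' coordinate, Å) and its radius r (in-plane distance from the axis, Å).
#' Atoms are binned by bearing and per-bin arithmetic means are reported. A
#' straight (flat) profile indicates a planar bilayer; buckling indicates
#' local membrane deformation.
#'
#' @param model Oriented [structure_model()].
#' @param belt_chains Chain ids of the belt protein; default: chains with
#'   role `"belt"`.
#' @param atoms Atom-name filter; default `NULL` uses all belt atoms
#'   (`"CA"` for a backbone-only profile).
#' @param bin_width_deg Bin width in degrees; must divide 360 (default 2).
#' @param by_chain If `TRUE`, profile each belt chain separately (adds a
#'   `chain` column) in addition to nothing else; default `FALSE` profiles
#'   all belt chains jointly.
#' @return A `belt_profile` tibble: `bin_center_deg`, `mean_height_A`,
#'   `mean_radius_A`, `n_atoms` (empty bins kept, with `NA` means). The
#'   attribute `bin_width_deg` records the binning; `n_belt_atoms` the total
#'   atom count.
#' @export
belt_height_profile <- function(model, belt_chains = NULL, atoms = NULL,
                                bin_width_deg = 2, by_chain = FALSE) {
  if (is.null(belt_chains)) belt_chains <- chains_with_role(model, "belt")
  if (length(belt_chains) == 0) abort("no belt chains (set chain_roles or pass belt_chains)")
  if (360 %% bin_width_deg != 0) abort("bin_width_deg must divide 360 exactly")
  at <- model %>% filter(.data$chain %in% belt_chains)
  if (!is.null(atoms)) at <- at %>% filter(.data$atom %in% atoms)
  if (nrow(at) == 0) abort("belt selection resolves to no atoms")
  theta <- rad2deg(atan2(at$y, at$x)) %% 360
  r <- sqrt(at$x^2 + at$y^2)
  n_bins <- as.integer(360 / bin_width_deg)
  bin <- pmin(floor(theta / bin_width_deg), n_bins - 1L)  # guard theta == 360-eps rounding
  grid <- tibble(bin = 0:(n_bins - 1L),
                 bin_center_deg = (0:(n_bins - 1L) + 0.5) * bin_width_deg)
  obs <- tibble(bin = bin, h = at$z, r = r,
                chain = at$chain)
  summarise_bins <- function(o) {
    s <- o %>% group_by(.data$bin) %>%
      summarise(mean_height_A = mean(.data$h),
                mean_radius_A = mean(.data$r),
                n_atoms = dplyr::n(), .groups = "drop")
    out <- grid %>% left_join(s, by = "bin") %>%
      mutate(n_atoms = ifelse(is.na(.data$n_atoms), 0L, .data$n_atoms)) %>%
      select(-"bin")
    out
  }
  prof <- if (by_chain) {
    obs %>% tidyr::nest(data = -"chain") %>%
      mutate(data = purrr::map(.data$data, summarise_bins)) %>%
      tidyr::unnest("data")
  } else {
    summarise_bins(obs)
  }
  if (!by_chain && sum(prof$n_atoms > 0) == 1) {
    warn("all belt atoms fall in a single bearing bin")
  }
  structure(prof,
            bin_width_deg = bin_width_deg,
            n_belt_atoms = nrow(at),
            class = c("belt_profile", class(prof)))
}

#' Buckling statistics of a belt profile
#'
#' The buckling baseline is the mean belt height around the circle (the
#' belt's absolute height is arbitrary), computed over non-empty bins.
#' `peak_to_peak_A` is max - min of the per-bin mean heights;
#' `rms_deviation_A` the root-mean-square deviation about the baseline.
#' With a sector map, the height range within each sector is also reported.
#'
#' @param profile A [belt_height_profile()] (joint, not per-chain).
#' @param sectors Optional sector map: tibble with columns `sector`,
#'   `start_deg`, `end_deg` (intervals `[start, end)`; multiple rows per
#'   sector allowed), e.g. from [protomer_sectors()].
#' @return List of class `buckling_stats`: `peak_to_peak_A`,
#'   `rms_deviation_A`, `baseline_A`, `n_bins_used`, and `per_sector`
#'   (tibble `sector`, `range_A`, `n_bins`; `NULL` without a sector map).
#' @export
buckling_stats <- function(profile, sectors = NULL) {
  used <- profile %>% filter(.data$n_atoms > 0)
  if (nrow(used) < 2) abort("need at least 2 non-empty bins for buckling statistics")
  h <- used$mean_height_A
  baseline <- mean(h)
  stats <- list(
    peak_to_peak_A = max(h) - min(h),
    rms_deviation_A = sqrt(mean((h - baseline)^2)),
    baseline_A = baseline,
    n_bins_used = nrow(used),
    per_sector = NULL
  )
  if (!is.null(sectors)) {
    sectors <- as_tibble(sectors)
    per <- sectors %>%
      dplyr::group_split(.data$sector) %>%
      purrr::map_dfr(function(sec) {
        in_sec <- rep(FALSE, nrow(used))
        for (i in seq_len(nrow(sec))) {
          in_sec <- in_sec | (used$bin_center_deg >= sec$start_deg[i] &
                                used$bin_center_deg < sec$end_deg[i])
        }
        hh <- used$mean_height_A[in_sec]
        tibble(sector = sec$sector[1],
               range_A = if (length(hh) >= 1) max(hh) - min(hh) else NA_real_,
               n_bins = sum(in_sec))
      })
    stats$per_sector <- per
  }
  structure(stats, class = "buckling_stats")
}

#' @export
print.buckling_stats <- function(x, ...) {
  cat("<buckling_stats> peak-to-peak ", sprintf("%.2f", x$peak_to_peak_A),
      " A, rms ", sprintf("%.2f", x$rms_deviation_A), " A over ",
      x$n_bins_used, " bins\n", sep = "")
  if (!is.null(x$per_sector)) print(x$per_sector)
  invisible(x)
}

#' Belt diameter
#'
#' Twice the mean radial distance of the belt Calpha atoms from the trimer
#' axis, in nm (nanodisc diameters in the 10–11 nm range indicate a belt
#' wrapped tightly around the transporter). Min and max radii are reported
#' alongside; fewer than 3 belt atoms is flagged as degenerate.
#'
#' @param model Oriented [structure_model()].
#' @param belt_chains Belt chain ids (default from `chain_roles`).
#' @return One-row tibble: `diameter_nm`, `r_mean_A`, `r_min_A`, `r_max_A`,
#'   `n_atoms`, `degenerate`.
#' @export
belt_diameter <- function(model, belt_chains = NULL) {
  if (is.null(belt_chains)) belt_chains <- chains_with_role(model, "belt")
  if (length(belt_chains) == 0) abort("no belt chains (set chain_roles or pass belt_chains)")
  at <- model %>% filter(.data$chain %in% belt_chains, .data$atom == "CA")
  if (nrow(at) == 0) abort("belt selection resolves to no CA atoms")
  r <- sqrt(at$x^2 + at$y^2)
  degenerate <- nrow(at) < 3
  if (degenerate) warn("belt has fewer than 3 CA atoms; diameter is degenerate")
  tibble(diameter_nm = 2 * mean(r) / 10,
         r_mean_A = mean(r), r_min_A = min(r), r_max_A = max(r),
         n_atoms = nrow(at), degenerate = degenerate)
}

#' Annotate the perimeter with the protomer domain underneath
#'
#' Walks the 360° perimeter in 1° sectors and assigns each sector to the
#' protomer domain (scaffold or transport Calpha set) whose atoms subtend
#' that bearing, by angular occupancy (atom count in the sector). Ties are
#' broken in favour of the domain with the smaller mean radius
#' (innermost-protein convention). Sectors subtended by no protomer atom are
#' labelled `"none"`.
#'
#' @param model Oriented [structure_model()].
#' @param config [analysis_config()] providing `scaffold` and `transport`
#'   domains.
#' @param protomer_chains Protomer chain ids (default from `chain_roles`).
#' @param sector_width_deg Sector width (default 1).
#' @return Tibble: `start_deg`, `end_deg`, `chain`, `role`, `label`
#'   (`"chain:role"` or `"none"`).
#' @export
annotate_sectors <- function(model, config, protomer_chains = NULL,
                             sector_width_deg = 1) {
  if (is.null(protomer_chains)) protomer_chains <- chains_with_role(model, "protomer")
  doms <- config_domains(config)
  n_sec <- as.integer(ceiling(360 / sector_width_deg))
  pieces <- list()
  for (ch in protomer_chains) {
    for (role in c("scaffold", "transport")) {
      sel <- select_domain(model, ch, doms[[role]], atoms = "CA")
      if (nrow(sel) == 0) next
      theta <- rad2deg(atan2(sel$y, sel$x)) %% 360
      pieces[[paste(ch, role)]] <- tibble(
        chain = ch, role = role,
        sec = pmin(floor(theta / sector_width_deg), n_sec - 1L),
        r = sqrt(sel$x^2 + sel$y^2))
    }
  }
  empty <- tibble(start_deg = (0:(n_sec - 1L)) * sector_width_deg,
                  end_deg = (1:n_sec) * sector_width_deg,
                  chain = NA_character_, role = NA_character_, label = "none")
  if (length(pieces) == 0) return(empty)
  occ <- bind_rows(pieces) %>%
    group_by(.data$sec, .data$chain, .data$role) %>%
    summarise(n = dplyr::n(), r_mean = mean(.data$r), .groups = "drop") %>%
    group_by(.data$sec) %>%
    arrange(dplyr::desc(.data$n), .data$r_mean, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup()
  out <- empty
  idx <- occ$sec + 1L
  out$chain[idx] <- occ$chain
  out$role[idx] <- occ$role
  out$label[idx] <- paste(occ$chain, occ$role, sep = ":")
  out
}

#' Collapse a sector annotation into per-protomer angular sectors
#'
#' Groups the 1° annotation of [annotate_sectors()] into contiguous angular
#' intervals per protomer chain (ignoring the scaffold/transport split), in
#' the shape [buckling_stats()] accepts as a sector map.
#'
#' @param annotation Output of [annotate_sectors()].
#' @return Tibble: `sector` (chain id), `start_deg`, `end_deg`.
#' @export
protomer_sectors <- function(annotation) {
  ann <- annotation %>% filter(!is.na(.data$chain))
  if (nrow(ann) == 0) return(tibble(sector = character(0), start_deg = numeric(0),
                                    end_deg = numeric(0)))
  ann <- ann %>% arrange(.data$start_deg)
  nr <- nrow(ann)
  new_run <- c(TRUE,
               ann$chain[-1] != ann$chain[-nr] | ann$start_deg[-1] != ann$end_deg[-nr])
  ann$run <- cumsum(new_run)
  ann %>% group_by(.data$run) %>%
    summarise(sector = .data$chain[1],
              start_deg = min(.data$start_deg),
              end_deg = max(.data$end_deg), .groups = "drop") %>%
    select("sector", "start_deg", "end_deg")
}
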