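#' Equilibrium fraction of binding sites occupied, with ligand depletion
#'
#' Single-site equilibrium between protomer binding sites at total
#' concentration S (three sites per trimer) and a ligand at total
#' concentration L with dissociation constant Kd. Because cryo-EM binding
#' experiments use protein at micromolar concentrations, ligand depletion can
#' matter: the bound concentration B solves the mass balance
#' \deqn{B^2 - (S + L' + K_d) B + S L' = 0,}
#' with L' = `active_fraction * L` (e.g. 0.5 for a racemic inhibitor of which
#' only one enantiomer binds), taking the root in `[0, min(S, L')]`. The
#' occupancy is p = B/S. When S is zero (or negligible against Kd) this
#' reduces to the familiar no-depletion form p = L'/(Kd + L'), which is used
#' directly (and flagged) for S = 0.
#'
#' @param conditions Data frame with columns `site_uM` (S), `ligand_uM` (L),
#'   `kd_uM` (Kd) and optionally `active_fraction` (default 1); any
#'   additional columns (labels etc.) are carried through.
#' @return The input tibble with columns `p_bound` (occupancy in `[0, 1]`),
#'   `bound_uM` and `no_depletion` (flag: TRUE where the S = 0 limit was
#'   used) appended.
#' @export
fraction_bound <- function(conditions) {
  cond <- as_tibble(conditions)
  need <- c("site_uM", "ligand_uM", "kd_uM")
  missing_cols <- setdiff(need, names(cond))
  if (length(missing_cols) > 0) {
    abort(paste0("conditions lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"active_fraction" %in% names(cond)) cond$active_fraction <- 1
  with(cond, {
    if (any(site_uM < 0 | ligand_uM < 0 | kd_uM < 0)) {
      abort("concentrations and Kd must be non-negative")
    }
    if (any(active_fraction <= 0 | active_fraction > 1)) {
      abort("active_fraction must lie in (0, 1]")
    }
  })
  res <- purrr::pmap_dfr(
    cond[, c("site_uM", "ligand_uM", "kd_uM", "active_fraction")],
    function(site_uM, ligand_uM, kd_uM, active_fraction) {
      l_active <- active_fraction * ligand_uM
      if (site_uM == 0) {
        p <- if (l_active == 0 && kd_uM == 0) 0 else l_active / (kd_uM + l_active)
        return(tibble(p_bound = p, bound_uM = 0, no_depletion = TRUE))
      }
      s <- site_uM
      b <- solve_bound(s, l_active, kd_uM)
      tibble(p_bound = b / s, bound_uM = b, no_depletion = FALSE)
    })
  dplyr::bind_cols(cond, res)
}

# stable smaller root of B^2 - (S+L+Kd) B + S L = 0, clamped to [0, min(S, L)]
solve_bound <- function(s, l, kd) {
  if (l == 0) return(0)
  a <- s + l + kd
  disc <- a^2 - 4 * s * l
  b <- if (a > 0) 2 * s * l / (a + sqrt(max(0, disc))) else 0
  min(max(b, 0), min(s, l))
}

#' Binomial / multinomial distribution of protomer states in a trimer
#'
#' With each protomer independently occupied with probability p, the number
#' of occupied protomers per trimer is Binomial(n, p) — the model behind the
#' observed mixtures of trimer classes at sub-saturating ligand. With more
#' than two per-protomer states, compositions follow a multinomial.
#'
#' @param p Either a single occupancy probability in `[0, 1]`, or a named
#'   probability vector over >= 2 per-protomer states (must sum to 1).
#' @param n Protomers per complex (default 3).
#' @return For scalar p: tibble `k` (0..n), `probability`, attribute
#'   `p`/`n`; mean composition is exactly `n * p`. For a probability vector:
#'   tibble with one count column per state and `probability`.
#' @export
trimer_state_distribution <- function(p, n = 3) {
  if (length(p) == 1 && is.null(names(p))) {
    if (p < 0 || p > 1) abort("p must lie in [0, 1]")
    out <- tibble(k = 0:n, probability = dbinom(0:n, n, p))
    return(structure(out, p = unname(p), n = n,
                     class = c("state_distribution", class(out))))
  }
  if (abs(sum(p) - 1) > 1e-9) abort("state probability vector must sum to 1")
  if (is.null(names(p))) names(p) <- paste0("state", seq_along(p))
  # all compositions (k_1, ..., k_m) with sum n
  combos <- expand.grid(rep(list(0:n), length(p)))
  combos <- combos[rowSums(combos) == n, , drop = FALSE]
  names(combos) <- names(p)
  prob <- apply(combos, 1, function(k) dmultinom(k, prob = p))
  out <- as_tibble(combos)
  out$probability <- prob
  structure(out, p = p, n = n, class = c("state_distribution", class(out)))
}

#' Observed particle-class fractions from counts
#'
#' Converts raw single-particle class counts into fractions and integer
#' percentages (rounded half away from zero, the convention used when such
#' percentages are printed).
#'
#' @param class_counts Named numeric vector or data frame with columns
#'   `label`, `count`.
#' @return Tibble: `label`, `count`, `fraction`, `percent` (integer).
#' @export
observed_state_fractions <- function(class_counts) {
  tab <- if (is.data.frame(class_counts)) {
    as_tibble(class_counts)
  } else {
    tibble(label = names(class_counts) %||% as.character(seq_along(class_counts)),
           count = as.numeric(class_counts))
  }
  if (!all(c("label", "count") %in% names(tab))) {
    abort("class counts need a label and a count per class")
  }
  if (any(tab$count < 0)) abort("class counts must be non-negative")
  total <- sum(tab$count)
  if (total <= 0) abort("total particle count is zero")
  tab %>% mutate(fraction = .data$count / total,
                 percent = as.integer(round_half_away(100 * .data$count / total)))
}

#' Fit the per-protomer occupancy to observed trimer-composition counts
#'
#' Maximum-likelihood estimate of the per-protomer occupancy p under the
#' binomial model, from particle counts keyed by the number k of occupied
#' protomers per trimer. With every composition observable the MLE is the
#' closed form `sum(k * c_k) / (n * sum(c_k))`. When only a subset of
#' compositions was observable (e.g. classes too small to reconstruct), set
#' `truncated = TRUE`: the likelihood is renormalised over the observed
#' compositions and maximised numerically, and the fit is flagged. A
#' likelihood-ratio goodness-of-fit against the saturated multinomial is
#' reported.
#'
#' @param class_counts Data frame with columns `k` (0..n) and `count`, or a
#'   named vector (names = k).
#' @param n Protomers per complex (default 3).
#' @param truncated Treat the supplied compositions as the only observable
#'   ones (renormalised likelihood).
#' @return An `occupancy_fit` object; see [tidy()] and [glance()] methods.
#' @export
fit_occupancy <- function(class_counts, n = 3, truncated = FALSE) {
  tab <- if (is.data.frame(class_counts)) {
    as_tibble(class_counts)
  } else {
    tibble(k = as.integer(names(class_counts)), count = as.numeric(class_counts))
  }
  if (!all(c("k", "count") %in% names(tab))) abort("counts need columns k and count")
  if (nrow(tab) == 0 || sum(tab$count) <= 0) abort("empty composition counts")
  if (any(tab$k < 0 | tab$k > n)) abort(paste0("k must lie in 0..", n))
  tab <- tab %>% group_by(.data$k) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>% arrange(.data$k)
  total <- sum(tab$count)
  single <- nrow(tab) == 1
  if (single) truncated <- TRUE
  loglik_fn <- function(p) {
    lp <- dbinom(tab$k, n, p, log = TRUE)
    if (truncated) lp <- lp - log(sum(dbinom(tab$k, n, p)))
    sum(tab$count * lp)
  }
  if (single) {
    p_hat <- tab$k[1] / n
  } else if (!truncated) {
    p_hat <- sum(tab$k * tab$count) / (n * total)
  } else {
    p_hat <- optimize(loglik_fn, interval = c(1e-9, 1 - 1e-9), maximum = TRUE,
                      tol = 1e-10)$maximum
  }
  ll <- loglik_fn(min(max(p_hat, 1e-12), 1 - 1e-12))
  # likelihood-ratio GOF vs the saturated multinomial over observed cells
  obs_p <- tab$count / total
  ll_sat <- sum(tab$count[tab$count > 0] * log(obs_p[tab$count > 0]))
  g2 <- 2 * (ll_sat - ll)
  df <- max(nrow(tab) - 1 - 1, 0)
  p_value <- if (df > 0) pchisq(g2, df, lower.tail = FALSE) else NA_real_
  structure(list(p_hat = p_hat, logLik = ll, g_squared = g2, df = df,
                 p_value = p_value, n = n, counts = tab, total = total,
                 truncated = truncated),
            class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat("<occupancy_fit> p =", sprintf("%.4f", x$p_hat),
      if (x$truncated) "(truncated likelihood)" else "", "\n")
  cat("  G2 =", sprintf("%.3f", x$g_squared), "df =", x$df,
      "p =", ifelse(is.na(x$p_value), "NA", sprintf("%.3g", x$p_value)), "\n")
  invisible(x)
}

#' @rdname fit_occupancy
#' @param x An `occupancy_fit`.
#' @param ... Unused.
#' @export
tidy.occupancy_fit <- function(x, ...) {
  tibble(term = "p", estimate = x$p_hat,
         truncated = x$truncated)
}

#' @rdname fit_occupancy
#' @export
glance.occupancy_fit <- function(x, ...) {
  tibble(p_hat = x$p_hat, logLik = x$logLik, g_squared = x$g_squared,
         df = x$df, p_value = x$p_value, n_particles = x$total,
         truncated = x$truncated)
}
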