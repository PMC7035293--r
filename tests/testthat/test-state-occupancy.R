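test_that("occupancy limits behave: no ligand, stoichiometric excess, S = 0", {
  expect_equal(fraction_bound(tibble::tibble(site_uM = 10, ligand_uM = 0,
                                             kd_uM = 1))$p_bound, 0)
  # Kd -> 0 with excess ligand saturates the sites
  expect_equal(fraction_bound(tibble::tibble(site_uM = 10, ligand_uM = 20,
                                             kd_uM = 1e-12))$p_bound,
               1, tolerance = 1e-9)
  # S = 0 uses the no-depletion limit and is flagged
  res0 <- fraction_bound(tibble::tibble(site_uM = 0, ligand_uM = 5, kd_uM = 5))
  expect_true(res0$no_depletion)
  expect_equal(res0$p_bound, 0.5)
})

test_that("the depletion solution matches numerical root-finding of the mass balance", {
  s <- 16.8; l <- 50; kd <- 0.12
  p <- fraction_bound(tibble::tibble(site_uM = s, ligand_uM = l, kd_uM = kd))$p_bound
  # independent oracle: uniroot on B^2 - (S+L+Kd) B + S L = 0 in [0, min(S, L)]
  f <- function(b) b^2 - (s + l + kd) * b + s * l
  b_star <- stats::uniroot(f, c(0, min(s, l)), tol = 1e-12)$root
  expect_equal(p, b_star / s, tolerance = 1e-6)
  expect_gt(p, 0.99)  # this condition saturates the sites
})

test_that("a racemic inhibitor halves the competent ligand pool", {
  full <- fraction_bound(tibble::tibble(site_uM = 13.5, ligand_uM = 120,
                                        kd_uM = 10, active_fraction = 1))$p_bound
  half <- fraction_bound(tibble::tibble(site_uM = 13.5, ligand_uM = 120,
                                        kd_uM = 10, active_fraction = 0.5))$p_bound
  only <- fraction_bound(tibble::tibble(site_uM = 13.5, ligand_uM = 60,
                                        kd_uM = 10, active_fraction = 1))$p_bound
  expect_lt(half, full)
  expect_equal(half, only, tolerance = 1e-12)
})

test_that("occupancy is monotone in ligand and Kd, and depletion only lowers it", {
  l_grid <- c(0.1, 1, 10, 100, 1000)
  p_l <- fraction_bound(tibble::tibble(site_uM = 5, ligand_uM = l_grid, kd_uM = 3))$p_bound
  expect_true(all(diff(p_l) > 0))
  kd_grid <- c(0.01, 0.1, 1, 10)
  p_kd <- fraction_bound(tibble::tibble(site_uM = 5, ligand_uM = 10, kd_uM = kd_grid))$p_bound
  expect_true(all(diff(p_kd) < 0))
  # depletion <= no-depletion, equal in the S -> 0 limit
  p_dep <- fraction_bound(tibble::tibble(site_uM = 8, ligand_uM = 10, kd_uM = 5))$p_bound
  p_no <- 10 / (10 + 5)
  expect_lte(p_dep, p_no)
  p_tiny <- fraction_bound(tibble::tibble(site_uM = 1e-7, ligand_uM = 10, kd_uM = 5))$p_bound
  expect_equal(p_tiny, p_no, tolerance = 1e-6)
})

test_that("sodium occupancy at 300 mM brackets two-of-three bound protomers", {
  # Kd 100-140 mM, concentrations in mM; protein sites (uM-scale) are
  # negligible so depletion is immaterial
  p <- fraction_bound(tibble::tibble(site_uM = 0.027, ligand_uM = 3e5,
                                     kd_uM = c(1e5, 1.2e5, 1.4e5)))$p_bound
  expect_true(all(p >= 0.68 & p <= 0.75))
})

test_that("binomial trimer distribution matches brute-force enumeration", {
  for (p in c(0, 0.25, 0.5, 0.7, 1)) {
    dist <- trimer_state_distribution(p)
    # oracle: enumerate all 2^3 protomer outcomes
    outcomes <- expand.grid(rep(list(0:1), 3))
    probs <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
    expected <- vapply(0:3, function(k) sum(probs[rowSums(outcomes) == k]),
                       numeric(1))
    expect_equal(dist$probability, expected, tolerance = 1e-12)
    expect_equal(sum(dist$probability), 1, tolerance = 1e-12)
    expect_equal(sum(dist$k * dist$probability), 3 * p, tolerance = 1e-12)
  }
  expect_equal(trimer_state_distribution(0.5)$probability, c(1, 3, 3, 1) / 8,
               tolerance = 1e-15)
  expect_equal(trimer_state_distribution(0.7)$probability[3], 0.441,
               tolerance = 1e-12)
})

test_that("the multinomial generalisation covers all compositions and sums to 1", {
  p <- c(inward_na = 0.5, outward_holo = 0.4, apo = 0.1)
  dist <- trimer_state_distribution(p)
  expect_equal(nrow(dist), choose(3 + 3 - 1, 3 - 1))  # 10 compositions
  expect_equal(sum(dist$probability), 1, tolerance = 1e-12)
  # the all-in-one-state cells are p_i^3
  pure <- dist[rowSums(dist[, names(p)] == 3) == 1, ]
  expect_equal(sort(unname(pure$probability)), sort(unname(p^3)),
               tolerance = 1e-12)
  expect_error(trimer_state_distribution(c(0.5, 0.4)), "sum to 1")
})

test_that("observed class fractions reproduce printed-style integer percentages", {
  counts <- c(a = 72313, b = 59666, c = 17736)
  fr <- observed_state_fractions(counts)
  expect_equal(fr$percent, c(48L, 40L, 12L))
  expect_equal(sum(fr$fraction), 1)
  expect_equal(observed_state_fractions(c(x = 5))$percent, 100L)
  expect_equal(observed_state_fractions(c(a = 1, b = 1))$percent, c(50L, 50L))
  expect_error(observed_state_fractions(c(a = 0, b = 0)), "zero")
})

test_that("the binomial MLE has its closed form on exact proportions", {
  counts <- data.frame(k = 0:3, count = 1e6 * dbinom(0:3, 3, 0.6))
  fit <- fit_occupancy(counts)
  expect_equal(fit$p_hat, 0.6, tolerance = 1e-12)
  expect_equal(fit$g_squared, 0, tolerance = 1e-6)
  expect_false(fit$truncated)
})

test_that("the MLE recovers p from sampled counts and matches a grid-search oracle", {
  set.seed(2024)
  draws <- stats::rbinom(10000, 3, 0.6)
  counts <- data.frame(k = as.integer(names(table(draws))),
                       count = as.vector(table(draws)))
  fit <- fit_occupancy(counts)
  expect_equal(fit$p_hat, 0.6, tolerance = 0.02)
  # independent oracle: grid search over the binomial log-likelihood
  grid <- seq(0.01, 0.99, by = 1e-4)
  ll <- vapply(grid, function(p) sum(counts$count * dbinom(counts$k, 3, p, log = TRUE)),
               numeric(1))
  expect_equal(fit$p_hat, grid[which.max(ll)], tolerance = 1e-4)
})

test_that("estimator bias shrinks as 1/sqrt(N) over seeds", {
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    draws <- stats::rbinom(4000, 3, 0.35)
    tab <- table(factor(draws, levels = 0:3))
    fit_occupancy(data.frame(k = 0:3, count = as.vector(tab)))$p_hat - 0.35
  }, numeric(1))
  expect_lt(abs(mean(errs)), 2 / sqrt(20 * 4000))
})

test_that("a single observed composition yields k/n with a truncation flag", {
  fit <- fit_occupancy(data.frame(k = 2, count = 500))
  expect_equal(fit$p_hat, 2 / 3)
  expect_true(fit$truncated)
})

test_that("truncated fits renormalise over the observable compositions", {
  # only k = 2 and k = 3 classes were reconstructable
  p_true <- 0.8
  c2 <- dbinom(2, 3, p_true) * 1e6
  c3 <- dbinom(3, 3, p_true) * 1e6
  fit <- fit_occupancy(data.frame(k = 2:3, count = c(c2, c3)), truncated = TRUE)
  expect_equal(fit$p_hat, p_true, tolerance = 1e-6)
  expect_true(fit$truncated)
  expect_error(fit_occupancy(data.frame(k = integer(0), count = numeric(0))), "empty")
})
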