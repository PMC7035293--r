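test_that("superposition of identical and purely translated sets is exact", {
  set.seed(11)
  pts <- matrix(rnorm(60, sd = 8), 20, 3)
  fit <- kabsch_superpose(pts, pts)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)

  shifted <- sweep(pts, 2, c(-5, 2, -7))  # reference = mobile + (5, -2, 7)
  fit2 <- kabsch_superpose(pts, shifted)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit2$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit2$translation, c(5, -2, 7), tolerance = 1e-9)
})

test_that("a forward-constructed rotation with noise is recovered (oracle check)", {
  set.seed(23)
  pts <- matrix(rnorm(150, sd = 10), 50, 3)
  axis <- unitize_t(rnorm(3))
  rot_true <- rotation_about(axis, 37 * pi / 180)
  trans_true <- c(3, -6, 2)
  noise <- matrix(rnorm(150, sd = 0.2), 50, 3)
  target <- pts %*% t(rot_true) + matrix(trans_true, 50, 3, byrow = TRUE) + noise
  fit <- kabsch_superpose(pts, target)
  # rotation recovered within 0.5 degrees
  rel <- fit$rotation %*% t(rot_true)
  ang_err <- acos(min(1, max(-1, (sum(diag(rel)) - 1) / 2))) * 180 / pi
  expect_lt(ang_err, 0.5)
  # rmsd close to the injected noise RMS (sqrt(3) * 0.2 ~ 0.346)
  expect_equal(fit$rmsd, sqrt(3) * 0.2, tolerance = 0.15)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("superposition agrees with an independent least-squares fit (bio3d)", {
  set.seed(31)
  pts <- matrix(rnorm(90, sd = 6), 30, 3)
  target <- pts %*% t(rotation_about(c(0, 0, 1), 1.1)) +
    matrix(c(4, 4, -2), 30, 3, byrow = TRUE) + matrix(rnorm(90, sd = 0.5), 30, 3)
  ours <- kabsch_superpose(pts, target)$rmsd
  theirs <- bio3d::rmsd(as.vector(t(target)), as.vector(t(pts)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("degenerate and mismatched inputs error clearly", {
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))  # collinear
  expect_error(kabsch_superpose(line + 0, line), "collinear")
  expect_error(kabsch_superpose(matrix(rnorm(12), 4), matrix(rnorm(15), 5)), "4.*5")
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)), "at least 3")
})

test_that("rmsd_between is symmetric, zero on self, and rigid-motion invariant", {
  tr <- default_trimer(noise_sigma = 0.4, seed = 5)
  m <- tr$model
  dom <- syn_cfg$domains$transport
  expect_equal(as.numeric(rmsd_between(m, "A", m, "A", dom)), 0, tolerance = 1e-10)
  ab <- rmsd_between(m, "A", m, "B", dom)
  ba <- rmsd_between(m, "B", m, "A", dom)
  expect_equal(as.numeric(ab), as.numeric(ba), tolerance = 1e-9)
  expect_equal(attr(ab, "n_pairs"), 40L)
  posed <- apply_transform(m, random_pose(3))
  expect_equal(as.numeric(rmsd_between(posed, "A", m, "B", dom)),
               as.numeric(ab), tolerance = 1e-8)
})

test_that("rmsd under per-atom Gaussian noise matches direct computation", {
  tr0 <- default_trimer()
  sigma <- 0.6
  trn <- default_trimer(noise_sigma = sigma, seed = 42)
  dom <- domain_definition("all", list(c(1, 400)), atoms = "CA")
  val <- as.numeric(rmsd_between(tr0$model, "A", trn$model, "A", dom, atoms = "CA"))
  # direct numerical oracle on the same paired points
  a <- select_domain(tr0$model, "A", dom)
  b <- select_domain(trn$model, "A", dom)
  fit <- kabsch_superpose(as.matrix(a[, c("x", "y", "z")]),
                          as.matrix(b[, c("x", "y", "z")]))
  expect_equal(val, fit$rmsd, tolerance = 1e-12)
  # and of the right magnitude for isotropic noise (~ sigma * sqrt(3))
  expect_equal(val, sigma * sqrt(3), tolerance = 0.25)
})

test_that("the pseudo-threefold axis of an exact C3 trimer is exact", {
  tr <- build_trimer(trimer_spec(elevator_offsets = c(0, 0, 0),
                                 gate_tip_distances = c(5, 5, 5)))
  fr <- pseudo_threefold_axis(tr$model, scaffold = syn_cfg$domains$scaffold,
                              out_marker = syn_cfg$out_marker)
  expect_lt(angle_between_deg(fr$axis, c(0, 0, 1)), 1e-6 * 180 / pi)
  expect_equal(fr$pair_angles_deg, rep(120, 3), tolerance = 1e-6)
  expect_equal(fr$origin, c(0, 0, 0), tolerance = 1e-8)
  expect_equal(fr$out_sign, 1)
  expect_equal(sum(fr$axis * fr$zero_direction), 0, tolerance = 1e-9)
})

test_that("axis estimation is equivariant under a rigid pose", {
  pose <- random_pose(17)
  tr0 <- default_trimer()
  trp <- default_trimer(pose = pose)
  fr <- pseudo_threefold_axis(trp$model, scaffold = syn_cfg$domains$scaffold)
  expected_axis <- as.vector(pose$rotation %*% c(0, 0, 1))
  expect_lt(angle_between_deg(fr$axis, expected_axis), 1e-5)
})

test_that("axis recovery stays within 2 degrees at 0.5 A coordinate noise", {
  tr <- default_trimer(noise_sigma = 0.5, seed = 99)
  fr <- pseudo_threefold_axis(tr$model, scaffold = syn_cfg$domains$scaffold)
  expect_lt(angle_between_deg(fr$axis, c(0, 0, 1)), 2)
})

test_that("strongly non-symmetric trimers are flagged", {
  tr <- default_trimer()
  m <- tr$model
  # rotate chain C's scaffold grossly about z to break the pseudo-symmetry
  idx <- m$chain == "C"
  rot <- rotation_about(c(0, 0, 1), 35 * pi / 180)
  m[idx, c("x", "y", "z")] <- as.matrix(m[idx, c("x", "y", "z")]) %*% t(rot)
  expect_warning(pseudo_threefold_axis(m, scaffold = syn_cfg$domains$scaffold),
                 "100-140")
})

test_that("non-trimeric input is an error", {
  tr <- default_trimer()
  expect_error(pseudo_threefold_axis(tr$model, protomer_chains = c("A", "B"),
                                     scaffold = syn_cfg$domains$scaffold),
               "3 protomer")
})

test_that("orient_to_axis is a pure rigid motion recovering the construction frame", {
  pose <- random_pose(29)
  trp <- default_trimer(pose = pose)
  tr0 <- default_trimer()
  fr <- pseudo_threefold_axis(trp$model, scaffold = syn_cfg$domains$scaffold,
                              out_marker = syn_cfg$out_marker)
  oriented <- orient_to_axis(trp$model, fr)
  # rigidity: pairwise distances preserved
  pick <- seq(1, nrow(trp$model), by = 37)
  d0 <- dist(as.matrix(trp$model[pick, c("x", "y", "z")]))
  d1 <- dist(as.matrix(oriented[pick, c("x", "y", "z")]))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  # canonical recovery up to the in-plane zero-direction convention:
  # axis along +z and the same cylindrical geometry as the unposed build
  fr1 <- pseudo_threefold_axis(oriented, scaffold = syn_cfg$domains$scaffold,
                               out_marker = syn_cfg$out_marker)
  expect_lt(angle_between_deg(fr1$axis, c(0, 0, 1)), 1e-5)
  expect_equal(fr1$origin, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(sort(oriented$z), sort(tr0$model$z), tolerance = 1e-6)
  r0 <- sqrt(tr0$model$x^2 + tr0$model$y^2)
  r1 <- sqrt(oriented$x^2 + oriented$y^2)
  expect_equal(sort(r1), sort(r0), tolerance = 1e-6)
})

test_that("orienting an already-canonical model is the identity", {
  tr <- default_trimer()
  fr <- pseudo_threefold_axis(tr$model, scaffold = syn_cfg$domains$scaffold,
                              out_marker = syn_cfg$out_marker)
  oriented <- orient_to_axis(tr$model, fr)
  # zero_direction points at chain A's scaffold centroid, which the builder
  # places on +x, so the model must come back unchanged
  dev <- max(abs(as.matrix(oriented[, c("x", "y", "z")]) -
                   as.matrix(tr$model[, c("x", "y", "z")])))
  expect_lt(dev, 1e-9)
})
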