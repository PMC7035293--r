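test_that("a planar circular belt profiles flat at its construction radius", {
  wb <- build_belt(belt_spec(radius = 55, n_atoms = 360))
  prof <- belt_height_profile(wb$model, bin_width_deg = 2)
  used <- prof[prof$n_atoms > 0, ]
  expect_equal(nrow(prof), 180L)
  expect_true(all(abs(used$mean_height_A) < 1e-9))
  expect_true(all(abs(used$mean_radius_A - 55) < 1e-9))
  expect_equal(sum(prof$n_atoms), 360L)
})

test_that("a sinusoidal belt reproduces the construction function at bin centres", {
  A <- 4
  wb <- build_belt(belt_spec(radius = 52.5, n_atoms = 720,
                             height = list(type = "sinusoid", amplitude = A,
                                           frequency = 3)))
  prof <- belt_height_profile(wb$model, bin_width_deg = 2)
  # oracle: evaluate the construction function at the bin centres
  expected <- A * sin(3 * prof$bin_center_deg * pi / 180)
  expect_true(all(abs(prof$mean_height_A - expected) < 0.05))
})

test_that("profiles are equivariant under rotation about the axis", {
  wb <- build_belt(belt_spec(radius = 50, n_atoms = 720,
                             height = list(type = "sinusoid", amplitude = 3,
                                           frequency = 3)))
  # a 0.2 degree pre-rotation keeps every atom off the bin boundaries, so the
  # 30 degree rotation is an exact 15-bin circular shift
  pre <- apply_transform(wb$model,
                         list(rotation = rotation_about(c(0, 0, 1), 0.2 * pi / 180),
                              translation = c(0, 0, 0)))
  prof0 <- belt_height_profile(pre, bin_width_deg = 2)
  shift_bins <- 15L # 30 degrees in 2-degree bins
  rot <- rotation_about(c(0, 0, 1), 30 * pi / 180)
  rotated <- apply_transform(pre, list(rotation = rot, translation = c(0, 0, 0)))
  prof1 <- belt_height_profile(rotated, bin_width_deg = 2)
  expect_equal(prof1$mean_height_A,
               prof0$mean_height_A[((seq_len(180) - 1 - shift_bins) %% 180) + 1],
               tolerance = 1e-9)
  # buckling statistics are invariant under that rotation
  expect_equal(buckling_stats(prof1)$peak_to_peak_A,
               buckling_stats(prof0)$peak_to_peak_A, tolerance = 1e-9)
})

test_that("weighted bin means conserve the global atom mean", {
  wb <- build_belt(belt_spec(radius = 48, n_atoms = 500,
                             height = list(type = "sinusoid", amplitude = 5,
                                           frequency = 2, phase_deg = 40)))
  prof <- belt_height_profile(wb$model, bin_width_deg = 5)
  used <- prof[prof$n_atoms > 0, ]
  expect_equal(sum(used$mean_height_A * used$n_atoms) / sum(used$n_atoms),
               mean(wb$model$z), tolerance = 1e-12)
})

test_that("refining the bin width barely changes a smooth profile", {
  wb <- build_belt(belt_spec(radius = 52.5, n_atoms = 1440,
                             height = list(type = "sinusoid", amplitude = 4,
                                           frequency = 3)))
  p2 <- belt_height_profile(wb$model, bin_width_deg = 2)
  p1 <- belt_height_profile(wb$model, bin_width_deg = 1)
  # both binnings track the smooth construction at their own bin centres,
  # so refining the bin width changes nothing beyond the curvature scale
  f <- function(deg) 4 * sin(3 * deg * pi / 180)
  expect_lt(max(abs(p2$mean_height_A - f(p2$bin_center_deg))), 0.05)
  expect_lt(max(abs(p1$mean_height_A - f(p1$bin_center_deg))), 0.05)
})

test_that("buckling statistics match closed forms", {
  flat <- build_belt(belt_spec(radius = 52.5, n_atoms = 360))
  bs_flat <- buckling_stats(belt_height_profile(flat$model, bin_width_deg = 2))
  expect_equal(bs_flat$peak_to_peak_A, 0, tolerance = 1e-9)
  expect_equal(bs_flat$rms_deviation_A, 0, tolerance = 1e-9)

  A <- 4
  sine <- build_belt(belt_spec(radius = 52.5, n_atoms = 720,
                               height = list(type = "sinusoid", amplitude = A,
                                             frequency = 3)))
  bs <- buckling_stats(belt_height_profile(sine$model, bin_width_deg = 2))
  expect_equal(bs$peak_to_peak_A, 2 * A, tolerance = 0.1)
  expect_equal(bs$rms_deviation_A, A / sqrt(2), tolerance = 0.05)
  expect_gte(bs$peak_to_peak_A, bs$rms_deviation_A)
})

test_that("a sector bump is localised to its sector", {
  wb <- build_belt(belt_spec(radius = 52.5, n_atoms = 720,
                             height = list(type = "sector_bump", center_deg = 60,
                                           amplitude = 6, width_deg = 80)))
  prof <- belt_height_profile(wb$model, bin_width_deg = 2)
  sectors <- tibble::tibble(sector = c("bump", "quiet"),
                            start_deg = c(0, 180), end_deg = c(120, 300))
  bs <- buckling_stats(prof, sectors)
  rng <- setNames(bs$per_sector$range_A, bs$per_sector$sector)
  expect_equal(unname(rng["bump"]), 6, tolerance = 0.05)
  expect_lt(rng["quiet"], 1e-9)
})

test_that("belt diameter is twice the mean CA radius, in nm", {
  wb <- build_belt(belt_spec(radius = 52.5, n_atoms = 400))
  d <- belt_diameter(wb$model)
  expect_equal(d$diameter_nm, 10.5, tolerance = 1e-9)
  expect_false(d$degenerate)
  # degenerate single-atom belt is flagged but still measured
  one <- structure_model(tibble::tibble(chain = "M", resno = 1, atom = "CA",
                                        x = 50, y = 0, z = 0),
                         chain_roles = c(M = "belt"))
  expect_warning(d1 <- belt_diameter(one), "degenerate")
  expect_equal(d1$diameter_nm, 10.0)
  expect_true(d1$degenerate)
})

test_that("empty belts and minimal belts behave as specified", {
  tr <- default_trimer()
  expect_error(belt_height_profile(tr$model), "belt")
  tiny <- build_belt(belt_spec(radius = 40, n_atoms = 3))
  prof <- belt_height_profile(tiny$model, bin_width_deg = 2)
  expect_equal(sum(prof$n_atoms > 0), 3L)
})

test_that("sector annotation finds the protomer under each bearing", {
  tr <- default_trimer()
  wb <- build_belt(belt_spec(radius = 52.5, n_atoms = 360), attach_to = tr$model)
  ann <- annotate_sectors(wb$model, syn_cfg)
  at0 <- ann[ann$start_deg == 0, ]
  expect_equal(at0$chain, "A")
  # rotating the trimer 120 degrees about the axis permutes the labels cyclically
  rot <- rotation_about(c(0, 0, 1), 2 * pi / 3)
  rotated <- apply_transform(wb$model, list(rotation = rot, translation = c(0, 0, 0)))
  ann_rot <- annotate_sectors(rotated, syn_cfg)
  expect_equal(ann_rot$chain[ann_rot$start_deg == 120], "A")
  # with no protomer atoms every sector is "none"
  belt_only <- build_belt(belt_spec(radius = 52.5, n_atoms = 60))
  ann_none <- annotate_sectors(belt_only$model, syn_cfg)
  expect_true(all(ann_none$label == "none"))
})

test_that("per-protomer sectors aggregate the annotation into intervals", {
  tr <- default_trimer()
  ann <- annotate_sectors(tr$model, syn_cfg)
  secs <- protomer_sectors(ann)
  expect_setequal(unique(secs$sector), c("A", "B", "C"))
  expect_true(all(secs$end_deg > secs$start_deg))
})
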