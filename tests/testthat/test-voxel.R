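test_that("grid sampling covers the domain with the right mask", {
  # box domain: every voxel is in-domain
  fg <- field_on_grid("diamond", domain_box(1, 1, 1), pitch = 100)
  expect_true(all(fg$mask))
  expect_equal(dim(fg$values), c(10L, 10L, 10L))

  # centred odd grid has a voxel exactly at the origin, where the gyroid is 0
  fg <- field_on_grid("gyroid", domain_box(1, 1, 1), pitch = 1000 / 11,
                      cell = 2 * pi)
  expect_equal(dim(fg$values)[1], 11L)
  expect_equal(fg$values[6, 6, 6], 0)

  # cylinder: per-slice mask fraction approximates pi/4 of the bounding box
  fg <- field_on_grid("gyroid", domain_cylinder(8, 3), pitch = 40)
  frac <- apply(fg$mask, 3, mean)
  expect_equal(length(unique(frac)), 1L)   # same ROI in every slice
  expect_lt(abs(frac[1] - pi / 4), 0.01)
})

test_that("oversized grids are rejected with a pitch suggestion", {
  expect_error(field_on_grid("gyroid", domain_cylinder(8, 3), pitch = 40,
                             max_voxels = 1e5),
               "coarsen the pitch")
  expect_error(field_on_grid("gyroid", domain_cylinder(8, 3), pitch = 2000),
               "pitch")  # pitch must resolve the domain
})

test_that("solidify respects the level-set conventions at the extremes", {
  fg <- field_on_grid("iwp", domain_cylinder(4, 2), pitch = 100)
  lo <- min(fg$values) - 1
  hi <- max(fg$values) + 1
  m_full <- solidify(fg, threshold = lo)
  expect_identical(m_full$occupancy, fg$mask)
  expect_equal(void_fraction(m_full), 0)
  m_empty <- solidify(fg, threshold = hi)
  expect_false(any(m_empty$occupancy))
  expect_equal(void_fraction(m_empty), 1)
  expect_error(solidify(fg, threshold = -1, mode = "sheet"), "nonnegative")
})

test_that("void_fraction matches hand-built occupancies", {
  fg <- field_on_grid("gyroid", domain_box(1, 1, 1), pitch = 100)
  model <- solidify(fg, threshold = min(fg$values) - 1)  # fully solid
  # checkerboard occupancy on a box domain has void fraction exactly 1/2
  idx <- which(array(TRUE, dim(model$occupancy)))
  coords <- arrayInd(idx, dim(model$occupancy))
  model$occupancy[] <- (rowSums(coords) %% 2L) == 0L
  expect_equal(void_fraction(model), 0.5)
})

test_that("balanced surfaces at t = 0 and the Monte-Carlo volume oracle agree", {
  # odd symmetry pins gyroid and diamond to exactly half solid at t = 0
  box <- domain_box(2.5, 2.5, 2.5)
  for (g in c("gyroid", "diamond")) {
    fg <- field_on_grid(g, box, pitch = 2500 / 64)
    phi <- void_fraction(solidify(fg, threshold = 0))
    expect_lt(abs(phi - 0.5), 0.005)
  }
  # all three: voxel count vs 1e6-point Monte-Carlo integration, 9 combos
  for (g in tpms_geometries()) {
    fg <- field_on_grid(g, box, pitch = 2500 / 64)
    for (t in c(-0.5, 0, 0.5)) {
      phi_vox <- void_fraction(solidify(fg, threshold = t))
      phi_mc <- 1 - mc_solid_fraction(g, threshold = t, n = 1e6, seed = 0)
      expect_lt(abs(phi_vox - phi_mc), 0.01)
    }
  }
})

test_that("skeletal porosity is nondecreasing in the threshold", {
  fg <- field_on_grid("diamond", domain_box(2.5, 2.5, 2.5), pitch = 100)
  ts <- seq(min(fg$values), max(fg$values), length.out = 20)
  phis <- vapply(ts, function(t) void_fraction(solidify(fg, t)), numeric(1))
  expect_true(all(diff(phis) >= 0))
})

test_that("threshold calibration hits targets across geometries and modes", {
  box <- domain_box(2.5, 2.5, 2.5)
  for (g in tpms_geometries()) {
    fg <- field_on_grid(g, box, pitch = 50)
    for (target in c(0.1, 0.2, 0.5, 0.8)) {
      cal <- calibrate_threshold(field = fg, target = target, tol = 1e-3)
      expect_lt(abs(cal$realized - target), 1e-3 + 1e-12)
      # realized value is reproducible from the returned threshold
      expect_equal(void_fraction(solidify(fg, cal$threshold)), cal$realized)
    }
  }
  # antisymmetry: gyroid at target 0.5 calibrates to t near 0
  fg <- field_on_grid("gyroid", box, pitch = 2500 / 64)
  cal <- calibrate_threshold(field = fg, target = 0.5)
  expect_lt(abs(cal$threshold), 0.02)
  # sheet mode converges too (solid shell around the surface)
  cal_sheet <- calibrate_threshold(field = fg, target = 0.5, mode = "sheet")
  expect_lt(abs(cal_sheet$realized - 0.5), 1e-3 + 1e-12)
  expect_gte(cal_sheet$threshold, 0)
})

test_that("invalid calibration targets are rejected", {
  expect_error(calibrate_threshold("gyroid", domain_box(1, 1, 1),
                                   target = 1.5, pitch = 100),
               "\\(0, 1\\)")
  expect_error(calibrate_threshold("gyroid", domain_box(1, 1, 1),
                                   target = 0, pitch = 100))
})

test_that("calibrated porosity is stable under grid refinement", {
  box <- domain_box(2.5, 2.5, 2.5)
  for (g in tpms_geometries()) {
    fg_h <- field_on_grid(g, box, pitch = 2500 / 32)
    cal <- calibrate_threshold(field = fg_h, target = 0.2)
    fg_h2 <- field_on_grid(g, box, pitch = 2500 / 64)
    phi_h2 <- void_fraction(solidify(fg_h2, cal$threshold))
    expect_lt(abs(cal$realized - phi_h2), 0.005)
  }
})

test_that("the calibration trace records a shrinking bracket", {
  cal <- calibrate_threshold("gyroid", domain_box(2.5, 2.5, 2.5),
                             target = 0.2, pitch = 100)
  tr <- cal$trace
  expect_true(all(diff(tr$t_hi - tr$t_lo) < 0))
  expect_equal(nrow(tr), cal$iterations)
})
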