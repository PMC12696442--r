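test_that("slice porosity is the pore share of the measured region", {
  all_solid <- matrix(1L, 50, 50)
  expect_equal(slice_porosity(all_solid), 0)
  # 100x100 ROI with 2000 pore pixels -> 0.20 exactly
  sl <- matrix(1L, 120, 120)
  sl[1:20, 1:100] <- 0L
  expect_equal(slice_porosity(sl, roi_rect(c(1, 100), c(1, 100))), 0.2)
  # exterior background is excluded from both numerator and denominator
  sl2 <- matrix(NA_integer_, 50, 50)
  sl2[11:40, 11:40] <- 1L
  sl2[11:25, 11:40] <- 0L
  expect_equal(slice_porosity(sl2), 0.5)
  expect_error(slice_porosity(matrix(NA_integer_, 10, 10)), "ROI")
})

test_that("ROI masks are validated", {
  expect_error(roi_mask(roi_rect(c(1, 60), c(1, 10)), c(50, 50)), "bounds")
  expect_equal(sum(roi_mask(roi_rect(c(1, 10), c(1, 10)), c(50, 50))), 100)
  m <- roi_mask(roi_circle(), c(101, 101))
  expect_lt(abs(sum(m) / 101^2 - pi / 4), 0.01)
})

test_that("label_pores measures single pores to within a pixel", {
  sl <- matrix(1L, 100, 100)
  rc <- expand.grid(r = 1:100, c = 1:100)
  hit <- (rc$r - 50)^2 + (rc$c - 50)^2 <= 25^2
  sl[as.matrix(rc[hit, ])] <- 0L
  rec <- label_pores(sl, pixel_size = 1)
  expect_equal(nrow(rec), 1L)
  expect_lt(abs(rec$ecd_um - 50), 1)         # ECD 50 px within 1 px
  expect_equal(rec$centroid_row, 50)
  expect_equal(rec$centroid_col, 50)
  expect_false(rec$touches_boundary)
})

test_that("ECD follows the closed form for known areas", {
  # two square pores of 100 and 400 px^2 at 10 um/px
  sl <- matrix(1L, 60, 60)
  sl[5:14, 5:14] <- 0L     # 100 px
  sl[30:49, 30:49] <- 0L   # 400 px
  rec <- dplyr::arrange(label_pores(sl, pixel_size = 10), area_px)
  expect_equal(rec$area_px, c(100L, 400L))
  expect_equal(rec$ecd_um, c(112.8379, 225.6758), tolerance = 1e-6)
  # identity ecd = 2 sqrt(area/pi) holds for every record
  expect_lt(max(abs(rec$ecd_um - 2 * sqrt(rec$area_um2 / pi))), 1e-9)
})

test_that("the minimum-size filter discards noise specks", {
  sl <- matrix(1L, 20, 20)
  sl[5, 5:7] <- 0L   # 3 px speck
  expect_equal(nrow(label_pores(sl, min_size_px = 4)), 0L)
  expect_equal(nrow(label_pores(sl, min_size_px = 3)), 1L)
})

test_that("raising min_size never adds pores nor shrinks the mean ECD", {
  sl <- random_binary(64, p = 0.45, seed = 11)
  sl[sl == 1L] <- 1L
  prev_n <- Inf; prev_ecd <- -Inf
  for (ms in c(1, 2, 4, 8, 16)) {
    rec <- label_pores(1L - sl, min_size_px = ms, pixel_size = 1)
    expect_lte(nrow(rec), prev_n)
    if (nrow(rec) > 0) {
      expect_gte(mean(rec$ecd_um), prev_ecd)
      prev_ecd <- mean(rec$ecd_um)
    }
    prev_n <- nrow(rec)
  }
})

test_that("4- and 8-connectivity differ only by merging", {
  # a diagonal chain is one pore under 8-connectivity, many under 4
  sl <- matrix(1L, 10, 10)
  for (i in 1:8) sl[i, i] <- 0L
  expect_equal(nrow(label_pores(sl, connectivity = 8, min_size_px = 1)), 1L)
  expect_equal(nrow(label_pores(sl, connectivity = 4, min_size_px = 1)), 8L)
  for (seed in 1:20) {
    img <- random_binary(32, p = 0.5, seed = seed)
    n8 <- nrow(label_pores(1L - img, connectivity = 8, min_size_px = 1))
    n4 <- nrow(label_pores(1L - img, connectivity = 4, min_size_px = 1))
    expect_lte(n8, n4)
  }
})

test_that("component labeling matches an independent flood-fill oracle", {
  for (seed in 1:100) {
    img <- random_binary(32, p = 0.4, seed = seed)
    pore <- 1L - img   # label the pore phase of the complement
    sl <- img
    for (conn in c(4, 8)) {
      rec <- label_pores(sl, connectivity = conn, min_size_px = 1,
                         pixel_size = 1)
      oracle <- flood_fill_label(pore, connectivity = conn)
      expect_equal(sort(rec$area_px),
                   sort(as.integer(tabulate(oracle, max(oracle)))))
    }
  }
  # EBImage's labeler (4-connectivity) agrees as a second, external check
  img <- random_binary(48, p = 0.45, seed = 123)
  rec <- label_pores(img, connectivity = 4, min_size_px = 1, pixel_size = 1)
  ebl <- EBImage::bwlabel(1 - img)
  expect_equal(sort(rec$area_px), sort(as.integer(tabulate(ebl, max(ebl)))))
})

test_that("stack aggregation reproduces phantom ground truth", {
  ph <- make_phantom("circular_channels", image_px = c(400, 400),
                     pixel_size = 10, diameter_um = 500, n_channels = 5,
                     n_slices = 3)
  ps <- pore_stats(ph, min_size_px = 4)
  expect_equal(ps$summary$n_pores, 15L)   # 5 channels x 3 slices
  expect_lt(abs(ps$summary$mean_ecd_um - 500), 10)       # within 1 px
  expect_lt(ps$summary$sd_ecd_um, 5)      # near-identical pores (pixelation)
  expect_equal(ps$summary$mean_porosity, ph$truth$porosity)
  expect_equal(ps$summary$sd_porosity, 0)
  # aggregates are recomputable from the records
  expect_equal(ps$summary$mean_ecd_um, mean(ps$pores$ecd_um))
  expect_equal(ps$summary$mean_porosity, mean(ps$slices$porosity))
})

test_that("an empty pore phase yields n_pores 0, not an error", {
  solid <- slice_stack(array(1L, c(32, 32, 2)), pixel_size = 10)
  ps <- pore_stats(solid)
  expect_equal(ps$summary$n_pores, 0L)
  expect_true(is.na(ps$summary$mean_ecd_um))
  expect_equal(ps$summary$mean_porosity, 0)
})

test_that("boundary-touching pores are flagged and excludable", {
  sl <- matrix(1L, 40, 40)
  sl[1:10, 18:22] <- 0L    # touches the image edge
  sl[25:30, 18:22] <- 0L   # interior
  st <- slice_stack(array(sl, c(40, 40, 1)), pixel_size = 1)
  rec <- label_pores(sl, pixel_size = 1)
  expect_equal(sort(rec$touches_boundary), c(FALSE, TRUE))
  ps_in <- pore_stats(st, include_boundary = TRUE)
  ps_ex <- pore_stats(st, include_boundary = FALSE)
  expect_equal(ps_in$summary$n_pores, 2L)
  expect_equal(ps_ex$summary$n_pores, 1L)
  expect_equal(ps_ex$summary$mean_ecd_um, 2 * sqrt(30 / pi))
})

test_that("tidy and glance expose the tabular views", {
  ph <- make_phantom("single_pore", image_px = c(100, 100), pixel_size = 10,
                     diameter_um = 300, n_slices = 2)
  ps <- pore_stats(ph)
  expect_s3_class(tidy(ps), "tbl_df")
  expect_equal(nrow(tidy(ps)), 2L)
  expect_equal(nrow(tidy(ps, "slices")), 2L)
  g <- glance(ps)
  expect_equal(nrow(g), 1L)
  expect_named(g, c("n_slices", "mean_porosity", "sd_porosity", "n_pores",
                    "mean_ecd_um", "sd_ecd_um"))
})

test_that("geometry comparison ranks by mean ECD with explicit ties", {
  ph_small <- make_phantom("single_pore", image_px = c(100, 100),
                           pixel_size = 10, diameter_um = 200, n_slices = 2)
  ph_big <- make_phantom("single_pore", image_px = c(100, 100),
                         pixel_size = 10, diameter_um = 400, n_slices = 2)
  s_small <- pore_stats(ph_small)
  s_big <- pore_stats(ph_big)
  cmp <- compare_geometries(list(a = s_small, b = s_big))
  expect_equal(cmp$geometry, c("b", "a"))        # larger ECD ranked first
  expect_equal(cmp$ecd_rank, c(1L, 2L))
  expect_false(any(cmp$tied))
  cmp_tie <- compare_geometries(list(a = s_small, b = s_small))
  expect_true(all(cmp_tie$tied))
  expect_equal(cmp_tie$ecd_rank, c(1L, 1L))
  # mismatched pixel sizes are not comparable
  ph_other <- make_phantom("single_pore", image_px = c(100, 100),
                           pixel_size = 20, diameter_um = 400, n_slices = 2)
  expect_error(compare_geometries(list(a = s_small,
                                       b = pore_stats(ph_other))),
               "pixel sizes")
  expect_error(compare_geometries(list(s_small, s_big)), "named")
})

test_that("morphometry CSVs are written and re-readable", {
  ph <- make_phantom("single_pore", image_px = c(80, 80), pixel_size = 10,
                     diameter_um = 300)
  ps <- pore_stats(ph)
  dir <- withr::local_tempdir()
  write_morphometry_csv(ps, dir)
  expect_setequal(list.files(dir), c("pores.csv", "slices.csv", "summary.csv"))
  back <- utils::read.csv(file.path(dir, "summary.csv"))
  expect_equal(back$mean_ecd_um, ps$summary$mean_ecd_um)
})
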