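test_that("the noiseless limit reproduces the ON-lattice positions exactly", {
  d <- default_design()
  g <- phrase_grids("DNA")[[1]]
  pp <- readout_params(p_user = 1, q = 1, fp_rate = 0, loc_sigma_nm = 0)
  f <- simulate_structure(d, g, user_key("DDC-1"), pp, seed = 1)
  expect_identical(f$truth$category, "ON")
  # expected spots: every 1-bit site plus both markers, at ON geometry
  sites <- oracle_sites(d, "ON")
  on_bits <- sites[!sites$marker, ]
  want <- rbind(
    on_bits[mapply(function(r, c) {
      if (r < 0) g$address[-r, c + 1] else g$bits[r + 1, c + 1]
    }, on_bits$row, on_bits$col) == 1, c("x", "y")],
    sites[sites$marker, c("x", "y")])
  got <- f$spots[order(f$spots$x_nm, f$spots$y_nm), ]
  want <- want[order(want$x, want$y), ]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
})

test_that("trigger-free transformation follows the spontaneous rate", {
  d <- default_design()
  g <- phrase_grids("DNA")[[1]]
  pp <- readout_params()
  ens <- simulate_ensemble(d, g, NULL, pp, 10000, seed = 2, keep_fields = FALSE)
  expect_true(within_3se(ens$tally$ON / 10000, pp$p_spont, 10000))
  # untransformed structures stay locked or stall intermediate
  expect_true(within_3se(ens$tally$OFF / 10000,
                         (1 - pp$p_spont) * (1 - pp$p_ic), 10000))
})

test_that("matched-key CorrInfo frequency follows the analytic yield p * q^n", {
  d <- default_design()
  g <- phrase_grids("DNA")[[1]]
  n <- count_biotin_sites(g)
  pp <- readout_params()
  ens <- simulate_ensemble(d, g, user_key("DDC-1"), pp, 10000, seed = 3,
                           keep_fields = FALSE)
  expect_true(within_3se(ens$tally$CorrInfo / 10000,
                         yield_theo(pp$p_user, pp$q, n)$y_theo, 10000))
  # mismatched keys fall to the spontaneous baseline
  mis <- simulate_ensemble(d, g, user_key("DDC-2"), pp, 5000, seed = 4,
                           keep_fields = FALSE)
  expect_lte(mis$tally$CorrInfo / 5000, pp$p_spont)
})

test_that("identical seeds give bit-for-bit identical spot fields", {
  d <- default_design()
  g <- phrase_grids("TECH")[[1]]
  pp <- readout_params()
  a <- simulate_ensemble(d, g, admin_key(), pp, 50, seed = 99)
  b <- simulate_ensemble(d, g, admin_key(), pp, 50, seed = 99)
  expect_identical(a$fields, b$fields)
  expect_identical(a$child_seeds, b$child_seeds)
})

test_that("OFF-truth structures keep the OFF marker separation", {
  d <- default_design()
  g <- phrase_grids("DNA")[[1]]
  pp <- readout_params(p_spont = 0, p_ic = 0, q = 1, loc_sigma_nm = 0)
  f <- simulate_structure(d, g, NULL, pp, seed = 8)
  expect_identical(f$truth$category, "OFF")
  mk <- f$spots[f$spots$x_nm < -6, ]   # marker column sits left of the array
  expect_equal(max(dist(mk)), marker_distance(d, "OFF"))
  expect_lt(max(dist(mk)), marker_distance(d, "ON"))
})

test_that("spot counts never exceed the lattice plus the marker pair", {
  d <- default_design()
  pp <- readout_params(fp_rate = 0.3)
  set.seed(17)
  for (i in 1:50) {
    f <- simulate_structure(d, random_grid(), admin_key(), pp)
    expect_lte(nrow(f$spots), n_label_sites(d) + 2)
  }
})

test_that("grid/design shape mismatches and bad parameters are rejected", {
  d <- default_design()
  g4 <- encoding_scheme("a5", grid_cols = 4)
  expect_error(simulate_structure(d, ddcaccess:::empty_grid(g4)),
               class = "ddc_design_error")
  expect_error(readout_params(q = 1.2), class = "ddc_parameter_error")
  expect_error(readout_params(loc_sigma_nm = -1), class = "ddc_parameter_error")
  # sequence-mode key against a sequence-free design cannot be simulated
  k <- user_key("DDC-1", competing_strands = "ACGT", invading_strands = "ACGT",
                mode = "sequence")
  expect_error(simulate_structure(d, phrase_grids("DNA")[[1]], k),
               class = "ddc_mode_error")
})

test_that("rasters sum Gaussians linearly and peak where the spots are", {
  one <- structure(list(spots = data.frame(x_nm = 0, y_nm = 0), truth = NULL),
                   class = "spot_field")
  img <- render_raster(one, pixel_nm = 1, psf_sigma_nm = 2)
  peak <- which(img == max(img), arr.ind = TRUE)
  expect_equal(attr(img, "x_nm")[peak[2]], 0)
  expect_equal(attr(img, "y_nm")[peak[1]], 0)
  # integrated intensity proportional to the number of spots
  three <- structure(list(spots = data.frame(x_nm = c(0, 20, 40), y_nm = c(0, 0, 0)),
                          truth = NULL), class = "spot_field")
  bbox <- c(-20, 60, -20, 20)
  i1 <- sum(render_raster(one, 1, 2, bbox = bbox))
  i3 <- sum(render_raster(three, 1, 2, bbox = bbox))
  expect_equal(i3 / i1, 3, tolerance = 1e-6)
  # empty field: blank canvas, not an error
  blank <- structure(list(spots = data.frame(x_nm = numeric(0), y_nm = numeric(0)),
                          truth = NULL), class = "spot_field")
  expect_true(all(render_raster(blank) == 0))
})

test_that("peak detection on a noiseless raster recovers the spots within a pixel", {
  d <- default_design()
  g <- phrase_grids("DNA")[[1]]
  pp <- readout_params(p_user = 1, q = 1, fp_rate = 0, loc_sigma_nm = 0)
  f <- simulate_structure(d, g, user_key("DDC-1"), pp, seed = 5)
  img <- render_raster(f, pixel_nm = 1, psf_sigma_nm = 1.5)
  found <- detect_spots(img, threshold = 0.2)
  expect_identical(nrow(found$spots), nrow(f$spots))
  for (i in seq_len(nrow(f$spots))) {
    dmin <- min(sqrt((found$spots$x_nm - f$spots$x_nm[i])^2 +
                     (found$spots$y_nm - f$spots$y_nm[i])^2))
    expect_lte(dmin, sqrt(2))   # within one pixel
  }
})
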