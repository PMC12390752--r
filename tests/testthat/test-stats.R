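test_that("observed yield is the exact count ratio with a Wilson interval", {
  expect_equal(yield_exp(85, 85)$y_exp, 1)
  expect_equal(yield_exp(0, 85)$y_exp, 0)
  # an OFF-retention sample of 85 structures reporting 86%: the unique
  # integer count rounding to 86% is M = 73
  M <- which(vapply(0:85, function(m) round(100 * m / 85), numeric(1)) == 86) - 1L
  expect_identical(M, 73L)
  ye <- yield_exp(73, 85)
  expect_equal(ye$y_exp, 73 / 85)
  expect_equal(round(100 * ye$y_exp), 86)
  # Wilson bounds against the base-R implementation, and sane ordering
  pt <- prop.test(73, 85, correct = FALSE)$conf.int
  expect_equal(c(ye$ci_low, ye$ci_high), as.numeric(pt))
  expect_true(ye$ci_low < ye$y_exp && ye$y_exp < ye$ci_high)
  expect_error(yield_exp(1, 0), class = "ddc_count_error")
  expect_error(yield_exp(9, 5), class = "ddc_count_error")
})

test_that("biotin-site counts cover data and address arrays", {
  sch <- default_scheme()
  expect_identical(count_biotin_sites(ddcaccess:::empty_grid(sch)), 0L)
  expect_identical(count_biotin_sites(ddcaccess:::empty_grid(sch),
                                      include_markers = TRUE), 2L)
  # the address row counts: word 1 adds one biotin site
  g <- assign_address(ddcaccess:::empty_grid(sch), 1, sch)
  expect_identical(count_biotin_sites(g), 1L)
  # sparse words carry fewer biotin sites: DNA < TECH < NANO (payload bits)
  payload <- vapply(c("DNA", "TECH", "NANO"), function(w) {
    count_biotin_sites(suppressWarnings(encode_text(w, sch))[[1]])
  }, integer(1))
  expect_true(payload[["DNA"]] < payload[["TECH"]])
  expect_true(payload[["TECH"]] < payload[["NANO"]])
  # elementwise-sum oracle on random grids
  set.seed(66)
  for (i in 1:200) {
    g <- assign_address(random_grid(sch), sample(0:31, 1), sch)
    oracle <- sum(as.integer(g$bits)) + sum(as.integer(g$address))
    expect_identical(count_biotin_sites(g), as.integer(oracle))
  }
})

test_that("theoretical yield is p * q^n with its degenerate limits", {
  expect_equal(yield_theo(0.5, 0.9, 0)$y_theo, 0.5)     # empty product
  expect_equal(yield_theo(0.76, 1, 12)$y_theo, 0.76)    # perfect binding
  expect_equal(yield_theo(0.89, 0.95, 7)$y_theo, 0.6215, tolerance = 1e-4)
  expect_error(yield_theo(1.2, 0.9, 3), class = "ddc_parameter_error")
  expect_error(yield_theo(0.9, 0.9, -1), class = "ddc_parameter_error")
  expect_error(yield_theo(0.9, 0.9, 2.5), class = "ddc_parameter_error")
  # strictly decreasing in n for q < 1, p > 0
  ys <- vapply(0:20, function(n) yield_theo(0.89, 0.95, n)$y_theo, numeric(1))
  expect_true(all(diff(ys) < 0))
  expect_true(all(ys <= 0.89))
})

test_that("condition tables account for every structure exactly once", {
  d <- default_design()
  g <- phrase_grids("DNA")[[1]]
  row <- run_condition(d, g, user_key("DDC-1"), readout_params(),
                       n_structures = 400, seed = 12)
  expect_identical(row$OFF + row$ON + row$IC + row$UC, 400L)
  expect_equal(row$frac_OFF + row$frac_ON + row$frac_IC + row$frac_UC, 1)
  expect_equal(row$y_theo, yield_theo(0.89, 0.95, count_biotin_sites(g))$y_theo)
  # Eq. 1 equals a brute-force recount of the tallied categories
  expect_equal(row$frac_CorrInfo, row$CorrInfo / row$n)
  # one-structure guard: integer counts, no NaN
  one <- run_condition(d, g, NULL, readout_params(), n_structures = 1, seed = 13)
  expect_identical(one$OFF + one$ON + one$IC + one$UC, 1L)
})

test_that("no-key conditions stay locked at the spontaneous rate", {
  d <- default_design()
  g <- phrase_grids("DNA")[[1]]
  pp <- readout_params()
  row <- run_condition(d, g, NULL, pp, n_structures = 2000, seed = 14)
  # ON calls follow p_spont; locked fraction is the untransformed mass that
  # does not stall intermediate
  expect_true(within_3se(row$frac_ON, pp$p_spont, 2000))
  expect_true(within_3se(row$frac_OFF + row$frac_UC,
                         (1 - pp$p_spont) * (1 - pp$p_ic), 2000))
})

test_that("the permission matrix reproduces the admin/user hierarchy", {
  d1 <- read_carrier_design(system.file("extdata", "DDC-1.json", package = "ddcaccess"))
  d2 <- read_carrier_design(system.file("extdata", "DDC-2.json", package = "ddcaccess"))
  grids <- list(phrase_grids("PEACE")[[1]], phrase_grids("LOVE")[[1]])
  grids[[1]]$carrier_ref <- "DDC-1"; grids[[2]]$carrier_ref <- "DDC-2"
  keys <- list(admin = admin_key(),
               user1 = user_key("DDC-1"), user2 = user_key("DDC-2"))
  pp <- readout_params()
  m <- hierarchy_matrix(list(d1, d2), grids, keys, pp,
                        n_structures = 800, seed = 15)
  expect_identical(dim(m), c(3L, 2L))
  # admin row exceeds every mismatched user cell
  expect_true(all(m["admin", ] > c(m["user1", "DDC-2"], m["user2", "DDC-1"])))
  # matched user access exceeds admin (p_user > p_admin)
  expect_gt(m["user1", "DDC-1"], m["admin", "DDC-1"])
  # determinism under a fixed seed
  m2 <- hierarchy_matrix(list(d1, d2), grids, keys, pp,
                         n_structures = 800, seed = 15)
  expect_identical(m, m2)
})

test_that("shipped experiment configs run end to end", {
  cfg <- system.file("extdata", "fig2.json", package = "ddcaccess")
  tab <- suppressWarnings(run_experiment(modifyList(
    jsonlite::read_json(cfg, simplifyVector = FALSE), list(n_structures = 60))))
  expect_identical(nrow(tab), 3L)            # none / admin / user
  expect_true(all(tab$OFF + tab$ON + tab$IC + tab$UC == 60L))
  cfg4 <- system.file("extdata", "fig4.json", package = "ddcaccess")
  m <- suppressWarnings(run_experiment(modifyList(
    jsonlite::read_json(cfg4, simplifyVector = FALSE), list(n_structures = 60))))
  expect_identical(dim(m), c(3L, 2L))
})
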