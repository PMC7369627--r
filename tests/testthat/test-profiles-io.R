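test_that("read_profile normalises units, skips headers and averages duplicate depths", {
  # micrometre depths with a comment line
  f_um <- write_profile_file(c("# sensor export", "-500 310", "0 305",
                               "100 250", "200 120", "300 0"))
  p_um <- read_profile(f_um, "O2", depth_unit = "um")
  expect_equal(p_um$depths, c(-0.5, 0, 0.1, 0.2, 0.3))
  expect_equal(p_um$values, c(310, 305, 250, 120, 0))

  # same data in mm with a header line parses identically
  f_mm <- write_profile_file(c("depth value", "-0.5 310", "0 305",
                               "0.1 250", "0.2 120", "0.3 0"))
  p_mm <- read_profile(f_mm, "O2", depth_unit = "mm")
  expect_equal(p_mm$depths, p_um$depths)
  expect_equal(p_mm$values, p_um$values)

  # comma dialect
  f_csv <- write_profile_file(c("0,305", "0.1,250", "0.2,120"))
  expect_equal(read_profile(f_csv, "O2")$values, c(305, 250, 120))

  # duplicate depths collapse by mean, rows get sorted
  f_dup <- write_profile_file(c("0.2 100", "0 300", "0.2 200", "0.1 250"))
  p_dup <- read_profile(f_dup, "O2")
  expect_equal(p_dup$depths, c(0, 0.1, 0.2))
  expect_equal(p_dup$values, c(300, 250, 150))
})

test_that("read_profile hard-errors on degenerate input with line numbers", {
  f_empty <- write_profile_file(character())
  expect_error(read_profile(f_empty, "O2"), "empty")

  f_bad <- write_profile_file(c("0 300", "0.1 250", "oops not-a-number",
                                "0.3 120"))
  expect_error(read_profile(f_bad, "O2"), "line 3")

  f_short <- write_profile_file(c("0 300", "0.1 250"))
  expect_error(read_profile(f_short, "O2"), "3 usable points|at least 3")
})

test_that("solute_profile enforces its invariants", {
  expect_error(solute_profile("O2", c(0, 0.1), c(1, 2)), "3 points")
  expect_error(solute_profile("O2", c(0, 0.2, 0.1), c(1, 2, 3)),
               "strictly increasing")
  expect_error(solute_profile("O2", c(0, 0.1, 0.2), c(1, NA, 3)),
               "non-finite")
  expect_error(solute_profile("O2", c(0, 0.1, 0.2), c(1, -10, 3)),
               "below -5")
  expect_error(solute_profile("pH", c(0, 0.1, 0.2), c(7, 15, 7)),
               "pH values")
  # small sensor-noise negatives are tolerated
  expect_s3_class(solute_profile("H2S", c(0, 0.1, 0.2), c(0, -1, 3)),
                  "solute_profile")
})

test_that("align_to_grid interpolates linearly and clips to the overlap", {
  b <- solute_profile("pH", c(0, 0.25, 0.5), c(8, 7, 6))
  a <- solute_profile("H2S", c(0.125, 0.25, 0.375), c(1, 2, 3))
  paired <- align_to_grid(a, b)
  expect_equal(paired$b, c(7.5, 7, 6.5))  # midpoints of linear segments

  # identical grids: values returned unchanged
  a2 <- solute_profile("H2S", c(0, 0.25, 0.5), c(1, 2, 3))
  expect_equal(align_to_grid(a2, b)$b, b$values)

  # grid of a extends deeper than b: deep points dropped from the pairing
  a3 <- solute_profile("H2S", c(0, 0.25, 0.5, 1.0, 1.5), c(1, 2, 3, 4, 5))
  expect_equal(nrow(align_to_grid(a3, b)), 3)

  # disjoint ranges are a hard error
  a4 <- solute_profile("H2S", c(5, 6, 7), c(1, 2, 3))
  expect_error(align_to_grid(a4, b), "overlap")
})

test_that("align_to_grid is exact for profiles linear in depth", {
  b <- solute_profile("pH", seq(0, 2, 0.25), 8 - 0.6 * seq(0, 2, 0.25))
  a <- solute_profile("H2S", seq(0.05, 1.95, 0.1), rep(1, 20))
  paired <- align_to_grid(a, b)
  expect_equal(paired$b, 8 - 0.6 * paired$depth, tolerance = 1e-12)
})

test_that("profile and summary writers round-trip exactly", {
  set.seed(1)
  p <- solute_profile("O2", sort(c(-0.5, runif(20, 0, 4))),
                      runif(21, 0, 330), resolution = 100, core_id = "C7",
                      treatment = "high", timepoint_day = 6,
                      profile_replicate = 2)
  f <- tempfile()
  write_profile(p, f)
  q <- read_profile(f, "O2", core_id = "C7", treatment = "high",
                    timepoint_day = 6, profile_replicate = 2,
                    resolution = 100)
  expect_identical(q$depths, p$depths)
  expect_identical(q$values, p$values)

  df <- data.frame(core_id = c("C1", "C2"), j_o2 = c(-58.123456789012345, NA),
                   opd = c(pi, exp(1)), flag = c("", "low r2"))
  f2 <- tempfile(fileext = ".csv")
  write_summary(df, f2)
  back <- read_summary(f2)
  expect_identical(back$j_o2, df$j_o2)
  expect_identical(back$opd, df$opd)
  expect_equal(nrow(write_summary(df[0, ], f2) |> read_summary()), 0)
})

test_that("experiment_set validates context coverage and replicate resolution", {
  ctx <- make_ctx("C1")
  p1 <- solute_profile("O2", c(0, 0.1, 0.2), c(3, 2, 1), resolution = 100,
                       core_id = "C1", timepoint_day = 6,
                       profile_replicate = 1)
  expect_s3_class(experiment_set(list(p1), list(ctx)), "experiment_set")

  p_orphan <- solute_profile("O2", c(0, 0.1, 0.2), c(3, 2, 1),
                             core_id = "C9", timepoint_day = 6,
                             profile_replicate = 1)
  expect_error(experiment_set(list(p1, p_orphan), list(ctx)), "C9")

  p2 <- solute_profile("O2", c(0, 0.25, 0.5), c(3, 2, 1), resolution = 250,
                       core_id = "C1", timepoint_day = 6,
                       profile_replicate = 2)
  expect_error(experiment_set(list(p1, p2), list(ctx)), "resolution")
})
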