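make_skel <- function(pts, um_per_pixel = 6.5) {
  n <- nrow(pts)
  steps <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  structure(list(points = pts, step_lengths = steps,
                 total_length_px = sum(steps),
                 cumulative_um = c(0, cumsum(steps)) * um_per_pixel,
                 um_per_pixel = um_per_pixel),
            class = "midline_skeleton")
}

test_that("a solid rectangle yields a clean midline with unit tail ratios", {
  reg <- region_from_mask(rect_mask(10, 200))
  sk <- skeletonize_region(reg)
  expect_s3_class(sk, "midline_skeleton")
  # single endpoint-to-endpoint path
  expect_equal(nrow(sk$points), length(sk$step_lengths) + 1)
  expect_true(all(sk$step_lengths %in% c(1, sqrt(2))))
  f <- extract_features(reg)
  expect_s3_class(f, "worm_features")
  expect_gte(f$length_um, 1200); expect_lte(f$length_um, 1300)
  expect_gte(f$thickness_um, 65); expect_lte(f$thickness_um, 70)
  expect_lt(abs(f$r1 - 1), 0.12)
  expect_lt(abs(f$r2 - 1), 0.12)
  expect_lte(f$r1, f$r2)
})

test_that("branched, short and degenerate regions are typed rejections", {
  # crossing bars leave a four-armed skeleton
  px <- matrix(FALSE, 200, 200)
  px[96:103, 20:180] <- TRUE
  px[20:180, 96:103] <- TRUE
  cross <- region_from_mask(px)
  r <- skeletonize_region(cross)
  expect_true(is_rejection(r))
  expect_equal(r$reason, "branched")

  short <- extract_features(region_from_mask(rect_mask(6, 30)))
  expect_true(is_rejection(short))
  expect_equal(short$reason, "too_short")

  dot <- skeletonize_region(region_from_mask(rect_mask(3, 3)))
  expect_true(is_rejection(dot))
  expect_equal(dot$reason, "degenerate")

  expect_error(skeletonize_region(list(mask = rect_mask(3, 3))), "worm_region")
})

test_that("midline length follows the orthogonal/diagonal step rule", {
  horiz <- make_skel(cbind(5, 1:101))
  expect_equal(measure_length(horiz), 650)
  diag <- make_skel(cbind(1:101, 1:101))
  expect_equal(measure_length(diag), 100 * sqrt(2) * 6.5, tolerance = 1e-12)
  expect_equal(measure_length(horiz, um_per_pixel = 7), 700)
})

test_that("thickness is area over midline length, linear in calibration", {
  reg <- region_from_mask(rect_mask(10, 200))
  reg$area_px <- 2000L
  sk <- make_skel(cbind(5, 1:201))  # 200 px of arc
  expect_equal(measure_thickness(reg, sk, um_per_pixel = 6.5), 65)
  expect_equal(measure_thickness(reg, sk, um_per_pixel = 7), 70)
})

test_that("diameter probes read a bar's width and reject out-of-range arcs", {
  reg <- region_from_mask(rect_mask(11, 200))
  sk <- skeletonize_region(reg)
  for (s in c(300, 650, 900)) {
    d <- diameter_at(reg, sk, s, "A")
    expect_lt(abs(d - 11 * 6.5), 6.5)
  }
  expect_error(diameter_at(reg, sk, 1e5, "A"), "exceeds")

  rat <- tail_ratios(reg, sk)
  expect_lt(abs(rat$r1 - 1), 0.12)
  expect_lte(rat$r1, rat$r2)
})

test_that("length and thickness scale linearly with calibration", {
  g <- measure_generated_worm(default_worm_specs()$male, seed = 5)
  f1 <- extract_features(g$region, um_per_pixel = 6.5)
  g$region$um_per_pixel <- 13
  f2 <- extract_features(g$region, um_per_pixel = 13)
  expect_equal(f2$length_um / f1$length_um, 2, tolerance = 1e-10)
  expect_equal(f2$thickness_um / f1$thickness_um, 2, tolerance = 1e-10)
})

test_that("rotating a worm mask by 90 degrees barely changes its features", {
  g <- measure_generated_worm(default_worm_specs()$hermaphrodite, seed = 9)
  f <- extract_features(g$region)
  rot <- region_from_mask(t(g$region$mask))
  fr <- extract_features(rot)
  expect_lt(abs(fr$length_um - f$length_um) / f$length_um, 0.01)
  expect_lt(abs(fr$thickness_um - f$thickness_um) / f$thickness_um, 0.01)
  expect_lt(abs(fr$r1 - f$r1) / f$r1, 0.05)
  expect_lt(abs(fr$r2 - f$r2) / f$r2, 0.05)
})

test_that("generator worms are measured within the oracle tolerances", {
  specs <- default_worm_specs()
  for (cl in c("hermaphrodite", "male")) {
    len_err <- c(); ratio_ok <- c()
    for (s in 1:30) {
      g <- measure_generated_worm(specs[[cl]], seed = s)
      f <- extract_features(g$region)
      if (is_rejection(f)) next
      len_err <- c(len_err, (f$length_um - g$worm$truth$length_um) /
                     g$worm$truth$length_um)
      ratio_ok <- c(ratio_ok, f$r1 <= f$r2)
    }
    expect_gte(length(len_err), 28)
    expect_true(all(ratio_ok))
    expect_lt(abs(mean(len_err)), 0.05)
    expect_gte(mean(abs(len_err) < 0.05), 0.9)
  }
})

test_that("a constant-width generator worm matches its thickness truth", {
  # flat taper targets give a near-constant tube of width 2 x halfwidth
  spec <- worm_spec("hermaphrodite", c(900, 1000), c(26, 26),
                    end_a = c(52, 52), end_b = c(52, 52),
                    tip_diameter_um = 52)
  g <- measure_generated_worm(spec, seed = 21)
  f <- extract_features(g$region)
  expect_s3_class(f, "worm_features")
  expect_lt(abs(f$thickness_um - 52) / 52, 0.15)
})

test_that("feature tables carry rejection reasons alongside measurements", {
  g <- measure_generated_worm(default_worm_specs()$male, seed = 2)
  short <- region_from_mask(rect_mask(6, 30), region_id = 2L)
  tab <- features_table(list(g$region, short))
  expect_equal(tab$status, c("ok", "too_short"))
  expect_true(is.na(tab$length_um[2]))
  expect_equal(tab$region_id, c(1L, 2L))
  empty <- features_table(list())
  expect_equal(nrow(empty), 0)
})
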