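test_that("worm and plate generation are seed-deterministic", {
  spec <- default_worm_specs()$male
  w1 <- make_worm(spec, seed = 5)
  w2 <- make_worm(spec, seed = 5)
  expect_identical(w1$mask, w2$mask)
  expect_identical(w1$truth, w2$truth)
  expect_false(identical(w1$mask, make_worm(spec, seed = 6)$mask))

  p1 <- render_plate(2, 1, 1, layout = "spaced", seed = 9)
  p2 <- render_plate(2, 1, 1, layout = "spaced", seed = 9)
  expect_identical(p1$image$pixels, p2$image$pixels)
  expect_identical(p1$truth, p2$truth)
})

test_that("truth length equals the midline polyline length", {
  for (cl in names(default_worm_specs())) {
    w <- make_worm(default_worm_specs()[[cl]], seed = 13)
    poly <- sum(sqrt(rowSums(diff(w$truth$midline_um)^2)))
    expect_equal(poly, w$truth$length_um, tolerance = 1e-9)
  }
})

test_that("a zero-curvature spec renders a straight, accurately measured worm", {
  spec <- worm_spec("hermaphrodite", c(950, 950), c(33, 33),
                    end_a = c(22, 46), end_b = c(14, 42),
                    curvature_per_um = 0)
  w <- make_worm(spec, seed = 3, theta0 = 0)  # axis-aligned phantom
  g <- list(worm = w, region = region_from_mask(w$mask))
  # straight midline: end-to-end chord equals arc length
  ml <- g$worm$truth$midline_um
  chord <- sqrt(sum((ml[nrow(ml), ] - ml[1, ])^2))
  expect_equal(chord, g$worm$truth$length_um, tolerance = 1e-6)
  # axis-aligned digitization is exact up to the end-cap trim
  # (~ one cap radius + 1.5 px per end, about 30 um here)
  f <- extract_features(g$region)
  expect_lt(abs(f$length_um - 950) / 950, 0.05)
  expect_lt(abs(f$length_um - (950 - 30)) / 950, 0.02)
})

test_that("tail-taper targets are recovered by the metrology within a pixel", {
  # axis-aligned straight phantoms: the probe check at the quantization
  # floor, free of the orientation-dependent chain digitization
  spec <- worm_spec("hermaphrodite", c(1000, 1000), c(33, 33),
                    end_a = c(22, 46), end_b = c(14, 42),
                    curvature_per_um = 0)
  for (s in c(3, 8, 15)) {
    w <- make_worm(spec, seed = s, theta0 = 0)
    g <- list(worm = w, region = region_from_mask(w$mask))
    sk <- skeletonize_region(g$region)
    dm <- c(diameter_at(g$region, sk, 20, "A"), diameter_at(g$region, sk, 120, "A"),
            diameter_at(g$region, sk, 20, "B"), diameter_at(g$region, sk, 120, "B"))
    tr <- g$worm$truth
    t1 <- c(tr$d20_a, tr$d120_a, tr$d20_b, tr$d120_b)
    t2 <- t1[c(3, 4, 1, 2)]
    err <- min(max(abs(dm - t1)), max(abs(dm - t2)))
    expect_lt(err, 6.5)
  }
})

test_that("class feature distributions separate in the documented directions", {
  pool <- render_feature_pool(c(hermaphrodite = 20, male = 20, larva = 20),
                              seed_base = 3000)
  means <- aggregate(pool[, 2:5], list(class = pool$class), mean)
  rownames(means) <- means$class
  expect_lt(means["male", "length_um"], means["hermaphrodite", "length_um"])
  expect_lt(means["larva", "length_um"], means["male", "length_um"])
  expect_gt(means["male", "r2"], means["hermaphrodite", "r2"])
  expect_lt(means["larva", "thickness_um"], means["male", "thickness_um"])
})

test_that("male blunt tails dominate hermaphrodite tails in paired draws", {
  specs <- default_worm_specs()
  wins <- 0; n <- 0
  for (s in 1:30) {
    fh <- extract_features(measure_generated_worm(specs$hermaphrodite,
                                                  seed = 4000 + s)$region)
    fm <- extract_features(measure_generated_worm(specs$male,
                                                  seed = 4000 + s)$region)
    if (is_rejection(fh) || is_rejection(fm)) next
    n <- n + 1
    wins <- wins + (fm$r2 > fh$r2)
  }
  expect_gte(wins / n, 0.9)
})

test_that("an empty plate renders a bare background", {
  p <- render_plate(0, 0, 0, noise_sd = 0, illum_gradient = 0, seed = 2)
  expect_length(p$truth$animals, 0)
  expect_true(is.na(p$truth$male_percentage))
  expect_equal(length(unique(as.vector(p$image$pixels))), 1)
  expect_length(extract_regions(binarize(p$image)), 0)
})

test_that("eggs capping hermaphrodite tails induce male miscalls", {
  cfg <- run_config()
  males_egg <- 0; males_free <- 0
  for (s in 1:3) {
    pe <- render_plate(10, 0, 0, layout = "spaced", eggs = 10,
                       eggs_at_tails = TRUE, seed = s)
    pf <- render_plate(10, 0, 0, layout = "spaced", eggs = 0, seed = s)
    males_egg <- males_egg + analyze_plate(pe$image, cfg)$counts[["male"]]
    males_free <- males_free + analyze_plate(pf$image, cfg)$counts[["male"]]
  }
  expect_gt(males_egg, males_free)
})

test_that("truth JSON export drops masks but keeps per-animal records", {
  p <- render_plate(2, 1, 0, layout = "spaced", seed = 4)
  path <- tempfile(fileext = ".json")
  write_truth_json(p$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_length(back$animals, 3)
  expect_null(back$animals[[1]]$mask)
  expect_equal(back$animals[[1]]$class_label, "hermaphrodite")
  expect_equal(back$counts$male, 1)
})

test_that("synthetic well records are deterministic and well-formed", {
  w1 <- synth_well_records(40, seed = 6)
  expect_identical(w1, synth_well_records(40, seed = 6))
  expect_equal(nrow(w1), 40)
  expect_named(w1, c("well_id", "manual_male", "manual_herm",
                     "auto_male", "auto_herm"))
  expect_true(all(w1$manual_male >= 0 & w1$auto_male >= 0 & w1$auto_herm >= 0))
  totals <- w1$manual_male + w1$manual_herm
  expect_true(all(totals >= 2))
})
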